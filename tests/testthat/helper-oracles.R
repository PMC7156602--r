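# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: the loop classifier works by exhaustive enclosing-pair
# enumeration, the folding oracle by exhaustive recursion over all nested
# pairings.

# all balanced dot-bracket strings of length n (any balanced string is
# nested by construction)
enum_dotbrackets <- function(n) {
  res <- character(0L)
  rec <- function(prefix, open, remaining) {
    if (remaining == 0L) {
      if (open == 0L) res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    rec(paste0(prefix, "."), open, remaining - 1L)
    if (open < remaining)  # must be closable within the remaining length
      rec(paste0(prefix, "("), open + 1L, remaining - 1L)
    if (open > 0L) rec(paste0(prefix, ")"), open - 1L, remaining - 1L)
  }
  rec("", 0L, n)
  res
}

oracle_pair_table <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  st <- integer(0L)
  pt <- integer(length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      st <- c(st, i)
    } else if (ch[i] == ")") {
      j <- st[length(st)]
      st <- st[-length(st)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  pt
}

# classify every position by exhaustive loop enumeration: the loop a point
# belongs to is the innermost pair strictly enclosing it; the loop kind
# follows from the pairs whose innermost enclosing pair is the closing pair
oracle_decompose <- function(db) {
  pt <- oracle_pair_table(db)
  n <- length(pt)
  opens <- which(pt > seq_len(n))
  enclosing <- function(lo, hi) {
    best <- NA_integer_
    for (i in opens) {
      j <- pt[i]
      if (i < lo && j > hi &&
          (is.na(best) || (j - i) < (pt[best] - best))) best <- i
    }
    best
  }
  u_p <- list(S = integer(0L), H = integer(0L), I = integer(0L),
              B = integer(0L), M = integer(0L))
  u_n <- c(S = 0L, H = 0L, I = 0L, B = 0L, M = 0L)
  for (i in opens) {
    j <- pt[i]
    kids <- Filter(function(k) {
      e <- enclosing(k, pt[k])
      !is.na(e) && e == i
    }, opens)
    inner <- if (j - i > 1L) (i + 1L):(j - 1L) else integer(0L)
    loop_unp <- Filter(function(x) {
      if (pt[x] != 0L) return(FALSE)
      e <- enclosing(x, x)
      !is.na(e) && e == i
    }, inner)
    loop_unp <- as.integer(loop_unp)
    nb <- length(kids)
    if (nb == 0L) {
      u_n[["H"]] <- u_n[["H"]] + 1L
      u_p$H <- c(u_p$H, loop_unp)
    } else if (nb == 1L) {
      k <- kids[[1L]]
      l <- pt[k]
      left <- loop_unp[loop_unp < k]
      right <- loop_unp[loop_unp > l]
      if (length(left) && length(right)) {
        u_n[["I"]] <- u_n[["I"]] + 1L
        u_p$I <- c(u_p$I, left, right)
      } else if (length(left) || length(right)) {
        u_n[["B"]] <- u_n[["B"]] + 1L
        u_p$B <- c(u_p$B, left, right)
      } # flush both sides: stacked pair, no loop
    } else {
      u_n[["M"]] <- u_n[["M"]] + 1L
      u_p$M <- c(u_p$M, loop_unp)
    }
  }
  u_n[["S"]] <- sum(vapply(opens, function(i) {
    !(i > 1L && pt[i - 1L] == pt[i] + 1L)
  }, logical(1L)))
  u_p$S <- c(opens, pt[opens])
  list(u_n = u_n, u_p = lapply(u_p, function(v) sort(as.integer(v))))
}

# maximum number of nested pairs by exhaustive recursion (no memoization,
# explores every pairing of the first position)
oracle_max_pairs <- function(seq, min_hairpin = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  f <- function(i, j) {
    if (j - i <= min_hairpin) return(0L)
    best <- f(i + 1L, j)
    for (k in (i + min_hairpin + 1L):j) {
      if (paste0(ch[i], ch[k]) %in% ok) {
        best <- max(best, 1L + f(i + 1L, k - 1L) + f(k + 1L, j))
      }
    }
    best
  }
  if (!length(ch)) return(0L)
  f(1L, length(ch))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# a structure containing at least one element of every kind: two helices
# (one with a bulge, one with an interior loop) nested in a multibranch loop
all_kinds_structure <- function() {
  db <- paste0("((", "((..((...))))", ".", "((..((...))..))", "))")
  parse_dotbracket(db, strrep("A", nchar(db)), id = "all_kinds")
}

expect_same_decomposition <- function(db) {
  d <- decompose(parse_dotbracket(db, strrep("A", nchar(db))))
  o <- oracle_decompose(db)
  expect_identical(unname(d$u_n), unname(o$u_n), label = db)
  for (k in names(o$u_p)) {
    expect_identical(as.integer(d$u_p[[k]]), o$u_p[[k]],
                     label = paste(db, "kind", k))
  }
}
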