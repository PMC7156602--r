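#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, strips whitespace, converts T to U and validates that only
#' A, C, G, U remain. DNA-convention input (dbSNP flanks, FASTA transcripts)
#' is thereby comparable with RNA transcripts.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over \{A,C,G,U\}.
#' @export
#' @examples
#' normalize_rna("acgt")  # "ACGU"
normalize_rna <- function(x) {
  x <- chartr("T", "U", toupper(gsub("[[:space:]]", "", x)))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,U,T}: ",
         substr(gsub("[ACGU]", "", x[bad][1L]), 1L, 10L), call. = FALSE)
  }
  x
}

complement_base <- function(b) chartr("ACGU", "UGCA", b)

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Construct a secondary structure from a pair table
#'
#' Validates that the pair table is an involution without self-pairs and that
#' the pairing is nested (pseudoknot-free); pseudoknotted input is rejected.
#'
#' @param id structure identifier.
#' @param seq RNA sequence string (normalized).
#' @param pairs integer vector, 1-based pairing partner per position
#'   (0 = unpaired).
#' @return an object of class `rna_structure` with fields `id`, `seq`,
#'   `db` (dot-bracket) and `pairs`.
#' @export
rna_structure <- function(id, seq, pairs) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  pairs <- as.integer(pairs)
  if (length(pairs) != n)
    stop("pair table length does not match sequence length", call. = FALSE)
  paired <- which(pairs > 0L)
  if (any(pairs[paired] == paired))
    stop("a base cannot pair with itself", call. = FALSE)
  if (any(pairs < 0L) || any(pairs > n))
    stop("pair table index out of range", call. = FALSE)
  if (!all(pairs[pairs[paired]] == paired))
    stop("pair table is not an involution", call. = FALSE)
  # nesting check: a closing index must match the most recent open pair
  open <- integer(0L)
  for (i in seq_len(n)) {
    p <- pairs[i]
    if (p > i) {
      open <- c(open, p)
    } else if (p > 0L && p < i) {
      if (!length(open) || open[length(open)] != i)
        stop("pairing is pseudoknotted (crossing pairs); only nested ",
             "structures are supported", call. = FALSE)
      open <- open[-length(open)]
    }
  }
  db <- rep(".", n)
  db[pairs > seq_len(n)] <- "("
  db[pairs > 0L & pairs < seq_len(n)] <- ")"
  structure(
    list(id = as.character(id), seq = seq,
         db = paste(db, collapse = ""), pairs = pairs),
    class = "rna_structure"
  )
}

#' Parse a dot-bracket string into a secondary structure
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @param seq RNA sequence of the same length (T accepted, normalized to U).
#' @param id structure identifier.
#' @return an `rna_structure`.
#' @export
#' @examples
#' s <- parse_dotbracket("(((...)))", "GGGAAACCC")
#' s$pairs  # 9 8 7 0 0 0 3 2 1
parse_dotbracket <- function(db, seq, id = "rna") {
  seq <- normalize_rna(seq)
  if (nchar(db) != nchar(seq))
    stop("dot-bracket and sequence lengths differ (", nchar(db), " vs ",
         nchar(seq), ")", call. = FALSE)
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket string may contain only '(', ')' and '.'",
         call. = FALSE)
  n <- length(ch)
  pairs <- integer(n)
  stack <- integer(0L)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop("unbalanced dot-bracket: unmatched ')' at position ", i,
             call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket: unmatched '(' at position ",
         stack[length(stack)], call. = FALSE)
  rna_structure(id, seq, pairs)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure '", x$id, "' (", nchar(x$seq), " nt, ",
      sum(x$pairs > 0L) / 2L, " pairs)\n", sep = "")
  cat(x$seq, "\n", x$db, "\n", sep = "")
  invisible(x)
}

#' Decompose a secondary structure into its five element kinds
#'
#' Standard RNA loop decomposition. Each closing pair (i, j) is classified by
#' the base pairs directly enclosed in it: no enclosed pair gives a hairpin
#' (H); one enclosed pair flush on both sides is a stacked pair (absorbed
#' into a stem); one enclosed pair with unpaired bases on exactly one side
#' gives a bulge (B); on both sides, an interior loop (I); two or more
#' enclosed pairs give a multibranch loop (M). Stems (S) are maximal runs of
#' consecutively stacked pairs and carry the paired bases of both strands.
#' Unpaired bases exterior to every pair belong to no element.
#'
#' @param x an `rna_structure` (or a dot-bracket string, in which case `seq`
#'   must be supplied to [parse_dotbracket()] first).
#' @return an `rna_decomposition`: list with `elements` (each a list with
#'   `kind`, `positions`, `closing_pairs`), `u_p` (per-kind position sets)
#'   and `u_n` (per-kind element counts), plus `n` and `id`.
#' @export
#' @examples
#' d <- decompose(parse_dotbracket("(((...)))", "GGGAAACCC"))
#' d$u_n            # S 1, H 1, I 0, B 0, M 0
#' d$u_p$H          # 4 5 6
decompose <- function(x) {
  stopifnot(inherits(x, "rna_structure"))
  pt <- x$pairs
  n <- length(pt)
  elements <- list()

  opens <- which(pt > seq_len(n))
  # stems: (i, j) and (i+1, j-1) both pairs => same stem
  if (length(opens)) {
    starts_new <- vapply(opens, function(i) {
      !(i > 1L && pt[i - 1L] == pt[i] + 1L)
    }, logical(1L))
    stem_id <- cumsum(starts_new)
    for (s in seq_len(max(stem_id))) {
      os <- opens[stem_id == s]
      elements[[length(elements) + 1L]] <- list(
        kind = "S",
        positions = sort(c(os, pt[os])),
        closing_pairs = cbind(i = os, j = pt[os])
      )
    }
  }

  for (i in opens) {
    j <- pt[i]
    children <- matrix(integer(0L), ncol = 2L)
    unpaired <- integer(0L)
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        children <- rbind(children, c(k, pt[k]))
        k <- pt[k] + 1L
      } else {
        unpaired <- c(unpaired, k)
        k <- k + 1L
      }
    }
    nb <- nrow(children)
    if (nb == 0L) {
      elements[[length(elements) + 1L]] <- list(
        kind = "H", positions = unpaired,
        closing_pairs = cbind(i = i, j = j))
    } else if (nb == 1L) {
      k1 <- children[1L, 1L]; l1 <- children[1L, 2L]
      left <- unpaired[unpaired < k1]
      right <- unpaired[unpaired > l1]
      if (length(left) && length(right)) {
        elements[[length(elements) + 1L]] <- list(
          kind = "I", positions = c(left, right),
          closing_pairs = cbind(i = c(i, k1), j = c(j, l1)))
      } else if (length(left) || length(right)) {
        elements[[length(elements) + 1L]] <- list(
          kind = "B", positions = c(left, right),
          closing_pairs = cbind(i = c(i, k1), j = c(j, l1)))
      }
      # flush on both sides: stacked pair, already inside a stem
    } else {
      elements[[length(elements) + 1L]] <- list(
        kind = "M", positions = unpaired,
        closing_pairs = cbind(i = c(i, children[, 1L]),
                              j = c(j, children[, 2L])))
    }
  }

  kinds <- vapply(elements, `[[`, character(1L), "kind")
  u_p <- lapply(ELEMENT_KINDS, function(k) {
    sort(unlist(lapply(elements[kinds == k], `[[`, "positions"),
                use.names = FALSE))
  })
  names(u_p) <- ELEMENT_KINDS
  u_n <- vapply(ELEMENT_KINDS, function(k) sum(kinds == k), integer(1L))

  structure(
    list(elements = elements, u_p = u_p, u_n = u_n, n = n, id = x$id),
    class = "rna_decomposition"
  )
}

#' @export
print.rna_decomposition <- function(x, ...) {
  cat("Loop decomposition of '", x$id, "' (", x$n, " nt)\n", sep = "")
  cat("  element counts:",
      paste(names(x$u_n), x$u_n, sep = ":", collapse = "  "), "\n")
  invisible(x)
}
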