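#' Validate a variant table
#'
#' A variant table is a data frame with columns `rsid`, `transcript_id`,
#' `position` (1-based, transcript-relative), `ref` and `alt` (single RNA
#' bases, ref != alt). Coordinates are transcript-relative; placing genomic
#' SNPs onto transcripts is the job of [map_flanks()].
#'
#' @param df data frame to validate.
#' @return the validated data frame (bases normalized to RNA letters).
#' @export
as_variants <- function(df) {
  need <- c("rsid", "transcript_id", "position", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("variant table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  df$position <- as.integer(df$position)
  if (nrow(df)) {
    df$ref <- normalize_rna(df$ref)
    df$alt <- normalize_rna(df$alt)
    if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L))
      stop("ref and alt must be single bases (SNVs only)", call. = FALSE)
    if (any(df$ref == df$alt))
      stop("ref and alt must differ (offending rsid: ",
           df$rsid[df$ref == df$alt][1L], ")", call. = FALSE)
    if (any(is.na(df$position) | df$position < 1L))
      stop("variant positions must be positive integers", call. = FALSE)
  }
  df
}

#' Apply SNVs to a sequence
#'
#' Substitutes each variant's alt allele at its position after checking that
#' the sequence carries the ref allele there. Length is unchanged.
#'
#' @param seq RNA sequence string.
#' @param variants variant data frame (see [as_variants()]).
#' @return the mutant sequence string.
#' @export
#' @examples
#' v <- data.frame(rsid = "rs1", transcript_id = "tx", position = 5,
#'                 ref = "A", alt = "G")
#' apply_variants("GGGAAACCC", v)  # "GGGAGACCC"
apply_variants <- function(seq, variants) {
  seq <- normalize_rna(seq)
  variants <- as_variants(variants)
  if (!nrow(variants)) return(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (r in seq_len(nrow(variants))) {
    p <- variants$position[r]
    if (p > n)
      stop("variant ", variants$rsid[r], " position ", p,
           " is beyond the sequence end (", n, " nt)", call. = FALSE)
    if (chars[p] != variants$ref[r])
      stop("reference allele mismatch for ", variants$rsid[r],
           " at position ", p, ": sequence has ", chars[p],
           ", variant expects ", variants$ref[r], call. = FALSE)
    chars[p] <- variants$alt[r]
  }
  paste(chars, collapse = "")
}

#' Enumerate all 3N single-point mutants of a sequence
#'
#' Every sequence at Hamming distance exactly 1 from `seq`, in deterministic
#' order: position-major, alternative alleles alphabetical. This is the
#' exhaustive background set used by the RS2 significance scheme.
#'
#' @param seq RNA sequence string of length N.
#' @return character vector of length 3N.
#' @export
#' @examples
#' enumerate_point_mutants("AC")  # CC GC UC AA AG AU
enumerate_point_mutants <- function(seq) {
  seq <- normalize_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "U")
  out <- character(3L * length(chars))
  k <- 0L
  for (p in seq_along(chars)) {
    for (alt in setdiff(bases, chars[p])) {
      k <- k + 1L
      tmp <- chars
      tmp[p] <- alt
      out[k] <- paste(tmp, collapse = "")
    }
  }
  out
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomly permute a sequence while holding fixed sites unchanged
#'
#' Returns a sequence whose bases at `fixed_sites` equal the input's and
#' whose bases elsewhere are a uniform random permutation of the input's
#' non-fixed bases (base composition is conserved). This is the elementary
#' move of the RS1 flank-permutation null.
#'
#' @param seq RNA sequence string.
#' @param fixed_sites integer vector of 1-based positions to hold fixed.
#' @param rng_seed optional integer; when given, the permutation is drawn
#'   under a local RNG seeded with it (the global RNG state is restored).
#' @return permuted sequence string.
#' @export
permute_nonfixed <- function(seq, fixed_sites = integer(0L),
                             rng_seed = NULL) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  fixed_sites <- as.integer(fixed_sites)
  if (any(fixed_sites < 1L | fixed_sites > n))
    stop("fixed_sites out of range 1..", n, call. = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  free <- setdiff(seq_len(n), fixed_sites)
  if (length(free) > 1L) {
    chars[free] <- with_local_seed(rng_seed, sample(chars[free]))
  }
  paste(chars, collapse = "")
}

#' Validate a haplotype
#'
#' A haplotype is a non-empty variant table whose variants all lie on one
#' transcript at strictly increasing, duplicate-free positions.
#'
#' @param variants variant data frame.
#' @return the validated table, sorted by position.
#' @export
as_haplotype <- function(variants) {
  variants <- as_variants(variants)
  if (!nrow(variants))
    stop("a haplotype must contain at least one variant", call. = FALSE)
  if (length(unique(variants$transcript_id)) != 1L)
    stop("all variants of a haplotype must share one transcript_id",
         call. = FALSE)
  variants <- variants[order(variants$position), , drop = FALSE]
  if (anyDuplicated(variants$position))
    stop("haplotype contains duplicate positions", call. = FALSE)
  variants
}
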