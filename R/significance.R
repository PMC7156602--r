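#' Add-one empirical p-value of an observed score against a background
#'
#' p = (1 + #\{b in background : b <= observed\}) / (n + 1). Low similarity
#' relative to the background (few background scores at or below the
#' observed) gives a small p: the one-sided test asks whether the variant
#' disrupts structure more than the null does. The add-one correction keeps
#' p > 0 (standard practice for permutation p-values).
#'
#' @param observed observed score.
#' @param background numeric vector of null scores.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, background) {
  n <- length(background)
  if (n < 1L) stop("background must be non-empty", call. = FALSE)
  (1 + sum(background <= observed)) / (n + 1)
}

new_significance <- function(method, observed_SS, background, rng_seed) {
  structure(
    list(method = method,
         observed_SS = observed_SS,
         background = background,
         p_value = empirical_pvalue(observed_SS, background),
         n_background = length(background),
         rng_seed = rng_seed),
    class = "rnasmc_significance"
  )
}

#' @export
print.rnasmc_significance <- function(x, ...) {
  cat(sprintf("%s: observed SS = %.4f, p = %.4g (background n = %d%s)\n",
              x$method, x$observed_SS, x$p_value, x$n_background,
              if (is.null(x$rng_seed)) "" else
                paste0(", seed ", x$rng_seed)))
  invisible(x)
}

rs1_shuffle_set <- function(n, sites, window) {
  free <- setdiff(seq_len(n), sites)
  if (is.null(window)) return(free)
  keep <- unique(unlist(lapply(sites, function(p) {
    max(1L, p - window):min(n, p + window)
  })))
  intersect(free, keep)
}

#' RS1: flank-permutation significance of a variant's structural effect
#'
#' The observed score is SS(fold(WT), fold(MT)). For each of `n_perm`
#' iterations the sequence around the variant sites is shuffled (the sites
#' themselves are held fixed); the same permutation is applied to build a
#' permuted WT (ref alleles at the sites) and a permuted MT (alt alleles),
#' both are folded and scored, and their SS joins the background. The
#' shared permutation isolates the allele effect from shuffle noise. The
#' p-value is the add-one empirical rank of the observed score
#' ([empirical_pvalue()]): a variant that disrupts structure more than
#' permuted contexts do gets a small p.
#'
#' @param seq wild-type RNA sequence string.
#' @param variants variant data frame (positions on `seq`).
#' @param n_perm number of permutations (the reference analysis uses
#'   10,000; smaller values trade resolution for speed).
#' @param rng_seed integer seed driving the permutations.
#' @param backend folding backend (see [folding_backend()]).
#' @param window optional integer: restrict shuffling to within `window` nt
#'   of each variant site (default `NULL`, shuffle the whole transcript
#'   outside the sites).
#' @param empty_kind empty-kind convention for [rnasmc_score()].
#' @return an `rnasmc_significance` with method `"RS1"`.
#' @export
rs1 <- function(seq, variants, n_perm = 10000L, rng_seed = 1L,
                backend = folding_backend("nussinov"), window = NULL,
                empty_kind = "zero") {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  seq <- normalize_rna(seq)
  variants <- as_variants(variants)
  if (!nrow(variants))
    stop("at least one variant is required", call. = FALSE)
  n <- nchar(seq)
  mt <- apply_variants(seq, variants)
  observed <- rnasmc_score(decompose(fold_rna(seq, backend, id = "WT")),
                           decompose(fold_rna(mt, backend, id = "MT")),
                           empty_kind = empty_kind)$SS

  sites <- variants$position
  shuffle <- rs1_shuffle_set(n, sites, window)
  wt_chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mt_chars <- strsplit(mt, "", fixed = TRUE)[[1L]]

  background <- with_local_seed(rng_seed, {
    vapply(seq_len(n_perm), function(b) {
      if (length(shuffle) > 1L) {
        ord <- sample(shuffle)
        pw <- wt_chars; pm <- mt_chars
        pw[shuffle] <- wt_chars[ord]
        pm[shuffle] <- mt_chars[ord]  # same permutation for both members
      } else {
        pw <- wt_chars; pm <- mt_chars
      }
      rnasmc_score(
        decompose(fold_rna(paste(pw, collapse = ""), backend, id = "pWT")),
        decompose(fold_rna(paste(pm, collapse = ""), backend, id = "pMT")),
        empty_kind = empty_kind)$SS
    }, numeric(1L))
  })
  new_significance("RS1", observed, background, rng_seed)
}

#' RS2: exhaustive point-mutant significance of a variant's structural effect
#'
#' For an N-nt sequence the background is the SS between the folded WT and
#' the fold of every one of the 3N single-point mutants (the observed
#' variant's own mutant included). The observed score is SS(fold(WT),
#' fold(MT)); the p-value is its add-one empirical rank in the background.
#' RS2 is exhaustive and fully deterministic: reruns are bit-identical.
#'
#' @param seq wild-type RNA sequence string.
#' @param variant a single-row variant data frame.
#' @param backend folding backend.
#' @param empty_kind empty-kind convention for [rnasmc_score()].
#' @return an `rnasmc_significance` with method `"RS2"` and
#'   `n_background = 3N`.
#' @export
rs2 <- function(seq, variant, backend = folding_backend("nussinov"),
                empty_kind = "zero") {
  seq <- normalize_rna(seq)
  variant <- as_variants(variant)
  if (nrow(variant) != 1L)
    stop("rs2 scores a single variant; use rs1/haplotype_effect for sets",
         call. = FALSE)
  d_wt <- decompose(fold_rna(seq, backend, id = "WT"))
  mutants <- enumerate_point_mutants(seq)
  background <- vapply(mutants, function(m) {
    rnasmc_score(d_wt, decompose(fold_rna(m, backend, id = "mut")),
                 empty_kind = empty_kind)$SS
  }, numeric(1L), USE.NAMES = FALSE)
  mt <- apply_variants(seq, variant)
  observed <- rnasmc_score(d_wt, decompose(fold_rna(mt, backend,
                                                    id = "MT")),
                           empty_kind = empty_kind)$SS
  new_significance("RS2", observed, background, NULL)
}

#' Combined structural effect of a haplotype
#'
#' The mutant carries all haplotype alleles simultaneously; significance is
#' assessed with the RS1 permutation scheme with every haplotype position
#' held fixed. A haplotype of one SNP is exactly [rs1()] of that SNP.
#'
#' @param seq wild-type RNA sequence string.
#' @param hap haplotype variant table (see [as_haplotype()]).
#' @inheritParams rs1
#' @return an `rnasmc_significance` with method `"RS1"`.
#' @export
haplotype_effect <- function(seq, hap, n_perm = 10000L, rng_seed = 1L,
                             backend = folding_backend("nussinov"),
                             window = NULL, empty_kind = "zero") {
  hap <- as_haplotype(hap)
  rs1(seq, hap, n_perm = n_perm, rng_seed = rng_seed, backend = backend,
      window = window, empty_kind = empty_kind)
}
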