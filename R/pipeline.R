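#' Run the scoring and significance pipeline over a variant table
#'
#' For each variant: fold the wild-type and mutant transcript, compute the
#' RNAsmc score, and (per `methods`) the RS1 and/or RS2 empirical p-values.
#' A variant is flagged significant when every computed method's p-value is
#' below `alpha` (the consensus-of-both-schemes reading).
#'
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @param variants variant data frame, or a TSV path (columns `rsid`,
#'   `transcript_id`, `position`, `ref`, `alt`).
#' @param methods character subset of `c("rs1", "rs2")`; empty means score
#'   only.
#' @param engine folding engine name for [folding_backend()].
#' @param n_perm RS1 permutation count.
#' @param seed master seed; each variant's RS1 run uses `seed + row index`.
#' @param alpha significance level (default 0.05).
#' @param window optional RS1 shuffle window (nt around each site).
#' @param empty_kind empty-kind convention for [rnasmc_score()].
#' @param out optional TSV path for the result table.
#' @param quiet suppress stage-count messages.
#' @return data frame with one row per variant: rsid, transcript_id,
#'   position, ref, alt, SS, p_rs1, p_rs2 (NA when not computed),
#'   significant.
#' @export
run_pipeline <- function(transcripts, variants,
                         methods = c("rs1", "rs2"),
                         engine = "nussinov", n_perm = 1000L, seed = 1L,
                         alpha = 0.05, window = NULL, empty_kind = "zero",
                         out = NULL, quiet = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(methods)) methods <- match.arg(methods, several.ok = TRUE)
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts) && is.null(names(transcripts)))
    transcripts <- read_fasta(transcripts)
  if (is.character(variants) && length(variants) == 1L)
    variants <- read_variants_tsv(variants)
  variants <- as_variants(variants)
  backend <- folding_backend(engine)
  say <- function(...) if (!quiet) message("[rnasmc] ", ...)
  say("engine=", backend$name, " seed=", seed, " variants=", nrow(variants),
      " transcripts=", length(transcripts))

  res <- data.frame(rsid = variants$rsid,
                    transcript_id = variants$transcript_id,
                    position = variants$position,
                    ref = variants$ref, alt = variants$alt,
                    SS = rep(NA_real_, nrow(variants)),
                    p_rs1 = rep(NA_real_, nrow(variants)),
                    p_rs2 = rep(NA_real_, nrow(variants)),
                    significant = rep(NA, nrow(variants)),
                    stringsAsFactors = FALSE)
  if (!nrow(variants)) {
    if (!is.null(out)) write_tsv(res, out)
    return(res)
  }
  missing_tx <- setdiff(variants$transcript_id, names(transcripts))
  if (length(missing_tx))
    stop("variant transcript not in FASTA: ", missing_tx[1L],
         call. = FALSE)

  for (r in seq_len(nrow(variants))) {
    v <- variants[r, , drop = FALSE]
    seq <- transcripts[[v$transcript_id]]
    mt <- apply_variants(seq, v)
    res$SS[r] <- rnasmc_score(
      decompose(fold_rna(seq, backend, id = "WT")),
      decompose(fold_rna(mt, backend, id = "MT")),
      empty_kind = empty_kind)$SS
    if ("rs1" %in% methods)
      res$p_rs1[r] <- rs1(seq, v, n_perm = n_perm,
                          rng_seed = seed + r, backend = backend,
                          window = window,
                          empty_kind = empty_kind)$p_value
    if ("rs2" %in% methods)
      res$p_rs2[r] <- rs2(seq, v, backend = backend,
                          empty_kind = empty_kind)$p_value
    ps <- c(res$p_rs1[r], res$p_rs2[r])
    ps <- ps[!is.na(ps)]
    res$significant[r] <- if (length(ps)) all(ps < alpha) else NA
  }
  say("scored=", nrow(res), " significant=",
      sum(res$significant %in% TRUE))
  if (!is.null(out)) write_tsv(res, out)
  res
}
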