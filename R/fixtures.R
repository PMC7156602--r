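random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate synthetic transcripts, planted SNPs and flank reads
#'
#' Produces a reproducible fixture set emulating the study's inputs: random
#' transcripts (optionally with an implanted perfectly complementary helix
#' so the built-in folder always finds base pairs, hence at least one stem
#' and one hairpin), SNPs planted at interior positions carrying the
#' transcript's own base as ref, 25-nt flank reads cut from the planted
#' context on a random strand, and a truth table for recovery checks.
#' Everything is a pure function of `seed`.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range integer vector of length 2: min and max transcript
#'   length (uniform); must be at least 60 when SNPs are planted so both
#'   25-nt flanks fit inside the transcript.
#' @param gc GC fraction of the random background sequence.
#' @param n_snps_per_transcript SNPs planted per transcript (0 allowed).
#' @param plant_hairpin implant an 8-bp complementary helix with a 4-nt loop.
#' @param minus_fraction fraction of flank reads reported on the reverse
#'   strand (dbSNP records either orientation).
#' @param seed integer seed.
#' @param dir optional directory: when given, writes `transcripts.fa`,
#'   `variants.tsv`, `flanks.tsv`, `truth.tsv` there.
#' @return list with `transcripts` (named character), `variants`, `flanks`,
#'   `truth` (data frames) and `seed`.
#' @export
generate_fixtures <- function(n_transcripts = 10L,
                              length_range = c(120L, 200L),
                              gc = 0.5,
                              n_snps_per_transcript = 1L,
                              plant_hairpin = TRUE,
                              minus_fraction = 0.5,
                              seed = 1L,
                              dir = NULL) {
  stopifnot(n_transcripts >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L],
            n_snps_per_transcript >= 0L, gc > 0, gc < 1)
  if (n_snps_per_transcript > 0L && length_range[1L] < 60L)
    stop("transcripts must be at least 60 nt to plant SNPs with 25-nt ",
         "flanks on both sides", call. = FALSE)

  with_local_seed(seed, {
    ids <- sprintf("tx_%03d", seq_len(n_transcripts))
    transcripts <- character(n_transcripts)
    names(transcripts) <- ids
    var_rows <- list()
    flank_rows <- list()
    truth_rows <- list()
    snp_i <- 0L

    for (t in seq_len(n_transcripts)) {
      n <- length_range[1L] +
        sample.int(length_range[2L] - length_range[1L] + 1L, 1L) - 1L
      chars <- strsplit(random_rna(n, gc), "", fixed = TRUE)[[1L]]
      if (plant_hairpin) {
        arm <- sample(c("A", "C", "G", "U"), 8L, replace = TRUE)
        rc_arm <- reverse_complement(paste(arm, collapse = ""))
        hp <- c(arm, sample(c("A", "C", "G", "U"), 4L, replace = TRUE),
                strsplit(rc_arm, "", fixed = TRUE)[[1L]])
        at <- sample(seq_len(n - length(hp) + 1L), 1L)
        chars[at:(at + length(hp) - 1L)] <- hp
      }
      seq <- paste(chars, collapse = "")
      transcripts[t] <- seq

      if (n_snps_per_transcript > 0L) {
        lo <- 27L; hi <- n - 26L
        if (hi - lo + 1L < n_snps_per_transcript)
          stop("transcript too short for ", n_snps_per_transcript,
               " interior SNPs", call. = FALSE)
        pos <- sort((lo:hi)[sample.int(hi - lo + 1L,
                                       n_snps_per_transcript)])
        for (p in pos) {
          snp_i <- snp_i + 1L
          ref <- substr(seq, p, p)
          alt <- sample(setdiff(c("A", "C", "G", "U"), ref), 1L)
          strand <- if (runif(1L) < minus_fraction) "-" else "+"
          up <- substr(seq, p - 25L, p - 1L)
          down <- substr(seq, p + 1L, p + 25L)
          rsid <- sprintf("rs_syn_%04d", snp_i)
          var_rows[[snp_i]] <- data.frame(
            rsid = rsid, transcript_id = ids[t], position = p,
            ref = ref, alt = alt, stringsAsFactors = FALSE)
          if (strand == "+") {
            flank_rows[[snp_i]] <- data.frame(
              rsid = rsid, upstream = up, downstream = down,
              ref = ref, alt = alt, stringsAsFactors = FALSE)
          } else {
            flank_rows[[snp_i]] <- data.frame(
              rsid = rsid,
              upstream = reverse_complement(down),
              downstream = reverse_complement(up),
              ref = complement_base(ref), alt = complement_base(alt),
              stringsAsFactors = FALSE)
          }
          truth_rows[[snp_i]] <- data.frame(
            rsid = rsid, transcript_id = ids[t], position = p,
            ref = ref, alt = alt, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }

    empty_var <- data.frame(rsid = character(), transcript_id = character(),
                            position = integer(), ref = character(),
                            alt = character(), stringsAsFactors = FALSE)
    variants <- if (length(var_rows)) do.call(rbind, var_rows) else empty_var
    flanks <- if (length(flank_rows)) do.call(rbind, flank_rows) else
      data.frame(rsid = character(), upstream = character(),
                 downstream = character(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE)
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      cbind(empty_var, strand = character(0L))

    out <- list(transcripts = transcripts, variants = variants,
                flanks = flanks, truth = truth, seed = seed)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_fasta(transcripts, file.path(dir, "transcripts.fa"))
      write_tsv(variants, file.path(dir, "variants.tsv"))
      write_tsv(flanks, file.path(dir, "flanks.tsv"))
      write_tsv(truth, file.path(dir, "truth.tsv"))
    }
    out
  })
}
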