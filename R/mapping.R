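match_starts <- function(pattern, subject, max_mismatch) {
  m <- Biostrings::matchPattern(pattern, subject,
                                max.mismatch = max_mismatch)
  BiocGenerics::start(m)
}

#' Reposition SNPs onto transcripts from 25-nt flank reads
#'
#' For each flank read and transcript, every exact occurrence (or up to
#' `max_mismatch` mismatches) of the upstream and downstream flanks is
#' located on the forward strand, and of their reverse complements on the
#' reverse strand. A record is accepted when an upstream match starting at
#' s_u and a downstream match starting at s_d on the same strand satisfy
#' |s_u - s_d| = 26 — the flank-start distance that places exactly one base,
#' the SNP, between two abutting 25-nt flanks. The SNP position is the base
#' between the flanks; on the reverse strand the transcript must carry the
#' complement of the read's ref allele there. A read may map to several
#' transcripts and a transcript may host several reads; multiple consistent
#' flank pairings within one transcript each produce a record.
#'
#' @param transcripts named character vector of transcript sequences
#'   (unique names; DNA letters accepted and normalized).
#' @param flanks flank-read data frame with columns `rsid`, `upstream`,
#'   `downstream`, `ref`, `alt` (25-nt flanks; dbSNP DNA convention
#'   accepted).
#' @param max_mismatch mismatches tolerated per flank (default 0, strict
#'   exact matching).
#' @return data frame with columns `rsid`, `transcript_id`, `snp_position`
#'   (1-based on the transcript), `strand` (`+`/`-`), `flank_start_distance`
#'   (signed s_d - s_u; always |26|), `ref`, `alt` (as given on the read).
#' @export
map_flanks <- function(transcripts, flanks, max_mismatch = 0L) {
  if (!length(transcripts)) stop("no transcripts supplied", call. = FALSE)
  if (is.null(names(transcripts)) || any(!nzchar(names(transcripts))))
    stop("transcripts must be named", call. = FALSE)
  if (anyDuplicated(names(transcripts)))
    stop("duplicate transcript ids: ",
         names(transcripts)[duplicated(names(transcripts))][1L],
         call. = FALSE)
  transcripts <- vapply(transcripts, normalize_rna, character(1L))
  flanks <- as_flanks(flanks)

  empty <- data.frame(rsid = character(), transcript_id = character(),
                      snp_position = integer(), strand = character(),
                      flank_start_distance = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE)
  if (!nrow(flanks)) return(empty)

  subjects <- lapply(transcripts, Biostrings::RNAString)
  records <- list()
  for (r in seq_len(nrow(flanks))) {
    up <- flanks$upstream[r]
    down <- flanks$downstream[r]
    rc_up <- reverse_complement(up)
    rc_down <- reverse_complement(down)
    for (tx in names(transcripts)) {
      subject <- subjects[[tx]]
      tx_chars <- transcripts[[tx]]
      # forward strand: ...upstream [SNP] downstream...
      su <- match_starts(up, subject, max_mismatch)
      sd <- match_starts(down, subject, max_mismatch)
      for (u in su) for (d in sd) {
        if (d - u == 26L) {
          pos <- u + 25L
          if (substr(tx_chars, pos, pos) == flanks$ref[r]) {
            records[[length(records) + 1L]] <- data.frame(
              rsid = flanks$rsid[r], transcript_id = tx,
              snp_position = pos, strand = "+",
              flank_start_distance = 26L,
              ref = flanks$ref[r], alt = flanks$alt[r],
              stringsAsFactors = FALSE)
          }
        }
      }
      # reverse strand: transcript carries RC(downstream) [SNP'] RC(upstream)
      su <- match_starts(rc_up, subject, max_mismatch)
      sd <- match_starts(rc_down, subject, max_mismatch)
      for (u in su) for (d in sd) {
        if (d - u == -26L) {
          pos <- d + 25L
          if (substr(tx_chars, pos, pos) ==
              complement_base(flanks$ref[r])) {
            records[[length(records) + 1L]] <- data.frame(
              rsid = flanks$rsid[r], transcript_id = tx,
              snp_position = pos, strand = "-",
              flank_start_distance = -26L,
              ref = flanks$ref[r], alt = flanks$alt[r],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(records)) return(empty)
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Convert mapped flank records to transcript-coordinate variants
#'
#' Reverse-strand records have their alleles complemented so that `ref`/
#' `alt` are expressed on the transcript strand, ready for
#' [apply_variants()].
#'
#' @param mapped output of [map_flanks()].
#' @return variant data frame (see [as_variants()]).
#' @export
mapped_to_variants <- function(mapped) {
  if (!nrow(mapped)) {
    return(as_variants(data.frame(rsid = character(),
      transcript_id = character(), position = integer(),
      ref = character(), alt = character(), stringsAsFactors = FALSE)))
  }
  neg <- mapped$strand == "-"
  ref <- ifelse(neg, complement_base(mapped$ref), mapped$ref)
  alt <- ifelse(neg, complement_base(mapped$alt), mapped$alt)
  as_variants(data.frame(rsid = mapped$rsid,
                         transcript_id = mapped$transcript_id,
                         position = mapped$snp_position,
                         ref = ref, alt = alt, stringsAsFactors = FALSE))
}
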