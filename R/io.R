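#' Read transcript sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of normalized RNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_rna(as.character(set))
  names(seqs) <- sub("[[:space:]].*$", "", names(set))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read Vienna dot-bracket records
#'
#' Record format: a `>id` header line, a sequence line, a structure line.
#' A trailing free-energy annotation on the structure line (whitespace then a
#' parenthesized number, as written by thermodynamic folders) is ignored.
#'
#' @param path dot-bracket file.
#' @return list of `rna_structure` objects.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads) || any(diff(heads) != 3L) ||
      heads[1L] != 1L || length(lines) != heads[length(heads)] + 2L)
    stop("malformed dot-bracket file: expected >id / sequence / structure ",
         "triplets", call. = FALSE)
  lapply(heads, function(h) {
    id <- sub("^>[[:space:]]*", "", lines[h])
    id <- sub("[[:space:]].*$", "", id)
    db <- strsplit(lines[h + 2L], "[[:space:]]+")[[1L]][1L]
    parse_dotbracket(db, lines[h + 1L], id = id)
  })
}

#' Write structures as a Vienna dot-bracket file
#'
#' @param structures an `rna_structure` or list of them.
#' @param path output file.
#' @export
write_dotbracket <- function(structures, path) {
  if (inherits(structures, "rna_structure")) structures <- list(structures)
  out <- unlist(lapply(structures, function(s) {
    c(paste0(">", s$id), s$seq, s$db)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a CT secondary-structure file
#'
#' Six-column CT format as produced by thermodynamic folders: a header line
#' with the base count (and optional title), then one row per base with
#' index, base, previous index, next index, pairing partner (0 = unpaired),
#' and the index again. Pseudoknotted pair tables are rejected.
#'
#' @param path CT file.
#' @return an `rna_structure`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CT file: ", path, call. = FALSE)
  head_tok <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  n <- suppressWarnings(as.integer(head_tok[1L]))
  if (is.na(n) || n < 1L)
    stop("malformed CT header: ", lines[1L], call. = FALSE)
  if (length(lines) < n + 1L)
    stop("CT file truncated: header declares ", n, " bases", call. = FALSE)
  id <- if (length(head_tok) > 1L) head_tok[2L] else "ct"
  body <- read.table(text = lines[2:(n + 1L)],
                     col.names = c("idx", "base", "prev", "nxt", "pair",
                                   "idx2"),
                     colClasses = c("integer", "character", "integer",
                                    "integer", "integer", "integer"))
  if (!identical(body$idx, seq_len(n)))
    stop("CT base indices are not 1..N", call. = FALSE)
  rna_structure(id, paste(body$base, collapse = ""), body$pair)
}

#' Write a structure as a CT file
#'
#' @param x an `rna_structure`.
#' @param path output file.
#' @export
write_ct <- function(x, path) {
  stopifnot(inherits(x, "rna_structure"))
  n <- nchar(x$seq)
  bases <- strsplit(x$seq, "", fixed = TRUE)[[1L]]
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                  seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L),
                  x$pairs, seq_len(n))
  writeLines(c(paste(n, x$id), rows), path)
  invisible(path)
}

#' Read a variant table (TSV)
#'
#' Tab-separated with a header row and columns `rsid`, `transcript_id`,
#' `position`, `ref`, `alt`; lines starting with `#` are comments.
#'
#' @param path TSV file.
#' @return validated variant data frame (see [as_variants()]).
#' @export
read_variants_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", quote = "")
  need <- c("rsid", "transcript_id", "position", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("variant TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$position <- as.integer(df$position)
  as_variants(df[need])
}

#' Read SNVs from a minimal VCF
#'
#' Accepts the VCF subset with single-base REF and ALT; CHROM is interpreted
#' as the transcript identifier. Multi-allelic or non-SNV records are skipped
#' with a warning.
#'
#' @param path VCF file (uncompressed text).
#' @return validated variant data frame.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(as_variants(data.frame(rsid = character(), transcript_id =
      character(), position = integer(), ref = character(),
      alt = character(), stringsAsFactors = FALSE)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1L)) < 5L
  if (any(short)) stop("malformed VCF record (fewer than 5 fields)",
                       call. = FALSE)
  df <- data.frame(
    rsid = vapply(fields, `[[`, character(1L), 3L),
    transcript_id = vapply(fields, `[[`, character(1L), 1L),
    position = as.integer(vapply(fields, `[[`, character(1L), 2L)),
    ref = vapply(fields, `[[`, character(1L), 4L),
    alt = vapply(fields, `[[`, character(1L), 5L),
    stringsAsFactors = FALSE
  )
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
    !grepl(",", df$alt, fixed = TRUE)
  if (any(!snv))
    warning(sum(!snv), " non-SNV VCF record(s) skipped")
  as_variants(df[snv, , drop = FALSE])
}

#' Read a flank-read table (TSV)
#'
#' Tab-separated with header columns `rsid`, `upstream`, `downstream`,
#' `ref`, `alt`; the flanks are the 25-nt regions immediately up- and
#' downstream of a SNP (dbSNP convention; DNA letters accepted).
#'
#' @param path TSV file.
#' @return data frame with normalized flanks.
#' @export
read_flanks_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", quote = "")
  need <- c("rsid", "upstream", "downstream", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("flank TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  as_flanks(df)
}

as_flanks <- function(df) {
  if (nrow(df)) {
    df$upstream <- normalize_rna(df$upstream)
    df$downstream <- normalize_rna(df$downstream)
    df$ref <- normalize_rna(df$ref)
    df$alt <- normalize_rna(df$alt)
    bad <- nchar(df$upstream) != 25L | nchar(df$downstream) != 25L
    if (any(bad))
      stop("flank reads must be exactly 25 nt (offending rsid: ",
           df$rsid[bad][1L], ")", call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
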