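#' Fold an RNA sequence by Nussinov-style base-pair maximization
#'
#' Deterministic dynamic program maximizing the number of nested base pairs
#' drawn from \{AU, UA, GC, CG, GU, UG\}, subject to a minimum hairpin size:
#' a pair (i, j) requires j - i > `min_hairpin`. Traceback ties are broken
#' deterministically (leave the interval's last base unpaired first,
#' otherwise pair it with the smallest admissible partner), so the result is
#' a pure function of the input.
#'
#' This built-in folder makes the scoring and significance machinery
#' self-contained and reproducible; structures from thermodynamic folders
#' can be supplied instead through [fold_rna()] / [folding_backend()].
#'
#' @param seq RNA sequence string (T accepted, normalized to U).
#' @param min_hairpin minimum number of unpaired bases a hairpin may enclose
#'   (default 3, the standard steric minimum).
#' @param id identifier for the returned structure.
#' @return an `rna_structure`.
#' @export
#' @examples
#' fold_nussinov("GGGAAACCC")$db  # "(((...)))"
fold_nussinov <- function(seq, min_hairpin = 3L, id = "rna") {
  seq <- normalize_rna(seq)
  if (nchar(seq) < 1L) stop("sequence must be non-empty", call. = FALSE)
  if (min_hairpin < 0L) stop("min_hairpin must be >= 0", call. = FALSE)
  pt <- .nussinov_pairs(seq, as.integer(min_hairpin))
  rna_structure(id, seq, pt)
}

#' Folding backends
#'
#' A folding backend is a list with a `name` and a `fold(seq, id)` function
#' returning an `rna_structure` for the given sequence. `folding_backend()`
#' constructs the built-in ones:
#' \describe{
#'   \item{`"nussinov"`}{the built-in pair-maximization folder.}
#'   \item{`"ct:<path>"`}{a fixed structure read from a CT file; the file's
#'     sequence must equal the folded sequence.}
#'   \item{`"vienna"`}{adapter shelling out to `RNAfold` (ViennaRNA) if the
#'     executable is on the PATH; thermodynamic MFE structures.}
#' }
#'
#' @param engine backend name as above.
#' @param min_hairpin minimum hairpin size for the built-in folder.
#' @return a folding backend list.
#' @export
folding_backend <- function(engine = "nussinov", min_hairpin = 3L) {
  if (!is.character(engine) || length(engine) != 1L || !nzchar(engine))
    stop("backend engine name must be a non-empty string", call. = FALSE)
  if (engine == "nussinov") {
    return(list(name = "nussinov",
                fold = function(seq, id = "rna")
                  fold_nussinov(seq, min_hairpin = min_hairpin, id = id)))
  }
  if (startsWith(engine, "ct:")) {
    path <- substring(engine, 4L)
    if (!file.exists(path))
      stop("CT backend file not found: ", path, call. = FALSE)
    fixed <- read_ct(path)
    return(list(name = engine,
                fold = function(seq, id = "rna") {
                  if (normalize_rna(seq) != fixed$seq)
                    stop("CT backend sequence does not match input sequence",
                         call. = FALSE)
                  rna_structure(id, fixed$seq, fixed$pairs)
                }))
  }
  if (engine == "vienna") {
    if (Sys.which("RNAfold") == "")
      stop("RNAfold executable not found on PATH", call. = FALSE)
    return(list(name = "vienna",
                fold = function(seq, id = "rna") {
                  seq <- normalize_rna(seq)
                  out <- system2("RNAfold", c("--noPS"), input = seq,
                                 stdout = TRUE)
                  if (length(out) < 2L)
                    stop("unparseable RNAfold output", call. = FALSE)
                  db <- strsplit(out[2L], "[[:space:]]+")[[1L]][1L]
                  parse_dotbracket(db, seq, id = id)
                }))
  }
  stop("unknown folding engine: ", engine, call. = FALSE)
}

#' Fold a sequence with an arbitrary backend, validating the result
#'
#' Invokes `backend$fold` and checks the contract: the returned object is a
#' valid nested `rna_structure` whose sequence equals the input. Backends
#' returning pseudoknotted pair tables fail the `rna_structure` validation.
#'
#' @param seq RNA sequence string.
#' @param backend a backend from [folding_backend()] or any list with a
#'   `name` and a `fold(seq, id)` function.
#' @param id identifier for the structure.
#' @return an `rna_structure`.
#' @export
fold_rna <- function(seq, backend = folding_backend("nussinov"),
                     id = "rna") {
  if (!is.list(backend) || !is.function(backend$fold) ||
      is.null(backend$name) || !nzchar(backend$name))
    stop("invalid folding backend (need a name and a fold function)",
         call. = FALSE)
  seq <- normalize_rna(seq)
  out <- backend$fold(seq, id = id)
  if (!inherits(out, "rna_structure"))
    stop("backend '", backend$name, "' did not return an rna_structure",
         call. = FALSE)
  # revalidate pair table (involution + nesting) in case the backend built
  # the object by hand
  out <- rna_structure(out$id, out$seq, out$pairs)
  if (out$seq != seq)
    stop("backend '", backend$name,
         "' returned a structure for a different sequence", call. = FALSE)
  out
}
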