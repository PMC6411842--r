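#' Reference coding region
#'
#' Construct the coordinate frame used throughout the package: the coding
#' (mRNA-like) strand of the reporter open reading frame, with position 1 the
#' first base of the start codon and positions 1-based inclusive. All mutation
#' positions, guide coordinates and windows are expressed on this frame.
#'
#' @param name Name of the region (used as the contig name in VCF-style
#'   export).
#' @param sequence Character scalar over `A`, `C`, `G`, `T` (case
#'   insensitive): the coding-strand sequence.
#' @return An object of class `reference_region` with elements `name`,
#'   `sequence` and `length`.
#' @examples
#' ref <- reference_region("toy", "ATGACGTTTTTTA")
#' ref_base(ref, 4)
#' @export
reference_region <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L || grepl("[^ACGT]", sequence)) {
    stop("reference sequence must be a non-empty string over A/C/G/T")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "reference_region"
  )
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf("<reference_region> %s: %d nt coding sequence\n",
              x$name, x$length))
  invisible(x)
}

#' Read a reference coding sequence from FASTA
#'
#' Reads a single-record FASTA file holding the coding strand of the reporter.
#'
#' @param path Path to a FASTA file with exactly one record.
#' @return A [reference_region()].
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected exactly one FASTA record, found ", length(set))
  }
  nm <- sub("\\s.*$", "", names(set)[1])
  reference_region(nm, as.character(set[[1]]))
}

#' Base at a coding position
#'
#' @param ref A [reference_region()].
#' @param pos Integer vector of 1-based coding positions.
#' @return Character vector of coding-strand bases.
#' @export
ref_base <- function(ref, pos) {
  stopifnot(inherits(ref, "reference_region"))
  if (any(pos < 1L | pos > ref$length)) {
    stop("position out of range 1..", ref$length)
  }
  substring(ref$sequence, pos, pos)
}

#' Complement of bases
#'
#' Watson-Crick complement of a character vector of bases (no reversal).
#'
#' @param base Character vector over A/C/G/T.
#' @return Complemented character vector.
#' @export
complement_base <- function(base) {
  chartr("ACGTacgt", "TGCAtgca", base)
}

#' Find homopolymer runs
#'
#' Maximal runs of identical bases of at least `min_run` nucleotides, the
#' sequence feature associated with polymerase-slippage indels.
#'
#' @param ref A [reference_region()].
#' @param min_run Minimum run length (>= 2).
#' @return A data frame with columns `start`, `end`, `base`, one row per run,
#'   sorted by `start`. Runs are disjoint and maximal.
#' @examples
#' find_homopolymers(reference_region("toy", "ACGTTTTTTA"), min_run = 6)
#' @export
find_homopolymers <- function(ref, min_run = 6L) {
  stopifnot(inherits(ref, "reference_region"), min_run >= 2L)
  r <- rle(strsplit(ref$sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run
  data.frame(
    start = (ends - r$lengths + 1L)[keep],
    end = ends[keep],
    base = r$values[keep],
    stringsAsFactors = FALSE
  )
}
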