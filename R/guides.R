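#' Guide RNA target
#'
#' Describes a 20-nt (by default) protospacer on the reporter coding
#' coordinate frame, together with its strand designation and PAM side.
#'
#' Strand bookkeeping follows a single configurable convention. A guide
#' "targeting" strand S is taken to mean that the protospacer (and PAM) lie
#' on S; the guide RNA then hybridizes to the complement of S, so the
#' displaced single-stranded ("non-target") strand of the R-loop is S
#' itself. Under this default (`convention = "protospacer"`), a guide
#' designated `NTS` (non-transcribed, i.e. coding/mRNA-like strand) has the
#' coding strand as its non-target strand, and a guide designated `TS`
#' (transcribed/template strand) has the template strand as its non-target
#' strand. The alternative reading, in which the guide anneals directly to
#' the designated strand (`convention = "hybridized"`), flips every
#' non-target-strand call to its complement. The convention in force is
#' carried in every summary this package emits.
#'
#' @param id Guide identifier.
#' @param start,end First and last coding position (1-based inclusive) of the
#'   protospacer; `end - start + 1` must equal `spacer_length`.
#' @param strand `"NTS"` or `"TS"`: the strand the guide is designated to
#'   target.
#' @param pam_side `"upstream"` or `"downstream"` in coding coordinates; the
#'   PAM occupies the 3 nt immediately adjacent on that side. Recorded for
#'   reporting only; window arithmetic uses the protospacer interval.
#' @param spacer_length Protospacer length in nt (default 20).
#' @param convention `"protospacer"` (default) or `"hybridized"`, see above.
#' @return An object of class `guide_target`.
#' @examples
#' g <- guide_target("sgRNA1", 277, 296, strand = "TS", pam_side = "upstream")
#' guide_window(g, margin = 10)
#' @export
guide_target <- function(id, start, end, strand, pam_side = "downstream",
                         spacer_length = 20L, convention = "protospacer") {
  start <- as.integer(start); end <- as.integer(end)
  strand <- match.arg(strand, c("NTS", "TS"))
  pam_side <- match.arg(pam_side, c("upstream", "downstream"))
  convention <- match.arg(convention, c("protospacer", "hybridized"))
  if (end - start + 1L != spacer_length) {
    stop(sprintf("guide %s: end - start + 1 = %d but spacer_length = %d",
                 id, end - start + 1L, spacer_length))
  }
  structure(
    list(id = id, start = start, end = end, strand = strand,
         pam_side = pam_side, spacer_length = as.integer(spacer_length),
         convention = convention),
    class = "guide_target"
  )
}

#' @export
print.guide_target <- function(x, ...) {
  cat(sprintf("<guide_target> %s: %d-%d (%s strand, PAM %s, %s convention)\n",
              x$id, x$start, x$end, x$strand, x$pam_side, x$convention))
  invisible(x)
}

#' Read guide definitions from TSV
#'
#' Expects columns `id`, `start`, `end`, `strand` (NTS|TS) and optionally
#' `pam_side`. Guides are validated against the reference if one is given.
#'
#' @param path TSV file path.
#' @param reference Optional [reference_region()]; protospacers must lie
#'   within it.
#' @param convention Strand convention applied to all guides, see
#'   [guide_target()].
#' @return Named list of `guide_target` objects.
#' @export
read_guides <- function(path, reference = NULL, convention = "protospacer") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("guide TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate guide ids in ", path)
  if (is.null(df$pam_side)) df$pam_side <- "downstream"
  guides <- lapply(seq_len(nrow(df)), function(i) {
    g <- guide_target(df$id[i], df$start[i], df$end[i],
                      strand = df$strand[i], pam_side = df$pam_side[i],
                      spacer_length = df$end[i] - df$start[i] + 1L,
                      convention = convention)
    if (!is.null(reference)) validate_guide(g, reference)
    g
  })
  stats::setNames(guides, df$id)
}

validate_guide <- function(guide, reference) {
  stopifnot(inherits(guide, "guide_target"),
            inherits(reference, "reference_region"))
  if (guide$start < 1L || guide$end > reference$length) {
    stop(sprintf("guide %s (%d-%d) outside reference %s (1-%d)",
                 guide$id, guide$start, guide$end,
                 reference$name, reference$length))
  }
  invisible(guide)
}

#' Window around a guide target
#'
#' The protospacer interval widened by `margin` nt on each side and clipped
#' to the reference (when supplied). Membership of mutations "within N nt of
#' the target" is evaluated against this interval.
#'
#' @param guide A [guide_target()].
#' @param margin Non-negative margin in nt; `margin = 0` is the protospacer
#'   itself.
#' @param reference Optional [reference_region()] used for clipping.
#' @return Integer vector `c(start, end)`.
#' @export
guide_window <- function(guide, margin = 0L, reference = NULL) {
  stopifnot(inherits(guide, "guide_target"), margin >= 0L)
  w <- c(guide$start - as.integer(margin), guide$end + as.integer(margin))
  if (!is.null(reference)) {
    w <- c(max(1L, w[1]), min(reference$length, w[2]))
  } else {
    w[1] <- max(1L, w[1])
  }
  w
}

#' Does the non-target strand carry the coding base?
#'
#' `TRUE` when, under the guide's strand convention, the displaced
#' (non-target) strand of the R-loop is the coding strand, so that
#' non-target-strand bases read directly off the reference.
#'
#' @param guide A [guide_target()].
#' @return Logical scalar.
#' @export
non_target_is_coding <- function(guide) {
  stopifnot(inherits(guide, "guide_target"))
  if (guide$convention == "protospacer") guide$strand == "NTS"
  else guide$strand == "TS"
}

#' Base on the non-target strand
#'
#' Returns the base at a coding position as read on the physical non-target
#' (displaced, single-stranded) strand of the guide-induced R-loop: the
#' coding base itself when the non-target strand is the coding strand, its
#' complement otherwise. Cytosines returned here are the residues vulnerable
#' to deamination while single-stranded.
#'
#' @param guide A [guide_target()].
#' @param pos Coding position(s), 1-based.
#' @param reference A [reference_region()].
#' @return Character vector of bases on the non-target strand.
#' @examples
#' ref <- reference_region("toy", paste(rep("ACGT", 10), collapse = ""))
#' g <- guide_target("g", 11, 30, strand = "TS")
#' non_target_base(g, 14, ref)  # coding T -> non-target strand A
#' @export
non_target_base <- function(guide, pos, reference) {
  b <- ref_base(reference, pos)
  if (non_target_is_coding(guide)) b else complement_base(b)
}
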