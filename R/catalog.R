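#' Read a catalog of reporter-inactivating substitutions
#'
#' The catalog lists coding-strand single-nucleotide substitutions known to
#' abolish reporter function (e.g. derived from large sets of sequenced
#' deaminase-induced resistant mutants). It is an input to the scorer, not
#' something this package derives. Columns: `position`, `ref`, `alt`, and
#' optionally `source`. The package ships a small synthetic example catalog
#' (`inactivating_catalog_synthetic.tsv`).
#'
#' @param path TSV path.
#' @param reference Optional [reference_region()]; catalog `ref` bases must
#'   match it.
#' @return Data frame of class `inactivating_catalog` with unique
#'   (position, ref, alt) rows.
#' @export
read_inactivating_catalog <- function(path, reference = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("catalog TSV must have columns: ", paste(need, collapse = ", "))
  }
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  df <- df[!duplicated(df[, need]), , drop = FALSE]
  if (!is.null(reference)) {
    obs <- ref_base(reference, df$position)
    bad <- which(obs != df$ref)
    if (length(bad) > 0) {
      stop("catalog reference mismatch at position(s): ",
           paste(df$position[bad], collapse = ", "))
    }
  }
  structure(df, class = c("inactivating_catalog", "data.frame"))
}

#' Potential inactivating cytosines in a guide's non-target strand
#'
#' Counts protospacer positions whose non-target-strand base is C and for
#' which at least one configured deamination outcome is a cataloged
#' inactivating substitution. Outcomes are expressed on the non-target
#' strand (`C>T` for direct replication over uracil; `C>G` and `C>A` from
#' processing of the uracil lesion) and translated back to coding-strand
#' substitutions through the guide's strand convention before catalog
#' lookup: under a guide whose non-target strand is the template strand,
#' non-target `C>T` corresponds to coding `G>A`.
#'
#' @param guide A [guide_target()].
#' @param reference A [reference_region()].
#' @param catalog An [read_inactivating_catalog()] data frame.
#' @param outcomes Deamination outcomes considered, a subset of
#'   `c("C>T", "C>G", "C>A")`. Restricting to `"C>T"` models the uracil-
#'   glycosylase-deficient (ung1) regime in which only direct C>T outcomes
#'   arise.
#' @return List with `count` and `positions` (coding positions).
#' @export
potential_inactivating_cytosines <- function(guide, reference, catalog,
                                             outcomes = c("C>T", "C>G", "C>A")) {
  stopifnot(inherits(guide, "guide_target"),
            inherits(reference, "reference_region"))
  outcomes <- match.arg(outcomes, c("C>T", "C>G", "C>A"),
                        several.ok = TRUE)
  validate_guide(guide, reference)
  coding_nt <- non_target_is_coding(guide)
  alts_nt <- sub("^C>", "", outcomes)
  pos_hits <- integer(0)
  for (p in guide$start:guide$end) {
    if (non_target_base(guide, p, reference) != "C") next
    coding_ref <- ref_base(reference, p)  # C if coding NT strand, else G
    coding_alts <- if (coding_nt) alts_nt else complement_base(alts_nt)
    hit <- any(catalog$position == p & catalog$ref == coding_ref &
                 catalog$alt %in% coding_alts)
    if (hit) pos_hits <- c(pos_hits, p)
  }
  list(count = length(pos_hits), positions = pos_hits)
}

#' Score and rank guides by inactivating-cytosine count
#'
#' Applies [potential_inactivating_cytosines()] to each guide and returns a
#' table sorted by count (descending), ties keeping input order.
#'
#' @param guides List of [guide_target()] objects.
#' @param reference A [reference_region()].
#' @param catalog Catalog data frame.
#' @param outcomes Passed through to the scorer.
#' @return Data frame with columns `guide`, `strand`, `count`, `positions`
#'   (comma-separated string).
#' @export
rank_guides <- function(guides, reference, catalog,
                        outcomes = c("C>T", "C>G", "C>A")) {
  res <- lapply(guides, potential_inactivating_cytosines,
                reference = reference, catalog = catalog,
                outcomes = outcomes)
  df <- data.frame(
    guide = vapply(guides, function(g) g$id, ""),
    strand = vapply(guides, function(g) g$strand, ""),
    count = vapply(res, function(r) r$count, 0L),
    positions = vapply(res, function(r) paste(r$positions, collapse = ","),
                       ""),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$count, seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  df
}
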