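#' Is any event of an isolate within a window of the guide target?
#'
#' An isolate is "in window" at margin m when at least one of its events
#' intersects the protospacer widened by m nt on each side. Substitutions
#' and deletions intersect via their [start, end] interval; insertions are
#' located at their anchor position.
#'
#' @param events Event data frame of one isolate (see [parse_mutation()]).
#' @param guide A [guide_target()].
#' @param margin Margin in nt (>= 0).
#' @param reference Optional [reference_region()] for window clipping.
#' @return Logical scalar.
#' @export
in_window <- function(events, guide, margin = 0L, reference = NULL) {
  w <- guide_window(guide, margin, reference)
  any(events$start <= w[2] & events$end >= w[1])
}

event_in_interval <- function(events, w) {
  events$start <= w[2] & events$end >= w[1]
}

#' Is an isolate's mutation complex?
#'
#' A complex mutation is two or more mutation events lying within
#' `distance` nt of each other in a single isolate — the signature of
#' translesion synthesis by DNA polymerase zeta. The inter-event distance is
#' the gap between nearest endpoints (`later$start - earlier$end`), and
#' clustering is transitive: a chain a-b-c in which consecutive gaps are
#' within `distance` counts as one cluster even if a and c are further
#' apart.
#'
#' @param events Event data frame of one isolate.
#' @param distance Clustering threshold in nt (default 10).
#' @return Logical scalar: `TRUE` if any cluster holds >= 2 events.
#' @examples
#' is_complex(parse_mutation("282T>A, 286-287del"))
#' is_complex(parse_mutation("259G>T"))
#' @export
is_complex <- function(events, distance = 10L) {
  n <- nrow(events)
  if (n < 2L) return(FALSE)
  ev <- events[order(events$start, events$end), , drop = FALSE]
  max_end <- ev$end[1]
  for (i in 2:n) {
    if (ev$start[i] - max_end <= distance) return(TRUE)
    max_end <- max(max_end, ev$end[i])
  }
  FALSE
}

#' Summarize a mutation spectrum against a guide target
#'
#' Produces the per-guide tallies used throughout the package: isolate
#' counts inside windows of several margins, event-class counts, the
#' substitution spectrum re-expressed on the physical non-target strand of
#' the R-loop, complex-mutation counts, single-nt indels at homopolymer
#' runs, and per-position / per-codon mutation counts.
#'
#' Counting rules: window membership is per isolate (an isolate with two
#' in-target events counts once); event-class and spectrum tallies are per
#' event; per-position counts increment every position covered by a
#' multi-nt event (each mutated nucleotide counts individually); codons are
#' `ceiling(pos / 3)`. Substitutions inside the protospacer (margin 0) are
#' re-expressed on the non-target strand via [non_target_base()] before
#' being tallied into the spectrum, so a coding-strand G>A under a guide
#' whose non-target strand is the template strand is counted as C>T.
#'
#' @param table A [mutation_table()] whose rows derive from `guide` (or a
#'   control table with `guide = NULL`, in which case window statistics are
#'   omitted).
#' @param guide A [guide_target()] or `NULL`.
#' @param reference A [reference_region()].
#' @param margins Integer vector of window margins to tabulate.
#' @param complex_distance Clustering threshold for [is_complex()].
#' @param min_run Minimum homopolymer run length for the indel tally.
#' @return An object of class `spectrum_summary`; see Details.
#' @export
summarize_spectrum <- function(table, guide, reference,
                               margins = c(0L, 2L, 10L),
                               complex_distance = 10L, min_run = 6L) {
  stopifnot(inherits(table, "mutation_table"),
            inherits(reference, "reference_region"))
  if (!is.null(guide)) validate_guide(guide, reference)
  n_iso <- nrow(table)
  events_per_iso <- table$events
  n_events <- sum(vapply(events_per_iso, nrow, 0L))

  complex_iso <- vapply(events_per_iso, is_complex,
                        logical(1), distance = complex_distance)

  class_count <- function(evs) {
    k <- unlist(lapply(evs, function(e) e$kind))
    c(substitution = sum(k == "substitution"),
      insertion = sum(k == "insertion"),
      deletion = sum(k == "deletion"))
  }

  out <- list(
    guide_id = if (is.null(guide)) NA_character_ else guide$id,
    n_isolates = n_iso,
    n_events = n_events,
    classes_all = class_count(events_per_iso),
    n_complex = sum(complex_iso),
    convention = if (is.null(guide)) NA_character_ else guide$convention,
    margins = margins,
    complex_distance = complex_distance,
    min_run = min_run
  )

  # per-position and per-codon counts: each covered nucleotide counts once
  pos_counts <- integer(reference$length)
  for (evs in events_per_iso) {
    for (j in seq_len(nrow(evs))) {
      span <- evs$start[j]:evs$end[j]
      pos_counts[span] <- pos_counts[span] + 1L
    }
  }
  nz <- which(pos_counts > 0L)
  out$per_position <- data.frame(pos = nz, count = pos_counts[nz])
  if (length(nz) > 0L) {
    out$per_codon <- stats::aggregate(
      list(count = pos_counts[nz]), by = list(codon = ceiling(nz / 3)),
      FUN = sum)
  } else {
    out$per_codon <- data.frame(codon = integer(), count = integer())
  }

  if (!is.null(guide)) {
    out$n_in_window <- vapply(margins, function(m) {
      sum(vapply(events_per_iso, in_window, logical(1),
                 guide = guide, margin = m, reference = reference))
    }, integer(1))
    names(out$n_in_window) <- as.character(margins)

    w0 <- guide_window(guide, 0L, reference)
    in_target_iso <- vapply(events_per_iso, in_window, logical(1),
                            guide = guide, margin = 0L, reference = reference)
    target_events <- lapply(events_per_iso, function(e) {
      e[event_in_interval(e, w0), , drop = FALSE]
    })
    out$classes_in_target <- class_count(target_events)
    out$n_complex_in_target <- sum(complex_iso & in_target_iso)

    # strand-resolved substitution spectrum of in-target single-nt
    # substitutions, on the non-target strand
    spec <- c("C>T" = 0L, "C>G" = 0L, "C>A" = 0L, "A>G" = 0L, "other" = 0L)
    bases <- c("A", "C", "G", "T")
    full_keys <- as.vector(outer(bases, bases, function(a, b) paste0(a, ">", b)))
    full <- stats::setNames(integer(length(full_keys)), full_keys)
    n_target_events <- 0L
    n_target_sub_at_C <- 0L
    coding_nt <- non_target_is_coding(guide)
    for (evs in target_events) {
      n_target_events <- n_target_events + nrow(evs)
      for (j in seq_len(nrow(evs))) {
        e <- evs[j, ]
        if (e$kind != "substitution" || e$start != e$end) next
        ref_nt <- if (coding_nt) e$ref else complement_base(e$ref)
        alt_nt <- if (coding_nt) e$alt else complement_base(e$alt)
        key <- paste0(ref_nt, ">", alt_nt)
        if (key %in% names(spec)) spec[key] <- spec[key] + 1L
        else spec["other"] <- spec["other"] + 1L
        full[key] <- full[key] + 1L
        if (ref_nt == "C") n_target_sub_at_C <- n_target_sub_at_C + 1L
      }
    }
    out$spectrum_non_target <- spec
    out$spectrum_full <- full[sub(">.*", "", names(full)) !=
                                sub(".*>", "", names(full))]
    out$n_in_target_events <- n_target_events
    out$n_in_target_sub_at_C <- n_target_sub_at_C
    out$homopolymer_indels <- homopolymer_indel_count(
      table, guide, reference, min_run = min_run)
  }
  structure(out, class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> guide %s: %d isolates, %d events\n",
              x$guide_id, x$n_isolates, x$n_events))
  if (!is.null(x$n_in_window)) {
    cat("  in window (margin -> isolates):",
        paste(names(x$n_in_window), x$n_in_window, sep = ":",
              collapse = "  "), "\n")
    cat("  complex:", x$n_complex,
        sprintf("(%d in target)", x$n_complex_in_target), "\n")
    cat("  non-target-strand substitution spectrum:",
        paste(names(x$spectrum_non_target), x$spectrum_non_target,
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Fraction of in-target mutation events at non-target-strand cytosines
#'
#' The numerator counts in-target single-nucleotide substitution events
#' whose reference base on the non-target strand is C (the deamination-
#' compatible events); the denominator is all in-target mutation events,
#' including indels. Both are reported alongside the fraction.
#'
#' @param summary A [summarize_spectrum()] result computed with a guide.
#' @return List with `numerator`, `denominator`, `fraction` (`NA` with a
#'   warning when the denominator is zero).
#' @export
deamination_fraction <- function(summary) {
  stopifnot(inherits(summary, "spectrum_summary"))
  if (is.null(summary$n_in_target_events)) {
    stop("summary was computed without a guide; no target to evaluate")
  }
  num <- summary$n_in_target_sub_at_C
  den <- summary$n_in_target_events
  if (den == 0L) {
    warning("no in-target events: deamination fraction undefined")
    return(list(numerator = 0L, denominator = 0L, fraction = NA_real_))
  }
  list(numerator = num, denominator = den, fraction = num / den)
}

#' One-sided binomial enrichment test for cytosine-biased mutation placement
#'
#' Formalizes the composition argument that an observed concentration of
#' mutations at non-target-strand cytosines is not explained by base
#' composition alone: under the null, each of `n_total` events falls on a C
#' independently with probability `c_fraction` (the C fraction of the
#' window), and the p-value is the exact upper tail P(X >= n_at_C).
#'
#' @param n_at_C Observed events at non-target-strand cytosines.
#' @param n_total Total events considered.
#' @param c_fraction Fraction of window positions that are C on the
#'   non-target strand.
#' @return Exact one-sided p-value.
#' @examples
#' composition_enrichment(10, 14, 0.30)
#' @export
composition_enrichment <- function(n_at_C, n_total, c_fraction) {
  stopifnot(n_at_C >= 0, n_at_C <= n_total,
            c_fraction >= 0, c_fraction <= 1)
  stats::pbinom(n_at_C - 1, n_total, c_fraction, lower.tail = FALSE)
}

#' Count isolates with single-nt indels at a homopolymer run in the target
#'
#' Counts in-target isolates carrying a 1-nt insertion or deletion anchored
#' inside — or, for insertions, immediately 5' of — a homopolymer run of at
#' least `min_run` nt that overlaps the protospacer. (An insertion anchored
#' at `run_start - 1` inserts between that base and the first run base, so
#' it is treated as within the run.)
#'
#' @param table A [mutation_table()].
#' @param guide A [guide_target()].
#' @param reference A [reference_region()].
#' @param min_run Minimum run length (default 6).
#' @return Integer count of isolates.
#' @export
homopolymer_indel_count <- function(table, guide, reference, min_run = 6L) {
  stopifnot(inherits(table, "mutation_table"))
  runs <- find_homopolymers(reference, min_run = min_run)
  w0 <- guide_window(guide, 0L, reference)
  runs <- runs[runs$start <= w0[2] & runs$end >= w0[1], , drop = FALSE]
  if (nrow(runs) == 0L) return(0L)
  hits <- vapply(table$events, function(evs) {
    if (!in_window(evs, guide, 0L, reference)) return(FALSE)
    for (j in seq_len(nrow(evs))) {
      e <- evs[j, ]
      one_del <- e$kind == "deletion" && e$start == e$end
      one_ins <- e$kind == "insertion" && e$insert_length == 1L
      if (!one_del && !one_ins) next
      lo <- if (one_ins) runs$start - 1L else runs$start
      if (any(e$start >= lo & e$start <= runs$end)) return(TRUE)
    }
    FALSE
  }, logical(1))
  sum(hits)
}
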