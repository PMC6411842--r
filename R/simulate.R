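#' Configuration for the forward simulator
#'
#' Describes the generative model used to emulate a reporter-gene
#' mutagenesis experiment. Each simulated isolate carries exactly one
#' inactivating mutation "cause": with probability `p_target` a
#' target-associated event at the guide, otherwise a dispersed background
#' event. Target-associated events fall into four classes:
#'
#' * `deamination` — a single-nucleotide substitution at a non-target-strand
#'   cytosine of the protospacer, with outcome drawn from
#'   `deamination_probs` (`C>T` from replication over uracil; `C>G`/`C>A`
#'   from processing of the uracil lesion);
#' * `homopolymer_indel` — a 1-nt insertion or deletion anchored in a
#'   homopolymer run (>= `min_run` nt) overlapping the protospacer;
#' * `complex` — two events within `complex_max_offset` nt of each other,
#'   emulating translesion-synthesis mutation clusters;
#' * `other_indel` — a short (1-3 nt) deletion or 1-nt insertion in the
#'   protospacer.
#'
#' Genotype toggles modify the model the way the corresponding repair
#' deficiencies act: `ung1 = TRUE` (no uracil glycosylase) collapses the
#' deamination outcomes to pure C>T; `rev3 = TRUE` (no polymerase zeta)
#' sets the complex-class probability to zero, redistributing its weight
#' proportionally over the remaining classes.
#'
#' Background events are drawn uniformly over a supplied inactivating
#' catalog when one is given, otherwise uniformly over the gene.
#'
#' @param reference A [reference_region()].
#' @param guide A [guide_target()].
#' @param n_isolates Number of isolates to simulate.
#' @param p_target Probability an isolate's mutation is target-associated.
#' @param class_probs Named probabilities over the four target classes;
#'   must sum to 1.
#' @param deamination_probs Named probabilities over `C>T`, `C>G`, `C>A`;
#'   must sum to 1.
#' @param genotype Genotype label written into the table.
#' @param ung1,rev3 Genotype toggles, see Details.
#' @param background_catalog Optional [read_inactivating_catalog()] data
#'   frame for background positions.
#' @param complex_max_offset Maximum offset of the secondary event of a
#'   complex cluster (default 10 nt, matching the clustering definition).
#' @param min_run Minimum homopolymer run length (default 6).
#' @param frequency Optional data frame describing a plating assay for
#'   [simulate_frequency_assay()]: columns `group`, `true_frequency`,
#'   `n_cultures`, and optionally `cells` (resuspended cells per culture,
#'   default 2e7), `d_selective`, `d_nonselective` (fold-dilution of the
#'   plated aliquots, defaults 10 and 1e5).
#' @param seed Integer RNG seed; identical seeds reproduce outputs exactly.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(reference, guide, n_isolates = 21L,
                              p_target = 0.76,
                              class_probs = c(deamination = 0.6,
                                              homopolymer_indel = 0.1,
                                              complex = 0.15,
                                              other_indel = 0.15),
                              deamination_probs = c("C>T" = 0.6,
                                                    "C>G" = 0.2,
                                                    "C>A" = 0.2),
                              genotype = "WT", ung1 = FALSE, rev3 = FALSE,
                              background_catalog = NULL,
                              complex_max_offset = 10L, min_run = 6L,
                              frequency = NULL, seed = 1L) {
  stopifnot(inherits(reference, "reference_region"),
            inherits(guide, "guide_target"),
            p_target >= 0, p_target <= 1, n_isolates >= 0)
  validate_guide(guide, reference)
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " must be non-negative and sum to 1")
    }
  }
  check_probs(class_probs, "class_probs")
  check_probs(deamination_probs, "deamination_probs")
  need <- c("deamination", "homopolymer_indel", "complex", "other_indel")
  if (!all(need %in% names(class_probs))) {
    stop("class_probs must be named: ", paste(need, collapse = ", "))
  }
  class_probs <- class_probs[need]

  if (ung1) deamination_probs <- c("C>T" = 1, "C>G" = 0, "C>A" = 0)
  if (rev3) {
    class_probs["complex"] <- 0
    if (sum(class_probs) == 0) stop("all class probabilities zero after rev3")
    class_probs <- class_probs / sum(class_probs)
  }

  # feasibility of the target classes against this guide
  c_pos <- which(vapply(guide$start:guide$end, function(p) {
    non_target_base(guide, p, reference) == "C"
  }, logical(1))) + guide$start - 1L
  if (length(c_pos) == 0 && p_target > 0 && class_probs["deamination"] > 0) {
    stop("guide ", guide$id, " has no non-target-strand C in its ",
         "protospacer but deamination probability is > 0")
  }
  runs <- find_homopolymers(reference, min_run = min_run)
  w0 <- guide_window(guide, 0L, reference)
  runs <- runs[runs$start <= w0[2] & runs$end >= w0[1], , drop = FALSE]
  if (nrow(runs) == 0 && class_probs["homopolymer_indel"] > 0) {
    warning("no homopolymer run (>= ", min_run, " nt) overlaps guide ",
            guide$id, ": homopolymer weight redistributed to other_indel")
    class_probs["other_indel"] <- class_probs["other_indel"] +
      class_probs["homopolymer_indel"]
    class_probs["homopolymer_indel"] <- 0
  }

  structure(
    list(reference = reference, guide = guide,
         n_isolates = as.integer(n_isolates), p_target = p_target,
         class_probs = class_probs, deamination_probs = deamination_probs,
         genotype = genotype, ung1 = ung1, rev3 = rev3,
         background_catalog = background_catalog,
         complex_max_offset = as.integer(complex_max_offset),
         min_run = as.integer(min_run),
         c_positions = c_pos, runs = runs,
         frequency = frequency, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

rand_alt <- function(ref_base_chr) {
  sample(setdiff(c("A", "C", "G", "T"), ref_base_chr), 1)
}

#' Simulate a table of sequenced resistant isolates
#'
#' Draws `n_isolates` isolate records from the generative model of a
#' [simulation_config()]. Every isolate is resistant by construction (one
#' inactivating event, plus a second event for complex clusters); fitness
#' and lethality are not modeled. The output round-trips through the
#' notation parser and table reader/writer.
#'
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [mutation_table()].
#' @export
simulate_isolates <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  ref <- config$reference; guide <- config$guide
  coding_nt <- non_target_is_coding(guide)
  classes <- names(config$class_probs)

  one_isolate <- function() {
    if (stats::runif(1) < config$p_target) {
      cls <- sample(classes, 1, prob = config$class_probs)
      if (cls == "deamination") {
        p <- if (length(config$c_positions) == 1) config$c_positions
             else sample(config$c_positions, 1)
        out <- sample(names(config$deamination_probs), 1,
                      prob = config$deamination_probs)
        alt_nt <- sub("^C>", "", out)
        if (coding_nt) ev <- event_row("substitution", p, p, "C", alt_nt)
        else ev <- event_row("substitution", p, p, "G",
                             complement_base(alt_nt))
        return(ev)
      }
      if (cls == "homopolymer_indel") {
        run <- config$runs[sample(nrow(config$runs), 1), ]
        anchor <- sample(run$start:run$end, 1)
        if (stats::runif(1) < 0.5) {
          return(event_row("deletion", anchor, anchor,
                           ref = ref_base(ref, anchor)))
        }
        return(event_row("insertion", anchor, anchor, alt = run$base,
                         insert_length = 1L))
      }
      if (cls == "complex") {
        p1 <- sample(guide$start:guide$end, 1)
        off <- sample(seq_len(config$complex_max_offset), 1) *
          sample(c(-1L, 1L), 1)
        p2 <- min(max(p1 + off, 1L), ref$length)
        if (p2 == p1) p2 <- p1 + 1L
        e1 <- event_row("substitution", p1, p1, ref_base(ref, p1),
                        rand_alt(ref_base(ref, p1)))
        e2 <- event_row("substitution", p2, p2, ref_base(ref, p2),
                        rand_alt(ref_base(ref, p2)))
        return(rbind(e1, e2))
      }
      # other_indel
      if (stats::runif(1) < 0.5) {
        len <- sample(1:3, 1)
        s <- sample(guide$start:guide$end, 1)
        e <- min(s + len - 1L, ref$length)
        return(event_row("deletion", s, e,
                         ref = substring(ref$sequence, s, e)))
      }
      s <- sample(guide$start:guide$end, 1)
      return(event_row("insertion", s, s, alt = sample(c("A","C","G","T"), 1),
                       insert_length = 1L))
    }
    # background
    if (!is.null(config$background_catalog)) {
      row <- config$background_catalog[
        sample(nrow(config$background_catalog), 1), ]
      return(event_row("substitution", row$position, row$position,
                       row$ref, row$alt))
    }
    p <- sample(ref$length, 1)
    event_row("substitution", p, p, ref_base(ref, p),
              rand_alt(ref_base(ref, p)))
  }

  notations <- vapply(seq_len(config$n_isolates), function(i) {
    format_mutation(one_isolate())
  }, character(1))
  mutation_table(sprintf("sim_%04d", seq_len(config$n_isolates)),
                 guide$id, config$genotype, notations,
                 reference = ref, source = "simulated")
}

#' Simulate colony counts for a plating assay
#'
#' Each culture is a suspension of `cells` cells of which a fraction `f`
#' (the group's true frequency) is mutant; aliquots diluted `d_selective`-
#' and `d_nonselective`-fold are plated, so colony counts are Poisson:
#' `n_selective ~ Pois(cells * f / d_selective)` and
#' `n_nonselective ~ Pois(cells / d_nonselective)`. Defaults (2e7 cells,
#' dilutions 10 and 1e5) give ~20 selective and ~200 nonselective colonies
#' at f = 1e-5, typical well-plated counts for such an assay.
#'
#' @param design A [simulation_config()] with a `frequency` block, or the
#'   design data frame itself (columns `group`, `true_frequency`,
#'   `n_cultures`, and optional plating columns; see
#'   [simulation_config()]).
#' @param seed Integer seed (overrides `config$seed` when a config is
#'   given).
#' @return Plating data frame in the [read_plating()] dialect.
#' @export
simulate_frequency_assay <- function(design, seed = NULL) {
  if (inherits(design, "simulation_config")) {
    if (is.null(seed)) seed <- design$seed
    design <- design$frequency
    if (is.null(design)) stop("simulation_config has no frequency block")
  }
  if (is.null(seed)) seed <- 1L
  stopifnot(is.data.frame(design),
            all(c("group", "true_frequency", "n_cultures") %in% names(design)))
  defaults <- list(cells = 2e7, d_selective = 10, d_nonselective = 1e5)
  for (nm in names(defaults)) {
    if (is.null(design[[nm]])) design[[nm]] <- defaults[[nm]]
  }
  set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    data.frame(
      culture_id = sprintf("%s_c%02d", d$group, seq_len(d$n_cultures)),
      group = d$group,
      n_selective = stats::rpois(d$n_cultures,
                                 d$cells * d$true_frequency / d$d_selective),
      d_selective = d$d_selective,
      n_nonselective = stats::rpois(d$n_cultures,
                                    d$cells / d$d_nonselective),
      d_nonselective = d$d_nonselective,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
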