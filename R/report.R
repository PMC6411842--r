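#' Paths to packaged example data
#'
#' Convenience accessor for the files under `extdata`: a synthetic 1773-nt
#' reporter coding sequence (`reference`), a synthetic guide table
#' (`guides`), the published 19-isolate mutation table for the first guide
#' (`table1`), a synthetic supplementary-style isolate list for three
#' further guides (`supplementary`), and a synthetic inactivating-
#' substitution catalog (`catalog`). All synthetic files are labelled as
#' such in their filenames; only `table1` transcribes published data.
#'
#' @param which One of `"reference"`, `"guides"`, `"table1"`,
#'   `"supplementary"`, `"catalog"`.
#' @return File path.
#' @export
dcas9mut_example <- function(which = c("reference", "guides", "table1",
                                       "supplementary", "catalog")) {
  which <- match.arg(which)
  file <- switch(which,
    reference = "reporter_cds_synthetic.fasta",
    guides = "guides_synthetic.tsv",
    table1 = "sgRNA1_table1.tsv",
    supplementary = "isolates_supplementary_synthetic.tsv",
    catalog = "inactivating_catalog_synthetic.tsv")
  system.file("extdata", file, package = "dcas9mut", mustWork = TRUE)
}

summary_as_list <- function(s) {
  out <- list(
    guide_id = s$guide_id,
    n_isolates = s$n_isolates,
    n_events = s$n_events,
    classes_all = as.list(s$classes_all),
    n_complex = s$n_complex,
    parameters = list(convention = s$convention,
                      margins = s$margins,
                      complex_distance = s$complex_distance,
                      min_run = s$min_run)
  )
  if (!is.null(s$n_in_window)) {
    out$n_in_window <- as.list(s$n_in_window)
    out$classes_in_target <- as.list(s$classes_in_target)
    out$n_complex_in_target <- s$n_complex_in_target
    out$spectrum_non_target <- as.list(s$spectrum_non_target)
    df <- deamination_fraction(s)
    out$deamination <- list(numerator = df$numerator,
                            denominator = df$denominator,
                            fraction = if (is.na(df$fraction)) NULL
                                       else signif(df$fraction, 3))
    out$homopolymer_indels <- s$homopolymer_indels
  }
  out
}

#' Spectrum report over a mutation table
#'
#' Runs [summarize_spectrum()] (plus [deamination_fraction()] and
#' [homopolymer_indel_count()]) for every guide present in a mutation table
#' and writes, per guide, a JSON summary, a per-position count TSV (BED-like
#' `pos`/`count`) and a per-codon count TSV. Every report embeds the strand
#' convention, margins and thresholds used.
#'
#' @param table A [mutation_table()] (or TSV path).
#' @param guides Named list from [read_guides()] (or TSV path).
#' @param reference A [reference_region()] (or FASTA path).
#' @param out_dir Output directory, created if missing.
#' @param margins,complex_distance,min_run Passed to [summarize_spectrum()].
#' @return Named list of `spectrum_summary` objects, invisibly.
#' @export
run_spectrum <- function(table, guides, reference, out_dir,
                         margins = c(0L, 2L, 10L), complex_distance = 10L,
                         min_run = 6L) {
  if (is.character(reference)) reference <- read_reference_fasta(reference)
  if (is.character(guides)) guides <- read_guides(guides, reference)
  if (is.character(table)) table <- read_mutation_table(table, reference)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  guide_ids <- unique(table$guide_id)
  res <- list()
  for (gid in guide_ids) {
    sub <- table[table$guide_id %in% gid, , drop = FALSE]
    class(sub) <- class(table)
    attr(sub, "source") <- attr(table, "source")
    g <- if (is.na(gid)) NULL else guides[[gid]]
    if (!is.na(gid) && is.null(g)) {
      stop("guide id in table but not in guide set: ", gid)
    }
    s <- summarize_spectrum(sub, g, reference, margins = margins,
                            complex_distance = complex_distance,
                            min_run = min_run)
    tag <- if (is.na(gid)) "no_guide" else gid
    jsonlite::write_json(summary_as_list(s),
                         file.path(out_dir, paste0(tag, "_summary.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    utils::write.table(s$per_position,
                       file.path(out_dir, paste0(tag, "_per_position.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(s$per_codon,
                       file.path(out_dir, paste0(tag, "_per_codon.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res[[tag]] <- s
  }
  invisible(res)
}

#' Frequency report over plating measurements
#'
#' Per-group median frequencies (3 significant digits), fold changes versus
#' a named reference group, and pairwise exact two-tailed Mann-Whitney
#' p-values (4 decimals, with the method used recorded per pair). Written
#' as JSON plus a TSV of group summaries.
#'
#' @param plating Plating data frame (or TSV path, see [read_plating()]).
#' @param out_dir Output directory.
#' @param reference_group Optional group name for fold changes.
#' @return List with `summary`, `folds`, `tests`, invisibly.
#' @export
run_frequency <- function(plating, out_dir, reference_group = NULL) {
  if (is.character(plating)) plating <- read_plating(plating)
  if (is.null(plating$frequency)) {
    plating$frequency <- mutation_frequency(
      plating$n_selective, plating$d_selective,
      plating$n_nonselective, plating$d_nonselective,
      culture_id = plating$culture_id)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- frequency_summary(plating$frequency, plating$group)
  folds <- NULL
  if (!is.null(reference_group)) {
    folds <- data.frame(
      group = summ$group,
      fold_vs_reference = vapply(summ$group, function(g) {
        fold_change(summ, g, reference_group)
      }, 0),
      stringsAsFactors = FALSE)
  }
  tests <- NULL
  if (nrow(summ) > 1) {
    pairs <- utils::combn(summ$group, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]; b <- pairs[2, k]
      t <- mann_whitney_exact(plating$frequency[plating$group == a],
                              plating$frequency[plating$group == b])
      data.frame(group_a = a, group_b = b, U = t$U,
                 p = round(t$p, 4), method = t$method,
                 stringsAsFactors = FALSE)
    }))
  }
  report <- list(
    groups = lapply(seq_len(nrow(summ)), function(i) {
      list(group = summ$group[i], n = summ$n[i],
           median = signif(summ$median[i], 3))
    }),
    fold_changes = folds,
    pairwise_tests = tests,
    parameters = list(summary_statistic = "median",
                      test = "exact two-tailed Mann-Whitney U",
                      reference_group = reference_group)
  )
  jsonlite::write_json(report, file.path(out_dir, "frequency_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(summ, file.path(out_dir, "frequency_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(summary = summ, folds = folds, tests = tests))
}

#' Simulate a dataset to disk
#'
#' Writes the simulated mutation table and plating TSVs, plus a sidecar
#' JSON recording seed, package version and strand convention.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tab <- simulate_isolates(config)
  p <- file.path(out_dir, "simulated_isolates.tsv")
  write_mutation_table(tab, p)
  paths <- c(paths, p)
  if (!is.null(config$frequency)) {
    plat <- simulate_frequency_assay(config)
    p <- file.path(out_dir, "simulated_plating.tsv")
    utils::write.table(plat, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dcas9mut")),
    guide = config$guide$id,
    convention = config$guide$convention,
    p_target = config$p_target,
    class_probs = as.list(config$class_probs),
    deamination_probs = as.list(config$deamination_probs),
    genotype = list(label = config$genotype, ung1 = config$ung1,
                    rev3 = config$rev3)
  )
  mp <- file.path(out_dir, "simulation_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
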