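base_config <- function(...) {
  simulation_config(fx_ref, fx_guides$sgRNA2, seed = 101L, ...)
}

test_that("configuration validates probability vectors and feasibility", {
  expect_error(base_config(p_target = 1.2), "p_target")
  expect_error(base_config(class_probs = c(deamination = 0.5,
                                           homopolymer_indel = 0.2,
                                           complex = 0.2,
                                           other_indel = 0.2)),
               "sum to 1")
  expect_error(base_config(deamination_probs = c("C>T" = 0.5, "C>G" = 0.2,
                                                 "C>A" = 0.2)),
               "sum to 1")
  # guide with no non-target-strand C cannot host deamination events:
  # an all-A stretch on the coding strand of an NTS guide
  ref_a <- reference_region("allA",
                            paste(rep("A", 100), collapse = ""))
  g <- guide_target("gA", 11, 30, strand = "NTS")
  expect_error(simulation_config(ref_a, g), "no non-target-strand C")
  # but is accepted when deamination is switched off
  cfg <- simulation_config(
    ref_a, g,
    class_probs = c(deamination = 0, homopolymer_indel = 0,
                    complex = 0.5, other_indel = 0.5))
  expect_s3_class(cfg, "simulation_config")
})

test_that("a guide without a homopolymer run redistributes that weight", {
  expect_warning(cfg <- base_config(), "redistributed")
  expect_equal(unname(cfg$class_probs["homopolymer_indel"]), 0)
  expect_equal(sum(cfg$class_probs), 1)
})

test_that("the same seed reproduces tables and counts exactly", {
  cfg <- simulation_config(fx_ref, fx_guides$sgRNA6, n_isolates = 50,
                           seed = 77L)
  t1 <- simulate_isolates(cfg)
  t2 <- simulate_isolates(cfg)
  expect_identical(t1$mutations, t2$mutations)
  t3 <- simulate_isolates(cfg, seed = 78L)
  expect_false(identical(t1$mutations, t3$mutations))

  design <- data.frame(group = c("a", "b"), true_frequency = c(1e-5, 1e-7),
                       n_cultures = 6L)
  p1 <- simulate_frequency_assay(design, seed = 5L)
  p2 <- simulate_frequency_assay(design, seed = 5L)
  expect_identical(p1, p2)
})

test_that("degenerate mixtures behave as configured", {
  # p_target = 1 with pure deamination: every isolate has an in-window
  # substitution at a non-target-strand C
  cfg <- simulation_config(
    fx_ref, fx_guides$sgRNA2, n_isolates = 100, p_target = 1,
    class_probs = c(deamination = 1, homopolymer_indel = 0, complex = 0,
                    other_indel = 0), seed = 3L)
  tab <- simulate_isolates(cfg)
  g <- fx_guides$sgRNA2
  for (ev in tab$events) {
    expect_true(in_window(ev, g, 0, fx_ref))
    expect_equal(ev$kind, "substitution")
    expect_equal(non_target_base(g, ev$start, fx_ref), "C")
  }
  # p_target = 0: no preference for the window beyond chance
  suppressWarnings(
    cfg0 <- simulation_config(fx_ref, g, n_isolates = 400, p_target = 0,
                              seed = 31L))
  tab0 <- simulate_isolates(cfg0)
  frac <- mean(vapply(tab0$events, in_window, logical(1), guide = g,
                      margin = 0, reference = fx_ref))
  expect_lt(frac, 0.05)  # window is 20/1773 of the gene
})

test_that("simulated tables are valid and round-trip through the TSV dialect", {
  suppressWarnings(cfg <- base_config(n_isolates = 40))
  tab <- simulate_isolates(cfg)
  expect_s3_class(tab, "mutation_table")
  expect_equal(nrow(tab), 40L)
  expect_true(all(vapply(tab$events, nrow, 0L) >= 1L))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(tab, tmp)
  again <- read_mutation_table(tmp, fx_ref)
  expect_equal(again$mutations, tab$mutations)
})

test_that("the ung1 toggle collapses deamination outcomes to C>T", {
  cfg <- simulation_config(
    fx_ref, fx_guides$sgRNA2, n_isolates = 150, p_target = 1,
    class_probs = c(deamination = 1, homopolymer_indel = 0, complex = 0,
                    other_indel = 0),
    ung1 = TRUE, seed = 9L)
  s <- summarize_spectrum(simulate_isolates(cfg), fx_guides$sgRNA2, fx_ref)
  expect_gt(unname(s$spectrum_non_target["C>T"]), 0)
  expect_equal(unname(s$spectrum_non_target["C>G"]), 0L)
  expect_equal(unname(s$spectrum_non_target["C>A"]), 0L)
})

test_that("the rev3 toggle eliminates generated complex clusters", {
  cfg <- simulation_config(
    fx_ref, fx_guides$sgRNA6, n_isolates = 200, p_target = 1,
    class_probs = c(deamination = 0.4, homopolymer_indel = 0.2,
                    complex = 0.3, other_indel = 0.1),
    rev3 = TRUE, seed = 19L)
  tab <- simulate_isolates(cfg)
  expect_equal(sum(vapply(tab$events, is_complex, logical(1))), 0L)
  # and without the toggle the same settings do generate clusters
  cfg_wt <- simulation_config(
    fx_ref, fx_guides$sgRNA6, n_isolates = 200, p_target = 1,
    class_probs = c(deamination = 0.4, homopolymer_indel = 0.2,
                    complex = 0.3, other_indel = 0.1), seed = 19L)
  expect_gt(sum(vapply(simulate_isolates(cfg_wt)$events, is_complex,
                       logical(1))), 0L)
})

test_that("frequency assay counts are Poisson draws at the configured scale", {
  design <- data.frame(group = "z", true_frequency = 0, n_cultures = 8L)
  plat <- simulate_frequency_assay(design, seed = 2L)
  expect_true(all(plat$n_selective == 0))
  expect_true(all(plat$n_nonselective > 0))

  design2 <- data.frame(group = "g", true_frequency = 1e-5, n_cultures = 200L)
  plat2 <- simulate_frequency_assay(design2, seed = 12L)
  f <- mutation_frequency(plat2$n_selective, plat2$d_selective,
                          plat2$n_nonselective, plat2$d_nonselective)
  # mean of 200 per-culture estimates within 3 SE of the truth
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 1e-5), 3 * se + 1e-7)
})
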