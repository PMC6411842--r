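g1 <- fx_guides$sgRNA1

test_that("window membership matches the printed in-target annotations", {
  expect_true(in_window(parse_mutation("287T>A"), g1, 0, fx_ref))
  expect_false(in_window(parse_mutation("259G>T"), g1, 0, fx_ref))
  expect_true(in_window(parse_mutation("259G>T"), g1, 18, fx_ref))
  # insertion membership is by anchor
  expect_true(in_window(parse_mutation("296ins(T)"), g1, 0, fx_ref))
  expect_false(in_window(parse_mutation("297ins(T)"), g1, 0, fx_ref))
})

test_that("complex calls follow the two-events-within-10-nt rule", {
  expect_true(is_complex(parse_mutation("282T>A, 286–287del")))
  expect_true(is_complex(parse_mutation("287T>A, 289G>C")))
  expect_false(is_complex(parse_mutation("259G>T")))
  expect_false(is_complex(parse_mutation("100A>G, 150A>G")))
  # exactly at the threshold counts; one beyond does not
  expect_true(is_complex(parse_mutation("100A>G, 110C>T")))
  expect_false(is_complex(parse_mutation("100A>G, 111C>T")))
  # transitive chaining: a-b close, b-c close, a-c far
  chain <- parse_mutation("100A>G, 108C>T, 116G>A")
  expect_true(is_complex(chain))
})

test_that("in_window and is_complex agree with exhaustive oracles", {
  set.seed(11)
  g <- guide_target("g", 41, 60, strand = "NTS")
  for (i in 1:300) {
    ev <- random_events(sample(1:4, 1), max_pos = 120L)
    expect_equal(is_complex(ev), oracle_complex(ev))
    m <- sample(0:12, 1)
    expect_equal(in_window(ev, g, m),
                 oracle_in_window(ev, 41 - m, 60 + m))
  }
})

test_that("summary counts are internally consistent on the packaged table", {
  s <- summarize_spectrum(fx_table1, g1, fx_ref)
  expect_equal(s$n_isolates, 19L)
  expect_equal(s$n_events, 22L)
  expect_equal(sum(s$classes_all), 22L)
  expect_equal(unname(s$n_in_window["0"]), 9L)
  expect_equal(s$n_complex_in_target, 3L)
  # window counts non-decreasing in margin
  expect_true(all(diff(s$n_in_window[order(s$margins)]) >= 0))
  # per-position counts: 22 events, multi-nt deletions count each base
  expect_equal(sum(s$per_position$count), sum(s$per_codon$count))
  expect_equal(s$per_codon$codon, sort(unique(ceiling(s$per_position$pos / 3))))
})

test_that("flipping the strand designation complements the spectrum only", {
  tab <- subset_table(fx_supp, "sgRNA2")
  g <- fx_guides$sgRNA2
  g_flip <- guide_target(g$id, g$start, g$end,
                         strand = if (g$strand == "NTS") "TS" else "NTS",
                         pam_side = g$pam_side)
  s <- summarize_spectrum(tab, g, fx_ref)
  sf <- summarize_spectrum(tab, g_flip, fx_ref)
  comp_key <- function(k) {
    paste0(complement_base(substr(k, 1, 1)), ">",
           complement_base(substr(k, 3, 3)))
  }
  for (k in names(s$spectrum_full)) {
    expect_equal(unname(sf$spectrum_full[comp_key(k)]),
                 unname(s$spectrum_full[k]),
                 label = paste("flipped count for", k))
  }
  expect_equal(sf$n_in_window, s$n_in_window)
  expect_equal(sf$classes_all, s$classes_all)
  expect_equal(sf$n_complex, s$n_complex)
})

test_that("deamination fraction counts substitutions at non-target C over all in-target events", {
  # constructed: 4 C>T at coding C + 1 A>G, all inside an NTS-guide target
  g <- guide_target("g", 291, 310, strand = "NTS")
  tab <- mutation_table(paste0("i", 1:5), "g", "WT",
                        c("293C>T", "296C>T", "299C>T", "302C>T", "308A>G"),
                        reference = fx_ref)
  d <- deamination_fraction(summarize_spectrum(tab, g, fx_ref))
  expect_equal(d$numerator, 4L)
  expect_equal(d$denominator, 5L)
  expect_equal(d$fraction, 0.8)

  # all-deletion table: zero numerator, full denominator
  tab2 <- mutation_table(paste0("d", 1:3), "g", "WT",
                         c("293del", "296del", "300–301del"),
                         reference = fx_ref)
  d2 <- deamination_fraction(summarize_spectrum(tab2, g, fx_ref))
  expect_equal(d2$numerator, 0L)
  expect_equal(d2$denominator, 3L)

  # no in-target events: flagged undefined
  b100 <- ref_base(fx_ref, 100)
  tab3 <- mutation_table("x", "g", "WT",
                         paste0("100", b100, ">",
                                setdiff(c("A", "C", "G", "T"), b100)[1]),
                         reference = fx_ref)
  s3 <- summarize_spectrum(tab3, g, fx_ref)
  expect_warning(d3 <- deamination_fraction(s3), "undefined")
  expect_true(is.na(d3$fraction))
})

test_that("composition enrichment equals the direct binomial tail sum", {
  direct <- function(k, n, p) {
    sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
  }
  expect_equal(composition_enrichment(10, 14, 0.30), direct(10, 14, 0.30))
  set.seed(3)
  for (i in 1:25) {
    n <- sample(1:30, 1); k <- sample(0:n, 1); p <- runif(1)
    expect_equal(composition_enrichment(k, n, p), direct(k, n, p),
                 tolerance = 1e-12)
  }
  expect_equal(composition_enrichment(0, 9, 0.4), 1.0)
  expect_equal(composition_enrichment(9, 9, 1.0), 1.0)
})

test_that("homopolymer indel counting respects run, length and anchoring rules", {
  g6 <- fx_guides$sgRNA6
  mk <- function(...) mutation_table(paste0("i", seq_along(c(...))), "sgRNA6",
                                     "WT", c(...), reference = fx_ref)
  # 1-nt deletion inside the T6 run at 948-953: counted
  expect_equal(homopolymer_indel_count(mk("950del"), g6, fx_ref), 1L)
  # insertion anchored just 5' of the run inserts into it: counted
  expect_equal(homopolymer_indel_count(mk("947ins(T)"), g6, fx_ref), 1L)
  # 2-nt deletion in the run: not a single-nt event
  expect_equal(homopolymer_indel_count(mk("950–951del"), g6, fx_ref), 0L)
  # 1-nt deletion outside any run
  expect_equal(homopolymer_indel_count(mk("944del"), g6, fx_ref), 0L)
  # guide without a qualifying run: always zero
  expect_equal(homopolymer_indel_count(mk("950del"), fx_guides$sgRNA2,
                                       fx_ref), 0L)
})

test_that("an empty table summarizes to zeros", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("isolate_id\tguide_id\tgenotype\tmutations", tmp)
  suppressWarnings(tab <- read_mutation_table(tmp, fx_ref))
  s <- summarize_spectrum(tab, g1, fx_ref)
  expect_equal(s$n_isolates, 0L)
  expect_equal(s$n_events, 0L)
  expect_equal(unname(s$n_in_window), rep(0L, 3))
  expect_equal(s$n_complex, 0L)
})
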