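---
title: "Analysing dCas9 R-loop mutagenesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing dCas9 R-loop mutagenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcas9mut)
```

## The assay this package analyses

Catalytically dead Cas9 (dCas9) binds DNA without cutting it, forming an
R-loop in which the ~20-nt protospacer strand complementary to the guide RNA
is hybridized to the guide while the other strand is displaced as
single-stranded DNA. Single-stranded DNA is chemically vulnerable — cytosine
deamination in particular is greatly elevated — so persistent dCas9 binding
can be mutagenic even without nuclease activity.

The experimental readout is a classic reporter-gene fluctuation-style assay:
cells expressing dCas9 and a guide targeting a counter-selectable reporter
(such as yeast *CAN1*, whose loss-of-function confers canavanine resistance)
are plated with and without selection, resistant isolates are Sanger
sequenced, and the resulting per-isolate mutation lists and colony counts
are the inputs to everything here. This package covers the dry half of that
workflow:

1. parsing compact per-isolate mutation notation into events
   (`parse_mutation()`, `read_mutation_table()`);
2. classifying events and isolates relative to a guide target with explicit
   strand bookkeeping (`summarize_spectrum()` and friends);
3. estimating mutation frequencies from plating counts and comparing groups
   with an exact nonparametric test (`mutation_frequency()`,
   `mann_whitney_exact()`);
4. scoring guides by their complement of inactivating non-target-strand
   cytosines (`potential_inactivating_cytosines()`);
5. simulating all of the above from a seeded generative model
   (`simulation_config()`, `simulate_isolates()`,
   `simulate_frequency_assay()`).

## Coordinates and strand bookkeeping

All positions are 1-based coding coordinates on the reporter open reading
frame (position 1 = first base of the start codon); no genome-level
coordinates are used. A guide is an interval `[start, end]` with a strand
designation: `NTS` for the non-transcribed (coding, mRNA-like) strand, `TS`
for the transcribed (template) strand.

The literature often says a guide "targets" a strand without stating whether
that strand carries the protospacer or is the strand the guide anneals to.
The two readings give complementary answers for every non-target-strand base
call, so the choice is made explicit and configurable:

* `convention = "protospacer"` (default): the designated strand carries the
  protospacer and PAM; the guide anneals to its complement; the displaced
  non-target strand of the R-loop **is** the designated strand. Under this
  reading, an NTS guide exposes the coding strand, so non-target-strand
  cytosines are coding-strand Cs and deamination shows up directly as coding
  C>T. This is the reading under which reported deamination signatures at
  coding-strand cytosines for NTS guides are literal, which is why it is the
  default.
* `convention = "hybridized"`: the guide anneals to the designated strand;
  every non-target-strand call is complemented.

Every summary and report embeds the convention used, so downstream
consumers never have to guess. `non_target_base()` is the single point
through which all strand translation flows, and flipping the designation
complements its output at every position (a tested invariant).

The PAM side is recorded for each guide but deliberately unused in window
arithmetic: windows are the protospacer widened by a symmetric margin and
clipped to the reference. Reports tabulate several margins (0, 2 and 10 nt
by default) because different datasets concentrate mutations inside the
protospacer, at its immediate periphery (1–2 nt), or within 10 nt; reporting
all three avoids committing to one definition of "near the target".

## Mutation notation and containers

Isolate mutations are written compactly: `259G>T`, `292del`, `286–287del`,
`294ins(T)`, `290ins(22 bp)`; comma-separated terms make up one isolate's
record. Design choices:

* Insertions are anchored 3′ of the stated position and located at their
  anchor for membership tests. Sidedness is not recoverable from the
  notation, so one rule is applied uniformly; all computed statistics depend
  only on consistency.
* A complex record's grouping into one isolate is taken from the input row,
  never inferred.
* En-dash and hyphen are both accepted in ranges; canonical output uses the
  en-dash. `parse_mutation()` and `format_mutation()` are exact inverses on
  valid events (property-tested), so tables round-trip byte-identically.
* Multi-nucleotide substitutions are representable even though single-nt
  substitutions dominate real spectra.

Tables carry one row per isolate with at least one event each (isolates are
selected for loss of reporter function). `export_vcf_records()` re-expresses
events as VCF 4.x records on the coding sequence as contig, left-anchoring
indels per VCF convention, with a right-anchored fallback for a deletion at
position 1 and `<INS>`/`SVLEN` for insertions of unknown sequence.

## Spectrum classification

* **Window membership** is per isolate: an isolate with two in-target events
  counts once, matching the way "x of n mutants had a mutation within m nt"
  is tallied. Event-level class counts are reported alongside for
  histogram-style output.
* **Complex mutations** are two or more events within 10 nt of each other
  (configurable). Distance is the gap between nearest endpoints
  (`later$start - earlier$end`), and clustering is transitive: chains count
  as one cluster. The boolean "is complex" is equivalent to "some pair is
  within the distance", which is how the exhaustive test oracle checks it.
* **The substitution spectrum** re-expresses in-target single-nt
  substitutions on the non-target strand before tallying, so C>T always
  means "C>T on the displaced strand" regardless of guide orientation.
* **Deamination fraction**: numerator = in-target substitutions at
  non-target-strand C; denominator = *all* in-target events including
  indels. Including non-substitution events in the denominator makes the
  statistic comparable with published "x of n mutations at C" counts, which
  include deletions in n.
* **Homopolymer indels**: single-nt insertions/deletions anchored in (or,
  for insertions, immediately 5′ of) a run of ≥ 6 identical bases
  overlapping the protospacer — the polymerase-slippage signature.
* **Per-position/per-codon counts** increment every nucleotide covered by a
  multi-nt event (each mutated nucleotide counts individually); codon =
  `ceiling(pos / 3)`.
* **Composition enrichment** (`composition_enrichment()`) formalizes the
  argument "mutations hit C more often than base composition predicts" as
  an exact one-sided binomial tail with success probability equal to the C
  fraction of the window. It is a deliberately simple null — events
  independent and uniform over window positions — adequate for the small
  counts involved.

## Frequency estimation and testing

Per-culture mutant frequency is the dilution-scaled colony ratio

$$
f \;=\; \frac{n_{\mathrm{sel}} \, d_{\mathrm{sel}}}
             {n_{\mathrm{nonsel}} \, d_{\mathrm{nonsel}}},
$$

with dilution factors read as fold-dilutions (≥ 1) of the plated aliquot, the
only reading under which the ratio is a frequency. Groups pool replicate
cultures and are summarized by the **median** (never the mean — single
jackpot cultures otherwise dominate), and fold changes are ratios of
medians.

Group comparisons use a two-tailed Mann–Whitney U test with an exact null:

* no ties, pooled n ≤ 20: dynamic-programming enumeration of the rank-sum
  distribution (number of m-subsets of {1..N} by sum);
* ties: exact permutation over all `choose(N, m)` assignments of the pooled
  mid-ranks when that is ≤ 2·10^5^;
* otherwise: normal approximation with tie correction and continuity
  correction.

The route taken is recorded in the result and in reports. The two-sided
p-value is `min(1, 2 × min(lower tail, upper tail))`. At the assay's typical
size — six cultures per group — complete separation gives the smallest
attainable p-value, 2/924 ≈ 0.0022, which is why that value recurs in
well-powered reporter assays:

```{r}
mann_whitney_exact(c(7, 8, 9, 10, 11, 12), 1:6)
```

P-values are reported to 4 decimal places, frequencies to 3 significant
digits. No multiple-testing correction is applied (pairwise tests are few
and reported individually).

## Scoring guides by inactivating cytosines

Not every deaminated cytosine inactivates the reporter, so raw C content of
a protospacer is a poor predictor of mutability-as-measured. The scorer
intersects three things: positions whose non-target-strand base is C; a
user-supplied catalog of coding-strand substitutions known to inactivate the
reporter (e.g. compiled from deaminase-mutagenesis datasets); and a
configurable outcome set. The default outcomes are `C>T`, `C>G` and `C>A`
(direct replication over uracil plus the two lesion-processing outcomes);
a `C>T`-only mode models the uracil-glycosylase-deficient regime. Building
a real catalog is out of scope; the packaged catalog is synthetic, sized so
that the example guides span scores 0–5.

## The simulator

`simulate_isolates()` draws each isolate's inactivating mutation from a
two-level mixture: with probability `p_target` a target-associated event —
deamination substitution at a non-target-strand protospacer C, single-nt
indel in an overlapping homopolymer run, a complex cluster (two
substitutions within 10 nt), or another short indel — otherwise a background
substitution, uniform over a supplied catalog or over the gene. Defaults
(`p_target = 0.76`, deamination outcomes 0.6/0.2/0.2, classes
0.6/0.1/0.15/0.15) echo the proportions seen in a strongly clustered
NTS-guide spectrum; they are configuration, not constants. Genotype toggles
act mechanistically: `ung1` collapses deamination outcomes to pure C>T,
`rev3` zeroes the complex class and renormalizes.

`simulate_frequency_assay()` models each culture as a suspension of `cells`
cells with mutant fraction f; colony counts are Poisson at
`cells × f / d_sel` and `cells / d_nonsel`. Defaults (2·10^7^ cells,
dilutions 10 and 10^5^) give ~20 selective and ~200 nonselective colonies at
f = 10^-5^, the scale at which such assays are typically read. There is no
Luria–Delbrück jackpot modeling: the simulator draws plating noise around a
fixed per-culture frequency, so it validates the estimator and test
machinery, not the biology of culture growth. Likewise the isolate
generator emulates the *structure* of real spectra (clustering, strand bias,
class mix), not fitness effects, hotspot sequence context beyond
homopolymers, or which mutations truly inactivate the protein — passing
recovery tests shows the pipeline's arithmetic is right, not that real data
will look like this.

Determinism: all randomness flows from a single integer seed; the same seed
reproduces tables and counts bit-identically.

## Numerical and degenerate-input choices

* Window clipping handles guides near the reference edges; no errors.
* A zero nonselective colony count makes the frequency undefined and is an
  error naming the culture; a zero reference-group median makes a fold
  change infinite and is flagged, not raised.
* A spectrum over an empty table is all zeros; a deamination fraction with
  zero denominator is `NA` with a warning.
* Guide ranking breaks ties by input order (stable), making output
  reproducible under reordering.
* Problem sizes used in the shipped validation suite: exhaustive
  Mann–Whitney enumeration up to pooled n = 10, 1,000 random event tables
  for the window/cluster oracles, 500 simulated isolates for mixture
  recovery, and 1,000 Monte-Carlo replicates of a 6-culture assay for
  estimator calibration — sizes at which exact enumeration is cheap and
  binomial/Monte-Carlo error bands are tight enough to be informative.

## Known limitations

* The strand convention is a modeling commitment; if a dataset's authors
  meant the opposite bookkeeping, use `convention = "hybridized"` rather
  than re-coding mutations.
* Insertion sidedness is conventional (3′); statistics near window edges can
  shift by one position under the opposite convention.
* The binomial composition test ignores position-specific selection (which
  inactivating-site structure induces); treat it as a composition argument,
  not a full null model.
* The simulator's background is uniform; real spontaneous spectra are not.
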