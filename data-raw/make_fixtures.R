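# Build the packaged example data under inst/extdata/.
#
# Everything here is synthetic: the reporter coding sequence is a randomly
# generated 1773-nt ORF constrained so that every reference allele quoted in
# the packaged mutation tables is consistent with it, the per-isolate lists
# for sgRNA2/sgRNA4/sgRNA6 are reconstructed to match the published aggregate
# counts, and the inactivating-substitution catalog is a small invented set.
# Run from the package root: Rscript data-raw/make_fixtures.R

set.seed(20181221)

BASES <- c("A", "C", "G", "T")
comp <- function(b) chartr("ACGT", "TGCA", b)

L <- 1773
seq <- sample(BASES, L, replace = TRUE, prob = c(0.31, 0.19, 0.19, 0.31))

# Fixed positions: start/stop codon, every ref allele used by the packaged
# mutation tables, the fully specified sgRNA2 window (exactly 6 C in 291-310),
# the guide-target landmarks, and the 6-nt T homopolymer at 948-953.
fixed <- c(
  "1" = "A", "2" = "T", "3" = "G",
  "259" = "G", "263" = "T",
  "282" = "T", "285" = "G", "286" = "A", "287" = "T", "289" = "G",
  "290" = "C", "291" = "C", "292" = "A", "293" = "C", "294" = "T",
  "295" = "A", "296" = "C", "297" = "T", "298" = "A", "299" = "C",
  "300" = "A", "301" = "G", "302" = "C", "303" = "T", "304" = "A",
  "305" = "C", "306" = "G", "307" = "T", "308" = "A", "309" = "G",
  "310" = "T", "315" = "G",
  "404" = "G", "412" = "G", "416" = "G",
  "591" = "C", "604" = "C", "610" = "C",
  "809" = "G", "923" = "G",
  "943" = "C", "945" = "C", "947" = "A",
  "948" = "T", "949" = "T", "950" = "T", "951" = "T", "952" = "T", "953" = "T",
  "954" = "G", "956" = "C", "958" = "C",
  "973" = "G", "1035" = "C", "1068" = "C", "1110" = "G",
  "1771" = "T", "1772" = "A", "1773" = "A"
)
fixed_pos <- as.integer(names(fixed))
seq[fixed_pos] <- unname(fixed)

# Break any homopolymer run of length >= 5 other than the designed T run, so
# that the sgRNA6 run is the only one a min_run = 6 scan can find.
repeat {
  r <- rle(seq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$lengths >= 5 & !(starts == 948 & ends == 953))
  if (length(bad) == 0) break
  i <- bad[1]
  cand <- setdiff(starts[i]:ends[i], fixed_pos)
  stopifnot(length(cand) > 0)
  p <- cand[ceiling(length(cand) / 2)]
  seq[p] <- sample(setdiff(BASES, seq[c(p - 1, p, p + 1)]), 1)
}

stopifnot(sum(seq[291:310] == "C") == 6)            # sgRNA2 composition 6/20
stopifnot(all(seq[fixed_pos] == unname(fixed)))

refstr <- paste(seq, collapse = "")

# --- reference FASTA -------------------------------------------------------
fa <- c(">CAN1syn synthetic 1773-nt reporter coding sequence (coding strand)",
        substring(refstr, seq(1, L, 60), pmin(seq(1, L, 60) + 59, L)))
writeLines(fa, "inst/extdata/reporter_cds_synthetic.fasta")

# --- guide table -----------------------------------------------------------
guides <- data.frame(
  id       = paste0("sgRNA", 1:8),
  start    = c(277, 291, 701, 601, 1101, 941, 401, 405),
  end      = c(296, 310, 720, 620, 1120, 960, 420, 424),
  strand   = c("TS", "NTS", "TS", "NTS", "TS", "NTS", "TS", "TS"),
  pam_side = c("upstream", "downstream", "upstream", "downstream",
               "upstream", "downstream", "upstream", "upstream")
)
write.table(guides, "inst/extdata/guides_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# --- published sgRNA1 isolate table (printed data, typed in verbatim) -------
t1 <- c("259G>T", "263T>G", "282T>A, 286–287del", "286–287del",
        "287T>A", "287T>A, 289G>C", "290C>A", "290ins(22 bp)",
        "291C>G, 294T>A", "292del", "294ins(T)", "591C>A", "801–808del",
        "809G>A", "892del", "923G>T", "973G>T", "1035C>A", "1068C>A")
tab1 <- data.frame(
  isolate_id = sprintf("sg1_%02d", seq_along(t1)),
  guide_id   = "sgRNA1",
  genotype   = "WT",
  mutations  = t1
)
con <- file("inst/extdata/sgRNA1_table1.tsv", open = "w", encoding = "UTF-8")
write.table(tab1, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

# --- synthetic supplementary-style isolate lists ---------------------------
sub_at <- function(pos, alt = NULL) {
  ref <- seq[pos]
  if (is.null(alt)) alt <- setdiff(BASES, ref)[1]
  stopifnot(ref != alt)
  paste0(pos, ref, ">", alt)
}

rows <- list()
add <- function(guide, muts) {
  i <- length(rows) + 1L
  rows[[i]] <<- data.frame(
    isolate_id = sprintf("%s_%02d", sub("sgRNA", "sg", guide),
                         sum(vapply(rows, function(r) r$guide_id, "") == guide) + 1L),
    guide_id = guide, genotype = "WT", mutations = paste(muts, collapse = ", "))
}

# sgRNA2 (target 291-310): 14 isolates in the protospacer (10 events at a
# non-target-strand C: 6 C>T, 2 C>G, 2 C>A; plus 1 A>G, 1 T>A, 2 deletions),
# 2 more within 10 nt, 5 dispersed background -> 16/21 within margin 10.
for (m in list("293C>T", "296C>T", "299C>T", "293C>T", "296C>T", "302C>T",
               "291C>G", "299C>G", "296C>A", "305C>A",
               "308A>G", "294T>A", "297del", "300–301del",
               "285G>A", "315G>T",
               sub_at(102), sub_at(455), sub_at(723), sub_at(1203), sub_at(1544)))
  add("sgRNA2", m)

# sgRNA4 (target 601-620): 4 isolates in the protospacer (3 deletions, one
# C>G -- the only in-target substitution), 3 at 1-2 nt downstream -> 7/20
# within margin 2; 13 dispersed background.
for (m in list("610C>G", "605del", "612–613del", "618del",
               "621del", "622del", "621–622del",
               sub_at(150), sub_at(230), sub_at(340), sub_at(480), sub_at(520),
               sub_at(700), sub_at(750), sub_at(850), sub_at(1000),
               sub_at(1150), sub_at(1300), sub_at(1450), sub_at(1600)))
  add("sgRNA4", m)

# sgRNA6 (target 941-960, T6 homopolymer at 948-953): 10 single-nt indels in
# the run, 4 single C>T substitutions, 6 complex clusters, 5 background
# -> 20/25 in target, 6/20 complex, 10/20 homopolymer indels.
for (m in list("950del", "951del", "948del", "953del", "950del",
               "949ins(T)", "952ins(T)", "951ins(T)", "948ins(T)", "952del",
               "943C>T", "945C>T", "956C>T", "958C>T",
               c(sub_at(942), sub_at(946)),
               c(sub_at(955), sub_at(959)),
               c("943C>A", "945–946del"),
               c("956C>G", "959–960del"),
               c(sub_at(944), sub_at(947)),
               c(sub_at(957), sub_at(960)),
               sub_at(200), sub_at(400), sub_at(600), sub_at(1100), sub_at(1400)))
  add("sgRNA6", m)

supp <- do.call(rbind, rows)
con <- file("inst/extdata/isolates_supplementary_synthetic.tsv",
            open = "w", encoding = "UTF-8")
write.table(supp, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)

# --- synthetic inactivating-substitution catalog ---------------------------
cat_df <- data.frame(
  position = c(291, 293, 296, 296, 299, 302, 404, 412, 416,
               604, 610, 943, 945, 956, 958, 1110),
  ref = c("C", "C", "C", "C", "C", "C", "G", "G", "G",
          "C", "C", "C", "C", "C", "C", "G"),
  alt = c("G", "T", "T", "A", "T", "T", "A", "A", "A",
          "T", "G", "T", "T", "T", "T", "A"),
  source = "synthetic"
)
stopifnot(all(seq[cat_df$position] == cat_df$ref))
write.table(cat_df, "inst/extdata/inactivating_catalog_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("fixtures written; C in 291-310:", sum(seq[291:310] == "C"),
    "; runs>=5:", sum(rle(seq)$lengths >= 5), "\n")
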