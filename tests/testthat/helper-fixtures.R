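# Shared fixtures: the packaged example data plus small constructed objects.

fx_ref <- read_reference_fasta(dcas9mut_example("reference"))
fx_guides <- read_guides(dcas9mut_example("guides"), fx_ref)
fx_table1 <- read_mutation_table(dcas9mut_example("table1"), fx_ref)
fx_supp <- read_mutation_table(dcas9mut_example("supplementary"), fx_ref)
fx_catalog <- read_inactivating_catalog(dcas9mut_example("catalog"), fx_ref)

subset_table <- function(table, guide_id) {
  sub <- table[table$guide_id %in% guide_id, , drop = FALSE]
  class(sub) <- class(table)
  attr(sub, "source") <- attr(table, "source")
  sub
}

# periodic toy reference: base at pos p is c("A","C","G","T")[(p-1) %% 4 + 1]
toy_ref <- reference_region("toy", paste(rep("ACGT", 30), collapse = ""))

# random event generator for round-trip and oracle properties
random_events <- function(n, max_pos = 100L) {
  rows <- lapply(seq_len(n), function(i) {
    kind <- sample(c("substitution", "deletion", "insertion"), 1)
    pos <- sample.int(max_pos, 1)
    if (kind == "substitution") {
      len <- sample(1:2, 1, prob = c(0.9, 0.1))
      repeat {
        ref <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        alt <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        if (ref != alt) break
      }
      data.frame(kind = kind, start = pos, end = pos + len - 1L,
                 ref = ref, alt = alt, insert_length = NA_integer_,
                 stringsAsFactors = FALSE)
    } else if (kind == "deletion") {
      len <- sample(1:5, 1)
      data.frame(kind = kind, start = pos, end = pos + len - 1L,
                 ref = "", alt = "", insert_length = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      if (runif(1) < 0.5) {
        seq <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                            replace = TRUE), collapse = "")
        data.frame(kind = kind, start = pos, end = pos, ref = "",
                   alt = seq, insert_length = nchar(seq),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(kind = kind, start = pos, end = pos, ref = "",
                   alt = "", insert_length = sample(1:30, 1),
                   stringsAsFactors = FALSE)
      }
    }
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# pairwise oracles, written independently of the package internals
oracle_complex <- function(events, distance = 10L) {
  n <- nrow(events)
  if (n < 2L) return(FALSE)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- events[i, ]; b <- events[j, ]
      if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
      if (b$start - a$end <= distance) return(TRUE)
    }
  }
  FALSE
}

oracle_in_window <- function(events, ws, we) {
  for (i in seq_len(nrow(events))) {
    covered <- events$start[i]:events$end[i]
    if (any(covered >= ws & covered <= we)) return(TRUE)
  }
  FALSE
}
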