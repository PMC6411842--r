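#' Mutation table of sequenced resistant isolates
#'
#' A `mutation_table` holds one row per independently sequenced resistant
#' isolate: its id, the guide it derives from (`NA` for no-guide controls),
#' its genotype label (e.g. `WT`, `ung1D`, `rev3D`) and the parsed mutation
#' events. Every isolate carries at least one event — isolates are selected
#' for loss of reporter function, so a sequenced isolate without an
#' inactivating mutation would indicate an upstream problem.
#'
#' @param isolate_id Character vector of unique isolate ids.
#' @param guide_id Character vector (recycled) of guide ids, `NA` for
#'   controls.
#' @param genotype Character vector (recycled) of genotype labels.
#' @param mutations Character vector of notation strings (see
#'   [mutation-notation]).
#' @param reference Optional [reference_region()] for allele validation.
#' @param source Provenance label stored in the table's metadata.
#' @return A data frame of class `mutation_table` with columns `isolate_id`,
#'   `guide_id`, `genotype`, `mutations` and a list-column `events` of parsed
#'   event data frames; attributes `reference_name` and `source`.
#' @export
mutation_table <- function(isolate_id, guide_id, genotype, mutations,
                           reference = NULL, source = "constructed") {
  n <- length(isolate_id)
  if (anyDuplicated(isolate_id)) {
    stop("duplicate isolate ids: ",
         paste(unique(isolate_id[duplicated(isolate_id)]), collapse = ", "))
  }
  tab <- data.frame(isolate_id = as.character(isolate_id),
                    guide_id = rep_len(as.character(guide_id), n),
                    genotype = rep_len(as.character(genotype), n),
                    mutations = as.character(mutations),
                    stringsAsFactors = FALSE)
  tab$events <- lapply(seq_len(n), function(i) {
    ev <- tryCatch(parse_mutation(tab$mutations[i], reference = reference),
                   error = function(e) {
                     stop(sprintf("isolate %s (row %d): %s",
                                  tab$isolate_id[i], i, conditionMessage(e)),
                          call. = FALSE)
                   })
    ev
  })
  tab$mutations <- vapply(tab$events, format_mutation, character(1))
  structure(tab,
            class = c("mutation_table", "data.frame"),
            reference_name = if (!is.null(reference)) reference$name else NA_character_,
            source = source)
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("<mutation_table> %d isolates, %d events (source: %s)\n",
              nrow(x), sum(vapply(x$events, nrow, 0L)), attr(x, "source")))
  print.data.frame(x[, c("isolate_id", "guide_id", "genotype", "mutations")],
                   ...)
  invisible(x)
}

#' Read a mutation table from TSV
#'
#' Expects UTF-8 TSV with header columns `isolate_id`, `guide_id`,
#' `genotype`, `mutations`. Empty `guide_id` fields become `NA` (no-guide
#' control). An empty file yields an empty table with a warning.
#'
#' @param path TSV file path.
#' @param reference Optional [reference_region()]; substitution reference
#'   alleles are validated against it.
#' @return A [mutation_table()].
#' @export
read_mutation_table <- function(path, reference = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("isolate_id", "guide_id", "genotype", "mutations")
  if (!all(need %in% names(df))) {
    stop("mutation TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("empty mutation table: ", path)
    tab <- df[, need]
    tab$events <- list()
    return(structure(tab, class = c("mutation_table", "data.frame"),
                     reference_name = if (!is.null(reference)) reference$name else NA_character_,
                     source = path))
  }
  df$guide_id[!nzchar(trimws(df$guide_id))] <- NA_character_
  mutation_table(df$isolate_id, df$guide_id, df$genotype, df$mutations,
                 reference = reference, source = path)
}

#' Write a mutation table to TSV
#'
#' Exact inverse of [read_mutation_table()]: notation is serialized in
#' canonical form, so read -> write -> read is the identity.
#'
#' @param table A [mutation_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(table, path) {
  stopifnot(inherits(table, "mutation_table"))
  out <- as.data.frame(table)[, c("isolate_id", "guide_id", "genotype",
                                  "mutations")]
  out$guide_id[is.na(out$guide_id)] <- ""
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a mutation table as VCF-style records
#'
#' Re-expresses events as VCF 4.x records with the coding sequence as the
#' contig. Substitutions map directly; insertions and deletions are
#' left-anchored at `start - 1` with the anchor base per VCF convention
#' (a deletion starting at position 1 has no left anchor and is emitted
#' right-anchored, with a message). Sequence-unknown insertions use the
#' symbolic allele `<INS>` with an `SVLEN` INFO field. Events of one isolate
#' are linked by `ISOLATE=` in INFO.
#'
#' @param table A [mutation_table()].
#' @param reference A [reference_region()] (required for anchor bases).
#' @return Data frame with columns `CHROM`, `POS`, `ID`, `REF`, `ALT`,
#'   `QUAL`, `FILTER`, `INFO`.
#' @export
export_vcf_records <- function(table, reference) {
  stopifnot(inherits(table, "mutation_table"),
            inherits(reference, "reference_region"))
  recs <- list()
  for (i in seq_len(nrow(table))) {
    ev <- table$events[[i]]
    iso <- table$isolate_id[i]
    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]
      info <- paste0("ISOLATE=", iso)
      if (e$kind == "substitution") {
        rec <- list(POS = e$start, REF = e$ref, ALT = e$alt)
      } else if (e$kind == "deletion") {
        deleted <- substring(reference$sequence, e$start, e$end)
        if (e$start == 1L) {
          anchor <- ref_base(reference, e$end + 1L)
          message("deletion at position 1 for isolate ", iso,
                  ": emitting right-anchored record")
          rec <- list(POS = 1L, REF = paste0(deleted, anchor), ALT = anchor)
        } else {
          anchor <- ref_base(reference, e$start - 1L)
          rec <- list(POS = e$start - 1L, REF = paste0(anchor, deleted),
                      ALT = anchor)
        }
      } else {
        anchor <- ref_base(reference, e$start)
        if (nzchar(e$alt)) {
          rec <- list(POS = e$start, REF = anchor,
                      ALT = paste0(anchor, e$alt))
        } else {
          rec <- list(POS = e$start, REF = anchor, ALT = "<INS>")
          info <- paste0(info, ";SVLEN=", e$insert_length)
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        CHROM = reference$name, POS = rec$POS, ID = ".",
        REF = rec$REF, ALT = rec$ALT, QUAL = ".", FILTER = ".",
        INFO = info, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(CHROM = character(), POS = integer(), ID = character(),
                      REF = character(), ALT = character(), QUAL = character(),
                      FILTER = character(), INFO = character()))
  }
  out <- do.call(rbind, recs)
  out[order(out$POS), , drop = FALSE]
}

#' Write VCF-style records to a VCF text file
#'
#' @param records Data frame from [export_vcf_records()].
#' @param reference The [reference_region()] used as contig.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, reference, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", reference$name, reference$length),
    "##INFO=<ID=ISOLATE,Number=1,Type=String,Description=\"Isolate id\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Insertion length\">",
    "##ALT=<ID=INS,Description=\"Insertion of unknown sequence\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  body <- apply(records, 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
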