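#' @title Compact mutation notation
#'
#' @description
#' Per-isolate mutations are written in a compact notation, one
#' comma-separated term per mutation event:
#'
#' * `259G>T` — single-nucleotide substitution (multi-nt substitutions,
#'   e.g. `12AC>GT`, are accepted);
#' * `292del` — single-nucleotide deletion;
#' * `286–287del` — multi-nucleotide deletion (en-dash or hyphen range);
#' * `294ins(T)` — insertion of known sequence 3' of the anchor position;
#' * `290ins(22 bp)` — insertion of known length but unknown sequence.
#'
#' Positions are 1-based coding coordinates. Insertions are anchored after
#' (3' of) the stated position; for window-membership purposes an insertion
#' is located at its anchor. Events parse into a data frame with columns
#' `kind` (`substitution`/`deletion`/`insertion`), `start`, `end`, `ref`,
#' `alt` and `insert_length`, sorted by `start`.
#'
#' @name mutation-notation
NULL

EN_DASH <- "–"

empty_events <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             ref = character(), alt = character(),
             insert_length = integer(), stringsAsFactors = FALSE)
}

event_row <- function(kind, start, end, ref = "", alt = "",
                      insert_length = NA_integer_) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             ref = ref, alt = alt, insert_length = as.integer(insert_length),
             stringsAsFactors = FALSE)
}

#' Parse a mutation notation string
#'
#' @param notation A non-empty notation string; see [mutation-notation] for
#'   the grammar. Whitespace around terms is tolerated and hyphen is accepted
#'   in place of the canonical en-dash.
#' @param reference Optional [reference_region()]. When supplied, substitution
#'   reference alleles are checked against it (a mismatch is an error),
#'   deleted positions must lie within it, and deletion `ref` fields are
#'   filled in from it.
#' @return Event data frame (see [mutation-notation]), sorted by `start`.
#' @examples
#' parse_mutation("282T>A, 286-287del")
#' parse_mutation("290ins(22 bp)")
#' @export
parse_mutation <- function(notation, reference = NULL) {
  stopifnot(is.character(notation), length(notation) == 1L)
  if (!nzchar(trimws(notation))) stop("empty mutation notation")
  terms <- trimws(strsplit(notation, ",")[[1]])
  events <- lapply(terms, parse_term)
  events <- do.call(rbind, events)
  events <- events[order(events$start, events$end), , drop = FALSE]
  rownames(events) <- NULL
  if (!is.null(reference)) events <- validate_events(events, reference)
  events
}

parse_term <- function(term) {
  t <- gsub(EN_DASH, "-", term)
  if (grepl("^(\\d+)([ACGTacgt]+)>([ACGTacgt]+)$", t)) {
    m <- regmatches(t, regexec("^(\\d+)([ACGTacgt]+)>([ACGTacgt]+)$", t))[[1]]
    start <- as.integer(m[2])
    ref <- toupper(m[3]); alt <- toupper(m[4])
    if (nchar(ref) != nchar(alt)) {
      stop("malformed mutation term (ref/alt length mismatch): ", term)
    }
    if (ref == alt) stop("malformed mutation term (ref equals alt): ", term)
    return(event_row("substitution", start, start + nchar(ref) - 1L, ref, alt))
  }
  if (grepl("^(\\d+)-(\\d+)del$", t)) {
    m <- regmatches(t, regexec("^(\\d+)-(\\d+)del$", t))[[1]]
    start <- as.integer(m[2]); end <- as.integer(m[3])
    if (end <= start) {
      stop("malformed mutation term (empty or inverted range): ", term)
    }
    return(event_row("deletion", start, end))
  }
  if (grepl("^(\\d+)del$", t)) {
    start <- as.integer(sub("del$", "", t))
    return(event_row("deletion", start, start))
  }
  if (grepl("^(\\d+)ins\\(([ACGTacgt]+)\\)$", t)) {
    m <- regmatches(t, regexec("^(\\d+)ins\\(([ACGTacgt]+)\\)$", t))[[1]]
    seq <- toupper(m[3])
    return(event_row("insertion", as.integer(m[2]), as.integer(m[2]),
                     alt = seq, insert_length = nchar(seq)))
  }
  if (grepl("^(\\d+)ins\\((\\d+)\\s*bp\\)$", t)) {
    m <- regmatches(t, regexec("^(\\d+)ins\\((\\d+)\\s*bp\\)$", t))[[1]]
    len <- as.integer(m[3])
    if (len < 1L) stop("malformed mutation term (zero-length insertion): ", term)
    return(event_row("insertion", as.integer(m[2]), as.integer(m[2]),
                     insert_length = len))
  }
  stop("malformed mutation term: ", term)
}

validate_events <- function(events, reference) {
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$start < 1L || e$end > reference$length) {
      stop(sprintf("event %s at %d-%d outside reference (1-%d)",
                   e$kind, e$start, e$end, reference$length))
    }
    if (e$kind == "substitution") {
      obs <- substring(reference$sequence, e$start, e$end)
      if (obs != e$ref) {
        stop(sprintf(
          "reference allele mismatch at %d: notation says %s, reference has %s",
          e$start, e$ref, obs))
      }
    } else if (e$kind == "deletion" && !nzchar(e$ref)) {
      events$ref[i] <- substring(reference$sequence, e$start, e$end)
    }
  }
  events
}

#' Format mutation events back to notation
#'
#' Canonical inverse of [parse_mutation()]: `parse_mutation(format_mutation(x))`
#' reproduces `x` for any valid event set. Ranges use the en-dash, terms are
#' joined by `", "`, and sequence-unknown insertions render as
#' `POSins(K bp)`.
#'
#' @param events Event data frame as produced by [parse_mutation()].
#' @return A single notation string.
#' @export
format_mutation <- function(events) {
  stopifnot(is.data.frame(events), nrow(events) >= 1L)
  events <- events[order(events$start, events$end), , drop = FALSE]
  terms <- vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    switch(e$kind,
      substitution = paste0(e$start, e$ref, ">", e$alt),
      deletion = if (e$start == e$end) paste0(e$start, "del")
                 else paste0(e$start, EN_DASH, e$end, "del"),
      insertion = if (nzchar(e$alt)) paste0(e$start, "ins(", e$alt, ")")
                  else paste0(e$start, "ins(", e$insert_length, " bp)"),
      stop("unknown event kind: ", e$kind)
    )
  }, character(1))
  paste(terms, collapse = ", ")
}
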