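#' The eight alternative-splicing event types
#'
#' `ES` exon skipping, `MES` multiple (consecutive) exon skipping, `MEE`
#' mutually exclusive exons, `IR` intron retention, `A5`/`A3` alternative
#' 5'-/3'-splice site (strand-relative: A5 shifts a donor, A3 an acceptor),
#' `AFE`/`ALE` alternative first/last exon.
#'
#' @format Character vector of length 8.
#' @export
EVENT_TYPES <- c("ES", "MES", "MEE", "IR", "A5", "A3", "AFE", "ALE")

# required number of event-defining blocks per type (NA = ">= 2")
.block_arity <- c(
  ES = 1L, MES = NA, MEE = NA, IR = 1L, A5 = 1L, A3 = 1L, AFE = 1L, ALE = 1L
)

#' Serialize coordinate blocks to their text form
#'
#' Blocks are written as `start-end` pairs joined by `;`, e.g.
#' `301-400;501-600`, the form used in the unified event TSV.
#'
#' @param blocks A list of data frames with `start` and `end` columns.
#' @return A character vector, one element per list entry.
#' @export
blocks_to_chr <- function(blocks) {
  vapply(
    blocks,
    function(b) paste(sprintf("%d-%d", b$start, b$end), collapse = ";"),
    character(1)
  )
}

#' Parse the text form of coordinate blocks
#'
#' @param x Character vector of `start-end[;start-end...]` strings.
#' @return A list of tibbles with integer `start` and `end` columns.
#' @export
chr_to_blocks <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !grepl("^\\d+-\\d+(;\\d+-\\d+)*$", s)) {
      stop("bad block syntax: ", s)
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    tibble::tibble(
      start = vapply(parts, function(p) as.integer(p[1]), integer(1)),
      end = vapply(parts, function(p) as.integer(p[2]), integer(1))
    )
  })
}

#' Construct a unified AS event table
#'
#' The unified format records, per event: a unique `event_id`, the
#' `gene_name`, `chrom` and `strand`, the `event_type`, and the event-defining
#' coordinate `blocks` — the skipped exon(s) for ES/MES/MEE, the retained
#' intron for IR, the alternative part of an exon for A5/A3 and the
#' alternative first/last exon for AFE/ALE — plus the `source_tool` label of
#' the producer.
#'
#' @param df A data frame with columns `event_id`, `gene_name`, `chrom`,
#'   `strand`, `event_type`, `blocks` (list of start/end data frames, or a
#'   character column in `start-end;...` form) and `source_tool`.
#' @return A validated event tibble with a list-column `blocks`.
#' @export
event_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c(
    "event_id", "gene_name", "chrom", "strand", "event_type",
    "blocks", "source_tool"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("event_table(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.character(df$blocks)) df$blocks <- chr_to_blocks(df$blocks)
  validate_events(df)
  df
}

#' Validate a unified event table
#'
#' Enforces the closed event-type enumeration, strand in `{+,-}`, per-type
#' block arity (one block for ES/IR/A5/A3/AFE/ALE, at least two for MES/MEE),
#' sorted pairwise-disjoint blocks, and unique event ids.
#'
#' @param events An event tibble.
#' @return `events`, invisibly.
#' @export
validate_events <- function(events) {
  if (nrow(events) == 0) return(invisible(events))
  bad_type <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad_type) > 0) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "))
  }
  if (!all(events$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  dup <- events$event_id[duplicated(events$event_id)]
  if (length(dup) > 0) {
    stop("duplicate event_id: ", paste(unique(dup), collapse = ", "))
  }
  nb <- vapply(events$blocks, nrow, integer(1))
  arity <- .block_arity[events$event_type]
  bad <- (!is.na(arity) & nb != arity) | (is.na(arity) & nb < 2L)
  if (any(bad)) {
    stop(
      "wrong block count for event(s): ",
      paste(events$event_id[bad], collapse = ", ")
    )
  }
  ok_blocks <- vapply(events$blocks, function(b) {
    all(b$start >= 1L) && all(b$end >= b$start) &&
      (nrow(b) < 2 || all(b$start[-1] > b$end[-nrow(b)]))
  }, logical(1))
  if (!all(ok_blocks)) {
    stop(
      "blocks must be sorted, disjoint, 1-based: ",
      paste(events$event_id[!ok_blocks], collapse = ", ")
    )
  }
  invisible(events)
}

#' Canonical comparison key of an event
#'
#' Two events are "the same" for matching, intersection and consensus purposes
#' when they agree on chromosome, strand, effective type and exact block
#' coordinates. `gene_name`, `event_id` and `source_tool` are deliberately
#' excluded: tools disagree on identifiers, coordinates are the comparable
#' signal. With `collapse_skipping = TRUE`, MES and MEE are treated as ES, the
#' convention used when most tools report any exon-skipping variant simply as
#' skipping.
#'
#' @param events An event tibble.
#' @param collapse_skipping Map MES/MEE to ES in the key (default `TRUE`).
#' @return Character vector of keys, one per event.
#' @export
event_key <- function(events, collapse_skipping = TRUE) {
  eff <- effective_type(events$event_type, collapse_skipping)
  paste(events$chrom, events$strand, eff, blocks_to_chr(events$blocks),
    sep = "|"
  )
}

#' Effective event type under skipping collapse
#'
#' @param type Character vector of event types.
#' @param collapse_skipping If `TRUE`, MES and MEE become ES.
#' @return Character vector of effective types.
#' @export
effective_type <- function(type, collapse_skipping = TRUE) {
  if (collapse_skipping) type[type %in% c("MES", "MEE")] <- "ES"
  type
}
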