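.unified_header <- c(
  "event_id", "gene_name", "chrom", "strand", "event_type", "blocks",
  "source_tool"
)

#' Write events in the unified TSV format
#'
#' Produces the package's flagship format: a tab-separated file with the exact
#' header `event_id gene_name chrom strand event_type blocks source_tool`,
#' blocks serialized as `start-end` pairs joined by `;`, no quoting, rows
#' sorted by `(chrom, first block start, event_type, event_id)`. Equal inputs
#' produce byte-identical files; an empty event set yields a header-only file.
#'
#' @param events An event tibble ([event_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unified <- function(events, path) {
  header <- paste(.unified_header, collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(events) == 0) {
    writeLines(header, con)
    return(invisible(path))
  }
  validate_events(events)
  rows <- events |>
    dplyr::mutate(
      .blocks_chr = blocks_to_chr(.data$blocks),
      .first_start = vapply(.data$blocks, function(b) b$start[1], integer(1))
    ) |>
    dplyr::arrange(
      .data$chrom, .data$.first_start, .data$event_type, .data$event_id
    )
  writeLines(c(header, paste(
    rows$event_id, rows$gene_name, rows$chrom, rows$strand, rows$event_type,
    rows$.blocks_chr, rows$source_tool,
    sep = "\t"
  )), con)
  invisible(path)
}

#' Read events from the unified TSV format
#'
#' Inverse of [write_unified()]: `read_unified(write_unified(E))` reproduces
#' `E` field-wise (up to the canonical row order). Parse failures (bad block
#' syntax, unknown event type, invalid strand) report the offending row.
#'
#' @param path Path to a unified event TSV.
#' @return An event tibble.
#' @export
read_unified <- function(path) {
  if (!file.exists(path)) stop("unified event file not found: ", path)
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || lines[1] != paste(.unified_header, collapse = "\t")) {
    stop("not a unified event TSV (bad header): ", path)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(event_table(tibble::tibble(
      event_id = character(0), gene_name = character(0), chrom = character(0),
      strand = character(0), event_type = character(0), blocks = list(),
      source_tool = character(0)
    )))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    stop("row ", which(nf != 7L)[1] + 1L, ": expected 7 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  df <- tibble::tibble(
    event_id = m[, 1], gene_name = m[, 2], chrom = m[, 3], strand = m[, 4],
    event_type = m[, 5], blocks_chr = m[, 6], source_tool = m[, 7]
  )
  for (i in seq_len(nrow(df))) {
    if (!df$strand[i] %in% c("+", "-")) {
      stop("row ", i + 1L, ": strand must be '+' or '-'")
    }
    if (!df$event_type[i] %in% EVENT_TYPES) {
      stop("row ", i + 1L, ": unknown event_type '", df$event_type[i], "'")
    }
    if (!grepl("^\\d+-\\d+(;\\d+-\\d+)*$", df$blocks_chr[i])) {
      stop("row ", i + 1L, ": bad block syntax '", df$blocks_chr[i], "'")
    }
  }
  df$blocks <- chr_to_blocks(df$blocks_chr)
  df <- dplyr::select(
    df, "event_id", "gene_name", "chrom", "strand", "event_type", "blocks",
    "source_tool"
  )
  event_table(df)
}
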