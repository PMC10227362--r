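#' Read alignment records from a SAM file
#'
#' Parses the eleven mandatory SAM columns of every non-header line into a
#' tibble. No filtering is applied; use the `flag` column to distinguish
#' unmapped (0x4), secondary (0x100) and supplementary (0x800) records.
#'
#' @param path Path to a SAM text file.
#' @return A tibble with `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readr::read_lines(path)
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble::tibble(
      qname = character(0), flag = integer(0), rname = character(0),
      pos = integer(0), mapq = integer(0), cigar = character(0)
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed SAM line ", which(nf < 11L)[1], ": fewer than 11 fields")
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  tibble::tibble(
    qname = m[, 1], flag = as.integer(m[, 2]), rname = m[, 3],
    pos = as.integer(m[, 4]), mapq = as.integer(m[, 5]), cigar = m[, 6]
  )
}

#' Decode CIGAR strings into reference blocks and splice junctions
#'
#' Reference-consuming operations (`M`, `=`, `X`, `D`) extend the current
#' block; `N` closes it and opens a junction spanning the skipped reference;
#' `I`, `S`, `H` and `P` consume no reference. Decoding is delegated to the
#' CIGAR machinery of GenomicAlignments and returned in tidy form. A junction
#' is reported as the pair (last reference base before the gap, first
#' reference base after it).
#'
#' @param pos Integer vector of 1-based leftmost mapping positions.
#' @param cigar Character vector of CIGAR strings (same length as `pos`).
#' @param read_id Optional ids used in error messages.
#' @return A list with `blocks` and `junctions`: each a list (one element per
#'   record) of tibbles with `start`/`end` resp. `donor`/`acceptor` columns.
#' @export
extract_alignment_blocks <- function(pos, cigar, read_id = NULL) {
  stopifnot(length(pos) == length(cigar))
  rl <- tryCatch(
    GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar,
      pos = pos, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE
    ),
    error = function(e) {
      id <- if (is.null(read_id)) "" else paste0(" (read ", read_id[1], ")")
      stop("invalid CIGAR", id, ": ", conditionMessage(e))
    }
  )
  blocks <- lapply(seq_along(rl), function(i) {
    r <- rl[[i]]
    tibble::tibble(
      start = BiocGenerics::start(r), end = BiocGenerics::end(r)
    )
  })
  junctions <- lapply(blocks, .blocks_junctions)
  list(blocks = blocks, junctions = junctions)
}
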