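#' Benchmark a splice-aware alignment against per-read truth
#'
#' Computes the mapping benchmark metrics: the fraction of unmapped reads
#' relative to all simulated reads, and precision — the proportion of
#' correctly mapped reads (and, separately, junctions) relative to all mapped
#' reads. Only primary alignments are scored (one vote per read); reads
#' present in the truth table but absent from the SAM count as unmapped, since
#' some mappers drop reads instead of emitting unmapped records. A read is
#' correct iff its chromosome matches, it has the same number of blocks as the
#' truth, every block boundary is within `tolerance` bases, and its junction
#' set equals the truth junction set within `tolerance`. Junction-level
#' tallies pool all junctions of all primary alignments.
#'
#' @param sam Path to a SAM file, or a tibble from [read_sam()].
#' @param truth A truth read tibble from [simulate_reads()].
#' @param tolerance Allowed per-boundary deviation in bases (default 0).
#' @return A one-row `mapping_metrics` tibble with `n_simulated`, `n_mapped`,
#'   `n_unmapped`, `n_reads_correct`, `n_junctions_observed`,
#'   `n_junctions_correct`, `fraction_unmapped`, `precision_read`,
#'   `precision_junction`.
#' @export
evaluate_mapping <- function(sam, truth, tolerance = 0L) {
  stopifnot(tolerance >= 0)
  if (is.character(sam)) sam <- read_sam(sam)
  if (nrow(truth) == 0) stop("empty truth read table")
  unknown <- setdiff(sam$qname, truth$read_id)
  if (length(unknown) > 0) {
    stop(
      "SAM read id(s) absent from truth: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    )
  }
  primary <- dplyr::filter(
    sam, bitwAnd(.data$flag, 0x100L) == 0L, bitwAnd(.data$flag, 0x800L) == 0L
  )
  mapped <- dplyr::filter(primary, bitwAnd(.data$flag, 0x4L) == 0L)
  n_sim <- nrow(truth)
  n_mapped <- nrow(mapped)
  n_unmapped <- n_sim - n_mapped
  truth_blocks <- stats::setNames(truth$blocks, truth$read_id)
  truth_junc <- stats::setNames(truth$junctions, truth$read_id)
  truth_chrom <- stats::setNames(truth$chrom, truth$read_id)
  n_reads_correct <- 0L
  n_j_obs <- 0L
  n_j_corr <- 0L
  if (n_mapped > 0) {
    dec <- extract_alignment_blocks(mapped$pos, mapped$cigar, mapped$qname)
    for (i in seq_len(n_mapped)) {
      id <- mapped$qname[i]
      tb <- truth_blocks[[id]]
      tj <- truth_junc[[id]]
      ob <- dec$blocks[[i]]
      oj <- dec$junctions[[i]]
      n_j_obs <- n_j_obs + nrow(oj)
      chrom_ok <- mapped$rname[i] == truth_chrom[[id]]
      if (chrom_ok && nrow(oj) > 0 && nrow(tj) > 0) {
        for (k in seq_len(nrow(oj))) {
          if (any(abs(oj$donor[k] - tj$donor) <= tolerance &
              abs(oj$acceptor[k] - tj$acceptor) <= tolerance)) {
            n_j_corr <- n_j_corr + 1L
          }
        }
      }
      blocks_ok <- chrom_ok && nrow(ob) == nrow(tb) &&
        all(abs(ob$start - tb$start) <= tolerance) &&
        all(abs(ob$end - tb$end) <= tolerance)
      junc_ok <- nrow(oj) == nrow(tj) &&
        (nrow(oj) == 0 ||
          (all(abs(oj$donor - tj$donor) <= tolerance) &&
            all(abs(oj$acceptor - tj$acceptor) <= tolerance)))
      if (blocks_ok && junc_ok) n_reads_correct <- n_reads_correct + 1L
    }
  }
  out <- tibble::tibble(
    n_simulated = n_sim,
    n_mapped = n_mapped,
    n_unmapped = n_unmapped,
    n_reads_correct = n_reads_correct,
    n_junctions_observed = n_j_obs,
    n_junctions_correct = n_j_corr,
    fraction_unmapped = n_unmapped / n_sim,
    precision_read = if (n_mapped == 0) NA_real_ else n_reads_correct / n_mapped,
    precision_junction = if (n_j_obs == 0) NA_real_ else n_j_corr / n_j_obs
  )
  class(out) <- c("mapping_metrics", class(out))
  out
}

#' Tabulate mapping metrics across tool labels
#'
#' @param metrics A named list of `mapping_metrics` rows (one per tool label).
#' @return A `mapping_report` tibble sorted by label with the columns
#'   `label`, `n_simulated`, `n_mapped`, `fraction_unmapped`,
#'   `precision_read`, `precision_junction` — the plot-ready pairs are
#'   (`precision_read`, `fraction_unmapped`).
#' @export
mapping_report <- function(metrics) {
  if (length(metrics) == 0) stop("at least one labeled metrics row required")
  labels <- names(metrics)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("metrics must be a named list (tool labels)")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  out <- dplyr::bind_rows(metrics) |>
    dplyr::mutate(label = labels, .before = 1) |>
    dplyr::select(
      "label", "n_simulated", "n_mapped", "fraction_unmapped",
      "precision_read", "precision_junction"
    ) |>
    dplyr::arrange(.data$label)
  class(out) <- c("mapping_report", class(out))
  out
}

#' Write a mapping report as TSV
#'
#' Precision columns of tools with zero mapped reads are written as `NA`.
#'
#' @param report A [mapping_report()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_report <- function(report, path) {
  readr::write_tsv(report, path, na = "NA")
  invisible(path)
}
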