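#' Gene models as a tidy exon table
#'
#' A gene model is represented as a tibble with one row per exon and columns
#' `gene_id`, `gene_name`, `chrom`, `strand`, `transcript_id`, `is_main`,
#' `exon_index`, `start`, `end`. Coordinates are 1-based inclusive (GTF/SAM
#' convention). `exon_index` numbers exons in transcription order, so index 1
#' is the first transcribed exon: the genomic-leftmost exon on the `+` strand
#' and the genomic-rightmost exon on the `-` strand. Exactly one transcript per
#' gene carries `is_main = TRUE`; it is the reference isoform against which
#' alternative-splicing events are defined.
#'
#' @param exons A data frame with at least `gene_id`, `chrom`, `strand`,
#'   `transcript_id`, `start`, `end`. `gene_name` defaults to `gene_id`,
#'   `is_main` is assigned by [assign_main_transcript()] when absent, and
#'   `exon_index` is recomputed from coordinates and strand.
#' @return A validated gene-model tibble.
#' @export
gene_models <- function(exons) {
  exons <- tibble::as_tibble(exons)
  required <- c("gene_id", "chrom", "strand", "transcript_id", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    stop("gene_models(): missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"gene_name" %in% names(exons)) exons$gene_name <- exons$gene_id
  exons$gene_name <- dplyr::coalesce(exons$gene_name, exons$gene_id)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- dplyr::arrange(exons, .data$gene_id, .data$transcript_id, .data$start)
  exons <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(
      exon_index = if (.data$strand[1] == "-") dplyr::n():1L else seq_len(dplyr::n())
    ) |>
    dplyr::ungroup()
  if (!"is_main" %in% names(exons)) {
    exons <- assign_main_transcript(exons)
  }
  exons <- dplyr::select(
    exons, "gene_id", "gene_name", "chrom", "strand",
    "transcript_id", "is_main", "exon_index", "start", "end"
  )
  validate_gene_models(exons)
  exons
}

#' Validate a gene-model exon table
#'
#' Checks the structural invariants: positive 1-based coordinates with
#' `end >= start`, strand in `{+,-}`, every transcript on a single chromosome
#' and strand with sorted non-overlapping exons, transcription-order
#' `exon_index`, and exactly one main transcript per gene.
#'
#' @param models A gene-model tibble.
#' @return `models`, invisibly; errors describe the first violated invariant.
#' @export
validate_gene_models <- function(models) {
  if (nrow(models) == 0) stop("gene model has zero exons")
  if (any(models$start < 1L)) stop("exon start must be >= 1")
  if (any(models$end < models$start)) stop("exon end must be >= start")
  if (!all(models$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  by_tx <- dplyr::group_by(models, .data$transcript_id)
  bad_mix <- dplyr::summarise(
    by_tx,
    mixed = dplyr::n_distinct(.data$chrom) > 1 | dplyr::n_distinct(.data$strand) > 1,
    .groups = "drop"
  )
  if (any(bad_mix$mixed)) {
    stop(
      "transcript(s) on mixed chromosomes or strands: ",
      paste(bad_mix$transcript_id[bad_mix$mixed], collapse = ", ")
    )
  }
  overlap <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(models, .data$start), .data$transcript_id),
    bad = dplyr::n() > 1 && any(.data$start[-1] <= .data$end[-dplyr::n()]),
    .groups = "drop"
  )
  if (any(overlap$bad)) {
    stop(
      "overlapping exons within transcript(s): ",
      paste(overlap$transcript_id[overlap$bad], collapse = ", ")
    )
  }
  mains <- models |>
    dplyr::distinct(.data$gene_id, .data$transcript_id, .data$is_main) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_main = sum(.data$is_main), .groups = "drop")
  if (any(mains$n_main != 1L)) {
    stop(
      "each gene must have exactly one main transcript; offending gene(s): ",
      paste(mains$gene_id[mains$n_main != 1L], collapse = ", ")
    )
  }
  invisible(models)
}

#' Assign the main transcript of each gene
#'
#' When the annotation does not tag a reference isoform, the main transcript is
#' chosen deterministically: the transcript with the most exons, ties broken by
#' the longest genomic span, then by lexicographic `transcript_id`.
#'
#' @param exons An exon table (no `is_main` needed).
#' @return The table with a logical `is_main` column.
#' @export
assign_main_transcript <- function(exons) {
  ranking <- exons |>
    dplyr::group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::summarise(
      n_exons = dplyr::n(),
      span = max(.data$end) - min(.data$start) + 1L,
      .groups = "drop_last"
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$n_exons), dplyr::desc(.data$span), .data$transcript_id,
      .by_group = TRUE
    ) |>
    dplyr::summarise(main_tx = .data$transcript_id[1], .groups = "drop")
  exons$is_main <- NULL
  dplyr::left_join(exons, ranking, by = "gene_id") |>
    dplyr::mutate(is_main = .data$transcript_id == .data$main_tx) |>
    dplyr::select(-"main_tx")
}

#' Introns of each transcript
#'
#' For consecutive exons `[s1,e1]`, `[s2,e2]` in genomic order the intron is
#' `[e1+1, s2-1]`; a transcript with `n` exons has `n - 1` introns and a
#' single-exon transcript has none. `intron_index` follows genomic order.
#'
#' @param models A gene-model tibble.
#' @param transcripts Optional character vector restricting the output to the
#'   given transcript ids.
#' @return A tibble with `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `intron_index`, `start`, `end`.
#' @export
transcript_introns <- function(models, transcripts = NULL) {
  if (!is.null(transcripts)) {
    models <- dplyr::filter(models, .data$transcript_id %in% transcripts)
  }
  models |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(
      .data$gene_id, .data$transcript_id, .data$chrom, .data$strand
    ) |>
    dplyr::reframe(.introns_of(.data$start, .data$end)) |>
    tibble::as_tibble()
}

.introns_of <- function(s, e) {
  n <- length(s)
  if (n < 2) {
    return(tibble::tibble(
      intron_index = integer(0), start = integer(0), end = integer(0)
    ))
  }
  tibble::tibble(
    intron_index = seq_len(n - 1L), start = e[-n] + 1L, end = s[-1L] - 1L
  )
}

#' Genomic span of each gene
#'
#' @param models A gene-model tibble.
#' @return A tibble with one row per gene: `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `start`, `end` (union span over all transcripts).
#' @export
gene_spans <- function(models) {
  models |>
    dplyr::group_by(
      .data$gene_id, .data$gene_name, .data$chrom, .data$strand
    ) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
}

#' Drop all alternative isoforms, keeping only main transcripts
#'
#' Emulates the truncated-annotation setting used to probe de novo event
#' detection: every gene is reduced to the description of its main transcript;
#' exon coordinates are untouched. Idempotent.
#'
#' @param models A gene-model tibble.
#' @return A gene-model tibble containing only `is_main` transcripts.
#' @export
truncate_annotation <- function(models) {
  out <- dplyr::filter(models, .data$is_main)
  validate_gene_models(out)
  out
}
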