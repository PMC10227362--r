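#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF through `rtracklayer::import()` and assembles
#' the exon features into a gene-model tibble. A transcript carrying a
#' `tag "main"` (or Ensembl's canonical tag) attribute becomes the main
#' transcript; otherwise the deterministic rule of
#' [assign_main_transcript()] applies. `gene_name` falls back to `gene_id`
#' when the annotation lacks it.
#'
#' @param path Path to a GTF file.
#' @return A gene-model tibble (see [gene_models()]).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readr::read_lines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  if (any(nfield != 9L)) {
    bad <- body[which(nfield != 9L)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated columns")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  feat <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    transcript_id = if ("transcript_id" %in% names(meta)) {
      as.character(meta$transcript_id)
    } else {
      NA_character_
    },
    gene_name = if ("gene_name" %in% names(meta)) {
      as.character(meta$gene_name)
    } else {
      NA_character_
    },
    tag = if ("tag" %in% names(meta)) as.character(meta$tag) else NA_character_
  )
  tx_feat <- dplyr::filter(feat, .data$type == "transcript")
  exons <- dplyr::filter(feat, .data$type == "exon")
  if (nrow(exons) == 0) stop("GTF contains no exon features: ", path)
  if (any(is.na(exons$transcript_id))) {
    stop("exon feature without transcript_id attribute in ", path)
  }
  empty_tx <- setdiff(tx_feat$transcript_id, exons$transcript_id)
  if (length(empty_tx) > 0) {
    stop(
      "transcript(s) with zero exons: ", paste(empty_tx, collapse = ", ")
    )
  }
  strands <- dplyr::distinct(exons, .data$transcript_id, .data$strand)
  dup <- strands$transcript_id[duplicated(strands$transcript_id)]
  if (length(dup) > 0) {
    stop("exons of transcript(s) on mixed strands: ", paste(dup, collapse = ", "))
  }
  tagged <- unique(c(
    tx_feat$transcript_id[!is.na(tx_feat$tag) &
      tx_feat$tag %in% c("main", "Ensembl_canonical")],
    exons$transcript_id[!is.na(exons$tag) &
      exons$tag %in% c("main", "Ensembl_canonical")]
  ))
  exons <- dplyr::select(
    exons, "gene_id", "gene_name", "chrom", "strand",
    "transcript_id", "start", "end"
  )
  tagged_genes <- unique(exons$gene_id[exons$transcript_id %in% tagged])
  if (length(tagged) > 0 &&
      setequal(tagged_genes, unique(exons$gene_id))) {
    exons$is_main <- exons$transcript_id %in% tagged
  }
  gene_models(exons)
}

#' Write gene models to a GTF file
#'
#' Emits gene, transcript and exon features with a fixed attribute order so
#' that identical models serialize to identical bytes; the main transcript of
#' each gene is marked with a `tag "main"` attribute and the file round-trips
#' through [read_gtf()] without loss of gene/transcript ids, exon coordinates,
#' strand or main-transcript assignment. An empty model collection produces a
#' file holding only the header comment.
#'
#' @param models A gene-model tibble (may have zero genes via a 0-row tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  header <- "#!annotation-source splicebench"
  if (is.null(models) || nrow(models) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  validate_gene_models(models)
  spans <- gene_spans(models) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id)
  tx <- models |>
    dplyr::group_by(
      .data$gene_id, .data$gene_name, .data$chrom, .data$strand,
      .data$transcript_id, .data$is_main
    ) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$is_main), .data$transcript_id)
  gtf_line <- function(chrom, feature, start, end, strand, attrs) {
    paste(chrom, "splicebench", feature, start, end, ".", strand, ".", attrs,
      sep = "\t"
    )
  }
  out <- character(0)
  exn <- dplyr::arrange(models, .data$transcript_id, .data$start)
  exn_split <- split(exn, exn$transcript_id)
  for (g in seq_len(nrow(spans))) {
    gs <- spans[g, ]
    out <- c(out, gtf_line(
      gs$chrom, "gene", gs$start, gs$end, gs$strand,
      sprintf('gene_id "%s"; gene_name "%s";', gs$gene_id, gs$gene_name)
    ))
    gtx <- tx[tx$gene_id == gs$gene_id, ]
    for (t in seq_len(nrow(gtx))) {
      tt <- gtx[t, ]
      tag <- if (tt$is_main) ' tag "main";' else ""
      out <- c(out, gtf_line(
        tt$chrom, "transcript", tt$start, tt$end, tt$strand,
        sprintf(
          'gene_id "%s"; transcript_id "%s"; gene_name "%s";%s',
          tt$gene_id, tt$transcript_id, tt$gene_name, tag
        )
      ))
      te <- exn_split[[tt$transcript_id]]
      out <- c(out, gtf_line(
        te$chrom, "exon", te$start, te$end, te$strand,
        sprintf(
          'gene_id "%s"; transcript_id "%s"; exon_number "%d"; gene_name "%s";%s',
          te$gene_id, te$transcript_id, te$exon_index, te$gene_name,
          if (tt$is_main) ' tag "main";' else ""
        )
      ))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, out), con)
  invisible(path)
}
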