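#' @title Normalizing heterogeneous event-reporting conventions
#' @description
#' Event detection tools report the same biological event in incompatible
#' coordinate conventions. Three dialects are supported and mapped into the
#' unified format using the gene model as the coordinate authority:
#'
#' * `skipped_exon` — the event-defining coordinates themselves (the
#'   convention of tools that report a skipped exon directly), optionally with
#'   a claimed event type, which lets this dialect carry all eight types;
#' * `flanking_exons` — the two neighboring exons of a skipping event; the
#'   skipped exon(s) are recovered as the main-transcript exons strictly
#'   between the flanks;
#' * `junction` — an anchoring exon plus splice junction(s); junctions are
#'   classified against the gene's main transcript into ES/MES (both sites on
#'   main-transcript introns with exons in between), A5/A3 (one shared splice
#'   site, the other shifted), or IR (a retained-intron flag over an
#'   annotated intron).
#'
#' A junction whose shifted site is not an annotated splice site of *any*
#' transcript of the gene is rejected as `novel-junction`; block derivation
#' always uses the main transcript only. This makes normalization sensitive
#' to annotation truncation exactly where de novo detection is hard: with
#' alternative isoforms removed from the annotation, shifted splice sites
#' (A5/A3) lose their annotation support and their junction records are
#' rejected, while skipping and retention records survive.
#' @name adapters
NULL

.resolve_gene <- function(spans, chrom, strand, lo, hi) {
  cand <- spans[
    spans$chrom == chrom & spans$strand == strand &
      spans$start <= lo & spans$end >= hi,
  ]
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[order(cand$end - cand$start, cand$gene_id), ]
  cand[1, ]
}

.mk_event <- function(gene_name, chrom, strand, type, blocks) {
  list(
    gene_name = gene_name, chrom = chrom, strand = strand,
    event_type = type, blocks = blocks
  )
}

# -- skipped-exon dialect ----------------------------------------------------

.norm_skipped_one <- function(row, spans) {
  blocks <- tryCatch(chr_to_blocks(row$blocks)[[1]], error = function(e) NULL)
  if (is.null(blocks)) return(list(reason = "parse-error"))
  type <- row$claimed_type
  if (is.na(type) || !nzchar(type)) {
    type <- if (nrow(blocks) == 1) "ES" else "MES"
  }
  if (!type %in% EVENT_TYPES) return(list(reason = "parse-error"))
  hint <- if ("gene" %in% names(row)) row$gene else NA_character_
  if (!is.na(hint) && nzchar(hint) &&
      any(spans$gene_id == hint | spans$gene_name == hint)) {
    g <- spans[spans$gene_id == hint | spans$gene_name == hint, ][1, ]
    return(list(event = .mk_event(g$gene_name, row$chrom, row$strand, type, blocks)))
  }
  gene <- .resolve_gene(
    spans, row$chrom, row$strand, min(blocks$start), max(blocks$end)
  )
  if (is.null(gene)) return(list(reason = "unresolved-gene"))
  list(event = .mk_event(gene$gene_name, row$chrom, row$strand, type, blocks))
}

#' Normalize skipped-exon dialect records
#'
#' Records carry the event-defining exon(s) verbatim (`blocks` in
#' `start-end[;...]` form); the type defaults to ES (one exon) or MES
#' (several) unless a `claimed_type` says otherwise. The gene is resolved by
#' containment of the blocks in a gene span (smallest span, then lexicographic
#' `gene_id`, on ties).
#'
#' @param records A tibble with `chrom`, `strand`, `blocks` and optional
#'   `gene`, `claimed_type` columns (see [read_dialect_tsv()]).
#' @param models A gene-model tibble.
#' @param tool Source-tool label stamped on the emitted events.
#' @param strict Raise an error on the first rejection instead of collecting
#'   it.
#' @return A list with `events` (event tibble) and `rejections` (tibble with
#'   `row`, `reason`).
#' @export
normalize_skipped_exon <- function(records, models, tool = "tool", strict = FALSE) {
  .normalize_dialect(records, models, tool, strict, .norm_skipped_one)
}

# -- flanking-exons dialect --------------------------------------------------

.norm_flanking_one <- function(row, spans, main_exons) {
  up <- c(row$up_start, row$up_end)
  dn <- c(row$down_start, row$down_end)
  if (any(is.na(c(up, dn))) || up[2] >= dn[1]) return(list(reason = "parse-error"))
  me <- main_exons[
    main_exons$chrom == row$chrom & main_exons$strand == row$strand,
  ]
  has_both <- me |>
    dplyr::group_by(.data$gene_id, .data$gene_name) |>
    dplyr::summarise(
      ok = any(.data$start == up[1] & .data$end == up[2]) &&
        any(.data$start == dn[1] & .data$end == dn[2]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$ok)
  if (nrow(has_both) == 0) return(list(reason = "unresolved-gene"))
  gid <- has_both$gene_id[1]
  between <- me[
    me$gene_id == gid & me$start > up[2] & me$end < dn[1],
  ]
  if (nrow(between) == 0) return(list(reason = "not-normalizable"))
  between <- between[order(between$start), ]
  list(event = .mk_event(
    has_both$gene_name[1], row$chrom, row$strand,
    if (nrow(between) == 1) "ES" else "MES",
    tibble::tibble(start = between$start, end = between$end)
  ))
}

#' Normalize flanking-exons dialect records
#'
#' Records give the upstream and downstream neighboring exons of a skipping
#' event; the skipped exon(s) are the main-transcript exons strictly between
#' the flanks (ES for one, MES for several). Adjacent flanks with nothing
#' annotated in between are rejected as `not-normalizable` (a candidate
#' retention or novel junction this dialect cannot express); flanks matching
#' no annotated transcript are rejected as `unresolved-gene`.
#'
#' @inheritParams normalize_skipped_exon
#' @param records A tibble with `chrom`, `strand`, `up_start`, `up_end`,
#'   `down_start`, `down_end`.
#' @return As [normalize_skipped_exon()].
#' @export
normalize_flanking_exons <- function(records, models, tool = "tool", strict = FALSE) {
  .normalize_dialect(records, models, tool, strict, .norm_flanking_one)
}

# -- junction dialect --------------------------------------------------------

.parse_junctions <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(tibble::tibble(d = integer(0), a = integer(0)))
  }
  if (!grepl("^\\d+:\\d+(;\\d+:\\d+)*$", x)) return(NULL)
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble::tibble(
    d = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    a = vapply(parts, function(p) as.integer(p[2]), integer(1))
  )
}

.classify_junction <- function(d, a, strand, gene_sites, main) {
  if (d >= a) return(list(reason = "parse-error"))
  if (!(d %in% gene_sites$left) || !(a %in% gene_sites$right)) {
    return(list(reason = "novel-junction"))
  }
  m_li <- main$start - 1L # annotated splice sites flanking each main intron
  m_ri <- main$end + 1L
  if (any(m_li == d & m_ri == a)) return(list(reason = "reference-junction"))
  # `main` rows are introns; exons strictly inside come from the exon table
  inside_ex <- gene_sites$main_exons[
    gene_sites$main_exons$start > d & gene_sites$main_exons$end < a,
  ]
  if (nrow(inside_ex) > 0) {
    if (d %in% m_li && a %in% m_ri) {
      inside_ex <- inside_ex[order(inside_ex$start), ]
      return(list(
        type = if (nrow(inside_ex) == 1) "ES" else "MES",
        blocks = tibble::tibble(start = inside_ex$start, end = inside_ex$end)
      ))
    }
    return(list(reason = "not-normalizable"))
  }
  if (a %in% m_ri) {
    d_ann <- m_li[match(a, m_ri)]
    type <- if (strand == "+") "A5" else "A3"
    return(list(type = type, blocks = tibble::tibble(
      start = min(d, d_ann) + 1L, end = max(d, d_ann)
    )))
  }
  if (d %in% m_li) {
    a_ann <- m_ri[match(d, m_li)]
    type <- if (strand == "+") "A3" else "A5"
    return(list(type = type, blocks = tibble::tibble(
      start = min(a, a_ann), end = max(a, a_ann) - 1L
    )))
  }
  list(reason = "not-normalizable")
}

.norm_junction_one <- function(row, spans, main_exons, all_introns, main_introns) {
  gene <- .resolve_gene(
    spans, row$chrom, row$strand, row$anchor_start, row$anchor_end
  )
  if (is.null(gene)) return(list(reason = "unresolved-gene"))
  gid <- gene$gene_id
  g_introns <- all_introns[all_introns$gene_id == gid, ]
  g_main_introns <- main_introns[main_introns$gene_id == gid, ]
  g_main_exons <- main_exons[main_exons$gene_id == gid, ]
  gene_sites <- list(
    left = g_introns$start - 1L,
    right = g_introns$end + 1L,
    main_exons = g_main_exons
  )
  retained <- isTRUE(row$retained) || identical(row$retained, 1L) ||
    identical(row$retained, 1)
  if (retained) {
    cover <- g_main_introns[
      g_main_introns$start >= row$anchor_start &
        g_main_introns$end <= row$anchor_end,
    ]
    if (nrow(cover) == 0) return(list(reason = "not-normalizable"))
    return(list(event = .mk_event(
      gene$gene_name, row$chrom, row$strand, "IR",
      tibble::tibble(start = cover$start[1], end = cover$end[1])
    )))
  }
  jn <- .parse_junctions(row$junctions)
  if (is.null(jn)) return(list(reason = "parse-error"))
  if (nrow(jn) == 0) return(list(reason = "not-normalizable"))
  results <- lapply(seq_len(nrow(jn)), function(k) {
    .classify_junction(jn$d[k], jn$a[k], row$strand, gene_sites, g_main_introns)
  })
  ok <- vapply(results, function(r) is.null(r$reason), logical(1))
  if (!any(ok)) return(list(reason = results[[1]]$reason))
  keys <- vapply(results[ok], function(r) {
    paste(r$type, paste(r$blocks$start, r$blocks$end, collapse = ";"))
  }, character(1))
  if (length(unique(keys)) > 1) return(list(reason = "ambiguous"))
  if (!all(ok)) return(list(reason = results[[which(!ok)[1]]]$reason))
  r <- results[[which(ok)[1]]]
  list(event = .mk_event(
    gene$gene_name, row$chrom, row$strand, r$type, r$blocks
  ))
}

#' Normalize junction dialect records
#'
#' Records carry an anchoring exon and one or more junctions given as genomic
#' `donor_end:acceptor_start` pairs (left flank last base, right flank first
#' base), or a retained-intron flag. Classification against the anchor gene's
#' main transcript follows the rules described in [adapters]. Records whose
#' junction uses a splice site annotated in no transcript of the gene are
#' rejected as `novel-junction`.
#'
#' @inheritParams normalize_skipped_exon
#' @param records A tibble with `chrom`, `strand`, `anchor_start`,
#'   `anchor_end`, `junctions`, `retained`.
#' @return As [normalize_skipped_exon()].
#' @export
normalize_junctions <- function(records, models, tool = "tool", strict = FALSE) {
  .normalize_dialect(records, models, tool, strict, .norm_junction_one)
}

# shared driver: iterates rows, dispatches to the per-row classifier,
# assembles events and the rejection report
.normalize_dialect <- function(records, models, tool, strict, fn) {
  spans <- gene_spans(models)
  main_models <- dplyr::filter(models, .data$is_main)
  main_exons <- dplyr::select(
    main_models, "gene_id", "gene_name", "chrom", "strand", "start", "end"
  )
  extra <- list()
  if (identical(fn, .norm_flanking_one)) {
    extra <- list(main_exons = main_exons)
  } else if (identical(fn, .norm_junction_one)) {
    extra <- list(
      main_exons = main_exons,
      all_introns = transcript_introns(models),
      main_introns = transcript_introns(main_models)
    )
  }
  events <- list()
  rej_row <- integer(0)
  rej_reason <- character(0)
  for (i in seq_len(nrow(records))) {
    res <- do.call(fn, c(list(records[i, ], spans), extra))
    if (!is.null(res$event)) {
      events[[length(events) + 1L]] <- res$event
    } else {
      if (strict) {
        stop("record ", i, " rejected (", res$reason, ") in strict mode")
      }
      rej_row <- c(rej_row, i)
      rej_reason <- c(rej_reason, res$reason)
    }
  }
  ev <- if (length(events) == 0) {
    event_table(tibble::tibble(
      event_id = character(0), gene_name = character(0), chrom = character(0),
      strand = character(0), event_type = character(0), blocks = list(),
      source_tool = character(0)
    ))
  } else {
    event_table(tibble::tibble(
      event_id = sprintf("%s_%05d", tool, seq_along(events)),
      gene_name = vapply(events, function(e) e$gene_name, character(1)),
      chrom = vapply(events, function(e) e$chrom, character(1)),
      strand = vapply(events, function(e) e$strand, character(1)),
      event_type = vapply(events, function(e) e$event_type, character(1)),
      blocks = lapply(events, function(e) e$blocks),
      source_tool = tool
    ))
  }
  list(
    events = ev,
    rejections = tibble::tibble(row = rej_row, reason = rej_reason)
  )
}

#' Normalize a batch of dialect record sets
#'
#' Dispatches each record set to its dialect's normalizer and pools the
#' unified events (event ids renumbered to stay unique) and the rejection
#' report. In `lenient` mode rejections are collected and normalization
#' continues; in `strict` mode the first rejection raises an error.
#'
#' @param record_sets A named list of record tibbles; names (or a `dialect`
#'   attribute on each tibble) must be `skipped_exon`, `flanking_exons` or
#'   `junction`.
#' @param models A gene-model tibble.
#' @param mode `"lenient"` or `"strict"`.
#' @param tool Source-tool label.
#' @return A list with `events` and `rejections` (tibble with `dialect`,
#'   `row`, `reason`).
#' @export
normalize_batch <- function(record_sets, models, mode = c("lenient", "strict"),
                            tool = "tool") {
  mode <- match.arg(mode)
  if (is.data.frame(record_sets)) {
    record_sets <- stats::setNames(
      list(record_sets), attr(record_sets, "dialect")
    )
  }
  valid <- c("skipped_exon", "flanking_exons", "junction")
  all_events <- list()
  all_rej <- list()
  for (d in names(record_sets)) {
    if (!d %in% valid) {
      stop("unknown dialect '", d, "'; expected one of: ", paste(valid, collapse = ", "))
    }
    fn <- switch(d,
      skipped_exon = normalize_skipped_exon,
      flanking_exons = normalize_flanking_exons,
      junction = normalize_junctions
    )
    res <- fn(record_sets[[d]], models, tool = tool, strict = mode == "strict")
    all_events[[d]] <- res$events
    all_rej[[d]] <- dplyr::mutate(res$rejections, dialect = d, .before = 1)
  }
  events <- dplyr::bind_rows(all_events)
  if (nrow(events) > 0) {
    events$event_id <- sprintf("%s_%05d", tool, seq_len(nrow(events)))
  }
  list(events = events, rejections = dplyr::bind_rows(all_rej))
}

#' Read a dialect TSV file
#'
#' Schemas: `skipped_exon`: `chrom strand blocks [gene] [claimed_type]`;
#' `flanking_exons`: `chrom strand up_start up_end down_start down_end`;
#' `junction`: `chrom strand anchor_start anchor_end junctions retained`
#' (junctions as `donor:acceptor` pairs joined by `;`, empty for
#' retained-intron records).
#'
#' @param path Path to the TSV.
#' @param dialect One of `skipped_exon`, `flanking_exons`, `junction`.
#' @return A record tibble with a `dialect` attribute.
#' @export
read_dialect_tsv <- function(path, dialect = c("skipped_exon", "flanking_exons", "junction")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  int_cols <- switch(dialect,
    skipped_exon = character(0),
    flanking_exons = c("up_start", "up_end", "down_start", "down_end"),
    junction = c("anchor_start", "anchor_end")
  )
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  if (dialect == "skipped_exon") {
    if (!"gene" %in% names(df)) df$gene <- NA_character_
    if (!"claimed_type" %in% names(df)) df$claimed_type <- NA_character_
  }
  if (dialect == "junction") {
    df$retained <- as.integer(df$retained)
    if (!"junctions" %in% names(df)) df$junctions <- NA_character_
  }
  attr(df, "dialect") <- dialect
  df
}

#' Write a dialect TSV file
#'
#' @param records A record tibble (with a `dialect` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dialect_tsv <- function(records, path) {
  readr::write_tsv(records, path, na = "")
  invisible(path)
}
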