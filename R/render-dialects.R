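#' Render truth events into a tool-reporting dialect
#'
#' Emulates how a detection tool following one of the three reporting
#' conventions would describe each truth event, using only the gene's main
#' transcript coordinates (what a tool can observe irrespective of which
#' annotation it was handed). Not every dialect can express every type: the
#' skipped-exon (direct-coordinates) dialect carries all eight types; the
#' flanking-exons dialect only skipping (ES/MES); the junction dialect
#' ES/MES, A5/A3 (the alternative junction) and IR (a retained flag on the
#' merged exon). Inexpressible events are silently omitted — the returned
#' records carry a `truth_event_id` column so coverage can be audited.
#'
#' @param truth A truth event tibble from [simulate_annotation()].
#' @param models The gene-model tibble the truth was simulated from.
#' @param dialect One of `skipped_exon`, `flanking_exons`, `junction`.
#' @return A record tibble in the dialect's schema (plus `truth_event_id`),
#'   with a `dialect` attribute.
#' @export
render_dialect <- function(truth, models,
                           dialect = c("skipped_exon", "flanking_exons", "junction")) {
  dialect <- match.arg(dialect)
  main <- dplyr::filter(models, .data$is_main)
  main_by_gene <- split(main[order(main$start), ], main$gene_id[order(main$start)])
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    ev <- truth[i, ]
    me <- main_by_gene[[ev$gene_id]]
    switch(dialect,
      skipped_exon = .render_skipped(ev),
      flanking_exons = .render_flanking(ev, me),
      junction = .render_junction(ev, me)
    )
  })
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  attr(out, "dialect") <- dialect
  out
}

.render_skipped <- function(ev) {
  tibble::tibble(
    chrom = ev$chrom, strand = ev$strand,
    blocks = blocks_to_chr(ev$blocks),
    gene = ev$gene_name, claimed_type = ev$event_type,
    truth_event_id = ev$event_id
  )
}

.render_flanking <- function(ev, me) {
  if (!ev$event_type %in% c("ES", "MES")) return(NULL)
  b <- ev$blocks[[1]]
  up <- me[me$end < b$start[1], ]
  dn <- me[me$start > b$end[nrow(b)], ]
  if (nrow(up) == 0 || nrow(dn) == 0) return(NULL)
  up <- up[nrow(up), ]
  dn <- dn[1, ]
  tibble::tibble(
    chrom = ev$chrom, strand = ev$strand,
    up_start = up$start, up_end = up$end,
    down_start = dn$start, down_end = dn$end,
    truth_event_id = ev$event_id
  )
}

.render_junction <- function(ev, me) {
  b <- ev$blocks[[1]]
  type <- ev$event_type
  jrow <- function(anchor_s, anchor_e, junctions, retained = 0L) {
    tibble::tibble(
      chrom = ev$chrom, strand = ev$strand,
      anchor_start = anchor_s, anchor_end = anchor_e,
      junctions = junctions, retained = retained,
      truth_event_id = ev$event_id
    )
  }
  if (type %in% c("ES", "MES")) {
    up <- me[me$end < b$start[1], ]
    dn <- me[me$start > b$end[nrow(b)], ]
    if (nrow(up) == 0 || nrow(dn) == 0) return(NULL)
    up <- up[nrow(up), ]
    dn <- dn[1, ]
    return(jrow(up$start, up$end, sprintf("%d:%d", up$end, dn$start)))
  }
  if (type == "IR") {
    left <- me[me$end == b$start - 1L, ]
    right <- me[me$start == b$end + 1L, ]
    if (nrow(left) == 0 || nrow(right) == 0) return(NULL)
    return(jrow(left$start[1], right$end[1], "", retained = 1L))
  }
  if (type %in% c("A5", "A3")) {
    end_side <- (type == "A5") == (ev$strand == "+")
    if (end_side) {
      ext <- me[me$end == b$start - 1L, ] # donor extended into the intron
      sh <- me[me$end == b$end, ] # donor retreated into the exon
      if (nrow(ext) == 1) {
        donor_exon <- ext
        d_new <- b$end
      } else if (nrow(sh) == 1) {
        donor_exon <- sh
        d_new <- b$start - 1L
      } else {
        return(NULL)
      }
      nxt <- me[me$start > donor_exon$end, ]
      if (nrow(nxt) == 0) return(NULL)
      a_ann <- nxt$start[1]
      anchor <- c(donor_exon$start, d_new)
      return(jrow(anchor[1], anchor[2], sprintf("%d:%d", d_new, a_ann)))
    } else {
      ext <- me[me$start == b$end + 1L, ] # acceptor extended into the intron
      sh <- me[me$start == b$start, ] # acceptor retreated into the exon
      if (nrow(ext) == 1) {
        acc_exon <- ext
        a_new <- b$start
      } else if (nrow(sh) == 1) {
        acc_exon <- sh
        a_new <- b$end + 1L
      } else {
        return(NULL)
      }
      prv <- me[me$end < acc_exon$start, ]
      if (nrow(prv) == 0) return(NULL)
      d_ann <- prv$end[nrow(prv)]
      return(jrow(a_new, acc_exon$end, sprintf("%d:%d", d_ann, a_new)))
    }
  }
  NULL # MEE/AFE/ALE have no single-junction encoding
}
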