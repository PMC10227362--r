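#' Re-derive AS events by diffing main and alternative transcripts
#'
#' An independent structural validator for simulated annotations: for every
#' non-main transcript it compares the exon chain against the gene's main
#' transcript and reconstructs the AS events that transform one into the
#' other, without consulting the simulator's own truth bookkeeping. Exact exon
#' matches are stripped; an alternative exon spanning several main exons plus
#' their introns yields IR; an alternative exon sharing one boundary with a
#' main exon but not the other yields A5/A3 (strand-aware: a genomic
#' end-boundary shift is a donor shift, hence A5 on `+` and A3 on `-`); novel
#' exons yield AFE/ALE at transcript ends or MEE opposite a missing internal
#' exon; remaining runs of missing internal exons yield ES/MES.
#'
#' @param models A gene-model tibble with main and alternative transcripts.
#' @return An event-like tibble with `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `event_type` and `blocks`; events that cannot be classified are
#'   reported with `event_type = NA`.
#' @export
rederive_events <- function(models) {
  alts <- dplyr::filter(models, !.data$is_main)
  out <- list()
  for (tid in unique(alts$transcript_id)) {
    a <- dplyr::arrange(dplyr::filter(alts, .data$transcript_id == tid), .data$start)
    gid <- a$gene_id[1]
    m <- models |>
      dplyr::filter(.data$gene_id == gid, .data$is_main) |>
      dplyr::arrange(.data$start)
    out[[tid]] <- .diff_transcripts(
      m$start, m$end, a$start, a$end, a$strand[1], gid, tid, a$chrom[1]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      gene_id = character(0), transcript_id = character(0),
      chrom = character(0), strand = character(0),
      event_type = character(0), blocks = list()
    ))
  }
  dplyr::bind_rows(out)
}

.diff_transcripts <- function(ms, me, as_, ae, strand, gid, tid, chrom) {
  n_m <- length(ms)
  n_a <- length(as_)
  m_used <- rep(FALSE, n_m)
  ev_type <- character(0)
  ev_blocks <- list()
  novel_idx <- integer(0)
  add <- function(type, s, e) {
    ev_type <<- c(ev_type, type)
    ev_blocks[[length(ev_blocks) + 1L]] <<-
      tibble::tibble(start = as.integer(s), end = as.integer(e))
  }
  for (k in seq_len(n_a)) {
    s <- as_[k]
    e <- ae[k]
    exact <- which(!m_used & ms == s & me == e)
    if (length(exact) > 0) {
      m_used[exact[1]] <- TRUE
      next
    }
    ov <- which(ms <= e & me >= s)
    if (length(ov) == 0) {
      novel_idx <- c(novel_idx, k)
      next
    }
    if (length(ov) > 1) {
      # candidate retention: one alt exon spanning main exons i..j verbatim
      i <- ov[1]
      j <- ov[length(ov)]
      if (ms[i] == s && me[j] == e) {
        for (t in i:(j - 1L)) add("IR", me[t] + 1L, ms[t + 1L] - 1L)
        m_used[i:j] <- TRUE
      } else {
        add(NA_character_, s, e)
      }
      next
    }
    i <- ov
    m_used[i] <- TRUE
    if (ms[i] == s && me[i] == e) next
    if (me[i] != e) {
      # genomic end boundary moved: donor side on "+", acceptor side on "-"
      add(
        if (strand == "+") "A5" else "A3",
        min(me[i], e) + 1L, max(me[i], e)
      )
    }
    if (ms[i] != s) {
      add(
        if (strand == "+") "A3" else "A5",
        min(ms[i], s), max(ms[i], s) - 1L
      )
    }
  }
  missing <- which(!m_used)
  for (k in novel_idx) {
    s <- as_[k]
    e <- ae[k]
    first_tx <- if (strand == "+") k == 1L else k == n_a
    last_tx <- if (strand == "+") k == n_a else k == 1L
    m_first <- if (strand == "+") 1L else n_m
    m_last <- if (strand == "+") n_m else 1L
    if (first_tx && m_first %in% missing) {
      add("AFE", s, e)
      missing <- setdiff(missing, m_first)
    } else if (last_tx && m_last %in% missing) {
      add("ALE", s, e)
      missing <- setdiff(missing, m_last)
    } else {
      partner <- missing[
        (me[missing] < s) &
          (missing == n_m | ms[pmin(missing + 1L, n_m)] > e)
      ]
      if (length(partner) >= 1) {
        i <- partner[length(partner)]
        b <- rbind(c(ms[i], me[i]), c(s, e))
        b <- b[order(b[, 1]), , drop = FALSE]
        add("MEE", b[, 1], b[, 2])
        missing <- setdiff(missing, i)
      } else {
        add(NA_character_, s, e)
      }
    }
  }
  if (length(missing) > 0) {
    runs <- split(missing, cumsum(c(1L, diff(missing) != 1L)))
    for (r in runs) {
      if (length(r) == 1L) add("ES", ms[r], me[r]) else add("MES", ms[r], me[r])
    }
  }
  tibble::tibble(
    gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
    event_type = ev_type, blocks = ev_blocks
  )
}

#' Fraction of truth events recovered by the structural validator
#'
#' Compares, per alternative transcript, the set of `(event_type, blocks)`
#' signatures recorded in a truth table against those independently re-derived
#' by [rederive_events()] from the transcript structures alone.
#'
#' @param models A gene-model tibble.
#' @param truth A truth event tibble from [simulate_annotation()].
#' @return A list with `recovered` (fraction of truth events re-derived),
#'   `n_truth`, `n_derived`, and tibbles `missed` and `extra`.
#' @export
truth_recovery <- function(models, truth) {
  sig <- function(df) {
    paste(df$transcript_id, df$event_type, blocks_to_chr(df$blocks), sep = "|")
  }
  derived <- rederive_events(models)
  ts <- sig(truth)
  ds <- sig(derived)
  list(
    recovered = mean(ts %in% ds),
    n_truth = nrow(truth),
    n_derived = nrow(derived),
    missed = truth[!ts %in% ds, ],
    extra = derived[!ds %in% ts, ]
  )
}
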