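#' Simulate an annotated genome with controlled AS events
#'
#' Generates `n_genes` non-overlapping genes on one synthetic chromosome
#' (`simchr1`, alternating strands). Each gene gets a main transcript holding
#' all of its exons and one alternative transcript realizing the configured
#' number of AS events (one, or two of distinct types), with event types drawn
#' from the configured proportions. Every realized event is recorded in the
#' returned truth table with its unified coordinates: the skipped exon(s) for
#' ES/MES, both mutually exclusive exons for MEE, the retained intron for IR,
#' the alternative part of the exon for A5/A3, and the alternative first/last
#' exon for AFE/ALE.
#'
#' Gene geometry: 4-12 exons of 50-300 bp separated by introns of 100-1000 bp,
#' 5000 bp intergenic gaps. Splice-site shifts (A5/A3) move a donor/acceptor
#' by 10-60 bp, strand-aware, extending into the intron or retreating into the
#' exon with equal probability. Event types infeasible for a sampled gene
#' (e.g. anchor constraints on a small gene) are resampled so that every gene
#' carries exactly the configured number of events. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `models` (gene-model tibble, main + alternative
#'   transcripts) and `truth` (event tibble with extra `gene_id` and
#'   `transcript_id` columns, `source_tool = "truth"`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_annotation_impl(cfg))
}

.sample1 <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

.simulate_annotation_impl <- function(cfg) {
  p <- cfg$event_types
  types <- names(p)
  .check_config_feasible(cfg)
  exon_rows <- vector("list", cfg$n_genes * 2L)
  truth_rows <- vector("list", cfg$n_genes)
  cursor <- 6000L
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%05d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_ex <- .sample1(4:12)
    ex_len <- sample(50:300, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(100:1000, n_ex - 1, replace = TRUE) else integer(0)
    ex_s <- integer(n_ex)
    ex_e <- integer(n_ex)
    pos <- cursor
    for (j in seq_len(n_ex)) {
      ex_s[j] <- pos
      ex_e[j] <- pos + ex_len[j] - 1L
      pos <- ex_e[j] + (if (j < n_ex) in_len[j] else 0L) + 1L
    }
    events <- .draw_gene_events(p, n_ex, ex_s, ex_e, strand, cfg)
    alt <- .realize_alt(ex_s, ex_e, events)
    main_tid <- paste0(gid, ".main")
    alt_tid <- paste0(gid, ".alt")
    exon_rows[[2L * g - 1L]] <- list(
      gene_id = gid, transcript_id = main_tid, is_main = TRUE,
      strand = strand, start = ex_s, end = ex_e
    )
    exon_rows[[2L * g]] <- list(
      gene_id = gid, transcript_id = alt_tid, is_main = FALSE,
      strand = strand, start = alt$start, end = alt$end
    )
    truth_rows[[g]] <- list(
      gene_id = gid, transcript_id = alt_tid, strand = strand,
      type = vapply(events, function(e) e$type, character(1)),
      blocks = lapply(events, function(e) .event_blocks(e, ex_s, ex_e))
    )
    cursor <- max(ex_e[n_ex], alt$end[length(alt$end)]) + 5001L
  }
  exons <- tibble::tibble(
    gene_id = rep(
      vapply(exon_rows, function(r) r$gene_id, character(1)),
      vapply(exon_rows, function(r) length(r$start), integer(1))
    ),
    chrom = "simchr1",
    strand = rep(
      vapply(exon_rows, function(r) r$strand, character(1)),
      vapply(exon_rows, function(r) length(r$start), integer(1))
    ),
    transcript_id = rep(
      vapply(exon_rows, function(r) r$transcript_id, character(1)),
      vapply(exon_rows, function(r) length(r$start), integer(1))
    ),
    is_main = rep(
      vapply(exon_rows, function(r) r$is_main, logical(1)),
      vapply(exon_rows, function(r) length(r$start), integer(1))
    ),
    start = unlist(lapply(exon_rows, function(r) r$start)),
    end = unlist(lapply(exon_rows, function(r) r$end))
  )
  models <- gene_models(exons)
  n_ev <- vapply(truth_rows, function(r) length(r$type), integer(1))
  truth <- tibble::tibble(
    gene_id = rep(vapply(truth_rows, function(r) r$gene_id, character(1)), n_ev),
    transcript_id = rep(
      vapply(truth_rows, function(r) r$transcript_id, character(1)), n_ev
    ),
    strand = rep(vapply(truth_rows, function(r) r$strand, character(1)), n_ev),
    event_type = unlist(lapply(truth_rows, function(r) r$type)),
    blocks = unlist(lapply(truth_rows, function(r) r$blocks), recursive = FALSE)
  )
  truth <- truth |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(event_id = sprintf("%s.e%d", .data$gene_id, dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      gene_name = .data$gene_id, chrom = "simchr1", source_tool = "truth"
    ) |>
    dplyr::select(
      "event_id", "gene_name", "chrom", "strand", "event_type", "blocks",
      "source_tool", "gene_id", "transcript_id"
    )
  validate_events(truth)
  list(models = models, truth = truth)
}

.check_config_feasible <- function(cfg) {
  # every configured type must be realizable on at least the largest gene
  # geometry (4-12 exons); all 8 types are, so only degenerate configs fail
  if (length(cfg$event_types) == 0) stop("configuration error: no event types")
  if (cfg$events_per_transcript == 2L && length(cfg$event_types) < 2) {
    stop(
      "configuration error: events_per_transcript = 2 requires at least ",
      "two event types (the two events of a transcript have distinct types)"
    )
  }
}

# -- event sampling ----------------------------------------------------------

.draw_gene_events <- function(p, n_ex, ex_s, ex_e, strand, cfg) {
  k <- cfg$events_per_transcript
  types <- names(p)
  if (k == 1L) {
    for (i in 1:200) {
      t1 <- .sample1_prob(types, p)
      e1 <- .draw_event(t1, n_ex, ex_s, ex_e, strand)
      if (!is.null(e1)) return(list(e1))
    }
    stop("configuration error: could not realize any event on a gene")
  }
  for (attempt in 1:400) {
    t1 <- .sample1_prob(types, p)
    t2 <- .sample1_prob(
      setdiff(types, t1), p[setdiff(types, t1)] / sum(p[setdiff(types, t1)])
    )
    for (try in 1:30) {
      e1 <- .draw_event(t1, n_ex, ex_s, ex_e, strand)
      e2 <- .draw_event(t2, n_ex, ex_s, ex_e, strand)
      if (is.null(e1) || is.null(e2)) break
      pair <- .resolve_pair(e1, e2, n_ex, ex_s, ex_e, cfg$events_per_exon)
      if (!is.null(pair)) return(pair)
    }
  }
  stop("configuration error: could not realize a compatible event pair on a gene")
}

.sample1_prob <- function(x, prob) {
  if (length(x) == 1) return(x)
  x[sample.int(length(x), 1, prob = prob)]
}

# one candidate realization of `type` on the gene, or NULL if infeasible
.draw_event <- function(type, n_ex, ex_s, ex_e, strand) {
  internal <- if (n_ex >= 3) 2:(n_ex - 1L) else integer(0)
  switch(type,
    ES = {
      if (length(internal) == 0) return(NULL)
      i <- .sample1(internal)
      list(type = "ES", exons = i, introns = integer(0), run = i)
    },
    MES = {
      len <- .sample1(2:3)
      starts <- internal[internal + len - 1L <= n_ex - 1L]
      if (length(starts) == 0) {
        len <- 2L
        starts <- internal[internal + 1L <= n_ex - 1L]
      }
      if (length(starts) == 0) return(NULL)
      i <- .sample1(starts)
      run <- i:(i + len - 1L)
      list(type = "MES", exons = run, introns = integer(0), run = run)
    },
    MEE = {
      cand <- internal[internal <= n_ex - 1L]
      if (length(cand) == 0) return(NULL)
      i <- .sample1(cand)
      is <- ex_e[i] + 1L
      ie <- ex_s[i + 1L] - 1L
      ilen <- ie - is + 1L
      max_len <- min(80L, ilen - 20L)
      if (max_len < 30L) return(NULL)
      nlen <- .sample1(30:max_len)
      ns <- is + .sample1(10:(ilen - nlen - 10L)) - 1L
      list(
        type = "MEE", exons = i, introns = i,
        partner = i, novel = c(ns, ns + nlen - 1L)
      )
    },
    IR = {
      if (n_ex < 4) return(NULL)
      t <- .sample1(2:(n_ex - 2L))
      list(type = "IR", exons = c(t, t + 1L), introns = t, t = t)
    },
    A5 = .draw_splice_shift("A5", n_ex, ex_s, ex_e, strand),
    A3 = .draw_splice_shift("A3", n_ex, ex_s, ex_e, strand),
    AFE = {
      drop_idx <- if (strand == "+") 1L else n_ex
      off <- .sample1(200:1000)
      len <- .sample1(50:300)
      novel <- if (strand == "+") {
        c(ex_s[1L] - off - len + 1L, ex_s[1L] - off)
      } else {
        c(ex_e[n_ex] + off, ex_e[n_ex] + off + len - 1L)
      }
      list(
        type = "AFE", exons = drop_idx, introns = integer(0),
        drop_idx = drop_idx, novel = novel
      )
    },
    ALE = {
      drop_idx <- if (strand == "+") n_ex else 1L
      off <- .sample1(200:1000)
      len <- .sample1(50:300)
      novel <- if (strand == "+") {
        c(ex_e[n_ex] + off, ex_e[n_ex] + off + len - 1L)
      } else {
        c(ex_s[1L] - off - len + 1L, ex_s[1L] - off)
      }
      list(
        type = "ALE", exons = drop_idx, introns = integer(0),
        drop_idx = drop_idx, novel = novel
      )
    },
    stop("unknown event type: ", type)
  )
}

# A5 shifts the donor of an intron, A3 the acceptor; on "+" the donor is the
# genomic end of the upstream exon, on "-" the genomic start of the downstream
# exon (and vice versa for the acceptor)
.draw_splice_shift <- function(type, n_ex, ex_s, ex_e, strand) {
  donor_side <- (type == "A5") == (strand == "+")
  # donor_side TRUE: modify exon t's genomic end at intron t
  # donor_side FALSE: modify exon (t+1)'s genomic start at intron t
  cand <- if (donor_side) 2:(n_ex - 1L) else seq_len(n_ex - 2L)
  if (length(cand) == 0) return(NULL)
  t <- .sample1(cand)
  j <- if (donor_side) t else t + 1L
  ilen <- ex_s[t + 1L] - ex_e[t] - 1L
  elen <- ex_e[j] - ex_s[j] + 1L
  dir <- .sample1(c("extend", "shorten"))
  cap <- if (dir == "extend") min(60L, ilen - 10L) else min(60L, elen - 10L)
  if (cap < 10L) {
    dir <- if (dir == "extend") "shorten" else "extend"
    cap <- if (dir == "extend") min(60L, ilen - 10L) else min(60L, elen - 10L)
    if (cap < 10L) return(NULL)
  }
  delta <- .sample1(10:cap)
  side <- if (donor_side) "end" else "start"
  list(
    type = type, exons = j, introns = t,
    exon = j, side = side, dir = dir, delta = delta
  )
}

# deterministic compatibility of a 2-event draw; returns the (possibly
# adjusted) pair or NULL
.resolve_pair <- function(e1, e2, n_ex, ex_s, ex_e, events_per_exon) {
  gap <- function(a, b) min(abs(outer(a, b, "-")))
  skipping <- c("ES", "MES", "MEE")
  if (length(intersect(e1$introns, e2$introns)) > 0) return(NULL)
  g <- gap(e1$exons, e2$exons)
  if (e1$type %in% skipping && e2$type %in% skipping && g < 2L) return(NULL)
  if ("MEE" %in% c(e1$type, e2$type) && g < 2L) return(NULL)
  if (events_per_exon == 1L) {
    if (g < 2L) return(NULL)
    return(list(e1, e2))
  }
  if (g == 0L) {
    # shared exon: only the A5+A3 combination on one exon is well defined
    if (!setequal(c(e1$type, e2$type), c("A5", "A3"))) return(NULL)
    if (e1$exon != e2$exon || e1$side == e2$side) return(NULL)
    if (e1$dir == "shorten" && e2$dir == "shorten") {
      elen <- ex_e[e1$exon] - ex_s[e1$exon] + 1L
      cap <- (elen - 20L) %/% 2L
      if (cap < 10L) return(NULL)
      e1$delta <- min(e1$delta, cap)
      e2$delta <- min(e2$delta, cap)
    }
    return(list(e1, e2))
  }
  list(e1, e2)
}

# -- realization -------------------------------------------------------------

.shifted_boundary <- function(e, ex_s, ex_e) {
  j <- e$exon
  if (e$side == "end") {
    if (e$dir == "extend") ex_e[j] + e$delta else ex_e[j] - e$delta
  } else {
    if (e$dir == "extend") ex_s[j] - e$delta else ex_s[j] + e$delta
  }
}

.realize_alt <- function(ex_s, ex_e, events) {
  n <- length(ex_s)
  keep <- rep(TRUE, n)
  s <- ex_s
  e <- ex_e
  novel_s <- integer(0)
  novel_e <- integer(0)
  for (ev in events) {
    switch(ev$type,
      ES = ,
      MES = {
        keep[ev$run] <- FALSE
      },
      MEE = {
        keep[ev$partner] <- FALSE
        novel_s <- c(novel_s, ev$novel[1])
        novel_e <- c(novel_e, ev$novel[2])
      },
      IR = {
        e[ev$t] <- ex_e[ev$t + 1L]
        keep[ev$t + 1L] <- FALSE
      },
      A5 = ,
      A3 = {
        b <- .shifted_boundary(ev, ex_s, ex_e)
        if (ev$side == "end") e[ev$exon] <- b else s[ev$exon] <- b
      },
      AFE = ,
      ALE = {
        keep[ev$drop_idx] <- FALSE
        novel_s <- c(novel_s, ev$novel[1])
        novel_e <- c(novel_e, ev$novel[2])
      }
    )
  }
  alt_s <- c(s[keep], novel_s)
  alt_e <- c(e[keep], novel_e)
  ord <- order(alt_s)
  list(start = alt_s[ord], end = alt_e[ord])
}

# unified-format blocks of one realized event, in main-transcript coordinates
.event_blocks <- function(e, ex_s, ex_e) {
  blk <- function(s, ed) tibble::tibble(start = as.integer(s), end = as.integer(ed))
  switch(e$type,
    ES = ,
    MES = blk(ex_s[e$run], ex_e[e$run]),
    MEE = {
      b <- rbind(
        c(ex_s[e$partner], ex_e[e$partner]),
        c(e$novel[1], e$novel[2])
      )
      b <- b[order(b[, 1]), , drop = FALSE]
      blk(b[, 1], b[, 2])
    },
    IR = blk(ex_e[e$t] + 1L, ex_s[e$t + 1L] - 1L),
    A5 = ,
    A3 = {
      b <- .shifted_boundary(e, ex_s, ex_e)
      if (e$side == "end") {
        e0 <- ex_e[e$exon]
        blk(min(e0, b) + 1L, max(e0, b))
      } else {
        s0 <- ex_s[e$exon]
        blk(min(s0, b), max(s0, b) - 1L)
      }
    },
    AFE = ,
    ALE = blk(e$novel[1], e$novel[2])
  )
}
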