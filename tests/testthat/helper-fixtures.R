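# Shared fixtures and independent oracles, built in code.

# a single-gene toy model: three exons [101,200], [301,400], [501,600] on "+"
toy_models <- function(strand = "+", chrom = "chr1") {
  gene_models(tibble::tibble(
    gene_id = "G1", gene_name = "G1", chrom = chrom, strand = strand,
    transcript_id = "G1.t1", is_main = TRUE,
    start = c(101L, 301L, 501L), end = c(200L, 400L, 600L)
  ))
}

# a 4-exon toy gene: [101,200], [301,400], [501,600], [701,800]
toy_models4 <- function(strand = "+") {
  gene_models(tibble::tibble(
    gene_id = "G1", gene_name = "G1", chrom = "chr1", strand = strand,
    transcript_id = "G1.t1", is_main = TRUE,
    start = c(101L, 301L, 501L, 701L), end = c(200L, 400L, 600L, 800L)
  ))
}

# deterministic generator of random valid unified events
random_events <- function(n, seed, source_tool = "gen") {
  withr::with_seed(seed, {
    types <- sample(EVENT_TYPES, n, replace = TRUE)
    blocks <- lapply(types, function(tp) {
      k <- if (tp %in% c("MES", "MEE")) sample(2:4, 1) else 1L
      starts <- sort(sample.int(100000L, k)) * 10L
      widths <- sample(20:500, k, replace = TRUE)
      # enforce disjointness: widths bounded by the gap of 10 * >=1
      ends <- pmin(starts + widths, c(starts[-1] - 1L, starts[k] + widths[k]))
      tibble::tibble(start = starts, end = pmax(ends, starts))
    })
    event_table(tibble::tibble(
      event_id = sprintf("ev%05d", seq_len(n)),
      gene_name = sample(sprintf("gene%03d", 1:50), n, replace = TRUE),
      chrom = sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      event_type = types,
      blocks = blocks,
      source_tool = source_tool
    ))
  })
}

# independent CIGAR walker (oracle for extract_alignment_blocks)
cigar_walk_oracle <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  kinds <- sub("\\d+", "", ops)
  ref <- pos
  bs <- integer(0)
  be <- integer(0)
  open <- NA_integer_
  for (k in seq_along(ops)) {
    if (kinds[k] %in% c("M", "=", "X", "D")) {
      if (is.na(open)) open <- ref
      ref <- ref + lens[k]
    } else if (kinds[k] == "N") {
      if (!is.na(open)) {
        bs <- c(bs, open)
        be <- c(be, ref - 1L)
        open <- NA_integer_
      }
      ref <- ref + lens[k]
    }
    # I, S, H, P: no reference consumed
  }
  if (!is.na(open)) {
    bs <- c(bs, open)
    be <- c(be, ref - 1L)
  }
  list(
    blocks = tibble::tibble(start = bs, end = be),
    junctions = tibble::tibble(
      donor = if (length(bs) > 1) be[-length(be)] else integer(0),
      acceptor = if (length(bs) > 1) bs[-1] else integer(0)
    )
  )
}

# brute-force maximum bipartite matching size via igraph (oracle for the
# greedy assignment)
max_matching_oracle <- function(reported, truth, rules) {
  n_r <- nrow(reported)
  n_t <- nrow(truth)
  edges <- integer(0)
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_t)) {
      ok <- reported$chrom[i] == truth$chrom[j] &&
        reported$strand[i] == truth$strand[j] &&
        (!rules$type_strict ||
          effective_type(reported$event_type[i], rules$collapse_skipping) ==
            effective_type(truth$event_type[j], rules$collapse_skipping))
      if (!ok) next
      rb <- reported$blocks[[i]]
      tb <- truth$blocks[[j]]
      agree <- nrow(rb) == nrow(tb) &&
        all(abs(rb$start - tb$start) <= rules$tolerance) &&
        all(abs(rb$end - tb$end) <= rules$tolerance)
      partial <- !agree && rules$partial_mes_credit &&
        truth$event_type[j] %in% c("MES", "MEE") && nrow(rb) == 1 &&
        any(abs(rb$start - tb$start) <= rules$tolerance &
          abs(rb$end - tb$end) <= rules$tolerance)
      if (agree || partial) edges <- c(edges, i, n_r + j)
    }
  }
  if (length(edges) == 0) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n_r), rep(TRUE, n_t)), edges = edges, directed = FALSE
  )
  igraph::max_bipartite_match(g)$matching_size
}
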