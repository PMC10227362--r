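skipped_rec <- function(blocks, chrom = "chr1", strand = "+",
                        gene = NA_character_, claimed = NA_character_) {
  tibble::tibble(
    chrom = chrom, strand = strand, blocks = blocks, gene = gene,
    claimed_type = claimed
  )
}

test_that("skipped-exon records convert by identity with gene lookup", {
  m <- toy_models()
  res <- normalize_skipped_exon(skipped_rec("301-400"), m)
  expect_equal(res$events$event_type, "ES")
  expect_equal(as.data.frame(res$events$blocks[[1]]),
    data.frame(start = 301L, end = 400L))
  expect_equal(res$events$gene_name, "G1")
  # two payload exons become MES
  res2 <- normalize_skipped_exon(skipped_rec("301-400;501-600"), m)
  expect_equal(res2$events$event_type, "MES")
  expect_equal(nrow(res2$events$blocks[[1]]), 2)
  # intergenic payload: rejected leniently, error in strict mode
  res3 <- normalize_skipped_exon(skipped_rec("5001-5100"), m)
  expect_equal(nrow(res3$events), 0)
  expect_equal(res3$rejections$reason, "unresolved-gene")
  expect_error(
    normalize_skipped_exon(skipped_rec("5001-5100"), m, strict = TRUE),
    "strict"
  )
})

test_that("flanking-exon records recover the exons strictly between", {
  m <- toy_models()
  rec <- tibble::tibble(
    chrom = "chr1", strand = "+", up_start = 101L, up_end = 200L,
    down_start = 501L, down_end = 600L
  )
  res <- normalize_flanking_exons(rec, m)
  expect_equal(res$events$event_type, "ES")
  expect_equal(as.data.frame(res$events$blocks[[1]]),
    data.frame(start = 301L, end = 400L))
  # two exons between distant flanks on a 4-exon gene -> MES
  m4 <- toy_models4()
  rec2 <- tibble::tibble(
    chrom = "chr1", strand = "+", up_start = 101L, up_end = 200L,
    down_start = 701L, down_end = 800L
  )
  res2 <- normalize_flanking_exons(rec2, m4)
  expect_equal(res2$events$event_type, "MES")
  expect_equal(res2$events$blocks[[1]]$start, c(301L, 501L))
  # adjacent flanks: nothing between them
  rec3 <- tibble::tibble(
    chrom = "chr1", strand = "+", up_start = 101L, up_end = 200L,
    down_start = 301L, down_end = 400L
  )
  res3 <- normalize_flanking_exons(rec3, m)
  expect_equal(res3$rejections$reason, "not-normalizable")
  # unknown flanks
  rec4 <- dplyr::mutate(rec, up_start = 1L, up_end = 50L)
  expect_equal(
    normalize_flanking_exons(rec4, m)$rejections$reason, "unresolved-gene"
  )
})

jn_rec <- function(junctions, anchor = c(101L, 200L), strand = "+",
                   retained = 0L) {
  tibble::tibble(
    chrom = "chr1", strand = strand, anchor_start = anchor[1],
    anchor_end = anchor[2], junctions = junctions, retained = retained
  )
}

test_that("junction records classify against the main transcript", {
  m <- toy_models()
  # junction (200, 501) skips the middle exon
  res <- normalize_junctions(jn_rec("200:501"), m)
  expect_equal(res$events$event_type, "ES")
  expect_equal(as.data.frame(res$events$blocks[[1]]),
    data.frame(start = 301L, end = 400L))
  # retained-intron flag with the merged exon as anchor
  res_ir <- normalize_junctions(jn_rec("", anchor = c(101L, 400L), retained = 1L), m)
  expect_equal(res_ir$events$event_type, "IR")
  expect_equal(as.data.frame(res_ir$events$blocks[[1]]),
    data.frame(start = 201L, end = 300L))
})

test_that("shifted splice sites yield strand-aware A5/A3 with the exonic difference", {
  # annotation holds main and the donor-extended alternative isoform
  m <- gene_models(tibble::tibble(
    gene_id = "G1", chrom = "chr1", strand = "+",
    transcript_id = c("t1", "t1", "t2", "t2"),
    is_main = c(TRUE, TRUE, FALSE, FALSE),
    start = c(101L, 301L, 101L, 301L),
    end = c(200L, 400L, 250L, 400L)
  ))
  # intron [201,300] becomes [251,300]: competing donors 200 vs 250 -> A5
  res <- normalize_junctions(jn_rec("250:301"), m)
  expect_equal(res$events$event_type, "A5")
  expect_equal(as.data.frame(res$events$blocks[[1]]),
    data.frame(start = 201L, end = 250L))
  # acceptor-retreated variant: intron [201,350], competing acceptors -> A3
  m2 <- gene_models(tibble::tibble(
    gene_id = "G1", chrom = "chr1", strand = "+",
    transcript_id = c("t1", "t1", "t2", "t2"),
    is_main = c(TRUE, TRUE, FALSE, FALSE),
    start = c(101L, 301L, 101L, 351L),
    end = c(200L, 400L, 200L, 400L)
  ))
  res2 <- normalize_junctions(jn_rec("200:351"), m2)
  expect_equal(res2$events$event_type, "A3")
  expect_equal(as.data.frame(res2$events$blocks[[1]]),
    data.frame(start = 301L, end = 350L))
  # same genomic geometry on the minus strand swaps the labels
  m_minus <- gene_models(dplyr::mutate(m, strand = "-"))
  res3 <- normalize_junctions(jn_rec("250:301", strand = "-"), m_minus)
  expect_equal(res3$events$event_type, "A3")
  m2_minus <- gene_models(dplyr::mutate(m2, strand = "-"))
  res4 <- normalize_junctions(jn_rec("200:351", strand = "-"), m2_minus)
  expect_equal(res4$events$event_type, "A5")
})

test_that("junctions with unannotated splice sites are rejected as novel", {
  m <- toy_models()
  res <- normalize_junctions(jn_rec("250:301"), m) # 250 annotated nowhere
  expect_equal(res$rejections$reason, "novel-junction")
  # a reference junction is not an event
  res2 <- normalize_junctions(jn_rec("200:301"), m)
  expect_equal(res2$rejections$reason, "reference-junction")
})

test_that("batch normalization pools dialects and reports rejections", {
  m <- toy_models()
  batch <- list(
    skipped_exon = skipped_rec("301-400"),
    flanking_exons = tibble::tibble(
      chrom = "chr1", strand = "+", up_start = 101L, up_end = 200L,
      down_start = 501L, down_end = 600L
    ),
    junction = jn_rec("200:501")
  )
  res <- normalize_batch(batch, m, tool = "x")
  expect_equal(nrow(res$events), 3)
  expect_length(unique(event_key(res$events)), 1) # same ES, three dialects
  expect_length(unique(res$events$event_id), 3)
  # lenient keeps going past rejections; strict stops
  batch$skipped_exon <- dplyr::bind_rows(
    batch$skipped_exon, skipped_rec("9001-9100")
  )
  res2 <- normalize_batch(batch, m, tool = "x")
  expect_equal(nrow(res2$events), 3)
  expect_equal(res2$rejections$reason, "unresolved-gene")
  expect_error(normalize_batch(batch, m, mode = "strict"), "strict")
  # empty input, empty output
  res3 <- normalize_batch(list(skipped_exon = skipped_rec(character(0))), m)
  expect_equal(nrow(res3$events), 0)
  expect_equal(nrow(res3$rejections), 0)
})

test_that("every truth event normalizes to its own key through each dialect", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 60, seed = 19))
  tk <- event_key(sim$truth)
  for (d in c("skipped_exon", "flanking_exons", "junction")) {
    recs <- render_dialect(sim$truth, sim$models, d)
    res <- normalize_batch(stats::setNames(list(recs), d), sim$models, tool = d)
    expect_equal(nrow(res$rejections), 0)
    expect_true(all(event_key(res$events) %in% tk))
    # rendered events map back to exactly the events the dialect expresses
    expect_equal(nrow(res$events), nrow(recs))
  }
})

test_that("normalization never invents coordinates outside the gene span", {
  sim <- simulate_annotation(load_preset("S1", n_genes = 40, seed = 29))
  spans <- gene_spans(sim$models)
  for (d in c("skipped_exon", "junction")) {
    recs <- render_dialect(sim$truth, sim$models, d)
    ev <- normalize_batch(stats::setNames(list(recs), d), sim$models, tool = d)$events
    j <- dplyr::left_join(ev, spans, by = "gene_name",
      suffix = c("", ".span"))
    for (i in seq_len(nrow(j))) {
      b <- j$blocks[[i]]
      expect_gte(min(b$start), j$start[i])
      expect_lte(max(b$end), j$end[i])
    }
  }
})

test_that("a genomic mirror with strand flip preserves A5/A3 labels", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 30, seed = 37))
  pivot <- max(sim$models$end) + 1000L
  mirror_models <- sim$models |>
    dplyr::mutate(
      new_start = pivot - end, new_end = pivot - start,
      start = new_start, end = new_end,
      strand = ifelse(strand == "+", "-", "+")
    ) |>
    dplyr::select(-new_start, -new_end) |>
    gene_models()
  mirror_truth <- sim$truth |>
    dplyr::mutate(
      strand = ifelse(strand == "+", "-", "+"),
      blocks = lapply(blocks, function(b) {
        tibble::tibble(start = rev(pivot - b$end), end = rev(pivot - b$start))
      })
    )
  validate_events(mirror_truth)
  for (d in c("skipped_exon", "junction")) {
    recs <- render_dialect(mirror_truth, mirror_models, d)
    res <- normalize_batch(stats::setNames(list(recs), d), mirror_models, tool = d)
    expect_equal(nrow(res$rejections), 0)
    expect_true(all(event_key(res$events) %in% event_key(mirror_truth)))
  }
  # type composition is invariant under the mirror
  expect_equal(
    table(mirror_truth$event_type), table(sim$truth$event_type)
  )
})
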