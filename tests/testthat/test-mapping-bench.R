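test_that("CIGAR decoding matches the by-hand walk on forced examples", {
  d <- extract_alignment_blocks(101L, "76M")
  expect_equal(as.data.frame(d$blocks[[1]]), data.frame(start = 101L, end = 176L))
  expect_equal(nrow(d$junctions[[1]]), 0)
  d2 <- extract_alignment_blocks(180L, "21M100N55M")
  expect_equal(
    as.data.frame(d2$blocks[[1]]),
    data.frame(start = c(180L, 301L), end = c(200L, 355L))
  )
  expect_equal(
    as.data.frame(d2$junctions[[1]]),
    data.frame(donor = 200L, acceptor = 301L)
  )
  # soft clips consume query only
  d3 <- extract_alignment_blocks(101L, "10S66M")
  expect_equal(as.data.frame(d3$blocks[[1]]), data.frame(start = 101L, end = 166L))
  expect_error(extract_alignment_blocks(1L, "banana", "r1"), "CIGAR")
})

test_that("CIGAR decoding agrees with an independent walker on varied strings", {
  cases <- list(
    c(50L, "10M5I10M"), c(10L, "5S20M3D7M"), c(99L, "30M200N30M100N16M"),
    c(1L, "76M"), c(7L, "10M1D10N5M"), c(3L, "2H10M4N10M2S")
  )
  for (cs in cases) {
    pos <- as.integer(cs[1])
    cig <- cs[2]
    got <- extract_alignment_blocks(pos, cig)
    want <- cigar_walk_oracle(pos, cig)
    expect_equal(as.data.frame(got$blocks[[1]]), as.data.frame(want$blocks),
      info = cig
    )
    expect_equal(
      as.data.frame(got$junctions[[1]]), as.data.frame(want$junctions),
      info = cig
    )
  }
})

test_that("mapping metrics are self-consistent on uncorrupted alignments", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 10, seed = 12))
  cfg <- load_preset("S0", n_genes = 10, n_reads = 50, seed = 12)
  rr <- simulate_reads(sim$models, cfg)
  m <- evaluate_mapping(rr$sam, rr$reads)
  expect_equal(m$fraction_unmapped, 0)
  expect_equal(m$precision_read, 1)
  expect_equal(m$precision_junction, 1)
  expect_equal(m$n_mapped + m$n_unmapped, m$n_simulated)
})

test_that("mapping metrics equal a brute-force recomputation on a small SAM", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 8, seed = 14))
  cfg <- load_preset("S0", n_genes = 8, n_reads = 40, seed = 14)
  rr <- simulate_reads(sim$models, cfg)
  corrupted <- corrupt_alignments(rr$sam, 0.2, 0.2, seed = 5)
  m <- evaluate_mapping(corrupted, rr$reads)
  # independent recomputation from the raw SAM text
  sam <- read_sam(corrupted)
  mapped <- sam[bitwAnd(sam$flag, 4L) == 0L, ]
  correct <- 0L
  for (i in seq_len(nrow(mapped))) {
    want <- rr$reads[rr$reads$read_id == mapped$qname[i], ]
    got <- cigar_walk_oracle(mapped$pos[i], mapped$cigar[i])
    if (identical(as.data.frame(got$blocks), as.data.frame(want$blocks[[1]])) &&
        identical(as.data.frame(got$junctions), as.data.frame(want$junctions[[1]])) &&
        mapped$rname[i] == want$chrom) {
      correct <- correct + 1L
    }
  }
  expect_equal(m$n_mapped, nrow(mapped))
  expect_equal(m$n_reads_correct, correct)
  expect_equal(m$fraction_unmapped, (40 - nrow(mapped)) / 40)
})

test_that("controlled corruption yields the analytic metric values", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 15, seed = 9))
  cfg <- load_preset("S0", n_genes = 15, n_reads = 100, seed = 9)
  rr <- simulate_reads(sim$models, cfg)
  corrupted <- corrupt_alignments(rr$sam, 0.2, 0.1, seed = 7)
  m <- evaluate_mapping(corrupted, rr$reads)
  expect_equal(m$fraction_unmapped, 0.2)
  expect_equal(m$precision_read, 70 / 80)
})

test_that("reads missing from the SAM count as unmapped (conservation)", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 8, seed = 10))
  cfg <- load_preset("S0", n_genes = 8, n_reads = 20, seed = 10)
  rr <- simulate_reads(sim$models, cfg)
  lines <- readLines(rr$sam)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(hdr, body[1:12]), f) # drop 8 reads entirely
  m <- evaluate_mapping(f, rr$reads)
  expect_equal(m$n_simulated, 20L)
  expect_equal(m$n_unmapped, 8L)
  expect_equal(m$n_mapped + m$n_unmapped, m$n_simulated)
  expect_equal(m$fraction_unmapped, 0.4)
})

test_that("tolerance is monotone and unknown reads or empty truth error", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 8, seed = 11))
  cfg <- load_preset("S0", n_genes = 8, n_reads = 30, seed = 11)
  rr <- simulate_reads(sim$models, cfg)
  shifted <- corrupt_alignments(rr$sam, 0, 0.3, seed = 1)
  m0 <- evaluate_mapping(shifted, rr$reads, tolerance = 0)
  m5 <- evaluate_mapping(shifted, rr$reads, tolerance = 5)
  mbig <- evaluate_mapping(shifted, rr$reads, tolerance = 2000)
  expect_lte(m0$n_reads_correct, m5$n_reads_correct)
  expect_lte(m5$n_reads_correct, mbig$n_reads_correct)
  expect_gt(mbig$n_reads_correct, m0$n_reads_correct)
  bad <- rr$reads[1:10, ]
  expect_error(evaluate_mapping(rr$sam, bad), "absent from truth")
  expect_error(evaluate_mapping(rr$sam, rr$reads[0, ]), "empty truth")
})

test_that("the mapping report is labeled, sorted and NA-safe", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 6, seed = 13))
  cfg <- load_preset("S0", n_genes = 6, n_reads = 10, seed = 13)
  rr <- simulate_reads(sim$models, cfg)
  m <- evaluate_mapping(rr$sam, rr$reads)
  all_unmapped <- corrupt_alignments(rr$sam, 1, 0, seed = 1)
  m_none <- evaluate_mapping(all_unmapped, rr$reads)
  rep <- mapping_report(list(zeta = m, alpha = m_none))
  expect_equal(rep$label, c("alpha", "zeta"))
  expect_true(is.na(rep$precision_read[rep$label == "alpha"]))
  expect_error(mapping_report(list(a = m, a = m)), "duplicate")
  f <- withr::local_tempfile()
  write_mapping_report(rep, f)
  expect_match(readLines(f)[2], "NA")
})
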