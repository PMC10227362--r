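# a two-exon toy gene long enough to host 76-bp reads
two_exon_models <- function() {
  gene_models(tibble::tibble(
    gene_id = "G1", gene_name = "G1", chrom = "simchr1", strand = "+",
    transcript_id = "G1.t", is_main = TRUE,
    start = c(101L, 301L), end = c(200L, 400L)
  ))
}

test_that("transcript-to-genome projection yields the forced coordinates", {
  m <- two_exon_models()
  cfg <- sim_config(n_genes = 1, n_reads = 400, read_length = 76, seed = 4)
  rr <- simulate_reads(m, cfg)
  sam <- read_sam(rr$sam)
  # a read starting at transcript offset 1 lies fully inside the first exon
  first <- which(vapply(rr$reads$blocks, function(b) b$start[1] == 101L &&
    nrow(b) == 1, logical(1)))
  expect_true(length(first) > 0)
  i <- first[1]
  expect_equal(rr$reads$blocks[[i]]$end, 176L)
  expect_equal(sam$cigar[sam$qname == rr$reads$read_id[i]], "76M")
  # a read starting at genomic 180 spans the junction: 21M100N55M
  spliced <- which(vapply(rr$reads$blocks, function(b) nrow(b) == 2 &&
    b$start[1] == 180L, logical(1)))
  expect_true(length(spliced) > 0)
  j <- spliced[1]
  expect_equal(as.data.frame(rr$reads$blocks[[j]]),
    data.frame(start = c(180L, 301L), end = c(200L, 355L)))
  expect_equal(as.data.frame(rr$reads$junctions[[j]]),
    data.frame(donor = 200L, acceptor = 301L))
  expect_equal(sam$cigar[sam$qname == rr$reads$read_id[j]], "21M100N55M")
})

test_that("error-free FASTQ equals the reference projection", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 5, seed = 6))
  cfg <- load_preset("S0", n_genes = 5, n_reads = 30, seed = 6)
  rr <- simulate_reads(sim$models, cfg)
  ref <- synthesize_reference(sim$models, cfg$seed)
  fq <- readLines(rr$fastq)
  seqs <- fq[seq(2, length(fq), by = 4)]
  strands <- sim$models$strand[match(rr$reads$transcript_id, sim$models$transcript_id)]
  for (i in seq_len(nrow(rr$reads))) {
    b <- rr$reads$blocks[[i]]
    proj <- paste(substring(ref$seq, b$start, b$end), collapse = "")
    if (strands[i] == "-") {
      proj <- chartr("ACGT", "TGCA", paste(rev(strsplit(proj, "")[[1]]), collapse = ""))
    }
    expect_equal(seqs[i], proj)
  }
})

test_that("substitution errors appear at roughly the configured rate", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 5, seed = 6))
  cfg0 <- load_preset("S0", n_genes = 5, n_reads = 150, seed = 6)
  cfg1 <- cfg0
  cfg1$error_rate <- 0.02
  r0 <- simulate_reads(sim$models, cfg0)
  r1 <- simulate_reads(sim$models, cfg1)
  s0 <- readLines(r0$fastq)[seq(2, 600, by = 4)]
  s1 <- readLines(r1$fastq)[seq(2, 600, by = 4)]
  mism <- sum(vapply(seq_along(s0), function(i) {
    sum(strsplit(s0[i], "")[[1]] != strsplit(s1[i], "")[[1]])
  }, numeric(1)))
  rate <- mism / (length(s0) * cfg0$read_length)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.035)
})

test_that("alignment corruption realizes exact largest-remainder counts", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 5, seed = 8))
  cfg <- load_preset("S0", n_genes = 5, n_reads = 10, seed = 8)
  rr <- simulate_reads(sim$models, cfg)
  # identity when u = m = 0
  out0 <- corrupt_alignments(rr$sam, 0, 0, seed = 1)
  expect_identical(readLines(out0), readLines(rr$sam))
  # u = 0.3 on 10 reads: exactly 3 unmapped records
  out <- corrupt_alignments(rr$sam, 0.3, 0, seed = 1)
  sam <- read_sam(out)
  expect_equal(sum(bitwAnd(sam$flag, 4L) != 0L), 3L)
  # misplacement shifts positions by exactly +1000
  out2 <- corrupt_alignments(rr$sam, 0, 0.2, seed = 2)
  s0 <- read_sam(rr$sam)
  s2 <- read_sam(out2)
  expect_equal(sum(s2$pos - s0$pos == 1000L), 2L)
  expect_equal(sum(s2$pos != s0$pos), 2L)
})

test_that("downsampling is uniform, order-preserving and deterministic", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 5, seed = 8))
  cfg <- load_preset("S0", n_genes = 5, n_reads = 100, seed = 8)
  rr <- simulate_reads(sim$models, cfg)
  # n = record count: identity
  f_all <- withr::local_tempfile(fileext = ".fastq")
  downsample_reads(rr$fastq, 100, seed = 1, out = f_all)
  expect_identical(readLines(f_all), readLines(rr$fastq))
  # n = 10: distinct ids, all from the input, input order kept
  f10 <- withr::local_tempfile(fileext = ".fastq")
  downsample_reads(rr$fastq, 10, seed = 1, out = f10)
  lines <- readLines(f10)
  ids <- sub("^@", "", lines[seq(1, 40, by = 4)])
  expect_length(unique(ids), 10)
  all_ids <- sub("^@", "", readLines(rr$fastq)[seq(1, 400, by = 4)])
  expect_true(all(ids %in% all_ids))
  expect_false(is.unsorted(match(ids, all_ids)))
  # same seed, same selection; SAM flavour consistent with FASTQ flavour
  f10b <- withr::local_tempfile(fileext = ".fastq")
  downsample_reads(rr$fastq, 10, seed = 1, out = f10b)
  expect_identical(readLines(f10), readLines(f10b))
  fsam <- withr::local_tempfile(fileext = ".sam")
  downsample_reads(rr$sam, 10, seed = 1, out = fsam)
  sam <- read_sam(fsam)
  expect_equal(nrow(sam), 10)
  expect_error(downsample_reads(rr$fastq, 101, seed = 1, out = f10), "downsample")
})
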