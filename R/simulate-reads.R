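#' Deterministic synthetic chromosome sequence
#'
#' Generates the base sequence of the simulated chromosome from a seed: an
#' i.i.d. A/C/G/T string long enough to cover every gene plus flanking
#' margin. Read sequences are substrings of this reference (with optional
#' substitution errors), so an error-free FASTQ equals the reference
#' projection of the read's true blocks exactly.
#'
#' @param models A gene-model tibble (defines the needed length).
#' @param seed Integer seed.
#' @return A list with `chrom`, `length` and `seq` (a single string).
#' @export
synthesize_reference <- function(models, seed) {
  len <- max(models$end) + 6000L
  seq <- withr::with_seed(
    seed,
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  )
  list(chrom = models$chrom[1], length = len, seq = seq)
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate single-end spliced reads with known genomic placements
#'
#' Samples `cfg$n_reads` reads of length `cfg$read_length` uniformly over
#' transcripts (a gene is drawn uniformly among genes with at least one
#' sufficiently long isoform, then an isoform uniformly within the gene, then
#' a start position uniformly along the transcript). Transcript coordinates
#' are projected to genomic blocks through the exon chain; the returned truth
#' table records each read's true chromosome, blocks and splice junctions.
#' The SAM file contains every read perfectly aligned (CIGAR with `M` and `N`
#' operations only, `N` spans equal to the junction gaps); the FASTQ carries
#' the transcript-orientation sequence drawn from the seeded synthetic
#' reference with substitutions at `cfg$error_rate` and constant `I`
#' qualities. Transcripts shorter than the read length are excluded from
#' sampling; no truncated reads are ever produced.
#'
#' @param models A gene-model tibble.
#' @param cfg A [sim_config()].
#' @param sam Output SAM path.
#' @param fastq Output FASTQ path.
#' @return A list with `reads` (truth read tibble: `read_id`,
#'   `transcript_id`, `chrom`, `blocks`, `junctions`), `sam` and `fastq`.
#' @export
simulate_reads <- function(models, cfg,
                           sam = tempfile(fileext = ".sam"),
                           fastq = tempfile(fileext = ".fastq")) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$read_length
  ref <- synthesize_reference(models, cfg$seed)
  tx <- models |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$strand) |>
    dplyr::summarise(tx_len = sum(.data$end - .data$start + 1L), .groups = "drop") |>
    dplyr::filter(.data$tx_len >= L)
  if (nrow(tx) == 0) {
    stop("all transcripts are shorter than the read length (", L, ")")
  }
  exon_map <- split(
    dplyr::arrange(models, .data$transcript_id, .data$start),
    dplyr::arrange(models, .data$transcript_id, .data$start)$transcript_id
  )
  genes <- unique(tx$gene_id)
  tx_by_gene <- split(tx$transcript_id, tx$gene_id)
  len_by_tx <- stats::setNames(tx$tx_len, tx$transcript_id)
  reads <- withr::with_seed(cfg$seed + 1L, {
    out <- vector("list", cfg$n_reads)
    for (i in seq_len(cfg$n_reads)) {
      gid <- .sample1(genes)
      tid <- .sample1(tx_by_gene[[gid]])
      p <- .sample1(seq_len(len_by_tx[[tid]] - L + 1L))
      ex <- exon_map[[tid]]
      proj <- .project_to_genome(p, L, ex$start, ex$end, ex$strand[1])
      out[[i]] <- list(
        read_id = sprintf("read%06d", i), transcript_id = tid,
        strand = ex$strand[1], blocks = proj
      )
    }
    out
  })
  truth <- tibble::tibble(
    read_id = vapply(reads, function(r) r$read_id, character(1)),
    transcript_id = vapply(reads, function(r) r$transcript_id, character(1)),
    chrom = ref$chrom,
    blocks = lapply(reads, function(r) {
      tibble::tibble(start = r$blocks$start, end = r$blocks$end)
    }),
    junctions = lapply(reads, function(r) .blocks_junctions(r$blocks))
  )
  # sequences: genomic-forward projection, transcript orientation for FASTQ
  geno_seq <- vapply(reads, function(r) {
    paste(substring(ref$seq, r$blocks$start, r$blocks$end), collapse = "")
  }, character(1))
  read_seq <- ifelse(
    vapply(reads, function(r) r$strand, character(1)) == "-",
    .revcomp(geno_seq), geno_seq
  )
  if (cfg$error_rate > 0) {
    read_seq <- withr::with_seed(
      cfg$seed + 2L, .add_substitutions(read_seq, cfg$error_rate)
    )
  }
  strands <- vapply(reads, function(r) r$strand, character(1))
  sam_seq <- ifelse(strands == "-", .revcomp(read_seq), read_seq)
  qual <- strrep("I", L)
  cigar <- vapply(reads, function(r) .blocks_cigar(r$blocks), character(1))
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$chrom, ref$length),
    "@PG\tID:splicebench",
    paste(
      truth$read_id, ifelse(strands == "-", 16L, 0L), ref$chrom,
      vapply(reads, function(r) r$blocks$start[1], integer(1)),
      60L, cigar, "*", 0L, 0L, sam_seq, qual,
      sep = "\t"
    )
  )
  writeLines(sam_lines, sam)
  fq_lines <- as.vector(rbind(
    paste0("@", truth$read_id), read_seq, "+", qual
  ))
  writeLines(fq_lines, fastq)
  list(reads = truth, sam = sam, fastq = fastq)
}

# project transcript interval [p, p+L-1] to genomic blocks (ascending)
.project_to_genome <- function(p, L, ex_s, ex_e, strand) {
  widths <- ex_e - ex_s + 1L
  if (strand == "-") {
    ord <- rev(seq_along(ex_s))
  } else {
    ord <- seq_along(ex_s)
  }
  w <- widths[ord]
  off <- cumsum(c(0L, w[-length(w)])) # tx coord before each exon
  a <- p
  b <- p + L - 1L
  bs <- integer(0)
  be <- integer(0)
  for (k in seq_along(ord)) {
    lo <- off[k] + 1L
    hi <- off[k] + w[k]
    if (b < lo || a > hi) next
    aa <- max(a, lo) - off[k] # 1-based within exon, transcription order
    bb <- min(b, hi) - off[k]
    j <- ord[k]
    if (strand == "+") {
      bs <- c(bs, ex_s[j] + aa - 1L)
      be <- c(be, ex_s[j] + bb - 1L)
    } else {
      bs <- c(bs, ex_e[j] - bb + 1L)
      be <- c(be, ex_e[j] - aa + 1L)
    }
  }
  ordg <- order(bs)
  list(start = bs[ordg], end = be[ordg])
}

.blocks_junctions <- function(blocks) {
  n <- length(blocks$start)
  if (n < 2) {
    return(tibble::tibble(donor = integer(0), acceptor = integer(0)))
  }
  tibble::tibble(
    donor = blocks$end[-n], acceptor = blocks$start[-1]
  )
}

.blocks_cigar <- function(blocks) {
  n <- length(blocks$start)
  m <- blocks$end - blocks$start + 1L
  if (n == 1) return(sprintf("%dM", m))
  gaps <- blocks$start[-1] - blocks$end[-n] - 1L
  paste0(
    paste0(m[-n], "M", gaps, "N", collapse = ""), m[n], "M"
  )
}

.add_substitutions <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- .sample1(setdiff(bases, ch[i]))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Corrupt a SAM file with known unmapped and misplaced fractions
#'
#' Turns a uniformly random `u`-fraction of reads into unmapped records and
#' shifts a disjoint `m`-fraction by +1000 bases, leaving the remainder
#' untouched. Counts use largest-remainder rounding so the realized fractions
#' are analytically exact, which gives the mapping benchmark a closed-form
#' expectation: `fraction_unmapped = u` and read-level precision
#' `(1 - u - m) / (1 - u)`.
#'
#' @param sam Input SAM path.
#' @param u Fraction of reads to unmap, in `[0,1]`.
#' @param m Fraction of reads to misplace, `u + m <= 1`.
#' @param seed Integer seed.
#' @param out Output SAM path.
#' @return `out`, invisibly.
#' @export
corrupt_alignments <- function(sam, u, m, seed, out = tempfile(fileext = ".sam")) {
  stopifnot(u >= 0, m >= 0, u + m <= 1)
  lines <- readr::read_lines(sam)
  hdr <- startsWith(lines, "@")
  body <- lines[!hdr]
  n <- length(body)
  counts <- .largest_remainder(c(u, m, 1 - u - m), n)
  idx <- withr::with_seed(seed, sample.int(n))
  unmapped <- idx[seq_len(counts[1])]
  misplaced <- idx[counts[1] + seq_len(counts[2])]
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (i in unmapped) {
    f <- fields[[i]]
    f[2] <- "4"
    f[3] <- "*"
    f[4] <- "0"
    f[5] <- "0"
    f[6] <- "*"
    fields[[i]] <- f
  }
  for (i in misplaced) {
    f <- fields[[i]]
    f[4] <- as.character(as.integer(f[4]) + 1000L)
    fields[[i]] <- f
  }
  writeLines(
    c(lines[hdr], vapply(fields, paste, character(1), collapse = "\t")), out
  )
  invisible(out)
}

# integer apportionment of n among proportions p (largest remainder; ties go
# to the earlier component)
.largest_remainder <- function(p, n) {
  q <- p * n
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- q - base
    take <- order(-frac, seq_along(p))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Downsample a FASTQ or SAM file uniformly at random
#'
#' Selects `n` records without replacement (seeded, deterministic) and writes
#' them preserving the input order; SAM headers are kept verbatim.
#'
#' @param path Input file.
#' @param n Target record count (must not exceed the record count).
#' @param seed Integer seed.
#' @param out Output path.
#' @param format `"fastq"` or `"sam"`; guessed from the file extension by
#'   default.
#' @return `out`, invisibly.
#' @export
downsample_reads <- function(path, n, seed, out,
                             format = c("auto", "fastq", "sam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path)) "sam" else "fastq"
  }
  lines <- readr::read_lines(path)
  if (format == "sam") {
    hdr <- lines[startsWith(lines, "@")]
    body <- lines[!startsWith(lines, "@")]
    n_rec <- length(body)
    if (n > n_rec) stop("cannot downsample to ", n, " from ", n_rec, " records")
    keep <- sort(withr::with_seed(seed, sample.int(n_rec, n)))
    writeLines(c(hdr, body[keep]), out)
  } else {
    if (length(lines) %% 4 != 0) stop("malformed FASTQ (line count not multiple of 4)")
    n_rec <- length(lines) %/% 4
    if (n > n_rec) stop("cannot downsample to ", n, " from ", n_rec, " records")
    keep <- sort(withr::with_seed(seed, sample.int(n_rec, n)))
    rows <- as.vector(vapply(keep, function(k) (k - 1L) * 4L + 1:4, integer(4)))
    writeLines(lines[rows], out)
  }
  invisible(out)
}
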