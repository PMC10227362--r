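#' Build a simulation configuration
#'
#' Describes one simulated study design: which AS event types to inject and in
#' what proportions, how many events one alternative transcript carries (1 or
#' 2; with 2 the types are distinct), whether one exon may take part in both
#' events of a transcript (`events_per_exon`), the per-base substitution
#' sequencing error rate, and the scale of the run (number of genes, read
#' length, read count) plus the seed controlling all randomness.
#'
#' @param event_types Named numeric vector of type proportions over a subset
#'   of [EVENT_TYPES]; must be non-negative and sum to 1 (within 1e-9).
#' @param events_per_transcript 1 or 2 AS events per alternative transcript.
#' @param events_per_exon 1 (events of one transcript use well-separated
#'   exons) or 2 (an exon may be involved in both events, e.g. a skipped exon
#'   directly flanking a shifted splice site, or A5 and A3 on the same exon).
#' @param error_rate Per-base substitution probability in `[0,1]`.
#' @param n_genes Number of simulated genes.
#' @param read_length Read length in bases (>= 20).
#' @param n_reads Number of single-end reads to simulate.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(event_types = c(ES = 0.25, IR = 0.25, A5 = 0.25, A3 = 0.25),
                       events_per_transcript = 1L,
                       events_per_exon = 1L,
                       error_rate = 0,
                       n_genes = 200L,
                       read_length = 76L,
                       n_reads = 5000L,
                       seed = 1L) {
  if (is.null(names(event_types)) || any(!names(event_types) %in% EVENT_TYPES)) {
    stop("event_types must be named with a subset of: ",
      paste(EVENT_TYPES, collapse = ", "))
  }
  if (any(event_types < 0) || abs(sum(event_types) - 1) > 1e-9) {
    stop("event_types proportions must be >= 0 and sum to 1")
  }
  if (!events_per_transcript %in% c(1L, 2L)) {
    stop("events_per_transcript must be 1 or 2")
  }
  if (!events_per_exon %in% c(1L, 2L)) {
    stop("events_per_exon must be 1 (disjoint exon sets) or 2 (sharing allowed)")
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  if (events_per_transcript == 2L && sum(event_types > 0) < 2) {
    stop(
      "events_per_transcript = 2 requires at least two event types ",
      "(the two events of a transcript have distinct types)"
    )
  }
  if (read_length < 20) stop("read_length must be >= 20")
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (n_genes < 1) stop("n_genes must be >= 1")
  structure(
    list(
      event_types = event_types[event_types > 0],
      events_per_transcript = as.integer(events_per_transcript),
      events_per_exon = as.integer(events_per_exon),
      error_rate = error_rate,
      n_genes = as.integer(n_genes),
      read_length = as.integer(read_length),
      n_reads = as.integer(n_reads),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Load one of the S0-S5 simulation designs
#'
#' The six designs tune the difficulty of the benchmark: `S0` injects the four
#' core event types (ES, IR, A5, A3) in equal proportions, one event per
#' transcript, error-free; `S1` adds the complex types MES, ALE and AFE (still
#' error-free); `S2` is `S1` with a 0.1% sequencing error rate; `S3` allows
#' two events (of distinct types) per transcript on disjoint exon sets; `S4`
#' additionally allows one exon to take part in both events; `S5` returns to
#' the four core types with two events per transcript, shared exons allowed
#' and caller-supplied ("realistic") proportions.
#'
#' @param name One of `"S0"`..`"S5"`.
#' @param proportions For `S5` only: named proportions over ES/IR/A5/A3
#'   (default equal; the biologically derived mixture is a free parameter).
#' @param ... Overrides passed to [sim_config()] (`n_genes`, `n_reads`,
#'   `seed`, ...).
#' @return A `sim_config`.
#' @export
load_preset <- function(name, proportions = NULL, ...) {
  presets <- c("S0", "S1", "S2", "S3", "S4", "S5")
  if (length(name) != 1 || !name %in% presets) {
    stop(
      "unknown preset '", paste(name, collapse = ","),
      "'; valid presets: ", paste(presets, collapse = ", ")
    )
  }
  core <- c(ES = 0.25, IR = 0.25, A5 = 0.25, A3 = 0.25)
  seven <- stats::setNames(rep(1 / 7, 7), c("ES", "IR", "A5", "A3", "MES", "ALE", "AFE"))
  args <- switch(name,
    S0 = list(event_types = core, events_per_transcript = 1L,
      events_per_exon = 1L, error_rate = 0),
    S1 = list(event_types = seven, events_per_transcript = 1L,
      events_per_exon = 1L, error_rate = 0),
    S2 = list(event_types = seven, events_per_transcript = 1L,
      events_per_exon = 1L, error_rate = 0.001),
    S3 = list(event_types = seven, events_per_transcript = 2L,
      events_per_exon = 1L, error_rate = 0.001),
    S4 = list(event_types = seven, events_per_transcript = 2L,
      events_per_exon = 2L, error_rate = 0.001),
    S5 = list(
      event_types = if (is.null(proportions)) core else proportions,
      events_per_transcript = 2L, events_per_exon = 2L, error_rate = 0.001
    )
  )
  if (!is.null(proportions) && name != "S5") {
    stop("proportions can only be supplied for preset S5")
  }
  do.call(sim_config, utils::modifyList(args, list(...)))
}
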