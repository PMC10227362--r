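#' Assemble a benchmark run configuration
#'
#' Collects everything one benchmark run needs: the simulation design (a
#' preset name or an explicit [sim_config()]), the base seed, the number of
#' replicates (each replicate re-simulates with seed `seed + i`), the tool
#' input declarations, matching rules and the output directory.
#'
#' @param preset Preset name (`"S0"`..`"S5"`) or `NULL` when `sim` is given.
#' @param sim An explicit [sim_config()] (overrides `preset`).
#' @param seed Base seed.
#' @param replicates Number of replicates (>= 1).
#' @param tools A tibble with columns `label`, `dialect`, `path` declaring
#'   tool outputs to normalize (labels must be unique).
#' @param rules A [match_rules()].
#' @param out_dir Output directory.
#' @param ... Extra arguments forwarded to [sim_config()] via [load_preset()]
#'   (e.g. `n_genes`, `n_reads`).
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "S0", sim = NULL, seed = 1L, replicates = 1L,
                       tools = NULL, rules = match_rules(),
                       out_dir = tempfile("splicebench_run_"), ...) {
  if (replicates < 1) stop("replicate count must be >= 1")
  if (!is.null(tools)) {
    if (anyDuplicated(tools$label)) {
      stop("tool labels must be unique")
    }
  }
  if (is.null(sim)) sim <- load_preset(preset, seed = seed, ...)
  structure(
    list(
      sim = sim, seed = as.integer(seed), replicates = as.integer(replicates),
      tools = tools, rules = rules, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: top-level keys `preset`, `seed`,
#' `replicates`, `out_dir`, an optional `sim` mapping of [sim_config()]
#' fields (`event_types` as a proportion mapping), optional `rules`
#' ([match_rules()] fields) and a `tools` list of `{label, dialect, path}`
#' mappings. Explicit arguments override file values.
#'
#' @param path Path to the YAML file.
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("preset", "seed", "replicates", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$event_types)) {
      sim_args$event_types <- unlist(sim_args$event_types)
    }
    args$sim <- do.call(sim_config, sim_args)
  }
  if (!is.null(y$rules)) args$rules <- do.call(match_rules, y$rules)
  if (!is.null(y$tools)) {
    args$tools <- dplyr::bind_rows(lapply(y$tools, tibble::as_tibble))
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

#' Simulate annotation, truth tables and reads for every replicate
#'
#' Writes, per replicate directory `rep1..repN` (seeded `seed + i`):
#' `annotation.gtf`, `annotation.truncated.gtf`, `truth_events.tsv` (unified
#' format), `truth_reads.tsv`, `reads.sam`, `reads.fastq`, and a
#' `manifest.tsv` listing the files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a tibble with `replicate`, `file`, `path`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  for (i in seq_len(config$replicates)) {
    rep_dir <- file.path(config$out_dir, paste0("rep", i))
    dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- config$sim
    cfg$seed <- config$seed + i
    sim <- simulate_annotation(cfg)
    paths <- c(
      annotation = file.path(rep_dir, "annotation.gtf"),
      annotation_truncated = file.path(rep_dir, "annotation.truncated.gtf"),
      truth_events = file.path(rep_dir, "truth_events.tsv"),
      truth_reads = file.path(rep_dir, "truth_reads.tsv"),
      sam = file.path(rep_dir, "reads.sam"),
      fastq = file.path(rep_dir, "reads.fastq")
    )
    write_gtf(sim$models, paths["annotation"])
    write_gtf(truncate_annotation(sim$models), paths["annotation_truncated"])
    write_unified(sim$truth, paths["truth_events"])
    reads <- simulate_reads(sim$models, cfg, sam = paths["sam"], fastq = paths["fastq"])
    write_truth_reads(reads$reads, paths["truth_reads"])
    manifest <- tibble::tibble(replicate = i, file = names(paths), path = unname(paths))
    readr::write_tsv(manifest, file.path(rep_dir, "manifest.tsv"))
    rows[[i]] <- manifest
  }
  invisible(dplyr::bind_rows(rows))
}

#' Normalize declared tool outputs into the unified format
#'
#' Reads each declared tool file in its dialect, normalizes it against the
#' annotation and writes `<label>.unified.tsv` plus a pooled
#' `rejections.tsv`.
#'
#' @param config A [run_config()] with a `tools` table.
#' @param models A gene-model tibble (e.g. from [read_gtf()]).
#' @param mode `"lenient"` or `"strict"`.
#' @return Invisibly, a list of event tibbles named by label, with the
#'   rejection report attached as attribute `rejections`.
#' @export
run_normalize <- function(config, models, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (is.null(config$tools) || nrow(config$tools) == 0) {
    stop("no tool inputs declared in the configuration")
  }
  missing <- config$tools$path[!file.exists(config$tools$path)]
  if (length(missing) > 0) {
    stop("tool input path(s) not found: ", paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  rej <- list()
  for (i in seq_len(nrow(config$tools))) {
    label <- config$tools$label[i]
    records <- read_dialect_tsv(config$tools$path[i], config$tools$dialect[i])
    res <- normalize_batch(
      stats::setNames(list(records), config$tools$dialect[i]),
      models,
      mode = mode, tool = label
    )
    write_unified(res$events, file.path(config$out_dir, paste0(label, ".unified.tsv")))
    out[[label]] <- res$events
    rej[[label]] <- dplyr::mutate(res$rejections, label = label, .before = 1)
  }
  rejections <- dplyr::bind_rows(rej)
  readr::write_tsv(rejections, file.path(config$out_dir, "rejections.tsv"))
  attr(out, "rejections") <- rejections
  invisible(out)
}

#' Event-level benchmark of unified event sets against truth
#'
#' Matches each labeled event set against the truth set, writes a metrics
#' TSV (per label and event type), and when several replicates are supplied
#' summarises per-label precision/recall with mean and standard deviation.
#'
#' @param events_by_label A named list of event tibbles, or a list of such
#'   lists (one per replicate).
#' @param truth A truth event tibble, or a list of them (one per replicate).
#' @param rules A [match_rules()].
#' @param out_dir Optional directory for `event_metrics.tsv` and
#'   `event_summary.tsv`.
#' @return A list with `metrics` (per replicate, label and type) and
#'   `summary` (per label: mean/sd of overall precision and recall).
#' @export
run_bench_events <- function(events_by_label, truth, rules = match_rules(),
                             out_dir = NULL) {
  replicated <- !is.data.frame(truth)
  reps <- if (replicated) seq_along(truth) else 1L
  metrics <- dplyr::bind_rows(lapply(reps, function(r) {
    ev <- if (replicated) events_by_label[[r]] else events_by_label
    tr <- if (replicated) truth[[r]] else truth
    dplyr::bind_rows(lapply(names(ev), function(lb) {
      precision_recall(match_events(ev[[lb]], tr, rules)) |>
        dplyr::mutate(label = lb, replicate = r, .before = 1)
    }))
  }))
  summary <- metrics |>
    dplyr::filter(.data$type == "overall") |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      precision_mean = mean(.data$precision),
      precision_sd = stats::sd(.data$precision),
      recall_mean = mean(.data$recall),
      recall_sd = stats::sd(.data$recall),
      .groups = "drop"
    )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(metrics, file.path(out_dir, "event_metrics.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "event_summary.tsv"))
  }
  list(metrics = metrics, summary = summary)
}

#' Write and read the truth read table
#'
#' TSV columns: `read_id`, `transcript_id`, `chrom`, `blocks`
#' (`start-end;...`) and `junctions` (`donor:acceptor;...`).
#'
#' @param reads A truth read tibble from [simulate_reads()].
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_truth_reads <- function(reads, path) {
  df <- tibble::tibble(
    read_id = reads$read_id,
    transcript_id = reads$transcript_id,
    chrom = reads$chrom,
    blocks = blocks_to_chr(reads$blocks),
    junctions = vapply(reads$junctions, function(j) {
      paste(sprintf("%d:%d", j$donor, j$acceptor), collapse = ";")
    }, character(1))
  )
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' @rdname write_truth_reads
#' @export
read_truth_reads <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  df$blocks <- chr_to_blocks(df$blocks)
  df$junctions <- lapply(df$junctions, function(x) {
    jn <- .parse_junctions(if (is.na(x)) "" else x)
    tibble::tibble(donor = jn$d, acceptor = jn$a)
  })
  tibble::as_tibble(df)
}
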