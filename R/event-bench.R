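#' Matching rules for event-level benchmarking
#'
#' @param tolerance Allowed per-boundary coordinate deviation in bases.
#' @param collapse_skipping Treat MES/MEE as ES (the convention when tools
#'   report any skipping variant as plain exon skipping). Default `TRUE`.
#' @param type_strict Require equal effective types for a match. Default
#'   `TRUE`.
#' @param partial_mes_credit Allow a reported single-block skipping event to
#'   match one block of a multi-exon truth skipping event; the truth event
#'   counts as found once at least one of its exons is recovered, and is then
#'   consumed. Default `TRUE`.
#' @return A `match_rules` list.
#' @export
match_rules <- function(tolerance = 0L, collapse_skipping = TRUE,
                        type_strict = TRUE, partial_mes_credit = TRUE) {
  stopifnot(tolerance >= 0)
  structure(
    list(
      tolerance = as.integer(tolerance),
      collapse_skipping = collapse_skipping,
      type_strict = type_strict,
      partial_mes_credit = partial_mes_credit
    ),
    class = "match_rules"
  )
}

.blocks_agree <- function(a, b, tol) {
  nrow(a) == nrow(b) &&
    all(abs(a$start - b$start) <= tol) && all(abs(a$end - b$end) <= tol)
}

#' Match reported events to truth events
#'
#' Builds all candidate (reported, truth) pairs — equal chromosome and
#' strand, equal effective type when `type_strict`, and block-wise agreement
#' within `tolerance` (or, with `partial_mes_credit`, a single reported block
#' matching one exon of a multi-block truth skipping event) — and assigns
#' them greedily in a deterministic order: exact coordinate matches first,
#' then by chromosome, first block start, truth id and reported id. The
#' assignment is injective both ways; duplicate reports of an already-consumed
#' truth event remain unmatched (false positives). A truth multi-exon
#' skipping event counts once regardless of block count.
#'
#' @param reported An event tibble.
#' @param truth An event tibble (the simulated ground truth).
#' @param rules A [match_rules()].
#' @return An `as_match` object; see [precision_recall()], [tidy()] and
#'   [glance()] methods.
#' @export
match_events <- function(reported, truth, rules = match_rules()) {
  validate_events(reported)
  validate_events(truth)
  tol <- rules$tolerance
  r_eff <- effective_type(reported$event_type, rules$collapse_skipping)
  t_eff <- effective_type(truth$event_type, rules$collapse_skipping)
  cand <- list()
  for (i in seq_len(nrow(reported))) {
    for (j in seq_len(nrow(truth))) {
      if (reported$chrom[i] != truth$chrom[j]) next
      if (reported$strand[i] != truth$strand[j]) next
      if (rules$type_strict && r_eff[i] != t_eff[j]) next
      rb <- reported$blocks[[i]]
      tb <- truth$blocks[[j]]
      full <- .blocks_agree(rb, tb, tol)
      partial <- !full && rules$partial_mes_credit &&
        truth$event_type[j] %in% c("MES", "MEE") && nrow(rb) == 1 &&
        any(abs(rb$start - tb$start) <= tol & abs(rb$end - tb$end) <= tol)
      if (full || partial) {
        exact <- .blocks_agree(rb, tb, 0L)
        cand[[length(cand) + 1L]] <- list(
          i = i, j = j, exact = exact,
          chrom = reported$chrom[i], start = rb$start[1]
        )
      }
    }
  }
  pairs <- tibble::tibble(
    reported_id = character(0), truth_id = character(0), exact = logical(0)
  )
  if (length(cand) > 0) {
    cd <- tibble::tibble(
      i = vapply(cand, function(x) x$i, integer(1)),
      j = vapply(cand, function(x) x$j, integer(1)),
      exact = vapply(cand, function(x) x$exact, logical(1)),
      chrom = vapply(cand, function(x) x$chrom, character(1)),
      start = vapply(cand, function(x) x$start, integer(1))
    )
    cd$truth_id <- truth$event_id[cd$j]
    cd$reported_id <- reported$event_id[cd$i]
    cd <- cd[order(!cd$exact, cd$chrom, cd$start, cd$truth_id, cd$reported_id), ]
    used_r <- logical(nrow(reported))
    used_t <- logical(nrow(truth))
    keep <- logical(nrow(cd))
    for (k in seq_len(nrow(cd))) {
      if (!used_r[cd$i[k]] && !used_t[cd$j[k]]) {
        used_r[cd$i[k]] <- TRUE
        used_t[cd$j[k]] <- TRUE
        keep[k] <- TRUE
      }
    }
    pairs <- dplyr::select(cd[keep, ], "reported_id", "truth_id", "exact")
  }
  by_type <- dplyr::left_join(
    tibble::tibble(event_id = truth$event_id, type = t_eff),
    dplyr::mutate(pairs, found = TRUE),
    by = c(event_id = "truth_id")
  ) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n_truth = dplyr::n(),
      n_correct = sum(!is.na(.data$found)),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      tibble::tibble(type = r_eff) |>
        dplyr::count(.data$type, name = "n_reported"),
      by = "type"
    ) |>
    dplyr::mutate(n_reported = dplyr::coalesce(.data$n_reported, 0L))
  reported_only <- setdiff(unique(r_eff), by_type$type)
  if (length(reported_only) > 0) {
    by_type <- dplyr::bind_rows(by_type, tibble::tibble(
      type = reported_only,
      n_truth = 0L,
      n_correct = 0L,
      n_reported = vapply(
        reported_only, function(tt) sum(r_eff == tt), integer(1),
        USE.NAMES = FALSE
      )
    ))
  }
  structure(
    list(
      pairs = pairs,
      n_truth = nrow(truth),
      n_reported = nrow(reported),
      n_correct = nrow(pairs),
      by_type = dplyr::arrange(by_type, .data$type),
      unmatched_truth = setdiff(truth$event_id, pairs$truth_id),
      unmatched_reported = setdiff(reported$event_id, pairs$reported_id),
      rules = rules
    ),
    class = "as_match"
  )
}

#' @export
print.as_match <- function(x, ...) {
  cat(
    "AS event match: ", x$n_correct, " correct of ", x$n_reported,
    " reported / ", x$n_truth, " truth events\n",
    sep = ""
  )
  invisible(x)
}

#' Precision and recall of a match result
#'
#' Recall is the number of correctly found events over the number of
#' simulated truth events; precision is over the number of reported events.
#' Either is `NA` when its denominator is zero. The returned table carries
#' one row per effective event type plus an `overall` row.
#'
#' @param m An `as_match` from [match_events()].
#' @return A tibble with `type`, `n_truth`, `n_reported`, `n_correct`,
#'   `precision`, `recall`.
#' @export
precision_recall <- function(m) {
  stopifnot(inherits(m, "as_match"))
  overall <- tibble::tibble(
    type = "overall", n_truth = m$n_truth, n_reported = m$n_reported,
    n_correct = m$n_correct
  )
  dplyr::bind_rows(overall, m$by_type) |>
    dplyr::mutate(
      precision = ifelse(.data$n_reported == 0, NA_real_,
        .data$n_correct / .data$n_reported),
      recall = ifelse(.data$n_truth == 0, NA_real_,
        .data$n_correct / .data$n_truth)
    )
}

#' @rdname precision_recall
#' @param x An `as_match` object.
#' @param ... Unused.
#' @method tidy as_match
#' @export
tidy.as_match <- function(x, ...) {
  dplyr::filter(precision_recall(x), .data$type != "overall")
}

#' @rdname precision_recall
#' @method glance as_match
#' @export
glance.as_match <- function(x, ...) {
  dplyr::select(
    dplyr::filter(precision_recall(x), .data$type == "overall"), -"type"
  )
}

#' Cross-tool intersection counts (UpSet regions)
#'
#' Groups all events by their canonical [event_key()] and counts, for every
#' non-empty subset of tools, the keys detected by exactly that subset. The
#' region counts sum to the number of distinct keys in the union.
#'
#' @param events_by_tool A named list (>= 2 labels) of event tibbles.
#' @param rules A [match_rules()] (only `collapse_skipping` is used; keys are
#'   exact-coordinate).
#' @return An `event_intersections` tibble with `subset` (labels joined by
#'   `&`), `n_tools`, `count`.
#' @export
intersect_toolsets <- function(events_by_tool, rules = match_rules()) {
  labels <- names(events_by_tool)
  if (length(labels) < 2) stop("at least 2 tool labels required")
  keys <- lapply(events_by_tool, event_key, collapse_skipping = rules$collapse_skipping)
  membership <- lapply(keys, unique)
  all_keys <- unique(unlist(membership))
  mat <- vapply(membership, function(k) all_keys %in% k, logical(length(all_keys)))
  if (length(all_keys) == 1) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, labels))
  subset_lab <- apply(mat, 1, function(r) paste(labels[r], collapse = "&"))
  out <- tibble::tibble(
    subset = subset_lab, n_tools = rowSums(mat)
  ) |>
    dplyr::count(.data$subset, .data$n_tools, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$n_tools), .data$subset)
  class(out) <- c("event_intersections", class(out))
  out
}

#' Consensus events supported by at least k tools
#'
#' Returns one representative event per canonical key reported by at least
#' `k` of the tools; the representative comes from the lexicographically
#' smallest supporting tool label, and the support count is recorded.
#' `k = 1` yields the union of keys, `k = n` the full intersection.
#'
#' @param events_by_tool A named list of event tibbles.
#' @param k Minimum support, `1 <= k <= length(events_by_tool)`.
#' @param rules A [match_rules()].
#' @return An event tibble with an extra `support` column.
#' @export
consensus_events <- function(events_by_tool, k, rules = match_rules()) {
  n_tools <- length(events_by_tool)
  if (k < 1 || k > n_tools) {
    stop("k must be between 1 and the number of tools (", n_tools, ")")
  }
  labels <- sort(names(events_by_tool))
  tagged <- dplyr::bind_rows(lapply(labels, function(lb) {
    ev <- events_by_tool[[lb]]
    ev$.label <- lb
    ev$.key <- event_key(ev, collapse_skipping = rules$collapse_skipping)
    ev
  }))
  support <- tagged |>
    dplyr::distinct(.data$.key, .data$.label) |>
    dplyr::count(.data$.key, name = "support")
  reps <- tagged |>
    dplyr::arrange(.data$.key, .data$.label, .data$event_id) |>
    dplyr::distinct(.data$.key, .keep_all = TRUE) |>
    dplyr::inner_join(support, by = ".key") |>
    dplyr::filter(.data$support >= k) |>
    dplyr::select(-".label", -".key")
  reps$event_id <- if (nrow(reps) > 0) {
    sprintf("consensus_%05d", seq_len(nrow(reps)))
  } else {
    character(0)
  }
  reps
}
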