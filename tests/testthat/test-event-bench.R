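mk_events <- function(ids, starts, types = "ES", strand = "+", tool = "t",
                      chrom = "chr1") {
  event_table(tibble::tibble(
    event_id = ids, gene_name = "G", chrom = chrom, strand = strand,
    event_type = rep_len(types, length(ids)),
    blocks = lapply(starts, function(s) {
      tibble::tibble(start = as.integer(s), end = as.integer(s) + 99L)
    }),
    source_tool = tool
  ))
}

test_that("matching assigns injectively and tallies unmatched sets", {
  truth <- mk_events(paste0("T", 1:4), c(1000, 3000, 5000, 7000))
  reported <- mk_events(c("R1", "R2", "F1"), c(1000, 3000, 99000), tool = "x")
  m <- match_events(reported, truth)
  expect_equal(m$n_correct, 2)
  expect_setequal(m$unmatched_truth, c("T3", "T4"))
  expect_equal(m$unmatched_reported, "F1")
  # conservation
  expect_equal(m$n_correct + length(m$unmatched_reported), m$n_reported)
  expect_equal(m$n_correct + length(m$unmatched_truth), m$n_truth)
  # duplicates of a consumed truth event are false positives
  dup <- mk_events(c("R1", "R2"), c(1000, 1000), tool = "x")
  m2 <- match_events(dup, truth)
  expect_equal(m2$n_correct, 1)
  expect_equal(length(m2$unmatched_reported), 1)
})

test_that("partial credit lets a single reported exon find a truth MES", {
  truth <- event_table(tibble::tibble(
    event_id = "T1", gene_name = "G", chrom = "chr1", strand = "+",
    event_type = "MES",
    blocks = list(tibble::tibble(start = c(301L, 501L), end = c(400L, 600L))),
    source_tool = "truth"
  ))
  reported <- mk_events("R1", 301, types = "ES")
  m <- match_events(reported, truth)
  expect_equal(m$n_correct, 1)
  # the MES is consumed: a second single-exon report is a false positive
  reported2 <- mk_events(c("R1", "R2"), c(301, 501), types = "ES")
  m2 <- match_events(reported2, truth)
  expect_equal(m2$n_correct, 1)
  expect_equal(length(m2$unmatched_reported), 1)
  # without partial credit there is no match at all
  m3 <- match_events(
    reported, truth, match_rules(partial_mes_credit = FALSE)
  )
  expect_equal(m3$n_correct, 0)
})

test_that("precision and recall follow their definitions, NA on empty sets", {
  truth <- mk_events(paste0("T", 1:4), c(1000, 3000, 5000, 7000))
  reported <- mk_events(paste0("R", 1:3), c(1000, 3000, 99000), tool = "x")
  pr <- glance(match_events(reported, truth))
  expect_equal(pr$recall, 0.5)
  expect_equal(pr$precision, 2 / 3)
  # truth vs truth
  self <- glance(match_events(truth, truth))
  expect_equal(self$precision, 1)
  expect_equal(self$recall, 1)
  # empty reported set
  empty <- glance(match_events(truth[0, ], truth))
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)
  # per-type breakdown sums to the overall tallies
  td <- tidy(match_events(reported, truth))
  expect_equal(sum(td$n_correct), pr$n_correct)
  expect_equal(sum(td$n_truth), pr$n_truth)
})

test_that("swapping reported and truth swaps precision and recall", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      a <- random_events(12, seed = rep, source_tool = "a")
      b <- random_events(15, seed = rep + 100, source_tool = "b")
      rules <- match_rules(partial_mes_credit = FALSE)
      ab <- glance(match_events(a, b, rules))
      ba <- glance(match_events(b, a, rules))
      expect_equal(ab$precision, ba$recall)
      expect_equal(ab$recall, ba$precision)
    }
  })
})

test_that("greedy assignment attains the maximum matching on small fixtures", {
  rules <- match_rules()
  for (s in 1:60) {
    n_t <- withr::with_seed(s, sample(1:12, 1))
    n_r <- withr::with_seed(s + 1000, sample(1:8, 1))
    truth <- random_events(n_t, seed = s, source_tool = "truth")
    # reported: a mix of copied truth events and perturbations
    reported <- withr::with_seed(s + 2000, {
      idx <- sample(n_t, n_r, replace = TRUE)
      r <- truth[idx, ]
      r$event_id <- sprintf("r%03d", seq_len(n_r))
      r$source_tool <- "x"
      flip <- runif(n_r) < 0.4
      r$blocks[flip] <- lapply(r$blocks[flip], function(b) {
        b$start <- b$start + sample(c(-3L, 0L, 17L), nrow(b), replace = TRUE)
        b$end <- pmax(b$end, b$start)
        b
      })
      r
    })
    m <- match_events(reported, truth, rules)
    expect_equal(m$n_correct, max_matching_oracle(reported, truth, rules),
      info = paste("seed", s)
    )
  }
})

test_that("intersection regions partition the union of event keys", {
  a <- mk_events(c("E1", "E2"), c(1000, 3000), tool = "A")
  b <- mk_events(c("E2b", "E3"), c(3000, 5000), tool = "B")
  tab <- intersect_toolsets(list(A = a, B = b))
  get <- function(s) tab$count[tab$subset == s]
  expect_equal(get("A"), 1)
  expect_equal(get("B"), 1)
  expect_equal(get("A&B"), 1)
  expect_equal(sum(tab$count), 3)
  # disjoint tools have no shared region
  d <- mk_events("E9", 90000, tool = "D")
  tab2 <- intersect_toolsets(list(A = a, D = d))
  expect_false("A&D" %in% tab2$subset)
  expect_error(intersect_toolsets(list(A = a)), "2 tool labels")
})

test_that("consensus respects the minimum-support threshold", {
  a <- mk_events(c("E1", "E2"), c(1000, 3000), tool = "A")
  b <- mk_events(c("E2b", "E3"), c(3000, 5000), tool = "B")
  c2 <- consensus_events(list(A = a, B = b), k = 2)
  expect_equal(nrow(c2), 1)
  expect_equal(c2$blocks[[1]]$start, 3000L)
  expect_equal(c2$support, 2)
  expect_equal(c2$source_tool, "A") # representative from smallest label
  c1 <- consensus_events(list(A = a, B = b), k = 1)
  expect_equal(nrow(c1), 3)
  expect_error(consensus_events(list(A = a, B = b), k = 3), "between 1")
})

test_that("intersections and consensus agree with set algebra on simulations", {
  sim <- simulate_annotation(load_preset("S0", n_genes = 50, seed = 43))
  # three synthetic "tools": random subsets of truth
  tools <- withr::with_seed(47, lapply(1:3, function(i) {
    keep <- runif(nrow(sim$truth)) < 0.7
    ev <- sim$truth[keep, ]
    ev$source_tool <- paste0("tool", i)
    ev
  }))
  names(tools) <- paste0("tool", 1:3)
  tab <- intersect_toolsets(tools)
  union_keys <- unique(unlist(lapply(tools, event_key)))
  expect_equal(sum(tab$count), length(union_keys))
  expect_equal(nrow(consensus_events(tools, k = 1)), length(union_keys))
  inter_keys <- Reduce(intersect, lapply(tools, event_key))
  expect_equal(nrow(consensus_events(tools, k = 3)), length(inter_keys))
})
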