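# build a ranked candidate tibble with controllable profiles
make_candidates <- function(n = 200, seed = 1, sources = c("ngs", "sampled")) {
  set.seed(seed)
  tibble::tibble(
    cdr1 = random_aa(n, 10), cdr2 = random_aa(n, 8), cdr3 = random_aa(n, 18),
    source = sample(sources, n, replace = TRUE),
    nll = sort(runif(n, 2, 40)),
    pI = runif(n, 5, 10),
    cdr_hydropathy = runif(n, 0, 2),
    cdr_positive_charge = runif(n, 0, 4),
    flags = ""
  )
}

test_that("a full panel is chosen with the top-100 quota satisfied", {
  cand <- make_candidates(200)
  rep <- select_candidates(cand, selection_config())
  expect_equal(nrow(rep$selected), 10)
  expect_gte(sum(rep$selected$rationale == "top_nll"), 3)
  top100 <- cand$nll[1:100]
  picked_top <- rep$selected$nll[rep$selected$rationale == "top_nll"]
  expect_true(all(picked_top %in% top100))
  # every chosen sequence passes the (empty) cutoffs and the size bound holds
  expect_lte(nrow(rep$selected), 10)
})

test_that("candidates over a descriptor cutoff are excluded with a reason", {
  cand <- make_candidates(50, seed = 3)
  cand$cdr_hydropathy[7] <- 5
  rep <- select_candidates(cand, selection_config(
    descriptor_cutoffs = c(cdr_hydropathy = 2.5)))
  expect_true(any(rep$excluded$reason == "descriptor_cutoff:cdr_hydropathy"))
  expect_false(cand$cdr3[7] %in% rep$selected$cdr3)
  expect_true(all(rep$selected$cdr_hydropathy <= 2.5))
})

test_that("mixed-source pools yield mixed-source panels", {
  # mirrors a published cluster whose ten picks combine NGS and sampled hits
  cand <- make_candidates(120, seed = 8)
  cand$source <- c(rep("sampled", 30), rep("ngs", 90))
  rep <- select_candidates(cand, selection_config())
  expect_setequal(unique(rep$selected$source), c("ngs", "sampled"))
  expect_lte(nrow(rep$selected), 10)
})

test_that("a missing source is swapped in when only one is represented early", {
  cand <- make_candidates(150, seed = 12)
  cand$source <- c(rep("ngs", 140), rep("sampled", 10))  # sampled only at high NLL
  rep <- select_candidates(cand, selection_config())
  expect_true("sampled" %in% rep$selected$source)
})

test_that("an all-failing pool returns an empty selection, not an error", {
  cand <- make_candidates(20, seed = 5)
  rep <- select_candidates(cand, selection_config(
    descriptor_cutoffs = c(cdr_hydropathy = -1)))
  expect_equal(nrow(rep$selected), 0)
  expect_equal(nrow(rep$excluded), 20)
})

test_that("liability-free variants are added for soft-flagged panels", {
  cand <- make_candidates(40, seed = 9)
  cand$flags <- "cdr3:4:NT:deamidation:moderate"
  cand$flags[25] <- ""
  rep <- select_candidates(cand, selection_config())
  expect_true(cand$cdr3[25] %in% rep$selected$cdr3 ||
                "liability_free_variant" %in% rep$selected$rationale)
})

test_that("selection is deterministic and respects irrelevant alternatives", {
  cfg <- selection_config(nll_spread_points = c(10, 25))
  for (i in 1:15) {
    cand <- make_candidates(60, seed = 100 + i)
    rep1 <- select_candidates(cand, cfg)
    rep2 <- select_candidates(cand, cfg)
    expect_identical(tidy(rep1), tidy(rep2))
    not_chosen <- setdiff(seq_len(nrow(cand)),
                          which(cand$cdr3 %in% rep1$selected$cdr3))
    drop <- sample(not_chosen, 1)
    rep3 <- select_candidates(cand[-drop, ], cfg)
    expect_identical(tidy(rep1)[, c("cdr3", "rationale")],
                     tidy(rep3)[, c("cdr3", "rationale")])
  }
})

test_that("selection summaries count sources and NLL spread", {
  cand <- make_candidates(80, seed = 44)
  rep <- select_candidates(cand, selection_config())
  g <- glance(rep)
  expect_equal(g$n_selected, nrow(rep$selected))
  expect_equal(g$n_ngs + g$n_sampled, g$n_selected)
  expect_lte(g$nll_min, g$nll_max)
})
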