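test_that("enrichment factor follows the pseudocount formula", {
  expect_equal(enrichment_factor(10, 100, 10, 100), 1.0)
  expect_equal(enrichment_factor(0, 100, 0, 100), 1.0)
  # hand-computed: ((5+1)/(101))/((1+1)/(201)) = (6/101)*(201/2)
  expect_equal(enrichment_factor(5, 100, 1, 200), (6 / 101) / (2 / 201))
  expect_error(enrichment_factor(10, 5, 1, 100), "exceed")
  expect_error(enrichment_factor(-1, 5, 1, 100))
})

test_that("enrichment factor is monotone in the cluster counts", {
  set.seed(2)
  for (i in 1:20) {
    t_sel <- sample(1000:5000, 1); t_base <- sample(1000:5000, 1)
    n_sel <- sample(0:(t_sel - 1), 1); n_base <- sample(0:(t_base - 1), 1)
    expect_gt(enrichment_factor(n_sel + 1, t_sel, n_base, t_base),
              enrichment_factor(n_sel, t_sel, n_base, t_base))
    expect_lt(enrichment_factor(n_sel, t_sel, n_base + 1, t_base),
              enrichment_factor(n_sel, t_sel, n_base, t_base))
  }
})

test_that("published per-cluster read counts reproduce the printed fold changes", {
  reads <- nkp46_cluster_reads()
  totals <- nkp46_round_totals()
  t0 <- totals$total_reads[totals$round == 0]
  t2 <- totals$total_reads[totals$round == 2]
  ef <- enrichment_factor(reads$reads_r2, t2, reads$reads_r0, t0,
                          round_to_integer = TRUE)
  expect_equal(ef, reads$reported_ef)
})

# a clustered object carrying the published counts: the four clusters plus a
# background cluster holding the remaining reads so round totals match
published_clusters <- function() {
  reads <- nkp46_cluster_reads()
  totals <- nkp46_round_totals()
  reps <- nkp46_representatives()
  bg0 <- totals$total_reads[1] - sum(reads$reads_r0)
  bg1 <- totals$total_reads[2] - sum(reads$reads_r1)
  bg2 <- totals$total_reads[3] - sum(reads$reads_r2)
  rep <- tibble::tibble(
    seq_id = c(sprintf("c%d", reads$cluster_id), "bg"),
    cdr1 = "GFTFSSYAIS", cdr2 = "SSGSNTAA",
    cdr3 = c("VFTPTDTVVFTNKEPYNY", "AGGMGSTTVVVSTIPYKY",
             "NPATSTVLIVRDLGYAY", "SLTYDQTTVYVSPLAYVD",
             "IRTPAESQVIVTLDWYRY"),
    count_r0 = c(reads$reads_r0, bg0),
    count_r1 = c(reads$reads_r1, bg1),
    count_r2 = c(reads$reads_r2, bg2)
  )
  cluster_by_cdr3(rep)
}

test_that("cluster ranking orders the published clusters as printed", {
  cl <- published_clusters()
  by_ef <- rank_clusters(cl, "enrichment", sel_round = 2, base_round = 0)
  # identify clusters by their centroid CDR3
  fams <- c("VFTPTDTVVFTNKEPYNY", "AGGMGSTTVVVSTIPYKY",
            "NPATSTVLIVRDLGYAY", "SLTYDQTTVYVSPLAYVD")
  ef_order <- by_ef$centroid_cdr3[by_ef$centroid_cdr3 %in% fams]
  expect_equal(ef_order, fams)  # printed descending-EF order
  by_freq <- rank_clusters(cl, "frequency", sel_round = 2)
  top_fams <- by_freq$centroid_cdr3[by_freq$centroid_cdr3 %in% fams]
  expect_equal(top_fams[1], "SLTYDQTTVYVSPLAYVD")  # 11,954 round-2 reads
  expect_error(rank_clusters(cl, "enrichment", sel_round = 9), "unknown round")
})

test_that("single cluster ranking returns a singleton list", {
  rep <- tibble::tibble(seq_id = "a", cdr1 = "GFTF", cdr2 = "SS",
                        cdr3 = "AGGMGSTT", count_r0 = 1L, count_r2 = 5L)
  out <- rank_clusters(cluster_by_cdr3(rep), "enrichment", 2, 0)
  expect_equal(nrow(out), 1)
})

test_that("positional frequencies are count-weighted and row-stochastic", {
  one <- tibble::tibble(seq_id = "a", cdr1 = "", cdr2 = "", cdr3 = "ACDY",
                        count_r2 = 7L, count_r0 = 1L)
  m <- positional_frequency(one, 2, "cdr3")
  expect_equal(dim(m), c(4, 20))
  expect_equal(unname(m[cbind(1:4, match(c("A", "C", "D", "Y"),
                                         amino_acids()))]), rep(1, 4))
  expect_equal(unname(rowSums(m)), rep(1, 4))

  two <- tibble::tibble(seq_id = c("a", "b"), cdr1 = "", cdr2 = "",
                        cdr3 = c("ACDY", "ACWY"), count_r0 = 1L,
                        count_r2 = c(1L, 1L))
  m2 <- positional_frequency(two, 2, "cdr3")
  expect_equal(unname(m2[3, c("D", "W")]), c(0.5, 0.5))
  expect_equal(unname(m2[1, "A"]), 1)

  wt <- tibble::tibble(seq_id = c("a", "b"), cdr1 = "", cdr2 = "",
                       cdr3 = c("ACDY", "ACWY"), count_r0 = 1L,
                       count_r2 = c(3L, 1L))
  m3 <- positional_frequency(wt, 2, "cdr3")
  expect_equal(unname(m3[3, c("D", "W")]), c(0.75, 0.25))
})

test_that("length outliers are excluded at the modal length and reported", {
  mixed <- tibble::tibble(seq_id = c("a", "b", "c"), cdr1 = "", cdr2 = "",
                          cdr3 = c("ACDY", "ACWY", "ACDEF"),
                          count_r0 = 1L, count_r2 = c(2L, 2L, 1L))
  m <- positional_frequency(mixed, 2, "cdr3")
  expect_equal(nrow(m), 4)
  expect_equal(attr(m, "excluded_fraction"), 0.2)
})

test_that("positional enrichment follows the pseudocount ratio", {
  same <- tibble::tibble(seq_id = c("a", "b"), cdr1 = "", cdr2 = "",
                         cdr3 = c("ACDY", "ACWY"),
                         count_r1 = c(2L, 2L), count_r2 = c(4L, 4L))
  e <- positional_enrichment(same, 2, 1, region = "cdr3")
  expect_true(all(abs(e - 1) < 1e-12))

  half <- tibble::tibble(seq_id = c("a", "b", "c", "d"), cdr1 = "", cdr2 = "",
                         cdr3 = c("ACDY", "ACWY", "ACWY", "ACWY"),
                         count_r1 = c(1L, 3L, 0L, 0L),
                         count_r2 = c(2L, 2L, 0L, 0L))
  e2 <- positional_enrichment(half, 2, 1, pseudo = 1e-6, region = "cdr3")
  expect_equal(unname(e2[3, "D"]), 2, tolerance = 1e-4)

  # residue absent in the baseline round: (0.1 + 0.001) / 0.001 = 101
  absent <- tibble::tibble(seq_id = c("a", "b"), cdr1 = "", cdr2 = "",
                           cdr3 = c("ACDY", "ACWY"),
                           count_r1 = c(10L, 0L), count_r2 = c(9L, 1L))
  e3 <- positional_enrichment(absent, 2, 1, pseudo = 0.001, region = "cdr3")
  expect_equal(unname(e3[3, "W"]), 0.101 / 0.001, tolerance = 1e-9)
})

test_that("swapping rounds gives the entrywise reciprocal with matched pseudo", {
  set.seed(6)
  rep <- tibble::tibble(
    seq_id = sprintf("s%d", 1:20), cdr1 = "", cdr2 = "",
    cdr3 = random_aa(20, 9),
    count_r1 = rpois(20, 6) + 1L, count_r2 = rpois(20, 6) + 1L
  )
  fwd <- positional_enrichment(rep, 2, 1, pseudo = 0.01, region = "cdr3")
  bwd <- positional_enrichment(rep, 1, 2, pseudo = 0.01, region = "cdr3")
  expect_equal(unclass(fwd), 1 / unclass(bwd), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(fwd > 0))
})
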