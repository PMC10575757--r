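test_that("liability flags match the published degradation panel", {
  deg <- nkp46_degradation()
  # the sequence with measurable CDR1 deamidation carries an Asn-Tyr motif
  fl1 <- detect_liabilities(deg$cdr1[1], deg$cdr2[1], deg$cdr3[1])
  ny <- fl1[fl1$region == "cdr1" & fl1$category == "deamidation", ]
  expect_equal(ny$position, 6)
  expect_equal(ny$motif, "NY")
  expect_equal(ny$severity, "low")
  # the CDR3 methionine is a high-severity oxidation site
  fl10 <- detect_liabilities(deg$cdr1[2], deg$cdr2[2], deg$cdr3[2])
  met <- fl10[fl10$category == "oxidation", ]
  expect_equal(met$region, "cdr3")
  expect_equal(met$position, 4)
  expect_equal(met$severity, "high")
  # Asn-Thr (moderate deamidation) in CDR2 and an Asp motif in CDR3
  fl22 <- detect_liabilities(deg$cdr1[3], deg$cdr2[3], deg$cdr3[3])
  expect_true(any(fl22$region == "cdr2" & fl22$motif == "NT" &
                    fl22$severity == "moderate"))
  expect_true(any(fl22$region == "cdr3" & fl22$category == "isomerization"))
  # CDR1 Asn and CDR2 Asn-Thr
  fl30 <- detect_liabilities(deg$cdr1[4], deg$cdr2[4], deg$cdr3[4])
  expect_true(any(fl30$region == "cdr1" & fl30$category == "deamidation"))
  expect_true(any(fl30$region == "cdr2" & fl30$motif == "NT"))
})

test_that("sequon rules compose with deamidation flags", {
  npt <- detect_liabilities("NPT", "", "")
  expect_false(any(npt$category == "glycosylation_sequon"))  # X = Pro
  ngs <- detect_liabilities("NGS", "", "")
  expect_true(any(ngs$category == "deamidation" & ngs$severity == "high" &
                    ngs$motif == "NG"))
  expect_true(any(ngs$category == "glycosylation_sequon" &
                    ngs$severity == "high" & ngs$motif == "NGS"))
  expect_equal(nrow(ngs), 2)
})

test_that("liability scanning matches an exhaustive pattern-scan oracle", {
  set.seed(41)
  for (i in 1:40) {
    c1 <- random_aa(1, sample(4:12, 1))
    c2 <- random_aa(1, sample(4:10, 1))
    c3 <- random_aa(1, sample(6:20, 1))
    got <- as.data.frame(detect_liabilities(c1, c2, c3))
    want <- oracle_liabilities(c1, c2, c3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      rownames(want) <- NULL
      expect_equal(got[order(got$region, got$position, got$category), ],
                   want[order(want$region, want$position, want$category), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("isoelectric point solves the zero-charge equation", {
  for (s in c("KKKKK", "DDDDD", "GFTFSSYAIS", "ACDEFGHIKLMNPQRSTVWY")) {
    pI <- isoelectric_point(s)
    expect_lt(abs(vhhmine:::net_charge(s, pI)), 1e-3)
  }
  expect_gt(isoelectric_point("KKKKK"), isoelectric_point("DDDDD"))
})

test_that("isoelectric point matches the fine-grid charge-scan oracle", {
  expect_equal(isoelectric_point("ACDEFGHIKLMNPQRSTVWY"),
               oracle_pi("ACDEFGHIKLMNPQRSTVWY"), tolerance = 1e-3)
  set.seed(19)
  for (s in random_aa(5, 15)) {
    expect_equal(isoelectric_point(s), oracle_pi(s), tolerance = 1e-3)
  }
})

test_that("adding basic residues never decreases the pI", {
  set.seed(23)
  for (s in random_aa(10, 12)) {
    expect_gte(isoelectric_point(paste0(s, "K")) + 1e-6,
               isoelectric_point(s))
  }
})

test_that("windowed hydropathy follows the declared scale", {
  expect_gt(cdr_hydropathy("IIIII", "", ""), cdr_hydropathy("RRRRR", "", ""))
  # a CDR shorter than the window contributes its full-length mean
  kd <- hydropathy_scale()
  expect_equal(cdr_hydropathy("ACD", "", "", window = 5),
               mean(kd[c("A", "C", "D")]))
  expect_equal(cdr_hydropathy("GWCAK", "", "", window = 5),
               mean(kd[strsplit("GWCAK", "")[[1]]]))
  # hand summation over every window of the published CDR3 tail
  s <- "VVVSTIPYKY"
  ch <- strsplit(s, "")[[1]]
  wins <- vapply(1:(nchar(s) - 4), function(i) mean(kd[ch[i:(i + 4)]]),
                 numeric(1))
  expect_equal(cdr_hydropathy("", "", s), max(wins))
  expect_equal(max(wins), 2.28, tolerance = 1e-9)
})

test_that("CDR positive charge counts R/K with fractional histidine", {
  expect_equal(cdr_positive_charge("GGGG", "GGGG", "GGGG"), 0)
  expect_equal(cdr_positive_charge("RGGG", "GGGG", "GKGG"), 2)
  expect_equal(cdr_positive_charge("HH", "", ""), 0.2)
  # hand count on a published candidate: R in CDR1 and CDR2, none in CDR3
  panel <- nkp46_panel()
  p29 <- panel[panel$id == 29, ]
  expect_equal(cdr_positive_charge(p29$cdr1, p29$cdr2, p29$cdr3), 2)
})

test_that("framework identity is alignment-length normalised", {
  fw <- random_aa(1, 87, seed = 7)
  expect_equal(framework_identity(fw, fw), 100)
  sub <- fw
  substr(sub, 40, 40) <- if (substr(fw, 40, 40) == "A") "C" else "A"
  expect_equal(framework_identity(fw, sub), 100 * 86 / 87, tolerance = 0.01)
  expect_equal(framework_identity(strrep("A", 30), strrep("C", 30)), 0)
})

test_that("descriptor traffic lights follow the mean/SD bands", {
  ref <- reference_stats(tibble::tibble(
    descriptor = c("cdr_hydropathy", "cdr_positive_charge"),
    mean = c(1, 2), sd = c(0.5, 1)))
  lights <- vhhmine:::traffic_light(c(1, 1.75, 2.5), 1, 0.5)
  expect_equal(lights, c("green", "yellow", "red"))

  rep <- as_repertoire(toy_repertoire())
  prof <- assess_developability(rep, reference = ref)
  expect_true(all(c("pI", "cdr_hydropathy", "cdr_positive_charge", "flags",
                    "light_cdr_hydropathy") %in% names(prof)))
  expect_true(all(prof$light_cdr_hydropathy %in% c("green", "yellow", "red")))
  # descriptors are pure functions of sequence: repeated calls identical
  prof2 <- assess_developability(rep, reference = ref)
  expect_identical(as.data.frame(prof), as.data.frame(prof2))
  # without a reference the values are reported and the lights omitted
  bare <- assess_developability(rep)
  expect_false(any(grepl("^light_", names(bare))))
  expect_true(all(is.finite(bare$pI)))
})
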