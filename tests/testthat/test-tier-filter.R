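annotated_cs <- function(af, assertion, gene = "GENE1", id = "case1") {
  n <- length(af)
  make_cs(calls_from_keys("chr1", seq_len(n) * 10L,
                          gene = rep_len(gene, n), af = af,
                          assertion = assertion), id = id,
          material = "ffpe", provenance = "ensemble")
}

test_that("frequency filter keeps rare variants and rescues pathogenic ones", {
  cs <- annotated_cs(af = c(0.004, 0.06, 0.02, 0.02, NA),
                     assertion = c(NA, NA, "pathogenic", NA, NA))
  kept <- frequency_filter(cs)
  expect_equal(kept$calls$pos, c(10L, 30L, 50L))
  # af 0.004 none -> kept; af 0.06 none -> removed at the 5% stage;
  # af 0.02 pathogenic -> rescued; af 0.02 none -> removed at 1%;
  # missing af -> treated as 0, kept
  expect_true(all(ifelse(is.na(kept$calls$af), 0, kept$calls$af) < 0.01 |
                    kept$calls$assertion %in% c("pathogenic",
                                                "likely_pathogenic")))
  # idempotence
  expect_equal(frequency_filter(kept)$calls, kept$calls)
})

test_that("every retained variant satisfies the retention predicate", {
  set.seed(71)
  for (i in 1:30) {
    n <- 50
    calls <- random_calls(n)
    calls$af <- ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.5))
    calls$assertion <- sample(c("pathogenic", "likely_pathogenic", "vus",
                                "benign", NA), n, replace = TRUE)
    calls$gene <- sample(c("G1", "G2", NA), n, replace = TRUE)
    cs <- make_cs(calls, material = "ffpe")
    kept <- frequency_filter(cs)$calls
    af <- ifelse(is.na(kept$af), 0, kept$af)
    path <- !is.na(kept$assertion) &
      kept$assertion %in% c("pathogenic", "likely_pathogenic")
    expect_true(all(af < 0.01 | path))
    dropped <- cs$calls[!(variant_key(cs$calls) %in% variant_key(kept)), ]
    af_d <- ifelse(is.na(dropped$af), 0, dropped$af)
    path_d <- !is.na(dropped$assertion) &
      dropped$assertion %in% c("pathogenic", "likely_pathogenic")
    expect_true(all(af_d >= 0.01 & !path_d))
  }
})

test_that("panel subsetting matches a membership oracle and nests", {
  set.seed(72)
  panels <- default_panels()
  expect_length(panels$CDGP$genes, 84)
  expect_length(panels$SDGP$genes, 166)
  expect_length(panels$aorta$genes, 27)
  expect_true(all(panels$CDGP$genes %in% panels$SDGP$genes))

  n <- 100
  calls <- random_calls(n)
  calls$gene <- sample(c(panels$SDGP$genes[1:20], "NOT_IN_PANEL", NA),
                       n, replace = TRUE)
  cs <- make_cs(calls, material = "ffpe")
  suppressMessages({
    small <- panel_subset(cs, panels$CDGP)
    big <- panel_subset(cs, panels$SDGP)
  })
  expect_equal(variant_key(small$calls),
               variant_key(cs$calls[!is.na(cs$calls$gene) &
                                      cs$calls$gene %in% panels$CDGP$genes,
                                    ]))
  # CDGP subset of SDGP implies nested retained sets
  expect_true(all(variant_key(small$calls) %in% variant_key(big$calls)))
  expect_error(gene_panel("empty", character()), "empty")
})

test_that("familial queries are answered from local depth, not exome success", {
  tgt <- region_set("chr1", 0L, 1000L, "t")
  # 14%-covered exome, but 25X at the queried position
  d <- rep.int(0L, 1000)
  d[1:140] <- 25L
  cov <- coverage_track("case1", tgt, d)
  calls <- annotated_cs(af = 0.001, assertion = NA_character_)
  req <- referral_request("case1", "familial_variant",
                          list(chrom = "chr1", pos = 10L, ref = "A",
                               alt = "G"))
  rep1 <- run_referral(req, calls, cov)
  expect_equal(rep1$familial_variant_status, "present")
  expect_false(rep1$yield_category == "failed")
  # absent variant at a covered position
  req2 <- referral_request("case1", "familial_variant",
                           list(chrom = "chr1", pos = 20L, ref = "A",
                                alt = "C"))
  expect_equal(run_referral(req2, calls, cov)$familial_variant_status,
               "absent")
  # uncovered position cannot be answered
  req3 <- referral_request("case1", "familial_variant",
                           list(chrom = "chr1", pos = 900L, ref = "A",
                                alt = "G"))
  expect_equal(run_referral(req3, calls, cov)$familial_variant_status,
               "uncovered")
})

test_that("the two-tier strategy short-circuits on a CDGP hit", {
  tgt <- region_set("chr1", 0L, 100L, "t")
  cov <- coverage_track("case1", tgt, rep.int(50L, 100))
  panels <- list(CDGP = gene_panel("CDGP", "GENE_A"),
                 SDGP = gene_panel("SDGP", c("GENE_A", "GENE_B")))
  req <- referral_request("case1", "general_scd")

  hit1 <- make_cs(calls_from_keys("chr1", c(10L, 20L),
                                  gene = c("GENE_A", "GENE_B"),
                                  af = c(0.001, 0.001),
                                  assertion = c("pathogenic", "pathogenic")),
                  id = "case1", material = "ffpe")
  r1 <- run_referral(req, hit1, cov, panels = panels)
  expect_equal(unique(r1$retained$tier), "CDGP")  # tier 2 never ran
  expect_equal(r1$yield_category, "positive")

  # only an SDGP-gene variant: tier 1 empty, tier 2 retains it
  hit2 <- make_cs(calls_from_keys("chr1", 20L, gene = "GENE_B", af = 0.001,
                                  assertion = "likely_pathogenic"),
                  id = "case1", material = "ffpe")
  r2 <- run_referral(req, hit2, cov, panels = panels)
  expect_equal(r2$retained$tier, "SDGP")
  expect_equal(r2$yield_category, "positive")

  # VUS only
  hit3 <- make_cs(calls_from_keys("chr1", 20L, gene = "GENE_B", af = 0.001,
                                  assertion = "vus"),
                  id = "case1", material = "ffpe")
  expect_equal(run_referral(req, hit3, cov, panels = panels)$yield_category,
               "vus_only")
  expect_error(run_referral(referral_request("c", "disease_panel",
                                             "nope"),
                            hit3, cov, panels = panels), "unknown panel")
})

test_that("referral payloads are validated against the category", {
  expect_error(referral_request("c", "familial_variant", "notalist"),
               "payload")
  expect_error(referral_request("c", "general_scd", "extra"), "payload")
  expect_s3_class(referral_request("c", "specified_gene", "KCNQ1"),
                  "referral_request")
})

test_that("cohort yield arithmetic matches the printed percentages", {
  cats <- c(rep("positive", 3), rep("vus_only", 4), rep("negative", 17))
  y <- cohort_yield(cats)
  expect_equal(y$n_success, 24L)
  expect_equal(y$yield_strict_pct, 12.5)
  expect_equal(y$yield_inclusive_pct, 29)
  # failed cases leave the denominator
  y2 <- cohort_yield(c(cats, rep("failed", 6)))
  expect_equal(y2$n_success, 24L)
  expect_equal(y2$yield_strict_pct, 12.5)
  expect_equal(cohort_yield(rep("negative", 5))$yield_strict_pct, 0)
  expect_error(cohort_yield(rep("failed", 3)), "no successfully")
})
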