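test_that("uniform coverage gives fold80 of exactly 1", {
  m <- sample_metrics(uniform_track(30L))
  expect_equal(m$mean_depth, 30)
  expect_equal(unname(m$pct_ge[["20"]]), 100)
  expect_equal(m$pct_zero, 0)
  expect_equal(m$fold80, 1)
})

test_that("fold80 uses the nearest-rank 20th percentile", {
  tgt <- region_set("chr1", 0L, 5L, "t")
  tr <- coverage_track("s", tgt, c(10L, 10L, 10L, 10L, 100L))
  m <- sample_metrics(tr)
  expect_equal(m$mean_depth, 28)
  expect_equal(m$fold80, 2.8)  # d20 = 10
  # all-zero 20th percentile: fold80 undefined
  z <- coverage_track("z", tgt, c(0L, 0L, 5L, 5L, 5L))
  expect_true(is.na(sample_metrics(z)$fold80))
})

test_that("metrics match a naive full-sort oracle on random tracks", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(50:400, 1)
    d <- sample(0:60, n, replace = TRUE)
    tr <- coverage_track("s", region_set("chr1", 0L, n, "t"), d)
    m <- sample_metrics(tr, thresholds = c(1, 10, 20, 30))
    expect_equal(m$mean_depth, mean(d))
    s <- sort(d)
    d20 <- s[ceiling(0.2 * n)]
    expect_equal(m$fold80, if (d20 == 0) NA_real_ else mean(d) / d20)
    for (t in c(1, 10, 20, 30))
      expect_equal(unname(m$pct_ge[[as.character(t)]]),
                   100 * sum(d >= t) / n)
    expect_equal(m$pct_zero, 100 * sum(d == 0) / n)
    # monotone in the threshold
    expect_true(all(diff(m$pct_ge) <= 0))
  }
})

test_that("the success boundary at 90% of targets >= 20X is inclusive", {
  tgt <- region_set("chr1", 0L, 1000L, "t")
  at <- function(p) {
    d <- rep.int(0L, 1000)
    d[seq_len(p * 10)] <- 25L
    sample_metrics(coverage_track("s", tgt, d))
  }
  expect_true(is_successful(at(90)))
  expect_false(is_successful(at(89.9)))
  bad <- at(90)
  bad$pct_ge <- bad$pct_ge[c("10", "30")]
  expect_error(is_successful(bad), "20X")
})

test_that("joint low-coverage flags the 6-of-24 zero-coverage case", {
  tgt <- region_set("chr1", 0L, 10L, "t")
  base_depth <- rep.int(50L, 10)
  tracks <- lapply(1:24, function(i) {
    d <- base_depth
    if (i <= 6) d[4] <- 0L  # exactly 6/24 = 25% at zero on base 4
    coverage_track(sprintf("s%d", i), tgt, d)
  })
  flagged <- joint_low_coverage(tracks)
  expect_equal(flagged$intervals,
               data.frame(chrom = "chr1", start = 3L, end = 4L))
  # 5 of 24 (< 25%) does not flag
  tracks5 <- tracks
  tracks5[[6]] <- coverage_track("s6", tgt, base_depth)
  expect_equal(total_bases(joint_low_coverage(tracks5)), 0L)
})

test_that("all-high cohorts yield no flagged bases", {
  tgt <- region_set("chr1", 0L, 50L, "t")
  tracks <- lapply(1:8, function(i)
    coverage_track(sprintf("s%d", i), tgt, rep.int(100L, 50)))
  expect_equal(total_bases(joint_low_coverage(tracks)), 0L)
})

test_that("joint low-coverage matches the per-base four-criterion oracle", {
  set.seed(62)
  tgt <- region_set("chr1", 0L, 300L, "t")
  qc <- qc_thresholds()
  for (i in 1:10) {
    D <- matrix(stats::rnbinom(12 * 300, mu = 25, size = 2), nrow = 12)
    tracks <- lapply(1:12, function(k)
      coverage_track(sprintf("s%d", k), tgt, D[k, ]))
    got <- joint_low_coverage(tracks, qc)
    want <- low_cov_oracle_flags(D, qc)
    m <- list(chr1 = c(want, rep(FALSE, CHROM_LEN - 300L)))
    expect_equal(got$intervals, mask_to_rs(m)$intervals)
  }
})

test_that("gene coverage curve handles boundaries and is monotone", {
  tgt <- region_set("chr1", 0L, 200L, "t")
  genes <- data.frame(chrom = "chr1", start = c(0L, 100L),
                      end = c(100L, 200L), gene = c("G1", "G2"))
  tr <- coverage_track("s", tgt, rep.int(30L, 200))
  cv <- gene_coverage_curve(tr, genes)
  expect_true(all(cv$prop_genes[cv$depth <= 30] == 1))

  # one gene exactly half covered at 20X: covered at f = 0.5, not 0.51
  d <- rep.int(0L, 200)
  d[1:50] <- 25L
  d[101:200] <- 25L
  tr2 <- coverage_track("s", tgt, d)
  cv2 <- gene_coverage_curve(tr2, genes, depth_thresholds = 20,
                             fraction_grid = c(0.5, 0.51))
  expect_equal(cv2$prop_genes[cv2$fraction == 0.5], 1)
  expect_equal(cv2$prop_genes[cv2$fraction == 0.51], 0.5)

  # per-gene counting oracle on a random fixture + monotonicity
  set.seed(63)
  d3 <- sample(0:40, 200, replace = TRUE)
  tr3 <- coverage_track("s", tgt, d3)
  grid <- seq(0, 1, by = 0.1)
  cv3 <- gene_coverage_curve(tr3, genes, fraction_grid = grid)
  frac <- list(G1 = d3[1:100], G2 = d3[101:200])
  for (dd in c(10, 20, 30)) {
    per_gene <- vapply(frac, function(v) mean(v >= dd), 0)
    want <- vapply(grid, function(f) mean(per_gene >= f), 0)
    expect_equal(cv3$prop_genes[cv3$depth == dd], want)
    expect_true(all(diff(cv3$prop_genes[cv3$depth == dd]) <= 0))
  }
  # a gene with no target bases is excluded with a message
  genes_bad <- rbind(genes, data.frame(chrom = "chr9", start = 0L,
                                       end = 10L, gene = "G3"))
  expect_message(gene_coverage_curve(tr3, genes_bad), "excluded")
})

test_that("perfectly decreasing metric pairs give Spearman rho of -1", {
  qc <- data.frame(qpcr = 1:10, din = rep(3, 10) + (1:10) * 0.1,
                   fragment_length = 1000 + 1:10,
                   pct_ge_20x = seq(99, 45, length.out = 10))
  r <- qc_correlation(qc)
  expect_equal(r$rho[r$metric == "qpcr"], -1)
  expect_true(r$r_squared[r$metric == "qpcr"] > 0.9)
})

test_that("an independent random metric shows weak correlation", {
  set.seed(64)
  weak <- 0L
  for (i in 1:50) {
    qc <- data.frame(qpcr = runif(100, 1, 15), din = runif(100, 1, 6),
                     fragment_length = runif(100, 300, 3000),
                     pct_ge_20x = runif(100, 40, 100))
    r <- qc_correlation(qc)
    if (abs(r$rho[r$metric == "qpcr"]) < 0.3) weak <- weak + 1L
  }
  expect_gte(weak, 48L)  # ~99% of seeds under independence
})

test_that("constant metrics report missing correlations", {
  qc <- data.frame(qpcr = rep(5, 6), din = 1:6, fragment_length = 1:6 * 100,
                   pct_ge_20x = seq(50, 100, 10))
  r <- qc_correlation(qc)
  expect_true(is.na(r$rho[r$metric == "qpcr"]))
})

test_that("lab advisories encode the protocol decision rules", {
  qc <- data.frame(sample_id = c("a", "b", "c", "d"),
                   qpcr = c(10, 10.1, 2, 14),
                   din = c(2, 2, 3.5, 2.9),
                   fragment_length = c(1200, 900, 800, 1000))
  adv <- lab_advisories(qc)
  expect_equal(adv$predicted_success, c(TRUE, FALSE, TRUE, FALSE))
  # frag iff fragment > 1000 OR din > 3 (both boundaries exclusive)
  expect_equal(adv$protocol, c("frag", "nofrag", "frag", "nofrag"))
})

test_that("cohorts are pooled by similar amplification potential", {
  set.seed(65)
  qc <- data.frame(sample_id = sprintf("s%02d", 1:16),
                   qpcr = sample(seq(1, 14, length.out = 16)),
                   din = rep(3, 16), fragment_length = rep(900, 16))
  adv <- lab_advisories(qc)
  expect_equal(sort(unique(adv$pool_id)), c(1L, 2L))
  expect_equal(sum(adv$pool_id == 1), 8L)
  # every sample in pool 1 amplifies better than any in pool 2
  expect_lt(max(adv$qpcr[adv$pool_id == 1]),
            min(adv$qpcr[adv$pool_id == 2]))
})
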