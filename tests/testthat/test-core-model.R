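test_that("read_vcf parses, splits multiallelics and drops foreign contigs", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    "chr1\t50\t.\tC\tT\t99\tPASS\t.\tGT\t0/1",
    "chr1\t100\t.\tA\tG,T\t50\tPASS\t.\tGT\t1/2",
    "chrUn\t7\t.\tA\tC\t10\tPASS\t.\tGT\t0/1"), vcf)
  expect_warning(
    cs <- read_vcf(vcf, "s1", "blood", "gatk", contigs = "chr1"),
    "dropped")
  expect_s3_class(cs, "call_set")
  expect_equal(nrow(cs$calls), 3L)  # biallelic + split multiallelic
  multi <- cs$calls[cs$calls$pos == 100, ]
  expect_equal(sort(multi$alt), c("G", "T"))
  expect_true(all(multi$chrom == "chr1"))
})

test_that("read_vcf matches an independent line-by-line text parse", {
  set.seed(41)
  df <- random_calls(20)
  cs0 <- make_cs(df, provenance = "gatk")
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(cs0, vcf)
  back <- read_vcf(vcf, "s1", "blood", "gatk")
  # naive oracle: parse non-header lines by hand
  lines <- grep("^#", readLines(vcf), invert = TRUE, value = TRUE)
  parts <- strsplit(lines, "\t")
  oracle_keys <- sort(vapply(parts, function(p)
    paste(p[1], p[2], p[4], p[5], sep = ":"), ""))
  expect_equal(sort(variant_key(back$calls)), oracle_keys)
  expect_equal(sort(variant_key(back$calls)), sort(variant_key(cs0$calls)))
})

test_that("contig aliases are applied at parse time", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               "1\t10\t.\tA\tG\t5\tPASS\t."), vcf)
  cs <- read_vcf(vcf, "s1", contig_alias = c("1" = "chr1"))
  expect_equal(cs$calls$chrom, "chr1")
})

test_that("SNVs pass through normalization unchanged", {
  n <- normalize_variant("chr1", 100L, "A", "G")
  expect_equal(n, list(chrom = "chr1", pos = 100L, ref = "A", alt = "G"))
})

test_that("normalization left-aligns and trims indels like the exhaustive oracle", {
  # worked example: deleting one A of a homopolymer run shifts left
  S <- "GGTAAAACGG"  # 1-based: run of A at 4-7
  lk <- sequence_lookup(c(chr1 = S))
  n <- normalize_variant("chr1", 6L, "AA", "A", lk)
  o <- normalize_oracle(S, 6L, "AA", "A")
  expect_equal(n$pos, o$pos)
  expect_equal(n$ref, o$ref)
  expect_equal(n$alt, o$alt)
  expect_lt(n$pos, 6L)  # moved to the start of the run

  set.seed(97)
  for (i in 1:100) {
    S <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    lk <- sequence_lookup(c(chr1 = S))
    pos <- sample(5:20, 1)
    lr <- sample(1:4, 1)
    ref <- substr(S, pos, pos + lr - 1L)
    alt <- if (runif(1) < 0.5) substr(ref, 1, 1) else
      paste0(ref, sample(c("A", "T"), 1))
    if (ref == alt) next
    n <- normalize_variant("chr1", pos, ref, alt, lk)
    o <- normalize_oracle(S, pos, ref, alt)
    expect_equal(unname(unlist(n[c("pos", "ref", "alt")])),
                 unname(unlist(o[c("pos", "ref", "alt")])),
                 info = sprintf("S=%s pos=%d %s>%s", S, pos, ref, alt))
    # idempotence
    n2 <- normalize_variant("chr1", n$pos, n$ref, n$alt, lk)
    expect_equal(n2, n)
  }
})

test_that("normalization flags a reference mismatch", {
  lk <- sequence_lookup(c(chr1 = "AAAA"))
  expect_error(normalize_variant("chr1", 2L, "C", "A", lk), "disagrees")
})

test_that("two representations of one indel compare equal after normalization", {
  S <- "GTTTTTTACG"
  lk <- sequence_lookup(c(chr1 = S))
  a <- normalize_variant("chr1", 3L, "TT", "T", lk)
  b <- normalize_variant("chr1", 6L, "TT", "T", lk)
  expect_equal(a, b)
})

test_that("read_bed merges overlaps and rejects malformed intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t15\t30"), bed)
  rs <- read_bed(bed, "t")
  expect_equal(rs$intervals,
               data.frame(chrom = "chr1", start = 10L, end = 30L))
  writeLines("chr1\t20\t20", bed)
  expect_error(read_bed(bed), "malformed")
})

test_that("single BED interval spans the expected bases", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)
  expect_equal(total_bases(read_bed(bed)), 10L)
})

test_that("region_set and call_set round-trip through their file formats", {
  set.seed(5)
  rs <- random_rs(50)
  f <- tempfile(fileext = ".bed")
  write_bed(rs, f)
  expect_equal(read_bed(f, rs$name)$intervals, rs$intervals)

  cs <- make_cs(random_calls(30), provenance = "gatk")
  v <- tempfile(fileext = ".vcf")
  write_vcf(cs, v)
  back <- read_vcf(v, "s1", "blood", "gatk")
  expect_equal(sort(variant_key(back$calls)), sort(variant_key(cs$calls)))
})

test_that("read_coverage fills absent bases with zero and expands runs", {
  tgt <- region_set("chr1", 0L, 100L, "target")
  f <- tempfile()
  file.create(f)
  expect_equal(read_coverage(f, tgt)$depth, rep(0L, 100))

  # bedGraph run covering the whole target at depth 7
  writeLines("chr1\t0\t100\t7", f)
  expect_equal(read_coverage(f, tgt)$depth, rep(7L, 100))

  # mixed runs: compare to a naive per-position expansion
  writeLines(c("chr1\t0\t40\t3", "chr1\t60\t90\t12"), f)
  oracle <- integer(100)
  oracle[1:40] <- 3L
  oracle[61:90] <- 12L
  expect_equal(read_coverage(f, tgt)$depth, oracle)

  # positions outside the target are ignored
  writeLines(c("chr1\t5\t9", "chr1\t500\t99"), f)
  expect_message(tr <- read_coverage(f, tgt), "outside")
  expect_equal(tr$depth[5], 9L)
})

test_that("coverage tracks round-trip through the per-base TSV", {
  set.seed(11)
  tgt <- region_set(c("chr1", "chr2"), c(0L, 50L), c(80L, 120L), "t")
  tr <- coverage_track("s1", tgt, sample.int(50, total_bases(tgt),
                                             replace = TRUE))
  f <- tempfile()
  write_coverage(tr, f)
  expect_equal(read_coverage(f, tgt)$depth, tr$depth)
})

test_that("qc table io validates ranges", {
  qc <- data.frame(sample_id = "s1", qpcr = 5.2, din = 3.1,
                   fragment_length = 1614, mapped_reads = 5e7,
                   pct_ge_20x = 95)
  f <- tempfile()
  write_qc_table(qc, f)
  expect_equal(read_qc_table(f), qc)
  qc$din <- 12
  write_qc_table(qc, f)
  expect_error(read_qc_table(f), "din")
})

test_that("call_set enforces variant-key uniqueness and allele sanity", {
  expect_error(make_cs(calls_from_keys("chr1", c(10L, 10L))), "duplicate")
  expect_error(make_cs(data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                  alt = "A")), "ref == alt")
  expect_error(make_cs(data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                  alt = "Z")), "A/C/G/T")
})
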