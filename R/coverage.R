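#' Per-base coverage tracks
#'
#' A `coverage_track` stores one non-negative integer depth per base of a
#' target `region_set`, in the canonical base order of the normalized
#' target (intervals sorted by chrom then start).
#'
#' @param sample_id Sample identifier.
#' @param target A `region_set`.
#' @param depth Integer vector, one value per target base.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(sample_id, target, depth) {
  stopifnot(is_region_set(target))
  depth <- as.integer(depth)
  if (length(depth) != total_bases(target))
    stop("coverage_track: depth length must equal target bases (",
         total_bases(target), ")")
  if (any(is.na(depth)) || any(depth < 0L))
    stop("coverage_track: depths must be non-negative integers")
  out <- list(sample_id = sample_id, target = target, depth = depth)
  class(out) <- "coverage_track"
  out
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track %s: %d bases, mean depth %.1f>\n",
              x$sample_id, length(x$depth), mean(x$depth)))
  invisible(x)
}

is_coverage_track <- function(x) inherits(x, "coverage_track")

#' Read a per-base coverage table or bedGraph into a coverage_track
#'
#' Three tab-separated columns (chrom, pos, depth; pos 1-based) are read as
#' per-base values; four columns (chrom, start, end, depth) as bedGraph runs
#' in 0-based half-open coordinates. Target bases absent from the file get
#' depth 0; positions outside the target are ignored with a message.
#'
#' @param path Path to the table (no header).
#' @param target A `region_set`.
#' @param sample_id Sample identifier for the returned track.
#' @return A `coverage_track`.
#' @export
read_coverage <- function(path, target, sample_id = basename(path)) {
  stopifnot(is_region_set(target))
  pos_tab <- region_positions(target)
  depth <- integer(nrow(pos_tab))
  info <- file.info(path)
  if (is.na(info$size)) stop("read_coverage: no such file: ", path)
  if (info$size > 0) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) == 4L) {  # bedGraph: expand runs to per-base rows
      w <- tab[[3]] - tab[[2]]
      tab <- data.frame(
        V1 = rep(tab[[1]], w),
        V2 = unlist(lapply(seq_len(nrow(tab)),
                           function(i) seq(tab[[2]][i] + 1L, tab[[3]][i]))),
        V3 = rep(tab[[4]], w), stringsAsFactors = FALSE)
    } else if (ncol(tab) != 3L) {
      stop("read_coverage: expected 3 (chrom,pos,depth) or 4 (bedGraph) columns")
    }
    idx <- match(paste(tab[[1]], tab[[2]]), paste(pos_tab$chrom, pos_tab$pos))
    outside <- sum(is.na(idx))
    if (outside > 0)
      message("read_coverage: ignored ", outside,
              " position(s) outside the target")
    keep <- !is.na(idx)
    depth[idx[keep]] <- as.integer(tab[[3]][keep])
  }
  coverage_track(sample_id, target, depth)
}

#' Write a coverage_track as a (chrom, pos, depth) TSV
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_coverage <- function(track, path) {
  stopifnot(is_coverage_track(track))
  pos_tab <- region_positions(track$target)
  utils::write.table(data.frame(pos_tab$chrom, pos_tab$pos, track$depth),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' QC thresholds used across the toolkit
#'
#' Defaults encode the operating rules of the validated FFPE exome protocol:
#' sequencing succeeds when 90\% of target bases reach 20X; a base is
#' jointly low-covered when >= 25\% of samples have zero depth, the maximum
#' is below 20X, the depth sum is below 100, or the median is below 20X;
#' qPCR above 10 predicts failure; fragment length above 1000 bp or DIN
#' above 3 selects the enzymatic-fragmentation library protocol; FFPE
#' libraries are pooled in batches of 8.
#'
#' @param success_pct20x Percent of target bases at >= 20X required for a
#'   successful sample.
#' @param low_cov_sample_frac_zero Fraction of samples with zero depth that
#'   flags a base (inclusive).
#' @param low_cov_max Flag a base when the across-sample maximum depth is
#'   strictly below this.
#' @param low_cov_sum Flag a base when the across-sample depth sum is
#'   strictly below this.
#' @param low_cov_median Flag a base when the across-sample median depth is
#'   strictly below this.
#' @param qpcr_fail qPCR value above which sequencing is predicted to fail.
#' @param frag_protocol_bp Fragment length above which the fragmentation
#'   protocol is chosen.
#' @param din_protocol DIN above which the fragmentation protocol is chosen.
#' @param pool_size Samples per sequencing pool.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(success_pct20x = 90,
                          low_cov_sample_frac_zero = 0.25,
                          low_cov_max = 20, low_cov_sum = 100,
                          low_cov_median = 20, qpcr_fail = 10,
                          frag_protocol_bp = 1000, din_protocol = 3,
                          pool_size = 8) {
  out <- list(success_pct20x = success_pct20x,
              low_cov_sample_frac_zero = low_cov_sample_frac_zero,
              low_cov_max = low_cov_max, low_cov_sum = low_cov_sum,
              low_cov_median = low_cov_median, qpcr_fail = qpcr_fail,
              frag_protocol_bp = frag_protocol_bp,
              din_protocol = din_protocol, pool_size = pool_size)
  if (any(unlist(out) <= 0)) stop("qc_thresholds: all thresholds positive")
  class(out) <- "qc_thresholds"
  out
}

#' Per-sample coverage metrics
#'
#' Computes mean depth, the percent of target bases at or above each depth
#' cutoff, the percent with zero depth, and the fold-80 base penalty:
#' mean depth divided by the depth at the 20th percentile of bases
#' (nearest-rank on the sorted depth vector), i.e. the extra sequencing
#' factor needed to lift 80\% of bases to the mean. 1 means perfectly
#' uniform; it is reported missing when the 20th-percentile depth is 0.
#'
#' @param track A `coverage_track`.
#' @param thresholds Integer depth cutoffs for the `pct_ge` table.
#' @return A list of class `coverage_metrics` with elements `sample_id`,
#'   `mean_depth`, `pct_ge` (named numeric), `pct_zero`, `fold80`.
#' @export
sample_metrics <- function(track, thresholds = c(10, 20, 30)) {
  stopifnot(is_coverage_track(track), length(track$depth) > 0)
  d <- track$depth
  n <- length(d)
  sorted <- sort(d)
  d20 <- sorted[ceiling(0.2 * n)]
  pct_ge <- vapply(thresholds, function(t) 100 * mean(d >= t), 0)
  names(pct_ge) <- as.character(thresholds)
  out <- list(sample_id = track$sample_id,
              mean_depth = mean(d),
              pct_ge = pct_ge,
              pct_zero = 100 * mean(d == 0L),
              fold80 = if (d20 == 0L) NA_real_ else mean(d) / d20)
  class(out) <- "coverage_metrics"
  out
}

#' Sequencing-success rule
#'
#' A sample is successfully sequenced when at least `success_pct20x`
#' percent (default 90) of its target bases are covered to at least 20X;
#' the boundary is inclusive.
#'
#' @param metrics A `coverage_metrics` object.
#' @param qc A `qc_thresholds` object.
#' @return Logical scalar.
#' @export
is_successful <- function(metrics, qc = qc_thresholds()) {
  if (!"20" %in% names(metrics$pct_ge))
    stop("is_successful: metrics lack a 20X entry")
  metrics$pct_ge[["20"]] >= qc$success_pct20x
}

#' Regions of joint low coverage across a cohort
#'
#' A target base is flagged when ANY of four criteria holds across the
#' cohort's tracks: the fraction of samples with zero depth reaches
#' `low_cov_sample_frac_zero` (inclusive); the maximum depth is below
#' `low_cov_max`; the depth sum is below `low_cov_sum`; or the median depth
#' is below `low_cov_median`. Flagged bases are merged into a region set.
#'
#' @param tracks List of `coverage_track`s sharing one target.
#' @param qc A `qc_thresholds` object.
#' @return A `region_set` named "joint_low_coverage".
#' @export
joint_low_coverage <- function(tracks, qc = qc_thresholds()) {
  stopifnot(length(tracks) >= 1)
  target <- tracks[[1]]$target
  for (tr in tracks)
    if (!identical(tr$target$intervals, target$intervals))
      stop("joint_low_coverage: tracks must share one target")
  depths <- lapply(tracks, `[[`, "depth")
  n <- length(depths)
  frac_zero <- Reduce(`+`, lapply(depths, function(d) d == 0L)) / n
  maxd <- do.call(pmax, depths)
  sumd <- Reduce(`+`, depths)
  D <- do.call(cbind, depths)
  medd <- apply(D, 1L, stats::median)
  flagged <- frac_zero >= qc$low_cov_sample_frac_zero |
    maxd < qc$low_cov_max | sumd < qc$low_cov_sum | medd < qc$low_cov_median
  positions_to_regions(region_positions(target)[flagged, , drop = FALSE],
                       "joint_low_coverage")
}

# internal: collapse a (chrom, pos) frame of 1-based bases into a region_set
positions_to_regions <- function(pos_tab, name) {
  if (nrow(pos_tab) == 0L) return(region_set(name = name))
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(pos_tab$chrom,
                           IRanges::IRanges(pos_tab$pos, pos_tab$pos)))
  gr_to_rs(gr, name)
}

#' Bases covered to a depth in both of two matched tracks
#'
#' Used to restrict matched blood/FFPE comparisons to the intersect of
#' regions covered to 20X in both samples.
#'
#' @param track_a,track_b `coverage_track`s over the same target.
#' @param depth_threshold Minimum depth required in both tracks.
#' @return A `region_set` of maximal intervals meeting the threshold.
#' @export
coverage_intersect <- function(track_a, track_b, depth_threshold = 20) {
  if (!identical(track_a$target$intervals, track_b$target$intervals))
    stop("coverage_intersect: tracks must share one target")
  ok <- track_a$depth >= depth_threshold & track_b$depth >= depth_threshold
  positions_to_regions(
    region_positions(track_a$target)[ok, , drop = FALSE],
    sprintf("joint_%dX", as.integer(depth_threshold)))
}

#' Gene-level sliding-threshold coverage curve
#'
#' For each depth cutoff and each fraction f on the grid, reports the
#' fraction of genes for which at least f of the gene's target bases reach
#' the cutoff (f = 0.5 means half the gene covered). The curve is monotone
#' non-increasing in both the depth cutoff and the fraction.
#'
#' @param track A `coverage_track`.
#' @param genes Data frame with columns chrom, start, end, gene (BED-style
#'   half-open intervals); a gene may span several rows.
#' @param depth_thresholds Depth cutoffs (default 10, 20, 30).
#' @param fraction_grid Fractions in \[0, 1\].
#' @return Data frame with columns depth, fraction, prop_genes.
#' @export
gene_coverage_curve <- function(track, genes,
                                depth_thresholds = c(10, 20, 30),
                                fraction_grid = seq(0, 1, by = 0.05)) {
  stopifnot(is_coverage_track(track))
  pos_tab <- region_positions(track$target)
  key <- paste(pos_tab$chrom, pos_tab$pos)
  per_gene <- split(genes, genes$gene)
  frac_ge <- lapply(per_gene, function(g) {
    gp <- region_positions(region_set(g$chrom, g$start, g$end, "g"))
    idx <- match(paste(gp$chrom, gp$pos), key)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)  # gene outside target: excluded
    vapply(depth_thresholds,
           function(d) mean(track$depth[idx] >= d), 0)
  })
  dropped <- sum(vapply(frac_ge, is.null, TRUE))
  if (dropped > 0)
    message("gene_coverage_curve: excluded ", dropped,
            " gene(s) with no target bases")
  frac_ge <- frac_ge[!vapply(frac_ge, is.null, TRUE)]
  if (length(frac_ge) == 0L) stop("gene_coverage_curve: no usable genes")
  M <- do.call(rbind, frac_ge)  # genes x depth cutoffs
  grid <- expand.grid(depth = depth_thresholds, fraction = fraction_grid)
  grid$prop_genes <- mapply(function(d, f) {
    mean(M[, match(d, depth_thresholds)] >= f)
  }, grid$depth, grid$fraction)
  grid[order(grid$depth, grid$fraction), ]
}

#' Correlation of pre-library QC metrics with sequencing success
#'
#' For each of qPCR value, DIN and fragment length, computes the Spearman
#' correlation (and p-value) with the percent of target bases at >= 20X,
#' plus a logistic fit of the success proportion on the metric
#' (quasibinomial GLM) with goodness of fit reported as the squared Pearson
#' correlation between fitted and observed proportions.
#'
#' @param qc Data frame with columns qpcr, din, fragment_length and
#'   pct_ge_20x (complete, n >= 4).
#' @return Data frame with one row per metric: metric, rho, p_value,
#'   intercept, slope, r_squared. Constant metrics yield NA rho.
#' @export
qc_correlation <- function(qc) {
  need <- c("qpcr", "din", "fragment_length", "pct_ge_20x")
  stopifnot(all(need %in% names(qc)))
  if (nrow(qc) < 4) stop("qc_correlation: need at least 4 samples")
  if (any(is.na(qc[need]))) stop("qc_correlation: missing metric values")
  p <- qc$pct_ge_20x / 100
  rows <- lapply(c("qpcr", "din", "fragment_length"), function(m) {
    x <- qc[[m]]
    if (stats::sd(x) == 0) {
      return(data.frame(metric = m, rho = NA_real_, p_value = NA_real_,
                        intercept = NA_real_, slope = NA_real_,
                        r_squared = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, qc$pct_ge_20x, method = "spearman", exact = FALSE))
    fit <- suppressWarnings(
      stats::glm(p ~ x, family = stats::quasibinomial()))
    data.frame(metric = m, rho = unname(ct$estimate),
               p_value = ct$p.value,
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               r_squared = stats::cor(stats::fitted(fit), p)^2)
  })
  do.call(rbind, rows)
}

#' Wet-lab advisory calls from pre-library QC
#'
#' Encodes the protocol's decision rules: sequencing is predicted to fail
#' when qPCR exceeds `qpcr_fail` (default 10); DNA with average fragment
#' length above 1000 bp and/or DIN above 3 goes to the
#' enzymatic-fragmentation library kit ("frag"), otherwise to the no-
#' fragmentation kit ("nofrag"); and libraries are pooled with samples of
#' similar amplification potential by sorting on qPCR and chunking into
#' pools of `pool_size`.
#'
#' @param qc Data frame with columns sample_id, qpcr, din, fragment_length.
#' @param thresholds A `qc_thresholds` object.
#' @return The input with added columns predicted_success, protocol,
#'   pool_id.
#' @export
lab_advisories <- function(qc, thresholds = qc_thresholds()) {
  stopifnot(all(c("sample_id", "qpcr", "din", "fragment_length") %in%
                  names(qc)))
  qc$predicted_success <- qc$qpcr <= thresholds$qpcr_fail
  qc$protocol <- ifelse(qc$fragment_length > thresholds$frag_protocol_bp |
                          qc$din > thresholds$din_protocol,
                        "frag", "nofrag")
  ord <- order(qc$qpcr)
  pool <- integer(nrow(qc))
  pool[ord] <- ceiling(seq_along(ord) / thresholds$pool_size)
  qc$pool_id <- pool
  qc
}
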