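#' Clustering configuration for problematic-region discovery
#'
#' @param window_bp Maximum gap (bp) joining two discordant positions into
#'   one cluster (default 100, the sliding-window width).
#' @param min_variants_per_region Minimum pooled member positions a cluster
#'   needs to be kept (default 2: a lone discordant call is noise, a
#'   cluster is a region enriched for them).
#' @param min_samples Minimum distinct samples that must contribute a
#'   position for a region to enter the blacklist (default 1).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(window_bp = 100, min_variants_per_region = 2,
                           min_samples = 1) {
  if (window_bp <= 0) stop("cluster_config: window_bp must be positive")
  if (min_variants_per_region < 1 || min_samples < 1)
    stop("cluster_config: minimum counts must be >= 1")
  out <- list(window_bp = as.integer(window_bp),
              min_variants_per_region = as.integer(min_variants_per_region),
              min_samples = as.integer(min_samples))
  class(out) <- "cluster_config"
  out
}

#' Cluster genomic positions by single-linkage within a sliding window
#'
#' Two positions on the same contig belong to one cluster iff a chain of
#' positions links them with successive gaps of at most `window_bp` — the
#' fixed point of iteratively merging variants within a sliding window into
#' larger regions. Each cluster becomes the half-open interval
#' [min_pos - 1, max_pos) (minimum width 1); clusters with fewer than
#' `min_variants_per_region` member positions (duplicates counted) are
#' dropped. The result is independent of input order.
#'
#' @param positions Data frame with columns chrom, pos (1-based; repeats
#'   across samples allowed).
#' @param cfg A `cluster_config`.
#' @return A `region_set` named "discordant_clusters", with a
#'   `cluster_info` attribute (per-cluster member counts).
#' @export
cluster_positions <- function(positions, cfg = cluster_config()) {
  if (is.null(positions) || nrow(positions) == 0L)
    return(structure(region_set(name = "discordant_clusters"),
                     cluster_info = data.frame(chrom = character(),
                                               start = integer(),
                                               end = integer(),
                                               n_members = integer())))
  positions <- positions[order(positions$chrom, positions$pos), ,
                         drop = FALSE]
  per_chrom <- split(positions$pos, positions$chrom)
  info <- do.call(rbind, lapply(names(per_chrom), function(ch) {
    p <- sort(per_chrom[[ch]])
    # single-linkage on a line: a gap > window between successive sorted
    # positions separates clusters; <= window chains them
    new_cluster <- c(TRUE, diff(p) > cfg$window_bp)
    id <- cumsum(new_cluster)
    do.call(rbind, lapply(split(p, id), function(m) {
      data.frame(chrom = ch, start = min(m) - 1L, end = max(m),
                 n_members = length(m), stringsAsFactors = FALSE)
    }))
  }))
  info <- info[info$n_members >= cfg$min_variants_per_region, , drop = FALSE]
  rownames(info) <- NULL
  rs <- if (nrow(info) == 0L) region_set(name = "discordant_clusters")
  else region_set(info$chrom, info$start, info$end,
                  name = "discordant_clusters")
  structure(rs, cluster_info = info)
}

#' Build the internal database of highly problematic regions
#'
#' Pools the anchor positions of every sample's discordant (FP/FN) calls,
#' clusters them with [cluster_positions()], and keeps the clusters
#' supported by at least `min_samples` distinct samples — yielding the
#' blacklist of regions enriched for non-overlapping variants used as a
#' stratification rung.
#'
#' @param per_sample_discordant Named list, one element per sample, each a
#'   data.frame of discordant calls with columns chrom, pos (e.g. the
#'   row-bound `fn`/`fp` frames from [discordant_calls()]).
#' @param cfg A `cluster_config`.
#' @return A `region_set` named "problematic_regions", with a
#'   `cluster_info` attribute (member and sample support per region).
#' @export
build_blacklist <- function(per_sample_discordant,
                            cfg = cluster_config()) {
  pooled <- do.call(rbind, lapply(names(per_sample_discordant), function(s) {
    d <- per_sample_discordant[[s]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(chrom = d$chrom, pos = d$pos, sample = s,
               stringsAsFactors = FALSE)
  }))
  clusters <- cluster_positions(pooled[, c("chrom", "pos")], cfg)
  info <- attr(clusters, "cluster_info")
  if (nrow(info) == 0L)
    return(structure(region_set(name = "problematic_regions"),
                     cluster_info = info))
  # distinct-sample support per cluster, via anchor-base membership
  info$n_samples <- vapply(seq_len(nrow(info)), function(i) {
    one <- region_set(info$chrom[i], info$start[i], info$end[i], "c")
    hit <- region_contains(one, pooled$chrom, pooled$pos)
    length(unique(pooled$sample[hit]))
  }, 1L)
  info <- info[info$n_samples >= cfg$min_samples, , drop = FALSE]
  rownames(info) <- NULL
  rs <- if (nrow(info) == 0L) region_set(name = "problematic_regions")
  else region_set(info$chrom, info$start, info$end,
                  name = "problematic_regions")
  structure(rs, cluster_info = info)
}
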