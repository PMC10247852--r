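#' Variant concordance between a truth and a test call set
#'
#' Both call sets are restricted to `region` (membership by the variant's
#' POS anchor base) and compared by exact normalized chrom/pos/ref/alt key,
#' genotype-blind. True positives are keys in both, false negatives keys
#' only in truth, false positives keys only in test. Sensitivity is
#' TP/(TP+FN) and positive predictive value TP/(TP+FP); a ratio with a zero
#' denominator is reported as NA, never as 0.
#'
#' @param truth,test `call_set`s (e.g. platinum catalogue vs sample, or
#'   blood vs FFPE of a matched pair).
#' @param region Optional `region_set` restriction; `NULL` compares all.
#' @param region_name Label stored on the result.
#' @return A one-row data.frame of class `concordance_result` with columns
#'   truth_label, test_label, region_name, truth_n, test_n, tp, fp, fn,
#'   sensitivity, ppv.
#' @export
compare_callsets <- function(truth, test, region = NULL,
                             region_name = if (is.null(region)) "all"
                             else region$name) {
  stopifnot(is_call_set(truth), is_call_set(test))
  tkeys <- variant_key(truth$calls)
  skeys <- variant_key(test$calls)
  if (!is.null(region)) {
    tkeys <- tkeys[region_contains(region, truth$calls$chrom,
                                   truth$calls$pos)]
    skeys <- skeys[region_contains(region, test$calls$chrom,
                                   test$calls$pos)]
  }
  tp <- length(intersect(tkeys, skeys))
  fn <- length(setdiff(tkeys, skeys))
  fp <- length(setdiff(skeys, tkeys))
  stopifnot(tp + fn == length(tkeys), tp + fp == length(skeys))
  res <- data.frame(
    truth_label = paste0(truth$sample_id, "/", truth$material),
    test_label = paste0(test$sample_id, "/", test$material),
    region_name = region_name,
    truth_n = length(tkeys), test_n = length(skeys),
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    stringsAsFactors = FALSE)
  class(res) <- c("concordance_result", "data.frame")
  res
}

#' The discordant variant keys of a comparison
#'
#' @param truth,test,region As in [compare_callsets()].
#' @return List with elements `fn` (keys only in truth) and `fp` (keys only
#'   in test), each a data.frame with chrom, pos, ref, alt.
#' @export
discordant_calls <- function(truth, test, region = NULL) {
  tc <- truth$calls
  sc <- test$calls
  if (!is.null(region)) {
    tc <- tc[region_contains(region, tc$chrom, tc$pos), , drop = FALSE]
    sc <- sc[region_contains(region, sc$chrom, sc$pos), , drop = FALSE]
  }
  cols <- c("chrom", "pos", "ref", "alt")
  list(fn = tc[!(variant_key(tc) %in% variant_key(sc)), cols, drop = FALSE],
       fp = sc[!(variant_key(sc) %in% variant_key(tc)), cols, drop = FALSE])
}

#' Summarize concordance across matched sample pairs
#'
#' Reports the arithmetic mean and the (min, max) range of each count and
#' ratio over a cohort of per-pair comparisons; undefined (NA) ratios are
#' excluded from their mean.
#'
#' @param results List of `concordance_result`s (or a row-bound data.frame
#'   of them).
#' @return Data frame with one row per field: field, mean, min, max.
#' @export
matched_pair_summary <- function(results) {
  if (is.data.frame(results)) tab <- results
  else tab <- do.call(rbind, results)
  stopifnot(nrow(tab) >= 1)
  fields <- c("truth_n", "test_n", "tp", "fp", "fn", "sensitivity", "ppv")
  out <- do.call(rbind, lapply(fields, function(f) {
    v <- tab[[f]]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(data.frame(field = f, mean = NA_real_, min = NA_real_,
                        max = NA_real_))
    data.frame(field = f, mean = mean(v), min = min(v), max = max(v))
  }))
  out
}

#' A ladder of stratification region sets
#'
#' Orders the region sets along which a comparison is progressively
#' restricted, mirroring the evaluation's x-axis: the raw target, then the
#' 20X matched intersect, then confident regions, then successive
#' exclusions of difficult-context sets (tandem repeats/homopolymers, bad
#' promoters, low mappability, high-stringency, internal problematic
#' regions, other difficult regions). Each rung is either a restriction
#' (intersect with a set) or an exclusion (subtract a set) applied
#' cumulatively to the previous rung.
#'
#' @param target The starting `region_set`.
#' @param restrict Named list of `region_set`s to intersect, in order.
#' @param exclude Named list of `region_set`s to subtract, in order
#'   (applied after the restrictions).
#' @return A list of class `stratification_ladder`: named list of
#'   (label, region_set) rungs, cumulative.
#' @export
stratification_ladder <- function(target, restrict = list(),
                                  exclude = list()) {
  stopifnot(is_region_set(target))
  rungs <- list(target = target)
  cur <- target
  for (nm in names(restrict)) {
    cur <- region_intersect(cur, restrict[[nm]], name = nm)
    rungs[[nm]] <- cur
  }
  for (nm in names(exclude)) {
    cur <- region_subtract(cur, exclude[[nm]], name = paste0("minus_", nm))
    rungs[[paste0("minus_", nm)]] <- cur
  }
  class(rungs) <- "stratification_ladder"
  rungs
}

#' Concordance along a stratification ladder
#'
#' Runs [compare_callsets()] once per rung; because rungs are cumulative
#' restrictions, tp, fp and fn are non-increasing down the ladder.
#'
#' @param truth,test `call_set`s.
#' @param ladder A `stratification_ladder` (or plain named list of
#'   `region_set`s).
#' @return Data frame with one `concordance_result` row per rung plus a
#'   `bases` column.
#' @export
stratified_concordance <- function(truth, test, ladder) {
  out <- do.call(rbind, lapply(names(ladder), function(nm) {
    r <- compare_callsets(truth, test, ladder[[nm]], region_name = nm)
    r$bases <- total_bases(ladder[[nm]])
    r
  }))
  rownames(out) <- NULL
  out
}

#' Three-way Venn partition of call sets
#'
#' Counts the seven membership classes of the union of three call sets'
#' variant keys (e.g. platinum truth vs blood-protocol vs FFPE-protocol
#' runs of one benchmark sample).
#'
#' @param a,b,c `call_set`s.
#' @return Named integer vector with elements a_only, b_only, c_only, ab,
#'   ac, bc, abc; sums to the size of the key union.
#' @export
venn_partition <- function(a, b, c) {
  ka <- variant_key(a$calls)
  kb <- variant_key(b$calls)
  kc <- variant_key(c$calls)
  u <- unique(c(ka, kb, kc))
  ina <- u %in% ka
  inb <- u %in% kb
  inc <- u %in% kc
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}

#' Round half-up to a fixed number of decimals
#'
#' Report-style rounding (0.5 always rounds away from zero), matching how
#' the concordance tables print three- and two-decimal ratios.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
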