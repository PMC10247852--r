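#' Run the full validation pipeline on a simulated matched cohort
#'
#' Executes the four evaluation stages end to end on data from
#' [simulate_cohort()]:
#' \enumerate{
#'   \item Feasibility/QC: per-sample coverage metrics, the 90\%-at-20X
#'     success rule, lab advisories, and QC-metric correlations against
#'     sequencing success.
#'   \item Performance: joint low-coverage regions across the FFPE tracks.
#'   \item Concordance: per-caller sets are merged into 2-of-3 ensemble
#'     call sets per material; each matched pair is compared raw
#'     (blood as truth), discordant calls are pooled and clustered into the
#'     internal problematic-region blacklist, and every pair is re-compared
#'     along the stratification ladder (target, matched 20X intersect,
#'     confident regions, difficult-context exclusions, the internal
#'     blacklist).
#'   \item Clinical value: a general referral (two-tier CDGP/SDGP triage)
#'     per sample and the cohort diagnostic-yield arithmetic.
#' }
#'
#' @param cfg A `sim_config`; its seed fixes every stage.
#' @param thresholds A `qc_thresholds`.
#' @param cluster A `cluster_config` for blacklist construction.
#' @param ens An `ensemble_config`.
#' @param out_dir Optional directory; when given, per-step TSV/BED reports
#'   are written there.
#' @return List with elements qc (table with metrics and advisories),
#'   correlations, low_coverage (region_set), raw (per-pair concordance
#'   rows), raw_summary, blacklist (region_set), stratified (long per-rung
#'   table), stratified_summary (mean tp/fp/fn per rung), reports (case
#'   reports), yield.
#' @export
run_pipeline <- function(cfg = sim_config(), thresholds = qc_thresholds(),
                         cluster = cluster_config(),
                         ens = ensemble_config(), out_dir = NULL) {
  cohort <- simulate_cohort(cfg)
  qc <- cohort$qc

  # --- step 1-2: coverage QC ---
  metrics <- lapply(cohort$coverage, function(cv)
    sample_metrics(cv$ffpe, thresholds = c(10, 20, 30)))
  qc$pct_ge_20x <- vapply(metrics, function(m) m$pct_ge[["20"]], 0)
  qc$mean_depth <- vapply(metrics, `[[`, 0, "mean_depth")
  qc$pct_zero <- vapply(metrics, `[[`, 0, "pct_zero")
  qc$fold80 <- vapply(metrics, `[[`, 0, "fold80")
  qc$successful <- vapply(metrics, is_successful, TRUE, qc = thresholds)
  qc <- lab_advisories(qc, thresholds)
  correlations <- if (nrow(qc) >= 4) qc_correlation(qc) else NULL
  low_cov <- joint_low_coverage(lapply(cohort$coverage, `[[`, "ffpe"),
                                thresholds)

  # --- step 3: ensemble + concordance on successful matched pairs ---
  ensembles <- lapply(cohort$samples, function(s) {
    list(sample_id = s$sample_id,
         blood = consensus_calls(unname(s$blood$callers), ens),
         ffpe = consensus_calls(unname(s$ffpe$callers), ens))
  })
  ok <- qc$successful
  used <- which(ok)
  if (length(used) == 0) used <- seq_along(ensembles)  # degenerate cohorts
  raw <- do.call(rbind, lapply(used, function(i)
    compare_callsets(ensembles[[i]]$blood, ensembles[[i]]$ffpe,
                     cohort$sim$target)))
  raw_summary <- matched_pair_summary(raw)

  discordant <- lapply(used, function(i) {
    d <- discordant_calls(ensembles[[i]]$blood, ensembles[[i]]$ffpe,
                          cohort$sim$target)
    rbind(d$fn, d$fp)
  })
  names(discordant) <- qc$sample_id[used]
  blacklist <- build_blacklist(discordant, cluster)

  ladders <- lapply(used, function(i) {
    stratification_ladder(
      cohort$sim$target,
      restrict = list(
        joint_20x = coverage_intersect(cohort$coverage[[i]]$blood,
                                       cohort$coverage[[i]]$ffpe, 20),
        confident = cohort$sim$confident),
      exclude = c(cohort$sim$exclusions, list(internal = blacklist)))
  })
  stratified <- do.call(rbind, lapply(seq_along(used), function(k) {
    s <- stratified_concordance(ensembles[[used[k]]]$blood,
                                ensembles[[used[k]]]$ffpe, ladders[[k]])
    s$sample_id <- qc$sample_id[used[k]]
    s
  }))
  stratified_summary <- do.call(rbind, lapply(
    split(stratified, factor(stratified$region_name,
                             levels = unique(stratified$region_name))),
    function(g) data.frame(region_name = g$region_name[1],
                           bases = mean(g$bases), tp = mean(g$tp),
                           fp = mean(g$fp), fn = mean(g$fn),
                           sensitivity = mean(g$sensitivity, na.rm = TRUE),
                           ppv = mean(g$ppv, na.rm = TRUE))))
  rownames(stratified_summary) <- NULL

  # --- step 4: triage (panels drawn from the simulated gene universe) ---
  panels <- simulated_panels(cohort$sim)
  reports <- lapply(seq_along(ensembles), function(i) {
    suppressMessages(
      run_referral(referral_request(qc$sample_id[i], "general_scd"),
                   ensembles[[i]]$ffpe, cohort$coverage[[i]]$ffpe,
                   panels = panels, qc = thresholds))
  })
  yield <- cohort_yield(reports)

  out <- list(qc = qc, correlations = correlations, low_coverage = low_cov,
              raw = raw, raw_summary = raw_summary, blacklist = blacklist,
              stratified = stratified,
              stratified_summary = stratified_summary,
              reports = reports, yield = yield, cohort = cohort)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Panels over the simulated gene universe
#'
#' Deterministically carves the toy exome's gene symbols into the tiered
#' panel sizes (84-gene CDGP nested in the 166-gene SDGP, plus a disjoint
#' 27-gene aorta panel) so that panel-based triage can be exercised on
#' simulated call sets.
#'
#' @param sim Output of [simulate_truth()].
#' @return Named list of `gene_panel`s: CDGP, SDGP, aorta.
#' @export
simulated_panels <- function(sim) {
  genes <- sort(unique(sim$genes$gene))
  n <- length(genes)
  if (n >= 193) {
    n_cdgp <- 84L; n_sdgp <- 166L; n_aorta <- 27L
  } else {
    # small toy exomes: keep the 84:166:27 shape, scaled to the universe
    n_sdgp <- max(2L, floor(n * 166 / 193))
    n_cdgp <- max(1L, floor(n_sdgp * 84 / 166))
    n_aorta <- max(1L, n - n_sdgp)
  }
  list(CDGP = gene_panel("CDGP", genes[seq_len(n_cdgp)]),
       SDGP = gene_panel("SDGP", genes[seq_len(n_sdgp)]),
       aorta = gene_panel("aorta",
                          genes[seq(n_sdgp + 1L,
                                    min(n, n_sdgp + n_aorta))]))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$qc, file.path(out_dir, "qc_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$correlations))
    utils::write.table(res$correlations,
                       file.path(out_dir, "qc_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$raw, file.path(out_dir, "concordance_raw.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$stratified,
                     file.path(out_dir, "concordance_stratified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(res$blacklist, file.path(out_dir, "blacklist.bed"))
  write_bed(res$low_coverage, file.path(out_dir, "joint_low_coverage.bed"))
  yield <- res$yield
  utils::write.table(data.frame(metric = names(yield),
                                value = unlist(yield)),
                     file.path(out_dir, "diagnostic_yield.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys `simulation`, `thresholds`,
#' `cluster` and `ensemble` override the corresponding constructor
#' defaults; the file round-trips losslessly through this representation.
#'
#' @param path Path to the YAML file.
#' @return List with sim_config, qc_thresholds, cluster_config,
#'   ensemble_config entries.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(sim = do.call(sim_config, as.list(y$simulation %||% list())),
       thresholds = do.call(qc_thresholds,
                            as.list(y$thresholds %||% list())),
       cluster = do.call(cluster_config, as.list(y$cluster %||% list())),
       ensemble = do.call(ensemble_config,
                          as.list(y$ensemble %||% list())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
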