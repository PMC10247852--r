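#' Gene panels
#'
#' @param name Panel label (e.g. "CDGP", "SDGP", "aorta").
#' @param genes Character vector of gene symbols (forced to uppercase).
#' @return A list of class `gene_panel`.
#' @export
gene_panel <- function(name, genes) {
  genes <- unique(toupper(genes))
  if (length(genes) == 0L) stop("gene_panel: empty panel")
  out <- list(name = name, genes = genes)
  class(out) <- "gene_panel"
  out
}

#' Default tiered panels
#'
#' Ships the three panels of the two-tier triage strategy with their
#' enforced sizes: the 84-gene cardio diagnostic panel (CDGP), the 166-gene
#' sudden-death panel (SDGP, a superset of the CDGP), and a 27-gene aorta
#' panel. Core cardiac and aortic disease genes are real symbols; the
#' remainder are synthetic placeholders (`CDGP_xx`, `SDGP_xx`, `AORTA_xx`)
#' that users replace with curated lists.
#'
#' @return Named list of `gene_panel`s: CDGP, SDGP, aorta.
#' @export
default_panels <- function() {
  core_cardio <- c("MYBPC3", "MYH7", "KCNQ1", "KCNH2", "SCN5A", "CALM1",
                   "CALM2", "CALM3", "RYR2", "TNNT2", "TNNI3", "TNNC1",
                   "LDLR", "PKP2", "DSP", "DSG2", "DSC2", "LMNA", "TPM1",
                   "ACTC1", "CASQ2", "KCNE1", "KCNE2", "KCNJ2")
  cdgp <- c(core_cardio, sprintf("CDGP_%02d", seq_len(84 - length(core_cardio))))
  sdgp <- c(cdgp, sprintf("SDGP_%02d", seq_len(166 - length(cdgp))))
  core_aorta <- c("FBN1", "TGFBR1", "TGFBR2", "TGFB2", "SMAD3", "ACTA2",
                  "MYH11", "COL3A1", "MYLK")
  aorta <- c(core_aorta, sprintf("AORTA_%02d", seq_len(27 - length(core_aorta))))
  list(CDGP = gene_panel("CDGP", cdgp),
       SDGP = gene_panel("SDGP", sdgp),
       aorta = gene_panel("aorta", aorta))
}

#' Read a gene panel from a plain-text list
#'
#' One gene symbol per line; blank lines and `#` comments ignored. The
#' default panels ship as editable lists under
#' `system.file("extdata/panels", package = "ffpewes")` (synthetic
#' placeholder contents at the enforced panel sizes).
#'
#' @param path Path to the list.
#' @param name Panel label (defaults to the file name).
#' @return A `gene_panel`.
#' @export
read_panel <- function(path, name = sub("\\..*$", "", basename(path))) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_panel(name, lines)
}

#' Population allele-frequency filter with pathogenic rescue
#'
#' Two-stage frequency filter: variants at or above the primary cutoff
#' (default 5\% overall population allele frequency) with no
#' pathogenic/likely-pathogenic assertion are removed outright; the second
#' stage retains variants below the secondary cutoff (default 1\%) plus
#' established pathogenic variants regardless of frequency. A missing
#' allele frequency is treated as 0 (rare until proven common).
#'
#' @param calls A `call_set` with `af` and `assertion` annotations.
#' @param af_cutoff_primary,af_cutoff_secondary Frequency cutoffs.
#' @return The filtered `call_set`; idempotent.
#' @export
frequency_filter <- function(calls, af_cutoff_primary = 0.05,
                             af_cutoff_secondary = 0.01) {
  stopifnot(is_call_set(calls))
  k <- calls$calls
  af <- ifelse(is.na(k$af), 0, k$af)
  pathogenic <- !is.na(k$assertion) &
    k$assertion %in% c("pathogenic", "likely_pathogenic")
  k <- k[af < af_cutoff_primary | pathogenic, , drop = FALSE]
  af <- ifelse(is.na(k$af), 0, k$af)
  pathogenic <- !is.na(k$assertion) &
    k$assertion %in% c("pathogenic", "likely_pathogenic")
  k <- k[af < af_cutoff_secondary | pathogenic, , drop = FALSE]
  call_set(calls$sample_id, calls$material, calls$provenance, k)
}

#' Restrict a call set to a gene panel
#'
#' @param calls A `call_set` with `gene` annotations; calls without a gene
#'   annotation are dropped (count reported via message).
#' @param panel A `gene_panel`.
#' @return The restricted `call_set`.
#' @export
panel_subset <- function(calls, panel) {
  stopifnot(is_call_set(calls), inherits(panel, "gene_panel"))
  k <- calls$calls
  unannotated <- sum(is.na(k$gene))
  if (unannotated > 0)
    message("panel_subset: dropped ", unannotated,
            " call(s) without gene annotation")
  k <- k[!is.na(k$gene) & toupper(k$gene) %in% panel$genes, , drop = FALSE]
  call_set(calls$sample_id, calls$material, calls$provenance, k)
}

#' A referral request for one case
#'
#' @param case_id Case identifier.
#' @param category One of "familial_variant" (payload: list with chrom,
#'   pos, ref, alt), "specified_gene" (payload: character vector of gene
#'   symbols), "disease_panel" (payload: panel name), "general_scd" (no
#'   payload; two-tier CDGP-then-SDGP strategy).
#' @param payload See `category`.
#' @return A list of class `referral_request`.
#' @export
referral_request <- function(case_id,
                             category = c("familial_variant",
                                          "specified_gene", "disease_panel",
                                          "general_scd"),
                             payload = NULL) {
  category <- match.arg(category)
  ok <- switch(category,
    familial_variant = is.list(payload) &&
      all(c("chrom", "pos", "ref", "alt") %in% names(payload)),
    specified_gene = is.character(payload) && length(payload) >= 1,
    disease_panel = is.character(payload) && length(payload) == 1,
    general_scd = is.null(payload))
  if (!ok) stop("referral_request: payload does not match category ",
                category)
  out <- list(case_id = case_id, category = category, payload = payload)
  class(out) <- "referral_request"
  out
}

# internal: depth at one genomic position of a track (0 when outside target)
depth_at <- function(track, chrom, pos) {
  pos_tab <- region_positions(track$target)
  i <- which(pos_tab$chrom == chrom & pos_tab$pos == pos)
  if (length(i) == 0L) return(0L)
  track$depth[i[1]]
}

#' Run one referral against a case's ensemble calls
#'
#' Applies the category-specific strategy:
#' \describe{
#'   \item{familial_variant}{Reports the queried variant present/absent
#'     when the local depth at its position reaches `local_depth_min`,
#'     else "uncovered". The whole-exome success rule is deliberately not
#'     applied: a failed exome can still answer a positional query.}
#'   \item{specified_gene}{Frequency filter, then restriction to the
#'     requested gene(s).}
#'   \item{disease_panel}{Frequency filter, then restriction to the named
#'     panel.}
#'   \item{general_scd}{Two tiers: frequency filter then CDGP; the SDGP
#'     tier runs only when tier 1 retains nothing
#'     pathogenic/likely-pathogenic.}
#' }
#' The case's yield category is "failed" when sequencing failed (except for
#' answerable familial queries), "positive" when a pathogenic or
#' likely-pathogenic variant is retained, "vus_only" when only VUS remain,
#' else "negative".
#'
#' @param request A `referral_request`.
#' @param calls The case's ensemble `call_set` (annotated).
#' @param coverage The case's `coverage_track`.
#' @param panels Named list of `gene_panel`s (needs CDGP and SDGP for
#'   general_scd).
#' @param qc A `qc_thresholds` object (whole-exome success rule).
#' @param local_depth_min Minimum local depth to answer a familial query.
#' @return A list of class `case_report` with case_id, category, retained
#'   (calls with a `tier` column), familial_variant_status, pct_ge_20x and
#'   yield_category.
#' @export
run_referral <- function(request, calls, coverage, panels = default_panels(),
                         qc = qc_thresholds(), local_depth_min = 20) {
  stopifnot(inherits(request, "referral_request"), is_call_set(calls),
            is_coverage_track(coverage))
  met <- sample_metrics(coverage, thresholds = c(20))
  success <- is_successful(met, qc)
  retained <- empty_calls()
  retained$tier <- character(0)
  familial_status <- NA_character_
  if (request$category == "familial_variant") {
    p <- request$payload
    d <- depth_at(coverage, p$chrom, p$pos)
    if (d < local_depth_min) {
      familial_status <- "uncovered"
    } else {
      key <- paste(p$chrom, p$pos, toupper(p$ref), toupper(p$alt), sep = ":")
      familial_status <- if (key %in% variant_key(calls$calls)) "present"
      else "absent"
    }
  } else if (request$category == "specified_gene") {
    f <- frequency_filter(calls)
    k <- f$calls[!is.na(f$calls$gene) &
                   toupper(f$calls$gene) %in% toupper(request$payload), ,
                 drop = FALSE]
    if (nrow(k)) k$tier <- "specified_gene"
    retained <- k
  } else if (request$category == "disease_panel") {
    if (!request$payload %in% names(panels))
      stop("run_referral: unknown panel name: ", request$payload)
    k <- panel_subset(frequency_filter(calls),
                      panels[[request$payload]])$calls
    if (nrow(k)) k$tier <- request$payload
    retained <- k
  } else {  # general_scd: two-tier CDGP -> SDGP
    if (!all(c("CDGP", "SDGP") %in% names(panels)))
      stop("run_referral: general_scd needs CDGP and SDGP panels")
    filtered <- frequency_filter(calls)
    t1 <- panel_subset(filtered, panels$CDGP)$calls
    if (nrow(t1)) t1$tier <- "CDGP"
    t1_positive <- any(!is.na(t1$assertion) &
                         t1$assertion %in% c("pathogenic",
                                             "likely_pathogenic"))
    if (t1_positive) {
      retained <- t1
    } else {
      t2 <- panel_subset(filtered, panels$SDGP)$calls
      if (nrow(t2)) t2$tier <- "SDGP"
      # SDGP is a superset; keep one row per key, preferring the CDGP label
      t2 <- t2[!(variant_key(t2) %in% variant_key(t1)), , drop = FALSE]
      retained <- rbind(t1, t2)
    }
  }
  yield <- if (request$category == "familial_variant") {
    if (familial_status == "uncovered" && !success) "failed"
    else if (familial_status == "present") "positive" else "negative"
  } else if (!success) {
    "failed"
  } else if (any(!is.na(retained$assertion) &
                 retained$assertion %in% c("pathogenic",
                                           "likely_pathogenic"))) {
    "positive"
  } else if (any(!is.na(retained$assertion) & retained$assertion == "vus")) {
    "vus_only"
  } else "negative"
  out <- list(case_id = request$case_id, category = request$category,
              retained = retained, familial_variant_status = familial_status,
              pct_ge_20x = met$pct_ge[["20"]], yield_category = yield)
  class(out) <- "case_report"
  out
}

#' Cohort diagnostic-yield arithmetic
#'
#' The strict yield is the percent of successfully analysed cases with a
#' pathogenic finding (printed to one decimal, half-up); the inclusive
#' yield adds cases with phenotype-relevant VUS/likely-pathogenic findings
#' (printed to the nearest integer). Failed cases are excluded from the
#' denominator.
#'
#' @param reports List of `case_report`s, or a character vector of yield
#'   categories ("positive", "vus_only", "negative", "failed").
#' @return List with n_success, n_positive, yield_strict_pct,
#'   n_vus_relevant, yield_inclusive_pct.
#' @export
cohort_yield <- function(reports) {
  cats <- if (is.character(reports)) reports
  else vapply(reports, `[[`, "", "yield_category")
  cats <- cats[cats != "failed"]
  n_success <- length(cats)
  if (n_success == 0L) stop("cohort_yield: no successfully analysed cases")
  n_positive <- sum(cats == "positive")
  n_vus <- sum(cats == "vus_only")
  list(n_success = n_success, n_positive = n_positive,
       yield_strict_pct = round_half_up(100 * n_positive / n_success, 1),
       n_vus_relevant = n_vus,
       yield_inclusive_pct = round_half_up(
         100 * (n_positive + n_vus) / n_success, 0))
}
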