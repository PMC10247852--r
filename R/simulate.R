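#' Simulation configuration
#'
#' Defines the synthetic study conditions: a toy exome, a truth variant
#' catalogue, matched blood/FFPE call sets with planted error rates
#' spatially enriched inside designated problematic regions, per-caller
#' noise on top of each material, and coverage whose yield and uniformity
#' degrade with the sample's qPCR value.
#'
#' Error-rate defaults are calibrated to the validation cohort's matched
#' comparison (FFPE false positives ~ 784/33,330 of calls, false negatives
#' ~ 1,023/33,569 of the blood set) and to the benchmark-sample comparison
#' (blood sensitivity ~ 0.999, PPV ~ 0.989), split into a base rate outside
#' problematic regions and a 60-fold enrichment inside them so that ~90\%
#' of discordant calls fall inside the planted regions. The depth model
#' draws per-base depths from a negative binomial with mean
#' `depth_scale * exp(-depth_decay * qpcr)` and dispersion size
#' `dispersion_scale * exp(-dispersion_decay * qpcr)`; the constants place
#' the per-base P(depth >= 20) = 0.90 crossover exactly at qPCR 10, the
#' protocol's predicted-failure boundary. qPCR, DIN and fragment-length
#' ranges default to the cohort's observed ranges and are negatively
#' coupled through a shared latent quality factor.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   configuration including this seed.
#' @param n_chroms,exons_per_chrom,exon_length,exon_gap,flank_bp Toy exome
#'   geometry (exons flanked by `flank_bp` on each side form the target).
#' @param n_truth_variants Truth catalogue size (uniform over the target).
#' @param titv_ratio Transition/transversion ratio of truth SNVs.
#' @param indel_fraction Fraction of truth variants that are short indels.
#' @param blood_fn_rate,blood_fp_rate,ffpe_fn_rate,ffpe_fp_rate Per-variant
#'   error rates outside problematic regions (FN) and overall FP intensity
#'   per truth variant (FP placement is enrichment-weighted).
#' @param n_problematic_regions,problematic_span_exons Planted problematic
#'   regions: runs of consecutive exons.
#' @param problematic_enrichment Multiplier (>= 1) on error rates inside
#'   problematic regions.
#' @param caller_miss_rates,caller_private_fp_rates Named per-caller drop
#'   probabilities and private false-positive intensities.
#' @param depth_scale,depth_decay,dispersion_scale,dispersion_decay Depth
#'   model constants (see above).
#' @param n_samples Number of matched sample pairs.
#' @param qpcr_range,din_range,fragment_range,qpcr_median,din_median,fragment_median
#'   Pre-library QC metric distributions.
#' @param exons_per_gene Consecutive exons grouped into one gene.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, exons_per_chrom = 500,
                       exon_length = 150, exon_gap = 150, flank_bp = 10,
                       n_truth_variants = 4000,
                       titv_ratio = 2.8, indel_fraction = 0.1,
                       blood_fn_rate = 0.0001, blood_fp_rate = 0.0108,
                       ffpe_fn_rate = 0.0025, ffpe_fp_rate = 0.0235,
                       n_problematic_regions = 40,
                       problematic_span_exons = 3,
                       problematic_enrichment = 60,
                       caller_miss_rates = c(gatk = 0.01, samtools = 0.02,
                                             freebayes = 0.015),
                       caller_private_fp_rates = c(gatk = 0.008,
                                                   samtools = 0.015,
                                                   freebayes = 0.012),
                       depth_scale = 212.27, depth_decay = 0.18,
                       dispersion_scale = 20, dispersion_decay = 0.08,
                       n_samples = 13,
                       qpcr_range = c(0.8, 14.8), qpcr_median = 5.2,
                       din_range = c(1.2, 6.1), din_median = 3.1,
                       fragment_range = c(266, 3296),
                       fragment_median = 1614,
                       exons_per_gene = 5) {
  rates <- c(blood_fn_rate, blood_fp_rate, ffpe_fn_rate, ffpe_fp_rate,
             caller_miss_rates, caller_private_fp_rates, indel_fraction)
  if (any(rates < 0 | rates > 1)) stop("sim_config: rates must be in [0,1]")
  if (problematic_enrichment < 1)
    stop("sim_config: problematic_enrichment must be >= 1")
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

# deterministic seed stream: op-specific offsets off the configured seed
sim_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Simulate the toy exome, stratifications and truth catalogue
#'
#' Builds the exon/target geometry, a confident-region set (~93\% of the
#' target), decorative difficult-context exclusion sets (tandem repeats and
#' homopolymers, bad promoters, low mappability, high-stringency, other),
#' the planted problematic regions where errors are enriched, a gene map,
#' and the truth call set: positions uniform over target bases, SNVs at the
#' configured Ti/Tv ratio, a fraction of short indels, and annotations
#' (gene, population allele frequency from a rare-heavy mixture, occasional
#' pathogenicity assertions).
#'
#' @param cfg A `sim_config`.
#' @return List with elements exons, target, confident, exclusions (named
#'   list of region_sets), problematic, genes (data.frame chrom, start,
#'   end, gene), truth (a `call_set`).
#' @export
simulate_truth <- function(cfg = sim_config()) {
  set.seed(sim_seed(cfg, 0))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  pitch <- cfg$exon_length + cfg$exon_gap
  exon_df <- do.call(rbind, lapply(chroms, function(ch) {
    s <- (seq_len(cfg$exons_per_chrom) - 1L) * pitch + cfg$exon_gap
    data.frame(chrom = ch, start = s, end = s + cfg$exon_length,
               stringsAsFactors = FALSE)
  }))
  exons <- region_set(exon_df$chrom, exon_df$start, exon_df$end, "exons")
  target <- flank_target(exons, cfg$flank_bp)
  target$name <- "target"
  tgt_iv <- target$intervals
  n_iv <- nrow(tgt_iv)

  pick_intervals <- function(k, name) {
    idx <- sort(sample.int(n_iv, min(k, n_iv)))
    region_set(tgt_iv$chrom[idx], tgt_iv$start[idx], tgt_iv$end[idx], name)
  }
  # confident regions: drop ~7% of target intervals
  non_conf <- sort(sample.int(n_iv, round(0.07 * n_iv)))
  confident <- region_set(tgt_iv$chrom[-non_conf], tgt_iv$start[-non_conf],
                          tgt_iv$end[-non_conf], "confident")
  exclusions <- list(
    tandem_repeats = pick_intervals(round(0.043 * n_iv), "tandem_repeats"),
    bad_promoters = pick_intervals(max(1, round(0.004 * n_iv)),
                                   "bad_promoters"),
    low_mappability = pick_intervals(round(0.054 * n_iv),
                                     "low_mappability"),
    ngs_high_stringency = pick_intervals(round(0.045 * n_iv),
                                         "ngs_high_stringency"),
    other_difficult = pick_intervals(round(0.013 * n_iv),
                                     "other_difficult"))
  # planted problematic regions: runs of consecutive exons (count capped so
  # they cannot swallow small toy exomes)
  span <- cfg$problematic_span_exons
  n_prob <- min(cfg$n_problematic_regions,
                max(1L, floor((n_iv - span + 1L) / (2L * span))))
  starts <- sample(seq_len(n_iv - span + 1L), n_prob)
  prob_df <- do.call(rbind, lapply(starts, function(i) {
    run <- tgt_iv[i:(i + span - 1L), ]
    run <- run[run$chrom == run$chrom[1], , drop = FALSE]
    data.frame(chrom = run$chrom[1], start = min(run$start),
               end = max(run$end), stringsAsFactors = FALSE)
  }))
  problematic <- region_set(prob_df$chrom, prob_df$start, prob_df$end,
                            "problematic")
  # gene map: consecutive exons grouped into genes
  gene_id <- ceiling(seq_len(cfg$exons_per_chrom) / cfg$exons_per_gene)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    e <- exon_df[exon_df$chrom == ch, ]
    data.frame(chrom = e$chrom, start = e$start, end = e$end,
               gene = sprintf("GENE_%s_%03d", sub("chr", "", ch), gene_id),
               stringsAsFactors = FALSE)
  }))

  # truth catalogue
  pos_tab <- region_positions(target)
  if (cfg$n_truth_variants > nrow(pos_tab))
    stop("simulate_truth: more truth variants than target bases")
  truth <- call_set("catalogue", "truth", "truth")
  if (cfg$n_truth_variants > 0) {
    idx <- sort(sample.int(nrow(pos_tab), cfg$n_truth_variants))
    vp <- pos_tab[idx, ]
    n <- nrow(vp)
    is_indel <- stats::runif(n) < cfg$indel_fraction
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(seq_len(n), function(i) {
      if (is_indel[i]) return(NA_character_)
      mutate_snv(ref[i], cfg$titv_ratio)
    }, "")
    for (i in which(is_indel)) {
      ins <- paste(sample(c("A", "C", "G", "T"),
                          sample(1:3, 1), replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5) {  # insertion
        alt[i] <- paste0(ref[i], ins)
      } else {                      # deletion
        tmp <- ref[i]
        ref[i] <- paste0(tmp, ins)
        alt[i] <- tmp
      }
    }
    gene_at <- gene_lookup(genes, vp$chrom, vp$pos)
    af <- sample_af_mixture(n)
    assertion <- sample(c("pathogenic", "likely_pathogenic", "vus", NA),
                        n, replace = TRUE,
                        prob = c(0.005, 0.003, 0.02, 0.972))
    truth <- call_set("catalogue", "truth", "truth", data.frame(
      chrom = vp$chrom, pos = vp$pos, ref = ref, alt = alt,
      genotype = sample(c("0/1", "1/1"), n, replace = TRUE,
                        prob = c(0.8, 0.2)),
      qual = round(stats::runif(n, 50, 2000), 1),
      callers = "truth", gene = gene_at, af = af, assertion = assertion,
      stringsAsFactors = FALSE))
  }
  list(exons = exons, target = target, confident = confident,
       exclusions = exclusions, problematic = problematic, genes = genes,
       truth = truth)
}

# transition with odds titv : 1, else one of the two transversions
mutate_snv <- function(ref, titv) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < titv / (titv + 1)) return(transition[[ref]])
  sample(setdiff(c("A", "C", "G", "T"), c(ref, transition[[ref]])), 1)
}

# rare-heavy population AF mixture: 60% rare (<1%), 10% low (1-5%),
# 30% common (5-50%)
sample_af_mixture <- function(n) {
  cls <- sample(1:3, n, replace = TRUE, prob = c(0.6, 0.1, 0.3))
  af <- numeric(n)
  af[cls == 1] <- stats::runif(sum(cls == 1), 0, 0.01)
  af[cls == 2] <- stats::runif(sum(cls == 2), 0.01, 0.05)
  af[cls == 3] <- stats::runif(sum(cls == 3), 0.05, 0.5)
  af
}

# gene symbol at each (chrom, pos); NA outside every gene exon
gene_lookup <- function(genes, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L,
                                                genes$end))
  q <- GenomicRanges::GRanges(as.character(chrom),
                              IRanges::IRanges(as.integer(pos),
                                               as.integer(pos)))
  h <- harmonize(q, gr)
  hit <- GenomicRanges::findOverlaps(h$a, h$b, select = "first")
  out[!is.na(hit)] <- genes$gene[hit[!is.na(hit)]]
  out
}

#' Expected planted error rates under a configuration
#'
#' Analytic per-material expectations given the geometry: the mean FN
#' probability of a truth variant (base rate outside problematic regions,
#' enrichment-multiplied inside, averaged over the realized truth
#' positions) and the overall FP intensity per truth variant.
#'
#' @param sim Output of [simulate_truth()].
#' @param cfg The `sim_config` used.
#' @return List with per-material `fn_rate` and `fp_rate` elements.
#' @export
expected_error_rates <- function(sim, cfg) {
  inside <- region_contains(sim$problematic, sim$truth$calls$chrom,
                            sim$truth$calls$pos)
  mean_fn <- function(base) {
    mean(ifelse(inside, pmin(1, base * cfg$problematic_enrichment), base))
  }
  list(blood = list(fn_rate = mean_fn(cfg$blood_fn_rate),
                    fp_rate = cfg$blood_fp_rate),
       ffpe = list(fn_rate = mean_fn(cfg$ffpe_fn_rate),
                   fp_rate = cfg$ffpe_fp_rate))
}

#' Simulate matched per-sample, per-material, per-caller call sets
#'
#' Each sample's material set is the truth catalogue minus FN draws (per-
#' variant probability, enrichment-multiplied inside problematic regions)
#' plus FP draws at novel enrichment-weighted positions. Each caller then
#' independently drops material calls at its miss rate and adds a small
#' private FP set, so a 2-of-3 consensus recovers the material set with
#' fewer private errors than any single caller.
#'
#' @param sim Output of [simulate_truth()].
#' @param cfg A `sim_config`.
#' @return List of samples; each has `sample_id` and per-material lists
#'   (`blood`, `ffpe`) holding `material` (the underlying `call_set`) and
#'   `callers` (named list of per-caller `call_set`s).
#' @export
simulate_callsets <- function(sim, cfg = sim_config()) {
  set.seed(sim_seed(cfg, 1))
  truth_calls <- sim$truth$calls
  pos_tab <- region_positions(sim$target)
  truth_key <- paste(truth_calls$chrom, truth_calls$pos)
  free <- !(paste(pos_tab$chrom, pos_tab$pos) %in% truth_key)
  free_tab <- pos_tab[free, ]
  w_free <- ifelse(region_contains(sim$problematic, free_tab$chrom,
                                   free_tab$pos),
                   cfg$problematic_enrichment, 1)
  inside_truth <- region_contains(sim$problematic, truth_calls$chrom,
                                  truth_calls$pos)
  rates <- list(blood = c(fn = cfg$blood_fn_rate, fp = cfg$blood_fp_rate),
                ffpe = c(fn = cfg$ffpe_fn_rate, fp = cfg$ffpe_fp_rate))

  material_set <- function(sample_id, material) {
    r <- rates[[material]]
    p_fn <- ifelse(inside_truth,
                   pmin(1, r[["fn"]] * cfg$problematic_enrichment),
                   r[["fn"]])
    kept <- truth_calls[stats::runif(nrow(truth_calls)) >= p_fn, ,
                        drop = FALSE]
    n_fp <- stats::rbinom(1, nrow(truth_calls), r[["fp"]])
    fp <- NULL
    if (n_fp > 0 && nrow(free_tab) > 0) {
      j <- sample.int(nrow(free_tab), n_fp, prob = w_free)
      ref <- sample(c("A", "C", "G", "T"), length(j), replace = TRUE)
      fp <- data.frame(
        chrom = free_tab$chrom[j], pos = free_tab$pos[j], ref = ref,
        alt = vapply(ref, function(r2) mutate_snv(r2, cfg$titv_ratio), ""),
        genotype = "0/1", qual = round(stats::runif(length(j), 30, 500), 1),
        callers = "sim", gene = gene_lookup(sim$genes, free_tab$chrom[j],
                                            free_tab$pos[j]),
        af = NA_real_, assertion = NA_character_, stringsAsFactors = FALSE)
    }
    call_set(sample_id, material, "material", rbind(kept, fp))
  }

  caller_view <- function(mat_cs, caller) {
    k <- mat_cs$calls
    keep <- stats::runif(nrow(k)) >= cfg$caller_miss_rates[[caller]]
    k <- k[keep, , drop = FALSE]
    n_priv <- stats::rbinom(1, nrow(truth_calls),
                            cfg$caller_private_fp_rates[[caller]])
    priv <- NULL
    if (n_priv > 0 && nrow(free_tab) > 0) {
      j <- sample.int(nrow(free_tab), n_priv)
      ref <- sample(c("A", "C", "G", "T"), length(j), replace = TRUE)
      priv <- data.frame(
        chrom = free_tab$chrom[j], pos = free_tab$pos[j], ref = ref,
        alt = vapply(ref, function(r2) mutate_snv(r2, cfg$titv_ratio), ""),
        genotype = "0/1", qual = round(stats::runif(length(j), 20, 200), 1),
        callers = caller, gene = NA_character_, af = NA_real_,
        assertion = NA_character_, stringsAsFactors = FALSE)
      priv <- priv[!(paste(priv$chrom, priv$pos, priv$ref, priv$alt) %in%
                       paste(k$chrom, k$pos, k$ref, k$alt)), , drop = FALSE]
    }
    if (nrow(k)) k$callers <- caller
    call_set(mat_cs$sample_id, mat_cs$material, caller, rbind(k, priv))
  }

  lapply(seq_len(cfg$n_samples), function(i) {
    id <- sprintf("S%02d", i)
    per_material <- lapply(c(blood = "blood", ffpe = "ffpe"),
                           function(mat) {
      m <- material_set(id, mat)
      list(material = m,
           callers = stats::setNames(
             lapply(names(cfg$caller_miss_rates),
                    function(cl) caller_view(m, cl)),
             names(cfg$caller_miss_rates)))
    })
    c(list(sample_id = id), per_material)
  })
}

#' Simulate the pre-library QC table
#'
#' Draws qPCR, DIN and fragment length from truncated distributions over
#' the configured ranges (defaulting to the cohort's observed ranges),
#' negatively coupled through one latent quality factor so that qPCR rises
#' as DIN and fragment length fall; mapped reads follow the depth model.
#'
#' @param cfg A `sim_config`.
#' @param n Number of samples (default `cfg$n_samples`).
#' @return Data frame with sample_id, qpcr, din, fragment_length,
#'   mapped_reads, pct_ge_20x (NA until coverage is simulated).
#' @export
simulate_qc_table <- function(cfg = sim_config(), n = cfg$n_samples) {
  set.seed(sim_seed(cfg, 2))
  if (n == 0) {
    return(data.frame(sample_id = character(), qpcr = numeric(),
                      din = numeric(), fragment_length = numeric(),
                      mapped_reads = numeric(), pct_ge_20x = numeric()))
  }
  z <- stats::rnorm(n)  # latent quality: high z = poor sample
  clamp <- function(x, r) pmin(r[2], pmax(r[1], x))
  qpcr <- clamp(cfg$qpcr_median + 3.2 * z, cfg$qpcr_range)
  din <- clamp(cfg$din_median - 0.9 * z + stats::rnorm(n, 0, 0.4),
               cfg$din_range)
  frag <- clamp(cfg$fragment_median - 600 * z + stats::rnorm(n, 0, 250),
                cfg$fragment_range)
  mu <- cfg$depth_scale * exp(-cfg$depth_decay * qpcr)
  total <- cfg$n_chroms * cfg$exons_per_chrom *
    (cfg$exon_length + 2 * cfg$flank_bp)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             qpcr = round(qpcr, 1), din = round(din, 1),
             fragment_length = round(frag),
             mapped_reads = round(mu * total / 100 *
                                    stats::runif(n, 0.9, 1.1)),
             pct_ge_20x = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate per-base coverage for one sample
#'
#' Per-base depths are independent negative-binomial draws with mean and
#' dispersion given by the configured depth model at the sample's qPCR
#' value: the mean decays and the overdispersion grows as amplification
#' potential worsens, so samples above qPCR 10 have expected \%>=20X below
#' the 90\% success threshold.
#'
#' @param cfg A `sim_config`.
#' @param qpcr The sample's qPCR value.
#' @param target The target `region_set`.
#' @param sample_id Identifier for the returned track.
#' @param seed_offset Extra offset into the seed stream (use the sample
#'   index so tracks are independent but reproducible).
#' @return A `coverage_track`.
#' @export
simulate_coverage <- function(cfg, qpcr, target, sample_id = "sim",
                              seed_offset = 0) {
  set.seed(sim_seed(cfg, 10 + seed_offset))
  mu <- cfg$depth_scale * exp(-cfg$depth_decay * qpcr)
  size <- cfg$dispersion_scale * exp(-cfg$dispersion_decay * qpcr)
  depth <- stats::rnbinom(total_bases(target), mu = mu, size = size)
  coverage_track(sample_id, target, depth)
}

#' Simulate a full matched cohort
#'
#' Convenience wrapper running [simulate_truth()], [simulate_qc_table()],
#' [simulate_callsets()] and per-sample coverage (FFPE tracks driven by the
#' sample's qPCR; matched blood tracks at blood-typical quality, qPCR 1).
#'
#' @param cfg A `sim_config`.
#' @return List with elements cfg, sim (truth geometry), qc, samples (call
#'   sets), coverage (per sample: list(blood, ffpe) `coverage_track`s).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  sim <- simulate_truth(cfg)
  qc <- simulate_qc_table(cfg)
  samples <- simulate_callsets(sim, cfg)
  coverage <- lapply(seq_len(cfg$n_samples), function(i) {
    list(blood = simulate_coverage(cfg, qpcr = 1, sim$target,
                                   sample_id = qc$sample_id[i],
                                   seed_offset = 2L * i),
         ffpe = simulate_coverage(cfg, qpcr = qc$qpcr[i], sim$target,
                                  sample_id = qc$sample_id[i],
                                  seed_offset = 2L * i + 1L))
  })
  names(coverage) <- qc$sample_id
  list(cfg = cfg, sim = sim, qc = qc, samples = samples,
       coverage = coverage)
}
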