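#' Ensemble consensus configuration
#'
#' The validated pipeline calls variants with three independent callers and
#' keeps variants called by at least two of them; `ensemble_config`
#' captures that threshold and the caller precedence order used when
#' merging per-caller attributes.
#'
#' @param min_callers Minimum number of supporting callers (default 2).
#' @param caller_labels Ordered caller labels; earlier labels win when
#'   merging genotypes/annotations.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(min_callers = 2,
                            caller_labels = c("gatk", "samtools",
                                              "freebayes")) {
  if (min_callers < 1 || min_callers > length(caller_labels))
    stop("ensemble_config: min_callers must be in 1..length(caller_labels)")
  out <- list(min_callers = as.integer(min_callers),
              caller_labels = caller_labels)
  class(out) <- "ensemble_config"
  out
}

#' Merge per-caller call sets into one ensemble call set
#'
#' Keeps exactly the variant keys present in at least `min_callers` of the
#' inputs. Each retained call records the union of supporting caller
#' labels; the genotype and annotations come from the first supporting
#' caller in `caller_labels` order (first non-missing wins) and the quality
#' is the maximum across supporters, so the result is independent of input
#' order.
#'
#' @param per_caller List of `call_set`s for one sample/material, one per
#'   caller (provenance = caller label).
#' @param cfg An `ensemble_config`.
#' @return A `call_set` with provenance "ensemble".
#' @export
consensus_calls <- function(per_caller, cfg = ensemble_config()) {
  if (length(per_caller) == 0L) stop("consensus_calls: empty input list")
  stopifnot(all(vapply(per_caller, is_call_set, TRUE)))
  ids <- unique(vapply(per_caller, `[[`, "", "sample_id"))
  mats <- unique(vapply(per_caller, `[[`, "", "material"))
  if (length(ids) != 1L || length(mats) != 1L)
    stop("consensus_calls: call sets must share sample_id and material")
  # order inputs by caller precedence so "first non-missing wins" is stable
  prov <- vapply(per_caller, `[[`, "", "provenance")
  ord <- order(match(prov, cfg$caller_labels))
  per_caller <- per_caller[ord]
  prov <- prov[ord]
  tabs <- lapply(seq_along(per_caller), function(i) {
    k <- per_caller[[i]]$calls
    if (nrow(k)) k$.caller <- prov[i]
    k
  })
  all_calls <- do.call(rbind, tabs)
  if (is.null(all_calls) || nrow(all_calls) == 0L)
    return(call_set(ids, mats, "ensemble"))
  key <- variant_key(all_calls)
  support <- table(key)
  keep_keys <- names(support)[support >= cfg$min_callers]
  kept <- all_calls[key %in% keep_keys, , drop = FALSE]
  merged <- do.call(rbind, lapply(split(kept, variant_key(kept)), function(g) {
    first_val <- function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[1] else v[NA_integer_]
    }
    data.frame(chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1],
               genotype = first_val(g$genotype),
               qual = if (all(is.na(g$qual))) NA_real_ else
                 max(g$qual, na.rm = TRUE),
               callers = paste(sort(unique(g$.caller)), collapse = ";"),
               gene = first_val(g$gene), af = first_val(g$af),
               assertion = first_val(g$assertion),
               stringsAsFactors = FALSE)
  }))
  call_set(ids, mats, "ensemble", merged)
}

#' Combine ensemble call sets into a multisample table
#'
#' The multisample table is the long union of all samples' calls with a
#' `sample_id` column, mirroring a multisample VCF from which per-sample
#' files are later extracted.
#'
#' @param callsets List of ensemble `call_set`s (distinct sample_ids).
#' @return A list of class `multisample_calls` with elements `samples`
#'   (metadata) and `calls`.
#' @export
build_multisample <- function(callsets) {
  stopifnot(length(callsets) >= 1, all(vapply(callsets, is_call_set, TRUE)))
  ids <- vapply(callsets, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("build_multisample: duplicate sample_ids")
  calls <- do.call(rbind, lapply(callsets, function(cs) {
    k <- cs$calls
    if (nrow(k) == 0L) return(NULL)
    k$sample_id <- cs$sample_id
    k
  }))
  if (is.null(calls)) {
    calls <- empty_calls()
    calls$sample_id <- character(0)
  }
  out <- list(samples = data.frame(
    sample_id = ids,
    material = vapply(callsets, `[[`, "", "material"),
    provenance = vapply(callsets, `[[`, "", "provenance"),
    stringsAsFactors = FALSE), calls = calls)
  class(out) <- "multisample_calls"
  out
}

#' Extract one sample's call_set from a multisample table
#'
#' @param table A `multisample_calls` object.
#' @param sample_id Sample to extract.
#' @return The sample's `call_set`, reproduced exactly.
#' @export
extract_sample <- function(table, sample_id) {
  stopifnot(inherits(table, "multisample_calls"))
  i <- match(sample_id, table$samples$sample_id)
  if (is.na(i)) stop("extract_sample: unknown sample_id: ", sample_id)
  calls <- table$calls[table$calls$sample_id == sample_id, , drop = FALSE]
  calls$sample_id <- NULL
  call_set(sample_id, table$samples$material[i],
           table$samples$provenance[i], calls)
}
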