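#' Variant call sets
#'
#' A `call_set` holds one sample's variants from one provenance (a single
#' caller or the ensemble). Each row of `calls` is one normalized
#' chrom/pos/ref/alt key with optional genotype, quality, supporting-caller
#' labels and annotations (gene, population allele frequency, pathogenicity
#' assertion). There is exactly one row per variant key.
#'
#' @param sample_id Sample identifier.
#' @param material One of "blood", "ffpe", "truth".
#' @param provenance Caller label or "ensemble".
#' @param calls Data frame with columns chrom, pos (1-based), ref, alt and
#'   optionally genotype, qual, callers (";"-joined labels), gene, af,
#'   assertion.
#' @return An object of class `call_set`.
#' @export
call_set <- function(sample_id, material = c("blood", "ffpe", "truth"),
                     provenance = "unknown", calls = empty_calls()) {
  material <- match.arg(material)
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  for (col in names(empty_calls()))
    if (is.null(calls[[col]]))
      calls[[col]] <- rep(empty_calls()[[col]][NA_integer_], nrow(calls))
  calls <- calls[names(empty_calls())]
  if (nrow(calls)) {
    calls$chrom <- as.character(calls$chrom)
    calls$pos <- as.integer(calls$pos)
    calls$ref <- toupper(as.character(calls$ref))
    calls$alt <- toupper(as.character(calls$alt))
    if (any(calls$ref == calls$alt)) stop("call_set: ref == alt")
    if (any(!grepl("^[ACGTN]+$", calls$ref)) ||
        any(!grepl("^[ACGTN]+$", calls$alt)))
      stop("call_set: alleles must be A/C/G/T/N")
    bad_af <- !is.na(calls$af) & (calls$af < 0 | calls$af > 1)
    if (any(bad_af)) stop("call_set: af outside [0,1]")
    key <- variant_key(calls)
    if (anyDuplicated(key)) stop("call_set: duplicate variant keys")
    calls <- calls[order(calls$chrom, calls$pos, calls$ref, calls$alt), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  out <- list(sample_id = sample_id, material = material,
              provenance = provenance, calls = calls)
  class(out) <- "call_set"
  out
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), genotype = character(), qual = numeric(),
             callers = character(), gene = character(), af = numeric(),
             assertion = character(), stringsAsFactors = FALSE)
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("<call_set %s [%s/%s]: %d variant(s)>\n",
              x$sample_id, x$material, x$provenance, nrow(x$calls)))
  invisible(x)
}

is_call_set <- function(x) inherits(x, "call_set")

#' Canonical string key for variant identity
#' @param calls Data frame with chrom, pos, ref, alt columns.
#' @return Character vector "chrom:pos:ref:alt".
#' @export
variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Normalize a variant to its left-aligned, parsimonious representation
#'
#' Applies the standard normalization loop: shared trailing bases are
#' trimmed (extending left from the reference when an allele would empty),
#' then shared leading bases beyond the mandatory indel anchor are dropped.
#' SNVs pass through unchanged; the operation is idempotent, so two
#' representations of the same indel compare equal afterwards.
#'
#' @param chrom,pos,ref,alt A single variant (pos is 1-based).
#' @param reference_lookup `NULL`, or a function `(chrom, start, end)` giving
#'   the reference bases of the 0-based half-open window as one string.
#'   Without a lookup, trimming is still performed but left extension (and
#'   hence full left-alignment) is not possible.
#' @return A list with elements chrom, pos, ref, alt.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, reference_lookup = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) || !nzchar(alt)) stop("normalize_variant: empty allele")
  if (ref == alt) stop("normalize_variant: ref == alt")
  if (!is.null(reference_lookup)) {
    seen <- reference_lookup(chrom, pos - 1L, pos - 1L + nchar(ref))
    if (!identical(toupper(seen), ref))
      stop(sprintf("normalize_variant: ref '%s' at %s:%d disagrees with reference '%s'",
                   ref, chrom, pos, seen))
  }
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (substr(ref, lr, lr) != substr(alt, la, la)) break
    if (lr == 1L || la == 1L) {
      # truncating would empty an allele: extend left from the reference
      if (is.null(reference_lookup) || pos <= 1L) break
      base <- toupper(reference_lookup(chrom, pos - 2L, pos - 1L))
      ref <- paste0(base, substr(ref, 1L, lr - 1L))
      alt <- paste0(base, substr(alt, 1L, la - 1L))
      pos <- pos - 1L
    } else {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
    }
  }
  # trim identical leading bases beyond the anchor
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Build a reference lookup from named sequences
#'
#' Convenience for tests and simulations: wraps a named character vector of
#' contig sequences into the `(chrom, start, end)` accessor that
#' [normalize_variant()] expects (0-based half-open window).
#'
#' @param sequences Named character vector, one element per contig.
#' @return A function `(chrom, start, end) -> string`.
#' @export
sequence_lookup <- function(sequences) {
  force(sequences)
  function(chrom, start, end) {
    s <- sequences[[chrom]]
    if (is.null(s)) stop("sequence_lookup: unknown contig ", chrom)
    substr(s, start + 1L, end)
  }
}

#' Read a VCF file into a call_set
#'
#' Parsing is delegated to `vcfR`; multiallelic records are split into one
#' call per alternate allele and every call is normalized (trimmed, and
#' left-aligned when a `reference_lookup` is supplied). Records on contigs
#' not in `contigs` are dropped with a warning.
#'
#' @param path Path to a VCF 4.x file (plain text).
#' @param sample_id,material,provenance Stored on the returned `call_set`.
#' @param contigs Optional character vector of allowed contig names.
#' @param contig_alias Optional named character vector mapping file contig
#'   names to canonical ones (e.g. `c("1" = "chr1")`), applied at parse time.
#' @param reference_lookup Optional reference accessor, see
#'   [normalize_variant()].
#' @return A `call_set`.
#' @export
read_vcf <- function(path, sample_id, material = "blood",
                     provenance = "unknown", contigs = NULL,
                     contig_alias = NULL, reference_lookup = NULL) {
  if (!file.exists(path)) stop("read_vcf: no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("read_vcf: parse error in ", path,
                                         ": ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files drop the dim
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(call_set(sample_id, material, provenance))
  gt <- NULL
  if (ncol(v@gt) >= 2L)
    gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
  chrom <- fix$CHROM
  if (!is.null(contig_alias)) {
    hit <- chrom %in% names(contig_alias)
    chrom[hit] <- unname(contig_alias[chrom[hit]])
  }
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(contigs)) {
    keep <- chrom %in% contigs
    if (any(!keep))
      warning(sprintf("read_vcf: dropped %d record(s) on contigs absent from the contig list",
                      sum(!keep)))
  }
  rows <- lapply(which(keep), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alts <- alts[alts != "." & nzchar(alts)]
    if (length(alts) == 0L) return(NULL)
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    if (is.na(pos)) stop("read_vcf: malformed POS at record ", i)
    do.call(rbind, lapply(alts, function(a) {
      n <- normalize_variant(chrom[i], pos, fix$REF[i], a, reference_lookup)
      data.frame(chrom = n$chrom, pos = n$pos, ref = n$ref, alt = n$alt,
                 genotype = if (is.null(gt)) NA_character_ else
                   as.character(gt[i]),
                 qual = suppressWarnings(as.numeric(fix$QUAL[i])),
                 callers = provenance, gene = NA_character_, af = NA_real_,
                 assertion = NA_character_, stringsAsFactors = FALSE)
    }))
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls)) calls <- empty_calls()
  calls <- calls[!duplicated(variant_key(calls)), , drop = FALSE]
  call_set(sample_id, material, provenance, calls)
}

#' Write a call_set as a minimal plain-text VCF
#'
#' Emits VCFv4.2 with contig header lines and a single-sample GT column.
#' Only variant identity, genotype and quality are written; INFO round-trip
#' is out of scope.
#'
#' @param cs A `call_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(cs, path) {
  stopifnot(is_call_set(cs))
  calls <- cs$calls
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=ffpewes(%s)", cs$provenance),
           sprintf("##contig=<ID=%s>", unique(calls$chrom)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", cs$sample_id, sep = "\t"))
  body <- character(0)
  if (nrow(calls))
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  ifelse(is.na(calls$qual), ".",
                         format(calls$qual, trim = TRUE)),
                  "PASS", ".", "GT",
                  ifelse(is.na(calls$genotype), "./.", calls$genotype),
                  sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read the sample QC table
#'
#' Tab-separated with header: sample_id, qpcr, din, fragment_length,
#' mapped_reads and optionally pct_ge_20x. Field ranges are validated
#' (qPCR >= 0, DIN in 1-10, percent in 0-100).
#'
#' @param path Path to the TSV.
#' @return Data frame, one row per sample.
#' @export
read_qc_table <- function(path) {
  qc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "qpcr", "din", "fragment_length", "mapped_reads")
  miss <- setdiff(need, names(qc))
  if (length(miss)) stop("read_qc_table: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(qc$pct_ge_20x)) qc$pct_ge_20x <- NA_real_
  validate_qc(qc)
  qc
}

validate_qc <- function(qc) {
  if (any(qc$qpcr < 0, na.rm = TRUE)) stop("qc: qpcr must be >= 0")
  if (any(qc$din < 1 | qc$din > 10, na.rm = TRUE))
    stop("qc: din must be in [1,10]")
  if (any(qc$pct_ge_20x < 0 | qc$pct_ge_20x > 100, na.rm = TRUE))
    stop("qc: pct_ge_20x must be in [0,100]")
  invisible(qc)
}

#' Write the sample QC table
#' @param qc Data frame as returned by [read_qc_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_qc_table <- function(qc, path) {
  utils::write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
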