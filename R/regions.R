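#' Genomic region sets
#'
#' A `region_set` is a named collection of half-open genomic intervals
#' (BED convention: 0-based start, exclusive end). On construction the
#' intervals are normalized: sorted by (chrom, start), with overlapping and
#' book-ended intervals merged, so that size accounting and set algebra are
#' independent of how the input was written.
#'
#' @param chrom Character vector of contig names.
#' @param start Integer vector of 0-based inclusive start offsets.
#' @param end Integer vector of 0-based exclusive end offsets.
#' @param name Label for the set (e.g. "target", "tandem_repeats").
#'
#' @return An object of class `region_set` with elements `name` and
#'   `intervals` (a data.frame with columns chrom, start, end).
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), name = "regions") {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(chrom) == 0L) {
    out <- list(name = name,
                intervals = data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       stringsAsFactors = FALSE))
    class(out) <- "region_set"
    return(out)
  }
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)) || any(!nzchar(chrom)))
    stop("region_set: chrom/start/end must be complete and non-empty")
  if (any(start < 0L)) stop("region_set: start must be >= 0")
  if (any(end <= start)) stop("region_set: end must exceed start")
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end)))
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  out <- list(name = name,
              intervals = data.frame(
                chrom = as.character(GenomeInfoDb::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                stringsAsFactors = FALSE))
  class(out) <- "region_set"
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s': %d interval(s), %d bases>\n",
              x$name, nrow(x$intervals), total_bases(x)))
  invisible(x)
}

is_region_set <- function(x) inherits(x, "region_set")

# internal: region_set <-> GRanges (1-based closed IRanges)
rs_to_gr <- function(rs) {
  stopifnot(is_region_set(rs))
  if (nrow(rs$intervals) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(rs$intervals$chrom,
                         IRanges::IRanges(rs$intervals$start + 1L,
                                          rs$intervals$end))
}

gr_to_rs <- function(gr, name) {
  gr <- GenomicRanges::reduce(gr)
  if (length(gr) == 0L) return(region_set(name = name))
  region_set(as.character(GenomeInfoDb::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             name = name)
}

# harmonize seqlevels so GenomicRanges set ops do not warn on disjoint contigs
harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Total bases in a region set
#'
#' @param a A `region_set`.
#' @return Integer number of bases covered.
#' @export
total_bases <- function(a) {
  stopifnot(is_region_set(a))
  sum(a$intervals$end - a$intervals$start)
}

#' Extend every interval symmetrically and re-merge
#'
#' Used to add flanking bases around capture exons (the target design adds
#' 10 bp on each side of every exon); intervals that come to touch or
#' overlap after flanking are merged.
#'
#' @param exons A `region_set`.
#' @param flank_bp Non-negative number of bases added to both sides.
#' @return A normalized `region_set`.
#' @export
flank_target <- function(exons, flank_bp) {
  stopifnot(is_region_set(exons), flank_bp >= 0)
  if (nrow(exons$intervals) == 0L) return(exons)
  region_set(exons$intervals$chrom,
             pmax(0L, exons$intervals$start - as.integer(flank_bp)),
             exons$intervals$end + as.integer(flank_bp),
             name = exons$name)
}

#' Intersection of two region sets
#' @param a,b `region_set` objects.
#' @param name Label for the result.
#' @return A `region_set` of bases present in both.
#' @export
region_intersect <- function(a, b, name = paste0(a$name, "&", b$name)) {
  h <- harmonize(rs_to_gr(a), rs_to_gr(b))
  gr_to_rs(GenomicRanges::intersect(h$a, h$b), name)
}

#' Subtraction of region sets
#' @param a,b `region_set` objects.
#' @param name Label for the result.
#' @return A `region_set` of bases in `a` but not `b`.
#' @export
region_subtract <- function(a, b, name = paste0(a$name, "-", b$name)) {
  h <- harmonize(rs_to_gr(a), rs_to_gr(b))
  gr_to_rs(GenomicRanges::setdiff(h$a, h$b), name)
}

#' Variant membership in a region set
#'
#' A variant belongs to a region iff its anchor base (POS, i.e. 0-based
#' offset pos-1) lies inside the set; the full REF span is not considered.
#' This mirrors how interval tools typically intersect VCF records and keeps
#' region-restricted comparisons deterministic for indels.
#'
#' @param a A `region_set`.
#' @param chrom,pos Vectors of contig names and 1-based positions.
#' @return Logical vector, one element per position.
#' @export
region_contains <- function(a, chrom, pos) {
  stopifnot(is_region_set(a), length(chrom) == length(pos))
  if (length(chrom) == 0L) return(logical(0))
  if (nrow(a$intervals) == 0L) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(as.character(chrom),
                              IRanges::IRanges(as.integer(pos),
                                               as.integer(pos)))
  h <- harmonize(q, rs_to_gr(a))
  GenomicRanges::countOverlaps(h$a, h$b) > 0L
}

#' Read a BED file into a region_set
#'
#' Accepts BED3+ (extra columns ignored), 0-based half-open coordinates.
#'
#' @param path Path to a plain-text BED file.
#' @param name Label for the set (defaults to the file name).
#' @return A normalized `region_set`.
#' @export
read_bed <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("read_bed: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) return(region_set(name = name))
  fields <- strsplit(lines, "\t| +")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop("read_bed: line ", which(nf < 3L)[1], " has fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop("read_bed: malformed interval at line ", bad[1])
  region_set(chrom, start, end, name = name)
}

#' Write a region_set as BED3
#' @param rs A `region_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(rs, path) {
  stopifnot(is_region_set(rs))
  utils::write.table(rs$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: per-base genomic positions (chrom, 1-based pos) of a region set,
# in normalized interval order; index in this frame is the canonical base
# index used by coverage tracks.
region_positions <- function(rs) {
  stopifnot(is_region_set(rs))
  iv <- rs$intervals
  if (nrow(iv) == 0L)
    return(data.frame(chrom = character(), pos = integer()))
  w <- iv$end - iv$start
  data.frame(chrom = rep(iv$chrom, w),
             pos = unlist(lapply(seq_len(nrow(iv)),
                                 function(i) seq(iv$start[i] + 1L, iv$end[i]))),
             stringsAsFactors = FALSE)
}
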