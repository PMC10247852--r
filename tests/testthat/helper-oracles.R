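# Brute-force oracles and fixture builders shared across tests.
# Every oracle is deliberately naive (per-base masks, pairwise scans,
# exhaustive enumeration) and independent of the package's implementation.

CHROM_LEN <- 10000L  # toy contig length for mask oracles

# --- region oracles: per-base boolean masks over fixed-length contigs ---

rs_mask <- function(rs, chroms = c("chr1", "chr2"), len = CHROM_LEN) {
  m <- lapply(chroms, function(ch) logical(len))
  names(m) <- chroms
  iv <- rs$intervals
  for (i in seq_len(nrow(iv))) {
    ch <- iv$chrom[i]
    m[[ch]][(iv$start[i] + 1L):iv$end[i]] <- TRUE
  }
  m
}

mask_to_rs <- function(m, name = "mask") {
  rows <- do.call(rbind, lapply(names(m), function(ch) {
    r <- rle(m[[ch]])
    if (!any(r$values)) return(NULL)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(chrom = ch, start = starts[r$values], end = ends[r$values])
  }))
  if (is.null(rows) || nrow(rows) == 0L) return(region_set(name = name))
  region_set(rows$chrom, rows$start, rows$end, name)
}

random_rs <- function(n, chroms = c("chr1", "chr2"), len = CHROM_LEN,
                      max_width = 200L, name = "rand") {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(len - max_width, n)
  w <- sample.int(max_width, n)
  region_set(ch, s, s + w, name)
}

# --- call-set fixtures ---

calls_from_keys <- function(chrom, pos, ref = NULL, alt = NULL, ...) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, ...,
             stringsAsFactors = FALSE)
}

random_calls <- function(n, chroms = c("chr1", "chr2"), len = CHROM_LEN) {
  pos <- sample.int(len, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE), pos = pos,
                   ref = ref, alt = alt, stringsAsFactors = FALSE)
  df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
}

make_cs <- function(calls, id = "s1", material = "blood",
                    provenance = "test") {
  call_set(id, material, provenance, calls)
}

# synthetic call_set with exactly the requested overlap structure:
# `both` shared keys, `only_a` extra in a, `only_b` extra in b
planted_pair <- function(both, only_a, only_b) {
  n <- both + only_a + only_b
  pos <- seq_len(n) * 10L
  a_idx <- seq_len(both + only_a)
  b_idx <- c(seq_len(both), both + only_a + seq_len(only_b))
  list(a = make_cs(calls_from_keys("chr1", pos[a_idx]), material = "truth"),
       b = make_cs(calls_from_keys("chr1", pos[b_idx]), material = "ffpe"))
}

# --- variant-normalization oracle: exhaustive shift-and-trim ------------
# All representations (p, r, a) equivalent to applying (pos, ref, alt) to
# the context string S are enumerated; the normal form is the minimal
# (nchar(r)+nchar(a)) representation at the leftmost position.
normalize_oracle <- function(S, pos, ref, alt, max_len = 8L) {
  M <- paste0(substr(S, 1, pos - 1), alt,
              substr(S, pos + nchar(ref), nchar(S)))
  reps <- list()
  for (p in seq_len(nchar(S))) {
    for (lr in 1:max_len) {
      if (p + lr - 1L > nchar(S)) break
      for (la in 1:max_len) {
        if (p + la - 1L > nchar(M)) break
        r <- substr(S, p, p + lr - 1L)
        a <- substr(M, p, p + la - 1L)
        if (r == a) next
        cand <- paste0(substr(S, 1, p - 1), a,
                       substr(S, p + lr, nchar(S)))
        if (cand == M && substr(S, 1, p - 1) == substr(M, 1, p - 1))
          reps[[length(reps) + 1L]] <- list(pos = p, ref = r, alt = a)
      }
    }
  }
  sums <- vapply(reps, function(x) nchar(x$ref) + nchar(x$alt), 1L)
  reps <- reps[sums == min(sums)]
  reps[[which.min(vapply(reps, `[[`, 1L, "pos"))]]
}

# --- clustering oracle: pairwise union-find ----------------------------
cluster_oracle <- function(positions, window) {
  if (nrow(positions) == 0L) return(positions[0, ])
  positions <- positions[order(positions$chrom, positions$pos), ]
  id <- seq_len(nrow(positions))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(positions))) for (j in seq_len(nrow(positions))) {
      if (positions$chrom[i] == positions$chrom[j] &&
          abs(positions$pos[i] - positions$pos[j]) <= window &&
          id[i] != id[j]) {
        id[id == max(id[i], id[j])] <- min(id[i], id[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  do.call(rbind, lapply(split(positions, id), function(g)
    data.frame(chrom = g$chrom[1], start = min(g$pos) - 1L,
               end = max(g$pos), n_members = nrow(g))))
}

# --- joint low-coverage oracle: explicit per-base loop ------------------
low_cov_oracle_flags <- function(depth_matrix, qc) {
  n <- nrow(depth_matrix)
  vapply(seq_len(ncol(depth_matrix)), function(j) {
    d <- depth_matrix[, j]
    sum(d == 0) / n >= qc$low_cov_sample_frac_zero ||
      max(d) < qc$low_cov_max || sum(d) < qc$low_cov_sum ||
      stats::median(d) < qc$low_cov_median
  }, TRUE)
}

# uniform-depth track over a fresh target
uniform_track <- function(depth, bases = 100L, id = "u") {
  tgt <- region_set("chr1", 0L, bases, "target")
  coverage_track(id, tgt, rep.int(depth, bases))
}
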