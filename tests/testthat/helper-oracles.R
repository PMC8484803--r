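# Independent oracles used by the property tests.  These deliberately share
# no code with the package: connected components come from an explicit
# union-find over the quadratic overlap graph, and overlap pairs from a
# double loop.

library(data.table)

# closed-interval overlap predicate matrix for one chromosome
.overlaps_mat <- function(start, end) {
  outer(start, end, "<=") & outer(end, start, ">=")
}

# Union-find connected components over the >= 1 bp overlap relation.
# Returns a data.table(row, comp, comp_start, comp_end): per input row its
# component id (arbitrary labels) and the component's merged bounds.
oracle_union_find <- function(iv) {
  iv <- as.data.table(iv)
  parent <- seq_len(nrow(iv))
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (ch in unique(iv$chr)) {
    idx <- which(iv$chr == ch)
    m <- .overlaps_mat(iv$start[idx], iv$end[idx])
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a < b && m[a, b]) {
          ra <- find(idx[a]); rb <- find(idx[b])
          if (ra != rb) parent[rb] <- ra
        }
      }
    }
  }
  comp <- vapply(seq_len(nrow(iv)), find, integer(1))
  out <- data.table(row = seq_len(nrow(iv)), comp = comp,
                    chr = iv$chr, start = iv$start, end = iv$end)
  out[, `:=`(comp_start = min(start), comp_end = max(end)), by = comp]
  out
}

# Quadratic all-pairs overlap oracle; ids are row indices.
oracle_all_pairs <- function(a, b, match_sample = FALSE) {
  a <- as.data.table(a); b <- as.data.table(b)
  res <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chr[i] != b$chr[j]) next
      if (match_sample && a$sample_id[i] != b$sample_id[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) + 1
      if (ov >= 1) {
        res[[length(res) + 1L]] <- data.table(
          row_a = i, row_b = j, overlap_bp = ov,
          frac_of_a = ov / (a$end[i] - a$start[i] + 1),
          frac_of_b = ov / (b$end[j] - b$start[j] + 1))
      }
    }
  }
  if (!length(res)) {
    return(data.table(row_a = integer(), row_b = integer(),
                      overlap_bp = numeric(), frac_of_a = numeric(),
                      frac_of_b = numeric()))
  }
  rbindlist(res)
}

# Random interval sets on a handful of chromosomes (seeded by the caller).
random_intervals <- function(n, n_chrom = 5, chrom_len = 1e7,
                             max_len = 2e5, samples = NULL) {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE)
  out <- data.table(chr = as.character(sample.int(n_chrom, n, replace = TRUE)),
                    start = as.numeric(start),
                    end = as.numeric(start +
                                       sample.int(max_len, n,
                                                  replace = TRUE) - 1))
  if (!is.null(samples)) {
    out[, sample_id := sample(samples, n, replace = TRUE)]
  }
  out[, cn := sample(c(0L, 1L, 3L, 4L), n, replace = TRUE)]
  out
}

# Small cleaned CNV table builder for unit tests.
make_cnv <- function(sample_id, chr, start, end, cn) {
  data.table(sample_id = sample_id, chr = as.character(chr),
             start = as.numeric(start), end = as.numeric(end),
             cn = as.integer(cn),
             cnv_type = ifelse(cn < 2, "deletion", "duplication"))
}
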