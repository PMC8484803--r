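# ROH summaries, ROH-based inbreeding coefficients, and detection of
# high-frequency ROH regions on the autosomes.

#' Default ROH length-group boundaries (bp): 0-2, 2-4, 4-8, 8-16, >16 Mb
#' @export
default_roh_breaks <- c(0, 2e6, 4e6, 8e6, 16e6, Inf)

#' Summarize ROH counts and lengths by length group
#'
#' @param roh ROH table from [read_plink_hom()]
#'   (`sample_id, chr, start, end`).
#' @param length_breaks half-open length-group boundaries in bp.
#' @return `data.table(length_group, n, total_length)`; zero rows for an
#'   empty input.
#' @export
roh_length_summary <- function(roh, length_breaks = default_roh_breaks) {
  assert_cols(roh, c("sample_id", "chr", "start", "end"))
  x <- as_dt(roh)
  if (nrow(x) == 0L) {
    return(data.table(length_group = factor(), n = integer(),
                      total_length = numeric()))
  }
  x[, length := end - start + 1]
  x[, length_group := length_group(length, length_breaks)]
  out <- x[, .(n = .N, total_length = sum(length)), by = length_group]
  setorder(out, length_group)
  out[]
}

#' ROH-based inbreeding coefficients
#'
#' Computes, per individual, `F_roh = sum(L_roh) / sum(L_auto)`: the total
#' autosomal ROH length divided by the total autosome length, plus the
#' per-length-group components of the same ratio (which sum to the total
#' over disjoint groups).  Non-autosomal segments are excluded.  When
#' `autosome_lengths` is not supplied, the denominator is derived from the
#' SNP map as the chip-covered span per autosome
#' (max position - min position + 1).
#'
#' @param roh ROH table (`sample_id, chr, start, end`).
#' @param autosome_lengths named numeric vector, chromosome -> length in bp,
#'   covering every autosome with ROH; or `NULL` to derive from `map`.
#' @param map SNP map used to derive autosome lengths when
#'   `autosome_lengths` is `NULL`.
#' @param length_breaks length-group boundaries in bp.
#' @return `data.table` with `sample_id, sum_l_roh_bp, sum_l_auto_bp,
#'   f_roh` and one `f_roh_<group>` column per length group.  Individuals
#'   present in `roh` but with no autosomal segment get `f_roh = 0`.
#' @export
froh <- function(roh, autosome_lengths = NULL, map = NULL,
                 length_breaks = default_roh_breaks) {
  assert_cols(roh, c("sample_id", "chr", "start", "end"))
  x <- as_dt(roh)
  x[, chr := normalize_chrom(chr)]
  samples <- sort(unique(x$sample_id))
  auto <- x[is_autosome(chr)]
  if (is.null(autosome_lengths)) {
    if (is.null(map)) {
      stop("supply autosome_lengths or a SNP map to derive them from",
           call. = FALSE)
    }
    m <- as_dt(map)
    assert_cols(m, c("chr", "pos"), "map")
    m[, chr := normalize_chrom(chr)]
    m <- m[is_autosome(chr)]
    al <- m[, .(len = max(pos) - min(pos) + 1), by = chr]
    autosome_lengths <- setNames(al$len, al$chr)
  }
  missing_chr <- setdiff(unique(auto$chr), names(autosome_lengths))
  if (length(missing_chr)) {
    stop("ROH on chromosome(s) absent from autosome_lengths: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  l_auto <- sum(autosome_lengths)
  groups <- levels(length_group(numeric(), length_breaks))
  if (nrow(auto)) {
    auto[, length := end - start + 1]
    auto[, length_group := length_group(length, length_breaks)]
    per <- auto[, .(sum_l_roh_bp = sum(length)), by = sample_id]
    perg <- dcast(auto[, .(l = sum(length)),
                       by = .(sample_id, length_group)],
                  sample_id ~ length_group, value.var = "l",
                  fill = 0, drop = FALSE)
  } else {
    per <- data.table(sample_id = character(), sum_l_roh_bp = numeric())
    perg <- data.table(sample_id = character())
  }
  out <- data.table(sample_id = samples)
  out <- merge(out, per, by = "sample_id", all.x = TRUE)
  out[is.na(sum_l_roh_bp), sum_l_roh_bp := 0]
  out[, sum_l_auto_bp := l_auto]
  out[, f_roh := sum_l_roh_bp / sum_l_auto_bp]
  for (g in groups) {
    col <- paste0("f_roh_", gsub("[^0-9A-Za-z]+", "_", g))
    v <- if (g %in% names(perg)) {
      perg[[g]][match(out$sample_id, perg$sample_id)]
    } else rep(NA_real_, nrow(out))
    v[is.na(v)] <- 0
    out[, (col) := v / l_auto]
  }
  out[]
}

#' Per-SNP ROH carrier incidence
#'
#' For every autosomal map SNP, counts the distinct individuals with at
#' least one ROH spanning the SNP position (closed intervals), and the
#' corresponding carrier frequency.
#'
#' @param roh ROH table (`sample_id, chr, start, end`).
#' @param map SNP map (`name, chr, pos`).
#' @param n_individuals frequency denominator; defaults to the number of
#'   distinct samples in `roh`.
#' @return `data.table(name, chr, pos, n_carriers, freq)` sorted by
#'   `(chr, pos)`.
#' @export
roh_incidence <- function(roh, map, n_individuals = NULL) {
  assert_cols(roh, c("sample_id", "chr", "start", "end"))
  assert_cols(map, c("name", "chr", "pos"))
  x <- as_dt(roh)
  x[, chr := normalize_chrom(chr)]
  if (is.null(n_individuals)) n_individuals <- uniqueN(x$sample_id)
  m <- as_dt(map)[, .(name, chr = normalize_chrom(chr), pos)]
  m <- m[is_autosome(chr)]
  x <- x[is_autosome(chr)]
  snp <- m[, .(name, chr, start = pos, end = pos)]
  if (nrow(x)) {
    rk <- x[, .(sample_id, chr, start, end)]
    setkey(rk, chr, start, end)
    hits <- foverlaps(snp, rk, by.x = c("chr", "start", "end"),
                      type = "any", nomatch = NULL)
    cnt <- hits[, .(n_carriers = uniqueN(sample_id)), by = .(name)]
  } else {
    cnt <- data.table(name = character(), n_carriers = integer())
  }
  out <- merge(m, cnt, by = "name", all.x = TRUE)
  out[is.na(n_carriers), n_carriers := 0L]
  out[, freq := n_carriers / n_individuals]
  out[order(chrom_rank(chr), pos)]
}

#' Detect high-frequency ROH regions
#'
#' Scans the per-SNP incidence for maximal runs of consecutive map SNPs
#' whose carrier frequency meets the threshold; region bounds are the
#' first/last SNP positions of the run.  Extending any reported region by
#' one flanking SNP would drop below the threshold.
#'
#' @param incidence output of [roh_incidence()], sorted by `(chr, pos)`.
#' @param threshold carrier-frequency cutoff in (0, 1]; default 0.3.
#' @return `data.table(chr, start, end, n_snps_in_region, peak_freq,
#'   mean_freq)`, one row per maximal region.
#' @export
high_freq_roh <- function(incidence, threshold = 0.3) {
  assert_cols(incidence, c("chr", "pos", "freq"))
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  x <- as_dt(incidence)[order(chrom_rank(chr), pos)]
  x[, hi := freq >= threshold]
  if (!any(x$hi)) {
    return(data.table(chr = character(), start = numeric(),
                      end = numeric(), n_snps_in_region = integer(),
                      peak_freq = numeric(), mean_freq = numeric()))
  }
  x[, run := cumsum(c(TRUE, hi[-1] != hi[-.N])), by = chr]
  out <- x[hi == TRUE,
           .(start = min(pos), end = max(pos), n_snps_in_region = .N,
             peak_freq = max(freq), mean_freq = mean(freq)),
           by = .(chr, run)]
  out[, run := NULL]
  out[order(chrom_rank(chr), start)]
}
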