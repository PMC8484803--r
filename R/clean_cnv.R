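# Standardization of raw CNV calls and the summary aggregates behind the
# brief-summary table and plots.

#' Default CNV length-group boundaries (bp)
#' @export
default_cnv_breaks <- c(0, 1e5, 5e5, 1e6, 5e6, Inf)

#' Standardize raw CNV calls
#'
#' Reformats parsed caller output into the clean CNV table: chromosome
#' labels are normalized, copy-neutral calls (cn = 2) and calls on
#' unrecognized chromosomes are dropped (and counted), CNV type and length
#' are derived, and rows are sorted by `(sample_id, chr, start)`.  A call
#' with cn < 2 is a deletion; cn > 2 a duplication; copy numbers above 4 are
#' retained with their integer state.
#'
#' @param records raw CNV records from [read_cnv()] (or any table with
#'   `sample_id, chr, start, end, cn`).
#' @param length_breaks length-group boundaries in bp.
#' @return list with `cnv` (the clean table: `sample_id, chr, start, end,
#'   cn, cnv_type, length, length_group`, plus `n_snps`/`conf` when present)
#'   and `report` (counts of input, retained, and dropped rows).
#' @export
clean_cnv <- function(records, length_breaks = default_cnv_breaks) {
  assert_cols(records, c("sample_id", "chr", "start", "end", "cn"))
  x <- as_dt(records)
  # idempotence: re-cleaning an already-clean table must be the identity
  x[, chr := normalize_chrom(chr)]
  n_in <- nrow(x)
  bad_chr <- !is_recognized_chrom(x$chr)
  x <- x[!bad_chr]
  n_cn2 <- sum(x$cn == 2L)
  x <- x[cn != 2L]
  x[, `:=`(cnv_type = ifelse(cn < 2L, "deletion", "duplication"),
           length = end - start + 1)]
  x[, length_group := length_group(length, length_breaks)]
  x <- x[order(sample_id, chrom_rank(chr), start)]
  core <- c("sample_id", "chr", "start", "end", "cn", "cnv_type",
            "length", "length_group")
  setcolorder(x, c(core, setdiff(names(x), core)))
  report <- list(n_input = n_in,
                 n_retained = nrow(x),
                 dropped_cn2 = n_cn2,
                 dropped_chrom = sum(bad_chr))
  if (nrow(x) == 0L) {
    warning("no CNV calls remain after filtering", call. = FALSE)
  }
  list(cnv = x[], report = report)
}

#' Summarize a clean CNV table
#'
#' Cross-tabulates counts and total lengths by length group x CNV type, by
#' chromosome x CNV type, by copy-number state, and per sample.  Every
#' marginal total equals the number of CNV rows.
#'
#' @param cnv clean CNV table from [clean_cnv()].
#' @param length_breaks length-group boundaries in bp (strictly increasing).
#' @return list of `data.table`s: `by_length_type`, `by_chrom_type`,
#'   `by_state`, `by_sample`, and scalar `total`.
#' @export
summarize_cnv <- function(cnv, length_breaks = default_cnv_breaks) {
  assert_cols(cnv, c("sample_id", "chr", "start", "end", "cn", "cnv_type"))
  if (nrow(cnv) == 0L) stop("empty CNV table", call. = FALSE)
  x <- as_dt(cnv)
  x[, length := end - start + 1]
  x[, length_group := length_group(length, length_breaks)]
  by_length_type <- x[, .(n = .N, total_length = sum(length)),
                      by = .(length_group, cnv_type)]
  setorder(by_length_type, length_group, cnv_type)
  by_chrom_type <- x[, .(n = .N, total_length = sum(length)),
                     by = .(chr, cnv_type)][order(chrom_rank(chr), cnv_type)]
  by_state <- x[, .(n = .N, total_length = sum(length)), by = .(cn)][order(cn)]
  by_sample <- x[, .(n = .N, total_length = sum(length)),
                 by = .(sample_id)][order(sample_id)]
  list(by_length_type = by_length_type,
       by_chrom_type = by_chrom_type,
       by_state = by_state,
       by_sample = by_sample,
       total = nrow(x))
}
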