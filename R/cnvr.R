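# CNVR calling: union-merge of CNVs that share at least one base pair.
# Intervals are 1-based closed, so [100,200] and [200,300] share bp 200 and
# merge, while bookended intervals ([100,200] + [201,300]) do not.

#' Call copy number variation regions (CNVRs)
#'
#' Merges CNVs from all samples into CNVRs defined as the union of sets of
#' CNVs that overlap by at least one base pair.  Per chromosome, CNVs are
#' sorted by start and a sweep merges a CNV into the current region when its
#' start is <= the current region end.  Each CNV belongs to exactly one
#' CNVR.  Region type is Deletion if every member has cn < 2, Duplication if
#' every member has cn > 2, and Mixed otherwise.
#'
#' @param cnv clean CNV table from [clean_cnv()].
#' @return list with `cnvr` (`cnvr_id, chr, start, end, n_cnv, n_samples,
#'   n_del, n_dup, cnvr_type, length`, in coordinate order) and `membership`
#'   (the input rows with a `cnvr_id` column appended).
#' @export
call_cnvr <- function(cnv) {
  assert_cols(cnv, c("sample_id", "chr", "start", "end", "cn"))
  x <- as_dt(cnv)
  if (nrow(x) == 0L) {
    empty <- data.table(cnvr_id = character(), chr = character(),
                        start = numeric(), end = numeric(),
                        n_cnv = integer(), n_samples = integer(),
                        n_del = integer(), n_dup = integer(),
                        cnvr_type = character(), length = numeric())
    return(list(cnvr = empty, membership = x))
  }
  x[, .row := .I]
  setorderv(x, c("chr", "start", "end"))
  # sweep per chromosome: new region whenever start > running max end
  x[, .new := {
    cm <- cummax(end)
    c(TRUE, start[-1] > cm[-.N])
  }, by = chr]
  x[, .ord := cumsum(.new), by = chr]
  x[, cnvr_id := paste0("CNVR_", chr, "_", .ord)]
  cnvr <- x[, .(chr = chr[1], start = min(start), end = max(end),
                n_cnv = .N, n_samples = uniqueN(sample_id),
                n_del = sum(cn < 2L), n_dup = sum(cn > 2L)),
            by = cnvr_id]
  cnvr[, cnvr_type := classify_cnvr_counts(n_del, n_dup)]
  cnvr[, length := end - start + 1]
  cnvr <- cnvr[order(chrom_rank(chr), start)]
  membership <- x[order(.row)]
  membership[, c(".row", ".new", ".ord") := NULL]
  list(cnvr = cnvr[], membership = membership[])
}

classify_cnvr_counts <- function(n_del, n_dup) {
  ifelse(n_del > 0L & n_dup > 0L, "Mixed",
         ifelse(n_del > 0L, "Deletion", "Duplication"))
}

#' Classify a CNVR from its member CNVs
#'
#' @param members CNV table of the region's members (needs `cn`).
#' @return `"Deletion"` if all members have cn < 2, `"Duplication"` if all
#'   have cn > 2, `"Mixed"` otherwise.
#' @export
classify_cnvr <- function(members) {
  assert_cols(members, "cn")
  if (nrow(members) == 0L) stop("empty member set", call. = FALSE)
  classify_cnvr_counts(sum(members$cn < 2L), sum(members$cn > 2L))
}

#' Summarize a CNVR table
#'
#' @param cnvr CNVR table from [call_cnvr()].
#' @param length_breaks length-group boundaries in bp.
#' @return list with `by_length_type` (counts by length group x region type)
#'   and `by_chrom` (count and total length per chromosome).
#' @export
cnvr_summaries <- function(cnvr, length_breaks = default_cnv_breaks) {
  x <- as_dt(cnvr)
  if (nrow(x) == 0L) {
    return(list(by_length_type = data.table(), by_chrom = data.table()))
  }
  assert_cols(x, c("chr", "start", "end", "cnvr_type"))
  x[, length := end - start + 1]
  x[, length_group := length_group(length, length_breaks)]
  by_length_type <- x[, .(n = .N, total_length = sum(length)),
                      by = .(length_group, cnvr_type)]
  setorder(by_length_type, length_group, cnvr_type)
  by_chrom <- x[, .(n = .N, total_length = sum(length)),
                by = .(chr)][order(chrom_rank(chr))]
  list(by_length_type = by_length_type, by_chrom = by_chrom)
}

#' Select high-frequency CNVRs
#'
#' Retains CNVRs carried by at least `common_cnv_threshold` of the cohort:
#' `n_samples / sample_size >= common_cnv_threshold`.
#'
#' @param cnvr CNVR table from [call_cnvr()].
#' @param sample_size total number of genotyped samples in the cohort; must
#'   be >= the largest `n_samples` in the table.
#' @param common_cnv_threshold carrier-fraction cutoff in (0, 1]; default
#'   0.05 (the conventional common-variant cutoff).
#' @return the subset of `cnvr` passing the threshold, with a `freq` column,
#'   input order preserved.
#' @export
high_freq_cnvr <- function(cnvr, sample_size, common_cnv_threshold = 0.05) {
  assert_cols(cnvr, c("cnvr_id", "n_samples"))
  if (common_cnv_threshold <= 0 || common_cnv_threshold > 1) {
    stop("common_cnv_threshold must be in (0, 1]", call. = FALSE)
  }
  x <- as_dt(cnvr)
  if (nrow(x) && sample_size < max(x$n_samples)) {
    stop("sample_size (", sample_size, ") is smaller than the largest ",
         "n_samples in the CNVR table (", max(x$n_samples), ")",
         call. = FALSE)
  }
  x[, freq := n_samples / sample_size]
  x[freq >= common_cnv_threshold]
}

#' Export a CNVR table as BED
#'
#' Converts the internal 1-based closed coordinates back to BED's 0-based
#' half-open convention for genome-browser use.
#'
#' @param cnvr CNVR table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cnvr_bed <- function(cnvr, path) {
  assert_cols(cnvr, c("chr", "start", "end", "cnvr_id"))
  bed <- data.table(chrom = cnvr$chr,
                    chromStart = format(cnvr$start - 1, scientific = FALSE,
                                        trim = TRUE),
                    chromEnd = format(cnvr$end, scientific = FALSE,
                                      trim = TRUE),
                    name = cnvr$cnvr_id)
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
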