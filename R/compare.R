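# Population- and individual-level comparison of interval sets.  A naive
# Venn count misleads when one long interval in set A overlaps several
# shorter intervals in set B, so the report carries the full multiplicity
# distribution and three region counts (A-anchored, B-anchored, merged).

#' Compare two interval sets
#'
#' Emits one pair per (a, b) combination that shares at least one base pair
#' on the same chromosome; with `match_sample = TRUE` the pair must
#' additionally agree on `sample_id` (individual-level comparison).
#' Chromosome labels are normalized on both sides; a mixed naming scheme
#' (one set with "chr" prefixes) triggers a warning, then proceeds.
#'
#' @param a,b tables with `chr, start, end` (plus `sample_id` when
#'   `match_sample`); row identifiers are taken from an `id` column if
#'   present, else built as `<set>_<row>`.
#' @param match_sample require equal `sample_id` for a pair to count.
#' @return list with `pairs`
#'   (`id_a, id_b, chr, start_a, end_a, start_b, end_b, overlap_bp,
#'   frac_of_a, frac_of_b`, ordered by `(chr, start_a, start_b)`) and
#'   `report` (see [overlap_report()]).
#' @export
compare_interval <- function(a, b, match_sample = FALSE) {
  need <- c("chr", "start", "end", if (match_sample) "sample_id")
  assert_cols(a, need, "a")
  assert_cols(b, need, "b")
  da <- prep_interval_set(a, "A")
  db <- prep_interval_set(b, "B")
  pref_a <- any(grepl("^chr", as.character(a$chr), ignore.case = TRUE))
  pref_b <- any(grepl("^chr", as.character(b$chr), ignore.case = TRUE))
  if (xor(pref_a, pref_b)) {
    warning("mixed chromosome naming schemes ('chr' prefix in one set ",
            "only); labels normalized before comparison", call. = FALSE)
  }
  by_cols <- c("chr", if (match_sample) "sample_id")
  bk <- copy(db)
  setnames(bk, c("id", "start", "end"), c("id_b", "start_b", "end_b"))
  setkeyv(bk, c(by_cols, "start_b", "end_b"))
  hits <- foverlaps(da, bk,
                    by.x = c(by_cols, "start", "end"),
                    type = "any", nomatch = NULL)
  pairs <- data.table(id_a = hits$id, id_b = hits$id_b, chr = hits$chr,
                      start_a = hits$start, end_a = hits$end,
                      start_b = hits$start_b, end_b = hits$end_b)
  pairs[, overlap_bp := overlap_width(start_a, end_a, start_b, end_b)]
  pairs[, `:=`(frac_of_a = overlap_bp / (end_a - start_a + 1),
               frac_of_b = overlap_bp / (end_b - start_b + 1))]
  setorderv(pairs, c("chr", "start_a", "start_b"))
  list(pairs = pairs[],
       report = overlap_report(pairs, da, db))
}

prep_interval_set <- function(x, label) {
  d <- as_dt(x)
  d[, chr := normalize_chrom(chr)]
  if (!"id" %in% names(d)) d[, id := paste0(label, "_", .I)]
  d[, id := as.character(id)]
  d
}

#' Recompute a comparison report from an overlap pair list
#'
#' The report is a pure function of the pair list plus the two input sets:
#' per-set totals, how many intervals of each set overlap at least one of
#' the other, unique-to-A/B counts, the multiplicity distribution (how many
#' B intervals each overlapping A interval hits, and vice versa), total
#' overlapped bp, mean overlap fractions, and three Venn-style region
#' counts: A-anchored (`overlapping_a`), B-anchored (`overlapping_b`), and
#' `merged_regions` — the number of >= 1 bp union-merged regions that
#' contain intervals from both sets.
#'
#' @param pairs pair table as produced by [compare_interval()].
#' @param a,b the interval sets (with `id, chr, start, end`).
#' @return a list of report fields.
#' @export
overlap_report <- function(pairs, a, b) {
  da <- prep_interval_set(a, "A")
  db <- prep_interval_set(b, "B")
  p <- as.data.table(pairs)
  ov_a <- unique(p$id_a)
  ov_b <- unique(p$id_b)
  mult_a <- if (nrow(p)) p[, .N, by = id_a][, table(N)] else table(integer())
  mult_b <- if (nrow(p)) p[, .N, by = id_b][, table(N)] else table(integer())
  merged <- merged_joint_regions(da, db)
  list(n_a = nrow(da), n_b = nrow(db),
       overlapping_a = length(ov_a), overlapping_b = length(ov_b),
       unique_a = nrow(da) - length(ov_a),
       unique_b = nrow(db) - length(ov_b),
       multiplicity_a = mult_a, multiplicity_b = mult_b,
       total_overlap_bp = sum(p$overlap_bp),
       mean_frac_a = if (nrow(p)) mean(p$frac_of_a) else NA_real_,
       mean_frac_b = if (nrow(p)) mean(p$frac_of_b) else NA_real_,
       merged_regions = merged)
}

# Union-merge A and B jointly; count merged regions containing both sources.
merged_joint_regions <- function(da, db) {
  all_iv <- rbind(da[, .(chr, start, end, src = "A")],
                  db[, .(chr, start, end, src = "B")])
  if (nrow(all_iv) == 0L) return(0L)
  setorderv(all_iv, c("chr", "start", "end"))
  all_iv[, .new := {
    cm <- cummax(end)
    c(TRUE, start[-1] > cm[-.N])
  }, by = chr]
  all_iv[, .grp := cumsum(.new), by = chr]
  both <- all_iv[, .(both = uniqueN(src) == 2L), by = .(chr, .grp)]
  sum(both$both)
}

#' Compare two clean CNV tables at population and individual level
#'
#' Runs [compare_interval()] twice: once ignoring sample identity (the
#' population level: are the same genomic regions found?) and once matching
#' on `sample_id` (the individual level: are they found in the same
#' animals/people?).  The individual-level pair set is always a subset of
#' the population-level one.
#'
#' @param a,b clean CNV tables from [clean_cnv()].
#' @param by_type additionally stratify population-level pairs by
#'   `(cnv_type_a, cnv_type_b)` into a 2x2 count table.
#' @return list with `population` and `individual` comparison results, and
#'   `by_type` (a 2x2 table) when requested.
#' @export
compare_cnv <- function(a, b, by_type = FALSE) {
  assert_cols(a, c("sample_id", "chr", "start", "end", "cnv_type"), "a")
  assert_cols(b, c("sample_id", "chr", "start", "end", "cnv_type"), "b")
  pop <- compare_interval(a, b, match_sample = FALSE)
  ind <- compare_interval(a, b, match_sample = TRUE)
  out <- list(population = pop, individual = ind)
  if (by_type) {
    da <- prep_interval_set(a, "A")[, .(id_a = id, cnv_type_a = cnv_type)]
    db <- prep_interval_set(b, "B")[, .(id_b = id, cnv_type_b = cnv_type)]
    p <- merge(merge(pop$pairs, da, by = "id_a"), db, by = "id_b")
    out$by_type <- table(p$cnv_type_a, p$cnv_type_b)
  }
  out
}

#' Compare two CNVR tables
#'
#' Population-level interval comparison of region sets (CNVRs carry no
#' sample identity).
#'
#' @param a,b CNVR tables from [call_cnvr()].
#' @return as [compare_interval()].
#' @export
compare_cnvr <- function(a, b) {
  a <- as_dt(a); b <- as_dt(b)
  if ("cnvr_id" %in% names(a)) a[, id := cnvr_id]
  if ("cnvr_id" %in% names(b)) b[, id := cnvr_id]
  compare_interval(a, b, match_sample = FALSE)
}
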