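# Gene annotation of genomic intervals and sample-weighted gene frequency.
# Frequency is always computed from per-sample CNV annotation, never from
# CNVR-level annotation, so that a region seen in one sample cannot lend a
# gene the apparent weight of the whole region.

#' Annotate intervals with overlapping genes
#'
#' A gene is annotated to an interval iff the two share at least one base
#' pair on the same (normalized) chromosome; strand is ignored.  One output
#' row is produced per (interval, gene) pair.
#'
#' @param intervals table with `chr, start, end`; any further columns
#'   (e.g. `sample_id`, `cnvr_id`, `cn`) are carried through.  If no
#'   `interval_id` column is present one is built as `chr:start-end`.
#' @param genes cleaned gene table from [read_refgene()]
#'   (`gene, chr, start, end`).
#' @return `data.table` with one row per overlapping pair: the interval
#'   columns plus `gene, gene_start, gene_end, overlap_bp, fully_contained`
#'   (TRUE when the gene lies entirely inside the interval).
#' @export
call_gene <- function(intervals, genes) {
  assert_cols(intervals, c("chr", "start", "end"))
  assert_cols(genes, c("gene", "chr", "start", "end"))
  x <- as_dt(intervals)
  g <- as_dt(genes)
  x[, chr := normalize_chrom(chr)]
  g[, chr := normalize_chrom(chr)]
  if (!"interval_id" %in% names(x)) {
    x[, interval_id := paste0(chr, ":", format(start, scientific = FALSE,
                                               trim = TRUE),
                              "-", format(end, scientific = FALSE,
                                          trim = TRUE))]
  }
  if (nrow(x) == 0L || nrow(g) == 0L) return(empty_gene_annotation(x))
  gk <- g[, .(gene, chr, gene_start = start, gene_end = end)]
  setkey(gk, chr, gene_start, gene_end)
  hits <- foverlaps(x, gk, by.x = c("chr", "start", "end"),
                    type = "any", nomatch = NULL)
  if (nrow(hits) == 0L) return(empty_gene_annotation(x))
  hits[, overlap_bp := overlap_width(start, end, gene_start, gene_end)]
  hits[, fully_contained := gene_start >= start & gene_end <= end]
  setorderv(hits, c("chr", "start", "gene_start", "gene"))
  hits[]
}

empty_gene_annotation <- function(x) {
  out <- x[0]
  out[, `:=`(gene = character(), gene_start = numeric(),
             gene_end = numeric(), overlap_bp = numeric(),
             fully_contained = logical())]
  out[]
}

#' Gene frequency from per-sample CNV annotation
#'
#' For each gene, counts the number of distinct samples whose CNVs overlap
#' it and the total number of overlapping CNVs.  A sample carrying two
#' disjoint CNVs over the same gene is counted once.
#'
#' @param annotated output of [call_gene()] run on per-sample CNVs (must
#'   carry `sample_id`).
#' @param sample_size cohort size used as the frequency denominator; must be
#'   positive.
#' @return `data.table(gene, chr, n_samples, n_cnv, fraction)` sorted by
#'   descending `n_samples`, ties broken by gene name.
#' @export
gene_frequency <- function(annotated, sample_size) {
  assert_cols(annotated, c("gene", "chr", "sample_id"))
  if (!is.numeric(sample_size) || sample_size <= 0) {
    stop("sample_size must be a positive number", call. = FALSE)
  }
  x <- as_dt(annotated)
  out <- x[, .(n_samples = uniqueN(sample_id), n_cnv = .N),
           by = .(gene, chr)]
  out[, fraction := n_samples / sample_size]
  out[order(-n_samples, gene)]
}

#' Extract the carriers of a gene
#'
#' Returns every annotated CNV row (with its sample id) whose gene
#' annotation includes `gene_name`.  Matching is case-sensitive; on a miss,
#' a warning names the nearest lexical matches in the annotation.
#'
#' @param annotated output of [call_gene()] on per-sample CNVs.
#' @param gene_name gene symbol to look up (case-sensitive).
#' @return the matching annotation rows, deduplicated at row level; empty
#'   (with a warning) when the gene is absent.
#' @export
get_samples <- function(annotated, gene_name) {
  assert_cols(annotated, c("gene", "sample_id"))
  x <- as_dt(annotated)
  hit <- x[gene == gene_name]
  if (nrow(hit) == 0L) {
    pool <- unique(x$gene)
    sugg <- unique(c(pool[toupper(pool) == toupper(gene_name)],
                     agrep(gene_name, pool, max.distance = 0.25,
                           ignore.case = TRUE, value = TRUE)))
    warning("gene '", gene_name, "' not found in annotation",
            if (length(sugg)) paste0("; did you mean: ",
                                     paste(head(sugg, 5), collapse = ", "),
                                     "?") else "",
            call. = FALSE)
  }
  unique(hit)
}

#' Consensus gene lists across studies
#'
#' Outer-joins two or more gene frequency tables on gene name, with
#' per-source `n_samples` columns and a presence count; the consensus subset
#' contains the genes present in every source.
#'
#' @param ... two or more gene frequency tables from [gene_frequency()], or
#'   a single (optionally named) list of them.
#' @return list with `union` (outer join, `gene`, one `n_samples_<src>`
#'   column per source, `n_sources`) and `consensus` (genes present in all
#'   sources).
#' @export
compare_gene <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) &&
      !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  if (length(lists) < 2L) {
    stop("compare_gene needs at least two gene lists", call. = FALSE)
  }
  nms <- names(lists)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0("src", seq_along(lists))
  }
  tabs <- Map(function(tab, nm) {
    assert_cols(tab, "gene", what = nm)
    tt <- as.data.table(tab)
    t <- data.table(gene = tt$gene,
                    n_samples = if ("n_samples" %in% names(tt))
                      tt$n_samples else NA_integer_,
                    present = TRUE)
    t <- unique(t, by = "gene")
    setnames(t, c("n_samples", "present"),
             paste0(c("n_samples_", "present_"), nm))
    t
  }, lists, nms)
  out <- Reduce(function(a, b) merge(a, b, by = "gene", all = TRUE), tabs)
  pres_cols <- paste0("present_", nms)
  for (pc in pres_cols) set(out, which(is.na(out[[pc]])), pc, FALSE)
  out[, n_sources := rowSums(as.matrix(.SD)), .SDcols = pres_cols]
  out[, (pres_cols) := NULL]
  setorder(out, -n_sources, gene)
  list(union = out[], consensus = out[n_sources == length(nms)])
}
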