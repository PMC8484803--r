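#' @import data.table
#' @importFrom stats median quantile setNames
#' @importFrom utils head tail
NULL

# All internal coordinates are 1-based, fully closed intervals (PLINK
# convention).  UCSC inputs are shifted at the reader boundary; every
# downstream overlap rule assumes closed intervals.

#' Normalize chromosome labels
#'
#' Strips any leading "chr" prefix (case-insensitive) and upper-cases
#' sex/mitochondrial labels so that "chr1", "Chr1" and "1" compare equal.
#' "M" is mapped to "MT".
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
normalize_chrom <- function(chrom) {
  x <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  x <- toupper(x)
  x[x == "M"] <- "MT"
  x
}

# Recognized chromosomes: autosomes 1..99 plus X, Y, MT.
is_recognized_chrom <- function(chrom) {
  grepl("^[0-9]+$", chrom) | chrom %in% c("X", "Y", "MT")
}

#' Test whether normalized chromosome labels are autosomal
#'
#' @param chrom character vector of normalized labels.
#' @return logical vector; TRUE for purely numeric labels.
#' @export
is_autosome <- function(chrom) {
  grepl("^[0-9]+$", as.character(chrom))
}

# Sort key placing autosomes numerically before X, Y, MT.
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 1e6 + 1
  r[chrom == "Y"] <- 1e6 + 2
  r[chrom == "MT"] <- 1e6 + 3
  r[is.na(r)] <- 1e6 + 10 + as.numeric(factor(chrom[is.na(r)]))
  r
}

# Label half-open length bins [b_i, b_{i+1}) in human-readable bp units.
format_bp <- function(x) {
  out <- character(length(x))
  out[is.infinite(x)] <- "Inf"
  mb <- is.finite(x) & x >= 1e6
  kb <- is.finite(x) & x >= 1e3 & x < 1e6
  sm <- is.finite(x) & x < 1e3
  out[mb] <- paste0(x[mb] / 1e6, " Mb")
  out[kb] <- paste0(x[kb] / 1e3, " kb")
  out[sm] <- paste0(x[sm], " bp")
  out
}

#' Assign lengths to half-open length groups
#'
#' Bins are half-open `[b_i, b_{i+1})`; the break vector must be strictly
#' increasing.  Labels are of the form "0-100 kb", "100 kb-1 Mb", ">= 5 Mb".
#'
#' @param length_bp numeric vector of interval lengths in bp.
#' @param breaks strictly increasing numeric vector of bin boundaries in bp;
#'   a final `Inf` is appended if absent.
#' @return factor of bin labels with one level per bin.
#' @export
length_group <- function(length_bp, breaks) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("length breaks must be strictly increasing", call. = FALSE)
  }
  if (!is.infinite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  labs <- ifelse(is.infinite(hi),
                 paste0(">= ", format_bp(lo)),
                 paste0(format_bp(lo), "-", format_bp(hi)))
  cut(length_bp, breaks = breaks, labels = labs, right = FALSE)
}

# Closed-interval overlap width; <= 0 means no shared bp.
overlap_width <- function(start_a, end_a, start_b, end_b) {
  pmin(end_a, end_b) - pmax(start_a, start_b) + 1
}

# Defensive conversion: always returns a table the caller does not share,
# so in-place := edits never leak into user data.
as_dt <- function(x) {
  if (is.data.table(x)) copy(x) else as.data.table(x)
}

# Stop unless x is a data.frame containing the named columns.
assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) stop(what, " must be a data.frame", call. = FALSE)
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# Write a tab-delimited table with fixed formatting (round-trip stable).
write_tsv_table <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA",
         scipen = 50L)
  invisible(path)
}

# Read a tab-delimited table written by write_tsv_table.
read_tsv_table <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}
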