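# Readers for per-sample CNV call tables.  Each reader returns one row per
# CNV line with verbatim chromosome labels; normalization happens in
# clean_cnv().  Provenance (source path, line number) travels with every row.

#' Read a CNV call table
#'
#' Parses CNV caller output into the raw internal layout with columns
#' `sample_id, chr, start, end, cn, n_snps, conf, source, line`.
#' Coordinates are taken as 1-based inclusive.  Malformed lines are collected
#' (with line numbers) in the `"malformed"` attribute rather than silently
#' dropped; if more than half of the non-empty lines fail to parse the
#' dialect is considered wrong and an error names the first offending line.
#'
#' @param path path to the input file.
#' @param dialect one of `"penncnv"` (whitespace-delimited raw output lines of
#'   the form `chr1:100-299 numsnp=10 length=200 state2,cn=1 SAMPLE ...`),
#'   `"cnvpartition"` (comma-separated export with a header), or `"generic"`
#'   (tab-delimited with the internal standard header).
#' @param col_map named character vector remapping the expected column names
#'   for the `cnvpartition`/`generic` dialects, e.g.
#'   `c(sample_id = "SampleID", chr = "Chr", ...)`.
#' @return a `data.table` of raw CNV records; attribute `"malformed"` holds a
#'   `data.table(line, text)` of unparseable lines.
#' @export
read_cnv <- function(path, dialect = c("penncnv", "cnvpartition", "generic"),
                     col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read CNV file: ", path, call. = FALSE)
  switch(dialect,
         penncnv      = read_cnv_penncnv(path),
         cnvpartition = read_cnv_delim(path, sep = ",", col_map = col_map,
                                       default_map = c(sample_id = "SampleID",
                                                       chr = "Chr",
                                                       start = "StartPosition",
                                                       end = "EndPosition",
                                                       cn = "CopyNumber",
                                                       conf = "Confidence"),
                                       path_label = path),
         generic      = read_cnv_delim(path, sep = "\t", col_map = col_map,
                                       default_map = c(sample_id = "sample_id",
                                                       chr = "chr",
                                                       start = "start",
                                                       end = "end",
                                                       cn = "cn",
                                                       n_snps = "n_snps"),
                                       path_label = path))
}

read_cnv_penncnv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty CNV file: ", path, call. = FALSE)
    return(empty_raw_cnv(path))
  }
  lineno <- which(keep)
  lines <- lines[keep]
  locus_re <- "^(\\S+):([0-9,]+)-([0-9,]+)$"

  parse_one <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 5L || !grepl(locus_re, tok[1])) return(NULL)
    m <- regmatches(tok[1], regexec(locus_re, tok[1]))[[1]]
    cn_tok <- grep("cn=", tok, value = TRUE)
    ns_tok <- grep("^numsnp=", tok, value = TRUE)
    cf_tok <- grep("^conf=", tok, value = TRUE)
    if (!length(cn_tok)) return(NULL)
    cn <- suppressWarnings(as.integer(sub(".*cn=", "", cn_tok[1])))
    start <- suppressWarnings(as.numeric(gsub(",", "", m[3])))
    end <- suppressWarnings(as.numeric(gsub(",", "", m[4])))
    if (is.na(cn) || is.na(start) || is.na(end) || end < start) return(NULL)
    n_snps <- if (length(ns_tok)) {
      suppressWarnings(as.integer(sub("^numsnp=", "", ns_tok[1])))
    } else NA_integer_
    conf <- if (length(cf_tok)) {
      suppressWarnings(as.numeric(sub("^conf=", "", cf_tok[1])))
    } else NA_real_
    # token 5 is the sample path/ID in PennCNV raw output
    list(sample_id = tok[5], chr = m[2], start = start, end = end,
         cn = cn, n_snps = n_snps, conf = conf)
  }

  parsed <- lapply(lines, parse_one)
  ok <- !vapply(parsed, is.null, logical(1))
  if (mean(!ok) > 0.5) {
    first_bad <- lineno[which(!ok)[1]]
    stop("dialect mismatch for ", path, ": >50% of lines unparseable as ",
         "PennCNV raw output; first offending line ", first_bad, call. = FALSE)
  }
  out <- rbindlist(parsed[ok])
  if (nrow(out)) {
    out[, `:=`(source = path, line = lineno[ok])]
  } else {
    out <- empty_raw_cnv(path)
  }
  malformed <- data.table(line = lineno[!ok], text = lines[!ok])
  setattr(out, "malformed", malformed)
  out[]
}

read_cnv_delim <- function(path, sep, col_map, default_map, path_label) {
  map <- default_map
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  raw <- tryCatch(fread(path, sep = sep, header = TRUE),
                  error = function(e) stop("cannot parse ", path_label, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (!nrow(raw)) {
    warning("empty CNV file: ", path_label, call. = FALSE)
    out <- empty_raw_cnv(path_label)
    setattr(out, "malformed", data.table(line = integer(), text = character()))
    return(out)
  }
  need <- c("sample_id", "chr", "start", "end", "cn")
  miss <- setdiff(map[need], names(raw))
  if (length(miss)) {
    stop("dialect mismatch for ", path_label, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- data.table(
    sample_id = as.character(raw[[map[["sample_id"]]]]),
    chr       = as.character(raw[[map[["chr"]]]]),
    start     = as.numeric(raw[[map[["start"]]]]),
    end       = as.numeric(raw[[map[["end"]]]]),
    cn        = as.integer(raw[[map[["cn"]]]]),
    n_snps    = if ("n_snps" %in% names(map) && map[["n_snps"]] %in% names(raw))
                  as.integer(raw[[map[["n_snps"]]]]) else NA_integer_,
    conf      = if ("conf" %in% names(map) && map[["conf"]] %in% names(raw))
                  as.numeric(raw[[map[["conf"]]]]) else NA_real_,
    source    = path_label,
    line      = seq_len(nrow(raw)) + 1L)
  bad <- is.na(out$start) | is.na(out$end) | is.na(out$cn) | out$end < out$start
  malformed <- data.table(line = out$line[bad],
                          text = paste0("row ", which(bad)))
  if (mean(bad) > 0.5) {
    stop("dialect mismatch for ", path_label, ": >50% of rows invalid; ",
         "first offending line ", malformed$line[1], call. = FALSE)
  }
  out <- out[!bad]
  setattr(out, "malformed", malformed)
  out[]
}

empty_raw_cnv <- function(path) {
  data.table(sample_id = character(), chr = character(), start = numeric(),
             end = numeric(), cn = integer(), n_snps = integer(),
             conf = numeric(), source = character(), line = integer())
}

#' Write a standardized CNV table
#'
#' Emits the internal standard tab-delimited layout
#' (`sample_id chr start end cn n_snps length`), readable back via
#' `read_cnv(dialect = "generic")`.
#'
#' @param cnv a CNV table with at least `sample_id, chr, start, end, cn`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cnv <- function(cnv, path) {
  assert_cols(cnv, c("sample_id", "chr", "start", "end", "cn"))
  x <- as.data.table(cnv)
  out <- data.table(sample_id = x$sample_id, chr = x$chr,
                    start = x$start, end = x$end, cn = x$cn,
                    n_snps = if ("n_snps" %in% names(x)) x$n_snps else NA_integer_,
                    length = x$end - x$start + 1)
  write_tsv_table(out, path)
}
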