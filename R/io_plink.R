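# PLINK-format readers: .hom ROH tables and .map/.bim SNP maps.

#' Read a PLINK `.hom` ROH table
#'
#' Parses the whitespace-delimited segment table written by `plink --homozyg`.
#' One row per homozygous segment; `sample_id` is taken from IID, with FID
#' preserved in the `fid` column for provenance.
#'
#' @param path path to the `.hom` file.
#' @return `data.table` with columns
#'   `sample_id, fid, chr, start, end, n_snps, length_kb, source, line`.
#' @export
read_plink_hom <- function(path) {
  if (!file.exists(path)) stop("cannot read .hom file: ", path, call. = FALSE)
  raw <- fread(path, header = TRUE)
  need <- c("FID", "IID", "CHR", "POS1", "POS2", "KB", "NSNP")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("not a PLINK .hom table (", path, "): missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data.table(sample_id = as.character(raw$IID),
             fid = as.character(raw$FID),
             chr = as.character(raw$CHR),
             start = as.numeric(raw$POS1),
             end = as.numeric(raw$POS2),
             n_snps = as.integer(raw$NSNP),
             length_kb = as.numeric(raw$KB),
             source = path,
             line = seq_len(nrow(raw)) + 1L)
}

#' Read a PLINK SNP map (`.map` or `.bim`)
#'
#' Entries are returned in file order.  Duplicate SNP names are deduplicated
#' keeping the first occurrence; the dropped duplicates are reported in the
#' `"duplicates"` attribute (`data.table(name, n)` with total occurrence
#' counts).
#'
#' @param path path to the map file.
#' @param dialect `"map"` (chr, name, cM, pos) or `"bim"`
#'   (chr, name, cM, pos, a1, a2).
#' @return `data.table` with columns `name, chr, pos` (and `a1, a2` for
#'   `.bim`); attribute `"duplicates"` reports duplicated names.
#' @export
read_snp_map <- function(path, dialect = c("map", "bim")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read map file: ", path, call. = FALSE)
  raw <- fread(path, header = FALSE,
               colClasses = list(character = 1:2))
  ncol_need <- if (dialect == "map") 4L else 6L
  if (ncol(raw) < ncol_need) {
    stop(path, " has ", ncol(raw), " columns; ", dialect, " layout needs ",
         ncol_need, call. = FALSE)
  }
  pos_raw <- raw[[4]]
  pos <- suppressWarnings(as.numeric(pos_raw))
  bad <- is.na(pos) | pos != floor(pos)
  if (any(bad)) {
    stop("non-integer position in ", path, " at line ", which(bad)[1],
         ": '", pos_raw[which(bad)[1]], "'", call. = FALSE)
  }
  out <- data.table(name = as.character(raw[[2]]),
                    chr = as.character(raw[[1]]),
                    pos = pos)
  if (dialect == "bim") {
    out[, `:=`(a1 = as.character(raw[[5]]), a2 = as.character(raw[[6]]))]
  }
  dup_names <- unique(out$name[duplicated(out$name)])
  dups <- out[, .N, by = name][N > 1L][, .(name, n = N)]
  if (length(dup_names)) out <- out[!duplicated(name)]
  setattr(out, "duplicates", dups)
  out[]
}

#' Write a SNP map in PLINK `.map` layout
#'
#' @param map `data.table` with `name, chr, pos`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_snp_map <- function(map, path) {
  assert_cols(map, c("name", "chr", "pos"))
  out <- data.table(chr = map$chr, name = map$name, cm = 0,
                    pos = format(map$pos, scientific = FALSE, trim = TRUE))
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
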