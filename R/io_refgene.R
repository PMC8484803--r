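# UCSC refGene / ensGene flat-file reader.  This is the only place in the
# package where a coordinate base shift occurs: UCSC txStart is 0-based
# half-open and is converted to 1-based inclusive on the way in.

#' Read and clean a UCSC-style gene table
#'
#' Parses the refGene/ensGene flat layout
#' (`bin, name, chrom, strand, txStart, txEnd, ..., name2, ...`), collapses
#' transcripts to genes, and converts coordinates to 1-based inclusive
#' (`start = txStart + 1`).  Duplicated `(gene, chr)` pairs are merged to
#' their union span `[min txStart, max txEnd]`.
#'
#' @param path path to the flat file (tab-delimited, no header).
#' @param source `"ucsc_refgene"` (gene symbol from `name2`) or `"ensgene"`
#'   (gene id from `name2`, transcript ids collapsed).
#' @return `data.table` with columns `gene, chr, start, end, strand,
#'   n_transcripts`, one row per distinct `(gene, chr)` pair, sorted by
#'   `(chr, start)`.
#' @export
read_refgene <- function(path, source = c("ucsc_refgene", "ensgene")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("cannot read gene file: ", path, call. = FALSE)
  raw <- fread(path, header = FALSE, sep = "\t")
  if (ncol(raw) < 13L) {
    stop(path, " has ", ncol(raw), " columns; UCSC refGene/ensGene layout ",
         "needs >= 13 (name2 is column 13)", call. = FALSE)
  }
  tx <- data.table(gene = as.character(raw[[13]]),
                   chr = as.character(raw[[3]]),
                   strand = as.character(raw[[4]]),
                   tx_start0 = as.numeric(raw[[5]]),
                   tx_end = as.numeric(raw[[6]]))
  bad_strand <- !tx$strand %in% c("+", "-")
  tx$strand[bad_strand] <- "unknown"
  out <- tx[, .(start = min(tx_start0) + 1,
                end = max(tx_end),
                strand = if (uniqueN(strand) == 1L) strand[1] else "unknown",
                n_transcripts = .N),
            by = .(gene, chr)]
  out[, chr := normalize_chrom(chr)]
  setorder(out, chr, start, gene)
  setcolorder(out, c("gene", "chr", "start", "end", "strand", "n_transcripts"))
  out[]
}

#' Export a one-column gene-symbol list
#'
#' Writes the gene symbols of a frequency or annotation table as a plain
#' one-column list, the input format expected by gene-set annotation web
#' tools such as DAVID.
#'
#' @param genes a table with a `gene` column, or a character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  g <- if (is.character(genes)) genes else {
    assert_cols(genes, "gene")
    genes$gene
  }
  writeLines(unique(g), path)
  invisible(path)
}
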