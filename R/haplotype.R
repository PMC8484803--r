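# Haplotype and diplotype frequency extraction over a SNP window.

#' Locate the SNP window covering a genomic region
#'
#' Returns all map SNPs with position inside `[start, end]` on `chrom`.
#' When the region contains no SNP, the window falls back to the two
#' flanking SNPs (nearest below `start` and nearest above `end`) and is
#' flagged `flanking_only`.
#'
#' @param map SNP map (`name, chr, pos`).
#' @param chrom chromosome of the region.
#' @param start_bp,end_bp region bounds (1-based inclusive).
#' @return object of class `snp_window`: list with `chr`, `snps`
#'   (`data.table(name, pos)` in map order), `index_first`/`index_last`
#'   (row indices in the chromosome-sorted map), `pos_first`/`pos_last`,
#'   and `flanking_only`.
#' @export
closer_snp <- function(map, chrom, start_bp, end_bp) {
  assert_cols(map, c("name", "chr", "pos"))
  if (end_bp < start_bp) stop("end_bp < start_bp", call. = FALSE)
  m <- as_dt(map)[, .(name, chr = normalize_chrom(chr), pos)]
  chrom <- normalize_chrom(chrom)
  mc <- m[chr == chrom][order(pos)]
  if (nrow(mc) == 0L) {
    stop("chromosome ", chrom, " absent from the SNP map", call. = FALSE)
  }
  inside <- which(mc$pos >= start_bp & mc$pos <= end_bp)
  flanking <- FALSE
  if (length(inside)) {
    idx <- c(min(inside), max(inside))
  } else {
    below <- which(mc$pos < start_bp)
    above <- which(mc$pos > end_bp)
    idx_set <- c(if (length(below)) max(below), if (length(above)) min(above))
    if (!length(idx_set)) {
      stop("no SNPs on chromosome ", chrom, " near [", start_bp, ", ",
           end_bp, "]", call. = FALSE)
    }
    idx <- range(idx_set)
    flanking <- TRUE
  }
  win <- mc[idx[1]:idx[2]]
  structure(list(chr = chrom,
                 snps = win[, .(name, pos)],
                 index_first = idx[1], index_last = idx[2],
                 pos_first = win$pos[1], pos_last = win$pos[nrow(win)],
                 flanking_only = flanking),
            class = "snp_window")
}

#' @export
print.snp_window <- function(x, ...) {
  cat("snp_window: chr", x$chr, ", ", nrow(x$snps), " SNPs [",
      format(x$pos_first, scientific = FALSE), "-",
      format(x$pos_last, scientific = FALSE), "]",
      if (x$flanking_only) " (flanking only)", "\n", sep = "")
  invisible(x)
}

#' Haplotype and diplotype frequencies over a SNP window
#'
#' Restricts the phased genotypes to the window's SNPs and tabulates (a) the
#' frequency of each distinct allele string among the 2N haploid sequences
#' and (b) the frequency of each unordered pair of haplotypes among the N
#' individuals.  Beagle phase is arbitrary with respect to parent of
#' origin, so diplotype pairs are unordered.  Haplotype ids `H1, H2, ...`
#' are assigned by descending count, ties broken lexicographically by
#' allele string.
#'
#' @param geno `phased_genotypes` from [read_phased_vcf()].
#' @param window a `snp_window` from [closer_snp()], or a character vector
#'   of SNP names.
#' @return list with `haplotype`
#'   (`data.table(haplotype_id, haplotype, count, freq)`, `freq` out of 2N)
#'   and `diplotype` (`data.table(diplotype, hap_1, hap_2, count, freq)`,
#'   `freq` out of N), both sorted by descending count.
#' @export
get_haplotype <- function(geno, window) {
  if (!inherits(geno, "phased_genotypes")) {
    stop("geno must be a phased_genotypes object", call. = FALSE)
  }
  snp_names <- if (inherits(window, "snp_window")) window$snps$name
               else as.character(window)
  missing <- setdiff(snp_names, geno$snps$name)
  if (length(missing)) {
    stop("window SNP(s) missing from the phased genotypes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(snp_names, geno$snps$name)
  h1 <- apply(geno$hap1[idx, , drop = FALSE], 2, paste0, collapse = "")
  h2 <- apply(geno$hap2[idx, , drop = FALSE], 2, paste0, collapse = "")
  n_ind <- length(geno$samples)
  haps <- c(h1, h2)
  tab <- data.table(haplotype = haps)[, .(count = .N), by = haplotype]
  tab <- tab[order(-count, haplotype)]
  tab[, haplotype_id := paste0("H", .I)]
  tab[, freq := count / (2 * n_ind)]
  setcolorder(tab, c("haplotype_id", "haplotype", "count", "freq"))
  id_of <- setNames(tab$haplotype_id, tab$haplotype)
  rank_of <- setNames(seq_len(nrow(tab)), tab$haplotype_id)
  d1 <- id_of[h1]; d2 <- id_of[h2]
  swap <- rank_of[d1] > rank_of[d2]
  lo <- ifelse(swap, d2, d1); hi <- ifelse(swap, d1, d2)
  dip <- data.table(hap_1 = lo, hap_2 = hi)[, .(count = .N),
                                            by = .(hap_1, hap_2)]
  dip[, diplotype := paste0(hap_1, "/", hap_2)]
  dip[, freq := count / n_ind]
  dip <- dip[order(-count, hap_1, hap_2)]
  setcolorder(dip, c("diplotype", "hap_1", "hap_2", "count", "freq"))
  list(haplotype = tab[], diplotype = dip[])
}
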