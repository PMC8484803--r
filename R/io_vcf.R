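# Phased-VCF reader (Beagle-style `0|1` GT fields) built on vcfR.

#' Read phased genotypes from a VCF
#'
#' Loads a VCF with phased GT fields and returns, per individual, the two
#' haploid allele sequences aligned to the site order of the file.  Only
#' biallelic sites are supported; an unphased GT (`0/1`) or a multi-allelic
#' ALT is an error naming the first offending site.
#'
#' @param path path to the VCF (plain text or gzipped).
#' @param convert_letter if `TRUE`, allele codes are converted to bases
#'   (0 = REF, 1 = ALT); if `FALSE` the `0`/`1` codes are kept.
#' @return an object of class `phased_genotypes`: a list with
#'   `snps` (`data.table(name, chr, pos, ref, alt)` in file order),
#'   `hap1`/`hap2` (character matrices, sites x individuals),
#'   `samples`, and `coding` (`"letter"` or `"code"`).
#' @export
read_phased_vcf <- function(path, convert_letter = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    stop("multi-allelic site not supported: ", fix[i, "CHROM"], ":",
         fix[i, "POS"], " (ALT = ", fix[i, "ALT"], ")", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  unphased <- !grepl("|", gt, fixed = TRUE)
  if (any(unphased)) {
    i <- which(rowSums(matrix(unphased, nrow = nrow(gt))) > 0)[1]
    stop("unphased genotype at site ", fix[i, "CHROM"], ":", fix[i, "POS"],
         "; only phased (|) GT fields are accepted", call. = FALSE)
  }
  a1 <- sub("\\|.*$", "", gt)
  a2 <- sub("^.*\\|", "", gt)
  bad <- !(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))
  if (any(bad)) {
    i <- which(rowSums(matrix(bad, nrow = nrow(gt))) > 0)[1]
    stop("missing or non-biallelic allele code at site ",
         fix[i, "CHROM"], ":", fix[i, "POS"], call. = FALSE)
  }
  dim(a1) <- dim(gt); dim(a2) <- dim(gt)
  if (convert_letter) {
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    a1 <- ifelse(a1 == "0", ref[row(a1)], alt[row(a1)])
    a2 <- ifelse(a2 == "0", ref[row(a2)], alt[row(a2)])
  }
  snps <- data.table(name = fix[, "ID"],
                     chr = normalize_chrom(fix[, "CHROM"]),
                     pos = as.numeric(fix[, "POS"]),
                     ref = fix[, "REF"],
                     alt = fix[, "ALT"])
  samples <- colnames(gt)
  dimnames(a1) <- dimnames(a2) <- list(snps$name, samples)
  structure(list(snps = snps, hap1 = a1, hap2 = a2, samples = samples,
                 coding = if (convert_letter) "letter" else "code"),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", nrow(x$snps), "sites x", length(x$samples),
      "individuals (", x$coding, "coding )\n")
  invisible(x)
}
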