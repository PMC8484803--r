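# Seeded synthetic-cohort generators.  Every input dialect the toolkit
# reads is emulated with planted, recoverable structure: a high-frequency
# CNVR carried by an exact number of samples, a gene overlapped by CNVs in
# an exact number of samples, shared ROH segments, two SNP maps differing
# by planted perturbation classes, and phased genotypes drawn from a known
# haplotype distribution.  The truth ledger records everything planted, so
# recovery tests read the ledger and never re-derive expectations.

#' Build a validated fixture configuration
#'
#' Planted carrier counts are exact: carriers are chosen by seeded sampling
#' without replacement, `round(fraction * n)` of them, so recovery
#' assertions can be exact rather than probabilistic.  Background CNVs are
#' private (one random sample each) and placed on disjoint slots so they
#' can never aggregate into a common region.
#'
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param n_samples CNV cohort size.
#' @param n_chromosomes number of autosomes in the fixture genome.
#' @param chrom_length_bp length of every fixture chromosome.
#' @param n_snps total SNPs on the chip map (split evenly per chromosome).
#' @param planted_cnvr list `(chr, start, end, carrier_fraction, cn)` for
#'   the planted common CNVR; `carrier_fraction = 0` disables it.
#' @param planted_gene list `(gene, chr, start, end, carrier_fraction, cn)`
#'   for the gene-overlap plant.
#' @param n_background_cnv number of private background CNVs.
#' @param roh list: `n_individuals`, `planted = (chr, start, end,
#'   carrier_fraction)`, `n_background_per_individual`,
#'   `background_length_range` (bp).
#' @param haplotype list: `chr`, `n_sites`, `window_size`, `n_individuals`,
#'   `freqs` (haplotype-pool sampling probabilities).
#' @param map_perturb list of target-map perturbation rates:
#'   `missing`, `chr_change`, `shift` (fractions of SNPs) and `shift_bp`.
#' @param n_genes,dup_gene_fraction size of the reference gene list and the
#'   fraction of genes written as duplicated transcript rows.
#' @return validated config list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_samples = 100L,
                           n_chromosomes = 5L,
                           chrom_length_bp = 1e8,
                           n_snps = 10000L,
                           planted_cnvr = list(chr = "1", start = 40000001,
                                               end = 40500000,
                                               carrier_fraction = 0.2,
                                               cn = 1L),
                           planted_gene = list(gene = "GENE_TARGET",
                                               chr = "2", start = 60000001,
                                               end = 60100000,
                                               carrier_fraction = 0.17,
                                               cn = 3L),
                           n_background_cnv = 150L,
                           roh = list(n_individuals = 50L,
                                      planted = list(chr = "3",
                                                     start = 20000001,
                                                     end = 22000000,
                                                     carrier_fraction = 0.4),
                                      n_background_per_individual = 3L,
                                      background_length_range = c(1e6, 2e6)),
                           haplotype = list(chr = "4", n_sites = 12L,
                                            window_size = 5L,
                                            n_individuals = 200L,
                                            freqs = c(0.6, 0.3, 0.1)),
                           map_perturb = list(missing = 0.03,
                                              chr_change = 0.01,
                                              shift = 0.05,
                                              shift_bp = 10000),
                           n_genes = 200L,
                           dup_gene_fraction = 0.3) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp, n_snps = as.integer(n_snps),
              planted_cnvr = planted_cnvr, planted_gene = planted_gene,
              n_background_cnv = as.integer(n_background_cnv), roh = roh,
              haplotype = haplotype, map_perturb = map_perturb,
              n_genes = as.integer(n_genes),
              dup_gene_fraction = dup_gene_fraction)
  fr <- c(planted_cnvr$carrier_fraction, planted_gene$carrier_fraction,
          roh$planted$carrier_fraction, map_perturb$missing,
          map_perturb$chr_change, map_perturb$shift, dup_gene_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions/rates must lie in [0, 1]", call. = FALSE)
  }
  for (p in list(planted_cnvr, planted_gene, roh$planted)) {
    if (as.integer(p$chr) > cfg$n_chromosomes ||
        p$end > cfg$chrom_length_bp || p$start < 1) {
      stop("planted region ", p$chr, ":", p$start, "-", p$end,
           " exceeds the fixture genome", call. = FALSE)
    }
  }
  if (abs(sum(haplotype$freqs) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1", call. = FALSE)
  }
  structure(cfg, class = "fixture_config")
}

#' Generate a full synthetic cohort
#'
#' Writes every input dialect the package reads — PennCNV raw CNV lines, a
#' CNVPartition CSV with the same calls, a PLINK `.hom` table, two PLINK
#' `.map` files (default + perturbed target assembly), a UCSC-style refGene
#' flat file, and a phased VCF — plus a machine-readable truth ledger
#' (`truth.json`) recording all planted structure.
#'
#' @param config a [fixture_config()].
#' @param out_dir output directory (created if absent).
#' @return list with `files` (named paths), `ledger` (the truth list), and
#'   `config`.
#' @export
gen_cohort <- function(config, out_dir) {
  if (!inherits(config, "fixture_config")) {
    stop("config must come from fixture_config()", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  ledger <- list(seed = config$seed)
  files <- list()

  samples <- sprintf("S%03d", seq_len(config$n_samples))
  chroms <- as.character(seq_len(config$n_chromosomes))

  ## ---- SNP maps ----------------------------------------------------------
  per_chr <- config$n_snps %/% config$n_chromosomes
  map_default <- rbindlist(lapply(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, per_chr))
    data.table(name = sprintf("SNP_%s_%05d", ch, seq_len(per_chr)),
               chr = ch, pos = as.numeric(pos))
  }))
  n_map <- nrow(map_default)
  n_miss <- round(config$map_perturb$missing * n_map)
  n_chg <- round(config$map_perturb$chr_change * n_map)
  n_shift <- round(config$map_perturb$shift * n_map)
  perturbed <- sample(map_default$name, n_miss + n_chg + n_shift)
  miss_names <- perturbed[seq_len(n_miss)]
  chg_names <- perturbed[n_miss + seq_len(n_chg)]
  shift_names <- perturbed[n_miss + n_chg + seq_len(n_shift)]
  map_target <- copy(map_default)[!name %in% miss_names]
  if (n_chg) {
    old <- map_target[name %in% chg_names, chr]
    new <- vapply(old, function(ch) sample(setdiff(chroms, ch), 1L),
                  character(1))
    map_target[name %in% chg_names, chr := new]
  }
  map_target[name %in% shift_names,
             pos := pos + config$map_perturb$shift_bp]
  map_target <- map_target[order(chrom_rank(chr), pos)]
  files$map_default <- file.path(out_dir, "default.map")
  files$map_target <- file.path(out_dir, "target.map")
  write_snp_map(map_default, files$map_default)
  write_snp_map(map_target, files$map_target)
  ledger$map <- list(n_snps = n_map,
                     missing_in_target = sort(miss_names),
                     chr_changed = sort(chg_names),
                     pos_shifted = sort(shift_names),
                     shift_bp = config$map_perturb$shift_bp)

  ## ---- CNV calls ---------------------------------------------------------
  mean_gap <- config$chrom_length_bp / per_chr
  truth_cnv <- list()
  pc <- config$planted_cnvr
  n_car <- round(pc$carrier_fraction * config$n_samples)
  cnvr_carriers <- if (n_car) sort(sample(samples, n_car)) else character(0)
  if (n_car) {
    truth_cnv$planted_cnvr <- data.table(
      sample_id = cnvr_carriers, chr = pc$chr, start = pc$start,
      end = pc$end, cn = pc$cn, origin = "planted_cnvr")
  }
  pg <- config$planted_gene
  n_gcar <- round(pg$carrier_fraction * config$n_samples)
  gene_carriers <- if (n_gcar) sort(sample(samples, n_gcar)) else character(0)
  if (n_gcar) {
    # each carrier CNV covers the gene with jittered margins, so carrier
    # intervals differ but every one overlaps the gene
    truth_cnv$planted_gene <- data.table(
      sample_id = gene_carriers, chr = pg$chr,
      start = pg$start - sample(1000:20000, n_gcar, replace = TRUE),
      end = pg$end + sample(1000:20000, n_gcar, replace = TRUE),
      cn = pg$cn, origin = "planted_gene")
  }
  # private background CNVs on disjoint 200 kb slots in [5, 35] Mb,
  # far from every planted region: they can never merge with anything
  n_bg <- config$n_background_cnv
  if (n_bg) {
    slot_w <- 2e5
    slots_per_chr <- floor(30e6 / slot_w)
    if (n_bg > slots_per_chr * config$n_chromosomes) {
      stop("too many background CNVs for the slot grid", call. = FALSE)
    }
    slot_id <- sample.int(slots_per_chr * config$n_chromosomes, n_bg)
    slot_chr <- chroms[(slot_id - 1L) %% config$n_chromosomes + 1L]
    slot_ofs <- 5e6 + ((slot_id - 1L) %/% config$n_chromosomes) * slot_w
    bg_len <- sample(2e4:1e5, n_bg, replace = TRUE)
    bg_start <- slot_ofs + sample.int(5e4, n_bg, replace = TRUE)
    truth_cnv$background <- data.table(
      sample_id = sample(samples, n_bg, replace = TRUE),
      chr = slot_chr, start = bg_start, end = bg_start + bg_len - 1,
      cn = sample(c(0L, 1L, 3L, 4L), n_bg, replace = TRUE),
      origin = "background")
  }
  cnv_truth <- rbindlist(truth_cnv)
  cnv_truth[, n_snps := pmax(3L, as.integer(round((end - start + 1) /
                                                    mean_gap)))]
  files$cnv_penncnv <- file.path(out_dir, "calls.rawcnv")
  writeLines(penncnv_lines(cnv_truth), files$cnv_penncnv)
  files$cnv_cnvpartition <- file.path(out_dir, "calls_cnvpartition.csv")
  fwrite(data.table(SampleID = cnv_truth$sample_id, Chr = cnv_truth$chr,
                    StartPosition = cnv_truth$start,
                    EndPosition = cnv_truth$end,
                    CopyNumber = cnv_truth$cn, Confidence = 30),
         files$cnv_cnvpartition, scipen = 50L)
  ledger$cnv <- list(truth = cnv_truth,
                     planted_cnvr = c(pc, list(carriers = cnvr_carriers)),
                     planted_gene = c(pg, list(carriers = gene_carriers)),
                     n_del = sum(cnv_truth$cn < 2L),
                     n_dup = sum(cnv_truth$cn > 2L))

  ## ---- ROH ---------------------------------------------------------------
  rcfg <- config$roh
  roh_ids <- sprintf("H%03d", seq_len(rcfg$n_individuals))
  pr <- rcfg$planted
  n_rcar <- round(pr$carrier_fraction * rcfg$n_individuals)
  roh_carriers <- if (n_rcar) sort(sample(roh_ids, n_rcar)) else character(0)
  segs <- list()
  if (n_rcar) {
    segs$planted <- data.table(sample_id = roh_carriers, chr = pr$chr,
                               start = pr$start, end = pr$end)
  }
  # background segments: 2 Mb slots in the 60-98 Mb stretch of each
  # chromosome (far from every planted region), at most 2 individuals per
  # slot, so background carrier frequency at any SNP stays <= 4/cohort
  nb <- rcfg$n_background_per_individual
  if (nb) {
    slot_w <- 2e6
    grid <- CJ(chr = chroms, slot = seq_len(19L))
    grid[, slot_start := 60e6 + (slot - 1) * slot_w]
    n_seg <- nb * rcfg$n_individuals
    if (n_seg > 2L * nrow(grid)) {
      stop("too many background ROH for the slot grid", call. = FALSE)
    }
    slot_pick <- sample(rep(seq_len(nrow(grid)), 2L), n_seg)
    len <- sample(seq(rcfg$background_length_range[1],
                      rcfg$background_length_range[2], by = 1000),
                  n_seg, replace = TRUE)
    st <- grid$slot_start[slot_pick] +
      sample.int(1e5, n_seg, replace = TRUE)
    segs$background <- data.table(
      sample_id = rep(roh_ids, each = nb),
      chr = grid$chr[slot_pick], start = st, end = st + len - 1)
  }
  roh_truth <- rbindlist(segs)
  roh_truth <- roh_truth[order(sample_id, chrom_rank(chr), start)]
  roh_truth[, `:=`(kb = round((end - start + 1) / 1000, 3),
                   nsnp = pmax(10L, as.integer(round((end - start + 1) /
                                                       mean_gap))))]
  files$plink_hom <- file.path(out_dir, "plink.hom")
  hom <- data.table(FID = roh_truth$sample_id, IID = roh_truth$sample_id,
                    PHE = -9, CHR = roh_truth$chr,
                    SNP1 = "snpA", SNP2 = "snpB",
                    POS1 = roh_truth$start, POS2 = roh_truth$end,
                    KB = roh_truth$kb, NSNP = roh_truth$nsnp,
                    DENSITY = 1, PHOM = 1, PHET = 0)
  fwrite(hom, files$plink_hom, sep = " ", quote = FALSE, scipen = 50L)
  per_ind <- roh_truth[, .(sum_l_roh_bp = sum(end - start + 1)),
                       by = sample_id]
  ledger$roh <- list(truth = roh_truth,
                     planted = c(pr, list(carriers = roh_carriers)),
                     individuals = roh_ids,
                     per_individual_bp = per_ind,
                     genome_bp = config$n_chromosomes *
                       config$chrom_length_bp)

  ## ---- reference genes ---------------------------------------------------
  pgr <- config$planted_gene
  n_rand <- config$n_genes - 1L
  g_chr <- sample(chroms, n_rand, replace = TRUE)
  g_start <- sample.int(config$chrom_length_bp - 3e5, n_rand)
  g_len <- sample(5e3:2e5, n_rand, replace = TRUE)
  genes <- data.table(gene = sprintf("GENE%04d", seq_len(n_rand)),
                      chr = g_chr, start = as.numeric(g_start),
                      end = as.numeric(g_start + g_len - 1),
                      strand = sample(c("+", "-"), n_rand, replace = TRUE))
  genes <- rbind(genes,
                 data.table(gene = pgr$gene, chr = pgr$chr,
                            start = pgr$start, end = pgr$end, strand = "+"))
  n_dup <- round(config$dup_gene_fraction * nrow(genes))
  dup_idx <- sample(seq_len(n_rand), n_dup)
  files$refgene <- file.path(out_dir, "refgene.txt")
  writeLines(refgene_lines(genes, dup_idx), files$refgene)
  ledger$genes <- list(n_distinct = nrow(genes),
                       n_transcript_rows = nrow(genes) + n_dup,
                       planted_gene = pgr$gene,
                       planted_span = c(pgr$start, pgr$end))

  ## ---- phased genotypes --------------------------------------------------
  hcfg <- config$haplotype
  hap_chr <- hcfg$chr
  chr_map <- map_default[chr == hap_chr]
  i0 <- floor(nrow(chr_map) / 2)
  sites <- chr_map[i0:(i0 + hcfg$n_sites - 1L)]
  w0 <- floor((hcfg$n_sites - hcfg$window_size) / 2) + 1L
  win_idx <- w0:(w0 + hcfg$window_size - 1L)
  bases <- c("A", "C", "G", "T")
  ra <- t(vapply(seq_len(hcfg$n_sites),
                 function(i) sample(bases, 2L), character(2)))
  n_hap_ind <- hcfg$n_individuals
  vcf_samples <- sprintf("P%03d", seq_len(n_hap_ind))
  # haplotype pool over the window, as 0/1 code vectors
  k <- hcfg$window_size
  pool <- list(rep(0L, k), rep(1L, k), rep(c(0L, 1L), length.out = k))
  draws <- sample(length(hcfg$freqs), 2L * n_hap_ind, replace = TRUE,
                  prob = hcfg$freqs)
  codes <- matrix(sample(0:1, hcfg$n_sites * 2L * n_hap_ind,
                         replace = TRUE),
                  nrow = hcfg$n_sites)
  for (j in seq_along(draws)) {
    codes[win_idx, j] <- pool[[draws[j]]]
  }
  hap_strings <- apply(codes[win_idx, , drop = FALSE], 2, function(cd) {
    paste0(ifelse(cd == 0L, ra[win_idx, 1], ra[win_idx, 2]), collapse = "")
  })
  hap_counts <- sort(table(hap_strings), decreasing = TRUE)
  d1 <- hap_strings[seq_len(n_hap_ind)]
  d2 <- hap_strings[n_hap_ind + seq_len(n_hap_ind)]
  dip <- paste(pmin(d1, d2), pmax(d1, d2), sep = "/")
  files$phased_vcf <- file.path(out_dir, "phased.vcf")
  writeLines(vcf_lines(sites, ra, codes, vcf_samples, hap_chr),
             files$phased_vcf)
  ledger$haplotype <- list(
    chr = hap_chr,
    window_snps = sites$name[win_idx],
    window_start = sites$pos[win_idx[1]],
    window_end = sites$pos[win_idx[length(win_idx)]],
    draw_index = draws,
    hap_counts = as.list(hap_counts),
    dip_counts = as.list(sort(table(dip), decreasing = TRUE)),
    n_individuals = n_hap_ind)

  files$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(ledger, files$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  list(files = files, ledger = ledger, config = config)
}

penncnv_lines <- function(cnv) {
  state <- c("0" = "state1", "1" = "state2", "3" = "state5", "4" = "state6")
  sprintf("chr%s:%s-%s numsnp=%d length=%s %s,cn=%d %s startsnp=SNPA endsnp=SNPB",
          cnv$chr,
          format(cnv$start, scientific = FALSE, trim = TRUE),
          format(cnv$end, scientific = FALSE, trim = TRUE),
          cnv$n_snps,
          format(cnv$end - cnv$start + 1, scientific = FALSE, trim = TRUE),
          state[as.character(cnv$cn)], cnv$cn, cnv$sample_id)
}

refgene_lines <- function(genes, dup_idx) {
  rows <- copy(genes)
  rows[, nm := sprintf("NM_%06d", seq_len(nrow(rows)))]
  if (length(dup_idx)) {
    # duplicated transcript rows: same gene, shifted sub-span
    extra <- copy(rows[dup_idx])
    extra[, `:=`(start = start + pmin(2000, pmax(0, (end - start) %/% 4)),
                 nm = paste0(nm, "b"))]
    rows <- rbind(rows, extra)
  }
  sprintf(paste0("0\t%s\tchr%s\t%s\t%s\t%s\t%s\t%s\t1\t%s,\t%s,\t0\t%s\t",
                 "cmpl\tcmpl\t0,"),
          rows$nm, rows$chr, rows$strand,
          format(rows$start - 1, scientific = FALSE, trim = TRUE),
          format(rows$end, scientific = FALSE, trim = TRUE),
          format(rows$start - 1, scientific = FALSE, trim = TRUE),
          format(rows$end, scientific = FALSE, trim = TRUE),
          format(rows$start - 1, scientific = FALSE, trim = TRUE),
          format(rows$end, scientific = FALSE, trim = TRUE),
          rows$gene)
}

vcf_lines <- function(sites, ra, codes, vcf_samples, chrom) {
  n_ind <- length(vcf_samples)
  header <- c("##fileformat=VCFv4.2",
              "##source=cnvroh_synthetic_fixture",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", vcf_samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    gt <- paste0(codes[i, seq_len(n_ind)], "|",
                 codes[i, n_ind + seq_len(n_ind)])
    paste(c(chrom, format(sites$pos[i], scientific = FALSE, trim = TRUE),
            sites$name[i], ra[i, 1], ra[i, 2], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  c(header, body)
}
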