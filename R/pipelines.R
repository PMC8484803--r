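# End-to-end pipelines composing the already-tested operations, with a
# per-run output directory and a checksummed artifact manifest.

#' Run the CNV post-analysis pipeline
#'
#' clean -> summarize -> call_cnvr -> annotate (when a gene list is given)
#' -> high-frequency selection, writing every artifact to `out_dir` and a
#' `manifest.tsv` with md5 checksums.  Reruns with the same inputs produce
#' identical checksums.
#'
#' @param config list (or path to a YAML file) with fields:
#'   `cnv_input` (path), `dialect` (`penncnv`/`cnvpartition`/`generic`),
#'   `sample_size`, optional `refgene` (path) and `refgene_source`,
#'   `common_cnv_threshold` (default 0.05), `length_breaks`,
#'   `out_dir`, `overwrite` (default FALSE).
#' @return list with `manifest` (`data.table(file, md5)`) and the main
#'   in-memory results (`cnv`, `cnvr`, `gene_freq`, `high_freq`).
#' @export
run_cnv_pipeline <- function(config) {
  cfg <- load_run_config(config)
  for (f in c("cnv_input", "sample_size", "out_dir")) {
    if (is.null(cfg[[f]])) stop("config field missing: ", f, call. = FALSE)
  }
  out_dir <- prepare_out_dir(cfg)
  thr <- cfg$common_cnv_threshold %||% 0.05
  breaks <- cfg$length_breaks %||% default_cnv_breaks
  run_stage <- stage_runner("cnv pipeline")

  raw <- run_stage("read_cnv",
                   read_cnv(cfg$cnv_input, cfg$dialect %||% "penncnv"))
  cleaned <- run_stage("clean_cnv", clean_cnv(raw, breaks))
  write_cnv(cleaned$cnv, file.path(out_dir, "clean_cnv.tsv"))
  summ <- run_stage("summarize_cnv", summarize_cnv(cleaned$cnv, breaks))
  write_tsv_table(summ$by_length_type,
                  file.path(out_dir, "cnv_summary_by_length_type.tsv"))
  write_tsv_table(summ$by_chrom_type,
                  file.path(out_dir, "cnv_summary_by_chrom_type.tsv"))
  write_tsv_table(summ$by_sample,
                  file.path(out_dir, "cnv_summary_by_sample.tsv"))
  called <- run_stage("call_cnvr", call_cnvr(cleaned$cnv))
  write_tsv_table(called$cnvr, file.path(out_dir, "cnvr.tsv"))
  write_cnvr_bed(called$cnvr, file.path(out_dir, "cnvr.bed"))
  cs <- run_stage("cnvr_summaries", cnvr_summaries(called$cnvr, breaks))
  write_tsv_table(cs$by_chrom, file.path(out_dir, "cnvr_by_chrom.tsv"))
  gene_freq <- NULL
  if (!is.null(cfg$refgene)) {
    genes <- run_stage("read_refgene",
                       read_refgene(cfg$refgene,
                                    cfg$refgene_source %||% "ucsc_refgene"))
    annot <- run_stage("call_gene", call_gene(cleaned$cnv, genes))
    gene_freq <- run_stage("gene_frequency",
                           gene_frequency(annot, cfg$sample_size))
    write_tsv_table(gene_freq, file.path(out_dir, "gene_frequency.tsv"))
    write_gene_list(gene_freq, file.path(out_dir, "gene_list.txt"))
  }
  hf <- run_stage("high_freq_cnvr",
                  high_freq_cnvr(called$cnvr, cfg$sample_size, thr))
  write_tsv_table(hf, file.path(out_dir, "high_freq_cnvr.tsv"))
  manifest <- write_manifest(out_dir)
  list(manifest = manifest, cnv = cleaned$cnv, cnvr = called$cnvr,
       gene_freq = gene_freq, high_freq = hf)
}

#' Run the ROH post-analysis pipeline
#'
#' SNP density -> length summary -> F_roh -> per-SNP incidence ->
#' high-frequency regions -> gene annotation (when a gene list is given),
#' writing every artifact to `out_dir` plus a checksummed manifest.
#'
#' @param config list (or path to a YAML file) with fields:
#'   `hom_input` (PLINK `.hom`), `map_input` (PLINK `.map`),
#'   optional `autosome_lengths` (named), `roh_threshold` (default 0.3),
#'   `length_breaks`, `refgene`, `refgene_source`, `out_dir`, `overwrite`.
#' @return list with `manifest` and the main results (`roh`, `froh`,
#'   `incidence`, `high_freq`, `annotation`).
#' @export
run_roh_pipeline <- function(config) {
  cfg <- load_run_config(config)
  for (f in c("hom_input", "map_input", "out_dir")) {
    if (is.null(cfg[[f]])) stop("config field missing: ", f, call. = FALSE)
  }
  out_dir <- prepare_out_dir(cfg)
  thr <- cfg$roh_threshold %||% 0.3
  breaks <- cfg$length_breaks %||% default_roh_breaks
  run_stage <- stage_runner("roh pipeline")

  roh <- run_stage("read_plink_hom", read_plink_hom(cfg$hom_input))
  map <- run_stage("read_snp_map", read_snp_map(cfg$map_input, "map"))
  dens <- run_stage("snp_density", snp_density(map))
  write_tsv_table(dens, file.path(out_dir, "snp_density.tsv"))
  ls <- run_stage("roh_length_summary", roh_length_summary(roh, breaks))
  write_tsv_table(ls, file.path(out_dir, "roh_length_summary.tsv"))
  al <- cfg$autosome_lengths
  if (!is.null(al)) al <- unlist(al)
  fr <- run_stage("froh", froh(roh, autosome_lengths = al, map = map,
                               length_breaks = breaks))
  write_tsv_table(fr, file.path(out_dir, "froh.tsv"))
  inc <- run_stage("roh_incidence", roh_incidence(roh, map))
  write_tsv_table(inc, file.path(out_dir, "roh_incidence.tsv"))
  hf <- run_stage("high_freq_roh", high_freq_roh(inc, thr))
  write_tsv_table(hf, file.path(out_dir, "high_freq_roh.tsv"))
  annot <- NULL
  if (!is.null(cfg$refgene) && nrow(hf)) {
    genes <- run_stage("read_refgene",
                       read_refgene(cfg$refgene,
                                    cfg$refgene_source %||% "ucsc_refgene"))
    annot <- run_stage("call_gene", call_gene(hf, genes))
    write_tsv_table(annot, file.path(out_dir, "roh_region_genes.tsv"))
  }
  manifest <- write_manifest(out_dir)
  list(manifest = manifest, roh = roh, froh = fr, incidence = inc,
       high_freq = hf, annotation = annot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  config
}

# Output directories are unique per run unless overwrite is set, so results
# of different runs cannot collide.
prepare_out_dir <- function(cfg) {
  out_dir <- cfg$out_dir
  if (dir.exists(out_dir) && length(list.files(out_dir)) &&
      !isTRUE(cfg$overwrite)) {
    stop("output directory ", out_dir, " exists and is non-empty; ",
         "set overwrite: true to reuse it", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

# Wrap each stage so a failure aborts with the stage name while earlier
# outputs stay on disk.
stage_runner <- function(pipeline) {
  function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(pipeline, " aborted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
}

write_manifest <- function(out_dir) {
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.table(
    file = files,
    md5 = as.character(tools::md5sum(file.path(out_dir, files))))
  write_tsv_table(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
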