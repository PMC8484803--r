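# SNP-anchored coordinate conversion between assemblies.  Two maps from the
# same chip are reconciled by SNP name; interval coordinates are then lifted
# through the matched marker positions — no interpolation, only observed SNP
# target positions define the new span.

#' Reconcile two SNP maps by marker name
#'
#' Full outer join of a default-assembly and a target-assembly map on SNP
#' name.  Each entry is classified as `same_chr` (present in both, same
#' normalized chromosome), `chr_changed`, `missing_in_target`, or
#' `missing_in_default`.  Densities are reported per chromosome for both
#' maps.  Zero shared names means the maps are not from the same chip and is
#' a hard error.
#'
#' @param default_map,target_map SNP maps from [read_snp_map()]
#'   (`name, chr, pos`).
#' @return list of class `converted_map` with `map` (one row per name:
#'   `name, chr_default, pos_default, chr_target, pos_target, match_class,
#'   pos_shifted`), `summary` (counts per class plus `n_pos_shifted`), and
#'   `density_default` / `density_target` from [snp_density()].
#' @export
convert_map <- function(default_map, target_map) {
  assert_cols(default_map, c("name", "chr", "pos"), "default_map")
  assert_cols(target_map, c("name", "chr", "pos"), "target_map")
  d <- as.data.table(default_map)[, .(name, chr_default = normalize_chrom(chr),
                                      pos_default = pos)]
  t <- as.data.table(target_map)[, .(name, chr_target = normalize_chrom(chr),
                                     pos_target = pos)]
  if (!length(intersect(d$name, t$name))) {
    stop("no SNP names shared between the two maps; coordinates can only ",
         "be converted for maps from the same type of SNP chip",
         call. = FALSE)
  }
  m <- merge(d, t, by = "name", all = TRUE)
  m[, match_class := fifelse(is.na(chr_target), "missing_in_target",
                      fifelse(is.na(chr_default), "missing_in_default",
                       fifelse(chr_default == chr_target, "same_chr",
                               "chr_changed")))]
  m[, pos_shifted := match_class == "same_chr" & pos_default != pos_target]
  m <- m[order(chrom_rank(fifelse(is.na(chr_default), chr_target,
                                  chr_default)),
               fifelse(is.na(pos_default), pos_target, pos_default))]
  cls <- c("same_chr", "chr_changed", "missing_in_target",
           "missing_in_default")
  summary <- as.list(setNames(vapply(cls, function(k) sum(m$match_class == k),
                                     integer(1)), cls))
  summary$n_pos_shifted <- sum(m$pos_shifted, na.rm = TRUE)
  structure(list(map = m[],
                 summary = summary,
                 density_default = snp_density(default_map),
                 density_target = snp_density(target_map)),
            class = "converted_map")
}

#' Per-chromosome SNP density
#'
#' For each chromosome: marker count, spanned bp (max - min position), and
#' mean inter-marker gap `span / (n - 1)`.  Chromosomes with fewer than two
#' markers get an undefined mean gap and are flagged.
#'
#' @param map SNP map (`name, chr, pos`).
#' @return `data.table(chr, n_snps, span_bp, mean_gap_bp, degenerate)`.
#' @export
snp_density <- function(map) {
  assert_cols(map, c("name", "chr", "pos"))
  x <- as_dt(map)
  x[, chr := normalize_chrom(chr)]
  out <- x[, .(n_snps = .N, span_bp = max(pos) - min(pos)), by = chr]
  out[, mean_gap_bp := fifelse(n_snps >= 2L, span_bp / (n_snps - 1),
                               NA_real_)]
  out[, degenerate := n_snps < 2L]
  out[order(chrom_rank(chr))]
}

#' Lift interval coordinates through a reconciled SNP map
#'
#' For each interval, the SNPs whose default position falls inside it (and
#' that carry a target position) vote on the target chromosome; the
#' converted interval is the `[min, max]` span of the retained SNPs' target
#' positions.  An interval fails with `no_snps_in_interval` when it contains
#' no usable SNP, or with `snps_split_across_chromosomes` when more than
#' `minority_tol` of its SNPs map off the modal target chromosome (a smaller
#' minority is dropped and flagged).  Modal-chromosome ties are broken
#' toward the interval's own chromosome if it is among the modes, else
#' toward the lexicographically smallest.  `order_inverted` marks intervals
#' whose SNP order is not monotone between assemblies; `chrom_changed`
#' marks intervals whose modal target chromosome differs from the default.
#'
#' @param intervals table with `chr, start, end` (an `id` column is carried
#'   through, else built from coordinates).
#' @param converted_map output of [convert_map()].
#' @param minority_tol maximum tolerated fraction of in-interval SNPs
#'   mapping off the modal chromosome (default 0.1).
#' @return list with `result` (per interval: input coordinates, `status`
#'   (`converted` or the failure reason), `chr_target, start_target,
#'   end_target, n_snps_used, n_snps_dropped, length_default, length_target,
#'   length_delta, order_inverted, chrom_changed`; `length_default` is the
#'   default-assembly span of the retained SNPs, so `length_delta` measures
#'   what the assembly change did to the same markers) and `summary`
#'   (`n_input, n_converted, n_failed`, per-reason counts, and quartiles of
#'   `length_delta`).
#' @export
convert_coord <- function(intervals, converted_map, minority_tol = 0.1) {
  assert_cols(intervals, c("chr", "start", "end"))
  if (!inherits(converted_map, "converted_map")) {
    stop("converted_map must be the output of convert_map()", call. = FALSE)
  }
  cm <- converted_map$map[match_class %in% c("same_chr", "chr_changed") &
                            !is.na(pos_target)]
  if (nrow(cm) == 0L) {
    stop("converted map has no usable entries", call. = FALSE)
  }
  x <- as_dt(intervals)
  x[, chr := normalize_chrom(chr)]
  if (!"id" %in% names(x)) {
    x[, id := paste0(chr, ":", format(start, scientific = FALSE, trim = TRUE),
                     "-", format(end, scientific = FALSE, trim = TRUE))]
  }
  res <- lapply(seq_len(nrow(x)), function(i) {
    iv <- x[i]
    snps <- cm[chr_default == iv$chr & pos_default >= iv$start &
                 pos_default <= iv$end]
    base <- data.table(id = iv$id, chr = iv$chr, start = iv$start,
                       end = iv$end)
    if (nrow(snps) == 0L) {
      return(base[, `:=`(status = "no_snps_in_interval",
                         chr_target = NA_character_,
                         start_target = NA_real_, end_target = NA_real_,
                         n_snps_used = 0L, n_snps_dropped = 0L,
                         length_default = NA_real_,
                         length_target = NA_real_, length_delta = NA_real_,
                         order_inverted = NA, chrom_changed = NA)])
    }
    tab <- snps[, .N, by = chr_target]
    modes <- tab[N == max(N), chr_target]
    modal <- if (iv$chr %in% modes) iv$chr else sort(modes)[1]
    n_minor <- nrow(snps) - tab[chr_target == modal, N]
    if (n_minor / nrow(snps) > minority_tol) {
      return(base[, `:=`(status = "snps_split_across_chromosomes",
                         chr_target = NA_character_,
                         start_target = NA_real_, end_target = NA_real_,
                         n_snps_used = 0L, n_snps_dropped = nrow(snps),
                         length_default = NA_real_,
                         length_target = NA_real_, length_delta = NA_real_,
                         order_inverted = NA, chrom_changed = NA)])
    }
    keep <- snps[chr_target == modal][order(pos_default)]
    dtp <- diff(keep$pos_target)
    monotone <- all(dtp >= 0) || all(dtp <= 0)
    st <- min(keep$pos_target); en <- max(keep$pos_target)
    # default-side length is the span of the same retained SNPs, so the
    # length delta isolates what the assembly change did to the markers
    ld <- max(keep$pos_default) - min(keep$pos_default) + 1
    base[, `:=`(status = "converted", chr_target = modal,
                start_target = st, end_target = en,
                n_snps_used = nrow(keep), n_snps_dropped = n_minor,
                length_default = ld,
                length_target = en - st + 1,
                length_delta = (en - st + 1) - ld,
                order_inverted = !monotone,
                chrom_changed = modal != iv$chr)]
  })
  result <- rbindlist(res)
  conv <- result[status == "converted"]
  summary <- list(
    n_input = nrow(result),
    n_converted = nrow(conv),
    n_failed = nrow(result) - nrow(conv),
    failures = as.list(table(result$status[result$status != "converted"])),
    length_delta = if (nrow(conv)) {
      as.list(setNames(as.numeric(quantile(conv$length_delta,
                                           c(0, 0.25, 0.5, 0.75, 1))),
                       c("min", "q1", "median", "q3", "max")))
    } else NULL)
  list(result = result[], summary = summary)
}
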