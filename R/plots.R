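# Plot preparation and rendering are split: every figure is built from a
# plot_spec whose prepared tables are testable on their own, and the
# renderer consumes only those tables — it never recomputes anything.

#' Default copy-number colours (two reds for losses, two blues for gains)
#' @export
default_cn_colors <- c("0" = "#8B0000", "1" = "#E34234",
                       "3" = "#4169E1", "4" = "#00008B")

#' Default CNVR-type colours
#' @export
default_cnvr_colors <- c(Deletion = "#E34234", Duplication = "#4169E1",
                         Mixed = "#9932CC")

#' Prepare a regional track plot (CNVs or ROHs, optionally with genes)
#'
#' Clips the intervals falling in `region` to its bounds (clipped edges are
#' flagged `truncated`), and stacks them into display lanes with a
#' deterministic first-fit assignment over start-sorted intervals, so no two
#' intervals in a lane overlap.  A gene track is appended when a gene table
#' is given.
#'
#' @param intervals table with `chr, start, end` (plus `sample_id` and
#'   `cn` / `cnv_type` when available, used for labels and colours).
#' @param region numeric `c(chrom, start_mb, end_mb)` or list
#'   `(chrom, start_mb, end_mb)`; bounds in Mb, start < end.
#' @param genes optional gene table (`gene, chr, start, end`).
#' @param kind plot kind stored in the spec (`"cnv_region"` or
#'   `"roh_region"`).
#' @param colors named colour overrides.
#' @return object of class `plot_spec`.
#' @export
prepare_region_tracks <- function(intervals, region, genes = NULL,
                                  kind = c("cnv_region", "roh_region"),
                                  colors = default_cn_colors) {
  kind <- match.arg(kind)
  assert_cols(intervals, c("chr", "start", "end"))
  region <- as.list(region)
  chrom <- normalize_chrom(region[[1]])
  start_bp <- as.numeric(region[[2]]) * 1e6
  end_bp <- as.numeric(region[[3]]) * 1e6
  if (start_bp >= end_bp) stop("region start must be < end", call. = FALSE)
  x <- as_dt(intervals)
  x[, chr := normalize_chrom(chr)]
  x <- x[chr == chrom & start <= end_bp & end >= start_bp]
  if (nrow(x)) {
    x[, truncated := start < start_bp | end > end_bp]
    x[, `:=`(plot_start = pmax(start, start_bp),
             plot_end = pmin(end, end_bp))]
    setorderv(x, c("plot_start", "plot_end"))
    lane_end <- numeric(0)
    lane <- integer(nrow(x))
    for (i in seq_len(nrow(x))) {
      fit <- which(lane_end < x$plot_start[i])
      if (length(fit)) {
        lane[i] <- fit[1]
      } else {
        lane[i] <- length(lane_end) + 1L
      }
      lane_end[lane[i]] <- x$plot_end[i]
    }
    x[, lane := lane]
  } else {
    x[, `:=`(truncated = logical(), plot_start = numeric(),
             plot_end = numeric(), lane = integer())]
  }
  gtrack <- NULL
  if (!is.null(genes)) {
    assert_cols(genes, c("gene", "chr", "start", "end"))
    g <- as_dt(genes)
    g[, chr := normalize_chrom(chr)]
    gtrack <- g[chr == chrom & start <= end_bp & end >= start_bp]
    if (nrow(gtrack)) {
      gtrack[, `:=`(plot_start = pmax(start, start_bp),
                    plot_end = pmin(end, end_bp))]
    }
  }
  structure(list(kind = kind,
                 data = list(tracks = x[], genes = gtrack),
                 region = list(chr = chrom, start_bp = start_bp,
                               end_bp = end_bp),
                 style = list(colors = colors)),
            class = "plot_spec")
}

#' Prepare a genome-wide CNVR distribution map
#'
#' One ideogram-style lane per chromosome; CNVRs are drawn as glyphs
#' coloured by region type (Deletion/Duplication/Mixed).
#'
#' @param cnvr CNVR table from [call_cnvr()].
#' @param chrom_lengths named numeric vector chromosome -> length in bp;
#'   defaults to the maximum CNVR end per chromosome.
#' @param colors named colour overrides for the three region types.
#' @return object of class `plot_spec`.
#' @export
prepare_cnvr_map <- function(cnvr, chrom_lengths = NULL,
                             colors = default_cnvr_colors) {
  x <- as_dt(cnvr)
  if (nrow(x)) assert_cols(x, c("chr", "start", "end", "cnvr_type"))
  else x <- data.table(chr = character(), start = numeric(),
                       end = numeric(), cnvr_type = character())
  x[, chr := normalize_chrom(chr)]
  if (is.null(chrom_lengths)) {
    if (nrow(x)) {
      cl <- x[, .(len = max(end)), by = chr]
      chrom_lengths <- setNames(cl$len, cl$chr)
    } else chrom_lengths <- numeric(0)
  }
  chroms <- names(chrom_lengths)[order(chrom_rank(names(chrom_lengths)))]
  ideo <- data.table(chr = chroms,
                     length = as.numeric(chrom_lengths[chroms]),
                     lane = seq_along(chroms))
  x[, lane := ideo$lane[match(chr, ideo$chr)]]
  structure(list(kind = "cnvr_map",
                 data = list(glyphs = x[], ideogram = ideo),
                 region = NULL,
                 style = list(colors = colors)),
            class = "plot_spec")
}

#' @export
print.plot_spec <- function(x, ...) {
  n <- if (!is.null(x$data$tracks)) nrow(x$data$tracks)
       else nrow(x$data$glyphs)
  cat("plot_spec <", x$kind, ">: ", n, " glyph(s)\n", sep = "")
  invisible(x)
}

#' Render a plot specification
#'
#' Builds a ggplot from the prepared tables of a `plot_spec` and optionally
#' writes it to file (format chosen by extension: png/jpeg/pdf/svg).  The
#' renderer reads only the spec; identical specs yield identical plots.
#'
#' @param spec a `plot_spec`.
#' @param path optional output path for [ggplot2::ggsave()].
#' @param width,height,dpi device settings passed to `ggsave`.
#' @return the ggplot object, invisibly.
#' @export
render_plotspec <- function(spec, path = NULL, width = 9, height = 5,
                            dpi = 300) {
  if (!inherits(spec, "plot_spec")) stop("not a plot_spec", call. = FALSE)
  p <- switch(spec$kind,
              cnv_region = ,
              roh_region = render_region(spec),
              cnvr_map = render_cnvr_map(spec),
              stop("unknown plot kind: ", spec$kind, call. = FALSE))
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  }
  invisible(p)
}

render_region <- function(spec) {
  tr <- spec$data$tracks
  p <- ggplot2::ggplot()
  if (nrow(tr)) {
    fill_col <- if ("cn" %in% names(tr)) factor(tr$cn) else "interval"
    p <- p + ggplot2::geom_rect(
      data = data.frame(tr, .fill = fill_col),
      ggplot2::aes(xmin = plot_start / 1e6, xmax = plot_end / 1e6,
                   ymin = lane - 0.4, ymax = lane + 0.4, fill = .fill))
    if ("cn" %in% names(tr)) {
      p <- p + ggplot2::scale_fill_manual(values = spec$style$colors,
                                          name = "copy number")
    } else {
      p <- p + ggplot2::guides(fill = "none")
    }
  }
  g <- spec$data$genes
  if (!is.null(g) && nrow(g)) {
    p <- p + ggplot2::geom_segment(
      data = g,
      ggplot2::aes(x = plot_start / 1e6, xend = plot_end / 1e6,
                   y = -1, yend = -1),
      linewidth = 3, colour = "darkgreen") +
      ggplot2::geom_text(
        data = g,
        ggplot2::aes(x = (plot_start + plot_end) / 2e6, y = -1.8,
                     label = gene), size = 2.5)
  }
  p + ggplot2::labs(
    x = paste0("chr", spec$region$chr, " position (Mb)"), y = "track") +
    ggplot2::coord_cartesian(xlim = c(spec$region$start_bp,
                                      spec$region$end_bp) / 1e6) +
    ggplot2::theme_minimal()
}

render_cnvr_map <- function(spec) {
  ideo <- spec$data$ideogram
  gl <- spec$data$glyphs
  p <- ggplot2::ggplot()
  if (nrow(ideo)) {
    p <- p + ggplot2::geom_segment(
      data = ideo,
      ggplot2::aes(x = 0, xend = length / 1e6, y = lane, yend = lane),
      colour = "grey70", linewidth = 1)
  }
  if (nrow(gl)) {
    p <- p + ggplot2::geom_rect(
      data = gl,
      ggplot2::aes(xmin = start / 1e6, xmax = end / 1e6,
                   ymin = lane - 0.35, ymax = lane + 0.35,
                   fill = cnvr_type)) +
      ggplot2::scale_fill_manual(values = spec$style$colors,
                                 name = "CNVR type")
  }
  p + ggplot2::scale_y_continuous(breaks = ideo$lane, labels = ideo$chr) +
    ggplot2::labs(x = "position (Mb)", y = "chromosome") +
    ggplot2::theme_minimal()
}
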