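# The five diagnostic plots. Every plot writes its underlying numbers as a
# TSV sibling (same path, .tsv extension) so figures can be regenerated,
# and tests assert on numbers, never on pixels.

open_device <- function(path, format = c("png", "svg"), width = 7,
                        height = 5) {
  format <- match.arg(format)
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 120)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
}

tsv_sibling <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".tsv")
}

#' Scaffold length barplot
#'
#' One bar per scaffold, sorted from shortest to longest; `scale = "log"`
#' plots log10 lengths.
#'
#' @param assembly An `assembly` (non-empty).
#' @param path Output image path.
#' @param scale `"linear"` or `"log"`.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, the exported data.frame (scaffold, length, plotted
#'   value), also written to the TSV sibling of `path`.
#' @export
plot_scaffold_lengths <- function(assembly, path, scale = c("linear", "log"),
                                  format = c("png", "svg")) {
  if (!length(assembly$ids)) stop2("empty assembly")
  scale <- match.arg(scale)
  ord <- order(assembly$lengths)
  df <- data.frame(scaffold = assembly$ids[ord],
                   length = as.numeric(assembly$lengths[ord]),
                   stringsAsFactors = FALSE)
  df$value <- if (scale == "log") log10(df$length) else df$length
  open_device(path, format)
  graphics::barplot(df$value, names.arg = NA, border = NA,
                    xlab = "scaffolds (sorted by length)",
                    ylab = if (scale == "log") "log10 length (bp)"
                           else "length (bp)",
                    main = "scaffold length distribution")
  grDevices::dev.off()
  write_commented_tsv(df, tsv_sibling(path))
  invisible(df)
}

#' Scaffold length vs coverage scatterplot
#'
#' One point per scaffold; optional cluster labels (e.g. from
#' [coverage_bimodality_check()]) color the points and are exported.
#'
#' @param summaries Output of [scaffold_summaries()] (non-empty).
#' @param path Output image path.
#' @param cluster Optional integer vector of per-scaffold cluster labels.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, the exported data.frame.
#' @export
plot_length_vs_coverage <- function(summaries, path, cluster = NULL,
                                    format = c("png", "svg")) {
  if (!nrow(summaries)) stop2("empty scaffold summaries")
  df <- data.frame(scaffold = summaries$scaffold,
                   length = summaries$length,
                   mean_depth = summaries$mean_depth,
                   cluster = if (is.null(cluster)) NA_integer_ else cluster,
                   stringsAsFactors = FALSE)
  open_device(path, format)
  col <- if (is.null(cluster)) "grey30" else
    c("grey30", "firebrick", "steelblue")[pmin(ifelse(is.na(cluster), 1L,
                                                      cluster), 3L)]
  graphics::plot(df$length, df$mean_depth, log = "x", pch = 19, cex = 0.6,
                 col = col, xlab = "scaffold length (bp)",
                 ylab = "mean coverage (x)",
                 main = "scaffold length vs coverage")
  grDevices::dev.off()
  write_commented_tsv(df, tsv_sibling(path))
  invisible(df)
}

# 2-D Scott-rule bandwidths: sd * n^(-1/6) per axis
scott_bandwidth <- function(x, y) {
  n <- length(x)
  c(max(stats::sd(x), 1e-6), max(stats::sd(y), 1e-6)) * n^(-1 / 6)
}

#' Variation vs coverage density plot
#'
#' Kernel density estimate over the cloud of per-window (SNP count, mean
#' coverage) dots, with the dots overplotted. More than one density mode
#' indicates dual genome behavior (aneuploidy, loss of heterozygosity,
#' mixed ploidy).
#'
#' @param windows Windows with statistics (>= 10 required).
#' @param path Output image path.
#' @param grid_n Grid resolution per axis (default 50).
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, a list with `points` (the dots) and `density` (long
#'   data.frame x, y, z of the KDE grid, exported as the TSV sibling; the
#'   grid integrates to 1).
#' @export
plot_variation_vs_coverage <- function(windows, path, grid_n = 50L,
                                       format = c("png", "svg")) {
  use <- is.finite(windows$mean_depth)
  if (sum(use) < 10L) stop2("need at least 10 windows")
  x <- windows$snp_count[use]
  y <- windows$mean_depth[use]
  # KDE needs spread on both axes; jitter-free fallback widens bandwidth
  h <- pmax(scott_bandwidth(x, y) * 2.5, 1e-3)  # kde2d full widths (~4 sd)
  # extend the grid one full bandwidth beyond the data so boundary modes
  # sit in the interior and the evaluated mass reaches ~1
  lims <- c(range(x) + c(-1, 1) * h[1], range(y) + c(-1, 1) * h[2])
  dens <- MASS::kde2d(x, y, h = h, n = grid_n, lims = lims)
  long <- data.frame(x = rep(dens$x, times = grid_n),
                     y = rep(dens$y, each = grid_n),
                     z = as.vector(dens$z))
  open_device(path, format)
  graphics::image(dens, col = grDevices::hcl.colors(30, "YlOrRd",
                                                    rev = TRUE),
                  xlab = "SNPs per window", ylab = "mean coverage (x)",
                  main = "variation vs coverage")
  graphics::points(x, y, pch = 19, cex = 0.3,
                   col = grDevices::adjustcolor("black", 0.3))
  grDevices::dev.off()
  write_commented_tsv(long, tsv_sibling(path))
  invisible(list(points = data.frame(snp_count = x, mean_depth = y),
                 density = dens, density_long = long))
}

#' Fair coin plot
#'
#' Genome-wide empirical allele-balance curve, per-scaffold curves, and
#' the simulated ideal-diploid expectation, with vertical reference lines
#' at the ideal balances 0.25, 1/3, 0.5 (and mirrored 2/3, 0.75).
#'
#' @param scan Output of [fair_coin_scan()] (genome result required).
#' @param path Output image path.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, a list with the exported curve table and the
#'   reference line positions.
#' @export
plot_fair_coin <- function(scan, path, format = c("png", "svg")) {
  g <- scan$genome
  if (is.null(g)) stop2("genome-scope fair-coin result required")
  ref_lines <- c(0.25, 1 / 3, 0.5, 2 / 3, 0.75)
  curves <- data.frame(scope = "genome", fraction = g$bin_mid,
                       density = g$empirical_hist,
                       stringsAsFactors = FALSE)
  curves <- rbind(curves,
                  data.frame(scope = "simulated", fraction = g$bin_mid,
                             density = g$simulated_hist,
                             stringsAsFactors = FALSE))
  for (sc in names(scan$per_scaffold)) {
    r <- scan$per_scaffold[[sc]]
    curves <- rbind(curves, data.frame(scope = sc, fraction = r$bin_mid,
                                       density = r$empirical_hist,
                                       stringsAsFactors = FALSE))
  }
  open_device(path, format)
  graphics::plot(g$bin_mid, g$empirical_hist, type = "n",
                 ylim = c(0, max(curves$density)),
                 xlab = "alternative allele fraction", ylab = "density",
                 main = "fair coin (allele balance)")
  graphics::abline(v = ref_lines, col = "grey70", lty = 3)
  for (sc in names(scan$per_scaffold)) {
    r <- scan$per_scaffold[[sc]]
    graphics::lines(r$bin_mid, r$empirical_hist,
                    col = grDevices::adjustcolor("steelblue", 0.4))
  }
  graphics::lines(g$bin_mid, g$simulated_hist, col = "red", lwd = 2)
  graphics::lines(g$bin_mid, g$empirical_hist, col = "black", lwd = 2)
  grDevices::dev.off()
  write_commented_tsv(curves, tsv_sibling(path))
  invisible(list(curves = curves, ref_lines = ref_lines))
}

#' Per-scaffold ploidy panel plot
#'
#' Five stacked panels for one scaffold: per-window diploid, triploid and
#' tetraploid support scores (missing windows blank), SNP positions along
#' the scaffold, and SNP coverages colored by local SNP density.
#'
#' @param scores A `ploidy_windows` data.frame.
#' @param variants A `variant_table`.
#' @param scaffold Scaffold id to plot.
#' @param path Output image path.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, the exported per-window score table for the
#'   scaffold.
#' @export
plot_ploidy_per_scaffold <- function(scores, variants, scaffold, path,
                                     format = c("png", "svg")) {
  s <- scores[scores$scaffold == scaffold, , drop = FALSE]
  if (!nrow(s)) stop2("no ploidy scores for scaffold ", scaffold)
  rec <- variants$records[variants$records$scaffold == scaffold, ,
                          drop = FALSE]
  len <- max(s$end)
  open_device(path, format, width = 7, height = 8)
  on.exit(grDevices::dev.off())  # par state dies with the device
  graphics::par(mfrow = c(5, 1), mar = c(2, 4, 1.5, 1))
  mids <- (s$start + s$end) / 2
  for (h in c("diploid", "triploid", "tetraploid")) {
    v <- s[[paste0("score_", h)]]
    graphics::plot(mids, v, type = "h", ylim = c(0, 1), xlim = c(0, len),
                   xlab = "", ylab = paste(h, "score"), lwd = 2,
                   col = "grey25")
  }
  graphics::plot(rec$pos0, rep(1, nrow(rec)), pch = "|", xlim = c(0, len),
                 ylim = c(0, 2), yaxt = "n", xlab = "",
                 ylab = "SNP positions")
  tot <- rec$ref_depth + rec$alt_depth
  col <- "grey40"
  if (nrow(rec) >= 2L) {
    d <- stats::density(rec$pos0, from = 0, to = len, n = 256)
    local_d <- stats::approx(d$x, d$y, xout = rec$pos0)$y
    pal <- grDevices::hcl.colors(20, "YlOrRd", rev = TRUE)
    col <- pal[pmin(20L, 1L + as.integer(19 * (local_d - min(local_d)) /
                                           max(1e-12, diff(range(local_d)))))]
  }
  graphics::plot(rec$pos0, tot, pch = 19, cex = 0.5, col = col,
                 xlim = c(0, len), ylim = c(0, max(tot, 1)),
                 xlab = "position (bp)", ylab = "SNP coverage")
  write_commented_tsv(as.data.frame(s), tsv_sibling(path))
  invisible(s)
}
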