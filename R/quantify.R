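#' Classify vessel segments by diameter
#'
#' Caliber classes as used for renal vasculature: small (d < 0.02 mm),
#' medium (0.02 mm <= d < 0.1 mm) and large (0.1 mm <= d); boundaries are
#' closed on the upper class.
#'
#' @param d_mm vessel diameters in millimeters (>= 0), vectorized.
#' @return factor with levels `small`, `medium`, `large`.
#' @export
classify_by_diameter <- function(d_mm) {
  if (any(d_mm < 0)) stop("diameter must be non-negative")
  cut(d_mm, breaks = c(-Inf, 0.02, 0.1, Inf), right = FALSE,
      labels = c("small", "medium", "large"))
}

#' Frequency distribution of vessel diameters
#'
#' Left-closed, right-open bins of fixed width starting at 0 (default
#' 2 micrometers); counts sum to the number of segments.
#'
#' @param g a `vessel_graph`, or a numeric vector of diameters in
#'   micrometers.
#' @param bin_width_um bin width in micrometers (> 0).
#' @return list with `breaks_um` (bin edges) and `counts`.
#' @export
diameter_histogram <- function(g, bin_width_um = 2) {
  if (bin_width_um <= 0) stop("bin width must be positive")
  d <- if (inherits(g, "vessel_graph"))
    vapply(g$segments, `[[`, numeric(1), "avg_diameter_um") else as.numeric(g)
  if (length(d) == 0)
    return(list(breaks_um = numeric(0), counts = integer(0)))
  nbin <- floor(max(d) / bin_width_um) + 1L
  breaks <- seq(0, nbin * bin_width_um, by = bin_width_um)
  idx <- pmin(floor(d / bin_width_um) + 1L, nbin)
  list(breaks_um = breaks, counts = tabulate(idx, nbins = nbin))
}

five_num <- function(x) {
  if (length(x) == 0)
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                whisker_lo = NA_real_, whisker_hi = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = max(min(x), q[1] - 1.5 * iqr),
       whisker_hi = min(max(x), q[3] + 1.5 * iqr))
}

#' Morphometric summary of a pruned vessel graph
#'
#' Computes the quantitative read-outs of the vessel analysis: the
#' diameter frequency distribution, segment caliber classes with per-class
#' length and straightness distributions (median, quartiles, 1.5 IQR
#' whiskers), and global totals — total vessel length, total vessel volume
#' from the centerline frustum quadrature, and optionally the organ volume
#' from a binary organ mask.
#'
#' @param g a pruned `vessel_graph`.
#' @param organ_mask optional logical array of the whole organ.
#' @param spacing voxel spacing of `organ_mask`, micrometers.
#' @param bin_width_um histogram bin width.
#' @return a `quant_report` list: `segments` (table with class column),
#'   `histogram`, `by_class`, `totals`.
#' @export
summarize_graph <- function(g, organ_mask = NULL, spacing = g$spacing,
                            bin_width_um = 2) {
  st <- segment_table(g)
  st$class <- classify_by_diameter(st$avg_diameter_um / 1000)
  by_class <- lapply(split(st, st$class), function(df)
    list(length_um = five_num(df$length_um),
         straightness = five_num(df$straightness)))
  totals <- list(
    n_segments = nrow(st),
    n_nodes = nrow(g$nodes),
    total_length_mm = sum(st$length_um) / 1e3,
    total_vessel_volume_mm3 = sum(st$volume_um3) / 1e9)
  if (!is.null(organ_mask)) {
    totals$organ_volume_mm3 <- sum(organ_mask) * prod(spacing) / 1e9
    totals$vessel_volume_fraction <-
      totals$total_vessel_volume_mm3 / totals$organ_volume_mm3
  }
  structure(list(segments = st,
                 histogram = diameter_histogram(st$avg_diameter_um, bin_width_um),
                 by_class = by_class, totals = totals),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<quant_report> %d segments, total length %.3f mm, vessel volume %.6f mm^3\n",
              t$n_segments, t$total_length_mm, t$total_vessel_volume_mm3))
  if (!is.null(t$organ_volume_mm3))
    cat(sprintf("  organ volume %.3f mm^3 (vessel fraction %.4f)\n",
                t$organ_volume_mm3, t$vessel_volume_fraction))
  cls <- table(x$segments$class)
  cat(sprintf("  classes: small %d, medium %d, large %d\n",
              cls["small"], cls["medium"], cls["large"]))
  invisible(x)
}

#' Write a morphometry report as JSON
#'
#' @param report a `quant_report` from [summarize_graph()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(totals = report$totals,
              class_counts = as.list(table(report$segments$class)),
              histogram = report$histogram,
              by_class = report$by_class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Plot the diameter histogram and per-class boxplots
#'
#' Reproduces the standard presentation of the vessel morphometry: the
#' diameter frequency distribution and box-and-whisker plots (median,
#' quartiles, 1.5 IQR whiskers) of segment length and straightness per
#' caliber class. Requires ggplot2.
#'
#' @param report a `quant_report`.
#' @return list of ggplot objects `histogram`, `length`, `straightness`.
#' @export
plot_quant <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_quant requires the ggplot2 package")
  st <- report$segments
  h <- report$histogram
  hdf <- data.frame(mid = h$breaks_um[-length(h$breaks_um)] +
                      diff(h$breaks_um) / 2, count = h$counts)
  list(
    histogram = ggplot2::ggplot(hdf, ggplot2::aes(x = mid, y = count)) +
      ggplot2::geom_col(width = diff(h$breaks_um)[1] * 0.9) +
      ggplot2::labs(x = "vessel diameter (um)", y = "frequency"),
    length = ggplot2::ggplot(st, ggplot2::aes(x = class,
                                              y = length_um / 1e3)) +
      ggplot2::geom_boxplot(coef = 1.5, outlier.shape = NA) +
      ggplot2::labs(x = NULL, y = "vessel length (mm)"),
    straightness = ggplot2::ggplot(st, ggplot2::aes(x = class,
                                                    y = straightness)) +
      ggplot2::geom_boxplot(coef = 1.5, outlier.shape = NA) +
      ggplot2::labs(x = NULL, y = "straightness"))
}
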