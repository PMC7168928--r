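# Computational counterparts of the study figures: band-filter images,
# 1-sigma biomarker ellipses, score histograms and error-vs-N curves.

#' Band-filter pseudo-color image of a map
#'
#' Per-pixel integrated (locally baseline-subtracted) band area over one
#' window -- the raw intensity filter used for pseudo-color tissue images --
#' rescaled to \[0, 1\] per image by default.  A degenerate (constant) image
#' rescales to all zeros.  The input map is never modified.
#'
#' @param map A [spectral_map()].
#' @param window A [band_window()].
#' @param normalize Divide each pixel by its reference intensity first
#'   (default `TRUE`).
#' @param rescale Min-max rescale to \[0, 1\] (default `TRUE`).
#' @inheritParams band_area
#' @return An `height x width` numeric matrix.
#' @export
band_filter_image <- function(map, window, normalize = TRUE,
                              rescale = TRUE, edge_points = 5,
                              clamp = TRUE) {
  stopifnot(inherits(map, "spectral_map"), inherits(window, "band_window"))
  Y <- map$intensities
  if (normalize) Y <- Y / map$reference_intensities
  area <- band_area_matrix(Y, map$wavenumbers, window, edge_points, clamp)
  img <- matrix(area, map$height, map$width, byrow = TRUE)
  if (rescale) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
           else matrix(0, map$height, map$width)
  }
  img
}

#' One-sigma covariance ellipse of a biomarker scatter
#'
#' Sample mean and covariance of a bivariate cloud, summarized as the
#' 1-sigma ellipse: semi-axes are the square roots of the covariance
#' eigenvalues and the orientation follows the leading eigenvector.  For
#' bivariate normal data the ellipse contains about `1 - exp(-1/2)` (39.3%)
#' of the points.
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @return An object of class `ellipse_summary`: `mean` (2-vector),
#'   `covariance` (2 x 2), `axes` (semi-axis lengths, descending) and
#'   `angle` (degrees, leading axis from the x-axis).
#' @export
one_sigma_ellipse <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 paired points", call. = FALSE)
  X <- cbind(x = x, y = y)
  mu <- colMeans(X)
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (min(vals) <= .Machine$double.eps * max(vals, 1))
    warning("degenerate covariance: ellipse collapses to a zero-width axis",
            call. = FALSE)
  structure(
    list(mean = mu, covariance = S, axes = sqrt(vals),
         angle = atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi),
    class = "ellipse_summary")
}

#' Points on a 1-sigma ellipse outline
#'
#' @param ellipse An [one_sigma_ellipse()] result.
#' @param n Number of outline points.
#' @return A data frame with columns `x`, `y`.
#' @export
ellipse_points <- function(ellipse, n = 100) {
  stopifnot(inherits(ellipse, "ellipse_summary"))
  t <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$angle * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  P <- R %*% rbind(ellipse$axes[1] * cos(t), ellipse$axes[2] * sin(t))
  data.frame(x = ellipse$mean[1] + P[1, ], y = ellipse$mean[2] + P[2, ])
}

#' Whether points fall inside a 1-sigma ellipse
#'
#' Mahalanobis containment test: a point lies inside the 1-sigma contour
#' when its squared Mahalanobis distance from the mean is below 1.
#'
#' @param ellipse An [one_sigma_ellipse()] result.
#' @param x,y Numeric vectors of points.
#' @return Logical vector.
#' @export
in_ellipse <- function(ellipse, x, y) {
  stopifnot(inherits(ellipse, "ellipse_summary"))
  d <- cbind(x - ellipse$mean[1], y - ellipse$mean[2])
  m <- rowSums((d %*% solve(ellipse$covariance)) * d)
  m < 1
}

#' Per-class score histograms with an overlap coefficient
#'
#' Normalized class-conditional histograms of the classification scores on
#' a common log-score axis (so the decision threshold 1 maps to 0), plus
#' the histogram overlap coefficient -- 0 for perfectly separated classes,
#' ~1 for indistinguishable ones.  Infinite log scores (saturated odds) are
#' clipped to the finite range.
#'
#' @param scored A `scored_spectra` data frame (`true_class`, `score`).
#' @param bins Number of histogram bins (default 100).
#' @return A list of class `score_histogram`: `breaks` (log-score),
#'   `density_normal`, `density_rod`, `overlap`.
#' @export
score_histogram <- function(scored, bins = 100) {
  if (!all(c("true_class", "score") %in% names(scored)))
    stop("`scored` needs `true_class` and `score` columns", call. = FALSE)
  ls <- log(pmax(scored$score, .Machine$double.xmin))
  fin <- is.finite(ls)
  if (!any(fin)) stop("no finite scores", call. = FALSE)
  rng <- range(ls[fin])
  ls <- pmin(pmax(ls, rng[1]), rng[2])
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  bw <- diff(breaks)[1]
  dens <- function(v) {
    if (!length(v)) return(numeric(bins))
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h$density
  }
  d_n <- dens(ls[scored$true_class == "normal"])
  d_r <- dens(ls[scored$true_class == "rod"])
  structure(
    list(breaks = breaks, density_normal = d_n, density_rod = d_r,
         overlap = sum(pmin(d_n, d_r)) * bw),
    class = "score_histogram")
}

#' Plot a band-filter image
#'
#' @param image Matrix from [band_filter_image()].
#' @param title Plot title.
#' @return A ggplot object (yellow-on-dark pseudo-color).
#' @export
plot_band_image <- function(image, title = "band-filter image") {
  df <- expand.grid(col = seq_len(ncol(image)), row = seq_len(nrow(image)))
  df$value <- as.vector(t(image))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#1a1a2e", high = "#ffd700") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "area") +
    ggplot2::theme_minimal()
}

#' Biomarker scatter with per-sample 1-sigma ellipses
#'
#' @param features Biomarker feature table ([biomarker_table()]).
#' @param xvar,yvar Names of the two biomarker columns to plot.
#' @param ellipses Draw per-sample 1-sigma ellipses and mean points.
#' @param max_points Per-sample cap on plotted raw points (plots stay
#'   readable for full maps); `Inf` plots all.
#' @return A ggplot object.
#' @export
plot_biomarker_scatter <- function(features, xvar = "mineral_to_matrix",
                                   yvar = "carbonate_to_matrix",
                                   ellipses = TRUE, max_points = 2000) {
  f <- features[features$valid & is.finite(features[[xvar]]) &
                  is.finite(features[[yvar]]), ]
  shown <- do.call(rbind, lapply(split(f, f$sample_id), function(g)
    if (nrow(g) > max_points) g[seq_len(max_points), ] else g))
  p <- ggplot2::ggplot(shown,
                       ggplot2::aes(x = .data[[xvar]], y = .data[[yvar]],
                                    colour = .data$sample_id)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.4,
                        ggplot2::aes(shape = .data$class)) +
    ggplot2::labs(x = xvar, y = yvar) +
    ggplot2::theme_minimal()
  if (ellipses) {
    for (sid in unique(f$sample_id)) {
      g <- f[f$sample_id == sid, ]
      if (nrow(g) < 3L) next
      el <- one_sigma_ellipse(g[[xvar]], g[[yvar]])
      ep <- ellipse_points(el)
      ep$sample_id <- sid
      p <- p +
        ggplot2::geom_path(data = ep,
                           ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$sample_id),
                           inherit.aes = FALSE, linewidth = 0.7) +
        ggplot2::annotate("point", x = el$mean[1], y = el$mean[2],
                          size = 2)
    }
  }
  p
}

#' Plot per-class score histograms
#'
#' @param hist A [score_histogram()] result.
#' @return A ggplot object with the threshold marked at log-score 0.
#' @export
plot_score_histogram <- function(hist) {
  stopifnot(inherits(hist, "score_histogram"))
  mids <- (utils::head(hist$breaks, -1) + utils::tail(hist$breaks, -1)) / 2
  df <- data.frame(
    log_score = rep(mids, 2),
    density = c(hist$density_normal, hist$density_rod),
    class = rep(c("normal", "rod"), each = length(mids)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_score, y = .data$density,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5, width = diff(hist$breaks)[1]) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "log(score)  [threshold at 0]", y = "density",
                  subtitle = sprintf("overlap coefficient %.3f",
                                     hist$overlap)) +
    ggplot2::theme_minimal()
}

#' Plot Type I / Type II error curves versus N
#'
#' @param curves Data frame from [error_curves()].
#' @param alpha Optional target error probability drawn as a reference line.
#' @return A ggplot object (log-scaled error axis).
#' @export
plot_error_curves <- function(curves, alpha = 0.05) {
  df <- data.frame(
    N = rep(curves$N, 2),
    error = c(curves$q1, curves$q2),
    type = rep(c("Type I (normal called ROD)", "Type II (ROD called normal)"),
               each = nrow(curves)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$N, y = .data$error,
                                        colour = .data$type)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of independent spectra N",
                  y = "error probability") +
    ggplot2::theme_minimal()
  if (!is.null(alpha))
    p <- p + ggplot2::geom_hline(yintercept = alpha, linetype = 2)
  p
}
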