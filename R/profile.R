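# Radial intensity profiling: per-cell statistics regressed against distance
# from the colony edge with locally weighted (tricube, local-linear)
# smoothing, evaluated on a fixed interspaced grid so profiles from colonies
# with different cell positions can be averaged pointwise.

#' Radial marker profile of one colony
#'
#' Locally weighted regression (tricube-weighted local-linear fit, the
#' lowess family) of a per-cell intensity statistic against distance from
#' the colony edge, evaluated on a fixed grid. The fixed grid makes
#' profiles comparable across colonies whose cells sit at different
#' positions.
#'
#' @param cells cell table with `edge_distance` and intensity columns
#'   (from [sample_cell_intensities()] + [edge_distances()]).
#' @param channel marker channel name.
#' @param statistic `"nuclear"`, `"cytoplasmic"` or `"nuc_cyt_ratio"`.
#' @param span smoothing span in (0, 1] (fraction of cells in each local
#'   fit).
#' @param grid_step grid spacing in µm.
#' @param grid_max last grid point (µm); defaults to the maximum observed
#'   edge distance.
#' @param min_cells fewer cells than this is an error.
#' @param drop_flagged exclude border-clipped and outside-colony cells.
#' @return data.frame of class `radial_profile` with columns `distance`,
#'   `mean`, `sem`, `n` (cells within a half-span window of each grid
#'   point), plus attributes `channel`, `statistic`, `span`.
#' @export
profile_colony <- function(cells, channel,
                           statistic = c("nuclear", "cytoplasmic",
                                         "nuc_cyt_ratio"),
                           span = 0.3, grid_step = 5, grid_max = NULL,
                           min_cells = 10L, drop_flagged = TRUE) {
  statistic <- match.arg(statistic)
  if (span <= 0 || span > 1) stopf("span must be in (0, 1]")
  col <- switch(statistic, nuclear = paste0("Nuc_", channel),
                cytoplasmic = paste0("Cyt_", channel),
                nuc_cyt_ratio = paste0("ratio_", channel))
  if (!col %in% names(cells)) stopf("column '%s' not found in cells", col)
  if (drop_flagged) {
    drop <- (!is.na(cells$clipped) & cells$clipped)
    if (!is.null(cells$outside)) drop <- drop | cells$outside
    cells <- cells[!drop, , drop = FALSE]
  }
  d <- cells$edge_distance
  y <- cells[[col]]
  keep <- is.finite(d) & is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (length(d) < min_cells)
    stopf("only %d usable cells (need >= %d) for profiling", length(d),
          min_cells)
  grid <- seq(0, grid_max %||% max(d), by = grid_step)
  fit <- stats::loess(y ~ d, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, data.frame(d = grid), se = TRUE)
  half_window <- span * diff(range(d)) / 2
  n <- vapply(grid, function(g) sum(abs(d - g) <= half_window), integer(1L))
  out <- data.frame(distance = grid, mean = as.numeric(pr$fit),
                    sem = ifelse(n >= 2, as.numeric(pr$se.fit), NA_real_),
                    n = n)
  structure(out, class = c("radial_profile", "data.frame"),
            channel = channel, statistic = statistic, span = span)
}

#' Pool radial profiles across replicate colonies
#'
#' Pointwise mean and standard error across colonies sharing the same grid
#' and statistic.
#'
#' @param profiles list of [profile_colony()] results.
#' @return `radial_profile` data.frame; `n` is the colony count per point.
#' @export
pool_profiles <- function(profiles) {
  if (!length(profiles)) stopf("no profiles to pool")
  g0 <- profiles[[1L]]$distance
  st0 <- attr(profiles[[1L]], "statistic")
  for (p in profiles[-1L]) {
    if (!isTRUE(all.equal(p$distance, g0)))
      stopf("profiles have mixed grids; re-profile with a common grid_max")
    if (!identical(attr(p, "statistic"), st0))
      stopf("profiles mix statistics (%s vs %s)", attr(p, "statistic"), st0)
  }
  mat <- vapply(profiles, function(p) p$mean, numeric(length(g0)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(g0))
  mu <- rowMeans(mat)
  k <- ncol(mat)
  se <- if (k >= 2) apply(mat, 1L, stats::sd) / sqrt(k)
        else rep(NA_real_, length(g0))
  structure(data.frame(distance = g0, mean = mu, sem = se, n = k),
            class = c("radial_profile", "data.frame"),
            channel = attr(profiles[[1L]], "channel"), statistic = st0,
            span = attr(profiles[[1L]], "span"))
}

#' Intensity profile along a line segment
#'
#' Mean intensity in a band of the given width along the segment, sampled
#' every `step_px` pixels, for each channel; the cross-section analogue of
#' drawing a line profile across a tissue image.
#'
#' @param image an [image_stack()].
#' @param p1,p2 segment endpoints in µm, `c(x, y)`.
#' @param width_px band width in pixels (odd values center the band).
#' @param step_px sampling step along the segment, in pixels.
#' @return data.frame: `distance` (µm along the segment) plus one column per
#'   channel.
#' @export
line_profile <- function(image, p1, p2, width_px = 1L, step_px = 1L) {
  stopifnot(inherits(image, "image_stack"))
  px <- image$pixel_size
  L <- sqrt(sum((p2 - p1)^2))
  if (L <= 0) stopf("degenerate (zero-length) segment")
  u <- (p2 - p1) / L                    # along
  v <- c(-u[2L], u[1L])                 # across
  s <- seq(0, L, by = step_px * px)
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * px
  H <- dim(image)[1L]; W <- dim(image)[2L]
  out <- data.frame(distance = s)
  for (ch in channel_names(image)) {
    m <- get_channel(image, ch)
    vals <- vapply(s, function(si) {
      xs <- p1[1L] + si * u[1L] + offs * v[1L]
      ys <- p1[2L] + si * u[2L] + offs * v[2L]
      mean(bilinear_sample(m, xs / px, ys / px))
    }, numeric(1L))
    out[[ch]] <- vals
  }
  out
}

# Bilinear interpolation at continuous pixel coordinates (0-based, pixel
# centers at integer + 0.5). Out-of-bounds samples clamp to the border.
bilinear_sample <- function(m, xpx, ypx) {
  H <- nrow(m); W <- ncol(m)
  gx <- pmin(pmax(xpx - 0.5, 0), W - 1)
  gy <- pmin(pmax(ypx - 0.5, 0), H - 1)
  x0 <- floor(gx); y0 <- floor(gy)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- gx - x0; fy <- gy - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}
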