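# Per-cell quantification: colony geometry, fixed-radius nuclear disk and
# dilated-annulus cytosolic sampling, distance-from-periphery assignment,
# and marker-ratio fate classification.

#' Detect the colony outline from the nuclei channel
#'
#' The colony mask is the filled largest connected component of the
#' smoothed, thresholded nuclei-channel foreground (smoothing merges the
#' punctate nuclei into one blob); the boundary polygon is traced from the
#' lightly re-smoothed mask at subpixel contour level 0.5.
#'
#' @param image an [image_stack()].
#' @param nuclei_channel channel used for detection.
#' @param smooth_sigma_um Gaussian smoothing sigma (µm) merging the punctate
#'   nuclei signal into a plateau over the colony; about the nucleus spacing.
#' @details Smoothing at the nucleus-spacing scale turns the dotted nuclei
#'   signal into an approximately uniform plateau over the colony. The mask
#'   threshold is the midpoint between the background level (median over a
#'   border frame of the image) and the interior plateau (median over the
#'   eroded foreground, away from the edge ramp): for a blurred step edge
#'   the half-maximum crossing recovers the true edge position, making the
#'   outline unbiased to first order in the smoothing width.
#' @return a `colony_geometry` list: `boundary_polygon` (µm), `mask` (binary
#'   matrix), `centroid` (µm), `equivalent_radius` (µm, radius of the circle
#'   of equal area), `area` (µm²).
#' @export
detect_colony <- function(image, nuclei_channel = "DAPI",
                          smooth_sigma_um = 15) {
  stopifnot(inherits(image, "image_stack"))
  m <- get_channel(image, nuclei_channel)
  px <- image$pixel_size
  if (diff(range(m)) <= 0)
    stopf("channel '%s' has no foreground; cannot detect colony",
          nuclei_channel)
  mn <- (m - min(m)) / diff(range(m))
  sg <- max(1, smooth_sigma_um / px)
  sm <- EBImage::gblur(ebi(mn), sigma = sg, boundary = "replicate")
  smm <- unebi(sm)
  H <- nrow(smm); W <- ncol(smm)
  fw <- max(3L, min(8L, H %/% 20, W %/% 20))   # border frame width (px)
  frame <- c(smm[c(seq_len(fw), H - fw + seq_len(fw)), ],
             smm[, c(seq_len(fw), W - fw + seq_len(fw))])
  bg <- stats::median(frame)
  rough <- smm > EBImage::otsu(sm, range = range(sm))
  if (!any(rough) || stats::median(smm[rough]) <= bg)
    stopf("channel '%s' has no foreground; cannot detect colony",
          nuclei_channel)
  # self-consistent plateau: the Otsu foreground is biased toward bright
  # interior patches, so re-estimate the plateau over the eroded current
  # mask (edge ramp excluded) until the mask stabilizes
  plateau <- stats::median(smm[rough])
  er <- EBImage::makeBrush(2L * ceiling(sg) + 1L, shape = "disc")
  mask <- rough
  for (it in 1:4) {
    mask <- smm > (plateau + bg) / 2
    core <- unebi(EBImage::erode(ebi(mask * 1), er)) > 0
    if (!any(core)) break
    p_new <- stats::median(smm[core])
    if (abs(p_new - plateau) < 1e-4 * (plateau - bg)) {
      plateau <- p_new; break
    }
    plateau <- p_new
  }
  mask <- smm > (plateau + bg) / 2
  if (sum(mask) == 0)
    stopf("channel '%s' has no foreground; cannot detect colony",
          nuclei_channel)
  lab <- EBImage::bwlabel(ebi(mask * 1))
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[which.max(areas)])
  mask <- EBImage::fillHull(lab == keep)
  mm <- unebi(mask) * 1

  # subpixel boundary: light blur then marching-squares contour at 0.5
  msm <- unebi(EBImage::gblur(ebi(mm), sigma = 1.5))
  cl <- grDevices::contourLines(x = (seq_len(ncol(mm)) - 0.5) * px,
                                y = (seq_len(nrow(mm)) - 0.5) * px,
                                z = t(msm), levels = 0.5)
  if (!length(cl))
    stopf("no closed colony contour found in channel '%s'", nuclei_channel)
  lens <- vapply(cl, function(cc) length(cc$x), integer(1L))
  cc <- cl[[which.max(lens)]]
  poly <- data.frame(x = cc$x, y = cc$y)
  area <- poly_area(poly)
  structure(list(boundary_polygon = poly, mask = mm,
                 centroid = poly_centroid(poly),
                 equivalent_radius = sqrt(area / pi), area = area),
            class = "colony_geometry")
}

#' @export
print.colony_geometry <- function(x, ...) {
  cat(sprintf("<colony_geometry> area %.4g µm², equivalent radius %.4g µm\n",
              x$area, x$equivalent_radius))
  invisible(x)
}

# Mean of non-zero pixels within an annulus (inner, outer] of radii in
# pixel units around a continuous (subpixel) center; the disk/annulus is
# rasterized at the true centroid, pixel centers inside count. Returns the
# mean and whether the mask was clipped at the image border.
sample_annulus <- function(m, cx, cy, inner, outer, nonzero_only = TRUE) {
  H <- nrow(m); W <- ncol(m)
  gx <- cx - 0.5; gy <- cy - 0.5          # continuous pixel-center coords
  j0 <- floor(gx - outer); j1 <- ceiling(gx + outer)
  i0 <- floor(gy - outer); i1 <- ceiling(gy + outer)
  jc <- max(0L, j0):min(W - 1L, j1)
  ic <- max(0L, i0):min(H - 1L, i1)
  clipped <- (j0 < 0L || i0 < 0L || j1 > W - 1L || i1 > H - 1L)
  if (!length(jc) || !length(ic))
    return(list(mean = NA_real_, clipped = TRUE))
  D2 <- outer((ic - gy)^2, (jc - gx)^2, "+")
  keep <- D2 <= outer^2 & (inner < 0 | D2 > inner^2)
  vals <- m[ic + 1L, jc + 1L, drop = FALSE][keep]
  if (nonzero_only) vals <- vals[vals != 0]
  list(mean = if (length(vals)) mean(vals) else NA_real_, clipped = clipped)
}

#' Per-cell nuclear and cytosolic intensity sampling
#'
#' For each nucleus centroid a binary disk of fixed radius (default 5 px,
#' i.e. 3.12 µm at the default calibration) samples the nuclear signal
#' (`Nuc`, mean of non-zero pixels per marker channel). The cytosolic signal
#' (`Cyt`) is the mean over the annulus obtained by dilating the disk radius
#' by `dilation_factor` and subtracting the original disk. Annuli of
#' neighboring cells may overlap; no exclusivity is enforced. Disks clipped
#' at the image border are flagged.
#'
#' @param image an [image_stack()].
#' @param records nucleus records from [segment_nuclei()].
#' @param channels marker channels to sample (default: all but the nuclei
#'   channel).
#' @param nuclei_channel excluded from the default channel set.
#' @param disk_radius_px nuclear disk radius in pixels (>= 1).
#' @param dilation_factor annulus outer radius as a multiple of the disk
#'   radius (>= 2).
#' @param nonzero_only average only non-zero pixel values, as the masking
#'   convention requires.
#' @param background optional [background_stats()] result; when given, the
#'   per-channel background median is subtracted before forming the
#'   Nuc:Cyt ratio (`Nuc`/`Cyt` themselves stay raw). Without subtraction
#'   a shared additive background compresses every ratio toward 1.
#' @return data.frame with one row per nucleus: `nucleus_id`, `x`, `y` (µm),
#'   `clipped`, and per channel `Nuc_<ch>`, `Cyt_<ch>`, `ratio_<ch>`
#'   (ratio is NA where the denominator is <= 0 or undefined). The disk
#'   radius in µm is attached as attribute `disk_radius_um`.
#' @export
sample_cell_intensities <- function(image, records, channels = NULL,
                                    nuclei_channel = "DAPI",
                                    disk_radius_px = 5L,
                                    dilation_factor = 2,
                                    nonzero_only = TRUE,
                                    background = NULL) {
  stopifnot(inherits(image, "image_stack"))
  if (disk_radius_px < 1) stopf("disk_radius_px must be >= 1")
  if (dilation_factor < 2) stopf("dilation_factor must be >= 2")
  px <- image$pixel_size
  channels <- channels %||% setdiff(channel_names(image), nuclei_channel)
  n <- nrow(records)
  H <- dim(image)[1]; W <- dim(image)[2]
  cx <- records$x / px; cy <- records$y / px   # continuous pixel coords
  inside <- cx >= 0 & cx < W & cy >= 0 & cy < H
  if (any(!inside))
    warnf("%d centroid(s) outside the image were skipped", sum(!inside))
  r_out <- dilation_factor * disk_radius_px
  out <- data.frame(nucleus_id = records$id, x = records$x, y = records$y,
                    clipped = logical(n))
  for (ch in channels) {
    m <- get_channel(image, ch)
    nuc <- cyt <- rep(NA_real_, n)
    clip <- rep(FALSE, n)
    for (i in which(inside)) {
      sn <- sample_annulus(m, cx[i], cy[i], -1, disk_radius_px, nonzero_only)
      sc <- sample_annulus(m, cx[i], cy[i], disk_radius_px, r_out,
                           nonzero_only)
      nuc[i] <- sn$mean; cyt[i] <- sc$mean
      clip[i] <- clip[i] || sn$clipped || sc$clipped
    }
    bgv <- 0
    if (!is.null(background)) {
      bi <- match(ch, background$channel)
      if (!is.na(bi)) bgv <- background$bg_median[bi]
    }
    out[[paste0("Nuc_", ch)]] <- nuc
    out[[paste0("Cyt_", ch)]] <- cyt
    out[[paste0("ratio_", ch)]] <-
      ifelse(!is.na(cyt) & (cyt - bgv) > 0, (nuc - bgv) / (cyt - bgv),
             NA_real_)
    out$clipped <- out$clipped | clip
  }
  out$clipped[!inside] <- NA
  attr(out, "disk_radius_um") <- disk_radius_px * px
  attr(out, "dilation_factor") <- dilation_factor
  out
}

#' Distance of each cell from the colony periphery
#'
#' Minimum Euclidean distance from the nucleus centroid to the colony
#' boundary polygon, in µm. Cells outside the polygon get a negative
#' distance and are flagged.
#'
#' @param cells data.frame with `x`, `y` columns (µm).
#' @param colony a [detect_colony()] result (or any list with a
#'   `boundary_polygon`).
#' @return `cells` with `edge_distance` and `outside` columns added.
#' @export
edge_distances <- function(cells, colony) {
  poly <- colony$boundary_polygon %||% colony
  d <- dist_to_chain(cells$x, cells$y, poly, closed = TRUE)
  inside <- points_in_polygon(cells$x, cells$y, poly)
  cells$edge_distance <- ifelse(inside, d, -d)
  cells$outside <- !inside
  cells
}

#' Per-channel background statistics outside the colony
#'
#' Median and MAD of each channel over pixels outside the colony mask;
#' the robust background estimate used by [classify_fate()].
#'
#' @param image an [image_stack()].
#' @param colony a [detect_colony()] result.
#' @return data.frame with `channel`, `bg_median`, `bg_mad`.
#' @export
background_stats <- function(image, colony) {
  outside <- colony$mask == 0
  if (!any(outside))
    return(data.frame(channel = channel_names(image), bg_median = 0,
                      bg_mad = 0))
  do.call(rbind, lapply(channel_names(image), function(ch) {
    v <- get_channel(image, ch)[outside]
    data.frame(channel = ch, bg_median = stats::median(v),
               bg_mad = stats::mad(v))
  }))
}

#' Classify cell fates from marker intensity ratios
#'
#' Winner-takes-all on background-subtracted nuclear intensities of the
#' fate-marker channels: a cell is called for the maximal marker when it
#' exceeds the runner-up by `margin` (default 1.2x) and exceeds an absolute
#' floor of `floor_k` background MADs; otherwise `unclassified`.
#'
#' @param cells output of [sample_cell_intensities()].
#' @param roles named character vector mapping fate label -> channel name,
#'   e.g. `c(SOX2 = "SOX2", T = "T", SOX17 = "SOX17")`.
#' @param background data.frame from [background_stats()], or NULL for zero
#'   background.
#' @param margin ratio the winner must exceed the runner-up by.
#' @param floor_k minimum winner level in background MADs above background.
#' @return `cells` with a `fate` column (factor including "unclassified").
#' @export
classify_fate <- function(cells, roles = c(SOX2 = "SOX2", T = "T",
                                           SOX17 = "SOX17"),
                          background = NULL, margin = 1.2, floor_k = 2) {
  cols <- paste0("Nuc_", roles)
  missing <- setdiff(cols, names(cells))
  if (length(missing))
    stopf("missing role channel column(s): %s",
          paste(missing, collapse = ", "))
  v <- as.matrix(cells[, cols, drop = FALSE])
  floorv <- rep(0, length(roles))
  if (!is.null(background)) {
    idx <- match(roles, background$channel)
    if (anyNA(idx)) stopf("background stats missing for a role channel")
    v <- sweep(v, 2L, background$bg_median[idx], "-")
    floorv <- floor_k * background$bg_mad[idx]
  }
  fate <- rep("unclassified", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    vi <- v[i, ]
    if (anyNA(vi)) next
    o <- order(vi, decreasing = TRUE)
    w <- o[1L]
    if (vi[w] > floorv[w] && vi[w] >= margin * max(vi[o[2L]], 0) &&
        vi[w] > vi[o[2L]])
      fate[i] <- names(roles)[w]
  }
  cells$fate <- factor(fate, levels = c(names(roles), "unclassified"))
  cells
}

#' Ratio of cell counts between two fates
#'
#' @param cells classified cells (with a `fate` column).
#' @param label_a,label_b fate labels for numerator and denominator.
#' @param roi optional polygon (µm) restricting the count.
#' @return list with `ratio` (NA when the denominator is 0), `count_a`,
#'   `count_b`, `n`.
#' @export
fate_count_ratio <- function(cells, label_a, label_b, roi = NULL) {
  if (!is.null(roi)) {
    keep <- points_in_polygon(cells$x, cells$y, roi)
    cells <- cells[keep, , drop = FALSE]
  }
  ca <- sum(cells$fate == label_a, na.rm = TRUE)
  cb <- sum(cells$fate == label_b, na.rm = TRUE)
  # a ratio with an empty group is flagged undefined (counts still tell
  # the story) rather than reported as 0 or Inf
  list(ratio = if (ca > 0 && cb > 0) ca / cb else NA_real_,
       count_a = ca, count_b = cb, n = nrow(cells))
}

#' Marker level in cells with vs without a fate label
#'
#' Mean ± sem of a marker's per-cell intensity in the group carrying
#' `group_label` and in all other classified cells, e.g. beta-catenin in
#' SOX2+ vs SOX2- cells.
#'
#' @param cells classified cells.
#' @param marker_channel channel whose intensity is compared.
#' @param group_label fate label defining the positive group.
#' @param statistic `"nuclear"` (Nuc), `"cytoplasmic"` (Cyt) or `"total"`
#'   (Nuc + Cyt).
#' @return data.frame with one row per group (`positive`, `negative`):
#'   n, mean, sem (NA when n < 2, flagged undefined).
#' @export
marker_level_by_fate <- function(cells, marker_channel, group_label,
                                 statistic = c("nuclear", "cytoplasmic",
                                               "total")) {
  statistic <- match.arg(statistic)
  val <- switch(statistic,
    nuclear = cells[[paste0("Nuc_", marker_channel)]],
    cytoplasmic = cells[[paste0("Cyt_", marker_channel)]],
    total = cells[[paste0("Nuc_", marker_channel)]] +
            cells[[paste0("Cyt_", marker_channel)]])
  if (is.null(val)) stopf("channel '%s' not found in cells", marker_channel)
  pos <- val[cells$fate == group_label & !is.na(val)]
  neg <- val[cells$fate != group_label & cells$fate != "unclassified" &
               !is.na(val)]
  out <- data.frame(
    group = c("positive", "negative"),
    n = c(length(pos), length(neg)),
    mean = c(if (length(pos)) mean(pos) else NA_real_,
             if (length(neg)) mean(neg) else NA_real_),
    sem = c(sem(pos), sem(neg)))
  out$empty <- out$n == 0L
  out
}
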