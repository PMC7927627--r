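# Tissue-structure morphometrics: circularity, gyration index, annular ring
# position, actomyosin cable angles, apical/basal mitosis split, wedge-cell
# shape, and the trilaminar localization map.

#' Tissue contour
#'
#' An ordered vertex chain (µm) outlining a tissue structure: the colony
#' outline, a fold outline, or a cross-section profile.
#'
#' @param vertices matrix or data.frame with columns `x`, `y` (µm).
#' @param closed is the chain a closed polygon?
#' @param source one of `"colony_outline"`, `"fold_outline"`,
#'   `"cross_section_outline"`.
#' @param check_simple verify the closed polygon is simple (no
#'   self-intersection); O(n^2), disable for very long contours.
#' @return a `tissue_contour` object.
#' @export
tissue_contour <- function(vertices, closed = TRUE,
                           source = c("colony_outline", "fold_outline",
                                      "cross_section_outline"),
                           check_simple = TRUE) {
  source <- match.arg(source)
  v <- as_poly(vertices)
  if (nrow(v) < 3L) stopf("a tissue contour needs at least 3 vertices")
  if (closed && check_simple && !is_simple_polygon(v))
    stopf("contour is self-intersecting; not a simple polygon")
  structure(list(vertices = v, closed = closed, source = source),
            class = "tissue_contour")
}

contour_vertices <- function(contour) {
  if (inherits(contour, "tissue_contour")) {
    if (!contour$closed)
      stopf("operation requires a closed contour")
    contour$vertices
  } else as_poly(contour)
}

#' Circularity shape factor
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a circle, pi/4 for a square, and
#' strictly below 1 for any non-circular shape. Area by the shoelace rule,
#' perimeter as the vertex-chain length. Invariant to rotation, translation
#' and uniform scaling.
#'
#' @param contour a closed [tissue_contour()] (or bare vertex matrix).
#' @return circularity in (0, 1].
#' @examples
#' sq <- tissue_contour(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' circularity(sq)   # pi/4
#' @export
circularity <- function(contour) {
  v <- contour_vertices(contour)
  a <- poly_area(v)
  p <- poly_perimeter(v)
  if (a <= 0 || p <= 0) stopf("degenerate contour (zero area or perimeter)")
  4 * pi * a / p^2
}

#' Gyration index of a tissue contour
#'
#' Perimeter of the contour divided by the perimeter of its convex hull:
#' the planar gyrification convention. 1 for any convex shape; grows as
#' the outline folds.
#'
#' @param contour a closed [tissue_contour()] (or bare vertex matrix).
#' @return gyration index >= 1.
#' @export
gyration_index <- function(contour) {
  v <- contour_vertices(contour)
  p <- poly_perimeter(v)
  if (p <= 0) stopf("degenerate contour")
  hull <- v[grDevices::chull(v[, 1L], v[, 2L]), , drop = FALSE]
  ph <- poly_perimeter(hull)
  if (ph <= 0) stopf("degenerate convex hull")
  p / ph
}

#' Relative position of the inner ring of an annular structure
#'
#' Builds the radial intensity profile of a channel from the colony
#' centroid outward and locates the innermost radius at which intensity
#' first rises through half of the profile peak (rising edge). Reports
#' that radius over the colony equivalent radius. A profile already above
#' half-max at the center (uniform disk) has no rising edge and returns a
#' "no ring" signal.
#'
#' @param image an [image_stack()].
#' @param channel marker channel forming the ring.
#' @param colony a [detect_colony()] result.
#' @param bin_um radial bin width (µm).
#' @return list with `ratio` (inner radius / equivalent radius, NA if no
#'   ring), `inner_radius` (µm), `no_ring` flag and the `profile`
#'   data.frame.
#' @export
ring_position <- function(image, channel, colony, bin_um = 2) {
  stopifnot(inherits(image, "image_stack"))
  m <- get_channel(image, channel)
  px <- image$pixel_size
  H <- nrow(m); W <- ncol(m)
  xs <- px_centers_um(W, px); ys <- px_centers_um(H, px)
  R2 <- outer((ys - colony$centroid["y"])^2, (xs - colony$centroid["x"])^2,
              "+")
  r <- sqrt(R2)
  rmax <- colony$equivalent_radius * 1.05
  sel <- r <= rmax
  bins <- floor(r[sel] / bin_um)
  prof <- tapply(m[sel], bins, mean)
  rb <- (as.numeric(names(prof)) + 0.5) * bin_um
  # light 3-bin running mean to stabilize the half-max crossing
  sm <- stats::filter(as.numeric(prof), rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  lo <- min(sm); hi <- max(sm)
  half <- lo + 0.5 * (hi - lo)
  profile <- data.frame(radius = rb, intensity = as.numeric(prof),
                        smoothed = as.numeric(sm))
  if (sm[1L] >= half || hi <= lo)
    return(list(ratio = NA_real_, inner_radius = NA_real_, no_ring = TRUE,
                profile = profile))
  above <- which(sm >= half)
  i <- above[1L]
  # linear interpolation of the rising-edge crossing
  r0 <- rb[i - 1L]; r1 <- rb[i]
  f <- (half - sm[i - 1L]) / (sm[i] - sm[i - 1L])
  inner <- r0 + f * (r1 - r0)
  list(ratio = inner / colony$equivalent_radius, inner_radius = inner,
       no_ring = FALSE, profile = profile)
}

#' Detect linear cable segments and their angles to the folding axis
#'
#' Thresholds the cable channel, decomposes each connected component into
#' approximately straight segments (greedy extraction of the hull chord
#' with the most collinear pixels, which also separates the arms of
#' crossing cables), keeps segments of at least `min_length_um`, and
#' measures
#' each segment's direction against the local tangent of the circular
#' prospective folding axis at the segment midpoint's azimuth; angles are
#' folded into [0, 90] degrees.
#'
#' @param image an [image_stack()].
#' @param channel cable channel (e.g. the diphosphorylated myosin stain).
#' @param colony a [detect_colony()] result (supplies center for the
#'   folding-axis circle).
#' @param folding_axis_offset distance of the folding axis from the colony
#'   edge (µm).
#' @param min_length_um minimum cable length (default 10 µm).
#' @param straight_tol_um perpendicular distance (µm) within which pixels
#'   count as collinear with a candidate segment; about one cable width.
#' @param breaks angle histogram bin edges (degrees).
#' @return list with `segments` (data.frame: endpoints, length,
#'   angle_to_axis) and `histogram` (data.frame: bin, count).
#' @export
cable_angles <- function(image, channel, colony, folding_axis_offset = 200,
                         min_length_um = 10, straight_tol_um = 1.5,
                         breaks = seq(0, 90, by = 10)) {
  stopifnot(inherits(image, "image_stack"))
  m <- get_channel(image, channel)
  px <- image$pixel_size
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), length = numeric(0),
                      angle_to_axis = numeric(0))
  if (diff(range(m)) <= 0)
    return(list(segments = empty,
                histogram = data.frame(bin = head(breaks, -1L), count = 0L)))
  mn <- (m - min(m)) / diff(range(m))
  mask <- mn > EBImage::otsu(ebi(mn), range = c(0, 1))
  lab <- EBImage::bwlabel(ebi(mask * 1))
  nlab <- max(lab)
  segs <- list()
  labm <- unebi(lab)
  idx <- which(labm > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    xs <- (idx[, 2L] - 0.5) * px
    ys <- (idx[, 1L] - 0.5) * px
    comp <- labm[idx]
    for (k in seq_len(nlab)) {
      sel <- comp == k
      if (sum(sel) < 3L) next
      segs <- c(segs, split_straight(xs[sel], ys[sel], straight_tol_um))
    }
  }
  out <- empty
  ctr <- colony$centroid
  for (s in segs) {
    if (s$length < min_length_um) next
    mid <- c((s$p1[1L] + s$p2[1L]) / 2, (s$p1[2L] + s$p2[2L]) / 2)
    az <- atan2(mid[2L] - ctr["y"], mid[1L] - ctr["x"]) * 180 / pi
    tangent <- az + 90
    dir <- atan2(s$p2[2L] - s$p1[2L], s$p2[1L] - s$p1[1L]) * 180 / pi
    ang <- abs((((dir - tangent) + 90) %% 180) - 90)
    out <- rbind(out, data.frame(x1 = s$p1[1L], y1 = s$p1[2L],
                                 x2 = s$p2[1L], y2 = s$p2[2L],
                                 length = s$length, angle_to_axis = ang))
  }
  counts <- if (nrow(out))
    as.integer(table(cut(out$angle_to_axis, breaks = breaks,
                         include.lowest = TRUE, right = TRUE)))
  else rep(0L, length(breaks) - 1L)
  list(segments = out,
       histogram = data.frame(bin = utils::head(breaks, -1L),
                              count = counts))
}

# Straight-segment decomposition of a pixel cloud. A single straight cable
# is one component; crossing cables merge into X- or T-shaped components
# that a principal-component split cannot separate, so segments are
# extracted greedily: among chords between convex-hull vertices of the
# remaining pixels, take the one collinear with the most pixels (within
# `tol` perpendicular distance), emit it, remove its inliers, repeat.
# Deterministic: candidates are scanned in a fixed order.
split_straight <- function(xs, ys, tol) {
  out <- list()
  repeat {
    n <- length(xs)
    if (n < 6L) break
    h <- grDevices::chull(xs, ys)
    best <- NULL; best_n <- 0L
    for (a in seq_along(h)) {
      for (b in seq_len(a - 1L)) {
        i <- h[a]; j <- h[b]
        ex <- xs[j] - xs[i]; ey <- ys[j] - ys[i]
        el <- sqrt(ex^2 + ey^2)
        if (el < 2 * tol) next
        perp <- abs((xs - xs[i]) * ey - (ys - ys[i]) * ex) / el
        inl <- perp <= tol
        if (sum(inl) > best_n) {
          best_n <- sum(inl)
          best <- list(i = i, j = j, inl = inl)
        }
      }
    }
    if (best_n < 6L) break
    i <- best$i
    ex <- xs[best$j] - xs[i]; ey <- ys[best$j] - ys[i]
    el <- sqrt(ex^2 + ey^2)
    t <- ((xs[best$inl] - xs[i]) * ex + (ys[best$inl] - ys[i]) * ey) / el
    dirv <- c(ex, ey) / el
    p1 <- c(xs[i], ys[i]) + min(t) * dirv
    p2 <- c(xs[i], ys[i]) + max(t) * dirv
    out <- c(out, list(list(p1 = p1, p2 = p2, length = max(t) - min(t))))
    xs <- xs[!best$inl]; ys <- ys[!best$inl]
  }
  out
}

#' Apical vs basal split of mitotic (PH3+) nuclei
#'
#' Splits the cell layer at the mid-surface equidistant between the apical
#' and basal boundaries and reports the percentage of PH3+ nuclei on each
#' side (summing to 100).
#'
#' @param nuclei data.frame with `x`, `z` (µm, z-up) and `ph3_positive`.
#' @param apical_surface,basal_surface polylines (data.frames with `x`,
#'   `z`).
#' @return list with `apical_pct`, `basal_pct`, `n_ph3`, `empty` flag.
#' @export
apical_basal_ph3 <- function(nuclei, apical_surface, basal_surface) {
  ph3 <- nuclei[which(nuclei$ph3_positive), , drop = FALSE]
  if (!nrow(ph3))
    return(list(apical_pct = NA_real_, basal_pct = NA_real_, n_ph3 = 0L,
                empty = TRUE))
  za <- stats::approx(apical_surface$x, apical_surface$z, xout = ph3$x,
                      rule = 2)$y
  zb <- stats::approx(basal_surface$x, basal_surface$z, xout = ph3$x,
                      rule = 2)$y
  mid <- (za + zb) / 2
  apical <- ph3$z > mid
  list(apical_pct = 100 * mean(apical), basal_pct = 100 * mean(!apical),
       n_ph3 = nrow(ph3), empty = FALSE)
}

# Length of the part of a polygon's boundary lying within `band` of a
# polyline surface. Edges are sampled at a spacing of band/2 so thin bands
# are resolved.
boundary_length_near <- function(poly, surface, band) {
  v <- as_poly(poly)
  n <- nrow(v)
  vx <- v[, 1L]; vy <- v[, 2L]
  nx <- c(vx[-1L], vx[1L]); ny <- c(vy[-1L], vy[1L])
  total <- 0
  for (i in seq_len(n)) {
    el <- sqrt((nx[i] - vx[i])^2 + (ny[i] - vy[i])^2)
    if (el == 0) next
    k <- max(8L, ceiling(el / (band / 2)))
    t <- (seq_len(k) - 0.5) / k
    sx <- vx[i] + t * (nx[i] - vx[i])
    sy <- vy[i] + t * (ny[i] - vy[i])
    d <- dist_to_chain(sx, sy, surface, closed = FALSE)
    total <- total + el * mean(d <= band)
  }
  total
}

#' Basal:apical cell length (wedge) ratio
#'
#' For each cell outline, the basal and apical edge lengths are the
#' portions of the cell polygon boundary within a fixed-width band of the
#' basal and apical surfaces; the wedge ratio is basal/apical. Cells
#' touching only one surface are excluded (and counted); extreme ratios
#' are capped and flagged.
#'
#' @param cell_polygons list of cell outline polygons (data.frames `x`,
#'   `z`, µm).
#' @param apical_surface,basal_surface surface polylines (`x`, `z`).
#' @param band_um band width around each surface (µm). Lateral membranes
#'   contribute about one band width per side to each surface's length, so
#'   the band should stay well below the apical/basal edge lengths.
#' @param cap maximum reported ratio (degenerate apices).
#' @return list with `ratios` per retained cell, `mean`, `sem`, `n`,
#'   `excluded`, `capped`.
#' @export
wedge_ratio <- function(cell_polygons, apical_surface, basal_surface,
                        band_um = 0.5, cap = 10) {
  ap <- data.frame(x = apical_surface$x,
                   y = apical_surface$z %||% apical_surface$y)
  ba <- data.frame(x = basal_surface$x,
                   y = basal_surface$z %||% basal_surface$y)
  ratios <- numeric(0)
  excluded <- 0L; capped <- 0L
  for (poly in cell_polygons) {
    p <- data.frame(x = poly$x, y = poly$z %||% poly$y)
    la <- boundary_length_near(p, ap, band_um)
    lb <- boundary_length_near(p, ba, band_um)
    if (la <= 0 || lb <= 0) { excluded <- excluded + 1L; next }
    r <- lb / la
    if (r > cap) { r <- cap; capped <- capped + 1L }
    ratios <- c(ratios, r)
  }
  list(ratios = ratios,
       mean = if (length(ratios)) mean(ratios) else NA_real_,
       sem = sem(ratios), n = length(ratios), excluded = excluded,
       capped = capped)
}

#' Trilaminar localization map and layer-order statistic
#'
#' Collects classified cells from one or more cross-sections into a single
#' map (positions colored by fate after aligning sections) and computes a
#' layer-order statistic: the mean signed normal offset of each fate's
#' cells from the SOX2-layer centerline (a loess fit of z against x over
#' the reference-fate cells). Positive offsets point toward larger z.
#' An optional permutation test shuffles fate labels to ask whether a
#' fate's offset differs from 0.
#'
#' @param cells data.frame with `x`, `z` and `fate` (cross-section
#'   coordinates, µm).
#' @param reference_fate fate defining the centerline (default `"SOX2"`).
#' @param span loess span of the centerline fit.
#' @param n_permutations permutations for the offset test (0 disables).
#' @return list with `map` (the input cells with `offset` added),
#'   `order_stats` (data.frame: fate, n, mean_offset, sem, p_perm),
#'   `undefined` flag (single-fate input).
#' @export
trilaminar_map <- function(cells, reference_fate = "SOX2", span = 0.75,
                           n_permutations = 0L) {
  cells <- cells[!is.na(cells$fate) & cells$fate != "unclassified", ,
                 drop = FALSE]
  if (!nrow(cells)) stopf("no classified cells for the localization map")
  fates <- unique(as.character(cells$fate))
  ref <- cells[cells$fate == reference_fate, , drop = FALSE]
  if (length(fates) < 2L || nrow(ref) < 5L) {
    cells$offset <- NA_real_
    return(list(map = cells, order_stats = NULL, undefined = TRUE))
  }
  fit <- stats::loess(z ~ x, data = ref, span = span, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  center <- stats::predict(fit, data.frame(x = cells$x))
  cells$offset <- cells$z - center
  stat_for <- function(df) {
    do.call(rbind, lapply(fates, function(f) {
      o <- df$offset[df$fate == f]
      data.frame(fate = f, n = length(o), mean_offset = mean(o),
                 sem = sem(o))
    }))
  }
  os <- stat_for(cells)
  os$p_perm <- NA_real_
  if (n_permutations > 0L) {
    # exchangeability null: compare each fate's mean offset, centered on
    # the grand mean offset, against label permutations
    grand <- mean(cells$offset)
    obs <- abs(os$mean_offset - grand)
    exceed <- rep(0L, nrow(os))
    for (b in seq_len(n_permutations)) {
      sh <- cells
      sh$fate <- sample(sh$fate)
      perm <- stat_for(sh)
      exceed <- exceed + (abs(perm$mean_offset - grand) >= obs)
    }
    os$p_perm <- (exceed + 1L) / (n_permutations + 1L)
  }
  list(map = cells, order_stats = os, undefined = FALSE)
}

#' Plot a trilaminar localization map
#' @param map result of [trilaminar_map()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_trilaminar <- function(map, ...) {
  cells <- map$map
  fates <- unique(as.character(cells$fate))
  cols <- stats::setNames(grDevices::hcl.colors(max(3L, length(fates)),
                                                "Dark 3")[seq_along(fates)],
                          fates)
  graphics::plot(cells$x, cells$z, col = cols[as.character(cells$fate)],
                 pch = 16, cex = 0.6, xlab = "x (µm)", ylab = "z (µm)", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(map)
}
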