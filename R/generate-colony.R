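# Synthetic colony rendering. Nuclei are anisotropic Gaussian blobs truncated
# at 2 sigma (sigma = radius / 2, so the truncation circle is the ground-truth
# nucleus outline); marker channels are painted flat per fate zone so that the
# mean pixel intensity inside a nucleus equals the zone's stated nuclear
# intensity exactly before noise.

px_centers_um <- function(n, pixel_size) ((seq_len(n) - 1) + 0.5) * pixel_size

# Analytic colony mask on the pixel grid (pixel-center inclusion test).
rasterize_colony_mask <- function(spec, poly, W, H) {
  px <- spec$pixel_size
  xs <- px_centers_um(W, px); ys <- px_centers_um(H, px)
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  ctr <- poly_centroid(poly)
  area <- pi * (spec$equivalent_diameter / 2)^2
  mask <- switch(spec$shape,
    circle = {
      R <- spec$equivalent_diameter / 2
      (X - ctr["x"])^2 + (Y - ctr["y"])^2 <= R^2
    },
    annulus = {
      f <- spec$annulus_inner_fraction
      ro <- sqrt(area / (pi * (1 - f^2))); ri <- f * ro
      d2 <- (X - ctr["x"])^2 + (Y - ctr["y"])^2
      d2 <= ro^2 & d2 >= ri^2
    },
    square = ,
    rectangle = {
      w <- diff(range(poly$x)); h <- diff(range(poly$y))
      abs(X - ctr["x"]) <= w / 2 & abs(Y - ctr["y"]) <= h / 2
    },
    triangle = {
      inside <- matrix(TRUE, H, W)
      v <- as_poly(poly); n <- nrow(v)
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        cr <- (v[j, 1] - v[i, 1]) * (Y - v[i, 2]) -
              (v[j, 2] - v[i, 2]) * (X - v[i, 1])
        inside <- inside & (cr >= 0)
      }
      inside
    })
  storage.mode(mask) <- "double"
  mask
}

# Distance (µm) from points to the colony edge; annulus counts the hole rim.
edge_distance_to_spec <- function(px_, py_, spec, poly) {
  d <- dist_to_chain(px_, py_, poly, closed = TRUE)
  if (spec$shape == "annulus") {
    ctr <- poly_centroid(poly)
    area <- pi * (spec$equivalent_diameter / 2)^2
    f <- spec$annulus_inner_fraction
    ro <- sqrt(area / (pi * (1 - f^2))); ri <- f * ro
    d_in <- sqrt((px_ - ctr["x"])^2 + (py_ - ctr["y"])^2) - ri
    d <- pmin(d, d_in)
  }
  d
}

# Analytic per-shape inclusion test (hot path of the placement loop).
point_in_colony <- function(px_, py_, spec, poly) {
  ctr <- poly_centroid(poly)
  area <- pi * (spec$equivalent_diameter / 2)^2
  dx <- px_ - ctr["x"]; dy <- py_ - ctr["y"]
  switch(spec$shape,
    circle = dx^2 + dy^2 <= (spec$equivalent_diameter / 2)^2,
    annulus = {
      f <- spec$annulus_inner_fraction
      ro <- sqrt(area / (pi * (1 - f^2))); ri <- f * ro
      d2 <- dx^2 + dy^2
      d2 <= ro^2 & d2 >= ri^2
    },
    square = ,
    rectangle = {
      w <- diff(range(poly$x)); h <- diff(range(poly$y))
      abs(dx) <= w / 2 & abs(dy) <= h / 2
    },
    triangle = {
      v <- as_poly(poly)
      inside <- rep(TRUE, length(px_))
      for (i in 1:3) {
        j <- if (i == 3L) 1L else i + 1L
        cr <- (v[j, 1] - v[i, 1]) * (py_ - v[i, 2]) -
              (v[j, 2] - v[i, 2]) * (px_ - v[i, 1])
        inside <- inside & cr >= 0
      }
      inside
    },
    points_in_polygon(px_, py_, poly))
}

# Sequential random placement with a minimum-separation rule; paired nuclei
# are seeded at 1.2 x radius so their rendered blobs merge for watershed tests.
place_nuclei <- function(spec, poly, n) {
  if (n == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), pair_id = integer(0)))
  sep <- 2 * spec$nuc_radius_mean
  touch_sep <- 1.2 * spec$nuc_radius_mean
  n_pairs <- round(spec$touching_fraction * n / 2)
  n_single <- n - 2L * n_pairs
  bb <- list(x = range(poly$x), y = range(poly$y))
  xs <- numeric(0); ys <- numeric(0); pair <- integer(0)
  budget <- 500L * n
  draw_point <- function() {
    c(runif(1, bb$x[1], bb$x[2]), runif(1, bb$y[1], bb$y[2]))
  }
  ok_at <- function(x, y, min_sep, skip = 0L) {
    if (!point_in_colony(x, y, spec, poly)) return(FALSE)
    if (!length(xs)) return(TRUE)
    d2 <- (xs - x)^2 + (ys - y)^2
    if (skip > 0L) d2 <- d2[-skip]
    !length(d2) || min(d2) >= min_sep^2
  }
  n_target <- n_single + n_pairs     # anchors count as one placement each
  placed_pairs <- 0L
  while (length(xs) < n && budget > 0L) {
    budget <- budget - 1L
    p <- draw_point()
    if (placed_pairs < n_pairs) {
      # pair anchor needs clearance for its partner too
      if (!ok_at(p[1], p[2], sep)) next
      partner <- NULL
      for (k in seq_len(24L)) {
        a <- runif(1, 0, 2 * pi)
        q <- p + touch_sep * c(cos(a), sin(a))
        xs2 <- c(xs, p[1]); ys2 <- c(ys, p[2])
        if (point_in_colony(q[1], q[2], spec, poly) &&
            (!length(xs) || min((xs - q[1])^2 + (ys - q[2])^2) >= sep^2)) {
          partner <- q; break
        }
      }
      if (is.null(partner)) next
      id <- placed_pairs + 1L
      xs <- c(xs, p[1], partner[1]); ys <- c(ys, p[2], partner[2])
      pair <- c(pair, id, id)
      placed_pairs <- placed_pairs + 1L
    } else {
      if (!ok_at(p[1], p[2], sep)) next
      xs <- c(xs, p[1]); ys <- c(ys, p[2]); pair <- c(pair, 0L)
    }
  }
  if (length(xs) < n)
    stopf(paste0("infeasible packing: cell_density %g cells/mm² cannot be ",
                 "placed at minimum separation %.3g µm (2 x nuc_radius_mean ",
                 "%.3g µm); placed %d of %d"),
          spec$cell_density, sep, spec$nuc_radius_mean, length(xs), n)
  data.frame(x = xs, y = ys, pair_id = pair)
}

# Paint truncated Gaussian blobs and the ground-truth label image.
render_nuclei <- function(nuc, spec, W, H) {
  px <- spec$pixel_size
  dapi <- matrix(0, H, W)
  lab <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  for (i in seq_len(nrow(nuc))) {
    r <- nuc$radius[i]; sg <- r / 2
    cx <- nuc$x[i]; cy <- nuc$y[i]
    jc <- floor(cx / px); ic <- floor(cy / px)      # 0-based pixel of centroid
    wr <- ceiling(r / px) + 1L
    j0 <- max(0L, jc - wr); j1 <- min(W - 1L, jc + wr)
    i0 <- max(0L, ic - wr); i1 <- min(H - 1L, ic + wr)
    if (j0 > j1 || i0 > i1) next
    xs <- px_centers_um(W, px)[(j0 + 1L):(j1 + 1L)] - cx
    ys <- px_centers_um(H, px)[(i0 + 1L):(i1 + 1L)] - cy
    D2 <- outer(ys^2, xs^2, "+")
    inside <- D2 <= r^2
    g <- spec$dapi_amplitude * exp(-D2 / (2 * sg^2)) * inside
    ri <- (i0 + 1L):(i1 + 1L); rj <- (j0 + 1L):(j1 + 1L)
    # per-pixel max: overlapping nuclei merge into one blob with a neck at
    # the overlap rather than a bridge brighter than either peak
    dapi[ri, rj] <- pmax(dapi[ri, rj], g)
    upd <- inside & (D2 < bestd[ri, rj])
    subl <- lab[ri, rj]; subd <- bestd[ri, rj]
    subl[upd] <- i; subd[upd] <- D2[upd]
    lab[ri, rj] <- subl; bestd[ri, rj] <- subd
  }
  list(dapi = dapi, labels = lab)
}

apply_noise <- function(m, noise, colwise_gradient = TRUE) {
  H <- nrow(m); W <- ncol(m)
  if (noise$illumination_gradient_fraction > 0) {
    gr <- 1 + noise$illumination_gradient_fraction *
      (((seq_len(W) - 0.5) / W) - 0.5)
    m <- sweep(m, 2L, gr, "*")
  }
  if (noise$photon_gain > 0)
    m <- matrix(rpois(length(m), noise$photon_gain * pmax(m, 0)) /
                  noise$photon_gain, H, W)
  m <- m + noise$background_level
  if (noise$gaussian_sd > 0)
    m <- m + matrix(rnorm(length(m), 0, noise$gaussian_sd), H, W)
  pmax(m, 0)
}

zone_index <- function(edge_dist, boundaries) {
  findInterval(edge_dist, boundaries) + 1L
}

#' Generate a synthetic micropatterned colony image with ground truth
#'
#' Renders one DAPI (nuclei) channel plus one channel per marker model of the
#' spec, together with complete ground truth: nucleus table (centroid, axes,
#' edge distance, fate label), ground-truth label image, fate-zone label map,
#' the generating intensity-vs-edge-distance profiles, cable segments and the
#' colony outline polygon. Deterministic given `spec$seed`.
#'
#' @param spec a [colony_spec()].
#' @return a list of class `colony_sim` with elements `image` (an
#'   [image_stack()]) and `truth` (a `ground_truth` list).
#' @examples
#' sim <- generate_colony(colony_spec(equivalent_diameter = 150,
#'                                    cell_density = 2000, noise = noise_off(),
#'                                    zone_boundaries = 30,
#'                                    zone_labels = c("T", "SOX2"),
#'                                    marker_models = list(
#'                                      T = marker_model("nuclear", 3, c(150, 15))),
#'                                    seed = 7))
#' nrow(sim$truth$nuclei)
#' @export
generate_colony <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  with_seed(spec$seed, {
    px <- spec$pixel_size
    poly0 <- shape_polygon(spec$shape, spec$equivalent_diameter,
                           annulus_inner_fraction = spec$annulus_inner_fraction)
    off <- c(spec$margin_um - min(poly0$x), spec$margin_um - min(poly0$y))
    poly <- data.frame(x = poly0$x + off[1], y = poly0$y + off[2])
    W <- as.integer(ceiling((diff(range(poly$x)) + 2 * spec$margin_um) / px))
    H <- as.integer(ceiling((diff(range(poly$y)) + 2 * spec$margin_um) / px))
    area <- pi * (spec$equivalent_diameter / 2)^2
    if (spec$shape == "annulus")
      area <- area   # equal-area convention: annulus band has the stated area
    n <- round(spec$cell_density / 1e6 * area)

    pts <- place_nuclei(spec, poly, n)
    nn <- nrow(pts)
    radius <- if (nn) pmin(pmax(rnorm(nn, spec$nuc_radius_mean,
                                      spec$nuc_radius_sd),
                                spec$nuc_radius_mean - 2 * spec$nuc_radius_sd),
                           spec$nuc_radius_mean + 2 * spec$nuc_radius_sd)
              else numeric(0)
    edge_dist <- if (nn) edge_distance_to_spec(pts$x, pts$y, spec, poly)
                 else numeric(0)
    zi <- zone_index(edge_dist, spec$zone_boundaries)
    nuclei <- data.frame(
      id = seq_len(nn), x = pts$x, y = pts$y, radius = radius,
      major_axis = 2 * radius, minor_axis = 2 * radius,
      orientation = rep(0, nn), aspect_ratio = rep(1, nn),
      edge_distance = edge_dist, zone = zi,
      fate = spec$zone_labels[zi] %||% character(0),
      pair_id = pts$pair_id,
      ph3_positive = rep(NA, nn), apical_side = rep(NA, nn))

    rend <- render_nuclei(nuclei, spec, W, H)
    cmask <- rasterize_colony_mask(spec, poly, W, H)
    dm <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(cmask)))))
    zone_map <- matrix(0L, H, W)
    inside <- cmask > 0
    zone_map[inside] <- zone_index(dm[inside] * px, spec$zone_boundaries)

    # nuclei blobs may overhang the adhesive pattern edge slightly, as in
    # real images; the colony mask confines cytoplasm, not nuclear stain
    channels <- list(DAPI = rend$dapi)
    nz_zone <- if (nn) zi else integer(0)
    for (nm in names(spec$marker_models)) {
      mm <- spec$marker_models[[nm]]
      img <- matrix(0, H, W)
      cyt_by_zone <- mm$zone_intensities / mm$nuc_cyt_ratio
      img[inside] <- cyt_by_zone[zone_map[inside]]
      if (nn) {
        nucpix <- rend$labels > 0L
        img[nucpix] <- mm$zone_intensities[nz_zone[rend$labels[nucpix]]]
      }
      channels[[nm]] <- img
    }

    cables <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                         y2 = numeric(0), length = numeric(0),
                         angle_to_axis = numeric(0))
    if (!is.null(spec$cable_spec)) {
      cs <- spec$cable_spec
      ctr <- poly_centroid(poly)
      r_axis <- spec$equivalent_diameter / 2 - spec$folding_axis_offset
      ch <- channels[[cs$channel]] %||% matrix(0, H, W)
      # exact population composition: angles recycled to n_cables and
      # randomly assigned, so a 70/30 mixture is 70/30 by count
      ang_seq <- sample(rep(cs$angles, length.out = cs$n_cables))
      for (k in seq_len(cs$n_cables)) {
        alpha <- runif(1, 0, 2 * pi)
        # cables sit in a band about the folding axis, not exactly on the
        # circle: distinct structures must not collinearly merge
        r_mid <- r_axis + runif(1, -cs$band_um / 2, cs$band_um / 2)
        mid <- c(ctr["x"] + r_mid * cos(alpha),
                 ctr["y"] + r_mid * sin(alpha))
        theta_rel <- ang_seq[k] + rnorm(1, 0, cs$angle_jitter_sd)
        dir_deg <- (alpha * 180 / pi + 90) + theta_rel   # tangent + offset
        d <- dir_deg * pi / 180
        L <- runif(1, cs$length_range[1], cs$length_range[2])
        p1 <- mid - L / 2 * c(cos(d), sin(d))
        p2 <- mid + L / 2 * c(cos(d), sin(d))
        ch <- draw_segment(ch, p1, p2, px, cs$width_px * px / 2, cs$intensity)
        fold <- abs(((theta_rel + 90) %% 180) - 90)
        cables <- rbind(cables, data.frame(
          x1 = p1[1], y1 = p1[2], x2 = p2[1], y2 = p2[2], length = L,
          angle_to_axis = fold))
      }
      channels[[cs$channel]] <- ch
    }

    channels <- lapply(channels, apply_noise, noise = spec$noise)
    image <- image_stack(channels, pixel_size = px)

    grid <- seq(0, max(c(edge_dist, spec$equivalent_diameter / 2)), by = 1)
    gp <- lapply(spec$marker_models, function(mm)
      data.frame(distance = grid,
                 value = mm$zone_intensities[zone_index(grid,
                                                        spec$zone_boundaries)]))

    truth <- structure(list(
      nuclei = nuclei, label_image = rend$labels, zone_map = zone_map,
      colony_mask = cmask, colony_polygon = poly,
      colony_centroid = poly_centroid(poly),
      equivalent_radius = spec$equivalent_diameter / 2,
      generating_profiles = gp, cable_segments = cables, spec = spec),
      class = "ground_truth")
    structure(list(image = image, truth = truth), class = "colony_sim")
  })
}

# Paint a line segment of given half-width (µm) and intensity, taking the
# per-pixel max so crossing cables do not sum.
draw_segment <- function(m, p1, p2, pixel_size, halfwidth, intensity) {
  H <- nrow(m); W <- ncol(m)
  j0 <- max(0L, floor(min(p1[1], p2[1]) / pixel_size) - 2L)
  j1 <- min(W - 1L, ceiling(max(p1[1], p2[1]) / pixel_size) + 2L)
  i0 <- max(0L, floor(min(p1[2], p2[2]) / pixel_size) - 2L)
  i1 <- min(H - 1L, ceiling(max(p1[2], p2[2]) / pixel_size) + 2L)
  if (j0 > j1 || i0 > i1) return(m)
  xs <- px_centers_um(W, pixel_size)[(j0 + 1L):(j1 + 1L)]
  ys <- px_centers_um(H, pixel_size)[(i0 + 1L):(i1 + 1L)]
  ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
  el2 <- max(ex^2 + ey^2, .Machine$double.eps)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  t <- pmin(1, pmax(0, ((X - p1[1]) * ex + (Y - p1[2]) * ey) / el2))
  dist <- sqrt((X - (p1[1] + t * ex))^2 + (Y - (p1[2] + t * ey))^2)
  sub <- m[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)]
  sub <- pmax(sub, intensity * (dist <= halfwidth))
  m[(i0 + 1L):(i1 + 1L), (j0 + 1L):(j1 + 1L)] <- sub
  m
}
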