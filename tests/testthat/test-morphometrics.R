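# Shape metrics against closed forms and quadrature oracles; ring position,
# cable angles, PH3 splits, wedge ratios and the trilaminar map.

perturbed_circle <- function(eps, k = 8, n = 720, R = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- R * (1 + eps * sin(k * th))
  data.frame(x = r * cos(th), y = r * sin(th))
}

test_that("circularity closed forms: square pi/4, near-circle ~ 1", {
  sq <- tissue_contour(data.frame(x = c(0, 2, 2, 0), y = c(0, 0, 2, 2)))
  expect_identical(circularity(sq), pi / 4)
  expect_gte(circularity(tissue_contour(regular_polygon(360))), 0.999)
})

test_that("perturbed-circle circularity matches the quadrature oracle", {
  eps <- 0.1; k <- 8
  got <- circularity(tissue_contour(perturbed_circle(eps, k),
                                    check_simple = FALSE))
  r <- function(t) 1 + eps * sin(k * t)
  dr <- function(t) eps * k * cos(k * t)
  A <- stats::integrate(function(t) 0.5 * r(t)^2, 0, 2 * pi,
                        subdivisions = 2000L)$value
  P <- stats::integrate(function(t) sqrt(r(t)^2 + dr(t)^2), 0, 2 * pi,
                        subdivisions = 2000L)$value
  expect_lt(abs(got / (4 * pi * A / P^2) - 1), 0.005)
})

test_that("circularity is invariant to rotation, translation and scale", {
  set.seed(5)
  pg <- perturbed_circle(0.07, 5)
  base <- circularity(tissue_contour(pg, check_simple = FALSE))
  th <- 0.83
  rot <- data.frame(x = pg$x * cos(th) - pg$y * sin(th) + 12,
                    y = pg$x * sin(th) + pg$y * cos(th) - 7)
  expect_equal(circularity(tissue_contour(rot, check_simple = FALSE)), base)
  scl <- data.frame(x = 3.7 * pg$x, y = 3.7 * pg$y)
  expect_equal(circularity(tissue_contour(scl, check_simple = FALSE)), base)
})

test_that("gyration index is 1 for convex shapes, exact for a star", {
  for (n in c(3, 4, 6, 60))
    expect_equal(gyration_index(tissue_contour(regular_polygon(n))), 1)
  # 5-point star with alternating radii 1 and 0.4: hand-computed perimeters
  a <- seq(0, 2 * pi, length.out = 11)[-11]
  R <- ifelse(seq_along(a) %% 2 == 1, 1, 0.4)
  star <- data.frame(x = R * cos(a), y = R * sin(a))
  edge <- sqrt(1 + 0.4^2 - 2 * 0.4 * cos(pi / 5))     # law of cosines
  p_star <- 10 * edge
  p_hull <- 10 * sin(pi / 5)                          # outer decagon chords
  expect_equal(gyration_index(tissue_contour(star)), p_star / p_hull,
               tolerance = 1e-12)
})

test_that("gyration index grows strictly with fold amplitude", {
  g <- vapply(c(0.02, 0.05, 0.1, 0.15), function(e)
    gyration_index(tissue_contour(perturbed_circle(e), check_simple = FALSE)),
    numeric(1))
  expect_true(all(diff(g) > 0))
  # and matches the quadrature oracle within 2%
  e <- 0.1
  r <- function(t) 1 + e * sin(8 * t); dr <- function(t) 0.8 * cos(8 * t)
  P <- stats::integrate(function(t) sqrt(r(t)^2 + dr(t)^2), 0, 2 * pi,
                        subdivisions = 2000L)$value
  hull_oracle <- poly_perimeter  # hull of the sampled outline
  pg <- perturbed_circle(e)
  hull <- pg[grDevices::chull(pg$x, pg$y), ]
  expect_lt(abs(gyration_index(tissue_contour(pg, check_simple = FALSE)) /
                  (P / poly_perimeter(hull)) - 1), 0.02)
})

test_that("self-intersecting or open contours are rejected", {
  bow <- data.frame(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(tissue_contour(bow), "self-intersecting")
  open_c <- tissue_contour(regular_polygon(12), closed = FALSE)
  expect_error(circularity(open_c), "closed")
})

test_that("ring position: annular marker recovered, disk flagged no-ring", {
  sim <- fixture("ring_colony", function() generate_colony(colony_spec(
    equivalent_diameter = 1000, cell_density = 4444,
    zone_boundaries = 200, zone_labels = c("ring", "interior"),
    marker_models = list(SOX2 = marker_model("nuclear", 1, c(150, 0)),
                         FLAT = marker_model("nuclear", 1, c(80, 80))),
    noise = noise_snr(10), seed = 6)))
  geom <- detect_colony(sim$image)
  rp <- ring_position(sim$image, "SOX2", geom)
  expect_false(rp$no_ring)
  expect_lt(abs(rp$ratio / 0.6 - 1), 0.02)
  expect_true(ring_position(sim$image, "FLAT", geom)$no_ring)
})

test_that("ring position is monotone in the generator inner radius", {
  ratios <- vapply(c(120, 200), function(band) {
    sim <- generate_colony(colony_spec(
      equivalent_diameter = 500, cell_density = 4444,
      zone_boundaries = band, zone_labels = c("ring", "interior"),
      marker_models = list(M = marker_model("nuclear", 1, c(150, 0))),
      noise = noise_snr(10), seed = 9))
    ring_position(sim$image, "M", detect_colony(sim$image))$ratio
  }, numeric(1))
  expect_gt(ratios[1], ratios[2])   # narrower band -> larger inner radius
})

test_that("cable angles recover orthogonal and tangential populations", {
  orth <- fixture("cables_orth", function() cable_colony(90, seed = 1))
  ca <- cable_angles(orth$image, "ppMLC", detect_colony(orth$image),
                     folding_axis_offset = 150)
  expect_gt(nrow(ca$segments), 10)
  expect_lt(mean(abs(ca$segments$angle_to_axis - 90)), 5)
  tang <- fixture("cables_tang", function() cable_colony(0, seed = 2))
  ca0 <- cable_angles(tang$image, "ppMLC", detect_colony(tang$image),
                      folding_axis_offset = 150)
  expect_lt(mean(abs(ca0$segments$angle_to_axis)), 5)
})

test_that("a 70/30 orthogonal/tangential mix lands in the right bins", {
  mixed <- fixture("cables_mixed", function()
    cable_colony(c(rep(90, 7), rep(0, 3)), seed = 3, n_cables = 100))
  ca <- cable_angles(mixed$image, "ppMLC", detect_colony(mixed$image),
                     folding_axis_offset = 150)
  h <- ca$histogram
  expect_identical(h$bin[which.max(h$count)], 80)  # mode in [80, 90]
  frac <- mean(ca$segments$angle_to_axis >= 80)
  expect_lt(abs(frac - 0.70), 0.10)
})

test_that("no qualifying cables yields an empty valid result", {
  sim <- plain_colony(seed = 5, density = 1500)
  img <- image_stack(list(DAPI = get_channel(sim$image, "DAPI"),
                          ppMLC = matrix(0, dim(sim$image)[1],
                                         dim(sim$image)[2])),
                     sim$image$pixel_size)
  ca <- cable_angles(img, "ppMLC", detect_colony(img),
                     folding_axis_offset = 50)
  expect_identical(nrow(ca$segments), 0L)
})

test_that("PH3 splits: degenerate cases and binomial recovery", {
  ap <- data.frame(x = c(0, 100), z = c(60, 60))
  ba <- data.frame(x = c(0, 100), z = c(10, 10))
  all_ap <- data.frame(x = runif(20, 0, 100), z = 50, ph3_positive = TRUE)
  r <- apical_basal_ph3(all_ap, ap, ba)
  expect_identical(r$apical_pct, 100)
  expect_identical(r$basal_pct, 0)
  expect_equal(r$apical_pct + r$basal_pct, 100)
  none <- data.frame(x = 1, z = 1, ph3_positive = FALSE)
  expect_true(apical_basal_ph3(none, ap, ba)$empty)
  # generator bias 0.8 at n = 60 within binomial slack
  spec <- cross_section_spec(width = 600, n_cells = 75, ph3_fraction = 0.8,
                             ph3_apical_bias = 0.8, noise = noise_off(),
                             seed = 9)
  sim <- generate_cross_section(spec)
  tr <- sim$truth
  r2 <- apical_basal_ph3(tr$nuclei, tr$apical_surface, tr$basal_surface)
  expect_gte(r2$n_ph3, 40)
  expect_lt(abs(r2$apical_pct - 80), 12)
})

test_that("wedge ratios: rectangles 1, trapezoids 3, apex capped", {
  ap <- data.frame(x = c(0, 100), z = c(50, 50))
  ba <- data.frame(x = c(0, 100), z = c(0, 0))
  rects <- lapply(seq(0, 80, by = 20), function(x0)
    data.frame(x = c(x0, x0 + 10, x0 + 10, x0), z = c(50, 50, 0, 0)))
  expect_equal(wedge_ratio(rects, ap, ba)$mean, 1)
  sim <- generate_cross_section(cross_section_spec(wedge_ratio = 3,
                                                   n_cells = 15,
                                                   noise = noise_off(),
                                                   seed = 4))
  tr <- sim$truth
  hin <- tr$cells$region == "hinge"
  wr <- wedge_ratio(tr$cell_polygons[hin], tr$apical_surface,
                    tr$basal_surface)
  expect_lt(abs(wr$mean / 3 - 1), 0.10)
  # triangle with its apex at the apical surface: capped and flagged
  tri <- list(data.frame(x = c(10, 90, 50), z = c(0, 0, 50)))
  res <- wedge_ratio(tri, ap, ba, cap = 10)
  expect_identical(res$capped, 1L)
  expect_identical(res$ratios, 10)
})

test_that("trilaminar map ranks the reference layer and flags shuffles", {
  set.seed(17)
  n <- 60
  cells <- data.frame(
    x = rep(seq(5, 295, length.out = n / 3), 3),
    z = c(rnorm(n / 3, 20, 2), rnorm(n / 3, 35, 2), rnorm(n / 3, 50, 2)),
    fate = rep(c("SOX2", "T", "SOX17"), each = n / 3))
  tm <- trilaminar_map(cells, n_permutations = 500)
  os <- tm$order_stats
  expect_false(tm$undefined)
  expect_lt(abs(os$mean_offset[os$fate == "SOX2"]), 1)
  expect_gt(os$mean_offset[os$fate == "T"], 10)
  expect_gt(os$mean_offset[os$fate == "SOX17"], 25)
  # extreme layers are displaced from the grand mean; the middle layer
  # sits near it by construction, so only the outer layers must flag
  expect_lt(os$p_perm[os$fate == "SOX17"], 0.05)
  expect_lt(os$p_perm[os$fate == "SOX2"], 0.05)
  # shuffled labels: offsets collapse toward 0 (well below the true
  # 15 and 30 um layer separations)
  sh <- cells; sh$fate <- sample(sh$fate)
  tms <- trilaminar_map(sh, n_permutations = 500)
  expect_true(all(abs(tms$order_stats$mean_offset) < 8))
  # single fate: map renders, order statistic undefined
  one <- cells[cells$fate == "SOX2", ]
  expect_true(trilaminar_map(one)$undefined)
  expect_error(trilaminar_map(data.frame(x = 1, z = 1,
                                         fate = "unclassified")),
               "no classified cells")
})
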