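# Per-cell quantification: colony geometry, disk/annulus sampling against
# brute-force oracles, edge distances, fate classification and count ratios.

test_that("colony equivalent radius is recovered within 2% at full scale", {
  geom <- detect_colony(full_circle()$image)
  expect_lt(abs(geom$equivalent_radius / 500 - 1), 0.02)
})

test_that("square colony polygon area is recovered within 2%", {
  geom <- detect_colony(full_square()$image)
  expect_lt(abs(geom$area / (pi * 500^2) - 1), 0.02)
})

test_that("an all-zero image cannot yield a colony", {
  img <- image_stack(list(DAPI = matrix(0, 64, 64)), 0.624)
  expect_error(detect_colony(img), "DAPI")
})

test_that("a uniform field samples to Nuc = Cyt = v with unit ratio", {
  img <- image_stack(list(DAPI = matrix(1, 64, 64),
                          M = matrix(7, 64, 64)), 1)
  rec <- data.frame(id = 1L, x = 32, y = 32)
  cl <- sample_cell_intensities(img, rec)
  expect_identical(cl$Nuc_M, 7)
  expect_identical(cl$Cyt_M, 7)
  expect_identical(cl$ratio_M, 1)
})

test_that("half-plane sampling matches the brute-force disk enumeration", {
  a <- 10; b <- 30
  m <- matrix(a, 64, 64); m[, 33:64] <- b
  img <- image_stack(list(DAPI = m, M = m), 1)
  cx <- 32; cy <- 31.5          # disk centered on the half-plane boundary
  cl <- sample_cell_intensities(img, data.frame(id = 1L, x = cx, y = cy))
  # independent oracle: enumerate every pixel center within 5 px
  vals <- c()
  for (i in 0:63) for (j in 0:63) {
    if ((j + 0.5 - cx)^2 + (i + 0.5 - cy)^2 <= 25) vals <- c(vals, m[i + 1, j + 1])
  }
  expect_equal(cl$Nuc_M, mean(vals))
  expect_lt(abs(cl$Nuc_M - (a + b) / 2), (b - a) / 10 * 1)  # ~1 px-row bias
})

test_that("the disk radius is recorded in physical units", {
  img <- image_stack(list(DAPI = matrix(1, 32, 32),
                          M = matrix(1, 32, 32)), 0.624)
  cl <- sample_cell_intensities(img, data.frame(id = 1L, x = 10, y = 10),
                                disk_radius_px = 5)
  expect_equal(attr(cl, "disk_radius_um"), 3.12)
})

test_that("sampling is local: pixels outside the masks cannot change it", {
  m <- matrix(runif(64 * 64), 64, 64) + 1
  img <- image_stack(list(DAPI = m, M = m), 1)
  rec <- data.frame(id = 1L, x = 32, y = 32)
  base <- sample_cell_intensities(img, rec)
  m2 <- m
  m2[1, 1] <- 1e6          # far outside disk and annulus
  m2[32, 32 + 12] <- 1e6   # just beyond the annulus outer radius (10 px)
  img2 <- image_stack(list(DAPI = m2, M = m2), 1)
  pert <- sample_cell_intensities(img2, rec)
  expect_identical(base$Nuc_M, pert$Nuc_M)
  expect_identical(base$Cyt_M, pert$Cyt_M)
  # a pixel inside the disk does change Nuc
  m3 <- m; m3[32, 32] <- 1e6
  img3 <- image_stack(list(DAPI = m3, M = m3), 1)
  expect_false(identical(base$Nuc_M,
                         sample_cell_intensities(img3, rec)$Nuc_M))
})

test_that("zero cytosolic signal flags the ratio undefined", {
  m <- matrix(0, 64, 64); m[29:35, 29:35] <- 50   # marker only in nucleus
  img <- image_stack(list(DAPI = m, M = m), 1)
  cl <- sample_cell_intensities(img, data.frame(id = 1L, x = 32, y = 32))
  expect_true(is.na(cl$ratio_M))
  expect_true(is.na(cl$Cyt_M) || cl$Cyt_M == 0)
})

test_that("generator Nuc:Cyt ratio 3 is recovered within 5% (no noise)", {
  sim <- ratio_colony(seed = 11, noise = noise_off())
  q <- quantify_colony(sim, seg_params(clahe = FALSE))
  r <- q$cells$ratio_SMAD2[!q$cells$clipped]
  expect_lt(abs(stats::median(r, na.rm = TRUE) / 3 - 1), 0.05)
})

test_that("generator Nuc:Cyt ratio 3 is recovered within 15% at SNR 5", {
  sim <- ratio_colony(seed = 12, noise = noise_snr(5))
  q <- quantify_colony(sim, seg_params(clahe = FALSE))
  r <- q$cells$ratio_SMAD2[!q$cells$clipped]
  expect_lt(abs(stats::median(r, na.rm = TRUE) / 3 - 1), 0.15)
})

test_that("edge distance honors symmetry, boundary and a brute-force oracle", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  R <- 100
  poly <- data.frame(x = R * cos(th) + 120, y = R * sin(th) + 120)
  colony <- list(boundary_polygon = poly)
  center <- edge_distances(data.frame(x = 120, y = 120), colony)
  expect_lt(abs(center$edge_distance / R - 1), 0.01)
  onb <- edge_distances(data.frame(x = 120 + R, y = 120), colony)
  expect_lt(abs(onb$edge_distance), 0.5)
  # arbitrary polygon vs densely sampled boundary
  set.seed(31)
  pg <- data.frame(x = c(0, 40, 55, 30, 10), y = c(0, 5, 35, 50, 30))
  pts <- data.frame(x = runif(20, 5, 35), y = runif(20, 8, 30))
  got <- edge_distances(pts, list(boundary_polygon = pg))$edge_distance
  dense <- do.call(rbind, lapply(seq_len(nrow(pg)), function(i) {
    j <- if (i == nrow(pg)) 1 else i + 1
    t <- seq(0, 1, length.out = 4000)
    cbind(pg$x[i] + t * (pg$x[j] - pg$x[i]),
          pg$y[i] + t * (pg$y[j] - pg$y[i]))
  }))
  oracle <- vapply(seq_len(nrow(pts)), function(k)
    min(sqrt((dense[, 1] - pts$x[k])^2 + (dense[, 2] - pts$y[k])^2)),
    numeric(1))
  expect_true(all(abs(abs(got) - oracle) < 0.1))
})

test_that("cells outside the polygon get negative flagged distances", {
  pg <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  d <- edge_distances(data.frame(x = c(5, 15), y = c(5, 5)),
                      list(boundary_polygon = pg))
  expect_false(d$outside[1]); expect_true(d$outside[2])
  expect_gt(d$edge_distance[1], 0); expect_lt(d$edge_distance[2], 0)
})

test_that("fate classification is winner-takes-all with a margin", {
  cells <- data.frame(nucleus_id = 1:3, x = 0, y = 0,
                      Nuc_SOX2 = c(100, 50, 100),
                      Nuc_T = c(10, 50, 90),
                      Nuc_SOX17 = c(10, 50, 10))
  out <- classify_fate(cells)
  expect_identical(as.character(out$fate),
                   c("SOX2", "unclassified", "unclassified"))
})

test_that("three-zone colony fates match ground truth for >= 95% of cells", {
  sim <- generate_colony(small_colony_spec(seed = 21))
  q <- quantify_colony(sim)
  idx <- nearest_truth(q$cells, sim$truth$nuclei)
  acc <- mean(as.character(q$cells$fate) == sim$truth$nuclei$fate[idx])
  expect_gte(acc, 0.95)
})

test_that("fate count ratios report exact counts and flag zero denominators", {
  cells <- data.frame(x = c(1:5), y = 1,
                      fate = c("T", "T", "SOX2", "SOX2", "SOX2"))
  r <- fate_count_ratio(cells, "T", "SOX2")
  expect_identical(r$count_a, 2L); expect_identical(r$count_b, 3L)
  expect_equal(r$ratio, 2 / 3)
  roi <- data.frame(x = c(2.5, 5.5, 5.5, 2.5), y = c(0, 0, 2, 2))
  r2 <- fate_count_ratio(cells, "T", "SOX2", roi = roi)
  expect_identical(r2$count_a, 0L)
  expect_true(is.na(r2$ratio))
})

test_that("smaller colonies have larger edge-band to interior cell ratios", {
  # fixed 50 um T band: band area scales with perimeter, interior with area
  ratios <- vapply(c(500, 1000), function(d) {
    sim <- generate_colony(colony_spec(equivalent_diameter = d,
                                       cell_density = 2000,
                                       noise = noise_off(), seed = 8))
    nt <- sim$truth$nuclei
    r <- fate_count_ratio(nt, "T", "SOX2")
    r$ratio
  }, numeric(1))
  expect_gt(ratios[1], ratios[2])
})

test_that("marker deficit in one fate group is recovered", {
  cells <- data.frame(x = 1, y = 1, fate = rep(c("SOX2", "T"), each = 40),
                      Nuc_bcat = rep(c(50, 100), each = 40) + rnorm(80, 0, 2))
  g <- marker_level_by_fate(cells, "bcat", "SOX2")
  expect_lt(abs(g$mean[g$group == "positive"] /
                  g$mean[g$group == "negative"] - 0.5), 0.05)
  # identical marker -> equal means; n = 1 -> sem undefined
  eq <- data.frame(x = 1, y = 1, fate = c("SOX2", "T", "T"),
                   Nuc_m = c(5, 5, 5))
  ge <- marker_level_by_fate(eq, "m", "SOX2")
  expect_equal(ge$mean[1], ge$mean[2])
  expect_true(is.na(ge$sem[ge$group == "positive"]))
})
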