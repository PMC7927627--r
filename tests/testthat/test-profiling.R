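# Radial profiling: smoother fidelity on constant/linear inputs, shift
# equivariance, step recovery through the full pipeline, pooling behavior
# and line profiles.

fake_cells <- function(n = 200, fn = function(d) rep(5, length(d)),
                       noise_sd = 0, seed = 1, dmax = 100) {
  withr::with_seed(seed, {
    d <- runif(n, 0, dmax)
    data.frame(nucleus_id = seq_len(n), x = d, y = d, clipped = FALSE,
               outside = FALSE, edge_distance = d,
               Nuc_M = fn(d) + rnorm(n, 0, noise_sd))
  })
}

test_that("the smoother preserves constants exactly", {
  p <- profile_colony(fake_cells(), "M", "nuclear")
  expect_equal(p$mean, rep(5, length(p$mean)))
})

test_that("a noiseless linear trend is recovered except at the grid edge", {
  cells <- fake_cells(fn = function(d) 2 * d + 3)
  p <- profile_colony(cells, "M", "nuclear")
  inner <- p$distance <= 0.95 * max(p$distance)
  expect_lt(max(abs(p$mean[inner] - (2 * p$distance[inner] + 3)) /
                  (2 * p$distance[inner] + 3)), 0.01)
})

test_that("the smoother is shift-equivariant in intensity", {
  cells <- fake_cells(fn = function(d) sin(d / 10) * 20 + 50, noise_sd = 3)
  p1 <- profile_colony(cells, "M", "nuclear")
  cells$Nuc_M <- cells$Nuc_M + 17
  p2 <- profile_colony(cells, "M", "nuclear")
  expect_equal(p2$mean, p1$mean + 17, tolerance = 1e-9)
})

test_that("noiseless monotone input yields a monotone profile", {
  cells <- fake_cells(fn = function(d) 100 - 0.8 * d)
  p <- profile_colony(cells, "M", "nuclear")
  inner <- p$distance <= 0.95 * max(p$distance)
  expect_true(all(diff(p$mean[inner]) < 1e-8))
})

test_that("pooled step profile stays within 10% of the generating profile", {
  profs <- list()
  for (seed in 1:5) {
    sim <- generate_colony(small_colony_spec(seed = seed))
    q <- quantify_colony(sim)
    cl <- q$cells
    cl$Nuc_T <- cl$Nuc_T - q$bg$bg_median[q$bg$channel == "T"]
    profs[[seed]] <- profile_colony(cl, "T", "nuclear", grid_max = 100)
  }
  pool <- pool_profiles(profs)
  gp <- generate_colony(small_colony_spec(seed = 1))$truth$
    generating_profiles$T
  gen <- stats::approx(gp$distance, gp$value, xout = pool$distance,
                       rule = 2)$y
  dr <- diff(range(gen))
  away <- abs(pool$distance - 50) > 0.3 * 100  # +/- one smoothing span
  expect_lt(max(abs(pool$mean - gen)[away]) / dr, 0.10)
})

test_that("pooling identical profiles gives zero sem; offsets cancel", {
  p <- profile_colony(fake_cells(fn = function(d) d + 1), "M", "nuclear")
  pool <- pool_profiles(list(p, p, p))
  expect_equal(pool$mean, p$mean)
  expect_equal(pool$sem, rep(0, nrow(pool)))
  up <- p; up$mean <- p$mean + 4
  dn <- p; dn$mean <- p$mean - 4
  expect_equal(pool_profiles(list(up, dn))$mean, p$mean)
})

test_that("pooled sem shrinks with replicate count", {
  mk <- function(seed) profile_colony(
    fake_cells(fn = function(d) 50 + 0.5 * d, noise_sd = 10, seed = seed,
               n = 120), "M", "nuclear", grid_max = 95)
  profs <- lapply(1:32, mk)
  sems <- vapply(c(2, 8, 32), function(k)
    mean(pool_profiles(profs[1:k])$sem), numeric(1))
  expect_true(all(diff(sems) < 0))
})

test_that("pooling on average beats any single replicate", {
  gen <- function(d) ifelse(d < 50, 150, 15)
  wins <- 0L
  for (trial in 1:20) {
    profs <- lapply(1:5, function(s) profile_colony(
      fake_cells(fn = gen, noise_sd = 30, seed = 100 * trial + s, n = 150),
      "M", "nuclear", grid_max = 95))
    grid <- profs[[1]]$distance
    g <- gen(grid)
    # away from the step, where smoothing bias is common to every profile
    # and the comparison isolates the noise advantage of pooling
    away <- abs(grid - 50) > 15
    rmse <- function(p) sqrt(mean((p$mean[away] - g[away])^2))
    if (rmse(pool_profiles(profs)) < min(vapply(profs, rmse, numeric(1))))
      wins <- wins + 1L
  }
  expect_gte(wins / 20, 0.8)
})

test_that("profiles with mixed grids or too few cells are rejected", {
  p1 <- profile_colony(fake_cells(), "M", "nuclear", grid_max = 100)
  p2 <- profile_colony(fake_cells(), "M", "nuclear", grid_max = 50)
  expect_error(pool_profiles(list(p1, p2)), "mixed grids")
  expect_error(profile_colony(fake_cells(n = 5), "M", "nuclear"),
               "usable cells")
})

test_that("line profiles: uniform flat, orthogonal ramp flat, ring peaks", {
  u <- image_stack(list(M = matrix(4, 80, 80)), 1)
  lp <- line_profile(u, c(10, 40), c(70, 40))
  expect_equal(unique(lp$M), 4)
  ramp <- image_stack(list(M = matrix(rep(1:80, each = 80), 80, 80,
                                      byrow = TRUE)), 1)
  # vertical ramp (varies along y), horizontal segment -> flat
  lp2 <- line_profile(ramp, c(10, 40), c(70, 40))
  expect_lt(diff(range(lp2$M)), 1e-9)
  # annulus of radius 25: two crossings separated by the diameter
  m <- matrix(0, 120, 120)
  for (i in 1:120) for (j in 1:120) {
    r <- sqrt((i - 60.5)^2 + (j - 60.5)^2)
    if (r >= 23 & r <= 27) m[i, j] <- 100
  }
  ring <- image_stack(list(M = m), 1)
  lp3 <- line_profile(ring, c(10, 60), c(110, 60))
  peaks <- lp3$distance[lp3$M > 50]
  sep <- max(peaks) - min(peaks)
  expect_lt(abs(sep - 2 * 25), 4 + 2)   # ring width + 2 px tolerance
  expect_error(line_profile(u, c(10, 10), c(10, 10)), "degenerate")
})
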