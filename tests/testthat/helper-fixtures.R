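# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; seeds are part of the fixture definition.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Three-zone colony at the study conditions (4444 cells/mm², T band within
# 50 µm, SOX17 band at 50-100 µm, SOX2 interior), scaled to ~200 nuclei.
small_colony_spec <- function(seed, noise = noise_snr(5),
                              touching_fraction = 0) {
  colony_spec(equivalent_diameter = 239, cell_density = 4444,
              touching_fraction = touching_fraction, noise = noise,
              seed = seed)
}

# Well-separated nuclei, no markers, no noise: segmentation geometry tests.
plain_colony <- function(seed = 3, noise = noise_off(), density = 1500,
                         diameter = 239) {
  generate_colony(colony_spec(equivalent_diameter = diameter,
                              cell_density = density, noise = noise,
                              zone_boundaries = numeric(0),
                              zone_labels = "all", marker_models = list(),
                              seed = seed))
}

# Full-scale colony for geometry-accuracy tests (placement noise at the
# boundary scales as 1/sqrt(n), so accuracy examples use ~3500 nuclei).
full_circle <- function() fixture("full_circle", function() {
  generate_colony(colony_spec(equivalent_diameter = 1000,
                              cell_density = 4444, noise = noise_snr(10),
                              seed = 2))
})

full_square <- function() fixture("full_square", function() {
  generate_colony(colony_spec(shape = "square", equivalent_diameter = 1000,
                              cell_density = 4444, noise = noise_snr(10),
                              seed = 2))
})

# Nuc:Cyt recovery fixture: nuclei matched to the 5 px sampling disk so the
# dilated annulus is a clean cytosol proxy (see the methods vignette).
ratio_colony <- function(seed, noise) {
  generate_colony(colony_spec(
    equivalent_diameter = 239, cell_density = 1500, noise = noise,
    nuc_radius_mean = 3.12, nuc_radius_sd = 0.05,
    zone_boundaries = numeric(0), zone_labels = "all",
    marker_models = list(SMAD2 = marker_model("nuclear", 3, 150)),
    seed = seed))
}

# Cable fixture: colony with a circumferential folding axis and oriented
# cables, nuclei dense enough for reliable colony detection.
cable_colony <- function(angles, seed, n_cables = 40) {
  generate_colony(colony_spec(
    equivalent_diameter = 600, cell_density = 4444, noise = noise_off(),
    zone_boundaries = numeric(0), zone_labels = "all",
    marker_models = list(), folding_axis_offset = 150,
    cable_spec = list(n_cables = n_cables, length_range = c(20, 30),
                      angles = angles), seed = seed))
}

# Segment + quantify (+ classify when fate channels exist) one colony.
# Sparse preparations disable local contrast equalization (see vignette).
quantify_colony <- function(sim, params = seg_params()) {
  seg <- segment_nuclei(sim$image, params)
  geom <- detect_colony(sim$image)
  bg <- background_stats(sim$image, geom)
  cl <- sample_cell_intensities(sim$image, seg$records, background = bg)
  cl <- edge_distances(cl, geom)
  if (all(c("Nuc_SOX2", "Nuc_T", "Nuc_SOX17") %in% names(cl)))
    cl <- classify_fate(cl, background = bg)
  list(cells = cl, geom = geom, seg = seg, bg = bg)
}

regular_polygon <- function(n, R = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  data.frame(x = R * cos(th), y = R * sin(th))
}

# Match each measured cell to the nearest ground-truth nucleus.
nearest_truth <- function(cells, truth_nuclei) {
  vapply(seq_len(nrow(cells)), function(i) {
    d <- (truth_nuclei$x - cells$x[i])^2 + (truth_nuclei$y - cells$y[i])^2
    which.min(d)
  }, integer(1L))
}
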