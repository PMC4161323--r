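# Shared in-code fixtures: geometry, simulated distances, small survey worlds.

# land strip occupying x < width, spanning well beyond the given bbox
strip_land <- function(width, bbox = c(0, 0, 60000, 60000)) {
  as_land_polygon(rbind(
    c(bbox[1] - 50000, bbox[2] - 50000),
    c(width,           bbox[2] - 50000),
    c(width,           bbox[4] + 50000),
    c(bbox[1] - 50000, bbox[4] + 50000)))
}

# half-normal perpendicular distances truncated at w
sim_hn_distances <- function(n, sigma, w, seed) {
  set.seed(seed)
  x <- abs(stats::rnorm(ceiling(n * 1.3) + 50, 0, sigma))
  x <- x[x <= w]
  stopifnot(length(x) >= n)
  x[seq_len(n)]
}

# a small all-sea world with flat truth, used by several survey tests
flat_world <- function(base = 5, nx = 30000, seed = 1L, detection_form = "unity",
                       sigma = 120, spacing = 3000, seg_len = 1500, w = 300,
                       frac_flying = 0) {
  grid <- make_grid(c(0, 0, nx, nx), 3000)
  truth <- make_truth(grid, base = base)
  scen <- scenario_config(seed = seed, platform = "boat", spacing = spacing,
                          segment_length = seg_len,
                          detection = list(form = detection_form,
                                           sigma = sigma, b = 2.5),
                          truncation = w, frac_flying = frac_flying)
  list(grid = grid, truth = truth, scen = scen,
       sim = simulate_survey(truth, grid, scen))
}

# synthetic density surface on a toy grid (for fusion/mapping tests)
toy_surface <- function(density, cv, n = length(density)) {
  data.frame(cell_id = seq_len(n), x = seq_len(n) * 3000, y = 1500,
             area = 9, density = density, cv = cv,
             extrapolated = FALSE)
}

fixture_path <- function(...) testthat::test_path("fixtures", ...)

# the standard hotspot scenario the package documents for validation:
# one region, straight west coast, offshore hotspot, ~300 boat segments
hotspot_world <- function(seed = 1L) {
  cfg <- default_config(seed = seed)
  coast <- strip_land(cfg$grid$coast_land_width, cfg$grid$bbox)
  grid <- make_grid(cfg$grid$bbox, cfg$grid$cellsize, coast)
  sc <- cfg$scenario
  truth <- make_truth(grid, base = sc$base_density, hotspots = list(sc$hotspot),
                      coastal_gradient = sc$coastal_gradient)
  scen <- scenario_config(seed = seed, platform = "boat",
                          spacing = sc$boat$spacing,
                          segment_length = sc$boat$segment_length,
                          detection = list(form = "half-normal",
                                           sigma = sc$boat$sigma, b = 2.5),
                          truncation = sc$boat$truncation,
                          frac_flying = 0)
  list(cfg = cfg, grid = grid, truth = truth, scen = scen,
       sim = simulate_survey(truth, grid, scen, coastline = coast))
}
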