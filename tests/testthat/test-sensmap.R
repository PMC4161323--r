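# Behaviour combination, CV-gated platform fusion, sensitivity map algebra.

test_that("sitting and flying densities add, CVs combine by variance", {
  sit <- toy_surface(c(2.0, 1.0, NA), c(0.2, 0.3, NA))
  fly <- toy_surface(c(0.0, 1.0, NA), c(NA, 0.3, NA))
  comb <- combine_behaviours(sit, fly)
  expect_equal(comb$density, c(2.0, 2.0, NA))
  expect_equal(comb$cv[1], 0.2)
  expect_equal(comb$cv[2], sqrt(0.09 + 0.09) / 2, tolerance = 1e-12)
  expect_true(is.na(comb$cv[3]))
  # a fully absent component passes the other through
  expect_message(alone <- combine_behaviours(sit, NULL), "absent")
  expect_equal(alone$density, sit$density)
  expect_error(combine_behaviours(sit, toy_surface(1, 0.1, n = 1)),
               "different grids")
})

test_that("platform fusion follows the max-density and lowest-CV rules", {
  boat   <- toy_surface(c(2.0, 2.0, 2.0, 5.0), c(0.20, 0.40, 0.60, 0.55))
  aerial <- toy_surface(c(3.0, 3.0, 3.0, 1.0), c(0.25, 0.45, 0.70, 0.28))
  fused <- fuse_platforms(boat, aerial)
  # both CVs < 0.3: take the maximum density
  expect_equal(fused$density[1], 3.0)
  expect_equal(fused$source[1], "aerial")
  # neither below 0.3: take the lowest CV
  expect_equal(fused$density[2], 2.0)
  expect_equal(fused$cv[2], 0.40)
  # both above 0.5: excluded, cell missing
  expect_true(is.na(fused$density[3]))
  # one excluded, the survivor is taken whatever its density
  expect_equal(fused$density[4], 1.0)
  expect_equal(fused$source[4], "aerial")
  expect_error(fuse_platforms(boat, aerial, cv_keep_max = 0.6),
               "below cv_exclude")
})

test_that("a lone platform fuses as itself under the same CV gates", {
  boat <- toy_surface(c(2.0, 4.0), c(0.2, 0.7))
  fused <- fuse_platforms(boat, NULL)
  expect_equal(fused$density, c(2.0, NA))
})

test_that("species layers are SSI times log density plus one", {
  s <- toy_surface(c(0, exp(1) - 1, 1, NA), c(0.1, 0.1, 0.1, NA))
  expect_equal(species_layer(s, 32)$value, c(0, 32, 32 * log(2), NA))
  expect_equal(species_layer(s, 1470)$value[3], 1470 * log(2))
  expect_equal(round(species_layer(s, 1470)$value[3], 2), 1018.93)
  s$density[1] <- -0.5
  expect_error(species_layer(s, 10), "negative density")
  expect_error(species_layer(s, -3), "ssi_value >= 0")
})

test_that("aggregation equals a brute-force per-cell sum over species", {
  set.seed(71)
  n <- 40
  layers <- lapply(1:5, function(i) {
    d <- runif(n, 0, 10)
    d[sample(n, 8)] <- NA   # patchy coverage per species
    species_layer(toy_surface(d, rep(0.1, n)), ssi_value = i * 50)
  })
  agg <- aggregate_layers(layers, season = "winter", risk_type = "collision")
  brute <- sapply(seq_len(n), function(k)
    sum(vapply(layers, function(l) {
      v <- l$value[k]; if (is.na(v)) 0 else v
    }, numeric(1))))
  expect_equal(agg$value, brute)
  expect_equal(attr(agg, "season"), "winter")
  # permutation invariance and additivity over disjoint species sets
  agg_rev <- aggregate_layers(rev(layers), season = "winter",
                              risk_type = "collision")
  expect_equal(agg$value, agg_rev$value)
  a12 <- aggregate_layers(layers[1:2], risk_type = "collision")
  a35 <- aggregate_layers(layers[3:5], risk_type = "collision")
  expect_equal(agg$value, a12$value + a35$value)
})

test_that("cells with no usable species data emit exactly zero and a mask", {
  l1 <- species_layer(toy_surface(c(1, NA, NA), c(0.1, NA, NA)), 100)
  l2 <- species_layer(toy_surface(c(NA, 2, NA), c(NA, 0.1, NA)), 10)
  agg <- aggregate_layers(list(l1, l2))
  expect_equal(agg$data_ok, c(TRUE, TRUE, FALSE))
  expect_identical(agg$value[3], 0)
  expect_equal(agg$value[1], 100 * log(2))
  expect_error(aggregate_layers(list()), "no species layers")
})

test_that("doubling all densities strictly increases every covered value", {
  d <- c(0.5, 2, 7)
  l1 <- aggregate_layers(list(species_layer(toy_surface(d, rep(0.1, 3)), 20)))
  l2 <- aggregate_layers(list(species_layer(toy_surface(2 * d, rep(0.1, 3)), 20)))
  expect_true(all(l2$value > l1$value))
})

test_that("the overall map uses the higher of the two categorical scores", {
  scored <- score_table(load_species_scores())
  hg <- scored[scored$species == "Herring gull", ]
  rtd <- scored[scored$species == "Red-throated diver", ]
  expect_equal(hg$collision_cat, 5L); expect_equal(hg$displacement_cat, 1L)
  expect_equal(hg$overall_cat, 5L)
  expect_equal(rtd$collision_cat, 3L); expect_equal(rtd$displacement_cat, 4L)
  expect_equal(rtd$overall_cat, 4L)
  dens <- list("Herring gull" = toy_surface(c(1, 2), c(0.1, 0.1)),
               "Red-throated diver" = toy_surface(c(2, 0), c(0.1, 0.1)))
  m <- overall_map(dens,
                   collision_cat = c("Herring gull" = 5L,
                                     "Red-throated diver" = 3L),
                   displacement_cat = c("Herring gull" = 1L,
                                        "Red-throated diver" = 4L))
  expect_equal(m$value[1], 5 * log(2) + 4 * log(3))
  # a species missing one risk class contributes the category it has
  m2 <- overall_map(dens["Herring gull"],
                    collision_cat = c("Herring gull" = 5L),
                    displacement_cat = integer(0))
  expect_equal(m2$value[2], 5 * log(3))
})

test_that("an isolated high-collision hotspot dominates the collision map", {
  # end-to-end: one species concentrated in one cell; the argmax of the
  # collision layer must be the truth hotspot cell
  g <- make_grid(c(0, 0, 30000, 30000), 3000)
  tr <- make_truth(g, base = 0.2,
                   hotspots = list(list(x = 16500, y = 19500, radius = 3000,
                                        amplitude = 30)))
  scen <- scenario_config(seed = 77, platform = "boat", spacing = 3000,
                          segment_length = 1500,
                          detection = list(form = "half-normal", sigma = 150,
                                           b = 2.5),
                          frac_flying = 0)
  sim <- simulate_survey(tr, g, scen)
  f <- fit_detection(rep(sim$observations$perp_distance,
                         sim$observations$count), w = 300,
                     form = "half-normal")
  segs <- correct_segment_counts(sim$segments, sim$observations, f)
  m <- suppressWarnings(fit_dsm(segs, terms = "xy"))
  surf <- predict_grid(m, g)
  surf$cv <- cell_cv(m, g, cv_p = f$cv_p, n_draws = 100, seed = 7)
  layer <- aggregate_layers(list(species_layer(surf, 1470)),
                            risk_type = "collision")
  truth_cell <- tr$cell_id[which.max(tr$density)]
  expect_equal(layer$cell_id[which.max(layer$value)], truth_cell)
})

test_that("layers serialise with a shared rendering scale in metadata", {
  lay <- aggregate_layers(list(species_layer(toy_surface(c(1, 3), c(.1, .1)),
                                             10)),
                          season = "summer", risk_type = "overall")
  p <- tempfile(fileext = ".csv")
  write_sensitivity_layer(lay, p, scale = c(0, 99))
  meta <- jsonlite::read_json(paste0(p, ".meta.json"))
  expect_equal(meta$shared_scale$max, 99)
  expect_equal(meta$risk_type, "overall")
  back <- read_table_csv(p)
  expect_equal(back$value, lay$value)
})
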