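# VIF screening, density surface fitting, prediction, CVs, fallback.

test_that("VIF is 1 for orthogonal covariates and Inf for collinear ones", {
  x1 <- rep(c(-1, 1), 50)
  x2 <- rep(c(-1, -1, 1, 1), 25)
  v <- compute_vif(data.frame(x1 = x1, x2 = x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-10)
  v2 <- compute_vif(data.frame(a = x1, b = 2 * x1))
  expect_true(is.infinite(v2[["a"]]))
})

test_that("VIF of a correlated pair matches the closed form 1/(1-r^2)", {
  set.seed(12)
  n <- 4000
  z <- rnorm(n)
  a <- z + rnorm(n, sd = sqrt(1 / 0.81 - 1))  # cor(a, z) ~ 0.9
  v <- compute_vif(data.frame(a = a, z = z))
  r2 <- cor(a, z)^2
  expect_equal(unname(v[["a"]]), 1 / (1 - r2), tolerance = 1e-8)
  expect_equal(unname(v[["a"]]), 5.26, tolerance = 0.6)
})

test_that("covariate screening drops the weaker of a collinear pair", {
  set.seed(13)
  n <- 200
  cdist <- runif(n, 0, 50)
  depth <- 2 * cdist + rnorm(n, sd = 1)   # strongly collinear with cdist
  other <- rnorm(n)
  covs <- data.frame(cdist = cdist, depth = depth, other = other)
  keep <- choose_covariates(covs, c(cdist = 0.4, depth = 0.25, other = 0.1))
  expect_setequal(keep, c("cdist", "other"))
  # all below threshold: keep everything
  covs2 <- data.frame(a = rnorm(n), b = rnorm(n))
  expect_setequal(choose_covariates(covs2, c(a = 1, b = 2)), c("a", "b"))
})

test_that("three-way collinearity resolves by greedy worst-first dropping", {
  set.seed(14)
  n <- 300
  a <- rnorm(n)
  b <- a + rnorm(n, sd = 0.05)
  c_ <- a - b + rnorm(n, sd = 0.05)
  covs <- data.frame(a = a, b = b, c_ = c_)
  keep <- choose_covariates(covs, c(a = 3, b = 2, c_ = 1), threshold = 5)
  expect_true("a" %in% keep)
  expect_true(max(compute_vif(covs[keep])) <= 5 || length(keep) < 2)
})

test_that("a constant-truth survey refits to a near-flat surface", {
  world <- flat_world(base = 5, detection_form = "half-normal", sigma = 120,
                      seed = 51, spacing = 3000, seg_len = 1500)
  obs <- world$sim$observations
  f <- fit_detection(rep(obs$perp_distance, obs$count), w = 300,
                     form = "half-normal")
  segs <- correct_segment_counts(world$sim$segments, obs, f)
  m <- suppressWarnings(fit_dsm(segs, terms = "xy"))
  surf <- predict_grid(m, world$grid)
  inside <- !is.na(surf$density) & !surf$extrapolated
  expect_true(all(abs(surf$density[inside] - 5) / 5 < 0.15))
})

test_that("an all-zero response yields a near-zero surface without crashing", {
  world <- flat_world(base = 5, detection_form = "unity", seed = 52)
  segs <- world$sim$segments
  segs$nhat <- 0
  m <- suppressWarnings(fit_dsm(segs, terms = "xy"))
  surf <- predict_grid(m, world$grid)
  expect_true(all(surf$density < 1e-4, na.rm = TRUE))
})

test_that("fitted values balance the observed total on the log link", {
  world <- flat_world(base = 6, detection_form = "unity", seed = 53)
  segs <- world$sim$segments
  counts <- tapply(world$sim$observations$count,
                   world$sim$observations$segment_id, sum)
  segs$nhat <- 0
  segs$nhat[match(as.integer(names(counts)), segs$segment_id)] <- counts
  m <- suppressWarnings(fit_dsm(segs, terms = "xy"))
  expect_lt(abs(sum(fitted(m$gam)) - sum(segs$nhat)) / sum(segs$nhat), 0.005)
})

test_that("prediction converts the linear predictor through the area offset", {
  # intercept-only model: density exp(b0) everywhere, abundance scales by area
  world <- flat_world(base = 5, detection_form = "unity", seed = 54)
  segs <- world$sim$segments
  counts <- tapply(world$sim$observations$count,
                   world$sim$observations$segment_id, sum)
  segs$nhat <- 0
  segs$nhat[match(as.integer(names(counts)), segs$segment_id)] <- counts
  m <- suppressWarnings(fit_dsm(segs, terms = character(0)))
  b0 <- unname(coef(m$gam)[1])
  grid <- world$grid
  grid$area[5] <- 4.5   # a coastal cell
  surf <- predict_grid(m, grid)
  expect_equal(surf$density, rep(exp(b0), nrow(grid)), tolerance = 1e-8)
  expect_equal(surf$density[5] * grid$area[5], exp(b0) * 4.5, tolerance = 1e-8)
})

test_that("predictions are invariant under translation of the coordinates", {
  world <- hotspot_world(seed = 55)
  obs <- world$sim$observations
  f <- fit_detection(rep(obs$perp_distance, obs$count), w = 300,
                     form = "half-normal")
  segs <- correct_segment_counts(world$sim$segments, obs, f)
  m1 <- suppressWarnings(fit_dsm(segs))
  s1 <- predict_grid(m1, world$grid)
  segs2 <- segs; segs2$x <- segs2$x + 5e5; segs2$y <- segs2$y - 2e5
  grid2 <- world$grid; grid2$x <- grid2$x + 5e5; grid2$y <- grid2$y - 2e5
  m2 <- suppressWarnings(fit_dsm(segs2))
  s2 <- predict_grid(m2, grid2)
  expect_equal(s1$density, s2$density, tolerance = 1e-6)
})

test_that("posterior-simulation CV matches the analytic lognormal CV on an intercept model", {
  world <- flat_world(base = 5, detection_form = "unity", seed = 56)
  segs <- world$sim$segments
  counts <- tapply(world$sim$observations$count,
                   world$sim$observations$segment_id, sum)
  segs$nhat <- 0
  segs$nhat[match(as.integer(names(counts)), segs$segment_id)] <- counts
  m <- suppressWarnings(fit_dsm(segs, terms = character(0)))
  cv <- cell_cv(m, world$grid, cv_p = 0, n_draws = 1000, seed = 3)
  v <- m$gam$Vp[1, 1]
  analytic <- sqrt(exp(v) - 1)   # CV of a lognormal with log-scale var v
  expect_lt(abs(median(cv, na.rm = TRUE) - analytic) / analytic, 0.1)
})

test_that("detection CV folds into the total CV in quadrature", {
  world <- flat_world(base = 5, detection_form = "unity", seed = 57)
  segs <- world$sim$segments
  counts <- tapply(world$sim$observations$count,
                   world$sim$observations$segment_id, sum)
  segs$nhat <- 0
  segs$nhat[match(as.integer(names(counts)), segs$segment_id)] <- counts
  m <- suppressWarnings(fit_dsm(segs, terms = character(0)))
  cv0 <- cell_cv(m, world$grid, cv_p = 0, n_draws = 400, seed = 5)
  cv4 <- cell_cv(m, world$grid, cv_p = 0.4, n_draws = 400, seed = 5)
  expect_equal(cv4, sqrt(cv0^2 + 0.4^2), tolerance = 1e-10)
  # the 3-4-5 identity
  expect_equal(sqrt(0.3^2 + 0.4^2), 0.5)
})

test_that("land cells and unfitted regions stay missing, not zero", {
  world <- hotspot_world(seed = 58)
  obs <- world$sim$observations
  f <- fit_detection(rep(obs$perp_distance, obs$count), w = 300,
                     form = "half-normal")
  segs <- correct_segment_counts(world$sim$segments, obs, f)
  m <- suppressWarnings(fit_dsm(segs))
  surf <- predict_grid(m, world$grid)
  expect_true(all(is.na(surf$density[!world$grid$is_sea])))
  expect_true(any(surf$extrapolated, na.rm = TRUE))
})

test_that("smoothing toward the null space flattens the surface monotonically", {
  world <- flat_world(base = 5, detection_form = "unity", seed = 59)
  segs <- world$sim$segments
  counts <- tapply(world$sim$observations$count,
                   world$sim$observations$segment_id, sum)
  segs$nhat <- 0
  segs$nhat[match(as.integer(names(counts)), segs$segment_id)] <- counts
  segs$x_c <- segs$x - mean(segs$x); segs$y_c <- segs$y - mean(segs$y)
  rough <- vapply(c(0.01, 1, 100, 1e5), function(lambda) {
    g <- mgcv::gam(nhat ~ s(x_c, y_c, k = 20) + offset(log(covered_area)),
                   data = segs, family = mgcv::nb(), sp = lambda)
    stats::sd(predict(g, type = "terms")[, 1])
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("coverage-normalised fallback divides corrected counts by effort", {
  g <- make_grid(c(0, 0, 9000, 9000), 3000)
  segs <- data.frame(segment_id = 1, x = 1500, y = 1500, nhat = 20,
                     covered_area = 0.6)
  surf <- relative_density_fallback(segs, g)
  expect_equal(surf$density[1], 20 / 0.6)
  expect_true(all(is.na(surf$density[-1])))  # no effort: missing, not zero
})

test_that("fallback densities over a uniform survey recover the truth", {
  world <- flat_world(base = 10, detection_form = "half-normal", sigma = 120,
                      seed = 60)
  obs <- world$sim$observations
  f <- fit_detection(rep(obs$perp_distance, obs$count), w = 300,
                     form = "half-normal")
  segs <- correct_segment_counts(world$sim$segments, obs, f)
  surf <- relative_density_fallback(segs, world$grid, cv_p = f$cv_p)
  covered <- !is.na(surf$density)
  est <- mean(surf$density[covered])
  n_eff <- sum(segs$covered_area)
  se <- sqrt(10 / n_eff / f$p_bar) + 10 * f$cv_p
  expect_lt(abs(est - 10), 3 * se)
})
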