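#' Variance inflation factors
#'
#' VIF for each covariate from regressing it on the others:
#' \eqn{VIF_j = 1 / (1 - R^2_j)}. Perfect collinearity is reported as
#' \code{Inf}.
#'
#' @param covariates data frame of numeric candidate covariates (>= 2
#'   columns, more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(ncol(covariates) >= 2L, nrow(covariates) > ncol(covariates))
  vapply(names(covariates), function(nm) {
    fit <- stats::lm(stats::reformulate(setdiff(names(covariates), nm), nm),
                     data = covariates)
    # a perfect fit is a legitimate input here (reported as Inf), so the
    # summary's perfect-fit warning is noise
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
}

#' Screen collinear covariates
#'
#' Greedy screening: while any VIF exceeds the threshold, drop the
#' offending covariate with the lowest single-term explanatory power and
#' recompute. Mirrors the practice of preferring distance-to-coast over
#' depth where the two are strongly collinear but coast distance explains
#' more deviance.
#'
#' @param covariates data frame of candidate covariates.
#' @param explanatory_power named numeric vector: single-term deviance
#'   explained (or any comparable score) per covariate; higher is better.
#' @param threshold VIF threshold (default 5).
#' @return character vector of retained covariate names.
#' @export
choose_covariates <- function(covariates, explanatory_power, threshold = 5) {
  keep <- names(covariates)
  stopifnot(all(keep %in% names(explanatory_power)))
  repeat {
    if (length(keep) < 2L) break
    vifs <- compute_vif(covariates[keep])
    if (max(vifs) <= threshold) break
    offenders <- names(vifs)[vifs > threshold]
    drop <- offenders[which.min(explanatory_power[offenders])]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Fit a density surface model
#'
#' Fits a GAM to detection-corrected segment abundances with a log link
#' and \code{log(covered_area)} offset: \eqn{\hat n_i \sim s(x, y) +
#' s(cdist)}, smoothing parameters by REML with the null-space double
#' penalty for automatic term selection. The response family is negative
#' binomial by default; Tweedie is available for species it fits poorly.
#' Coordinates are centred internally so predictions are invariant under
#' translation of the input coordinate system. Regions are fitted
#' independently (pass segments from a single region).
#'
#' Spatial smoothing is not boundary-aware: instead of a soap-film smooth,
#' land avoidance comes from (i) restricting prediction to the sea mask,
#' (ii) the coast-distance covariate, and (iii) an extrapolation flag on
#' cells outside the surveyed hull, which together keep confident
#' predictions from leaking across headlands.
#'
#' @param segments segment table with \code{nhat} (from
#'   [correct_segment_counts()]), \code{x, y, covered_area} and any terms.
#' @param family \code{"nb"} or \code{"tweedie"}.
#' @param terms character vector of smooth terms among \code{"xy"},
#'   \code{"cdist"}, \code{"depth"}.
#' @param k_xy basis dimension for the 2-D smooth (default 30).
#' @param k_cdist basis dimension for 1-D smooths (default 10).
#' @param select use the double-penalty term selection (default TRUE).
#' @param tweedie_p Tweedie power; default profiles it within (1.1, 1.9).
#' @return object of class \code{density_model} wrapping the mgcv fit.
#' @export
fit_dsm <- function(segments, family = c("nb", "tweedie"),
                    terms = c("xy", "cdist"), k_xy = 30, k_cdist = 10,
                    select = TRUE, tweedie_p = NULL) {
  family <- match.arg(family)
  stopifnot(all(c("nhat", "x", "y", "covered_area") %in% names(segments)),
            all(segments$covered_area > 0))
  dat <- segments
  x0 <- mean(dat$x); y0 <- mean(dat$y)
  dat$x_c <- dat$x - x0
  dat$y_c <- dat$y - y0
  n_loc <- nrow(unique(dat[, c("x_c", "y_c")]))
  if ("xy" %in% terms && n_loc <= k_xy) {
    k_xy <- max(3L, n_loc - 1L)
    warning("fewer unique locations than basis dimension; k for s(x,y) shrunk to ", k_xy)
  }
  # 1-D smooths need more unique covariate values than basis functions;
  # shrink k (or drop the term) for sparse designs such as few transects
  shrink_1d <- function(term, k) {
    nu <- length(unique(dat[[term]]))
    if (nu <= k) {
      k_new <- max(3L, nu - 1L)
      if (nu < 4L) {
        warning("too few unique ", term, " values; dropping s(", term, ")")
        return(NA_integer_)
      }
      warning("k for s(", term, ") shrunk to ", k_new)
      return(k_new)
    }
    k
  }
  k_cd <- if ("cdist" %in% terms) shrink_1d("cdist", k_cdist) else NA_integer_
  k_dp <- if ("depth" %in% terms) shrink_1d("depth", k_cdist) else NA_integer_
  if ("cdist" %in% terms && is.na(k_cd)) terms <- setdiff(terms, "cdist")
  if ("depth" %in% terms && is.na(k_dp)) terms <- setdiff(terms, "depth")
  tstr <- c(
    if ("xy" %in% terms) sprintf("s(x_c, y_c, k = %d)", k_xy),
    if ("cdist" %in% terms) sprintf("s(cdist, k = %d)", k_cd),
    if ("depth" %in% terms) sprintf("s(depth, k = %d)", k_dp))
  if (is.null(tstr)) tstr <- "1"
  form <- stats::as.formula(paste("nhat ~", paste(tstr, collapse = " + "),
                                  "+ offset(log(covered_area))"))
  fam <- if (family == "nb") mgcv::nb() else
    if (is.null(tweedie_p)) mgcv::tw() else mgcv::Tweedie(p = tweedie_p)
  fit <- mgcv::gam(form, data = dat, family = fam, method = "REML",
                   select = select)
  structure(list(gam = fit, family = family, terms = terms,
                 x0 = x0, y0 = y0,
                 region = if ("region" %in% names(segments))
                   unique(segments$region)[1L] else "main",
                 data_hull = grDevices::chull(dat$x_c, dat$y_c),
                 data_xy = dat[, c("x_c", "y_c")],
                 cdist_range = if ("cdist" %in% terms)
                   range(dat$cdist, na.rm = TRUE) else NULL),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat("Density surface model (", x$family, " family), region ",
      x$region, "\n", sep = "")
  print(summary(x$gam))
  invisible(x)
}

# extrapolation flag: outside the convex hull of effort, or outside the
# fitted cdist range
flag_extrapolated <- function(model, grid) {
  hull <- model$data_xy[model$data_hull, , drop = FALSE]
  ring <- as.matrix(hull)
  inside <- point_in_ring(grid$x - model$x0, grid$y - model$y0, ring)
  extra <- !inside
  if (!is.null(model$cdist_range)) {
    extra <- extra | grid$cdist < model$cdist_range[1L] |
      grid$cdist > model$cdist_range[2L]
  }
  extra
}

#' Predict densities on the grid
#'
#' Predicts abundance per grid cell with the cell's sea area (9 km^2, or
#' less for coastal cells) as the offset, then converts to density in
#' birds/km^2. Land cells get \code{NA}, not zero. Cells outside the
#' surveyed covariate hull are still predicted but flagged
#' \code{extrapolated}.
#'
#' @param model a \code{density_model}.
#' @param grid grid with covariates populated.
#' @return data frame of class \code{density_surface}: \code{cell_id, x, y,
#'   area, density, cv} (NA until [cell_cv()]), \code{extrapolated}.
#' @export
predict_grid <- function(model, grid) {
  nd <- data.frame(x_c = grid$x - model$x0, y_c = grid$y - model$y0,
                   cdist = grid$cdist, covered_area = grid$area)
  if ("depth" %in% model$terms) nd$depth <- grid$depth
  dens <- rep(NA_real_, nrow(grid))
  sea <- grid$is_sea & grid$area > 0
  if (any(sea)) {
    ab <- as.numeric(stats::predict(model$gam, newdata = nd[sea, , drop = FALSE],
                                    type = "response"))
    dens[sea] <- ab / grid$area[sea]
  }
  out <- data.frame(cell_id = grid$cell_id, x = grid$x, y = grid$y,
                    area = grid$area, density = dens, cv = NA_real_,
                    extrapolated = flag_extrapolated(model, grid) & sea)
  out$extrapolated[!sea] <- NA
  class(out) <- c("density_surface", "data.frame")
  out
}

#' Per-cell density CVs by posterior simulation
#'
#' Draws coefficient vectors from the Bayesian posterior of the fitted GAM,
#' \eqn{\beta^* \sim N(\hat\beta, V_\beta)}, recomputes the predicted
#' density in every cell for each draw, and takes CV = sd/mean across
#' draws. Detection-function uncertainty is folded in by the delta method:
#' total CV = sqrt(CV_gam^2 + cv_p^2). Because autocorrelation between
#' segments is ignored, these CVs should be viewed as minima.
#'
#' @param model a \code{density_model}.
#' @param grid the prediction grid.
#' @param cv_p detection-probability CV from the pooled detection model.
#' @param n_draws posterior draws (default 200).
#' @param seed integer seed for the draws.
#' @return numeric vector of per-cell total CVs (NA on land).
#' @export
cell_cv <- function(model, grid, cv_p = 0, n_draws = 200, seed = 1L) {
  nd <- data.frame(x_c = grid$x - model$x0, y_c = grid$y - model$y0,
                   cdist = grid$cdist, covered_area = grid$area)
  if ("depth" %in% model$terms) nd$depth <- grid$depth
  sea <- grid$is_sea & grid$area > 0
  cv <- rep(NA_real_, nrow(grid))
  if (!any(sea)) return(cv)
  Xp <- stats::predict(model$gam, newdata = nd[sea, , drop = FALSE],
                       type = "lpmatrix")
  Vb <- model$gam$Vp
  ev <- eigen(Vb, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    warning("coefficient covariance not positive definite; ridge-stabilised")
    Vb <- Vb + diag(2 * abs(min(ev)), nrow(Vb))
  }
  if (max(abs(Vb)) == 0) {
    cv[sea] <- sqrt(cv_p^2)
    return(cv)
  }
  set.seed(seed)
  B <- MASS::mvrnorm(n_draws, stats::coef(model$gam), Vb)
  eta <- Xp %*% t(B)   # cells x draws, log scale (offset cancels in CV)
  mu <- exp(eta)
  m <- rowMeans(mu)
  s <- apply(mu, 1L, stats::sd)
  cv_gam <- ifelse(m > 0, s / m, 0)
  cv[sea] <- sqrt(cv_gam^2 + cv_p^2)
  cv
}

#' Coverage-normalised relative densities (no-model fallback)
#'
#' For species with enough observations to fit a detection function but
#' too sparse a distribution to support a density surface model: corrected
#' counts are summed over the segments whose midpoints fall in each grid
#' cell and divided by the summed covered area in that cell. Cells with no
#' effort are missing, not zero. No smoothing is involved, so no model CV
#' is available; \code{cv} carries only the detection component.
#'
#' @param segments segment table with \code{nhat} and \code{covered_area}.
#' @param grid the prediction grid.
#' @param cv_p detection-probability CV carried through (default NA).
#' @return a \code{density_surface} data frame.
#' @export
relative_density_fallback <- function(segments, grid, cv_p = NA_real_) {
  cell <- locate_cell(segments$x, segments$y, grid)
  ok <- !is.na(cell)
  num <- tapply(segments$nhat[ok], cell[ok], sum)
  den <- tapply(segments$covered_area[ok], cell[ok], sum)
  dens <- rep(NA_real_, nrow(grid))
  idx <- match(as.integer(names(num)), grid$cell_id)
  dens[idx] <- as.numeric(num) / as.numeric(den)
  dens[!grid$is_sea] <- NA_real_
  out <- data.frame(cell_id = grid$cell_id, x = grid$x, y = grid$y,
                    area = grid$area, density = dens,
                    cv = ifelse(is.na(dens), NA_real_, cv_p),
                    extrapolated = FALSE)
  out$extrapolated[is.na(dens)] <- NA
  class(out) <- c("density_surface", "data.frame")
  out
}

#' Write a density surface as grid CSV
#'
#' @param surface a \code{density_surface}.
#' @param path output path.
#' @export
write_density_surface <- function(surface, path) {
  write_table_csv(as.data.frame(surface), path)
}
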