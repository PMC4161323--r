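#' Detection function key forms
#'
#' Probability of detecting a bird at perpendicular distance \code{x} from
#' the transect line. Two key forms are supported, with no adjustment
#' terms: the half-normal \eqn{g(x) = exp(-x^2 / (2 \sigma^2))} and the
#' hazard-rate \eqn{g(x) = 1 - exp(-(x/\sigma)^{-b})}. The hazard-rate
#' shape must satisfy \code{b > 1} for an integrable shoulder.
#'
#' @param x perpendicular distance (m), >= 0.
#' @param sigma scale parameter (m), > 0.
#' @return detection probabilities in (0, 1].
#' @export
g_half_normal <- function(x, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(x < 0)) stop("distances must be >= 0")
  exp(-x^2 / (2 * sigma^2))
}

#' @rdname g_half_normal
#' @param b hazard-rate shape parameter, > 1.
#' @export
g_hazard_rate <- function(x, sigma, b) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(b <= 1)) stop("hazard-rate shape b must be > 1")
  if (any(x < 0)) stop("distances must be >= 0")
  out <- 1 - exp(-(x / sigma)^(-b))
  out[x == 0] <- 1
  out
}

# g for a fitted/parameterised model
g_eval <- function(x, form, sigma, b = NULL) {
  switch(form,
         "half-normal" = g_half_normal(x, sigma),
         "hazard-rate" = g_hazard_rate(x, sigma, b),
         "unity" = rep(1, length(x)),
         stop("unknown form: ", form))
}

# effective strip half-width: integral of g over [left, w] (m);
# the half-normal has a closed form via the normal CDF
esw_integral <- function(form, sigma, b, w, left = 0) {
  if (form == "unity") return(w - left)
  if (form == "half-normal") {
    return(sigma * sqrt(2 * pi) *
             (stats::pnorm(w / sigma) - stats::pnorm(left / sigma)))
  }
  stats::integrate(function(x) g_eval(x, form, sigma, b), left, w,
                   rel.tol = 1e-9)$value
}

#' Unity (strip transect) detection model
#'
#' Certain detection across the whole strip: used for flying birds recorded
#' on strip transects, which are assumed to have detection probability 1.
#'
#' @param w truncation distance / strip half-width (m).
#' @return a \code{detection_model} with \code{p_bar = 1}, \code{cv_p = 0}.
#' @export
unity_model <- function(w) {
  structure(list(form = "unity", sigma = NA_real_, b = NA_real_, w = w,
                 left = 0, loglik = NA_real_, npar = 0L, AIC = NA_real_,
                 esw = w, p_bar = 1, cv_p = 0, n_obs = NA_integer_,
                 converged = TRUE, insufficient = FALSE),
            class = "detection_model")
}

#' Fit a detection function by maximum likelihood
#'
#' Fits one key form to pooled perpendicular-distance data by maximising
#' the conditional likelihood of the observed distances,
#' \eqn{f(x) = g(x) / \int_0^w g}. Exact distances (boat strips) use the
#' continuous likelihood; distance-band counts (aerial surveys) use the
#' interval-censored multinomial likelihood with cell probabilities
#' \eqn{\int_{band} g / \int g}. Optimisation is quasi-Newton on
#' log-transformed parameters with three starts to guard against
#' hazard-rate local optima. Species with fewer than \code{n_min}
#' observations are not fitted: an explicit insufficient-sample result is
#' returned so the caller can route the species to presence/relative-density
#' mapping instead.
#'
#' The effective strip half-width ESW is \eqn{\int g} by numeric
#' quadrature, the mean detection probability is \code{p_bar = ESW /
#' (w - left)}, and \code{cv_p} comes from the inverse observed information
#' via the delta method.
#'
#' @param distances exact perpendicular distances (m), already truncated at
#'   \code{w}; \code{NULL} for binned data.
#' @param w truncation distance (m). For binned data defaults to the
#'   outermost band edge.
#' @param form \code{"half-normal"} or \code{"hazard-rate"}.
#' @param band_edges band edges (m) for binned data; the first edge is the
#'   left-truncation point (inner edge of the first band).
#' @param band_counts observation counts per band
#'   (length \code{length(band_edges) - 1}).
#' @param n_min minimum observations required (default 50).
#' @return object of class \code{detection_model}.
#' @export
fit_detection <- function(distances = NULL, w = NULL,
                          form = c("half-normal", "hazard-rate"),
                          band_edges = NULL, band_counts = NULL,
                          n_min = 50) {
  form <- match.arg(form)
  binned <- is.null(distances)
  if (binned) {
    stopifnot(!is.null(band_edges), !is.null(band_counts),
              length(band_counts) == length(band_edges) - 1L)
    if (is.null(w)) w <- band_edges[length(band_edges)]
    left <- band_edges[1L]
    n <- sum(band_counts)
  } else {
    stopifnot(!is.null(w), all(distances >= 0))
    distances <- distances[distances <= w]
    left <- 0
    n <- length(distances)
  }
  base <- list(form = form, w = w, left = left, n_obs = n,
               insufficient = FALSE, converged = FALSE)
  if (n < n_min) {
    base$insufficient <- TRUE
    return(structure(c(base, list(sigma = NA_real_, b = NA_real_,
                                  loglik = NA_real_, npar = NA_integer_,
                                  AIC = NA_real_, esw = NA_real_,
                                  p_bar = NA_real_, cv_p = NA_real_)),
                     class = "detection_model"))
  }
  npar <- if (form == "hazard-rate") 2L else 1L
  unpack <- function(theta) {
    sigma <- exp(theta[1L])
    b <- if (npar == 2L) 1 + exp(theta[2L]) else NULL
    list(sigma = sigma, b = b)
  }
  nll <- function(theta) {
    p <- unpack(theta)
    mu <- try(esw_integral(form, p$sigma, p$b, w, left), silent = TRUE)
    if (inherits(mu, "try-error") || !is.finite(mu) || mu <= 0) return(1e10)
    if (binned) {
      lo <- band_edges[-length(band_edges)]
      hi <- band_edges[-1L]
      cellp <- vapply(seq_along(lo), function(i)
        esw_integral(form, p$sigma, p$b, hi[i], lo[i]), numeric(1L)) / mu
      cellp <- pmax(cellp, 1e-300)
      val <- -sum(band_counts * log(cellp))
    } else {
      gx <- g_eval(distances, form, p$sigma, p$b)
      if (any(gx <= 0)) return(1e10)
      val <- -(sum(log(gx)) - n * log(mu))
    }
    if (!is.finite(val)) 1e10 else val
  }
  scale_guess <- if (binned) {
    mids <- (band_edges[-1L] + band_edges[-length(band_edges)]) / 2
    sqrt(sum(band_counts * mids^2) / max(n, 1L))
  } else sqrt(mean(distances^2))
  if (!is.finite(scale_guess) || scale_guess <= 0) {
    # pathological data, e.g. all distances zero
    return(structure(c(base, list(sigma = NA_real_, b = NA_real_,
                                  loglik = NA_real_, npar = npar,
                                  AIC = NA_real_, esw = NA_real_,
                                  p_bar = NA_real_, cv_p = NA_real_,
                                  message = "degenerate distance data")),
                     class = "detection_model"))
  }
  starts <- lapply(c(0.5, 1, 2), function(f) {
    th <- log(scale_guess * f)
    if (npar == 2L) c(th, log(1.5)) else th
  })
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, nll, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    return(structure(c(base, list(sigma = NA_real_, b = NA_real_,
                                  loglik = NA_real_, npar = npar,
                                  AIC = NA_real_, esw = NA_real_,
                                  p_bar = NA_real_, cv_p = NA_real_,
                                  message = "optimiser did not converge")),
                     class = "detection_model"))
  }
  theta <- best$par
  p <- unpack(theta)
  esw <- esw_integral(form, p$sigma, p$b, w, left)
  p_bar <- esw / (w - left)
  # delta-method CV of p_bar from the observed information on theta
  cv_p <- tryCatch({
    H <- stats::optimHess(theta, nll)
    V <- solve(H)
    eps <- 1e-4
    grad <- vapply(seq_along(theta), function(j) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
      pp <- unpack(tp); pm <- unpack(tm)
      (esw_integral(form, pp$sigma, pp$b, w, left) -
         esw_integral(form, pm$sigma, pm$b, w, left)) / (2 * eps)
    }, numeric(1L))
    v <- drop(t(grad) %*% V %*% grad)
    if (v < 0) 0 else sqrt(v) / esw
  }, error = function(e) NA_real_)
  loglik <- -best$value
  structure(c(base[setdiff(names(base), "converged")],
              list(converged = TRUE, sigma = p$sigma,
                   b = if (npar == 2L) p$b else NA_real_,
                   loglik = loglik, npar = npar,
                   AIC = -2 * loglik + 2 * npar,
                   esw = esw, p_bar = p_bar, cv_p = cv_p)),
            class = "detection_model")
}

#' @export
print.detection_model <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat("Detection model: insufficient sample (n =", x$n_obs, ")\n")
    return(invisible(x))
  }
  cat("Detection model:", x$form, "\n")
  cat("  sigma =", signif(x$sigma, 4),
      if (!is.na(x$b)) paste(" b =", signif(x$b, 4)) else "", "\n")
  cat("  w =", x$w, " ESW =", signif(x$esw, 4),
      " p_bar =", signif(x$p_bar, 4), " cv_p =", signif(x$cv_p, 3), "\n")
  cat("  n =", x$n_obs, " logLik =", signif(x$loglik, 6),
      " AIC =", signif(x$AIC, 6), "\n")
  invisible(x)
}

#' Select a detection model by AIC
#'
#' Returns the converged candidate with the lowest AIC; exact ties break
#' toward the model with fewer parameters.
#'
#' @param fits list of \code{detection_model} fits on identical data.
#' @return the selected \code{detection_model}.
#' @export
select_model <- function(fits) {
  ok <- Filter(function(f) isTRUE(f$converged) && !isTRUE(f$insufficient), fits)
  if (length(ok) == 0L) stop("no converged detection fit to select from")
  aic <- vapply(ok, `[[`, numeric(1L), "AIC")
  np <- vapply(ok, `[[`, numeric(1L), "npar")
  ok[[order(aic, np)[1L]]]
}

#' Detection-corrected segment abundance
#'
#' Horvitz-Thompson correction: the corrected count for each segment is the
#' observed count divided by the average detection probability of the
#' matching pooled detection model. Flying birds recorded on strip
#' transects are assumed to have detection probability 1, so their counts
#' pass through uncorrected (pass \code{model = unity_model(w)} for those
#' records). Corrected counts are intended to be paired with the full
#' \code{covered_area} offset downstream.
#'
#' @param segments segment table.
#' @param observations observation table already filtered to one species /
#'   behaviour / season / platform pool.
#' @param model the pooled \code{detection_model} for that pool.
#' @return \code{segments} with an \code{nhat} column (0 where nothing was
#'   seen).
#' @export
correct_segment_counts <- function(segments, observations, model) {
  stopifnot(inherits(model, "detection_model"))
  if (isTRUE(model$insufficient)) stop("cannot correct counts with an insufficient-sample model")
  if (!isTRUE(model$converged)) stop("cannot correct counts with a non-converged model")
  counts <- tapply(observations$count, observations$segment_id, sum)
  nhat <- rep(0, nrow(segments))
  idx <- match(as.integer(names(counts)), segments$segment_id)
  nhat[idx[!is.na(idx)]] <- counts[!is.na(idx)] / model$p_bar
  segments$nhat <- nhat
  segments
}

#' Bootstrap CV of the average detection probability
#'
#' Seeded nonparametric bootstrap cross-check for the analytic
#' (delta-method) \code{cv_p}: resamples the distances, refits, and takes
#' the CV of \code{p_bar} across resamples.
#'
#' @param distances exact perpendicular distances (m).
#' @param w truncation distance (m).
#' @param form key form to refit.
#' @param n_boot resamples (default 200).
#' @param seed integer seed.
#' @return bootstrap CV of \code{p_bar}.
#' @export
bootstrap_cv_p <- function(distances, w, form = "half-normal",
                           n_boot = 200, seed = 1L) {
  set.seed(seed)
  p <- vapply(seq_len(n_boot), function(i) {
    d <- sample(distances, replace = TRUE)
    f <- fit_detection(d, w = w, form = form, n_min = 1)
    if (isTRUE(f$converged)) f$p_bar else NA_real_
  }, numeric(1L))
  p <- p[!is.na(p)]
  stats::sd(p) / mean(p)
}

#' Serialise a detection fit report
#'
#' Writes a JSON report for one detection pool (species, platform,
#' behaviour, season): selected form, parameters, AIC table, ESW, average
#' detection probability and its CV, and sample size.
#'
#' @param fits list of candidate \code{detection_model} fits.
#' @param selected the selected model.
#' @param pool named list identifying the pool.
#' @param path output JSON path.
#' @export
write_detection_report <- function(fits, selected, pool, path) {
  report <- list(
    pool = pool,
    candidates = lapply(fits, function(f)
      list(form = f$form, converged = f$converged, AIC = f$AIC,
           sigma = f$sigma, b = f$b)),
    selected = list(form = selected$form, sigma = selected$sigma,
                    b = selected$b, w = selected$w, esw = selected$esw,
                    p_bar = selected$p_bar, cv_p = selected$cv_p,
                    n_obs = selected$n_obs, AIC = selected$AIC))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
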