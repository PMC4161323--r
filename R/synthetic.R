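#' Season from calendar month
#'
#' Surveys are pooled into two seasons: April to September is summer,
#' October to March is winter.
#'
#' @param month integer 1-12.
#' @return \code{"summer"} or \code{"winter"}.
#' @export
season_from_month <- function(month) {
  stopifnot(all(month %in% 1:12))
  ifelse(month >= 4L & month <= 9L, "summer", "winter")
}

#' Survey scenario configuration
#'
#' Bundles everything the synthetic survey generator needs: the transect
#' design, the detection truth, and the behaviour split. Defaults describe a
#' boat line-transect survey with 300 m strips, a half-normal detection
#' function with sigma = 120 m, and 10-min-style segments about 1.8 km long.
#'
#' @param seed integer random seed; a fixed seed gives byte-identical output.
#' @param platform \code{"boat"} or \code{"aerial"}.
#' @param season \code{"summer"} or \code{"winter"}.
#' @param species species code used in the output tables.
#' @param spacing transect spacing (m), parallel north-south lines.
#' @param segment_length segment length (m).
#' @param detection list: \code{form} ("half-normal", "hazard-rate" or
#'   "unity"), \code{sigma} (m), \code{b} (hazard shape, > 1).
#' @param truncation strip half-width / truncation distance w (m).
#' @param band_edges aerial distance-band edges (m), outermost = truncation.
#'   The first edge is the inner edge of the first band (the blind strip
#'   under the platform is left-truncated away).
#' @param frac_flying fraction of birds flying, in [0, 1].
#' @param mean_group_size 1 disables clustering; > 1 draws geometric group
#'   sizes with that mean (size-biased detection is not modelled).
#' @return object of class \code{scenario_config}.
#' @export
scenario_config <- function(seed = 1L,
                            platform = c("boat", "aerial"),
                            season = c("summer", "winter"),
                            species = "synthetic_seabird",
                            spacing = 6000,
                            segment_length = 1800,
                            detection = list(form = "half-normal", sigma = 120, b = 2.5),
                            truncation = 300,
                            band_edges = c(44, 163, 282, 426),
                            frac_flying = 0.3,
                            mean_group_size = 1) {
  platform <- match.arg(platform)
  season <- match.arg(season)
  stopifnot(spacing > 0, segment_length > 0, truncation > 0,
            frac_flying >= 0, frac_flying <= 1, mean_group_size >= 1)
  if (!detection$form %in% c("half-normal", "hazard-rate", "unity"))
    stop("unknown detection form: ", detection$form)
  if (platform == "aerial") {
    stopifnot(length(band_edges) >= 2L, all(diff(band_edges) > 0))
    truncation <- band_edges[length(band_edges)]
  }
  structure(list(seed = as.integer(seed), platform = platform, season = season,
                 species = species, spacing = spacing,
                 segment_length = segment_length, detection = detection,
                 truncation = truncation, band_edges = band_edges,
                 frac_flying = frac_flying, mean_group_size = mean_group_size),
            class = "scenario_config")
}

#' Construct a truth density surface
#'
#' Density per cell is \code{base * exp(gradient * cdist)} plus a sum of
#' Gaussian hotspots, clipped at zero. With no hotspots and zero gradient the
#' surface is flat at \code{base}.
#'
#' @param grid a grid from [make_grid()].
#' @param base baseline density, birds/km^2 (>= 0).
#' @param hotspots list of \code{list(x =, y =, radius =, amplitude =)}
#'   (m, m, m, birds/km^2).
#' @param coastal_gradient coefficient per km of coast distance (negative
#'   concentrates birds inshore); cells with no coast distance use 0.
#' @return data frame \code{cell_id, density} of class \code{truth_surface};
#'   land cells get density 0.
#' @export
make_truth <- function(grid, base = 5, hotspots = list(), coastal_gradient = 0) {
  if (base < 0) stop("base density must be >= 0")
  cd <- ifelse(is.na(grid$cdist), 0, grid$cdist)
  dens <- base * exp(coastal_gradient * cd)
  for (h in hotspots) {
    r2 <- (grid$x - h$x)^2 + (grid$y - h$y)^2
    dens <- dens + h$amplitude * exp(-r2 / (2 * h$radius^2))
  }
  dens <- pmax(dens, 0)
  dens[!grid$is_sea] <- 0
  structure(data.frame(cell_id = grid$cell_id, density = dens),
            class = c("truth_surface", "data.frame"))
}

# evaluate detection truth g(x)
g_truth <- function(x, detection) {
  switch(detection$form,
         "half-normal" = g_half_normal(x, detection$sigma),
         "hazard-rate" = g_hazard_rate(x, detection$sigma, detection$b),
         "unity" = rep(1, length(x)))
}

#' Simulate a line-transect survey over a truth surface
#'
#' Lays parallel north-south transects across the grid's bounding box,
#' splits them into segments, places bird groups by an inhomogeneous Poisson
#' process with intensity equal to the truth density of the segment's cell
#' (perpendicular distances uniform across the strip), and thins detections
#' by the scenario's detection function. Boat observations keep the exact
#' perpendicular distance; aerial observations are binned into distance
#' bands. Behaviour (sitting/flying) is a Bernoulli split; the p = 1 strip
#' convention for flying birds is an analysis-time choice, so flying birds
#' here are generated with distances like sitting birds.
#'
#' @param truth a \code{truth_surface} from [make_truth()].
#' @param grid the grid the truth lives on.
#' @param scenario a [scenario_config()].
#' @param coastline optional land polygon for segment \code{cdist}.
#' @param bathymetry optional \code{ascii_grid} for segment depth.
#' @return \code{list(segments =, observations =)} data frames in the
#'   package's CSV dialect.
#' @export
simulate_survey <- function(truth, grid, scenario, coastline = NULL,
                            bathymetry = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  w <- scenario$truncation
  L <- scenario$segment_length
  xmin <- min(grid$x) - 1500; xmax <- max(grid$x) + 1500
  ymin <- min(grid$y) - 1500; ymax <- max(grid$y) + 1500
  tx <- seq(xmin + scenario$spacing / 2, xmax, by = scenario$spacing)
  segs <- list(); obs <- list(); sid <- 0L
  dens_by_cell <- truth$density[order(truth$cell_id)]
  for (x0 in tx) {
    y_starts <- seq(ymin, ymax - L, by = L)
    for (y0 in y_starts) {
      mid_y <- y0 + L / 2
      cell <- locate_cell(x0, mid_y, grid)
      if (is.na(cell) || !grid$is_sea[grid$cell_id == cell]) next
      sid <- sid + 1L
      D <- dens_by_cell[cell]
      gen_area_km2 <- 2 * w * L / 1e6
      # searched area excludes the aerial blind strip under the platform
      left <- if (scenario$platform == "aerial") scenario$band_edges[1L] else 0
      area_km2 <- 2 * (w - left) * L / 1e6
      n_groups <- stats::rpois(1L, D * gen_area_km2 / scenario$mean_group_size)
      seg_obs <- NULL
      if (n_groups > 0L) {
        xdist <- stats::runif(n_groups, 0, w)
        detected <- stats::runif(n_groups) < g_truth(xdist, scenario$detection)
        if (any(detected)) {
          xdist <- xdist[detected]
          size <- if (scenario$mean_group_size > 1)
            stats::rgeom(length(xdist), 1 / scenario$mean_group_size) + 1L
          else rep(1L, length(xdist))
          flying <- stats::runif(length(xdist)) < scenario$frac_flying
          seg_obs <- data.frame(
            segment_id = sid,
            species = scenario$species,
            count = size,
            behaviour = ifelse(flying, "flying", "sitting"),
            perp_distance = if (scenario$platform == "boat") xdist else NA_real_,
            band_index = if (scenario$platform == "aerial")
              findInterval(xdist, scenario$band_edges, left.open = TRUE) + 1L
            else NA_integer_,
            sea_state = NA_integer_,
            stringsAsFactors = FALSE)
          if (scenario$platform == "aerial") {
            # birds inside the blind strip (below the first band edge) or
            # beyond the outermost edge are unobservable from the air
            keep <- seg_obs$band_index >= 2L &
              seg_obs$band_index <= length(scenario$band_edges)
            seg_obs <- seg_obs[keep, , drop = FALSE]
            seg_obs$band_index <- seg_obs$band_index - 1L
            if (nrow(seg_obs) == 0L) seg_obs <- NULL
          }
        }
      }
      cd <- if (!is.null(coastline))
        suppressWarnings(coast_distance(x0, mid_y, coastline))
      else grid$cdist[grid$cell_id == cell]
      segs[[sid]] <- data.frame(
        segment_id = sid, platform = scenario$platform,
        season = scenario$season, x = x0, y = mid_y, length = L,
        strip_halfwidth = w, covered_area = area_km2,
        cdist = cd,
        depth = if (!is.null(bathymetry)) depth_at(x0, mid_y, bathymetry) else NA_real_,
        species_recorded = "all", stringsAsFactors = FALSE)
      if (!is.null(seg_obs)) obs[[length(obs) + 1L]] <- seg_obs
    }
  }
  segments <- do.call(rbind, segs)
  observations <- if (length(obs)) do.call(rbind, obs) else
    data.frame(segment_id = integer(0), species = character(0),
               count = integer(0), behaviour = character(0),
               perp_distance = numeric(0), band_index = integer(0),
               sea_state = integer(0), stringsAsFactors = FALSE)
  rownames(segments) <- NULL; rownames(observations) <- NULL
  list(segments = segments, observations = observations)
}
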