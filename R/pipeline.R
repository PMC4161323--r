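#' Default pipeline configuration
#'
#' One list holds every tunable the pipeline uses, with the field's
#' standard constants as defaults: 3 km grid cells, 300 m boat strips, a
#' minimum of 50 observations per detection pool, CV fusion thresholds of
#' 0.3 (keep-maximum) and 0.5 (exclude), basis dimensions 30 and 10 for
#' the spatial and coast-distance smooths, and a VIF threshold of 5.
#' Without input paths the pipeline runs on a self-contained synthetic
#' scenario with a straight western coastline and an offshore hotspot.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param outdir output directory.
#' @return a \code{run_config} list.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("seasens_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    paths = list(segments = NULL, observations = NULL, grid = NULL,
                 bathymetry = NULL, coastline = NULL, species_scores = NULL),
    seasons = "summer",
    regions = "main",
    grid = list(bbox = c(0, 0, 60000, 60000), cellsize = 3000,
                coast_land_width = 6000),
    scenario = list(species = "Northern gannet", base_density = 4,
                    hotspot = list(x = 40500, y = 40500, radius = 9000,
                                   amplitude = 18),
                    coastal_gradient = -0.02,
                    boat = list(spacing = 6000, segment_length = 1800,
                                sigma = 120, truncation = 300),
                    aerial = list(spacing = 5000, segment_length = 1000,
                                  band_edges = c(44, 163, 282, 426)),
                    frac_flying = 0.3),
    detection = list(forms = c("half-normal", "hazard-rate"), min_n = 50,
                     truncation_boat = 300),
    dsm = list(family = "nb", k_xy = 30, k_cdist = 10, vif_threshold = 5,
               n_draws = 200),
    fusion = list(cv_keep_max = 0.3, cv_exclude = 0.5),
    map = list(per_risk_scores = "raw"),  # or "categorical"
    thresholds = default_class_thresholds()
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default. The result is validated.
#'
#' @param path YAML file path.
#' @return a validated \code{run_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a \code{run_config} list.
#' @return the config, invisibly, or an error naming the offending fields.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  f <- config$fusion
  if (!(f$cv_keep_max > 0 && f$cv_keep_max < f$cv_exclude))
    bad <- c(bad, "fusion$cv_keep_max, fusion$cv_exclude (need 0 < cv_keep_max < cv_exclude)")
  if (config$detection$min_n < 1) bad <- c(bad, "detection$min_n (must be >= 1)")
  if (config$grid$cellsize <= 0) bad <- c(bad, "grid$cellsize (must be > 0)")
  if (!config$dsm$family %in% c("nb", "tweedie"))
    bad <- c(bad, "dsm$family (nb or tweedie)")
  if (!is.null(config$map$per_risk_scores) &&
      !config$map$per_risk_scores %in% c("raw", "categorical"))
    bad <- c(bad, "map$per_risk_scores (raw or categorical)")
  if (length(bad)) stop("invalid configuration: ", paste(bad, collapse = "; "))
  invisible(config)
}

# straight north-south coastline: a land strip on the western edge
default_coastline <- function(config) {
  b <- config$grid$bbox
  wkt <- sprintf("POLYGON ((%f %f, %f %f, %f %f, %f %f, %f %f))",
                 b[1] - 30000, b[2] - 30000,
                 b[1] + config$grid$coast_land_width, b[2] - 30000,
                 b[1] + config$grid$coast_land_width, b[4] + 30000,
                 b[1] - 30000, b[4] + 30000,
                 b[1] - 30000, b[2] - 30000)
  parse_wkt_polygon(wkt)
}

run_log <- function(stage, ...) {
  message(sprintf("[seasens %s] %s", stage, paste0(...)))
}

#' Run the pipeline
#'
#' Orchestrates the stages end-to-end: \code{simulate} writes a synthetic
#' survey (grid, truth, segments, observations) for boat and aerial
#' platforms; \code{fit-detection} fits and selects pooled detection
#' functions per platform/behaviour; \code{fit-dsm} fits density surface
#' models and predicts density and CV per grid cell; \code{score}
#' reproduces the species sensitivity tables from the bundled factor
#' scores; \code{map} fuses platforms under the CV rules and writes
#' collision, displacement and overall sensitivity maps. \code{all} runs
#' everything in order. Outputs are delimited text plus a JSON manifest;
#' the same config and seed reproduce byte-identical CSVs.
#'
#' @param config a \code{run_config} (see [default_config()],
#'   [read_config()]).
#' @param stage one of \code{"all"}, \code{"simulate"},
#'   \code{"fit-detection"}, \code{"fit-dsm"}, \code{"score"},
#'   \code{"map"}.
#' @return invisibly, a list of the artifacts written.
#' @export
run_pipeline <- function(config = default_config(),
                         stage = c("all", "simulate", "fit-detection",
                                   "fit-dsm", "score", "map")) {
  stage <- match.arg(stage)
  validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  stages_run <- character(0)
  t_start <- Sys.time()

  if (stage %in% c("all", "simulate")) {
    stages_run <- c(stages_run, "simulate")
    artifacts$simulate <- stage_simulate(config)
  }
  if (stage %in% c("all", "fit-detection")) {
    stages_run <- c(stages_run, "fit-detection")
    artifacts$detection <- stage_fit_detection(config)
  }
  if (stage %in% c("all", "fit-dsm")) {
    stages_run <- c(stages_run, "fit-dsm")
    artifacts$dsm <- stage_fit_dsm(config)
  }
  if (stage %in% c("all", "score")) {
    stages_run <- c(stages_run, "score")
    artifacts$score <- stage_score(config)
  }
  if (stage %in% c("all", "map")) {
    stages_run <- c(stages_run, "map")
    artifacts$map <- stage_map(config)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("seasens")),
    seed = config$seed,
    stages = stages_run,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    fusion_thresholds = config$fusion,
    class_thresholds = lapply(config$thresholds, as.list),
    files = unname(unlist(artifacts)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(artifacts)
}

stage_simulate <- function(config) {
  outdir <- config$outdir
  run_log("simulate", "building grid and truth")
  coast <- if (!is.null(config$paths$coastline))
    parse_wkt_polygon(paste(readLines(config$paths$coastline), collapse = " "))
  else default_coastline(config)
  grid <- make_grid(config$grid$bbox, config$grid$cellsize, coast,
                    region = config$regions[1L])
  sc <- config$scenario
  truth <- make_truth(grid, base = sc$base_density,
                      hotspots = list(sc$hotspot),
                      coastal_gradient = sc$coastal_gradient)
  files <- c(grid = file.path(outdir, "grid.csv"),
             truth = file.path(outdir, "truth.csv"))
  write_table_csv(grid, files["grid"])
  write_table_csv(truth, files["truth"])
  for (platform in c("boat", "aerial")) {
    p <- sc[[platform]]
    for (season in config$seasons) {
      scen <- scenario_config(
        seed = config$seed + match(platform, c("boat", "aerial")) * 1000L +
          match(season, c("summer", "winter")),
        platform = platform, season = season, species = sc$species,
        spacing = p$spacing, segment_length = p$segment_length,
        detection = list(form = "half-normal",
                         sigma = if (is.null(p$sigma)) 120 else p$sigma,
                         b = 2.5),
        truncation = if (is.null(p$truncation)) 300 else p$truncation,
        band_edges = if (is.null(p$band_edges)) c(44, 163, 282, 426) else p$band_edges,
        frac_flying = sc$frac_flying)
      sim <- simulate_survey(truth, grid, scen, coastline = coast)
      tag <- paste0(platform, "_", season)
      fs <- file.path(outdir, paste0("segments_", tag, ".csv"))
      fo <- file.path(outdir, paste0("observations_", tag, ".csv"))
      write_table_csv(sim$segments, fs)
      write_table_csv(sim$observations, fo)
      files <- c(files, fs, fo)
      run_log("simulate", sprintf("%s %s: %d segments, %d observations",
                                  platform, season, nrow(sim$segments),
                                  nrow(sim$observations)))
    }
  }
  files
}

# pooled detection fits for one platform/season pair of tables
fit_pool <- function(segments, observations, behaviour, config) {
  platform <- segments$platform[1L]
  obs <- observations[observations$behaviour == behaviour, , drop = FALSE]
  if (platform == "boat" && behaviour == "flying") {
    # flying birds on strip transects: detection probability 1
    return(list(fits = list(), selected = unity_model(config$detection$truncation_boat)))
  }
  if (platform == "boat") {
    fits <- lapply(config$detection$forms, function(fm)
      fit_detection(distances = rep(obs$perp_distance, obs$count),
                    w = config$detection$truncation_boat, form = fm,
                    n_min = config$detection$min_n))
  } else {
    edges <- config$scenario$aerial$band_edges
    counts <- vapply(seq_len(length(edges) - 1L), function(k)
      sum(obs$count[obs$band_index == k]), numeric(1L))
    fits <- lapply(config$detection$forms, function(fm)
      fit_detection(band_edges = edges, band_counts = counts, form = fm,
                    n_min = config$detection$min_n))
  }
  sel <- tryCatch(select_model(fits), error = function(e) NULL)
  if (is.null(sel)) run_log("fit-detection",
                            "no usable fit for ", platform, "/", behaviour,
                            " (falling back to presence mapping)")
  list(fits = fits, selected = sel)
}

stage_fit_detection <- function(config) {
  outdir <- config$outdir
  files <- character(0)
  for (platform in c("boat", "aerial")) {
    for (season in config$seasons) {
      tag <- paste0(platform, "_", season)
      fs <- file.path(outdir, paste0("segments_", tag, ".csv"))
      fo <- file.path(outdir, paste0("observations_", tag, ".csv"))
      if (!file.exists(fs)) stop("missing input: ", fs)
      if (!file.exists(fo)) stop("missing input: ", fo)
      segments <- read_table_csv(fs)
      observations <- read_table_csv(fo)
      for (behaviour in c("sitting", "flying")) {
        pool <- fit_pool(segments, observations, behaviour, config)
        if (is.null(pool$selected)) next
        fp <- file.path(outdir, paste0("detection_", tag, "_", behaviour, ".json"))
        write_detection_report(pool$fits, pool$selected,
                               pool = list(species = config$scenario$species,
                                           platform = platform,
                                           behaviour = behaviour,
                                           season = season),
                               path = fp)
        files <- c(files, fp)
        run_log("fit-detection", sprintf("%s %s %s: %s, p_bar %.3f",
                                         platform, season, behaviour,
                                         pool$selected$form, pool$selected$p_bar))
      }
    }
  }
  files
}

stage_fit_dsm <- function(config) {
  outdir <- config$outdir
  grid <- read_table_csv(file.path(outdir, "grid.csv"))
  files <- character(0)
  for (platform in c("boat", "aerial")) {
    for (season in config$seasons) {
      tag <- paste0(platform, "_", season)
      segments <- read_table_csv(file.path(outdir, paste0("segments_", tag, ".csv")))
      observations <- read_table_csv(file.path(outdir, paste0("observations_", tag, ".csv")))
      for (behaviour in c("sitting", "flying")) {
        pool <- fit_pool(segments, observations, behaviour, config)
        if (is.null(pool$selected)) next
        obs <- observations[observations$behaviour == behaviour, , drop = FALSE]
        seg <- correct_segment_counts(segments, obs, pool$selected)
        surface <- tryCatch({
          model <- fit_dsm(seg, family = config$dsm$family,
                           terms = c("xy", "cdist"),
                           k_xy = config$dsm$k_xy,
                           k_cdist = config$dsm$k_cdist)
          surf <- predict_grid(model, grid)
          surf$cv <- cell_cv(model, grid, cv_p = pool$selected$cv_p,
                             n_draws = config$dsm$n_draws,
                             seed = config$seed + 7L)
          surf
        }, error = function(e) {
          run_log("fit-dsm", "DSM failed for ", tag, "/", behaviour,
                  "; using coverage-normalised fallback (", conditionMessage(e), ")")
          relative_density_fallback(seg, grid, cv_p = pool$selected$cv_p)
        })
        fp <- file.path(outdir, paste0("density_", tag, "_", behaviour, ".csv"))
        write_density_surface(surface, fp)
        files <- c(files, fp)
        run_log("fit-dsm", sprintf("%s %s: mean density %.2f birds/km2",
                                   tag, behaviour,
                                   mean(surface$density, na.rm = TRUE)))
      }
    }
  }
  files
}

stage_score <- function(config) {
  outdir <- config$outdir
  path <- config$paths$species_scores
  scores <- if (is.null(path)) load_species_scores() else load_species_scores(path)
  scored <- score_table(scores, config$thresholds)
  files <- c(file.path(outdir, "sensitivity_collision_ranking.csv"),
             file.path(outdir, "sensitivity_displacement_ranking.csv"),
             file.path(outdir, "species_sensitivity.csv"))
  write_table_csv(sensitivity_ranking(scored, "collision"), files[1L])
  write_table_csv(sensitivity_ranking(scored, "displacement"), files[2L])
  write_table_csv(scored, files[3L])
  run_log("score", nrow(scored), " species scored")
  files
}

stage_map <- function(config) {
  outdir <- config$outdir
  scored <- read_table_csv(file.path(outdir, "species_sensitivity.csv"))
  sp <- config$scenario$species
  row <- scored[scored$species == sp, , drop = FALSE]
  if (nrow(row) == 0L) stop("species not in the sensitivity table: ", sp)
  files <- character(0)
  layers <- list()
  for (season in config$seasons) {
    fused_by_species <- list()
    per_platform <- list()
    for (platform in c("boat", "aerial")) {
      tag <- paste0(platform, "_", season)
      fsit <- file.path(outdir, paste0("density_", tag, "_sitting.csv"))
      ffly <- file.path(outdir, paste0("density_", tag, "_flying.csv"))
      sit <- if (file.exists(fsit)) read_table_csv(fsit) else NULL
      fly <- if (file.exists(ffly)) read_table_csv(ffly) else NULL
      if (is.null(sit) && is.null(fly)) next
      per_platform[[platform]] <- suppressMessages(combine_behaviours(sit, fly))
    }
    if (length(per_platform) == 0L) stop("missing input: no density surfaces for ", season)
    fused <- fuse_platforms(per_platform$boat, per_platform$aerial,
                            cv_keep_max = config$fusion$cv_keep_max,
                            cv_exclude = config$fusion$cv_exclude)
    fused_by_species[[sp]] <- fused
    ff <- file.path(outdir, paste0("density_fused_", season, ".csv"))
    write_table_csv(fused, ff)
    files <- c(files, ff)
    categorical <- identical(config$map$per_risk_scores, "categorical")
    for (risk in c("collision", "displacement")) {
      score_col <- paste0(risk, if (categorical) "_cat" else "_score")
      lay <- aggregate_layers(
        lapply(fused_by_species, species_layer,
               ssi_value = row[[score_col]]),
        season = season, risk_type = risk)
      layers[[paste0(risk, "_", season)]] <- lay
    }
    layers[[paste0("overall_", season)]] <- overall_map(
      fused_by_species,
      collision_cat = stats::setNames(row$collision_cat, sp),
      displacement_cat = stats::setNames(row$displacement_cat, sp),
      season = season)
  }
  for (risk in c("collision", "displacement", "overall")) {
    group <- layers[grep(paste0("^", risk, "_"), names(layers))]
    sc <- shared_scale(group)
    for (nm in names(group)) {
      fp <- file.path(outdir, paste0("sensitivity_map_", nm, ".csv"))
      write_sensitivity_layer(group[[nm]], fp, scale = sc)
      files <- c(files, fp)
    }
  }
  run_log("map", length(files), " map artifacts written")
  files
}
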