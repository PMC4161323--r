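#' Combine sitting and flying density surfaces
#'
#' Per-cell sum of the sitting and flying densities for one species /
#' season / platform. CVs are combined assuming independence of the two
#' components: \eqn{CV = \sqrt{(d_s CV_s)^2 + (d_f CV_f)^2} / (d_s +
#' d_f)}. A missing component contributes zero (its absence is noted via a
#' message); cells missing in both stay missing.
#'
#' @param sitting,flying \code{density_surface} data frames on the same
#'   grid (either may be NULL).
#' @return a combined \code{density_surface}.
#' @export
combine_behaviours <- function(sitting, flying) {
  if (is.null(sitting) && is.null(flying)) stop("both components missing")
  if (is.null(sitting) || is.null(flying)) {
    message("one behaviour component absent; treating it as zero density")
    return(if (is.null(sitting)) flying else sitting)
  }
  if (!identical(sitting$cell_id, flying$cell_id))
    stop("density surfaces are on different grids")
  d_s <- sitting$density; d_f <- flying$density
  ds0 <- ifelse(is.na(d_s), 0, d_s)
  df0 <- ifelse(is.na(d_f), 0, d_f)
  dens <- ifelse(is.na(d_s) & is.na(d_f), NA_real_, ds0 + df0)
  var_s <- ifelse(is.na(d_s) | is.na(sitting$cv), 0, (d_s * sitting$cv)^2)
  var_f <- ifelse(is.na(d_f) | is.na(flying$cv), 0, (d_f * flying$cv)^2)
  cv <- ifelse(is.na(dens) | dens == 0, ifelse(is.na(dens), NA_real_, 0),
               sqrt(var_s + var_f) / dens)
  out <- sitting
  out$density <- dens
  out$cv <- cv
  out$extrapolated <- sitting$extrapolated | flying$extrapolated
  out
}

#' Fuse boat and aerial density surfaces by CV rules
#'
#' Per cell: candidates with CV above \code{cv_exclude} (default 0.5) are
#' discarded as unreliable. Among the survivors, if the maximum-density
#' candidate has CV below \code{cv_keep_max} (default 0.3) it is taken;
#' otherwise the candidate with the lowest CV is taken. Cells with no
#' surviving candidate are missing. Candidates with missing CV are treated
#' as unusable. The fused CV is the chosen candidate's CV, carried through
#' for reporting (no fused CV is recomputed).
#'
#' @param boat,aerial \code{density_surface} data frames on one grid
#'   (either may be NULL).
#' @param cv_keep_max CV below which the maximum density wins (default 0.3).
#' @param cv_exclude CV above which a candidate is dropped (default 0.5).
#' @return fused \code{density_surface} with a \code{source} column
#'   (\code{"boat"}, \code{"aerial"} or NA).
#' @export
fuse_platforms <- function(boat, aerial, cv_keep_max = 0.3, cv_exclude = 0.5) {
  if (cv_keep_max >= cv_exclude)
    stop("cv_keep_max must be below cv_exclude")
  surfaces <- Filter(Negate(is.null), list(boat = boat, aerial = aerial))
  if (length(surfaces) == 0L) stop("no density surface supplied")
  ids <- lapply(surfaces, `[[`, "cell_id")
  if (length(unique(ids)) != 1L) stop("density surfaces are on different grids")
  n <- nrow(surfaces[[1L]])
  dens <- rep(NA_real_, n); cv <- rep(NA_real_, n)
  src <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    cand_d <- numeric(0); cand_cv <- numeric(0); cand_s <- character(0)
    for (nm in names(surfaces)) {
      d <- surfaces[[nm]]$density[k]; v <- surfaces[[nm]]$cv[k]
      if (!is.na(d) && !is.na(v) && v <= cv_exclude) {
        cand_d <- c(cand_d, d); cand_cv <- c(cand_cv, v)
        cand_s <- c(cand_s, nm)
      }
    }
    if (length(cand_d) == 0L) next
    imax <- which.max(cand_d)
    pick <- if (cand_cv[imax] < cv_keep_max) imax else which.min(cand_cv)
    dens[k] <- cand_d[pick]; cv[k] <- cand_cv[pick]; src[k] <- cand_s[pick]
  }
  out <- surfaces[[1L]]
  out$density <- dens
  out$cv <- cv
  out$source <- src
  out$extrapolated <- NULL
  out
}

#' Per-species sensitivity layer
#'
#' Multiplies the species sensitivity value by the natural logarithm of
#' density plus one in each cell: \eqn{value = SSI \times \ln(d + 1)}.
#' The log damps the dominance of extreme densities so layers are
#' comparable between species and areas. Cells with missing density stay
#' missing for this species.
#'
#' @param density a (fused) \code{density_surface}.
#' @param ssi_value the species' sensitivity score (raw index or category
#'   value), >= 0.
#' @return data frame \code{cell_id, value}.
#' @export
species_layer <- function(density, ssi_value) {
  stopifnot(length(ssi_value) == 1L, ssi_value >= 0)
  d <- density$density
  if (any(!is.na(d) & d < 0)) stop("negative density")
  data.frame(cell_id = density$cell_id, value = ssi_value * log1p(d))
}

#' Aggregate species layers into a sensitivity map
#'
#' Sums the per-species sensitivity values in each cell, treating
#' species-level missing cells as zero. The \code{data_ok} mask is TRUE
#' where at least one species had a usable density; where no species did,
#' the emitted value is exactly zero and \code{data_ok} is FALSE — those
#' cells flag areas where coverage and model fits were too poor to use,
#' not areas without birds.
#'
#' @param layers list of per-species layers from [species_layer()], all on
#'   one grid.
#' @param season season label stored on the result.
#' @param risk_type \code{"collision"}, \code{"displacement"} or
#'   \code{"overall"}.
#' @return data frame of class \code{sensitivity_layer}: \code{cell_id,
#'   value, data_ok} with attributes \code{season}, \code{risk_type}.
#' @export
aggregate_layers <- function(layers, season = "summer",
                             risk_type = c("collision", "displacement",
                                           "overall")) {
  risk_type <- match.arg(risk_type)
  if (length(layers) == 0L) stop("no species layers to aggregate")
  ids <- layers[[1L]]$cell_id
  for (l in layers) if (!identical(l$cell_id, ids))
    stop("layers are on different grids")
  vals <- vapply(layers, function(l) ifelse(is.na(l$value), 0, l$value),
                 numeric(length(ids)))
  ok <- vapply(layers, function(l) !is.na(l$value), logical(length(ids)))
  if (length(ids) == 1L) {  # vapply drops to vectors for 1-cell grids
    vals <- matrix(vals, nrow = 1L); ok <- matrix(ok, nrow = 1L)
  }
  value <- rowSums(vals)
  data_ok <- rowSums(ok) > 0
  value[!data_ok] <- 0
  out <- data.frame(cell_id = ids, value = value, data_ok = data_ok)
  attr(out, "season") <- season
  attr(out, "risk_type") <- risk_type
  class(out) <- c("sensitivity_layer", "data.frame")
  out
}

#' Overall sensitivity map from categorical scores
#'
#' For the combined collision-and-displacement map each species enters with
#' its overall category: the higher of its collision category (1-5) and
#' displacement category (1-4). Per cell the map is
#' \eqn{\sum_{species} overall\_cat \times \ln(d + 1)} over the fused
#' densities. A species missing one risk class contributes the category it
#' has.
#'
#' @param densities named list of fused \code{density_surface}s, one per
#'   species.
#' @param collision_cat,displacement_cat named integer vectors of category
#'   values per species (names matching \code{densities}; either may omit
#'   species).
#' @param season season label.
#' @return a \code{sensitivity_layer} with \code{risk_type = "overall"}.
#' @export
overall_map <- function(densities, collision_cat, displacement_cat,
                        season = "summer") {
  layers <- lapply(names(densities), function(sp) {
    cc <- if (sp %in% names(collision_cat)) collision_cat[[sp]] else 0L
    dc <- if (sp %in% names(displacement_cat)) displacement_cat[[sp]] else 0L
    species_layer(densities[[sp]], max(cc, dc))
  })
  aggregate_layers(layers, season = season, risk_type = "overall")
}

#' Write a sensitivity layer as grid CSV
#'
#' The shared rendering scale (min/max over the layers written together,
#' so summer and winter maps can use one scale) is recorded in a JSON
#' sidecar when \code{scale} is given.
#'
#' @param layer a \code{sensitivity_layer}.
#' @param path output CSV path.
#' @param scale optional numeric \code{c(min, max)} shared scale to record.
#' @export
write_sensitivity_layer <- function(layer, path, scale = NULL) {
  write_table_csv(as.data.frame(layer), path)
  meta <- list(season = attr(layer, "season"),
               risk_type = attr(layer, "risk_type"))
  if (!is.null(scale)) meta$shared_scale <- list(min = scale[1L], max = scale[2L])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Shared rendering scale across layers
#'
#' @param layers list of \code{sensitivity_layer}s (e.g. the summer and
#'   winter maps of one risk type).
#' @return numeric \code{c(min, max)} over all layers' values.
#' @export
shared_scale <- function(layers) {
  vals <- unlist(lapply(layers, `[[`, "value"))
  c(min(vals), max(vals))
}
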