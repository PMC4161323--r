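#' Round half to even
#'
#' Banker's rounding to integer, with values within a small tolerance of an
#' exact half snapped to that half first so floating-point products of the
#' index formulas land on the intended side. The published half-cases fix
#' this convention: displacement 22.5 -> 22 and 16.5 -> 16, collision
#' 7.5 -> 8.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_even <- function(x) {
  snapped <- ifelse(abs(x * 2 - round(x * 2)) < 1e-9, round(x * 2) / 2, x)
  f <- floor(snapped)
  frac <- snapped - f
  out <- ifelse(frac < 0.5, f,
                ifelse(frac > 0.5, f + 1,
                       ifelse(f %% 2 == 0, f, f + 1)))
  out
}

#' Conservation-factor banding rules
#'
#' The four conservation importance factors are scored on fixed bands:
#' \describe{
#'   \item{Birds Directive status}{Annex 1 species score 5, migratory
#'     species that are features of Special Protection Areas score 3, other
#'     marine species score 1.}
#'   \item{Biogeographic population share}{percentage of the biogeographic
#'     population in English waters in any season: >20 scores 5, 10-19.9
#'     scores 4, 5-9.9 scores 3, 1-4.9 scores 2, <1 scores 1.}
#'   \item{Adult survival}{annual adult survival probability: <0.749 scores
#'     1, 0.75-0.799 scores 2, 0.80-0.849 scores 3, 0.85-0.899 scores 4,
#'     >0.90 scores 5.}
#'   \item{UK threat status}{from the red/amber/green listings of the two
#'     most recent Birds of Conservation Concern reviews: green/green 1,
#'     amber then green 2, green then amber 3, amber/amber 4, red in the
#'     later review 5. Combinations outside this list are rejected.}
#' }
#'
#' @param status one of \code{"annex1"}, \code{"migratory_spa_feature"},
#'   \code{"other"}.
#' @return integer score.
#' @export
score_directive <- function(status) {
  vapply(status, function(s)
    switch(s, annex1 = 5L, migratory_spa_feature = 3L, other = 1L,
           stop("unknown Birds Directive status: ", s)),
    integer(1L), USE.NAMES = FALSE)
}

#' @rdname score_directive
#' @param pct percentage of the biogeographic population, in [0, 100].
#' @export
score_pct_population <- function(pct) {
  if (any(pct < 0 | pct > 100)) stop("percentage must be in [0, 100]")
  ifelse(pct > 20, 5L,
         ifelse(pct >= 10, 4L,
                ifelse(pct >= 5, 3L,
                       ifelse(pct >= 1, 2L, 1L))))
}

#' @rdname score_directive
#' @param s annual adult survival probability, in (0, 1).
#' @export
score_survival <- function(s) {
  if (any(s <= 0 | s >= 1)) stop("survival must be in (0, 1)")
  ifelse(s > 0.90, 5L,
         ifelse(s >= 0.85, 4L,
                ifelse(s >= 0.80, 3L,
                       ifelse(s >= 0.75, 2L, 1L))))
}

#' @rdname score_directive
#' @param bocc2,bocc3 listings (\code{"green"}, \code{"amber"},
#'   \code{"red"}) in the earlier and later review respectively.
#' @export
score_bocc <- function(bocc2, bocc3) {
  mapply(function(b2, b3) {
    if (b3 == "red") return(5L)
    if (b2 == "amber" && b3 == "amber") return(4L)
    if (b2 == "green" && b3 == "amber") return(3L)
    if (b2 == "amber" && b3 == "green") return(2L)
    if (b2 == "green" && b3 == "green") return(1L)
    stop("threat-status combination not represented: ", b2, "/", b3)
  }, bocc2, bocc3, USE.NAMES = FALSE)
}

#' Conservation importance total
#'
#' Sum of the four conservation factor scores (population share, adult
#' survival, UK threat status, Birds Directive status); ranges 4 to 20.
#'
#' @param scores data frame with columns \code{a_pct_pop, b_survival,
#'   c_threat, d_directive}.
#' @return integer vector.
#' @export
conservation_importance <- function(scores) {
  ci <- scores$a_pct_pop + scores$b_survival + scores$c_threat +
    scores$d_directive
  stopifnot(all(ci >= 4 & ci <= 20))
  as.integer(ci)
}

#' Collision and displacement vulnerability indices
#'
#' The collision index weights flight-altitude exposure highest: the
#' percentage of flight time at turbine blade height (\code{e}, 0-100) is
#' multiplied by the mean of the three remaining flight-behaviour factors
#' (manoeuvrability \code{f}, time flying \code{g}, nocturnal activity
#' \code{h}, each 1-5) and by the conservation importance total, then
#' rounded half-to-even:
#' \deqn{collision = round(e \times (f + g + h)/3 \times CI)}
#' The displacement index combines disturbance susceptibility (\code{i})
#' and habitat specialisation (\code{j}):
#' \deqn{displacement = round(i \times j \times CI / 10)}
#' The two scales rank species within an impact and are not comparable
#' across impacts.
#'
#' @param e_blade_pct percentage of flight at blade height, 0-100.
#' @param f_manoeuvre,g_time_flying,h_nocturnal ordinal 1-5 scores.
#' @param ci conservation importance total (4-20).
#' @return integer score.
#' @export
collision_index <- function(e_blade_pct, f_manoeuvre, g_time_flying,
                            h_nocturnal, ci) {
  stopifnot(all(e_blade_pct >= 0 & e_blade_pct <= 100),
            all(f_manoeuvre %in% 1:5), all(g_time_flying %in% 1:5),
            all(h_nocturnal %in% 1:5), all(ci >= 4 & ci <= 20))
  raw <- e_blade_pct * (f_manoeuvre + g_time_flying + h_nocturnal) * ci / 3
  as.integer(round_half_even(raw))
}

#' @rdname collision_index
#' @param i_disturbance,j_habitat ordinal 1-5 scores.
#' @export
displacement_index <- function(i_disturbance, j_habitat, ci) {
  stopifnot(all(i_disturbance %in% 1:5), all(j_habitat %in% 1:5),
            all(ci >= 4 & ci <= 20))
  raw <- i_disturbance * j_habitat * ci / 10
  as.integer(round_half_even(raw))
}

#' Default risk-class thresholds
#'
#' Score thresholds separating the risk classes. The displacement scale has
#' no Very High class: the top displacement rank is High, acknowledging
#' the lower population risk of displacement relative to collision.
#'
#' @return list with elements \code{collision} and \code{displacement},
#'   each a named decreasing numeric vector of lower bounds per class.
#' @export
default_class_thresholds <- function() {
  list(collision = c("Very high" = 850, "High" = 410, "Moderate" = 190,
                     "Low" = 50),
       displacement = c("High" = 20, "Moderate" = 9, "Low" = 6))
}

risk_class_levels <- c("Very high", "High", "Moderate", "Low", "Very low")

#' Classify a vulnerability score into a risk class
#'
#' Scores at or above each threshold take that class; anything below the
#' last threshold is Very Low. Category values for overall mapping run
#' Very High = 5 down to Very Low = 1; because displacement has no Very
#' High class its categories top out at 4.
#'
#' @param score integer vulnerability score(s).
#' @param risk_type \code{"collision"} or \code{"displacement"}.
#' @param thresholds as [default_class_thresholds()].
#' @return data frame with \code{class} and \code{category}.
#' @export
classify_risk <- function(score, risk_type = c("collision", "displacement"),
                          thresholds = default_class_thresholds()) {
  risk_type <- match.arg(risk_type)
  th <- thresholds[[risk_type]]
  if (risk_type == "displacement" && "Very high" %in% names(th))
    stop("the Very High class is not assigned for displacement risk")
  if (any(diff(th) >= 0)) stop("thresholds must be strictly decreasing")
  cls <- character(length(score))
  for (k in seq_along(score)) {
    hit <- which(score[k] >= th)
    cls[k] <- if (length(hit)) names(th)[hit[1L]] else "Very low"
  }
  category <- 6L - match(cls, risk_class_levels)  # VH=5 ... VL=1
  data.frame(class = cls, category = category, stringsAsFactors = FALSE)
}

#' Load the bundled species factor-score table
#'
#' Ten factor scores per species for 54 marine bird species using English
#' territorial waters, compiled from published reviews of seabird
#' vulnerability to offshore wind farms. Columns: four conservation
#' factors (\code{a_pct_pop, b_survival, c_threat, d_directive}), blade
#' height exposure (\code{e_blade_pct}), flight manoeuvrability
#' (\code{f_manoeuvre}), time flying (\code{g_time_flying}), nocturnal
#' activity (\code{h_nocturnal}), disturbance susceptibility
#' (\code{i_disturbance}) and habitat specialisation (\code{j_habitat}).
#'
#' @param path CSV path; defaults to the bundled table. User tables in the
#'   same schema are accepted.
#' @return validated data frame of factor scores.
#' @export
load_species_scores <- function(path = system.file("extdata",
                                                   "species_factor_scores.csv",
                                                   package = "seasens")) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "scientific_name", "a_pct_pop", "b_survival",
              "c_threat", "d_directive", "e_blade_pct", "f_manoeuvre",
              "g_time_flying", "h_nocturnal", "i_disturbance", "j_habitat")
  missing <- setdiff(needed, names(x))
  if (length(missing)) stop("factor table missing columns: ",
                            paste(missing, collapse = ", "))
  ord <- c("a_pct_pop", "b_survival", "c_threat", "f_manoeuvre",
           "g_time_flying", "h_nocturnal", "i_disturbance", "j_habitat")
  for (cn in ord) if (any(!x[[cn]] %in% 1:5))
    stop("column ", cn, " outside 1-5")
  if (any(!x$d_directive %in% c(1L, 3L, 5L))) stop("d_directive must be 1, 3 or 5")
  if (any(x$e_blade_pct < 0 | x$e_blade_pct > 100))
    stop("e_blade_pct must be in [0, 100]")
  x
}

#' Score a species factor table
#'
#' Computes, for every species: the conservation importance total, the
#' collision and displacement vulnerability indices, risk classes and
#' category values under the given thresholds, the overall category
#' (the higher of the two), and dense ranks within each impact
#' (descending score; ties share a rank and keep input order).
#'
#' @param scores factor-score table as from [load_species_scores()].
#' @param thresholds as [default_class_thresholds()].
#' @return data frame of class \code{species_sensitivity}, in input order.
#' @export
score_table <- function(scores, thresholds = default_class_thresholds()) {
  ci <- conservation_importance(scores)
  col <- collision_index(scores$e_blade_pct, scores$f_manoeuvre,
                         scores$g_time_flying, scores$h_nocturnal, ci)
  dis <- displacement_index(scores$i_disturbance, scores$j_habitat, ci)
  ccl <- classify_risk(col, "collision", thresholds)
  dcl <- classify_risk(dis, "displacement", thresholds)
  out <- data.frame(species = scores$species,
                    scientific_name = scores$scientific_name,
                    ci = ci,
                    collision_score = col,
                    collision_class = ccl$class,
                    collision_cat = ccl$category,
                    displacement_score = dis,
                    displacement_class = dcl$class,
                    displacement_cat = dcl$category,
                    stringsAsFactors = FALSE)
  out$overall_cat <- pmax(out$collision_cat, out$displacement_cat)
  out$collision_rank <- match(-out$collision_score,
                              sort(unique(-out$collision_score)))
  out$displacement_rank <- match(-out$displacement_score,
                                 sort(unique(-out$displacement_score)))
  class(out) <- c("species_sensitivity", "data.frame")
  out
}

#' Ranked sensitivity listing for one impact
#'
#' @param scored a \code{species_sensitivity} table from [score_table()].
#' @param risk_type \code{"collision"} or \code{"displacement"}.
#' @return the table sorted by descending score (stable within ties).
#' @export
sensitivity_ranking <- function(scored,
                                risk_type = c("collision", "displacement")) {
  risk_type <- match.arg(risk_type)
  col <- paste0(risk_type, "_score")
  scored[order(-scored[[col]]), , drop = FALSE]
}
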