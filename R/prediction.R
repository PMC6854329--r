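# Predictions from fitted DI models: plot biomass for arbitrary community
# scenarios, diversity-effect estimates with uncertainty, and pairwise
# prediction surfaces (heatmaps) over all two-species combinations.

# one design-matrix row for a scenario, block effects averaged out (zero
# under the sum-to-zero coding)
scenario_row <- function(fit, P, Sp = 0) {
  if (is.null(fit$mm))
    stop("fit carries no model-matrix metadata; refit via fit_di_model()")
  mm <- fit$mm
  pool <- mm$pool
  stopifnot(length(P) == pool$S)
  if (any(P < 0) || abs(sum(P) - 1) > 1e-9)
    stop("scenario proportions must be non-negative and sum to 1")
  spec <- mm$spec
  x <- numeric(ncol(mm$X))
  names(x) <- colnames(mm$X)
  x[mm$groups$identity] <- P
  base <- de_base_covariates(matrix(P, 1L), spec$structure, pool)
  if (length(mm$groups$DE_base)) x[mm$groups$DE_base] <- base
  if (length(mm$groups$DE_Sp)) x[mm$groups$DE_Sp] <- base * Sp
  if (length(mm$groups$DE_P11)) x[mm$groups$DE_P11] <- base * P[pool$focal]
  x
}

value_se <- function(fit, x, cols = seq_along(x)) {
  x_sub <- numeric(length(x))
  x_sub[cols] <- x[cols]
  active <- which(x_sub != 0)
  aliased <- setdiff(active, fit$estimable)
  if (length(aliased))
    warning("scenario loads ", length(aliased),
            " aliased coefficient(s); their contribution is omitted")
  xe <- x_sub[fit$estimable]
  est <- sum(xe * fit$coefficients[fit$estimable])
  se <- sqrt(max(0, drop(xe %*% fit$vcov %*% xe)))
  c(estimate = est, se = se)
}

#' Predict plot biomass for a community scenario
#'
#' Computes `x' theta` for a composition (with its pattern indicator), with
#' block effects at their average (zero under sum-to-zero coding), and the
#' standard error `sqrt(x' Cov(theta) x)`.
#'
#' @param fit a `di_fit` from [fit_di_model()] (must carry its model
#'   matrix).
#' @param composition proportion vector of length S (or named by species
#'   abbreviation; omitted species are 0).  Must sum to 1.
#' @param Sp pattern indicator: 1 for an aggregated mixture, 0 otherwise.
#' @return Named numeric vector `c(estimate, se)` in grams per plot.
#' @export
predict_biomass <- function(fit, composition, Sp = 0) {
  P <- expand_composition(composition, fit$mm$pool)
  x <- scenario_row(fit, P, Sp)
  value_se(fit, x)
}

#' Estimated diversity effect for a community scenario
#'
#' The contribution of the diversity-effect columns alone: predicted
#' biomass minus the identity-plus-block prediction.  Exactly zero (with
#' zero SE) for monocultures.
#'
#' @inheritParams predict_biomass
#' @return Named numeric vector `c(estimate, se)` in grams per plot.
#' @examples
#' # see the package vignette for a worked 4-species example
#' @export
diversity_effect <- function(fit, composition, Sp = 0) {
  P <- expand_composition(composition, fit$mm$pool)
  x <- scenario_row(fit, P, Sp)
  de_cols <- c(fit$mm$groups$DE_base, fit$mm$groups$DE_Sp,
               fit$mm$groups$DE_P11)
  if (!length(de_cols)) return(c(estimate = 0, se = 0))
  value_se(fit, x, de_cols)
}

expand_composition <- function(composition, pool) {
  if (!is.null(names(composition)) &&
      all(names(composition) %in% pool$species$abbr)) {
    P <- stats::setNames(numeric(pool$S), pool$species$abbr)
    P[names(composition)] <- composition
    unname(P)
  } else {
    stopifnot(length(composition) == pool$S)
    as.numeric(composition)
  }
}

#' Pairwise prediction surface
#'
#' Predicted biomass for every two-species combination, expressed as a
#' percentage of a reference maximum (e.g. the largest observed plot
#' biomass).  The diagonal holds monoculture predictions (identical across
#' scenario kinds); off-diagonal cell (i, j) is the stated two-species
#' scenario:
#' \describe{
#'   \item{`dispersed_5050`}{50:50 mixture, dispersed pattern.}
#'   \item{`aggregated_5050`}{50:50 mixture, aggregated pattern.}
#'   \item{`dispersed_4040_focal20`}{40:40 mixture plus 20% of the focal
#'     species, dispersed; rows/columns involving the focal species itself
#'     are `NA`.}
#' }
#'
#' @param fit a `di_fit`.
#' @param pool a [species_pool()].
#' @param scenario_kind one of the three kinds above.
#' @param reference_max positive reference biomass (g) that maps to 100%.
#' @return Symmetric S-by-S matrix of percentages, dimnames = species
#'   abbreviations.
#' @export
pairwise_heatmap <- function(fit, pool = fit$mm$pool,
                             scenario_kind = c("dispersed_5050",
                                               "aggregated_5050",
                                               "dispersed_4040_focal20"),
                             reference_max) {
  scenario_kind <- match.arg(scenario_kind)
  stopifnot(reference_max > 0)
  S <- pool$S
  out <- matrix(NA_real_, S, S,
                dimnames = list(pool$species$abbr, pool$species$abbr))
  Sp <- if (scenario_kind == "aggregated_5050") 1 else 0
  focal20 <- scenario_kind == "dispersed_4040_focal20"
  for (i in seq_len(S)) {
    P <- numeric(S); P[i] <- 1
    out[i, i] <- value_se(fit, scenario_row(fit, P, 0))[["estimate"]]
  }
  for (i in seq_len(S - 1L)) {
    for (j in (i + 1L):S) {
      if (focal20 && (i == pool$focal || j == pool$focal)) next
      P <- numeric(S)
      if (focal20) {
        P[c(i, j)] <- 0.4
        P[pool$focal] <- 0.2
      } else {
        P[c(i, j)] <- 0.5
      }
      v <- value_se(fit, scenario_row(fit, P, Sp))[["estimate"]]
      out[i, j] <- out[j, i] <- v
    }
  }
  100 * out / reference_max
}
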