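#' Population-level birth-death model parameters
#'
#' Deterministic exponential birth-death interpretation of how single-cell
#' effects (growth inhibition, lysis) propagate to bulk culture size over a
#' fixed exposure. Each condition grows as
#' `N(t) = N(0) * exp((alpha - lambda) * t)` with net per-capita growth
#' rate `alpha` and lysis rate `lambda` (both 1/min); under balanced
#' growth the single-cell elongation rate doubles as the per-capita
#' population growth rate.
#'
#' @param alpha_control,alpha_treated Net growth rates (1/min).
#' @param lambda_control,lambda_treated Lysis rates (1/min).
#' @param duration_min Exposure time (min); the bulk assay default is 210.
#' @param n0 Optional initial density (CFU/mL) carried as metadata.
#' @return A `population_params` list.
#' @export
population_params <- function(alpha_control, alpha_treated,
                              lambda_control = 0, lambda_treated = 0,
                              duration_min = 210, n0 = NULL) {
  p <- list(alpha_control = alpha_control, alpha_treated = alpha_treated,
            lambda_control = lambda_control,
            lambda_treated = lambda_treated,
            duration_min = duration_min, n0 = n0)
  if (any(vapply(p[1:4], function(x) !is.numeric(x) || x < 0, logical(1))))
    stop("all rates must be numeric and >= 0.", call. = FALSE)
  if (duration_min <= 0) stop("`duration_min` must be > 0.", call. = FALSE)
  class(p) <- "population_params"
  p
}

#' Predicted treated/control population ratio
#'
#' Closed-form solution of the two-condition birth-death model:
#' `ratio = exp(((alpha_treated - lambda_treated) -
#' (alpha_control - lambda_control)) * duration_min)`. A ratio of 1 means
#' no effect; ratios below 1 translate into positive CFU reductions via
#' [reduction_percent()].
#'
#' @param p A [population_params()] object.
#' @return The treated/control ratio (dimensionless).
#' @examples
#' p <- population_params(alpha_control = 0.030, alpha_treated = 0.0255,
#'                        duration_min = 180)
#' predict_ratio(p)          # exp(-0.81)
#' reduction_percent(predict_ratio(p))
#' @export
predict_ratio <- function(p) {
  stopifnot(inherits(p, "population_params"))
  exp(((p$alpha_treated - p$lambda_treated) -
         (p$alpha_control - p$lambda_control)) * p$duration_min)
}

#' Percent reduction implied by a population ratio
#'
#' The bulk-assay reporting convention: `100 * (1 - ratio)`.
#'
#' @param ratio Treated/control ratio (>= 0).
#' @return Percentage reduction (negative when the treated population
#'   outgrows the control).
#' @export
reduction_percent <- function(ratio) {
  if (any(ratio < 0)) stop("`ratio` must be >= 0.", call. = FALSE)
  100 * (1 - ratio)
}

#' Growth inhibition required for a target CFU reduction
#'
#' Analytic inversion of [predict_ratio()] for `alpha_treated`: the
#' fraction of the control growth rate that must be removed to reach a
#' given percent reduction within `duration_min`, at the given lysis
#' rates. Used to ask whether observed single-cell effects can account for
#' a bulk kill.
#'
#' @param target_reduction_percent Target reduction, `0 <= target < 100`.
#' @param alpha_control Control growth rate (1/min).
#' @param lambda_control,lambda_treated Lysis rates (1/min).
#' @param duration_min Exposure time (min).
#' @return Inhibition fraction in `[0, 1]`.
#' @examples
#' required_inhibition(55.51, alpha_control = 0.030, duration_min = 180)
#' @export
required_inhibition <- function(target_reduction_percent, alpha_control,
                                lambda_control = 0, lambda_treated = 0,
                                duration_min = 210) {
  if (target_reduction_percent < 0 || target_reduction_percent >= 100)
    stop("`target_reduction_percent` must be in [0, 100).", call. = FALSE)
  ratio <- 1 - target_reduction_percent / 100
  alpha_treated <- log(ratio) / duration_min + alpha_control -
    lambda_control + lambda_treated
  if (alpha_treated < 0)
    stop("infeasible target: it would require a negative treated growth ",
         "rate (inhibition > 100%).", call. = FALSE)
  1 - alpha_treated / alpha_control
}

#' Lysis rate required for a target CFU reduction without growth inhibition
#'
#' With equal growth rates and no baseline lysis, a reduction `R` within
#' `duration_min` needs `lambda = -log(1 - R/100) / duration_min` (1/min).
#' Comparing this to the lysis rate recovered from single-cell data
#' quantifies whether lysis alone can explain a bulk kill.
#'
#' @inheritParams required_inhibition
#' @return Required lysis rate (1/min).
#' @examples
#' required_lysis_rate(90, duration_min = 210)  # log(10)/210
#' @export
required_lysis_rate <- function(target_reduction_percent,
                                duration_min = 210) {
  if (target_reduction_percent < 0 || target_reduction_percent >= 100)
    stop("`target_reduction_percent` must be in [0, 100).", call. = FALSE)
  -log(1 - target_reduction_percent / 100) / duration_min
}
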