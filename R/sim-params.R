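#' Simulation parameters for the trench simulator
#'
#' Bundles the ground-truth rates, division law, treatment schedule and
#' device geometry used by [simulate_trench()], [simulate_trenches()] and
#' [simulate_population()]. Defaults describe a mother-machine experiment on
#' a fast-growing Gram-positive rod: 75 µm dead-end trenches imaged every
#' minute, a 90-min pre-treatment, a 180-min antimicrobial treatment window
#' and a return to plain medium afterwards. Growth and division defaults are
#' plausible for *B. subtilis* in rich medium at 37 °C; they are not fitted
#' values.
#'
#' @param alpha0 Baseline single-cell elongation rate (1/min); cell length
#'   grows as `L(t) = L_birth * exp(alpha * t)`.
#' @param inhibition Fractional reduction of `alpha0` inside the treatment
#'   window (dimensionless, in `[0, 1)`); the effective rate during treatment
#'   is `alpha0 * (1 - inhibition)`.
#' @param lambda0 Baseline lysis rate (events per cell per hour).
#' @param lambda_treat Lysis rate during the treatment window (events per
#'   cell per hour).
#' @param div_len_mean Mean of the per-cell division-threshold length (µm).
#' @param div_len_cv Coefficient of variation of the division threshold.
#' @param div_asym_sd Standard deviation of the daughter length fraction
#'   around 0.5 at division.
#' @param obs_noise_sd Standard deviation of the multiplicative lognormal
#'   length-measurement noise (`0` gives noise-free observations).
#' @param trench_len Trench length (µm). Trench width (1 µm, single-file
#'   geometry) is assumed and not a computational parameter.
#' @param frame_interval Observation sampling period (min).
#' @param t_total Total simulated duration (min).
#' @param treat_start,treat_end Treatment window bounds (min); the window is
#'   the half-open interval `[treat_start, treat_end)`.
#' @param n_trenches Number of trenches for [simulate_trenches()].
#' @param init_fill Fraction of the trench initially occupied by cells at
#'   time zero (founders drawn with random sizes and cycle phases). Set to 0
#'   to start from a single founder cell.
#' @param init_lengths Optional numeric vector of founder cell lengths (µm),
#'   ordered from the dead end; overrides `init_fill` for deterministic
#'   initial conditions.
#' @param seed Integer RNG seed. Required: the simulator never draws from
#'   the global RNG stream implicitly.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(inhibition = 0.15, n_trenches = 4, seed = 1)
#' p
#' @export
sim_params <- function(alpha0 = 0.028,
                       inhibition = 0,
                       lambda0 = 0.01,
                       lambda_treat = 0.05,
                       div_len_mean = 6,
                       div_len_cv = 0.1,
                       div_asym_sd = 0.04,
                       obs_noise_sd = 0.02,
                       trench_len = 75,
                       frame_interval = 1,
                       t_total = 360,
                       treat_start = 90,
                       treat_end = 270,
                       n_trenches = 20,
                       init_fill = 0.6,
                       init_lengths = NULL,
                       seed = NULL) {
  if (is.null(seed) || is.na(seed)) {
    stop("`seed` must be set explicitly; the simulator does not use the ",
         "global RNG state.", call. = FALSE)
  }
  p <- list(
    alpha0 = alpha0, inhibition = inhibition,
    lambda0 = lambda0, lambda_treat = lambda_treat,
    div_len_mean = div_len_mean, div_len_cv = div_len_cv,
    div_asym_sd = div_asym_sd, obs_noise_sd = obs_noise_sd,
    trench_len = trench_len, frame_interval = frame_interval,
    t_total = t_total, treat_start = treat_start, treat_end = treat_end,
    n_trenches = as.integer(n_trenches), init_fill = init_fill,
    init_lengths = init_lengths, seed = as.integer(seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("alpha0", "inhibition", "lambda0", "lambda_treat",
              "div_len_mean", "div_len_cv", "div_asym_sd", "obs_noise_sd",
              "trench_len", "frame_interval", "t_total",
              "treat_start", "treat_end", "init_fill")) {
    if (!num1(p[[f]])) stop("`", f, "` must be a single finite number.",
                            call. = FALSE)
  }
  if (p$alpha0 < 0 || p$lambda0 < 0 || p$lambda_treat < 0)
    stop("rates must be >= 0.", call. = FALSE)
  if (p$inhibition < 0 || p$inhibition >= 1)
    stop("`inhibition` must satisfy 0 <= inhibition < 1.", call. = FALSE)
  if (!(p$treat_start >= 0 && p$treat_start < p$treat_end &&
        p$treat_end <= p$t_total))
    stop("treatment window must satisfy 0 <= treat_start < treat_end <= ",
         "t_total.", call. = FALSE)
  if (p$div_len_mean <= 0 || p$div_len_mean >= p$trench_len)
    stop("`div_len_mean` must be positive and smaller than `trench_len`.",
         call. = FALSE)
  if (p$frame_interval <= 0) stop("`frame_interval` must be > 0.",
                                  call. = FALSE)
  if (p$div_len_cv < 0 || p$div_asym_sd < 0 || p$obs_noise_sd < 0)
    stop("dispersion parameters must be >= 0.", call. = FALSE)
  if (p$init_fill < 0 || p$init_fill >= 1)
    stop("`init_fill` must be in [0, 1).", call. = FALSE)
  if (!is.null(p$init_lengths)) {
    if (!is.numeric(p$init_lengths) || any(p$init_lengths <= 0) ||
        sum(p$init_lengths) > p$trench_len)
      stop("`init_lengths` must be positive lengths fitting in the trench.",
           call. = FALSE)
  }
  if (p$n_trenches < 1L) stop("`n_trenches` must be >= 1.", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Trench simulation parameters\n")
  cat(sprintf("  elongation: alpha0 = %.4g/min, inhibition = %.3g\n",
              x$alpha0, x$inhibition))
  cat(sprintf("  lysis: lambda0 = %.3g/h, lambda_treat = %.3g/h\n",
              x$lambda0, x$lambda_treat))
  cat(sprintf("  division: threshold %.3g um (CV %.3g), asym sd %.3g\n",
              x$div_len_mean, x$div_len_cv, x$div_asym_sd))
  cat(sprintf("  geometry: trench %.3g um; frames every %.3g min for %g min\n",
              x$trench_len, x$frame_interval, x$t_total))
  cat(sprintf("  treatment window: [%g, %g) min; %d trenches; seed %d\n",
              x$treat_start, x$treat_end, x$n_trenches, x$seed))
  invisible(x)
}

#' Read or write simulator configuration as YAML
#'
#' The YAML file holds one mapping whose keys mirror the arguments of
#' [sim_params()].
#'
#' @param path Path to a YAML file.
#' @return `read_sim_config()` returns a validated `sim_params` object.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_params, cfg)
}

#' @rdname read_sim_config
#' @param params A `sim_params` object.
#' @export
write_sim_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  x <- unclass(params)
  x$init_lengths <- if (is.null(x$init_lengths)) NULL else as.numeric(x$init_lengths)
  yaml::write_yaml(x[!vapply(x, is.null, logical(1))], path)
  invisible(path)
}
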