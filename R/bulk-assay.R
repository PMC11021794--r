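#' Bulk assay configuration
#'
#' Protocol constants of the Miles-Misra colony-count assay: the overnight
#' culture is diluted to OD600 0.165 (about 1.5e8 CFU/mL), pre-diluted
#' 1:5000, and 10 µL is seeded into a 200 µL well with peptide at
#' 100 µg/mL; after 210 min of shaking incubation, 10 µL aliquots are
#' serially diluted and drop-plated.
#'
#' @param od_cfu_per_ml CFU/mL at the reference OD600.
#' @param predilution Pre-dilution factor applied before seeding.
#' @param aliquot_ul Seeded (and plated) aliquot volume (µL).
#' @param well_volume_ul Final well volume (µL).
#' @param peptide_conc_ug_ml Peptide concentration in the well (µg/mL).
#' @param incubation_min Incubation time (min).
#' @param dilution_ladder Admissible plate dilution factors.
#' @param countable_band Colony-count range considered distinct/countable.
#' @param alpha_level Significance level for the ANOVA report.
#' @return An `assay_config` list.
#' @export
assay_config <- function(od_cfu_per_ml = 1.5e8, predilution = 5000,
                         aliquot_ul = 10, well_volume_ul = 200,
                         peptide_conc_ug_ml = 100, incubation_min = 210,
                         dilution_ladder = c(10, 100, 1000),
                         countable_band = c(3, 300), alpha_level = 0.05) {
  cfg <- list(od_cfu_per_ml = od_cfu_per_ml, predilution = predilution,
              aliquot_ul = aliquot_ul, well_volume_ul = well_volume_ul,
              peptide_conc_ug_ml = peptide_conc_ug_ml,
              incubation_min = incubation_min,
              dilution_ladder = dilution_ladder,
              countable_band = countable_band, alpha_level = alpha_level)
  if (any(vapply(cfg[1:6], function(x) !is.numeric(x) || any(x <= 0),
                 logical(1))))
    stop("all assay quantities must be positive.", call. = FALSE)
  class(cfg) <- "assay_config"
  cfg
}

#' CFU/mL from a plate colony count
#'
#' The drop-plate back-calculation
#' `CFU/mL = colonies x 20 x dilution_factor x 5`: a 10 µL drop is 1/100
#' of a millilitre (the 20 x 5 factors), scaled by the plate's dilution.
#'
#' @param colonies Non-negative integer colony count(s).
#' @param dilution_factor Plate dilution factor(s), from `dilution_ladder`.
#' @param dilution_ladder Admissible dilution factors.
#' @return CFU/mL (vectorised).
#' @examples
#' cfu_per_ml(36, 100)   # 360000
#' cfu_per_ml(17, 1000)  # 1700000
#' @export
cfu_per_ml <- function(colonies, dilution_factor,
                       dilution_ladder = c(10, 100, 1000)) {
  if (any(colonies < 0)) stop("`colonies` must be >= 0.", call. = FALSE)
  if (!all(dilution_factor %in% dilution_ladder))
    stop("unknown dilution factor: ",
         paste(setdiff(dilution_factor, dilution_ladder), collapse = ", "),
         call. = FALSE)
  colonies * 20 * dilution_factor * 5
}

#' Initial inoculum of the bulk assay
#'
#' Bookkeeping from the protocol constants: the pre-diluted culture
#' density, the number of cells seeded per well, and the resulting initial
#' well density.
#'
#' @param config An [assay_config()].
#' @return A list with `prediluted_cfu_per_ml`, `cfu_per_well`,
#'   `well_cfu_per_ml`.
#' @examples
#' inoculum_cfu(assay_config())  # 3e4 CFU/mL, 300 CFU/well, 1500 CFU/mL
#' @export
inoculum_cfu <- function(config = assay_config()) {
  stopifnot(inherits(config, "assay_config"))
  pred <- config$od_cfu_per_ml / config$predilution
  per_well <- pred * config$aliquot_ul / 1000
  list(prediluted_cfu_per_ml = pred,
       cfu_per_well = per_well,
       well_cfu_per_ml = per_well / (config$well_volume_ul / 1000))
}

#' Percent CFU reduction of a treated culture relative to control
#'
#' `100 * (1 - treated/control)`; 100% is complete elimination.
#'
#' @param treated_cfu_ml,control_cfu_ml CFU/mL values.
#' @return Percent reduction (vectorised over `treated_cfu_ml`).
#' @export
percent_reduction <- function(treated_cfu_ml, control_cfu_ml) {
  if (any(control_cfu_ml <= 0))
    stop("`control_cfu_ml` must be > 0.", call. = FALSE)
  100 * (1 - treated_cfu_ml / control_cfu_ml)
}

#' One-way ANOVA with Tukey HSD across assay conditions
#'
#' Standard one-way analysis of variance on replicate CFU/mL values by
#' condition, followed by Tukey's honest-significant-difference pairwise
#' comparisons. Statistics can optionally be run on log10-transformed
#' values; raw CFU/mL is the default.
#'
#' @param data data.frame with columns `condition` and `cfu_per_ml` (one
#'   row per replicate).
#' @param alpha_level Significance threshold for the `significant` flags.
#' @param log_transform Analyse `log10(cfu_per_ml + 1)` instead of raw
#'   values.
#' @return A list with `f_statistic`, `p_value`, `pairwise` (data.frame
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`, `significant`) and
#'   `alpha_level`.
#' @export
anova_tukey <- function(data, alpha_level = 0.05, log_transform = FALSE) {
  stopifnot(all(c("condition", "cfu_per_ml") %in% names(data)))
  data$condition <- factor(data$condition)
  if (nlevels(data$condition) < 2L)
    stop("at least 2 conditions are required.", call. = FALSE)
  if (any(table(data$condition) < 2L))
    stop("at least 2 replicates per condition are required.",
         call. = FALSE)
  y <- if (log_transform) log10(data$cfu_per_ml + 1) else data$cfu_per_ml
  wg_var <- tapply(y, data$condition, stats::var)
  if (all(wg_var == 0))
    stop("degenerate data: zero within-group variance in every condition; ",
         "the ANOVA F statistic is undefined.", call. = FALSE)
  fit <- stats::aov(y ~ condition, data = data.frame(y = y,
                                                     condition =
                                                       data$condition))
  sm <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$condition
  pairwise <- data.frame(comparison = rownames(tk),
                         diff = tk[, "diff"], lwr = tk[, "lwr"],
                         upr = tk[, "upr"], p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] <= alpha_level,
                         row.names = NULL)
  list(f_statistic = sm[["F value"]][1L], p_value = sm[["Pr(>F)"]][1L],
       pairwise = pairwise, alpha_level = alpha_level,
       log_transform = log_transform)
}

#' Select the countable plate from a dilution series
#'
#' Operationalises "the least diluted plate that yields distinct
#' colonies": the smallest dilution factor whose count falls inside the
#' countable band. If no plate is in the band, the least diluted plate
#' with a count below the band's upper limit is used (counts above the
#' band are confluent and unusable); if every plate is confluent the most
#' diluted plate is returned with a warning.
#'
#' @param counts data.frame with columns `dilution_factor` and `colonies`
#'   for one condition x replicate.
#' @param countable_band `c(min, max)` countable colony range.
#' @return One row of `counts`.
#' @export
select_countable <- function(counts, countable_band = c(3, 300)) {
  counts <- counts[order(counts$dilution_factor), , drop = FALSE]
  in_band <- counts$colonies >= countable_band[1L] &
    counts$colonies <= countable_band[2L]
  if (any(in_band)) return(counts[which(in_band)[1L], , drop = FALSE])
  below <- counts$colonies <= countable_band[2L]
  if (any(below)) return(counts[which(below)[1L], , drop = FALSE])
  warning("all plates confluent; using the most diluted plate.",
          call. = FALSE)
  counts[nrow(counts), , drop = FALSE]
}

#' Per-replicate CFU/mL from a plate-count table
#'
#' Applies [select_countable()] then [cfu_per_ml()] for every
#' condition x replicate of a tidy plate-count table.
#'
#' @param counts data.frame with columns `condition`, `replicate`,
#'   `dilution_factor`, `colonies`.
#' @param config An [assay_config()].
#' @return data.frame `condition`, `replicate`, `dilution_factor`,
#'   `colonies`, `cfu_per_ml`.
#' @export
cfu_table <- function(counts, config = assay_config()) {
  need <- c("condition", "replicate", "dilution_factor", "colonies")
  stopifnot(all(need %in% names(counts)))
  parts <- split(counts, list(counts$condition, counts$replicate),
                 drop = TRUE)
  rows <- lapply(parts, function(d) {
    sel <- select_countable(d[, c("dilution_factor", "colonies")],
                            config$countable_band)
    data.frame(condition = d$condition[1L], replicate = d$replicate[1L],
               dilution_factor = sel$dilution_factor,
               colonies = sel$colonies,
               cfu_per_ml = cfu_per_ml(sel$colonies, sel$dilution_factor,
                                       config$dilution_ladder))
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res[order(res$condition, res$replicate), , drop = FALSE]
}

#' Simulate drop-plating of a culture of known density
#'
#' Colony counts are Poisson samples of the expected number of cells in a
#' plated drop: `colonies ~ Poisson(cfu_per_ml * drop_ml / dilution)`,
#' with `drop_ml = aliquot_ul / 1000`.
#'
#' @param true_cfu_ml True culture density (CFU/mL).
#' @param config An [assay_config()].
#' @return data.frame `dilution_factor`, `colonies` (one row per rung of
#'   the dilution ladder).
#' @export
simulate_plate_counts <- function(true_cfu_ml, config = assay_config()) {
  drop_ml <- config$aliquot_ul / 1000
  expected <- true_cfu_ml * drop_ml / config$dilution_ladder
  data.frame(dilution_factor = config$dilution_ladder,
             colonies = stats::rpois(length(expected), expected))
}

#' Simulate the full bulk assay from population-model rates
#'
#' End-to-end in-silico Miles-Misra assay: the well is inoculated at the
#' protocol density, each condition grows deterministically at its net
#' birth-death rate for the incubation time, and plating adds Poisson
#' counting noise before the CFU back-calculation. Useful for checking
#' that the bulk statistics recover the population model's reduction.
#'
#' @param pop A [population_params()] object (its `duration_min` is used
#'   as the incubation time).
#' @param n_replicates Replicates per condition.
#' @param config An [assay_config()].
#' @param seed RNG seed (required).
#' @return A list with `counts` (full plate table), `cfu` (per-replicate
#'   countable-plate CFU/mL), `mean_cfu` (per condition),
#'   `percent_reduction` and `true_percent_reduction` (the noise-free
#'   model value).
#' @export
simulate_bulk_assay <- function(pop, n_replicates = 3,
                                config = assay_config(), seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  if (is.null(seed)) stop("`seed` must be set.", call. = FALSE)
  n0 <- if (is.null(pop$n0)) inoculum_cfu(config)$well_cfu_per_ml else pop$n0
  final <- c(
    control = n0 * exp((pop$alpha_control - pop$lambda_control) *
                         pop$duration_min),
    treated = n0 * exp((pop$alpha_treated - pop$lambda_treated) *
                         pop$duration_min)
  )
  counts <- withr::with_seed(seed, {
    do.call(rbind, lapply(names(final), function(cond) {
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        cbind(condition = cond, replicate = r,
              simulate_plate_counts(final[[cond]], config))
      }))
    }))
  })
  cfu <- cfu_table(counts, config)
  mean_cfu <- tapply(cfu$cfu_per_ml, cfu$condition, mean)
  list(counts = counts, cfu = cfu, mean_cfu = mean_cfu,
       percent_reduction = percent_reduction(mean_cfu[["treated"]],
                                             mean_cfu[["control"]]),
       true_percent_reduction = reduction_percent(predict_ratio(pop)))
}
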