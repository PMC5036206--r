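#' Simulation configuration
#'
#' Parameters of the synthetic small-area generator. The defaults emulate the
#' English setting the pipeline is designed for: 32 482 lower-layer super
#' output areas (LSOAs) of about 1 500 residents each, a monotone deprivation
#' gradient in admission rates that is steeper for emergency (Q1/Q5 = 1.71)
#' than for elective (1.20) episodes, a female admission spike in the
#' reproductive ages 20-40, Gompertz mortality with a deprivation hazard
#' gradient, and an 8.8% rate of episodes with a missing age, sex or area
#' field.
#'
#' @param n_areas number of small areas (>= 5, one per quintile minimum).
#' @param mean_area_pop mean residents per area.
#' @param rate_gradient_elective expected crude Q1/Q5 elective episode-rate
#'   ratio (>= 1). Intermediate quintiles interpolate geometrically.
#' @param rate_gradient_emergency expected crude Q1/Q5 emergency ratio (>= 1).
#' @param base_rate_elective elective episodes per person-year in the
#'   least-deprived quintile (crude, i.e. at that quintile's age structure).
#' @param base_rate_emergency emergency episodes per person-year, ditto.
#' @param female_repro_multiplier factor applied to female admission rates at
#'   ages 20-40 (the reproductive-age spike).
#' @param gompertz_intercept baseline hazard per person-year at age 0.
#' @param gompertz_slope log-hazard increment per year of age.
#' @param mortality_gradient Q1/Q5 hazard ratio (>= 1), applied at every age.
#' @param female_mortality_ratio female/male hazard ratio in (0, 1]; keeps the
#'   female hazard at or below the male hazard at every age.
#' @param missing_rate proportion of episodes with one of age/sex/area blanked,
#'   in `[0, 1)`.
#' @param tariff_mean mean tariff unit cost in pounds.
#' @param tariff_shape gamma shape of the unit-cost distribution.
#' @param seed master integer seed; all generator streams derive from it.
#' @return an object of class `simulation_config` (a validated named list).
#' @export
simulation_config <- function(n_areas = 32482L,
                              mean_area_pop = 1500,
                              rate_gradient_elective = 1.20,
                              rate_gradient_emergency = 1.71,
                              base_rate_elective = 0.19804,
                              base_rate_emergency = 0.11495,
                              female_repro_multiplier = 1.8,
                              gompertz_intercept = 8e-5,
                              gompertz_slope = 0.09,
                              mortality_gradient = 1.5,
                              female_mortality_ratio = 0.8,
                              missing_rate = 0.088,
                              tariff_mean = 1400,
                              tariff_shape = 2,
                              seed = 1L) {
  cfg <- list(
    n_areas = as.integer(n_areas),
    mean_area_pop = as.numeric(mean_area_pop),
    rate_gradient_elective = as.numeric(rate_gradient_elective),
    rate_gradient_emergency = as.numeric(rate_gradient_emergency),
    base_rate_elective = as.numeric(base_rate_elective),
    base_rate_emergency = as.numeric(base_rate_emergency),
    female_repro_multiplier = as.numeric(female_repro_multiplier),
    gompertz_intercept = as.numeric(gompertz_intercept),
    gompertz_slope = as.numeric(gompertz_slope),
    mortality_gradient = as.numeric(mortality_gradient),
    female_mortality_ratio = as.numeric(female_mortality_ratio),
    missing_rate = as.numeric(missing_rate),
    tariff_mean = as.numeric(tariff_mean),
    tariff_shape = as.numeric(tariff_shape),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) {
    config_error("`cfg` must be a simulation_config object")
  }
  if (is.na(cfg$n_areas) || cfg$n_areas < 5) {
    config_error("`n_areas` must be at least 5 (one area per deprivation quintile)")
  }
  if (cfg$mean_area_pop <= 0) config_error("`mean_area_pop` must be positive")
  for (f in c("rate_gradient_elective", "rate_gradient_emergency",
              "mortality_gradient", "female_repro_multiplier")) {
    if (cfg[[f]] < 1) config_error(sprintf("`%s` must be >= 1 (Q1/Q5 ratio)", f))
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    config_error("`missing_rate` must lie in [0, 1)")
  }
  if (cfg$female_mortality_ratio <= 0 || cfg$female_mortality_ratio > 1) {
    config_error("`female_mortality_ratio` must lie in (0, 1]")
  }
  if (cfg$base_rate_elective <= 0 || cfg$base_rate_emergency <= 0) {
    config_error("baseline episode rates must be positive")
  }
  if (cfg$tariff_mean <= 0 || cfg$tariff_shape <= 0) {
    config_error("`tariff_mean` and `tariff_shape` must be positive")
  }
  cfg
}

#' Write / read a simulation configuration as YAML
#'
#' Every field serialises and reads back unchanged, so a run is reproducible
#' from its echoed config alone.
#'
#' @param cfg a `simulation_config`.
#' @param path file path.
#' @return `read_simulation_config()` returns the reconstructed config.
#' @export
write_simulation_config <- function(cfg, path) {
  validate_simulation_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}

#' Life-table and lifetime-cost options
#'
#' The life-table conventions that banded mortality inputs leave open are
#' exposed here and echoed into every run log.
#'
#' @param q_convention how the annual death probability is obtained from the
#'   central death rate m: `"central"` uses q = m directly (the default,
#'   simplest reading of a rate-based life table); `"actuarial"` uses
#'   q = m / (1 + m/2).
#' @param max_age terminal age closing the open 85+ interval (default 110);
#'   survival mass beyond it is discarded.
#' @param weighting survival weight for expected annual costs: `"start"`
#'   (start-of-year survival, default) or `"midyear"`.
#' @return an object of class `life_table_options`.
#' @export
life_table_options <- function(q_convention = c("central", "actuarial"),
                               max_age = 110L,
                               weighting = c("start", "midyear")) {
  opts <- list(
    q_convention = match.arg(q_convention),
    max_age = as.integer(max_age),
    weighting = match.arg(weighting)
  )
  if (opts$max_age < OPEN_AGE) {
    config_error("`max_age` must be at least 85 (the open age group)")
  }
  structure(opts, class = "life_table_options")
}
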