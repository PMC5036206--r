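#' @importFrom dplyr %>% mutate select filter group_by summarise ungroup
#'   arrange left_join inner_join anti_join bind_rows n across all_of
#'   distinct pull rename count first
#' @importFrom tibble tibble as_tibble
#' @importFrom tidyr expand_grid complete pivot_wider
NULL

# ---- Gompertz machinery ----------------------------------------------------

# Hazard ratio applied to quintile g (1 = most deprived): Q1 gets the full
# gradient, Q5 gets 1, intermediate quintiles interpolate geometrically.
quintile_hazard_factor <- function(gradient, quintile_index) {
  gradient^((5 - quintile_index) / 4)
}

# Per-year hazard at single ages 0..max_age for one quintile and sex.
gompertz_hazard <- function(cfg, quintile_index, sex, ages) {
  sex_fac <- ifelse(sex == "female", cfg$female_mortality_ratio, 1)
  cfg$gompertz_intercept * exp(cfg$gompertz_slope * ages) *
    quintile_hazard_factor(cfg$mortality_gradient, quintile_index) * sex_fac
}

# Annual death probabilities and survivorship for one quintile and sex.
# Returns list(q = q(0..max_age), surv = S(0..max_age) with S(0) = 1,
# q_open = survivor-weighted death probability for the open 85+ group).
gompertz_schedule <- function(cfg, quintile_index, sex, max_age = 110L) {
  ages <- 0:max_age
  q <- 1 - exp(-gompertz_hazard(cfg, quintile_index, sex, ages))
  surv <- cumprod(c(1, 1 - q[-length(q)]))
  open <- ages >= OPEN_AGE
  q_open <- sum(surv[open] * q[open]) / sum(surv[open])
  list(ages = ages, q = q, surv = surv, q_open = q_open)
}

# Stationary-population age shares (single years 0..84 plus 85+) for one
# quintile, jointly normalised over both sexes so that lower female mortality
# yields a female-heavier population, as in real mid-year estimates.
population_shares <- function(cfg, quintile_index) {
  w <- lapply(SEXES, function(s) {
    sch <- gompertz_schedule(cfg, quintile_index, s)
    c(sch$surv[1:OPEN_AGE], sum(sch$surv[(OPEN_AGE + 1):length(sch$surv)]))
  })
  total <- sum(vapply(w, sum, numeric(1)))
  tibble(
    sex = rep(SEXES, each = OPEN_AGE + 1L),
    age = rep(0:OPEN_AGE, times = 2L),
    share = c(w[[1]], w[[2]]) / total
  )
}

# ---- Areas and population --------------------------------------------------

#' Simulate small areas with deprivation ranks and resident populations
#'
#' Draws `n_areas` areas with distinct deprivation ranks (1 = most deprived),
#' assigns quintiles, and samples resident counts by sex and single year of
#' age (0-84 plus an open 85+ group). More-deprived areas receive a younger
#' age structure: ages are thinned by the same Gompertz survivorship, scaled
#' by the quintile mortality gradient, that later drives the simulated deaths,
#' so the population and mortality components are internally consistent.
#'
#' @param cfg a [simulation_config()].
#' @return a list with `areas` (tibble: `area_id`, `imd_rank`, `quintile`) and
#'   `population` (tibble: `area_id`, `sex`, `age`, `count`; `age` 85 denotes
#'   the open 85+ group).
#' @export
simulate_areas <- function(cfg) {
  validate_simulation_config(cfg)
  with_stream(cfg$seed, "areas", {
    areas <- tibble(
      area_id = sprintf("A%06d", seq_len(cfg$n_areas)),
      imd_rank = sample.int(cfg$n_areas)
    )
    areas <- assign_quintiles(areas)
    shares <- lapply(1:5, function(g) {
      population_shares(cfg, g) %>% mutate(quintile = QUINTILES[g])
    }) %>% bind_rows()
    population <- expand_grid(
      area_id = areas$area_id,
      sex = SEXES,
      age = 0:OPEN_AGE
    ) %>%
      left_join(select(areas, "area_id", "quintile"), by = "area_id") %>%
      left_join(shares, by = c("quintile", "sex", "age")) %>%
      mutate(count = rpois(n(), cfg$mean_area_pop * .data$share)) %>%
      select("area_id", "sex", "age", "count")
    list(areas = areas, population = population)
  })
}

# ---- Tariff catalogue ------------------------------------------------------

#' Simulate a pseudo-HRG reference-cost tariff catalogue
#'
#' Twenty healthcare-resource-group codes with gamma-distributed unit costs,
#' a typical length of stay, a trim point and an excess-bed-day per diem, so
#' that the long-stay supplement path of the costing is exercised. Costs are
#' in integer pence.
#'
#' @param cfg a [simulation_config()].
#' @return tibble: `hrg_code`, `unit_cost_pence`, `trim_point_days`,
#'   `excess_per_diem_pence`, `mean_los_days`.
#' @export
simulate_tariffs <- function(cfg) {
  validate_simulation_config(cfg)
  with_stream(cfg$seed, "tariffs", {
    n <- 20L
    unit_cost <- round(100 * rgamma(n, shape = cfg$tariff_shape,
                                    rate = cfg$tariff_shape / cfg$tariff_mean))
    mean_los <- round(runif(n, 1, 10), 1)
    tibble(
      hrg_code = sprintf("H%02d", seq_len(n)),
      unit_cost_pence = pmax(unit_cost, 100),
      trim_point_days = as.integer(ceiling(2.5 * mean_los) + 2L),
      excess_per_diem_pence = round(0.05 * pmax(unit_cost, 100)),
      mean_los_days = mean_los
    )
  })
}

# ---- Episode rates ---------------------------------------------------------

# Unitless age shapes of the admission-rate curves: a childhood peak, a dip
# around age 10, then exponential growth into old age (steeper for emergency
# admissions). Levels are calibrated against the least-deprived quintile's
# realised age structure, so only the relative profile matters here.
elective_shape <- function(age) 1.15 * exp(-age / 6) + 0.28 * exp(0.033 * age)
emergency_shape <- function(age) 2.2 * exp(-age / 4) + 0.23 * exp(0.036 * age)

episode_rate_shape <- function(admission_type, age, sex, cfg) {
  base <- switch(admission_type,
    elective = elective_shape(age),
    emergency = emergency_shape(age)
  )
  repro <- sex == "female" & age >= 20 & age <= 40
  base * ifelse(repro, cfg$female_repro_multiplier, 1)
}

#' Simulate finished consultant episodes
#'
#' Per-cell episode counts are Poisson with mean population x age/sex baseline
#' x quintile scalar, with separate elective and emergency gradients (the
#' emergency gradient is steeper by default). Quintile scalars are solved
#' against the realised population so that the *expected crude* Q1/Q5 rate
#' ratio equals the configured gradient exactly; the quintile-specific age
#' structures would otherwise confound the crude ratio. Each episode carries a
#' pseudo-HRG code and a geometric length of stay with HRG-specific mean. A
#' fraction `missing_rate` of episodes has one of age, sex or area id blanked,
#' uniformly at random across cells.
#'
#' @param areas,population as returned by [simulate_areas()].
#' @param tariffs as returned by [simulate_tariffs()].
#' @param cfg a [simulation_config()].
#' @return a list with `episodes` (tibble: `age`, `sex`, `area_id`,
#'   `admission_type`, `hrg_code`, `length_of_stay`, `year`), `cell_means`
#'   (per-cell expected counts) and `ground_truth` (per-quintile expected
#'   counts, rates and target ratios).
#' @export
simulate_episodes <- function(areas, population, tariffs, cfg) {
  validate_simulation_config(cfg)
  if (any(population$count < 0)) validation_error("population counts must be nonnegative")
  pop <- population %>%
    left_join(select(areas, "area_id", "quintile"), by = "area_id")

  cell_means <- lapply(c("elective", "emergency"), function(ty) {
    grad <- if (ty == "elective") cfg$rate_gradient_elective else cfg$rate_gradient_emergency
    base <- if (ty == "elective") cfg$base_rate_elective else cfg$base_rate_emergency
    cells <- pop %>%
      mutate(shape = episode_rate_shape(ty, .data$age, .data$sex, cfg))
    crude <- cells %>%
      group_by(.data$quintile) %>%
      summarise(crude = sum(.data$count * .data$shape) / sum(.data$count),
                .groups = "drop")
    crude5 <- crude$crude[crude$quintile == "Q5"]
    scalars <- crude %>%
      mutate(
        target_ratio = quintile_hazard_factor(grad, match(.data$quintile, QUINTILES)),
        scalar = (base / crude5) * .data$target_ratio * crude5 / .data$crude
      )
    cells %>%
      left_join(select(scalars, "quintile", "scalar", "target_ratio"),
                by = "quintile") %>%
      mutate(admission_type = ty,
             mean = .data$count * .data$shape * .data$scalar) %>%
      select("area_id", "quintile", "sex", "age", "admission_type",
             "pop" = "count", "mean", "target_ratio")
  }) %>% bind_rows()

  ground_truth <- cell_means %>%
    group_by(.data$admission_type, .data$quintile) %>%
    summarise(
      expected_episodes = sum(.data$mean),
      pop = sum(.data$pop[!duplicated(paste(.data$area_id, .data$sex, .data$age))]),
      target_ratio_vs_q5 = first(.data$target_ratio),
      .groups = "drop"
    ) %>%
    mutate(expected_rate_per_100k = .data$expected_episodes / .data$pop * 1e5)

  episodes <- with_stream(cfg$seed, "episodes", {
    counts <- rpois(nrow(cell_means), cell_means$mean)
    idx <- rep.int(seq_len(nrow(cell_means)), counts)
    n_ep <- length(idx)
    hrg <- sample(tariffs$hrg_code, n_ep, replace = TRUE)
    mean_los <- tariffs$mean_los_days[match(hrg, tariffs$hrg_code)]
    ep <- tibble(
      age = as.integer(cell_means$age[idx]),
      sex = cell_means$sex[idx],
      area_id = cell_means$area_id[idx],
      admission_type = cell_means$admission_type[idx],
      hrg_code = hrg,
      length_of_stay = rgeom(n_ep, prob = 1 / (1 + mean_los)),
      year = "2011/12"
    )
    if (cfg$missing_rate > 0 && n_ep > 0) {
      blank <- runif(n_ep) < cfg$missing_rate
      field <- sample(c("age", "sex", "area_id"), n_ep, replace = TRUE)
      ep$age[blank & field == "age"] <- NA_integer_
      ep$sex[blank & field == "sex"] <- NA_character_
      ep$area_id[blank & field == "area_id"] <- NA_character_
    }
    ep
  })

  list(episodes = episodes, cell_means = cell_means, ground_truth = ground_truth)
}

# ---- Mortality -------------------------------------------------------------

#' Simulate death counts by area, sex and 5-year age band
#'
#' Deaths are binomial per population cell with annual death probability
#' `1 - exp(-h)` under the Gompertz hazard scaled by the quintile mortality
#' gradient; the female hazard sits below the male hazard at every age. The
#' open 85+ cell uses the survivor-weighted death probability over ages
#' 85-110. Counts are aggregated to the 5-year bands (0-4 ... 80-84, 85+) the
#' national mortality extracts use.
#'
#' @inheritParams simulate_episodes
#' @return a list with `mortality` (tibble: `area_id`, `sex`, `age_band`,
#'   `deaths`) and `expected_band_rates` (tibble of expected pooled death
#'   rates per quintile x sex x band, the generator's analytic ground truth
#'   for survival-recovery checks).
#' @export
simulate_mortality <- function(areas, population, cfg) {
  validate_simulation_config(cfg)
  if (any(population$count < 0)) validation_error("population counts must be nonnegative")
  schedules <- expand_grid(quintile = QUINTILES, sex = SEXES) %>%
    mutate(q = mapply(function(g, s) {
      sch <- gompertz_schedule(cfg, match(g, QUINTILES), s)
      list(c(sch$q[1:OPEN_AGE], sch$q_open))
    }, .data$quintile, .data$sex))
  q_tbl <- schedules %>%
    rowwise_unpack_q()
  cells <- population %>%
    left_join(select(areas, "area_id", "quintile"), by = "area_id") %>%
    left_join(q_tbl, by = c("quintile", "sex", "age")) %>%
    mutate(age_band = band_of_age(.data$age))
  deaths <- with_stream(cfg$seed, "mortality", {
    cells %>%
      mutate(deaths = rbinom(n(), .data$count, .data$q)) %>%
      group_by(.data$area_id, .data$sex, .data$age_band) %>%
      summarise(deaths = sum(.data$deaths), .groups = "drop")
  })
  expected <- cells %>%
    group_by(.data$quintile, .data$sex, .data$age_band) %>%
    summarise(
      pop = sum(.data$count),
      expected_deaths = sum(.data$count * .data$q),
      .groups = "drop"
    ) %>%
    mutate(rate = ifelse(.data$pop > 0, .data$expected_deaths / .data$pop, 0))
  list(mortality = deaths, expected_band_rates = expected)
}

# helper: unpack the per-(quintile, sex) q vectors into long (age, q) rows
rowwise_unpack_q <- function(schedules) {
  out <- lapply(seq_len(nrow(schedules)), function(i) {
    tibble(
      quintile = schedules$quintile[i],
      sex = schedules$sex[i],
      age = 0:OPEN_AGE,
      q = schedules$q[[i]]
    )
  })
  bind_rows(out)
}

# ---- One-call dataset ------------------------------------------------------

#' Simulate a complete synthetic dataset
#'
#' Runs the area/population, tariff, episode and mortality generators from a
#' single configuration. Each generator draws from its own seed stream derived
#' from the master seed, so outputs are reproducible component by component.
#'
#' @param cfg a [simulation_config()].
#' @return an object of class `ineqcost_simulation`: a list with `areas`,
#'   `population`, `tariffs`, `episodes`, `mortality`, `ground_truth` and the
#'   echoed `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  ap <- simulate_areas(cfg)
  tariffs <- simulate_tariffs(cfg)
  eps <- simulate_episodes(ap$areas, ap$population, tariffs, cfg)
  mort <- simulate_mortality(ap$areas, ap$population, cfg)
  structure(
    list(
      areas = ap$areas,
      population = ap$population,
      tariffs = tariffs,
      episodes = eps$episodes,
      episode_cell_means = eps$cell_means,
      mortality = mort$mortality,
      ground_truth = list(
        episode_summary = eps$ground_truth,
        mortality_band_rates = mort$expected_band_rates
      ),
      config = cfg
    ),
    class = "ineqcost_simulation"
  )
}

#' @export
print.ineqcost_simulation <- function(x, ...) {
  cat("Synthetic small-area hospital dataset\n")
  cat(sprintf("  areas:      %d (quintiles Q1..Q5)\n", nrow(x$areas)))
  cat(sprintf("  population: %s residents\n",
              format(sum(x$population$count), big.mark = " ")))
  cat(sprintf("  episodes:   %s\n", format(nrow(x$episodes), big.mark = " ")))
  cat(sprintf("  deaths:     %s\n", format(sum(x$mortality$deaths), big.mark = " ")))
  invisible(x)
}
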