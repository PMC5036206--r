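test_that("configuration validates its fields and round-trips through YAML", {
  expect_error(simulation_config(n_areas = 4), "n_areas",
               class = "ineqcost_config_error")
  expect_error(simulation_config(missing_rate = 1), "missing_rate",
               class = "ineqcost_config_error")
  expect_error(simulation_config(rate_gradient_emergency = 0.9),
               "rate_gradient_emergency", class = "ineqcost_config_error")
  expect_error(simulation_config(mortality_gradient = 0.5),
               class = "ineqcost_config_error")

  cfg <- simulation_config(n_areas = 123, mean_area_pop = 777.5,
                           missing_rate = 0.05, seed = 99L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  expect_identical(read_simulation_config(path), cfg)
})

test_that("area generator produces the configured scale and quintile split", {
  cfg <- simulation_config(n_areas = 5, mean_area_pop = 1500, seed = 11)
  ap <- simulate_areas(cfg)
  expect_equal(nrow(ap$areas), 5)
  expect_equal(sort(as.character(ap$areas$quintile)), paste0("Q", 1:5))

  # national population ~ n_areas * mean_area_pop within Poisson noise
  total <- sum(ap$population$count)
  expect_lt(abs(total - 5 * 1500), 4 * sqrt(5 * 1500))

  cfg2 <- simulation_config(n_areas = 40, mean_area_pop = 1000, seed = 12)
  total2 <- sum(simulate_areas(cfg2)$population$count)
  expect_lt(abs(total2 - 40000), 4 * sqrt(40000))
})

test_that("same seed gives identical outputs; streams are label-independent", {
  cfg <- simulation_config(n_areas = 20, mean_area_pop = 300, seed = 5)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$areas, s2$areas)
  expect_identical(s1$population, s2$population)
  expect_identical(s1$tariffs, s2$tariffs)
  expect_identical(s1$episodes, s2$episodes)
  expect_identical(s1$mortality, s2$mortality)

  # running a generator alone reproduces its slice of the full dataset:
  # each sub-generator has its own derived seed stream
  alone <- simulate_areas(cfg)
  expect_identical(alone$areas, s1$areas)
  expect_identical(alone$population, s1$population)
  expect_identical(simulate_tariffs(cfg), s1$tariffs)
})

test_that("deprived quintiles get a younger age structure", {
  sim <- shared_sim()
  pop <- dplyr::left_join(sim$population,
                          dplyr::select(sim$areas, area_id, quintile),
                          by = "area_id")
  by_q <- pop |>
    dplyr::group_by(quintile) |>
    dplyr::summarise(mean_age = sum(age * count) / sum(count),
                     share_80plus = sum(count[age >= 80]) / sum(count))
  expect_lt(by_q$mean_age[by_q$quintile == "Q1"],
            by_q$mean_age[by_q$quintile == "Q5"])
  expect_lt(by_q$share_80plus[by_q$quintile == "Q1"],
            by_q$share_80plus[by_q$quintile == "Q5"])
})

test_that("female reproductive-age admission rates exceed male rates", {
  sim <- shared_sim()
  eps <- sim$episodes[!is.na(sim$episodes$sex) & !is.na(sim$episodes$age), ]
  pop <- sim$population
  rate <- function(s, lo, hi) {
    sum(eps$sex == s & eps$age >= lo & eps$age <= hi) /
      sum(pop$count[pop$sex == s & pop$age >= lo & pop$age <= hi])
  }
  expect_gt(rate("female", 20, 40), rate("male", 20, 40))
})

test_that("missingness matches the configured rate and is cell-independent", {
  cfg0 <- simulation_config(n_areas = 20, mean_area_pop = 300,
                            missing_rate = 0, seed = 31)
  s0 <- simulate_dataset(cfg0)
  expect_identical(filter_groupable(s0$episodes)$dropped_count, 0L)

  sim <- shared_sim() # default missing_rate = 0.088
  n <- nrow(sim$episodes)
  blanked <- sum(is.na(sim$episodes$age) | is.na(sim$episodes$sex) |
                   is.na(sim$episodes$area_id))
  p <- sim$config$missing_rate
  expect_lt(abs(blanked - n * p), 4 * sqrt(n * p * (1 - p)))

  # independence of cell: among episodes with a known area, the fraction with
  # a blanked age or sex is 2/3 of the missing rate in every quintile
  eps <- dplyr::left_join(sim$episodes,
                          dplyr::select(sim$areas, area_id, quintile),
                          by = "area_id")
  eps <- eps[!is.na(eps$area_id), ]
  per_q <- eps |>
    dplyr::group_by(quintile) |>
    dplyr::summarise(n = dplyr::n(),
                     frac = mean(is.na(age) | is.na(sex)))
  p2 <- p * 2 / 3
  expect_true(all(abs(per_q$frac - p2) < 4 * sqrt(p2 * (1 - p2) / per_q$n)))
})

test_that("realised episode counts match the generator's expected counts", {
  sim <- shared_sim()
  gt <- sim$ground_truth$episode_summary
  eps <- filter_groupable(sim$episodes)$kept |>
    dplyr::left_join(dplyr::select(sim$areas, area_id, quintile), by = "area_id") |>
    dplyr::count(admission_type, quintile)
  cmp <- dplyr::left_join(gt, eps, by = c("admission_type", "quintile"))
  # kept counts are thinned by (1 - missing_rate)
  kept_mean <- cmp$expected_episodes * (1 - sim$config$missing_rate)
  expect_true(all(abs(cmp$n - kept_mean) < 4 * sqrt(kept_mean)))
})

test_that("mortality has the configured sex and deprivation structure", {
  sim <- shared_sim()
  gt <- sim$ground_truth$mortality_band_rates
  # the female hazard sits below the male hazard, so every closed band's
  # expected rate is lower for women (the open 85+ band is excluded: women's
  # longer survivorship shifts its internal age mix upward, which can raise
  # the crude open-band rate even with a lower hazard at every age)
  sex_wide <- gt |>
    dplyr::filter(age_band != "85+") |>
    tidyr::pivot_wider(id_cols = c(quintile, age_band),
                       names_from = sex, values_from = rate)
  expect_true(all(sex_wide$female < sex_wide$male))
  # expected (analytic) band rates honour the hazard gradient at every band
  wide <- gt |>
    dplyr::filter(quintile %in% c("Q1", "Q5")) |>
    dplyr::select(quintile, sex, age_band, rate) |>
    tidyr::pivot_wider(names_from = quintile, values_from = rate)
  expect_true(all(wide$Q1 > wide$Q5))
})

test_that("zero Gompertz slope gives geometric survival", {
  cfg <- simulation_config(n_areas = 50, mean_area_pop = 2000,
                           gompertz_slope = 0, gompertz_intercept = 0.02,
                           mortality_gradient = 1, female_mortality_ratio = 1,
                           seed = 77)
  ap <- simulate_areas(cfg)
  mort <- simulate_mortality(ap$areas, ap$population, cfg)
  surv <- survival_from_counts(mort$mortality, ap$population, ap$areas)
  q <- 1 - exp(-0.02)
  closed_form <- (1 - q)^(0:85)
  est <- surv[surv$quintile == "Q3" & surv$sex == "male" & surv$age <= 85, ]
  # pooled band rates are noisy; compare at a loose Monte-Carlo tolerance
  expect_true(all(abs(est$survival - closed_form) < 0.05))
  # and with a gradient of 1 all quintiles share one hazard in expectation
  gt <- mort$expected_band_rates |>
    tidyr::pivot_wider(id_cols = c(sex, age_band),
                       names_from = quintile, values_from = rate)
  expect_equal(gt$Q1, gt$Q5, tolerance = 1e-10)
})
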