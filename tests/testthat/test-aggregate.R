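test_that("quintiles are near-equal fifths of areas, most deprived first", {
  a10 <- tibble::tibble(area_id = paste0("A", 1:10), imd_rank = 10:1)
  q10 <- assign_quintiles(a10)
  expect_equal(as.character(q10$quintile[q10$imd_rank <= 2]), c("Q1", "Q1"))
  expect_equal(as.character(q10$quintile[q10$imd_rank >= 9]), c("Q5", "Q5"))

  a5 <- tibble::tibble(area_id = paste0("B", 1:5), imd_rank = c(3, 1, 5, 2, 4))
  q5 <- assign_quintiles(a5)
  expect_equal(sort(as.character(q5$quintile)), paste0("Q", 1:5))
  expect_equal(as.character(q5$quintile[q5$imd_rank == 1]), "Q1")

  # 32482 areas: sizes 6497, 6497, 6496, 6496, 6496 (remainder to Q1, Q2)
  big <- tibble::tibble(area_id = as.character(1:32482),
                        imd_rank = sample(32482))
  sizes <- table(assign_quintiles(big)$quintile)
  expect_equal(as.integer(sizes), c(6497L, 6497L, 6496L, 6496L, 6496L))
})

test_that("invalid deprivation ranks are rejected with the offending values", {
  dup <- tibble::tibble(area_id = paste0("A", 1:6),
                        imd_rank = c(1, 2, 2, 3, 4, 4))
  expect_error(assign_quintiles(dup), "2, 4",
               class = "ineqcost_validation_error")
  expect_error(assign_quintiles(tibble::tibble(area_id = "A", imd_rank = 0.5)),
               class = "ineqcost_validation_error")
})

test_that("strata add exactly: elective + emergency = all in every cell and margin", {
  s <- shared_summary()
  wide <- s$cells |>
    tidyr::pivot_wider(id_cols = c(quintile, sex, age),
                       names_from = admission_type,
                       values_from = c(episode_n, total_cost_pence))
  expect_equal(wide$episode_n_elective + wide$episode_n_emergency,
               wide$episode_n_all)
  expect_identical(wide$total_cost_pence_elective + wide$total_cost_pence_emergency,
                   wide$total_cost_pence_all)
  qs <- s$quintile_summary |>
    tidyr::pivot_wider(id_cols = quintile, names_from = admission_type,
                       values_from = rate_per_100k)
  expect_equal(qs$elective + qs$emergency, qs$all)
})

test_that("populations are conserved through quintile aggregation", {
  sim <- shared_sim()
  pop_q <- population_by_quintile(sim$population, sim$areas)
  expect_equal(sum(pop_q$pop), sum(sim$population$count))
  by_sex_age <- pop_q |>
    dplyr::group_by(sex, age) |>
    dplyr::summarise(pop = sum(pop), .groups = "drop")
  nat <- sim$population |>
    dplyr::group_by(sex, age) |>
    dplyr::summarise(pop = sum(count), .groups = "drop")
  expect_equal(by_sex_age, nat)
})

test_that("episodes in unknown areas or impossible cells are hard errors", {
  sim <- shared_sim()
  f <- filter_groupable(sim$episodes)
  eps <- cost_episodes(utils::head(f$kept, 50), sim$tariffs)
  eps$area_id[1] <- "NOPE"
  expect_error(aggregate_costs(eps, sim$areas, sim$population),
               "NOPE", class = "ineqcost_lookup_error")
  expect_error(aggregate_costs(cost_episodes(f$kept, sim$tariffs),
                               sim$areas, sim$population,
                               costing = "not a config"),
               class = "ineqcost_config_error")
})

test_that("zero episodes aggregate to zero counts and rates, not blanks", {
  sim <- shared_sim()
  none <- cost_episodes(sim$episodes[0, ], sim$tariffs)
  s <- aggregate_costs(none, sim$areas, sim$population)
  populated <- s$cells[s$cells$pop > 0, ]
  expect_true(all(populated$episode_n == 0))
  expect_true(all(populated$rate_per_100k == 0))
  expect_true(all(populated$avg_cost_pence == 0))
  expect_equal(nrow(render_table1(s)), 6)
})

test_that("published quintile rates give the published percentage excesses", {
  ref <- ref_episode_rates()
  r <- function(col, q) ref[[col]][ref$quintile == q]
  expect_equal(rate_excess_pct(r("elective_rate", "Q1"), r("elective_rate", "Q5")), 20)
  expect_equal(rate_excess_pct(r("emergency_rate", "Q1"), r("emergency_rate", "Q5")), 71)
  expect_equal(rate_excess_pct(r("all_rate", "Q1"), r("all_rate", "Q5")), 39)
  expect_equal(rate_excess_pct(150, 150), 0)
  expect_error(rate_excess_pct(10, 0), class = "ineqcost_validation_error")
})

test_that("crude rate ratios recover the configured gradients", {
  sim <- shared_sim()
  s <- shared_summary()
  gt <- sim$ground_truth$episode_summary
  for (ty in c("elective", "emergency")) {
    target <- if (ty == "elective") sim$config$rate_gradient_elective else
      sim$config$rate_gradient_emergency
    realised <- 1 + rate_ratio(s, "Q1", "Q5", stratum = ty, digits = NULL) / 100
    keep <- 1 - sim$config$missing_rate
    e1 <- keep * gt$expected_episodes[gt$quintile == "Q1" & gt$admission_type == ty]
    e5 <- keep * gt$expected_episodes[gt$quintile == "Q5" & gt$admission_type == ty]
    se_log <- sqrt(1 / e1 + 1 / e5)
    expect_lt(abs(log(realised / target)), 3 * se_log)
  }
})
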