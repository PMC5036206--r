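test_that("band rates pool deaths and populations, not area-level rates", {
  areas <- assign_quintiles(tibble::tibble(area_id = paste0("A", 1:5),
                                           imd_rank = 1:5))
  # 3 areas of Q-mixed sizes collapse within their quintiles; use one quintile
  pop <- tibble::tibble(
    area_id = rep(c("A1", "A2", "A3"), each = 2),
    sex = "female",
    age = rep(c(0L, 1L), 3),
    count = c(900, 100, 50, 50, 10, 10)
  )
  deaths <- tibble::tibble(
    area_id = c("A1", "A2", "A3"),
    sex = "female",
    age_band = "0-4",
    deaths = c(10L, 5L, 2L)
  )
  suppressWarnings(r <- mortality_rates(deaths, pop, areas))
  got <- r$rate[r$quintile == "Q1" & r$age_band == "0-4"]
  expect_equal(got, 10 / 1000) # pooled within area A1's quintile
  # oracle on the pooled aggregate (A1+A2+A3 live in Q1..Q3 here): check a
  # direct D/N division too
  expect_equal(r$rate[r$quintile == "Q2" & r$age_band == "0-4"], 5 / 100)
  expect_equal(r$rate[r$quintile == "Q3" & r$age_band == "0-4"], 2 / 20)
})

test_that("impossible and degenerate death counts are handled explicitly", {
  areas <- assign_quintiles(tibble::tibble(area_id = paste0("A", 1:5),
                                           imd_rank = 1:5))
  pop <- tibble::tibble(area_id = "A1", sex = "male", age = 3L, count = 5L)
  deaths <- tibble::tibble(area_id = "A1", sex = "male", age_band = "0-4",
                           deaths = 10L)
  expect_error(suppressWarnings(mortality_rates(deaths, pop, areas)),
               class = "ineqcost_validation_error")
  # zero population with zero deaths: rate 0 with a warning
  pop0 <- tibble::tibble(area_id = "A1", sex = "male", age = c(3L, 40L),
                         count = c(5L, 0L))
  expect_warning(
    r <- mortality_rates(deaths[0, ], pop0, areas),
    "empty population"
  )
  expect_true(all(r$rate[r$pop == 0] == 0))
})

test_that("band expansion is piecewise constant with the open band held to max_age", {
  one <- tibble::tibble(age_band = c("0-4", "5-9", "10+"),
                        rate = c(0.002, 0.001, 0.15))
  out <- expand_bands(one, max_age = 20)
  expect_equal(out$age, 0:20)
  expect_equal(out$rate[out$age <= 4], rep(0.002, 5))
  expect_equal(out$rate[out$age >= 10], rep(0.15, 11))

  open85 <- tibble::tibble(age_band = c(sprintf("%d-%d", seq(0, 80, 5), seq(4, 84, 5)), "85+"),
                           rate = c(rep(0.001, 17), 0.15))
  out85 <- expand_bands(open85, max_age = 110)
  expect_equal(out85$rate[out85$age >= 85], rep(0.15, 26))

  single <- tibble::tibble(age_band = "0+", rate = 0.01)
  flat <- expand_bands(single, max_age = 50)
  expect_equal(flat$rate, rep(0.01, 51))
})

test_that("gappy, overlapping or unclosed band sets are rejected", {
  expect_error(expand_bands(tibble::tibble(age_band = c("0-4", "10-14", "15+"),
                                           rate = c(0.1, 0.1, 0.1))),
               class = "ineqcost_validation_error")
  expect_error(expand_bands(tibble::tibble(age_band = c("0-4", "3-9", "10+"),
                                           rate = c(0.1, 0.1, 0.1))),
               class = "ineqcost_validation_error")
  expect_error(expand_bands(tibble::tibble(age_band = c("0-4", "5-9"),
                                           rate = c(0.1, 0.1))),
               class = "ineqcost_validation_error")
  expect_error(expand_bands(tibble::tibble(age_band = c("5-9", "10+"),
                                           rate = c(0.1, 0.1))),
               class = "ineqcost_validation_error")
})

test_that("survival curves follow the life-table recursion", {
  flat0 <- tibble::tibble(age = 0:10, rate = 0)
  expect_equal(survival_curve(flat0)$survival, rep(1, 11))

  absorbing <- tibble::tibble(age = 0:5, rate = c(1, 0, 0, 0, 0, 0))
  expect_equal(survival_curve(absorbing)$survival, c(1, rep(0, 5)))

  const <- tibble::tibble(age = 0:99, rate = 0.01)
  expect_equal(survival_curve(const)$survival, 0.99^(0:99), tolerance = 1e-14)

  # actuarial convention: q = m / (1 + m/2)
  q_act <- 0.01 / (1 + 0.005)
  expect_equal(survival_curve(const, q_convention = "actuarial")$survival,
               (1 - q_act)^(0:99), tolerance = 1e-14)

  expect_error(survival_curve(tibble::tibble(age = 0:2, rate = c(0, 1.2, 0))),
               class = "ineqcost_validation_error")
})

test_that("raising any hazard weakly lowers survival at all later ages", {
  set.seed(808)
  for (i in 1:20) {
    m <- runif(30, 0, 0.2)
    base <- survival_curve(tibble::tibble(age = 0:29, rate = m))$survival
    expect_true(all(diff(base) <= 0))
    expect_true(all(base >= 0) && base[1] == 1)
    j <- sample(30, 1)
    m2 <- m
    m2[j] <- min(1, m[j] + runif(1, 0, 0.3))
    bumped <- survival_curve(tibble::tibble(age = 0:29, rate = m2))$survival
    expect_true(all(bumped[1:j] == base[1:j]))
    if (j < 30) expect_true(all(bumped[(j + 1):30] <= base[(j + 1):30]))
  }
})

test_that("a deprivation hazard gradient orders the survival curves", {
  sim <- shared_sim()
  gt <- sim$ground_truth$mortality_band_rates
  surv <- gt |>
    dplyr::select(quintile, sex, age_band, rate) |>
    expand_bands(max_age = 110) |>
    survival_curve()
  wide <- surv |>
    dplyr::filter(quintile %in% c("Q1", "Q5"), age > 0) |>
    tidyr::pivot_wider(id_cols = c(sex, age), names_from = quintile,
                       values_from = survival)
  expect_true(all(wide$Q1 < wide$Q5))
})
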