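# Survival-weighted expected annual costs and cumulative lifetime costs.

#' Annual average-cost profile by quintile, sex and age
#'
#' Pulls c-bar (uplifted average annual cost per head, pence) for one
#' admission stratum from a `group_cost_summary`. Ages run 0..85 with 85
#' standing for the open 85+ group. Cells with zero population have no
#' observable average cost; they are returned as `NA` and handled by the
#' consumer.
#'
#' @param summary a `group_cost_summary`.
#' @param stratum `"all"`, `"elective"` or `"emergency"`.
#' @return tibble `quintile`, `sex`, `age`, `avg_cost_pence`.
#' @export
annual_cost_profile <- function(summary, stratum = "all") {
  stopifnot(inherits(summary, "group_cost_summary"))
  summary$cells %>%
    filter(.data$admission_type == stratum) %>%
    select("quintile", "sex", "age", "avg_cost_pence")
}

#' Expected annual cost: survival-weighted average cost
#'
#' Multiplies each group's average annual cost per head by the probability of
#' being alive to incur it. Average costs are only observed up to the open
#' 85+ group, so ages beyond 84 reuse the 85+ value (the truncation of the
#' source tables). The survival weight is start-of-year `S(a)` by default, or
#' the mid-year average `(S(a) + S(a+1)) / 2`.
#'
#' @param survival tibble `quintile`, `sex`, `age`, `survival` from
#'   [survival_curve()].
#' @param costs tibble `quintile`, `sex`, `age` (0..85), `avg_cost_pence`
#'   from [annual_cost_profile()].
#' @param weighting `"start"` or `"midyear"`.
#' @param na_cost how to treat ages whose average cost is unobservable (zero
#'   population in the period data): `"zero"` (default; such ages contribute
#'   no cost — at quintile scale they are empty old-age cells whose survival
#'   weight is already near zero) or `"error"`.
#' @return tibble `quintile`, `sex`, `age`, `survival`, `avg_cost_pence`,
#'   `expected_pence`.
#' @export
expected_annual <- function(survival, costs,
                            weighting = c("start", "midyear"),
                            na_cost = c("zero", "error")) {
  weighting <- match.arg(weighting)
  na_cost <- match.arg(na_cost)
  grid_s <- unique(paste(survival$quintile, survival$sex))
  grid_c <- unique(paste(costs$quintile, costs$sex))
  if (!setequal(grid_s, grid_c)) {
    shape_error("survival and cost profiles cover different quintile x sex groups")
  }
  capped <- costs %>%
    mutate(age = pmin(.data$age, OPEN_AGE))
  open_value <- capped %>% filter(.data$age == OPEN_AGE)
  joined <- survival %>%
    mutate(.cost_age = pmin(.data$age, OPEN_AGE)) %>%
    left_join(rename(capped, .cost_age = "age"),
              by = c("quintile", "sex", ".cost_age")) %>%
    select(-".cost_age")
  if (any(is.na(joined$avg_cost_pence))) {
    if (na_cost == "error") {
      bad <- joined %>% filter(is.na(.data$avg_cost_pence))
      validation_error(sprintf(
        "average cost unobservable at %d age(s), e.g. %s %s age %d",
        nrow(bad), as.character(bad$quintile[1]), bad$sex[1], bad$age[1]
      ))
    }
    joined$avg_cost_pence[is.na(joined$avg_cost_pence)] <- 0
  }
  joined %>%
    group_by(.data$quintile, .data$sex) %>%
    arrange(.data$age, .by_group = TRUE) %>%
    mutate(
      .weight = if (weighting == "start") {
        .data$survival
      } else {
        (.data$survival + dplyr::lead(.data$survival,
                                      default = dplyr::last(.data$survival))) / 2
      },
      expected_pence = .data$.weight * .data$avg_cost_pence
    ) %>%
    ungroup() %>%
    select("quintile", "sex", "age", "survival", "avg_cost_pence",
           "expected_pence")
}

#' Cumulative and lifetime expected costs
#'
#' Running sum of the expected annual cost from age 0; the lifetime cost L is
#' the cumulative value at the terminal age. The projection holds period
#' rates, costs and each individual's deprivation quintile fixed over the
#' lifetime, with no discounting.
#'
#' @param expected tibble from [expected_annual()].
#' @return object of class `lifetime_cost`: list with `profile` (adds
#'   `cumulative_pence` per age) and `lifetime` (tibble `quintile`, `sex`,
#'   `lifetime_pence`).
#' @export
cumulative_lifetime <- function(expected) {
  if (any(expected$expected_pence < 0)) {
    validation_error("expected annual costs must be nonnegative")
  }
  profile <- expected %>%
    group_by(.data$quintile, .data$sex) %>%
    arrange(.data$age, .by_group = TRUE) %>%
    mutate(cumulative_pence = cumsum(.data$expected_pence)) %>%
    ungroup()
  lifetime <- profile %>%
    group_by(.data$quintile, .data$sex) %>%
    summarise(lifetime_pence = dplyr::last(.data$cumulative_pence),
              .groups = "drop")
  structure(list(profile = profile, lifetime = lifetime),
            class = "lifetime_cost")
}

#' @export
print.lifetime_cost <- function(x, ...) {
  cat("Expected lifetime hospital costs (GBP)\n\n")
  wide <- x$lifetime %>%
    mutate(lifetime_gbp = round(pence_to_pounds(.data$lifetime_pence))) %>%
    select("quintile", "sex", "lifetime_gbp") %>%
    pivot_wider(names_from = "sex", values_from = "lifetime_gbp")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Lifetime costs from survival curves and a cost summary
#'
#' Convenience wrapper chaining [annual_cost_profile()], [expected_annual()]
#' and [cumulative_lifetime()].
#'
#' @param survival tibble from [survival_curve()].
#' @param summary a `group_cost_summary`.
#' @param stratum admission stratum (default `"all"`).
#' @param weighting survival weighting convention.
#' @return a `lifetime_cost` object.
#' @export
lifetime_costs <- function(survival, summary, stratum = "all",
                           weighting = c("start", "midyear")) {
  expected_annual(survival, annual_cost_profile(summary, stratum = stratum),
                  weighting = weighting) %>%
    cumulative_lifetime()
}
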