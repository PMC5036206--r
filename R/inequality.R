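# Counterfactual cost of inequality: observed cost minus the cost had every
# quintile experienced the least-deprived quintile's age/sex-specific average
# costs, applied to its own demographic profile (direct standardisation).

#' Age/sex average-cost profile of a reference quintile
#'
#' @param summary a `group_cost_summary`.
#' @param reference quintile label supplying the reference profile (default
#'   `"Q5"`, the least deprived).
#' @param stratum admission stratum (default `"all"`).
#' @return tibble `sex`, `age`, `avg_cost_pence` (uplifted cost per head).
#' @export
reference_cost_profile <- function(summary, reference = "Q5", stratum = "all") {
  stopifnot(inherits(summary, "group_cost_summary"))
  summary$cells %>%
    filter(.data$quintile == reference, .data$admission_type == stratum) %>%
    select("sex", "age", "avg_cost_pence")
}

#' Counterfactual cost under a reference cost profile
#'
#' For each quintile g and sex s, the cost its population would incur if every
#' resident experienced the reference quintile's age/sex-specific average
#' annual cost: `sum_a N(g,a,s) x cbar(ref,a,s)`. Cells with zero population
#' contribute nothing.
#'
#' @param population quintile-level population tibble (`quintile`, `sex`,
#'   `age`, `pop`), e.g. `summary$population`.
#' @param profile reference profile from [reference_cost_profile()].
#' @return tibble `quintile`, `sex`, `cost_pence`.
#' @export
counterfactual_cost <- function(population, profile) {
  joined <- population %>%
    left_join(profile, by = c("sex", "age"))
  bad <- joined %>% filter(.data$pop > 0, is.na(.data$avg_cost_pence))
  if (nrow(bad) > 0) {
    validation_error(sprintf(
      "reference profile undefined for %d populated cell(s), e.g. %s age %d",
      nrow(bad), bad$sex[1], bad$age[1]
    ))
  }
  joined %>%
    group_by(.data$quintile, .data$sex) %>%
    summarise(cost_pence = sum(ifelse(.data$pop > 0,
                                      .data$pop * .data$avg_cost_pence, 0)),
              .groups = "drop")
}

#' Observed (uplifted) cost by quintile and sex
#'
#' Computed as `sum_a N(g,a,s) x cbar(g,a,s)` — term-by-term the same products
#' as the counterfactual, so the reference quintile's gap is exactly zero by
#' construction rather than zero up to floating-point reassociation.
#'
#' @param summary a `group_cost_summary`.
#' @param stratum admission stratum (default `"all"`).
#' @return tibble `quintile`, `sex`, `cost_pence`.
#' @export
observed_cost <- function(summary, stratum = "all") {
  stopifnot(inherits(summary, "group_cost_summary"))
  summary$cells %>%
    filter(.data$admission_type == stratum) %>%
    group_by(.data$quintile, .data$sex) %>%
    summarise(cost_pence = sum(ifelse(.data$pop > 0,
                                      .data$pop * .data$avg_cost_pence, 0)),
              .groups = "drop")
}

#' Observed-minus-counterfactual cost gaps with margins
#'
#' Element-wise difference on the quintile x sex grid plus per-quintile,
#' per-sex and grand totals. Negative gaps (a quintile cheaper than the
#' reference at its own demography) are reported, not floored.
#'
#' @param observed,counterfactual tibbles `quintile`, `sex`, `cost_pence` on
#'   identical grids.
#' @param reference optional label of the reference (comparator) quintile,
#'   recorded for reporting.
#' @return object of class `inequality_cost`: list with `by_cell` (observed,
#'   counterfactual and gap per quintile x sex), `quintile_totals`,
#'   `sex_totals`, `grand_total_pence` and `reference`.
#' @export
inequality_gap <- function(observed, counterfactual, reference = NULL) {
  key_obs <- paste(observed$quintile, observed$sex)
  key_cf <- paste(counterfactual$quintile, counterfactual$sex)
  if (nrow(observed) != nrow(counterfactual) ||
      !setequal(key_obs, key_cf) || anyDuplicated(key_obs)) {
    shape_error("observed and counterfactual are not defined on the same quintile x sex grid")
  }
  by_cell <- observed %>%
    rename(observed_pence = "cost_pence") %>%
    inner_join(rename(counterfactual, counterfactual_pence = "cost_pence"),
               by = c("quintile", "sex")) %>%
    mutate(gap_pence = .data$observed_pence - .data$counterfactual_pence) %>%
    arrange(.data$quintile, .data$sex)
  quintile_totals <- by_cell %>%
    group_by(.data$quintile) %>%
    summarise(gap_pence = sum(.data$gap_pence), .groups = "drop")
  sex_totals <- by_cell %>%
    group_by(.data$sex) %>%
    summarise(gap_pence = sum(.data$gap_pence), .groups = "drop")
  structure(
    list(
      by_cell = by_cell,
      quintile_totals = quintile_totals,
      sex_totals = sex_totals,
      grand_total_pence = sum(by_cell$gap_pence),
      reference = reference
    ),
    class = "inequality_cost"
  )
}

#' Cost of inequality relative to the least-deprived quintile
#'
#' Convenience wrapper: builds the reference profile, the counterfactual and
#' the observed costs from one summary and returns the gap object.
#'
#' @param summary a `group_cost_summary`.
#' @param reference reference quintile (default `"Q5"`).
#' @param stratum admission stratum (default `"all"`).
#' @return an `inequality_cost` object.
#' @export
cost_of_inequality <- function(summary, reference = "Q5", stratum = "all") {
  profile <- reference_cost_profile(summary, reference = reference,
                                    stratum = stratum)
  cf <- counterfactual_cost(summary$population, profile)
  obs <- observed_cost(summary, stratum = stratum)
  inequality_gap(obs, cf, reference = reference)
}

#' @export
print.inequality_cost <- function(x, ...) {
  cat("Cost of inequality vs reference quintile\n\n")
  print(as.data.frame(render_table2(x)), row.names = FALSE)
  cat(sprintf("\nGrand total: GBP %s\n",
              format(round(pence_to_pounds(x$grand_total_pence)),
                     big.mark = " ", scientific = FALSE)))
  invisible(x)
}
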