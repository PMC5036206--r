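# Presentation-layer tables: quintile-ordered reports with rounding applied
# only here. Every number is re-derivable from the underlying objects.

fmt_int <- function(x) {
  format(round(x), big.mark = " ", scientific = FALSE, trim = TRUE)
}

#' Episode counts and rates by admission type and quintile
#'
#' Quintile-ordered rows Q1..Q5 plus Overall; counts as integers and rates as
#' integer episodes per 100 000 residents, for elective, emergency and all
#' admissions. Empty strata render as zeros.
#'
#' @param summary a `group_cost_summary`.
#' @return a tibble with columns `quintile`, then `<stratum>_n` and
#'   `<stratum>_rate` for elective, emergency and all.
#' @export
render_table1 <- function(summary) {
  stopifnot(inherits(summary, "group_cost_summary"))
  qs <- summary$quintile_summary %>%
    mutate(
      episode_n = round(.data$episode_n),
      rate = round(dplyr::coalesce(.data$rate_per_100k, 0))
    ) %>%
    select("quintile", "admission_type", "episode_n", "rate") %>%
    pivot_wider(names_from = "admission_type",
                values_from = c("episode_n", "rate"))
  qs %>%
    select("quintile",
           elective_n = "episode_n_elective", elective_rate = "rate_elective",
           emergency_n = "episode_n_emergency", emergency_rate = "rate_emergency",
           all_n = "episode_n_all", all_rate = "rate_all") %>%
    arrange(factor(.data$quintile, levels = c(QUINTILES, "Overall")))
}

#' Estimated cost of inequality by quintile and sex
#'
#' Quintile-ordered rows with female, male and total gaps in whole pounds;
#' the reference quintile's cells are rendered as a dash, and an `Overall` row
#' totals the remaining quintiles. The reference quintile's own observed
#' costs are attached as the `"footnote"` attribute.
#'
#' @param ineq an `inequality_cost`.
#' @return a tibble of formatted character columns `quintile`, `female`,
#'   `male`, `total`, with a `"footnote"` attribute.
#' @export
render_table2 <- function(ineq) {
  stopifnot(inherits(ineq, "inequality_cost"))
  ref <- ineq$reference
  wide <- ineq$by_cell %>%
    mutate(gap_gbp = pence_to_pounds(.data$gap_pence)) %>%
    select("quintile", "sex", "gap_gbp") %>%
    pivot_wider(names_from = "sex", values_from = "gap_gbp") %>%
    mutate(total = .data$female + .data$male,
           quintile = as.character(.data$quintile)) %>%
    arrange(factor(.data$quintile, levels = QUINTILES))
  keep <- if (is.null(ref)) rep(TRUE, nrow(wide)) else wide$quintile != ref
  overall <- tibble(
    quintile = "Overall",
    female = sum(wide$female[keep]),
    male = sum(wide$male[keep]),
    total = sum(wide$total[keep])
  )
  out <- bind_rows(wide, overall) %>%
    mutate(across(c("female", "male", "total"), fmt_int))
  if (!is.null(ref)) {
    out[out$quintile == ref, c("female", "male", "total")] <- "-"
    comp <- ineq$by_cell %>%
      filter(.data$quintile == ref) %>%
      mutate(observed_gbp = pence_to_pounds(.data$observed_pence))
    footnote <- sprintf(
      "Comparator group %s - observed costs are GBP %s, %s and %s for women, men and total, respectively.",
      ref,
      fmt_int(comp$observed_gbp[comp$sex == "female"]),
      fmt_int(comp$observed_gbp[comp$sex == "male"]),
      fmt_int(sum(comp$observed_gbp))
    )
    attr(out, "footnote") <- footnote
  }
  out
}

#' Plot survival curves by quintile and sex
#'
#' @param survival tibble `quintile`, `sex`, `age`, `survival`.
#' @return a ggplot object.
#' @export
plot_survival <- function(survival) {
  ggplot2::ggplot(survival,
                  ggplot2::aes(x = .data$age, y = .data$survival,
                               colour = .data$quintile)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Age (years)", y = "Probability of survival",
                  colour = "IMD quintile") +
    ggplot2::theme_minimal()
}

#' Plot cumulative expected lifetime costs by quintile and sex
#'
#' @param lifetime a `lifetime_cost` object.
#' @return a ggplot object.
#' @export
plot_cumulative_costs <- function(lifetime) {
  stopifnot(inherits(lifetime, "lifetime_cost"))
  ggplot2::ggplot(lifetime$profile,
                  ggplot2::aes(x = .data$age,
                               y = pence_to_pounds(.data$cumulative_pence),
                               colour = .data$quintile)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Age (years)", y = "Cumulative expected cost (GBP)",
                  colour = "IMD quintile") +
    ggplot2::theme_minimal()
}
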