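# Quintile assignment and reduction of costed episodes to per-cell totals,
# rates per 100 000 and average annual cost per head.

#' Assign deprivation quintiles from area ranks
#'
#' Areas are sorted by deprivation rank (1 = most deprived) and cut into five
#' near-equal groups of *areas* (not population-weighted): Q1 is the most
#' deprived fifth, Q5 the least. When the number of areas is not divisible by
#' 5 the remainder areas go to the more-deprived quintiles first, so group
#' sizes differ by at most one and the split is deterministic.
#'
#' @param areas tibble with `area_id` and `imd_rank` (distinct positive
#'   integers; rank 1 = most deprived).
#' @return the input with a `quintile` factor column (levels Q1..Q5).
#' @export
assign_quintiles <- function(areas) {
  if (!all(c("area_id", "imd_rank") %in% names(areas))) {
    shape_error("`areas` needs columns `area_id` and `imd_rank`")
  }
  ranks <- areas$imd_rank
  if (any(is.na(ranks)) || any(ranks < 1) || any(ranks != round(ranks))) {
    validation_error("IMD ranks must be distinct positive integers")
  }
  dup <- unique(ranks[duplicated(ranks)])
  if (length(dup) > 0) {
    validation_error(sprintf("duplicate IMD rank(s): %s",
                             paste(sort(dup), collapse = ", ")))
  }
  n <- nrow(areas)
  if (n < 5) validation_error("need at least 5 areas to form quintiles")
  sizes <- rep(n %/% 5, 5)
  rem <- n %% 5
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(areas$imd_rank)
  quintile <- character(n)
  quintile[ord] <- rep(QUINTILES, times = sizes)
  dplyr::mutate(areas, quintile = factor(quintile, levels = QUINTILES))
}

#' Collapse an area-level population table to quintile level
#'
#' @param population tibble `area_id`, `sex`, `age`, `count`.
#' @param areas quintile lookup from [assign_quintiles()].
#' @return tibble `quintile`, `sex`, `age`, `pop` covering the full grid.
#' @export
population_by_quintile <- function(population, areas) {
  missing_areas <- setdiff(unique(population$area_id), areas$area_id)
  if (length(missing_areas) > 0) {
    lookup_error(sprintf("population rows reference unknown area(s): %s",
                         paste(head(sort(missing_areas), 5), collapse = ", ")))
  }
  population %>%
    left_join(select(areas, "area_id", "quintile"), by = "area_id") %>%
    group_by(.data$quintile, .data$sex, .data$age) %>%
    summarise(pop = sum(.data$count), .groups = "drop") %>%
    complete(quintile = factor(QUINTILES, levels = QUINTILES),
             sex = SEXES, age = 0:OPEN_AGE, fill = list(pop = 0))
}

#' Aggregate costed episodes to quintile x age x sex summaries
#'
#' Reduces groupable costed episodes to per-cell episode counts, cost totals,
#' rates per 100 000 residents, and average annual cost per head c-bar =
#' uplifted total cost / population. Each cell is reported for elective and
#' emergency strata and their exact sum (`admission_type = "all"`), together
#' with quintile-level and overall margins (the Table-1-shaped report).
#'
#' @param costed costed, groupable episodes (no missing age/sex/area) from
#'   [cost_episodes()].
#' @param areas quintile lookup from [assign_quintiles()].
#' @param population area-level population table.
#' @param costing a [costing_config()] carrying the missing-data uplift
#'   (default: no uplift).
#' @return object of class `group_cost_summary`: list with `cells` (per
#'   quintile x sex x age x stratum), `quintile_summary` (margins incl.
#'   Overall), `population` (quintile-level) and `inflation_factor`.
#' @export
aggregate_costs <- function(costed, areas, population,
                            costing = costing_config(0)) {
  if (!inherits(costing, "costing_config")) {
    config_error("`costing` must be a costing_config object")
  }
  if (nrow(costed) > 0) {
    if (any(is.na(costed$age)) || any(is.na(costed$sex)) || any(is.na(costed$area_id))) {
      validation_error("costed episodes contain missing age/sex/area; run filter_groupable() first")
    }
    bad <- setdiff(unique(costed$area_id), areas$area_id)
    if (length(bad) > 0) {
      lookup_error(sprintf("episode area id(s) absent from the area lookup: %s",
                           paste(head(sort(bad), 5), collapse = ", ")))
    }
  }
  pop_q <- population_by_quintile(population, areas)
  fac <- costing$inflation_factor

  by_type <- costed %>%
    left_join(select(areas, "area_id", "quintile"), by = "area_id") %>%
    group_by(.data$quintile, .data$sex, .data$age, .data$admission_type) %>%
    summarise(episode_n = n(), total_cost_pence = sum(.data$cost_pence),
              .groups = "drop")
  all_type <- by_type %>%
    group_by(.data$quintile, .data$sex, .data$age) %>%
    summarise(episode_n = sum(.data$episode_n),
              total_cost_pence = sum(.data$total_cost_pence),
              .groups = "drop") %>%
    mutate(admission_type = "all")
  cells <- bind_rows(by_type, all_type) %>%
    complete(quintile = factor(QUINTILES, levels = QUINTILES),
             sex = SEXES, age = 0:OPEN_AGE,
             admission_type = c("elective", "emergency", "all"),
             fill = list(episode_n = 0L, total_cost_pence = 0)) %>%
    left_join(pop_q, by = c("quintile", "sex", "age"))
  ghost <- cells %>% filter(.data$pop == 0, .data$episode_n > 0)
  if (nrow(ghost) > 0) {
    validation_error(sprintf(
      "episodes recorded in zero-population cell(s), e.g. %s %s age %d",
      as.character(ghost$quintile[1]), ghost$sex[1], ghost$age[1]
    ))
  }
  cells <- cells %>%
    mutate(
      rate_per_100k = ifelse(.data$pop > 0, .data$episode_n / .data$pop * 1e5, NA_real_),
      avg_cost_pence = ifelse(.data$pop > 0,
                              .data$total_cost_pence * fac / .data$pop, NA_real_)
    ) %>%
    arrange(.data$quintile, .data$sex, .data$age, .data$admission_type)

  q_pop <- pop_q %>%
    group_by(.data$quintile) %>%
    summarise(pop = sum(.data$pop), .groups = "drop")
  q_sum <- cells %>%
    group_by(.data$quintile, .data$admission_type) %>%
    summarise(episode_n = sum(.data$episode_n),
              total_cost_pence = sum(.data$total_cost_pence), .groups = "drop") %>%
    left_join(q_pop, by = "quintile")
  overall <- q_sum %>%
    group_by(.data$admission_type) %>%
    summarise(episode_n = sum(.data$episode_n),
              total_cost_pence = sum(.data$total_cost_pence),
              pop = sum(.data$pop), .groups = "drop") %>%
    mutate(quintile = "Overall")
  quintile_summary <- bind_rows(
    q_sum %>% mutate(quintile = as.character(.data$quintile)),
    overall
  ) %>%
    mutate(
      rate_per_100k = ifelse(.data$pop > 0, .data$episode_n / .data$pop * 1e5, NA_real_),
      inflated_cost_pence = .data$total_cost_pence * fac,
      avg_cost_pence = ifelse(.data$pop > 0, .data$inflated_cost_pence / .data$pop,
                              NA_real_)
    ) %>%
    arrange(factor(.data$quintile, levels = c(QUINTILES, "Overall")),
            .data$admission_type)

  structure(
    list(cells = cells, quintile_summary = quintile_summary,
         population = pop_q, inflation_factor = fac),
    class = "group_cost_summary"
  )
}

#' @export
print.group_cost_summary <- function(x, ...) {
  cat("Group cost summary (uplift factor",
      format(x$inflation_factor, digits = 6), ")\n\n")
  print(as.data.frame(render_table1(x)), row.names = FALSE)
  invisible(x)
}

#' Percentage excess of one rate over another
#'
#' `100 * (rate_num / rate_den - 1)`, rounded to the nearest integer per cent
#' by default (the reporting convention; pass `digits = NULL` for the raw
#' value).
#'
#' @param rate_num,rate_den numeric rates; the denominator must be positive.
#' @param digits rounding digits, or `NULL` for unrounded.
#' @return numeric percentage excess.
#' @export
rate_excess_pct <- function(rate_num, rate_den, digits = 0) {
  if (any(!is.finite(rate_den)) || any(rate_den <= 0)) {
    validation_error("rate ratio undefined: denominator rate must be positive")
  }
  out <- 100 * (rate_num / rate_den - 1)
  if (is.null(digits)) out else round(out, digits)
}

#' Quintile rate ratio from a group cost summary
#'
#' @param summary a `group_cost_summary`.
#' @param g_num,g_den quintile labels, e.g. `"Q1"`, `"Q5"`.
#' @param stratum `"elective"`, `"emergency"` or `"all"`.
#' @param digits rounding digits for the percentage (default integer percent).
#' @return percentage excess of `g_num`'s rate over `g_den`'s.
#' @export
rate_ratio <- function(summary, g_num = "Q1", g_den = "Q5",
                       stratum = "all", digits = 0) {
  stopifnot(inherits(summary, "group_cost_summary"))
  qs <- summary$quintile_summary
  get_rate <- function(g) {
    r <- qs$rate_per_100k[qs$quintile == g & qs$admission_type == stratum]
    if (length(r) != 1) {
      lookup_error(sprintf("no unique rate for quintile %s, stratum %s", g, stratum))
    }
    r
  }
  rate_excess_pct(get_rate(g_num), get_rate(g_den), digits = digits)
}
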