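# Episode costing: tariff lookup with excess bed-day supplements, the
# missing-data exclusion, and the cost uplift that compensates for it.

#' Cost episodes from a reference-cost tariff table
#'
#' Each episode is costed as `unit_cost + max(0, length_of_stay - trim_point)
#' x excess_per_diem` for its healthcare resource group (HRG): the tariff
#' covers stays up to the trim point, and each excess bed day attracts a per
#' diem supplement. No local-price (market forces factor) adjustment is made.
#' Costs are exact integer pence.
#'
#' @param episodes tibble of episode records with at least `hrg_code` and
#'   `length_of_stay`.
#' @param tariffs reference-cost table: `hrg_code`, `unit_cost_pence`,
#'   `trim_point_days`, `excess_per_diem_pence`.
#' @return the input with a `cost_pence` column appended.
#' @export
cost_episodes <- function(episodes, tariffs) {
  validate_tariffs(tariffs)
  unknown <- setdiff(unique(episodes$hrg_code), tariffs$hrg_code)
  if (length(unknown) > 0) {
    lookup_error(sprintf(
      "episodes reference HRG code(s) absent from the tariff table: %s",
      paste(sort(unknown), collapse = ", ")
    ))
  }
  i <- match(episodes$hrg_code, tariffs$hrg_code)
  excess_days <- pmax(0, episodes$length_of_stay - tariffs$trim_point_days[i])
  dplyr::mutate(
    episodes,
    cost_pence = tariffs$unit_cost_pence[i] +
      excess_days * tariffs$excess_per_diem_pence[i]
  )
}

validate_tariffs <- function(tariffs) {
  needed <- c("hrg_code", "unit_cost_pence", "trim_point_days",
              "excess_per_diem_pence")
  missing_cols <- setdiff(needed, names(tariffs))
  if (length(missing_cols) > 0) {
    shape_error(sprintf("tariff table lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tariffs$hrg_code)) {
    validation_error("tariff table has duplicate HRG codes")
  }
  if (any(tariffs$unit_cost_pence < 0) || any(tariffs$excess_per_diem_pence < 0) ||
      any(tariffs$trim_point_days < 0)) {
    validation_error("tariff costs and trim points must be nonnegative")
  }
  invisible(tariffs)
}

#' Drop episodes that cannot be grouped and measure the missing fraction
#'
#' Episodes missing any of age, sex or area of residence cannot be assigned to
#' an age x sex x deprivation-quintile cell and are excluded. The observed
#' missing fraction feeds [costing_config()], whose uplift compensates group
#' cost totals for the exclusion.
#'
#' @param episodes episode tibble with `age`, `sex`, `area_id` columns.
#' @return list with `kept` (groupable episodes), `dropped_count` and
#'   `missing_fraction` (0 for empty input).
#' @export
filter_groupable <- function(episodes) {
  total <- nrow(episodes)
  if (total == 0) {
    return(list(kept = episodes, dropped_count = 0L, missing_fraction = 0))
  }
  ok <- !is.na(episodes$age) & !is.na(episodes$sex) & !is.na(episodes$area_id)
  list(
    kept = episodes[ok, , drop = FALSE],
    dropped_count = sum(!ok),
    missing_fraction = sum(!ok) / total
  )
}

#' Costing configuration: missing fraction and cost uplift
#'
#' The uplift is multiplicative by `1 + missing_fraction`, applied to group
#' cost totals only (never to populations), under the assumption that
#' ungroupable episodes are equally distributed across all patient groups and
#' HRGs. Note this is a literal percentage uplift, not the renormalisation
#' `1 / (1 - missing_fraction)`; the small difference is deliberate and
#' documented in the methods vignette.
#'
#' @param missing_fraction proportion of episodes dropped, in `[0, 1)`.
#' @return object of class `costing_config` with `missing_fraction` and
#'   `inflation_factor`.
#' @export
costing_config <- function(missing_fraction) {
  if (!is.numeric(missing_fraction) || length(missing_fraction) != 1 ||
      is.na(missing_fraction) || missing_fraction < 0 || missing_fraction >= 1) {
    config_error("`missing_fraction` must be a single number in [0, 1)")
  }
  structure(
    list(missing_fraction = missing_fraction,
         inflation_factor = 1 + missing_fraction),
    class = "costing_config"
  )
}

#' Uplift group cost totals for the missing-data exclusion
#'
#' @param totals numeric vector of nonnegative group cost totals.
#' @param cfg a [costing_config()].
#' @return the totals multiplied by the inflation factor.
#' @export
inflate_totals <- function(totals, cfg) {
  if (!inherits(cfg, "costing_config")) {
    config_error("`cfg` must be a costing_config object")
  }
  if (any(totals < 0, na.rm = TRUE)) {
    validation_error("cost totals must be nonnegative")
  }
  totals * cfg$inflation_factor
}
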