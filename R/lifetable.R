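# Period life tables: pooled banded death rates, band-to-single-year
# expansion, and survival curves per deprivation quintile and sex.

#' Five-year age band labels
#'
#' The banded mortality extracts use 0-4, 5-9, ..., 80-84 and an open 85+
#' group.
#'
#' @return character vector of band labels in age order.
#' @export
age_band_levels <- function() {
  c(sprintf("%d-%d", seq(0, 80, 5), seq(4, 84, 5)), "85+")
}

#' Map single-year ages to 5-year bands
#'
#' @param age integer ages (85 denotes the open 85+ group).
#' @return factor of band labels.
#' @export
band_of_age <- function(age) {
  lab <- ifelse(age >= OPEN_AGE, "85+",
                sprintf("%d-%d", 5 * (age %/% 5), 5 * (age %/% 5) + 4))
  factor(lab, levels = age_band_levels())
}

# Parse "lo-hi" / "lo+" band labels into lower/upper bounds (upper = Inf for
# the open band).
parse_bands <- function(labels) {
  open <- grepl("\\+$", labels)
  lower <- suppressWarnings(ifelse(open, as.numeric(sub("\\+$", "", labels)),
                                   as.numeric(sub("-.*$", "", labels))))
  upper <- suppressWarnings(ifelse(open, Inf, as.numeric(sub("^.*-", "", labels))))
  if (any(is.na(lower)) || any(is.na(upper))) {
    validation_error("age bands must look like '0-4' or '85+'")
  }
  tibble(age_band = labels, lower = lower, upper = upper)
}

#' Pooled mortality rates by quintile, sex and age band
#'
#' Deaths and populations are pooled across the areas of each quintile before
#' dividing — `m = sum(D) / sum(N)` — which is the population-weighted rate,
#' not the mean of area-level rates. Populations given by single year of age
#' are collapsed onto the death bands.
#'
#' @param mortality tibble `area_id`, `sex`, `age_band`, `deaths`.
#' @param population tibble `area_id`, `sex`, `age`, `count` (single years,
#'   85 = 85+).
#' @param areas quintile lookup from [assign_quintiles()].
#' @return tibble `quintile`, `sex`, `age_band`, `deaths`, `pop`, `rate`.
#' @export
mortality_rates <- function(mortality, population, areas) {
  pop_band <- population %>%
    left_join(select(areas, "area_id", "quintile"), by = "area_id") %>%
    mutate(age_band = band_of_age(.data$age)) %>%
    group_by(.data$quintile, .data$sex, .data$age_band) %>%
    summarise(pop = sum(.data$count), .groups = "drop")
  deaths_band <- mortality %>%
    left_join(select(areas, "area_id", "quintile"), by = "area_id") %>%
    mutate(age_band = factor(.data$age_band, levels = age_band_levels())) %>%
    group_by(.data$quintile, .data$sex, .data$age_band) %>%
    summarise(deaths = sum(.data$deaths), .groups = "drop")
  out <- pop_band %>%
    left_join(deaths_band, by = c("quintile", "sex", "age_band")) %>%
    mutate(deaths = dplyr::coalesce(.data$deaths, 0L))
  bad <- out %>% filter(.data$deaths > .data$pop)
  if (nrow(bad) > 0) {
    validation_error(sprintf(
      "deaths exceed population in %d cell(s), e.g. %s %s band %s",
      nrow(bad), as.character(bad$quintile[1]), bad$sex[1],
      as.character(bad$age_band[1])
    ))
  }
  if (any(out$pop == 0 & out$deaths == 0)) {
    warning("empty population band(s); mortality rate set to 0 there",
            call. = FALSE)
  }
  out %>%
    mutate(rate = ifelse(.data$pop > 0, .data$deaths / .data$pop, 0)) %>%
    arrange(.data$quintile, .data$sex, .data$age_band)
}

#' Expand banded rates to single years of age
#'
#' Piecewise-constant expansion: every year within a band receives the band's
#' rate, and ages beyond the open band's lower bound (85+) all receive the
#' open band's rate up to `max_age` — the truncated extracts force the
#' assumption that rates stop rising after 85.
#'
#' @param band_rates tibble with `age_band`, `rate` and any id columns (e.g.
#'   `quintile`, `sex`), one row per band per group.
#' @param max_age final single year of age produced (default 110).
#' @return tibble with the id columns plus `age` (0..`max_age`) and `rate`.
#' @export
expand_bands <- function(band_rates, max_age = 110L) {
  id_cols <- setdiff(names(band_rates), c("age_band", "rate", "deaths", "pop"))
  bands <- parse_bands(as.character(band_rates$age_band))
  df <- band_rates %>%
    mutate(.lower = bands$lower, .upper = bands$upper)
  check_one <- function(g) {
    g <- g[order(g$.lower), ]
    if (g$.lower[1] != 0) validation_error("age bands must start at 0")
    if (sum(is.infinite(g$.upper)) != 1 || !is.infinite(g$.upper[nrow(g)])) {
      validation_error("exactly one open-ended (85+) band must close the age range")
    }
    if (nrow(g) > 1) {
      gaps <- g$.lower[-1] != g$.upper[-nrow(g)] + 1
      if (any(gaps)) validation_error("age bands have a gap or overlap")
    }
    g
  }
  grouped <- if (length(id_cols) > 0) {
    split(df, df[id_cols], drop = TRUE)
  } else {
    list(df)
  }
  out <- lapply(grouped, function(g) {
    g <- check_one(g)
    upper <- pmin(g$.upper, max_age)
    if (g$.lower[nrow(g)] > max_age) {
      validation_error("`max_age` is below the open band's lower bound")
    }
    n_years <- upper - g$.lower + 1
    idx <- rep.int(seq_len(nrow(g)), n_years)
    res <- g[idx, id_cols, drop = FALSE]
    res$age <- as.integer(sequence(n_years, from = g$.lower))
    res$rate <- g$rate[idx]
    res
  })
  as_tibble(bind_rows(out))
}

#' Survival curves from single-year death rates
#'
#' A period life table: a hypothetical cohort is subjected to the
#' cross-sectional rates at every age. `S(0) = 1` and
#' `S(a+1) = S(a) * (1 - q(a))`, with the annual death probability q taken
#' either directly as the central rate m (default) or via the actuarial
#' conversion `q = m / (1 + m/2)`; q is clipped to `[0, 1]`.
#'
#' @param rates tibble with `age`, `rate` and id columns (e.g. `quintile`,
#'   `sex`), single years from 0 per group (use [expand_bands()] first).
#' @param q_convention `"central"` or `"actuarial"`.
#' @return tibble with the id columns plus `age` and `survival`.
#' @export
survival_curve <- function(rates, q_convention = c("central", "actuarial")) {
  q_convention <- match.arg(q_convention)
  if (any(rates$rate < 0 | rates$rate > 1)) {
    validation_error("death rates must lie in [0, 1]")
  }
  id_cols <- setdiff(names(rates), c("age", "rate"))
  df <- rates %>% arrange(across(all_of(c(id_cols, "age"))))
  grouped <- if (length(id_cols) > 0) {
    split(df, df[id_cols], drop = TRUE)
  } else {
    list(df)
  }
  out <- lapply(grouped, function(g) {
    if (!identical(as.integer(g$age), seq(0L, length.out = nrow(g)))) {
      validation_error("rates must cover contiguous single years from age 0")
    }
    q <- switch(q_convention,
      central = g$rate,
      actuarial = g$rate / (1 + g$rate / 2)
    )
    q <- pmin(pmax(q, 0), 1)
    res <- g[, id_cols, drop = FALSE]
    res$age <- g$age
    res$survival <- cumprod(c(1, 1 - q[-length(q)]))
    res
  })
  as_tibble(bind_rows(out))
}

#' Quintile x sex survival curves straight from the input tables
#'
#' Convenience wrapper chaining [mortality_rates()], [expand_bands()] and
#' [survival_curve()].
#'
#' @inheritParams mortality_rates
#' @param opts a [life_table_options()].
#' @return tibble `quintile`, `sex`, `age`, `survival`.
#' @export
survival_from_counts <- function(mortality, population, areas,
                                 opts = life_table_options()) {
  mortality_rates(mortality, population, areas) %>%
    select("quintile", "sex", "age_band", "rate") %>%
    expand_bands(max_age = opts$max_age) %>%
    survival_curve(q_convention = opts$q_convention)
}
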