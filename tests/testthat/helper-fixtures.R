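# Shared fixtures and independent oracles. All simulated data is generated in
# code; the only stored fixtures are the published 2011/12 whole-population
# reference figures shipped in extdata.

ref_path <- function(name) {
  system.file("extdata", name, package = "ineqcost", mustWork = TRUE)
}

ref_episode_rates <- function() {
  readr::read_tsv(ref_path("reference_episode_rates_2011_12.tsv"),
                  show_col_types = FALSE)
}

ref_inequality_gaps <- function() {
  readr::read_tsv(ref_path("reference_inequality_gaps_2011_12.tsv"),
                  show_col_types = FALSE)
}

ref_headlines <- function() {
  tbl <- readr::read_tsv(ref_path("reference_headline_figures_2011_12.tsv"),
                         show_col_types = FALSE)
  stats::setNames(tbl$value, tbl$name)
}

# One moderate synthetic dataset reused across test files (memoised per
# session). 250 areas x 800 residents keeps every downstream cell populated
# while staying fast.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(simulation_config(
        n_areas = 250, mean_area_pop = 800, seed = 424242
      ))
    }
    cache
  }
})

# Shared downstream summary of the shared sim (no missing data handling: the
# default config blanks 8.8%, which filter_groupable removes).
shared_summary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- shared_sim()
      f <- filter_groupable(sim$episodes)
      costed <- cost_episodes(f$kept, sim$tariffs)
      cache <<- aggregate_costs(costed, sim$areas, sim$population,
                                costing = costing_config(f$missing_fraction))
    }
    cache
  }
})

# Straight-line independent costing oracle: per-episode loop, no joins or
# grouped verbs, accumulating totals per quintile x admission type.
brute_force_totals <- function(episodes, tariffs, areas) {
  qmap <- stats::setNames(as.character(areas$quintile), areas$area_id)
  totals <- list()
  for (i in seq_len(nrow(episodes))) {
    row <- episodes[i, ]
    j <- which(tariffs$hrg_code == row$hrg_code)
    extra <- max(0, row$length_of_stay - tariffs$trim_point_days[j])
    cost <- tariffs$unit_cost_pence[j] + extra * tariffs$excess_per_diem_pence[j]
    key <- paste(qmap[[row$area_id]], row$admission_type)
    if (is.null(totals[[key]])) totals[[key]] <- c(n = 0, cost = 0)
    totals[[key]] <- totals[[key]] + c(n = 1, cost = cost)
  }
  totals
}

# Independent micro-simulation oracle: n individual life courses under annual
# death probability q(a) and annual cost cbar(a) incurred at the start of each
# year while alive. Returns the vector of individual lifetime costs.
micro_sim_lifetimes <- function(q, cbar, n, seed) {
  stopifnot(length(q) == length(cbar))
  set.seed(seed)
  alive <- rep(TRUE, n)
  total <- numeric(n)
  for (a in seq_along(q)) {
    total <- total + cbar[a] * alive
    total_alive <- sum(alive)
    if (total_alive == 0) break
    dies <- stats::runif(n) < q[a]
    alive <- alive & !dies
  }
  total
}

# Minimal hand-built group_cost_summary for formula-level tests: `cells` needs
# quintile, sex, age, admission_type, pop, avg_cost_pence columns.
make_summary <- function(cells, population, inflation_factor = 1) {
  structure(
    list(cells = cells, population = population,
         quintile_summary = NULL, inflation_factor = inflation_factor),
    class = "group_cost_summary"
  )
}
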