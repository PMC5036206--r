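# Delimited-text readers and writers for the five input tables and the
# simulated-dataset bundle. All files are headered TSV.

#' Read the input tables
#'
#' Column layouts match what [write_dataset()] produces: episodes (`age`,
#' `sex`, `area_id`, `admission_type`, `hrg_code`, `length_of_stay`, `year`),
#' tariffs (`hrg_code`, `unit_cost_pence`, `trim_point_days`,
#' `excess_per_diem_pence`), population (`area_id`, `sex`, `age`, `count`),
#' mortality (`area_id`, `sex`, `age_band`, `deaths`) and areas (`area_id`,
#' `imd_rank`).
#'
#' @param path file path.
#' @return a tibble.
#' @name readers
NULL

#' @rdname readers
#' @export
read_episodes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    age = readr::col_integer(), sex = readr::col_character(),
    area_id = readr::col_character(), admission_type = readr::col_character(),
    hrg_code = readr::col_character(), length_of_stay = readr::col_integer(),
    year = readr::col_character()
  ), na = "NA", progress = FALSE)
}

#' @rdname readers
#' @export
read_tariffs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' @rdname readers
#' @export
read_population <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    area_id = readr::col_character(), sex = readr::col_character(),
    age = readr::col_integer(), count = readr::col_integer()
  ), progress = FALSE)
}

#' @rdname readers
#' @export
read_mortality <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    area_id = readr::col_character(), sex = readr::col_character(),
    age_band = readr::col_character(), deaths = readr::col_integer()
  ), progress = FALSE)
}

#' @rdname readers
#' @export
read_areas <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    area_id = readr::col_character(), imd_rank = readr::col_integer(),
    .default = readr::col_character()
  ), progress = FALSE)
  assign_quintiles(tbl[, c("area_id", "imd_rank")])
}

#' Write a simulated dataset as delimited text
#'
#' Writes the five analysis inputs plus the echoed configuration and the
#' generator's ground truth. Re-running with the same configuration (same
#' seed) reproduces every file byte for byte.
#'
#' @param sim an `ineqcost_simulation` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ineqcost_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), na = "NA", progress = FALSE)
  }
  w(sim$areas %>% mutate(quintile = as.character(.data$quintile)), "areas.tsv")
  w(sim$population, "population.tsv")
  w(sim$tariffs, "tariffs.tsv")
  w(sim$episodes, "episodes.tsv")
  w(sim$mortality %>% mutate(age_band = as.character(.data$age_band)),
    "mortality.tsv")
  w(sim$ground_truth$episode_summary, "ground_truth_episodes.tsv")
  w(sim$ground_truth$mortality_band_rates %>%
      mutate(age_band = as.character(.data$age_band)),
    "ground_truth_mortality.tsv")
  write_simulation_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
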