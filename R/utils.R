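#' @importFrom rlang abort .data :=
#' @importFrom stats rpois rbinom rgamma rgeom runif setNames
#' @importFrom utils head
NULL

SEXES <- c("female", "male")
QUINTILES <- paste0("Q", 1:5)
OPEN_AGE <- 85L # single-year ages run 0..84 plus the open 85+ group

#' Derive a reproducible child seed from a master seed and a stream label
#'
#' Each stochastic generator in the package draws from its own stream, derived
#' deterministically from the master seed and a fixed label. Adding a new
#' generator (a new label) therefore never perturbs the output of existing
#' ones.
#'
#' @param seed master integer seed.
#' @param label character stream label, e.g. `"episodes"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- 5381
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((h * 31 + abs(seed)) %% 2147483647)
}

# Evaluate expr under a local RNG stream; the caller's RNG state is restored.
with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, label))
  expr
}

config_error <- function(msg) abort(msg, class = "ineqcost_config_error")
validation_error <- function(msg) abort(msg, class = "ineqcost_validation_error")
lookup_error <- function(msg) abort(msg, class = "ineqcost_lookup_error")
shape_error <- function(msg) abort(msg, class = "ineqcost_shape_error")

#' Convert pence to pounds
#'
#' Costs are carried as integer pence through aggregation so that totals are
#' exact; conversion to pounds happens only at reporting time.
#'
#' @param pence numeric vector of pence.
#' @return numeric vector of pounds.
#' @export
pence_to_pounds <- function(pence) pence / 100
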