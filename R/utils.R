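#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad rnorm runif rlnorm cor p.adjust ks.test
#'   wilcox.test prop.test binom.test predict quantile setNames
#' @importFrom utils read.csv write.csv head packageVersion
NULL

# -- condition helpers ---------------------------------------------------

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("smv_validation_error", "smv_error")))
}

stop_blinding <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("smv_blinding_error", "smv_error")))
}

# -- seed substreams -----------------------------------------------------

#' Derive a reproducible sub-seed from a global seed and a stage name
#'
#' A single run seed fans out into independent per-stage seeds so that
#' individual pipeline stages (simulation, quality scoring, selection,
#' training) can be re-run in isolation and still reproduce exactly.
#'
#' @param seed integer global seed.
#' @param stream character stage label, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "simulate")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer(((abs(seed) %% 1e6) * 1048573 + h) %% 2147483647)
}

# Round half away from zero (presentation rounding for percentages; base
# round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# log2 CV -> additive standard deviation on the log2 scale, assuming
# log-normal multiplicative noise.
cv_to_log2_sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)
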