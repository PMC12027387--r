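# Internal helpers shared across modules.

# Derive a sub-seed for an independent RNG stream from the master seed.
# Keeps results < 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + stream * 2654435) %% 2147483562 + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# log2-scale noise sd implied by a coefficient of variation on the raw scale
# (small-cv approximation sd(ln I) ~ cv).
cv_to_sd_log2 <- function(cv) cv / log(2)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

is_proportion <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# Pearson r between two planted-effect vectors generated with a target
# correlation: draw z2 conditionally on z1.
rbinorm <- function(n, mean1, mean2, sd1, sd2, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  cbind(mean1 + sd1 * z1, mean2 + sd2 * z2)
}
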