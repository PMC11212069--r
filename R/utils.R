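`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Each (trait, stratum) pair in the simulator draws from its own stream keyed
#' by name, so adding a trait to a configuration does not perturb the draws of
#' the others. The hash is a plain polynomial rolling hash modulo a prime;
#' the result always fits in a 32-bit integer.
#'
#' @param seed master integer seed.
#' @param key character scalar naming the stream.
#' @return an integer usable with [set.seed()].
#' @keywords internal
sub_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000000007
  as.integer((abs(seed) * 7919 + h) %% 2147483647L)
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("`%s` must be a single finite number", name))
}
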