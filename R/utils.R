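#' @keywords internal
"_PACKAGE"

# Classed error helpers so callers can distinguish bad input from bugs.
tf_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "thermofoot_error")))
}

stop_invalid <- function(msg) tf_stop(msg, "tf_invalid_input")
stop_schema  <- function(msg) tf_stop(msg, "tf_schema_error")
stop_config  <- function(msg) tf_stop(msg, "tf_config_error")
stop_degenerate <- function(msg) tf_stop(msg, "tf_degenerate_input")

assert_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}

#' Convert temperatures between Celsius and Kelvin
#'
#' All user-facing interfaces (configs, tables, CLI) use degrees Celsius;
#' the model works in Kelvin internally.
#'
#' @param temp_C,temp_K numeric vector of temperatures.
#' @return numeric vector of converted temperatures.
#' @examples
#' celsius_to_kelvin(29)   # 302.15
#' kelvin_to_celsius(302.15)
#' @export
celsius_to_kelvin <- function(temp_C) temp_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_K) temp_K - 273.15

# Evaluate `expr` with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
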