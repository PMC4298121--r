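# internal validation / RNG helpers

stop_vascmr <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "vascmr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

config_error <- function(field, msg) {
  stop_vascmr(sprintf("configuration error in field `%s`: %s", field, msg),
              "vascmr_config_error", field = field)
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error(field, "must be a single finite number")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    config_error(field, sprintf("must be in %s%g, %g]",
                                if (strict_lower) "(" else "[", lower, upper))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards. seed = NULL consumes the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed) || abs(seed) >= 2^31)
    config_error("seed", "must be a single integer below 2^31 in magnitude")
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
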