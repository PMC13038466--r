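# Internal helpers: error conditions, argument checks, RNG hygiene.

stop_param <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("dnsnmr_param_error", "dnsnmr_error", "error")))
}

stop_runtime <- function(msg, class = "dnsnmr_error") {
  stop(errorCondition(msg, class = c(class, "dnsnmr_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("`%s` must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower))
    stop_param(sprintf("`%s` must be %s %g (got %g)", name,
                       if (strict_lower) ">" else ">=", lower, x))
  if (x > upper || (strict_upper && x >= upper))
    stop_param(sprintf("`%s` must be %s %g (got %g)", name,
                       if (strict_upper) "<" else "<=", upper, x))
  x
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (abs(x - round(x)) > 1e-8)
    stop_param(sprintf("`%s` must be an integer (got %g)", name, x))
  as.integer(round(x))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream (the acquisition seed contract: identical inputs, identical
# bits, no side effects on the session RNG).
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

fmt_num <- function(x, digits = 6) format(signif(x, digits), trim = TRUE)
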