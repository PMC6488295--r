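`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so library functions never clobber user seeds.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialize RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# round to nearest `digits`-decimal value, ties away from zero (the 0.01
# degree unit grid must not depend on banker's rounding)
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_clamp <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "clampadapt_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open = TRUE, class = "parameter_domain_error") {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    bound <- if (open) sprintf("(%g, %g)", lower, upper)
             else sprintf("[%g, %g]", lower, upper)
    stop_clamp(sprintf("'%s' must be a finite number in %s", name, bound),
               class)
  }
  invisible(x)
}

check_columns <- function(df, cols, where = "trial table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_clamp(sprintf("%s is missing required column(s): %s", where,
                       paste(missing, collapse = ", ")),
               "missing_column_error")
  }
  invisible(df)
}
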