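#' Run code with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the previous RNG state so
#' library code never perturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Display rounding for per-slice means: 0.5 always rounds up (base `round`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_oildrops <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "oildrops_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
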