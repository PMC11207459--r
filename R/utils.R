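#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulators do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Normalised root-mean-square error
#'
#' RMSE between `x` and the reference `ref`, normalised by the RMS of the
#' reference.
#'
#' @param x estimate (numeric array).
#' @param ref reference of the same shape.
#' @return scalar NRMSE.
#' @export
nrmse <- function(x, ref) {
  stopifnot(length(x) == length(ref))
  sqrt(mean((as.numeric(x) - as.numeric(ref))^2)) /
    sqrt(mean(as.numeric(ref)^2))
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical or 0/1 arrays of identical shape.
#' @return 2|A∩B| / (|A|+|B|); defined as 1 when both masks are empty.
#' @export
dice_coef <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

## linear interpolation with constant extrapolation at the ends
interp_curve <- function(t, v, t_out) {
  approx(t, v, xout = t_out, rule = 2)$y
}

stop_config <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_config(sprintf("`%s` must be positive and finite", name))
  invisible(x)
}
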