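# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar <- function(x, name, positive = FALSE,
                               nonnegative = FALSE, integer = FALSE,
                               allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L &&
    (is.finite(x) || (allow_inf && is.infinite(x) && x > 0))
  if (!ok)
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonnegative && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

check_probability <- function(x, name) {
  stop_if_not_scalar(x, name)
  if (x < 0 || x > 1)
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' Derive a reproducible per-trajectory RNG seed
#'
#' Trajectory streams are a deterministic function of the global seed and
#' the trajectory index, so ensembles are reproducible regardless of the
#' order in which trajectories are simulated.
#'
#' @param seed global integer seed.
#' @param index trajectory index (1-based).
#' @return an integer seed below 2^31.
#' @export
trajectory_seed <- function(seed, index) {
  stop_if_not_scalar(seed, "seed", integer = TRUE)
  stop_if_not_scalar(index, "index", integer = TRUE)
  # splitmix-style integer hash kept within R's 32-bit integer range
  h <- (as.double(seed) * 2654435761 + as.double(index) * 40503 + 12345) %%
    2147483629
  as.integer(h) + 1L
}

# inverse error function via the normal quantile
erfinv <- function(u) qnorm((1 + u) / 2) / sqrt(2)
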