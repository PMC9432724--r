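# Four-state kinetic model of mRNA localization.
#
# States: an mRNA is binding-competent ("sticky", S) or not (U), and near
# the mitochondrial surface (N) or far from it (F).  Competence switches
# on at rate k_S and off at rate k_U; spatial transport moves the mRNA
# into the proximal region at rate k_R and out at rate k_L.  Competent
# proximal mRNA are bound, so there is no direct S_N -> S_F transition:
# a bound mRNA can only leave the surface after losing competence.

#' Rate constants of the four-state localization model
#'
#' @param k_S rate of gaining binding competence (1/s).
#' @param k_U rate of losing binding competence (1/s).
#' @param k_R rate of reaching the mitochondria-proximal region (1/s).
#' @param k_L rate of leaving the proximal region (1/s).
#' @return an object of class `four_state_rates` with read-only
#'   equilibrium fractions `f_s = k_S/(k_S + k_U)` (competent fraction)
#'   and `f_d = k_R/(k_R + k_L)` (proximal volume fraction).
#' @examples
#' r <- four_state_rates(1, 1, 1, 1)
#' r$f_s
#' @export
four_state_rates <- function(k_S, k_U, k_R, k_L) {
  for (nm in c("k_S", "k_U", "k_R", "k_L"))
    stop_if_not_scalar(get(nm), nm, nonnegative = TRUE)
  if (k_S + k_U <= 0)
    stop("at least one of k_S, k_U must be > 0", call. = FALSE)
  if (k_R + k_L <= 0)
    stop("at least one of k_R, k_L must be > 0", call. = FALSE)
  structure(
    list(k_S = k_S, k_U = k_U, k_R = k_R, k_L = k_L,
         f_s = k_S / (k_S + k_U), f_d = k_R / (k_R + k_L)),
    class = "four_state_rates")
}

#' @export
print.four_state_rates <- function(x, ...) {
  cat("Four-state localization rates (1/s):\n")
  cat(sprintf("  k_S = %g  k_U = %g  k_R = %g  k_L = %g\n",
              x$k_S, x$k_U, x$k_R, x$k_L))
  cat(sprintf("  f_s = %.6g  f_d = %.6g\n", x$f_s, x$f_d))
  invisible(x)
}

#' Stationary distribution of the four-state model
#'
#' Returns the unique steady state of the kinetic scheme in which bound
#' (competent, proximal) mRNA cannot move away without first losing
#' competence.  The closed-form solution divides by `k_U` and `k_L`;
#' the absorbing limits `k_U = 0` (permanently sticky) or `k_L = 0`
#' (proximal region absorbing) are rejected.
#'
#' @param rates a [four_state_rates()] object.
#' @return an object of class `four_state_distribution`: a list with the
#'   four state probabilities `p_SN`, `p_SF`, `p_UN`, `p_UF` (sticky/not
#'   x near/far) and the normalizer `Z`.
#' @examples
#' steady_state(four_state_rates(1, 1, 1, 1))  # (0.4, 0.1, 0.3, 0.2)
#' @export
steady_state <- function(rates) {
  stopifnot(inherits(rates, "four_state_rates"))
  kS <- rates$k_S; kU <- rates$k_U; kR <- rates$k_R; kL <- rates$k_L
  if (kU <= 0)
    stop("degenerate chain: k_U = 0 makes the bound state absorbing; ",
         "use limit_rapid_transport()/limit_slow_transport() for limits",
         call. = FALSE)
  if (kL <= 0)
    stop("degenerate chain: k_L = 0 makes the proximal region absorbing",
         call. = FALSE)
  # unnormalized weights, U_F == 1
  w_SN <- kR * kS * (kL + kR + kS + kU) / (kL * kU * (kR + kU))
  w_SF <- kS / (kR + kU)
  w_UN <- kR * (kR + kS + kU) / (kL * (kR + kU))
  w_UF <- 1
  Z <- w_SN + w_SF + w_UN + w_UF
  structure(
    list(p_SN = w_SN / Z, p_SF = w_SF / Z,
         p_UN = w_UN / Z, p_UF = w_UF / Z, Z = Z),
    class = "four_state_distribution")
}

#' @export
print.four_state_distribution <- function(x, ...) {
  cat("Four-state steady state:\n")
  cat(sprintf("  p_SN = %.6f  p_SF = %.6f\n", x$p_SN, x$p_SF))
  cat(sprintf("  p_UN = %.6f  p_UF = %.6f\n", x$p_UN, x$p_UF))
  cat(sprintf("  localized (near) fraction = %.6f\n", x$p_SN + x$p_UN))
  invisible(x)
}

#' Steady-state localized (proximal) fraction
#'
#' The probability that an mRNA is in the mitochondria-proximal region,
#' `p_SN + p_UN`, at the stationary distribution.
#'
#' @inheritParams steady_state
#' @return a probability.
#' @export
localized_fraction <- function(rates) {
  ss <- steady_state(rates)
  ss$p_SN + ss$p_UN
}

#' Localized fraction in the rapid-transport limit
#'
#' When spatial transport is much faster than competence switching
#' (`k_R, k_L >> k_S, k_U`) the localized fraction reduces to
#' `f_s + (1 - f_s) * f_d`: competent mRNA always find the surface, and
#' incompetent mRNA equilibrate over the accessible volume.
#'
#' @param f_s equilibrium competent fraction, in \[0, 1\].
#' @param f_d proximal fraction of the accessible volume, in \[0, 1\].
#' @return a probability.
#' @export
limit_rapid_transport <- function(f_s, f_d) {
  check_probability(f_s, "f_s")
  check_probability(f_d, "f_d")
  f_s + (1 - f_s) * f_d
}

#' Localized fraction in the slow-transport limit
#'
#' When competence switching is much faster than transport
#' (`k_S, k_U >> k_R, k_L`) the localized fraction is
#' `1 / (1 + (1 - f_s) * (1 - f_d) / f_d)`.  As `f_d -> 0` localization
#' vanishes (returned as 0 when `f_d = 0` and `f_s < 1`), unlike the
#' rapid-transport limit -- the kinetic signature of this regime.
#'
#' @inheritParams limit_rapid_transport
#' @return a probability.
#' @export
limit_slow_transport <- function(f_s, f_d) {
  check_probability(f_s, "f_s")
  check_probability(f_d, "f_d")
  if (f_d == 0) return(if (f_s == 1) 1 else 0)
  1 / (1 + (1 - f_s) * (1 - f_d) / f_d)
}

#' Simulate the four-state chain (validation oracle)
#'
#' Continuous-time Markov chain simulation of the four-state scheme,
#' started from the far, non-competent state (as for an mRNA freshly
#' exported from the nucleus).  Used to cross-validate [steady_state()];
#' occupancy fractions converge to the stationary distribution.
#'
#' @inheritParams steady_state
#' @param duration total simulated time (s).
#' @param seed integer RNG seed.
#' @param n_batches number of batches for the batch-means standard error.
#' @return a list with `occupancy` (named fractions of time in SN, SF,
#'   UN, UF), `se` (batch-means standard errors) and `n_transitions`.
#' @export
simulate_ctmc <- function(rates, duration, seed, n_batches = 20L) {
  stopifnot(inherits(rates, "four_state_rates"))
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  set.seed(seed)
  kS <- rates$k_S; kU <- rates$k_U; kR <- rates$k_R; kL <- rates$k_L
  # per-state exit rates and destinations (1 = SN, 2 = SF, 3 = UN, 4 = UF)
  dest <- list(`1` = c(3L),     `2` = c(4L, 1L),
               `3` = c(1L, 4L), `4` = c(2L, 3L))
  rate <- list(`1` = c(kU),     `2` = c(kU, kR),
               `3` = c(kS, kL), `4` = c(kS, kR))
  state <- 4L
  t_now <- 0
  batch_len <- duration / n_batches
  occ <- matrix(0, nrow = n_batches, ncol = 4L)
  batch <- 1L
  n_trans <- 0L
  while (t_now < duration) {
    rs <- rate[[state]]
    tot <- sum(rs)
    dt <- if (tot > 0) rexp(1L, tot) else duration - t_now
    t_end <- min(t_now + dt, duration)
    # spread the sojourn over the batches it covers
    while (t_now < t_end) {
      b_end <- min(batch * batch_len, t_end)
      occ[batch, state] <- occ[batch, state] + (b_end - t_now)
      t_now <- b_end
      if (t_now >= batch * batch_len && batch < n_batches)
        batch <- batch + 1L
    }
    if (t_now < duration && tot > 0) {
      state <- dest[[state]][sample.int(length(rs), 1L, prob = rs)]
      n_trans <- n_trans + 1L
    }
  }
  frac <- occ / batch_len
  occupancy <- colMeans(frac)
  se <- apply(frac, 2L, sd) / sqrt(n_batches)
  names(occupancy) <- names(se) <- c("SN", "SF", "UN", "UF")
  list(occupancy = occupancy, se = se, n_transitions = n_trans)
}
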