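# Closed-form predictors for MTS counts, exposure times and diffusive
# search times.  All expressions neglect ribosome steric exclusion and
# are exact in the low-occupancy regime (rho_ribo << 1/footprint).

#' Mean number of translated MTSs per mRNA
#'
#' The steady-state expected number of nascent peptides carrying a fully
#' translated MTS on one mRNA, `beta = k_init * (L - l_MTS) / k_elong`:
#' the ribosome flux `k_init` times the time each ribosome spends beyond
#' codon `l_MTS`.  Returns 0 when `L <= l_MTS` (the MTS is never
#' completed).
#'
#' @param gene a [gene_kinetics()] object.
#' @return expected count (dimensionless).
#' @examples
#' beta(gene_kinetics(0.3253, 14.5086, 393))  # ~6.57
#' @export
beta <- function(gene) {
  stopifnot(inherits(gene, "gene_kinetics"))
  gene$k_init * max(gene$L - gene$l_MTS, 0) / gene$k_elong
}

#' Mean number of mature, binding-competent MTSs per mRNA
#'
#' With a Poisson maturation step at rate `k_MTS` after MTS translation,
#' the steady-state expected number of mature MTSs is
#' \deqn{\beta_{mature} = \frac{k_{init}}{k_{elong}}\left\{L - l_{MTS} -
#'   \frac{k_{elong}}{k_{MTS}}\left[1 - e^{-(k_{MTS}/k_{elong})(L - l_{MTS})}
#'   \right]\right\}.}
#' Recovers [beta()] as `k_MTS -> Inf` and is monotonically increasing in
#' `k_MTS`.
#'
#' @inheritParams beta
#' @param k_MTS maturation rate (1/s), `> 0` (may be `Inf`).
#' @return expected count (dimensionless).
#' @examples
#' g <- gene_kinetics(0.1259, 7.7468, 483, name = "constitutive-median")
#' beta_mature(g, 1 / 45)  # ~2.45
#' @export
beta_mature <- function(gene, k_MTS) {
  stopifnot(inherits(gene, "gene_kinetics"))
  stop_if_not_scalar(k_MTS, "k_MTS", positive = TRUE, allow_inf = TRUE)
  d <- max(gene$L - gene$l_MTS, 0)
  if (d == 0) return(0)
  if (!is.finite(k_MTS)) return(beta(gene))
  x <- (k_MTS / gene$k_elong) * d
  (gene$k_init / gene$k_elong) *
    (d - (gene$k_elong / k_MTS) * (1 - exp(-x)))
}

#' Mean maturation wait conditioned on maturing before termination
#'
#' For an MTS that matures before its ribosome terminates (a window of
#' length `t_max` after MTS translation), the mean wait from translation
#' to maturity is
#' `(1/k_MTS) * [1 - e^{-k t_max}(k t_max + 1)] / (1 - e^{-k t_max})`.
#' Tends to `t_max/2` as `k_MTS -> 0` (maturation instant conditionally
#' uniform) and to `1/k_MTS` as `k_MTS -> Inf`.
#'
#' @param k_MTS maturation rate (1/s).
#' @param t_max time from MTS completion to ribosome termination (s).
#' @return time (s).
#' @export
mean_wait_time <- function(k_MTS, t_max) {
  stop_if_not_scalar(k_MTS, "k_MTS", positive = TRUE, allow_inf = TRUE)
  stop_if_not_scalar(t_max, "t_max", positive = TRUE)
  if (!is.finite(k_MTS)) return(0)
  x <- k_MTS * t_max
  # small-x expansion avoids catastrophic cancellation:
  # E[t | t < t_max] = t_max (1/2 - x/12 + O(x^3))
  if (x < 1e-4) return(t_max * (0.5 - x / 12))
  (1 / k_MTS) * (1 - exp(-x) * (x + 1)) / (1 - exp(-x))
}

#' Mean exposure time of a mature MTS
#'
#' The mean time that a mature MTS is exposed on the mRNA before its
#' ribosome terminates:
#' `(1/k_MTS) * [1 - e^{-k t_max}(k t_max + 1)]`, with
#' `t_max = (L - l_MTS)/k_elong`.  This is the conditional wait of
#' [mean_wait_time()] multiplied by the probability `1 - e^{-k t_max}`
#' that maturation beats termination; note its `k_MTS -> Inf` limit is 0
#' under this bookkeeping (see [mature_exposure_time_alt()] for the
#' per-translated-MTS average, which recovers `t_max` in that limit).
#'
#' @inheritParams beta_mature
#' @return time (s).
#' @examples
#' mature_exposure_time(gene_kinetics(0.3253, 14.5086, 393), 1 / 40)  # ~3.67 s
#' @export
mature_exposure_time <- function(gene, k_MTS) {
  stopifnot(inherits(gene, "gene_kinetics"))
  stop_if_not_scalar(k_MTS, "k_MTS", positive = TRUE, allow_inf = TRUE)
  t_max <- gene$t_max
  if (t_max == 0) return(0)
  if (!is.finite(k_MTS)) return(0)
  x <- k_MTS * t_max
  (1 / k_MTS) * (1 - exp(-x) * (x + 1))
}

#' Mean competent-exposure time averaged over all translated MTSs
#'
#' Alternative bookkeeping of the mature exposure time: the expected
#' competent time contributed by an arbitrary translated MTS (counting
#' MTSs that never mature as 0), `t_max - (1/k)(1 - e^{-k t_max})`.
#' This form recovers the instantaneous exposure time `t_max` as
#' `k_MTS -> Inf` and satisfies
#' `beta_mature = beta * alt / t_max` exactly.
#'
#' @inheritParams mature_exposure_time
#' @return time (s).
#' @export
mature_exposure_time_alt <- function(gene, k_MTS) {
  stopifnot(inherits(gene, "gene_kinetics"))
  stop_if_not_scalar(k_MTS, "k_MTS", positive = TRUE, allow_inf = TRUE)
  t_max <- gene$t_max
  if (t_max == 0) return(0)
  if (!is.finite(k_MTS)) return(t_max)
  x <- k_MTS * t_max
  t_max - (1 / k_MTS) * (1 - exp(-x))
}

#' Mean diffusive search time to an inner cylinder
#'
#' Mean first-passage time for a particle with diffusivity `D`, starting
#' uniformly over the cross-sectional area between radii `r1` and `r2`,
#' to reach an absorbing inner cylinder of radius `r1` while confined by
#' a reflecting outer cylinder of radius `r2`:
#' \deqn{t_{search} = \frac{1}{2D}\left[\frac{r_2^4}{r_2^2 - r_1^2}
#'   \ln\frac{r_2}{r_1} - \frac{3 r_2^2 - r_1^2}{4}\right].}
#'
#' @param r1 inner (absorbing) radius, um.
#' @param r2 outer (reflecting) radius, um; `r2 > r1`.
#' @param D diffusivity, um^2/s.
#' @return time (s).
#' @examples
#' mean_search_time(0.375, 1.56525, 0.1)  # ~9.56 s at 4% MVF
#' @export
mean_search_time <- function(r1, r2, D) {
  stop_if_not_scalar(r1, "r1", positive = TRUE)
  stop_if_not_scalar(r2, "r2", positive = TRUE)
  stop_if_not_scalar(D, "D", positive = TRUE)
  if (r1 >= r2) stop("`r1` must be smaller than `r2`", call. = FALSE)
  (1 / (2 * D)) *
    (r2^4 / (r2^2 - r1^2) * log(r2 / r1) - (3 * r2^2 - r1^2) / 4)
}
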