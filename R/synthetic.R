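# Synthetic gene cohorts.
#
# The measurement data behind the conditional / constitutive gene groups
# are summarised by their group-median kinetics; this generator draws
# log-normal cohorts around those medians and inverts the
# rate-estimation relations to produce the (P, occ) measurement columns,
# so that the full estimation pipeline can be exercised end to end on
# data with known ground truth.

#' Specification of a synthetic two-group cohort
#'
#' Defaults centre each group on the published group-median kinetics:
#' conditional genes `L = 393 aa`, `k_init = 0.3253 1/s`,
#' `k_elong = 14.5086 aa/s` (shorter, faster-elongating) and
#' constitutive genes `L = 483 aa`, `k_init = 0.1259 1/s`,
#' `k_elong = 7.7468 aa/s` (longer, slower-elongating).  Spreads are
#' log-scale standard deviations (default 0.4 for all three parameters;
#' the sources report medians only, so the spread is a fixture choice).
#'
#' @param n_conditional,n_constitutive group sizes.
#' @param conditional,constitutive named lists with elements `L`,
#'   `k_init`, `k_elong` (group medians).
#' @param sdlog log-scale standard deviation, recycled to the three
#'   parameters `(L, k_init, k_elong)`.
#' @param seed integer seed.
#' @return an object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_conditional = 52L, n_constitutive = 70L,
                                  conditional = list(L = 393,
                                                     k_init = 0.3253,
                                                     k_elong = 14.5086),
                                  constitutive = list(L = 483,
                                                      k_init = 0.1259,
                                                      k_elong = 7.7468),
                                  sdlog = 0.4, seed = 1L) {
  stop_if_not_scalar(n_conditional, "n_conditional", positive = TRUE,
                     integer = TRUE)
  stop_if_not_scalar(n_constitutive, "n_constitutive", positive = TRUE,
                     integer = TRUE)
  sdlog <- rep_len(sdlog, 3L)
  for (grp in list(conditional, constitutive))
    stopifnot(all(c("L", "k_init", "k_elong") %in% names(grp)),
              all(unlist(grp) > 0))
  structure(
    list(n_conditional = as.integer(n_conditional),
         n_constitutive = as.integer(n_constitutive),
         conditional = conditional, constitutive = constitutive,
         sdlog = sdlog, seed = as.integer(seed)),
    class = "synthetic_cohort_spec")
}

#' Generate a synthetic measurement cohort
#'
#' Draws per-gene kinetics log-normally around the group medians (the
#' log-normal median equals the scale parameter, so sample medians track
#' the specified medians), rounds `L` to whole codons with a floor of
#' `l_MTS + 10`, and inverts the calibration relations into `(P, occ)`
#' measurement columns: `P = k_init * T_div / alpha` and
#' `occ = occ_ref * (k_init/k_init_ref) * (k_elong_ref/k_elong)`.  The
#' true kinetics are attached as attribute `"truth"` so estimation
#' round-trips can be verified.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param cal a [calibrate()] object with `occ_ref` set (default: the
#'   TIM50 calibration with `occ_ref = 1`).
#' @param l_MTS MTS-completing codon (default 100).
#' @return a data.frame with columns `name`, `group`, `P`, `occ`, `L`.
#' @export
generate_synthetic_cohort <- function(spec, cal = default_calibration(),
                                      l_MTS = 100L) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"),
            inherits(cal, "rate_calibration"))
  if (is.na(cal$occ_ref))
    stop("calibration must have `occ_ref` set to invert occupancies",
         call. = FALSE)
  set.seed(spec$seed)
  draw_group <- function(n, med, label) {
    L <- pmax(round(rlnorm(n, log(med$L), spec$sdlog[1])), l_MTS + 10L)
    k_init <- rlnorm(n, log(med$k_init), spec$sdlog[2])
    k_elong <- rlnorm(n, log(med$k_elong), spec$sdlog[3])
    data.frame(name = sprintf("%s_%03d", label, seq_len(n)),
               group = label, k_init = k_init, k_elong = k_elong,
               L = as.integer(L), stringsAsFactors = FALSE)
  }
  truth <- rbind(draw_group(spec$n_conditional, spec$conditional,
                            "conditional"),
                 draw_group(spec$n_constitutive, spec$constitutive,
                            "constitutive"))
  out <- data.frame(
    name = truth$name, group = truth$group,
    P = truth$k_init * cal$T_div / cal$alpha,
    occ = cal$occ_ref * (truth$k_init / cal$k_init_ref) *
      (cal$k_elong_ref / truth$k_elong),
    L = truth$L, stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}

#' Default TIM50 rate calibration
#'
#' The reference-gene calibration: 4095 proteins over 6 mRNA with a
#' 90-minute division time gives `k_init_ref = 0.1264 1/s`; with
#' `P_ref = 15.12`, `alpha = 45.14`; `k_elong_ref = 4 aa/s`.  The
#' reference occupancy is fixed at 1 (occupancies are relative, so the
#' unit is arbitrary).
#'
#' @return a `rate_calibration`.
#' @export
default_calibration <- function() {
  calibrate(4095, 6, 15.12, 5400, k_elong_ref = 4, occ_ref = 1,
            ref_name = "TIM50")
}
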