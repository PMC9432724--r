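# Gene-specific translation-rate estimation.
#
# Initiation rates follow from protein-per-mRNA measurements: at steady
# state protein production k_init * N_mRNA balances effective protein
# decay, which in growing yeast is dominated by dilution at cell
# division (effective protein lifetime = division time, 90 min).
# Elongation rates follow from ribosome occupancy, which is proportional
# to ribosome density N_ribo/L = k_init/k_elong.  Both are calibrated on
# the reference gene TIM50 (absolute protein and mRNA counts available,
# k_elong = 4 aa/s).

#' Calibrate rate estimation on a reference gene
#'
#' Computes the reference initiation rate
#' `k_init_ref = (N_prot/N_mRNA)/T_div` and the proportionality constant
#' `alpha = k_init_ref * T_div / P_ref` that converts relative
#' protein-per-mRNA measurements to initiation rates.
#'
#' @param N_prot proteins per cell of the reference gene.
#' @param N_mRNA mRNA copies per cell of the reference gene.
#' @param P_ref relative protein-per-mRNA measurement of the reference
#'   gene (arbitrary units).
#' @param T_div effective protein lifetime = division time (s, default
#'   5400 = 90 min).
#' @param k_elong_ref reference elongation rate (aa/s, default 4, the
#'   TIM50 value).
#' @param occ_ref reference ribosome occupancy (arbitrary units); may be
#'   left `NA` and resolved from the input table by
#'   [build_gene_table()].
#' @param ref_name name of the reference gene (default `"TIM50"`).
#' @return an object of class `rate_calibration`.
#' @examples
#' cal <- calibrate(4095, 6, 15.12, 5400)
#' signif(cal$k_init_ref, 4)  # 0.1264
#' signif(cal$alpha, 4)       # 45.14
#' @export
calibrate <- function(N_prot, N_mRNA, P_ref, T_div = 5400,
                      k_elong_ref = 4, occ_ref = NA_real_,
                      ref_name = "TIM50") {
  stop_if_not_scalar(N_prot, "N_prot", positive = TRUE)
  stop_if_not_scalar(N_mRNA, "N_mRNA", positive = TRUE)
  stop_if_not_scalar(P_ref, "P_ref", positive = TRUE)
  stop_if_not_scalar(T_div, "T_div", positive = TRUE)
  stop_if_not_scalar(k_elong_ref, "k_elong_ref", positive = TRUE)
  k_init_ref <- (N_prot / N_mRNA) / T_div
  structure(
    list(k_init_ref = k_init_ref,
         alpha = k_init_ref * T_div / P_ref,
         T_div = T_div, P_ref = P_ref, k_elong_ref = k_elong_ref,
         occ_ref = occ_ref, ref_name = ref_name),
    class = "rate_calibration")
}

#' @export
print.rate_calibration <- function(x, ...) {
  cat(sprintf("Rate calibration on %s: k_init_ref = %.4g 1/s, alpha = %.4g,\n",
              x$ref_name, x$k_init_ref, x$alpha))
  cat(sprintf("  T_div = %g s, k_elong_ref = %g aa/s, occ_ref = %s\n",
              x$T_div, x$k_elong_ref,
              if (is.na(x$occ_ref)) "(from table)" else format(x$occ_ref)))
  invisible(x)
}

#' Estimate an initiation rate from protein per mRNA
#'
#' `k_init = alpha * P / T_div`.
#'
#' @param P relative protein-per-mRNA measurement (> 0).
#' @param cal a [calibrate()] object.
#' @return rate (1/s).
#' @export
estimate_kinit <- function(P, cal) {
  stopifnot(inherits(cal, "rate_calibration"))
  if (any(!is.finite(P)) || any(P <= 0))
    stop("`P` must be positive", call. = FALSE)
  cal$alpha * P / cal$T_div
}

#' Estimate an elongation rate from ribosome occupancy
#'
#' Occupancy is proportional to ribosome density `k_init/k_elong`, so
#' only ratios to the reference gene matter:
#' `k_elong = k_elong_ref * (k_init/k_init_ref) * (occ_ref/occ)`.
#'
#' @param k_init estimated initiation rate (1/s).
#' @param occ relative ribosome occupancy (> 0).
#' @param cal a [calibrate()] object with `occ_ref` resolved.
#' @return rate (codons/s).
#' @export
estimate_kelong <- function(k_init, occ, cal) {
  stopifnot(inherits(cal, "rate_calibration"))
  if (any(!is.finite(occ)) || any(occ <= 0))
    stop("`occ` must be positive", call. = FALSE)
  if (any(!is.finite(k_init)) || any(k_init <= 0))
    stop("`k_init` must be positive", call. = FALSE)
  if (is.na(cal$occ_ref))
    stop("calibration has no `occ_ref`; supply it or use build_gene_table()",
         call. = FALSE)
  cal$k_elong_ref * (k_init / cal$k_init_ref) * (cal$occ_ref / occ)
}

#' Build a per-gene kinetics table from measurements
#'
#' Converts a measurement table (columns `name`, `group`, `P`, `occ`,
#' `L`) into per-gene translation kinetics, appending the derived
#' predictors `beta`, `beta_mature` (at `tau_MTS`), `t_expo` and
#' `t_expo_mature`.  If the calibration's `occ_ref` is `NA`, it is taken
#' from the table row whose `name` equals the calibration's reference
#' gene.  Invalid rows (non-positive `P`, `occ` or `L`) are dropped with
#' a warning naming them.
#'
#' @param measurements data.frame with columns `name`, `group`, `P`,
#'   `occ`, `L`.
#' @param cal a [calibrate()] object.
#' @param tau_MTS maturation time used for the derived columns (s,
#'   default 40).
#' @param l_MTS MTS-completing codon (default 100).
#' @return a data.frame with columns `name`, `group`, `L`, `k_init`,
#'   `k_elong`, `beta`, `beta_mature`, `t_expo`, `t_expo_mature`.
#' @export
build_gene_table <- function(measurements, cal, tau_MTS = 40, l_MTS = 100L) {
  stopifnot(inherits(cal, "rate_calibration"))
  need <- c("name", "group", "P", "occ", "L")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(measurements) == 0L) {
    warning("empty measurement table")
    return(data.frame(name = character(0), group = character(0),
                      L = integer(0), k_init = numeric(0),
                      k_elong = numeric(0), beta = numeric(0),
                      beta_mature = numeric(0), t_expo = numeric(0),
                      t_expo_mature = numeric(0)))
  }
  if (is.na(cal$occ_ref)) {
    ref <- measurements$name == cal$ref_name
    if (!any(ref))
      stop(sprintf("reference gene '%s' not in table and occ_ref not set",
                   cal$ref_name), call. = FALSE)
    cal$occ_ref <- measurements$occ[which(ref)[1L]]
  }
  ok <- is.finite(measurements$P) & measurements$P > 0 &
    is.finite(measurements$occ) & measurements$occ > 0 &
    is.finite(measurements$L) & measurements$L >= 1
  if (any(!ok))
    warning("dropping invalid rows: ",
            paste(measurements$name[!ok], collapse = ", "))
  mm <- measurements[ok, , drop = FALSE]
  k_init <- estimate_kinit(mm$P, cal)
  k_elong <- estimate_kelong(k_init, mm$occ, cal)
  k_MTS <- 1 / tau_MTS
  rows <- lapply(seq_len(nrow(mm)), function(i) {
    g <- gene_kinetics(k_init[i], k_elong[i], round(mm$L[i]), l_MTS,
                       mm$name[i])
    data.frame(name = g$name, group = mm$group[i], L = g$L,
               k_init = g$k_init, k_elong = g$k_elong,
               beta = beta(g), beta_mature = beta_mature(g, k_MTS),
               t_expo = g$t_expo,
               t_expo_mature = mature_exposure_time(g, k_MTS),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write the tab-separated gene tables
#'
#' Measurement tables have header columns `name`, `group`, `P`, `occ`,
#' `L`; kinetics tables the columns produced by [build_gene_table()].
#'
#' @param file path to a tab-separated table with one header line.
#' @return a data.frame.
#' @export
read_gene_table <- function(file) {
  read.delim(file, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_gene_table
#' @param x a data.frame.
#' @export
write_gene_table <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
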