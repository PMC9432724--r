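# Per-gene translation kinetics and the MTS competence model.

#' Per-gene translation kinetics
#'
#' Bundles the translation parameters of one gene: initiation rate,
#' elongation rate and transcript length, together with the codon index
#' at which the mitochondrial targeting sequence (MTS) is fully
#' translated and clear of the ribosome exit tunnel (default 100 codons:
#' an MTS of up to ~70 aa plus ~30 aa of exit tunnel).
#'
#' Derived quantities exposed as list elements:
#' `rho_ribo = k_init/k_elong` (mean ribosomes per codon, neglecting
#' exclusion), `t_max = (L - l_MTS)/k_elong` (time from MTS completion to
#' termination), `T_total = L/k_elong`, and the instantaneous-model MTS
#' exposure time `t_expo = t_max`.
#'
#' @param k_init translation initiation rate (1/s).
#' @param k_elong elongation rate (codons/s).
#' @param L transcript length (codons).
#' @param l_MTS codon index completing the MTS (default 100).  `L < l_MTS`
#'   is allowed: such a gene never becomes binding-competent.
#' @param name optional gene identifier.
#' @return an object of class `gene_kinetics`.
#' @examples
#' gene_kinetics(0.3253, 14.5086, 393, name = "conditional-median")
#' @export
gene_kinetics <- function(k_init, k_elong, L, l_MTS = 100L, name = "gene") {
  stop_if_not_scalar(k_init, "k_init", positive = TRUE)
  stop_if_not_scalar(k_elong, "k_elong", positive = TRUE)
  stop_if_not_scalar(L, "L", positive = TRUE, integer = TRUE)
  stop_if_not_scalar(l_MTS, "l_MTS", positive = TRUE, integer = TRUE)
  t_max <- max(L - l_MTS, 0) / k_elong
  structure(
    list(name = as.character(name), k_init = k_init, k_elong = k_elong,
         L = as.integer(L), l_MTS = as.integer(l_MTS),
         rho_ribo = k_init / k_elong, t_max = t_max,
         T_total = L / k_elong, t_expo = t_max),
    class = "gene_kinetics")
}

#' @export
print.gene_kinetics <- function(x, ...) {
  cat(sprintf("Gene '%s': k_init = %g 1/s, k_elong = %g aa/s, L = %d aa (l_MTS = %d)\n",
              x$name, x$k_init, x$k_elong, x$L, x$l_MTS))
  cat(sprintf("  rho_ribo = %.4g /codon, t_expo = %.4g s, T_total = %.4g s, beta = %.4g\n",
              x$rho_ribo, x$t_expo, x$T_total, beta(x)))
  invisible(x)
}

#' MTS binding-competence model
#'
#' In the instantaneous model an MTS confers binding competence as soon
#' as the translating ribosome passes codon `l_MTS` (the limit
#' `k_MTS -> Inf`).  In the maturation model each translated MTS matures
#' into a binding-competent state after an exponential delay with rate
#' `k_MTS` (mean maturation time `tau_MTS = 1/k_MTS`), reflecting folding
#' of the amphipathic helix and/or chaperone engagement.
#'
#' @param mode `"instantaneous"` or `"maturation"`.
#' @param k_MTS maturation rate (1/s); required (finite, positive) in
#'   maturation mode.  Alternatively supply `tau_MTS` (s).
#' @param tau_MTS mean maturation time (s); `k_MTS = 1/tau_MTS`.
#' @return an object of class `competence_model` with elements `mode`,
#'   `k_MTS` and `tau_MTS`.
#' @examples
#' competence_model("maturation", tau_MTS = 40)
#' @export
competence_model <- function(mode = c("instantaneous", "maturation"),
                             k_MTS = NULL, tau_MTS = NULL) {
  mode <- match.arg(mode)
  if (mode == "instantaneous") {
    k <- Inf
  } else {
    if (is.null(k_MTS) && is.null(tau_MTS))
      stop("maturation mode needs `k_MTS` or `tau_MTS`", call. = FALSE)
    k <- if (!is.null(k_MTS)) k_MTS else 1 / tau_MTS
    stop_if_not_scalar(k, "k_MTS", positive = TRUE)
  }
  structure(list(mode = mode, k_MTS = k, tau_MTS = 1 / k),
            class = "competence_model")
}

#' @export
print.competence_model <- function(x, ...) {
  if (x$mode == "instantaneous")
    cat("Competence model: instantaneous (k_MTS -> Inf)\n")
  else
    cat(sprintf("Competence model: maturation, k_MTS = %g 1/s (tau_MTS = %g s)\n",
                x$k_MTS, x$tau_MTS))
  invisible(x)
}
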