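# Stochastic translation of a single mRNA: Gillespie simulation of
# ribosome loading, elongation with a 1-codon exclusion footprint,
# termination, MTS maturation and mRNA decay.  The compute kernel lives
# in src/translation.cpp; this file provides the user-facing trajectory
# simulator and the ensemble competence statistics.

.reason_labels <- c("window", "decay", "gain", "loss")

# low-level advance used by both the translation-only simulator and the
# coupled translation-diffusion simulator
advance_translation <- function(state, gene, model, k_decay, window,
                                stop_on_gain = FALSE, stop_on_loss = FALSE,
                                record = FALSE) {
  res <- .advance_translation_cpp(
    state$pos, state$mature, gene$k_init, gene$k_elong, gene$L,
    gene$l_MTS, model$mode == "maturation",
    if (is.finite(model$k_MTS)) model$k_MTS else 0,
    k_decay, window, stop_on_gain, stop_on_loss, record)
  res$reason <- .reason_labels[res$reason + 1L]
  res
}

empty_translation_state <- function() {
  list(pos = integer(0), mature = logical(0))
}

#' Sample a nuclear residence time
#'
#' Nuclear residence is normally distributed with mean 60 s and standard
#' deviation 30 s; non-positive draws are rejected and redrawn, so the
#' result is a sample from the zero-truncated normal (mean ~61.66 s).
#'
#' @param n number of samples.
#' @param mean,sd parameters of the underlying normal (s).
#' @return strictly positive times (s).
#' @export
sample_nuclear_residence <- function(n = 1L, mean = 60, sd = 30) {
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= 0))
    out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Simulate the translation history of one mRNA
#'
#' Exact-stochastic (Gillespie) trajectory of ribosome dynamics on a
#' single mRNA from nuclear export to decay (or a time horizon).
#' Initiation occurs at `k_init` only when codon 1 is free; each ribosome
#' advances at `k_elong` into a free codon and terminates from codon `L`
#' at `k_elong`; in the maturation model each ribosome past `l_MTS`
#' carries an independent exponential maturation clock at `k_MTS`; decay
#' at `k_decay` ends the trajectory and discards all ribosomes.
#'
#' @param gene a [gene_kinetics()] object.
#' @param model a [competence_model()].
#' @param k_decay cytosolic mRNA decay rate (1/s, default 0.0017, i.e. a
#'   600 s mean decay time).
#' @param seed integer RNG seed.
#' @param max_time horizon on cytosolic time (s); required when
#'   `k_decay = 0`.
#' @param include_nuclear sample a nuclear residence time (no translation,
#'   no decay) and include it in the lifetime (default TRUE).
#' @param record keep the full event log.
#' @return an object of class `translation_trajectory`: lifetime and
#'   time-in-state accounting (`t_nuclear`, `t_cytosolic`, `T_lifetime`,
#'   `t_translated`, `t_mature`, `t_competent`), time-averaged counts over
#'   cytosolic life (`mean_ribosomes`, `mean_translated_mts`,
#'   `mean_mature_mts`), the decay flag, and (if `record`) the event log.
#' @examples
#' g <- gene_kinetics(0.1, 5, 300)
#' simulate_translation(g, competence_model("instantaneous"), seed = 1)
#' @export
simulate_translation <- function(gene, model, k_decay = 0.0017, seed = NULL,
                                 max_time = Inf, include_nuclear = TRUE,
                                 record = FALSE) {
  stopifnot(inherits(gene, "gene_kinetics"),
            inherits(model, "competence_model"))
  stop_if_not_scalar(k_decay, "k_decay", nonnegative = TRUE)
  if (k_decay == 0 && !is.finite(max_time))
    stop("with k_decay = 0 a finite `max_time` horizon is required",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t_nuc <- if (include_nuclear) sample_nuclear_residence(1L) else 0
  res <- advance_translation(empty_translation_state(), gene, model,
                             k_decay, max_time, record = record)
  t_cyt <- res$elapsed
  out <- list(
    gene = gene$name, mode = model$mode,
    t_nuclear = t_nuc, t_cytosolic = t_cyt,
    T_lifetime = t_nuc + t_cyt,
    t_translated = res$t_translated, t_mature = res$t_mature,
    t_competent = res$t_competent,
    mean_ribosomes = if (t_cyt > 0) res$int_ribo / t_cyt else 0,
    mean_translated_mts = if (t_cyt > 0) res$int_translated / t_cyt else 0,
    mean_mature_mts = if (t_cyt > 0) res$int_mature / t_cyt else 0,
    decayed = res$reason == "decay",
    n_events = res$n_events, n_terminated = res$n_terminated)
  if (record) out$log <- res$log
  structure(out, class = "translation_trajectory")
}

#' @export
print.translation_trajectory <- function(x, ...) {
  cat(sprintf("Translation trajectory of '%s' (%s model):\n", x$gene, x$mode))
  cat(sprintf("  lifetime %.1f s (nuclear %.1f s); %s\n", x$T_lifetime,
              x$t_nuclear, if (x$decayed) "decayed" else "horizon reached"))
  cat(sprintf("  competent %.1f s (%.1f%% of lifetime); mean ribosomes %.2f\n",
              x$t_competent, 100 * x$t_competent / x$T_lifetime,
              x$mean_ribosomes))
  invisible(x)
}

#' Simulate a translation-only ensemble
#'
#' @inheritParams simulate_translation
#' @param n_trajectories ensemble size (default 50).
#' @param seed global seed; per-trajectory streams are derived with
#'   [trajectory_seed()].
#' @return a data.frame with one row per trajectory (columns as in the
#'   fields of [simulate_translation()]).
#' @export
simulate_translation_ensemble <- function(gene, model, n_trajectories = 50L,
                                          seed = 1L, k_decay = 0.0017,
                                          max_time = Inf,
                                          include_nuclear = TRUE) {
  rows <- lapply(seq_len(n_trajectories), function(i) {
    tr <- simulate_translation(gene, model, k_decay,
                               seed = trajectory_seed(seed, i),
                               max_time = max_time,
                               include_nuclear = include_nuclear)
    as.data.frame(tr[c("t_nuclear", "t_cytosolic", "T_lifetime",
                       "t_translated", "t_mature", "t_competent",
                       "mean_ribosomes", "mean_translated_mts",
                       "mean_mature_mts", "decayed")])
  })
  do.call(rbind, rows)
}

#' Lifetime-weighted binding-competent fraction of an ensemble
#'
#' The fraction of total mRNA lifetime during which at least one
#' binding-competent MTS is exposed (translated MTS in the instantaneous
#' model, mature MTS in the maturation model), aggregated across
#' trajectories with lifetime weights: trajectories enter localization
#' measurements in proportion to how long they live.
#'
#' @param ensemble a data.frame from [simulate_translation_ensemble()].
#' @param include_nuclear include nuclear residence in the denominator
#'   (default TRUE; set FALSE to express the fraction over cytosolic life
#'   only).
#' @return a probability.
#' @export
competent_fraction <- function(ensemble, include_nuclear = TRUE) {
  if (!is.data.frame(ensemble) || nrow(ensemble) == 0L)
    stop("`ensemble` must be a non-empty trajectory data.frame",
         call. = FALSE)
  denom <- if (include_nuclear) sum(ensemble$T_lifetime)
           else sum(ensemble$t_cytosolic)
  if (denom <= 0) stop("total lifetime must be positive", call. = FALSE)
  sum(ensemble$t_competent) / denom
}

#' Lifetime-weighted CHX-localizable fraction
#'
#' Cycloheximide freezes elongation, leaving every fully translated MTS
#' exposed indefinitely; an mRNA with at least one translated (not
#' necessarily mature) MTS at the moment of drug application can
#' therefore localize.  This statistic is the lifetime-weighted fraction
#' of life with >= 1 translated MTS -- the probability that a randomly
#' sampled mRNA is localizable under CHX.  It coincides with
#' [competent_fraction()] in the instantaneous model and bounds it from
#' above in the maturation model.
#'
#' @inheritParams competent_fraction
#' @return a probability.
#' @export
chx_localizable_fraction <- function(ensemble, include_nuclear = TRUE) {
  if (!is.data.frame(ensemble) || nrow(ensemble) == 0L)
    stop("`ensemble` must be a non-empty trajectory data.frame",
         call. = FALSE)
  denom <- if (include_nuclear) sum(ensemble$T_lifetime)
           else sum(ensemble$t_cytosolic)
  if (denom <= 0) stop("total lifetime must be positive", call. = FALSE)
  sum(ensemble$t_translated) / denom
}

#' Export a recorded event log as a tab-separated file
#'
#' @param trajectory a `translation_trajectory` simulated with
#'   `record = TRUE`.
#' @param file path to write (tab-separated, one header line).
#' @return the file path, invisibly.
#' @export
write_event_log <- function(trajectory, file) {
  stopifnot(inherits(trajectory, "translation_trajectory"))
  if (is.null(trajectory$log))
    stop("trajectory was simulated without `record = TRUE`", call. = FALSE)
  lg <- trajectory$log
  lg$event <- c("initiation", "elongation", "maturation",
                "decay")[lg$event + 1L]
  write.table(lg, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
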