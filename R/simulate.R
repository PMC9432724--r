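# Coupled translation-diffusion trajectories.
#
# One mRNA is followed from synthesis to decay: a nuclear residence (no
# translation, no decay), export at the outer reflecting wall, then an
# event loop that merges spatial region transitions (realized
# first-passage times, which remain valid while translation events fire)
# with the Gillespie translation process.  A competent mRNA entering the
# binding region binds at the crossing instant and stays bound until its
# last competent MTS is lost; unbinding re-places the mRNA at a random
# radius within the binding region.  Decay ends the trajectory anywhere,
# including while bound.

#' Configuration of a coupled simulation
#'
#' @param gene a [gene_kinetics()].
#' @param competence a [competence_model()].
#' @param geometry a [cylinder_geometry()] (or use
#'   [geometry_from_mvf()]).
#' @param k_decay cytosolic decay rate (1/s; default 0.0017).
#' @param nuclear_mean,nuclear_sd nuclear residence distribution (s).
#' @param n_trajectories ensemble size (default 50).
#' @param seed global integer seed.
#' @param max_time cytosolic-time horizon (s); used when `k_decay = 0`
#'   (default 6000 s, ten mean lifetimes).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(gene, competence, geometry,
                              k_decay = 0.0017, nuclear_mean = 60,
                              nuclear_sd = 30, n_trajectories = 50L,
                              seed = 1L, max_time = 6000) {
  stopifnot(inherits(gene, "gene_kinetics"),
            inherits(competence, "competence_model"),
            inherits(geometry, "cylinder_geometry"))
  stop_if_not_scalar(k_decay, "k_decay", nonnegative = TRUE)
  stop_if_not_scalar(n_trajectories, "n_trajectories", positive = TRUE,
                     integer = TRUE)
  structure(
    list(gene = gene, competence = competence, geometry = geometry,
         k_decay = k_decay, nuclear_mean = nuclear_mean,
         nuclear_sd = nuclear_sd,
         n_trajectories = as.integer(n_trajectories),
         seed = as.integer(seed), max_time = max_time),
    class = "simulation_config")
}

# number of competent MTSs in a translation state under the active model
state_competent <- function(state, gene, model) {
  if (model$mode == "maturation") sum(state$mature)
  else sum(state$pos >= gene$l_MTS)
}

# per-trajectory pooled sampler over a fixed inverse-survival table:
# draws are taken in blocks so the interpolation overhead is amortized
make_pool <- function(drawfun, size = 256L) {
  buf <- numeric(0)
  i <- 0L
  function() {
    if (i >= length(buf)) {
      buf <<- drawfun(size)
      i <<- 0L
    }
    i <<- i + 1L
    buf[i]
  }
}

#' Simulate one coupled translation-diffusion trajectory
#'
#' Spatial motion is advanced by realized first-passage times, which are
#' independent of the translation process; translation is advanced by
#' the Gillespie kernel over the corresponding windows (stopping and
#' restarting at region changes is statistically exact because every
#' translation clock is memoryless).  Consecutive unbound segments in
#' regions 2 and 3 are batched into a single translation window; the
#' batch ends when the mRNA reaches the binding region, where competence
#' is checked (a competent mRNA binds at the crossing instant) and,
#' while unbound inside region 1, a competence gain binds the mRNA
#' immediately and cancels the scheduled exit.
#'
#' @param config a [simulation_config()].
#' @param index trajectory index; the RNG stream is derived from
#'   `(seed, index)` via [trajectory_seed()], so records are reproducible
#'   independently of execution order.
#' @param propagator optional precomputed [mito_propagator()] for the
#'   configured geometry (built and cached automatically otherwise).
#' @return an object of class `trajectory_record`: lifetime accounting
#'   (`T_lifetime`, `t_nuclear`, `t_region1`, `t_region2`, `t_region3`,
#'   `t_bound`), competence accounting (`t_translated_mts`,
#'   `t_competent`), localization fractions `f_loc_binding` (region 1,
#'   bound or unbound) and `f_loc_imaging` (regions 1 + 2), the decay
#'   flag and event counts.
#' @export
simulate_mrna <- function(config, index = 1L, propagator = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  prop <- propagator %||% mito_propagator(config$geometry)
  gene <- config$gene
  model <- config$competence
  set.seed(trajectory_seed(config$seed, index))

  t_nuc <- sample_nuclear_residence(1L, config$nuclear_mean,
                                    config$nuclear_sd)
  horizon <- if (config$k_decay > 0) Inf else config$max_time

  # pooled draws from the fixed-entry first-passage tables
  p_tab1 <- make_pool(function(n) sample_fpt_table(prop$tab1, n))
  p_r3i <- make_pool(function(n) sample_fpt_table(prop$tab3_inner, n))
  p_r3o <- make_pool(function(n) sample_fpt_table(prop$tab3_outer, n))
  p_r2 <- list(
    inner = list(u = make_pool(function(n) runif(n)),
                 inner = make_pool(function(n)
                   sample_fpt_table(prop$r2_from_inner$inner, n)),
                 outer = make_pool(function(n)
                   sample_fpt_table(prop$r2_from_inner$outer, n)),
                 p = prop$r2_from_inner$p_inner),
    outer = list(u = make_pool(function(n) runif(n)),
                 inner = make_pool(function(n)
                   sample_fpt_table(prop$r2_from_outer$inner, n)),
                 outer = make_pool(function(n)
                   sample_fpt_table(prop$r2_from_outer$outer, n)),
                 p = prop$r2_from_outer$p_inner))

  state <- empty_translation_state()
  acc <- c(r1 = 0, r2 = 0, r3 = 0, bound = 0)
  t_translated <- 0
  t_competent <- 0
  t_cyt <- 0
  n_transitions <- 0L
  n_bindings <- 0L
  decayed <- FALSE

  # current spatial status
  bound <- FALSE
  region <- 3L
  entry <- "outer_wall"   # how the current region was entered
  unbind_r0 <- NA_real_   # fresh radius after an unbinding event

  advance_and_account <- function(window, regions, durations,
                                  stop_on_gain = FALSE) {
    # advance translation over `window`; attribute elapsed time to the
    # spatial segments (regions/durations) it spans
    res <- advance_translation(state, gene, model, config$k_decay, window,
                               stop_on_gain = stop_on_gain)
    state <<- list(pos = res$pos, mature = res$mature)
    left <- res$elapsed
    for (j in seq_along(durations)) {
      d <- min(durations[j], left)
      key <- c("r1", "r2", "r3")[regions[j]]
      acc[key] <<- acc[key] + d
      left <- left - d
      if (left <= 0) break
    }
    t_translated <<- t_translated + res$t_translated
    t_competent <<- t_competent + res$t_competent
    t_cyt <<- t_cyt + res$elapsed
    res
  }

  repeat {
    remaining <- horizon - t_cyt
    if (remaining <= 0) break

    if (bound) {
      res <- advance_translation(state, gene, model, config$k_decay,
                                 remaining, stop_on_loss = TRUE)
      state <- list(pos = res$pos, mature = res$mature)
      acc["bound"] <- acc["bound"] + res$elapsed
      t_translated <- t_translated + res$t_translated
      t_competent <- t_competent + res$t_competent
      t_cyt <- t_cyt + res$elapsed
      if (res$reason == "decay") { decayed <- TRUE; break }
      if (res$reason == "window") break           # horizon reached
      # lost the last competent MTS: release within the binding region
      bound <- FALSE
      region <- 1L
      entry <- "unbinding"
      unbind_r0 <- sample_unbinding_position(prop)
      next
    }

    if (region == 1L) {
      # single segment: a competence gain inside the binding region must
      # interrupt the scheduled exit (immediate binding)
      fpt <- if (identical(entry, "unbinding"))
        sample_region1_exit(prop, 1L, r0 = unbind_r0)
      else p_tab1()
      res <- advance_and_account(min(fpt, remaining), 1L, fpt,
                                 stop_on_gain = TRUE)
      if (res$reason == "decay") { decayed <- TRUE; break }
      if (res$reason == "gain") {
        bound <- TRUE
        n_bindings <- n_bindings + 1L
        next
      }
      if (res$elapsed >= remaining) break
      n_transitions <- n_transitions + 1L
      region <- 2L
      entry <- "inner"
      next
    }

    # batch consecutive region-2/3 segments until the binding region is
    # reached (or the batch/horizon limit)
    max_seg <- 256L
    seg_region <- integer(max_seg)
    seg_dur <- numeric(max_seg)
    n_seg <- 0L
    total <- 0
    enters_r1 <- FALSE
    while (n_seg < max_seg && total < remaining) {
      if (region == 2L) {
        side <- p_r2[[entry]]
        to_inner <- side$u() < side$p
        dur <- if (to_inner) side$inner() else side$outer()
        n_seg <- n_seg + 1L
        seg_region[n_seg] <- 2L
        seg_dur[n_seg] <- dur
        total <- total + dur
        if (to_inner) { enters_r1 <- TRUE; break }
        region <- 3L
        entry <- "inner_edge"
      } else {
        dur <- if (identical(entry, "outer_wall")) p_r3o() else p_r3i()
        n_seg <- n_seg + 1L
        seg_region[n_seg] <- 3L
        seg_dur[n_seg] <- dur
        total <- total + dur
        region <- 2L
        entry <- "outer"
      }
    }
    seg_region <- seg_region[seq_len(n_seg)]
    seg_dur <- seg_dur[seq_len(n_seg)]
    n_transitions <- n_transitions + n_seg

    res <- advance_and_account(min(total, remaining), seg_region, seg_dur)
    if (res$reason == "decay") { decayed <- TRUE; break }
    if (res$elapsed >= remaining) break
    if (enters_r1) {
      region <- 1L
      if (state_competent(state, gene, model) > 0) {
        # competent mRNA crossing into binding range binds on entry
        bound <- TRUE
        n_bindings <- n_bindings + 1L
      } else {
        entry <- "entry_edge"   # start at r_a - eps
      }
    }
    # otherwise the batch ended at the segment cap: region/entry already
    # point at the pending segment's region
  }

  T_life <- t_nuc + t_cyt
  structure(
    list(gene = gene$name, index = index,
         T_lifetime = T_life, t_nuclear = t_nuc,
         t_region1 = unname(acc["r1"]), t_region2 = unname(acc["r2"]),
         t_region3 = unname(acc["r3"]), t_bound = unname(acc["bound"]),
         t_translated_mts = t_translated, t_competent = t_competent,
         f_loc_binding = (acc[["r1"]] + acc[["bound"]]) / T_life,
         f_loc_imaging = (acc[["r1"]] + acc[["bound"]] + acc[["r2"]]) /
           T_life,
         decayed = decayed, n_transitions = n_transitions,
         n_bindings = n_bindings),
    class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("Trajectory %d of '%s': lifetime %.1f s%s\n", x$index,
              x$gene, x$T_lifetime,
              if (x$decayed) " (decayed)" else " (horizon)"))
  cat(sprintf("  bound %.1f s | region1 %.1f s | region2 %.1f s | region3 %.1f s | nucleus %.1f s\n",
              x$t_bound, x$t_region1, x$t_region2, x$t_region3,
              x$t_nuclear))
  cat(sprintf("  f_loc(binding) = %.3f, f_loc(imaging) = %.3f\n",
              x$f_loc_binding, x$f_loc_imaging))
  invisible(x)
}

#' Simulate an ensemble of coupled trajectories
#'
#' @inheritParams simulate_mrna
#' @return a data.frame with one row per [simulate_mrna()] record.
#' @export
simulate_ensemble <- function(config, propagator = NULL) {
  prop <- propagator %||% mito_propagator(config$geometry)
  rows <- lapply(seq_len(config$n_trajectories), function(i) {
    rec <- simulate_mrna(config, i, prop)
    as.data.frame(rec[c("index", "T_lifetime", "t_nuclear", "t_region1",
                        "t_region2", "t_region3", "t_bound",
                        "t_translated_mts", "t_competent",
                        "f_loc_binding", "f_loc_imaging", "decayed",
                        "n_transitions", "n_bindings")])
  })
  out <- do.call(rbind, rows)
  attr(out, "gene") <- config$gene$name
  out
}

#' Lifetime-weighted ensemble localization
#'
#' Aggregates per-trajectory localization fractions with lifetime
#' weights, `sum_i f_i T_i / sum_i T_i`: an mRNA enters a localization
#' measurement in proportion to how long it lives.  The `binding`
#' measure counts time within binding range of the surface (region 1,
#' bound or unbound); the `imaging` measure counts time within the
#' diffraction-limited distance (regions 1 and 2).
#'
#' @param records a data.frame from [simulate_ensemble()].
#' @param measure `"binding"` or `"imaging"`.
#' @return a probability.
#' @examples
#' recs <- data.frame(f_loc_binding = c(0.5, 1), T_lifetime = c(100, 300))
#' ensemble_localization(recs)  # 0.875
#' @export
ensemble_localization <- function(records, measure = c("binding", "imaging")) {
  measure <- match.arg(measure)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  f <- if (measure == "binding") records$f_loc_binding
       else records$f_loc_imaging
  sum(f * records$T_lifetime) / sum(records$T_lifetime)
}

#' Lifetime-weighted CHX localization of an ensemble
#'
#' The localization expected after cycloheximide application: the
#' lifetime-weighted fraction of life with at least one fully translated
#' (not necessarily mature) MTS, whose exposure CHX would freeze.
#'
#' @inheritParams ensemble_localization
#' @return a probability.
#' @export
ensemble_chx_localization <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  sum(records$t_translated_mts) / sum(records$T_lifetime)
}

#' Parameter sweep of the coupled simulator
#'
#' Re-runs an ensemble while varying one axis; all rows share the base
#' seed (matched RNG streams) for variance reduction, so monotone trends
#' are visible at modest ensemble sizes.
#'
#' @param config a [simulation_config()] providing the base condition.
#' @param axis one of `"mvf"`, `"k_init"`, `"k_elong"`, `"tau_MTS"`,
#'   `"D"`, `"k_decay"`.
#' @param values numeric vector of axis values.
#' @return a data.frame with one row per value: the axis value, binding
#'   and imaging localization, CHX localization, and mean lifetime.
#'   Inadmissible values (e.g. an MVF too large for the geometry) yield a
#'   row of `NA`s with the error message in the `note` column.
#' @export
sweep_localization <- function(config,
                               axis = c("mvf", "k_init", "k_elong",
                                        "tau_MTS", "D", "k_decay"),
                               values) {
  axis <- match.arg(axis)
  rows <- lapply(values, function(v) {
    cfg <- config
    err <- tryCatch({
      if (axis == "mvf") {
        cfg$geometry <- geometry_from_mvf(
          v, accessible_fraction = config$geometry$accessible_fraction,
          r_m = config$geometry$r_m, r_b = config$geometry$r_b,
          eps = config$geometry$eps, D = config$geometry$D)
      } else if (axis == "k_init") {
        cfg$gene <- gene_kinetics(v, config$gene$k_elong, config$gene$L,
                                  config$gene$l_MTS, config$gene$name)
      } else if (axis == "k_elong") {
        cfg$gene <- gene_kinetics(config$gene$k_init, v, config$gene$L,
                                  config$gene$l_MTS, config$gene$name)
      } else if (axis == "tau_MTS") {
        cfg$competence <- competence_model("maturation", tau_MTS = v)
      } else if (axis == "D") {
        g <- config$geometry; g$D <- v
        cfg$geometry <- do.call(cylinder_geometry,
                                g[c("r_m", "r_a", "r_b", "R_out", "eps",
                                    "D", "f_m", "accessible_fraction",
                                    "V_cell")])
      } else {
        cfg$k_decay <- v
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(err))
      return(data.frame(value = v, loc_binding = NA_real_,
                        loc_imaging = NA_real_, loc_chx = NA_real_,
                        mean_lifetime = NA_real_, note = err,
                        stringsAsFactors = FALSE))
    recs <- simulate_ensemble(cfg)
    data.frame(value = v,
               loc_binding = ensemble_localization(recs, "binding"),
               loc_imaging = ensemble_localization(recs, "imaging"),
               loc_chx = ensemble_chx_localization(recs),
               mean_lifetime = mean(recs$T_lifetime), note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "axis") <- axis
  out
}
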