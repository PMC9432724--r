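# Structured experiment runner: YAML config in, tab-separated tables and
# a run manifest out.  This is the programmatic face of the command-line
# script in `inst/cli/mitoloc.R`.

um_from <- function(cfg, key, default = NULL) {
  # lengths are um by default; a `<key>_nm` variant is converted
  if (!is.null(cfg[[paste0(key, "_nm")]]))
    return(cfg[[paste0(key, "_nm")]] / 1000)
  cfg[[key]] %||% default
}

config_gene <- function(cfg) {
  g <- cfg$gene
  if (is.null(g)) stop("config needs a `gene` section", call. = FALSE)
  gene_kinetics(g$k_init, g$k_elong, g$L, g$l_MTS %||% 100L,
                g$name %||% "gene")
}

config_competence <- function(cfg) {
  cm <- cfg$competence %||% list(mode = "instantaneous")
  if ((cm$mode %||% "instantaneous") == "instantaneous")
    competence_model("instantaneous")
  else competence_model("maturation", k_MTS = cm$k_MTS,
                        tau_MTS = cm$tau_MTS)
}

config_geometry <- function(cfg) {
  gm <- cfg$geometry %||% list(mvf = 0.04)
  args <- list(r_m = um_from(gm, "r_m", 0.350),
               eps = um_from(gm, "eps", 0.010),
               D = gm$D %||% 0.1)
  args$r_b <- um_from(gm, "r_b", args$r_m + 0.250)
  r_a <- um_from(gm, "r_a")
  if (!is.null(r_a)) args$r_a <- r_a
  if (!is.null(gm$mvf)) {
    do.call(geometry_from_mvf,
            c(list(f_m = gm$mvf,
                   accessible_fraction = gm$accessible_fraction %||% 0.8),
              args))
  } else {
    R_out <- um_from(gm, "R_out")
    if (is.null(R_out))
      stop("geometry needs `mvf` or `R_out`", call. = FALSE)
    do.call(cylinder_geometry, c(list(R_out = R_out), args))
  }
}

config_simulation <- function(cfg) {
  simulation_config(
    gene = config_gene(cfg), competence = config_competence(cfg),
    geometry = config_geometry(cfg),
    k_decay = cfg$k_decay %||% 0.0017,
    nuclear_mean = cfg$nuclear_mean %||% 60,
    nuclear_sd = cfg$nuclear_sd %||% 30,
    n_trajectories = cfg$n_trajectories %||% 50L,
    seed = cfg$seed %||% 1L,
    max_time = cfg$max_time %||% 6000)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run a configured experiment
#'
#' Dispatches on `command` in a structured (YAML) configuration and
#' writes deterministic tab-separated outputs plus a `manifest.txt`
#' recording the seed, a config hash and the package version.  Commands:
#' \describe{
#'   \item{simulate}{coupled ensemble for one gene; writes
#'     `trajectories.tsv` and a one-row `summary.tsv` with binding,
#'     imaging and CHX localization.}
#'   \item{sweep}{[sweep_localization()] over `sweep$axis` /
#'     `sweep$values`; writes `summary.tsv`.}
#'   \item{rates}{[build_gene_table()] on the table at `rates$input`;
#'     writes `genes.tsv`.}
#'   \item{synth}{[generate_synthetic_cohort()]; writes `genes.tsv`.}
#'   \item{fourstate}{steady state and both transport limits for the
#'     rates in `fourstate`; writes `summary.tsv`.}
#'   \item{closedform}{beta, beta_mature, exposure and search times for
#'     the configured gene/condition; writes `summary.tsv`.}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named list of the tables written.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    cfg_hash <- unname(tools::md5sum(config))
  } else {
    cfg <- config
    tf <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, tf)
    cfg_hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  cmd <- cfg$command %||% stop("config needs a `command`", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  out <- list()

  if (cmd == "simulate") {
    sc <- config_simulation(cfg)
    recs <- simulate_ensemble(sc)
    out$trajectories <- recs
    out$summary <- data.frame(
      gene = sc$gene$name,
      loc_binding = ensemble_localization(recs, "binding"),
      loc_imaging = ensemble_localization(recs, "imaging"),
      loc_chx = ensemble_chx_localization(recs),
      competent_fraction = sum(recs$t_competent) / sum(recs$T_lifetime),
      mean_lifetime = mean(recs$T_lifetime),
      n_trajectories = nrow(recs))
    write_tsv(recs, file.path(out_dir, "trajectories.tsv"))
    write_tsv(out$summary, file.path(out_dir, "summary.tsv"))
  } else if (cmd == "sweep") {
    sc <- config_simulation(cfg)
    sw <- cfg$sweep %||% stop("sweep command needs a `sweep` section",
                              call. = FALSE)
    out$summary <- sweep_localization(sc, sw$axis, as.numeric(sw$values))
    write_tsv(out$summary, file.path(out_dir, "summary.tsv"))
  } else if (cmd == "rates") {
    rc <- cfg$rates %||% list()
    meas <- read_gene_table(rc$input %||%
                              stop("rates command needs `rates$input`",
                                   call. = FALSE))
    cal <- default_calibration()
    if (!is.null(rc$occ_ref)) cal$occ_ref <- rc$occ_ref else
      cal$occ_ref <- NA_real_
    out$genes <- build_gene_table(meas, cal, rc$tau_MTS %||% 40)
    write_tsv(out$genes, file.path(out_dir, "genes.tsv"))
  } else if (cmd == "synth") {
    sy <- cfg$synth %||% list()
    spec <- synthetic_cohort_spec(
      n_conditional = sy$n_conditional %||% 52L,
      n_constitutive = sy$n_constitutive %||% 70L,
      sdlog = sy$sdlog %||% 0.4, seed = seed)
    out$genes <- generate_synthetic_cohort(spec)
    write_tsv(out$genes, file.path(out_dir, "genes.tsv"))
  } else if (cmd == "fourstate") {
    fs <- cfg$fourstate %||% stop("fourstate command needs a `fourstate` section",
                                  call. = FALSE)
    r <- four_state_rates(fs$k_S, fs$k_U, fs$k_R, fs$k_L)
    ss <- steady_state(r)
    out$summary <- data.frame(
      k_S = r$k_S, k_U = r$k_U, k_R = r$k_R, k_L = r$k_L,
      p_SN = ss$p_SN, p_SF = ss$p_SF, p_UN = ss$p_UN, p_UF = ss$p_UF,
      localized = ss$p_SN + ss$p_UN,
      limit_rapid = limit_rapid_transport(r$f_s, r$f_d),
      limit_slow = limit_slow_transport(r$f_s, r$f_d))
    write_tsv(out$summary, file.path(out_dir, "summary.tsv"))
  } else if (cmd == "closedform") {
    gene <- config_gene(cfg)
    model <- config_competence(cfg)
    geom <- config_geometry(cfg)
    k <- model$k_MTS
    out$summary <- data.frame(
      gene = gene$name, beta = beta(gene),
      beta_mature = beta_mature(gene, k),
      t_expo = gene$t_expo,
      t_expo_mature = mature_exposure_time(gene, k),
      t_search = mean_search_time(geom$r_a, geom$R_out, geom$D))
    write_tsv(out$summary, file.path(out_dir, "summary.tsv"))
  } else {
    stop(sprintf("unknown command '%s'", cmd), call. = FALSE)
  }

  manifest <- c(
    sprintf("command: %s", cmd),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("config_md5: %s", cfg_hash),
    sprintf("package: mitoloc %s", as.character(packageVersion("mitoloc"))),
    sprintf("outputs: %s", paste(names(out), collapse = ", ")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out)
}
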