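test_that("steady-state ribosome and translated-MTS counts match flux balance", {
  g <- gene_kinetics(0.1, 5, 300)
  inst <- competence_model("instantaneous")
  reps <- sapply(1:8, function(i) {
    tr <- simulate_translation(g, inst, k_decay = 0, seed = 300 + i,
                               max_time = 2e4, include_nuclear = FALSE)
    c(tr$mean_ribosomes, tr$mean_translated_mts)
  })
  # N_ribo = k_init L / k_elong = 6; translated MTSs = beta = 4
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_within_se(mean(reps[1, ]), 6, se[1])
  expect_within_se(mean(reps[2, ]), beta(g), se[2])
})

test_that("mature-MTS count matches beta_mature at low occupancy", {
  grid <- list(c(0.05, 5, 300, 1 / 20), c(0.02, 2, 400, 1 / 60),
               c(0.1, 8, 500, 1 / 40))
  for (p in grid) {
    g <- gene_kinetics(p[1], p[2], p[3])
    mat <- competence_model("maturation", k_MTS = p[4])
    reps <- sapply(1:6, function(i)
      simulate_translation(g, mat, k_decay = 0, seed = 400 + i,
                           max_time = 1.5e4,
                           include_nuclear = FALSE)$mean_mature_mts)
    se <- sd(reps) / sqrt(length(reps))
    expect_within_se(mean(reps), beta_mature(g, p[4]), se)
  }
})

test_that("a transcript shorter than the MTS region is never competent", {
  g <- gene_kinetics(0.2, 5, 90, l_MTS = 100)
  for (mode in list(competence_model("instantaneous"),
                    competence_model("maturation", tau_MTS = 10))) {
    tr <- simulate_translation(g, mode, k_decay = 0.0017, seed = 5)
    expect_equal(tr$t_competent, 0)
    expect_equal(tr$t_translated, 0)
  }
})

test_that("ribosomes exclude each other and maturity implies translation", {
  g <- gene_kinetics(0.5, 2, 60, l_MTS = 30)   # crowded short transcript
  mat <- competence_model("maturation", tau_MTS = 5)
  set.seed(61)
  state <- mitoloc:::empty_translation_state()
  for (i in 1:400) {
    res <- mitoloc:::advance_translation(state, g, mat, k_decay = 0,
                                         window = 0.5)
    state <- list(pos = res$pos, mature = res$mature)
    if (length(state$pos) > 1) {
      expect_true(all(diff(state$pos) <= -1))   # strictly ordered, gap >= 1
      expect_lte(max(table(state$pos)), 1)
    }
    expect_true(all(state$pos <= g$L & state$pos >= 1))
    # a mature flag requires a translated MTS
    expect_true(all(!state$mature | state$pos >= g$l_MTS))
  }
})

test_that("trajectories are reproducible from their seed", {
  g <- cond_median()
  mat <- competence_model("maturation", tau_MTS = 40)
  a <- simulate_translation(g, mat, seed = 42, record = TRUE)
  b <- simulate_translation(g, mat, seed = 42, record = TRUE)
  expect_identical(a$log, b$log)
  expect_identical(a$T_lifetime, b$T_lifetime)
  c <- simulate_translation(g, mat, seed = 43)
  expect_false(identical(a$T_lifetime, c$T_lifetime))
})

test_that("nuclear residence is a truncated normal with the known mean", {
  set.seed(77)
  x <- sample_nuclear_residence(2e5)
  expect_true(all(x > 0))
  # zero-truncated N(60, 30): mean = 60 + 30 * phi(-2)/(1 - Phi(-2))
  mu <- 60 + 30 * dnorm(-2) / (1 - pnorm(-2))
  expect_equal(mu, 61.657, tolerance = 1e-3)
  expect_within_se(mean(x), mu, sd(x) / sqrt(length(x)))
  set.seed(123); s1 <- sample_nuclear_residence(10)
  set.seed(123); s2 <- sample_nuclear_residence(10)
  expect_identical(s1, s2)
})

test_that("CHX-localizable fraction dominates competence under maturation", {
  g <- cond_median()
  inst_ens <- simulate_translation_ensemble(g, competence_model("instantaneous"),
                                            n_trajectories = 20L, seed = 9)
  expect_equal(chx_localizable_fraction(inst_ens),
               competent_fraction(inst_ens))
  mat_ens <- simulate_translation_ensemble(
    g, competence_model("maturation", tau_MTS = 40),
    n_trajectories = 20L, seed = 9)
  expect_gte(chx_localizable_fraction(mat_ens), competent_fraction(mat_ens))
  # excluding nuclear time raises the fraction
  expect_gt(competent_fraction(mat_ens, include_nuclear = FALSE),
            competent_fraction(mat_ens))
  expect_error(competent_fraction(mat_ens[0, ]), "non-empty")
})

test_that("saturated translation gives near-total competence", {
  g <- gene_kinetics(0.5, 1, 600)   # beta = 250
  ens <- simulate_translation_ensemble(g, competence_model("instantaneous"),
                                       n_trajectories = 15L, seed = 21,
                                       k_decay = 0, max_time = 2e4,
                                       include_nuclear = FALSE)
  expect_gt(competent_fraction(ens), 0.9)
})

test_that("competent fraction rises with beta in binned medians", {
  # parameter sets drawn from the physiological ranges; the mean exposed
  # MTS count is predictive of the lifetime competence fraction
  set.seed(31)
  n <- 60
  k_init <- exp(runif(n, log(1e-3), log(0.5)))
  L <- round(runif(n, 150, 600))
  k_elong <- runif(n, 1, 10)
  inst <- competence_model("instantaneous")
  fr <- sapply(1:n, function(i) {
    g <- gene_kinetics(k_init[i], k_elong[i], L[i])
    competent_fraction(simulate_translation_ensemble(
      g, inst, n_trajectories = 30L, seed = 500 + i))
  })
  b <- k_init * (L - 100) / k_elong
  bins <- cut(log10(b), breaks = c(-Inf, -1, -0.3, 0.3, 1, Inf))
  med <- tapply(fr, bins, median)
  med <- med[!is.na(med)]
  expect_true(all(diff(med) > 0))
})

test_that("the event log export is tab-separated and replayable", {
  g <- gene_kinetics(0.1, 5, 200)
  tr <- simulate_translation(g, competence_model("instantaneous"),
                             seed = 3, record = TRUE)
  f <- tempfile(fileext = ".tsv")
  write_event_log(tr, f)
  lg <- read.delim(f)
  expect_true(all(c("time", "event", "n_ribosomes") %in% names(lg)))
  expect_true(all(diff(lg$time) >= 0))
  expect_true(all(lg$n_mature_mts <= lg$n_translated_mts))
  expect_true(all(lg$n_translated_mts <= lg$n_ribosomes))
  unlink(f)
})
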