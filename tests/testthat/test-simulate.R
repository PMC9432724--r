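test_that("ensemble localization is the lifetime-weighted mean", {
  recs <- data.frame(f_loc_binding = c(0.5, 1.0), f_loc_imaging = c(0.6, 1.0),
                     T_lifetime = c(100, 300),
                     t_translated_mts = c(10, 200))
  expect_equal(ensemble_localization(recs, "binding"), 0.875)
  expect_equal(ensemble_localization(recs[1, ], "binding"), 0.5)
  eq <- data.frame(f_loc_binding = c(0.2, 0.8), T_lifetime = c(50, 50))
  expect_equal(ensemble_localization(eq), 0.5)
  expect_equal(ensemble_chx_localization(recs), 210 / 400)
  expect_error(ensemble_localization(recs[0, ]), "non-empty")
})

test_that("trajectory time bookkeeping is exact and reproducible", {
  cfg <- simulation_config(cond_median(),
                           competence_model("maturation", tau_MTS = 40),
                           geom04(), n_trajectories = 6L, seed = 17)
  recs <- simulate_ensemble(cfg)
  total <- recs$t_nuclear + recs$t_region1 + recs$t_region2 +
    recs$t_region3 + recs$t_bound
  expect_equal(total, recs$T_lifetime, tolerance = 1e-9)
  expect_true(all(recs$f_loc_binding >= 0 & recs$f_loc_binding <= 1))
  expect_true(all(recs$f_loc_imaging >= recs$f_loc_binding - 1e-12))
  # bit-identical replay of a single trajectory
  a <- simulate_mrna(cfg, 3L)
  b <- simulate_mrna(cfg, 3L)
  expect_identical(a, b)
})

test_that("a never-competent mRNA equilibrates to the annular area fractions", {
  geom <- geom04()
  g0 <- gene_kinetics(0.1, 5, 80)   # L < l_MTS: no MTS is ever completed
  cfg <- simulation_config(g0, competence_model("instantaneous"), geom,
                           k_decay = 0, n_trajectories = 12L, seed = 7,
                           max_time = 1500)
  recs <- simulate_ensemble(cfg)
  expect_equal(sum(recs$t_bound), 0)
  expect_equal(sum(recs$t_translated_mts), 0)
  cyto <- recs$t_region1 + recs$t_region2 + recs$t_region3
  shares <- cbind(recs$t_region1, recs$t_region2, recs$t_region3) / cyto
  areas <- mitoloc:::region_area_fractions(geom)
  for (j in 1:3)
    expect_within_se(mean(shares[, j]), areas[j],
                     sd(shares[, j]) / sqrt(nrow(shares)))
})

test_that("a permanently competent mRNA binds once and stays bound", {
  geom <- geom04()
  g <- gene_kinetics(0.5, 1, 600)   # beta = 250: competence never lapses
  cfg <- simulation_config(g, competence_model("instantaneous"), geom,
                           k_decay = 0, n_trajectories = 5L, seed = 23,
                           max_time = 4000)
  recs <- simulate_ensemble(cfg)
  expect_true(all(recs$n_bindings == 1))
  expect_true(all(recs$f_loc_binding > 0.85))
  expect_true(all(recs$t_bound > 0.9 * (recs$t_bound + recs$t_region1)))
})

test_that("CHX localization exceeds maturation-limited localization", {
  cfg <- simulation_config(cond_median(),
                           competence_model("maturation", tau_MTS = 40),
                           geom04(), n_trajectories = 30L, seed = 3)
  recs <- simulate_ensemble(cfg)
  expect_gt(ensemble_chx_localization(recs),
            ensemble_localization(recs, "binding"))
})

test_that("binding localization rises with mitochondrial volume fraction", {
  mat40 <- competence_model("maturation", tau_MTS = 40)
  loc <- sapply(c(0.01, 0.04, 0.15), function(f) {
    cfg <- simulation_config(cond_median(), mat40, geometry_from_mvf(f),
                            n_trajectories = 30L, seed = 11)
    ensemble_localization(simulate_ensemble(cfg), "binding")
  })
  expect_true(all(diff(loc) > 0))
})

test_that("slow-elongating genes stay localized regardless of MVF", {
  # TIM50-like kinetics: long mature exposure, many competent MTSs
  mat40 <- competence_model("maturation", tau_MTS = 40)
  tim <- gene_kinetics(0.1264, 4, 476, name = "TIM50-like")
  loc <- sapply(c(0.01, 0.15), function(f) {
    cfg <- simulation_config(tim, mat40, geometry_from_mvf(f),
                            n_trajectories = 25L, seed = 13)
    ensemble_localization(simulate_ensemble(cfg), "binding")
  })
  expect_true(all(loc > 0.6))
  expect_lt(loc[2] - loc[1], 0.25)
})

test_that("faster elongation lowers localization at fixed initiation", {
  inst <- competence_model("instantaneous")
  loc <- sapply(c(2, 6, 18), function(ke) {
    g <- gene_kinetics(0.02, ke, 400)
    cfg <- simulation_config(g, inst, geom04(), n_trajectories = 30L,
                            seed = 19)
    ensemble_localization(simulate_ensemble(cfg), "binding")
  })
  expect_true(all(diff(loc) < 0))
})

test_that("sweep returns one row per value and flags inadmissible ones", {
  cfg <- simulation_config(gene_kinetics(0.1, 5, 80),
                           competence_model("instantaneous"), geom04(),
                           k_decay = 0, n_trajectories = 4L, seed = 29,
                           max_time = 400)
  sw <- sweep_localization(cfg, "mvf", c(0.02, 0.08, 0.9))
  expect_equal(nrow(sw), 3L)
  expect_true(is.na(sw$loc_binding[3]))
  expect_match(sw$note[3], "region 3")
  # never-competent localization tracks the (increasing) area fraction
  expect_gt(sw$loc_binding[2], sw$loc_binding[1])
})
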