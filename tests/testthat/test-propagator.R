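test_that("the MVF maps to the outer radius through accessible volume", {
  expect_equal(geometry_from_mvf(0.04)$R_out, 0.350 / sqrt(0.05),
               tolerance = 1e-12)
  expect_equal(geometry_from_mvf(0.04)$R_out, 1.5652, tolerance = 1e-4)
  expect_equal(geometry_from_mvf(0.01)$R_out, 3.1305, tolerance = 1e-4)
  # region 3 must retain positive width
  f_crit <- 0.8 * (0.350 / 0.600)^2
  expect_error(geometry_from_mvf(f_crit), "region 3")
  expect_error(geometry_from_mvf(0.5), "region 3")
  expect_error(cylinder_geometry(R_out = 0.62, eps = 0.05), "eps")
})

test_that("spectral means equal the exact annulus mean first-passage times", {
  geom <- geom04()
  prop <- mito_propagator(geom)
  r0 <- geom$r_a - geom$eps
  m1 <- mitoloc:::spectral_mean(prop$modes1$lambda,
                                mitoloc:::survival_coefs(prop$modes1, r0))
  expect_equal(m1, mitoloc:::mfpt_absorb_outer(r0, geom$r_m,
                                               geom$r_a + geom$eps, geom$D),
               tolerance = 1e-6)
  r3 <- geom$r_b + geom$eps
  m3 <- mitoloc:::spectral_mean(prop$modes3$lambda,
                                mitoloc:::survival_coefs(prop$modes3, r3))
  expect_equal(m3, mitoloc:::mfpt_absorb_inner(r3, geom$r_b - geom$eps,
                                               geom$R_out, geom$D),
               tolerance = 1e-4)
})

test_that("splitting probabilities follow the logarithmic formula", {
  geom <- geom04()
  # entry from region 1: boundaries 0.365 / 0.610, start 0.385
  expect_equal(region2_split_probability(geom, geom$r_a + geom$eps),
               0.8961, tolerance = 1e-4)
  # log-midpoint start splits evenly
  mid <- sqrt((geom$r_a - geom$eps) * (geom$r_b + geom$eps))
  expect_equal(region2_split_probability(geom, mid), 0.5, tolerance = 1e-12)
  # complementary exits sum to one exactly
  r0 <- 0.5
  p_in <- region2_split_probability(geom, r0)
  p_out <- log(r0 / (geom$r_a - geom$eps)) /
    log((geom$r_b + geom$eps) / (geom$r_a - geom$eps))
  expect_equal(p_in + p_out, 1, tolerance = 1e-12)
  # empirical exit sides agree
  prop <- mito_propagator(geom)
  set.seed(88)
  tr <- sample_region2_transit(prop, "inner", 4000)
  p_hat <- mean(tr$exit_side == "inner")
  expect_within_se(p_hat, 0.8961, sqrt(0.8961 * 0.1039 / 4000))
})

test_that("sampled first-passage times reproduce the spectral distributions", {
  geom <- geom04()
  prop <- mito_propagator(geom)
  set.seed(90)
  # region 1: mean and survival checkpoints
  x1 <- sample_region1_exit(prop, 10000)
  expect_true(all(x1 > 0))
  mu1 <- mitoloc:::mfpt_absorb_outer(geom$r_a - geom$eps, geom$r_m,
                                     geom$r_a + geom$eps, geom$D)
  expect_within_se(mean(x1), mu1, sd(x1) / sqrt(length(x1)))
  coefs <- mitoloc:::survival_coefs(prop$modes1, geom$r_a - geom$eps)
  qs <- quantile(x1, seq(0.05, 0.95, by = 0.1))
  S_theory <- mitoloc:::spectral_survival(prop$modes1$lambda, coefs, qs)
  S_emp <- sapply(qs, function(q) mean(x1 > q))
  for (j in seq_along(qs))
    expect_within_se(S_emp[j], S_theory[j],
                     sqrt(S_theory[j] * (1 - S_theory[j]) / length(x1)))
  # region 3 from both entries: means against the exact MFPT
  x3i <- sample_region3_return(prop, "inner_edge", 20000)
  mu3i <- mitoloc:::mfpt_absorb_inner(geom$r_b + geom$eps,
                                      geom$r_b - geom$eps, geom$R_out,
                                      geom$D)
  expect_within_se(mean(x3i), mu3i, sd(x3i) / sqrt(length(x3i)))
  x3o <- sample_region3_return(prop, "outer_wall", 20000)
  mu3o <- mitoloc:::mfpt_absorb_inner(geom$R_out, geom$r_b - geom$eps,
                                      geom$R_out, geom$D)
  expect_within_se(mean(x3o), mu3o, sd(x3o) / sqrt(length(x3o)))
  expect_gt(mu3o, mu3i)
  expect_gt(mean(x3o), mean(x3i))
})

test_that("samplers agree with the Euler-Maruyama oracle", {
  geom <- geom04()
  prop <- mito_propagator(geom)
  # region 1 exit
  sde1 <- sde_first_passage(2000, geom$r_a - geom$eps, geom$r_m,
                            geom$r_a + geom$eps, "reflecting", "absorbing",
                            D = geom$D, dt = 1e-7, seed = 91)
  set.seed(92)
  x1 <- sample_region1_exit(prop, 10000)
  se <- sqrt(var(sde1$time) / nrow(sde1) + var(x1) / length(x1))
  expect_within_se(mean(x1), mean(sde1$time), se)
  # region 2: splitting and conditional means
  sde2 <- sde_first_passage(2500, geom$r_a + geom$eps, geom$r_a - geom$eps,
                            geom$r_b + geom$eps, "absorbing", "absorbing",
                            D = geom$D, dt = 5e-7, seed = 93)
  p_exact <- region2_split_probability(geom, geom$r_a + geom$eps)
  expect_within_se(mean(sde2$side == 1), p_exact,
                   sqrt(p_exact * (1 - p_exact) / nrow(sde2)))
  set.seed(94)
  tr <- sample_region2_transit(prop, "inner", 20000)
  for (side in c(1, 2)) {
    lbl <- c("inner", "outer")[side]
    a <- sde2$time[sde2$side == side]
    b <- tr$time[tr$exit_side == lbl]
    expect_within_se(mean(b), mean(a),
                     sqrt(var(a) / length(a) + var(b) / length(b)))
  }
})

test_that("unbinding radii are area-uniform over the binding annulus", {
  geom <- geom04()
  set.seed(95)
  r <- sample_unbinding_position(geom, 2e5)
  expect_true(all(r >= geom$r_m & r <= geom$r_a))
  mu <- (2 / 3) * (geom$r_a^3 - geom$r_m^3) / (geom$r_a^2 - geom$r_m^2)
  expect_equal(mu, 0.36265, tolerance = 1e-4)
  expect_within_se(mean(r), mu, sd(r) / sqrt(length(r)))
  # goodness of fit against the closed-form CDF at alpha = 0.01
  cdf <- function(q) (q^2 - geom$r_m^2) / (geom$r_a^2 - geom$r_m^2)
  ks <- suppressWarnings(ks.test(r, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("shrinking the buffer shrinks the region-1 exit time", {
  means <- sapply(c(0.004, 0.008, 0.012), function(e) {
    g <- cylinder_geometry(R_out = 1.5652, eps = e)
    m <- radial_modes(g$r_m, g$r_a + e, "reflecting", "absorbing", g$D,
                      n_modes = 60L)
    mitoloc:::spectral_mean(m$lambda,
                            mitoloc:::survival_coefs(m, g$r_a - e))
  })
  expect_true(all(diff(means) > 0))
})

test_that("area-averaged region-3 first passage matches the search-time formula", {
  geom <- geom04()
  prop <- mito_propagator(geom)
  a <- geom$r_b - geom$eps; b <- geom$R_out
  # deterministic: area average of the exact MFPT equals the closed form
  avg <- integrate(function(r)
    mitoloc:::mfpt_absorb_inner(r, a, b, geom$D) * 2 * r / (b^2 - a^2),
    a, b)$value
  expect_equal(avg, mean_search_time(a, b, geom$D), tolerance = 1e-8)
  # stochastic: FPTs from area-uniform starts
  set.seed(96)
  r0 <- sqrt(a^2 + runif(1500) * (b^2 - a^2))
  t <- vapply(r0, function(r)
    mitoloc:::sample_fpt_bisect(prop$modes3, r, r - a, 1L), numeric(1))
  expect_within_se(mean(t), mean_search_time(a, b, geom$D),
                   sd(t) / sqrt(length(t)))
})

test_that("search times bracket the two gene groups across geometries", {
  for (f_m in c(0.01, 0.04, 0.15)) {
    geom <- geometry_from_mvf(f_m)
    a <- geom$r_b - geom$eps; b <- geom$R_out
    m3 <- mito_propagator(geom)$modes3
    # spectral area-average vs closed form at each geometry
    avg <- integrate(function(r) {
      sapply(r, function(ri)
        mitoloc:::spectral_mean(m3$lambda,
                                mitoloc:::survival_coefs(m3, ri))) *
        2 * r / (b^2 - a^2)
    }, a, b, subdivisions = 50)$value
    expect_equal(avg, mean_search_time(a, b, geom$D), tolerance = 1e-3)
  }
})
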