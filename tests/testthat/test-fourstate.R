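test_that("steady state matches the generator null space on random rates", {
  set.seed(101)
  for (i in 1:200) {
    k <- exp(runif(4, log(1e-3), log(1e3)))
    ss <- steady_state(four_state_rates(k[1], k[2], k[3], k[4]))
    oracle <- fourstate_null_space(k[1], k[2], k[3], k[4])
    expect_equal(c(ss$p_SN, ss$p_SF, ss$p_UN, ss$p_UF), unname(oracle),
                 tolerance = 1e-10)
    expect_equal(ss$p_SN + ss$p_SF + ss$p_UN + ss$p_UF, 1,
                 tolerance = 1e-12)
  }
})

test_that("symmetric rates give the known stationary distribution", {
  ss <- steady_state(four_state_rates(1, 1, 1, 1))
  expect_equal(c(ss$p_SN, ss$p_SF, ss$p_UN, ss$p_UF),
               c(0.4, 0.1, 0.3, 0.2), tolerance = 1e-12)
  expect_equal(localized_fraction(four_state_rates(1, 1, 1, 1)), 0.7,
               tolerance = 1e-12)
})

test_that("a never-sticky mRNA equilibrates spatially", {
  # k_S = 0: both sticky states empty, localization is the volume fraction
  ss <- steady_state(four_state_rates(0, 1, 1, 1))
  expect_equal(ss$p_SN, 0)
  expect_equal(ss$p_SF, 0)
  expect_equal(ss$p_SN + ss$p_UN, 0.5, tolerance = 1e-12)
})

test_that("a permanently sticky mRNA ends bound", {
  r <- four_state_rates(1e9, 1, 1, 1)
  expect_gt(localized_fraction(r), 0.999)
})

test_that("degenerate absorbing rates are rejected with a clear error", {
  expect_error(steady_state(four_state_rates(1, 0, 1, 1)), "absorbing")
  expect_error(steady_state(four_state_rates(1, 1, 1, 0)), "absorbing")
})

test_that("transport limits reduce to their closed forms", {
  expect_equal(limit_rapid_transport(0.5, 0.5), 0.75)
  expect_equal(limit_rapid_transport(1, 0.3), 1)
  expect_equal(limit_rapid_transport(0, 0.3), 0.3)
  expect_equal(limit_slow_transport(0.5, 0.5), 2 / 3)
  expect_equal(limit_slow_transport(1, 0.3), 1)
  # low proximal volume kills localization only in the slow regime
  expect_equal(limit_slow_transport(0.7, 0), 0)
  expect_lt(limit_slow_transport(0.7, 1e-4), 1e-3)
  expect_gt(limit_rapid_transport(0.7, 1e-4), 0.69)
  expect_error(limit_rapid_transport(1.2, 0.5), "0, 1")
})

test_that("localized fraction approaches each limit in its regime", {
  # switching and transport rates drawn on a common O(1) scale so that a
  # 10^3 scale separation realizes each limiting regime
  for (i in 1:50) {
    set.seed(200 + i)
    kS <- exp(runif(1, log(0.5), log(2)))
    kU <- exp(runif(1, log(0.5), log(2)))
    kR <- exp(runif(1, log(0.5), log(2)))
    kL <- exp(runif(1, log(0.5), log(2)))
    f_s <- kS / (kS + kU)
    f_d <- kR / (kR + kL)
    rapid <- localized_fraction(four_state_rates(kS, kU, 1e3 * kR, 1e3 * kL))
    slow <- localized_fraction(four_state_rates(kS, kU, 1e-3 * kR, 1e-3 * kL))
    expect_lt(abs(rapid - limit_rapid_transport(f_s, f_d)), 1e-2)
    expect_lt(abs(slow - limit_slow_transport(f_s, f_d)), 1e-2)
  }
})

test_that("localization is monotone in stickiness and in arrival rate", {
  kS_grid <- c(0.01, 0.1, 1, 10, 100)
  loc_S <- sapply(kS_grid, function(k)
    localized_fraction(four_state_rates(k, 1, 0.5, 2)))
  expect_true(all(diff(loc_S) >= -1e-12))
  loc_R <- sapply(kS_grid, function(k)
    localized_fraction(four_state_rates(0.7, 1, k, 2)))
  expect_true(all(diff(loc_R) >= -1e-12))
})

test_that("the CTMC oracle converges to the analytic steady state", {
  r <- four_state_rates(1, 1, 1, 1)
  sim <- simulate_ctmc(r, duration = 2e4, seed = 7)
  ss <- steady_state(r)
  target <- c(ss$p_SN, ss$p_SF, ss$p_UN, ss$p_UF)
  for (j in 1:4)
    expect_within_se(sim$occupancy[j], target[j], sim$se[j])
  # never-sticky chain has empty sticky states
  sim0 <- simulate_ctmc(four_state_rates(0, 1, 1, 1), 1e3, seed = 8)
  expect_equal(unname(sim0$occupancy[c("SN", "SF")]), c(0, 0))
  # reproducibility
  sim_b <- simulate_ctmc(r, duration = 2e4, seed = 7)
  expect_identical(sim$occupancy, sim_b$occupancy)
})
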