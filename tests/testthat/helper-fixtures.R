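# shared fixtures: group-median genes, default geometry, comparison helpers

cond_median <- function() gene_kinetics(0.3253, 14.5086, 393,
                                        name = "conditional-median")
cons_median <- function() gene_kinetics(0.1259, 7.7468, 483,
                                        name = "constitutive-median")

geom04 <- function() geometry_from_mvf(0.04)

# |x - y| within z standard errors
expect_within_se <- function(x, y, se, z = 3) {
  expect_lt(abs(x - y), z * se + 1e-12)
}

# brute-force stationary distribution of the four-state chain: null space
# of the explicitly assembled generator matrix (independent oracle)
fourstate_null_space <- function(kS, kU, kR, kL) {
  # state order: SN, SF, UN, UF; Q[i, j] = rate i -> j
  Q <- matrix(0, 4, 4)
  Q[1, 3] <- kU                      # SN -> UN (no SN -> SF)
  Q[2, 4] <- kU; Q[2, 1] <- kR      # SF -> UF, SF -> SN
  Q[3, 1] <- kS; Q[3, 4] <- kL      # UN -> SN, UN -> UF
  Q[4, 2] <- kS; Q[4, 3] <- kR      # UF -> SF, UF -> UN
  diag(Q) <- -rowSums(Q)
  ns <- svd(t(Q))$v[, 4]            # x with t(Q) x = 0, i.e. pi Q = 0
  p <- ns / sum(ns)
  names(p) <- c("SN", "SF", "UN", "UF")
  p
}
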