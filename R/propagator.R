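# Exact first-passage sampling for radially symmetric diffusion in the
# concentric-cylinder geometry.
#
# The axial coordinate never changes region membership, so the problem is
# 2-D radial diffusion in the cross-sectional plane.  For each region the
# radial diffusion operator D (1/r) d/dr (r d/dr) on [a, b] with a
# reflecting or absorbing condition at each end is expanded in Bessel
# eigenfunctions phi_n(r) = J0(k_n r) C_n - Y0(k_n r) D_n.  Survival
# functions, exit-side splitting fluxes and first-passage densities are
# spectral sums sum_n c_n exp(-D k_n^2 t); sampling inverts the survival
# function.  The fixed-step Euler-Maruyama integrator (.sde_fpt_cpp) is
# the independent oracle.

# ---- eigensystem -----------------------------------------------------------

# basis coefficients enforcing the boundary condition at `a`
mode_basis <- function(k, a, bc_a) {
  if (bc_a == "absorbing") list(C = besselY(k * a, 0), D = besselJ(k * a, 0))
  else                     list(C = besselY(k * a, 1), D = besselJ(k * a, 1))
}

phi_eval <- function(r, k, C, D) {
  besselJ(outer(r, k), 0) * rep(C, each = length(r)) -
    besselY(outer(r, k), 0) * rep(D, each = length(r))
}

dphi_eval <- function(r, k, C, D) {
  -(besselJ(outer(r, k), 1) * rep(C, each = length(r)) -
      besselY(outer(r, k), 1) * rep(D, each = length(r))) *
    rep(k, each = length(r))
}

#' Bessel eigensystem of a radial annulus
#'
#' Computes the eigenvalues and eigenfunctions of radial diffusion on
#' `[a, b]` with reflecting or absorbing boundaries, by bracketing sign
#' changes of the boundary determinant on a fine wavenumber grid and
#' refining each root with bisection ([stats::uniroot()]).
#'
#' @param a,b inner and outer radii (um), `0 < a < b`.
#' @param bc_a,bc_b `"reflecting"` or `"absorbing"`.
#' @param D diffusivity (um^2/s).
#' @param n_modes number of eigenmodes retained.
#' @return an object of class `radial_modes`: eigen-wavenumbers `k`,
#'   decay rates `lambda = D k^2`, basis coefficients, norms
#'   `N_n = int r phi_n^2 dr`, overlaps `B_n = int r phi_n dr`, and the
#'   boundary derivatives `dphi_a`, `dphi_b`.
#' @keywords internal
#' @export
radial_modes <- function(a, b, bc_a, bc_b, D, n_modes = 120L) {
  stopifnot(a > 0, b > a, D > 0)
  bc_a <- match.arg(bc_a, c("reflecting", "absorbing"))
  bc_b <- match.arg(bc_b, c("reflecting", "absorbing"))
  if (bc_a == "reflecting" && bc_b == "reflecting")
    stop("at least one boundary must be absorbing", call. = FALSE)

  gfun <- function(k) {
    bs <- mode_basis(k, a, bc_a)
    if (bc_b == "absorbing")
      besselJ(k * b, 0) * bs$C - besselY(k * b, 0) * bs$D
    else
      besselJ(k * b, 1) * bs$C - besselY(k * b, 1) * bs$D
  }

  # asymptotic spacing pi/(b - a); scan finely enough to catch every root
  dk <- pi / (b - a) / 16
  k_hi <- (n_modes + 2) * pi / (b - a) + 20 * dk
  grid <- seq(dk / 10, k_hi, by = dk)
  gv <- vapply(grid, gfun, numeric(1))
  sgn <- which(gv[-1] * gv[-length(gv)] < 0)
  roots <- numeric(0)
  for (i in sgn) {
    r <- uniroot(gfun, lower = grid[i], upper = grid[i + 1],
                 tol = .Machine$double.eps^0.75)$root
    roots <- c(roots, r)
    if (length(roots) >= n_modes) break
  }
  if (length(roots) < n_modes)
    stop("eigenvalue search found too few modes", call. = FALSE)
  k <- roots[seq_len(n_modes)]
  bs <- mode_basis(k, a, bc_a)

  # norms and overlaps by composite Simpson quadrature
  m <- 2L * max(2048L, 16L * n_modes) + 1L
  r <- seq(a, b, length.out = m)
  h <- (b - a) / (m - 1)
  w <- rep(c(2, 4), length.out = m); w[1] <- w[m] <- 1
  w <- w * h / 3
  phim <- phi_eval(r, k, bs$C, bs$D)          # m x n_modes
  Nn <- as.numeric(crossprod(phim^2, w * r))
  Bn <- as.numeric(crossprod(phim, w * r))

  structure(
    list(a = a, b = b, bc_a = bc_a, bc_b = bc_b, D = D,
         k = k, lambda = D * k^2, C = bs$C, Dc = bs$D,
         Nn = Nn, Bn = Bn,
         dphi_a = as.numeric(dphi_eval(a, k, bs$C, bs$D)),
         dphi_b = as.numeric(dphi_eval(b, k, bs$C, bs$D))),
    class = "radial_modes")
}

# eigenfunction values at a start radius
modes_phi_at <- function(modes, r0) {
  as.numeric(phi_eval(r0, modes$k, modes$C, modes$Dc))
}

# survival-series coefficients for a start at r0: S(t) = sum c exp(-lambda t)
survival_coefs <- function(modes, r0) {
  modes_phi_at(modes, r0) * modes$Bn / modes$Nn
}

# exit-rate series coefficients at each absorbing boundary:
# J_side(t) = sum q exp(-lambda t);  P_side = sum q / lambda
flux_coefs <- function(modes, r0) {
  base <- modes_phi_at(modes, r0) / modes$Nn * modes$D
  list(inner = base * modes$a * modes$dphi_a,
       outer = -base * modes$b * modes$dphi_b)
}

spectral_survival <- function(lambda, coefs, t) {
  s <- drop(exp(-outer(t, lambda)) %*% coefs)
  pmin(pmax(s, 0), 1)
}

# mean of the FPT distribution sum c exp(-lambda t): integral of survival
spectral_mean <- function(lambda, coefs) sum(coefs / lambda)

# ---- closed-form annulus mean first-passage times (cross-checks) ----------

# MFPT from r0 with absorbing inner boundary a and reflecting outer b
mfpt_absorb_inner <- function(r0, a, b, D) {
  (b^2 / (2 * D)) * log(r0 / a) - (r0^2 - a^2) / (4 * D)
}

# MFPT from r0 with reflecting inner boundary a and absorbing outer b
mfpt_absorb_outer <- function(r0, a, b, D) {
  (b^2 - r0^2) / (4 * D) + (a^2 / (2 * D)) * log(r0 / b)
}

# ---- survival inversion ----------------------------------------------------

# Tabulated inverse of a spectral survival function for repeated sampling
# from a fixed start.  `d_near` is the distance from the start to the
# relevant absorbing boundary, used for the small-time half-space tail
# t = d^2 / (4 D erfinv(u)^2).
make_fpt_table <- function(lambda, coefs, D, d_near, n_grid = 500L) {
  total <- sum(coefs)               # 1 up to truncation defect
  t_min <- 5 / max(lambda)
  t_max <- max(log(max(total, 1e-12) / 1e-9) / min(lambda), t_min * 10)
  tg <- exp(seq(log(t_min), log(t_max), length.out = n_grid))
  Sg <- spectral_survival(lambda, coefs, tg)
  # enforce strict monotone decrease in t for invertibility
  Sg <- rev(cummax(rev(Sg)))
  keep <- c(TRUE, diff(Sg) < 0)
  tg <- tg[keep]; Sg <- Sg[keep]
  m <- length(tg)
  list(S_incr = rev(Sg), logt_incr = rev(log(tg)),   # increasing in S
       lambda1 = min(lambda),
       S_head = Sg[1], S_tail = Sg[m], t_tail = tg[m],
       D = D, d_near = d_near)
}

sample_fpt_table <- function(tbl, n, u = runif(n)) {
  t <- numeric(length(u))
  head_idx <- u >= tbl$S_head
  tail_idx <- u <= tbl$S_tail
  mid <- !(head_idx | tail_idx)
  if (any(head_idx))  # very short times: half-space approximation
    t[head_idx] <- tbl$d_near^2 / (4 * tbl$D * erfinv(u[head_idx])^2)
  if (any(tail_idx))  # deep tail: slowest-mode exponential
    t[tail_idx] <- tbl$t_tail +
      log(tbl$S_tail / pmax(u[tail_idx], 1e-300)) / tbl$lambda1
  if (any(mid))
    t[mid] <- exp(approx(x = tbl$S_incr, y = tbl$logt_incr, xout = u[mid],
                         ties = "ordered")$y)
  t
}

# Direct bisection inversion for a one-off start radius (used after
# unbinding, where r0 is freshly sampled each time).
sample_fpt_bisect <- function(modes, r0, d_near, n = 1L, u = runif(n),
                              rel_tol = 1e-9) {
  coefs <- survival_coefs(modes, r0)
  lambda <- modes$lambda
  t_lo0 <- 5 / max(lambda)
  vapply(u, function(ui) {
    if (spectral_survival(lambda, coefs, t_lo0) <= ui)
      return(d_near^2 / (4 * modes$D * erfinv(ui)^2))
    lo <- t_lo0
    hi <- lo * 2
    while (spectral_survival(lambda, coefs, hi) > ui) hi <- hi * 2
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (spectral_survival(lambda, coefs, mid) > ui) lo <- mid else hi <- mid
      if ((hi - lo) < rel_tol * lo) break
    }
    sqrt(lo * hi)
  }, numeric(1))
}

# ---- per-geometry propagator (cached) --------------------------------------

.propagator_cache <- new.env(parent = emptyenv())

geometry_key <- function(geom) {
  paste(format(c(geom$r_m, geom$r_a, geom$r_b, geom$R_out, geom$eps,
                 geom$D), digits = 15), collapse = "|")
}

#' Build (and cache) the first-passage propagator for a geometry
#'
#' Precomputes the Bessel eigensystems of the three diffusion regions and
#' tabulated inverse survival functions for the fixed entry positions:
#' region 1 entered at `r_a - eps` (reflecting at `r_m`, absorbing at
#' `r_a + eps`); region 2 entered at `r_a + eps` or `r_b - eps`
#' (absorbing at `r_a - eps` and `r_b + eps`), with exit-side-conditioned
#' first-passage tables; region 3 entered at `r_b + eps` or at the outer
#' wall `R_out` (absorbing at `r_b - eps`, reflecting at `R_out`).
#' Results are cached per geometry.
#'
#' @param geom a [cylinder_geometry()].
#' @param n_modes eigenmodes per region.
#' @return an object of class `mito_propagator`.
#' @export
mito_propagator <- function(geom, n_modes = 120L) {
  stopifnot(inherits(geom, "cylinder_geometry"))
  key <- paste0(geometry_key(geom), "#", n_modes)
  hit <- .propagator_cache[[key]]
  if (!is.null(hit)) return(hit)

  eps <- geom$eps; D <- geom$D
  m1 <- radial_modes(geom$r_m, geom$r_a + eps, "reflecting", "absorbing",
                     D, n_modes)
  m2 <- radial_modes(geom$r_a - eps, geom$r_b + eps, "absorbing",
                     "absorbing", D, n_modes)
  m3 <- radial_modes(geom$r_b - eps, geom$R_out, "absorbing", "reflecting",
                     D, n_modes)

  # region 1: entry at r_a - eps
  r1_entry <- geom$r_a - eps
  tab1 <- make_fpt_table(m1$lambda, survival_coefs(m1, r1_entry), D,
                         (geom$r_a + eps) - r1_entry)

  # region 2: conditional exit tables from both entry points
  split2 <- function(r0) {
    log((geom$r_b + eps) / r0) / log((geom$r_b + eps) / (geom$r_a - eps))
  }
  cond_tables <- function(r0) {
    fx <- flux_coefs(m2, r0)
    p_in <- spectral_mean(m2$lambda, fx$inner)   # sum q/lambda
    p_out <- spectral_mean(m2$lambda, fx$outer)
    list(
      p_inner_spectral = p_in, p_outer_spectral = p_out,
      p_inner = split2(r0),
      inner = make_fpt_table(m2$lambda, fx$inner / m2$lambda / p_in, D,
                             r0 - (geom$r_a - eps)),
      outer = make_fpt_table(m2$lambda, fx$outer / m2$lambda / p_out, D,
                             (geom$r_b + eps) - r0))
  }
  r2_in <- cond_tables(geom$r_a + eps)
  r2_out <- cond_tables(geom$r_b - eps)

  # region 3: entries at r_b + eps and at the outer wall
  tab3_inner <- make_fpt_table(m3$lambda,
                               survival_coefs(m3, geom$r_b + eps), D,
                               (geom$r_b + eps) - (geom$r_b - eps))
  tab3_outer <- make_fpt_table(m3$lambda,
                               survival_coefs(m3, geom$R_out), D,
                               geom$R_out - (geom$r_b - eps))

  prop <- structure(
    list(geom = geom, modes1 = m1, modes2 = m2, modes3 = m3,
         tab1 = tab1, r2_from_inner = r2_in, r2_from_outer = r2_out,
         tab3_inner = tab3_inner, tab3_outer = tab3_outer),
    class = "mito_propagator")
  .propagator_cache[[key]] <- prop
  prop
}

as_propagator <- function(x) {
  if (inherits(x, "mito_propagator")) x else mito_propagator(x)
}

# ---- user-facing samplers --------------------------------------------------

#' Sample the exit time from region 1 (unbound)
#'
#' First-passage time for an mRNA entering the binding region at
#' `r_a - eps` (or starting from `r0`) to reach the absorbing boundary at
#' `r_a + eps`, with the mitochondrial surface `r_m` reflecting.
#'
#' @param x a [cylinder_geometry()] or [mito_propagator()].
#' @param n number of samples.
#' @param r0 optional start radius in `[r_m, r_a]`; default is the entry
#'   position `r_a - eps`.
#' @return times (s).
#' @export
sample_region1_exit <- function(x, n = 1L, r0 = NULL) {
  prop <- as_propagator(x)
  g <- prop$geom
  if (is.null(r0))
    return(sample_fpt_table(prop$tab1, n))
  stopifnot(r0 >= g$r_m, r0 < g$r_a + g$eps)
  sample_fpt_bisect(prop$modes1, r0, (g$r_a + g$eps) - r0, n)
}

#' Sample a transit through region 2
#'
#' Draws the exit side from the logarithmic splitting probability
#' `P(inner | r0) = ln(r_out/r0) / ln(r_out/r_in)` (with absorbing radii
#' `r_in = r_a - eps`, `r_out = r_b + eps`) and a first-passage time from
#' the exit-side-conditioned distribution.
#'
#' @inheritParams sample_region1_exit
#' @param entry_side `"inner"` (entered from region 1, start `r_a + eps`)
#'   or `"outer"` (entered from region 3, start `r_b - eps`).
#' @return a data.frame with columns `exit_side` (`"inner"`/`"outer"`)
#'   and `time` (s).
#' @export
sample_region2_transit <- function(x, entry_side = c("inner", "outer"),
                                   n = 1L) {
  prop <- as_propagator(x)
  entry_side <- match.arg(entry_side)
  ct <- if (entry_side == "inner") prop$r2_from_inner else prop$r2_from_outer
  to_inner <- runif(n) < ct$p_inner
  time <- numeric(n)
  if (any(to_inner))
    time[to_inner] <- sample_fpt_table(ct$inner, sum(to_inner))
  if (any(!to_inner))
    time[!to_inner] <- sample_fpt_table(ct$outer, sum(!to_inner))
  data.frame(exit_side = ifelse(to_inner, "inner", "outer"), time = time,
             stringsAsFactors = FALSE)
}

#' Splitting probability of region 2
#'
#' Probability that a particle started at `r0` inside the annulus with
#' absorbing radii `r_a - eps` and `r_b + eps` exits through the inner
#' boundary.
#'
#' @inheritParams sample_region1_exit
#' @param r0 start radius.
#' @export
region2_split_probability <- function(x, r0) {
  g <- if (inherits(x, "mito_propagator")) x$geom else x
  r_in <- g$r_a - g$eps; r_out <- g$r_b + g$eps
  stopifnot(r0 > r_in, r0 < r_out)
  log(r_out / r0) / log(r_out / r_in)
}

#' Sample the return time through region 3
#'
#' First-passage time to the absorbing boundary `r_b - eps` for an mRNA
#' entering region 3 at `r_b + eps` (`"inner_edge"`) or placed at the
#' reflecting outer wall `R_out` (`"outer_wall"`, as after nuclear
#' export).
#'
#' @inheritParams sample_region1_exit
#' @param start `"inner_edge"` or `"outer_wall"`.
#' @return times (s).
#' @export
sample_region3_return <- function(x, start = c("inner_edge", "outer_wall"),
                                  n = 1L) {
  prop <- as_propagator(x)
  start <- match.arg(start)
  tbl <- if (start == "inner_edge") prop$tab3_inner else prop$tab3_outer
  sample_fpt_table(tbl, n)
}

#' Sample the radial position after unbinding
#'
#' When a bound mRNA loses its last competent MTS it is released at a
#' random radius in `[r_m, r_a]` with density proportional to `r`
#' (uniform over the annular area), i.e. CDF
#' `(r^2 - r_m^2) / (r_a^2 - r_m^2)`.
#'
#' @inheritParams sample_region1_exit
#' @return radii (um).
#' @export
sample_unbinding_position <- function(x, n = 1L) {
  g <- if (inherits(x, "mito_propagator")) x$geom else x
  sqrt(g$r_m^2 + runif(n) * (g$r_a^2 - g$r_m^2))
}

#' Euler-Maruyama first-passage oracle
#'
#' Fixed-step integration of the radial SDE `dr = (D/r) dt + sqrt(2D) dW`
#' with reflecting/absorbing boundary handling.  Slow but assumption-free;
#' used to validate the spectral samplers.
#'
#' @param n number of walkers.
#' @param r0 start radius (um).
#' @param a,b inner and outer radii (um).
#' @param bc_a,bc_b `"reflecting"` or `"absorbing"`.
#' @param D diffusivity (um^2/s).
#' @param dt time step (s).
#' @param max_time censoring horizon (s).
#' @param seed integer RNG seed.
#' @return a data.frame with `time` and `side` (1 = absorbed at `a`,
#'   2 = absorbed at `b`, 0 = censored at `max_time`).
#' @export
sde_first_passage <- function(n, r0, a, b, bc_a = "reflecting",
                              bc_b = "absorbing", D = 0.1, dt = 1e-5,
                              max_time = Inf, seed = NULL) {
  bc_a <- match.arg(bc_a, c("reflecting", "absorbing"))
  bc_b <- match.arg(bc_b, c("reflecting", "absorbing"))
  if (!is.null(seed)) set.seed(seed)
  .sde_fpt_cpp(as.integer(n), r0, a, b,
               as.integer(bc_a == "absorbing"),
               as.integer(bc_b == "absorbing"), D, dt,
               if (is.finite(max_time)) max_time else 1e12)
}
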