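# Concentric-cylinder geometry of the mitochondrial neighbourhood.
#
# The cytoplasm around one mitochondrial tubule is modelled as nested
# cylinders (cross-section: nested circles).  Region 1 (r_m < r < r_a) is
# close enough for a competent mRNA to bind; region 2 (r_a < r < r_b)
# appears mitochondrial in diffraction-limited imaging but cannot bind;
# region 3 (r_b < r < R_out) is the remaining cytosol.  The outer radius
# is reflecting: an mRNA wandering far from one tubule approaches another
# tubule of the network.

#' Concentric-cylinder geometry
#'
#' @param r_m mitochondrial tubule radius (um, default 0.350).
#' @param r_a binding-range radius (um, default `r_m + 0.025`): the ~25 nm
#'   reach of a ribosome (13-14 nm radius) plus an ~5 nm MTS helix and
#'   linker.
#' @param r_b imaging-range radius (um, default `r_m + 0.250`, the Abbe
#'   resolution limit).
#' @param R_out outer reflecting radius (um); usually derived from the
#'   mitochondrial volume fraction via [geometry_from_mvf()].
#' @param eps boundary buffer (um, default 0.010) keeping first-passage
#'   problems away from zero-width gaps.
#' @param D mRNA diffusivity (um^2/s, default 0.1).
#' @param f_m reported mitochondrial volume fraction (informational when
#'   `R_out` is given directly).
#' @param accessible_fraction fraction of cell volume available to
#'   mitochondria and cytosol (default 0.8; the rest is nucleus/vacuole).
#' @param V_cell reference cell volume (um^3, default 42, informational).
#' @return an object of class `cylinder_geometry`.
#' @export
cylinder_geometry <- function(r_m = 0.350, r_a = r_m + 0.025,
                              r_b = r_m + 0.250, R_out, eps = 0.010,
                              D = 0.1, f_m = NA_real_,
                              accessible_fraction = 0.8, V_cell = 42) {
  stop_if_not_scalar(r_m, "r_m", positive = TRUE)
  stop_if_not_scalar(r_a, "r_a", positive = TRUE)
  stop_if_not_scalar(r_b, "r_b", positive = TRUE)
  stop_if_not_scalar(R_out, "R_out", positive = TRUE)
  stop_if_not_scalar(eps, "eps", positive = TRUE)
  stop_if_not_scalar(D, "D", positive = TRUE)
  if (!(r_m < r_a && r_a < r_b && r_b < R_out))
    stop("radii must satisfy r_m < r_a < r_b < R_out", call. = FALSE)
  gaps <- c(r_a - r_m, r_b - r_a, R_out - r_b)
  if (any(eps >= gaps))
    stop("buffer `eps` must be smaller than every inter-radius gap",
         call. = FALSE)
  structure(
    list(r_m = r_m, r_a = r_a, r_b = r_b, R_out = R_out, eps = eps,
         D = D, f_m = f_m, accessible_fraction = accessible_fraction,
         V_cell = V_cell),
    class = "cylinder_geometry")
}

#' Geometry from a mitochondrial volume fraction
#'
#' Maps a reported mitochondrial volume fraction `f_m` to the outer
#' reflecting radius.  Only a fraction (default 80%) of the cell volume
#' is accessible to mitochondria and cytosol, so the simulated volume
#' fraction `(r_m/R_out)^2` is set to `f_m / accessible_fraction`, i.e.
#' `R_out = r_m / sqrt(f_m / accessible_fraction)`.
#'
#' @param f_m reported mitochondrial volume fraction (physiological range
#'   roughly 0.01-0.15).
#' @param ... overrides passed to [cylinder_geometry()] (`r_m`, `r_b`,
#'   `eps`, `D`, ...).
#' @inheritParams cylinder_geometry
#' @return a `cylinder_geometry`.
#' @examples
#' geometry_from_mvf(0.04)$R_out  # ~1.565 um
#' @export
geometry_from_mvf <- function(f_m, accessible_fraction = 0.8, ...) {
  stop_if_not_scalar(f_m, "f_m", positive = TRUE)
  dots <- list(...)
  r_m <- dots$r_m %||% 0.350
  r_b <- dots$r_b %||% (r_m + 0.250)
  if (f_m / accessible_fraction >= (r_m / r_b)^2)
    stop(sprintf(
      "f_m = %g too large: requires f_m/%g < (r_m/r_b)^2 = %.4g so that region 3 exists",
      f_m, accessible_fraction, (r_m / r_b)^2), call. = FALSE)
  R_out <- r_m / sqrt(f_m / accessible_fraction)
  args <- c(list(R_out = R_out, f_m = f_m,
                 accessible_fraction = accessible_fraction), dots)
  do.call(cylinder_geometry, args)
}

#' @export
print.cylinder_geometry <- function(x, ...) {
  cat("Concentric-cylinder geometry (um):\n")
  cat(sprintf("  r_m = %.4g, r_a = %.4g, r_b = %.4g, R_out = %.4g, eps = %.3g\n",
              x$r_m, x$r_a, x$r_b, x$R_out, x$eps))
  cat(sprintf("  D = %g um^2/s, reported MVF = %s\n", x$D,
              if (is.na(x$f_m)) "(direct R_out)" else format(x$f_m)))
  invisible(x)
}

# cross-sectional area fractions of the three cytosolic regions
region_area_fractions <- function(geom) {
  tot <- geom$R_out^2 - geom$r_m^2
  c(region1 = (geom$r_a^2 - geom$r_m^2) / tot,
    region2 = (geom$r_b^2 - geom$r_a^2) / tot,
    region3 = (geom$R_out^2 - geom$r_b^2) / tot)
}
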