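#' Isometric force under uniform CSA reduction
#'
#' First scenario of the geometric sarcomere force model: the whole sarcomere
#' cross-section shrinks, filament number falls in proportion, lattice spacing
#' and per-filament force are unchanged, so relative force is exactly `1 - f`.
#'
#' @param f CSA reduction fraction(s) in \[0, 1).
#' @return Relative isometric force F(f)/F(0).
#' @export
uniform_force <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1))
    stop("`f` must lie in [0, 1)")
  1 - f
}

#' Geometry of the heterogeneous-CSA force model
#'
#' The second scenario models a myofibril of circular cross-section whose CSA
#' tapers smoothly from the sarcomere center to the Z-disk while the filament
#' count stays constant. A filament at normalized radius x (fraction of the
#' bundle radius R) is displaced inward by Delta(x) = x * (1 - sqrt(1 - f)) * R
#' over an axial run h, following the chosen taper profile with zero slope at
#' the A-band end. Its insertion tilt at the Z-disk reduces its axial force by
#' cos(theta). `aspect` is rho_g = R / h.
#'
#' @param profile taper centerline shape: `"circular_arc"` (default; tilt
#'   theta = 2 * atan(Delta / h), the chord-tangent angle of an arc tangent to
#'   the axis at the A-band) or `"parabolic"` (theta = atan(2 * Delta / h)).
#' @param aspect bundle radius / taper axial length (rho_g), default 0.6.
#' @param n_radial number of radial quadrature samples (>= 1000).
#' @return An object of class `force_geometry`.
#' @export
force_geometry <- function(profile = c("circular_arc", "parabolic"),
                           aspect = 0.6, n_radial = 4001L) {
  profile <- match.arg(profile)
  if (!is.numeric(aspect) || aspect <= 0) stop("`aspect` must be positive")
  if (n_radial < 1000L) stop("`n_radial` must be at least 1000")
  structure(list(profile = profile, aspect = aspect, n_radial = as.integer(n_radial)),
            class = "force_geometry")
}

#' Z-disk insertion tilt of a filament at normalized radius x
#' @noRd
insertion_tilt <- function(x, f, geom) {
  c0 <- geom$aspect * (1 - sqrt(1 - f))   # Delta(x)/h = c0 * x
  switch(geom$profile,
         circular_arc = 2 * atan(c0 * x),
         parabolic    = atan(2 * c0 * x))
}

#' Isometric force under Z-disk-only CSA reduction
#'
#' Second scenario: only the Z-disk CSA is reduced by fraction `f` (Z-disk
#' radius ratio sqrt(1 - f)); filaments curve toward the axis and insert at
#' the Z-disk with tilt theta(x), so relative force is the uniform-density
#' radial integral of the axial component,
#' F(f) = integral_0^1 2 x cos(theta(x)) dx.
#'
#' @inheritParams uniform_force
#' @param geom a [force_geometry()].
#' @return Relative isometric force.
#' @export
heterogeneous_force <- function(f, geom = force_geometry()) {
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1))
    stop("`f` must lie in [0, 1)")
  # composite Simpson quadrature over the normalized radius
  n <- geom$n_radial
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(0, 1, length.out = n)
  w <- c(1, rep(c(4, 2), length.out = n - 2), 1) / 3 * (x[2] - x[1])
  vapply(f, function(fi) {
    th1 <- insertion_tilt(1, fi, geom)
    if (th1 >= pi / 2) stop("insertion tilt reaches 90 degrees: geometry infeasible")
    sum(w * 2 * x * cos(insertion_tilt(x, fi, geom)))
  }, numeric(1))
}

#' Closed-form relative force for the circular-arc taper
#'
#' For the circular-arc profile, cos(theta) = (1 - t^2)/(1 + t^2) with
#' t = q x and q = rho_g (1 - sqrt(1 - f)), giving
#' F(f) = (2 / q^2) * log(1 + q^2) - 1.
#'
#' @inheritParams heterogeneous_force
#' @return Relative isometric force (closed form).
#' @export
heterogeneous_force_closed <- function(f, geom = force_geometry()) {
  if (geom$profile != "circular_arc")
    stop("closed form available for the circular_arc profile only")
  q <- geom$aspect * (1 - sqrt(1 - f))
  ifelse(q == 0, 1, (2 / q^2) * log1p(q^2) - 1)
}

#' Force-reduction curves for both model scenarios
#'
#' @param f_grid vector of CSA reduction fractions in \[0, 1).
#' @inheritParams heterogeneous_force
#' @return A data.frame of class `force_curve` with columns `f`, `scenario`
#'   (`"uniform"` / `"heterogeneous"`), `relative_force`, `percent_loss`.
#' @export
force_curve <- function(f_grid = seq(0, 0.9, by = 0.05), geom = force_geometry()) {
  if (length(f_grid) == 0L) stop("empty `f` grid")
  u <- uniform_force(f_grid)
  h <- heterogeneous_force(f_grid, geom)
  out <- data.frame(
    f = rep(f_grid, 2L),
    scenario = rep(c("uniform", "heterogeneous"), each = length(f_grid)),
    relative_force = c(u, h))
  out$percent_loss <- 100 * (1 - out$relative_force)
  attr(out, "geometry") <- geom
  class(out) <- c("force_curve", "data.frame")
  out
}

#' @export
print.force_geometry <- function(x, ...) {
  cat(sprintf("<force_geometry> %s taper, aspect rho_g = R/h = %g\n",
              x$profile, x$aspect))
  invisible(x)
}

#' @export
plot.force_curve <- function(x, ...) {
  fu <- x[x$scenario == "uniform", ]
  fh <- x[x$scenario == "heterogeneous", ]
  graphics::plot(fu$f, fu$relative_force, type = "l", col = "grey40", lwd = 2,
                 xlab = "CSA reduction fraction f",
                 ylab = "relative isometric force", ylim = c(0, 1), ...)
  graphics::lines(fh$f, fh$relative_force, col = "steelblue", lwd = 2)
  graphics::legend("bottomleft", legend = c("uniform CSA", "Z-disk CSA only"),
                   col = c("grey40", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}
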