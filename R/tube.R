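# Quasi-static forward model: inflation-extension of an incompressible
# anisotropic thick-walled tube. Maps zero-pressure geometry + luminal
# pressure + axial stretch to the deformed lumen perimeter and the
# transmural stress profile. The equilibrium condition is the classical
# pressure integral P = int_{ri}^{ro} (sigma_theta - sigma_r)/r dr, with
# wall incompressibility r(R)^2 = ri^2 + (R^2 - Ri0^2)/lambda_z linking the
# deformed and reference radii.

#' Zero-pressure tube geometry
#'
#' @param inner_radius_mm Zero-pressure inner (lumen) radius in mm.
#' @param thickness_mm Zero-pressure wall thickness in mm; must be smaller
#'   than the inner radius (physiological wall/lumen ratio).
#' @return An object of class `tube_geometry`.
#' @export
tube_geometry <- function(inner_radius_mm, thickness_mm) {
  stopifnot(inner_radius_mm > 0, thickness_mm > 0)
  if (thickness_mm >= inner_radius_mm)
    stop("wall thickness must be smaller than the inner radius")
  structure(list(inner_radius_mm = inner_radius_mm,
                 thickness_mm = thickness_mm,
                 outer_radius_mm = inner_radius_mm + thickness_mm),
            class = "tube_geometry")
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("Zero-pressure tube: inner radius %.3f mm, thickness %.3f mm\n",
              x$inner_radius_mm, x$thickness_mm))
  invisible(x)
}

#' Convert pressure from mmHg to kPa
#'
#' @param pressure_mmHg Pressure in mmHg (>= 0).
#' @return Pressure in kPa (1 atm = 760 mmHg = 101.325 kPa).
#' @examples
#' mmhg_to_kpa(133)
#' @export
mmhg_to_kpa <- function(pressure_mmHg) {
  if (any(pressure_mmHg < 0)) stop("pressure must be non-negative")
  pressure_mmHg * 101.325 / 760
}

# Gauss-Legendre nodes/weights on [a, b]; reference nodes on [-1, 1] are
# memoized per order (they are used thousands of times per inverse solve)
.gauss_cache <- new.env(parent = emptyenv())
.gauss_nodes <- function(n, a, b) {
  key <- as.character(n)
  ref <- .gauss_cache[[key]]
  if (is.null(ref)) {
    ref <- pracma::gaussLegendre(n, -1, 1)
    .gauss_cache[[key]] <- ref
  }
  list(x = (a + b) / 2 + (b - a) / 2 * ref$x, w = (b - a) / 2 * ref$w)
}

# deformed radius (mm) at reference radius R for deformed inner radius ri
.deformed_r2 <- function(R, geometry, ri, lz) {
  ri^2 + (R^2 - geometry$inner_radius_mm^2) / lz
}

#' Luminal pressure sustaining a given deformed inner radius
#'
#' Evaluates the equilibrium pressure integral across the reference wall by
#' fixed-order Gauss-Legendre quadrature. The integrand is the hoop-radial
#' Cauchy stress difference of the constitutive model at the local stretches
#' `lambda_theta(R) = r/R`, `lambda_z`, `lambda_r = 1/(lambda_theta
#' lambda_z)`.
#'
#' @param geometry A [tube_geometry] (zero-pressure reference).
#' @param params An [mr_params] object.
#' @param inner_radius_current Deformed inner radius in mm.
#' @param axial_stretch Axial stretch (default 1.25).
#' @param n_quad Quadrature order (default 16).
#' @return Pressure in kPa (negative if the wall is radially compressed).
#' @export
luminal_pressure <- function(geometry, params, inner_radius_current,
                             axial_stretch = 1.25, n_quad = 16) {
  stopifnot(inherits(geometry, "tube_geometry"), inherits(params, "mr_params"),
            inner_radius_current > 0, axial_stretch > 0)
  g <- .gauss_nodes(n_quad, geometry$inner_radius_mm,
                    geometry$outer_radius_mm)
  r2 <- .deformed_r2(g$x, geometry, inner_radius_current, axial_stretch)
  if (any(r2 <= 0))
    stop("luminal_pressure: inner radius below the collapse limit")
  lt <- sqrt(r2) / g$x
  d <- .stress_diffs(params, lt, rep(axial_stretch, length(lt)))
  # (sigma_theta - sigma_r)/r * dr/dR = diff * R / (lambda_z r^2)
  P <- sum(g$w * d$d1 * g$x / (axial_stretch * r2))
  if (!is.finite(P)) stop("luminal_pressure: non-finite quadrature result")
  P
}

#' Inflate a tube to a prescribed luminal pressure
#'
#' Solves `luminal_pressure(r_i) = pressure` for the deformed inner radius by
#' safeguarded bracketing and returns the deformed configuration with its
#' transmural Cauchy stress profile. The radial stress satisfies
#' `sigma_r = -pressure` at the lumen and `0` at the outer surface (to
#' quadrature tolerance); the hoop and axial stresses follow from the
#' constitutive stress differences.
#'
#' @param geometry A [tube_geometry].
#' @param params An [mr_params] object.
#' @param pressure_kPa Luminal pressure in kPa (>= 0).
#' @param axial_stretch Axial stretch (default 1.25).
#' @param n_quad Quadrature order for the pressure integral (default 16).
#' @param n_profile Number of transmural sample points for the stress
#'   profile (default 33).
#' @param tol Root tolerance on the inner radius in mm (default 1e-10).
#' @return An object of class `deformed_tube`: list with `inner_radius_mm`,
#'   `outer_radius_mm`, `lumen_perimeter_cm`, `profile` (data.frame
#'   `radius_mm`, `sigma_theta_kPa`, `sigma_r_kPa`, `sigma_z_kPa`),
#'   `max_principal_lumen_kPa`, and the applied load.
#' @export
inflate <- function(geometry, params, pressure_kPa, axial_stretch = 1.25,
                    n_quad = 16, n_profile = 33, tol = 1e-10) {
  ri <- .inflate_radius(geometry, params, pressure_kPa, axial_stretch,
                        n_quad, tol)
  Ri0 <- geometry$inner_radius_mm
  ro <- sqrt(.deformed_r2(geometry$outer_radius_mm, geometry, ri,
                          axial_stretch))

  # transmural stress profile on a dense reference grid: sigma_r by
  # cumulative trapezoid of the equilibrium integrand from the lumen
  Rg <- seq(Ri0, geometry$outer_radius_mm, length.out = n_profile)
  r2 <- .deformed_r2(Rg, geometry, ri, axial_stretch)
  r <- sqrt(r2)
  lt <- r / Rg
  d <- .stress_diffs(params, lt, rep(axial_stretch, length(lt)))
  integrand <- d$d1 * Rg / (axial_stretch * r2)
  cumint <- c(0, cumsum(diff(Rg) * (integrand[-1] + integrand[-length(Rg)]) / 2))
  sigma_r <- -pressure_kPa + cumint
  profile <- data.frame(radius_mm = r,
                        sigma_theta_kPa = sigma_r + d$d1,
                        sigma_r_kPa = sigma_r,
                        sigma_z_kPa = sigma_r + d$d2)
  structure(list(inner_radius_mm = ri, outer_radius_mm = ro,
                 lumen_perimeter_cm = 2 * pi * ri / 10,
                 profile = profile,
                 max_principal_lumen_kPa = max(profile[1, c("sigma_theta_kPa",
                                                            "sigma_r_kPa",
                                                            "sigma_z_kPa")]),
                 pressure_kPa = pressure_kPa, axial_stretch = axial_stretch,
                 geometry = geometry),
            class = "deformed_tube")
}

# radius-only inflation solve: the hot path of the inverse algorithm
.inflate_radius <- function(geometry, params, pressure_kPa,
                            axial_stretch = 1.25, n_quad = 16, tol = 1e-10) {
  stopifnot(pressure_kPa >= 0)
  f <- function(ri) luminal_pressure(geometry, params, ri, axial_stretch,
                                     n_quad) - pressure_kPa
  Ri0 <- geometry$inner_radius_mm
  # lower end: strongly compressed wall -> negative pressure
  lo <- 0.3 * Ri0
  flo <- f(lo)
  while (flo > 0 && lo > 1e-3 * Ri0) { lo <- lo / 2; flo <- f(lo) }
  if (flo > 0) stop("inflate: failed to bracket from below")
  hi <- max(Ri0, lo * 2)
  fhi <- f(hi)
  nexp <- 0
  while (fhi < 0) {
    lo <- hi; flo <- fhi
    hi <- hi * 1.25
    fhi <- f(hi)
    nexp <- nexp + 1
    if (nexp > 40)
      stop("inflate: pressure ", format(pressure_kPa),
           " kPa exceeds the inflation limit of this tube")
  }
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = tol)$root
}

#' @export
print.deformed_tube <- function(x, ...) {
  cat(sprintf(paste0("Inflated tube at %.3f kPa (axial stretch %.2f):\n",
                     "  inner radius %.3f mm, outer radius %.3f mm, ",
                     "lumen perimeter %.4f cm\n",
                     "  max principal stress at lumen %.2f kPa\n"),
              x$pressure_kPa, x$axial_stretch, x$inner_radius_mm,
              x$outer_radius_mm, x$lumen_perimeter_cm,
              x$max_principal_lumen_kPa))
  invisible(x)
}

#' Export a transmural stress profile as CSV
#'
#' @param tube A `deformed_tube` from [inflate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stress_profile_csv <- function(tube, path) {
  stopifnot(inherits(tube, "deformed_tube"))
  utils::write.csv(tube$profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
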