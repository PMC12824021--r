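# Constitutive core: strain energy and stress response of the two-fiber-family
# anisotropic Mooney-Rivlin model under incompressible, shear-free loading.
#
#   W = c1 (I1 - 3) + D1 (exp(D2 (I1 - 3)) - 1)
#       + K1/(2 K2) [exp(K2 (J4 - 1)^2) + exp(K2 (J6 - 1)^2) - 2]
#
# The fiber families lie at +/- theta from the circumferential direction in
# the circumferential-axial plane, so under principal stretches
# (lambda_c, lambda_a, lambda_r) both families see the same squared stretch
# I4 = I6 = lambda_c^2 cos^2(theta) + lambda_a^2 sin^2(theta).

# exponent ceiling: beyond this exp() is effectively an overflow for the
# energies involved, and the caller gets an explicit range error
.exp_cap <- 500

.deg2rad <- function(deg) deg * pi / 180

#' Kinematic invariants of a shear-free principal-stretch state
#'
#' Builds the invariants of the right Cauchy-Green tensor
#' `C = diag(lambda_c^2, lambda_a^2, lambda_r^2)` together with the fiber
#' invariants for two families at `+/- theta` from the circumferential
#' direction. The volume-normalized forms are `J4 = I4 * I3^(-1/3)` and
#' `J6 = I6 * I3^(-1/3)`; for an isochoric state (`I3 = 1`) they coincide
#' with `I4`, `I6`.
#'
#' @param lambda_c,lambda_a,lambda_r Principal stretches (circumferential,
#'   axial, radial), all > 0. Vectors are recycled to a common length.
#' @param theta Fiber half-angle in degrees, in `[0, 90)`.
#' @return An object of class `kinematic_state`: a list with the stretches
#'   and `I1`, `I2`, `I3`, `I4`, `I6`, `J4`, `J6`, plus the unit fiber
#'   directions `na`, `nb` (3-vectors in the c-a-r frame).
#' @examples
#' invariants_from_stretches(1.3, 1.25, 1 / (1.3 * 1.25), theta = 0)$I4
#' @export
invariants_from_stretches <- function(lambda_c, lambda_a, lambda_r, theta) {
  if (any(lambda_c <= 0) || any(lambda_a <= 0) || any(lambda_r <= 0))
    stop("principal stretches must be positive")
  if (theta < 0 || theta >= 90)
    stop("theta must lie in [0, 90) degrees")
  th <- .deg2rad(theta)
  ct2 <- cos(th)^2; st2 <- sin(th)^2
  lc2 <- lambda_c^2; la2 <- lambda_a^2; lr2 <- lambda_r^2
  I1 <- lc2 + la2 + lr2
  I2 <- lc2 * la2 + la2 * lr2 + lr2 * lc2
  I3 <- lc2 * la2 * lr2
  I4 <- lc2 * ct2 + la2 * st2
  I6 <- I4  # families symmetric about the circumferential axis
  J4 <- I4 * I3^(-1 / 3)
  structure(list(lambda_c = lambda_c, lambda_a = lambda_a,
                 lambda_r = lambda_r, theta = theta,
                 I1 = I1, I2 = I2, I3 = I3, I4 = I4, I6 = I6,
                 J4 = J4, J6 = J4,
                 na = c(cos(th), sin(th), 0), nb = c(cos(th), -sin(th), 0)),
            class = "kinematic_state")
}

#' Strain-energy density
#'
#' Evaluates the anisotropic Mooney-Rivlin strain energy per unit reference
#' volume at a kinematic state. For `K2` below the internal floor the
#' anisotropic term uses its analytic `K2 -> 0` limit
#' `(K1/2)[(J4-1)^2 + (J6-1)^2]`.
#'
#' @param params An [mr_params] object. Its `theta` is not consulted here;
#'   the fiber geometry is already encoded in `state`.
#' @param state A `kinematic_state` from [invariants_from_stretches()].
#' @return Energy density in kPa (vectorized over the state's stretches).
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "mr_params"), inherits(state, "kinematic_state"))
  i1m3 <- state$I1 - 3
  a4 <- (state$J4 - 1)^2
  a6 <- (state$J6 - 1)^2
  if (any(params$D2 * i1m3 > .exp_cap) ||
      any(params$K2 * pmax(a4, a6) > .exp_cap))
    stop("strain_energy: exponential overflow at extreme stretch")
  iso <- params$c1 * i1m3 + params$D1 * (exp(params$D2 * i1m3) - 1)
  if (params$K2 > .k2_floor) {
    aniso <- params$K1 / (2 * params$K2) *
      (exp(params$K2 * a4) + exp(params$K2 * a6) - 2)
  } else {
    aniso <- params$K1 / 2 * (a4 + a6)
  }
  iso + aniso
}

# dW/dI1 and the per-family fiber response dW/dI4 (= dW/dI6 at I4 = I6),
# both regular at K2 -> 0; shared by the biaxial and tube stress kernels
.psi1 <- function(params, I1) {
  if (params$D1 == 0 || params$D2 == 0) return(rep(params$c1, length(I1)))
  e <- params$D2 * (I1 - 3)
  if (any(e > .exp_cap)) stop("stress evaluation: exponential overflow")
  params$c1 + params$D1 * params$D2 * exp(e)
}

.psi4 <- function(params, I4) {
  if (params$K1 == 0) return(rep(0, length(I4)))
  e <- params$K2 * (I4 - 1)^2
  if (any(e > .exp_cap)) stop("stress evaluation: exponential overflow")
  params$K1 * (I4 - 1) * exp(e)
}

# Cauchy stress differences for an incompressible shear-free state with
# in-plane stretches (l1, l2): returns sigma_1 - sigma_r and sigma_2 - sigma_r
# where direction 1 carries fiber weight cos^2(theta), direction 2 sin^2.
.stress_diffs <- function(params, l1, l2) {
  th <- .deg2rad(params$theta)
  ct2 <- cos(th)^2; st2 <- sin(th)^2
  lr2 <- 1 / (l1^2 * l2^2)
  I1 <- l1^2 + l2^2 + lr2
  I4 <- l1^2 * ct2 + l2^2 * st2
  p1 <- .psi1(params, I1)
  p4 <- .psi4(params, I4)
  list(d1 = 2 * p1 * (l1^2 - lr2) + 4 * p4 * l1^2 * ct2,
       d2 = 2 * p1 * (l2^2 - lr2) + 4 * p4 * l2^2 * st2,
       lagrange = 2 * p1 * lr2)
}

#' Plane-stress biaxial Cauchy and engineering stresses
#'
#' Stress response of an incompressible sheet loaded in its
#' circumferential-axial plane: the radial stretch is eliminated by
#' incompressibility (`lambda_r = 1/(lambda_c lambda_a)`) and the Lagrange
#' pressure is fixed by the plane-stress condition `sigma_r = 0`.
#'
#' @param params An [mr_params] object.
#' @param lambda_c,lambda_a In-plane stretches (> 0); vectors are recycled.
#' @return An object of class `stress_state`: list with Cauchy stresses
#'   `sigma_c`, `sigma_a`, `sigma_r` (kPa), engineering (first
#'   Piola-Kirchhoff) stresses `P_c`, `P_a` (kPa), and the Lagrange pressure
#'   `p`.
#' @examples
#' biaxial_cauchy_stress(mr_params(10, 0, 0, 0, 1, 0), 1.2, 1.2)
#' @export
biaxial_cauchy_stress <- function(params, lambda_c, lambda_a) {
  stopifnot(inherits(params, "mr_params"))
  if (any(lambda_c <= 0) || any(lambda_a <= 0))
    stop("stretches must be positive")
  d <- .stress_diffs(params, lambda_c, lambda_a)
  structure(list(sigma_c = d$d1, sigma_a = d$d2,
                 sigma_r = rep(0, length(d$d1)),
                 P_c = d$d1 / lambda_c, P_a = d$d2 / lambda_a,
                 p = d$lagrange,
                 lambda_c = lambda_c, lambda_a = lambda_a),
            class = "stress_state")
}

#' @export
print.stress_state <- function(x, ...) {
  df <- data.frame(lambda_c = x$lambda_c, lambda_a = x$lambda_a,
                   sigma_c_kPa = x$sigma_c, sigma_a_kPa = x$sigma_a,
                   P_c_kPa = x$P_c, P_a_kPa = x$P_a)
  cat("Plane-stress biaxial state(s):\n")
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Cauchy stress-stretch curve under a standard loading protocol
#'
#' Evaluates the Cauchy stress in one in-plane direction along a monotone
#' stretch grid for one of three idealized protocols: `"equibiaxial"`
#' (both in-plane stretches equal), `"strip"` (transverse stretch held at 1)
#' or `"uniaxial"` (transverse in-plane Cauchy stress driven to zero by a
#' nested root find).
#'
#' @param params An [mr_params] object.
#' @param direction `"circumferential"` or `"axial"`: the direction whose
#'   stress is reported (and stretched).
#' @param protocol One of `"equibiaxial"`, `"uniaxial"`, `"strip"`.
#' @param stretch Monotone stretch grid starting at values >= 1.
#' @return A data.frame with columns `stretch` and `stress_kPa`.
#' @export
stress_stretch_curve <- function(params,
                                 direction = c("circumferential", "axial"),
                                 protocol = c("equibiaxial", "uniaxial",
                                              "strip"),
                                 stretch = seq(1, 1.3, length.out = 31)) {
  direction <- match.arg(direction)
  protocol <- match.arg(protocol)
  stopifnot(inherits(params, "mr_params"))
  if (length(stretch) < 2 || any(diff(stretch) <= 0) || any(stretch <= 0))
    stop("stretch must be a monotone increasing positive grid")

  circ_loaded <- direction == "circumferential"
  loaded_stress <- function(ll, lt) {
    s <- if (circ_loaded) biaxial_cauchy_stress(params, ll, lt)
         else biaxial_cauchy_stress(params, lt, ll)
    if (circ_loaded) s$sigma_c else s$sigma_a
  }
  transverse_stress <- function(ll, lt) {
    s <- if (circ_loaded) biaxial_cauchy_stress(params, ll, lt)
         else biaxial_cauchy_stress(params, lt, ll)
    if (circ_loaded) s$sigma_a else s$sigma_c
  }

  stress <- switch(protocol,
    equibiaxial = loaded_stress(stretch, stretch),
    strip = loaded_stress(stretch, rep(1, length(stretch))),
    uniaxial = {
      lt_prev <- 1
      vapply(stretch, function(ll) {
        f <- function(lt) transverse_stress(ll, lt)
        lo <- 0.3; hi <- max(1.05, lt_prev * 1.2)
        if (f(lo) * f(hi) > 0)
          stop("stress_stretch_curve: uniaxial transverse root find failed ",
               "to bracket at stretch ", format(ll))
        r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
        lt_prev <<- r$root
        loaded_stress(ll, r$root)
      }, numeric(1))
    })
  data.frame(stretch = stretch, stress_kPa = stress)
}
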