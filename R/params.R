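#' Anisotropic Mooney-Rivlin material parameters
#'
#' Constructor for the six-coefficient parameter set of the two-fiber-family
#' anisotropic Mooney-Rivlin strain-energy function used throughout the
#' package: an isotropic Mooney-Rivlin/exponential part governed by `c1`,
#' `D1`, `D2` and an anisotropic fiber part governed by `K1`, `K2` and the
#' fiber half-angle `theta` (degrees from the circumferential direction; the
#' two collagen-fiber families sit symmetrically at +theta and -theta in the
#' circumferential-axial plane).
#'
#' @param c1 Stress-like coefficient (kPa), >= 0.
#' @param D1 Stress-like coefficient of the isotropic exponential (kPa), >= 0.
#' @param D2 Dimensionless exponent of the isotropic exponential, >= 0.
#' @param K1 Stress-like fiber coefficient (kPa), >= 0.
#' @param K2 Dimensionless fiber exponent, > 0. Values below `1e-6` are
#'   floored to `1e-6` to avoid division by zero in the energy; the stress
#'   expressions themselves are regular at `K2 = 0`.
#' @param theta Fiber half-angle in degrees. Fitting constrains it to
#'   (0, 45); storage allows `[0, 90)` so sensitivity studies can explore
#'   wider angles.
#' @return An object of class `mr_params` (a named list with elements
#'   `c1`, `D1`, `D2`, `K1`, `K2`, `theta`).
#' @examples
#' p <- mr_params(2.6970, 15.1322, 0.9272, 2.1722, 0.9338, 5.56)
#' p
#' @export
mr_params <- function(c1, D1, D2, K1, K2, theta) {
  vals <- c(c1 = c1, D1 = D1, D2 = D2, K1 = K1, K2 = K2, theta = theta)
  if (any(!is.finite(vals)))
    stop("material parameters must be finite numbers")
  if (c1 < 0 || D1 < 0 || D2 < 0 || K1 < 0)
    stop("c1, D1, D2 and K1 must be non-negative")
  if (K2 < 0)
    stop("K2 must be positive")
  K2 <- max(K2, .k2_floor)
  if (theta < 0 || theta >= 90)
    stop("theta must lie in [0, 90) degrees")
  structure(list(c1 = c1, D1 = D1, D2 = D2, K1 = K1, K2 = K2, theta = theta),
            class = "mr_params")
}

# floor replacing K2 = 0 (division by K2 in the energy)
.k2_floor <- 1e-6

#' @export
print.mr_params <- function(x, digits = 4, ...) {
  cat("Anisotropic Mooney-Rivlin parameters\n")
  cat(sprintf("  c1 = %.*f kPa, D1 = %.*f kPa, D2 = %.*f\n",
              digits, x$c1, digits, x$D1, digits, x$D2))
  cat(sprintf("  K1 = %.*f kPa, K2 = %.*f, theta = %.2f deg\n",
              digits, x$K1, digits, x$K2, x$theta))
  invisible(x)
}

#' @export
as.data.frame.mr_params <- function(x, ...) {
  data.frame(c1_kPa = x$c1, D1_kPa = x$D1, D2 = x$D2,
             K1_kPa = x$K1, K2 = x$K2, theta_deg = x$theta)
}

#' Scale the stress-like coefficients of a parameter set
#'
#' Multiplies `c1`, `D1` and `K1` by a common factor `k`, leaving the
#' dimensionless exponents `D2`, `K2` and the fiber angle untouched. Because
#' every stress is homogeneous of degree one in the stress-like triple, this
#' scales all stresses (and effective moduli) by exactly `k`; it is the
#' "proportional adjustment" performed in the inner loop of the inverse
#' algorithm.
#'
#' @param params An [mr_params] object.
#' @param k Positive scale factor.
#' @return An [mr_params] object with scaled stress-like coefficients.
#' @export
scale_stiffness <- function(params, k) {
  stopifnot(inherits(params, "mr_params"), is.finite(k), k > 0)
  mr_params(params$c1 * k, params$D1 * k, params$D2,
            params$K1 * k, params$K2, params$theta)
}

#' Replace the anisotropy coefficients of a parameter set
#'
#' Returns a copy of `params` with `K2` and/or `theta` replaced; used by the
#' middle and outer corrective loops of the inverse algorithm.
#'
#' @param params An [mr_params] object.
#' @param K2,theta Replacement values; `NULL` keeps the current one.
#' @return An [mr_params] object.
#' @export
set_anisotropy <- function(params, K2 = NULL, theta = NULL) {
  stopifnot(inherits(params, "mr_params"))
  mr_params(params$c1, params$D1, params$D2, params$K1,
            if (is.null(K2)) params$K2 else K2,
            if (is.null(theta)) params$theta else theta)
}

#' Read or write material parameters as JSON
#'
#' Parameter sets are serialized as flat JSON mappings with unit-bearing keys
#' `c1_kPa`, `D1_kPa`, `D2`, `K1_kPa`, `K2`, `theta_deg`.
#'
#' @param path File path.
#' @return `read_params_json()` returns an [mr_params] object;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("c1_kPa", "D1_kPa", "D2", "K1_kPa", "K2", "theta_deg")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file ", path, " is missing keys: ",
         paste(miss, collapse = ", "))
  mr_params(x$c1_kPa, x$D1_kPa, x$D2, x$K1_kPa, x$K2, x$theta_deg)
}

#' @rdname read_params_json
#' @param params An [mr_params] object to serialize.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "mr_params"))
  jsonlite::write_json(
    list(c1_kPa = params$c1, D1_kPa = params$D1, D2 = params$D2,
         K1_kPa = params$K1, K2 = params$K2, theta_deg = params$theta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
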