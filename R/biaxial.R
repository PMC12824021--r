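# Planar biaxial testing: protocol simulation and bounded least-squares
# parameter identification. A force-controlled rig prescribes force ratios
# between the circumferential and axial axes; engineering (first
# Piola-Kirchhoff) stress vs stretch is the fitted quantity, the usual
# convention when forces and undeformed dimensions are what the rig records.

#' Biaxial loading protocol
#'
#' A force-controlled protocol: the two in-plane engineering-stress targets
#' grow proportionally to `(force_ratio_c, force_ratio_a) * max_force`.
#' The standard battery is the five ratios 1:1, 1:0.75, 0.75:1, 1:0.5 and
#' 0.5:1 at a maximal force of 2 N.
#'
#' @param force_ratio_c,force_ratio_a Dimensionless ratios in (0, 1].
#' @param max_force Maximal force in N (default 2).
#' @param n_steps Number of load steps per protocol (default 12).
#' @param id Protocol label.
#' @return An object of class `biaxial_protocol`.
#' @export
biaxial_protocol <- function(force_ratio_c, force_ratio_a, max_force = 2,
                             n_steps = 12, id = NULL) {
  stopifnot(force_ratio_c > 0, force_ratio_c <= 1,
            force_ratio_a > 0, force_ratio_a <= 1,
            max_force > 0, n_steps >= 1)
  if (is.null(id))
    id <- sprintf("%g:%g", force_ratio_c, force_ratio_a)
  structure(list(force_ratio_c = force_ratio_c,
                 force_ratio_a = force_ratio_a,
                 max_force = max_force, n_steps = n_steps, id = id),
            class = "biaxial_protocol")
}

#' The five standard force-ratio protocols
#'
#' @param max_force Maximal force in N.
#' @param n_steps Load steps per protocol.
#' @return A list of five [biaxial_protocol] objects (ratios 1:1, 1:0.75,
#'   0.75:1, 1:0.5, 0.5:1).
#' @export
standard_protocols <- function(max_force = 2, n_steps = 12) {
  ratios <- list(c(1, 1), c(1, 0.75), c(0.75, 1), c(1, 0.5), c(0.5, 1))
  lapply(ratios, function(r)
    biaxial_protocol(r[1], r[2], max_force = max_force, n_steps = n_steps))
}

#' Sample geometry of a square biaxial specimen
#'
#' @param edge_length_mm Edge length in mm (nominal 20).
#' @param thickness_mm Wall thickness in mm.
#' @return An object of class `sample_geometry`.
#' @export
sample_geometry <- function(edge_length_mm = 20, thickness_mm) {
  stopifnot(edge_length_mm > 0, thickness_mm > 0)
  structure(list(edge_length_mm = edge_length_mm,
                 thickness_mm = thickness_mm),
            class = "sample_geometry")
}

#' Convert an applied force to engineering stress
#'
#' First Piola-Kirchhoff stress referred to the undeformed cross-section
#' `edge_length x thickness`.
#'
#' @param force_N Applied force in N (>= 0).
#' @param geometry A [sample_geometry].
#' @return Engineering stress in kPa.
#' @examples
#' force_to_stress(2, sample_geometry(20, 2.42))  # ~41.32 kPa
#' @export
force_to_stress <- function(force_N, geometry) {
  stopifnot(inherits(geometry, "sample_geometry"))
  if (any(force_N < 0)) stop("force must be non-negative")
  area_mm2 <- geometry$edge_length_mm * geometry$thickness_mm
  if (area_mm2 <= 0) stop("specimen cross-section area must be positive")
  # N / mm^2 = MPa; * 1000 -> kPa
  force_N / area_mm2 * 1000
}

# Damped Newton with finite-difference Jacobian for the 2x2 stress-target
# system; continuation over the load path supplies good starting points.
.solve_stretches_for_stress <- function(params, Pc_target, Pa_target,
                                        start = c(1, 1), tol = 1e-10,
                                        maxit = 60) {
  f <- function(l) {
    s <- biaxial_cauchy_stress(params, l[1], l[2])
    c(s$P_c - Pc_target, s$P_a - Pa_target)
  }
  x <- start
  fx <- f(x)
  for (it in seq_len(maxit)) {
    if (max(abs(fx)) < tol) return(list(lambda = x, residual = fx, iter = it))
    h <- 1e-7 * pmax(abs(x), 1)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + h[j]
      J[, j] <- (f(xp) - fx) / h[j]
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      xn <- x + alpha * step
      if (all(xn > 0.2)) {
        fn <- tryCatch(f(xn), error = function(e) NULL)
        if (!is.null(fn) && all(is.finite(fn)) &&
            sum(fn^2) < sum(fx^2) * (1 - 1e-4 * alpha) + 1e-300) {
          x <- xn; fx <- fn; break
        }
      }
      alpha <- alpha / 2
      if (alpha < 1e-6) return(NULL)
    }
  }
  if (max(abs(fx)) < 1e-6 * max(1, abs(Pc_target), abs(Pa_target)))
    return(list(lambda = x, residual = fx, iter = maxit))
  NULL
}

#' Simulate one force-controlled biaxial protocol
#'
#' For each load fraction `t` the engineering-stress targets
#' `(t * ratio_c, t * ratio_a) * P_max` are met by solving the two
#' plane-stress equilibrium equations for the in-plane stretches.
#'
#' @param params An [mr_params] object.
#' @param geometry A [sample_geometry].
#' @param protocol A [biaxial_protocol].
#' @return A data.frame with columns `protocol_id`, `load_fraction`,
#'   `lambda_c`, `lambda_a`, `Pc_kPa`, `Pa_kPa`.
#' @export
simulate_protocol <- function(params, geometry, protocol) {
  stopifnot(inherits(params, "mr_params"),
            inherits(geometry, "sample_geometry"),
            inherits(protocol, "biaxial_protocol"))
  Pmax <- force_to_stress(protocol$max_force, geometry)
  tgrid <- seq_len(protocol$n_steps) / protocol$n_steps
  out <- vector("list", length(tgrid))
  start <- c(1, 1)
  for (i in seq_along(tgrid)) {
    t <- tgrid[i]
    Pc <- t * protocol$force_ratio_c * Pmax
    Pa <- t * protocol$force_ratio_a * Pmax
    sol <- .solve_stretches_for_stress(params, Pc, Pa, start = start)
    if (is.null(sol))
      stop("simulate_protocol: stretch solve failed for protocol ",
           protocol$id, " at load step ", i)
    start <- sol$lambda
    out[[i]] <- data.frame(protocol_id = protocol$id, load_fraction = t,
                           lambda_c = sol$lambda[1], lambda_a = sol$lambda[2],
                           Pc_kPa = Pc, Pa_kPa = Pa)
  }
  do.call(rbind, out)
}

#' Read or write a biaxial dataset as CSV
#'
#' The on-disk format is a header-bearing CSV with columns `protocol_id`,
#' `load_fraction`, `lambda_c`, `lambda_a`, `Pc_kPa`, `Pa_kPa`.
#'
#' @param path File path.
#' @return `read_biaxial_csv()` returns the dataset data.frame.
#' @export
read_biaxial_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dat <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("failed to parse biaxial CSV ", path, ": ",
                         conditionMessage(e)))
  if (nrow(dat) == 0) stop("biaxial CSV ", path, " contains no records")
  need <- c("protocol_id", "load_fraction", "lambda_c", "lambda_a",
            "Pc_kPa", "Pa_kPa")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("biaxial CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(dat), need)
  if (length(extra))
    stop("biaxial CSV ", path, " has unknown column(s): ",
         paste(extra, collapse = ", "))
  num <- need[-1]
  bad <- num[!vapply(dat[num], is.numeric, logical(1))]
  if (length(bad))
    stop("biaxial CSV ", path, ": non-numeric column(s): ",
         paste(bad, collapse = ", "))
  dat
}

#' @rdname read_biaxial_csv
#' @param dataset A biaxial dataset data.frame.
#' @export
write_biaxial_csv <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# predicted engineering stresses at the dataset's recorded stretch pairs
.predict_biaxial <- function(params, dataset) {
  s <- biaxial_cauchy_stress(params, dataset$lambda_c, dataset$lambda_a)
  cbind(Pc = s$P_c, Pa = s$P_a)
}

.biaxial_residuals <- function(params, dataset) {
  pred <- .predict_biaxial(params, dataset)
  c(pred[, "Pc"] - dataset$Pc_kPa, pred[, "Pa"] - dataset$Pa_kPa)
}

#' Fit anisotropic Mooney-Rivlin parameters to biaxial data
#'
#' Bounded nonlinear least squares on the pooled engineering-stress
#' residuals of both in-plane directions over all protocols
#' (Levenberg-Marquardt with box bounds, multi-start). Bounds: `c1, D1, D2,
#' K1 >= 0`, `K2` above the internal floor, `theta` in (0, 45) degrees.
#' `R^2 = 1 - SSres/SStot` with `SStot` taken about the pooled mean of both
#' stress components.
#'
#' @param dataset A biaxial dataset data.frame (see [read_biaxial_csv()] for
#'   the column contract), spanning at least two protocols.
#' @param initial_guess Optional [mr_params] used as one of the starts.
#' @param n_starts Number of seeded random multi-starts (default 8).
#' @param seed Integer seed for the multi-start sampler.
#' @return An object of class `biaxial_fit` with elements `params`
#'   ([mr_params]), `r_squared`, `residual_norm`, `convergence` (per-start
#'   report), `dataset` and `n_obs`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @export
fit_biaxial <- function(dataset, initial_guess = NULL, n_starts = 8,
                        seed = 1L) {
  need <- c("protocol_id", "lambda_c", "lambda_a", "Pc_kPa", "Pa_kPa")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (length(unique(dataset$protocol_id)) < 2)
    stop("dataset must span at least two protocols for identifiability")
  n_res <- 2L * nrow(dataset)
  if (n_res < 6L)
    stop("fewer residuals (", n_res, ") than parameters (6)")

  sc <- max(dataset$Pc_kPa, dataset$Pa_kPa)  # data stress scale
  lower <- c(0, 0, 0, 0, .k2_floor, 1e-3)
  upper <- c(Inf, Inf, Inf, Inf, Inf, 45 - 1e-3)
  p2v <- function(p) c(p$c1, p$D1, p$D2, p$K1, p$K2, p$theta)
  v2p <- function(v) mr_params(v[1], v[2], v[3], v[4], v[5], v[6])

  res_fn <- function(v) .biaxial_residuals(v2p(v), dataset) / sc

  starts <- list()
  if (!is.null(initial_guess)) {
    stopifnot(inherits(initial_guess, "mr_params"))
    starts <- list(p2v(initial_guess))
  }
  # one canonical start plus seeded log-uniform draws, all relative to the
  # data's stress scale so the fit is unit-equivariant
  starts <- c(starts, list(c(0.05, 0.3, 1, 0.05, 1, 20) * c(sc, sc, 1, sc, 1, 1)))
  starts <- c(starts, .with_seed(seed, {
    lapply(seq_len(max(0, n_starts - length(starts))), function(i) {
      c(10^stats::runif(1, -3, 0) * sc, 10^stats::runif(1, -2.5, 0.5) * sc,
        10^stats::runif(1, -1, 0.7), 10^stats::runif(1, -3, 0) * sc,
        10^stats::runif(1, -1.5, 1), stats::runif(1, 2, 43))
    })
  }))

  fits <- lapply(starts, function(v0) {
    v0 <- pmin(pmax(v0, lower + 1e-9), c(rep(1e6, 5), upper[6]))
    tryCatch(
      minpack.lm::nls.lm(par = v0, lower = lower, upper = upper,
                         fn = res_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("fit_biaxial: no start converged")
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  k1s <- vapply(fits, function(f) f$par[4], numeric(1))
  # best residual wins; near-ties broken by lower K1
  best <- order(dev + 1e-9 * min(dev) * rank(k1s))[1]
  fit <- fits[[best]]
  params <- v2p(fit$par)

  obs <- c(dataset$Pc_kPa, dataset$Pa_kPa)
  ss_res <- sum(.biaxial_residuals(params, dataset)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  structure(list(params = params,
                 r_squared = 1 - ss_res / ss_tot,
                 residual_norm = sqrt(ss_res),
                 convergence = data.frame(
                   start = seq_along(fits), deviance = dev,
                   info = vapply(fits, function(f) f$info, numeric(1))),
                 dataset = dataset, n_obs = n_res),
            class = "biaxial_fit")
}

#' @export
print.biaxial_fit <- function(x, ...) {
  cat("Biaxial fit of the anisotropic Mooney-Rivlin model\n")
  cat(sprintf("  %d stress observations, R^2 = %.4f\n", x$n_obs, x$r_squared))
  print(x$params)
  invisible(x)
}

#' @export
coef.biaxial_fit <- function(object, ...) {
  p <- object$params
  c(c1 = p$c1, D1 = p$D1, D2 = p$D2, K1 = p$K1, K2 = p$K2, theta = p$theta)
}

#' @export
summary.biaxial_fit <- function(object, ...) {
  res <- .biaxial_residuals(object$params, object$dataset)
  out <- list(params = object$params, r_squared = object$r_squared,
              residual_norm = object$residual_norm,
              max_abs_residual = max(abs(res)),
              n_obs = object$n_obs,
              protocols = unique(object$dataset$protocol_id))
  class(out) <- "summary.biaxial_fit"
  out
}

#' @export
print.summary.biaxial_fit <- function(x, ...) {
  cat("Biaxial fit summary\n")
  cat(sprintf("  protocols: %s\n", paste(x$protocols, collapse = ", ")))
  cat(sprintf("  R^2 = %.4f, residual norm = %.4g kPa, max |res| = %.4g kPa\n",
              x$r_squared, x$residual_norm, x$max_abs_residual))
  print(x$params)
  invisible(x)
}

#' @export
predict.biaxial_fit <- function(object, newdata = NULL, ...) {
  dat <- if (is.null(newdata)) object$dataset else newdata
  pred <- .predict_biaxial(object$params, dat)
  data.frame(lambda_c = dat$lambda_c, lambda_a = dat$lambda_a,
             Pc_kPa = pred[, "Pc"], Pa_kPa = pred[, "Pa"])
}

#' @export
residuals.biaxial_fit <- function(object, ...) {
  .biaxial_residuals(object$params, object$dataset)
}

#' @export
plot.biaxial_fit <- function(x, ...) {
  dat <- x$dataset
  pred <- .predict_biaxial(x$params, dat)
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  for (dir in c("c", "a")) {
    obs <- dat[[paste0("P", dir, "_kPa")]]
    lam <- dat[[paste0("lambda_", dir)]]
    graphics::plot(lam, obs, xlab = bquote(lambda[.(dir)]),
                   ylab = sprintf("P_%s (kPa)", dir),
                   main = sprintf("%s direction", dir), ...)
    graphics::points(lam, pred[, paste0("P", dir)], pch = 3, col = 2)
  }
  graphics::legend("topleft", legend = c("data", "fit"), pch = c(1, 3),
                   col = c(1, 2), bty = "n")
  invisible(x)
}
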