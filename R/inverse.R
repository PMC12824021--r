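# Inverse estimation: the triple-loop algorithm recovering the
# circumferential shrinkage ratio S and the stiffness scale k of one subject
# from two imaged states (diastolic/systolic pressure and minimum/maximum
# lumen perimeter). The inner loop determines (S, k) under fixed anisotropy
# (K2, theta); when no admissible solution exists (0 < S <= 1, k > 0 with
# both perimeters matched), the middle loop steps K2 (0.01 per step) and the
# outer loop steps theta (1 degree per step) until a feasible pair is found.

#' Subject record for inverse estimation
#'
#' Clinical inputs for one aorta: cuff pressures, the minimum and maximum
#' lumen perimeters over the cardiac cycle from echocardiography, and the
#' wall thickness measured on the excised sample.
#'
#' @param id Subject label.
#' @param pressure_sys_mmHg,pressure_dia_mmHg Systolic and diastolic cuff
#'   pressure in mmHg (`sys > dia > 0`).
#' @param perimeter_min_cm,perimeter_max_cm Minimum and maximum lumen
#'   perimeter in cm (`max > min > 0`).
#' @param thickness_mm Wall thickness in mm.
#' @param reference_perimeter_cm Reference (imaged) perimeter the shrinkage
#'   ratio is applied to; defaults to the maximum perimeter. Only the
#'   product `S * reference` enters the mechanics, so this choice rescales
#'   the reported `S`, not the recovered material.
#' @param axial_stretch In vivo axial stretch (default 1.25, i.e. 20 percent
#'   axial shrinkage to the zero-pressure state).
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(id, pressure_sys_mmHg, pressure_dia_mmHg,
                           perimeter_min_cm, perimeter_max_cm, thickness_mm,
                           reference_perimeter_cm = NULL,
                           axial_stretch = 1.25) {
  if (!(pressure_sys_mmHg > pressure_dia_mmHg && pressure_dia_mmHg > 0))
    stop("need pressure_sys > pressure_dia > 0")
  if (!(perimeter_max_cm >= perimeter_min_cm && perimeter_min_cm > 0))
    stop("need perimeter_max >= perimeter_min > 0")
  if (thickness_mm <= 0) stop("thickness must be positive")
  if (axial_stretch <= 0) stop("axial_stretch must be positive")
  if (is.null(reference_perimeter_cm))
    reference_perimeter_cm <- perimeter_max_cm
  structure(list(id = as.character(id),
                 pressure_sys_mmHg = pressure_sys_mmHg,
                 pressure_dia_mmHg = pressure_dia_mmHg,
                 perimeter_min_cm = perimeter_min_cm,
                 perimeter_max_cm = perimeter_max_cm,
                 thickness_mm = thickness_mm,
                 reference_perimeter_cm = reference_perimeter_cm,
                 axial_stretch = axial_stretch),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf(paste0("Subject %s: BP %g/%g mmHg, perimeter %g-%g cm, ",
                     "thickness %g mm, axial stretch %.2f\n"),
              x$id, x$pressure_sys_mmHg, x$pressure_dia_mmHg,
              x$perimeter_min_cm, x$perimeter_max_cm, x$thickness_mm,
              x$axial_stretch))
  invisible(x)
}

#' Iteration configuration for the triple-loop algorithm
#'
#' @param delta_K2 Middle-loop step on `K2` (default 0.01).
#' @param delta_theta_deg Outer-loop step on `theta` in degrees (default 1).
#' @param k_bracket Admissible range for the stiffness scale `k` (default
#'   `c(1e-3, 1e3)`); solutions outside it are rejected.
#' @param perimeter_rtol Relative tolerance on both perimeter matches
#'   (default 1e-5).
#' @param max_middle,max_outer Step budgets for the corrective loops.
#' @param n_quad Quadrature order of the tube forward model.
#' @param radius_tol Root tolerance (mm) of the inflation solves.
#' @return An object of class `iteration_config`.
#' @export
iteration_config <- function(delta_K2 = 0.01, delta_theta_deg = 1,
                             k_bracket = c(1e-3, 1e3),
                             perimeter_rtol = 1e-5,
                             max_middle = 40, max_outer = 44,
                             n_quad = 16, radius_tol = 1e-10) {
  stopifnot(delta_K2 > 0, delta_theta_deg > 0, perimeter_rtol > 0,
            length(k_bracket) == 2, all(k_bracket > 0),
            k_bracket[1] < k_bracket[2], max_middle >= 0, max_outer >= 0)
  structure(list(delta_K2 = delta_K2, delta_theta_deg = delta_theta_deg,
                 k_bracket = k_bracket, perimeter_rtol = perimeter_rtol,
                 max_middle = max_middle, max_outer = max_outer,
                 n_quad = n_quad, radius_tol = radius_tol),
            class = "iteration_config")
}

#' Zero-pressure geometry from a subject and a shrinkage ratio
#'
#' The zero-pressure inner radius is `S * reference_perimeter / (2 pi)`.
#' The zero-pressure thickness follows from wall-area conservation under the
#' axial shrink: the wall cross-section area in the unloaded state equals
#' `axial_stretch` times the imaged-state area (incompressibility), with the
#' imaged-state area built from the reference perimeter radius and the
#' measured thickness.
#'
#' @param subject A [subject_record].
#' @param S Circumferential shrinkage ratio in (0, 1].
#' @return A [tube_geometry].
#' @export
zero_pressure_geometry <- function(subject, S) {
  stopifnot(inherits(subject, "subject_record"))
  if (!(S > 0 && S <= 1))
    stop("shrinkage ratio S must lie in (0, 1]")
  r_ref <- subject$reference_perimeter_cm * 10 / (2 * pi)  # mm
  ri0 <- S * r_ref
  area_vivo <- pi * ((r_ref + subject$thickness_mm)^2 - r_ref^2)
  area_0 <- subject$axial_stretch * area_vivo
  t0 <- sqrt(ri0^2 + area_0 / pi) - ri0
  tube_geometry(ri0, t0)
}

# perimeter (cm) of the subject's tube at shrinkage S, scale k, pressure kPa
.forward_perimeter <- function(subject, params, S, pressure_kPa, config) {
  geom <- zero_pressure_geometry(subject, S)
  ri <- .inflate_radius(geom, params, pressure_kPa, subject$axial_stretch,
                        n_quad = config$n_quad, tol = config$radius_tol)
  2 * pi * ri / 10
}


#' Inner loop: recover shrinkage and stiffness scale at fixed anisotropy
#'
#' Determines the two inner-loop unknowns - the circumferential shrinkage
#' ratio `S` and the stiffness scale `k` multiplying the stress-like
#' coefficients `(c1, D1, K1)` (`D2`, `K2`, `theta` fixed) - such that the
#' tube inflated at diastolic pressure reproduces the minimum perimeter and
#' at systolic pressure the maximum perimeter. Because every stress is
#' homogeneous of degree one in the stress-like triple, the pressure
#' sustaining a fixed deformed radius scales exactly with `k`; with both
#' observed radii fixed by the perimeters, `k` therefore cancels in the
#' pressure ratio, and `S` solves the scalar equation
#' `p_sys(S) / p_dia(S) = P_sys / P_dia`
#' (where `p_x(S)` is the unscaled equilibrium pressure holding the
#' observed radius at shrinkage `S`), after which `k = P_dia / p_dia(S)`
#' in closed form. The ratio residual is U-shaped in `S` over the
#' admissible range, so up to two exact `(S, k)` solutions can exist; the
#' solution requiring the smallest proportional adjustment of the initial
#' guess (minimal `|log k|`) is selected. Infeasibility - no sign change of
#' the ratio residual for `S` in (0, 1], or no admissible `S` at all - is
#' returned as a signal, not an error.
#'
#' @param subject A [subject_record].
#' @param base_params An [mr_params] giving the initial guess.
#' @param K2,theta Anisotropy values held fixed during this loop (default:
#'   those of `base_params`).
#' @param config An [iteration_config].
#' @return A list with `feasible` (logical), and when feasible `S`, `k`,
#'   `n_roots` (number of admissible solutions found), `all_S`/`all_k`
#'   (every admissible root), and `residual_dia`, `residual_sys` (relative
#'   perimeter mismatches of the final full inflation solves); when
#'   infeasible, `reason`.
#' @export
inner_loop <- function(subject, base_params, K2 = NULL, theta = NULL,
                       config = iteration_config()) {
  stopifnot(inherits(subject, "subject_record"),
            inherits(base_params, "mr_params"))
  params0 <- set_anisotropy(base_params, K2 = K2, theta = theta)
  P_dia <- mmhg_to_kpa(subject$pressure_dia_mmHg)
  P_sys <- mmhg_to_kpa(subject$pressure_sys_mmHg)
  r_dia <- subject$perimeter_min_cm * 10 / (2 * pi)  # mm
  r_sys <- subject$perimeter_max_cm * 10 / (2 * pi)
  ratio_target <- P_sys / P_dia

  pressures <- function(S) tryCatch({
    geom <- zero_pressure_geometry(subject, S)
    c(luminal_pressure(geom, params0, r_dia, subject$axial_stretch,
                       config$n_quad),
      luminal_pressure(geom, params0, r_sys, subject$axial_stretch,
                       config$n_quad))
  }, error = function(e) c(NA_real_, NA_real_))

  ratio_residual <- function(S) {
    p <- pressures(S)
    # admissibility: positive diastolic holding pressure (k > 0)
    if (!all(is.finite(p)) || p[1] <= 0) return(NA_real_)
    p[2] / p[1] - ratio_target
  }

  Sgrid <- seq(0.02, 1, length.out = 80)
  fv <- vapply(Sgrid, ratio_residual, numeric(1))
  ok <- which(is.finite(fv))
  if (!length(ok))
    return(list(feasible = FALSE,
                reason = "no admissible shrinkage in (0, 1]"))

  # The ratio residual is U-shaped over the admissible range: it blows up
  # both deep in the exponential stiffening regime (small S) and towards
  # the zero-holding-pressure boundary (large S), so up to two roots - two
  # exact (S, k) matches of the two observations - can exist. Root-find
  # every bracketing interval of the scan, then select the solution
  # requiring the smallest proportional adjustment of the initial guess
  # (minimal |log k|), the inner loop's notion of staying closest to the
  # starting material.
  roots <- numeric(0)
  for (j in seq_len(length(ok) - 1)) {
    i1 <- ok[j]; i2 <- ok[j + 1]
    if (i2 - i1 == 1 && sign(fv[i1]) != sign(fv[i2])) {
      r <- stats::uniroot(ratio_residual, c(Sgrid[i1], Sgrid[i2]),
                          f.lower = fv[i1], f.upper = fv[i2],
                          tol = 1e-13, maxiter = 200)
      roots <- c(roots, r$root)
    }
  }
  if (!length(roots)) {
    reason <- if (all(fv[ok] > 0))
      "pressure ratio unattainable: residual positive over (0, 1]"
    else if (all(fv[ok] < 0))
      "pressure ratio unattainable: residual negative over (0, 1]"
    else "ratio residual changes sign only across an inadmissible gap"
    return(list(feasible = FALSE, reason = reason))
  }
  ks <- vapply(roots, function(S) P_dia / pressures(S)[1], numeric(1))
  admissible <- is.finite(ks) & ks > 0 &
    ks >= config$k_bracket[1] & ks <= config$k_bracket[2]
  if (!any(admissible))
    return(list(feasible = FALSE,
                reason = "no root with positive stiffness scale"))
  roots <- roots[admissible]; ks <- ks[admissible]
  sel <- which.min(abs(log(ks)))
  S <- roots[sel]
  k <- ks[sel]
  n_roots <- length(roots)

  # independent verification: full inflation solves at the scaled parameters
  pk <- scale_stiffness(params0, k)
  res_dia <- tryCatch(
    (.forward_perimeter(subject, pk, S, P_dia, config) -
       subject$perimeter_min_cm) / subject$perimeter_min_cm,
    error = function(e) NA_real_)
  res_sys <- tryCatch(
    (.forward_perimeter(subject, pk, S, P_sys, config) -
       subject$perimeter_max_cm) / subject$perimeter_max_cm,
    error = function(e) NA_real_)
  if (!is.finite(res_dia) || !is.finite(res_sys) ||
      abs(res_dia) >= config$perimeter_rtol ||
      abs(res_sys) >= config$perimeter_rtol)
    return(list(feasible = FALSE,
                reason = "perimeters not matched within tolerance at the ratio solution"))
  list(feasible = TRUE, S = S, k = k, n_roots = n_roots,
       all_S = roots, all_k = ks,
       residual_dia = res_dia, residual_sys = res_sys)
}

# expanding alternating-sign offset schedule: +d, -d, +2d, -2d, ...
.alternating_offsets <- function(step, n) {
  m <- rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)]
  s <- rep(c(1, -1), length.out = n)
  s * m * step
}

#' Triple-loop inverse estimation for one subject
#'
#' Runs the inner loop; on infeasibility the middle loop perturbs `K2` by an
#' expanding alternating schedule (`+0.01, -0.01, +0.02, ...`, floored at
#' the positive floor) and, when its budget is exhausted, the outer loop
#' perturbs `theta` by `+/- 1, 2, ...` degrees within (0, 45] and restarts
#' the middle loop. The first feasible `(S, k)` wins.
#'
#' @param subject A [subject_record].
#' @param initial_params An [mr_params] initial guess.
#' @param config An [iteration_config].
#' @return An object of class `invivo_fit`: `S`, `k`, `final_params` (the
#'   initial guess with stress-like coefficients scaled by `k` and possibly
#'   stepped `K2`/`theta`), `loop_counts` (inner/middle/outer invocation
#'   counts), `residuals`, `feasible`, the `subject` and `initial_params`.
#'   Methods: `print`, `coef`, `summary`.
#' @export
estimate_invivo <- function(subject, initial_params,
                            config = iteration_config()) {
  stopifnot(inherits(subject, "subject_record"),
            inherits(initial_params, "mr_params"))
  counts <- c(inner = 0L, middle = 0L, outer = 0L)
  attempts <- list()

  try_one <- function(K2, theta) {
    counts["inner"] <<- counts["inner"] + 1L
    res <- inner_loop(subject, initial_params, K2 = K2, theta = theta,
                      config = config)
    attempts[[length(attempts) + 1]] <<-
      list(K2 = K2, theta = theta, feasible = res$feasible,
           reason = if (res$feasible) NA_character_ else res$reason)
    res
  }

  theta_offsets <- c(0, .alternating_offsets(config$delta_theta_deg,
                                             config$max_outer))
  K2_offsets <- c(0, .alternating_offsets(config$delta_K2,
                                          config$max_middle))
  for (i_th in seq_along(theta_offsets)) {
    theta <- initial_params$theta + theta_offsets[i_th]
    if (theta <= 0 || theta > 45) next
    if (i_th > 1) counts["outer"] <- counts["outer"] + 1L
    seen_K2 <- numeric(0)
    for (i_k2 in seq_along(K2_offsets)) {
      K2 <- max(initial_params$K2 + K2_offsets[i_k2], .k2_floor)
      if (any(abs(K2 - seen_K2) < 1e-12)) next  # floored duplicates
      seen_K2 <- c(seen_K2, K2)
      if (i_k2 > 1) counts["middle"] <- counts["middle"] + 1L
      res <- try_one(K2, theta)
      if (res$feasible) {
        final <- scale_stiffness(
          set_anisotropy(initial_params, K2 = K2, theta = theta), res$k)
        return(structure(list(S = res$S, k = res$k, final_params = final,
                              loop_counts = counts,
                              residuals = c(dia = res$residual_dia,
                                            sys = res$residual_sys),
                              feasible = TRUE, attempts = attempts,
                              subject = subject,
                              initial_params = initial_params,
                              config = config),
                         class = "invivo_fit"))
      }
    }
  }
  stop("estimate_invivo: no feasible (S, k) within the loop budgets for ",
       "subject ", subject$id, "; attempts:\n",
       paste(vapply(attempts, function(a)
         sprintf("  K2=%.4f theta=%.2f: %s", a$K2, a$theta, a$reason),
         character(1)), collapse = "\n"))
}

#' @export
print.invivo_fit <- function(x, digits = 4, ...) {
  cat(sprintf("In vivo estimate for subject %s\n", x$subject$id))
  cat(sprintf("  S = %.4f (shrinkage %.2f%%), k = %.4f\n",
              x$S, 100 * x$S, x$k))
  cat(sprintf("  loops: inner %d, middle %d, outer %d\n",
              x$loop_counts["inner"], x$loop_counts["middle"],
              x$loop_counts["outer"]))
  print(x$final_params, digits = digits)
  invisible(x)
}

#' @export
coef.invivo_fit <- function(object, ...) {
  p <- object$final_params
  c(S = object$S, k = object$k, c1 = p$c1, D1 = p$D1, D2 = p$D2,
    K1 = p$K1, K2 = p$K2, theta = p$theta)
}

#' @export
summary.invivo_fit <- function(object, ...) {
  ym_c <- effective_young_modulus(object$final_params, "circumferential")
  ym_a <- effective_young_modulus(object$final_params, "axial")
  out <- list(fit = object, YMc = ym_c, YMa = ym_a,
              AI = anisotropy_index(ym_c, ym_a))
  class(out) <- "summary.invivo_fit"
  out
}

#' @export
print.summary.invivo_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  YMc = %.2f kPa, YMa = %.2f kPa, AI = %.2f\n",
              x$YMc, x$YMa, x$AI))
  invisible(x)
}

#' Cohort-level inverse estimation under a named initial-guess setting
#'
#' Applies [estimate_invivo()] to every subject under one of three
#' initial-guess settings: `"M01"` (subject-specific ex vivo parameters),
#' `"M02"` (one common parameter set for all subjects: the packaged AD1 ex
#' vivo fit), `"M03"` (the packaged 5-percent-perturbed variant of M02), or
#' `"custom"` (caller-supplied `init_params`). Effective Young's moduli, the
#' anisotropy index and - when ex vivo parameters are available - relative
#' errors of the moduli are appended per subject.
#'
#' @param subjects List of [subject_record]s (may be empty).
#' @param mode `"M01"`, `"M02"`, `"M03"` or `"custom"`.
#' @param exvivo_params Named list of [mr_params] keyed by subject id.
#'   Required in M01 mode (it supplies the initial guesses); in other modes
#'   optional, used only as the moduli baseline for relative errors.
#' @param init_params [mr_params] for `"custom"` mode.
#' @param config An [iteration_config].
#' @param modulus_protocol Loading protocol for the effective moduli
#'   (default `"strip"`).
#' @return An object of class `invivo_cohort`: a list with `results` (the
#'   per-subject table: S, k, final coefficients, YMc, YMa, AI, REs,
#'   feasibility), `fits` (the `invivo_fit` objects), `mode` and the initial
#'   guess(es).
#' @export
estimate_invivo_cohort <- function(subjects,
                                   mode = c("M01", "M02", "M03", "custom"),
                                   exvivo_params = NULL, init_params = NULL,
                                   config = iteration_config(),
                                   modulus_protocol = "strip") {
  mode <- match.arg(mode)
  if (mode == "M01" && is.null(exvivo_params))
    stop("M01 mode needs per-subject ex vivo parameters (exvivo_params)")
  if (mode == "M02") init_params <- initial_guess_m02()
  if (mode == "M03") init_params <- initial_guess_m03()
  if (mode == "custom" && is.null(init_params))
    stop("custom mode needs init_params")

  cols <- c("id", "S_pct", "k", "c1_kPa", "D1_kPa", "D2", "K1_kPa", "K2",
            "theta_deg", "YMc_kPa", "YMa_kPa", "AI", "RE_YMc_pct",
            "RE_YMa_pct", "feasible")
  if (!length(subjects)) {
    empty <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), 13), list(logical(0))),
      cols))
    return(structure(list(results = empty, fits = list(), mode = mode,
                          init_params = init_params),
                     class = "invivo_cohort"))
  }

  fits <- list()
  rows <- lapply(subjects, function(sub) {
    init <- if (mode == "M01") {
      p <- exvivo_params[[sub$id]]
      if (is.null(p)) stop("no ex vivo parameters for subject ", sub$id)
      p
    } else init_params
    fit <- tryCatch(estimate_invivo(sub, init, config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(id = sub$id, S_pct = NA, k = NA, c1_kPa = NA,
                        D1_kPa = NA, D2 = NA, K1_kPa = NA, K2 = NA,
                        theta_deg = NA, YMc_kPa = NA, YMa_kPa = NA, AI = NA,
                        RE_YMc_pct = NA, RE_YMa_pct = NA, feasible = FALSE))
    }
    fits[[sub$id]] <<- fit
    p <- fit$final_params
    ym_c <- effective_young_modulus(p, "circumferential",
                                    protocol = modulus_protocol)
    ym_a <- effective_young_modulus(p, "axial", protocol = modulus_protocol)
    re_c <- re_a <- NA_real_
    if (!is.null(exvivo_params[[sub$id]])) {
      pe <- exvivo_params[[sub$id]]
      re_c <- relative_error(
        ym_c, effective_young_modulus(pe, "circumferential",
                                      protocol = modulus_protocol))
      re_a <- relative_error(
        ym_a, effective_young_modulus(pe, "axial",
                                      protocol = modulus_protocol))
    }
    data.frame(id = sub$id, S_pct = 100 * fit$S, k = fit$k,
               c1_kPa = p$c1, D1_kPa = p$D1, D2 = p$D2, K1_kPa = p$K1,
               K2 = p$K2, theta_deg = p$theta,
               YMc_kPa = ym_c, YMa_kPa = ym_a,
               AI = anisotropy_index(ym_c, ym_a),
               RE_YMc_pct = re_c, RE_YMa_pct = re_a, feasible = TRUE)
  })
  structure(list(results = do.call(rbind, rows), fits = fits, mode = mode,
                 init_params = init_params),
            class = "invivo_cohort")
}

#' @export
print.invivo_cohort <- function(x, ...) {
  cat(sprintf("In vivo cohort estimates (%d subjects, initial setting %s)\n",
              nrow(x$results), x$mode))
  if (!is.null(x$init_params) && x$mode != "M01") {
    cat("  common initial guess:\n")
    print(x$init_params)
  }
  df <- x$results
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round_half_away(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.invivo_fit <- function(x, n_points = 25, ...) {
  sub <- x$subject
  geom <- zero_pressure_geometry(sub, x$S)
  P_grid <- seq(0, mmhg_to_kpa(sub$pressure_sys_mmHg) * 1.15,
                length.out = n_points)
  per <- vapply(P_grid, function(P)
    inflate(geom, x$final_params, P, sub$axial_stretch)$lumen_perimeter_cm,
    numeric(1))
  graphics::plot(P_grid, per, type = "l",
                 xlab = "luminal pressure (kPa)",
                 ylab = "lumen perimeter (cm)",
                 main = sprintf("Subject %s: fitted pressure-perimeter curve",
                                sub$id), ...)
  graphics::points(mmhg_to_kpa(c(sub$pressure_dia_mmHg,
                                 sub$pressure_sys_mmHg)),
                   c(sub$perimeter_min_cm, sub$perimeter_max_cm),
                   pch = 19, col = 2)
  graphics::legend("topleft", c("model", "measured"), lty = c(1, NA),
                   pch = c(NA, 19), col = c(1, 2), bty = "n")
  invisible(x)
}
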