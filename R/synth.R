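# Seeded generators for synthetic biaxial datasets and virtual subjects
# with known ground truth, so fitting and inverse estimation can be
# exercised end-to-end without any external data. Parameter ranges span the
# values observed across the packaged ex vivo fits; geometry and pressure
# ranges span the packaged clinical cohort.

#' Specification of a synthetic subject cohort
#'
#' Ranges default to the spans observed in the packaged reference cohort
#' and ex vivo parameter tables: stress-like coefficients are sampled
#' log-uniformly (they span three orders of magnitude across real
#' specimens), exponents and the fiber angle uniformly.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; generation is deterministic per
#'   `(seed, index)`.
#' @param c1_range,D1_range,K1_range Ranges (kPa) for the stress-like
#'   coefficients, sampled log-uniformly.
#' @param D2_range,K2_range,theta_range Ranges for the exponents and the
#'   fiber half-angle (degrees), sampled uniformly.
#' @param perimeter_range Reference lumen perimeter range in cm.
#' @param thickness_range Wall thickness range in mm.
#' @param pressure_sys_range,pressure_dia_range Cuff pressure ranges, mmHg.
#' @param S_range True circumferential shrinkage range.
#' @param perimeter_noise_cv Multiplicative noise CV on the generated
#'   perimeters (0 = exact forward-model perimeters).
#' @param axial_stretch In vivo axial stretch.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed = 1L,
                        c1_range = c(0.05, 10), D1_range = c(5, 25),
                        K1_range = c(0.05, 2.5), D2_range = c(0.6, 2.2),
                        K2_range = c(0.1, 10), theta_range = c(5, 40),
                        perimeter_range = c(8, 15),
                        thickness_range = c(1.2, 2.8),
                        pressure_sys_range = c(79, 140),
                        pressure_dia_range = c(45, 91),
                        S_range = c(0.55, 0.90),
                        perimeter_noise_cv = 0,
                        axial_stretch = 1.25) {
  ranges <- list(c1_range = c1_range, D1_range = D1_range,
                 K1_range = K1_range, D2_range = D2_range,
                 K2_range = K2_range, theta_range = theta_range,
                 perimeter_range = perimeter_range,
                 thickness_range = thickness_range,
                 pressure_sys_range = pressure_sys_range,
                 pressure_dia_range = pressure_dia_range,
                 S_range = S_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] || any(r <= 0))
      stop("invalid range for ", nm)
  }
  stopifnot(n_subjects >= 1, perimeter_noise_cv >= 0, axial_stretch > 0)
  structure(c(list(n_subjects = as.integer(n_subjects),
                   seed = as.integer(seed),
                   perimeter_noise_cv = perimeter_noise_cv,
                   axial_stretch = axial_stretch), ranges),
            class = "cohort_spec")
}

.runif_log <- function(range) exp(stats::runif(1, log(range[1]),
                                               log(range[2])))
.runif_in <- function(range) stats::runif(1, range[1], range[2])

#' Generate one virtual subject with known ground truth
#'
#' Samples true material parameters and geometry, builds the zero-pressure
#' tube from the true shrinkage, inflates it at the diastolic and systolic
#' pressures to produce the two observed perimeters (optionally perturbed
#' by multiplicative noise), and returns the observable subject record
#' alongside the generating truth. Deterministic for a given
#' `(spec$seed, index)` pair.
#'
#' @param spec A [cohort_spec].
#' @param index Subject index (1-based).
#' @param max_retries Resampling budget for configurations whose inflation
#'   fails (default 8).
#' @return A list with `subject` ([subject_record]), `params` (true
#'   [mr_params]) and `S` (true shrinkage).
#' @export
generate_subject <- function(spec, index, max_retries = 8) {
  stopifnot(inherits(spec, "cohort_spec"), index >= 1)
  .with_seed((spec$seed * 100003 + index) %% 2147483647, {
    for (attempt in seq_len(max_retries)) {
      params <- mr_params(.runif_log(spec$c1_range),
                          .runif_log(spec$D1_range), .runif_in(spec$D2_range),
                          .runif_log(spec$K1_range), .runif_in(spec$K2_range),
                          .runif_in(spec$theta_range))
      ref_perim <- .runif_in(spec$perimeter_range)
      thickness <- .runif_in(spec$thickness_range)
      p_dia <- .runif_in(spec$pressure_dia_range)
      p_sys <- max(spec$pressure_sys_range[1], p_dia + 15) +
        stats::runif(1, 0, 20)
      p_sys <- min(p_sys, spec$pressure_sys_range[2])
      S_true <- .runif_in(spec$S_range)

      # temporary record carrying the sampled reference geometry; the
      # perimeter fields are placeholders until the forward model fills them
      proto <- subject_record(sprintf("SYN%03d", index), p_sys, p_dia,
                              perimeter_min_cm = ref_perim * 0.5,
                              perimeter_max_cm = ref_perim,
                              thickness_mm = thickness,
                              reference_perimeter_cm = ref_perim,
                              axial_stretch = spec$axial_stretch)
      geom <- zero_pressure_geometry(proto, S_true)
      per <- tryCatch({
        c(inflate(geom, params, mmhg_to_kpa(p_dia),
                  spec$axial_stretch)$lumen_perimeter_cm,
          inflate(geom, params, mmhg_to_kpa(p_sys),
                  spec$axial_stretch)$lumen_perimeter_cm)
      }, error = function(e) NULL)
      if (is.null(per)) next
      if (spec$perimeter_noise_cv > 0)
        per <- per * (1 + stats::rnorm(2, 0, spec$perimeter_noise_cv))
      if (!(per[2] > per[1] && per[1] > 0)) next
      subject <- subject_record(proto$id, p_sys, p_dia,
                                perimeter_min_cm = per[1],
                                perimeter_max_cm = per[2],
                                thickness_mm = thickness,
                                reference_perimeter_cm = ref_perim,
                                axial_stretch = spec$axial_stretch)
      return(list(subject = subject, params = params, S = S_true))
    }
    stop("generate_subject: no inflatable configuration found for index ",
         index, " after ", max_retries, " attempts")
  })
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec].
#' @return A list of [generate_subject()] results of length
#'   `spec$n_subjects`.
#' @export
generate_cohort <- function(spec) {
  lapply(seq_len(spec$n_subjects), function(i) generate_subject(spec, i))
}

#' Generate a synthetic five-protocol biaxial dataset
#'
#' Simulates the standard five force-ratio protocols for a known parameter
#' set and adds seeded Gaussian noise to the engineering stresses. The
#' provenance (seed and noise level) travels with the dataset as
#' attributes.
#'
#' @param params True [mr_params].
#' @param geometry A [sample_geometry].
#' @param noise_sd Additive stress noise standard deviation in kPa.
#' @param seed Integer seed for the noise.
#' @param protocols List of [biaxial_protocol]s (default
#'   [standard_protocols()]).
#' @return A biaxial dataset data.frame (see [read_biaxial_csv()]) with
#'   attributes `provenance` (`"synthetic"`), `seed` and `noise_sd`.
#' @export
generate_biaxial <- function(params, geometry, noise_sd = 0, seed = 1L,
                             protocols = standard_protocols()) {
  dat <- do.call(rbind, lapply(protocols, function(pr)
    simulate_protocol(params, geometry, pr)))
  if (noise_sd > 0) {
    noise <- .with_seed(seed, stats::rnorm(2 * nrow(dat), 0, noise_sd))
    dat$Pc_kPa <- pmax(dat$Pc_kPa + noise[seq_len(nrow(dat))], 0)
    dat$Pa_kPa <- pmax(dat$Pa_kPa + noise[-seq_len(nrow(dat))], 0)
  }
  attr(dat, "provenance") <- "synthetic"
  attr(dat, "seed") <- seed
  attr(dat, "noise_sd") <- noise_sd
  dat
}
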