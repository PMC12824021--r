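# Stiffness summaries and nonparametric statistics: effective Young's
# moduli from proportional fits to stress-stretch curves, the anisotropy
# index, relative errors, quantile descriptives and the exact one-sided
# Wilcoxon signed-rank test.

#' Effective Young's modulus of a parameter set
#'
#' Slope of the linear proportional function `sigma = E (lambda - 1)` fitted
#' through the origin-anchored point (1, 0) to the Cauchy stress-stretch
#' curve over the stretch interval `[1.0, 1.3]`:
#' `E = sum(sigma_i (lambda_i - 1)) / sum((lambda_i - 1)^2)`.
#'
#' @param params An [mr_params] object.
#' @param direction `"circumferential"` or `"axial"`.
#' @param protocol Loading protocol of the curve (default `"strip"`: the
#'   transverse in-plane stretch held at 1, which reproduces the packaged
#'   reference moduli from their parameter sets; see
#'   [stress_stretch_curve()]).
#' @param stretch Stretch grid (default 31 uniform points on `[1, 1.3]`).
#' @return Effective modulus in kPa.
#' @export
effective_young_modulus <- function(params,
                                    direction = c("circumferential",
                                                  "axial"),
                                    protocol = "strip",
                                    stretch = seq(1, 1.3,
                                                  length.out = 31)) {
  direction <- match.arg(direction)
  if (length(stretch) < 2 || all(stretch == 1))
    stop("degenerate stretch grid")
  curve <- stress_stretch_curve(params, direction, protocol, stretch)
  x <- curve$stretch - 1
  sum(curve$stress_kPa * x) / sum(x^2)
}

#' Anisotropy index of a pair of effective moduli
#'
#' `AI = (YMc - YMa) / ((YMc + YMa) / 2)`: the normalized difference of the
#' circumferential and axial effective Young's moduli, bounded in (-2, 2)
#' and zero for an isotropic response.
#'
#' @param YMc,YMa Effective moduli in kPa (> 0).
#' @return Dimensionless index.
#' @examples
#' anisotropy_index(181.46, 142.92)
#' @export
anisotropy_index <- function(YMc, YMa) {
  if (any(YMc <= 0) || any(YMa <= 0))
    stop("effective moduli must be positive")
  (YMc - YMa) / (0.5 * (YMc + YMa))
}

#' Relative error in percent
#'
#' @param estimate,reference Numeric; `reference` must be non-zero.
#' @return `100 * (estimate - reference) / reference`.
#' @export
relative_error <- function(estimate, reference) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (estimate - reference) / reference
}

#' Relative perimeter change over the cardiac cycle
#'
#' @param min_cm,max_cm Minimum and maximum lumen perimeter (cm),
#'   `0 < min <= max`.
#' @return Percent change `100 * (max - min) / min`.
#' @export
perimeter_change <- function(min_cm, max_cm) {
  if (any(min_cm <= 0)) stop("minimum perimeter must be positive")
  if (any(max_cm < min_cm)) stop("need max_cm >= min_cm")
  100 * (max_cm - min_cm) / min_cm
}

#' Median and interquartile range
#'
#' Sample quantiles by linear interpolation between order statistics at
#' positions `1 + (n - 1) q` (the type-7 convention).
#'
#' @param values Numeric vector, length >= 1.
#' @return A named numeric vector `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  if (!length(values) || any(!is.finite(values)))
    stop("values must be a non-empty finite numeric vector")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# exact null distribution of the signed-rank sum via the generating
# function over doubled ranks (average ranks of ties are half-integers);
# counts stay exact in doubles for n <= 25 (2^25 < 2^53)
.signed_rank_distribution <- function(ranks2) {
  counts <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts)
    counts <- c(counts, rep(0, r)) + shifted
  }
  counts  # counts[w + 1] = #sign vectors with doubled statistic w
}

#' Exact one-sided Wilcoxon signed-rank test for paired data
#'
#' Computes `W`, the sum of the ranks of the positive differences `x - y`
#' (average ranks for tied magnitudes, zero differences dropped with `n`
#' reduced), and the exact one-sided p-value under the uniform sign-flip
#' null by full enumeration of the `2^n` sign assignments (evaluated through
#' the rank generating function, which is exact and equal to the explicit
#' enumeration). `alternative = "less"` gives `P(W* <= W)`, `"greater"`
#' gives `P(W* >= W)`. The effect size `r` is derived from the exact p via
#' [effect_size_r()].
#'
#' @param x,y Paired numeric vectors of equal length (`n <= 25` after
#'   dropping zero differences).
#' @param alternative `"less"` or `"greater"`.
#' @return An object of class `paired_test`: `W`, `p`, `r`, `n`,
#'   `alternative`.
#' @export
wilcoxon_exact <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero; test undefined")
  if (n > 25) stop("exact enumeration supports at most 25 non-zero pairs")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  counts <- .signed_rank_distribution(as.integer(round(2 * rk)))
  total <- 2^n
  w2 <- round(2 * W)
  p <- if (alternative == "less") {
    sum(counts[seq_len(w2 + 1)]) / total
  } else {
    sum(counts[seq(w2 + 1, length(counts))]) / total
  }
  r <- if (p > 0 && p < 1) effect_size_r(p, n) else NA_real_
  structure(list(W = W, p = p, r = r, n = n,
                 alternative = alternative),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(paste0("Exact Wilcoxon signed-rank test (one-sided, %s)\n",
                     "  n = %d non-zero pairs, W = %g, p = %.4g, ",
                     "effect size r = %.3f\n"),
              x$alternative, x$n, x$W, x$p, x$r))
  invisible(x)
}

#' Effect size from an exact one-sided p-value
#'
#' `r = qnorm(1 - p) / sqrt(n)`: the standard-normal upper quantile of the
#' exact p-value scaled by the square root of the pair count. This is the
#' z-based effect size computed from the exact (rather than asymptotic)
#' significance level.
#'
#' @param p One-sided p-value in (0, 1).
#' @param n Number of pairs (>= 1).
#' @return Dimensionless effect size.
#' @export
effect_size_r <- function(p, n) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie strictly in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  stats::qnorm(1 - p) / sqrt(n)
}

#' Statistics summary as JSON
#'
#' Serializes a [wilcoxon_exact()] result to a small JSON file with keys
#' `W`, `p`, `r`, `n`, `alternative`.
#'
#' @param test A `paired_test` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_test_json <- function(test, path) {
  stopifnot(inherits(test, "paired_test"))
  jsonlite::write_json(list(W = test$W, p = test$p, r = test$r, n = test$n,
                            alternative = test$alternative),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
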