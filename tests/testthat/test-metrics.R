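test_that("effective modulus equals an independent dense-grid regression", {
  p <- ad1_params()
  grid <- seq(1, 1.3, length.out = 10000)
  for (proto in c("strip", "equibiaxial")) {
    E <- effective_young_modulus(p, "circumferential", proto,
                                 stretch = grid)
    dense <- stress_stretch_curve(p, "circumferential", proto, grid)
    E_ref <- unname(coef(stats::lm(stress_kPa ~ 0 + I(stretch - 1),
                                   data = dense)))
    expect_lt(abs(E - E_ref) / E_ref, 0.001)
    # the default 31-point grid agrees with the dense evaluation closely
    E31 <- effective_young_modulus(p, "circumferential", proto)
    expect_lt(abs(E31 - E_ref) / E_ref, 0.02)
  }
})

test_that("effective modulus is homogeneous of degree one", {
  p <- ad1_params()
  E1c <- effective_young_modulus(p, "circumferential")
  E1a <- effective_young_modulus(p, "axial")
  for (k in c(0.7, 3)) {
    pk <- scale_stiffness(p, k)
    expect_equal(effective_young_modulus(pk, "circumferential"), k * E1c,
                 tolerance = 1e-10)
    expect_equal(effective_young_modulus(pk, "axial"), k * E1a,
                 tolerance = 1e-10)
  }
  expect_error(effective_young_modulus(p, stretch = c(1, 1)), "degenerate")
})

test_that("anisotropy index reproduces reference values and its symmetry", {
  expect_equal(round_half_away(anisotropy_index(181.46, 142.92), 2), 0.24)
  expect_equal(round_half_away(anisotropy_index(3413.61, 142.87), 2), 1.84)
  expect_equal(anisotropy_index(57.3, 57.3), 0)
  expect_equal(anisotropy_index(10, 250), -anisotropy_index(250, 10))
  # bounded in (-2, 2)
  set.seed(2)
  a <- runif(50, 1e-3, 1e4); b <- runif(50, 1e-3, 1e4)
  ai <- anisotropy_index(a, b)
  expect_true(all(ai > -2 & ai < 2))
  expect_error(anisotropy_index(-1, 2), "positive")
})

test_that("relative error and perimeter change match reference arithmetic", {
  expect_equal(round_half_away(relative_error(126.38, 181.46), 2), -30.35)
  expect_equal(relative_error(5, 5), 0)
  expect_equal(relative_error(10, 5), 100)
  expect_error(relative_error(1, 0), "non-zero")
  expect_equal(round_half_away(perimeter_change(10.58, 12.96), 1), 22.5)
  expect_equal(perimeter_change(8.50, 9.69), 14, tolerance = 1e-12)
  expect_equal(perimeter_change(7, 7), 0)
  expect_error(perimeter_change(0, 1), "positive")
})

test_that("median and quartiles follow the interpolation convention", {
  m01 <- aorta_fixture("stiffness_m01")
  q <- median_iqr(m01$RE_YMc_pct)
  expect_equal(round_half_away(q[["median"]], 2), -14.50)
  expect_equal(round_half_away(q[["q1"]], 2), -19.66)
  expect_equal(round_half_away(q[["q3"]], 2), -6.67)
  expect_equal(median_iqr(3.7), c(median = 3.7, q1 = 3.7, q3 = 3.7))
  # independent sort-and-interpolate oracle
  oracle <- function(v, prob) {
    s <- sort(v); n <- length(s)
    h <- 1 + (n - 1) * prob
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  set.seed(8)
  for (n in c(1, 2, 3, 7, 20, 50)) {
    v <- rnorm(n)
    q <- median_iqr(v)
    expect_equal(q[["median"]], oracle(v, 0.5), tolerance = 1e-12)
    expect_equal(q[["q1"]], oracle(v, 0.25), tolerance = 1e-12)
    expect_equal(q[["q3"]], oracle(v, 0.75), tolerance = 1e-12)
  }
  expect_error(median_iqr(numeric(0)), "non-empty")
})

test_that("exact signed-rank test agrees with full enumeration", {
  # brute-force oracle over all 2^n sign assignments
  oracle <- function(x, y, alternative) {
    d <- x - y; d <- d[d != 0]; n <- length(d)
    rk <- rank(abs(d)); W <- sum(rk[d > 0])
    count <- 0
    for (m in 0:(2^n - 1)) {
      signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
      Wm <- sum(rk[signs])
      hit <- if (alternative == "less") Wm <= W + 1e-9 else Wm >= W - 1e-9
      count <- count + hit
    }
    list(W = W, p = count / 2^n)
  }
  set.seed(13)
  for (i in 1:12) {
    n <- sample(3:12, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)  # rounding provokes ties and zero differences
    if (all(x == y)) x[1] <- x[1] + 1
    for (alt in c("less", "greater")) {
      got <- wilcoxon_exact(x, y, alt)
      ref <- oracle(x, y, alt)
      expect_equal(got$W, ref$W)
      expect_equal(got$p, ref$p, tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_exact(1:4, 1:4), "zero")
  expect_error(wilcoxon_exact(1:3, 1:4), "equal length")
})

test_that("signed-rank statistics reproduce the reference comparisons", {
  m01 <- aorta_fixture("stiffness_m01")
  w_c <- wilcoxon_exact(m01$YMc_invivo_kPa, m01$YMc_exvivo_kPa, "less")
  expect_equal(w_c$W, 0)
  expect_equal(w_c$p, 1 / 1024)
  expect_equal(round_half_away(w_c$r, 2), 0.98)
  w_a <- wilcoxon_exact(m01$YMa_invivo_kPa, m01$YMa_exvivo_kPa, "less")
  expect_equal(w_a$W, 8)
  expect_equal(w_a$p, 25 / 1024)
  expect_equal(round_half_away(w_a$r, 2), 0.62)
  # all differences positive under "less": the statistic saturates
  sat <- wilcoxon_exact(c(2, 3, 4), c(1, 2, 3), "less")
  expect_equal(sat$W, 6)
  expect_equal(sat$p, 1)
})

test_that("effect size follows the exact-p normal-quantile form", {
  expect_equal(round_half_away(effect_size_r(25 / 1024, 10), 2), 0.62)
  expect_equal(round_half_away(effect_size_r(1 / 1024, 10), 2), 0.98)
  expect_equal(round_half_away(effect_size_r(2 / 1024, 10), 3), 0.913)
  expect_equal(effect_size_r(0.5, 7), 0)
  expect_error(effect_size_r(0, 10), "0, 1")
  expect_error(effect_size_r(1, 10), "0, 1")
})
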