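test_that("invariants at the identity and for aligned fibers are exact", {
  for (th in c(0, 17.3, 44.9)) {
    st <- invariants_from_stretches(1, 1, 1, th)
    expect_equal(st$I1, 3)
    expect_equal(st$I3, 1)
    expect_equal(st$I4, 1)
    expect_equal(st$J4, 1)
  }
  # fiber along the circumferential direction sees the squared hoop stretch
  st <- invariants_from_stretches(1.3, 1.25, 1 / (1.3 * 1.25), 0)
  expect_equal(st$I4, 1.69)
  expect_error(invariants_from_stretches(-1, 1, 1, 0), "positive")
  expect_error(invariants_from_stretches(1, 1, 1, 95), "theta")
})

test_that("fiber invariant matches the explicit matrix-product oracle", {
  cases <- list(c(1.2, 1.1, 30), c(1.05, 1.3, 10), c(0.9, 1.4, 44),
                c(1.33, 0.95, 5.56))
  for (cs in cases) {
    lc <- cs[1]; la <- cs[2]; th <- cs[3]
    lr <- lam_r(lc, la)
    st <- invariants_from_stretches(lc, la, lr, th)
    C <- diag(c(lc^2, la^2, lr^2))
    na <- c(cos(th * pi / 180), sin(th * pi / 180), 0)
    nb <- c(cos(th * pi / 180), -sin(th * pi / 180), 0)
    expect_equal(st$I4, drop(t(na) %*% C %*% na), tolerance = 1e-12)
    expect_equal(st$I6, drop(t(nb) %*% C %*% nb), tolerance = 1e-12)
    expect_equal(st$I1, sum(diag(C)), tolerance = 1e-12)
    expect_equal(st$I3, det(C), tolerance = 1e-12)
  }
})

test_that("strain energy equals a term-by-term hand evaluation", {
  p <- ad1_params()
  lc <- la <- 1.1
  lr <- lam_r(lc, la)
  st <- invariants_from_stretches(lc, la, lr, p$theta)
  # independent term-wise evaluation of the energy
  i1m3 <- (lc^2 + la^2 + lr^2) - 3
  th <- p$theta * pi / 180
  i4 <- lc^2 * cos(th)^2 + la^2 * sin(th)^2
  w_ref <- p$c1 * i1m3 + p$D1 * (exp(p$D2 * i1m3) - 1) +
    p$K1 / (2 * p$K2) * (2 * exp(p$K2 * (i4 - 1)^2) - 2)
  expect_equal(strain_energy(p, st), w_ref, tolerance = 1e-12)
  # identity state carries no energy
  expect_equal(strain_energy(p, invariants_from_stretches(1, 1, 1, p$theta)),
               0)
  # no fiber stiffness, no anisotropic contribution
  p0 <- mr_params(p$c1, p$D1, p$D2, 0, p$K2, p$theta)
  w_iso <- p$c1 * i1m3 + p$D1 * (exp(p$D2 * i1m3) - 1)
  expect_equal(strain_energy(p0, st), w_iso, tolerance = 1e-12)
})

test_that("small-K2 energies use the analytic limit and stay finite", {
  st <- invariants_from_stretches(1.2, 1.1, lam_r(1.2, 1.1), 20)
  p_small <- mr_params(1, 1, 1, 2, 1e-9, 20)  # K2 floored internally
  w_ref <- 1 * (st$I1 - 3) + 1 * (exp(st$I1 - 3) - 1) +
    p_small$K1 / 2 * ((st$J4 - 1)^2 + (st$J6 - 1)^2)
  expect_equal(strain_energy(p_small, st), w_ref, tolerance = 1e-6)
  expect_error(strain_energy(mr_params(1, 1, 50, 0, 1, 0),
                             invariants_from_stretches(3, 3, lam_r(3, 3), 0)),
               "overflow")
})

test_that("analytic biaxial stresses match finite differences of the energy", {
  p <- ad1_params()
  set.seed(11)
  for (i in 1:20) {
    lc <- runif(1, 0.9, 1.35)
    la <- runif(1, 0.9, 1.35)
    s <- biaxial_cauchy_stress(p, lc, la)
    h <- 1e-6
    fd_c <- lc * (w_hat(p, lc + h, la) - w_hat(p, lc - h, la)) / (2 * h)
    fd_a <- la * (w_hat(p, lc, la + h) - w_hat(p, lc, la - h)) / (2 * h)
    denom <- max(abs(fd_c), abs(fd_a), 1e-8)
    expect_lt(abs(s$sigma_c - fd_c) / denom, 1e-6)
    expect_lt(abs(s$sigma_a - fd_a) / denom, 1e-6)
    # engineering stress is Cauchy over stretch in each diagonal direction
    expect_equal(s$P_c, s$sigma_c / lc, tolerance = 1e-12)
    expect_equal(s$P_a, s$sigma_a / la, tolerance = 1e-12)
  }
})

test_that("energy is nonnegative for randomized incompressible states", {
  p <- ad1_params()
  set.seed(5)
  for (i in 1:50) {
    lc <- exp(runif(1, -0.4, 0.4))
    la <- exp(runif(1, -0.4, 0.4))
    st <- invariants_from_stretches(lc, la, lam_r(lc, la), p$theta)
    expect_gte(st$I1, 3)
    expect_gte(strain_energy(p, st), 0)
  }
})

test_that("stress is homogeneous of degree one in the stress-like triple", {
  p <- ad1_params()
  for (k in c(0.25, 0.70, 3)) {
    pk <- scale_stiffness(p, k)
    s1 <- biaxial_cauchy_stress(p, 1.22, 1.13)
    sk <- biaxial_cauchy_stress(pk, 1.22, 1.13)
    expect_equal(sk$sigma_c, k * s1$sigma_c, tolerance = 1e-12)
    expect_equal(sk$sigma_a, k * s1$sigma_a, tolerance = 1e-12)
  }
})

test_that("symmetric loadings give symmetric stresses", {
  # isotropic response under equal stretch
  p0 <- mr_params(5, 2, 1, 0, 1, 0)
  s <- biaxial_cauchy_stress(p0, 1.2, 1.2)
  expect_equal(s$sigma_c, s$sigma_a, tolerance = 1e-12)
  # fibers at 45 degrees sit symmetrically between the two loading axes
  p45 <- mr_params(2, 3, 1, 4, 2, 45 - 1e-12)
  s45 <- biaxial_cauchy_stress(p45, 1.25, 1.25)
  expect_equal(s45$sigma_c, s45$sigma_a, tolerance = 1e-8)
  # unloaded state is stress-free
  s0 <- biaxial_cauchy_stress(ad1_params(), 1, 1)
  expect_equal(s0$sigma_c, 0)
  expect_equal(s0$sigma_a, 0)
})

test_that("stress-stretch curves are protocol-consistent", {
  p <- ad1_params()
  grid <- seq(1.05, 1.3, length.out = 6)
  cv <- stress_stretch_curve(p, "circumferential", "equibiaxial", grid)
  direct <- biaxial_cauchy_stress(p, grid, grid)$sigma_c
  expect_equal(cv$stress_kPa, direct, tolerance = 1e-12)
  # isotropic equibiaxial curves coincide across directions
  p0 <- isotropic_params()
  c1v <- stress_stretch_curve(p0, "circumferential", "equibiaxial")
  c2v <- stress_stretch_curve(p0, "axial", "equibiaxial")
  expect_equal(c1v$stress_kPa, c2v$stress_kPa, tolerance = 1e-12)
  # doubling the stress-like triple doubles the whole curve
  c2x <- stress_stretch_curve(scale_stiffness(p, 2), "circumferential",
                              "equibiaxial", grid)
  expect_equal(c2x$stress_kPa, 2 * cv$stress_kPa, tolerance = 1e-12)
  # uniaxial: the transverse in-plane stress is driven to zero
  cu <- stress_stretch_curve(p, "circumferential", "uniaxial",
                             seq(1, 1.3, length.out = 7))
  expect_true(all(diff(cu$stress_kPa) > 0))
  expect_equal(cu$stress_kPa[1], 0, tolerance = 1e-8)
})
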