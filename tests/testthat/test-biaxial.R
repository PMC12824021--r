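test_that("force-to-stress conversion is the engineering-stress definition", {
  g <- sample_geometry(20, 2.42)
  expect_equal(force_to_stress(2, g), 2 / (0.020 * 0.00242) / 1000,
               tolerance = 1e-12)  # 41.32 kPa
  expect_equal(force_to_stress(0, g), 0)
  g2 <- sample_geometry(20, 2 * 2.42)
  expect_equal(force_to_stress(2, g2), force_to_stress(2, g) / 2,
               tolerance = 1e-12)
  expect_error(force_to_stress(-1, g), "non-negative")
  expect_error(sample_geometry(20, 0), ">")
})

test_that("protocol simulation meets its stress targets", {
  p <- ad1_params()
  g <- sample_geometry(20, 2.42)
  pr <- biaxial_protocol(1, 0.5, n_steps = 6)
  dat <- simulate_protocol(p, g, pr)
  expect_equal(nrow(dat), 6)
  # solved stretches reproduce the engineering-stress targets
  s <- biaxial_cauchy_stress(p, dat$lambda_c, dat$lambda_a)
  expect_lt(max(abs(s$P_c - dat$Pc_kPa)), 1e-8)
  expect_lt(max(abs(s$P_a - dat$Pa_kPa)), 1e-8)
  # the load path starts arbitrarily close to the unloaded state
  pr_fine <- biaxial_protocol(1, 1, n_steps = 50)
  dat_fine <- simulate_protocol(isotropic_params(), g, pr_fine)
  expect_lt(abs(dat_fine$lambda_c[1] - 1), 0.05)
  # isotropic equibiaxial loading keeps both stretches equal
  expect_equal(dat_fine$lambda_c, dat_fine$lambda_a, tolerance = 1e-10)
})

test_that("noiseless generate-then-fit reproduces the stress response", {
  p <- ad1_params()
  g <- sample_geometry(20, 2.42)
  dat <- generate_biaxial(p, g)
  fit <- fit_biaxial(dat, seed = 1)
  expect_gte(fit$r_squared, 0.999)
  pred <- predict(fit)
  max_stress <- max(dat$Pc_kPa, dat$Pa_kPa)
  err <- max(abs(c(pred$Pc_kPa - dat$Pc_kPa, pred$Pa_kPa - dat$Pa_kPa)))
  expect_lt(err / max_stress, 0.01)
  # the generating parameters themselves have R^2 = 1 on their own data
  obs <- c(dat$Pc_kPa, dat$Pa_kPa)
  res <- c(biaxial_cauchy_stress(p, dat$lambda_c, dat$lambda_a)$P_c -
             dat$Pc_kPa,
           biaxial_cauchy_stress(p, dat$lambda_c, dat$lambda_a)$P_a -
             dat$Pa_kPa)
  expect_equal(1 - sum(res^2) / sum((obs - mean(obs))^2), 1,
               tolerance = 1e-10)
})

test_that("fitting a zero-angle dataset pins theta near its bound yet matches", {
  p0 <- mr_params(2, 10, 1, 1.5, 1, 0)
  g <- sample_geometry(20, 2)
  dat <- generate_biaxial(p0, g)
  fit <- fit_biaxial(dat, seed = 2)
  pred <- predict(fit)
  max_stress <- max(dat$Pc_kPa, dat$Pa_kPa)
  err <- max(abs(c(pred$Pc_kPa - dat$Pc_kPa, pred$Pa_kPa - dat$Pa_kPa)))
  expect_lt(err / max_stress, 0.01)
  expect_gt(coef(fit)["theta"], 0)
  expect_lt(coef(fit)["theta"], 45)
})

test_that("fit is invariant to record order and equivariant to stress units", {
  p <- ad1_params()
  g <- sample_geometry(20, 2.42)
  dat <- generate_biaxial(p, g)
  fit1 <- fit_biaxial(dat, seed = 3)
  perm <- sample(seq_len(nrow(dat)))
  fit2 <- fit_biaxial(dat[perm, ], seed = 3)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
  # stress unit rescaling rescales the stress-like coefficients, leaving
  # the predicted response equivalent
  dat_pa <- dat
  dat_pa$Pc_kPa <- dat$Pc_kPa * 1000
  dat_pa$Pa_kPa <- dat$Pa_kPa * 1000
  fit_pa <- fit_biaxial(dat_pa, seed = 3)
  pred_pa <- predict(fit_pa, dat_pa)
  pred <- predict(fit1, dat)
  max_stress <- max(dat_pa$Pc_kPa)
  expect_lt(max(abs(pred_pa$Pc_kPa - 1000 * pred$Pc_kPa)) / max_stress,
            0.01)
})

test_that("moderate stress noise keeps the fit quality above 0.91", {
  p <- ad1_params()
  g <- sample_geometry(20, 2.42)
  max_stress <- force_to_stress(2, g)
  for (seed in 1:3) {
    dat <- generate_biaxial(p, g, noise_sd = 0.02 * max_stress, seed = seed)
    fit <- fit_biaxial(dat, seed = seed)
    expect_gt(fit$r_squared, 0.91)
  }
})

test_that("fit input contracts are enforced", {
  p <- ad1_params()
  g <- sample_geometry(20, 2.42)
  one <- simulate_protocol(p, g, biaxial_protocol(1, 1, n_steps = 8))
  expect_error(fit_biaxial(one), "two protocols")
  two <- rbind(one[1, ], simulate_protocol(p, g,
                                           biaxial_protocol(1, 0.5,
                                                            n_steps = 1)))
  expect_error(fit_biaxial(two), "residuals")
})
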