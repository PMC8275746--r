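test_that("basis index sets have the predicted size and structure", {
  # enumeration of (j, l, m) under 2j + l = N + 2, even N, |m| <= l
  count <- function(n_max) {
    n <- 0
    for (N in seq(0, n_max, by = 2)) for (j in 1:((N + 2) / 2)) {
      l <- N + 2 - 2 * j
      n <- n + 2 * l + 1
    }
    n
  }
  s6 <- map_basis_spec(6, 5)
  s8 <- map_basis_spec(8, 5)
  expect_equal(nrow(s6$index), count(6))
  expect_equal(nrow(s6$index), 50)
  expect_equal(nrow(s8$index), 95)
  expect_true(all(s6$index$l %% 2 == 0))
  expect_true(all(2 * s6$index$j + s6$index$l == s6$index$N + 2))
  expect_error(map_basis_spec(5, 5), "even")
  expect_error(map_basis_spec(6, -1), "u0")
})

test_that("basis columns at the origin are 1 for (1,0,0) and 0 for l > 0", {
  sch <- gradient_scheme(rbind(c(0, 0, 1), c(1, 0, 0)), c(0, 6))
  spec <- map_basis_spec(6, 5)
  A <- map_basis_matrix(sch, spec)
  i100 <- which(spec$index$j == 1 & spec$index$l == 0)
  expect_equal(A[1, i100], 1, tolerance = 1e-12)
  expect_true(all(abs(A[1, spec$index$l > 0]) < 1e-12))
})

test_that("scale length follows u0 = sqrt(2 MD tau) from a low-b tensor fit", {
  sch <- scheme_488
  tau <- sch$Delta - sch$delta / 3
  D <- 0.4267
  iso <- powderavg:::signal_array(exp(-sch$b_values * D), sch)
  est <- estimate_u0(sch, iso)
  expect_equal(est$u0, sqrt(2 * D * tau), tolerance = 1e-8)
  iso2 <- powderavg:::signal_array(exp(-sch$b_values * 2 * D), sch)
  expect_equal(estimate_u0(sch, iso2)$u0, sqrt(2) * est$u0,
               tolerance = 1e-8)
  # kappa = Inf study model: per-direction mono-exponential, MD recovered
  sig <- simulate_signal(sch, tissue_model(kappa = Inf))
  expect_equal(estimate_u0(sch, sig)$MD, (1 + 2 * 0.14) / 3,
               tolerance = 1e-6)
})

test_that("a matched isotropic Gaussian concentrates in the leading coefficient", {
  sch <- scheme_488
  tau <- sch$Delta - sch$delta / 3
  D <- 0.4267
  u0 <- sqrt(2 * D * tau)
  iso <- exp(-sch$b_values * D)
  fit <- fit_map(sch, iso, n_max = 6, u0 = u0, mode = "ls")
  i100 <- which(fit$basis$index$j == 1 & fit$basis$index$l == 0)
  expect_equal(fit$coefficients[i100], 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$coefficients[-i100])), 1e-8)

  # the continuous average is exp(-b MD) at arbitrary, off-shell b
  b_query <- c(0, 0.37, 2.2, 5.05, 9.9, 14)
  pa <- map_powder_average(fit, b_query)
  expect_equal(pa$s_bar, exp(-b_query * D), tolerance = 1e-8)
})

test_that("zero Laplacian weight reduces to plain least squares", {
  sig <- simulate_signal(scheme_344, tissue_model(kappa = 9))
  f0 <- fit_map(scheme_344, sig, n_max = 6, mode = "laplacian",
                lambda_reg = 0)
  fl <- fit_map(scheme_344, sig, n_max = 6, mode = "ls")
  expect_lt(max(abs(f0$coefficients - fl$coefficients)), 1e-10)
  expect_error(fit_map(scheme_344, sig, n_max = 6, mode = "laplacian",
                       lambda_reg = -1), "negative")
})

test_that("residual norm is non-decreasing in the regularization weight", {
  sig <- simulate_signal(scheme_344, tissue_model(kappa = 1))
  noisy <- add_noise(sig, 0.0283, "gaussian", seed = 2)
  lams <- 10^seq(-5, 1, length.out = 13)
  res <- vapply(lams, function(l) {
    fit_map(scheme_344, noisy, n_max = 6, mode = "laplacian",
            lambda_reg = l)$residual_norm
  }, numeric(1))
  expect_true(all(diff(res) >= -1e-10))
})

test_that("isotropic-subspace radial functions are orthogonal", {
  u0 <- 5.811
  spec <- map_basis_spec(8, u0)
  iso_j <- spec$index$j[spec$index$l == 0 & spec$index$m == 0]
  # Gram under 4 pi q^2 dq by dense radial quadrature
  qs <- seq(1e-6, 2.5 / u0, length.out = 20000)
  dq <- qs[2] - qs[1]
  F <- sapply(iso_j, function(j) powderavg:::xi_radial(j, 0, u0, qs))
  G <- crossprod(F * sqrt(4 * pi * qs^2 * dq))
  Gn <- G / sqrt(outer(diag(G), diag(G)))   # correlation form
  expect_lt(max(abs(Gn - diag(length(iso_j)))), 1e-6)
})

test_that("displacement-space duals Fourier-transform back to the signal basis", {
  u0 <- 5.8
  j0 <- function(z) ifelse(abs(z) < 1e-8, 1, sin(z) / z)
  for (j in 1:4) {
    for (q in c(0.004, 0.01, 0.03)) {
      f <- function(r) {
        (-1)^(j - 1) * (2 * pi * u0^2)^(-3 / 2) *
          powderavg:::propagator_radial(j, 0, 1 / (2 * pi * u0), r) *
          j0(2 * pi * q * r) * 4 * pi * r^2
      }
      v <- stats::integrate(f, 0, 60 * u0, rel.tol = 1e-10,
                            subdivisions = 400)$value
      expect_lt(abs(v - powderavg:::xi_radial(j, 0, u0, q)), 1e-6)
    }
  }
})

test_that("constrained fits keep the propagator nonnegative on the grid", {
  sig <- simulate_signal(scheme_344, tissue_model(kappa = 9))
  noisy <- add_noise(sig, 0.0707, "rician", seed = 11)
  vals <- noisy$values / mean(noisy$values[scheme_344$b_values == 0])
  fit <- fit_map(scheme_344, vals, n_max = 6, mode = "constrained")
  pv <- map_propagator(fit, seq(0.02, 1, by = 0.02) * 5 * fit$basis$u0,
                       lebedev_rule(43)$directions)
  expect_gt(min(pv), -1e-9)
})

test_that("fits are rotation-invariant in their isotropic coefficients", {
  R <- powderavg:::rotation_matrix(c(1, -0.4, 0.8), 0.65)
  model <- tissue_model(kappa = 9)
  model_rot <- tissue_model(mu_hat = drop(R %*% model$mu_hat[[1]]), kappa = 9)
  sch_rot <- gradient_scheme(scheme_344$directions %*% t(R),
                             scheme_344$b_values, scheme_344$shell_ids)
  f1 <- fit_map(scheme_344, simulate_signal(scheme_344, model),
                n_max = 6, mode = "ls")
  f2 <- fit_map(sch_rot, simulate_signal(sch_rot, model_rot),
                n_max = 6, mode = "ls")
  iso <- f1$basis$index$l == 0
  expect_lt(max(abs(f1$coefficients[iso] - f2$coefficients[iso])), 1e-8)
})

test_that("shelled noise-free fits agree with the harmonic shell estimator", {
  for (kap in c(1, Inf)) {
    sig <- simulate_signal(scheme_488, tissue_model(kappa = kap))
    fit <- fit_map(scheme_488, sig, n_max = 8, mode = "ls")
    pa_map <- map_powder_average(fit, b_shells_study)
    pa_sh <- average_all_shells(scheme_488, sig, method = "sh", L = 6)
    expect_lt(max(abs(pa_map$s_bar - pa_sh$s_bar)), 2e-2)
    expect_lt(max(abs(pa_map$s_bar - gt_study)), 1e-2)
    expect_lt(abs(map_powder_average(fit, 0)$s_bar - 1), 1e-2)
  }
})

test_that("mode preconditions are enforced", {
  small <- build_scheme("shelled_lebedev", 19, b_shells_study[1:2])
  sig <- simulate_signal(small, tissue_model(kappa = 9))
  expect_error(fit_map(small, sig, n_max = 8, mode = "ls"), "samples")
})
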