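test_that("arithmetic and generic weighted means behave as stated", {
  expect_equal(arithmetic_average(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(arithmetic_average(rep(3.3, 17)), 3.3)
  expect_error(arithmetic_average(numeric(0)), "empty")

  expect_equal(weighted_average(c(0, 1), c(1, 3)), 0.75)
  s <- runif(10)
  expect_equal(weighted_average(s, rep(2, 10)), arithmetic_average(s),
               tolerance = 1e-12)
  w <- runif(10)
  expect_equal(weighted_average(s, w), weighted_average(s, 7.3 * w),
               tolerance = 1e-12)
  expect_error(weighted_average(s, rep(0, 10)), "zero")
  expect_error(weighted_average(s, w[1:3]), "lengths")
})

test_that("Lebedev averaging is exact on constants and kills pure harmonics", {
  rule <- lebedev_rule(43)
  expect_equal(lebedev_average(rep(0.7, 43), rule), 0.7, tolerance = 1e-12)
  Y <- sh_basis(rule$directions, 2, even_only = TRUE)
  y20 <- Y[, attr(Y, "orders") == 2 & attr(Y, "degrees") == 0]
  expect_lt(abs(lebedev_average(y20, rule)), 1e-10)

  # noise-free dispersed signal at b = 1.5 reproduces the closed form
  sig <- simulate_signal(scheme_344, tissue_model(kappa = 1))
  sh1 <- scheme_344$shell_ids == 1
  expect_lt(abs(lebedev_average(sig$values[sh1], rule,
                                scheme_344$directions[sh1, ]) -
                  gt_study[1]), 1e-3)

  # direction mismatch is refused, naming the offending index
  bad <- rule$directions[c(2, 1, 3:43), ]
  expect_error(lebedev_average(sig$values[sh1], rule, bad), "direction 1")
})

test_that("spherical-harmonic isotropic component recovers known signals", {
  expect_equal(sh_powder_average(dirs_61, rep(0.4, 61), L = 6)$s_bar, 0.4,
               tolerance = 1e-10)
  # pure quadratic form u' M u: average is Tr(M)/3
  M <- diag(c(1, 2, 3))
  s <- rowSums((dirs_61 %*% M) * dirs_61)
  expect_equal(sh_powder_average(dirs_61, s, L = 2)$s_bar, 2,
               tolerance = 1e-10)
  # dispersed signal at b = 6
  sig <- simulate_signal(scheme_488, tissue_model(kappa = 1))
  sh4 <- scheme_488$shell_ids == 4
  expect_lt(abs(sh_powder_average(scheme_488$directions[sh4, ],
                                  sig$values[sh4], L = 6)$s_bar -
                  gt_study[4]), 1e-3)
  # clustered directions are rejected with a condition diagnostic
  clustered <- dirs_61 * 0.001 + matrix(rep(c(0, 0, 1), each = 61), 61, 3)
  clustered <- clustered / sqrt(rowSums(clustered^2))
  expect_error(sh_powder_average(clustered, rep(1, 61), L = 6),
               "condition")
})

test_that("tensor trace estimator equals the order-2 harmonic estimator", {
  M <- diag(c(1, 2, 3))
  s <- rowSums((dirs_61 %*% M) * dirs_61)
  ta <- tensor_powder_average(dirs_61, s)
  expect_equal(ta$s_bar, 2, tolerance = 1e-10)
  expect_equal(tensor_powder_average(dirs_61, rep(0.9, 61))$s_bar, 0.9,
               tolerance = 1e-10)

  set.seed(42)
  for (i in 1:100) {
    s <- runif(61)
    expect_equal(tensor_powder_average(dirs_61, s)$s_bar,
                 sh_powder_average(dirs_61, s, L = 2)$s_bar,
                 tolerance = 1e-9)
  }
  expect_error(tensor_powder_average(dirs_61[1:4, ], runif(4)), "6")
})

test_that("optimal weights: symmetry, normalization and harmonic residuals", {
  # octahedron representatives: symmetry forces equal weights
  octa <- diag(3)
  w <- knutsson_weights(octa, k_max = 2)
  expect_equal(w$weights, rep(1 / 3, 3), tolerance = 1e-10)

  w61 <- knutsson_weights(dirs_61, k_max = 18)
  expect_equal(sum(w61$weights), 1, tolerance = 1e-10)
  # weights deviate from uniform by < 10 percent on a well-spread 61-set
  expect_lt(max(abs(w61$weights - 1 / 61)), 0.1 / 61)

  # residual harmonic content of the weighted sampling function, in an
  # exactly solvable regime (more directions than coefficients)
  wk <- knutsson_weights(dirs_61, k_max = 6, v_diag = function(k) rep(1, length(k)))
  B <- sh_basis(dirs_61, 6, even_only = TRUE)
  g <- drop(crossprod(B, wk$weights))
  expect_lt(max(abs(g[-1])), 1e-8)
  expect_equal(g[1], 1 / sqrt(4 * pi), tolerance = 1e-8)

  expect_error(knutsson_weights(dirs_61, k_max = 3), "even")
})

test_that("unit spectral weighting reproduces the harmonic estimator", {
  set.seed(7)
  for (L in c(2, 4, 6)) {
    wL <- knutsson_weights(dirs_61, k_max = L,
                           v_diag = function(k) rep(1, length(k)))
    for (i in 1:25) {
      s <- runif(61)
      expect_equal(weighted_average(s, wL),
                   sh_powder_average(dirs_61, s, L = L)$s_bar,
                   tolerance = 1e-9)
    }
  }
})

test_that("all shell estimators are rotation-equivariant on noise-free signals", {
  R <- powderavg:::rotation_matrix(c(0.3, -1, 2), 0.8)
  model <- tissue_model(kappa = 9)
  model_rot <- tissue_model(mu_hat = drop(R %*% model$mu_hat[[1]]), kappa = 9)
  sch_rot <- gradient_scheme(scheme_344$directions %*% t(R),
                             scheme_344$b_values, scheme_344$shell_ids)
  sig <- simulate_signal(scheme_344, model)
  sig_rot <- simulate_signal(sch_rot, model_rot)
  for (m in c("arithmetic", "sh", "tensor", "knutsson")) {
    pa <- average_all_shells(scheme_344, sig, method = m)
    pa_rot <- average_all_shells(sch_rot, sig_rot, method = m)
    expect_lt(max(abs(pa$s_bar - pa_rot$s_bar)), 1e-8)
  }
})

test_that("whole-scheme averaging matches the closed form and validates input", {
  sig <- simulate_signal(scheme_488, tissue_model(kappa = Inf))
  pa <- average_all_shells(scheme_488, sig, method = "arithmetic")
  expect_equal(pa$b_values, b_shells_study)
  expect_lt(max(abs(pa$s_bar - gt_study)), 5e-3)
  pa_sh <- average_all_shells(scheme_488, sig, method = "sh", L = 6)
  expect_lt(max(abs(pa_sh$s_bar - gt_study)), 5e-3)

  # b0 normalization: scaling all signals leaves the average unchanged
  pa_scaled <- average_all_shells(scheme_488, 3.7 * sig$values,
                                  method = "arithmetic")
  expect_equal(pa_scaled$s_bar, pa$s_bar, tolerance = 1e-12)

  ns <- build_scheme("nonshelled", 40, b_max = 12, seed = 2)
  sig_ns <- simulate_signal(ns, tissue_model(kappa = Inf))
  expect_error(average_all_shells(ns, sig_ns, method = "arithmetic"),
               "not shelled")
  expect_error(average_all_shells(scheme_488, sig, method = "lebedev"),
               "Lebedev")
})
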