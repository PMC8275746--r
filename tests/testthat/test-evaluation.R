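test_that("error metrics reproduce their closed-form examples", {
  gt <- ground_truth_average(b_shells_study)
  est <- matrix(gt, 8, 3)
  expect_equal(compute_d1(est, gt), 0)
  expect_equal(compute_d1(est + 0.01, gt), 0.01, tolerance = 1e-12)
  alt <- est + 0.02 * rep_len(c(1, -1), 8)
  expect_equal(compute_d1(alt, gt), 0.02, tolerance = 1e-12)
  expect_error(compute_d1(est[1:5, ], gt), "mismatch")

  expect_equal(compute_d2(est + 0.01 * b_shells_study, gt, b_shells_study), 1,
               tolerance = 1e-12)
  expect_equal(compute_d2(est - 0.01 * b_shells_study, gt, b_shells_study), -1,
               tolerance = 1e-12)
  expect_equal(compute_d2(est + 0.3, gt, b_shells_study), 0)
  expect_error(compute_d2(est[1:2, ], gt[1:2], b_shells_study[1:2]), "3")
})

test_that("metric symmetries hold", {
  set.seed(1)
  gt <- ground_truth_average(b_shells_study)
  est <- matrix(gt, 8, 3) + matrix(rnorm(24, sd = 0.02), 8, 3)
  # joint permutation of the b axis leaves d1 unchanged; kappa permutation too
  pb <- sample(8); pk <- sample(3)
  expect_equal(compute_d1(est[pb, pk], gt[pb]), compute_d1(est, gt),
               tolerance = 1e-14)
  # negating the bias flips d2
  neg <- matrix(gt, 8, 3) - (est - gt)
  expect_equal(compute_d2(neg, gt, b_shells_study),
               -compute_d2(est, gt, b_shells_study), tolerance = 1e-12)
})

test_that("the normality statistic matches an independent order-statistic oracle", {
  # brute-force A^2 for composite normality, coded from the definition
  ad_stat_oracle <- function(x) {
    n <- length(x)
    z <- sort((x - mean(x)) / stats::sd(x))
    p <- stats::pnorm(z)
    i <- seq_len(n)
    -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  }
  x <- c(0.31, -1.2, 0.05, 2.2, -0.44, 0.9, -0.73, 1.5, 0.02, -0.6)
  expect_equal(ad_test(x)$statistic, ad_stat_oracle(x), tolerance = 1e-12)
  expect_error(ad_test(x[1:5]), "8")
  expect_error(ad_test(rep(1, 20)), "constant")
})

test_that("the normality test calibrates at its nominal level and has power", {
  set.seed(10)
  rej_norm <- mean(replicate(1000, ad_test(rnorm(100))$reject))
  expect_gte(rej_norm, 0.03)
  expect_lte(rej_norm, 0.07)
  rej_exp <- mean(replicate(1000, ad_test(rexp(100))$reject))
  expect_gt(rej_exp, 0.99)
})

test_that("noise-free experiments give near-zero error and are reproducible", {
  cfg <- experiment_config(scheme_488,
                           methods = list(method_spec("arithmetic")),
                           sigma_list = 0, n_realizations = 1,
                           master_seed = 3)
  res <- run_experiment(cfg)
  expect_lt(res$metrics$d1, 5e-3)

  cfg2 <- experiment_config(scheme_344,
                            methods = list(method_spec("arithmetic"),
                                           method_spec("sh", L = 4)),
                            sigma_list = c(0.0707, 0.0283),
                            n_realizations = 4, master_seed = 17)
  r1 <- run_experiment(cfg2)
  r2 <- run_experiment(cfg2)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$samples, r2$samples)
  expect_equal(nrow(r1$aggregates), 4)   # 2 methods x 2 sigma levels
  expect_true(all(r1$aggregates$sd_d1 >= 0))
})

test_that("adding a method does not perturb the shared noise draws", {
  base <- experiment_config(scheme_152,
                            methods = list(method_spec("arithmetic")),
                            sigma_list = 0.0707, n_realizations = 3,
                            master_seed = 5)
  more <- experiment_config(scheme_152,
                            methods = list(method_spec("arithmetic"),
                                           method_spec("tensor")),
                            sigma_list = 0.0707, n_realizations = 3,
                            master_seed = 5)
  r_base <- run_experiment(base)
  r_more <- run_experiment(more)
  a1 <- r_base$metrics[r_base$metrics$method == "arithmetic", ]
  a2 <- r_more$metrics[r_more$metrics$method == "arithmetic", ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_identical(a1, a2)
})

test_that("incompatible method/scheme cells are skipped, not fatal", {
  cfg <- experiment_config(scheme_488,   # 61 directions: no Lebedev rule
                           methods = list(method_spec("lebedev"),
                                          method_spec("arithmetic")),
                           sigma_list = 0.0707, n_realizations = 2,
                           master_seed = 1)
  res <- run_experiment(cfg)
  leb <- res$metrics[res$metrics$method == "lebedev", ]
  ari <- res$metrics[res$metrics$method == "arithmetic", ]
  expect_true(all(is.na(leb$d1)))
  expect_true(all(is.finite(ari$d1)))
})

test_that("Gaussian-noise averages decrease in error as noise shrinks", {
  cfg <- experiment_config(scheme_488,
                           methods = list(method_spec("arithmetic")),
                           sigma_list = c(0.1414, 0.0707, 0.0283, 0.0071,
                                          0.0014),
                           n_realizations = 25, master_seed = 8)
  res <- run_experiment(cfg, keep_samples = FALSE)
  agg <- res$aggregates[order(-res$aggregates$sigma), ]
  expect_true(all(diff(agg$mean_d1) < 0))
})

test_that("normality screening runs over the cell grid", {
  cfg <- experiment_config(scheme_152,
                           methods = list(method_spec("arithmetic")),
                           sigma_list = 0.0283, n_realizations = 40,
                           master_seed = 2)
  res <- run_experiment(cfg)
  scr <- ad_screen(res)
  expect_equal(nrow(scr), 8 * 3)   # b-values x kappa values
  expect_true(all(scr$p_value > 0 & scr$p_value < 1))
  expect_identical(scr$reject, scr$p_value < 0.05)
})
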