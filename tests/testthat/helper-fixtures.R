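# shared study constants and small fixtures, built once per test run

b_shells_study <- seq(1.5, 12, by = 1.5)
gt_study <- ground_truth_average(b_shells_study)

# printed reference values of the closed-form orientational average
gt_printed <- c(0.5640, 0.3541, 0.2386, 0.1682, 0.1221, 0.0903,
                0.0678, 0.0514)

scheme_344 <- build_scheme("shelled_lebedev", 43, b_shells_study)
scheme_152 <- build_scheme("shelled_lebedev", 19, b_shells_study)
scheme_488 <- build_scheme("shelled_uniform", 61, b_shells_study, seed = 1)

dirs_61 <- scheme_488$directions[scheme_488$shell_ids == 1, ]

# dense spherical mean of a tissue model's signal at one b, by quadrature
dense_orientational_mean <- function(b, model, degree = 41) {
  q <- sphere_quadrature(degree)
  sch <- gradient_scheme(q$directions, rep(b, nrow(q$directions)))
  sig <- simulate_signal(sch, model, quad_degree = degree)
  sum(sig$values * q$weights) / (4 * pi)
}
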