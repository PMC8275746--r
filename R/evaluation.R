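#' Mean absolute error of powder-average estimates (d1)
#'
#' \deqn{d_1 = \frac{1}{JK}\sum_{j=1}^{J}\sum_{k=1}^{K}
#'   |\bar S_{est}(b_j, \kappa_k) - \bar S_{gt}(b_j)|}
#' over the b-value / dispersion grid (J = 8 nonzero b-values and K = 3
#' kappa values in the study, hence the 1/24 normalization).
#'
#' @param est matrix of estimates, b-values x kappa values.
#' @param gt vector of ground-truth averages, one per b-value.
#' @return the mean absolute deviation.
#' @export
compute_d1 <- function(est, gt) {
  est <- as.matrix(est)
  if (nrow(est) != length(gt)) stop("shape mismatch: nrow(est) != length(gt)")
  mean(abs(est - gt))
}

#' Correlation of the signed bias with b (d2)
#'
#' The per-b bias is \eqn{\epsilon_j = \frac{1}{K}\sum_k
#' (\bar S_{est}(b_j,\kappa_k) - \bar S_{gt}(b_j))}; d2 is the Pearson
#' correlation of \eqn{(b_j, \epsilon_j)}.  A b-independent (constant)
#' bias has zero variance in \eqn{\epsilon}; by convention d2 = 0 then
#' (no b-dependent bias).
#'
#' @param est matrix of estimates, b-values x kappa values.
#' @param gt ground-truth vector per b-value.
#' @param b_values the b-values (>= 3 required).
#' @return Pearson correlation in \[-1, 1\].
#' @export
compute_d2 <- function(est, gt, b_values) {
  est <- as.matrix(est)
  if (nrow(est) != length(gt) || nrow(est) != length(b_values)) {
    stop("shape mismatch")
  }
  if (length(b_values) < 3) stop("need at least 3 b-values for a correlation")
  eps <- rowMeans(est - gt)
  if (stats::sd(eps) < 1e-14 || stats::sd(b_values) < 1e-14) return(0)
  stats::cor(b_values, eps)
}

#' Anderson-Darling composite normality test
#'
#' Tests the null hypothesis that the sample is Gaussian with unknown mean
#' and variance (composite case): the statistic is corrected for sample
#' size as \eqn{A^{*2} = A^2 (1 + 0.75/n + 2.25/n^2)} and the p-value
#' follows the standard case-3 approximation formulas.
#'
#' @param samples numeric vector, length >= 8, non-constant.
#' @param alpha rejection level (default 0.05).
#' @return list of class `ad_result` with `statistic` (A^2), `p_value` and
#'   `reject`.
#' @export
ad_test <- function(samples, alpha = 0.05) {
  if (length(samples) < 8) stop("need at least 8 samples")
  if (stats::sd(samples) < 1e-300) stop("constant sample")
  ht <- nortest::ad.test(samples)
  out <- list(statistic = unname(ht$statistic),
              p_value = ht$p.value,
              reject = ht$p.value < alpha,
              alpha = alpha)
  class(out) <- "ad_result"
  out
}

#' @export
print.ad_result <- function(x, ...) {
  cat("Anderson-Darling normality test: A^2 =",
      format(x$statistic, digits = 4), ", p =",
      format(x$p_value, digits = 4),
      if (x$reject) paste0("(reject normality at ", x$alpha, ")")
      else paste0("(normality not rejected at ", x$alpha, ")"), "\n")
  invisible(x)
}

#' Monte-Carlo experiment configuration
#'
#' @param scheme a [gradient_scheme()] (shelled or not).
#' @param methods list of method descriptors from [method_spec()].
#' @param kappa_list Watson concentrations (default 1, 9, Inf).
#' @param sigma_list channel noise levels sigma_g.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param n_realizations noise realizations per cell (>= 1).
#' @param master_seed integer master seed.
#' @param model_args extra arguments for [tissue_model()] (D_par, D_perp,
#'   mu_hat).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(scheme, methods,
                              kappa_list = c(1, 9, Inf),
                              sigma_list = c(0.1414, 0.0707, 0.0283,
                                             0.0071, 0.0014),
                              noise_model = c("gaussian", "rician"),
                              n_realizations = 100,
                              master_seed = 1L,
                              model_args = list()) {
  noise_model <- match.arg(noise_model)
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  if (any(sigma_list < 0)) stop("sigma levels must be >= 0")
  out <- list(scheme = scheme, methods = methods, kappa_list = kappa_list,
              sigma_list = sigma_list, noise_model = noise_model,
              n_realizations = as.integer(n_realizations),
              master_seed = as.integer(master_seed),
              model_args = model_args)
  class(out) <- "experiment_config"
  out
}

#' Powder-averaging method descriptor
#'
#' @param name one of `"arithmetic"`, `"lebedev"`, `"sh"`, `"tensor"`,
#'   `"knutsson"`, `"map"`, `"mapl"`.
#' @param ... options: `L` (sh order), `k_max` (knutsson), `n_max`
#'   (map/mapl), `lambda_reg` (mapl), `constrained` (map; default TRUE).
#' @return list descriptor with a `tag` label.
#' @export
method_spec <- function(name, ...) {
  opts <- list(...)
  tag <- switch(name,
    sh = paste0("sh_L", if (is.null(opts$L)) 6 else opts$L),
    map = paste0("map", if (is.null(opts$n_max)) 6 else opts$n_max),
    mapl = paste0("mapl", if (is.null(opts$n_max)) 6 else opts$n_max),
    name)
  c(list(name = name, tag = tag), opts)
}

# apply one method to (normalized) noisy signals; returns s_bar at the
# shell b-values (shell methods) or at b_query (MAP methods)
apply_method <- function(m, scheme, values, b_query) {
  if (m$name %in% c("arithmetic", "lebedev", "sh", "tensor", "knutsson")) {
    pa <- average_all_shells(scheme, values, method = m$name,
                             L = if (is.null(m$L)) 6 else m$L,
                             k_max = m$k_max)
    # align to b_query order
    pa$s_bar[match(round(b_query, 9), round(pa$b_values, 9))]
  } else {
    n_max <- if (is.null(m$n_max)) 6 else m$n_max
    mode <- if (m$name == "mapl") "laplacian"
            else if (isTRUE(m$constrained) || is.null(m$constrained))
              "constrained" else "ls"
    fit <- fit_map(scheme, values, n_max = n_max, mode = mode,
                   lambda_reg = m$lambda_reg)
    map_powder_average(fit, b_query)$s_bar
  }
}

#' Run the Monte-Carlo comparison experiment
#'
#' For each realization and each noise level: simulate the noise-free
#' Watson signal for every kappa, add noise (one independent seeded stream
#' per (realization, kappa, sigma) cell, shared across methods), normalize
#' by the mean b = 0 signal, apply every configured method, and score d1
#' and d2 against the closed-form ground truth.  Also collects the
#' orientationally-averaged signals per (method, sigma, b, kappa) across
#' realizations for normality screening.
#'
#' @param config an [experiment_config()].
#' @param keep_samples logical; keep the per-realization averaged signals
#'   (needed for [ad_screen()]).
#' @return list of class `experiment_result` with `metrics` (data.frame:
#'   method, sigma, realization, d1, d2), `aggregates` (mean/sd per
#'   method x sigma), and optionally `samples` (array method x sigma x b x
#'   kappa x realization).
#' @export
run_experiment <- function(config, keep_samples = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  scheme <- config$scheme
  b_query <- if (!is.null(scheme$shell_ids)) {
    sort(unique(scheme$b_values[scheme$b_values > 0]))
  } else {
    seq(1.5, 12, by = 1.5)
  }
  gt <- do.call(ground_truth_average,
                c(list(b = b_query),
                  config$model_args[names(config$model_args) %in%
                                      c("D_par", "D_perp")]))
  nk <- length(config$kappa_list)
  ns <- length(config$sigma_list)
  nr <- config$n_realizations
  nm <- length(config$methods)
  # one seed per (realization, kappa, sigma) cell
  seeds <- local({
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$master_seed)
    array(sample.int(.Machine$integer.max - 1L, nr * nk * ns),
          dim = c(nr, nk, ns))
  })
  # noise-free signals per kappa (shared across realizations)
  noise_free <- lapply(config$kappa_list, function(kap) {
    margs <- config$model_args
    margs$kappa <- kap
    simulate_signal(scheme, do.call(tissue_model, margs))
  })
  tags <- vapply(config$methods, `[[`, "", "tag")
  metrics <- NULL
  samples <- if (keep_samples) {
    array(NA_real_, dim = c(nm, ns, length(b_query), nk, nr),
          dimnames = list(tags, paste0("sigma", config$sigma_list),
                          paste0("b", b_query),
                          paste0("kappa", config$kappa_list), NULL))
  } else NULL
  for (si in seq_len(ns)) {
    sg <- config$sigma_list[si]
    for (r in seq_len(nr)) {
      est <- vector("list", nm)
      for (mi in seq_len(nm)) est[[mi]] <- matrix(NA_real_, length(b_query), nk)
      for (ki in seq_len(nk)) {
        noisy <- if (sg > 0) {
          add_noise(noise_free[[ki]], sg, model = config$noise_model,
                    seed = seeds[r, ki, si])
        } else noise_free[[ki]]
        vals <- noisy$values
        if (scheme$n_b0 > 0) vals <- vals / mean(vals[scheme$b_values == 0])
        for (mi in seq_len(nm)) {
          s_est <- tryCatch(
            apply_method(config$methods[[mi]], scheme, vals, b_query),
            error = function(e) rep(NA_real_, length(b_query)))
          est[[mi]][, ki] <- s_est
          if (keep_samples) samples[mi, si, , ki, r] <- s_est
        }
      }
      for (mi in seq_len(nm)) {
        if (anyNA(est[[mi]])) {
          metrics <- rbind(metrics, data.frame(
            method = tags[mi], sigma = sg, realization = r,
            d1 = NA_real_, d2 = NA_real_))
        } else {
          metrics <- rbind(metrics, data.frame(
            method = tags[mi], sigma = sg, realization = r,
            d1 = compute_d1(est[[mi]], gt),
            d2 = compute_d2(est[[mi]], gt, b_query)))
        }
      }
    }
  }
  agg <- do.call(rbind, lapply(split(metrics,
                                     list(metrics$method, metrics$sigma),
                                     drop = TRUE), function(df) {
    data.frame(method = df$method[1], sigma = df$sigma[1],
               mean_d1 = mean(df$d1), sd_d1 = stats::sd(df$d1),
               mean_d2 = mean(df$d2), sd_d2 = stats::sd(df$d2),
               n = nrow(df))
  }))
  rownames(agg) <- NULL
  out <- list(metrics = metrics, aggregates = agg, samples = samples,
              b_values = b_query, config = config)
  class(out) <- "experiment_result"
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment:", length(unique(x$metrics$method)), "methods x",
      length(unique(x$metrics$sigma)), "noise levels x",
      max(x$metrics$realization), "realizations\n")
  print(x$aggregates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Normality screening of averaged signals
#'
#' Applies the Anderson-Darling test across realizations for every
#' (method, sigma, b, kappa) cell of an experiment run with
#' `keep_samples = TRUE`, mirroring the per-cell screening of simulated
#' orientational averages.
#'
#' @param result an [run_experiment()] result with samples.
#' @param alpha rejection level.
#' @return data.frame with method, sigma, b, kappa, statistic, p_value,
#'   reject.
#' @export
ad_screen <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "experiment_result"))
  if (is.null(result$samples)) stop("experiment was run without samples")
  dn <- dimnames(result$samples)
  out <- NULL
  for (mi in seq_along(dn[[1]])) for (si in seq_along(dn[[2]]))
    for (bi in seq_along(dn[[3]])) for (ki in seq_along(dn[[4]])) {
      x <- result$samples[mi, si, bi, ki, ]
      if (anyNA(x)) next
      tst <- tryCatch(ad_test(x, alpha), error = function(e) NULL)
      if (is.null(tst)) next
      out <- rbind(out, data.frame(
        method = dn[[1]][mi], sigma = dn[[2]][si], b = dn[[3]][bi],
        kappa = dn[[4]][ki], statistic = tst$statistic,
        p_value = tst$p_value, reject = tst$reject))
    }
  out
}
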