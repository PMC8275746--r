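#' Watson orientation-distribution density
#'
#' Density of the antipodally-symmetric Watson distribution
#' \deqn{W(n, \mu) = M(1/2, 3/2, \kappa)^{-1} \exp(\kappa (\mu \cdot n)^2) / (4\pi),}
#' normalized so that it integrates to one over the unit sphere.  The
#' confluent hypergeometric normalization is computed through the stable
#' identity \eqn{M(1/2, 3/2, \kappa) = \sqrt{\pi}\,\mathrm{erfi}(\sqrt{\kappa})/(2\sqrt{\kappa})}
#' for \eqn{\kappa > 0}.  Only concentration (\eqn{\kappa \ge 0})
#' distributions are supported; \eqn{\kappa = \infty} is the Dirac
#' (no-dispersion) case and is handled analytically by the simulator, not
#' by this density.
#'
#' @param n_hat unit vector(s), n x 3 matrix or length-3 vector.
#' @param mu_hat mean direction, unit 3-vector.
#' @param kappa concentration parameter, >= 0 and finite.
#' @return density value(s), 1/steradian.
#' @export
watson_density <- function(n_hat, mu_hat, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa < 0) {
    stop("kappa must be a single value >= 0 (girdle distributions with ",
         "kappa < 0 are out of scope)")
  }
  if (!is.finite(kappa)) {
    stop("kappa = Inf is a Dirac ODF; handled analytically by the simulator")
  }
  n_hat <- as_unit_matrix(n_hat)
  mu_hat <- as.numeric(mu_hat)
  mu_hat <- mu_hat / sqrt(sum(mu_hat^2))
  t2 <- drop(n_hat %*% mu_hat)^2
  exp(kappa * t2) / (4 * pi * kummer_m_half(kappa))
}

# M(1/2, 3/2, kappa) via the erfi identity; continuous at kappa = 0
kummer_m_half <- function(kappa) {
  if (kappa < 1e-12) return(1 + kappa / 3)
  sqrt(pi) * pracma::erfi(sqrt(kappa)) / (2 * sqrt(kappa))
}

#' Watson-dispersed axisymmetric tissue model
#'
#' One or more Watson-dispersed compartments sharing a prolate axisymmetric
#' diffusion tensor shape.  Defaults are the study constants: parallel
#' diffusivity 1 um^2/ms, perpendicular 0.14 um^2/ms, mean direction
#' (0.4, 0.6, -0.693) normalized.
#'
#' @param mu_hat mean direction(s): unit 3-vector, or list of them (one per
#'   compartment).
#' @param kappa Watson concentration(s); `Inf` means no dispersion (Dirac
#'   ODF).
#' @param fraction compartment signal fractions, must sum to 1.
#' @param D_par,D_perp parallel / perpendicular diffusivity, um^2/ms, with
#'   D_par >= D_perp >= 0.
#' @return object of class `tissue_model`.
#' @export
tissue_model <- function(mu_hat = c(0.4, 0.6, -0.693), kappa = Inf,
                         fraction = NULL, D_par = 1, D_perp = 0.14) {
  if (!is.list(mu_hat)) mu_hat <- list(mu_hat)
  ncomp <- length(mu_hat)
  kappa <- rep_len(kappa, ncomp)
  if (is.null(fraction)) fraction <- rep(1 / ncomp, ncomp)
  if (abs(sum(fraction) - 1) > 1e-12) stop("fractions must sum to 1")
  if (!(D_par >= D_perp && D_perp >= 0)) {
    stop("prolate tensor required: D_par >= D_perp >= 0")
  }
  if (any(kappa < 0)) stop("kappa must be >= 0")
  mu_hat <- lapply(mu_hat, function(m) {
    m <- as.numeric(m)
    m / sqrt(sum(m^2))
  })
  out <- list(mu_hat = mu_hat, kappa = kappa, fraction = fraction,
              D_par = D_par, D_perp = D_perp)
  class(out) <- "tissue_model"
  out
}

#' The study's crossing-fiber configuration
#'
#' Two equal-fraction Watson compartments with identical tensor shape and
#' concentration whose mean directions cross at pi/4 or pi/2 radians.
#' Because shape and dispersion are shared, the true orientational average
#' is identical to the single-compartment case.
#'
#' @param angle crossing angle: `"pi/2"` or `"pi/4"`.
#' @param kappa shared concentration parameter.
#' @param D_par,D_perp tensor shape, um^2/ms.
#' @return a two-compartment [tissue_model()].
#' @export
crossing_model <- function(angle = c("pi/2", "pi/4"), kappa = Inf,
                           D_par = 1, D_perp = 0.14) {
  angle <- match.arg(angle)
  mu2 <- if (angle == "pi/2") c(-0.384, -0.576, -0.721)
         else c(-0.011, -0.017, -0.999)
  tissue_model(mu_hat = list(c(0.4, 0.6, -0.693), mu2),
               kappa = kappa, fraction = c(0.5, 0.5),
               D_par = D_par, D_perp = D_perp)
}

#' Simulate noise-free diffusion-weighted signals
#'
#' Evaluates
#' \deqn{S(b, u) = \sum_c f_c \int W(n, \mu_c) e^{-b\, u^T D(n) u}\, dn}
#' at every sample of the scheme, where D(n) is the axisymmetric prolate
#' tensor oriented along n.  Since
#' \eqn{u^T D(n) u = D_\perp + (D_\parallel - D_\perp)(u \cdot n)^2},
#' the convolution is evaluated by a high-order spherical product
#' quadrature for finite kappa; kappa = Inf short-circuits to the pure
#' tensor signal \eqn{\exp(-b\, u^T D(\mu) u)}.  S = 1 at b = 0.
#'
#' @param scheme a [gradient_scheme()].
#' @param model a [tissue_model()].
#' @param quad_degree spherical-quadrature exactness degree for the Watson
#'   convolution (default 45).
#' @return object of class `signal_array`: list with `values`, `scheme`,
#'   `noise_sigma` (0) and `noise_model` ("none").
#' @export
simulate_signal <- function(scheme, model, quad_degree = 45) {
  stopifnot(inherits(scheme, "gradient_scheme"),
            inherits(model, "tissue_model"))
  u <- scheme$directions
  b <- scheme$b_values
  dD <- model$D_par - model$D_perp
  vals <- numeric(length(b))
  quad <- NULL
  for (ci in seq_along(model$mu_hat)) {
    mu <- model$mu_hat[[ci]]
    kap <- model$kappa[ci]
    if (is.finite(kap)) {
      if (is.null(quad)) quad <- sphere_quadrature(quad_degree)
      w_odf <- watson_density(quad$directions, mu, kap) * quad$weights
      # ct2[i, k] = (u_i . n_k)^2
      ct2 <- (u %*% t(quad$directions))^2
      decay <- exp(-outer(b * dD, rep(1, nrow(quad$directions))) * ct2)
      comp <- exp(-b * model$D_perp) * drop(decay %*% w_odf)
    } else {
      ct2 <- drop(u %*% mu)^2
      comp <- exp(-b * (model$D_perp + dD * ct2))
    }
    vals <- vals + model$fraction[ci] * comp
  }
  vals[b == 0] <- 1
  signal_array(vals, scheme)
}

signal_array <- function(values, scheme, noise_sigma = 0,
                         noise_model = "none") {
  stopifnot(length(values) == length(scheme$b_values))
  out <- list(values = as.numeric(values), scheme = scheme,
              noise_sigma = noise_sigma, noise_model = noise_model)
  class(out) <- "signal_array"
  out
}

#' @export
print.signal_array <- function(x, ...) {
  cat("signal array:", length(x$values), "samples, noise:",
      x$noise_model, if (x$noise_sigma > 0) paste0("(sigma_g = ",
      x$noise_sigma, ")") else "", "\n")
  invisible(x)
}

#' Closed-form ground-truth orientational average
#'
#' The orientationally-averaged signal of an axisymmetric Gaussian
#' compartment is, irrespective of the orientation distribution,
#' \deqn{\bar{S}(b) = \frac{\sqrt{\pi} e^{-b D_\perp}}{2}
#'   \frac{\mathrm{erf}(\sqrt{b(D_\parallel - D_\perp)})}
#'        {\sqrt{b(D_\parallel - D_\perp)}}.}
#' The continuous limit \eqn{\bar S \to e^{-b D_\perp}} is used when
#' \eqn{b (D_\parallel - D_\perp)} is numerically zero.
#'
#' @param b b-value(s), ms/um^2, >= 0.
#' @param D_par,D_perp diffusivities, um^2/ms, with D_par >= D_perp >= 0.
#' @return the normalized average signal(s).
#' @examples
#' ground_truth_average(seq(1.5, 12, by = 1.5))
#' @export
ground_truth_average <- function(b, D_par = 1, D_perp = 0.14) {
  if (D_par < D_perp) stop("prolate assumption violated: D_par < D_perp")
  if (any(b < 0)) stop("b must be >= 0")
  x <- b * (D_par - D_perp)
  out <- exp(-b * D_perp)
  big <- x >= 1e-12
  sx <- sqrt(x[big])
  out[big] <- out[big] * sqrt(pi) / 2 * pracma::erf(sx) / sx
  out
}

#' Add Gaussian or Rician noise to simulated signals
#'
#' Gaussian: S + N(0, sigma_g).  Rician:
#' \eqn{\sqrt{(S + N_r(0,\sigma_g))^2 + N_i(0,\sigma_g)^2}} with
#' independent real/imaginary channel draws, reproducing the magnitude-MRI
#' noise floor.  Deterministic for a fixed seed.
#'
#' @param signals a `signal_array` (or numeric vector together with
#'   `scheme`).
#' @param sigma_g channel noise standard deviation (>= 0); study levels are
#'   0.1414, 0.0707, 0.0283, 0.0071, 0.0014.
#' @param model `"gaussian"` or `"rician"`.
#' @param seed integer seed.
#' @return a `signal_array` with noisy values.
#' @export
add_noise <- function(signals, sigma_g, model = c("gaussian", "rician"),
                      seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(signals, "signal_array"))
  if (sigma_g < 0) stop("sigma_g must be >= 0")
  if (sigma_g == 0) return(signals)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- signals$values
  n <- length(s)
  vals <- if (model == "gaussian") {
    s + stats::rnorm(n, 0, sigma_g)
  } else {
    sqrt((s + stats::rnorm(n, 0, sigma_g))^2 + stats::rnorm(n, 0, sigma_g)^2)
  }
  signal_array(vals, signals$scheme, noise_sigma = sigma_g,
               noise_model = model)
}
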