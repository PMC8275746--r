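#' Arithmetic powder average of one shell
#'
#' \eqn{\bar S = (1/n)\sum_i S_i}: the standard estimator when directions
#' are (approximately) uniform on the sphere.
#'
#' @param signals_on_shell numeric signal values of a single shell.
#' @return the arithmetic mean.
#' @export
arithmetic_average <- function(signals_on_shell) {
  if (length(signals_on_shell) == 0) stop("empty shell")
  mean(signals_on_shell)
}

#' Weighted powder average of one shell
#'
#' \eqn{\bar S = \sum_i w_i S_i / \sum_i w_i}.  The result is invariant to
#' positive rescaling of the weights.
#'
#' @param signals_on_shell numeric signal values.
#' @param weights numeric weights (same length) or a `weight_set`.
#' @return the weighted mean.
#' @export
weighted_average <- function(signals_on_shell, weights) {
  if (inherits(weights, "weight_set")) weights <- weights$weights
  if (length(weights) != length(signals_on_shell)) {
    stop("signal / weight lengths differ")
  }
  sw <- sum(weights)
  if (abs(sw) < 1e-300) stop("weights sum to zero")
  sum(weights * signals_on_shell) / sw
}

#' Lebedev-quadrature powder average of one shell
#'
#' Weighted average with the Lebedev rule weights; requires the signals to
#' be sampled exactly at the rule's node directions (up to antipodal flip).
#' This is the quadrature estimate of the spherical mean,
#' \eqn{Q[S]/(4\pi)} with normalized weights.
#'
#' @param signals_on_shell signal values, one per rule node.
#' @param rule a [lebedev_rule()].
#' @param directions optional n x 3 matrix of the sampling directions; when
#'   supplied they are checked against the rule nodes (tolerance 1e-9).
#' @return the quadrature average.
#' @export
lebedev_average <- function(signals_on_shell, rule, directions = NULL) {
  stopifnot(inherits(rule, "quadrature_rule"))
  if (length(signals_on_shell) != nrow(rule$directions)) {
    stop("signal count does not match rule node count")
  }
  if (!is.null(directions)) {
    directions <- as_unit_matrix(directions)
    for (i in seq_len(nrow(directions))) {
      d <- min(sum((directions[i, ] - rule$directions[i, ])^2),
               sum((directions[i, ] + rule$directions[i, ])^2))
      if (d > 1e-18) {
        stop("direction ", i, " does not match the quadrature node ",
             "(offset ", format(sqrt(d)), ")")
      }
    }
  }
  sum(rule$weights * signals_on_shell)
}

#' Spherical-harmonic powder average of one shell
#'
#' Least-squares fit of the even-order real spherical-harmonic series
#' \eqn{s = Y a} truncated at order L; the powder average is the isotropic
#' component \eqn{\bar S = a_0 Y_0^0 = a_0/\sqrt{4\pi}}.  The normal
#' equations are solved through a pseudoinverse with relative cutoff 1e-10.
#'
#' @param directions n x 3 unit vectors of the shell.
#' @param signals signal values.
#' @param L even truncation order (2, 4 or 6 in the study).
#' @return list with `s_bar` and `fit` (class `sh_fit`: coefficients,
#'   orders, degrees, order L).
#' @export
sh_powder_average <- function(directions, signals, L = 6) {
  if (L %% 2 != 0) stop("L must be even")
  directions <- as_unit_matrix(directions)
  Y <- sh_basis(directions, L, even_only = TRUE)
  if (nrow(Y) < ncol(Y)) {
    stop("need at least ", ncol(Y), " samples for L = ", L)
  }
  sol <- pinv_solve(Y, signals)
  if (sol$rank < ncol(Y)) {
    stop("rank-deficient spherical-harmonic design (condition number ",
         format(sol$cond, digits = 3), "); directions too clustered")
  }
  a <- drop(sol$x)
  fit <- list(coefficients = a, orders = attr(Y, "orders"),
              degrees = attr(Y, "degrees"), order = L)
  class(fit) <- "sh_fit"
  list(s_bar = a[1] / sqrt(4 * pi), fit = fit)
}

#' Cartesian-tensor powder average of one shell
#'
#' Represents the shell signal as the quadratic form \eqn{S(u) = u^T M u}
#' with symmetric M, fit in least squares from design rows
#' \eqn{[u_x^2, u_y^2, u_z^2, u_x u_y, u_x u_z, u_y u_z]}; the powder
#' average is \eqn{\mathrm{Tr}(M)/3 = h^T m} with
#' \eqn{h = (1/3, 1/3, 1/3, 0, 0, 0)^T}.  Equivalent to the
#' spherical-harmonic estimator truncated at order 2.  Note the
#' off-diagonal design columns carry single products, so the fitted
#' off-diagonal entries absorb the factor 2 of the symmetric expansion;
#' the trace is unaffected.
#'
#' @param directions n x 3 unit vectors (>= 6 non-degenerate).
#' @param signals signal values.
#' @return list with `s_bar` and `fit` (class `tensor_fit`: `m_vector` =
#'   (Mxx, Myy, Mzz, Mxy, Mxz, Myz)).
#' @export
tensor_powder_average <- function(directions, signals) {
  directions <- as_unit_matrix(directions)
  if (nrow(directions) < 6) stop("need at least 6 directions")
  U <- cbind(directions[, 1]^2, directions[, 2]^2, directions[, 3]^2,
             directions[, 1] * directions[, 2],
             directions[, 1] * directions[, 3],
             directions[, 2] * directions[, 3])
  sol <- pinv_solve(U, signals)
  if (sol$rank < 6) {
    stop("singular tensor design (condition number ",
         format(sol$cond, digits = 3), ")")
  }
  m <- drop(sol$x)
  fit <- list(m_vector = m)
  class(fit) <- "tensor_fit"
  list(s_bar = sum(m[1:3]) / 3, fit = fit)
}

#' Optimal direction weights by spherical-harmonic response shaping
#'
#' Computes the weight vector \eqn{w_0 = (B^T V B)^{-1} (V B)^T g_0} that
#' makes the weighted sampling function
#' \eqn{G(x) = \sum_i w_i \delta(x - u_i)} as rotationally invariant as
#' possible: its spherical-harmonic coefficients are pushed toward
#' \eqn{g_{km} \propto \delta_{k0}\delta_{m0}}.  B is the even-order real
#' spherical-harmonic basis (orders 0..k_max) evaluated at the directions,
#' V a diagonal per-order importance weighting (default
#' \eqn{(1 + k^2/36)^{-1}}, adequate for typical brain signal decay
#' profiles), and g_0 is nonzero only in the (0,0) entry (value
#' \eqn{1/\sqrt{4\pi}}, the coefficient of a perfectly isotropic unit-mass
#' sampling).  Weights are returned normalized to sum to one; the weighted
#' average is invariant to that scale.
#'
#' With V = 1 up to order L and 0 above, the induced weighted average
#' coincides with the spherical-harmonic estimator of order L.
#'
#' @param directions n x 3 unit vectors.
#' @param k_max maximum (even) spherical-harmonic order; the study uses
#'   18, 14 and 10 for 61, 43 and 19 directions.
#' @param v_diag per-order importance: either a function of the order k or
#'   a named numeric vector indexed by order; default
#'   \eqn{(1+k^2/36)^{-1}}.
#' @param rcond relative pseudoinverse cutoff.
#' @return object of class `weight_set`: list with `weights` (sum 1),
#'   `method = "knutsson"` and `k_max`.
#' @export
knutsson_weights <- function(directions, k_max = 18,
                             v_diag = function(k) 1 / (1 + k^2 / 36),
                             rcond = 1e-10) {
  if (k_max %% 2 != 0) stop("k_max must be even")
  directions <- as_unit_matrix(directions)
  Bt <- sh_basis(directions, k_max, even_only = TRUE)  # n_dir x n_coef
  orders <- attr(Bt, "orders")
  v <- if (is.function(v_diag)) v_diag(orders) else as.numeric(v_diag[
    as.character(orders)])
  if (any(!is.finite(v)) || any(v < 0)) stop("invalid v_diag")
  keep <- v > 0
  # w = (B^T V B)^+ B^T V g0 with B = t(Bt); only the (0,0) row of g0 is
  # nonzero so B^T V g0 = v_0 * Y00 * 1 column of Bt
  g0 <- numeric(sum(keep))
  g0[which(orders[keep] == 0)] <- 1 / sqrt(4 * pi)
  Bk <- Bt[, keep, drop = FALSE]
  vk <- v[keep]
  M <- Bk %*% (vk * t(Bk))            # B^T V B, n_dir x n_dir
  rhs <- Bk %*% (vk * g0)
  sv <- svd(M)
  pos <- sv$d > rcond * sv$d[1]
  if (sv$d[1] / sv$d[max(which(pos))] > 1e14) {
    stop("ill-conditioned weight system (condition number ",
         format(sv$d[1] / sv$d[length(sv$d)], digits = 3), ")")
  }
  w <- sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], rhs) / sv$d[pos])
  w <- drop(w)
  w <- w / sum(w)
  out <- list(weights = w, method = "knutsson", k_max = k_max)
  class(out) <- "weight_set"
  out
}

#' @export
print.weight_set <- function(x, ...) {
  cat("weight set (", x$method, "): ", length(x$weights), " weights, ",
      "k_max = ", x$k_max, "\n", sep = "")
  invisible(x)
}

#' Powder-average every shell of a scheme
#'
#' Applies a shell-by-shell estimator independently to each nonzero-b shell
#' of a shelled scheme.  When the scheme contains b = 0 samples, all
#' signals are first normalized by the mean b = 0 signal.
#'
#' @param scheme a shelled [gradient_scheme()].
#' @param signals a `signal_array` on that scheme (or numeric vector).
#' @param method one of `"arithmetic"`, `"lebedev"`, `"sh"`, `"tensor"`,
#'   `"knutsson"`.
#' @param L spherical-harmonic order for `method = "sh"`.
#' @param k_max maximum order for `method = "knutsson"`; defaults to 18,
#'   14 or 10 according to the per-shell direction count (61/43/19), else
#'   the largest of those not exceeding sensible for the count.
#' @param rule a [lebedev_rule()] for `method = "lebedev"`; defaults to the
#'   rule whose node count matches the shell size (error if none does).
#' @return object of class `powder_average`: list with `b_values`,
#'   `s_bar`, `method_tag`.
#' @export
average_all_shells <- function(scheme, signals,
                               method = c("arithmetic", "lebedev", "sh",
                                          "tensor", "knutsson"),
                               L = 6, k_max = NULL, rule = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "gradient_scheme"))
  vals <- if (inherits(signals, "signal_array")) signals$values
          else as.numeric(signals)
  if (length(vals) != length(scheme$b_values)) stop("signal length mismatch")
  if (is.null(scheme$shell_ids)) {
    stop("scheme is not shelled; shell-by-shell estimators require shells ",
         "(use the MAP-MRI route for non-shelled data)")
  }
  if (scheme$n_b0 > 0) {
    s0 <- mean(vals[scheme$b_values == 0])
    vals <- vals / s0
  }
  shells <- sort(setdiff(unique(scheme$shell_ids), 0L))
  b_out <- numeric(length(shells))
  s_out <- numeric(length(shells))
  w_cache <- NULL
  for (si in seq_along(shells)) {
    idx <- scheme$shell_ids == shells[si] & scheme$b_values > 0
    u <- scheme$directions[idx, , drop = FALSE]
    s <- vals[idx]
    b_out[si] <- scheme$b_values[idx][1]
    s_out[si] <- switch(method,
      arithmetic = arithmetic_average(s),
      lebedev = {
        r <- if (!is.null(rule)) rule else {
          np <- nrow(u)
          if (!(np %in% c(3, 19, 43))) {
            stop("shell of ", np, " directions is not a supported Lebedev ",
                 "node set; the quadrature method cannot be employed here")
          }
          lebedev_rule(np)
        }
        lebedev_average(s, r, directions = u)
      },
      sh = sh_powder_average(u, s, L = L)$s_bar,
      tensor = tensor_powder_average(u, s)$s_bar,
      knutsson = {
        if (is.null(w_cache)) {
          km <- if (!is.null(k_max)) k_max else
            default_kmax(nrow(u))
          w_cache <- knutsson_weights(u, k_max = km)
        }
        weighted_average(s, w_cache)
      })
  }
  out <- list(b_values = b_out, s_bar = s_out,
              method_tag = if (method == "sh") paste0("sh_L", L) else method)
  class(out) <- "powder_average"
  out
}

# study defaults: k_max 18 / 14 / 10 for 61 / 43 / 19 directions; in
# between, pick the largest of those whose coefficient count the direction
# count can plausibly shape
default_kmax <- function(n_dir) {
  if (n_dir >= 61) 18 else if (n_dir >= 43) 14 else 10
}

#' @export
print.powder_average <- function(x, ...) {
  cat("powder average (", x$method_tag, "):\n", sep = "")
  print(data.frame(b = x$b_values, s_bar = x$s_bar), row.names = FALSE)
  invisible(x)
}
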