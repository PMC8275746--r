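#' MAP-MRI spherical basis specification
#'
#' Index set of the Mean Apparent Propagator (MAP-MRI) representation in
#' spherical coordinates: basis functions are indexed by (j, l, m) with
#' j >= 1, even l >= 0, |m| <= l and 2j + l = N + 2 for N = 0, 2, ...,
#' n_max.  Odd l is excluded (single-diffusion-encoding signals are
#' antipodally symmetric).  The coefficient count is
#' (n_max/2+1)(n_max/2+2)(2 n_max+3)/6: 50 for n_max = 6, 95 for n_max = 8.
#'
#' @param n_max even maximum expansion order (6 or 8 in the study).
#' @param u0 basis scale length, um (typically from [estimate_u0()]).
#' @return object of class `map_basis_spec`: list with `n_max`, `u0` and
#'   `index` (data.frame with columns j, l, m, N).
#' @export
map_basis_spec <- function(n_max, u0) {
  if (n_max %% 2 != 0 || n_max < 0) stop("n_max must be a nonnegative even integer")
  if (!(u0 > 0)) stop("u0 must be positive")
  idx <- NULL
  for (N in seq(0, n_max, by = 2)) {
    for (j in seq_len((N + 2) %/% 2)) {
      l <- N + 2 - 2 * j
      if (l %% 2 != 0) next
      for (m in seq(-l, l)) {
        idx <- rbind(idx, c(j, l, m, N))
      }
    }
  }
  idx <- as.data.frame(idx)
  names(idx) <- c("j", "l", "m", "N")
  out <- list(n_max = as.integer(n_max), u0 = u0, index = idx)
  class(out) <- "map_basis_spec"
  out
}

#' @export
print.map_basis_spec <- function(x, ...) {
  cat("MAP-MRI spherical basis: n_max =", x$n_max, ", u0 =",
      format(x$u0), "um,", nrow(x$index), "coefficients\n")
  invisible(x)
}

# generalized Laguerre polynomial L_n^a(x), stable three-term recurrence
laguerre <- function(n, a, x) {
  if (n == 0) return(rep(1, length(x)))
  Lm1 <- rep(1, length(x))
  L <- 1 + a - x
  if (n == 1) return(L)
  for (k in 2:n) {
    Lp <- ((2 * k - 1 + a - x) * L - (k - 1 + a) * Lm1) / k
    Lm1 <- L
    L <- Lp
  }
  L
}

# monomial coefficients of L_n^a(y): c_k = (-1)^k/k! * choose(n+a, n-k)
laguerre_coefs <- function(n, a) {
  k <- 0:n
  (-1)^k / factorial(k) *
    exp(lgamma(n + a + 1) - lgamma(n - k + 1) - lgamma(a + k + 1))
}

# radial part of Xi_jl at wavenumber q (um^-1), scale u0 (um):
# xi_jl(q) = (-1)^{l/2} (2 pi^2 u0^2 q^2)^{l/2} e^{-2 pi^2 u0^2 q^2}
#            L_{j-1}^{l+1/2}(4 pi^2 u0^2 q^2)
# (the sqrt(4 pi) prefactor cancels against Y_0^0 for the isotropic terms
# and is carried in the full basis matrix below)
xi_radial <- function(j, l, u0, q) {
  x <- 2 * pi^2 * u0^2 * q^2
  (-1)^(l / 2) * x^(l / 2) * exp(-x) * laguerre(j - 1, l + 1 / 2, 2 * x)
}

# q (um^-1) from b (ms/um^2) under b = (2 pi q)^2 tau, tau = Delta - delta/3
q_of_b <- function(b, tau) sqrt(b / tau) / (2 * pi)

#' MAP-MRI basis design matrix
#'
#' Evaluates every basis function
#' \deqn{\Xi_{jlm}(u_0, q, \hat q) = \sqrt{4\pi}\, i^{-l}
#'   (2\pi^2 u_0^2 q^2)^{l/2} e^{-2\pi^2 u_0^2 q^2}
#'   L_{j-1}^{l+1/2}(4\pi^2 u_0^2 q^2)\, Y_l^m(\hat q)}
#' at the scheme samples, with real spherical harmonics (for even l the
#' factor \eqn{i^{-l}} contributes the sign \eqn{(-1)^{l/2}}).  The
#' wavenumber follows \eqn{b = (2\pi q)^2 (\Delta - \delta/3)}, so that
#' the j = 1, l = 0 term equals \eqn{e^{-b \cdot \mathrm{MD}}} when
#' \eqn{u_0^2 = 2\,\mathrm{MD}\,\tau}.
#'
#' @param scheme a [gradient_scheme()] (timing used for the b-q mapping).
#' @param spec a [map_basis_spec()].
#' @return numeric matrix, samples x coefficients, columns ordered as
#'   `spec$index`.
#' @export
map_basis_matrix <- function(scheme, spec) {
  stopifnot(inherits(scheme, "gradient_scheme"),
            inherits(spec, "map_basis_spec"))
  if (any(spec$index$l %% 2 != 0)) stop("odd l is not supported")
  tau <- scheme_tau(scheme)
  q <- q_of_b(scheme$b_values, tau)
  lmax <- max(spec$index$l)
  Y <- sh_basis(scheme$directions, lmax, even_only = TRUE)
  yo <- attr(Y, "orders"); yd <- attr(Y, "degrees")
  A <- matrix(0, length(q), nrow(spec$index))
  for (cc in seq_len(nrow(spec$index))) {
    j <- spec$index$j[cc]; l <- spec$index$l[cc]; m <- spec$index$m[cc]
    ycol <- which(yo == l & yd == m)
    A[, cc] <- sqrt(4 * pi) * xi_radial(j, l, spec$u0, q) * Y[, ycol]
  }
  A
}

#' Estimate the MAP-MRI scale length u0 from low-b data
#'
#' Fits a log-linear diffusion tensor to the samples with
#' b <= `b_cut` (default 3 ms/um^2) and sets
#' \eqn{u_0 = \sqrt{2\,\mathrm{MD}\,\tau}} with \eqn{\tau = \Delta -
#' \delta/3} and MD the mean diffusivity of the fit.
#'
#' @param scheme a [gradient_scheme()].
#' @param signals `signal_array` or numeric vector.
#' @param b_cut maximum b used for the tensor fit, ms/um^2.
#' @param floor_signal signals are clamped to this positive floor before
#'   taking logs (guards against noise-negative values).
#' @return list with `u0` (um), `MD` (um^2/ms) and `tau` (ms).
#' @export
estimate_u0 <- function(scheme, signals, b_cut = 3, floor_signal = 1e-4) {
  vals <- if (inherits(signals, "signal_array")) signals$values
          else as.numeric(signals)
  sel <- scheme$b_values <= b_cut
  if (sum(sel & scheme$b_values > 0) < 6) {
    stop("not enough low-b samples for a tensor fit")
  }
  u <- scheme$directions[sel, , drop = FALSE]
  b <- scheme$b_values[sel]
  s <- pmax(vals[sel], floor_signal)
  X <- cbind(1, -b * u[, 1]^2, -b * u[, 2]^2, -b * u[, 3]^2,
             -2 * b * u[, 1] * u[, 2], -2 * b * u[, 1] * u[, 3],
             -2 * b * u[, 2] * u[, 3])
  beta <- pinv_solve(X, log(s))$x
  MD <- sum(beta[2:4]) / 3
  if (!(MD > 0)) stop("nonpositive mean-diffusivity estimate")
  tau <- scheme_tau(scheme)
  list(u0 = sqrt(2 * MD * tau), MD = MD, tau = tau)
}

# analytic Gaussian moment: int_0^inf q^(2k) exp(-c q^2) dq
gauss_moment <- function(k, c) exp(lgamma(k + 1 / 2)) / (2 * c^(k + 1 / 2))

# polynomial coefficients (in powers of q) of the radial factor
# A_jl(q) = (2 pi^2 u0^2)^{l/2} q^l L_{j-1}^{l+1/2}(4 pi^2 u0^2 q^2)
# so that xi = +/- A e^{-beta q^2}, beta = 2 pi^2 u0^2
radial_poly <- function(j, l, beta) {
  lag <- laguerre_coefs(j - 1, l + 1 / 2)   # coefs in y = 2 beta q^2
  p <- numeric(l + 2 * (j - 1) + 1)         # index k+1 <-> q^k
  for (mm in seq_along(lag)) {
    pw <- l + 2 * (mm - 1)
    p[pw + 1] <- p[pw + 1] + beta^(l / 2) * lag[mm] * (2 * beta)^(mm - 1)
  }
  p
}

# coefficients of the radial Laplacian factor: if f = A(q) e^{-beta q^2},
# (Lap f)_radial = [A'' + 2A'/q - l(l+1)A/q^2 - 6 beta A - 4 beta q A'
#                   + 4 beta^2 q^2 A] e^{-beta q^2}
laplacian_poly <- function(p, l, beta) {
  deg <- length(p) - 1
  out <- numeric(deg + 3)
  for (k in 0:deg) {
    a <- p[k + 1]
    if (a == 0) next
    if (k >= 2) out[k - 1] <- out[k - 1] + a * k * (k - 1)        # A''
    if (k >= 1) out[k - 1] <- out[k - 1] + a * 2 * k              # 2A'/q
    if (l > 0)  out[k - 1] <- out[k - 1] - a * l * (l + 1)        # -l(l+1)A/q^2
    out[k + 1] <- out[k + 1] - a * 6 * beta                       # -6 beta A
    out[k + 1] <- out[k + 1] - a * 4 * beta * k                   # -4 beta q A'
    out[k + 3] <- out[k + 3] + a * 4 * beta^2                     # +4 b^2 q^2 A
  }
  out
}

#' Analytic Laplacian-energy Gram matrix of the MAP-MRI basis
#'
#' Entry (a, b) is \eqn{\int \nabla^2 \Xi_a(\mathbf q)\, \nabla^2
#' \Xi_b(\mathbf q)\, d\mathbf q}; by spherical-harmonic orthonormality the
#' matrix is block diagonal in (l, m), and the radial integrals of
#' (polynomial x Gaussian) products are evaluated in closed form via
#' Gaussian moments.  Used as the MAPL regularizer.
#'
#' @param spec a [map_basis_spec()].
#' @return symmetric positive semi-definite matrix, coefficients squared.
#' @export
map_laplacian_gram <- function(spec) {
  beta <- 2 * pi^2 * spec$u0^2
  idx <- spec$index
  n <- nrow(idx)
  # precompute Laplacian polynomials per (j, l)
  jl <- unique(idx[, c("j", "l")])
  lp <- list()
  for (r in seq_len(nrow(jl))) {
    j <- jl$j[r]; l <- jl$l[r]
    sign_l <- (-1)^(l / 2)
    lp[[paste(j, l)]] <- sign_l * sqrt(4 * pi) *
      laplacian_poly(radial_poly(j, l, beta), l, beta)
  }
  R <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (idx$l[a] != idx$l[b] || idx$m[a] != idx$m[b]) next
      pa <- lp[[paste(idx$j[a], idx$l[a])]]
      pb <- lp[[paste(idx$j[b], idx$l[b])]]
      # int (pa pb) q^2 e^{-2 beta q^2} dq ; pa pb via convolution
      conv <- numeric(length(pa) + length(pb) - 1)
      for (i in seq_along(pa)) {
        if (pa[i] == 0) next
        conv[i:(i + length(pb) - 1)] <- conv[i:(i + length(pb) - 1)] +
          pa[i] * pb
      }
      val <- 0
      for (k in seq_along(conv)) {
        if (conv[k] == 0) next
        pw <- (k - 1) + 2       # extra q^2 from the volume element
        if (pw %% 2 != 0) next  # odd powers cannot appear
        val <- val + conv[k] * gauss_moment(pw / 2, 2 * beta)
      }
      R[a, b] <- R[b, a] <- val
    }
  }
  R
}

#' Fit the MAP-MRI representation
#'
#' Fits \eqn{s = A c} with the spherical MAP-MRI design matrix in one of
#' three modes:
#' \describe{
#'   \item{ls}{pseudoinverse least squares (requires at least as many
#'     samples as coefficients).}
#'   \item{constrained}{least squares subject to nonnegativity of the
#'     reconstructed propagator on a radial-angular grid in displacement
#'     space (quadratic program with linear inequalities, solved by lazy
#'     constraint generation and dual coordinate descent).}
#'   \item{laplacian}{MAPL: minimizes \eqn{\|Ac - s\|^2 + \lambda\, c^T R c}
#'     with the analytic Laplacian Gram R; when `lambda_reg` is NULL,
#'     lambda is chosen by generalized cross-validation over a logarithmic
#'     grid 1e-5..1e1 relative to the mean diagonal of \eqn{A^T A}.}
#' }
#'
#' @param scheme a [gradient_scheme()].
#' @param signals `signal_array` or numeric vector (normalized so that
#'   S(0) is about 1).
#' @param n_max even basis order (6 or 8).
#' @param u0 basis scale, um; when NULL it is estimated from the data via
#'   [estimate_u0()].
#' @param mode `"ls"`, `"constrained"` or `"laplacian"`.
#' @param lambda_reg Laplacian regularization weight (laplacian mode);
#'   NULL for GCV selection.
#' @param constraint_grid optional list with `r` (radii, um) and
#'   `directions` (n x 3) for constrained mode; defaults to radii
#'   seq(0.02, 1, 0.02) * 5 u0 and the 43-pair Lebedev directions.
#' @return object of class `map_fit`: coefficients, basis spec, mode,
#'   lambda_reg, residual_norm, tau.
#' @export
fit_map <- function(scheme, signals, n_max = 6, u0 = NULL,
                    mode = c("ls", "constrained", "laplacian"),
                    lambda_reg = NULL, constraint_grid = NULL) {
  mode <- match.arg(mode)
  vals <- if (inherits(signals, "signal_array")) signals$values
          else as.numeric(signals)
  if (is.null(u0)) u0 <- estimate_u0(scheme, vals)$u0
  spec <- map_basis_spec(n_max, u0)
  A <- map_basis_matrix(scheme, spec)
  n <- nrow(A); p <- ncol(A)
  if (mode == "ls" && n < p) {
    stop("ls mode needs at least ", p, " samples; got ", n,
         " (use laplacian or constrained mode)")
  }
  if (!is.null(lambda_reg) && lambda_reg < 0) stop("negative lambda_reg")

  lambda_used <- NA_real_
  if (mode == "ls") {
    cvec <- drop(pinv_solve(A, vals)$x)
  } else if (mode == "laplacian") {
    R <- map_laplacian_gram(spec)
    AtA <- crossprod(A)
    Atb <- crossprod(A, vals)
    scale_ref <- mean(diag(AtA))
    if (is.null(lambda_reg)) {
      lgrid <- scale_ref * 10^seq(-5, 1, length.out = 25)
      # R is scaled to comparable magnitude so the relative grid is meaningful
      Rn <- R / max(mean(diag(R)), .Machine$double.eps)
      gcv <- vapply(lgrid, function(lam) {
        cl <- tryCatch(solve(AtA + lam * Rn, Atb), error = function(e) NULL)
        if (is.null(cl)) return(Inf)
        res <- vals - drop(A %*% cl)
        edf <- sum(diag(solve(AtA + lam * Rn, AtA)))
        n * sum(res^2) / (n - edf)^2
      }, numeric(1))
      lam <- lgrid[which.min(gcv)]
      cvec <- drop(solve(AtA + lam * Rn, Atb))
      lambda_used <- lam / scale_ref
    } else {
      Rn <- R / max(mean(diag(R)), .Machine$double.eps)
      lam <- lambda_reg * scale_ref
      cvec <- if (lambda_reg == 0) drop(pinv_solve(A, vals)$x)
              else drop(solve(AtA + lam * Rn, Atb))
      lambda_used <- lambda_reg
    }
  } else {
    if (is.null(constraint_grid)) {
      constraint_grid <- list(r = seq(0.02, 1, by = 0.02) * 5 * u0,
                              directions = lebedev_rule(43)$directions)
    }
    G <- propagator_matrix(spec, constraint_grid$r,
                           constraint_grid$directions)
    cvec <- qp_lsi(A, vals, G)
  }
  res <- vals - drop(A %*% cvec)
  out <- list(coefficients = cvec, basis = spec, mode = mode,
              lambda_reg = lambda_used, residual_norm = sqrt(sum(res^2)),
              tau = scheme_tau(scheme))
  class(out) <- "map_fit"
  out
}

#' @export
print.map_fit <- function(x, ...) {
  cat("MAP-MRI fit: n_max =", x$basis$n_max, ", u0 =",
      format(x$basis$u0, digits = 4), "um, mode =", x$mode,
      if (x$mode == "laplacian") paste0("(lambda = ",
        format(x$lambda_reg, digits = 3), ")") else "",
      "\n  residual norm", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

# propagator (EAP) basis matrix at displacement grid points r * direction.
# The displacement-space duals of the q-space basis have the same
# Hermite-Laguerre functional form with scale 1/(2 pi u0), overall factor
# (2 pi u0^2)^(-3/2) and Fourier eigenvalue sign (-1)^(j-1); the l-sign
# (-1)^{l/2} of the q-space basis is absorbed by the plane-wave expansion.
propagator_matrix <- function(spec, radii, directions) {
  u0 <- spec$u0
  u0r <- 1 / (2 * pi * u0)
  grid <- NULL
  for (r in radii) grid <- rbind(grid, r * directions)
  rmag <- rep(radii, each = nrow(directions))
  lmax <- max(spec$index$l)
  rd <- directions
  Y <- sh_basis(rd, lmax, even_only = TRUE)
  Y <- Y[rep(seq_len(nrow(rd)), times = length(radii)), , drop = FALSE]
  yo <- attr(sh_basis(rd[1, , drop = FALSE], lmax), "orders")
  yd <- attr(sh_basis(rd[1, , drop = FALSE], lmax), "degrees")
  G <- matrix(0, length(rmag), nrow(spec$index))
  for (cc in seq_len(nrow(spec$index))) {
    j <- spec$index$j[cc]; l <- spec$index$l[cc]; m <- spec$index$m[cc]
    ycol <- which(yo == l & yd == m)
    rad <- (-1)^(j - 1) * (2 * pi * u0^2)^(-3 / 2) *
      propagator_radial(j, l, u0r, rmag)
    G[, cc] <- sqrt(4 * pi) * rad * Y[, ycol]
  }
  G
}

# least squares with inequality constraints G c >= 0: lazy constraint
# generation; each pooled subproblem is solved in the dual (nonnegative
# multipliers) by accelerated projected gradient.  The dual Hessian
# H = Gp Q^-1 Gp' is never formed: with V = R^-T G' (R the Cholesky factor
# of Q) every product H z = V_p' (V_p z) costs O(p * pool).
qp_lsi <- function(A, s, G, tol = 1e-10, max_outer = 60L) {
  AtA <- crossprod(A) + diag(1e-10 * mean(diag(crossprod(A))), ncol(A))
  Atb <- crossprod(A, s)
  ch <- chol(AtA)
  qsolve <- function(x) backsolve(ch, forwardsolve(t(ch), x))
  V <- forwardsolve(t(ch), t(G))          # p x n_constraints
  c0 <- drop(qsolve(Atb))
  cvec <- c0
  pool <- integer(0)
  u <- numeric(0)
  for (outer in seq_len(max_outer)) {
    viol <- drop(G %*% cvec)
    bad <- which(viol < -tol)
    if (length(bad) == 0) break
    add <- setdiff(bad[order(viol[bad])], pool)
    u <- c(u, numeric(length(add)))
    pool <- c(pool, add)
    Vp <- V[, pool, drop = FALSE]
    d <- drop(G[pool, , drop = FALSE] %*% c0)
    L <- svd(Vp, nu = 0, nv = 0)$d[1]^2
    tstep <- 1 / L
    z <- u
    tk <- 1
    for (it in seq_len(20000L)) {
      grad <- drop(crossprod(Vp, Vp %*% z)) + d
      u_new <- pmax(0, z - tstep * grad)
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- u_new + ((tk - 1) / tk_new) * (u_new - u)
      conv <- max(abs(u_new - u)) < 1e-12 * (1 + max(abs(u_new)))
      u <- u_new
      tk <- tk_new
      if (conv) break
    }
    cvec <- drop(qsolve(Atb + drop(crossprod(G[pool, , drop = FALSE], u))))
  }
  cvec
}

# xi_radial without the q-space l sign (-1)^{l/2}, for the propagator
propagator_radial <- function(j, l, u0r, rmag) {
  x <- 2 * pi^2 * u0r^2 * rmag^2
  x^(l / 2) * exp(-x) * laguerre(j - 1, l + 1 / 2, 2 * x)
}

#' Reconstruct the propagator from a MAP-MRI fit
#'
#' Evaluates the ensemble-average propagator (the Fourier dual of the
#' fitted signal) at displacement points `r * direction`.
#'
#' @param fit a [fit_map()] result.
#' @param radii displacement magnitudes, um.
#' @param directions n x 3 unit vectors.
#' @return matrix, length(radii) * nrow(directions) values (radii vary
#'   slowest), as a vector aligned with the constraint grid layout.
#' @export
map_propagator <- function(fit, radii, directions) {
  G <- propagator_matrix(fit$basis, radii, as_unit_matrix(directions))
  drop(G %*% fit$coefficients)
}

#' Continuous powder average from a MAP-MRI fit
#'
#' The isotropic part of the fitted representation evaluated at arbitrary
#' b-values,
#' \deqn{\bar S(b) = \sum_{N\ even} c_{(1+N/2)00}\,
#'   \Xi_{(1+N/2)00}(u_0, q(b)),}
#' which interpolates the powder-averaged signal between (and beyond) the
#' acquired shells.
#'
#' @param fit a [fit_map()] result.
#' @param b_query b-values, ms/um^2, >= 0.
#' @return object of class `powder_average`.
#' @export
map_powder_average <- function(fit, b_query) {
  stopifnot(inherits(fit, "map_fit"))
  if (any(b_query < 0)) stop("b_query must be >= 0")
  q <- q_of_b(b_query, fit$tau)
  idx <- fit$basis$index
  iso <- which(idx$l == 0 & idx$m == 0)
  s <- numeric(length(b_query))
  for (cc in iso) {
    # sqrt(4 pi) * Y00 = 1 for the isotropic terms
    s <- s + fit$coefficients[cc] *
      xi_radial(idx$j[cc], 0, fit$basis$u0, q)
  }
  out <- list(b_values = b_query, s_bar = s,
              method_tag = paste0(if (fit$mode == "laplacian") "mapl"
                                  else "map", fit$basis$n_max))
  class(out) <- "powder_average"
  out
}
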