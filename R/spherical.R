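#' Real spherical harmonic basis evaluated at unit vectors
#'
#' Evaluates the real, orthonormal spherical harmonics \eqn{Y_k^m} at a set
#' of unit vectors.  Magnitude diffusion-weighted signals under single
#' diffusion encoding are antipodally symmetric, so by default only even
#' orders are used; odd orders can be requested for generic spherical work.
#'
#' The convention is the usual real basis: \eqn{Y_{k0} = N_{k0} P_k(\cos\theta)},
#' \eqn{Y_{km} = \sqrt{2} N_{km} P_k^m(\cos\theta)\cos(m\phi)} for \eqn{m>0} and
#' \eqn{\sqrt{2} N_{k|m|} P_k^{|m|}(\cos\theta)\sin(|m|\phi)} for \eqn{m<0},
#' with \eqn{N_{km} = \sqrt{(2k+1)(k-m)!/(4\pi (k+m)!)}} and
#' Condon--Shortley phase in \eqn{P_k^m}.  \eqn{Y_0^0 = 1/\sqrt{4\pi}}.
#'
#' @param directions numeric matrix, n x 3, rows are unit vectors.
#' @param lmax maximum spherical harmonic order.
#' @param even_only logical; keep only even orders (default TRUE).
#' @return matrix n x n_coeff with attributes `orders` and `degrees`
#'   (integer vectors giving k and m per column).
#' @export
sh_basis <- function(directions, lmax, even_only = TRUE) {
  directions <- as_unit_matrix(directions)
  n <- nrow(directions)
  ct <- pmin(pmax(directions[, 3], -1), 1)
  phi <- atan2(directions[, 2], directions[, 1])
  ks <- if (even_only) seq(0L, lmax, by = 2L) else seq(0L, lmax)
  ncoef <- sum(2L * ks + 1L)
  B <- matrix(0, n, ncoef)
  orders <- integer(ncoef)
  degrees <- integer(ncoef)
  col <- 1L
  for (k in ks) {
    # associated Legendre P_k^m(cos theta), m = 0..k, Condon-Shortley phase
    P <- if (k == 0L) matrix(1, 1, n) else pracma::legendre(k, ct)
    for (m in seq(-k, k)) {
      am <- abs(m)
      Nkm <- sqrt((2 * k + 1) / (4 * pi) *
                    exp(lgamma(k - am + 1) - lgamma(k + am + 1)))
      val <- Nkm * P[am + 1L, ]
      if (m > 0) {
        val <- sqrt(2) * val * cos(m * phi)
      } else if (m < 0) {
        val <- sqrt(2) * val * sin(am * phi)
      }
      B[, col] <- val
      orders[col] <- k
      degrees[col] <- m
      col <- col + 1L
    }
  }
  attr(B, "orders") <- orders
  attr(B, "degrees") <- degrees
  B
}

#' Product Gauss-Legendre quadrature on the sphere
#'
#' Tensor-product rule (Gauss-Legendre in cos(theta) x uniform in phi)
#' integrating spherical polynomials up to the requested degree exactly.
#' Used to evaluate the Watson convolution integral and dense orientational
#' means; weights sum to 4*pi.
#'
#' @param degree polynomial exactness degree (>= 35 recommended for the
#'   Watson kernels used here).
#' @return list with `directions` (n x 3) and `weights` (sum 4*pi).
#' @export
sphere_quadrature <- function(degree = 35) {
  n_t <- ceiling((degree + 1) / 2) + 1
  n_p <- 2 * (degree + 1)
  gl <- pracma::gaussLegendre(n_t, -1, 1)
  phi <- 2 * pi * (seq_len(n_p) - 1) / n_p
  ct <- rep(gl$x, each = n_p)
  st <- sqrt(pmax(1 - ct^2, 0))
  ph <- rep(phi, times = n_t)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_p) * (2 * pi / n_p)
  list(directions = dirs, weights = w)
}

# coerce to n x 3 matrix of unit rows; error if any row is (near) zero
as_unit_matrix <- function(x, tol = 1e-8) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 3, byrow = FALSE)
  if (ncol(x) != 3) stop("directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm < tol)) stop("zero-length direction vector")
  x / nrm
}

# Moore-Penrose pseudoinverse solve with relative singular-value cutoff.
# Used everywhere an inverse of a possibly ill-conditioned normal matrix
# appears; returns list(x, rank, cond).
pinv_solve <- function(A, b, rcond = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  list(x = x, rank = sum(keep), cond = sv$d[1] / sv$d[length(sv$d)])
}

# rotation matrix from axis-angle; helper for rotation-invariance checks
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
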