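#' Uniform gradient directions by antipodal electrostatic repulsion
#'
#' Distributes n directions on the hemisphere by minimizing the Coulomb
#' energy of antipodal charge pairs,
#' \deqn{E = \sum_{i<j} 1/|u_i - u_j| + 1/|u_i + u_j|,}
#' the classical electrostatic-repulsion criterion for diffusion gradient
#' schemes.  Optimization is projected gradient descent on the sphere with
#' backtracking (step halving), started from a seeded random configuration;
#' the result is deterministic for a fixed seed.
#'
#' @param n number of directions (>= 2).
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum gradient iterations.
#' @param tol relative energy-change convergence threshold.
#' @return object of class `direction_set`: list with `directions`
#'   (n x 3 unit rows) and `energy` (final repulsion cost).
#' @examples
#' d <- repulsion_directions(6, seed = 1)
#' @export
repulsion_directions <- function(n, seed = 1L, max_iter = 2000L,
                                 tol = 1e-10) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("n must be an integer >= 2")
  }
  n <- as.integer(n)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  # flip to upper hemisphere for reproducible canonical form
  flip <- u[, 3] < 0
  u[flip, ] <- -u[flip, ]

  e <- pair_energy(u)
  step <- 0.1 / n
  for (it in seq_len(max_iter)) {
    g <- pair_energy_grad(u)
    # project gradient onto tangent planes
    g <- g - u * rowSums(g * u)
    repeat {
      v <- u - step * g
      v <- v / sqrt(rowSums(v^2))
      e_new <- pair_energy(v)
      if (e_new <= e || step < 1e-16) break
      step <- step / 2
    }
    if (e_new > e) break
    converged <- (e - e_new) < tol * abs(e)
    u <- v
    e <- e_new
    step <- step * 1.5
    if (converged) break
  }
  out <- list(directions = u, energy = e)
  class(out) <- "direction_set"
  out
}

pair_energy <- function(u) {
  n <- nrow(u)
  G <- tcrossprod(u)                     # u_i . u_j
  dm <- sqrt(pmax(2 - 2 * G, 0))         # |u_i - u_j|
  dp <- sqrt(pmax(2 + 2 * G, 0))         # |u_i + u_j|
  iu <- upper.tri(G)
  sum(1 / dm[iu]) + sum(1 / dp[iu])
}

pair_energy_grad <- function(u) {
  n <- nrow(u)
  G <- tcrossprod(u)
  dm <- sqrt(pmax(2 - 2 * G, 0)); diag(dm) <- Inf
  dp <- sqrt(pmax(2 + 2 * G, 0)); diag(dp) <- Inf
  # dE/du_i = sum_j -(u_i - u_j)/|u_i-u_j|^3 - (u_i + u_j)/|u_i+u_j|^3
  cm <- 1 / dm^3
  cp <- 1 / dp^3
  # grad_i = -(rowSums(cm) u_i - cm %*% u) - (rowSums(cp) u_i + cp %*% u)
  -(rowSums(cm) * u - cm %*% u) - (rowSums(cp) * u + cp %*% u)
}

#' @export
print.direction_set <- function(x, ...) {
  cat("direction set:", nrow(x$directions),
      "unit vectors, repulsion energy", format(x$energy), "\n")
  invisible(x)
}

# minimum pairwise angle (radians), treating u and -u as identical
min_pair_angle <- function(u) {
  G <- abs(tcrossprod(u))
  diag(G) <- 0
  acos(pmin(max(G[upper.tri(G)], 0), 1))
}
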