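#' Gradient sampling scheme
#'
#' Container for a single-diffusion-encoding sampling scheme: unit gradient
#' directions, b-values (ms/um^2), optional shell labels, and pulse timing
#' (Delta, delta, in ms).  b = 0 samples are kept in the scheme (counted in
#' `n_b0`) and used only for normalization, never for shell averaging.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param b_values numeric vector of b-values, ms/um^2, >= 0.
#' @param shell_ids optional integer labels; all b within a shell must be
#'   identical (0 is reserved for b = 0 samples).
#' @param Delta,delta diffusion time and gradient duration in ms; must
#'   satisfy Delta > delta/3 > 0.
#' @return object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(directions, b_values, shell_ids = NULL,
                            Delta = 43.1, delta = 10.6) {
  directions <- as_unit_matrix(directions)
  b_values <- as.numeric(b_values)
  if (nrow(directions) != length(b_values)) {
    stop("directions and b_values lengths differ")
  }
  if (any(b_values < 0)) stop("b-values must be >= 0")
  if (!(Delta > delta / 3 && delta > 0)) {
    stop("timing must satisfy Delta > delta/3 > 0")
  }
  if (!is.null(shell_ids)) {
    shell_ids <- as.integer(shell_ids)
    if (length(shell_ids) != length(b_values)) stop("shell_ids length mismatch")
    for (s in unique(shell_ids)) {
      bs <- b_values[shell_ids == s]
      if (diff(range(bs)) > 1e-9) {
        stop("b-values within shell ", s, " are not identical")
      }
    }
  }
  out <- list(directions = directions, b_values = b_values,
              shell_ids = shell_ids, Delta = Delta, delta = delta,
              n_b0 = sum(b_values == 0))
  class(out) <- "gradient_scheme"
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("gradient scheme:", length(x$b_values), "samples (",
      x$n_b0, "with b = 0 ),",
      if (is.null(x$shell_ids)) "non-shelled" else
        paste(length(setdiff(unique(x$shell_ids), 0L)), "shells"),
      "\n  b range [", min(x$b_values), ",", max(x$b_values),
      "] ms/um^2, Delta =", x$Delta, "ms, delta =", x$delta, "ms\n")
  invisible(x)
}

# effective diffusion time tau = Delta - delta/3 (ms)
scheme_tau <- function(scheme) scheme$Delta - scheme$delta / 3

#' Build the study sampling schemes
#'
#' Constructs the gradient schemes of the simulation study:
#' \describe{
#'   \item{shelled_uniform}{one repulsion-optimized direction set replicated
#'     across all shells (e.g. 61 directions x 8 b-values).}
#'   \item{shelled_lebedev}{Lebedev antipodal-pair nodes (19 or 43)
#'     replicated across shells, enabling quadrature weighting.}
#'   \item{shelled_random}{n directions drawn without replacement from a
#'     102-point repulsion-optimized set, replicated across shells.}
#'   \item{nonshelled}{total samples spread over the q-space ball up to
#'     b_max: radii fixed so b covers (0, b_max] uniformly, directions
#'     relaxed by antipodal electrostatic repulsion of the 3D positions.}
#'   \item{nonshelled_random}{directions uniform on the sphere, b uniform
#'     on (0, b_max].}
#' }
#' Every scheme carries one b = 0 sample per distinct direction (shelled
#' kinds) or per nominal shell-size equivalent (non-shelled kinds).
#'
#' @param kind one of the scheme kinds above.
#' @param n_dir number of directions per shell (shelled kinds) or total
#'   number of nonzero-b samples (non-shelled kinds).
#' @param b_shells b-values of the shells, ms/um^2 (shelled kinds).
#' @param b_max maximum b-value, ms/um^2 (non-shelled kinds).
#' @param seed integer seed (direction optimization and random draws).
#' @param Delta,delta pulse timing, ms.
#' @param n_b0 number of b = 0 samples; default is the per-shell direction
#'   count, or n_dir divided by the shell count for non-shelled kinds.
#' @return a [gradient_scheme()].
#' @examples
#' sch <- build_scheme("shelled_lebedev", 43,
#'                     b_shells = seq(1.5, 12, by = 1.5))
#' @export
build_scheme <- function(kind = c("shelled_uniform", "shelled_lebedev",
                                  "shelled_random", "nonshelled",
                                  "nonshelled_random"),
                         n_dir, b_shells = seq(1.5, 12, by = 1.5),
                         b_max = 12, seed = 1L,
                         Delta = 43.1, delta = 10.6, n_b0 = NULL) {
  kind <- match.arg(kind)
  shelled <- kind %in% c("shelled_uniform", "shelled_lebedev", "shelled_random")
  if (shelled && length(b_shells) == 0) stop("b_shells must be nonempty")
  if (!shelled && !(b_max > 0)) stop("b_max must be positive")

  if (shelled) {
    dirs <- switch(kind,
      shelled_uniform = repulsion_directions(n_dir, seed = seed)$directions,
      shelled_lebedev = {
        rule <- lebedev_rule(n_dir)
        rule$directions
      },
      shelled_random = {
        pool <- repulsion_directions(102, seed = seed)$directions
        if (n_dir > nrow(pool)) stop("cannot draw ", n_dir, " from 102-point pool")
        idx <- local({
          old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
          on.exit(if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv()))
          set.seed(seed + 1L)
          sample.int(nrow(pool), n_dir)
        })
        pool[idx, , drop = FALSE]
      })
    if (nrow(dirs) != n_dir) stop("direction count mismatch: got ",
                                  nrow(dirs), ", requested ", n_dir)
    n_sh <- length(b_shells)
    if (is.null(n_b0)) n_b0 <- n_dir
    directions <- rbind(dirs[((seq_len(n_b0) - 1L) %% n_dir) + 1L, ,
                             drop = FALSE],
                        dirs[rep(seq_len(n_dir), times = n_sh), ])
    b_values <- c(rep(0, n_b0), rep(b_shells, each = n_dir))
    shell_ids <- c(rep(0L, n_b0), rep(seq_len(n_sh), each = n_dir))
    sch <- gradient_scheme(directions, b_values, shell_ids, Delta, delta)
  } else {
    n_total <- n_dir
    if (is.null(n_b0)) n_b0 <- max(1L, round(n_total / 8))
    if (kind == "nonshelled") {
      # radii give b_i uniform over (0, b_max]; directions from 3D antipodal
      # repulsion of the ball positions at those fixed radii
      b_values_nz <- b_max * (seq_len(n_total) - 0.5) / n_total
      dirs <- ball_repulsion_directions(b_values_nz / b_max, seed = seed)
    } else {
      drawn <- local({
        old <- if (exists(".Random.seed", envir = globalenv()))
          get(".Random.seed", envir = globalenv()) else NULL
        on.exit(if (!is.null(old))
          assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
        list(b = stats::runif(n_total, 0, b_max),
             u = matrix(stats::rnorm(3 * n_total), n_total, 3))
      })
      b_values_nz <- drawn$b
      dirs <- drawn$u / sqrt(rowSums(drawn$u^2))
    }
    b0_dirs <- repulsion_directions(n_b0, seed = seed)$directions
    directions <- rbind(b0_dirs, dirs)
    b_values <- c(rep(0, n_b0), b_values_nz)
    sch <- gradient_scheme(directions, b_values, shell_ids = NULL,
                           Delta = Delta, delta = delta)
  }
  sch
}

# Antipodal electrostatic relaxation of points in the ball at fixed radii
# proportional to sqrt(b) (q ~ sqrt(b)); only the directions move.
ball_repulsion_directions <- function(b_frac, seed, max_iter = 400L,
                                      tol = 1e-10) {
  n <- length(b_frac)
  r <- sqrt(b_frac)    # q-space radius, relative units
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  energy <- function(u) {
    x <- u * r
    sq <- rowSums(x^2)
    G <- tcrossprod(x)
    dm <- sqrt(pmax(outer(sq, sq, "+") - 2 * G, 0)); diag(dm) <- Inf
    dp <- sqrt(pmax(outer(sq, sq, "+") + 2 * G, 1e-18))
    sum(1 / pmax(dm[upper.tri(dm)], 1e-9)) +
      sum(1 / pmax(dp[upper.tri(dp)], 1e-9)) + sum(1 / pmax(diag(dp), 1e-9)) / 2
  }
  grad <- function(u) {
    x <- u * r
    sq <- rowSums(x^2)
    G <- tcrossprod(x)
    dm <- sqrt(pmax(outer(sq, sq, "+") - 2 * G, 0)); diag(dm) <- Inf
    dp <- sqrt(pmax(outer(sq, sq, "+") + 2 * G, 1e-18))
    cm <- 1 / pmax(dm, 1e-9)^3
    cp <- 1 / pmax(dp, 1e-9)^3
    g <- (rowSums(cm) * x - cm %*% x) + (rowSums(cp) * x + cp %*% x)
    -g * r   # d x_i / d u_i = r_i; sign: gradient of the energy
  }
  e <- energy(u)
  step <- 0.05
  for (it in seq_len(max_iter)) {
    g <- grad(u)
    g <- g - u * rowSums(g * u)   # project onto the tangent planes
    repeat {
      v <- u - step * g
      v <- v / sqrt(rowSums(v^2))
      e_new <- energy(v)
      if (e_new <= e || step < 1e-14) break
      step <- step / 2
    }
    if (e_new > e) break
    converged <- (e - e_new) < tol * abs(e)
    u <- v; e <- e_new; step <- step * 1.5
    if (converged) break
  }
  u
}

#' Perturb shell b-values to emulate gradient-strength bias
#'
#' Each nonzero b is replaced by b(1 + d) with d drawn uniformly from
#' \[-fraction, +fraction\], emulating uncorrected bias in gradient
#' strength (samples land slightly off their nominal shell).  Shell labels
#' are dropped because the data are no longer shelled; directions are
#' unchanged.
#'
#' @param scheme a [gradient_scheme()].
#' @param fraction perturbation half-width as a fraction of b (0 <= f < 1);
#'   the study uses 0.1 ("on the order of 10 percent").
#' @param seed integer seed.
#' @return a [gradient_scheme()] without shell ids (unless fraction = 0,
#'   where the input is returned unchanged).
#' @export
perturb_b <- function(scheme, fraction = 0.1, seed = 1L) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must be in [0, 1); b could become nonpositive otherwise")
  }
  if (fraction == 0) return(scheme)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  b <- scheme$b_values
  nz <- b > 0
  b[nz] <- b[nz] * (1 + stats::runif(sum(nz), -fraction, fraction))
  gradient_scheme(scheme$directions, b, shell_ids = NULL,
                  Delta = scheme$Delta, delta = scheme$delta)
}
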