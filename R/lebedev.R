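#' Lebedev quadrature rules on the hemisphere
#'
#' Returns antipodal-pair representatives of the octahedrally-symmetric
#' Lebedev grids together with their quadrature weights.  Because single
#' diffusion encoding signals satisfy S(u) = S(-u), one direction per
#' antipodal pair suffices: pair weights are doubled and then normalized to
#' sum to one.  Supported sizes are 3 pairs (6-point octahedral grid,
#' exactness degree 3), 19 pairs (38-point grid, degree 9) and 43 pairs
#' (86-point grid, degree 15).
#'
#' Grid parameters are the octahedral-orbit node coordinates and weights
#' obtained by solving the spherical-harmonic exactness conditions to
#' machine precision; they agree with the classical tabulations.
#'
#' @param n_pairs number of antipodal-pair representatives: 3, 19 or 43.
#' @return object of class `quadrature_rule`: list with `directions`
#'   (n_pairs x 3 unit rows), `weights` (sum 1) and `degree`.
#' @examples
#' rule <- lebedev_rule(43)
#' sum(rule$weights)  # 1
#' @export
lebedev_rule <- function(n_pairs) {
  if (!is.numeric(n_pairs) || length(n_pairs) != 1 ||
      !(n_pairs %in% c(3, 19, 43))) {
    stop("unsupported n_pairs; supported sizes are 3, 19, 43 ",
         "(6-, 38- and 86-point Lebedev grids)")
  }
  full <- switch(as.character(n_pairs),
    "3"  = lebedev_grid_006(),
    "19" = lebedev_grid_038(),
    "43" = lebedev_grid_086()
  )
  hemi <- antipodal_reduce(full$points, full$weights)
  rule <- list(directions = hemi$directions,
               weights = hemi$weights / sum(hemi$weights),
               degree = full$degree)
  class(rule) <- "quadrature_rule"
  rule
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat("Lebedev quadrature rule:", nrow(x$directions),
      "antipodal-pair directions, exactness degree", x$degree, "\n")
  invisible(x)
}

# ---- octahedral orbit generators -------------------------------------------

# 6 vertices of the octahedron
orbit_vertices <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# 8 cube corners
orbit_corners <- function() {
  s <- 1 / sqrt(3)
  as.matrix(expand.grid(x = c(s, -s), y = c(s, -s), z = c(s, -s)))
}

# 24-point orbit (a, a, b) with b = sqrt(1 - 2 a^2), all sign/position perms
orbit_aab <- function(a) {
  b <- sqrt(max(1 - 2 * a^2, 0))
  out <- NULL
  for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
    out <- rbind(out,
                 c(sx * a, sy * a, sz * b),
                 c(sx * a, sy * b, sz * a),
                 c(sx * b, sy * a, sz * a))
  }
  out
}

# 24-point orbit (a, b, 0) with b = sqrt(1 - a^2)
orbit_ab0 <- function(a) {
  b <- sqrt(1 - a^2)
  out <- NULL
  for (pq in list(c(a, b), c(b, a))) {
    for (sx in c(1, -1)) for (sy in c(1, -1)) {
      out <- rbind(out,
                   c(sx * pq[1], sy * pq[2], 0),
                   c(sx * pq[1], 0, sy * pq[2]),
                   c(0, sx * pq[1], sy * pq[2]))
    }
  }
  out
}

lebedev_grid_006 <- function() {
  list(points = orbit_vertices(),
       weights = rep(1 / 6, 6),
       degree = 3L)
}

lebedev_grid_038 <- function() {
  a <- 0.4597008433809831
  list(points = rbind(orbit_vertices(), orbit_corners(), orbit_ab0(a)),
       weights = c(rep(1 / 105, 6), rep(9 / 280, 8), rep(1 / 35, 24)),
       degree = 9L)
}

lebedev_grid_086 <- function() {
  ab1 <- 0.36960284645415026
  ab2 <- 0.69435400660266634
  ac  <- 0.37424303909034118
  list(points = rbind(orbit_vertices(), orbit_corners(),
                      orbit_aab(ab1), orbit_aab(ab2), orbit_ab0(ac)),
       weights = c(rep(0.01154401154401154, 6),
                   rep(0.01194390908585628, 8),
                   rep(0.01111055571060340, 24),
                   rep(0.01187650129453714, 24),
                   rep(0.01181230374690448, 24)),
       degree = 15L)
}

# keep one representative per antipodal pair; pair weight = sum of the two
antipodal_reduce <- function(points, weights, tol = 1e-10) {
  n <- nrow(points)
  used <- rep(FALSE, n)
  dirs <- NULL
  w <- NULL
  for (i in seq_len(n)) {
    if (used[i]) next
    d2 <- rowSums((points + matrix(points[i, ], n, 3, byrow = TRUE))^2)
    j <- which(!used & d2 < tol^0.5)
    j <- setdiff(j, i)
    if (length(j) != 1) stop("grid is not antipodally symmetric")
    used[c(i, j)] <- TRUE
    # canonical representative: positive z, then positive y, then x
    p <- points[i, ]
    if (p[3] < -tol || (abs(p[3]) < tol && p[2] < -tol) ||
        (abs(p[3]) < tol && abs(p[2]) < tol && p[1] < 0)) {
      p <- -p
    }
    dirs <- rbind(dirs, p)
    w <- c(w, weights[i] + weights[j])
  }
  rownames(dirs) <- NULL
  list(directions = dirs, weights = w)
}

#' Apply a quadrature rule to function values at its nodes
#'
#' Computes the normalized quadrature \eqn{\sum_i w_i f_i} (weights summing
#' to 1), i.e. the spherical mean \eqn{(1/4\pi)\oint f}.
#'
#' @param rule a [lebedev_rule()] object.
#' @param values function values at `rule$directions` (antipodally-symmetric
#'   integrand assumed).
#' @return the estimated spherical mean.
#' @export
quadrature_mean <- function(rule, values) {
  stopifnot(inherits(rule, "quadrature_rule"),
            length(values) == nrow(rule$directions))
  sum(rule$weights * values)
}
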