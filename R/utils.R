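# Internal helpers: units, superposition, geometry primitives.

# Boltzmann constant in kcal mol^-1 K^-1.
.kB <- 0.0019872041

# 1 kcal/mol expressed in the internal dynamical unit Da A^2 ps^-2.
# (Da A^2 ps^-2 = 1.66054e-23 J per molecule ~= 10 J/mol.)
.KCAL <- 418.4

#' @noRd
kBT_kcal <- function(temperature) .kB * temperature

#' Optimal rigid-body superposition (Kabsch)
#'
#' Returns the rotation matrix and translation that superpose the mobile
#' coordinate set onto the fixed one in the least-squares sense, handling the
#' improper-rotation (reflection) case.
#'
#' @param mobile,fixed numeric matrices (n x 3) of paired coordinates.
#' @return list with `R` (3 x 3 rotation), `centers` and `rmsd`.
#' @keywords internal
#' @noRd
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(fixed, 2, cf)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(R = R, center_mobile = cm, center_fixed = cf, rmsd = rmsd)
}

#' @noRd
apply_kabsch <- function(mobile, fit) {
  sweep(sweep(mobile, 2, fit$center_mobile) %*% t(fit$R), 2, fit$center_fixed, `+`)
}

#' Superpose one coordinate frame onto a reference
#' @noRd
superpose_frame <- function(mobile, fixed) {
  apply_kabsch(mobile, kabsch(mobile, fixed))
}

# Frames as an F x 3N matrix -> list of N x 3 matrices and back.
#' @noRd
frame_to_mat <- function(x) matrix(x, ncol = 3, byrow = TRUE)

#' @noRd
mat_to_frame <- function(m) as.numeric(t(m))

#' Torsion angle (degrees) defined by four points
#' @noRd
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

#' Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
#' @noRd
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Place a fourth atom from three reference atoms and internal coordinates
#'
#' Natural-extension reference frame (NeRF) construction: returns the position
#' at distance `bond` from c, with angle `angle` (deg) at c relative to b-c,
#' and torsion `torsion` (deg) about b-c relative to a.
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180   # sign convention matches dihedral()
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
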