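# Real even-order spherical harmonics (orthonormal basis) and sphere
# quadrature. Antipodally symmetric functions such as fiber orientation
# distributions only need even degrees, so odd degrees are omitted
# throughout.

#' Number of real even-order spherical-harmonic coefficients
#'
#' @param lmax Maximum (even) harmonic degree.
#' @return Integer, \eqn{(lmax+1)(lmax+2)/2}.
#' @export
sh_ncoef <- function(lmax) {
  stopifnot(lmax >= 0, lmax %% 2 == 0)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

#' Evaluate the real even-order spherical-harmonic basis
#'
#' Returns the orthonormal real basis \eqn{Y_{lm}} for even degrees
#' \eqn{l = 0, 2, \dots, lmax}, ordered by degree and, within a degree, by
#' order \eqn{m = -l, \dots, l}. Negative orders carry \eqn{\sin(|m|\phi)},
#' positive orders \eqn{\cos(m\phi)}, both with a \eqn{\sqrt{2}} factor, so
#' that \eqn{\int Y_{lm} Y_{l'm'} d\Omega = \delta_{ll'}\delta_{mm'}}.
#'
#' @param dirs Numeric matrix (n x 3) of directions; rows are normalized
#'   internally.
#' @param lmax Maximum even degree.
#' @return Matrix (n x `sh_ncoef(lmax)`).
#' @export
sh_basis <- function(dirs, lmax) {
  dirs <- matrix(as.numeric(dirs), ncol = 3)
  nrm <- sqrt(rowSums(dirs^2))
  nrm[nrm == 0] <- 1
  dirs <- dirs / nrm
  ct <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  B <- matrix(0, n, sh_ncoef(lmax))
  col <- 1L
  for (l in seq(0L, lmax, by = 2L)) {
    if (l == 0L) {
      P <- matrix(1, 1L, n)
    } else {
      P <- pracma::legendre(l, ct)
      if (is.null(dim(P))) P <- matrix(P, ncol = n)
    }
    for (m in seq(-l, l)) {
      am <- abs(m)
      # orthonormalization constant; log-gamma avoids factorial overflow
      nc <- sqrt((2 * l + 1) / (4 * pi) *
                   exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- P[am + 1L, ] * nc
      B[, col] <- if (m < 0) {
        sqrt(2) * plm * sin(am * phi)
      } else if (m == 0) {
        plm
      } else {
        sqrt(2) * plm * cos(am * phi)
      }
      col <- col + 1L
    }
  }
  B
}

#' Column indices of the zonal (m = 0) coefficients
#'
#' @param lmax Maximum even degree.
#' @return Integer vector, one index per even degree.
#' @export
sh_zonal_index <- function(lmax) {
  idx <- integer(0)
  offset <- 0L
  for (l in seq(0L, lmax, by = 2L)) {
    idx <- c(idx, offset + l + 1L)
    offset <- offset + 2L * l + 1L
  }
  idx
}

#' Gauss-Legendre product quadrature on the sphere
#'
#' Nodes are a tensor grid of Gauss-Legendre abscissae in \eqn{\cos\theta}
#' and an equispaced trapezoid rule in \eqn{\phi}; the rule integrates
#' spherical polynomials up to degree \eqn{2n - 1} exactly, which makes it a
#' machine-precision oracle for band-limited integrands such as products of
#' spherical harmonics.
#'
#' @param n Number of polar nodes (2n azimuthal nodes are used).
#' @return List with `dirs` (2n^2 x 3) and `weights` summing to \eqn{4\pi}.
#' @export
sphere_quadrature <- function(n = 24) {
  gl <- pracma::gaussLegendre(n, -1, 1)
  nphi <- 2L * n
  phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = n)
  list(dirs = cbind(st * cos(ph), st * sin(ph), ct),
       weights = rep(gl$w, each = nphi) * (2 * pi / nphi))
}

# Deterministic, approximately uniform point set on the upper hemisphere
# (Fibonacci spiral). Used for FOD nonnegativity constraints and as the
# skeleton for gradient schemes.
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
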