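# Single-shell 3-tissue constrained spherical deconvolution. Per voxel the
# b0 + shell attenuations are fit jointly by a WM fiber orientation
# distribution (even-order spherical harmonics, convolved with the zonal WM
# response via the Funk-Hecke eigenvalues sqrt(4*pi/(2l+1)) * r_l) plus
# nonnegative isotropic GM and CSF scalars. FOD nonnegativity is enforced
# exactly at a dense direction set by a primal active-set quadratic
# program.

csd_design <- function(gtab, responses, lmax) {
  nc <- sh_ncoef(lmax)
  n <- length(gtab$bvals)
  shell <- gtab$bvals > 0
  M <- matrix(0, n, nc + 2L)
  # b0 rows: the WM b0 response is isotropic, so only c00 contributes
  M[!shell, 1] <- responses$wm$b0
  M[!shell, nc + 1L] <- responses$gm[["b0"]]
  M[!shell, nc + 2L] <- responses$csf[["b0"]]
  B <- sh_basis(gtab$bvecs[shell, , drop = FALSE], lmax)
  ldeg <- rep(seq(0L, lmax, by = 2L), times = 2L * seq(0L, lmax, by = 2L) + 1L)
  lam <- sqrt(4 * pi / (2 * ldeg + 1)) * responses$wm$shell[ldeg / 2L + 1L]
  M[shell, seq_len(nc)] <- sweep(B, 2, lam, "*")
  M[shell, nc + 1L] <- responses$gm[["shell"]]
  M[shell, nc + 2L] <- responses$csf[["shell"]]
  M
}

# With a single b0 plus one shell, the three isotropic compartments (the
# FOD's l = 0 term, GM and CSF) are mutually collinear - the classic
# single-shell 3-tissue degeneracy. A tiny ridge on the normal matrix
# makes the quadratic program strictly convex; the nonnegativity
# constraints (FOD >= 0, GM/CSF >= 0) then pin down the physically
# meaningful allocation wherever one exists.

# Exact FOD-nonnegativity via the dual. The per-voxel problem
#   min ||M x - y||^2  s.t.  G x >= 0
# (G stacks the FOD amplitudes at the constraint directions and the GM/CSF
# nonnegativity rows) is a strictly convex QP after a tiny ridge on
# Q = M'M. Its dual is a nonnegative least-squares problem in the
# multipliers mu, solved by Lawson-Hanson with ridge-protected passive
# solves; the primal solution x = Q^{-1}(M'y + G'mu) then satisfies the
# constraints to solver precision. Everything quadratic in the design
# (Q^{-1}G', G Q^{-1} G') is precomputed once per gradient scheme.
nnls_lh <- function(BtB, Btf, max_iter = 300) {
  n <- length(Btf)
  mu <- numeric(n)
  P <- logical(n)
  w <- Btf
  # absolute tolerance in FOD-amplitude units: the residual constraint
  # violation of the primal solution equals the final dual gradient
  tol <- 1e-7
  it <- 0L
  repeat {
    it <- it + 1L
    cand <- which(!P & w > tol)
    if (length(cand) == 0L || it > max_iter) break
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    repeat {
      idx <- which(P)
      k <- length(idx)
      ridge <- 1e-12 * max(mean(diag(BtB)[idx]), 1)
      s <- tryCatch(
        drop(solve(BtB[idx, idx] + ridge * diag(k), Btf[idx])),
        error = function(e) rep(-1, k))
      if (all(s > 0)) {
        mu[] <- 0
        mu[idx] <- s
        break
      }
      neg <- which(s <= 0)
      cur <- mu[idx]
      alpha <- min(cur[neg] / (cur[neg] - s[neg] + 1e-300))
      mu[idx] <- cur + alpha * (s - cur)
      off <- idx[mu[idx] <= 1e-14]
      mu[off] <- 0
      P[off] <- FALSE
      if (!any(P)) break
    }
    w <- Btf - drop(BtB %*% mu)
  }
  list(mu = mu, iterations = it)
}

csd_solve_voxel <- function(y, M, pre, nc, max_iter) {
  cvec <- drop(crossprod(M, y))
  x <- drop(pre$Qinv %*% cvec)
  gx <- drop(pre$G %*% x)
  it <- 0L
  if (min(gx) < -1e-12) {
    r <- nnls_lh(pre$GQiGt, -gx, max_iter)
    x <- x + drop(pre$QinvGt %*% r$mu)
    it <- r$iterations
  }
  amp <- drop(pre$Bc %*% x[seq_len(nc)])
  x[nc + 1:2] <- pmax(x[nc + 1:2], 0)
  list(x = x, iterations = it,
       max_violation = max(0, -min(amp)) / max(max(amp), 1e-3))
}

#' Fit single-shell 3-tissue constrained spherical deconvolution
#'
#' Solves, per voxel, for WM fiber-orientation-distribution spherical
#' harmonic coefficients together with nonnegative GM and CSF scalars that
#' jointly minimize the squared misfit to the b0 + shell attenuations,
#' subject to FOD nonnegativity at a dense constraint direction set.
#'
#' @param dwi 4-D signal array, or matrix (voxels x measurements).
#' @param gtab Single-shell [gradient_table()].
#' @param responses Group-averaged [estimate_responses()] /
#'   [average_responses()] result.
#' @param lmax Even harmonic degree. `NULL` (default) picks the largest
#'   even degree (at most 8 and the responses' lmax) the measurement count
#'   supports, warning when it is lowered below 8; an explicit `lmax` that
#'   leaves more unknowns than measurements is an error.
#' @param mask Logical 3-D array (volume input).
#' @param n_constraint Number of constraint directions (Fibonacci
#'   hemisphere).
#' @param max_iter Maximum dual (Lawson-Hanson) iterations per voxel.
#' @return Object of class `fod_field`: `coefficients` (voxels x
#'   coefficients), `gm` and `csf` fraction maps, `lmax`, mask bookkeeping
#'   and a `diagnostics` tibble.
#' @export
fit_ss3t_csd <- function(dwi, gtab, responses, lmax = NULL, mask = NULL,
                         n_constraint = 150, max_iter = 300) {
  n_meas <- length(gtab$bvals)
  if (!is.null(lmax)) {
    if (lmax %% 2 != 0) stop("lmax must be even", call. = FALSE)
    if (sh_ncoef(lmax) + 2L > n_meas) {
      stop("lmax ", lmax, " gives ", sh_ncoef(lmax) + 2L, " unknowns for ",
           n_meas, " measurements; lower lmax", call. = FALSE)
    }
    if (lmax > responses$lmax) {
      stop("responses only support lmax up to ", responses$lmax,
           call. = FALSE)
    }
  } else {
    lmax <- min(8L, responses$lmax)
    while (lmax > 0L && sh_ncoef(lmax) + 2L > n_meas) lmax <- lmax - 2L
    if (lmax < min(8L, responses$lmax)) {
      warning("lmax lowered to ", lmax, " to keep the per-voxel system ",
              "overdetermined (", n_meas, " measurements)")
    }
  }
  nc <- sh_ncoef(lmax)
  M <- csd_design(gtab, responses, lmax)
  Bc <- sh_basis(fibonacci_hemisphere(n_constraint), lmax)
  G <- rbind(cbind(Bc, matrix(0, nrow(Bc), 2L)),
             diag(nc + 2L)[nc + 1:2, , drop = FALSE])
  Q <- crossprod(M)
  Q <- Q + (1e-8 * mean(diag(Q))) * diag(ncol(Q))
  Qinv <- chol2inv(chol(Q))
  QinvGt <- Qinv %*% t(G)
  pre <- list(G = G, Bc = Bc, Qinv = Qinv, QinvGt = QinvGt,
              GQiGt = G %*% QinvGt)

  volume_input <- !is.matrix(dwi)
  if (volume_input) {
    stopifnot(length(dim(dwi)) == 4)
    if (is.null(mask)) stop("a mask is required for volume input",
                            call. = FALSE)
    mask <- as_mask(mask)
    check_same_grid(dwi, mask, what = "dwi and mask")
    gs <- dim(dwi)[1:3]
    idx <- which(mask)
    Y <- matrix(dwi, nrow = prod(gs))[idx, , drop = FALSE]
  } else {
    Y <- dwi
    idx <- seq_len(nrow(Y))
  }
  shell <- gtab$bvals > 0
  s0 <- rowMeans(Y[, !shell, drop = FALSE])
  ok <- s0 > 0
  A <- Y / ifelse(s0 > 0, s0, 1)

  nvox <- nrow(A)
  coefs <- matrix(0, nvox, nc)
  gm <- csf <- iters <- viol <- numeric(nvox)
  for (i in seq_len(nvox)) {
    if (!ok[i]) next
    r <- csd_solve_voxel(A[i, ], M, pre, nc, max_iter)
    coefs[i, ] <- r$x[seq_len(nc)]
    gm[i] <- r$x[nc + 1L]
    csf[i] <- r$x[nc + 2L]
    iters[i] <- r$iterations
    viol[i] <- r$max_violation
  }
  diagnostics <- tibble::tibble(voxel = idx, iterations = iters,
                                max_violation = viol, excluded = !ok)
  out <- list(coefficients = coefs, lmax = lmax, gm = gm, csf = csf,
              diagnostics = diagnostics, scale = 1)
  if (volume_input) {
    to_map <- function(v) { a <- array(NA_real_, gs); a[idx] <- v; a }
    out$gm <- to_map(gm)
    out$csf <- to_map(csf)
    out$mask <- mask
    out$mask_index <- idx
    out$grid <- gs
  } else {
    out$mask <- NULL
  }
  structure(out, class = "fod_field")
}

#' @export
print.fod_field <- function(x, ...) {
  cat("<fod_field> ", nrow(x$coefficients), " voxels, lmax ", x$lmax,
      " (", ncol(x$coefficients), " coefficients)\n", sep = "")
  invisible(x)
}

fod_iso_values <- function(fod) {
  if (is.null(fod$mask)) list(gm = fod$gm, csf = fod$csf)
  else list(gm = fod$gm[fod$mask_index], csf = fod$csf[fod$mask_index])
}

#' Globally normalize a fitted FOD field
#'
#' Scales all WM coefficients and the GM/CSF fractions by one global factor
#' per subject so that the subject's median total tissue signal (WM FOD
#' integral + GM + CSF) over `wm_mask` voxels equals 1. Idempotent.
#'
#' @param fod A [fit_ss3t_csd()] result.
#' @param wm_mask Optional logical array restricting the median to WM
#'   voxels; defaults to all fitted voxels.
#' @return The rescaled `fod_field`.
#' @export
normalize_fods <- function(fod, wm_mask = NULL) {
  afd <- afd_from_sh(fod$coefficients)
  iso <- fod_iso_values(fod)
  total <- afd + iso$gm + iso$csf
  if (!is.null(wm_mask) && !is.null(fod$mask)) {
    wm_mask <- as_mask(wm_mask)
    keep <- wm_mask[fod$mask_index]
    total <- total[keep]
  }
  med <- median(total, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) {
    stop("median total tissue signal is zero; cannot normalize",
         call. = FALSE)
  }
  fod$coefficients <- fod$coefficients / med
  fod$gm <- fod$gm / med
  fod$csf <- fod$csf / med
  fod$scale <- fod$scale / med
  fod
}

#' Apparent fiber density from a FOD field
#'
#' AFD is the surface integral of the WM FOD over the sphere; in the
#' orthonormal real basis (constant basis function \eqn{1/(2\sqrt\pi)})
#' this is \eqn{c_{00} \cdot 2\sqrt\pi}.
#'
#' @param fod A `fod_field`.
#' @return A 3-D map (`NA` outside the mask) for volume fits, otherwise a
#'   vector.
#' @export
afd_map <- function(fod) {
  v <- afd_from_sh(fod$coefficients)
  if (is.null(fod$mask)) return(v)
  a <- array(NA_real_, fod$grid)
  a[fod$mask_index] <- v
  a
}

#' @param coefficients Spherical-harmonic coefficient vector or matrix
#'   (voxels x coefficients), orthonormal real basis.
#' @rdname afd_map
#' @export
afd_from_sh <- function(coefficients) {
  if (is.matrix(coefficients)) coefficients[, 1] * 2 * sqrt(pi)
  else coefficients[1] * 2 * sqrt(pi)
}

#' Locate FOD peaks by dense amplitude evaluation
#'
#' @param coefficients Coefficient vector of one voxel.
#' @param lmax Harmonic degree of the coefficients.
#' @param n_peaks Number of peaks to return.
#' @param min_separation Minimum angular separation between peaks, degrees.
#' @param n_dirs Size of the dense hemisphere grid.
#' @return Tibble with peak directions and amplitudes, strongest first.
#' @export
fod_peaks <- function(coefficients, lmax, n_peaks = 2, min_separation = 30,
                      n_dirs = 4000) {
  dirs <- fibonacci_hemisphere(n_dirs)
  amp <- drop(sh_basis(dirs, lmax) %*% coefficients)
  found <- list()
  ord <- order(amp, decreasing = TRUE)
  cosmin <- cos(min_separation * pi / 180)
  for (i in ord) {
    d <- dirs[i, ]
    if (length(found) &&
        any(vapply(found, function(p) abs(sum(p$dir * d)) > cosmin,
                   logical(1)))) next
    found[[length(found) + 1L]] <- list(dir = d, amplitude = amp[i])
    if (length(found) == n_peaks) break
  }
  tibble::tibble(
    peak = seq_along(found),
    x = vapply(found, function(p) p$dir[1], numeric(1)),
    y = vapply(found, function(p) p$dir[2], numeric(1)),
    z = vapply(found, function(p) p$dir[3], numeric(1)),
    amplitude = vapply(found, function(p) p$amplitude, numeric(1)))
}
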