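# Conventional single-tensor fit by linear least squares on log-signals,
# plus the eigenvalue-based scalar metrics shared with the bi-tensor fit.

# log-linear design: log S = c0 - b g' D g, tensor packed as
# (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
dti_design <- function(gtab, intercept = TRUE) {
  G <- gtab$bvecs
  b <- gtab$bvals
  X <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
             2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  X <- -b * X
  if (intercept) X <- cbind(1, X)
  X
}

tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

mat_to_tensor6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

# Scalar metrics from a matrix of packed tensors (n x 6). Eigenvalues are
# clipped below at zero (and optionally into a band) before any metric is
# computed. Returns md/ad/rd in the tensor's units and unitless fa in [0,1],
# plus the principal eigenvector.
tensor_metrics <- function(tensors, eig_clip = c(0, Inf)) {
  n <- nrow(tensors)
  fa <- md <- ad <- rd <- numeric(n)
  evec1 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    e <- eigen(tensor6_to_mat(tensors[i, ]), symmetric = TRUE)
    l <- pmin(pmax(e$values, eig_clip[1]), eig_clip[2])  # sorted descending
    md[i] <- mean(l)
    ad[i] <- l[1]
    rd[i] <- (l[2] + l[3]) / 2
    ss <- sum(l^2)
    fa[i] <- if (ss > 0) {
      min(sqrt(1.5 * sum((l - md[i])^2) / ss), 1)
    } else 0
    evec1[i, ] <- e$vectors[, 1]
  }
  list(fa = fa, md = md, ad = ad, rd = rd, evec1 = evec1)
}

check_dti_scheme <- function(gtab) {
  if (sum(gtab$bvals == 0) < 1) stop("at least one b = 0 volume is required",
                                     call. = FALSE)
  dirs <- gtab$bvecs[gtab$bvals > 0, , drop = FALSE]
  # directions identical up to sign probe the same tensor component
  canon <- t(apply(dirs, 1, function(g) if (g[3] < 0) -g else g))
  if (nrow(unique(round(canon, 6))) < 6) {
    stop("at least 6 distinct diffusion directions are required",
         call. = FALSE)
  }
  invisible(TRUE)
}

# core fit on a voxel-by-measurement matrix; returns per-voxel results
dti_core <- function(Y, gtab, eig_clip = c(0, Inf)) {
  X <- dti_design(gtab)
  n <- nrow(Y)
  ok <- apply(Y > 0, 1, all) & !apply(is.na(Y), 1, any)
  tensors <- matrix(NA_real_, n, 6)
  s0 <- rep(NA_real_, n)
  if (any(ok)) {
    cf <- qr.coef(qr(X), t(log(Y[ok, , drop = FALSE])))
    if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1)
    s0[ok] <- exp(cf[1, ])
    tensors[ok, ] <- t(cf[-1, , drop = FALSE])
  }
  met <- list(fa = rep(NA_real_, n), md = rep(NA_real_, n),
              ad = rep(NA_real_, n), rd = rep(NA_real_, n),
              evec1 = matrix(NA_real_, n, 3))
  if (any(ok)) {
    m <- tensor_metrics(tensors[ok, , drop = FALSE], eig_clip)
    met$fa[ok] <- m$fa; met$md[ok] <- m$md
    met$ad[ok] <- m$ad; met$rd[ok] <- m$rd
    met$evec1[ok, ] <- m$evec1
  }
  list(tensors = tensors, s0 = s0, metrics = met, excluded = !ok)
}

#' Fit the conventional diffusion tensor by linear least squares
#'
#' Per voxel, solves the log-linear system \eqn{\log S = \log S_0 - b g^T D g}
#' in least squares and derives FA, MD, AD and RD from the sorted,
#' nonnegativity-clipped eigenvalues (AD = \eqn{\lambda_1}, RD =
#' \eqn{(\lambda_2+\lambda_3)/2}, MD their mean, FA the normalized
#' eigenvalue dispersion). Voxels with non-positive signals are excluded
#' with a warning; voxels outside the mask carry `NA`.
#'
#' @param dwi 4-D signal array, or a matrix (voxels x measurements).
#' @param gtab A [gradient_table()] with >= 6 distinct directions and a b0.
#' @param mask Optional logical 3-D array (required for 4-D input).
#' @return An object of class `dti_fit`: tensor field (packed 6-vectors),
#'   `s0`, metric maps `fa`, `md`, `ad`, `rd`, principal directions, the
#'   mask, and the indices of excluded voxels.
#' @export
fit_dti <- function(dwi, gtab, mask = NULL) {
  check_dti_scheme(gtab)
  if (is.matrix(dwi)) {
    res <- dti_core(dwi, gtab)
    if (any(res$excluded)) {
      warning(sum(res$excluded),
              " voxel(s) with non-positive signal excluded from the tensor fit")
    }
    return(structure(list(
      tensors = res$tensors, s0 = res$s0,
      fa = res$metrics$fa, md = res$metrics$md,
      ad = res$metrics$ad, rd = res$metrics$rd,
      evec1 = res$metrics$evec1, mask = NULL,
      excluded = res$excluded, gtab = gtab), class = "dti_fit"))
  }
  stopifnot(length(dim(dwi)) == 4)
  if (is.null(mask)) stop("a mask is required for volume input", call. = FALSE)
  mask <- as_mask(mask)
  check_same_grid(dwi, mask, what = "dwi and mask")
  gs <- dim(dwi)[1:3]
  idx <- which(mask)
  flat <- matrix(dwi, nrow = prod(gs))
  out <- list(tensors = NULL, s0 = NULL, metrics = NULL)
  if (length(idx)) {
    res <- dti_core(flat[idx, , drop = FALSE], gtab)
    if (any(res$excluded)) {
      warning(sum(res$excluded),
              " masked voxel(s) with non-positive signal excluded from the tensor fit")
    }
  } else {
    res <- list(tensors = matrix(NA_real_, 0, 6), s0 = numeric(0),
                metrics = list(fa = numeric(0), md = numeric(0),
                               ad = numeric(0), rd = numeric(0),
                               evec1 = matrix(NA_real_, 0, 3)),
                excluded = logical(0))
  }
  to_map <- function(v) {
    a <- array(NA_real_, gs); a[idx] <- v; a
  }
  structure(list(
    tensors = res$tensors, s0 = to_map(res$s0),
    fa = to_map(res$metrics$fa), md = to_map(res$metrics$md),
    ad = to_map(res$metrics$ad), rd = to_map(res$metrics$rd),
    evec1 = res$metrics$evec1, mask = mask, mask_index = idx,
    excluded = res$excluded, gtab = gtab), class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  n <- if (is.null(x$mask)) nrow(x$tensors) else length(x$mask_index)
  cat("<dti_fit> ", n, " voxels fitted (", sum(x$excluded), " excluded)\n",
      sep = "")
  invisible(x)
}
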