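# Forward signal model for a two-compartment (free water + tissue) voxel
# and magnitude-MR noise.

tensor_quadform <- function(tensor, dirs) {
  # g' T g for each row of dirs
  rowSums((dirs %*% tensor) * dirs)
}

check_psd <- function(tensor, tol = 1e-10) {
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -tol * max(abs(ev), 1e-12))) {
    stop("tissue tensor must be positive semidefinite", call. = FALSE)
  }
  invisible(ev)
}

#' Simulate the diffusion signal of a free-water-contaminated voxel
#'
#' Bi-compartment signal on attenuations:
#' \deqn{S(g, b) = s_0 [ f \exp(-b d_{iso}) + (1 - f) \sum_k w_k \exp(-b g^T T_k g) ]}
#' where \eqn{f} is the free-water fraction and \eqn{T_k} the tissue
#' compartment tensor(s). At b = 0 the signal equals `s0` exactly.
#'
#' @param fw Free-water fraction in \[0, 1\].
#' @param tensor A symmetric positive-semidefinite 3x3 tensor (mm^2/s), or a
#'   list of `list(tensor =, weight =)` components (weights are renormalized
#'   to sum to one) for crossing-fiber voxels.
#' @param gtab A [gradient_table()].
#' @param s0 Non-diffusion-weighted signal.
#' @param d_iso Isotropic free-water diffusivity (mm^2/s); 3.0e-3 is the
#'   diffusivity of free water at body temperature.
#' @return Numeric vector, one signal value per gradient entry.
#' @export
simulate_voxel_signal <- function(fw, tensor, gtab, s0 = 100, d_iso = 3.0e-3) {
  stopifnot(fw >= 0, fw <= 1)
  if (is.matrix(tensor)) tensor <- list(list(tensor = tensor, weight = 1))
  w <- vapply(tensor, function(cmp) cmp$weight, numeric(1))
  w <- w / sum(w)
  for (cmp in tensor) check_psd(cmp$tensor)
  b <- gtab$bvals
  a_tissue <- rep(0, length(b))
  for (k in seq_along(tensor)) {
    q <- tensor_quadform(tensor[[k]]$tensor, gtab$bvecs)
    a_tissue <- a_tissue + w[k] * exp(-b * q)
  }
  a_tissue[b == 0] <- 1
  s0 * (fw * exp(-b * d_iso) + (1 - fw) * a_tissue)
}

#' Add Rician noise to a magnitude signal
#'
#' Each value s is replaced by \eqn{\sqrt{(s + n_1)^2 + n_2^2}} with
#' \eqn{n_1, n_2} independent zero-mean Gaussians of scale `sigma` -- the
#' magnitude-MR noise model. `sigma = 0` returns the input unchanged.
#'
#' @param signal Numeric vector or array.
#' @param sigma Noise scale (same units as the signal), >= 0.
#' @param seed Optional integer seed; the global RNG state is restored.
#' @return Object of the same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (sigma == 0) return(signal)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  n <- length(signal)
  out <- sqrt((signal + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}
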