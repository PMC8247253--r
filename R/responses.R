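# Three-tissue response functions estimated from the data themselves:
# the WM response is the zonal (m = 0) spherical-harmonic profile of
# single-fiber voxels after rotating each voxel's principal direction to
# the pole; GM and CSF responses are mean attenuations over their masks.
# All responses are expressed on attenuations (S / S0).

rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  cz <- v[3]
  if (cz > 1 - 1e-12) return(diag(3))
  if (cz < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2], -v[1], 0)                     # v x z
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - cz) * (K %*% K)
}

#' Estimate per-subject three-tissue response functions
#'
#' Single-fiber voxels are selected inside the WM mask as those with
#' FA above `fa_threshold` (at most the `n_single_fiber` highest-FA
#' voxels); each voxel's shell attenuation profile is rotated so its
#' principal diffusion direction lies along z and projected onto the zonal
#' even-order harmonics, then averaged. GM and CSF responses are the mean
#' b0 and shell attenuations over their masks.
#'
#' @param dwi 4-D signal array.
#' @param gtab Single-shell [gradient_table()].
#' @param masks Named list of logical arrays `wm`, `gm`, `csf`.
#' @param fa_threshold FA cut for single-fiber selection. The default sits
#'   slightly below the textbook 0.7 because even modest background free
#'   water depresses the raw-DTI FA of genuine single-fiber voxels.
#' @param n_single_fiber Maximum number of single-fiber voxels used.
#' @param lmax Maximum even harmonic degree of the WM response.
#' @return Object of class `response_set`: `wm` (`b0` zonal l = 0
#'   coefficient and `shell` zonal coefficient vector), `gm` and `csf`
#'   (named `b0`/`shell` scalars), `lmax`, `bvals`.
#' @export
estimate_responses <- function(dwi, gtab, masks, fa_threshold = 0.65,
                               n_single_fiber = 300, lmax = 8) {
  stopifnot(all(c("wm", "gm", "csf") %in% names(masks)))
  masks <- lapply(masks, as_mask)
  for (nm in c("wm", "gm", "csf")) {
    if (!any(masks[[nm]])) stop("tissue mask '", nm, "' is empty",
                                call. = FALSE)
  }
  shell <- gtab$bvals > 0
  b <- unique(round(gtab$bvals[shell]))
  if (length(b) != 1) stop("single-shell data required", call. = FALSE)

  dfit <- fit_dti(dwi, gtab, masks$wm)
  fa <- dfit$fa[dfit$mask_index]
  sf <- which(!is.na(fa) & fa > fa_threshold)
  if (length(sf) == 0) {
    stop("no single-fiber voxels with FA > ", fa_threshold,
         " found in the WM mask; relax fa_threshold", call. = FALSE)
  }
  sf <- sf[order(fa[sf], decreasing = TRUE)][seq_len(min(length(sf),
                                                         n_single_fiber))]
  vox <- dfit$mask_index[sf]

  gs <- dim(dwi)[1:3]
  flat <- matrix(dwi, nrow = prod(gs))
  zi <- sh_zonal_index(lmax)
  nz <- length(zi)
  dirs <- gtab$bvecs[shell, , drop = FALSE]

  r_shell <- matrix(NA_real_, length(vox), nz)
  r_b0 <- numeric(length(vox))
  for (k in seq_along(vox)) {
    y <- flat[vox[k], ]
    s0 <- mean(y[!shell])
    Avals <- y[shell] / s0
    R <- rotation_to_z(dfit$evec1[sf[k], ])
    U <- dirs %*% t(R)
    Z <- sh_basis(U, lmax)[, zi, drop = FALSE]
    r_shell[k, ] <- qr.coef(qr(Z), Avals)
    r_b0[k] <- 2 * sqrt(pi) * mean(y[!shell] / s0)   # zonal l=0 of constant 1
  }

  tissue_mean <- function(mask) {
    idx <- which(mask)
    ys <- flat[idx, , drop = FALSE]
    s0 <- rowMeans(ys[, !shell, drop = FALSE])
    ok <- s0 > 0
    c(b0 = mean(ys[ok, !shell, drop = FALSE] / s0[ok]),
      shell = mean(ys[ok, shell, drop = FALSE] / s0[ok]))
  }
  structure(list(
    wm = list(b0 = mean(r_b0), shell = colMeans(r_shell)),
    gm = tissue_mean(masks$gm), csf = tissue_mean(masks$csf),
    lmax = lmax, bvals = c(0, b), n_single_fiber = length(vox)),
    class = "response_set")
}

#' Average response functions across subjects
#'
#' Arithmetic mean per coefficient per tissue; all inputs must share the
#' same `lmax` and shells.
#'
#' @param per_subject List of [estimate_responses()] results.
#' @return A `response_set`.
#' @export
average_responses <- function(per_subject) {
  stopifnot(length(per_subject) >= 1)
  ref <- per_subject[[1]]
  for (r in per_subject[-1]) {
    if (r$lmax != ref$lmax || !isTRUE(all.equal(r$bvals, ref$bvals))) {
      stop("response sets have mismatched lmax or shells", call. = FALSE)
    }
  }
  mean_of <- function(f) Reduce(`+`, lapply(per_subject, f)) /
    length(per_subject)
  structure(list(
    wm = list(b0 = mean_of(function(r) r$wm$b0),
              shell = mean_of(function(r) r$wm$shell)),
    gm = mean_of(function(r) r$gm),
    csf = mean_of(function(r) r$csf),
    lmax = ref$lmax, bvals = ref$bvals,
    n_single_fiber = mean_of(function(r) r$n_single_fiber)),
    class = "response_set")
}

#' @export
print.response_set <- function(x, ...) {
  cat("<response_set> lmax ", x$lmax, "; shells ",
      paste(x$bvals, collapse = ", "), " s/mm^2\n", sep = "")
  cat("  wm zonal (shell): ",
      paste(sprintf("%.4f", x$wm$shell), collapse = " "), "\n", sep = "")
  cat("  gm shell ", sprintf("%.4f", x$gm[["shell"]]),
      ", csf shell ", sprintf("%.4f", x$csf[["shell"]]), "\n", sep = "")
  invisible(x)
}
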