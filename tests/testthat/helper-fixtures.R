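# Shared fixtures, all generated in code.

fixture_gtab <- function(n = 30, seed = 7) {
  make_gradient_table(n, b = 1000, n_b0 = 1, seed = seed)
}

# a tensor with given eigenvalues, principal axis rotated about z by `ang`
fixture_tensor <- function(evals = c(1.6, 0.35, 0.35) * 1e-3, ang = 0) {
  R <- matrix(c(cos(ang), -sin(ang), 0,
                sin(ang), cos(ang), 0,
                0, 0, 1), 3, 3)
  R %*% diag(evals) %*% t(R)
}

# a small three-tissue test volume: WM single fibers along z, a GM block and
# a CSF block, noiseless; used for response estimation and CSD tests
fixture_tissue_volume <- function(gtab) {
  gs <- c(6L, 6L, 6L)
  dwi <- array(0, c(gs, length(gtab$bvals)))
  wm <- gm <- csf <- array(FALSE, gs)
  sig_wm <- simulate_voxel_signal(0, diag(c(0.3, 0.3, 1.7) * 1e-3), gtab)
  sig_gm <- simulate_voxel_signal(0, diag(rep(0.8e-3, 3)), gtab)
  sig_csf <- simulate_voxel_signal(1, diag(rep(3e-3, 3)), gtab)
  for (x in 1:6) for (y in 1:6) for (z in 1:6) {
    s <- if (y <= 3) {
      wm[x, y, z] <- TRUE; sig_wm
    } else if (y <= 5) {
      gm[x, y, z] <- TRUE; sig_gm
    } else {
      csf[x, y, z] <- TRUE; sig_csf
    }
    dwi[x, y, z, ] <- s
  }
  list(dwi = dwi, masks = list(wm = wm, gm = gm, csf = csf))
}

fixture_responses <- local({
  cache <- NULL
  function(gtab = fixture_gtab()) {
    if (is.null(cache)) {
      vol <- fixture_tissue_volume(gtab)
      cache <<- estimate_responses(vol$dwi, gtab, vol$masks)
    }
    cache
  }
})

# phantom configuration small enough for unit tests
tiny_phantom_config <- function(n_subjects = 2L, ...) {
  phantom_config(grid_shape = c(10L, 12L, 8L), n_subjects = n_subjects,
                 lesion_count = 1:2, lesion_radius = c(1.5, 2.2),
                 seed = 5L, ...)
}

# random binary mask pair with wmh inside wm
random_mask_pair <- function(gs = c(8L, 8L, 6L)) {
  wm <- array(runif(prod(gs)) < 0.6, gs)
  wmh <- wm & array(runif(prod(gs)) < 0.3, gs)
  list(wm = wm, wmh = wmh)
}
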