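# Synthetic single-shell diffusion-MRI cohorts with known ground truth.
#
# Geometry: all subjects share one 1 mm isotropic grid (standing in for
# template registration). A CSF slab occupies the low-y face of the grid --
# the "ventricle" -- a one-voxel GM slab sits at the far face, and the rest
# of the interior is a white-matter slab with fibers along x (a configurable
# fraction of voxels holds a second, orthogonal fiber population). Lesions
# are spheres seeded near the ventricle face; ground-truth free water inside
# a lesion rises toward the ventricle across `fw_lesion_range`, and fiber
# density is coupled to free water through `coupling_beta`.

#' Phantom configuration
#'
#' Defaults define the simulated study conditions: 20 subjects on a
#' 16 x 16 x 10 grid at 1 mm^3, 30 diffusion directions at b = 1000 s/mm^2
#' plus one b0, SNR 40 on the b0 signal, free water rising from 0.1 at the
#' lesion rim to 0.7 at the periventricular core, and fiber density
#' decreasing with free water at slope `coupling_beta = -0.8`.
#'
#' @param grid_shape Integer vector (3), voxels per axis.
#' @param voxel_size Numeric vector (3), mm per axis.
#' @param n_subjects Number of subjects.
#' @param n_directions,n_b0,b Acquisition scheme (see [make_gradient_table()]).
#' @param snr b0 signal over Rician sigma; `Inf` for noiseless data.
#' @param s0 Non-diffusion-weighted signal (arbitrary units).
#' @param d_iso Isotropic free-water diffusivity, mm^2/s.
#' @param fw_lesion_range Ground-truth free water from lesion rim to
#'   periventricular core, both in \[0, 1\].
#' @param fw_nawm Background free-water fraction in normal-appearing WM.
#' @param coupling_beta Slope of fiber density per unit free water
#'   (`density = density_baseline + coupling_beta * fw`, clipped at 0).
#' @param density_baseline Fiber density at zero free water.
#' @param crossing_fraction Fraction of WM voxels holding two orthogonal
#'   fiber populations.
#' @param fiber_evals Eigenvalues (mm^2/s) of the healthy single-fiber
#'   tensor, sorted descending.
#' @param d_degraded Isotropic diffusivity (mm^2/s) of degraded,
#'   fiber-depleted tissue; the voxel tissue tensor is the density-weighted
#'   mixture `density * fiber + (1 - density) * d_degraded * I`, so losing
#'   fibers raises mean and radial diffusivity while axial diffusivity and
#'   anisotropy fall.
#' @param d_gm Isotropic gray-matter diffusivity, mm^2/s.
#' @param lesion_count Integer vector of candidate lesion counts per subject.
#' @param lesion_radius Range (voxels) of lesion sphere radii.
#' @param fw_jitter SD of the seeded jitter added to lesion free water
#'   (clipped back into `fw_lesion_range`); breaks ties in the quartile
#'   split.
#' @param htn_logodds Intercept and slope (on standardized lesion free
#'   water) of the hypertension model; the slope makes hypertension a true
#'   confounder of the free-water / microbleed association.
#' @param outcome_logodds Per-outcome logistic coefficients on standardized
#'   mean lesion free water (`z = (FW - 0.4) / 0.1`), plus a hypertension
#'   term for microbleeds.
#' @param seed Integer seed; every random draw in the cohort derives from it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(16L, 16L, 10L),
                           voxel_size = c(1, 1, 1),
                           n_subjects = 20L,
                           n_directions = 30L,
                           n_b0 = 1L,
                           b = 1000,
                           snr = 40,
                           s0 = 100,
                           d_iso = 3.0e-3,
                           fw_lesion_range = c(0.1, 0.7),
                           fw_nawm = 0.10,
                           coupling_beta = -0.8,
                           density_baseline = 1,
                           crossing_fraction = 0.3,
                           fiber_evals = c(1.7e-3, 0.3e-3, 0.3e-3),
                           d_degraded = 1.2e-3,
                           d_gm = 0.8e-3,
                           lesion_count = 2:3,
                           lesion_radius = c(2, 3.2),
                           fw_jitter = 0.02,
                           htn_logodds = c(intercept = -1.7, fw = 1.0),
                           outcome_logodds = list(
                             lacune = c(intercept = 0.9, fw = 1.0),
                             microbleed = c(intercept = -0.3, fw = 1.0,
                                            hypertension = 1.5)),
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
              n_subjects = as.integer(n_subjects),
              n_directions = as.integer(n_directions), n_b0 = as.integer(n_b0),
              b = b, snr = snr, s0 = s0, d_iso = d_iso,
              fw_lesion_range = fw_lesion_range, fw_nawm = fw_nawm,
              coupling_beta = coupling_beta,
              density_baseline = density_baseline,
              crossing_fraction = crossing_fraction,
              fiber_evals = fiber_evals, d_degraded = d_degraded, d_gm = d_gm,
              lesion_count = as.integer(lesion_count),
              lesion_radius = lesion_radius, fw_jitter = fw_jitter,
              htn_logodds = htn_logodds, outcome_logodds = outcome_logodds,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape <= 0)) {
    stop("grid_shape must be three positive integers", call. = FALSE)
  }
  fr <- cfg$fw_lesion_range
  if (length(fr) != 2 || fr[1] < 0 || fr[2] > 1 || fr[1] > fr[2]) {
    stop("fw_lesion_range must satisfy 0 <= low <= high <= 1", call. = FALSE)
  }
  if (!(cfg$snr > 0)) stop("snr must be positive", call. = FALSE)
  if (is.null(cfg$seed)) stop("seed is mandatory", call. = FALSE)
  # lesion spheres must fit inside the WM slab
  wm_dims <- c(cfg$grid_shape[1], cfg$grid_shape[2] - 3, cfg$grid_shape[3] - 2)
  if (2 * cfg$lesion_radius[2] + 1 > min(wm_dims)) {
    stop("lesion radius exceeds the white-matter extent of the grid",
         call. = FALSE)
  }
  invisible(cfg)
}

# Tissue masks implied by the grid geometry (shared across subjects).
phantom_geometry <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  iy <- array(rep(seq_len(ny), each = nx), dim = grid_shape)
  iz <- array(rep(seq_len(nz), each = nx * ny), dim = grid_shape)
  csf <- iy <= 2
  gm <- iy == ny
  wm <- iy >= 3 & iy <= ny - 1 & iz >= 2 & iz <= nz - 1 & !gm
  list(wm = wm, gm = gm, csf = csf, iy = iy, iz = iz,
       depth = pmin(pmax((iy - 3) / (ny - 1 - 3), 0), 1))
}

# One subject's ground truth; assumes the RNG is already positioned.
simulate_subject_truth <- function(cfg, geom) {
  gs <- cfg$grid_shape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]

  # lesion spheres seeded near the ventricle face
  n_les <- if (length(cfg$lesion_count) == 1) cfg$lesion_count else
    sample(cfg$lesion_count, 1)
  rmax <- cfg$lesion_radius[2]
  wmh <- array(FALSE, gs)
  ax <- seq_len(nx); ay <- seq_len(ny); az <- seq_len(nz)
  for (k in seq_len(n_les)) {
    r <- runif(1, cfg$lesion_radius[1], cfg$lesion_radius[2])
    cx <- runif(1, 1 + r, nx - r)
    cy <- runif(1, 3 + r, min(3 + r + 4, ny - 1 - r))
    cz <- runif(1, 2 + r, nz - 1 - r)
    d2 <- outer(outer((ax - cx)^2, (ay - cy)^2, "+"), (az - cz)^2, "+")
    wmh <- wmh | (d2 <= r^2)
  }
  wmh <- wmh & geom$wm
  if (!any(wmh)) stop("lesion seeding produced no lesion voxels", call. = FALSE)

  # free water: CSF = 1, GM low, WM background, lesions graded toward the
  # ventricle with seeded jitter to break ties
  fw <- array(0, gs)
  fw[geom$csf] <- 1
  fw[geom$gm] <- 0.05
  fw[geom$wm] <- cfg$fw_nawm
  fr <- cfg$fw_lesion_range
  les_fw <- fr[2] - (fr[2] - fr[1]) * geom$depth[wmh]
  les_fw <- les_fw + rnorm(sum(wmh), sd = cfg$fw_jitter)
  fw[wmh] <- pmin(pmax(les_fw, fr[1]), fr[2])

  # fiber density coupled to free water, clipped at zero
  density <- array(0, gs)
  density[geom$wm] <- pmax(
    cfg$density_baseline + cfg$coupling_beta * fw[geom$wm], 0)

  # crossing-fiber assignment within WM
  crossing <- array(FALSE, gs)
  crossing[geom$wm] <- runif(sum(geom$wm)) < cfg$crossing_fraction

  list(fw = fw, density = density, wmh_mask = wmh, wm_mask = geom$wm,
       gm_mask = geom$gm, csf_mask = geom$csf, crossing = crossing)
}

# Noiseless 4-D signal for one subject's truth.
phantom_signal <- function(truth, cfg, gtab) {
  gs <- cfg$grid_shape
  n_meas <- length(gtab$bvals)
  brain <- truth$wm_mask | truth$gm_mask | truth$csf_mask
  idx <- which(brain)
  G <- gtab$bvecs
  # quadratic-form design rows [gx^2, gy^2, gz^2, 2gxy, 2gxz, 2gyz]
  G6 <- cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
              2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
  b <- gtab$bvals

  fw <- truth$fw[idx]
  density <- truth$density[idx]
  in_wm <- truth$wm_mask[idx]
  in_gm <- truth$gm_mask[idx]
  crossing <- truth$crossing[idx]

  fe <- cfg$fiber_evals
  tvec_x <- c(fe[1], fe[2], fe[3], 0, 0, 0)     # fiber along x
  tvec_z <- c(fe[3], fe[2], fe[1], 0, 0, 0)     # fiber along z
  iso6 <- c(1, 1, 1, 0, 0, 0)

  # mixture tensors, density * fiber + (1 - density) * d_degraded * I,
  # held as per-voxel 6-vectors (6 x nv)
  Tx <- outer(tvec_x, density) + outer(iso6 * cfg$d_degraded, 1 - density)
  Tz <- outer(tvec_z, density) + outer(iso6 * cfg$d_degraded, 1 - density)
  Tx[, in_gm] <- iso6 * cfg$d_gm
  Tz[, in_gm] <- iso6 * cfg$d_gm
  csf_vox <- !in_wm & !in_gm
  Tx[, csf_vox] <- iso6 * cfg$d_iso
  Tz[, csf_vox] <- iso6 * cfg$d_iso

  Qx <- G6 %*% Tx                       # n_meas x nv
  Ax <- exp(-b * Qx)
  w_cross <- ifelse(crossing & in_wm, 0.5, 0)
  if (any(w_cross > 0)) {
    Az <- exp(-b * (G6 %*% Tz))
    A_tissue <- sweep(Ax, 2, 1 - w_cross, "*") + sweep(Az, 2, w_cross, "*")
  } else {
    A_tissue <- Ax
  }
  A_tissue[b == 0, ] <- 1
  A <- sweep(A_tissue, 2, 1 - fw, "*") + outer(exp(-b * cfg$d_iso), fw)
  A[b == 0, ] <- 1

  dwi <- array(0, c(gs, n_meas))
  flat <- matrix(dwi, nrow = prod(gs))
  flat[idx, ] <- t(cfg$s0 * A)
  array(flat, c(gs, n_meas))
}

#' Simulate a synthetic diffusion-MRI cohort
#'
#' Generates `n_subjects` subjects on a shared grid with ground-truth free
#' water, fiber density, tissue masks and lesion masks, noiseless bi-tensor
#' signals, Rician noise at `sigma = s0 / snr`, and a covariate/outcome
#' table whose binary outcomes follow a logistic model on mean lesion free
#' water (with hypertension as a built-in confounder of the microbleed
#' association). Fully deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return A list of class `dwi_cohort` with elements `subjects` (each a
#'   list with `dwi`, `truth`), `gtab`, `covariates` (tibble, one row per
#'   subject) and `config`.
#' @export
simulate_cohort <- function(config = phantom_config()) {
  validate_phantom_config(config)
  geom <- phantom_geometry(config$grid_shape)
  gtab <- make_gradient_table(config$n_directions, config$b, config$n_b0,
                              seed = config$seed)
  sigma <- if (is.finite(config$snr)) config$s0 / config$snr else 0

  withr::local_seed(config$seed)
  subjects <- vector("list", config$n_subjects)
  cov_rows <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    truth <- simulate_subject_truth(config, geom)
    dwi <- phantom_signal(truth, config, gtab)
    if (sigma > 0) dwi <- add_rician_noise(dwi, sigma)

    fw_les <- mean(truth$fw[truth$wmh_mask])
    z <- (fw_les - 0.4) / 0.1
    hl <- config$htn_logodds
    htn <- rbinom(1, 1, plogis(hl[["intercept"]] + hl[["fw"]] * z))
    ol <- config$outcome_logodds
    lacune <- rbinom(1, 1, plogis(ol$lacune[["intercept"]] +
                                    ol$lacune[["fw"]] * z))
    mb_lo <- ol$microbleed[["intercept"]] + ol$microbleed[["fw"]] * z +
      ol$microbleed[["hypertension"]] * htn
    microbleed <- rbinom(1, 1, plogis(mb_lo))

    cov_rows[[s]] <- tibble::tibble(
      subject = sprintf("sub-%03d", s),
      age = rnorm(1, 49.7, 6.5),
      gender = rbinom(1, 1, 0.71),
      hypertension = htn,
      duration = rlnorm(1, log(2), 0.9),
      icv = rnorm(1, 1.45e6, 1.2e5),
      lacune = lacune,
      microbleed = microbleed,
      fw_wmh_truth = fw_les)
    subjects[[s]] <- list(dwi = dwi, truth = truth)
  }
  structure(list(subjects = subjects, gtab = gtab,
                 covariates = dplyr::bind_rows(cov_rows), config = config),
            class = "dwi_cohort")
}

#' @export
print.dwi_cohort <- function(x, ...) {
  cat("<dwi_cohort> ", length(x$subjects), " subjects on a ",
      paste(x$config$grid_shape, collapse = " x "), " grid, ",
      x$config$n_directions, " directions at b = ", x$config$b,
      " s/mm^2, SNR ", x$config$snr, "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Per subject: `dwi.nii.gz`, `dwi.bval`/`dwi.bvec`, `wm_mask.nii.gz`,
#' `wmh_mask.nii.gz`, `truth_fw.nii.gz`, `truth_density.nii.gz`; cohort
#' covariates as `covariates.tsv` and the configuration (with seed) as
#' `config.yaml`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$config$voxel_size
  for (s in seq_along(cohort$subjects)) {
    sd <- file.path(dir, cohort$covariates$subject[s])
    dir.create(sd, showWarnings = FALSE)
    sub <- cohort$subjects[[s]]
    write_volume(sub$dwi, file.path(sd, "dwi.nii.gz"), vs)
    write_bval_bvec(cohort$gtab, file.path(sd, "dwi"))
    write_volume(sub$truth$wm_mask, file.path(sd, "wm_mask.nii.gz"), vs)
    write_volume(sub$truth$wmh_mask, file.path(sd, "wmh_mask.nii.gz"), vs)
    write_volume(sub$truth$fw, file.path(sd, "truth_fw.nii.gz"), vs)
    write_volume(sub$truth$density, file.path(sd, "truth_density.nii.gz"), vs)
  }
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  cfg$outcome_logodds <- lapply(cfg$outcome_logodds, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate a tabular regional cohort for statistical studies
#'
#' A lightweight generator of per-subject regional summaries used to study
#' the statistical estimators at scale without simulating images. Mean
#' lesion free water is Gaussian; hypertension both shifts free water (by
#' `confounder_shift`) and independently raises the outcome log-odds (by
#' `confounder_logodds`), making it a genuine confounder. The outcome
#' follows \eqn{logit(p) = \beta_0 + \beta_1 (10 \cdot FW - 4) + \beta_2 HTN},
#' i.e. the exposure coefficient is per 0.1 of free-water fraction.
#'
#' @param n_subjects Cohort size.
#' @param outcome_intercept,exposure_logodds,confounder_logodds Logistic
#'   coefficients (`exposure_logodds` per 0.1 FW).
#' @param confounder_prevalence Hypertension prevalence.
#' @param confounder_shift Additive FW shift in hypertensive subjects.
#' @param fw_mean,fw_sd Free-water distribution in non-hypertensive subjects.
#' @param seed Optional seed.
#' @return Tibble with columns `subject`, `fw_wmh`, `hypertension`, `age`,
#'   `gender`, `outcome`.
#' @export
simulate_regional_cohort <- function(n_subjects = 200,
                                     outcome_intercept = -0.3,
                                     exposure_logodds = 0.5,
                                     confounder_logodds = 1.2,
                                     confounder_prevalence = 0.3,
                                     confounder_shift = 0.08,
                                     fw_mean = 0.4, fw_sd = 0.08,
                                     seed = NULL) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  htn <- rbinom(n_subjects, 1, confounder_prevalence)
  fw <- pmin(pmax(rnorm(n_subjects, fw_mean, fw_sd) +
                    confounder_shift * htn, 0), 1)
  lo <- outcome_intercept + exposure_logodds * (10 * fw - 4) +
    confounder_logodds * htn
  tibble::tibble(
    subject = sprintf("sub-%03d", seq_len(n_subjects)),
    fw_wmh = fw,
    hypertension = htn,
    age = rnorm(n_subjects, 49.7, 6.5),
    gender = rbinom(n_subjects, 1, 0.71),
    outcome = rbinom(n_subjects, 1, plogis(lo)))
}
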