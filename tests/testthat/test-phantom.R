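test_that("cohorts are deterministic and satisfy the truth invariants", {
  cfg <- tiny_phantom_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)

  for (sub in a$subjects) {
    tr <- sub$truth
    expect_true(all(tr$fw >= 0 & tr$fw <= 1))
    expect_true(all(tr$wm_mask[tr$wmh_mask]))            # wmh subset of wm
    expect_true(all(tr$density >= 0))
    fr <- cfg$fw_lesion_range
    les_fw <- tr$fw[tr$wmh_mask]
    expect_true(all(les_fw >= fr[1] - 1e-12 & les_fw <= fr[2] + 1e-12))
  }
})

test_that("noiseless cohorts reproduce the voxel signal model exactly", {
  cfg <- tiny_phantom_config(snr = Inf, crossing_fraction = 0)
  co <- simulate_cohort(cfg)
  sub <- co$subjects[[1]]
  tr <- sub$truth
  # b0 equals s0 exactly inside tissue
  b0 <- sub$dwi[, , , which(co$gtab$bvals == 0)[1]]
  expect_true(all(b0[tr$wm_mask] == cfg$s0))
  # one lesion voxel checked against simulate_voxel_signal on the truth
  v <- which(tr$wmh_mask, arr.ind = TRUE)[1, ]
  fw <- tr$fw[v[1], v[2], v[3]]
  dens <- tr$density[v[1], v[2], v[3]]
  Tt <- dens * diag(cfg$fiber_evals) +
    (1 - dens) * diag(rep(cfg$d_degraded, 3))
  expect_equal(sub$dwi[v[1], v[2], v[3], ],
               simulate_voxel_signal(fw, Tt, co$gtab, s0 = cfg$s0,
                                     d_iso = cfg$d_iso),
               tolerance = 1e-12)
})

test_that("free water and fiber density are anticorrelated by construction", {
  cfg <- tiny_phantom_config(snr = Inf, coupling_beta = -0.8)
  co <- simulate_cohort(cfg)
  tr <- co$subjects[[1]]$truth
  r <- cor(tr$fw[tr$wmh_mask], tr$density[tr$wmh_mask])
  expect_lte(r, -0.95)
})

test_that("lesions that cannot fit the white matter are rejected", {
  expect_error(phantom_config(grid_shape = c(8L, 8L, 6L),
                              lesion_radius = c(2, 3.2)),
               "extent")
  expect_error(phantom_config(fw_lesion_range = c(0.8, 0.2)), "low")
  expect_error(phantom_config(snr = 0), "snr")
})

test_that("tabular cohort outcomes converge to the logistic prevalence", {
  n <- 5000
  d <- simulate_regional_cohort(n, outcome_intercept = -0.3,
                                exposure_logodds = 0.5,
                                confounder_logodds = 1.2, seed = 2)
  p_implied <- mean(plogis(-0.3 + 0.5 * (10 * d$fw_wmh - 4) +
                             1.2 * d$hypertension))
  se <- sqrt(p_implied * (1 - p_implied) / n)
  expect_lt(abs(mean(d$outcome) - p_implied), 4 * se)
})

test_that("written cohorts round-trip and validate cleanly", {
  cfg <- tiny_phantom_config()
  co <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "covariates.tsv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_equal(yaml::read_yaml(file.path(dir, "config.yaml"))$seed, 5L)

  fw_file <- read_volume(file.path(dir, co$covariates$subject[1],
                                   "truth_fw.nii.gz"))
  expect_equal(array(fw_file, dim(fw_file)),
               co$subjects[[1]]$truth$fw, tolerance = 1e-6)

  v <- validate_inputs(dir)
  expect_true(all(v$status == "pass"))

  # a mask on the wrong grid is a named failure, not an error
  bad <- file.path(dir, co$covariates$subject[1], "wm_mask.nii.gz")
  write_volume(array(TRUE, c(4, 4, 4)), bad)
  v2 <- validate_inputs(dir)
  expect_true(any(v2$status == "fail" & v2$check == "grid_consistent"))
})
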