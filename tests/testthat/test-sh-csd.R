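test_that("the real even spherical-harmonic basis is orthonormal", {
  q <- sphere_quadrature(24)
  B <- sh_basis(q$dirs, 8)
  G <- t(B) %*% (B * q$weights)
  expect_lt(max(abs(G - diag(ncol(B)))), 1e-10)
  expect_equal(ncol(B), (8 + 1) * (8 + 2) / 2)
  expect_equal(length(sh_zonal_index(8)), 5)
})

test_that("WM responses reproduce the analytic zonal projection", {
  gt <- fixture_gtab()
  resp <- fixture_responses(gt)
  # quadrature oracle: project the aligned single-fiber attenuation
  # profile onto the zonal harmonics
  Tz <- diag(c(0.3, 0.3, 1.7) * 1e-3)
  q <- sphere_quadrature(32)
  prof <- exp(-1000 * rowSums((q$dirs %*% Tz) * q$dirs))
  Z <- sh_basis(q$dirs, 8)[, sh_zonal_index(8)]
  oracle <- drop(t(Z) %*% (prof * q$weights))
  expect_equal(resp$wm$shell, oracle, tolerance = 1e-3)
  # CSF response: pure isotropic attenuation exp(-3) at the shell
  expect_equal(unname(resp$csf[["shell"]]), exp(-3), tolerance = 1e-9)
  # selection is FA-gated: a volume of purely isotropic WM has no
  # single-fiber voxels
  gs <- c(3, 3, 3)
  iso <- array(rep(simulate_voxel_signal(0, diag(rep(1e-3, 3)), gt),
                   each = prod(gs)), c(gs, length(gt$bvals)))
  m <- array(TRUE, gs)
  expect_error(estimate_responses(iso, gt, list(wm = m, gm = m, csf = m)),
               "fa_threshold")
})

test_that("response averaging is the per-coefficient arithmetic mean", {
  r <- fixture_responses()
  expect_equal(average_responses(list(r, r))$wm$shell, r$wm$shell)
  r2 <- r
  r2$wm$shell <- r$wm$shell * 3
  avg <- average_responses(list(r, r2))
  expect_equal(avg$wm$shell, 2 * r$wm$shell)      # midpoint
  r3 <- r
  r3$bvals <- c(0, 2000)
  expect_error(average_responses(list(r, r3)), "mismatch")
})

test_that("SS3T-CSD resolves fibers, free water and CSF", {
  gt <- fixture_gtab()
  resp <- fixture_responses(gt)
  Tx <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  Tz <- diag(c(0.3, 0.3, 1.7) * 1e-3)
  Y <- rbind(
    simulate_voxel_signal(0, Tx, gt),
    simulate_voxel_signal(1, diag(rep(3e-3, 3)), gt),
    simulate_voxel_signal(0, list(list(tensor = Tx, weight = 0.5),
                                  list(tensor = Tz, weight = 0.5)), gt))
  expect_warning(fod <- fit_ss3t_csd(Y, gt, resp), "lmax lowered")

  # single fiber along x: peak within 5 degrees, no isotropic leakage
  pk <- fod_peaks(fod$coefficients[1, ], fod$lmax, n_peaks = 1)
  ang <- acos(min(abs(pk$x[1]), 1)) * 180 / pi
  expect_lt(ang, 5)
  expect_lte(fod$gm[1], 0.02)
  expect_lte(fod$csf[1], 0.02)

  # pure CSF: csf fraction ~ 1, WM energy negligible
  expect_equal(fod$csf[2], 1, tolerance = 0.02)
  expect_lt(sum(fod$coefficients[2, ]^2) / sum(fod$coefficients[1, ]^2),
            1e-3)

  # orthogonal crossing: two peaks within 10 degrees, balanced amplitudes
  pk2 <- fod_peaks(fod$coefficients[3, ], fod$lmax, n_peaks = 2)
  angs <- vapply(1:2, function(i) {
    d <- c(pk2$x[i], pk2$y[i], pk2$z[i])
    min(acos(pmin(abs(d[1]), 1)), acos(pmin(abs(d[3]), 1))) * 180 / pi
  }, numeric(1))
  expect_lt(max(angs), 10)
  ratio <- pk2$amplitude[1] / pk2$amplitude[2]
  expect_true(ratio >= 0.8 && ratio <= 1.25)

  # nonnegativity invariant
  expect_true(all(fod$diagnostics$max_violation <= 1e-4))
})

test_that("lmax handling follows the measurement count", {
  gt <- fixture_gtab()
  resp <- fixture_responses(gt)
  Y <- matrix(simulate_voxel_signal(0.2, diag(c(1.7, 0.3, 0.3) * 1e-3), gt),
              1)
  expect_error(fit_ss3t_csd(Y, gt, resp, lmax = 7), "even")
  expect_error(fit_ss3t_csd(Y, gt, resp, lmax = 8), "lower lmax")
  expect_warning(f <- fit_ss3t_csd(Y, gt, resp), "lowered to 6")
  expect_equal(ncol(f$coefficients), 28)
})

test_that("AFD equals the spherical surface integral of the FOD", {
  # analytic identities
  z <- rep(0, sh_ncoef(8))
  expect_equal(afd_from_sh(z), 0)
  u <- z; u[1] <- 1 / (2 * sqrt(pi))     # uniform density, unit integral
  expect_equal(afd_from_sh(u), 1, tolerance = 1e-12)

  # quadrature oracle on random coefficient vectors
  q <- sphere_quadrature(24)
  B <- sh_basis(q$dirs, 8)
  set.seed(11)
  for (i in 1:20) {
    cf <- rnorm(sh_ncoef(8))
    integral <- sum(drop(B %*% cf) * q$weights)
    expect_equal(afd_from_sh(cf), integral, tolerance = 1e-6)
  }
  # linearity
  cf <- rnorm(sh_ncoef(8))
  expect_equal(afd_from_sh(3 * cf), 3 * afd_from_sh(cf), tolerance = 1e-12)
})

test_that("raising free water lowers AFD monotonically", {
  gt <- fixture_gtab()
  resp <- fixture_responses(gt)
  sw <- vapply(seq(0, 0.8, 0.1), function(f) {
    s <- simulate_voxel_signal(f, diag(c(1.7, 0.3, 0.3) * 1e-3), gt)
    fod <- suppressWarnings(fit_ss3t_csd(matrix(s, 1), gt, resp))
    afd_from_sh(fod$coefficients[1, ])
  }, numeric(1))
  expect_true(all(diff(sw) < 0))
})

test_that("global normalization fixes the median total tissue signal", {
  gt <- fixture_gtab()
  resp <- fixture_responses(gt)
  set.seed(21)
  Y <- t(replicate(12, {
    f <- runif(1, 0, 0.5)
    2 * simulate_voxel_signal(f, diag(c(1.7, 0.3, 0.3) * 1e-3), gt)
  }))
  fod <- suppressWarnings(fit_ss3t_csd(Y, gt, resp))
  nf <- normalize_fods(fod)
  total <- afd_from_sh(nf$coefficients) + nf$gm + nf$csf
  expect_equal(median(total), 1, tolerance = 1e-9)
  # idempotence
  nf2 <- normalize_fods(nf)
  expect_equal(nf2$coefficients, nf$coefficients, tolerance = 1e-12)

  # scaling the input DWI leaves normalized AFD unchanged
  fod_scaled <- suppressWarnings(fit_ss3t_csd(Y / 2, gt, resp))
  expect_equal(afd_from_sh(normalize_fods(fod_scaled)$coefficients),
               afd_from_sh(nf$coefficients), tolerance = 1e-8)
})

test_that("AFD correlates with ground-truth fiber density in the phantom", {
  cfg <- tiny_phantom_config(snr = Inf)
  co <- simulate_cohort(cfg)
  sub <- co$subjects[[1]]
  tr <- sub$truth
  resp <- estimate_responses(sub$dwi, co$gtab,
                             list(wm = tr$wm_mask, gm = tr$gm_mask,
                                  csf = tr$csf_mask))
  fod <- suppressWarnings(fit_ss3t_csd(sub$dwi, co$gtab, resp,
                                       mask = tr$wm_mask))
  afd <- afd_map(normalize_fods(fod, tr$wm_mask))
  r <- cor(afd[tr$wm_mask], tr$density[tr$wm_mask])
  expect_gte(r, 0.9)
})
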