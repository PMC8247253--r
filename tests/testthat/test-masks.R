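# brute-force erosion oracle: a voxel survives if all 6 face neighbors are
# inside the mask (out-of-grid counts as background)
erode_oracle <- function(mask, n) {
  for (k in seq_len(n)) {
    out <- mask
    d <- dim(mask)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!mask[x, y, z]) next
      nb <- list(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                 c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
      for (p in nb) {
        if (any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3] ||
            !mask[p[1], p[2], p[3]]) {
          out[x, y, z] <- FALSE
          break
        }
      }
    }
    mask <- out
  }
  mask
}

test_that("NAWM construction matches a brute-force morphology oracle", {
  wm <- array(FALSE, c(7, 7, 7))
  wm[2:6, 2:6, 2:6] <- TRUE                      # 5x5x5 solid cube
  empty <- array(FALSE, c(7, 7, 7))
  nawm <- make_nawm(wm, empty, erode_voxels = 2)
  expect_equal(which(nawm), which(erode_oracle(wm, 2)))
  expect_equal(sum(nawm), 1)                     # single center voxel

  # erode 0 is a plain set difference
  wmh <- array(FALSE, c(7, 7, 7)); wmh[3, 3, 3] <- TRUE
  expect_equal(make_nawm(wm, wmh, 0), wm & !wmh)

  # full erosion empties the mask with a warning, not an error
  expect_warning(e <- make_nawm(wm, empty, 3), "empty")
  expect_equal(sum(e), 0)
})

test_that("quartile splitting follows rank order and the tie rule", {
  gs <- c(4, 2, 1)
  wmh <- array(TRUE, gs)
  fw <- array(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8), gs)
  q <- split_fw_quartiles(fw, wmh)
  expect_equal(vapply(q, sum, numeric(1)),
               c(fwq1 = 2, fwq2 = 2, fwq3 = 2, fwq4 = 2))
  expect_true(all(q$fwq1[fw <= 0.2]))            # two smallest in FWq1

  # 100 distinct values: 25 voxels per sub-mask, disjoint, union = wmh
  gs2 <- c(10, 10, 1)
  wmh2 <- array(TRUE, gs2)
  set.seed(5)
  fw2 <- array(sample(seq(0.01, 1, 0.01)), gs2)
  q2 <- split_fw_quartiles(fw2, wmh2)
  expect_equal(unname(vapply(q2, sum, numeric(1))), rep(25, 4))
  expect_equal(q2$fwq1 | q2$fwq2 | q2$fwq3 | q2$fwq4, wmh2)
  expect_equal(sum(q2$fwq1 & q2$fwq2), 0)
  # rank oracle: FWq1 holds exactly the 25 lowest values
  expect_setequal(fw2[q2$fwq1], sort(fw2)[1:25])

  # all values equal: everything in FWq1 by the tie rule
  fw3 <- array(0.5, gs)
  q3 <- split_fw_quartiles(fw3, wmh)
  expect_equal(sum(q3$fwq1), 8)
  expect_equal(sum(q3$fwq2) + sum(q3$fwq3) + sum(q3$fwq4), 0)

  expect_error(split_fw_quartiles(array(1, c(1, 3, 1)),
                                  array(TRUE, c(1, 3, 1))), "4 voxels")
})

test_that("regional means recompose and handle missing data", {
  gs <- c(4, 4, 2)
  wmh <- array(runif(prod(gs)) < 0.8, gs)
  set.seed(8)
  fw <- array(runif(prod(gs)), gs)
  q <- split_fw_quartiles(fw, wmh)
  row <- regional_means(list(fw = fw), c(list(wmh = wmh), q))
  # partition-of-mean identity
  recomposed <- sum(vapply(1:4, function(k) {
    row[[paste0("n_fwq", k)]] * row[[paste0("fw_fwq", k)]]
  }, numeric(1))) / row$n_wmh
  expect_equal(recomposed, row$fw_wmh, tolerance = 1e-12)

  # constants and tiny regions
  m2 <- array(FALSE, gs); m2[1:2, 1, 1] <- TRUE
  v <- array(0, gs); v[1, 1, 1] <- 0.2; v[2, 1, 1] <- 0.4
  r2 <- regional_means(list(v = v), list(roi = m2))
  expect_equal(r2$v_roi, 0.3)
  r3 <- regional_means(list(v = v), list(none = array(FALSE, gs)))
  expect_true(is.na(r3$v_none))
})

test_that("ICV correction is a simple volume fraction", {
  m <- array(FALSE, c(5, 5, 5)); m[1:10] <- TRUE
  expect_equal(corrected_volume(m, c(1, 1, 1), 1000), 0.01)
  expect_equal(corrected_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1), 50), 0)
  expect_equal(corrected_volume(m, c(1, 1, 1), 2000),
               corrected_volume(m, c(1, 1, 1), 1000) / 2)
  expect_error(corrected_volume(m, c(1, 1, 1), 0), "positive")
})

test_that("lesion probability maps count lesion frequency exactly", {
  gs <- c(5, 5, 3)
  # a voxel lesional in 11 of 20 subjects
  masks <- lapply(1:20, function(i) {
    m <- array(FALSE, gs)
    if (i <= 11) m[3, 3, 2] <- TRUE
    m
  })
  lpm <- build_lpm(masks)
  expect_equal(lpm$prob[3, 3, 2], 0.55)
  expect_equal(lpm$peak_probability, 0.55)

  # identical masks: probabilities in {0, 1}
  same <- lapply(1:5, function(i) masks[[1]])
  expect_true(all(build_lpm(same)$prob %in% c(0, 1)))

  # conservation and permutation invariance on random cohorts
  set.seed(13)
  rnd <- lapply(1:12, function(i) array(runif(prod(gs)) < 0.3, gs))
  lpm2 <- build_lpm(rnd)
  expect_equal(sum(lpm2$prob) * 12, sum(vapply(rnd, sum, numeric(1))),
               tolerance = 1e-9)
  lpm3 <- build_lpm(rev(rnd))
  expect_equal(lpm2$prob, lpm3$prob)

  expect_error(build_lpm(list(rnd[[1]], array(FALSE, c(2, 2, 2)))), "grid")
})

test_that("peak cluster size matches a brute-force component scan", {
  gs <- c(6, 6, 1)
  m <- array(FALSE, gs)
  m[1:2, 1:2, 1] <- TRUE                 # 4-voxel cluster
  m[5, 5, 1] <- TRUE                     # isolated voxel
  lpm <- build_lpm(list(m))
  expect_equal(lpm$peak_probability, 1)
  expect_equal(lpm$peak_cluster_size, 4) # largest 26-connected plateau

  # diagonal contact counts as connected (26-connectivity)
  m2 <- array(FALSE, gs)
  m2[1, 1, 1] <- TRUE; m2[2, 2, 1] <- TRUE
  expect_equal(build_lpm(list(m2))$peak_cluster_size, 2)
})

test_that("mask-set invariants hold on random inputs", {
  set.seed(17)
  for (i in 1:25) {
    mp <- random_mask_pair()
    nawm <- suppressWarnings(make_nawm(mp$wm, mp$wmh))
    expect_equal(sum(nawm & mp$wmh), 0)
    expect_true(all(mp$wm[nawm]))
    if (sum(mp$wmh) >= 4) {
      fw <- array(runif(length(mp$wm)), dim(mp$wm))
      q <- split_fw_quartiles(fw, mp$wmh)
      u <- q$fwq1 | q$fwq2 | q$fwq3 | q$fwq4
      expect_equal(u, mp$wmh)
      expect_equal(sum(q$fwq1 & q$fwq2) + sum(q$fwq2 & q$fwq3) +
                     sum(q$fwq3 & q$fwq4) + sum(q$fwq1 & q$fwq3) +
                     sum(q$fwq1 & q$fwq4) + sum(q$fwq2 & q$fwq4), 0)
      # distinct values: sizes differ by at most 3
      sizes <- vapply(q, sum, numeric(1))
      expect_lte(diff(range(sizes)), 3)
    }
  }
})
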