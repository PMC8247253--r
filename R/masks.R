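# Mask algebra for lesion analysis: NAWM construction, free-water quartile
# subregions, regional summaries, ICV-corrected volumes and lesion
# probability maps.

#' Erode a binary mask
#'
#' Iterative morphological erosion with the 6-connected (face-neighbor)
#' structuring element; voxels on the grid boundary are treated as adjacent
#' to background.
#'
#' @param mask Logical 3-D array.
#' @param n Number of erosion passes.
#' @return Logical array.
#' @export
erode_mask <- function(mask, n = 1) {
  mask <- as_mask(mask)
  for (k in seq_len(n)) {
    m <- array(as.numeric(mask), dim(mask))
    keep <- mask
    for (d in 1:3) for (s in c(-1L, 1L)) {
      keep <- keep & (shift_array(m, d, s) > 0)
    }
    mask <- keep
  }
  mask
}

#' Build the normal-appearing white matter mask
#'
#' NAWM is the white-matter mask minus the lesion mask, eroded
#' `erode_voxels` times in three dimensions to keep partial-volume
#' contaminated voxels out. Lesion voxels outside the WM mask are logged
#' and intersected away.
#'
#' @param wm,wmh Logical arrays on the same grid.
#' @param erode_voxels Number of 6-connected erosion passes (default 2).
#' @return Logical NAWM mask (possibly empty, with a warning).
#' @export
make_nawm <- function(wm, wmh, erode_voxels = 2) {
  wm <- as_mask(wm); wmh <- as_mask(wmh)
  check_same_grid(wm, wmh, what = "wm and wmh masks")
  stray <- sum(wmh & !wm)
  if (stray > 0) {
    message(stray, " lesion voxel(s) outside the WM mask were ignored")
  }
  nawm <- wm & !(wmh & wm)
  nawm <- erode_mask(nawm, erode_voxels)
  if (!any(nawm)) warning("NAWM mask is empty after erosion")
  nawm
}

#' Split a lesion mask into free-water quartile subregions
#'
#' Thresholds at the 25th/50th/75th percentiles of the free-water map over
#' lesion voxels. A voxel joins FWq_k when its value lies in
#' \eqn{(q_{k-1}, q_k]} (lowest interval closed below), so values tied with
#' a boundary fall into the lower quartile; with all values equal, every
#' voxel lands in FWq1.
#'
#' @param fw Scalar free-water map.
#' @param wmh Logical lesion mask with at least 4 voxels.
#' @return Named list of four disjoint logical masks `fwq1` .. `fwq4` whose
#'   union is `wmh`.
#' @export
split_fw_quartiles <- function(fw, wmh) {
  wmh <- as_mask(wmh)
  check_same_grid(fw, wmh, what = "fw map and wmh mask")
  vals <- fw[wmh]
  if (length(vals) < 4) {
    stop("lesion mask has fewer than 4 voxels; quartile split undefined",
         call. = FALSE)
  }
  q <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  k <- 1L + (vals > q[1]) + (vals > q[2]) + (vals > q[3])
  idx <- which(wmh)
  out <- lapply(1:4, function(j) {
    m <- array(FALSE, dim(wmh))
    m[idx[k == j]] <- TRUE
    m
  })
  names(out) <- paste0("fwq", 1:4)
  out
}

#' Mean of metric maps over named regions
#'
#' @param metric_maps Named list of scalar maps on the subject grid.
#' @param masks Named list of logical region masks.
#' @return One-row tibble with a `<metric>_<region>` column per
#'   combination plus `n_<region>` voxel counts; empty regions give `NA`.
#'   Voxels carrying `NA` in a map are excluded from its mean.
#' @export
regional_means <- function(metric_maps, masks) {
  stopifnot(length(names(metric_maps)) == length(metric_maps),
            length(names(masks)) == length(masks))
  do.call(check_same_grid, c(unname(metric_maps), unname(masks)))
  row <- list()
  for (rg in names(masks)) {
    m <- as_mask(masks[[rg]])
    row[[paste0("n_", rg)]] <- sum(m)
    for (met in names(metric_maps)) {
      v <- metric_maps[[met]][m]
      v <- v[!is.na(v)]
      row[[paste0(met, "_", rg)]] <- if (length(v)) mean(v) else NA_real_
    }
  }
  tibble::as_tibble(row)
}

#' ICV-corrected mask volume
#'
#' @param mask Logical array.
#' @param voxel_size Voxel dimensions, mm.
#' @param icv Intracranial volume, mm^3 (> 0).
#' @return Dimensionless volume fraction `count * voxel_volume / icv`.
#' @export
corrected_volume <- function(mask, voxel_size = c(1, 1, 1), icv) {
  if (icv <= 0) stop("icv must be positive", call. = FALSE)
  sum(as_mask(mask)) * prod(voxel_size) / icv
}

# 26-connected component labelling by flood fill (used on the few voxels of
# an LPM peak plateau, so a plain BFS is ample).
label_components_26 <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  idx <- which(mask)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  for (v in idx) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      co <- arrayInd(p, dims)
      cand <- sweep(nb, 2, as.integer(co), "+")
      keep <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
        cand[, 2] >= 1 & cand[, 2] <= dims[2] &
        cand[, 3] >= 1 & cand[, 3] <= dims[3]
      cand <- cand[keep, , drop = FALSE]
      lin <- cand[, 1] + dims[1] * (cand[, 2] - 1L) +
        dims[1] * dims[2] * (cand[, 3] - 1L)
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

#' Build a lesion probability map
#'
#' Voxelwise mean of binary lesion masks across subjects: the value at a
#' voxel is the fraction of subjects in whom that voxel is lesional. The
#' peak statistic reports the maximum probability and the volume of the
#' largest 26-connected component of voxels within `tol` of the peak.
#'
#' @param masks List of logical arrays on a common grid (one per subject).
#' @param voxel_size Voxel dimensions, mm.
#' @param tol Tolerance defining the peak plateau.
#' @return Object of class `lesion_probability_map`: `prob` map,
#'   `n_subjects`, `peak_probability`, `peak_cluster_size` (mm^3).
#' @export
build_lpm <- function(masks, voxel_size = c(1, 1, 1), tol = 1e-9) {
  stopifnot(length(masks) >= 1)
  masks <- lapply(masks, as_mask)
  do.call(check_same_grid, c(unname(masks), list(what = "lesion masks")))
  n <- length(masks)
  prob <- Reduce(`+`, lapply(masks, function(m) array(as.numeric(m), dim(m)))) / n
  peak <- max(prob)
  cluster_mm3 <- 0
  if (peak > 0) {
    plateau <- prob >= peak - tol
    lab <- label_components_26(plateau)
    cluster_mm3 <- max(tabulate(lab[lab > 0])) * prod(voxel_size)
  }
  structure(list(prob = prob, n_subjects = n, peak_probability = peak,
                 peak_cluster_size = cluster_mm3, voxel_size = voxel_size),
            class = "lesion_probability_map")
}

#' @export
print.lesion_probability_map <- function(x, ...) {
  cat("<lesion_probability_map> ", x$n_subjects, " subjects; peak ",
      sprintf("%.3f", x$peak_probability), " (cluster ",
      x$peak_cluster_size, " mm^3)\n", sep = "")
  invisible(x)
}
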