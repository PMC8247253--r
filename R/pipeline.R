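# End-to-end orchestration: phantom -> voxel models -> masks/ROIs -> lesion
# probability maps -> cohort statistics, with per-stage status and timing.

default_analysis_options <- function() {
  list(
    # MDt is an exact linear combination of ADt and RDt, so the
    # multivariate statistic uses a nonsingular subset; ADt remains in the
    # paired tests and correlations
    manova_metrics = c("afd", "fat", "mdt", "rdt"),
    correlation_pairs = list(c("fw_wmh", "afd_wmh"), c("fw_wmh", "mdt_wmh"),
                             c("afd_wmh", "fat_wmh"), c("afd_wmh", "adt_wmh"),
                             c("afd_wmh", "rdt_wmh")),
    correlation_covariates = c("age", "gender", "wmh_vol_corr"),
    cie_candidates = c("age", "gender", "hypertension", "wmh_vol_corr",
                       "afd_wmh"),
    cie_threshold = 0.10,
    alpha = 0.05,
    erode_voxels = 2)
}

#' Run the full lesion free-water pipeline
#'
#' Simulates (or ingests) a cohort, fits the single-tensor and bi-tensor
#' models and the 3-tissue CSD per subject, builds NAWM and free-water
#' quartile masks, extracts the per-subject regional table, accumulates
#' lesion probability maps per quartile, and runs the cohort statistics
#' (paired WMH-vs-NAWM tests, MANOVA over the quartile subregions,
#' correlations, change-in-estimate logistic regressions for lacunes and
#' microbleeds). Fully deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param cohort Optional pre-built [simulate_cohort()] result (the
#'   simulation stage is then skipped).
#' @param outdir Optional directory; cohort tables and reports are written
#'   there as TSV/JSON.
#' @param analysis Named list overriding entries of the default analysis
#'   options (metric set, correlation pairs and covariates, candidate order
#'   and threshold of the change-in-estimate step, alpha, NAWM erosion).
#' @param smooth_weight Free-water spatial smoothing weight.
#' @param verbose Print stage progress.
#' @return Object of class `fw_pipeline_report`: `stages` (status/timing
#'   tibble), `cohort_table`, `responses`, `lpm` (per quartile),
#'   `stats`, `qualitative` recovery summary, and the `config`.
#' @export
run_pipeline <- function(config = phantom_config(), cohort = NULL,
                         outdir = NULL, analysis = list(),
                         smooth_weight = 0.3, verbose = FALSE) {
  opts <- utils::modifyList(default_analysis_options(), analysis)
  stages <- list()
  note <- function(stage, status, secs, msg = "") {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      stage = stage, status = status, seconds = round(secs, 2),
      message = msg)
    if (verbose) message(sprintf("[%s] %s (%.1fs) %s", stage, status,
                                 secs, msg))
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    note(stage, "ok", proc.time()[["elapsed"]] - t0)
    res
  }

  if (is.null(cohort)) {
    cohort <- timed("simulate", simulate_cohort(config))
  } else {
    config <- cohort$config
    note("simulate", "skipped", 0, "cohort supplied")
  }
  gtab <- cohort$gtab
  n_sub <- length(cohort$subjects)
  vs <- config$voxel_size

  fits <- timed("fit_models", {
    lapply(seq_len(n_sub), function(s) {
      sub <- cohort$subjects[[s]]
      tr <- sub$truth
      # voxel models are fitted inside the WM mask - the region every
      # downstream analysis reads from
      dti <- fit_dti(sub$dwi, gtab, tr$wm_mask)
      fw <- fit_freewater(sub$dwi, gtab, tr$wm_mask, d_iso = config$d_iso,
                          smooth_weight = smooth_weight)
      resp <- estimate_responses(sub$dwi, gtab,
                                 list(wm = tr$wm_mask, gm = tr$gm_mask,
                                      csf = tr$csf_mask))
      list(dti = dti, fw = fw, resp = resp)
    })
  })

  responses <- timed("average_responses",
                     average_responses(lapply(fits, `[[`, "resp")))

  afd_maps <- timed("csd_afd", {
    lapply(seq_len(n_sub), function(s) {
      fod <- suppressWarnings(
        fit_ss3t_csd(cohort$subjects[[s]]$dwi, gtab, responses,
                     mask = cohort$subjects[[s]]$truth$wm_mask))
      fod <- normalize_fods(fod, cohort$subjects[[s]]$truth$wm_mask)
      afd_map(fod)
    })
  })

  masks_tbl <- timed("masks_regions", {
    rows <- lapply(seq_len(n_sub), function(s) {
      tr <- cohort$subjects[[s]]$truth
      f <- fits[[s]]
      nawm <- make_nawm(tr$wm_mask, tr$wmh_mask, opts$erode_voxels)
      fwq <- split_fw_quartiles(f$fw$fw, tr$wmh_mask)
      regions <- c(list(wmh = tr$wmh_mask, nawm = nawm), fwq)
      maps <- list(fw = f$fw$fw, fat = f$fw$fat, mdt = f$fw$mdt,
                   adt = f$fw$adt, rdt = f$fw$rdt,
                   fa = f$dti$fa, md = f$dti$md, ad = f$dti$ad,
                   rd = f$dti$rd, afd = afd_maps[[s]])
      row <- regional_means(maps, regions)
      icv <- cohort$covariates$icv[s]
      row$wmh_vol_corr <- corrected_volume(tr$wmh_mask, vs, icv)
      for (q in names(fwq)) {
        row[[paste0(q, "_vol_corr")]] <- corrected_volume(fwq[[q]], vs, icv)
      }
      row$subject <- cohort$covariates$subject[s]
      list(row = row, fwq = fwq)
    })
    rows
  })
  cohort_table <- dplyr::left_join(
    dplyr::bind_rows(lapply(masks_tbl, `[[`, "row")),
    cohort$covariates, by = "subject") |>
    dplyr::relocate("subject")
  cohort_table$fw_wmh_pct <- 100 * cohort_table$fw_wmh

  lpm <- timed("lesion_probability_maps", {
    qs <- paste0("fwq", 1:4)
    setNames(lapply(qs, function(q) {
      build_lpm(lapply(masks_tbl, function(m) m$fwq[[q]]), vs)
    }), qs)
  })

  stats <- list()
  qualitative <- NULL
  if (n_sub < 2) {
    note("statistics", "skipped", 0, "insufficient subjects")
  } else {
    stats <- timed("statistics", {
      out <- list()
      metrics <- c("fw", "afd", "fat", "mdt", "adt", "rdt",
                   "fa", "md", "ad", "rd")
      out$paired <- dplyr::bind_rows(lapply(metrics, function(m) {
        dplyr::bind_cols(tibble::tibble(metric = m),
                         paired_t(cohort_table[[paste0(m, "_wmh")]],
                                  cohort_table[[paste0(m, "_nawm")]]))
      }))
      long <- tidyr::pivot_longer(
        cohort_table,
        cols = dplyr::matches(paste0("^(", paste(opts$manova_metrics,
                                                 collapse = "|"),
                                     ")_fwq[1-4]$")),
        names_to = c("metric", "subregion"), names_sep = "_",
        values_to = "value") |>
        tidyr::pivot_wider(id_cols = c("subject", "subregion"),
                           names_from = "metric", values_from = "value")
      out$manova <- oneway_manova(long, group = "subregion",
                                  metrics = opts$manova_metrics)
      out$correlations <- if (n_sub < 4) {
        structure(list(status = "skipped",
                       reason = "fewer than 4 subjects"),
                  class = "cie_skip")
      } else {
        correlation_suite(
          cohort_table, opts$correlation_pairs,
          covariates = opts$correlation_covariates, alpha = opts$alpha)
      }
      for (oc in c("lacune", "microbleed")) {
        out[[paste0("cie_", oc)]] <- if (length(unique(
          cohort_table[[oc]])) < 2) {
          structure(list(status = "skipped",
                         reason = "outcome has a single class"),
                    class = "cie_skip")
        } else {
          # separation is a real possibility in small cohorts; report it
          # as a structured skip rather than failing the run
          tryCatch(
            logistic_cie(cohort_table, outcome = oc,
                         exposure = "fw_wmh_pct",
                         candidates = opts$cie_candidates,
                         threshold = opts$cie_threshold),
            error = function(e) structure(
              list(status = "skipped", reason = conditionMessage(e)),
              class = "cie_skip"))
        }
      }
      out
    })
    # subjects whose NAWM erodes away on coarse grids contribute NA rows
    d_fw <- na.omit(cohort_table$fw_wmh - cohort_table$fw_nawm)
    qualitative <- tibble::tibble(
      check = c("fw_wmh_gt_nawm", "afd_fwq1_gt_fwq4", "mdt_fwq4_gt_fwq1",
                "fw_afd_wmh_correlation"),
      value = c(mean(d_fw),
                mean(cohort_table$afd_fwq1 > cohort_table$afd_fwq4),
                mean(cohort_table$mdt_fwq4 > cohort_table$mdt_fwq1),
                cor(cohort_table$fw_wmh, cohort_table$afd_wmh)),
      detail = c(
        sprintf("sign test p = %.3g",
                binom.test(sum(d_fw > 0), length(d_fw))$p.value),
        "fraction of subjects", "fraction of subjects",
        "across-subject Pearson r"))
  }

  report <- structure(list(
    stages = dplyr::bind_rows(stages), cohort_table = cohort_table,
    responses = responses, lpm = lpm, stats = stats,
    qualitative = qualitative, config = config), class = "fw_pipeline_report")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      format(cohort_table, digits = 17),
      file.path(outdir, "cohort_table.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(stages = report$stages,
           qualitative = report$qualitative,
           lpm = lapply(lpm, function(l) list(
             peak_probability = l$peak_probability,
             peak_cluster_size = l$peak_cluster_size))),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' @export
print.fw_pipeline_report <- function(x, ...) {
  cat("<fw_pipeline_report> ", nrow(x$cohort_table), " subjects\n", sep = "")
  print(x$stages)
  if (!is.null(x$qualitative)) {
    cat("qualitative recovery:\n")
    print(x$qualitative)
  }
  invisible(x)
}

#' Validate a written cohort directory
#'
#' Report-only checks of grid consistency across volumes and masks,
#' gradient-table sanity (unit norms, single shell, at least one b0), and
#' covariate completeness. Nothing is an error: every check is returned as
#' a pass/fail row.
#'
#' @param dir Directory produced by [write_cohort()].
#' @return Tibble with columns `check`, `subject`, `status`, `detail`.
#' @export
validate_inputs <- function(dir) {
  rows <- list()
  add <- function(check, subject, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check, subject = subject,
      status = if (ok) "pass" else "fail", detail = detail)
  }
  cov_path <- file.path(dir, "covariates.tsv")
  if (!file.exists(cov_path)) {
    add("covariates_present", "-", FALSE, "covariates.tsv missing")
    return(dplyr::bind_rows(rows))
  }
  cov <- utils::read.delim(cov_path)
  need <- c("subject", "age", "gender", "hypertension", "icv", "lacune",
            "microbleed")
  miss <- setdiff(need, names(cov))
  add("covariates_columns", "-", length(miss) == 0,
      if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
      else "")
  if (!length(miss)) {
    add("covariates_complete", "-",
        !anyNA(cov[need]), "NA values present if failing")
  }
  for (s in cov$subject) {
    sd <- file.path(dir, s)
    dwi_p <- file.path(sd, "dwi.nii.gz")
    if (!file.exists(dwi_p)) {
      add("dwi_present", s, FALSE, "dwi.nii.gz missing")
      next
    }
    dwi <- read_volume(dwi_p)
    gd <- dim(dwi)[1:3]
    for (m in c("wm_mask", "wmh_mask")) {
      mp <- file.path(sd, paste0(m, ".nii.gz"))
      if (!file.exists(mp)) {
        add("mask_present", s, FALSE, paste(m, "missing"))
        next
      }
      md <- dim(read_volume(mp))[1:3]
      add("grid_consistent", s, identical(md, gd),
          paste0(m, ": ", paste(md, collapse = "x"), " vs dwi ",
                 paste(gd, collapse = "x")))
    }
    gt <- tryCatch(read_bval_bvec(file.path(sd, "dwi")),
                   error = function(e) NULL)
    if (is.null(gt)) {
      # re-read leniently to report which rows are off
      bvals <- scan(file.path(sd, "dwi.bval"), quiet = TRUE)
      bv <- t(matrix(scan(file.path(sd, "dwi.bvec"), quiet = TRUE),
                     nrow = 3, byrow = TRUE))
      bad <- which(bvals > 0 & abs(sqrt(rowSums(bv^2)) - 1) > 1e-3)
      add("bvec_norms", s, length(bad) == 0,
          paste("rows off unit norm:", paste(bad, collapse = ", ")))
    } else {
      add("bvec_norms", s, TRUE, "")
      add("gradient_matches_dwi", s, length(gt$bvals) == dim(dwi)[4],
          sprintf("%d entries vs %d volumes", length(gt$bvals),
                  dim(dwi)[4]))
      add("single_shell", s,
          length(unique(round(gt$bvals[gt$bvals > 0]))) == 1, "")
    }
  }
  dplyr::bind_rows(rows)
}

#' Read a pipeline run configuration from YAML
#'
#' The file may contain any [phantom_config()] field; missing fields take
#' the defaults. A `seed` entry is mandatory.
#'
#' @param path YAML file.
#' @return A `phantom_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must name a seed", call. = FALSE)
  if (!is.null(y$outcome_logodds)) {
    y$outcome_logodds <- lapply(y$outcome_logodds, unlist)
  }
  known <- names(formals(phantom_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(phantom_config, y)
}
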