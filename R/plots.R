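# ggplot2 views of the main result types.

#' Plot an axial slice of a lesion probability map
#'
#' @param object A [build_lpm()] result.
#' @param slice Axial (z) slice index; defaults to the slice containing the
#'   peak probability.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lesion_probability_map <- function(object, slice = NULL, ...) {
  if (is.null(slice)) {
    pk <- arrayInd(which.max(object$prob), dim(object$prob))
    slice <- pk[3]
  }
  df <- expand.grid(x = seq_len(dim(object$prob)[1]),
                    y = seq_len(dim(object$prob)[2]))
  df$p <- as.vector(object$prob[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P(lesion)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Lesion probability, slice z = %d", slice),
                  subtitle = sprintf("peak %.2f, cluster %g mm^3",
                                     object$peak_probability,
                                     object$peak_cluster_size)) +
    ggplot2::theme_minimal()
}

#' Plot per-subregion metric distributions from a cohort table
#'
#' Boxplots of a per-subject regional metric across the free-water
#' quartile subregions (and optionally WMH/NAWM).
#'
#' @param cohort_table Cohort table from [run_pipeline()].
#' @param metric Metric prefix, e.g. `"afd"` or `"mdt"`.
#' @param regions Regions to show.
#' @return A ggplot object.
#' @export
plot_regional_metric <- function(cohort_table, metric = "afd",
                                 regions = paste0("fwq", 1:4)) {
  cols <- paste0(metric, "_", regions)
  stopifnot(all(cols %in% names(cohort_table)))
  long <- tidyr::pivot_longer(cohort_table[c("subject", cols)],
                              cols = dplyr::all_of(cols),
                              names_to = "region", values_to = "value")
  long$region <- factor(sub(paste0("^", metric, "_"), "", long$region),
                        levels = regions)
  ggplot2::ggplot(long, ggplot2::aes(.data$region, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Forest-style view of a change-in-estimate ledger
#'
#' Shows the crude exposure odds ratio, the OR after adding each candidate,
#' and the final adjusted OR with its confidence interval.
#'
#' @param object A [logistic_cie()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cie_report <- function(object, ...) {
  rows <- tibble::tibble(
    label = c("crude", object$ledger$candidate, "final"),
    or = c(object$crude$or, object$ledger$or_with, object$final$or),
    lo = c(object$crude$ci_low, rep(NA, nrow(object$ledger)),
           object$final$ci_low),
    hi = c(object$crude$ci_high, rep(NA, nrow(object$ledger)),
           object$final$ci_high),
    retained = c(TRUE, object$ledger$retained, TRUE))
  rows$label <- factor(rows$label, levels = rev(rows$label))
  ggplot2::ggplot(rows, ggplot2::aes(.data$or, .data$label,
                                     color = .data$retained)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black",
                                           `FALSE` = "grey60"),
                                guide = "none") +
    ggplot2::labs(x = sprintf("OR for %s on %s", object$exposure,
                              object$outcome), y = NULL) +
    ggplot2::theme_minimal()
}
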