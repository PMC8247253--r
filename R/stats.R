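# Cohort statistics: paired comparisons, one-way MANOVA with generalized
# eta squared and Bonferroni post hoc tests, Pearson and partial
# correlations, change-in-estimate logistic regression, and Cohen's kappa.

#' Paired t test
#'
#' Classical paired t on the within-subject differences, two-sided. With
#' all differences zero the statistic is 0 and p = 1; a zero-variance
#' difference with nonzero mean is reported with a degenerate,
#' zero-adjacent p and flagged.
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return One-row tibble: `estimate` (mean difference), `statistic`, `df`,
#'   `p.value`, `n`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(estimate = 0, statistic = 0,
                            df = length(d) - 1, p.value = 1,
                            n = length(d), degenerate = FALSE))
    }
    warning("zero variance of differences with nonzero mean; ",
            "p reported as the smallest representable value")
    return(tibble::tibble(estimate = mean(d),
                          statistic = sign(mean(d)) * Inf,
                          df = length(d) - 1,
                          p.value = .Machine$double.xmin,
                          n = length(d), degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 n = length(d), degenerate = FALSE)
}

#' One-way MANOVA with generalized eta squared and Bonferroni post hoc
#'
#' Multivariate Pillai trace across the metrics, per-metric univariate F
#' with \eqn{\eta^2_g = SS_{between} / (SS_{between} + SS_{within})} (for a
#' one-way between-group design the generalized and classical eta squared
#' coincide), and all pairwise group contrasts per metric by pooled-variance
#' t tests with Bonferroni adjustment (`p_adj = min(1, m * p)` over the `m`
#' pairwise tests of one metric).
#'
#' With `repeated = TRUE` a within-subject (repeated-measures) univariate
#' F is computed instead, using `subject` as the blocking factor; this
#' variant acknowledges that subregions are repeated within subject and is
#' offered as a clearly separate alternative to the between-group analysis.
#'
#' @param data Long-format data frame: one row per subject x group.
#' @param group Name of the grouping column (e.g. the FW quartile).
#' @param metrics Character vector of metric columns.
#' @param repeated Use the repeated-measures variant.
#' @param subject Subject identifier column (repeated variant only).
#' @return Object of class `manova_report` with `multivariate`,
#'   `univariate` and `posthoc` tibbles.
#' @export
oneway_manova <- function(data, group = "subregion", metrics,
                          repeated = FALSE, subject = "subject") {
  g <- factor(data[[group]])
  stopifnot(nlevels(g) >= 2, all(metrics %in% names(data)))
  if (any(table(g) < 2)) stop("each group needs at least 2 observations",
                              call. = FALSE)
  Y <- as.matrix(data[metrics])
  storage.mode(Y) <- "double"

  # within-group residual covariance must be nonsingular for Pillai; the
  # check runs on the residual correlation matrix so that metrics on very
  # different scales (mm^2/s diffusivities vs unitless fractions) are
  # weighted equally
  resid <- Y - apply(Y, 2, function(col) ave(col, g))
  sds <- apply(resid, 2, sd)
  if (any(sds == 0) ||
      min(eigen(cor(resid), symmetric = TRUE,
                only.values = TRUE)$values) < 1e-10) {
    stop("singular within-group covariance; use fewer metrics",
         call. = FALSE)
  }
  if (length(metrics) >= 2) {
    fit <- manova(Y ~ g)
    st <- summary(fit, test = "Pillai")$stats
    multivariate <- tibble::tibble(
      statistic = st["g", "Pillai"], approx_f = st["g", "approx F"],
      df1 = st["g", "num Df"], df2 = st["g", "den Df"],
      p.value = st["g", "Pr(>F)"])
  } else {
    # one response: Pillai's trace reduces to eta squared and the
    # approximate F is the one-way ANOVA F
    a <- anova(lm(Y[, 1] ~ g))
    ssb <- a["g", "Sum Sq"]; ssw <- a["Residuals", "Sum Sq"]
    multivariate <- tibble::tibble(
      statistic = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0,
      approx_f = if (ssb == 0) 0 else a["g", "F value"],
      df1 = a["g", "Df"], df2 = a["Residuals", "Df"],
      p.value = if (ssb == 0) 1 else a["g", "Pr(>F)"])
  }

  uni <- lapply(metrics, function(m) {
    y <- data[[m]]
    if (repeated) {
      subj <- factor(data[[subject]])
      a <- anova(lm(y ~ subj + g))
      ssb <- a["g", "Sum Sq"]; ssw <- a["Residuals", "Sum Sq"]
      tibble::tibble(metric = m, statistic = a["g", "F value"],
                     df1 = a["g", "Df"], df2 = a["Residuals", "Df"],
                     eta2g = ssb / (ssb + ssw),
                     p.value = a["g", "Pr(>F)"])
    } else {
      a <- anova(lm(y ~ g))
      ssb <- a["g", "Sum Sq"]; ssw <- a["Residuals", "Sum Sq"]
      fstat <- if (ssw == 0 && ssb == 0) 0 else a["g", "F value"]
      tibble::tibble(metric = m, statistic = fstat,
                     df1 = a["g", "Df"], df2 = a["Residuals", "Df"],
                     eta2g = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0,
                     p.value = if (ssb == 0) 1 else a["g", "Pr(>F)"])
    }
  })
  univariate <- dplyr::bind_rows(uni)

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m_tests <- length(pairs)
  ph <- list()
  for (m in metrics) {
    for (pr in pairs) {
      yi <- data[[m]][g == pr[1]]
      yj <- data[[m]][g == pr[2]]
      if (sd(c(yi - mean(yi), yj - mean(yj))) == 0) {
        p <- if (mean(yi) == mean(yj)) 1 else 0
        tstat <- if (p == 1) 0 else sign(mean(yi) - mean(yj)) * Inf
      } else {
        tt <- t.test(yi, yj, var.equal = TRUE)
        p <- tt$p.value; tstat <- unname(tt$statistic)
      }
      ph[[length(ph) + 1L]] <- tibble::tibble(
        metric = m, group1 = pr[1], group2 = pr[2],
        estimate = mean(yi) - mean(yj), statistic = tstat,
        p.value = p, p.adjusted = min(1, m_tests * p))
    }
  }
  structure(list(multivariate = multivariate, univariate = univariate,
                 posthoc = dplyr::bind_rows(ph), group = group,
                 metrics = metrics, n_groups = nlevels(g),
                 repeated = repeated),
            class = "manova_report")
}

#' @export
print.manova_report <- function(x, ...) {
  cat("<manova_report> ", x$n_groups, " groups, ",
      length(x$metrics), " metrics",
      if (x$repeated) " (repeated-measures variant)", "\n", sep = "")
  print(x$univariate)
  invisible(x)
}

#' @export
tidy.manova_report <- function(x, ...) x$univariate

#' @export
glance.manova_report <- function(x, ...) x$multivariate

#' Pearson and partial correlations with Bonferroni adjustment
#'
#' Pearson r and p per pair; partial correlation by correlating the
#' least-squares residuals of each variable on the covariates, with the
#' degrees of freedom reduced by the number of covariates. Both families
#' are Bonferroni-adjusted over the tested pairs. With an empty covariate
#' set the partial correlation equals the Pearson correlation exactly.
#'
#' @param data Data frame of per-subject values.
#' @param pairs List of character 2-vectors naming variable pairs.
#' @param covariates Character vector of adjustment columns.
#' @param alpha Family-wise significance level.
#' @return Tibble, one row per pair.
#' @export
correlation_suite <- function(data, pairs, covariates = character(),
                              alpha = 0.05) {
  if (is.character(pairs)) pairs <- list(pairs)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    cols <- c(pr, covariates)
    d <- data[complete.cases(data[cols]), cols, drop = FALSE]
    n <- nrow(d)
    x <- d[[pr[1]]]; y <- d[[pr[2]]]
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant column in pair ", pr[1], " ~ ", pr[2],
              "; correlation undefined")
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], n = n,
                            pearson_r = NA_real_, pearson_p = NA_real_,
                            partial_r = NA_real_, partial_p = NA_real_))
    }
    ct <- stats::cor.test(x, y)
    if (length(covariates)) {
      Z <- as.matrix(d[covariates])
      rx <- residuals(lm(x ~ Z))
      ry <- residuals(lm(y ~ Z))
      rp <- cor(rx, ry)
      dfp <- n - 2 - length(covariates)
      tp <- rp * sqrt(dfp / (1 - rp^2))
      pp <- 2 * pt(-abs(tp), dfp)
    } else {
      rp <- unname(ct$estimate); pp <- ct$p.value
    }
    tibble::tibble(var1 = pr[1], var2 = pr[2], n = n,
                   pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
                   partial_r = rp, partial_p = pp)
  })
  out <- dplyr::bind_rows(rows)
  out$pearson_p_adj <- pmin(1, out$pearson_p * m)
  out$partial_p_adj <- pmin(1, out$partial_p * m)
  out$significant <- !is.na(out$partial_p_adj) & out$partial_p_adj < alpha
  out
}

nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  cox <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  cox / (1 - exp(-fit$null.deviance / n))
}

check_separation <- function(fit, label) {
  p <- fitted(fit)
  if (!fit$converged || any(abs(coef(fit)) > 15) ||
      all(p > 1 - 1e-8 | p < 1e-8)) {
    stop("(quasi-)complete separation or non-convergence in model ", label,
         " (iterations: ", fit$iter, "); inspect the offending variable",
         call. = FALSE)
  }
  invisible(fit)
}

or_ci <- function(fit, exposure, level = 0.95) {
  est <- coef(fit)[exposure]
  se <- sqrt(diag(vcov(fit)))[exposure]
  zq <- qnorm(1 - (1 - level) / 2)
  p <- 2 * pnorm(-abs(est / se))
  tibble::tibble(or = exp(est), ci_low = exp(est - zq * se),
                 ci_high = exp(est + zq * se), p.value = unname(p))
}

#' Logistic regression with change-in-estimate confounder selection
#'
#' Fits the crude model `outcome ~ exposure` by maximum likelihood, then
#' walks the candidate list in the given order: each candidate is added to
#' the working model and the percent change of the exposure odds ratio
#' relative to the working model (or relative to the crude model with
#' `base = "crude"`) is recorded; candidates changing the OR by at least
#' `threshold` are retained, which is the classical evidence-of-confounding
#' rule at a 10% cutoff. The final model is exposure plus the retained set,
#' reported with Wald 95% CI and Nagelkerke pseudo-R^2.
#'
#' @param data Data frame.
#' @param outcome Binary outcome column (both classes must be present).
#' @param exposure Exposure column.
#' @param candidates Candidate confounders, in evaluation order.
#' @param threshold Retention threshold on |change in OR| / OR.
#' @param base `"current"` (sequential, default) or `"crude"`.
#' @return Object of class `cie_report` with `crude`, `ledger`, `retained`
#'   and `final` elements.
#' @export
logistic_cie <- function(data, outcome, exposure, candidates = character(),
                         threshold = 0.10, base = c("current", "crude")) {
  base <- match.arg(base)
  yv <- data[[outcome]]
  if (length(unique(na.omit(yv))) < 2) {
    stop("outcome '", outcome, "' has a single class", call. = FALSE)
  }
  fml <- function(terms) {
    stats::reformulate(terms, response = outcome)
  }
  crude_fit <- glm(fml(exposure), data = data, family = binomial())
  check_separation(crude_fit, "outcome ~ exposure")
  crude <- or_ci(crude_fit, exposure)

  working <- exposure
  or_work <- crude$or
  ledger <- list()
  retained <- character()
  for (cand in candidates) {
    fit_c <- glm(fml(c(working, cand)), data = data, family = binomial())
    check_separation(fit_c, paste("with", cand))
    or_c <- unname(exp(coef(fit_c)[exposure]))
    ref <- if (base == "crude") crude$or else or_work
    change <- (or_c - ref) / ref
    keep <- abs(change) >= threshold
    ledger[[length(ledger) + 1L]] <- tibble::tibble(
      candidate = cand, or_with = or_c, pct_change = 100 * change,
      retained = keep)
    if (keep) {
      retained <- c(retained, cand)
      if (base == "current") {
        working <- c(working, cand)
        or_work <- or_c
      }
    }
  }
  final_fit <- glm(fml(c(exposure, retained)), data = data,
                   family = binomial())
  check_separation(final_fit, "final model")
  final <- or_ci(final_fit, exposure)
  final$r2_nagelkerke <- nagelkerke_r2(final_fit)
  final$adjusted_for <- paste(retained, collapse = ", ")
  structure(list(crude = crude,
                 ledger = if (length(ledger)) dplyr::bind_rows(ledger)
                 else tibble::tibble(candidate = character(),
                                     or_with = numeric(),
                                     pct_change = numeric(),
                                     retained = logical()),
                 retained = retained, final = final,
                 outcome = outcome, exposure = exposure,
                 threshold = threshold, base = base,
                 final_fit = final_fit),
            class = "cie_report")
}

#' @export
print.cie_report <- function(x, ...) {
  cat("<cie_report> ", x$outcome, " ~ ", x$exposure,
      " (change-in-estimate, ", 100 * x$threshold, "% cutoff)\n", sep = "")
  cat(sprintf("  crude OR %.3f (%.3f-%.3f), p = %.3g\n",
              x$crude$or, x$crude$ci_low, x$crude$ci_high, x$crude$p.value))
  if (nrow(x$ledger)) print(x$ledger)
  cat(sprintf("  final OR %.3f (%.3f-%.3f), p = %.3g, R2 = %.2f%s\n",
              x$final$or, x$final$ci_low, x$final$ci_high,
              x$final$p.value, x$final$r2_nagelkerke,
              if (length(x$retained)) paste0(" [", x$final$adjusted_for, "]")
              else ""))
  invisible(x)
}

#' @export
tidy.cie_report <- function(x, ...) x$ledger

#' @export
glance.cie_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(outcome = x$outcome,
                                  exposure = x$exposure), x$final)
}

#' Cohen's kappa for two binary raters
#'
#' Agreement beyond chance from the 2x2 table,
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, with a large-sample standard
#' error and normal-approximation confidence interval.
#'
#' @param rater1,rater2 Equal-length binary vectors.
#' @param level Confidence level.
#' @return One-row tibble: `kappa`, `se`, `conf_low`, `conf_high`, `n`.
#'   With both raters constant and equal, kappa is undefined (`NA`, with a
#'   warning).
#' @export
cohens_kappa <- function(rater1, rater2, level = 0.95) {
  keep <- complete.cases(rater1, rater2)
  r1 <- factor(rater1[keep], levels = sort(unique(c(rater1, rater2))))
  r2 <- factor(rater2[keep], levels = levels(r1))
  n <- length(r1)
  if (n < 2) stop("need at least 2 ratings", call. = FALSE)
  tab <- table(r1, r2) / n
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12) {
    warning("expected agreement is 1 (both raters constant); ",
            "kappa undefined")
    return(tibble::tibble(kappa = NA_real_, se = NA_real_,
                          conf_low = NA_real_, conf_high = NA_real_, n = n))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  zq <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(kappa = kappa, se = se,
                 conf_low = max(-1, kappa - zq * se),
                 conf_high = min(1, kappa + zq * se), n = n)
}
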