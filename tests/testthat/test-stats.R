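test_that("paired t matches hand arithmetic and its symmetries", {
  x <- c(5.1, 4.8, 6.0, 5.6, 5.3)
  y <- c(4.9, 4.9, 5.5, 5.1, 5.0)
  res <- paired_t(x, y)
  d <- x - y
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p.value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)

  # identity and antisymmetry
  same <- paired_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  sw <- paired_t(y, x)
  expect_equal(sw$statistic, -res$statistic)
  expect_equal(sw$p.value, res$p.value)

  # zero-variance nonzero-mean differences: flagged, p near zero
  expect_warning(dg <- paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_true(dg$degenerate)
  expect_lt(dg$p.value, 1e-300)
})

test_that("MANOVA F and eta2g equal brute-force sums of squares", {
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 4),
    m1 = c(1.1, 1.3, 0.9, 1.0, 2.0, 2.2, 1.9, 2.1, 3.2, 2.8, 3.0, 3.1),
    m2 = c(5, 6, 5.5, 5.2, 5.1, 6.2, 5.4, 5.6, 7.0, 7.2, 6.8, 7.1))
  rep_ <- oneway_manova(d, group = "g", metrics = c("m1", "m2"))
  for (m in c("m1", "m2")) {
    y <- d[[m]]
    gm <- mean(y)
    ssb <- sum(tapply(y, d$g, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(y, d$g, function(v) sum((v - mean(v))^2)))
    f_oracle <- (ssb / 2) / (ssw / 9)
    row <- rep_$univariate[rep_$univariate$metric == m, ]
    expect_equal(row$statistic, f_oracle, tolerance = 1e-10)
    expect_equal(row$eta2g, ssb / (ssb + ssw), tolerance = 1e-10)
  }
  expect_true(all(rep_$univariate$eta2g >= 0 & rep_$univariate$eta2g <= 1))

  # identical groups: F = 0, eta2g = 0
  d0 <- data.frame(g = rep(c("a", "b"), each = 3), m1 = rep(c(1, 2, 3), 2))
  r0 <- oneway_manova(d0, group = "g", metrics = "m1")
  expect_equal(r0$univariate$statistic, 0)
  expect_equal(r0$univariate$eta2g, 0)

  # Bonferroni multiplication rule on the post hoc family
  expect_equal(rep_$posthoc$p.adjusted,
               pmin(1, rep_$posthoc$p.value * 3), tolerance = 1e-12)
  expect_true(all(rep_$posthoc$p.adjusted >= rep_$posthoc$p.value))

  # singular metric sets are refused
  d$m3 <- d$m1 * 2
  expect_error(oneway_manova(d, group = "g", metrics = c("m1", "m3")),
               "singular")
})

test_that("partial correlation matches the precision-matrix oracle", {
  d <- data.frame(
    x = c(1.2, 2.1, 2.9, 4.3, 5.1, 6.2),
    y = c(2.0, 2.8, 4.1, 4.6, 6.2, 6.8),
    z = c(0.5, 1.1, 1.4, 2.2, 2.4, 3.1))
  out <- correlation_suite(d, list(c("x", "y")), covariates = "z")
  P <- solve(cor(d[c("x", "y", "z")]))
  r_oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(out$partial_r, r_oracle, tolerance = 1e-10)

  # empty covariate set reduces to Pearson
  out0 <- correlation_suite(d, list(c("x", "y")))
  expect_equal(out0$partial_r, out0$pearson_r)
  expect_equal(out0$partial_p, out0$pearson_p)

  # y = x: r = 1 with p at the machine floor
  d2 <- data.frame(x = rnorm(20)); d2$y <- d2$x
  o2 <- correlation_suite(d2, list(c("x", "y")))
  expect_equal(o2$pearson_r, 1, tolerance = 1e-12)
  expect_lt(o2$pearson_p, 1e-15)

  # a covariate orthogonal to both variables changes r negligibly
  set.seed(2)
  n <- 400
  d3 <- data.frame(x = rnorm(n), y = rnorm(n))
  d3$y <- d3$x * 0.5 + d3$y
  z <- rnorm(n)
  z <- residuals(lm(z ~ d3$x + d3$y))      # exactly orthogonal in-sample
  d3$z <- z
  oa <- correlation_suite(d3, list(c("x", "y")))
  ob <- correlation_suite(d3, list(c("x", "y")), covariates = "z")
  expect_lt(abs(oa$pearson_r - ob$partial_r), 1e-10)

  # constant column is flagged
  d4 <- data.frame(x = rep(1, 6), y = rnorm(6))
  expect_warning(o4 <- correlation_suite(d4, list(c("x", "y"))), "constant")
  expect_true(is.na(o4$pearson_r))
})

test_that("Bonferroni adjustment spans the tested pair family", {
  set.seed(4)
  d <- as.data.frame(matrix(rnorm(40), 10))
  names(d) <- c("a", "b", "c", "e")
  out <- correlation_suite(d, list(c("a", "b"), c("a", "c"), c("b", "e")))
  expect_equal(out$pearson_p_adj, pmin(1, out$pearson_p * 3))
  expect_true(all(out$pearson_p_adj >= out$pearson_p))
  expect_true(all(out$pearson_p_adj <= 1))
})

test_that("change-in-estimate selection retains real confounders only", {
  # an in-sample orthogonal candidate changes nothing and is excluded
  set.seed(6)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 * x))
  z <- residuals(lm(rnorm(n) ~ x + y))
  d <- data.frame(outcome = y, x = x, z = z)
  rep_ <- logistic_cie(d, "outcome", "x", candidates = "z")
  expect_false(rep_$ledger$retained[1])
  expect_lt(abs(rep_$ledger$pct_change[1]), 10)
  expect_equal(rep_$final$or, rep_$crude$or, tolerance = 0.02)

  # a built-in confounder shifts the OR by >= 10% and is retained
  dc <- simulate_regional_cohort(400, seed = 9)
  rc <- logistic_cie(dc, "outcome", "fw_wmh",
                     candidates = c("age", "hypertension"))
  expect_true(rc$ledger$retained[rc$ledger$candidate == "hypertension"])
  expect_false(rc$ledger$retained[rc$ledger$candidate == "age"])
  expect_gte(abs(rc$ledger$pct_change[rc$ledger$candidate ==
                                        "hypertension"]), 10)

  # the final model agrees with a reference maximum-likelihood fit
  ref <- glm(outcome ~ fw_wmh + hypertension, data = dc, binomial())
  expect_equal(unname(rc$final$or), unname(exp(coef(ref)["fw_wmh"])),
               tolerance = 1e-8)
  # Nagelkerke pseudo-R2 against the closed form
  n2 <- nrow(dc)
  cox <- 1 - exp((ref$deviance - ref$null.deviance) / n2)
  expect_equal(rc$final$r2_nagelkerke, cox / (1 - exp(-ref$null.deviance / n2)),
               tolerance = 1e-10)

  # separation is a named error
  ds <- data.frame(outcome = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 10, 11, 12))
  expect_error(suppressWarnings(logistic_cie(ds, "outcome", "x")),
               "separation")
  expect_error(logistic_cie(data.frame(outcome = c(1, 1, 1), x = 1:3),
                            "outcome", "x"), "single class")
})

test_that("Cohen's kappa matches the 2x2 agreement arithmetic", {
  r1 <- c(1, 1, 0, 0, 1, 0, 1, 0, 1, 1)
  r2 <- c(1, 0, 0, 0, 1, 0, 1, 1, 1, 1)
  res <- cohens_kappa(r1, r2)
  tab <- table(r1, r2) / 10
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  expect_equal(res$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(res$kappa,
                 e1071::classAgreement(table(r1, r2))$kappa,
                 tolerance = 1e-10)
  }

  # perfect agreement
  expect_equal(cohens_kappa(r1, r1)$kappa, 1)
  # chance agreement: matched marginals with p_obs = p_exp
  a <- c(rep(1, 2), rep(0, 2), rep(1, 2), rep(0, 2))
  b <- c(rep(1, 2), rep(1, 2), rep(0, 2), rep(0, 2))
  expect_equal(cohens_kappa(a, b)$kappa, 0, tolerance = 1e-12)
  # undefined when both raters are constant and equal
  expect_warning(k0 <- cohens_kappa(rep(1, 5), rep(1, 5)), "undefined")
  expect_true(is.na(k0$kappa))
})

test_that("null cohorts do not inflate the false-positive rate", {
  # no exposure effect, no confounding: rejections should track alpha
  set.seed(31)
  rejections <- replicate(60, {
    d <- simulate_regional_cohort(60, exposure_logodds = 0,
                                  confounder_logodds = 0,
                                  confounder_shift = 0)
    cs <- correlation_suite(d, list(c("fw_wmh", "age")))
    ci <- logistic_cie(d, "outcome", "fw_wmh")
    c(cs$pearson_p < 0.05, ci$crude$p.value < 0.05)
  })
  expect_lte(mean(rejections), 0.12)
})
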