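# Log-scale models, AICc selection and averaging, quantile and
# distributional tests, diagnostics and robustness refits.

test_that("OLS fits report coefficient arithmetic and reject singular designs", {
  b <- truth_scale_table(seed = 1)
  fit <- fit_lm(b, model_spec("Sex", "sex"))
  co <- fit$coefficients
  expect_equal(unname(co[, 3]), unname(co[, 1] / co[, 2]), tolerance = 1e-12)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-9)
  expect_equal(fit$K, 3)                      # intercept + sex + variance

  # constant response: slope indistinguishable from zero
  b0 <- b; b0$mcp_km2 <- 40
  fit0 <- suppressWarnings(fit_lm(b0, model_spec("Sex", "sex")))  # perfect fit
  expect_equal(unname(fit0$coefficients["sexM", 1]), 0, tolerance = 1e-12)

  # duplicated covariate -> aliased
  b$log_mass2 <- b$log_mass
  expect_error(
    fit_lm(b, structure(list(name = "dup", terms = c("log_mass", "log_mass2"),
                             base = "e"), class = "model_spec")),
    "aliased")
})

test_that("the sex-effect CI covers the generating value at its nominal rate", {
  hits <- 0
  for (s in 1:100) {
    b <- truth_scale_table(seed = 1000 + s)
    co <- fit_lm(b, model_spec("Sex", "sex"))$coefficients
    lo <- co["sexM", 1] - qt(0.975, 67) * co["sexM", 2]
    hi <- co["sexM", 1] + qt(0.975, 67) * co["sexM", 2]
    if (lo <= 0.65 && 0.65 <= hi) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("AICc selection: weights normalise, the best model has delta 0, duplicates split evenly", {
  b <- truth_scale_table(seed = 2)
  tab <- aicc_table(b, candidate_models())
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(tab$delta_AICc[1], 0)
  expect_equal(tab$weight[1], max(tab$weight))
  expect_equal(tab$evidence_ratio[1], 1)
  expect_true(all(tab$evidence_ratio >= 1))

  twin <- aicc_table(b, list(model_spec("A", "sex"), model_spec("B", "sex")))
  expect_equal(twin$weight, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(twin$delta_AICc, c(0, 0), tolerance = 1e-12)

  # the small-sample correction vanishes as n grows
  expect_equal(aicc(-100, 3, 1e6) - (-2 * -100 + 2 * 3), 0, tolerance = 1e-4)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("model averaging follows the unconditional-variance formula", {
  mk_fit <- function(name, est, se) {
    structure(list(name = name,
                   coefficients = matrix(c(est, se, est / se, 0.5), 1,
                                         dimnames = list("sexM", c("Estimate", "Std. Error", "t", "p")))),
              class = "hr_fit")
  }
  sel <- data.frame(model = c("m1", "m2"), weight = c(0.5, 0.5))
  attr(sel, "fits") <- list(mk_fit("m1", 1.0 + 0.3, 0.2), mk_fit("m2", 1.0 - 0.3, 0.2))
  avg <- model_average(sel)
  expect_equal(avg$estimate, 1.0)
  expect_equal(avg$unconditional_se, sqrt(0.2^2 + 0.3^2), tolerance = 1e-12)

  # a term present in one model only: averaged within its subset, weight_sum recorded
  attr(sel, "fits")[[2]]$coefficients <-
    matrix(c(5, 1, 5, 0), 1, dimnames = list("log_mass", c("Estimate", "Std. Error", "t", "p")))
  avg2 <- model_average(sel)
  expect_equal(avg2$estimate[avg2$term == "log_mass"], 5)
  expect_equal(avg2$weight_sum[avg2$term == "log_mass"], 0.5)
  expect_false("pc1" %in% avg2$term)
})

test_that("back-transformation turns log-scale contrasts into ratios", {
  expect_equal(backtransform_ratio(0, base = "e")$ratio, 1)
  r <- backtransform_ratio(0.5, 0.1, base = "e")
  expect_equal(r$ratio, exp(0.5))
  expect_equal(r$ci, exp(0.5 + c(-1.96, 1.96) * 0.1))
  expect_equal(backtransform_ratio(2, base = "10")$ratio, 100)
})

test_that("quantile fits minimise the check loss and equal group-quantile differences", {
  b <- truth_scale_table(seed = 3)
  qf <- quantile_fits(b, taus = c(0.25, 0.5, 0.75), B = 200, seed = 4)
  pinball <- function(u, tau) sum(u * (tau - (u < 0)))
  for (i in seq_len(nrow(qf))) {
    tau <- qf$tau[i]
    for (sx in c("F", "M")) {
      y <- b$log_mcp[b$sex == sx]
      fitted_m <- if (sx == "F") qf$intercept[i] else qf$intercept[i] + qf$beta[i]
      # brute force: no candidate value beats the fitted group quantile
      best <- min(vapply(y, function(m) pinball(y - m, tau), numeric(1)))
      expect_lte(pinball(y - fitted_m, tau), best + 1e-12)
    }
    d <- quantile(b$log_mcp[b$sex == "M"], tau, type = 1) -
         quantile(b$log_mcp[b$sex == "F"], tau, type = 1)
    expect_equal(qf$beta[i], unname(d), tolerance = 1e-9)
    expect_equal(qf$ratio[i], exp(qf$beta[i]), tolerance = 1e-12)
    expect_true(qf$ci_low[i] <= qf$beta[i] && qf$beta[i] <= qf$ci_high[i])
  }
  expect_error(quantile_fits(b, taus = 1.2), "tau")
})

test_that("dispersion test is location-invariant and catches spread differences", {
  set.seed(5)
  x <- rnorm(60)
  d <- dispersion_test(c(x, x + 3), rep(c("F", "M"), each = 60))
  # identical up to location shift; floating-point rank ties keep it near 0
  expect_lt(abs(d$chi2), 0.05)
  expect_gt(d$p, 0.9)
  expect_equal(d$df, 1)

  y <- c(rnorm(200), rnorm(200, sd = 10))
  d2 <- dispersion_test(y, rep(c("a", "b"), each = 200))
  expect_lt(d2$p, 0.001)
  expect_gt(d2$iqr_by_group[["b"]], d2$iqr_by_group[["a"]])
  expect_error(dispersion_test(rnorm(4), c("a", "a", "b", "b")), "3 values")
})

test_that("the energy statistic matches hand computation and its p-value is affine-invariant", {
  set.seed(6)
  x <- rnorm(30)
  e0 <- energy_perm_test(x, x, n_perm = 99, seed = 7)
  expect_equal(e0$E, 0, tolerance = 1e-12)
  expect_gt(e0$p, 0.5)

  # x = (0,0), y = (1,1): between mean 1, within means 0 -> E = 2
  e2 <- energy_perm_test(c(0, 0), c(1, 1), n_perm = 99, seed = 8)
  expect_equal(e2$E, 2)
  expect_gte(e2$p, 1 / 100)

  y <- rnorm(20, 1)
  p1 <- energy_perm_test(x, y, n_perm = 499, seed = 9)$p
  p2 <- energy_perm_test(3 + 2 * x, 3 + 2 * y, n_perm = 499, seed = 9)$p
  expect_identical(p1, p2)
})

test_that("influence diagnostics flag a gross outlier and refits keep the sex sign", {
  b <- truth_scale_table(seed = 10)
  b$mcp_km2[5] <- 5000                                # gross outlier in the response
  b$log_mcp <- log(b$mcp_km2)
  fit <- fit_lm(b, model_spec("Sex", "sex"))
  diag <- influence_diagnostics(fit, b)
  expect_equal(names(which.max(fit$cooks_d)), "5")
  expect_true(b$animal_id[5] %in% diag$influential_ids)
  expect_equal(sign(diag$sex_coef[["estimate"]]), sign(diag$sex_coef_refit[["estimate"]]))
  expect_lt(diag$refit_n, fit$n)

  # clean data: few flags at the 4/n convention
  b2 <- truth_scale_table(seed = 11)
  fit2 <- fit_lm(b2, model_spec("Sex", "sex"))
  diag2 <- influence_diagnostics(fit2, b2)
  expect_lt(length(diag2$influential_ids) / fit2$n, 0.15)
})

test_that("robustness refits agree with the log-scale conclusion", {
  # homoscedastic data: HC3 within 15% of classical standard errors
  set.seed(12)
  b <- truth_scale_table(seed = 12, sd_log = 0)
  b$mcp_km2 <- b$mcp_km2 + rnorm(69, 0, 5)   # additive, equal-variance noise
  rr <- robustness_refits(b)
  expect_lt(abs(rr$hc_ols$se_hc3 / rr$hc_ols$se_classical - 1), 0.15)

  # Gamma-log sign matches log-OLS sign across seeds
  agree <- 0
  for (s in 1:25) {
    bs <- truth_scale_table(seed = 100 + s)
    rs <- robustness_refits(bs)
    ols_sign <- sign(fit_lm(bs, model_spec("Sex", "sex"))$coefficients["sexM", 1])
    if (rs$gamma_log$sign == ols_sign && rs$hc_ols$sign == ols_sign) agree <- agree + 1
  }
  expect_gte(agree, 24)

  single <- truth_scale_table(seed = 13)
  single <- single[single$sex == "M", ]
  expect_error(robustness_refits(single), "both sexes")
})

test_that("permutation p-values are invariant to common shifts of the pooled data", {
  b <- truth_scale_table(seed = 14)
  x <- b$log_mcp[b$sex == "F"]
  y <- b$log_mcp[b$sex == "M"]
  p1 <- energy_perm_test(x, y, n_perm = 199, seed = 15)$p
  p2 <- energy_perm_test(x - 10, y - 10, n_perm = 199, seed = 15)$p
  expect_identical(p1, p2)
})
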