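# The statistical layer: log-scale candidate linear models compared with
# AICc, Akaike weights, evidence ratios and model averaging; back-transformed
# sex ratios; quantile regression via exact check-loss minimisation for the
# binary sex design; Fligner-Killeen and permutation energy-distance tests;
# influence diagnostics and robustness refits (HC3, Gamma-log).

#' Candidate model specification
#'
#' Terms vocabulary: `sex`, `log_mass`, `z_body_length`, `z_chest_circ`,
#' `pc1`, `pc2`, `log_n_fixes`, `tracking_days`, `sex:log_mass`. `z_*` terms
#' are standardised on the fitted subset; `sex` is coded F = 0, M = 1
#' (female reference). The response is `log_mcp` in the stated base.
#'
#' @param name model label.
#' @param terms character vector of terms (may be empty for the null model).
#' @param base log base of the response: `"e"` (default) or `"10"`.
#' @export
model_spec <- function(name, terms = character(), base = c("e", "10")) {
  base <- match.arg(base)
  if ("sex:log_mass" %in% terms && !all(c("sex", "log_mass") %in% terms))
    stop("interaction requires both main effects", call. = FALSE)
  structure(list(name = name, terms = terms, base = base), class = "model_spec")
}

#' The default candidate set: Sex, Additive, Interaction, Mass, Null
#' @param base log base for the response.
#' @export
candidate_models <- function(base = "e") {
  list(model_spec("Sex", "sex", base),
       model_spec("Additive", c("sex", "log_mass"), base),
       model_spec("Interaction", c("sex", "log_mass", "sex:log_mass"), base),
       model_spec("Mass", "log_mass", base),
       model_spec("Null", character(), base))
}

term_vars <- function(terms) {
  vars <- setdiff(unique(unlist(strsplit(terms, ":", fixed = TRUE))), character(0))
  sub("^z_", "", vars)
}

build_model_frame <- function(table, spec, subset_ids = NULL) {
  vars <- term_vars(spec$terms)
  resp <- if (spec$base == "e") log(table$mcp_km2) else log10(table$mcp_km2)
  df <- data.frame(log_mcp = resp)
  for (v in vars) {
    col <- table[[v]]
    if (is.null(col)) col <- table[[paste0(v, "_cm")]]   # z_body_length -> body_length_cm
    if (is.null(col)) stop("table lacks required covariate: ", v, call. = FALSE)
    df[[v]] <- col
  }
  df$animal_id <- table$animal_id
  df <- df[stats::complete.cases(df[, setdiff(names(df), "animal_id"), drop = FALSE]), ,
           drop = FALSE]
  if (!is.null(subset_ids)) df <- df[df$animal_id %in% subset_ids, , drop = FALSE]
  if ("sex" %in% names(df)) df$sex <- factor(df$sex, levels = c("F", "M"))
  for (term in spec$terms) {
    if (startsWith(term, "z_")) {
      v <- sub("^z_", "", term)
      df[[term]] <- as.numeric(scale(df[[v]]))
    }
  }
  df
}

model_formula <- function(spec) {
  rhs_terms <- vapply(spec$terms, function(tm) {
    if (tm == "sex:log_mass") return("sex:log_mass")
    if (startsWith(tm, "z_")) return(tm)
    tm
  }, character(1))
  rhs <- if (length(rhs_terms)) paste(rhs_terms, collapse = " + ") else "1"
  stats::as.formula(paste("log_mcp ~", rhs))
}

#' Fit one candidate model by ordinary least squares
#'
#' @param table bear-record table (see [assemble_table()]).
#' @param spec a [model_spec()].
#' @param subset_ids optional animal_id subset (used to fit all candidates on
#'   a common complete-case sample).
#' @return object of class `hr_fit`: coefficient table (estimate, SE, t,
#'   two-sided p), `r_squared`, `adj_r_squared`, `logLik`, `n`, `K`
#'   (parameters incl. intercept and residual variance), residuals, leverage,
#'   Cook's distance, the underlying `lm`, and the response log base.
#' @export
fit_lm <- function(table, spec, subset_ids = NULL) {
  df <- build_model_frame(table, spec, subset_ids)
  p <- length(spec$terms) + 1L
  if (nrow(df) <= p)
    stop("insufficient data: n = ", nrow(df), " for ", p, " coefficients", call. = FALSE)
  fit <- stats::lm(model_formula(spec), data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; aliased terms: ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)
  structure(list(name = spec$name, spec = spec,
                 coefficients = sm$coefficients,
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 logLik = as.numeric(stats::logLik(fit)),
                 n = nrow(df), K = length(stats::coef(fit)) + 1L,
                 residuals = stats::residuals(fit),
                 leverage = stats::hatvalues(fit),
                 cooks_d = stats::cooks.distance(fit),
                 lm = fit, base = spec$base,
                 animal_ids = df$animal_id),
            class = "hr_fit")
}

#' Small-sample Akaike information criterion
#' @param logLik Gaussian log-likelihood.
#' @param K parameter count including intercept and residual variance.
#' @param n sample size.
#' @export
aicc <- function(logLik, K, n) {
  if (n - K - 1 <= 0) stop("AICc undefined: n <= K + 1", call. = FALSE)
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from a vector of AICc differences
#' @param delta ΔAICc values (minimum need not be 0; it is re-centred).
#' @export
akaike_weights <- function(delta) {
  d <- delta - min(delta)
  w <- exp(-d / 2)
  w / sum(w)
}

#' AICc model-selection table over a candidate set
#'
#' All candidates are refit on the intersection of their complete cases so
#' AICc values are comparable.
#'
#' @param table bear-record table.
#' @param specs list of [model_spec()]s.
#' @return data.frame sorted by AICc: `model, K, n_used, AICc, delta_AICc,
#'   weight, evidence_ratio, r_squared`; attribute `fits` holds the `hr_fit`s
#'   (in table order).
#' @export
aicc_table <- function(table, specs) {
  if (length(specs) < 2) stop("aicc_table requires >= 2 candidate models", call. = FALSE)
  common <- Reduce(intersect, lapply(specs, function(s) build_model_frame(table, s)$animal_id))
  fits <- lapply(specs, function(s) fit_lm(table, s, subset_ids = common))
  ic <- vapply(fits, function(f) aicc(f$logLik, f$K, f$n), numeric(1))
  delta <- ic - min(ic)
  w <- akaike_weights(delta)
  out <- data.frame(model = vapply(fits, `[[`, character(1), "name"),
                    K = vapply(fits, `[[`, integer(1), "K"),
                    n_used = vapply(fits, `[[`, integer(1), "n"),
                    AICc = ic, delta_AICc = delta, weight = w,
                    evidence_ratio = max(w) / w,
                    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
                    stringsAsFactors = FALSE)
  ord <- order(out$AICc)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  out
}

#' Model-averaged coefficients with unconditional standard errors
#'
#' Natural averaging: each term is averaged over the models containing it,
#' with weights renormalised within that subset. Unconditional variance is
#' `sum_w * (se^2 + (b - b_bar)^2)` per the standard information-theoretic
#' formula.
#'
#' @param selection an [aicc_table()] result (with its `fits` attribute).
#' @return data.frame: `term, estimate, unconditional_se, ci_low, ci_high,
#'   weight_sum`.
#' @export
model_average <- function(selection) {
  fits <- attr(selection, "fits")
  if (is.null(fits)) stop("selection table lacks its fits attribute", call. = FALSE)
  w <- selection$weight
  terms <- unique(unlist(lapply(fits, function(f) rownames(f$coefficients))))
  rows <- lapply(terms, function(tm) {
    has <- vapply(fits, function(f) tm %in% rownames(f$coefficients), logical(1))
    wi <- w[has] / sum(w[has])
    b <- vapply(fits[has], function(f) f$coefficients[tm, 1], numeric(1))
    se <- vapply(fits[has], function(f) f$coefficients[tm, 2], numeric(1))
    bbar <- sum(wi * b)
    use <- sqrt(sum(wi * (se^2 + (b - bbar)^2)))
    data.frame(term = tm, estimate = bbar, unconditional_se = use,
               ci_low = bbar - 1.96 * use, ci_high = bbar + 1.96 * use,
               weight_sum = sum(w[has]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Back-transform a log-scale coefficient to a ratio with 95% CI
#'
#' @param beta coefficient on the log scale.
#' @param se standard error (optional; `NA` gives no CI).
#' @param base `"e"` or `"10"`.
#' @return list: `ratio`, `ci` (length 2 or `NA`).
#' @export
backtransform_ratio <- function(beta, se = NA_real_, base = c("e", "10")) {
  base <- match.arg(base)
  b <- if (base == "e") exp(1) else 10
  ratio <- b^beta
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else b^(beta + c(-1.96, 1.96) * se)
  list(ratio = ratio, ci = ci)
}

# tau-th sample quantile as a check-loss minimiser (lower endpoint of the
# minimising interval; type-1 quantile)
pinball_quantile <- function(x, tau) stats::quantile(x, tau, type = 1, names = FALSE)

#' Sex-contrast quantile regression of log home-range area
#'
#' Minimises the pinball (check) loss for `log_mcp ~ sex`; with a single
#' binary predictor the exact minimiser is the pair of group tau-quantiles,
#' so `beta(tau)` is the male-female difference of group quantiles.
#' Confidence intervals by case-resampling bootstrap (percentile).
#'
#' @param table bear-record table with `log_mcp` and `sex`.
#' @param taus quantile levels.
#' @param B bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return data.frame: `tau, intercept, beta, ci_low, ci_high, ratio`
#'   (`ratio = exp(beta)`).
#' @export
quantile_fits <- function(table, taus = c(0.25, 0.50, 0.75), B = 2000,
                          seed = 1L, conf = 0.95) {
  if (any(taus <= 0 | taus >= 1)) stop("tau must lie in (0, 1)", call. = FALSE)
  ok <- !is.na(table$log_mcp) & !is.na(table$sex)
  y <- table$log_mcp[ok]
  sex <- table$sex[ok]
  if (length(unique(sex)) < 2) stop("both sexes must be present", call. = FALSE)
  yf <- y[sex == "F"]
  ym <- y[sex == "M"]
  set.seed(seed)
  boot_beta <- matrix(NA_real_, B, length(taus))
  for (b in seq_len(B)) {
    bf <- sample(yf, replace = TRUE)
    bm <- sample(ym, replace = TRUE)
    boot_beta[b, ] <- vapply(taus, function(tau)
      pinball_quantile(bm, tau) - pinball_quantile(bf, tau), numeric(1))
  }
  alpha <- (1 - conf) / 2
  out <- lapply(seq_along(taus), function(i) {
    tau <- taus[i]
    q_f <- pinball_quantile(yf, tau)
    q_m <- pinball_quantile(ym, tau)
    ci <- stats::quantile(boot_beta[, i], c(alpha, 1 - alpha), names = FALSE)
    data.frame(tau = tau, intercept = q_f, beta = q_m - q_f,
               ci_low = ci[1], ci_high = ci[2], ratio = exp(q_m - q_f))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fligner-Killeen dispersion test with descriptive IQRs
#'
#' @param x numeric values (log scale).
#' @param group grouping factor (e.g. sex).
#' @return list: `chi2, df, p, iqr_by_group`.
#' @export
dispersion_test <- function(x, group) {
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 3))
    stop("dispersion_test requires >= 2 groups with >= 3 values each", call. = FALSE)
  ft <- stats::fligner.test(x, group)
  list(chi2 = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value,
       iqr_by_group = tapply(x, group, stats::IQR))
}

# energy statistic from a pooled absolute-distance matrix and index sets;
# within-sample means use the standard 1/n^2 convention (zero diagonal
# included), which makes E vanish when the two samples coincide
energy_stat_from_D <- function(D, ix, iy) {
  between <- mean(D[ix, iy, drop = FALSE])
  within_x <- mean(D[ix, ix])
  within_y <- mean(D[iy, iy])
  2 * between - within_x - within_y
}

#' Permutation energy-distance two-sample test
#'
#' `E = 2 mean|x_i - y_j| - mean|x_i - x_i'| - mean|y_j - y_j'|` with means
#' over all ordered pairs (the standard 1/n^2 within-sample convention, so E
#' is zero when the samples coincide and positive in expectation otherwise);
#' the p-value is `(1 + #{permuted E >= observed}) / (n_perm + 1)` under
#' label permutation of the pooled sample.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @return list: `E, p, n_perm, seed`.
#' @export
energy_perm_test <- function(x, y, n_perm = 10000, seed = 1L) {
  if (length(x) < 2 || length(y) < 2)
    stop("energy_perm_test requires >= 2 values per sample", call. = FALSE)
  z <- c(x, y)
  n <- length(z)
  nx <- length(x)
  D <- abs(outer(z, z, `-`))
  obs <- energy_stat_from_D(D, seq_len(nx), (nx + 1):n)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    ix <- sample.int(n, nx)
    e <- energy_stat_from_D(D, ix, setdiff(seq_len(n), ix))
    if (e >= obs) count <- count + 1L
  }
  list(E = obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm, seed = seed)
}

#' Influence diagnostics and a refit-without-flagged comparison
#'
#' Flags observations with Cook's distance above `cook_threshold`
#' (default 4/n) and refits the model without them, reporting the sign and
#' 95% CI of the sex coefficient before and after.
#'
#' @param fit an `hr_fit` (from [fit_lm()]).
#' @param table the bear-record table the fit came from.
#' @param cook_threshold numeric or `NULL` for 4/n.
#' @return list: `influential_ids`, `cook_threshold`, `max_cooks_d`,
#'   `sex_coef` and `sex_coef_refit` (each `estimate, ci_low, ci_high` or
#'   `NULL` when the model has no sex term), `refit_n`.
#' @export
influence_diagnostics <- function(fit, table, cook_threshold = NULL) {
  n <- fit$n
  if (is.null(cook_threshold)) cook_threshold <- 4 / n
  flagged <- fit$cooks_d > cook_threshold
  ids <- fit$animal_ids[flagged]
  sex_row <- grep("^sexM$", rownames(fit$coefficients))
  get_sex <- function(f) {
    i <- grep("^sexM$", rownames(f$coefficients))
    if (!length(i)) return(NULL)
    est <- f$coefficients[i, 1]
    se <- f$coefficients[i, 2]
    c(estimate = est, ci_low = est - 1.96 * se, ci_high = est + 1.96 * se)
  }
  refit <- NULL
  if (length(ids)) {
    keep <- setdiff(fit$animal_ids, ids)
    refit <- fit_lm(table, fit$spec, subset_ids = keep)
  }
  list(influential_ids = ids, cook_threshold = cook_threshold,
       max_cooks_d = max(fit$cooks_d),
       sex_coef = get_sex(fit),
       sex_coef_refit = if (!is.null(refit)) get_sex(refit) else get_sex(fit),
       refit_n = if (!is.null(refit)) refit$n else fit$n)
}

#' Robustness refits on the raw area scale
#'
#' (i) OLS on untransformed MCP area with HC3 (heteroscedasticity-consistent)
#' standard errors; (ii) Gamma GLM with a log link. Both report the sex
#' coefficient's sign and 95% CI; this is an agreement report, not a
#' hypothesis decision.
#'
#' @param table bear-record table with `mcp_km2 > 0` and `sex`.
#' @return list with `hc_ols` (`estimate, se_classical, se_hc3, ci_low,
#'   ci_high, sign`) and `gamma_log` (`estimate, se, ci_low, ci_high, sign`).
#' @export
robustness_refits <- function(table) {
  df <- table[!is.na(table$mcp_km2) & !is.na(table$sex), , drop = FALSE]
  if (any(df$mcp_km2 <= 0)) stop("mcp_km2 must be positive", call. = FALSE)
  df$sex <- factor(df$sex, levels = c("F", "M"))
  if (nlevels(droplevels(df$sex)) < 2)
    stop("robustness_refits requires both sexes in the table", call. = FALSE)
  ols <- stats::lm(mcp_km2 ~ sex, data = df)
  vc <- sandwich::vcovHC(ols, type = "HC3")
  b <- stats::coef(ols)["sexM"]
  se_hc <- sqrt(vc["sexM", "sexM"])
  gm <- stats::glm(mcp_km2 ~ sex, family = stats::Gamma(link = "log"), data = df)
  gb <- stats::coef(gm)["sexM"]
  gse <- sqrt(stats::vcov(gm)["sexM", "sexM"])
  list(hc_ols = list(estimate = unname(b),
                     se_classical = summary(ols)$coefficients["sexM", 2],
                     se_hc3 = se_hc,
                     ci_low = unname(b - 1.96 * se_hc),
                     ci_high = unname(b + 1.96 * se_hc),
                     sign = sign(unname(b))),
       gamma_log = list(estimate = unname(gb), se = gse,
                        ci_low = unname(gb - 1.96 * gse),
                        ci_high = unname(gb + 1.96 * gse),
                        sign = sign(unname(gb))))
}
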