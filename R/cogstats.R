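#' Longitudinal cognitive decline score
#'
#' Decline is the previous score minus the current score, so that larger
#' values mean more decline. Stroop interference is a completion time, for
#' which a larger raw difference means *less* decline; its difference score
#' is therefore reversed (multiplied by -1).
#'
#' @param previous,current Scores at the earlier and later measurement.
#' @param domain One of `"immediate_recall"`, `"delayed_recall"`,
#'   `"processing_speed"`, `"stroop_interference"`.
#' @return Decline score(s), same length as the inputs.
#' @export
#' @examples
#' decline_score(10, 7, "delayed_recall")        # 3
#' decline_score(40, 55, "stroop_interference")  # 15 (slower = more decline)
decline_score <- function(previous, current, domain) {
  domain <- match.arg(domain, cognitive_domains()$domain)
  if (any(is.na(previous)) || any(is.na(current)))
    stop("missing cognitive score")
  d <- previous - current
  if (domain == "stroop_interference") -d else d
}

#' Sign-preserving cube root
#'
#' `cube_root(x)^3 == x` for any real `x`, including negatives — the
#' transform applied to leakage rates, plasma volumes and Stroop scores to
#' obtain approximately normal distributions.
#'
#' @param x Numeric.
#' @return Signed cube root of `x`.
#' @export
cube_root <- function(x) sign(x) * abs(x)^(1 / 3)

#' Head-size-corrected, log-transformed regional volume
#'
#' `log(volume / ICV)` (natural log): regional volumes are divided by
#' intracranial volume to correct for head size and log-transformed to
#' obtain normal distributions.
#'
#' @param volume Regional volume (> 0), cm^3.
#' @param ICV Intracranial volume (> 0), cm^3.
#' @return Transformed value(s).
#' @export
icv_normalize_log <- function(volume, ICV) {
  if (any(volume <= 0) || any(ICV <= 0))
    stop("volume and ICV must be > 0")
  log(volume / ICV)
}

# numeric coding of covariates: sex male=1/female=0, education ordinal 1:3
covariate_matrix <- function(data, covariates) {
  cols <- lapply(covariates, function(nm) {
    v <- data[[nm]]
    if (is.null(v)) stop("covariate not found in data: ", nm)
    if (nm == "sex" && !is.numeric(v))
      v <- as.numeric(v %in% c("male", "m", "M", "1"))
    as.numeric(v)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- covariates
  m
}

#' Covariate-adjusted regression of decline on leakage
#'
#' Ordinary least squares of an outcome (a cognitive decline score) on a
#' focal predictor (a transformed leakage rate) plus covariates (by default
#' age, sex and education, entered unstandardized; sex coded 0/1, education
#' as an ordinal 1-3 numeric). The standardized beta is the coefficient of
#' the z-scored predictor in the model with z-scored outcome — the
#' conventional standardized regression coefficient for a focal predictor —
#' and the p-value is the two-sided t-test on that coefficient.
#'
#' @param data A data frame (e.g. from [generate_cohort()] after
#'   [prepare_cohort_analysis()]).
#' @param outcome,predictor Column names of the outcome and focal
#'   predictor (numeric).
#' @param covariates Character vector of covariate column names.
#' @return An object of class `regression_result`: `outcome`, `predictor`,
#'   `covariates`, `n`, `standardized_beta`, `unstandardized_beta`,
#'   `se_unstandardized`, `p_value`, `df_residual`.
#' @export
fit_adjusted_regression <- function(data, outcome, predictor,
                                    covariates = c("age", "sex", "education")) {
  y <- as.numeric(data[[outcome]])
  x <- as.numeric(data[[predictor]])
  if (is.null(data[[outcome]]) || is.null(data[[predictor]]))
    stop("outcome or predictor column not found")
  Z <- covariate_matrix(data, covariates)
  ok <- stats::complete.cases(y, x, Z)
  y <- y[ok]; x <- x[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(y)
  p_tot <- 1L + ncol(Z)
  if (n <= p_tot + 1L) stop("too few complete observations for the design")
  X <- cbind(`(Intercept)` = 1, predictor = x, Z)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: predictor collinear with covariates")
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  b <- fit$coefficients["predictor"]
  tval <- b / se[2]
  structure(list(outcome = outcome, predictor = predictor,
                 covariates = covariates, n = n,
                 standardized_beta = unname(b * stats::sd(x) / stats::sd(y)),
                 unstandardized_beta = unname(b),
                 se_unstandardized = unname(se[2]),
                 p_value = unname(2 * stats::pt(abs(tval), df,
                                                lower.tail = FALSE)),
                 df_residual = df),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("%s ~ %s + %s  (n = %d)\n", x$outcome, x$predictor,
              paste(x$covariates, collapse = " + "), x$n))
  cat(sprintf("  standardized beta = %.3f, unstandardized beta = %.4g, p = %.4g\n",
              x$standardized_beta, x$unstandardized_beta, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with ordered p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, find the largest k with \eqn{p_{(k)} \le k q / m} and reject
#' the k tests with the smallest p-values. The main analysis applies it to
#' a family of four tests (one per cognitive domain) at q = 0.05.
#'
#' @param p_values P-values in (0, 1].
#' @param q Target false discovery rate.
#' @return An object of class `fdr_result`: `m`, `q`, `p_values`,
#'   `p_adjusted` (BH-adjusted), `rejected` (logical, in input order).
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  m <- length(p)
  if (m < 1L) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  padj <- numeric(m)
  padj[o] <- pmin(adj, 1)
  structure(list(m = m, q = q, p_values = p, p_adjusted = padj,
                 rejected = rejected),
            class = "fdr_result")
}

#' Power of the partial F-test in multiple linear regression
#'
#' Power to detect an effect of size \eqn{f^2} for `tested_predictors`
#' coefficients in a linear model with `total_predictors` predictors and
#' total sample size `n`: noncentral F with numerator df
#' `tested_predictors`, denominator df `n - total_predictors - 1` and
#' noncentrality \eqn{\lambda = f^2 n}.
#'
#' @param n Total sample size.
#' @param f2 Cohen's effect size f^2 (> 0).
#' @param alpha Significance level.
#' @param total_predictors Total number of predictors in the model.
#' @param tested_predictors Number of predictors being tested.
#' @return Power in (0, 1).
#' @export
power_f_test <- function(n, f2, alpha = 0.05, total_predictors = 4,
                         tested_predictors = 1) {
  df1 <- tested_predictors
  df2 <- n - total_predictors - 1
  if (any(df2 < 1)) stop("n too small for the design")
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = f2 * n, lower.tail = FALSE)
}

#' A priori sample size for multiple regression
#'
#' Smallest total N whose partial-F power reaches the request, found by an
#' exact linear scan of [power_f_test()]. The defaults — medium effect
#' \eqn{f^2 = 0.15}, alpha 0.05, power 0.80, one tested predictor among
#' four — give N = 55.
#'
#' @inheritParams power_f_test
#' @param power Target power in (0, 1).
#' @param n_max Scan ceiling (error if power not reached by then).
#' @return Minimum total sample size (integer).
#' @export
required_sample_size <- function(f2 = 0.15, alpha = 0.05, power = 0.80,
                                 total_predictors = 4, tested_predictors = 1,
                                 n_max = 100000L) {
  if (f2 <= 0) stop("effect size f2 must be > 0 (power unreachable)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  for (n in seq.int(total_predictors + 2L, n_max)) {
    if (power_f_test(n, f2, alpha, total_predictors, tested_predictors) >= power)
      return(n)
  }
  stop("requested power not reached by n_max")
}

#' Cognitive-decline equivalent of a leakage increase
#'
#' Chains two fitted coefficients: a per-year increase of the transformed
#' leakage rate (from a leakage-on-age regression) and the unstandardized
#' decline-per-leakage-unit coefficient (from a decline-on-leakage
#' regression). Over `years` years the expected decline is
#' `unstd_beta * per_year_leakage_coeff * years`. Expressing that decline
#' as years of cognitive ageing needs an external normative ageing slope
#' (score units per year), supplied by the user; it is not derivable from
#' this package.
#'
#' @param unstd_beta Decline score units per transformed-leakage unit.
#' @param per_year_leakage_coeff Transformed-leakage units per year.
#' @param years Time span in years (>= 0).
#' @param normative_slope Optional normative decline per year of ageing.
#' @return List with `leakage_increase`, `decline`, and `ageing_years`
#'   (`NA` unless `normative_slope` is given).
#' @export
#' @examples
#' # 286 score units per unit leakage, 1.2e-4 per year, over 10 years:
#' ageing_equivalent_decline(286, 1.2e-4, 10)$decline  # 0.3432
ageing_equivalent_decline <- function(unstd_beta, per_year_leakage_coeff,
                                      years, normative_slope = NULL) {
  if (years < 0) stop("years must be >= 0")
  inc <- per_year_leakage_coeff * years
  dec <- unstd_beta * inc
  list(leakage_increase = inc, decline = dec,
       ageing_years = if (is.null(normative_slope)) NA_real_
       else dec / normative_slope)
}

#' Add decline scores and transformed predictors to a cohort table
#'
#' Computes the four per-domain decline scores (Stroop reversed), cube-root
#' transforms of the decline and current Stroop scores and of all regional
#' leakage/plasma-volume values, and log ICV-normalized volumes.
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]).
#' @return The cohort with added columns `decline_<domain>`,
#'   `<region>_ki_cbrt`, `<region>_vp_cbrt`, `stroop_decline_cbrt`,
#'   `stroop_curr_cbrt`, `wmh_icv_log`, `hippocampal_volume_icv_log`.
#' @export
prepare_cohort_analysis <- function(cohort) {
  for (d in cognitive_domains()$domain) {
    cohort[[paste0("decline_", d)]] <-
      decline_score(cohort[[paste0(d, "_prev")]],
                    cohort[[paste0(d, "_curr")]], d)
  }
  for (r in c("wm", "gm", "hc")) {
    cohort[[paste0(r, "_ki_cbrt")]] <- cube_root(cohort[[paste0(r, "_ki")]])
    cohort[[paste0(r, "_vp_cbrt")]] <- cube_root(cohort[[paste0(r, "_vp")]])
  }
  cohort$stroop_decline_cbrt <- cube_root(cohort$decline_stroop_interference)
  cohort$stroop_curr_cbrt <- cube_root(cohort$stroop_interference_curr)
  cohort$wmh_icv_log <- icv_normalize_log(cohort$wmh_cm3, cohort$icv_cm3)
  cohort$hippocampal_volume_icv_log <-
    icv_normalize_log(cohort$hippocampal_volume_cm3, cohort$icv_cm3)
  cohort
}

#' Main decline-on-leakage analysis for one region
#'
#' Regresses decline in each of the four cognitive domains on the
#' cube-root-transformed regional leakage rate, adjusted for age, sex and
#' education, and applies Benjamini-Hochberg correction across the four
#' tests. The Stroop domain uses the cube-root-transformed (reversed)
#' decline score as its outcome.
#'
#' @param cohort A prepared cohort (see [prepare_cohort_analysis()]).
#' @param region `"wm"`, `"gm"` or `"hc"`.
#' @param q False discovery rate for the four-test family.
#' @param covariates Covariate column names.
#' @return A `data.frame` with one row per domain: outcome, predictor, n,
#'   standardized and unstandardized beta, p, BH-adjusted p, rejected flag.
#' @export
run_decline_analysis <- function(cohort, region = "wm", q = 0.05,
                                 covariates = c("age", "sex", "education")) {
  region <- match.arg(region, c("wm", "gm", "hc"))
  pred <- paste0(region, "_ki_cbrt")
  if (is.null(cohort[[pred]])) cohort <- prepare_cohort_analysis(cohort)
  fits <- lapply(cognitive_domains()$domain, function(d) {
    outc <- if (d == "stroop_interference") "stroop_decline_cbrt"
    else paste0("decline_", d)
    fit_adjusted_regression(cohort, outc, pred, covariates)
  })
  p <- vapply(fits, `[[`, numeric(1), "p_value")
  fdr <- benjamini_hochberg(p, q = q)
  data.frame(
    outcome = vapply(fits, `[[`, character(1), "outcome"),
    predictor = pred,
    n = vapply(fits, `[[`, numeric(1), "n"),
    std_beta = vapply(fits, `[[`, numeric(1), "standardized_beta"),
    unstd_beta = vapply(fits, `[[`, numeric(1), "unstandardized_beta"),
    p = p, p_adjusted = fdr$p_adjusted, rejected = fdr$rejected,
    stringsAsFactors = FALSE)
}
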