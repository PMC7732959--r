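test_that("decline scores follow the difference-score convention", {
  expect_equal(decline_score(10, 7, "delayed_recall"), 3)
  expect_equal(decline_score(40, 55, "stroop_interference"), 15)
  for (d in cognitive_domains()$domain)
    expect_equal(decline_score(12, 12, d), 0)
  expect_error(decline_score(NA, 7, "delayed_recall"), "missing")
})

test_that("transforms are sign-preserving and exact", {
  expect_equal(cube_root(8), 2)
  expect_equal(cube_root(-0.027), -0.3)
  expect_equal(cube_root(0), 0)
  x <- c(-2.5, -1e-6, 0, 1e-6, 3.7)
  expect_equal(cube_root(x)^3, x)

  expect_equal(icv_normalize_log(1500, 1500), 0)
  expect_equal(icv_normalize_log(1500 / exp(1), 1500), -1)
  expect_equal(icv_normalize_log(30, 1500), log(0.02))
  expect_error(icv_normalize_log(-1, 1500), "> 0")
})

test_that("adjusted regression equals the hand normal-equations solution", {
  df <- data.frame(
    y   = c(2.1, 3.4, 1.9, 5.0, 4.2, 3.3),
    x   = c(0.5, 1.2, 0.3, 2.0, 1.7, 1.1),
    age = c(60, 70, 65, 80, 75, 68),
    sex = c(0, 1, 0, 1, 1, 0),
    education = c(1, 2, 2, 3, 1, 2))
  fit <- fit_adjusted_regression(df, "y", "x")
  X <- cbind(1, df$x, df$age, df$sex, df$education)
  beta_hand <- solve(t(X) %*% X, t(X) %*% df$y)
  expect_equal(fit$unstandardized_beta, beta_hand[2], tolerance = 1e-10)
  expect_equal(fit$standardized_beta,
               beta_hand[2] * sd(df$x) / sd(df$y), tolerance = 1e-10)
  expect_equal(fit$df_residual, 1L)

  df$dup <- df$x
  expect_error(fit_adjusted_regression(df, "y", "x",
                                       c("dup", "age", "sex")),
               "rank-deficient")
})

test_that("standardized/unstandardized relation holds on random fits", {
  set.seed(21)
  for (i in 1:10) {
    n <- 40
    df <- data.frame(y = rnorm(n), x = rnorm(n), age = rnorm(n, 65, 10),
                     sex = rbinom(n, 1, .5), education = sample(1:3, n, TRUE))
    fit <- fit_adjusted_regression(df, "y", "x")
    expect_equal(fit$standardized_beta,
                 fit$unstandardized_beta * sd(df$x) / sd(df$y),
                 tolerance = 1e-8)
    expect_gt(fit$p_value, 0)
    expect_lte(fit$p_value, 1)
  }
})

test_that("regression matches lm() and its t-test p-value", {
  co <- prepare_cohort_analysis(generate_cohort(cohort_spec(seed = 2)))
  fit <- fit_adjusted_regression(co, "decline_delayed_recall", "wm_ki_cbrt")
  ref <- lm(decline_delayed_recall ~ wm_ki_cbrt + age +
              I(sex == "male") + education, data = co)
  sref <- summary(ref)$coefficients
  expect_equal(fit$unstandardized_beta, unname(coef(ref)["wm_ki_cbrt"]),
               tolerance = 1e-10)
  expect_equal(fit$p_value, unname(sref["wm_ki_cbrt", 4]), tolerance = 1e-10)
})

test_that("Benjamini-Hochberg reproduces the step-up rule", {
  # family led by p = .006: only that test survives at q = .05
  r1 <- benjamini_hochberg(c(0.006, 0.30, 0.50, 0.80))
  expect_equal(r1$rejected, c(TRUE, FALSE, FALSE, FALSE))
  # family led by p = .044: nothing survives (0.044 > 0.05/4)
  r2 <- benjamini_hochberg(c(0.044, 0.30, 0.50, 0.80))
  expect_equal(r2$rejected, rep(FALSE, 4))
  expect_equal(benjamini_hochberg(rep(1, 4))$rejected, rep(FALSE, 4))

  # oracle: p.adjust("BH") on random vectors, and the step-up definition
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(3:10, 1))^2
    r <- benjamini_hochberg(p, q = 0.05)
    expect_equal(r$p_adjusted, p.adjust(p, "BH"))
    expect_equal(r$rejected, p.adjust(p, "BH") <= 0.05)
  }
  expect_error(benjamini_hochberg(c(0, 0.5)), "p-values")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "p-values")
})

test_that("noncentral-F power analysis reproduces the planned N = 55", {
  expect_identical(required_sample_size(f2 = 0.15, alpha = 0.05,
                                        power = 0.80, total_predictors = 4,
                                        tested_predictors = 1), 55L)
  expect_lt(power_f_test(54, 0.15), 0.80)
  expect_gte(power_f_test(55, 0.15), 0.80)

  # power monotone in N and f2; required N decreases as f2 doubles
  ns <- seq(20, 200, by = 10)
  expect_true(all(diff(power_f_test(ns, 0.15)) > 0))
  expect_true(all(power_f_test(ns, 0.30) > power_f_test(ns, 0.15)))
  expect_lt(required_sample_size(f2 = 0.30), 55L)

  # large-sample lower bound: chi-square limit of the noncentral F
  lambda_star <- uniroot(function(l)
    pchisq(qchisq(0.95, 1), 1, ncp = l, lower.tail = FALSE) - 0.80,
    c(1, 30))$root
  expect_gte(required_sample_size(f2 = 0.15), ceiling(lambda_star / 0.15))

  expect_error(required_sample_size(f2 = 0), "f2")
})

test_that("ageing-equivalent decline chains the two fitted coefficients", {
  r <- ageing_equivalent_decline(286, 1.2e-4, 10)
  expect_equal(r$leakage_increase, 1.2e-3)
  expect_equal(r$decline, 0.3432)
  expect_true(is.na(r$ageing_years))
  expect_equal(ageing_equivalent_decline(0, 1.2e-4, 10)$decline, 0)
  rn <- ageing_equivalent_decline(286, 1.2e-4, 10, normative_slope = 0.073)
  expect_equal(rn$ageing_years, 0.3432 / 0.073)
  expect_error(ageing_equivalent_decline(286, 1.2e-4, -1), "years")
})

test_that("the four-domain analysis flags delayed recall for WM leakage", {
  co <- prepare_cohort_analysis(
    generate_cohort(cohort_spec(n_subjects = 400, seed = 3)))
  res <- run_decline_analysis(co, region = "wm")
  expect_equal(nrow(res), 4L)
  expect_true(res$rejected[res$outcome == "decline_delayed_recall"])
  expect_equal(sum(res$rejected), 1L)
})
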