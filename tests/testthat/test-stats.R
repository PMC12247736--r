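test_that("noiseless linear data is fit exactly", {
  set.seed(1)
  tab <- simulate_subjects(200, seed = 1)
  beta <- c(2, -1.5, 0.03, 4, 0.5)
  tab$age <- 10 + beta[1] * tab$mean_radius_mm +
    beta[2] * tab$mean_tortuosity + beta[3] * tab$total_volume_mm3 +
    beta[4] * tab$sd_radius_mm + beta[5] * tab$mean_segment_length_mm
  f <- age ~ mean_radius_mm + mean_tortuosity + total_volume_mm3 +
    sd_radius_mm + mean_segment_length_mm
  fit <- fit_linear(tab, f)
  expect_equal(suppressWarnings(summary(fit))$adj.r.squared, 1,
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(10, beta), tolerance = 1e-8)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- simulate_subjects(100, seed = 2)
  tab$age <- 50
  expect_error(fit_linear(tab, age ~ mean_radius_mm), "zero variance")
  tab2 <- simulate_subjects(100, seed = 3)
  tab2$dup <- tab2$mean_radius_mm
  expect_error(fit_linear(tab2, age ~ mean_radius_mm + dup), "dup")
})

test_that("coefficient estimates have near-nominal confidence coverage", {
  # Monte-Carlo: known coefficients with Gaussian noise; 95% CIs should
  # cover each true coefficient in at least 93% of replicates
  n <- 300
  beta <- c(5, 1.2, -0.8)
  cover <- matrix(NA, 500, 2)
  for (r in 1:500) {
    set.seed(r)
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- beta[1] + beta[2] * x1 + beta[3] * x2 + rnorm(n, 0, 2)
    fit <- fit_linear(tibble::tibble(y = y, x1 = x1, x2 = x2),
                      y ~ x1 + x2)
    ci <- confint(fit)
    cover[r, ] <- ci[2:3, 1] <= beta[2:3] & beta[2:3] <= ci[2:3, 2]
  }
  expect_gte(mean(cover[, 1]), 0.93)
  expect_gte(mean(cover[, 2]), 0.93)
})

test_that("nested ANOVA matches a from-scratch SSR oracle", {
  for (r in 1:10) {
    set.seed(r)
    n <- 120
    X <- matrix(rnorm(n * 6), n)
    y <- X[, 1:3] %*% c(1, 0.5, -1) + rnorm(n)
    tab <- tibble::tibble(y = as.vector(y))
    for (j in 1:6) tab[[paste0("x", j)]] <- X[, j]
    red <- fit_linear(tab, y ~ x1 + x2 + x3)
    full <- fit_linear(tab, y ~ x1 + x2 + x3 + x4 + x5 + x6)
    cmp <- nested_anova(red, full)
    # independent oracle: direct SSR computation from residuals
    ssr_r <- sum(residuals(red)^2)
    ssr_f <- sum(residuals(full)^2)
    f_oracle <- ((ssr_r - ssr_f) / 3) / (ssr_f / (n - 7))
    expect_equal(cmp$f_statistic, f_oracle, tolerance = 1e-8)
    expect_equal(cmp$df_num, 3)
    expect_equal(cmp$df_den, n - 7)
    expect_equal(cmp$p_value, pf(f_oracle, 3, n - 7, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("adding an all-zeros column changes nothing: F = 0, p = 1", {
  set.seed(4)
  tab <- tibble::tibble(y = rnorm(50), x = rnorm(50), z = 0)
  red <- fit_linear(tab, y ~ x)
  full <- fit_linear(tab, y ~ x + z, allow_aliased = TRUE)
  cmp <- nested_anova(red, full)
  expect_equal(cmp$f_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$df_num, 0)
})

test_that("non-nested models are refused", {
  tab <- tibble::tibble(y = rnorm(30), a = rnorm(30), b = rnorm(30))
  m1 <- fit_linear(tab, y ~ a)
  m2 <- fit_linear(tab, y ~ b)
  expect_error(nested_anova(m1, m2), "not nested")
})

test_that("the protocol df bookkeeping: 11 added features, n = 655", {
  # 68 cortical regions + intercept + 11 vessel features = rank 80;
  # 655 complete rows give denominator df 575 for the added-features test
  tab <- simulate_subjects(655, seed = 10, n_ct = 68)
  cmp <- compare_models(tab, "age_cortex", "age_cortex_vessels")
  expect_equal(cmp$df_num, 11)
  expect_equal(cmp$df_den, 575)
  expect_gte(cmp$adj_r2_full, cmp$adj_r2_reduced)
})

test_that("the F-test of 11 pure-noise features has nominal type-I error", {
  n <- 150
  reject <- logical(400)
  for (r in seq_along(reject)) {
    set.seed(1000 + r)
    tab <- tibble::tibble(y = rnorm(n), x = rnorm(n))
    for (j in 1:11) tab[[paste0("v", j)]] <- rnorm(n)
    red <- fit_linear(tab, y ~ x)
    full <- fit_linear(tab, stats::as.formula(
      paste("y ~ x +", paste0("v", 1:11, collapse = " + "))))
    reject[r] <- nested_anova(red, full)$p_value < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("cross-validated R2: noiseless, null, deterministic", {
  tab <- simulate_subjects(400, seed = 20)
  tab$age <- 20 + 3 * tab$mean_radius_mm + 0.002 * tab$total_volume_mm3
  cv <- crossval_r2(tab, age ~ mean_radius_mm + total_volume_mm3,
                    k = 10, seed = 1)
  expect_gt(cv$r2, 0.999)

  # response independent of predictors: R2 near or below 0
  worst <- -Inf
  for (s in 1:20) {
    tabn <- simulate_subjects(500, seed = 30 + s, vessel_age_effect = 0)
    tabn$age <- rnorm(500)
    cvn <- crossval_r2(tabn, age ~ mean_radius_mm + mean_tortuosity +
                         total_volume_mm3, k = 10, seed = s)
    worst <- max(worst, cvn$r2)
  }
  expect_lte(worst, 0.05)

  cv2 <- crossval_r2(tab, age ~ mean_radius_mm + total_volume_mm3,
                     k = 10, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$r2, cv2$r2)

  expect_error(crossval_r2(tab[1:8, ], age ~ mean_radius_mm, k = 10),
               "fewer rows")
})

test_that("every subject is predicted exactly once out of fold", {
  tab <- simulate_subjects(203, seed = 40)
  cv <- crossval_r2(tab, "age_vessels", k = 10, seed = 3)
  expect_equal(nrow(cv$predictions), 203)
  expect_equal(sort(unique(cv$folds$fold)), 1:10)
  expect_equal(cv$folds$row, seq_len(203))
})

test_that("hypertension labeling follows the strict-threshold rule", {
  # truth table including the boundary: 'above' is strict
  d <- c(95, 85, 90, 91, 85, 60, NA)
  s <- c(120, 135, 140, 140, 141, 200, 130)
  expect_identical(label_hypertension(d, s),
                   c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, NA))
})

test_that("age split: older is strictly above 60", {
  tab <- tibble::tibble(age = c(59.9, 60, 60.1, 75))
  sp <- split_by_age(tab)
  expect_equal(as.character(sp$age_group),
               c("younger", "younger", "older", "older"))
})

test_that("logistic fits flag degenerate outcomes and detect signal", {
  tab <- simulate_subjects(300, seed = 50)
  tab$hypertension <- FALSE
  expect_error(fit_logistic(tab, "htn_vessels"), "single-class")

  # perfectly separable outcome is flagged, not fatal
  sep_tab <- tibble::tibble(y = rep(c(TRUE, FALSE), each = 30),
                            x = c(rnorm(30, 5), rnorm(30, -5)))
  expect_warning(fit_sep <- fit_logistic(sep_tab, y ~ x), "separation")
  expect_true(attr(fit_sep, "separation"))

  # power: hypertension driven by one vessel feature; the vessel-augmented
  # model beats cortex-only by LRT in nearly all replicates
  hits <- logical(40)
  for (r in seq_along(hits)) {
    tb <- simulate_subjects(300, seed = 60 + r)
    lp <- -1 + 3 * scale(tb$mean_radius_mm)[, 1]
    set.seed(60 + r)
    tb$hypertension <- runif(300) < stats::plogis(lp)
    # strong effects commonly produce quasi-separation: the flag (a warning)
    # is exercised in its own expectation below, so quiet it here
    cmp <- suppressWarnings(
      compare_models(tb, "htn_cortex", "htn_cortex_vessels"))
    hits[r] <- cmp$lrt_p < 0.01
  }
  expect_gte(mean(hits), 0.95)
})

test_that("simulated blood pressure matches its exceedance probability", {
  # diastolic ~ N(75 + 4a, 8), systolic ~ N(120 + 10a, 12); the labeled
  # prevalence must match the closed-form normal exceedance within MC error
  tab <- simulate_subjects(20000, seed = 70)
  a <- (tab$age - 50) / 20
  p_true <- 1 - pnorm(90, 75 + 4 * a, 8) * pnorm(140, 120 + 10 * a, 12)
  expect_lt(abs(mean(tab$hypertension) - mean(p_true)), 0.01)
})

test_that("model comparison results tidy into one-row tibbles", {
  tab <- simulate_subjects(300, seed = 80)
  cmp <- compare_models(tab, "age_cortex", "age_cortex_vessels")
  td <- tidy(cmp)
  expect_equal(nrow(td), 1)
  expect_true(all(c("f_statistic", "df_num", "df_den", "p_value") %in%
                    names(td)))
  cv <- crossval_r2(tab, "age_vessels", k = 5, seed = 1)
  expect_equal(glance(cv)$n, 300)
})
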