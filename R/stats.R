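#' Model formulas of the evaluation protocol
#'
#' The protocol relates subject phenotypes to two predictor blocks: regional
#' cortical thickness columns and the 11 vessel-morphology features. Age
#' models regress age on one or both blocks; dependent-variable (DV) models
#' (diastolic/systolic blood pressure, MMSE) add age and sex as covariates;
#' hypertension models are logistic with age and sex as covariates.
#'
#' Cortical thickness columns are recognized by the `ct_` prefix (one column
#' per region, consumed as given); vessel features by the names in
#' [vessel_feature_names()].
#'
#' @param id one of `"age_cortex"`, `"age_vessels"`, `"age_cortex_vessels"`,
#'   `"dv_cortex"`, `"dv_vessels"`, `"dv_cortex_vessels"`,
#'   `"htn_cortex"`, `"htn_vessels"`, `"htn_cortex_vessels"`.
#' @param table the subject table the formula will be applied to (used to
#'   enumerate the cortical-thickness columns).
#' @param dv for `dv_*` ids: the dependent variable column, one of
#'   `"diastolic_bp"`, `"systolic_bp"`, `"mmse"`.
#' @return a `formula`.
#' @export
protocol_formula <- function(id, table, dv = NULL) {
  ct <- grep("^ct_", names(table), value = TRUE)
  vf <- intersect(vessel_feature_names(), names(table))
  blocks <- list(cortex = ct, vessels = vf,
                 cortex_vessels = c(ct, vf))
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  head_ <- parts[1]
  block <- paste(parts[-1], collapse = "_")
  if (!block %in% names(blocks) || length(blocks[[block]]) == 0)
    stop("unknown or empty predictor block in formula id: ", id,
         call. = FALSE)
  rhs <- blocks[[block]]
  if (head_ == "age") {
    lhs <- "age"
  } else if (head_ == "dv") {
    if (is.null(dv)) stop("`dv` required for dv_* formulas", call. = FALSE)
    lhs <- dv
    rhs <- c("age", "factor(sex)", rhs)
  } else if (head_ == "htn") {
    lhs <- "hypertension"
    rhs <- c("age", "factor(sex)", rhs)
  } else stop("unknown formula id: ", id, call. = FALSE)
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

resolve_formula <- function(formula, table, dv = NULL) {
  if (inherits(formula, "formula")) return(formula)
  protocol_formula(formula, table, dv = dv)
}

#' Ordinary least-squares fit of a protocol model
#'
#' Fits by OLS with listwise deletion of rows missing any model variable.
#' Categorical sex expands to indicator contrasts. A rank-deficient design
#' is an error naming the collinear columns, unless `allow_aliased = TRUE`
#' (aliased terms are then dropped, as in the underlying [stats::lm()]).
#'
#' @param table subject table (one row per subject).
#' @param formula a formula, or a protocol id accepted by
#'   [protocol_formula()].
#' @param dv dependent-variable column for `dv_*` ids.
#' @param allow_aliased keep a rank-deficient fit instead of erroring.
#' @return an `lm` object (so `broom::tidy()`/`glance()` and
#'   [nested_anova()] apply), with the resolved formula attached.
#' @export
fit_linear <- function(table, formula, dv = NULL, allow_aliased = FALSE) {
  f <- resolve_formula(formula, table, dv)
  resp <- all.vars(f)[1]
  if (resp %in% names(table)) {
    y <- table[[resp]]
    if (stats::var(y, na.rm = TRUE) == 0 || all(is.na(y)))
      stop("response `", resp, "` has zero variance", call. = FALSE)
  }
  fit <- stats::lm(f, data = table, na.action = stats::na.omit)
  check_aliased(fit, allow_aliased)
  fit
}

check_aliased <- function(fit, allow_aliased) {
  aliased <- is.na(stats::coef(fit))
  if (any(aliased) && !allow_aliased)
    stop("rank-deficient design; collinear columns: ",
         paste(names(aliased)[aliased], collapse = ", "), call. = FALSE)
  invisible(fit)
}

#' Maximum-likelihood logistic fit of a hypertension model
#'
#' Binomial GLM with logit link. Perfect separation is detected (fitted
#' probabilities numerically 0 or 1) and flagged with a warning; the fit is
#' still returned. A single-class outcome is an error.
#'
#' @inheritParams fit_linear
#' @return a `glm` object with a `separation` attribute (logical).
#' @export
fit_logistic <- function(table, formula, allow_aliased = FALSE) {
  f <- resolve_formula(formula, table)
  resp <- all.vars(f)[1]
  y <- table[[resp]]
  y <- y[!is.na(y)]
  if (length(unique(y)) < 2)
    stop("single-class outcome: `", resp,
         "` must contain both classes", call. = FALSE)
  fit <- withCallingHandlers(
    stats::glm(f, data = table, family = stats::binomial(),
               na.action = stats::na.omit),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warning("possible perfect separation in logistic fit",
                call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
  check_aliased(fit, allow_aliased)
  eps <- 1e-8
  attr(fit, "separation") <- any(fit$fitted.values < eps |
                                 fit$fitted.values > 1 - eps)
  fit
}

#' Nested-model analysis of variance
#'
#' Compares a reduced model against a full model containing its predictors
#' plus extras: `F = ((SSR_red - SSR_full) / df_num) / (SSR_full / df_den)`,
#' with `df_num` the number of (non-aliased) added predictors and `df_den`
#' the full model's residual degrees of freedom; p from the F distribution.
#' Both fits must use the same rows. For logistic fits the same machinery is
#' applied to deviances, and a likelihood-ratio test is reported alongside as
#' `lrt_stat` / `lrt_p` (an extension beyond the F protocol).
#'
#' If the added block contributes nothing to the rank (all aliased),
#' `F = 0`, `p = 1`.
#'
#' @param reduced,full nested fitted models (`lm` or both `glm`).
#' @return a `vm_model_comparison`: list with `f_statistic`, `df_num`,
#'   `df_den`, `p_value`, `adj_r2_reduced`, `adj_r2_full` (linear fits only),
#'   and for logistic fits `lrt_stat`, `lrt_p`.
#' @export
nested_anova <- function(reduced, full) {
  is_glm <- inherits(full, "glm")
  if (is_glm != inherits(reduced, "glm"))
    stop("reduced and full must both be lm or both be glm", call. = FALSE)
  xr <- colnames(stats::model.matrix(reduced))
  xf <- colnames(stats::model.matrix(full))
  if (!all(xr %in% xf))
    stop("models are not nested: reduced has predictors absent from full",
         call. = FALSE)
  nr <- stats::nobs(reduced); nf <- stats::nobs(full)
  if (nr != nf)
    stop("models were fit on different rows (", nr, " vs ", nf,
         "); refit on common complete cases", call. = FALSE)
  rank_r <- reduced$rank; rank_f <- full$rank
  df_num <- rank_f - rank_r
  df_den <- nf - rank_f
  if (is_glm) {
    dev_r <- stats::deviance(reduced); dev_f <- stats::deviance(full)
    if (df_num <= 0) {
      f <- 0; p <- 1
    } else {
      f <- ((dev_r - dev_f) / df_num) / (dev_f / df_den)
      p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
    }
    lrt <- dev_r - dev_f
    lrt_p <- if (df_num > 0)
      stats::pchisq(lrt, df_num, lower.tail = FALSE) else 1
    out <- list(f_statistic = f, df_num = df_num, df_den = df_den,
                p_value = p, adj_r2_reduced = NA_real_,
                adj_r2_full = NA_real_, lrt_stat = lrt, lrt_p = lrt_p)
  } else {
    ssr_r <- sum(stats::residuals(reduced)^2)
    ssr_f <- sum(stats::residuals(full)^2)
    if (df_num <= 0) {
      f <- 0; p <- 1
    } else {
      a <- stats::anova(reduced, full)
      f <- a$F[2]
      p <- a$`Pr(>F)`[2]
      # anova() and the SSR identity agree; keep anova's values
      stopifnot(abs(a$Df[2] - df_num) < .Machine$double.eps)
    }
    out <- list(f_statistic = f, df_num = df_num, df_den = df_den,
                p_value = p,
                adj_r2_reduced = summary(reduced)$adj.r.squared,
                adj_r2_full = summary(full)$adj.r.squared,
                lrt_stat = NA_real_, lrt_p = NA_real_)
  }
  structure(out, class = "vm_model_comparison")
}

#' @export
print.vm_model_comparison <- function(x, ...) {
  cat(sprintf("Nested-model ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_num, x$df_den, x$f_statistic, x$p_value))
  if (!is.na(x$adj_r2_full))
    cat(sprintf("  adjusted R2: reduced %.3f, full %.3f\n",
                x$adj_r2_reduced, x$adj_r2_full))
  if (!is.na(x$lrt_stat))
    cat(sprintf("  likelihood-ratio test: chi2(%d) = %.3f, p = %.3g\n",
                x$df_num, x$lrt_stat, x$lrt_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vm_model_comparison <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, df_num = x$df_num, df_den = x$df_den,
    p_value = x$p_value, adj_r2_reduced = x$adj_r2_reduced,
    adj_r2_full = x$adj_r2_full, lrt_stat = x$lrt_stat, lrt_p = x$lrt_p
  )
}

#' @exportS3Method generics::glance
glance.vm_model_comparison <- function(x, ...) tidy(x)

#' Compare reduced vs full protocol models on common complete cases
#'
#' Fits both models on the rows complete for the union of their variables
#' (listwise deletion over the full model's variables), then runs
#' [nested_anova()]. This is the protocol's model-comparison step in one
#' call.
#'
#' @param table subject table.
#' @param reduced_id,full_id protocol formula ids (see [protocol_formula()]).
#' @param dv dependent-variable column for `dv_*` ids.
#' @return a `vm_model_comparison`.
#' @export
compare_models <- function(table, reduced_id, full_id, dv = NULL) {
  f_red <- resolve_formula(reduced_id, table, dv)
  f_full <- resolve_formula(full_id, table, dv)
  vars <- union(all.vars(f_red), all.vars(f_full))
  cc <- stats::complete.cases(table[, vars, drop = FALSE])
  tab <- table[cc, , drop = FALSE]
  logistic <- grepl("^htn", full_id[1]) ||
    (length(all.vars(f_full)) && all.vars(f_full)[1] == "hypertension")
  if (logistic) {
    red <- fit_logistic(tab, f_red, allow_aliased = TRUE)
    full <- fit_logistic(tab, f_full, allow_aliased = TRUE)
  } else {
    red <- fit_linear(tab, f_red, allow_aliased = TRUE)
    full <- fit_linear(tab, f_full, allow_aliased = TRUE)
  }
  nested_anova(red, full)
}

#' k-fold cross-validated coefficient of determination
#'
#' Subjects are partitioned into `k` folds by a seeded shuffle (not
#' stratified); each fold is predicted by a model fit to the remaining
#' folds, so every subject is predicted exactly once out-of-fold. The
#' pooled `R^2 = 1 - SS_res / SS_tot` is the coefficient of determination
#' over all out-of-fold predictions (it can be negative when the model
#' predicts worse than the mean).
#'
#' @inheritParams fit_linear
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold shuffle; recorded in the result.
#' @return a `vm_crossval`: list with `r2`, `folds` (tibble row/fold),
#'   `predictions` (tibble observed/predicted/fold), `k`, `seed`.
#' @export
crossval_r2 <- function(table, formula, dv = NULL, k = 10, seed = 1L) {
  f <- resolve_formula(formula, table, dv)
  vars <- all.vars(f)
  cc <- stats::complete.cases(table[, vars, drop = FALSE])
  tab <- table[cc, , drop = FALSE]
  n <- nrow(tab)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("fewer rows (", n, ") than folds (", k, ")", call. = FALSE)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  fold <- sample(rep_len(seq_len(k), n))
  p <- length(attr(stats::terms(f), "term.labels"))
  if (min(tabulate(fold, k)) < 1 || (n - max(tabulate(fold, k))) <= p)
    stop("a training fold has fewer rows than predictors; use a smaller k",
         call. = FALSE)
  resp <- vars[1]
  obs <- tab[[resp]]
  pred <- numeric(n)
  for (fd in seq_len(k)) {
    test <- fold == fd
    fit <- stats::lm(f, data = tab[!test, , drop = FALSE])
    pred[test] <- stats::predict(fit, newdata = tab[test, , drop = FALSE])
  }
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  structure(
    list(r2 = r2,
         folds = tibble::tibble(row = seq_len(n), fold = fold),
         predictions = tibble::tibble(observed = obs, predicted = pred,
                                      fold = fold),
         k = k, seed = seed),
    class = "vm_crossval"
  )
}

#' @export
print.vm_crossval <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated R2 = %.3f (seed %d, n = %d)\n",
              x$k, x$r2, x$seed, nrow(x$predictions)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.vm_crossval <- function(x, ...) {
  tibble::tibble(r2 = x$r2, k = x$k, seed = x$seed,
                 n = nrow(x$predictions))
}

#' Hypertension labeling rule
#'
#' TRUE iff diastolic blood pressure is above 90 mmHg or systolic above
#' 140 mmHg — strict inequalities, so a subject at exactly 90/140 is not
#' labeled. Missing pressures give `NA` (excluded downstream).
#'
#' @param diastolic_bp,systolic_bp mmHg; vectorized.
#' @return logical vector.
#' @export
label_hypertension <- function(diastolic_bp, systolic_bp) {
  ok <- !is.na(diastolic_bp) & !is.na(systolic_bp)
  out <- rep(NA, length(diastolic_bp))
  out[ok] <- diastolic_bp[ok] > 90 | systolic_bp[ok] > 140
  out
}

#' Split subjects into older and younger groups
#'
#' Older is strictly above the cut (default 60 years), younger is at or
#' below it.
#'
#' @param table subject table with an `age` column.
#' @param cut_years age threshold.
#' @return the table with an `age_group` factor column
#'   (`"younger"`/`"older"`).
#' @export
split_by_age <- function(table, cut_years = 60) {
  dplyr::mutate(table, age_group = factor(
    ifelse(.data$age > cut_years, "older", "younger"),
    levels = c("younger", "older")))
}

#' Simulate a subject phenotype table
#'
#' Generates the tabular inputs of the evaluation protocol with known
#' structure: age uniform over 20–88 years; sex balanced; `n_ct` regional
#' cortical-thickness columns (`ct_*`, mm) declining linearly with age plus
#' Gaussian noise; the 11 vessel features with age trends (radius and volume
#' grow, tortuosity grows, counts shrink slightly) plus noise; blood
#' pressures rising with age; MMSE near ceiling with a mild age decline; and
#' the hypertension label applied via [label_hypertension()]. Effect sizes
#' default to magnitudes typical of aging cohorts so that age models have
#' moderate, not perfect, explanatory power.
#'
#' @param n subjects.
#' @param seed integer seed.
#' @param n_ct number of cortical-thickness regions.
#' @param vessel_age_effect multiplier on the age trends of vessel features
#'   (0 = no signal).
#' @param noise_sd multiplier on all noise SDs.
#' @return a tibble, one row per subject.
#' @export
simulate_subjects <- function(n = 500, seed = 1L, n_ct = 8,
                              vessel_age_effect = 1, noise_sd = 1) {
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  age <- stats::runif(n, 20, 88)
  a <- (age - 50) / 20 # centered, unit-ish scale
  sex <- sample(c("F", "M"), n, replace = TRUE)
  tab <- tibble::tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = age, sex = sex,
    diastolic_bp = 75 + 4 * a + stats::rnorm(n, 0, 8 * noise_sd),
    systolic_bp = 120 + 10 * a + stats::rnorm(n, 0, 12 * noise_sd),
    mmse = pmin(30, round(29 - 0.8 * pmax(a, 0) +
                            stats::rnorm(n, 0, 1 * noise_sd)))
  )
  # heterogeneous regional thinning slopes (mm per ~20 years), so the
  # cortex-only age model explains a substantial but not near-perfect share
  # of variance, as in real cohorts
  ct_slope <- stats::runif(n_ct, 0.01, 0.09)
  for (r in seq_len(n_ct))
    tab[[sprintf("ct_%02d", r)]] <-
      2.5 - ct_slope[r] * a + stats::rnorm(n, 0, 0.15 * noise_sd)
  # effect sizes scaled so the vessels-only age model has moderate explanatory
  # power (cross-validated R2 ~ 0.4 at the defaults), the regime reported for
  # vascular-morphology aging cohorts
  e <- 0.4 * vessel_age_effect
  tab$total_volume_mm3 <- 9000 + 600 * e * a + stats::rnorm(n, 0, 900 * noise_sd)
  tab$total_length_mm <- 1400 - 60 * e * a + stats::rnorm(n, 0, 140 * noise_sd)
  tab$n_segments <- pmax(1, round(120 - 6 * e * a +
                                    stats::rnorm(n, 0, 12 * noise_sd)))
  tab$n_bifurcations <- pmax(0, round(55 - 3 * e * a +
                                        stats::rnorm(n, 0, 7 * noise_sd)))
  tab$n_endpoints <- tab$n_bifurcations + 2 +
    pmax(0, round(stats::rnorm(n, 8, 3 * noise_sd)))
  tab$mean_radius_mm <- 1.1 + 0.08 * e * a + stats::rnorm(n, 0, 0.08 * noise_sd)
  tab$sd_radius_mm <- 0.4 + 0.03 * e * a + stats::rnorm(n, 0, 0.05 * noise_sd)
  tab$max_radius_mm <- 2.8 + 0.2 * e * a + stats::rnorm(n, 0, 0.25 * noise_sd)
  tab$mean_tortuosity <- 1.15 + 0.04 * e * a +
    stats::rnorm(n, 0, 0.04 * noise_sd)
  tab$sd_tortuosity <- 0.12 + 0.01 * e * a + stats::rnorm(n, 0, 0.02 * noise_sd)
  tab$mean_segment_length_mm <- 11 - 0.6 * e * a +
    stats::rnorm(n, 0, 1.2 * noise_sd)
  tab$hypertension <- label_hypertension(tab$diastolic_bp, tab$systolic_bp)
  tab
}
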