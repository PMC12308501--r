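# Stats module: condition-reactivity mixed models, change-score vs trait
# regressions with robust SEs, baseline-dependence regressions, residualized
# plotting values and model diagnostics.

new_plinet_fit <- function(model_id, family, terms, fit, n_obs,
                           n_participants = NA_integer_,
                           convergence = "ok", alpha_corrected = 0.05) {
  structure(
    list(model_id = model_id, family = family, terms = terms, fit = fit,
         n_obs = n_obs, n_participants = n_participants,
         convergence = convergence, alpha_corrected = alpha_corrected),
    class = "plinet_fit"
  )
}

#' @export
print.plinet_fit <- function(x, ...) {
  cat(sprintf("<plinet_fit> %s [%s], n = %d, convergence: %s, alpha = %.3g\n",
              x$model_id, x$family, x$n_obs, x$convergence,
              x$alpha_corrected))
  print(x$terms)
  invisible(x)
}

#' @rdname tidy.plinet_fit
#' @method tidy plinet_fit
#' @export
tidy.plinet_fit <- function(x, ...) x$terms

#' Tidy and summarize fitted pipeline models
#'
#' `tidy()` returns the term table (coefficient, standard error, z or t
#' statistic, two-sided p-value, 95% Wald confidence limits, and a
#' significance label at the model's corrected alpha, with p in
#' \[0.05, 0.10) labelled as an exploratory trend). `glance()` returns a
#' one-row model summary.
#'
#' @param x A `plinet_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.plinet_fit
NULL

#' @rdname tidy.plinet_fit
#' @method glance plinet_fit
#' @export
glance.plinet_fit <- function(x, ...) {
  tibble(model_id = x$model_id, family = x$family, n_obs = x$n_obs,
         n_participants = x$n_participants, convergence = x$convergence,
         alpha_corrected = x$alpha_corrected)
}

significance_label <- function(p, alpha) {
  dplyr::case_when(
    p < alpha ~ "significant",
    p >= 0.05 & p < 0.10 ~ "exploratory trend",
    TRUE ~ "ns"
  )
}

# Wald-z term table for a lmer fit (the models report z statistics).
tidy_wald_z <- function(fit, alpha) {
  est <- lme4::fixef(fit)
  # the finite-difference Hessian path can fail on degenerate fits; fall back
  # to the RX-factor covariance, and to NA (flagged downstream) if even that
  # is not positive definite
  V <- tryCatch(
    suppressWarnings(as.matrix(stats::vcov(fit))),
    error = function(e) tryCatch(
      suppressWarnings(as.matrix(stats::vcov(fit, use.hessian = FALSE))),
      error = function(e2) matrix(NA_real_, length(est), length(est))
    )
  )
  se <- sqrt(diag(V))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(z), p_value = unname(p),
    ci_lo = unname(est - qnorm(0.975) * se),
    ci_hi = unname(est + qnorm(0.975) * se),
    label = significance_label(unname(p), alpha)
  )
}

# t term table for an lm fit, optionally with HC1 sandwich SEs.
tidy_lm <- function(fit, alpha, robust = FALSE) {
  if (robust) {
    ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC1"))
    est <- ct[, 1]; se <- ct[, 2]; stat <- ct[, 3]; p <- ct[, 4]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[, 1]; se <- sm[, 2]; stat <- sm[, 3]; p <- sm[, 4]
  }
  df_resid <- stats::df.residual(fit)
  tcrit <- if (df_resid > 0) stats::qt(0.975, df = df_resid) else NA_real_
  tibble(
    term = rownames(if (robust) ct else summary(fit)$coefficients),
    estimate = unname(est), std_error = unname(se),
    statistic = unname(stat), p_value = unname(p),
    ci_lo = unname(est - tcrit * se), ci_hi = unname(est + tcrit * se),
    label = significance_label(unname(p), alpha)
  )
}

lmer_convergence <- function(fit, terms = NULL) {
  msgs <- fit@optinfo$conv$lme4$messages
  flag <- if (lme4::isSingular(fit)) {
    "singular"
  } else if (!is.null(msgs) && length(msgs) > 0) {
    paste(msgs, collapse = "; ")
  } else {
    "ok"
  }
  if (!is.null(terms) && any(!is.finite(terms$std_error))) {
    flag <- paste(flag, "standard errors unavailable", sep = "; ")
  }
  flag
}

check_metrics_table <- function(metrics) {
  needed <- c("participant_id", "diagnosis", "age_months", "sex",
              "condition", "band", "metric", "value")
  missing <- setdiff(needed, names(metrics))
  if (length(missing) > 0) {
    stop_arg("metrics table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  invisible(metrics)
}

subset_cell <- function(metrics, metric, band, kappa = NULL) {
  out <- metrics |>
    dplyr::filter(.data$metric == !!metric, .data$band == !!band)
  if (!is.null(kappa) && "kappa" %in% names(out)) {
    out <- dplyr::filter(out, abs(.data$kappa - !!kappa) < 1e-9)
  }
  droplevels_safe(out)
}

droplevels_safe <- function(df) {
  df$diagnosis <- factor(as.character(df$diagnosis), levels = c("TD", "ASD"))
  if ("condition" %in% names(df)) {
    df$condition <- factor(as.character(df$condition), levels = c("DR", "EO"))
  }
  df$sex <- factor(as.character(df$sex), levels = c("female", "male"))
  df
}

# Covariate factors with a single observed level cannot enter a model
# formula; drop them and report what was dropped so degraded fits are
# flagged rather than fatal.
estimable_covariates <- function(d, candidates) {
  keep <- character(); dropped <- character()
  for (v in candidates) {
    if (dplyr::n_distinct(d[[v]]) > 1) keep <- c(keep, v)
    else dropped <- c(dropped, v)
  }
  list(keep = keep, dropped = dropped)
}

with_dropped <- function(flag, dropped) {
  if (length(dropped) == 0) return(flag)
  paste(flag, paste("dropped:", paste(dropped, collapse = ", ")), sep = "; ")
}

#' Condition-reactivity mixed-effects model for one metric and band
#'
#' Fits `value ~ diagnosis * condition + age_months + sex` with a random
#' intercept per participant (maximum likelihood), on the long-format metrics
#' table restricted to one graph metric and frequency band. Inference is by
#' Wald z tests; the corrected significance threshold defaults to
#' 0.01 = 0.05 / 5, a Bonferroni correction across the five frequency bands
#' (never across metrics). Reference levels: TD, DR, female.
#'
#' @param metrics A long metrics tibble (see [simulate_metrics()] or
#'   [run_pipeline()]): columns `participant_id`, `diagnosis`, `age_months`,
#'   `sex`, `condition`, `band`, `metric`, `value` (and optionally `kappa`).
#' @param metric One of `"SW"`, `"C"`, `"L"`.
#' @param band Band name.
#' @param kappa Optional density filter when the table carries a sweep.
#' @param alpha_corrected Corrected per-test alpha (default 0.05 / 5).
#' @return A `plinet_fit` (family `"mixed"`); non-convergence or a singular
#'   random-effect fit is flagged in `$convergence`, never silently dropped.
#' @export
#' @examples
#' m <- simulate_metrics(simulate_cohort(6, 6, seed = 1), bands = "beta",
#'                       metrics = "SW", seed = 2)
#' fit_condition_model(m, "SW", "beta")$alpha_corrected
fit_condition_model <- function(metrics, metric, band, kappa = NULL,
                                alpha_corrected = 0.05 / 5) {
  check_metrics_table(metrics)
  d <- subset_cell(metrics, metric, band, kappa)
  if (any(table(unique(d[, c("participant_id", "diagnosis")])$diagnosis) < 2)) {
    stop_arg("need at least 2 participants per group")
  }
  if (dplyr::n_distinct(d$condition) < 2) {
    stop_arg("both conditions must be present")
  }
  cov <- estimable_covariates(d, c("age_months", "sex"))
  form <- stats::as.formula(paste(
    "value ~ diagnosis * condition",
    paste(c("", cov$keep), collapse = " + "),
    "+ (1 | participant_id)"))
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = FALSE))
  terms <- tidy_wald_z(fit, alpha_corrected)
  new_plinet_fit(
    model_id = sprintf("condition/%s/%s", metric, band), family = "mixed",
    terms = terms, fit = fit, n_obs = nrow(d),
    n_participants = dplyr::n_distinct(d$participant_id),
    convergence = with_dropped(lmer_convergence(fit, terms), cov$dropped),
    alpha_corrected = alpha_corrected
  )
}

#' Group-specific condition model
#'
#' Same structure as [fit_condition_model()] minus the diagnosis terms,
#' fitted within a single diagnostic group:
#' `value ~ condition + age_months + sex + (1 | participant_id)`.
#'
#' @inheritParams fit_condition_model
#' @param group `"ASD"` or `"TD"`.
#' @param alpha Per-test alpha for labelling (default 0.05; these follow-up
#'   models are exploratory, triggered by a significant omnibus interaction).
#' @return A `plinet_fit`.
#' @export
fit_groupwise_condition_model <- function(metrics, metric, band, group,
                                          kappa = NULL, alpha = 0.05) {
  check_metrics_table(metrics)
  group <- match.arg(group, c("ASD", "TD"))
  d <- subset_cell(metrics, metric, band, kappa) |>
    dplyr::filter(.data$diagnosis == group)
  if (nrow(d) == 0) stop_arg("no rows for group %s", group)
  cov <- estimable_covariates(d, c("age_months", "sex"))
  form <- stats::as.formula(paste(
    "value ~ condition", paste(c("", cov$keep), collapse = " + "),
    "+ (1 | participant_id)"))
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = FALSE))
  terms <- tidy_wald_z(fit, alpha)
  new_plinet_fit(
    model_id = sprintf("condition/%s/%s/%s", metric, band, group),
    family = "mixed", terms = terms, fit = fit,
    n_obs = nrow(d), n_participants = dplyr::n_distinct(d$participant_id),
    convergence = with_dropped(lmer_convergence(fit, terms), cov$dropped),
    alpha_corrected = alpha
  )
}

#' Condition change scores (EO minus DR) with baseline
#'
#' Pivots the long metrics table to one row per participant x band x metric
#' with `delta = EO - DR` and `baseline = DR`. Participants missing either
#' condition in a cell are skipped with a warning.
#'
#' @param metrics A long metrics tibble.
#' @return A tibble: `participant_id`, `diagnosis`, `age_months`, `sex`,
#'   `srs_raw_total` (if present), `band`, `metric`, `kappa` (if present),
#'   `delta`, `baseline`.
#' @export
#' @examples
#' m <- simulate_metrics(simulate_cohort(4, 4, seed = 1), bands = "beta",
#'                       metrics = "SW", seed = 2)
#' compute_delta(m)
compute_delta <- function(metrics) {
  check_metrics_table(metrics)
  id_cols <- intersect(
    c("participant_id", "diagnosis", "age_months", "sex", "srs_raw_total",
      "band", "metric", "kappa"),
    names(metrics)
  )
  wide <- metrics |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(id_cols),
                       names_from = "condition", values_from = "value")
  if (!all(c("DR", "EO") %in% names(wide))) {
    stop_arg("metrics table must contain both DR and EO rows")
  }
  incomplete <- is.na(wide$DR) | is.na(wide$EO)
  if (any(incomplete)) {
    rlang::warn(sprintf(
      "%d participant-cell(s) missing one condition were skipped", sum(incomplete)
    ), class = "plinet_incomplete_pairs")
  }
  wide |>
    dplyr::filter(!incomplete) |>
    dplyr::mutate(delta = .data$EO - .data$DR, baseline = .data$DR) |>
    dplyr::select(-"DR", -"EO")
}

#' Change-score versus trait regression
#'
#' Ordinary least squares predicting the SRS raw total from the condition
#' change score: `srs ~ delta * diagnosis + age_months + sex` (or
#' `srs ~ delta + age_months + sex` within a single group). With
#' `robust = TRUE` (default), heteroscedasticity-robust HC1 sandwich standard
#' errors are used for inference. These follow-up regressions use alpha 0.05
#' (each tests a distinct hypothesis; they are triggered by the omnibus
#' interaction and reported as exploratory).
#'
#' @param delta A change-score tibble from [compute_delta()].
#' @param metric,band Cell to analyse.
#' @param robust Use HC1 sandwich standard errors (default `TRUE`).
#' @param group Optional single group (`"ASD"` or `"TD"`) for the
#'   group-specific variant.
#' @param alpha Per-test alpha (default 0.05).
#' @return A `plinet_fit` (family `"ols_robust"` or `"ols"`). Rank-deficient
#'   fits are flagged in `$convergence`.
#' @export
fit_srs_model <- function(delta, metric, band, robust = TRUE, group = NULL,
                          alpha = 0.05) {
  if (!"srs_raw_total" %in% names(delta) || anyNA(delta$srs_raw_total)) {
    stop_arg("`delta` must carry a complete srs_raw_total column")
  }
  d <- delta |>
    dplyr::filter(.data$metric == !!metric, .data$band == !!band) |>
    droplevels_safe()
  if (!is.null(group)) {
    group <- match.arg(group, c("ASD", "TD"))
    d <- dplyr::filter(d, .data$diagnosis == group)
  }
  cov <- estimable_covariates(
    d, if (is.null(group)) c("diagnosis", "age_months", "sex")
       else c("age_months", "sex"))
  lead <- if ("diagnosis" %in% cov$keep) "delta * diagnosis" else "delta"
  form <- stats::reformulate(c(lead, setdiff(cov$keep, "diagnosis")),
                             response = "srs_raw_total")
  fit <- lm(form, data = d)
  conv <- with_dropped(if (anyNA(coef(fit))) "rank deficient" else "ok",
                       setdiff(cov$dropped, if (is.null(group)) character() else "diagnosis"))
  new_plinet_fit(
    model_id = sprintf("srs/%s/%s%s", metric, band,
                       if (is.null(group)) "" else paste0("/", group)),
    family = if (robust) "ols_robust" else "ols",
    terms = tidy_lm(fit, alpha, robust = robust), fit = fit, n_obs = nrow(d),
    n_participants = nrow(d), convergence = conv, alpha_corrected = alpha
  )
}

#' Baseline-dependence regression
#'
#' Ordinary least squares predicting the condition change score from its
#' baseline: `delta ~ baseline * diagnosis + age_months + sex`, with
#' Bonferroni alpha 0.01 = 0.05 / 5 across the five bands. The null
#' expectation under shared independent noise is a slope near -1 (regression
#' to the mean: `cov(X, Y - X) / var(X) = -1` for iid X, Y), so estimated
#' slopes must be judged against that artifactual baseline, not against 0.
#'
#' @param delta A change-score tibble from [compute_delta()].
#' @param metric,band Cell to analyse.
#' @param alpha_corrected Corrected alpha (default 0.05 / 5).
#' @return A `plinet_fit` (family `"ols"`).
#' @export
fit_baseline_model <- function(delta, metric, band,
                               alpha_corrected = 0.05 / 5) {
  d <- delta |>
    dplyr::filter(.data$metric == !!metric, .data$band == !!band) |>
    droplevels_safe()
  cov <- estimable_covariates(d, c("diagnosis", "age_months", "sex"))
  lead <- if ("diagnosis" %in% cov$keep) "baseline * diagnosis" else "baseline"
  form <- stats::reformulate(c(lead, setdiff(cov$keep, "diagnosis")),
                             response = "delta")
  fit <- lm(form, data = d)
  conv <- with_dropped(if (anyNA(coef(fit))) "rank deficient" else "ok",
                       cov$dropped)
  new_plinet_fit(
    model_id = sprintf("baseline/%s/%s", metric, band), family = "ols",
    terms = tidy_lm(fit, alpha_corrected, robust = FALSE), fit = fit,
    n_obs = nrow(d), n_participants = nrow(d), convergence = conv,
    alpha_corrected = alpha_corrected
  )
}

#' Covariate-adjusted values for plotting
#'
#' Residualizes a column on age and sex by least squares (optionally within
#' diagnostic group), the adjustment used for scatter plots of trait scores
#' against change scores. Residuals are orthogonal to the covariate design
#' columns and have mean ~0 (per group when `by_group`).
#'
#' @param data A tibble with `age_months`, `sex` and (when `by_group`)
#'   `diagnosis`.
#' @param col Name of the column to adjust (string).
#' @param by_group Residualize within diagnosis groups (default `FALSE`).
#' @return `data` with an added column `<col>_adj`.
#' @export
#' @examples
#' coh <- simulate_cohort(5, 5, seed = 1)
#' residualize(coh, "srs_raw_total", by_group = TRUE)
residualize <- function(data, col, by_group = FALSE) {
  stopifnot(col %in% names(data))
  adj_one <- function(df) {
    r <- resid(lm(stats::reformulate(c("age_months", "sex"), response = col),
                  data = df))
    df[[paste0(col, "_adj")]] <- as.numeric(r)
    df
  }
  if (by_group) {
    data |>
      dplyr::group_by(.data$diagnosis) |>
      dplyr::group_modify(~ adj_one(.x)) |>
      dplyr::ungroup() |>
      dplyr::relocate(dplyr::all_of(names(data)))
  } else {
    adj_one(data)
  }
}

#' Residual and random-effect diagnostics for a fitted model
#'
#' Numeric summaries of the checks applied to the primary models: residual
#' skewness and excess kurtosis (approximate normality), the slope of
#' residuals against fitted values (zero by the normal equations for a
#' correctly specified least-squares fit; in mixed models random-effect
#' shrinkage leaves a positive trend even when well specified, reported for
#' reference), the slope of |residual| against fitted values with its p-value
#' (a variance trend flags heteroscedasticity), and, for mixed models,
#' skewness of the estimated random intercepts. Plot with
#' [ggplot2::autoplot()].
#'
#' @param x A `plinet_fit`.
#' @param hetero_alpha Threshold on the |residual|-trend p-value below which
#'   the heteroscedasticity flag is set (default 0.05).
#' @return A `plinet_diagnostics` object: list with `summary` (one-row
#'   tibble) and the underlying residuals/fitted/random-intercept vectors.
#' @export
model_diagnostics <- function(x, hetero_alpha = 0.05) {
  stopifnot(inherits(x, "plinet_fit"))
  r <- resid(x$fit)
  f <- fitted(x$fit)
  trend <- coef(lm(r ~ f))[["f"]]
  het_fit <- summary(lm(abs(r) ~ f))$coefficients
  # degenerate fits (constant fitted values, zero residual df) have no
  # estimable trend row
  if ("f" %in% rownames(het_fit) && ncol(het_fit) >= 4) {
    het_slope <- het_fit["f", "Estimate"]
    het_p <- het_fit["f", "Pr(>|t|)"]
  } else {
    het_slope <- NA_real_
    het_p <- NA_real_
  }
  ranefs <- if (x$family == "mixed") {
    lme4::ranef(x$fit)$participant_id[["(Intercept)"]]
  } else {
    numeric()
  }
  summary <- tibble(
    model_id = x$model_id,
    resid_skewness = e1071::skewness(r),
    resid_kurtosis = e1071::kurtosis(r),
    resid_fitted_slope = trend,
    hetero_slope = het_slope,
    hetero_p = het_p,
    heteroscedastic = het_p < hetero_alpha,
    ranef_skewness = if (length(ranefs) > 2) e1071::skewness(ranefs) else NA_real_
  )
  structure(list(summary = summary, residuals = as.numeric(r),
                 fitted = as.numeric(f), ranef = as.numeric(ranefs),
                 model_id = x$model_id),
            class = "plinet_diagnostics")
}

#' @export
print.plinet_diagnostics <- function(x, ...) {
  cat(sprintf("<plinet_diagnostics> %s\n", x$model_id))
  print(x$summary)
  invisible(x)
}

#' Run the full condition / trait / baseline analysis suite
#'
#' Orchestrates the three analysis families over every metric x band cell of
#' a long metrics table:
#'
#' 1. condition-reactivity mixed models for each cell (Bonferroni alpha
#'    0.05 / 5 across bands);
#' 2. for cells whose diagnosis-by-condition interaction passes the corrected
#'    alpha (the gate; override with `gate = FALSE`), group-specific
#'    condition models and change-score-versus-SRS regressions with HC1
#'    robust errors (overall and per group);
#' 3. baseline-dependence regressions for every cell.
#'
#' @param metrics A long metrics tibble.
#' @param alpha_corrected Corrected alpha for the omnibus models and the gate
#'   (default 0.05 / 5).
#' @param gate If `FALSE`, follow-up analyses run for every cell regardless
#'   of the omnibus interaction (testing override).
#' @param robust Robust SEs for the SRS regressions (default `TRUE`).
#' @param kappa Optional density filter.
#' @return A list of tibbles: `condition` (all omnibus terms), `gated_cells`,
#'   `groupwise`, `srs`, `baseline`, plus `fits` (the underlying
#'   `plinet_fit` objects, named by model id).
#' @export
condition_analysis <- function(metrics, alpha_corrected = 0.05 / 5,
                               gate = TRUE, robust = TRUE, kappa = NULL) {
  check_metrics_table(metrics)
  cells <- metrics |>
    dplyr::distinct(.data$metric, .data$band)
  fits <- list()
  omnibus <- purrr::pmap_dfr(cells, function(metric, band) {
    f <- fit_condition_model(metrics, metric, band, kappa = kappa,
                             alpha_corrected = alpha_corrected)
    fits[[f$model_id]] <<- f
    dplyr::mutate(tidy(f), metric = metric, band = band,
                  convergence = f$convergence, .before = 1)
  })
  inter <- omnibus |>
    dplyr::filter(.data$term == "diagnosisASD:conditionEO")
  gated <- if (gate) {
    dplyr::filter(inter, .data$p_value < alpha_corrected)
  } else {
    inter
  }
  gated_cells <- dplyr::select(gated, "metric", "band")
  deltas <- compute_delta(metrics)
  groupwise <- srs <- tibble()
  if (nrow(gated_cells) > 0) {
    groupwise <- purrr::pmap_dfr(gated_cells, function(metric, band) {
      purrr::map_dfr(c("TD", "ASD"), function(g) {
        f <- fit_groupwise_condition_model(metrics, metric, band, g,
                                           kappa = kappa)
        fits[[f$model_id]] <<- f
        dplyr::mutate(tidy(f), metric = metric, band = band, group = g,
                      .before = 1)
      })
    })
    srs <- purrr::pmap_dfr(gated_cells, function(metric, band) {
      purrr::map_dfr(list(NULL, "TD", "ASD"), function(g) {
        f <- fit_srs_model(deltas, metric, band, robust = robust, group = g)
        fits[[f$model_id]] <<- f
        dplyr::mutate(tidy(f), metric = metric, band = band,
                      group = if (is.null(g)) "all" else g, .before = 1)
      })
    })
  }
  baseline <- purrr::pmap_dfr(cells, function(metric, band) {
    f <- fit_baseline_model(deltas, metric, band,
                            alpha_corrected = alpha_corrected)
    fits[[f$model_id]] <<- f
    dplyr::mutate(tidy(f), metric = metric, band = band, .before = 1)
  })
  list(condition = omnibus, gated_cells = gated_cells, groupwise = groupwise,
       srs = srs, baseline = baseline, fits = fits)
}
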