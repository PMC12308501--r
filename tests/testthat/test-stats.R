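cohort_small <- function(n = 27, seed = 1) simulate_cohort(n, n + 4, seed = seed)

test_that("compute_delta is exact arithmetic with baseline carried alongside", {
  coh <- cohort_small(4)
  m <- simulate_metrics(coh, bands = "beta", metrics = "SW", seed = 2)
  d <- compute_delta(m)
  wide <- tidyr::pivot_wider(m, id_cols = "participant_id",
                             names_from = "condition", values_from = "value")
  expect_equal(nrow(d), nrow(coh))                 # participants x bands x metrics
  expect_equal(d$delta + d$baseline,
               wide$EO[match(d$participant_id, wide$participant_id)])
  expect_equal(d$baseline,
               wide$DR[match(d$participant_id, wide$participant_id)])
  # EO == DR everywhere -> all deltas zero
  m0 <- m
  m0$value <- ave(m0$value, m0$participant_id, FUN = function(v) v[1])
  expect_true(all(compute_delta(m0)$delta == 0))
  # missing condition -> skipped with warning
  m_miss <- m[-1, ]
  expect_warning(d_miss <- compute_delta(m_miss),
                 class = "plinet_incomplete_pairs")
  expect_equal(nrow(d_miss), nrow(coh) - 1)
})

test_that("condition model uses the Bonferroni-corrected alpha and flags convergence", {
  m <- simulate_metrics(cohort_small(8), bands = "beta", metrics = "SW",
                        seed = 3)
  f <- fit_condition_model(m, "SW", "beta")
  expect_equal(f$alpha_corrected, 0.05 / 5)
  expect_true(all(c("diagnosisASD", "conditionEO", "diagnosisASD:conditionEO",
                    "age_months", "sexmale") %in% tidy(f)$term))
  tt <- tidy(f)
  expect_true(all(tt$ci_lo <= tt$estimate & tt$estimate <= tt$ci_hi))
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
  expect_true(f$convergence %in% c("ok", "singular") ||
                nchar(f$convergence) > 0)
  expect_s3_class(glance(f), "tbl_df")
})

test_that("with no participant variance the mixed model matches the OLS oracle", {
  m <- simulate_metrics(cohort_small(10), bands = "beta", metrics = "SW",
                        sigma_participant = 0, sigma_resid = 0.05, seed = 4)
  f <- fit_condition_model(m, "SW", "beta")
  d <- dplyr::filter(m, metric == "SW", band == "beta")
  ols <- lm(value ~ diagnosis * condition + age_months + sex, data = d)
  expect_equal(unname(tidy(f)$estimate[match(names(coef(ols)), tidy(f)$term)]),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("group-specific models recover an injected within-group condition effect", {
  hits <- vapply(1:30, function(s) {
    coh <- simulate_cohort(23, 31, seed = s)
    m <- simulate_metrics(coh, bands = "beta", metrics = "SW",
                          effects = list(SW.beta = c(interaction = 0.08)),
                          seed = 1000 + s)
    f <- fit_groupwise_condition_model(m, "SW", "beta", "ASD")
    tidy(f)$estimate[tidy(f)$term == "conditionEO"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # no injected effect in TD: CI covers 0 at roughly the nominal rate
  cover <- vapply(1:30, function(s) {
    coh <- simulate_cohort(23, 31, seed = s)
    m <- simulate_metrics(coh, bands = "beta", metrics = "SW",
                          effects = list(SW.beta = c(interaction = 0.08)),
                          seed = 2000 + s)
    f <- fit_groupwise_condition_model(m, "SW", "beta", "TD")
    tt <- tidy(f)[tidy(f)$term == "conditionEO", ]
    tt$ci_lo <= 0 && 0 <= tt$ci_hi
  }, logical(1))
  expect_gte(mean(cover), 0.8)
  # group subset of the full data equals a direct fit on that subset
  coh <- simulate_cohort(12, 12, seed = 5)
  m <- simulate_metrics(coh, bands = "beta", metrics = "SW", seed = 6)
  f_sub <- fit_groupwise_condition_model(m, "SW", "beta", "ASD")
  m_asd <- dplyr::filter(m, diagnosis == "ASD")
  f_dir <- fit_groupwise_condition_model(m_asd, "SW", "beta", "ASD")
  expect_equal(tidy(f_sub), tidy(f_dir))
})

test_that("trait regressions: sign recovery, robust/classical agreement, degenerate SRS", {
  # positive delta-SRS association injected in the ASD group only
  hits <- vapply(1:30, function(s) {
    coh <- simulate_cohort(23, 31, seed = s)
    m <- simulate_metrics(coh, bands = "beta", metrics = "SW",
                          srs_assoc = list(metric = "SW", band = "beta",
                                           slope = c(TD = 0, ASD = 150),
                                           sd = 8),
                          seed = 3000 + s)
    f <- fit_srs_model(compute_delta(m), "SW", "beta", group = "ASD")
    tidy(f)$estimate[tidy(f)$term == "delta"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # homoscedastic data: HC1 and classical SEs agree within 15% at n = 54
  ratios <- vapply(1:5, function(s) {
    coh <- simulate_cohort(23, 31, seed = 10 + s)
    m <- simulate_metrics(coh, bands = "beta", metrics = "SW", seed = 20 + s)
    d <- compute_delta(m)
    fr <- fit_srs_model(d, "SW", "beta", robust = TRUE)
    fc <- fit_srs_model(d, "SW", "beta", robust = FALSE)
    se_r <- tidy(fr)$std_error[tidy(fr)$term == "delta"]
    se_c <- tidy(fc)$std_error[tidy(fc)$term == "delta"]
    se_r / se_c
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1), 0.15)
  # constant SRS -> zero slopes
  coh <- simulate_cohort(10, 10, seed = 30)
  m <- simulate_metrics(coh, bands = "beta", metrics = "SW", seed = 31)
  m$srs_raw_total <- 50
  f0 <- suppressWarnings(fit_srs_model(compute_delta(m), "SW", "beta"))
  slopes <- tidy(f0)$estimate[tidy(f0)$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-10))
})

test_that("baseline-dependence slope is -1 for iid conditions and ~0 for added noise", {
  # iid DR and EO: regression to the mean gives slope -1
  covers <- vapply(1:40, function(s) {
    coh <- simulate_cohort(23, 31, seed = s)
    m <- simulate_metrics(coh, bands = "beta", metrics = "SW",
                          sigma_participant = 0, sigma_resid = 0.05,
                          seed = 4000 + s)
    f <- fit_baseline_model(compute_delta(m), "SW", "beta")
    tt <- tidy(f)[tidy(f)$term == "baseline", ]
    c(tt$ci_lo <= -1 && -1 <= tt$ci_hi, tt$estimate)
  }, numeric(2))
  expect_gte(mean(covers[1, ]), 0.85)              # nominal 95% coverage
  expect_lt(abs(mean(covers[2, ]) + 1), 0.1)       # mean estimate near -1
  expect_equal(fit_baseline_model(compute_delta(
    simulate_metrics(cohort_small(8), bands = "beta", metrics = "SW",
                     sigma_participant = 0, seed = 4)
  ), "SW", "beta")$alpha_corrected, 0.01)
  # EO = DR + independent noise: cov(X, eps) = 0 -> slope ~0
  slopes <- vapply(1:40, function(s) {
    coh <- simulate_cohort(23, 31, seed = s)
    set.seed(5000 + s)
    dr <- 1 + rnorm(nrow(coh), 0, 0.05)
    eo <- dr + rnorm(nrow(coh), 0, 0.05)
    m <- dplyr::bind_rows(
      dplyr::mutate(coh, condition = factor("DR", c("DR", "EO")), value = dr),
      dplyr::mutate(coh, condition = factor("EO", c("DR", "EO")), value = eo)
    ) |>
      dplyr::mutate(band = "beta", metric = "SW", kappa = 0.2)
    f <- fit_baseline_model(compute_delta(m), "SW", "beta")
    tidy(f)$estimate[tidy(f)$term == "baseline"]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.1)
  # EO identical to DR: all coefficients zero
  coh <- cohort_small(8)
  m <- simulate_metrics(coh, bands = "beta", metrics = "SW", seed = 7)
  m$value <- ave(m$value, m$participant_id, FUN = function(v) v[1])
  fz <- fit_baseline_model(compute_delta(m), "SW", "beta")
  expect_true(all(abs(tidy(fz)$estimate) < 1e-10))
})

test_that("residualize produces covariate-orthogonal, centred residuals matching the projection oracle", {
  coh <- simulate_cohort(15, 15, seed = 8)
  out <- residualize(coh, "srs_raw_total", by_group = TRUE)
  for (g in c("ASD", "TD")) {
    sub <- out[out$diagnosis == g, ]
    X <- model.matrix(~ age_months + sex, data = sub)
    prods <- crossprod(X, sub$srs_raw_total_adj)
    expect_true(all(abs(prods) < 1e-8))
    expect_lt(abs(mean(sub$srs_raw_total_adj)), 1e-10)
    # explicit hat-matrix oracle
    H <- X %*% solve(crossprod(X)) %*% t(X)
    r_oracle <- as.numeric((diag(nrow(sub)) - H) %*% sub$srs_raw_total)
    expect_equal(sub$srs_raw_total_adj, r_oracle, tolerance = 1e-10)
  }
  out2 <- residualize(coh, "srs_raw_total", by_group = FALSE)
  expect_lt(abs(mean(out2$srs_raw_total_adj)), 1e-10)
})

test_that("diagnostics report sane summaries and flag constructed heteroscedasticity", {
  m <- simulate_metrics(cohort_small(15), bands = "beta", metrics = "SW",
                        seed = 9)
  f <- fit_condition_model(m, "SW", "beta")
  dg <- model_diagnostics(f)
  expect_true(is.finite(dg$summary$resid_fitted_slope))
  expect_false(is.na(dg$summary$resid_skewness))
  expect_gt(length(dg$ranef), 2)
  # for least squares the residual-vs-fitted slope is 0 by construction
  d_ols <- compute_delta(m)
  f_ols <- fit_baseline_model(d_ols, "SW", "beta")
  expect_lt(abs(model_diagnostics(f_ols)$summary$resid_fitted_slope), 1e-10)
  # residual skewness is small for a well-specified Gaussian fit, most of the time
  skews <- vapply(1:20, function(s) {
    mm <- simulate_metrics(cohort_small(15, seed = s), bands = "beta",
                           metrics = "SW", seed = 100 + s)
    abs(model_diagnostics(fit_condition_model(mm, "SW", "beta"))$summary$resid_skewness)
  }, numeric(1))
  expect_gte(mean(skews < 0.5), 0.9)
  # constructed heteroscedasticity: residual spread grows with the mean
  set.seed(99)
  n <- 200
  d <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:n),
    diagnosis = factor(rep(c("TD", "ASD"), n / 2), c("TD", "ASD")),
    age_months = sample(44:109, n, TRUE),
    sex = factor(sample(c("female", "male"), n, TRUE), c("female", "male")),
    srs_raw_total = runif(n, 30, 90),
    x = runif(n, 0, 1)
  )
  d$delta <- 2 * d$x + rnorm(n, 0, 0.1 + 2 * d$x)
  d$baseline <- d$x; d$metric <- "SW"; d$band <- "beta"
  fh <- fit_baseline_model(d, "SW", "beta")
  expect_true(model_diagnostics(fh)$summary$heteroscedastic)
})

test_that("the interaction gate controls which cells get follow-up analyses", {
  coh <- simulate_cohort(23, 31, seed = 40)
  m <- simulate_metrics(coh, bands = c("beta", "alpha"), metrics = c("SW", "C"),
                        effects = list(SW.beta = c(interaction = 0.3)),
                        sigma_participant = 0.03, sigma_resid = 0.03,
                        seed = 41)
  res <- condition_analysis(m)
  expect_equal(nrow(res$condition), 4 * 6)         # 4 cells x 6 terms
  expect_true(all(c("SW") %in% res$gated_cells$metric))
  expect_true(nrow(res$gated_cells) >= 1)
  expect_true(all(paste(res$groupwise$metric, res$groupwise$band) %in%
                    paste(res$gated_cells$metric, res$gated_cells$band)))
  # baseline models run for every cell regardless of the gate
  expect_equal(dplyr::n_distinct(res$baseline$metric, res$baseline$band), 4)
  # override: follow-ups everywhere
  res_all <- condition_analysis(m, gate = FALSE)
  expect_equal(nrow(res_all$gated_cells), 4)
  expect_equal(dplyr::n_distinct(res_all$srs$metric, res_all$srs$band), 4)
})
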