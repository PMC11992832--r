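test_that("pearson_test matches hand-computed and reference values", {
  expect_equal(pearson_test(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_test(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearson_test(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)

  set.seed(88)
  for (i in 1:20) {
    x <- rnorm(sample(5:60, 1))
    y <- rnorm(length(x)) + 0.3 * x
    ours <- pearson_test(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_identical(ours$df, length(x) - 2L)
  }
})

test_that("degenerate correlation inputs raise explicit errors", {
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)),
               class = "asrt_undefined_correlation")
  expect_error(pearson_test(1:2, 1:2), class = "asrt_precondition_error")
  expect_error(pearson_test(1:3, 1:4))
})

test_that("sidak adjustment matches the closed form and its properties", {
  expect_equal(sidak_adjust(0.01, m = 3), 0.029701, tolerance = 1e-12)
  expect_identical(sidak_adjust(0.2, m = 1), 0.2)
  expect_identical(sidak_adjust(1, m = 7), 1)
  expect_identical(sidak_adjust(0, m = 7), 0)

  p <- sort(runif(25))
  for (m in c(1, 2, 6, 15)) {
    adj <- sidak_adjust(p, m = m)
    expect_equal(adj, 1 - (1 - p)^m, tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj) >= 0))          # monotone in p
    expect_true(all(sidak_adjust(p, m + 1) >= adj)) # monotone in m
  }
  expect_error(sidak_adjust(1.2), class = "asrt_precondition_error")
})

test_that("nakagawa_r2 components combine as specified", {
  r2 <- nakagawa_r2(1, var_random = 1, var_resid = 2)
  expect_equal(r2$marginal, 0.25)
  expect_equal(r2$conditional, 0.50)
  expect_equal(r2$icc_adjusted, 1 / 3)
  r0 <- nakagawa_r2(2, var_random = 0, var_resid = 1)
  expect_equal(r0$marginal, r0$conditional)
  expect_equal(nakagawa_r2(0, var_random = 1, var_resid = pi^2 / 3)$marginal, 0)
  expect_error(nakagawa_r2(-1, var_random = 1, var_resid = 1),
               class = "asrt_precondition_error")
})

test_that("nakagawa_r2 on a fitted intercept model matches the plug-in form", {
  set.seed(5)
  d <- data.frame(id = factor(rep(1:30, each = 20)))
  u <- rnorm(30, 0, 2)
  d$x <- rnorm(600)
  d$y <- 1 + 0.8 * d$x + u[d$id] + rnorm(600, 0, 1.5)
  m <- lme4::lmer(y ~ x + (1 | id), data = d)
  ours <- nakagawa_r2(m)
  vf <- var(as.numeric(lme4::getME(m, "X") %*% lme4::fixef(m)))
  vr <- as.data.frame(lme4::VarCorr(m))$vcov[1]
  vres <- stats::sigma(m)^2
  manual <- nakagawa_r2(vf, var_random = vr, var_resid = vres)
  expect_equal(ours$marginal, manual$marginal, tolerance = 1e-9)
  expect_equal(ours$conditional, manual$conditional, tolerance = 1e-9)
  expect_equal(ours$icc_adjusted, manual$icc_adjusted, tolerance = 1e-9)
  expect_gte(ours$conditional, ours$marginal)
})

test_that("RT model recovers a null fit on no-effect data", {
  design <- design_spec("study1", n_blocks = 10)
  spec <- cohort_spec(6, means = c(learn_asym = 0, practice_amp = 0,
                                   theta_rt = 0, sigma_rt = 20),
                      sds = c(learn_asym = 0, practice_amp = 0,
                              mu_rt = 10, sigma_rt = 0),
                      noise_family = "normal", seed = 33)
  sim <- simulate_cohort(design, spec)
  rt_f <- filter_trials(sim$trials, analysis = "rt")
  fit <- fit_rt_model(rt_f, model_spec("log_rt", random = "no_time_slope",
                                       ddf = "asymptotic"))
  est <- fit$fixef$estimate[fit$fixef$term != "(Intercept)"]
  expect_true(all(abs(est) < 0.02)) # log scale; effects are zero
  expect_true(fit$converged)
  expect_identical(fit$spec$outcome, "log_rt")
  expect_gte(fit$r2$conditional, fit$r2$marginal)
})

test_that("RT model detects a strong triplet effect and reports Type III tests", {
  sim <- small_sim()
  rt_f <- filter_trials(sim$trials, analysis = "rt")
  fit <- fit_rt_model(rt_f, model_spec("log_rt", random = "no_time_slope"))
  expect_identical(fit$anova$test[1], "F")
  expect_true(all(c("time", "triplet", "ocir_c", "time:triplet:ocir_c")
                  %in% fit$anova$term))
  expect_true(all(fit$anova$p_value >= 0 & fit$anova$p_value <= 1,
                  na.rm = TRUE))
})

test_that("accuracy model tests terms by likelihood ratio with correct dfs", {
  sim <- small_sim()
  acc_f <- filter_trials(sim$trials, analysis = "accuracy")
  fit <- fit_accuracy_model(acc_f,
                            model_spec("accuracy", random = "no_time_slope"),
                            aggregate = TRUE)
  expect_identical(unique(fit$anova$test), "LRT")
  expect_identical(nrow(fit$anova), 7L)
  expect_true(all(fit$anova$df1 == 1)) # 2-level factors, continuous OCI-R
  expect_true(all(fit$anova$p_value > 0 & fit$anova$p_value <= 1))
  expect_true(fit$aggregated)
})

test_that("an all-correct outcome raises a separation error", {
  sim <- small_sim()
  acc <- filter_trials(sim$trials, analysis = "accuracy")$trials
  acc$correct <- 1L
  expect_error(fit_accuracy_model(acc), class = "asrt_separation_error")
})

test_that("cell contrasts are Sidak-adjusted over the pairwise family", {
  sim <- small_sim()
  rt_f <- filter_trials(sim$trials, analysis = "rt")
  fit <- fit_rt_model(rt_f, model_spec("log_rt", random = "no_time_slope",
                                       ddf = "asymptotic"))
  ctr <- cell_contrasts(fit, ~ time * triplet, df_method = "asymptotic")
  k <- choose(4L, 2L) # 2 epochs x 2 triplet types
  k <- as.integer(k)
  expect_identical(nrow(ctr), k)
  expect_identical(unique(ctr$m), k)
  expect_equal(ctr$p_sidak, sidak_adjust(ctr$p_value, m = k))
  expect_true(all(ctr$p_sidak >= ctr$p_value))
  # response scale: differences are in milliseconds, not log units
  expect_true(any(abs(ctr$estimate) > 1))

  emm <- emmeans::emmeans(fit$model, ~ time * triplet,
                          lmer.df = "asymptotic")
  ref <- as.data.frame(emmeans::contrast(emmeans::regrid(emm),
                                         method = "pairwise",
                                         adjust = "sidak"))
  expect_equal(ctr$p_sidak, ref$p.value, tolerance = 1e-8)
})
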