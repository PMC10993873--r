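test_that("AICc matches its closed form and converges to AIC", {
  expect_equal(aicc(100, k = 5, n = 40), 100 + 60 / 34, tolerance = 1e-12)
  expect_equal(aicc(100, k = 5, n = 1e4) - 100, 60 / (1e4 - 6))
  expect_lt(aicc(100, k = 5, n = 1e4) - 100, 0.01)
  expect_identical(aicc(100, k = 5, n = 6), Inf)
  # fitted-model path agrees with the closed form
  fit <- lm(mpg ~ wt + hp, data = mtcars)
  k <- attr(logLik(fit), "df")
  expect_equal(aicc(fit), AIC(fit) + 2 * k * (k + 1) / (nrow(mtcars) - k - 1))
})

test_that("perfusion model set never combines rrMTT with rrCBF or rrCBV", {
  set <- strokefate:::perfusion_model_set()
  expect_length(set, 6L)
  for (tm in set)
    expect_false("rrMTT" %in% tm && any(c("rrCBF", "rrCBV") %in% tm))
})

test_that("multi-model inference ranks by AICc with stable diagnostics", {
  spec <- cohort_effect_spec(seed = 61L)
  st <- cohort_subject_table(make_cohort(spec))
  r1 <- multimodel_inference(st, "volume_change")
  r2 <- multimodel_inference(st, "volume_change")
  expect_identical(r1$table, r2$table)           # determinism
  expect_false(is.unsorted(r1$table$AICc))
  expect_equal(r1$table$dAICc[r1$table$model == "base"], 0)
  expect_true(all(c("rrCBF & rrCBV", "rrMTT", "base", "rrCBV", "rrCBF",
                    "NULL") %in% r1$table$model))
  # base model has no perfusion coefficients
  expect_false(any(grepl("rrCBF|rrCBV|rrMTT",
                         r1$coefficients[["base"]]$term)))

  rs <- multimodel_inference(st, "sds")
  expect_true(all(rs$table$r2 <= 1 & rs$table$r2 >= 0, na.rm = TRUE))

  # every ranked model keeps enough residual information for AICc
  tiny <- st[1:8, ]
  tiny$lesion_location <- rep(c("cortical", "subcortical"), 4L)
  rt <- multimodel_inference(tiny, "volume_change")
  expect_true(all(rt$table$n <= 8))
  expect_true(all(rt$table$n > rt$table$k + 1))
  expect_true(all(is.finite(rt$table$AICc)))
})

test_that("generating perfusion configuration wins the AICc ranking", {
  # rrMTT generated as a free covariate: the identifiability condition for
  # recovering the generating configuration (see cohort_effect_spec docs)
  wins <- vapply(1:40, function(i) {
    st <- cohort_subject_table(make_cohort(
      cohort_effect_spec(seed = 6200L + i, mtt_model = "independent")))
    r <- multimodel_inference(st, "volume_change")
    r$table$model[1L] == "rrCBF & rrCBV"
  }, logical(1L))
  expect_gte(mean(wins), 0.8)
})

test_that("Kenward-Roger mixed model controls the null and finds true effects", {
  # balanced duplication leaves fixed-effect estimates unchanged
  coh <- make_cohort(cohort_effect_spec(seed = 63L))
  f1 <- fit_perfusion_lmm(coh, "rrCBF", posthoc = FALSE)
  coh2 <- rbind(coh, coh)
  f2 <- fit_perfusion_lmm(coh2, "rrCBF", posthoc = FALSE)
  expect_equal(lme4::fixef(f1$model), lme4::fixef(f2$model), tolerance = 1e-6)
  expect_true(all(c("timepoint", "occlusion", "sex") %in% f1$effects$term))

  # power against a planted 2-SD time effect
  set.seed(64)
  rej <- vapply(1:40, function(i) {
    spec <- null_effect_spec(seed = 6400L + i)
    spec$rr_timepoint$day4$cbf <- 100 + 2 * 15   # 2 SD shift at day 4
    coh <- make_cohort(spec)
    f <- fit_perfusion_lmm(coh, "rrCBF", terms = "timepoint", posthoc = FALSE)
    f$effects$p[f$effects$term == "timepoint"] < 0.05
  }, logical(1L))
  expect_gt(mean(rej), 0.9)

  # Bonferroni post-hoc contrasts are exposed
  fp <- fit_perfusion_lmm(coh, "rrCBF")
  expect_s3_class(fp$posthoc, "data.frame")
  expect_equal(nrow(fp$posthoc), 3L)  # three pairwise timepoint contrasts
})

test_that("beta GLMM with log link recovers planted fraction differences", {
  set.seed(65)
  sim_once <- function(mu_ipsi, mu_contra, n = 40L) {
    d <- data.frame(subject = rep(seq_len(n), 2L),
                    hemisphere = rep(c("ipsi", "contra"), each = n))
    mu <- ifelse(d$hemisphere == "ipsi", mu_ipsi, mu_contra)
    d$f_hypo <- rbeta(2L * n, mu * 20, (1 - mu) * 20)
    fit_fraction_glmm(d, "f_hypo", ~ hemisphere)
  }
  f <- sim_once(0.2, 0.05)
  co <- f$coefficients
  est <- co$estimate[co$term == "hemisphereipsi"]
  expect_gt(est, 0)
  # back-transformed fitted means lie inside the unit interval
  mu_hat <- exp(sum(co$estimate))
  expect_true(mu_hat > 0 && mu_hat < 1)

  expect_error(fit_fraction_glmm(
    data.frame(subject = 1:4, hemisphere = "ipsi", f_hypo = c(0, 1, 0, 1)),
    "f_hypo", ~ 1), "boundary")
  expect_error(fit_fraction_glmm(
    data.frame(subject = 1:2, hemisphere = "a", f_hypo = c(0.5, 1.2)),
    "f_hypo", ~ 1), "fractions")
})

test_that("hyperacute correlations behave like Pearson's r", {
  d <- data.frame(rrMTT = 1:10, adc_lesion = 1:10)
  out <- correlate_hyperacute(d)
  expect_equal(out$r, 1)
  expect_lt(out$p, 1e-8)

  expect_error(correlate_hyperacute(data.frame(rrMTT = c(1, 1, 1),
                                               adc_lesion = 1:3)),
               "variance")
  expect_error(correlate_hyperacute(data.frame(rrMTT = c(1, NA, 2),
                                               adc_lesion = c(1, 2, NA))),
               "pairs")

  # null sampling distribution: 95% of |r| below ~0.32 at n = 40
  set.seed(66)
  rs <- replicate(400, cor(rnorm(40), rnorm(40)))
  expect_lt(abs(quantile(abs(rs), 0.95) - 0.32), 0.05)

  # planted r = 0.4 detected in roughly 72% of samples
  det <- replicate(300, {
    x <- rnorm(40); y <- 0.4 * x + sqrt(1 - 0.16) * rnorm(40)
    cor.test(x, y)$p.value < 0.05
  })
  expect_gt(mean(det), 0.58)
  expect_lt(mean(det), 0.86)
})
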