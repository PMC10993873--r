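#' Second-order corrected Akaike Information Criterion
#'
#' AICc = AIC + 2k(k+1)/(n - k - 1), with k the number of estimated
#' parameters (including the intercept, and the residual variance for
#' gaussian models) and n the number of observations.
#'
#' @param fit a fitted `lm` or `glm`, or a numeric AIC value
#' @param k number of parameters (required when `fit` is numeric)
#' @param n number of observations (required when `fit` is numeric)
#' @return AICc value
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (is.numeric(fit)) {
    if (is.null(k) || is.null(n)) stop("k and n are required with numeric AIC")
    aic <- fit
  } else {
    aic <- stats::AIC(fit)
    k <- attr(stats::logLik(fit), "df")
    n <- stats::nobs(fit)
  }
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

# Nagelkerke pseudo-R2 for a GLM. The null log-likelihood is derived from
# the stored null deviance (ll0 = ll - (null.deviance - deviance) / 2), which
# avoids refitting in the caller's environment.
nagelkerke_r2 <- function(fit) {
  n <- stats::nobs(fit)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- ll - (fit$null.deviance - fit$deviance) / 2
  cox <- 1 - exp(2 * (ll0 - ll) / n)
  cox / (1 - exp(2 * ll0 / n))
}

# Scale-and-center continuous columns of a data.frame (two-level factors and
# characters left alone), as standardized-coefficient preprocessing.
scale_continuous <- function(data, cols) {
  for (cl in cols) {
    x <- data[[cl]]
    if (is.numeric(x) && length(unique(x)) > 2L)
      data[[cl]] <- as.numeric(scale(x))
  }
  data
}

#' Linear mixed model of a relative regional perfusion index over time
#'
#' Fits `index ~ timepoint + occlusion + sex + (1 | subject)` by REML and
#' tests each fixed term with a Kenward-Roger F-test (full model against
#' the model with the term dropped). Bonferroni-adjusted pairwise
#' timepoint contrasts are reported as post-hoc tests. If the random
#' intercept is estimated singular the model is downgraded to a fixed
#' effects linear model with a warning.
#'
#' @param cohort long-format cohort table with columns `subject`,
#'   `timepoint`, `occlusion`, `sex` and the index column
#' @param index which index to model: "rrCBF", "rrCBV" or "rrMTT"
#' @param roi ROI whose rows enter the model (default "acute", the
#'   post-ischemic lesion)
#' @param ddf denominator-degrees-of-freedom method; Kenward-Roger is the
#'   default, Satterthwaite the faster fallback
#' @param terms fixed terms to test (default all three)
#' @param posthoc compute Bonferroni pairwise timepoint contrasts
#' @return list of class `perfusion_lmm`: `model`, `effects` (term, F,
#'   ndf, ddf, p), `posthoc` (or NULL), `singular`
#' @export
fit_perfusion_lmm <- function(cohort, index = c("rrCBF", "rrCBV", "rrMTT"),
                              roi = "acute",
                              ddf = c("Kenward-Roger", "Satterthwaite"),
                              terms = c("timepoint", "occlusion", "sex"),
                              posthoc = TRUE) {
  index <- match.arg(index)
  ddf <- match.arg(ddf)
  d <- cohort[cohort$hemisphere == "ipsi" & cohort$roi == roi &
                is.finite(cohort[[index]]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable rows for index ", index)
  d$subject <- factor(d$subject)
  d$timepoint <- factor(d$timepoint)
  d$occlusion <- factor(d$occlusion)
  d$sex <- factor(d$sex)
  if (length(unique(d$timepoint)) < 2L)
    stop("at least two timepoints per subject are required")
  d$.y <- d[[index]]

  rhs <- paste(terms, collapse = " + ")
  full_f <- stats::as.formula(paste(".y ~", rhs, "+ (1 | subject)"))
  fit <- lme4::lmer(full_f, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  singular <- lme4::isSingular(fit, tol = 1e-4)

  if (singular) {
    warning("singular random-effect fit; downgrading to fixed-effects lm")
    lmfit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
    an <- stats::drop1(lmfit, test = "F")
    eff <- data.frame(term = rownames(an)[-1L], F = an$`F value`[-1L],
                      ndf = an$Df[-1L],
                      ddf = stats::df.residual(lmfit),
                      p = an$`Pr(>F)`[-1L], row.names = NULL)
    model <- lmfit
  } else {
    eff <- do.call(rbind, lapply(terms, function(tm) {
      kept <- setdiff(terms, tm)
      rhs_red <- if (length(kept)) paste(kept, collapse = " + ") else "1"
      red_f <- stats::as.formula(paste(".y ~", rhs_red, "+ (1 | subject)"))
      red <- lme4::lmer(red_f, data = d, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular =
                          lme4::.makeCC(action = "ignore", tol = 1e-4)))
      if (ddf == "Kenward-Roger") {
        kr <- pbkrtest::KRmodcomp(fit, red)
        st <- kr$stats
        data.frame(term = tm, F = st$Fstat, ndf = st$ndf, ddf = st$ddf,
                   p = st$p.value)
      } else {
        a <- stats::anova(lmerTest::as_lmerModLmerTest(fit),
                          ddf = "Satterthwaite")
        i <- match(tm, rownames(a))
        data.frame(term = tm, F = a$`F value`[i], ndf = a$NumDF[i],
                   ddf = a$DenDF[i], p = a$`Pr(>F)`[i])
      }
    }))
    model <- fit
  }

  ph <- NULL
  if (posthoc && "timepoint" %in% terms) {
    emm <- emmeans::emmeans(model, "timepoint",
                            lmer.df = if (ddf == "Kenward-Roger")
                              "kenward-roger" else "satterthwaite")
    ph <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "bonferroni"))
  }
  structure(list(model = model, effects = eff, posthoc = ph,
                 singular = singular, index = index, ddf = ddf),
            class = "perfusion_lmm")
}

#' Beta-family GLMM of voxel-class fractions
#'
#' Models fractions of abnormally perfused voxels with a beta-family
#' generalized linear mixed model with log link and a random subject
#' intercept. Because the beta likelihood excludes exact 0 and 1, fractions
#' are first compressed by (y * (n - 1) + 0.5) / n. glmmTMB's default
#' starting values put the log-link intercept on the boundary, so the
#' intercept is started at log(mean(y)).
#'
#' @param data data.frame of fractions plus design columns
#' @param response name of the fraction column (values in [0, 1])
#' @param fixed right-hand-side formula of fixed effects, e.g.
#'   `~ hemisphere + roi + timepoint`
#' @param subject name of the subject (random intercept) column
#' @return list of class `fraction_glmm`: `model`, `coefficients` (fixed
#'   effects with SE, z, p), `converged`
#' @export
fit_fraction_glmm <- function(data, response = "f_hypo",
                              fixed = ~ hemisphere + roi + timepoint,
                              subject = "subject") {
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y < 0 | y > 1))
    stop("fractions must lie in [0, 1]")
  n <- length(y)
  if (all(y %in% c(0, 1))) stop("all fractions on the boundary; beta model undefined")
  data$.y <- (y * (n - 1) + 0.5) / n
  data[[subject]] <- factor(data[[subject]])
  f <- stats::as.formula(paste(".y ~", paste(deparse(fixed[[2L]]), collapse = ""),
                               "+ (1 |", subject, ")"))
  X <- stats::model.matrix(fixed, data)
  start <- list(beta = c(log(mean(data$.y)), rep(0, ncol(X) - 1L)))
  fit <- suppressWarnings(glmmTMB::glmmTMB(
    f, data = data, family = glmmTMB::beta_family(link = "log"),
    start = start))
  co <- summary(fit)$coefficients$cond
  structure(list(model = fit,
                 coefficients = data.frame(term = rownames(co),
                                           estimate = co[, 1L], se = co[, 2L],
                                           z = co[, 3L], p = co[, 4L],
                                           row.names = NULL),
                 converged = isTRUE(fit$fit$convergence == 0)),
            class = "fraction_glmm")
}

# The model set: four perfusion configurations (rrMTT never together with
# rrCBF or rrCBV), the base model without perfusion terms, and the
# intercept-only NULL model.
perfusion_model_set <- function() {
  list("rrCBF & rrCBV" = c("rrCBF", "rrCBV"),
       "rrMTT" = "rrMTT",
       "base" = character(0),
       "rrCBV" = "rrCBV",
       "rrCBF" = "rrCBF",
       "NULL" = NULL)
}

#' Multi-model inference of stroke outcome on perfusion configurations
#'
#' Regresses an outcome on occlusion duration, sex and their interaction,
#' acute ischemic volume and lesion location (nuisance terms), plus one of
#' four perfusion-index configurations: rrCBF & rrCBV, rrMTT alone, rrCBV,
#' or rrCBF (rrMTT is never combined with rrCBF or rrCBV, being their
#' quotient by the central volume theorem). A base model without perfusion
#' terms and an intercept-only NULL model complete the set. Continuous
#' predictors are scaled and centered; models are ranked by AICc and each
#' perfusion model is tested against the base model (nested F-test for the
#' gaussian outcome, likelihood-ratio chi-square for the Poisson outcome).
#'
#' @param data one row per subject with columns `volume_change` or
#'   `sds_day4`, `occlusion`, `sex`, `acute_volume`, `lesion_location`,
#'   `rrCBF`, `rrCBV`, `rrMTT`
#' @param outcome "volume_change" (gaussian) or "sds" (Poisson, log link)
#' @return list of class `model_ranking`: `table` (one row per model,
#'   sorted by AICc), `models` (fitted objects), `outcome`
#' @export
multimodel_inference <- function(data, outcome = c("volume_change", "sds")) {
  outcome <- match.arg(outcome)
  yvar <- if (outcome == "volume_change") "volume_change" else "sds_day4"
  nuisance <- c("occlusion * sex", "acute_volume", "lesion_location")
  perf_all <- c("rrCBF", "rrCBV", "rrMTT")
  need <- c(yvar, "occlusion", "sex", "acute_volume", "lesion_location",
            perf_all)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  d$sex <- factor(d$sex)
  d$occlusion <- factor(d$occlusion)
  d$lesion_location <- stats::relevel(factor(d$lesion_location,
    levels = c("cortical", "subcortical", "diencephalic")), ref = "cortical")
  d <- scale_continuous(d, c("acute_volume", perf_all))
  n <- nrow(d)

  # degenerate factors (single observed level) cannot enter the design
  if (nlevels(droplevels(d$lesion_location)) < 2L)
    nuisance <- setdiff(nuisance, "lesion_location")
  if (nlevels(droplevels(d$sex)) < 2L || nlevels(droplevels(d$occlusion)) < 2L)
    nuisance[nuisance == "occlusion * sex"] <- paste(
      c(if (nlevels(droplevels(d$occlusion)) > 1L) "occlusion",
        if (nlevels(droplevels(d$sex)) > 1L) "sex"), collapse = " + ")
  nuisance <- nuisance[nzchar(nuisance)]
  d$lesion_location <- droplevels(d$lesion_location)

  set <- perfusion_model_set()
  stopifnot(!any(vapply(set, function(tm)
    "rrMTT" %in% tm && any(c("rrCBF", "rrCBV") %in% tm), logical(1L))))

  fit_one <- function(terms) {
    rhs <- if (is.null(terms)) "1" else paste(c(nuisance, terms), collapse = " + ")
    f <- stats::as.formula(paste(yvar, "~", rhs))
    if (outcome == "volume_change") stats::lm(f, data = d)
    else stats::glm(f, data = d, family = stats::poisson(link = "log"))
  }
  models <- lapply(set, fit_one)
  base <- models[["base"]]

  rows <- lapply(names(set), function(nm) {
    m <- models[[nm]]
    k <- attr(stats::logLik(m), "df")
    if (n <= k + 1) {
      return(data.frame(model = nm, k = k, n = n, AICc = NA_real_,
                        dAICc = NA_real_, F = NA_real_, p_vs_base = NA_real_,
                        rmse = NA_real_, df_residual = NA_real_,
                        r2 = NA_real_, dispersion = NA_real_, unfit = TRUE))
    }
    a <- aicc(m)
    cmp <- c(F = NA_real_, p = NA_real_)
    if (!nm %in% c("base", "NULL")) {
      if (outcome == "volume_change") {
        an <- stats::anova(base, m)
        cmp <- c(F = an$F[2L], p = an$`Pr(>F)`[2L])
      } else {
        an <- stats::anova(base, m, test = "Chisq")
        cmp <- c(F = an$Deviance[2L], p = an$`Pr(>Chi)`[2L])
      }
    }
    r2 <- if (outcome == "volume_change") summary(m)$adj.r.squared
          else nagelkerke_r2(m)
    # Pearson dispersion: overdispersion diagnostic for the Poisson branch
    disp <- if (outcome == "sds")
      sum(stats::residuals(m, type = "pearson")^2) / stats::df.residual(m)
    else NA_real_
    data.frame(model = nm, k = k, n = n, AICc = a, dAICc = NA_real_,
               F = cmp[[1L]], p_vs_base = cmp[[2L]],
               rmse = sqrt(mean(stats::residuals(m, type = "response")^2)),
               df_residual = stats::df.residual(m), r2 = r2,
               dispersion = disp, unfit = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[!tab$unfit, , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[tab$model == "base"]
  tab <- tab[order(tab$AICc), , drop = FALSE]
  rownames(tab) <- NULL

  coefs <- lapply(models, function(m) {
    ci <- suppressMessages(stats::confint.default(m))
    data.frame(term = names(stats::coef(m)), beta = stats::coef(m),
               lo = ci[, 1L], hi = ci[, 2L], row.names = NULL)
  })
  structure(list(table = tab, models = models, coefficients = coefs,
                 outcome = outcome, n = n),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Multi-model inference for", x$outcome, "(n =", x$n, "), ranked by AICc\n")
  print(x$table[, c("model", "k", "AICc", "dAICc", "F", "p_vs_base", "rmse",
                    "df_residual", "r2")], digits = 4L)
  invisible(x)
}

#' Correlations between hyperacute perfusion indices and edema markers
#'
#' Pearson correlations with two-sided p-values and a configurable
#' multiplicity correction over the requested pairs.
#'
#' @param data data.frame of subject-level values
#' @param pairs list of 2-element character vectors naming column pairs
#' @param adjust p.adjust method (default "holm"; "none" for raw)
#' @return data.frame: x, y, n, r, p, p_adj
#' @export
correlate_hyperacute <- function(data, pairs = list(c("rrMTT", "adc_lesion")),
                                 adjust = "holm") {
  rows <- lapply(pairs, function(pr) {
    x <- data[[pr[1L]]]; y <- data[[pr[2L]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ",
                           paste(pr, collapse = " ~ "))
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("zero variance in ", paste(pr, collapse = " or "))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(x = pr[1L], y = pr[2L], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}
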