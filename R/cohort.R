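#' Effect structure for simulated cohorts
#'
#' Defaults emulate the reported cohort-level effect structure of the
#' experiment this pipeline targets: acute-to-subacute lesion volume
#' reduction larger in females than males (cell means averaging to about
#' -31 vs -8 percent with between-subject SD near 30), hyperacute rrCBF
#' coupling positively and rrCBV negatively to volume change (standardized
#' magnitudes 15.5 and 16.8), rrMTT carrying no independent effect, relative
#' perfusion collapsing to ~35 percent of contralateral during occlusion and
#' recovering toward (males) supranormal levels by day four, delayed-injury
#' tissue relatively hypoperfused shortly after recanalization, and an
#' integer sensorimotor deficit score (SDS, 0-22) linked to lesion
#' evolution.
#'
#' @param n_per_group subjects per sex x occlusion cell (>= 2)
#' @param vc_cell_mean named list of volume-change cell means (percent) for
#'   `F45`, `F90`, `M45`, `M90`
#' @param vc_sd residual between-subject volume-change SD after couplings
#' @param beta_cbf,beta_cbv,beta_mtt coupling of volume change to the
#'   standardized hyperacute (0.5 h) rr indices
#' @param rr_timepoint list per timepoint of lesion-ROI rr index means/SDs;
#'   day-4 means may be split by sex (named vector `c(F = , M = )`)
#' @param subject_sd SD of the per-subject random intercept shared across
#'   timepoints
#' @param mtt_model how the rrMTT covariate is generated: "ratio" (default)
#'   ties it to 100 * rrCBV / rrCBF plus `mtt_noise_sd` of decoupling noise,
#'   as the central volume theorem implies for the underlying maps;
#'   "independent" draws it as a free covariate (mean 100, SD
#'   `mtt_independent_sd`), the identifiability condition required when the
#'   generating regression model itself is to be recovered from the data
#' @param mtt_noise_sd decoupling noise of rrMTT around 100 * rrCBV / rrCBF
#'   (mean-of-ratios vs ratio-of-means plus MTT estimation error)
#' @param mtt_independent_sd SD of rrMTT under `mtt_model = "independent"`
#' @param roi_noise_sd SD of per-ROI deviations from the lesion-level index
#' @param delayed_hypo_05h ipsilateral vs contralateral hypoperfused-voxel
#'   fraction means in delayed-injury tissue at 0.5 h
#' @param day4_hyper ipsilateral hyperperfused-fraction means at day 4 per
#'   ROI (contralateral fraction mean in `contra`)
#' @param fraction_precision beta-distribution precision of fractions
#' @param sds_mean baseline SDS mean; `sds_b_vc`, `sds_b_mtt` log-link
#'   couplings of day-4 SDS to standardized volume change and rrMTT
#' @param seed RNG seed
#' @return list of class `cohort_effect_spec`
#' @export
cohort_effect_spec <- function(n_per_group = 10L,
                               vc_cell_mean = list(F45 = -38, F90 = -25,
                                                   M45 = -12, M90 = -4),
                               vc_sd = 19.4,
                               beta_cbf = 15.5, beta_cbv = -16.8,
                               beta_mtt = 0,
                               rr_timepoint = list(
                                 occlusion = list(cbf = 35, cbf_sd = 12,
                                                  cbv = 55, cbv_sd = 12),
                                 post_0.5h = list(cbf = 100, cbf_sd = 15,
                                                  cbv = 100, cbv_sd = 15),
                                 day4 = list(cbf = c(F = 112, M = 130),
                                             cbf_sd = 20,
                                             cbv = c(F = 105, M = 118),
                                             cbv_sd = 18)),
                               subject_sd = 8,
                               mtt_model = c("ratio", "independent"),
                               mtt_noise_sd = 5,
                               mtt_independent_sd = 15,
                               roi_noise_sd = 5,
                               delayed_hypo_05h = c(ipsi = 0.20, contra = 0.05),
                               day4_hyper = c(core = 0.35, salvageable = 0.30,
                                              delayed = 0.25, contra = 0.10),
                               fraction_precision = 20,
                               sds_mean = 8, sds_b_vc = 0.3, sds_b_mtt = -0.1,
                               seed = NULL) {
  mtt_model <- match.arg(mtt_model)
  stopifnot(n_per_group >= 2L, vc_sd > 0, subject_sd >= 0,
            fraction_precision > 0, sds_mean > 0)
  if (mtt_noise_sd < 0 || roi_noise_sd < 0) stop("SDs must be nonnegative")
  structure(as.list(environment()), class = "cohort_effect_spec")
}

rbeta_mu <- function(n, mu, phi) {
  mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  stats::rbeta(n, mu * phi, (1 - mu) * phi)
}

#' Simulate a long-format cohort table with known effect structure
#'
#' One row per subject x timepoint x ROI x hemisphere, carrying relative
#' regional perfusion indices (ipsilateral rows), hypo/normo/hyperperfused
#' voxel fractions, lesion volumes and volume change, lesion location and
#' SDS. Group means converge to the specification as the cell size grows;
#' identical seeds give identical tables.
#'
#' @param spec a [cohort_effect_spec()]
#' @return data.frame of class `cohort_table`
#' @export
make_cohort <- function(spec = cohort_effect_spec()) {
  stopifnot(inherits(spec, "cohort_effect_spec"))
  maybe_set_seed(spec$seed)
  cells <- expand.grid(sex = c("F", "M"), occlusion = c(45L, 90L),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sex <- rep(cells$sex, each = spec$n_per_group)
  occ <- rep(cells$occlusion, each = spec$n_per_group)
  ns <- length(sex)
  subject <- sprintf("S%03d", seq_len(ns))
  tps <- c("occlusion", "post_0.5h", "day4")
  rois <- c("acute", "core", "salvageable", "delayed")

  subj_int <- stats::rnorm(ns, 0, spec$subject_sd)
  z_cbf <- stats::rnorm(ns); z_cbv <- stats::rnorm(ns)

  # subject x timepoint lesion-level rr indices
  rr_mu <- function(tp, par) {
    m <- spec$rr_timepoint[[tp]][[par]]
    if (length(m) > 1L) unname(m[sex]) else rep(m, ns)
  }
  cbf_st <- cbv_st <- mtt_st <- matrix(NA_real_, ns, length(tps),
                                       dimnames = list(NULL, tps))
  for (tp in tps) {
    zc <- if (tp == "post_0.5h") z_cbf else stats::rnorm(ns)
    zv <- if (tp == "post_0.5h") z_cbv else stats::rnorm(ns)
    cbf_st[, tp] <- pmax(rr_mu(tp, "cbf") + subj_int +
                           spec$rr_timepoint[[tp]]$cbf_sd * zc, 5)
    cbv_st[, tp] <- pmax(rr_mu(tp, "cbv") + subj_int +
                           spec$rr_timepoint[[tp]]$cbv_sd * zv, 5)
    mtt_st[, tp] <- if (spec$mtt_model == "independent") {
      pmax(stats::rnorm(ns, 100, spec$mtt_independent_sd), 5)
    } else {
      100 * cbv_st[, tp] / cbf_st[, tp] +
        stats::rnorm(ns, 0, spec$mtt_noise_sd)
    }
  }

  cellmean <- unlist(spec$vc_cell_mean)
  vc_mu <- unname(cellmean[paste0(sex, occ)])
  volume_change <- pmax(vc_mu + spec$beta_cbf * z_cbf +
                          spec$beta_cbv * z_cbv +
                          spec$beta_mtt * stats::rnorm(ns) +
                          stats::rnorm(ns, 0, spec$vc_sd), -95)
  acute_volume <- pmax(stats::rnorm(ns, 0.17, 0.09), 0.02) * 500
  lesion_location <- sample(c("cortical", "subcortical", "diencephalic"),
                            ns, replace = TRUE, prob = c(0.45, 0.40, 0.15))
  lam <- spec$sds_mean *
    exp(spec$sds_b_vc * (volume_change - mean(cellmean)) / 30 +
        spec$sds_b_mtt * (mtt_st[, "post_0.5h"] - 100) / 15)
  sds_day4 <- pmin(stats::rpois(ns, lam), 22L)
  sds_baseline <- pmin(stats::rpois(ns, 10), 22L)

  g <- expand.grid(hemisphere = c("ipsi", "contra"), roi = rois,
                   timepoint = tps, s = seq_len(ns),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nr <- nrow(g)
  si <- g$s
  tpi <- g$timepoint
  idx_st <- cbind(si, match(tpi, tps))

  roi_off <- ifelse(g$roi == "acute", 0, stats::rnorm(nr, 0, spec$roi_noise_sd))
  cbf_r <- cbf_st[idx_st] + roi_off -
    ifelse(g$roi == "delayed" & tpi == "post_0.5h", 25, 0)
  cbv_r <- cbv_st[idx_st] + roi_off
  mtt_r <- if (spec$mtt_model == "independent") {
    mtt_st[idx_st] + ifelse(g$roi == "acute", 0,
                            stats::rnorm(nr, 0, spec$roi_noise_sd))
  } else {
    100 * pmax(cbv_r, 5) / pmax(cbf_r, 5) +
      stats::rnorm(nr, 0, spec$mtt_noise_sd)
  }
  ipsi <- g$hemisphere == "ipsi"

  hypo_mu <- rep(0.05, nr)
  hyper_mu <- rep(0.08, nr)
  hypo_mu[ipsi & tpi == "occlusion"] <- 0.7
  hypo_mu[g$roi == "delayed" & tpi == "post_0.5h"] <-
    ifelse(ipsi[g$roi == "delayed" & tpi == "post_0.5h"],
           spec$delayed_hypo_05h[["ipsi"]], spec$delayed_hypo_05h[["contra"]])
  d4 <- tpi == "day4"
  hyper_mu[d4 & !ipsi] <- spec$day4_hyper[["contra"]]
  for (r in c("core", "salvageable", "delayed"))
    hyper_mu[d4 & ipsi & g$roi == r] <- spec$day4_hyper[[r]]
  hyper_mu[d4 & ipsi & g$roi == "acute"] <-
    mean(spec$day4_hyper[c("core", "salvageable")])

  f_hypo <- rbeta_mu(nr, hypo_mu, spec$fraction_precision)
  f_hyper <- pmin(rbeta_mu(nr, hyper_mu * (1 - f_hypo),
                           spec$fraction_precision), 1 - f_hypo)

  out <- data.frame(
    subject = subject[si], sex = sex[si], occlusion = occ[si],
    timepoint = tpi, roi = g$roi, hemisphere = g$hemisphere,
    rrCBF = ifelse(ipsi, cbf_r, NA_real_),
    rrCBV = ifelse(ipsi, cbv_r, NA_real_),
    rrMTT = ifelse(ipsi, mtt_r, NA_real_),
    f_hypo = f_hypo, f_normo = 1 - f_hypo - f_hyper, f_hyper = f_hyper,
    volume_change = volume_change[si], acute_volume = acute_volume[si],
    lesion_location = lesion_location[si],
    sds_baseline = sds_baseline[si], sds_day4 = sds_day4[si])
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Collapse a cohort table to one row per subject
#'
#' Subject-level view used by the outcome models: hyperacute (0.5 h)
#' lesion-ROI rr indices plus the outcome and nuisance columns.
#'
#' @param cohort a `cohort_table`
#' @param timepoint timepoint supplying the perfusion indices
#' @return data.frame, one row per subject
#' @export
cohort_subject_table <- function(cohort, timepoint = "post_0.5h") {
  d <- cohort[cohort$timepoint == timepoint & cohort$roi == "acute" &
                cohort$hemisphere == "ipsi", , drop = FALSE]
  keep <- c("subject", "sex", "occlusion", "rrCBF", "rrCBV", "rrMTT",
            "volume_change", "acute_volume", "lesion_location",
            "sds_baseline", "sds_day4")
  keep <- intersect(keep, names(d))
  out <- d[!duplicated(d$subject), keep, drop = FALSE]
  rownames(out) <- NULL
  out
}
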