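#' Pipeline configuration with study defaults
#'
#' Collects every tunable of the per-subject pipeline. Defaults equal the
#' study values where the protocol states one (2-SD lesion thresholds,
#' 85-115 percent binning band, oscillation index 0.17, CBV truncation at
#' the 400th image, 30 uL inclusion volume); remaining parameters carry the
#' package defaults documented on the respective functions.
#'
#' @param threshold_sd lesion threshold width in contralateral SDs
#' @param binning_band normoperfusion band (percent of contralateral median)
#' @param oi_threshold oscillation-index regularization limit
#' @param truncation_index CBV integration cutoff (frame ordinal)
#' @param baseline_window pre-bolus frames for DSC baseline
#' @param min_cluster_voxels,closing_radius lesion-mask cleanup parameters
#' @param inclusion_min_ul minimum acute lesion volume for inclusion (uL)
#' @param aif_k curves averaged into the arterial reference
#' @param csf_adc_max,csf_t2_max CSF-like parameter cutoffs
#' @param t2_weighted use S^2 variance-stabilizing weights in the T2 fit
#'   (recommended: the last echo sits near the noise floor)
#' @param seed base RNG seed for cohort simulation
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(threshold_sd = 2, binning_band = c(85, 115),
                            oi_threshold = 0.17, truncation_index = 400L,
                            baseline_window = c(20L, 170L),
                            min_cluster_voxels = 8L, closing_radius = 1L,
                            inclusion_min_ul = 30, aif_k = 10L,
                            csf_adc_max = 1.2e-3, csf_t2_max = 90,
                            t2_weighted = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Tunables that differ from the study defaults (echoed in reports).
config_deviations <- function(config) {
  ref <- unclass(pipeline_config())
  cur <- unclass(config)
  changed <- names(ref)[!vapply(names(ref), function(n)
    isTRUE(all.equal(ref[[n]], cur[[n]])), logical(1L))]
  cur[changed]
}

# Round-trip a pipeline configuration through JSON.
config_to_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  cfg <- do.call(pipeline_config, x[names(x) %in% names(formals(pipeline_config))])
  cfg
}

#' Run the full per-subject pipeline on raw volumes
#'
#' Chains the analysis stages in acquisition order: ADC fitting from the
#' occlusion diffusion data and T2 fitting from the day-4 multi-echo data;
#' contralateral reference statistics and 2-SD thresholding; cluster-size /
#' closing mask cleanup; tissue-fate parcellation with mirrored homologues;
#' volume metrics, volume change and lesion location; and, per timepoint
#' with DSC data, perfusion maps and the ROI perfusion profile. Subjects
#' whose acute lesion is smaller than the inclusion volume are flagged
#' excluded. Missing timepoints yield a partial run with the gaps recorded
#' in `missing_timepoints`.
#'
#' @param record a `subject_images` object from [simulate_subject()], a
#'   list with the same structure read from disk, or a zero-argument
#'   function returning one (lazy generation keeps raw 4D data out of
#'   memory between subjects in cohort runs)
#' @param config a [pipeline_config()]
#' @param keep_maps retain the per-timepoint perfusion maps in the result
#'   (they are large; cohort runs drop them)
#' @return list of class `subject_result`: `profile` rows (long format),
#'   `summary` (one row), `fate`, `maps` per timepoint, `included`
#' @export
run_subject <- function(record, config = pipeline_config(),
                        keep_maps = TRUE) {
  if (is.function(record)) record <- record()
  atlas <- record$phantom
  tps <- c("occlusion", "post_0.5h", "day4")
  have <- intersect(tps, names(record$timepoints))
  missing_tp <- setdiff(tps, have)

  # --- parametric maps ---------------------------------------------------
  if (!"occlusion" %in% have)
    stop("occlusion timepoint (acute diffusion data) is required")
  occ <- record$timepoints[["occlusion"]]
  adc_fit <- fit_adc(occ$dwi$b0, occ$dwi$dwi, occ$dwi$b)
  adc_map <- adc_fit$values

  t2_map <- NULL
  if ("day4" %in% have) {
    d4 <- record$timepoints[["day4"]]
    t2_fit <- fit_t2(d4$echoes$echoes, d4$echoes$te,
                     weighted = isTRUE(config$t2_weighted))
    t2_map <- t2_fit$values
  }

  # --- segmentation ------------------------------------------------------
  ref_adc <- reference_stats(adc_map, atlas, "adc",
                             csf_adc_max = config$csf_adc_max,
                             csf_t2_max = config$csf_t2_max)
  acute <- threshold_lesion(adc_map, ref_adc, atlas, "adc",
                            n_sd = config$threshold_sd,
                            csf_adc_max = config$csf_adc_max,
                            csf_t2_max = config$csf_t2_max)
  acute <- clean_mask(acute, config$min_cluster_voxels, config$closing_radius)

  subacute <- array(FALSE, dim = dim(acute))
  if (!is.null(t2_map)) {
    ref_t2 <- reference_stats(t2_map, atlas, "t2",
                              csf_adc_max = config$csf_adc_max,
                              csf_t2_max = config$csf_t2_max)
    subacute <- threshold_lesion(t2_map, ref_t2, atlas, "t2",
                                 n_sd = config$threshold_sd,
                                 csf_adc_max = config$csf_adc_max,
                                 csf_t2_max = config$csf_t2_max)
    subacute <- clean_mask(subacute, config$min_cluster_voxels,
                           config$closing_radius)
  }

  fate <- classify_fate(acute, subacute)
  hemi_mask <- atlas$brain & atlas$hemisphere == 2L
  vm <- volume_metrics(fate, hemi_mask, atlas$voxel_volume_ul,
                       config$inclusion_min_ul)
  included <- attr(vm, "included")
  vc <- if (vm$volume_ul[vm$roi == "acute"] > 0) {
    volume_change(vm$volume_ul[vm$roi == "acute"],
                  vm$volume_ul[vm$roi == "subacute"])
  } else NA_real_
  loc <- lesion_location(acute, atlas)

  # --- perfusion per timepoint -------------------------------------------
  contra_mask <- atlas$brain & atlas$hemisphere == 1L
  homols <- fate_homologues(fate, atlas$midline_axis)
  quantify <- contra_mask | fate$acute | fate$subacute |
    Reduce(`|`, homols)
  profiles <- list()
  maps <- list()
  adc_lesion_05h <- NA_real_
  for (tp in have) {
    rec <- record$timepoints[[tp]]
    if (is.null(rec$dsc)) next
    pm <- perfusion_maps(rec$dsc, atlas$brain, contra_mask,
                         baseline_window = config$baseline_window,
                         oi_threshold = config$oi_threshold,
                         aif_k = config$aif_k, quantify_mask = quantify)
    maps[[tp]] <- pm
    pr <- perfusion_profile(pm, fate, atlas, band = config$binning_band)
    pr <- cbind(subject = record$subject, timepoint = tp, pr)
    profiles[[tp]] <- pr
    if (tp == "post_0.5h" && any(fate$acute)) {
      adc05 <- fit_adc(rec$dwi$b0, rec$dwi$dwi, rec$dwi$b)$values
      adc_lesion_05h <- mean(adc05[fate$acute], na.rm = TRUE)
    }
  }
  profile <- if (length(profiles)) do.call(rbind, profiles) else NULL
  if (!is.null(profile)) rownames(profile) <- NULL

  summary_row <- data.frame(
    subject = record$subject,
    sex = record$sex %||% NA_character_,
    occlusion = record$occlusion %||% NA_integer_,
    acute_volume_ul = vm$volume_ul[vm$roi == "acute"],
    subacute_volume_ul = vm$volume_ul[vm$roi == "subacute"],
    acute_volume = vm$hemisphere_fraction[vm$roi == "acute"],
    volume_change = vc,
    lesion_location = loc,
    adc_lesion_05h = adc_lesion_05h,
    sds_baseline = record$sds_baseline %||% NA_integer_,
    sds_day4 = record$sds_day4 %||% NA_integer_,
    included = included,
    n_missing_timepoints = length(missing_tp))

  structure(list(profile = profile, summary = summary_row, fate = fate,
                 volume_metrics = vm,
                 maps = if (keep_maps) maps else NULL,
                 included = included,
                 missing_timepoints = missing_tp,
                 provenance = list(config = unclass(config),
                                   package_version =
                                     as.character(utils::packageVersion("strokefate")))),
            class = "subject_result")
}

#' Run the pipeline over a cohort and fit the outcome models
#'
#' Processes every subject with [run_subject()], concatenates the profile
#' and summary tables, drops excluded subjects from the statistical stage,
#' and (when the design allows) fits the multi-model inference of lesion
#' volume change. The statistics stage is skipped with a warning when any
#' modeled cell has fewer than 2 included subjects.
#'
#' @param records list of `subject_images`, or of zero-argument functions
#'   each returning one (recommended for large cohorts: raw volumes then
#'   live only while their subject is processed)
#' @param config a [pipeline_config()]
#' @param fit_models run the outcome-model stage
#' @return list of class `cohort_result`: `summary` (per subject),
#'   `profile` (long), `ranking` (volume-change [multimodel_inference()] or
#'   NULL), `excluded` subject ids
#' @export
run_cohort <- function(records, config = pipeline_config(),
                       fit_models = TRUE) {
  if (length(records) == 0L) stop("empty cohort")
  results <- lapply(records, function(r) {
    out <- run_subject(r, config = config, keep_maps = FALSE)
    out$fate <- NULL   # keep only the tabular results at cohort scale
    out
  })
  summary <- do.call(rbind, lapply(results, `[[`, "summary"))
  profile <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$profile)) return(NULL)
    r$profile
  }))
  rownames(summary) <- NULL
  if (!is.null(profile)) rownames(profile) <- NULL
  excluded <- summary$subject[!summary$included]

  ranking <- NULL
  if (fit_models) {
    inc <- summary[summary$included & is.finite(summary$volume_change), ,
                   drop = FALSE]
    # hyperacute perfusion indices from the 0.5 h acute-lesion profile
    hyper <- profile[profile$timepoint == "post_0.5h" &
                       profile$roi == "acute" &
                       profile$hemisphere == "ipsi", , drop = FALSE]
    if (nrow(hyper)) {
      w <- stats::reshape(hyper[, c("subject", "parameter", "rr_index")],
                          direction = "wide", idvar = "subject",
                          timevar = "parameter")
      names(w) <- sub("^rr_index\\.", "rr", names(w))
      names(w) <- sub("^rrcbf$", "rrCBF", names(w))
      names(w) <- sub("^rrcbv$", "rrCBV", names(w))
      names(w) <- sub("^rrmtt$", "rrMTT", names(w))
      inc <- merge(inc, w, by = "subject")
    }
    cell_n <- table(inc$sex, inc$occlusion)
    if (length(cell_n) < 4L || any(cell_n < 2L) ||
        !all(c("rrCBF", "rrCBV", "rrMTT") %in% names(inc))) {
      warning("cohort cells too small after exclusions; statistics stage skipped")
    } else {
      ranking <- multimodel_inference(inc, "volume_change")
    }
  }
  structure(list(summary = summary, profile = profile, ranking = ranking,
                 excluded = excluded,
                 provenance = list(config = unclass(config),
                                   non_default = config_deviations(config))),
            class = "cohort_result")
}
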