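#' Simulate a complete imaging subject (raw volumes at all timepoints)
#'
#' Builds a phantom whose planted acute-to-subacute volume change is drawn
#' from the sex x occlusion cell of the effect specification, then
#' generates raw acquisitions at the three timepoints with
#' timepoint-specific perfusion truth: during occlusion the lesion
#' territory is severely hypoperfused (CBF ~25 percent of contralateral,
#' delayed-injury tissue ~55 percent); 0.5 h after recanalization flow is
#' largely restored with a subject-specific hyperacute multiplier, except
#' in delayed-injury tissue which remains relatively hypoperfused; by day
#' four the (sub)acute lesion territory is hyperperfused, more strongly in
#' males. Diffusion truth carries the acute ADC drop at occlusion and
#' pseudo-normalizes afterwards; T2 truth is elevated in the subacute
#' lesion only at day 4.
#'
#' @param subject subject id string
#' @param sex "F" or "M"
#' @param occlusion occlusion duration, 45 or 90 (min)
#' @param config an [acquisition_config()] (noise applies to all series)
#' @param spec a [cohort_effect_spec()] supplying cell means
#' @param shape,voxel_size phantom grid
#' @param seed per-subject RNG seed
#' @return list of class `subject_images`: `phantom`, per-timepoint list
#'   `timepoints` with elements `dwi`, `echoes`, `dsc`, plus demographic
#'   fields and the planted `volume_change_pct`
#' @export
simulate_subject <- function(subject, sex = c("F", "M"),
                             occlusion = c(45L, 90L),
                             config = acquisition_config(noise_sd = 20),
                             spec = cohort_effect_spec(),
                             shape = c(32L, 32L, 10L),
                             voxel_size = c(0.45, 0.45, 1.2),
                             seed = 1L) {
  sex <- match.arg(as.character(sex), c("F", "M"))
  occlusion <- as.integer(occlusion)[1L]
  stopifnot(occlusion %in% c(45L, 90L))
  set.seed(as.integer(seed))

  cellmean <- unlist(spec$vc_cell_mean)[paste0(sex, occlusion)]
  vc <- max(min(stats::rnorm(1L, cellmean, 20), 120), -80)
  # size jitter capped above so the lesion cannot reach the midline
  radius <- min(max(stats::rnorm(1L, 0, 0.6), -2), 1.1)
  lesion <- lesion_spec(radii = pmax(c(6, 7, 3) + radius, 2),
                        volume_change_pct = vc)
  phantom <- make_phantom(shape, lesion, voxel_size)

  hyper_cbf <- stats::rnorm(1L, 1.0, 0.12)
  hyper_cbv <- stats::rnorm(1L, 1.0, 0.12)
  day4_mult <- if (sex == "M") 1.30 else 1.12

  lt <- phantom$lesion_truth
  healthy_adc <- make_phantom(shape, lesion_spec(
    radii = lesion$radii, volume_change_pct = vc,
    adc_drop = c(core = 0, salvageable = 0),
    t2_raise = c(core = 0, delayed = 0)), voxel_size)$truth

  tp_truth <- function(tp) {
    tr <- phantom$truth
    cbf <- tr$cbf; cbv <- tr$cbv
    adc <- tr$adc; t2 <- tr$t2
    if (tp == "occlusion") {
      cbf[lt$acute] <- cbf[lt$acute] * 0.25
      cbf[lt$delayed] <- cbf[lt$delayed] * 0.55
      cbv[lt$acute] <- cbv[lt$acute] * 0.80
      cbv[lt$delayed] <- cbv[lt$delayed] * 0.90
      t2 <- healthy_adc$t2                     # no vasogenic edema yet
    } else if (tp == "post_0.5h") {
      cbf[lt$acute] <- cbf[lt$acute] * pmax(hyper_cbf, 0.2)
      cbv[lt$acute] <- cbv[lt$acute] * pmax(hyper_cbv, 0.2)
      cbf[lt$delayed] <- cbf[lt$delayed] * 0.70
      adc <- healthy_adc$adc + 0.5 * (tr$adc - healthy_adc$adc)
      t2 <- healthy_adc$t2 + 0.3 * (tr$t2 - healthy_adc$t2)
    } else {                                    # day4
      sub <- lt$subacute
      cbf[sub] <- cbf[sub] * day4_mult
      cbv[sub] <- cbv[sub] * (0.6 + 0.4 * day4_mult)
      adc <- healthy_adc$adc + 0.15 * (tr$adc - healthy_adc$adc)
      # t2 stays at phantom truth: subacute elevation fully developed
    }
    w <- cbf > 0
    mtt <- cbv * 0
    mtt[w] <- cbv[w] / cbf[w]
    ph <- phantom
    ph$truth <- list(adc = adc, t2 = t2, cbf = cbf, cbv = cbv, mtt = mtt)
    ph
  }

  tps <- c("occlusion", "post_0.5h", "day4")
  timepoints <- lapply(tps, function(tp) {
    ph <- tp_truth(tp)
    list(timepoint = tp,
         truth = ph$truth,
         dwi = simulate_dwi(ph, config),
         echoes = simulate_multiecho(ph, config),
         dsc = simulate_dsc(ph, config))
  })
  names(timepoints) <- tps

  structure(list(subject = subject, sex = sex, occlusion = occlusion,
                 phantom = phantom, timepoints = timepoints,
                 volume_change_pct = vc,
                 sds_baseline = min(stats::rpois(1L, 10), 22L),
                 sds_day4 = min(stats::rpois(1L,
                   spec$sds_mean * exp(spec$sds_b_vc * (vc - mean(unlist(spec$vc_cell_mean))) / 30)),
                   22L)),
            class = "subject_images")
}
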