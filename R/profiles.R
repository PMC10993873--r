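#' Relative regional perfusion index
#'
#' ROI mean of a perfusion map expressed as a percentage of the mean over
#' the contralateral homologue: 100 * mean(map[roi]) / mean(map[homologue]).
#' Non-finite voxels (masked MTT, failed fits) are dropped from both means.
#'
#' @param map 3D perfusion map
#' @param roi logical ROI mask
#' @param homologue logical mask of the mirrored contralateral homologue
#' @param winsorize optional two-sided quantile (e.g. 0.01) at which both
#'   value sets are clipped before averaging, to blunt non-physiological
#'   deconvolution values near vessels and CSF; off (`NULL`) by default —
#'   the voxel-binning path is the study's own mitigation
#' @return percentage (scalar)
#' @export
rr_index <- function(map, roi, homologue, winsorize = NULL) {
  check_same_grid(map, roi)
  check_same_grid(map, homologue)
  rv <- map[roi]; hv <- map[homologue]
  rv <- rv[is.finite(rv)]; hv <- hv[is.finite(hv)]
  if (!is.null(winsorize)) {
    stopifnot(winsorize > 0, winsorize < 0.5)
    clip <- function(x) {
      q <- stats::quantile(x, c(winsorize, 1 - winsorize), names = FALSE)
      pmin(pmax(x, q[1L]), q[2L])
    }
    rv <- clip(rv); hv <- clip(hv)
  }
  if (length(rv) == 0L) stop("ROI is empty")
  if (length(hv) == 0L) stop("homologue is empty")
  hm <- mean(hv)
  if (hm == 0) stop("homologue mean is zero; rr index undefined")
  100 * mean(rv) / hm
}

#' Repercentage a perfusion map to an internal control value
#'
#' Each voxel is expressed as a percentage of the contralateral median:
#' 100 * value / median.
#'
#' @param map 3D perfusion map
#' @param homologue_median contralateral median (> 0)
#' @return voxelwise percent map
#' @export
repercentage <- function(map, homologue_median) {
  if (!is.finite(homologue_median) || homologue_median <= 0)
    stop("contralateral median must be positive")
  100 * map / homologue_median
}

#' Bin repercentaged perfusion voxels into hypo/normo/hyperperfused classes
#'
#' For CBF and CBV, voxels strictly above 115 percent of the contralateral
#' median are hyperperfused and voxels strictly below 85 percent are
#' hypoperfused. For MTT the classification is reversed: short MTT (< 85)
#' marks hyperperfusion and long MTT (> 115) hypoperfusion. Values exactly
#' at 85 or 115, and everything between, are normoperfused.
#'
#' @param pct_map voxelwise percent map from [repercentage()]
#' @param parameter "cbf", "cbv" or "mtt"
#' @param band normoperfusion band in percent (default `c(85, 115)`)
#' @return integer array: -1 hypo, 0 normo, +1 hyper (NA propagated), with
#'   attribute `levels = c("hypo", "normo", "hyper")`
#' @export
bin_voxels <- function(pct_map, parameter = c("cbf", "cbv", "mtt"),
                       band = c(85, 115)) {
  parameter <- match.arg(parameter)
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  cls <- array(0L, dim = dim(pct_map) %||% length(pct_map))
  up <- pct_map > band[2L]
  dn <- pct_map < band[1L]
  if (parameter == "mtt") {
    cls[up] <- -1L   # long transit time = hypoperfused
    cls[dn] <- 1L    # short transit time = hyperperfused
  } else {
    cls[up] <- 1L
    cls[dn] <- -1L
  }
  cls[is.na(pct_map)] <- NA_integer_
  if (!is.null(dim(pct_map))) dim(cls) <- dim(pct_map)
  attr(cls, "levels") <- c("hypo", "normo", "hyper")
  cls
}

#' Voxel-class fractions within an ROI
#'
#' Counts of hypo-, normo- and hyperperfused voxels expressed as fractions
#' of the ROI voxel count; the triple sums to exactly 1. Voxels with an
#' undefined class (NA) are counted as normoperfused so the partition stays
#' exact; their number is reported in the `n_undefined` attribute.
#'
#' @param class_map output of [bin_voxels()]
#' @param roi logical ROI mask
#' @return named numeric vector `c(f_hypo, f_normo, f_hyper)`
#' @export
class_fractions <- function(class_map, roi) {
  n <- sum(roi)
  if (n == 0L) stop("ROI is empty")
  v <- class_map[roi]
  nau <- sum(is.na(v))
  f_hypo <- sum(v == -1L, na.rm = TRUE) / n
  f_hyper <- sum(v == 1L, na.rm = TRUE) / n
  # residual + one compensation step so the triple sums to exactly 1 in
  # floating point, honoring the partition contract
  f_normo <- 1 - f_hypo - f_hyper
  f_normo <- f_normo + (1 - (f_hypo + f_normo + f_hyper))
  out <- c(f_hypo = f_hypo, f_normo = f_normo, f_hyper = f_hyper)
  attr(out, "n_undefined") <- nau
  out
}

#' Per-subject, per-timepoint perfusion profile over the fate ROIs
#'
#' For each fate ROI (acute lesion, core, salvageable, delayed) and each
#' perfusion parameter, computes the relative regional index against the
#' mirrored homologue and the hypo/normo/hyper voxel-class fractions of
#' both the ipsilateral ROI and its contralateral homologue, after
#' repercentaging the map to the contralateral hemisphere median (CSF
#' excluded).
#'
#' @param maps a [perfusion_maps()] object (or list with `cbf`, `cbv`,
#'   `mtt` arrays)
#' @param fate a [classify_fate()] object
#' @param atlas a `stroke_atlas`
#' @param contralateral_hemisphere hemisphere code of the control side
#' @param band normoperfusion band in percent
#' @return data.frame: roi, hemisphere, parameter, rr_index (ipsi rows
#'   only), f_hypo, f_normo, f_hyper, n_voxels
#' @export
perfusion_profile <- function(maps, fate, atlas,
                              contralateral_hemisphere = 1L,
                              band = c(85, 115)) {
  params <- c(cbf = "cbf", cbv = "cbv", mtt = "mtt")
  homols <- fate_homologues(fate, atlas$midline_axis)
  contra_brain <- atlas$brain & atlas$hemisphere == contralateral_hemisphere &
    atlas$labels != atlas_labels[["csf"]]
  rois <- c("acute", "core", "salvageable", "delayed")
  rows <- list()
  for (p in names(params)) {
    map <- maps[[params[[p]]]]
    cv <- map[contra_brain]
    med <- stats::median(cv[is.finite(cv)])
    pct <- repercentage(map, med)
    cls <- bin_voxels(pct, p, band)
    for (r in rois) {
      roi <- fate[[r]]; hom <- homols[[r]]
      if (!any(roi)) next
      rr <- tryCatch(rr_index(map, roi, hom), error = function(e) NA_real_)
      fi <- class_fractions(cls, roi)
      fc <- class_fractions(cls, hom)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, hemisphere = "ipsi", parameter = p, rr_index = rr,
        f_hypo = fi[[1L]], f_normo = fi[[2L]], f_hyper = fi[[3L]],
        n_voxels = sum(roi))
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, hemisphere = "contra", parameter = p, rr_index = NA_real_,
        f_hypo = fc[[1L]], f_normo = fc[[2L]], f_hyper = fc[[3L]],
        n_voxels = sum(hom))
    }
  }
  do.call(rbind, rows)
}
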