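#' Contralateral reference statistics for lesion thresholding
#'
#' Computes mean, SD and median of a parametric map over the contralateral
#' MCA territory (S1FL, S2 and CPu labels), after excluding CSF both by
#' atlas label and by parameter cutoff (ADC above `csf_adc_max` or T2 above
#' `csf_t2_max` is CSF-like).
#'
#' @param map 3D parametric map (ADC in mm^2/s or T2 in ms)
#' @param atlas a `stroke_atlas` (or list with `labels` and `hemisphere`)
#' @param mode "adc" or "t2"; selects the CSF parameter cutoff
#' @param contralateral_hemisphere hemisphere code holding the reference
#'   tissue (default 1 = left)
#' @param min_voxels floor on the number of reference voxels
#' @param csf_adc_max,csf_t2_max CSF-like parameter cutoffs
#' @return list of class `reference_stats`: `mean`, `sd`, `median`, `n`,
#'   `mode`
#' @export
reference_stats <- function(map, atlas, mode = c("adc", "t2"),
                            contralateral_hemisphere = 1L,
                            min_voxels = 100L,
                            csf_adc_max = 1.2e-3, csf_t2_max = 90) {
  mode <- match.arg(mode)
  check_same_grid(map, atlas$labels)
  sel <- atlas$labels %in% mca_reference_labels() &
    atlas$hemisphere == contralateral_hemisphere
  vals <- map[sel]
  vals <- vals[is.finite(vals)]
  vals <- if (mode == "adc") vals[vals <= csf_adc_max] else vals[vals <= csf_t2_max]
  if (length(vals) < min_voxels)
    stop(sprintf("only %d reference voxels (< %d) after CSF exclusion",
                 length(vals), min_voxels))
  s <- stats::sd(vals)
  if (!is.finite(s) || s <= 0)
    stop("reference SD is not positive; degenerate reference region")
  structure(list(mean = mean(vals), sd = s, median = stats::median(vals),
                 n = length(vals), mode = mode),
            class = "reference_stats")
}

#' Threshold a parametric map against contralateral statistics
#'
#' Acute ischemic tissue: ADC strictly below mean - 2 SD of the
#' contralateral reference. Subacute infarct: T2 strictly above
#' mean + 2 SD. Only ipsilateral voxels are eligible; CSF is excluded by
#' atlas label and by the same parameter cutoffs used for the reference.
#'
#' @param map 3D parametric map
#' @param ref a [reference_stats()] of matching mode
#' @param atlas a `stroke_atlas`
#' @param mode "adc" (lesion below threshold) or "t2" (lesion above)
#' @param ipsilateral_hemisphere hemisphere code being segmented (default 2)
#' @param n_sd threshold width in reference SDs
#' @param csf_adc_max,csf_t2_max CSF-like parameter cutoffs
#' @return logical lesion mask
#' @export
threshold_lesion <- function(map, ref, atlas, mode = c("adc", "t2"),
                             ipsilateral_hemisphere = 2L, n_sd = 2,
                             csf_adc_max = 1.2e-3, csf_t2_max = 90) {
  mode <- match.arg(mode)
  if (!inherits(ref, "reference_stats") || ref$mode != mode)
    stop("reference statistics do not match the map mode")
  check_same_grid(map, atlas$labels)
  eligible <- atlas$hemisphere == ipsilateral_hemisphere &
    atlas$brain & atlas$labels != atlas_labels[["csf"]]
  eligible <- eligible & if (mode == "adc") map <= csf_adc_max else map <= csf_t2_max
  mask <- if (mode == "adc") {
    map < ref$mean - n_sd * ref$sd
  } else {
    map > ref$mean + n_sd * ref$sd
  }
  mask & eligible & is.finite(map)
}

# 26-connected component labeling of a 3D logical mask (BFS on voxel
# indices). Returns an integer array, 0 = background.
label_components <- function(mask) {
  shape <- dim(mask)
  stopifnot(length(shape) == 3L)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0L, , drop = FALSE]
  lab <- array(0L, dim = shape)
  ids <- which(mask)
  if (length(ids) == 0L) return(lab)
  coord <- arrayInd(ids, shape)
  inmask <- array(FALSE, dim = shape); inmask[ids] <- TRUE
  cur <- 0L
  for (start in ids) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      vc <- arrayInd(v, shape)
      cand <- sweep(nb, 2L, as.integer(vc), `+`)
      keep <- cand[, 1L] >= 1L & cand[, 1L] <= shape[1L] &
        cand[, 2L] >= 1L & cand[, 2L] <= shape[2L] &
        cand[, 3L] >= 1L & cand[, 3L] <= shape[3L]
      cand <- cand[keep, , drop = FALSE]
      ci <- cand[, 1L] + (cand[, 2L] - 1L) * shape[1L] +
        (cand[, 3L] - 1L) * shape[1L] * shape[2L]
      ci <- ci[inmask[ci] & lab[ci] == 0L]
      if (length(ci)) {
        lab[ci] <- cur
        queue <- c(queue, ci)
      }
    }
  }
  lab
}

# 3D dilation/erosion with a box/ball structuring element of given radius,
# implemented by index shifting (out-of-volume treated as background).
morph3d <- function(mask, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (radius <= 0) return(mask)
  shape <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -radius:radius, dy = -radius:radius,
                                dz = -radius:radius))
  offs <- offs[sqrt(rowSums(offs^2)) <= radius + 1e-9, , drop = FALSE]
  acc <- if (op == "dilate") array(FALSE, shape) else array(TRUE, shape)
  for (r in seq_len(nrow(offs))) {
    sh <- shift3d(mask, offs[r, ], fill = FALSE)
    acc <- if (op == "dilate") acc | sh else acc & sh
  }
  acc
}

shift3d <- function(mask, off, fill = FALSE) {
  shape <- dim(mask)
  out <- array(fill, shape)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[[a]]
    if (abs(o) >= shape[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- seq(1L + o, shape[a]); src[[a]] <- seq(1L, shape[a] - o)
    } else {
      dst[[a]] <- seq(1L, shape[a] + o); src[[a]] <- seq(1L - o, shape[a])
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- mask[src[[1L]], src[[2L]], src[[3L]]]
  out
}

#' Automated surrogate for manual lesion-mask noise correction
#'
#' Removes 26-connected components smaller than `min_cluster_voxels`, then
#' applies a morphological closing (dilation followed by erosion) of the
#' given radius. The operation is idempotent: applying it twice gives the
#' same mask as applying it once.
#'
#' @param mask logical 3D array
#' @param min_cluster_voxels smallest retained component size
#' @param closing_radius structuring-element radius in voxels (0 = skip)
#' @return cleaned logical mask
#' @export
clean_mask <- function(mask, min_cluster_voxels = 50L, closing_radius = 1L) {
  stopifnot(min_cluster_voxels >= 0, closing_radius >= 0)
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cluster_voxels)
  out <- array(lab %in% keep & lab > 0L, dim = dim(mask))
  if (closing_radius > 0 && any(out)) {
    # pad by the radius so the closing equals the infinite-lattice closing
    # (clipping the dilation at the array edge would break idempotence)
    r <- as.integer(closing_radius)
    sh <- dim(out)
    pad <- array(FALSE, dim = sh + 2L * r)
    ix <- lapply(sh, function(n) seq_len(n) + r)
    pad[ix[[1L]], ix[[2L]], ix[[3L]]] <- out
    pad <- morph3d(morph3d(pad, r, "dilate"), r, "erode")
    out <- pad[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE]
    dim(out) <- sh
  }
  out
}

#' Parcellate acute and subacute lesions into tissue fates
#'
#' Set algebra on co-registered masks: lesion core = acute AND subacute,
#' salvageable tissue = acute minus subacute, delayed injury = subacute
#' minus acute. The identities core U salvageable = acute and
#' core U delayed = subacute hold exactly, and the three fate parcels are
#' pairwise disjoint.
#'
#' @param acute_mask acute (diffusion-defined) lesion mask
#' @param subacute_mask subacute (T2-defined) infarct mask, in the same
#'   (native) space
#' @return list of class `fate_masks`: `acute`, `subacute`, `core`,
#'   `salvageable`, `delayed`
#' @export
classify_fate <- function(acute_mask, subacute_mask) {
  if (!identical(dim(acute_mask), dim(subacute_mask)))
    stop("acute and subacute masks are not on the same grid")
  structure(list(acute = acute_mask, subacute = subacute_mask,
                 core = acute_mask & subacute_mask,
                 salvageable = acute_mask & !subacute_mask,
                 delayed = subacute_mask & !acute_mask),
            class = "fate_masks")
}

#' Mirror a mask across the hemispheric midline
#'
#' The contralateral homologue of an ROI is its reflection across the
#' midline plane (an exact voxel permutation for an even-dimension axis, so
#' mirroring twice returns the original mask bit-exactly). A warning is
#' issued when the mask overlaps its own mirror (ROI touching the midline).
#'
#' @param mask logical 3D array
#' @param axis midline axis (default 1)
#' @return mirrored mask
#' @export
mirror_homologue <- function(mask, axis = 1L) {
  m <- mirror_volume(mask, axis)
  if (any(m & mask))
    warning("mask overlaps its mirrored homologue across the midline")
  m
}

# Homologues of every fate parcel.
fate_homologues <- function(fate, axis = 1L) {
  lapply(fate[c("acute", "subacute", "core", "salvageable", "delayed")],
         function(m) suppressWarnings(mirror_homologue(m, axis)))
}

#' Volumes and hemispheric fractions of the fate parcels
#'
#' @param fate a [classify_fate()] object
#' @param hemisphere_mask logical mask of the ipsilateral hemisphere brain
#' @param voxel_volume_ul voxel volume in microlitres
#' @param inclusion_min_ul acute-lesion volume below which the subject is
#'   flagged excluded (default 30 uL)
#' @return data.frame with one row per ROI: voxel count, volume (uL),
#'   hemispheric fraction, plus the subject-level `included` flag as an
#'   attribute
#' @export
volume_metrics <- function(fate, hemisphere_mask, voxel_volume_ul,
                           inclusion_min_ul = 30) {
  stopifnot(inherits(fate, "fate_masks"), voxel_volume_ul > 0)
  hv <- sum(hemisphere_mask)
  if (hv == 0) stop("hemisphere mask is empty")
  rois <- c("acute", "subacute", "core", "salvageable", "delayed")
  n <- vapply(fate[rois], sum, numeric(1L))
  out <- data.frame(roi = rois, n_voxels = as.integer(n),
                    volume_ul = n * voxel_volume_ul,
                    hemisphere_fraction = n / hv, row.names = NULL)
  attr(out, "included") <- out$volume_ul[out$roi == "acute"] >= inclusion_min_ul
  attr(out, "hemisphere_volume_ul") <- hv * voxel_volume_ul
  out
}

#' Acute-to-subacute lesion volume change
#'
#' Signed percent change 100 * (V_T2 - V_ADC) / V_ADC between the
#' T2-derived subacute infarct volume and the ADC-derived acute ischemic
#' volume.
#'
#' @param adc_volume acute (ADC) lesion volume, > 0
#' @param t2_volume subacute (T2) lesion volume
#' @return percent change (negative = shrinkage)
#' @export
volume_change <- function(adc_volume, t2_volume) {
  if (any(adc_volume <= 0)) stop("acute (ADC) lesion volume must be positive")
  100 * (t2_volume - adc_volume) / adc_volume
}

#' Classify lesion location from the atlas labels under the acute mask
#'
#' Majority vote of atlas labels: cortical (cortex/S1FL/S2), subcortical
#' (striatum/CPu) or diencephalic (thalamus).
#'
#' @param acute_mask acute lesion mask
#' @param atlas a `stroke_atlas`
#' @return one of "cortical", "subcortical", "diencephalic"
#' @export
lesion_location <- function(acute_mask, atlas) {
  labs <- atlas$labels[acute_mask]
  counts <- c(cortical = sum(labs %in% cortical_labels()),
              subcortical = sum(labs %in% subcortical_labels()),
              diencephalic = sum(labs == atlas_labels[["thalamus"]]))
  if (all(counts == 0)) return(NA_character_)
  names(counts)[which.max(counts)]
}
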