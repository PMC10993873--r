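#' Atlas label codes used by the synthetic phantom
#'
#' Integer codes of the parcellated label volume: background (0), CSF (1),
#' cortex (2), striatum (3), primary somatosensory cortex S1FL (4),
#' secondary somatosensory cortex S2 (5), caudate putamen CPu (6),
#' thalamus (7) and arterial voxels (8). S1FL, S2 and CPu form the
#' middle-cerebral-artery (MCA) territory used for contralateral reference
#' statistics.
#' @export
atlas_labels <- c(background = 0L, csf = 1L, cortex = 2L, striatum = 3L,
                  s1fl = 4L, s2 = 5L, cpu = 6L, thalamus = 7L, artery = 8L)

# Labels making up the contralateral MCA reference territory.
mca_reference_labels <- function() atlas_labels[c("s1fl", "s2", "cpu")]

cortical_labels   <- function() atlas_labels[c("cortex", "s1fl", "s2")]
subcortical_labels <- function() atlas_labels[c("striatum", "cpu")]

#' Build a mirror-symmetric two-hemisphere rat-brain-like atlas
#'
#' The label volume is an ellipsoidal "brain" split by a grid-plane midline
#' on the first axis (which must have even length so that mirroring is an
#' exact voxel permutation). Within each hemisphere an outer cortical shell
#' is subdivided into S1FL and S2 bands, the interior into caudate putamen,
#' residual striatum and a medial thalamus, with a small ventricular CSF
#' compartment and a handful of arterial voxels per hemisphere. All labels
#' are defined on the mirrored coordinate, so the volume is exactly
#' symmetric about the midline.
#'
#' @param shape grid dimensions, first axis even
#' @param voxel_size physical voxel size in mm per axis
#' @return list with `labels` (integer array), `hemisphere` (integer array,
#'   1 = left, 2 = right), `brain` (logical array), `voxel_size`,
#'   `midline_axis` (always 1) and `voxel_volume_ul` (microlitres)
#' @export
make_atlas <- function(shape = c(32L, 32L, 10L),
                       voxel_size = c(0.45, 0.45, 1.2)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), shape[1L] %% 2L == 0L,
            length(voxel_size) == 3L, all(voxel_size > 0))
  nx <- shape[1L]; ny <- shape[2L]; nz <- shape[3L]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2

  xi <- seq_len(nx); yi <- seq_len(ny); zi <- seq_len(nz)
  # mirrored lateral coordinate: identical for (x, nx + 1 - x)
  u <- abs(xi - cx)
  X <- array(rep(u, times = ny * nz), dim = shape)
  Y <- array(rep(rep(yi - cy, each = nx), times = nz), dim = shape)
  Z <- array(rep(zi - cz, each = nx * ny), dim = shape)

  ax <- 0.46 * nx; ay <- 0.46 * ny; az <- 0.44 * nz
  q <- (X / ax)^2 + (Y / ay)^2 + (Z / az)^2
  brain <- q <= 1

  labels <- array(atlas_labels[["background"]], dim = shape)
  # interior vs cortical shell by the ellipsoid quadratic form
  shell <- brain & q > 0.55
  interior <- brain & !shell
  labels[shell] <- atlas_labels[["cortex"]]
  labels[interior] <- atlas_labels[["striatum"]]

  # cortical subfields as anterior/posterior bands of the shell
  s1 <- shell & Y >= -0.45 * ay & Y < -0.05 * ay
  s2 <- shell & Y >= -0.05 * ay & Y < 0.35 * ay
  labels[s1] <- atlas_labels[["s1fl"]]
  labels[s2] <- atlas_labels[["s2"]]

  # caudate putamen: lateral anterior interior block
  cpu <- interior & X > 0.12 * ax & X < 0.62 * ax & Y > -0.5 * ay & Y < 0.25 * ay
  labels[cpu] <- atlas_labels[["cpu"]]

  # thalamus: medial posterior interior block
  thal <- interior & X <= 0.25 * ax & Y >= 0.25 * ay
  labels[thal] <- atlas_labels[["thalamus"]]

  # lateral ventricles: small CSF ellipsoids, one per hemisphere
  vent <- interior &
    ((X - 0.18 * ax) / (0.10 * ax))^2 + ((Y + 0.30 * ay) / (0.22 * ay))^2 +
      (Z / (0.45 * az))^2 <= 1
  labels[vent] <- atlas_labels[["csf"]]

  # arterial voxels: short medial line per hemisphere near the brain base
  art <- brain & X > 0.60 * ax & X < 0.80 * ax & abs(Y + 0.1 * ay) < 0.10 * ay &
    abs(Z) < 0.45 * az
  labels[art] <- atlas_labels[["artery"]]

  hemi <- array(ifelse(rep(xi, times = ny * nz) <= nx / 2, 1L, 2L), dim = shape)

  structure(list(labels = labels, hemisphere = hemi, brain = brain,
                 voxel_size = voxel_size, midline_axis = 1L,
                 voxel_volume_ul = prod(voxel_size)),  # 1 mm^3 == 1 uL
            class = "stroke_atlas")
}

#' Ground-truth tissue parameter values of the phantom
#'
#' Per-label ADC (mm^2/s), T2 (ms), CBF (relative flow units) and MTT (s);
#' CBV is CBF * MTT so the central volume theorem holds exactly. Values are
#' conventional rodent-brain magnitudes at high field.
#'
#' @return data.frame keyed by label code
#' @export
tissue_truth_table <- function() {
  data.frame(
    label = unname(atlas_labels),
    tissue = names(atlas_labels),
    adc = c(0,    2.8e-3, 0.75e-3, 0.70e-3, 0.76e-3, 0.74e-3, 0.69e-3, 0.72e-3, 0.80e-3),
    t2  = c(0,    160,    48,      44,      49,      48,      43,      46,      50),
    cbf = c(0,    4,      60,      50,      62,      58,      52,      48,      400),
    mtt = c(0,    8,      1.6,     1.8,     1.5,     1.6,     1.8,     1.7,     0.8),
    row.names = NULL
  )
}

#' Lesion geometry and fate composition for phantom construction
#'
#' The acute (diffusion) lesion is an ellipsoid in the right hemisphere; the
#' subacute (T2) lesion is a second ellipsoid whose volume is scaled by
#' `volume_change_pct` and whose center may be shifted, so that all three
#' tissue fates (core, salvageable, delayed injury) can be populated.
#'
#' @param center lesion center in voxel coordinates; `NULL` places it in the
#'   right MCA territory automatically
#' @param radii acute ellipsoid semi-axes in voxels
#' @param volume_change_pct planted acute-to-subacute volume change,
#'   100 * (V_subacute - V_acute) / V_acute
#' @param subacute_shift voxel offset of the subacute ellipsoid center
#' @param adc_drop fractional ADC reduction inside the acute lesion
#'   (core, salvageable); at least 0.3 to stand clear of contralateral noise
#' @param t2_raise fractional T2 elevation inside the subacute lesion
#' @param composition "ellipsoids" derives the fates from two overlapping
#'   ellipsoids (difference classes are thin shells, as in real lesion
#'   evolution); "split" builds compact fate blocks — the posterior part of
#'   the acute ellipsoid proceeds to infarction (core), the anterior part
#'   recovers (salvageable), and a separate adjacent ellipsoid suffers
#'   delayed injury — the natural fixture when each class must be
#'   recoverable in isolation
#' @param split_fraction for "split": anterior fraction of the acute
#'   ellipsoid assigned to salvageable tissue
#' @return list of class `lesion_spec`
#' @export
lesion_spec <- function(center = NULL, radii = c(6, 7, 3),
                        volume_change_pct = -20, subacute_shift = c(0, 2, 0),
                        adc_drop = c(core = 0.40, salvageable = 0.32),
                        t2_raise = c(core = 0.38, delayed = 0.30),
                        composition = c("ellipsoids", "split"),
                        split_fraction = 0.35) {
  composition <- match.arg(composition)
  stopifnot(volume_change_pct > -100, all(radii > 0),
            split_fraction > 0, split_fraction < 1)
  structure(list(center = center, radii = radii,
                 volume_change_pct = volume_change_pct,
                 subacute_shift = subacute_shift,
                 adc_drop = adc_drop, t2_raise = t2_raise,
                 composition = composition, split_fraction = split_fraction),
            class = "lesion_spec")
}

#' Generate a two-hemisphere phantom with a planted lesion of known fate
#'
#' Builds the symmetric atlas, plants an acute and a subacute lesion in the
#' right hemisphere per `lesion_spec`, derives the ground-truth fate parcels
#' (core = acute intersect subacute, salvageable = acute minus subacute,
#' delayed = subacute minus acute) and writes the corresponding ADC
#' reduction and T2 elevation into the truth maps. Perfusion truth (CBF,
#' CBV, MTT) is left hemispherically symmetric; timepoint-specific
#' perfusion effects are applied by the subject simulator.
#'
#' @param shape,voxel_size forwarded to [make_atlas()]
#' @param lesion a [lesion_spec()]
#' @param seed RNG seed (only consumed by downstream stochastic steps; the
#'   phantom itself is deterministic)
#' @return object of class `stroke_phantom`: the atlas plus `truth` maps
#'   (adc, t2, cbf, cbv, mtt) and `lesion_truth` masks (acute, subacute,
#'   core, salvageable, delayed)
#' @export
make_phantom <- function(shape = c(32L, 32L, 10L), lesion = lesion_spec(),
                         voxel_size = c(0.45, 0.45, 1.2), seed = NULL) {
  atlas <- make_atlas(shape, voxel_size)
  shape <- dim(atlas$labels)
  maybe_set_seed(seed)

  if (is.null(lesion$center)) {
    # centroid of the right-hemisphere CPu, nudged toward cortex
    idx <- which(atlas$labels == atlas_labels[["cpu"]] & atlas$hemisphere == 2L,
                 arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("atlas has no right-hemisphere CPu voxels")
    lesion$center <- colMeans(idx) + c(1.5, 0, 0)
  }
  eligible <- atlas$brain & atlas$labels != atlas_labels[["csf"]]
  acute <- ellipsoid_mask(shape, lesion$center, lesion$radii) & eligible
  if ((lesion$composition %||% "ellipsoids") == "split") {
    # compact fate blocks: anterior cap of the acute ellipsoid recovers,
    # the rest infarcts, and a separate adjacent ellipsoid is injured late
    yy <- array(rep(rep(seq_len(shape[2L]), each = shape[1L]),
                    times = shape[3L]), dim = shape)
    y_cut <- lesion$center[2L] +
      (2 * lesion$split_fraction - 1) * lesion$radii[2L]
    delayed_center <- lesion$center + c(0, 1.40 * lesion$radii[2L], 0)
    delayed_blob <- ellipsoid_mask(shape, delayed_center,
                                   lesion$radii * 0.80) & eligible & !acute
    subac <- (acute & yy > y_cut) | delayed_blob
  } else {
    scale <- (1 + lesion$volume_change_pct / 100)^(1 / 3)
    subac <- ellipsoid_mask(shape, lesion$center + lesion$subacute_shift,
                            lesion$radii * scale) & eligible
  }
  if (!any(acute)) stop("planted acute lesion is empty")
  if (!any(subac)) stop("planted subacute lesion is empty")
  if (any((acute | subac) & atlas$hemisphere == 1L))
    stop("planted lesion crosses the midline into the left hemisphere")

  core <- acute & subac
  salvageable <- acute & !subac
  delayed <- subac & !acute

  tt <- tissue_truth_table()
  lut <- function(col) {
    v <- numeric(max(tt$label) + 1L)
    v[tt$label + 1L] <- tt[[col]]
    array(v[atlas$labels + 1L], dim = shape)
  }
  adc <- lut("adc"); t2 <- lut("t2"); cbf <- lut("cbf"); mtt <- lut("mtt")

  adc[core] <- adc[core] * (1 - lesion$adc_drop[["core"]])
  adc[salvageable] <- adc[salvageable] * (1 - lesion$adc_drop[["salvageable"]])
  t2[core] <- t2[core] * (1 + lesion$t2_raise[["core"]])
  t2[delayed] <- t2[delayed] * (1 + lesion$t2_raise[["delayed"]])
  cbv <- cbf * mtt
  # re-derive MTT from the stored CBV so MTT == CBV/CBF holds bit-exactly
  w <- cbf > 0
  mtt[w] <- cbv[w] / cbf[w]
  mtt[!w] <- 0

  structure(c(atlas,
              list(truth = list(adc = adc, t2 = t2, cbf = cbf, cbv = cbv,
                                mtt = mtt),
                   lesion_truth = list(acute = acute, subacute = subac,
                                       core = core, salvageable = salvageable,
                                       delayed = delayed),
                   lesion_spec = lesion)),
            class = c("stroke_phantom", "stroke_atlas"))
}

#' @export
print.stroke_phantom <- function(x, ...) {
  cat("stroke_phantom:", paste(dim(x$labels), collapse = " x "),
      "grid,", format(x$voxel_volume_ul, digits = 3), "uL voxels\n")
  cat("  brain voxels:", sum(x$brain),
      "| acute lesion:", sum(x$lesion_truth$acute),
      "| subacute lesion:", sum(x$lesion_truth$subacute), "\n")
  invisible(x)
}
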