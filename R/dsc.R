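#' Convert DSC signal to concentration time curves
#'
#' Applies the transverse relaxivity relation
#' C(t) = -ln(S(t) / S0) / TE with TE in seconds and S0 the per-voxel mean
#' signal over the pre-bolus baseline window. Voxels whose baseline mean is
#' non-positive are masked out entirely; individual frames with
#' non-positive signal are set to `NA`.
#'
#' @param series a `dsc_series` (4D array in `data` plus timing metadata)
#'   or a plain voxels-by-frames signal matrix (then `te_ms`,
#'   `frame_interval` must be given)
#' @param baseline_window integer range `c(first, last)` of baseline frames;
#'   must end before the bolus frame
#' @param te_ms echo time in ms (taken from the series when available)
#' @param frame_interval frame spacing in s (taken from the series)
#' @return object of class `conc_series`: `values` (voxels x frames matrix),
#'   `shape` (original grid, or NULL for matrix input), `valid` (logical per
#'   voxel), `s0`, `baseline_window`, `frame_interval`, frame ordinals
#' @export
signal_to_concentration <- function(series, baseline_window = c(20L, 170L),
                                    te_ms = NULL, frame_interval = NULL) {
  if (inherits(series, "dsc_series")) {
    d <- dim(series$data)
    sig <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4L])
    shape <- d[1:3]
    te_ms <- te_ms %||% series$te
    frame_interval <- frame_interval %||% series$frame_interval
    bolus <- series$bolus_image_index
    trunc_idx <- series$truncation_index
  } else {
    sig <- as.matrix(series)
    shape <- NULL
    bolus <- NA_integer_
    trunc_idx <- NA_integer_
    if (is.null(te_ms) || is.null(frame_interval))
      stop("te_ms and frame_interval are required for matrix input")
  }
  stopifnot(te_ms > 0, frame_interval > 0)
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) != 2L || baseline_window[1L] > baseline_window[2L])
    stop("baseline_window must be c(first, last) with first <= last")
  if (baseline_window[2L] > ncol(sig))
    stop("baseline window extends past the series")
  if (!is.na(bolus) && baseline_window[2L] >= bolus)
    stop("baseline window must end before the bolus frame")
  bw <- seq(baseline_window[1L], baseline_window[2L])
  if (length(bw) == 0L) stop("empty baseline window")

  s0 <- rowMeans(sig[, bw, drop = FALSE])
  valid <- is.finite(s0) & s0 > 0
  te_s <- te_ms / 1000
  conc <- matrix(NA_real_, nrow = nrow(sig), ncol = ncol(sig))
  if (any(valid)) {
    sv <- sig[valid, , drop = FALSE]
    bad <- sv <= 0
    ratio <- sv / s0[valid]
    ratio[bad] <- 1          # placeholder; masked below
    cv <- -log(ratio) / te_s
    cv[bad] <- NA_real_
    conc[valid, ] <- cv
  }
  structure(list(values = conc, shape = shape, valid = valid, s0 = s0,
                 baseline_window = baseline_window,
                 frame_interval = frame_interval,
                 bolus_image_index = bolus, truncation_index = trunc_idx,
                 te_ms = te_ms),
            class = "conc_series")
}

conc_matrix <- function(conc) {
  if (inherits(conc, "conc_series")) conc$values else as.matrix(conc)
}

#' Extract an arterial reference curve from the contralateral hemisphere
#'
#' Deterministic automated selection: candidate voxels in the contralateral
#' mask are ranked by a composite of peak concentration (high), bolus
#' arrival frame (early) and first moment of the curve (narrow/early mass),
#' each as a rank sum; the top `k` curves are averaged. Voxels whose peak
#' occurs at or before the bolus frame are not eligible.
#'
#' @param conc a `conc_series` from [signal_to_concentration()]
#' @param contralateral_mask logical array (grid input) or logical/integer
#'   vector of voxel rows (matrix input)
#' @param k number of curves averaged
#' @param bolus_image_index required when the series carries no bolus frame
#' @return object of class `aif`: `curve`, `source_voxels` (row indices),
#'   `peak_frame`, `frame_interval`
#' @export
extract_aif <- function(conc, contralateral_mask, k = 10L,
                        bolus_image_index = NULL) {
  cm <- conc_matrix(conc)
  bolus <- bolus_image_index %||% conc$bolus_image_index
  if (is.null(bolus) || is.na(bolus)) bolus <- 0L
  rows <- if (is.logical(contralateral_mask) ||
              (is.numeric(contralateral_mask) && is.array(contralateral_mask))) {
    which(as.logical(contralateral_mask))
  } else {
    as.integer(contralateral_mask)  # explicit voxel row indices
  }
  rows <- rows[conc$valid[rows]]
  if (length(rows) == 0L) stop("contralateral mask is empty")

  cand <- cm[rows, , drop = FALSE]
  cand[is.na(cand)] <- 0
  nfr <- ncol(cand)
  # selection metrics on lightly smoothed curves restricted to the
  # post-bolus window, so baseline noise cannot fake an early arrival
  sm <- t(apply(cand, 1L, smooth_curve, width = 5L))
  win <- seq.int(min(max(1L, bolus), nfr), nfr)
  smw <- sm[, win, drop = FALSE]
  pk <- apply(smw, 1L, max)
  pf <- win[apply(smw, 1L, which.max)]
  eligible <- pk > 0 & pf > bolus
  if (!any(eligible)) stop("no contralateral voxel has a post-bolus peak")
  cand <- cand[eligible, , drop = FALSE]
  smw <- smw[eligible, , drop = FALSE]
  rows <- rows[eligible]; pk <- pk[eligible]; pf <- pf[eligible]

  arrival <- apply(smw / pk, 1L, function(x) {
    w <- which(x > 0.1)
    if (length(w)) w[1L] else ncol(smw)
  })
  pos <- pmax(smw, 0)
  fm <- as.numeric(pos %*% seq_len(ncol(smw))) /
    pmax(rowSums(pos), .Machine$double.eps)

  score <- rank(-pk, ties.method = "first") +
    rank(arrival, ties.method = "first") + rank(fm, ties.method = "first")
  ord <- order(score, rows)  # voxel index as the deterministic tiebreak
  sel <- ord[seq_len(min(k, length(ord)))]
  curve <- colMeans(cand[sel, , drop = FALSE])
  structure(list(curve = curve, source_voxels = rows[sel],
                 peak_frame = which.max(curve),
                 frame_interval = conc$frame_interval %||% NULL),
            class = "aif")
}

#' Oscillation index of a residue function
#'
#' OI = sum |r(k) - 2 r(k+1) + r(k+2)| / (L * max r), evaluated over the
#' first `L` samples. Exported (and pluggable in [osvd_deconvolve()]) so
#' that variant normalizations can be swapped in.
#'
#' @param r residue curve
#' @param L number of leading samples entering the index
#' @return nonnegative scalar; 0 for an all-zero curve, `Inf` when the
#'   curve has no positive part
#' @export
oscillation_index <- function(r, L = length(r)) {
  r <- r[seq_len(L)]
  mx <- max(r)
  if (mx <= 0) return(if (all(r == 0)) 0 else Inf)
  sum(abs(diff(r, differences = 2L))) / (L * mx)
}

# Fast column maxima/minima.
col_max <- function(m) {
  i <- max.col(t(m), ties.method = "first")
  m[cbind(i, seq_len(ncol(m)))]
}
col_min <- function(m) -col_max(-m)

# Moving-average smoothing that leaves curve endpoints unsmoothed.
smooth_curve <- function(x, width) {
  if (width <= 1L) return(x)
  f <- stats::filter(x, rep(1 / width, width), sides = 2L)
  f[is.na(f)] <- x[is.na(f)]
  as.numeric(f)
}

#' Oscillation-index-regularized block-circulant SVD deconvolution
#'
#' Estimates flow-scaled residue functions and CBF by circular
#' deconvolution of tissue concentration curves with an arterial reference
#' curve. Curves of length L are zero-padded to 2L and the convolution is
#' expressed as a block-circulant matrix (with the frame interval folded
#' in), whose SVD is computed once. Tissue curves and the AIF are first
#' smoothed with the same moving-average kernel (`smooth_width` frames):
#' because convolution commutes, filtering both sides leaves the underlying
#' residue unchanged while suppressing frame-to-frame noise at this short
#' repetition time.
#'
#' For every voxel the number of retained singular components is chosen
#' adaptively over a truncation grid scanned from strong regularization
#' toward the full spectrum: the least-regularized reconstruction whose
#' residue both keeps its oscillation index at or below `oi_threshold` and
#' keeps its negative lobe within `max_negative_fraction` of its peak is
#' selected (residue functions are nonnegative up to filtering ripple, so a
#' growing negative lobe marks the onset of the smooth instability that the
#' oscillation index alone cannot see). If no truncation qualifies, the
#' strongest regularization on the grid is used. CBF is the maximum of the
#' selected residue over its first L samples.
#'
#' @param tissue_conc a `conc_series` or a voxels-by-frames matrix of
#'   concentration curves (NA frames are treated as 0)
#' @param aif an [extract_aif()] object or a numeric AIF curve of the same
#'   frame length
#' @param oi_threshold oscillation-index limit (default 0.17)
#' @param dt frame interval in seconds (taken from the inputs when present)
#' @param n_grid number of candidate truncations scanned (log-spaced)
#' @param smooth_width moving-average width (frames) applied to tissue and
#'   AIF alike; 1 disables
#' @param max_negative_fraction largest tolerated ratio of the residue's
#'   negative excursion to its peak
#' @param oi_fun oscillation-index function, signature `(r, L)`; the default
#'   is [oscillation_index()]
#' @return list of class `osvd_fit`: `cbf` (per voxel), `residue`
#'   (L x nvox matrix at the selected truncation), `n_components`,
#'   `oscillation_index` per voxel, `dt`, `L`
#' @export
osvd_deconvolve <- function(tissue_conc, aif, oi_threshold = 0.17, dt = NULL,
                            n_grid = 64L, smooth_width = 5L,
                            max_negative_fraction = 0.3, oi_fun = NULL) {
  cm <- conc_matrix(tissue_conc)
  if (inherits(tissue_conc, "conc_series"))
    dt <- dt %||% tissue_conc$frame_interval
  a <- if (inherits(aif, "aif")) aif$curve else as.numeric(aif)
  if (inherits(aif, "aif")) dt <- dt %||% aif$frame_interval
  if (is.null(dt)) stop("frame interval dt is required")
  stopifnot(dt > 0)
  L <- ncol(cm)
  if (length(a) != L) stop("AIF length must match the tissue curves")
  if (all(a == 0)) stop("AIF is identically zero")
  cm[is.na(cm)] <- 0

  if (smooth_width > 1L) {
    a <- smooth_curve(a, smooth_width)
    tcm <- t(cm)  # filter() runs column-wise
    f <- stats::filter(tcm, rep(1 / smooth_width, smooth_width), sides = 2L)
    na <- is.na(f)
    f[na] <- tcm[na]
    cm <- t(f)
  }

  N <- 2L * L
  # block-circulant convolution matrix: column j is the zero-padded AIF
  # circularly shifted by j - 1, scaled by dt
  first_col <- dt * c(a, numeric(L))
  idx <- outer(seq_len(N), seq_len(N), function(i, j) ((i - j) %% N) + 1L)
  D <- matrix(first_col[idx], N, N)
  sv <- svd(D)

  B <- crossprod(sv$u, rbind(t(cm), matrix(0, L, nrow(cm))))  # N x nvox
  Bs <- B / sv$d

  grid <- sort(unique(pmin(N, pmax(1L, round(exp(seq(log(2), log(N),
                                                     length.out = n_grid)))))))
  nvox <- nrow(cm)
  Rcur <- matrix(0, N, nvox)
  best_m <- rep(grid[1L], nvox)     # strongest regularization as fallback
  best_oi <- rep(NA_real_, nvox)
  prev <- 0L
  use_custom <- !is.null(oi_fun)
  # pass 1: scan the truncation grid, record each voxel's largest
  # admissible truncation
  for (g in seq_along(grid)) {
    m <- grid[g]
    cols <- seq(prev + 1L, m)
    Rcur <- Rcur + sv$v[, cols, drop = FALSE] %*% Bs[cols, , drop = FALSE]
    prev <- m
    if (use_custom) {
      oi <- apply(Rcur, 2L, oi_fun, L = L)
      mx <- col_max(Rcur[seq_len(L), , drop = FALSE])
      mn <- col_min(Rcur)
    } else {
      met <- .residue_metrics(Rcur, L)
      mx <- met$max_l
      mn <- met$min_all
      oi <- ifelse(mx > 0, met$d2sum / (L * mx),
                   ifelse(met$d2sum == 0, 0, Inf))
    }
    ok <- oi <= oi_threshold & (mx <= 0 | -mn <= max_negative_fraction * mx)
    if (g == 1L) best_oi <- oi
    if (any(ok)) {
      best_m[ok] <- m
      best_oi[ok] <- oi[ok]
    }
  }
  # pass 2: rebuild the selected reconstruction, voxels grouped by their
  # chosen truncation
  Rbest <- matrix(0, N, nvox)
  for (m in sort(unique(best_m))) {
    vv <- which(best_m == m)
    Rbest[, vv] <- sv$v[, seq_len(m), drop = FALSE] %*%
      Bs[seq_len(m), vv, drop = FALSE]
  }

  res <- Rbest[seq_len(L), , drop = FALSE]
  cbf <- .col_max_l(Rbest, L)
  zero <- rowSums(cm != 0) == 0L
  cbf[zero] <- 0
  res[, zero] <- 0
  structure(list(cbf = cbf, residue = res, n_components = best_m,
                 oscillation_index = best_oi, dt = dt, L = L,
                 oi_threshold = oi_threshold,
                 smooth_width = smooth_width,
                 max_negative_fraction = max_negative_fraction),
            class = "osvd_fit")
}

#' Cerebral blood volume by truncated numeric integration
#'
#' Trapezoidal integral of the concentration curve from the first frame
#' through `truncation_index` (1-based ordinal, inclusive); frames beyond
#' the truncation have no effect on the result. Negative concentration
#' values (noise, recirculation) are clipped to zero for the integration.
#'
#' @param conc a `conc_series` or voxels-by-frames matrix
#' @param truncation_index last integrated frame ordinal
#' @param dt frame interval (s), taken from a `conc_series` when present
#' @param min_frame first frame that must precede the truncation (the
#'   baseline end, used for validation); defaults to 1
#' @return numeric vector of CBV values (concentration x seconds)
#' @export
compute_cbv <- function(conc, truncation_index = NULL, dt = NULL,
                        min_frame = NULL) {
  cm <- conc_matrix(conc)
  if (inherits(conc, "conc_series")) {
    dt <- dt %||% conc$frame_interval
    truncation_index <- truncation_index %||% conc$truncation_index
    min_frame <- min_frame %||% conc$baseline_window[2L]
  }
  if (is.null(dt)) stop("frame interval dt is required")
  if (is.null(truncation_index) || is.na(truncation_index))
    stop("truncation_index is required")
  truncation_index <- min(as.integer(truncation_index), ncol(cm))
  if (!is.null(min_frame) && truncation_index <= min_frame)
    stop("truncation_index must lie beyond the baseline window")
  cm <- cm[, seq_len(truncation_index), drop = FALSE]
  cm[is.na(cm)] <- 0
  cm[cm < 0] <- 0
  trapz_rows(cm, dt)
}

#' Mean transit time by the central volume theorem
#'
#' MTT = CBV / CBF where CBF exceeds `eps`; masked (`NA`) elsewhere, never
#' infinite.
#'
#' @param cbv,cbf numeric vectors or arrays on the same grid
#' @param eps positive flow floor below which MTT is masked
#' @return MTT in the time units implied by CBV/CBF; same shape as input
#' @export
compute_mtt <- function(cbv, cbf, eps = 1e-8) {
  if (!is.null(dim(cbv)) || !is.null(dim(cbf))) check_same_grid(cbv, cbf)
  if (length(cbv) != length(cbf)) stop("cbv and cbf differ in length")
  out <- rep(NA_real_, length(cbf))
  w <- is.finite(cbf) & cbf > eps & is.finite(cbv)
  out[w] <- cbv[w] / cbf[w]
  if (!is.null(dim(cbv))) dim(out) <- dim(cbv)
  out
}

#' Compute CBF, CBV and MTT maps from a DSC series
#'
#' Full per-subject perfusion quantification: signal-to-concentration
#' conversion, automated arterial reference extraction from the
#' contralateral hemisphere, oscillation-index-regularized deconvolution
#' over the brain mask, truncated CBV integration normalized by the AIF
#' integral (so CBV = CBF x MTT in consistent relative units), and the
#' central-volume MTT.
#'
#' @param series a `dsc_series`
#' @param brain_mask logical array of voxels to quantify
#' @param contralateral_mask logical array of AIF candidate voxels
#' @param baseline_window pre-bolus frames for S0
#' @param oi_threshold oscillation-index limit
#' @param aif_k curves averaged into the AIF
#' @param aif_override optional numeric AIF curve ("manual mask" path):
#'   bypasses automated selection
#' @param quantify_mask optional logical array restricting the (costly)
#'   deconvolution to the voxels actually analyzed downstream; defaults to
#'   the whole brain mask
#' @param deconv_start first frame entering the deconvolution window; the
#'   window runs to the end of the series (CBV alone uses the truncation
#'   index). Defaults to 15 frames before the bolus.
#' @param ... further arguments passed to [osvd_deconvolve()]
#' @return list of class `perfusion_maps`: `cbf`, `cbv`, `mtt` (3D arrays,
#'   NA outside the mask), `aif`, `fit` (the `osvd_fit`), `mask`
#' @export
perfusion_maps <- function(series, brain_mask, contralateral_mask,
                           baseline_window = c(20L, 170L),
                           oi_threshold = 0.17, aif_k = 10L,
                           aif_override = NULL, deconv_start = NULL,
                           quantify_mask = NULL, ...) {
  stopifnot(inherits(series, "dsc_series"))
  conc <- signal_to_concentration(series, baseline_window)
  shape <- conc$shape
  quantify <- if (is.null(quantify_mask)) brain_mask else quantify_mask
  rows <- which(as.logical(quantify) & as.logical(brain_mask) & conc$valid)
  if (length(rows) == 0L) stop("brain mask contains no valid voxels")

  aif <- if (is.null(aif_override)) {
    extract_aif(conc, which(as.logical(contralateral_mask)), k = aif_k)
  } else {
    structure(list(curve = as.numeric(aif_override),
                   source_voxels = integer(0),
                   peak_frame = which.max(aif_override),
                   frame_interval = conc$frame_interval), class = "aif")
  }

  trunc_idx <- series$truncation_index
  start <- deconv_start %||% max(1L, series$bolus_image_index - 15L)
  win <- seq(start, ncol(conc$values))
  cm <- conc$values[rows, win, drop = FALSE]
  fit <- osvd_deconvolve(cm, aif$curve[win], oi_threshold = oi_threshold,
                         dt = conc$frame_interval, ...)

  cbv_raw <- compute_cbv(conc$values[rows, , drop = FALSE],
                         truncation_index = trunc_idx,
                         dt = conc$frame_interval,
                         min_frame = baseline_window[2L])
  aif_cbv <- compute_cbv(matrix(aif$curve, nrow = 1L),
                         truncation_index = trunc_idx,
                         dt = conc$frame_interval)
  if (aif_cbv <= 0) stop("AIF integral is non-positive")
  cbv <- cbv_raw / aif_cbv

  to_map <- function(v) {
    m <- array(NA_real_, dim = shape)
    m[rows] <- v
    m
  }
  cbf_map <- to_map(fit$cbf)
  cbv_map <- to_map(cbv)
  mtt_map <- compute_mtt(cbv_map, cbf_map)
  structure(list(cbf = cbf_map, cbv = cbv_map, mtt = mtt_map, aif = aif,
                 fit = fit, mask = to_map(rep(1, length(rows))) == 1,
                 oi_threshold = oi_threshold),
            class = "perfusion_maps")
}
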