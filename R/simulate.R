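#' Acquisition parameters for the synthetic scanner
#'
#' Defaults follow the acquisition this pipeline targets: two-point
#' diffusion weighting at b = 0 and 1454 s/mm^2 along three directions,
#' multi-echo T2 at TE = 30/50/80/190 ms, and a DSC-PWI time series at
#' TR/TE = 164/13 ms with the contrast bolus injected at the 180th image
#' and the concentration integral truncated at the 400th image.
#'
#' @param b_values diffusion b-values in s/mm^2 (first must be 0)
#' @param echo_times multi-echo TE values in ms
#' @param dsc_tr,dsc_te DSC repetition/echo time in ms
#' @param bolus_image_index 1-based frame ordinal of bolus injection
#' @param truncation_index 1-based frame ordinal ending the CBV integral
#' @param n_frames total DSC frames
#' @param noise_sd acquisition noise standard deviation (signal units)
#' @param noise_model "gaussian" (default) or "rician"
#' @param s0 baseline equilibrium signal
#' @param seed RNG seed used by the simulators; NULL leaves the stream alone
#' @return list of class `acquisition_config`
#' @export
acquisition_config <- function(b_values = c(0, 1454),
                               echo_times = c(30, 50, 80, 190),
                               dsc_tr = 164, dsc_te = 13,
                               bolus_image_index = 180L,
                               truncation_index = 400L,
                               n_frames = 420L,
                               noise_sd = 0, noise_model = c("gaussian", "rician"),
                               s0 = 1000, seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(b_values[1L] == 0, all(b_values >= 0),
            all(echo_times > 0), !anyDuplicated(echo_times),
            dsc_tr > 0, dsc_te > 0, s0 > 0)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  bolus_image_index <- as.integer(bolus_image_index)
  truncation_index <- as.integer(truncation_index)
  n_frames <- as.integer(n_frames)
  if (!(bolus_image_index < truncation_index && truncation_index <= n_frames))
    stop("need bolus_image_index < truncation_index <= n_frames")
  structure(list(b_values = b_values, echo_times = echo_times,
                 dsc_tr = dsc_tr, dsc_te = dsc_te,
                 bolus_image_index = bolus_image_index,
                 truncation_index = truncation_index, n_frames = n_frames,
                 noise_sd = noise_sd, noise_model = noise_model,
                 s0 = s0, seed = seed),
            class = "acquisition_config")
}

add_noise <- function(signal, sd, model) {
  if (sd == 0) return(signal)
  n <- length(signal)
  if (model == "rician") {
    sqrt((signal + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
  } else {
    signal + stats::rnorm(n, 0, sd)
  }
}

#' Simulate diffusion-weighted volumes from phantom truth
#'
#' Noiseless signal follows S(b) = S0 * exp(-b * ADC) per gradient
#' direction; the phantom's diffusion truth is isotropic so the three
#' direction volumes are identical before noise.
#'
#' @param phantom a [make_phantom()] object
#' @param config an [acquisition_config()]
#' @param n_directions number of diffusion gradient directions
#' @return list with `b0` (array), `dwi` (list of arrays, one per direction
#'   at the high b-value), and `b` (the high b-value)
#' @export
simulate_dwi <- function(phantom, config = acquisition_config(),
                         n_directions = 3L) {
  if (config$noise_sd < 0) stop("noise_sd must be nonnegative")
  maybe_set_seed(config$seed)
  adc <- phantom$truth$adc
  b_hi <- max(config$b_values)
  s0 <- config$s0 * phantom$brain  # signal only inside the brain
  dwi <- lapply(seq_len(n_directions), function(d) {
    s <- s0 * exp(-b_hi * adc)
    array(add_noise(s, config$noise_sd, config$noise_model), dim = dim(adc))
  })
  b0 <- array(add_noise(s0, config$noise_sd, config$noise_model),
              dim = dim(adc))
  list(b0 = b0, dwi = dwi, b = b_hi)
}

#' Simulate multi-echo T2-weighted volumes from phantom truth
#'
#' Noiseless signal follows S(TE) = S0 * exp(-TE / T2). Voxels with
#' non-positive truth T2 (background) yield zero signal; a truth T2 of
#' `Inf` gives a flat decay (equal signal at all echoes).
#'
#' @inheritParams simulate_dwi
#' @return list with `echoes` (list of arrays, one per TE) and `te` (ms)
#' @export
simulate_multiecho <- function(phantom, config = acquisition_config()) {
  if (config$noise_sd < 0) stop("noise_sd must be nonnegative")
  maybe_set_seed(config$seed)
  t2 <- phantom$truth$t2
  s0 <- config$s0 * phantom$brain
  echoes <- lapply(config$echo_times, function(te) {
    s <- s0 * exp(-ifelse(t2 > 0, te / t2, Inf))
    s[!phantom$brain] <- 0
    array(add_noise(s, config$noise_sd, config$noise_model), dim = dim(t2))
  })
  list(echoes = echoes, te = config$echo_times)
}

#' Gamma-variate arterial input function
#'
#' C_a(t) = A * (t - t0)^alpha * exp(-(t - t0) / beta) for t > t0, else 0.
#'
#' @param t time vector (s)
#' @param t0 bolus arrival time (s)
#' @param alpha shape exponent
#' @param beta time constant (s)
#' @param amplitude scale A (concentration units)
#' @return numeric vector, nonnegative
#' @export
gamma_variate_aif <- function(t, t0, alpha = 3, beta = 1.5, amplitude = 0.09) {
  out <- numeric(length(t))
  w <- t > t0
  out[w] <- amplitude * (t[w] - t0)^alpha * exp(-(t[w] - t0) / beta)
  out
}

# Tissue residue functions sampled at dt with R(0) = 1, so the flow-scaled
# residue peaks exactly at CBF. The trapezoidal integral of the exponential
# equals MTT to O(dt^2), so the concentration integral convention
# int C dt = CBV * int AIF dt holds to the same order.
residue_curve <- function(n, dt, mtt, family = c("exponential", "boxcar")) {
  family <- match.arg(family)
  tau <- (seq_len(n) - 1L) * dt
  switch(family,
    exponential = exp(-tau / mtt),
    boxcar = as.numeric(tau < mtt))
}

#' Simulate a DSC-PWI time series from phantom perfusion truth
#'
#' Per voxel the concentration curve is the convolution
#' C(t) = CBF * (AIF (*) R)(t) * dt with residue R from `residue_family`,
#' normalized so that the full-curve concentration integral equals
#' CBV * integral(AIF). Signal follows the transverse relaxivity relation
#' S(t) = S0 * exp(-TE * k * C(t)) with k = 1 in relative units; frames
#' before the bolus are at baseline.
#'
#' @inheritParams simulate_dwi
#' @param aif_spec list of gamma-variate parameters (`alpha`, `beta`,
#'   `amplitude`); the bolus arrival is pinned to
#'   `config$bolus_image_index`
#' @param residue_family "exponential" or "boxcar"
#' @param artery_scale arterial voxels (atlas label "artery") carry the
#'   arterial concentration directly, C(t) = artery_scale * AIF(t), rather
#'   than a convolved tissue curve; the default gives them a deep,
#'   physiological signal drop
#' @param keep_truth if TRUE, attach the noiseless concentration array
#' @return object of class `dsc_series`: 4D `data` array (x, y, z, frame)
#'   plus timing metadata
#' @export
simulate_dsc <- function(phantom, config = acquisition_config(),
                         aif_spec = list(alpha = 3, beta = 1.5, amplitude = 0.09),
                         residue_family = c("exponential", "boxcar"),
                         artery_scale = 280, keep_truth = FALSE) {
  residue_family <- match.arg(residue_family)
  if (config$noise_sd < 0) stop("noise_sd must be nonnegative")
  maybe_set_seed(config$seed)
  cbf <- phantom$truth$cbf; cbv <- phantom$truth$cbv; mtt <- phantom$truth$mtt
  if (any(cbf > 0 & mtt <= 0))
    stop("MTT must be positive wherever CBF > 0")

  dt <- config$dsc_tr / 1000
  n <- config$n_frames
  t <- (seq_len(n) - 1L) * dt
  t0 <- (config$bolus_image_index - 1L) * dt
  aif <- gamma_variate_aif(t, t0, aif_spec$alpha %||% 3, aif_spec$beta %||% 1.5,
                           aif_spec$amplitude %||% 0.09)
  if (any(aif < 0)) stop("AIF specification yields a negative curve")

  # arterial voxels carry the input function itself
  is_artery <- if (!is.null(phantom$labels)) {
    phantom$labels == atlas_labels[["artery"]]
  } else array(FALSE, dim = dim(cbf))

  # concentration per unique (CBF, MTT) tissue class
  key <- paste(cbf, mtt)
  key[is_artery] <- "artery"
  uk <- unique(key[cbf > 0 | is_artery])
  conc_class <- matrix(0, nrow = length(uk), ncol = n,
                       dimnames = list(uk, NULL))
  for (i in seq_along(uk)) {
    if (uk[i] == "artery") {
      conc_class[i, ] <- artery_scale * aif
      next
    }
    v <- which(key == uk[i])[1L]
    r <- residue_curve(n, dt, mtt[v], residue_family)
    cc <- cbf[v] * dt * stats::convolve(aif, rev(r), type = "open")[seq_len(n)]
    conc_class[i, ] <- cc
  }
  # pre-bolus frames are exactly baseline (clears FFT round-off dust)
  conc_class[, seq_len(config$bolus_image_index - 1L)] <- 0
  te_s <- config$dsc_te / 1000
  shape <- dim(cbf)
  nvox <- prod(shape)
  s0 <- as.numeric(config$s0 * phantom$brain)
  sig <- matrix(0, nrow = nvox, ncol = n)
  brain_rows <- which(as.logical(phantom$brain))
  sig[brain_rows, ] <- config$s0
  rows <- match(key, uk)
  has <- which(!is.na(rows) & (cbf > 0 | is_artery))
  sig[has, ] <- s0[has] * exp(-te_s * conc_class[rows[has], , drop = FALSE])
  if (config$noise_sd > 0) {
    # background carries noise too, but only brain rows are ever analyzed;
    # restrict the draw to keep large cohorts fast
    sig[brain_rows, ] <- add_noise(sig[brain_rows, ], config$noise_sd,
                                   config$noise_model)
  }
  out <- structure(list(data = array(sig, dim = c(shape, n)),
                        tr = config$dsc_tr, te = config$dsc_te,
                        frame_interval = dt,
                        bolus_image_index = config$bolus_image_index,
                        truncation_index = config$truncation_index,
                        s0 = config$s0, aif_truth = aif),
                   class = "dsc_series")
  if (keep_truth) {
    conc <- matrix(0, nrow = nvox, ncol = n)
    conc[has, ] <- conc_class[rows[has], , drop = FALSE]
    out$truth_conc <- array(conc, dim = c(shape, n))
  }
  out
}

#' @export
print.dsc_series <- function(x, ...) {
  d <- dim(x$data)
  cat("dsc_series:", paste(d[1:3], collapse = " x "), "voxels,", d[4L],
      "frames @", x$frame_interval, "s; bolus at frame",
      x$bolus_image_index, "\n")
  invisible(x)
}
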