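# Shared fixtures, built in code. The cache avoids regenerating the same
# deterministic phantom across test files.

.fixtures <- new.env(parent = emptyenv())

small_phantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- make_phantom(shape = c(24L, 24L, 8L),
                                      lesion = lesion_spec(radii = c(4.5, 5, 2.5)),
                                      voxel_size = c(0.6, 0.6, 1.5))
  .fixtures$phantom
}

# A minimal phantom-like object with hand-set truth maps, for closed-form
# forward-model checks.
flat_phantom <- function(adc = 7e-4, t2 = 50, cbf = 60, mtt = 4,
                         shape = c(4L, 4L, 2L)) {
  ones <- array(1, dim = shape)
  brain <- array(TRUE, dim = shape)
  cbv <- cbf * mtt
  structure(list(labels = array(2L, dim = shape), brain = brain,
                 hemisphere = array(rep(c(1L, 2L), each = shape[1L] / 2L),
                                    dim = shape),
                 voxel_size = c(1, 1, 1), midline_axis = 1L,
                 voxel_volume_ul = 1,
                 truth = list(adc = adc * ones, t2 = t2 * ones,
                              cbf = cbf * ones, cbv = cbv * ones,
                              mtt = mtt * ones)),
            class = c("stroke_phantom", "stroke_atlas"))
}

# Gamma-variate AIF and forward-convolved tissue curves on the acquisition
# time base, independent of the deconvolution code path (open discrete
# convolution of full-length curves).
forward_dsc_curves <- function(cbf, mtt, n = 420L, dt = 0.164,
                               bolus = 180L, amplitude = 0.09) {
  t <- (seq_len(n) - 1L) * dt
  aif <- gamma_variate_aif(t, (bolus - 1L) * dt, amplitude = amplitude)
  cm <- t(vapply(seq_along(cbf), function(i) {
    r <- exp(-(t - t[1L]) / mtt[i])
    cbf[i] * dt * stats::convolve(aif, rev(r), type = "open")[seq_len(n)]
  }, numeric(n)))
  list(aif = aif, conc = cm, dt = dt, t = t)
}

# Signal-domain noise at a given baseline SNR, returned as concentration.
conc_with_snr <- function(conc, snr, te_s = 0.013, s0 = 1000) {
  sig <- s0 * exp(-te_s * conc) +
    matrix(stats::rnorm(length(conc), 0, s0 / snr), nrow = nrow(conc))
  -log(pmax(sig, 1e-12) / s0) / te_s
}

# Null-effect cohort specification for type-I error simulations.
null_effect_spec <- function(n_per_group = 10L, seed = NULL) {
  cohort_effect_spec(
    n_per_group = n_per_group,
    vc_cell_mean = list(F45 = -20, F90 = -20, M45 = -20, M90 = -20),
    beta_cbf = 0, beta_cbv = 0, beta_mtt = 0,
    rr_timepoint = list(
      occlusion = list(cbf = 100, cbf_sd = 15, cbv = 100, cbv_sd = 15),
      post_0.5h = list(cbf = 100, cbf_sd = 15, cbv = 100, cbv_sd = 15),
      day4 = list(cbf = 100, cbf_sd = 15, cbv = 100, cbv_sd = 15)),
    seed = seed)
}
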