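test_that("signal-to-concentration conversion inverts the relaxivity model", {
  n <- 60L
  s0 <- 800
  sig <- matrix(s0, nrow = 3L, ncol = n)
  te_s <- 0.013
  c_true <- c(0, 2, 35)
  for (i in 1:3) sig[i, 31:60] <- s0 * exp(-te_s * c_true[i])
  conc <- signal_to_concentration(sig, baseline_window = c(1L, 30L),
                                  te_ms = 13, frame_interval = 0.164)
  expect_equal(conc$values[, 60L], c_true, tolerance = 1e-12)
  expect_true(all(conc$values[, 1:30] == 0))

  # non-positive frames are masked, non-positive baselines drop the voxel
  sig2 <- sig; sig2[2L, 40L] <- -1
  conc2 <- signal_to_concentration(sig2, c(1L, 30L), 13, 0.164)
  expect_true(is.na(conc2$values[2L, 40L]))
  sig3 <- sig; sig3[1L, 1:30] <- 0
  conc3 <- signal_to_concentration(sig3, c(1L, 30L), 13, 0.164)
  expect_false(conc3$valid[1L])

  expect_error(signal_to_concentration(sig, c(31L, 30L), 13, 0.164))
})

test_that("simulator round-trip recovers planted concentration exactly", {
  ph <- small_phantom()
  cfg <- acquisition_config(noise_sd = 0)
  dsc <- simulate_dsc(ph, cfg, keep_truth = TRUE)
  conc <- signal_to_concentration(dsc)
  tc <- matrix(dsc$truth_conc, nrow = prod(dim(ph$labels)))
  w <- which(ph$brain & ph$truth$cbf > 0)
  expect_lt(max(abs(conc$values[w, ] - tc[w, ])) / max(tc), 1e-9)
})

test_that("arterial reference extraction is deterministic and sensible", {
  n <- 80L
  t <- (seq_len(n) - 1L) * 0.164
  base <- gamma_variate_aif(t, t0 = 2, amplitude = 1)
  cm <- rbind(base, base, base)
  conc <- list(values = cm, valid = rep(TRUE, 3L), frame_interval = 0.164,
               bolus_image_index = 13L)
  class(conc) <- "conc_series"

  # single-voxel mask: the AIF is that voxel's curve
  a1 <- extract_aif(conc, c(TRUE, FALSE, FALSE))
  expect_equal(a1$curve, unname(base))
  # identical voxels: independent of k
  a2 <- extract_aif(conc, rep(TRUE, 3L), k = 2L)
  a3 <- extract_aif(conc, rep(TRUE, 3L), k = 10L)
  expect_equal(a2$curve, a3$curve)

  # no post-bolus peak anywhere: error
  flat <- conc; flat$values <- matrix(0, 3L, n)
  expect_error(extract_aif(flat, rep(TRUE, 3L)), "peak")
  expect_error(extract_aif(conc, rep(FALSE, 3L)), "empty")
})

test_that("planted arterial voxels dominate automated AIF selection", {
  ph <- small_phantom()
  hits <- vapply(1:20, function(s) {
    cfg <- acquisition_config(noise_sd = 20, seed = 1000L + s)
    dsc <- simulate_dsc(ph, cfg)
    conc <- signal_to_concentration(dsc)
    aif <- extract_aif(conc, ph$brain & ph$hemisphere == 1L)
    all(ph$labels[aif$source_voxels] == atlas_labels[["artery"]])
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("deconvolution recovers an impulse-kernel identity", {
  L <- 60L; dt <- 0.164
  f <- 8L
  aif <- numeric(L); aif[f] <- 1 / dt          # unit-area impulse at frame f
  r_true <- exp(-(seq_len(L) - 1L) * dt / 1.5)
  cbf <- 35
  tissue <- rep(0, L)
  tissue[f:L] <- cbf * r_true[seq_len(L - f + 1L)]
  fit <- osvd_deconvolve(matrix(tissue, 1L), aif, dt = dt, smooth_width = 1L)
  expect_equal(fit$cbf, cbf, tolerance = 1e-6)

  # zero tissue curve: CBF 0 with a flat residue, not an error
  fit0 <- osvd_deconvolve(matrix(0, 1L, L), aif, dt = dt)
  expect_identical(fit0$cbf, 0)
  expect_true(all(fit0$residue == 0))

  expect_error(osvd_deconvolve(matrix(tissue, 1L), numeric(L), dt = dt),
               "zero")
})

test_that("deconvolution is scale-equivariant in tissue and AIF", {
  set.seed(21)
  fw <- forward_dsc_curves(cbf = c(40, 80), mtt = c(3, 6))
  win <- 165:420
  cm <- fw$conc[, win]; aif <- fw$aif[win]
  f1 <- osvd_deconvolve(cm, aif, dt = fw$dt)
  f2 <- osvd_deconvolve(3 * cm, aif, dt = fw$dt)
  f3 <- osvd_deconvolve(cm, 2 * aif, dt = fw$dt)
  expect_equal(f2$cbf, 3 * f1$cbf, tolerance = 1e-8)
  expect_equal(f3$cbf, f1$cbf / 2, tolerance = 1e-8)
})

test_that("oscillation index of every reported residue is within threshold", {
  set.seed(22)
  fw <- forward_dsc_curves(cbf = runif(30, 20, 100), mtt = runif(30, 2, 10))
  cm <- conc_with_snr(fw$conc, snr = 50)
  win <- 165:420
  fit <- osvd_deconvolve(cm[, win], fw$aif[win], dt = fw$dt)
  oi <- vapply(seq_len(ncol(fit$residue)), function(j)
    oscillation_index(fit$residue[, j], fit$L), numeric(1L))
  expect_true(all(oi <= 0.17 + 1e-12))
  expect_true(all(fit$oscillation_index <= 0.17 + 1e-12))
})

test_that("truncated CBV integration follows the trapezoid contract", {
  dt <- 0.164
  # zero curve
  expect_equal(compute_cbv(matrix(0, 1L, 500L), 400L, dt), 0)
  # constant curve: integral = c * T with T the window duration
  cm <- matrix(2.5, 1L, 500L)
  expect_equal(compute_cbv(cm, 400L, dt), 2.5 * dt * 399L)
  # frames past the truncation index are irrelevant, bit-exactly
  set.seed(23)
  a <- matrix(runif(500), 1L)
  b <- a; b[, 401:500] <- 99
  expect_identical(compute_cbv(a, 400L, dt), compute_cbv(b, 400L, dt))
  # negative values are clipped for the integration
  neg <- matrix(-1, 1L, 500L)
  expect_equal(compute_cbv(neg, 400L, dt), 0)
  expect_error(compute_cbv(a, 400L, dt, min_frame = 450L), "beyond")
})

test_that("central-volume MTT masks zero flow instead of dividing", {
  expect_equal(compute_mtt(8, 2), 4)
  expect_true(is.na(compute_mtt(8, 0)))
  m <- compute_mtt(array(c(8, 8), c(2, 1, 1)), array(c(2, 0), c(2, 1, 1)))
  expect_equal(as.numeric(m), c(4, NA))
})

test_that("CBV is linear in concentration", {
  set.seed(24)
  a <- matrix(runif(420), 1L); b <- matrix(runif(420), 1L)
  dt <- 0.164
  expect_equal(compute_cbv(a + b, 400L, dt),
               compute_cbv(a, 400L, dt) + compute_cbv(b, 400L, dt),
               tolerance = 1e-12)
})

test_that("noiseless voxelwise MTT estimates stay within 10% of truth", {
  set.seed(25)
  cbf <- runif(40, 20, 100); mtt <- runif(40, 2, 10)
  fw <- forward_dsc_curves(cbf, mtt)
  win <- 165:420
  fit <- osvd_deconvolve(fw$conc[, win], fw$aif[win], dt = fw$dt)
  cbv <- compute_cbv(fw$conc, 400L, fw$dt) /
    compute_cbv(matrix(fw$aif, 1L), 400L, fw$dt)
  mtt_est <- compute_mtt(cbv, fit$cbf)
  expect_lt(max(abs(mtt_est - mtt) / mtt), 0.10)
})
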