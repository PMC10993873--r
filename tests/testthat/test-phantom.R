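test_that("atlas label volume is mirror-symmetric with disjoint CSF", {
  a <- make_atlas(c(24L, 24L, 8L))
  expect_identical(a$labels, mirror_volume(a$labels, a$midline_axis))
  expect_true(all(a$labels[a$labels == atlas_labels[["csf"]]] !=
                    atlas_labels[["cortex"]]))
  expect_true(sum(a$labels %in% mca_reference_labels() &
                    a$hemisphere == 1L) >= 100L)
})

test_that("fate composition of the planted lesion follows the set algebra", {
  ph <- small_phantom()
  lt <- ph$lesion_truth
  expect_identical(lt$core | lt$salvageable, lt$acute)
  expect_identical(lt$core | lt$delayed, lt$subacute)
  expect_false(any(lt$core & lt$delayed))
  expect_false(any(lt$salvageable & lt$delayed))

  # core-only lesion: identical acute and subacute masks
  ph_eq <- make_phantom(c(24L, 24L, 8L),
                        lesion_spec(radii = c(4, 4, 2), volume_change_pct = 0,
                                    subacute_shift = c(0, 0, 0)))
  expect_identical(ph_eq$lesion_truth$acute, ph_eq$lesion_truth$subacute)
  expect_false(any(ph_eq$lesion_truth$salvageable))
  expect_false(any(ph_eq$lesion_truth$delayed))

  # shrinking lesion without shift: subacute strictly inside acute
  ph_shr <- make_phantom(c(24L, 24L, 8L),
                         lesion_spec(radii = c(4.5, 5, 2.5),
                                     volume_change_pct = -40,
                                     subacute_shift = c(0, 0, 0)))
  expect_false(any(ph_shr$lesion_truth$subacute & !ph_shr$lesion_truth$acute))
  expect_false(any(ph_shr$lesion_truth$delayed))
})

test_that("phantom construction rejects midline-crossing and empty lesions", {
  expect_error(make_phantom(c(24L, 24L, 8L),
                            lesion_spec(center = c(12, 12, 4),
                                        radii = c(6, 6, 2))),
               "midline")
  expect_error(make_phantom(c(24L, 24L, 8L),
                            lesion_spec(center = c(23, 2, 1),
                                        radii = c(0.1, 0.1, 0.1))),
               "empty")
})

test_that("phantom truth satisfies the central volume theorem exactly", {
  ph <- small_phantom()
  w <- ph$truth$cbf > 0
  expect_identical(ph$truth$mtt[w], ph$truth$cbv[w] / ph$truth$cbf[w])
  # lesion-core ADC is reduced by at least 30% against contralateral tissue
  contra <- ph$truth$adc[ph$labels %in% mca_reference_labels() &
                           ph$hemisphere == 1L]
  expect_true(mean(ph$truth$adc[ph$lesion_truth$core]) <
                0.7 * mean(contra))
  expect_true(mean(ph$truth$t2[ph$lesion_truth$subacute]) >
                mean(ph$truth$t2[mirror_volume(ph$lesion_truth$subacute)]))
})

test_that("diffusion forward model follows S(b) = S0 exp(-b ADC)", {
  ph <- flat_phantom(adc = 7e-4)
  cfg <- acquisition_config(noise_sd = 0)
  d <- simulate_dwi(ph, cfg)
  expect_equal(unique(as.numeric(d$dwi[[1L]])),
               cfg$s0 * exp(-1454 * 7e-4), tolerance = 1e-12)
  expect_equal(d$dwi[[1L]], d$dwi[[3L]])  # isotropic truth

  ph0 <- flat_phantom(adc = 0)
  d0 <- simulate_dwi(ph0, cfg)
  expect_equal(d0$dwi[[2L]], d0$b0)

  cfg_bad <- acquisition_config()
  cfg_bad$noise_sd <- -1
  expect_error(simulate_dwi(ph, cfg_bad), "nonnegative")
})

test_that("multi-echo forward model follows S(TE) = S0 exp(-TE/T2)", {
  ph <- flat_phantom(t2 = 50)
  cfg <- acquisition_config(noise_sd = 0)
  m <- simulate_multiecho(ph, cfg)
  expect_equal(as.numeric(m$echoes[[3L]][1, 1, 1] / m$echoes[[1L]][1, 1, 1]),
               exp(-1), tolerance = 1e-12)  # TE 80 vs 30 at T2 = 50
  ph_inf <- flat_phantom(t2 = Inf)
  m_inf <- simulate_multiecho(ph_inf, cfg)
  expect_equal(m_inf$echoes[[1L]], m_inf$echoes[[4L]])
})

test_that("DSC forward model is linear in CBV and respects baselines", {
  shape <- c(4L, 4L, 2L)
  ph <- flat_phantom(cbf = 60, mtt = 4, shape = shape)
  # two tissue classes with CBV ratio 2:1 at equal MTT
  ph$truth$cbf[1:16] <- 30
  ph$truth$cbv <- ph$truth$cbf * ph$truth$mtt
  cfg <- acquisition_config(noise_sd = 0, n_frames = 420L)
  dsc <- simulate_dsc(ph, cfg, keep_truth = TRUE)
  tc <- matrix(dsc$truth_conc, nrow = prod(shape))
  int_hi <- sum(tc[32L, ]); int_lo <- sum(tc[1L, ])
  expect_equal(int_hi / int_lo, 2, tolerance = 1e-12)

  # zero-flow voxels stay at baseline for every frame
  ph0 <- flat_phantom(cbf = 0, mtt = 4, shape = shape)
  ph0$truth$cbv <- ph0$truth$cbf * ph0$truth$mtt
  d0 <- simulate_dsc(ph0, cfg)
  expect_true(all(d0$data == cfg$s0))

  # frames before the bolus are at baseline
  pre <- matrix(dsc$data[, , , seq_len(cfg$bolus_image_index - 1L)],
                nrow = prod(shape))
  expect_true(all(pre[ph$brain, ] == cfg$s0))

  expect_error(simulate_dsc(flat_phantom(mtt = 0), cfg), "MTT")
})

test_that("exponential-residue DSC curves have first-moment shift near MTT", {
  fw <- forward_dsc_curves(cbf = 50, mtt = 4)
  t <- fw$t
  fm <- function(x) sum(t * x) / sum(x)
  # first moment of C minus first moment of the AIF approximates the MTT of
  # the exponential residue (moment-matching oracle on the discrete curves)
  expect_equal(fm(fw$conc[1L, ]) - fm(fw$aif), 4, tolerance = 0.05)
})

test_that("seeded simulation is bit-reproducible", {
  ph <- small_phantom()
  cfg <- acquisition_config(noise_sd = 15, seed = 42L)
  expect_identical(simulate_dwi(ph, cfg), simulate_dwi(ph, cfg))
  expect_identical(simulate_dsc(ph, cfg)$data, simulate_dsc(ph, cfg)$data)
  spec <- cohort_effect_spec(seed = 7L)
  expect_identical(make_cohort(spec), make_cohort(spec))
})

test_that("cohort generator reproduces planted group structure", {
  # null effects: sex difference in volume change vanishes at large n
  spec0 <- null_effect_spec(n_per_group = 250L, seed = 3L)
  coh0 <- make_cohort(spec0)
  st0 <- cohort_subject_table(coh0)
  d <- st0$volume_change
  diff0 <- mean(d[st0$sex == "F"]) - mean(d[st0$sex == "M"])
  se <- sqrt(stats::var(d[st0$sex == "F"]) / sum(st0$sex == "F") +
               stats::var(d[st0$sex == "M"]) / sum(st0$sex == "M"))
  expect_lt(abs(diff0), 3 * se)

  # planted -25 point female-vs-male difference recovered within 2 pooled SE
  spec1 <- cohort_effect_spec(
    n_per_group = 10L,
    vc_cell_mean = list(F45 = -30, F90 = -30, M45 = -5, M90 = -5),
    seed = 4L)
  st1 <- cohort_subject_table(make_cohort(spec1))
  d1 <- st1$volume_change
  diff1 <- mean(d1[st1$sex == "F"]) - mean(d1[st1$sex == "M"])
  se1 <- sqrt(stats::var(d1[st1$sex == "F"]) / 20 +
                stats::var(d1[st1$sex == "M"]) / 20)
  expect_lt(abs(diff1 - (-25)), 2 * se1)

  expect_error(cohort_effect_spec(vc_sd = -1))
  expect_error(cohort_effect_spec(n_per_group = 1L))
})
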