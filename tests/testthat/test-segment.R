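test_that("reference statistics exclude CSF and demand variability", {
  a <- make_atlas(c(24L, 24L, 8L))
  sel <- a$labels %in% mca_reference_labels() & a$hemisphere == 1L
  map <- array(0.75e-3, dim = dim(a$labels))
  n_ref <- sum(sel)
  map[sel] <- seq(1, 100, length.out = n_ref) * 1e-5  # spread below CSF cutoff

  rs <- reference_stats(map, a, "adc")
  vals <- seq(1, 100, length.out = n_ref) * 1e-5
  expect_equal(rs$mean, mean(vals))
  expect_equal(rs$sd, sd(vals))
  expect_equal(rs$n, n_ref)

  # constant region: sd = 0 is rejected
  mapc <- array(0.75e-3, dim = dim(a$labels))
  expect_error(reference_stats(mapc, a, "adc"), "SD")
  # too few voxels after raising the floor
  expect_error(reference_stats(map, a, "adc", min_voxels = n_ref + 1L),
               "reference voxels")

  # planting CSF-like high values inside the reference region leaves the
  # statistics unchanged (parameter-cutoff exclusion oracle)
  t2map <- array(48, dim = dim(a$labels))
  idx <- which(sel)
  set.seed(31)
  t2map[idx] <- rnorm(n_ref, 48, 3)
  base <- reference_stats(t2map, a, "t2")
  t2csf <- t2map
  t2csf[idx[1:20]] <- 150  # CSF-like, above the 90 ms cutoff
  with_csf <- reference_stats(t2csf, a, "t2")
  ref_vals <- t2map[idx][-(1:20)]
  expect_equal(with_csf$mean, mean(ref_vals[ref_vals <= 90]))
})

test_that("lesion thresholding follows the strict 2-SD contracts", {
  a <- make_atlas(c(24L, 24L, 8L))
  set.seed(32)
  map <- array(rnorm(prod(dim(a$labels)), 0.75e-3, 2e-5), dim = dim(a$labels))
  rs <- reference_stats(map, a, "adc")
  ipsi <- a$hemisphere == 2L & a$brain & a$labels != atlas_labels[["csf"]]
  i1 <- which(ipsi)[1:3]
  map[i1[1L]] <- rs$mean - 2.5 * rs$sd   # below: lesioned
  map[i1[2L]] <- rs$mean                 # at the mean: not lesioned
  map[i1[3L]] <- rs$mean - 2.0 * rs$sd   # exactly at threshold: strict, out
  m <- threshold_lesion(map, rs, a, "adc")
  expect_true(m[i1[1L]])
  expect_false(m[i1[2L]])
  expect_false(m[i1[3L]])
  # contralateral voxels are never segmented
  expect_false(any(m[a$hemisphere == 1L]))

  # T2 mode: above mean + 2 sd, reversed side; monotone in the voxel value
  t2 <- array(rnorm(prod(dim(a$labels)), 48, 2), dim = dim(a$labels))
  rt <- reference_stats(t2, a, "t2")
  t2a <- t2; t2a[i1[1L]] <- rt$mean + 3 * rt$sd
  ma <- threshold_lesion(t2a, rt, a, "t2")
  expect_true(ma[i1[1L]])
  t2b <- t2a; t2b[i1[1L]] <- t2a[i1[1L]] + 5  # raising T2 keeps membership
  mb <- threshold_lesion(t2b, rt, a, "t2")
  expect_true(all(ma[i1[1L]] <= mb[i1[1L]]))
  expect_error(threshold_lesion(t2a, rs, a, "t2"), "mode")
})

test_that("mask cleanup removes specks, closes holes and is idempotent", {
  empty <- array(FALSE, dim = c(10L, 10L, 6L))
  expect_identical(clean_mask(empty), empty)

  single <- empty; single[5, 5, 3] <- TRUE
  expect_false(any(clean_mask(single, min_cluster_voxels = 2L)))

  set.seed(33)
  for (i in 1:100) {
    m <- array(runif(10 * 10 * 6) < 0.25, dim = c(10L, 10L, 6L))
    c1 <- clean_mask(m, min_cluster_voxels = 4L, closing_radius = 1L)
    expect_identical(clean_mask(c1, min_cluster_voxels = 4L,
                                closing_radius = 1L), c1)
  }
})

test_that("fate parcellation identities hold exactly", {
  sh <- c(6L, 6L, 4L)
  # enumeration example: acute = {a, b}, subacute = {b, c}
  acute <- array(FALSE, sh); subac <- array(FALSE, sh)
  acute[1:2] <- TRUE; subac[2:3] <- TRUE
  f <- classify_fate(acute, subac)
  expect_identical(which(f$core), 2L)
  expect_identical(which(f$salvageable), 1L)
  expect_identical(which(f$delayed), 3L)

  # equal masks: everything is core
  fe <- classify_fate(acute, acute)
  expect_identical(fe$core, acute)
  expect_false(any(fe$salvageable) || any(fe$delayed))

  expect_error(classify_fate(acute, array(FALSE, c(5L, 6L, 4L))), "grid")

  set.seed(34)
  for (i in 1:1000) {
    a <- array(runif(48) < 0.4, dim = c(4L, 4L, 3L))
    s <- array(runif(48) < 0.4, dim = c(4L, 4L, 3L))
    ff <- classify_fate(a, s)
    expect_identical(sum(ff$core) + sum(ff$salvageable), sum(a))
    expect_identical(sum(ff$core) + sum(ff$delayed), sum(s))
    expect_identical(ff$core | ff$salvageable, a)
    expect_identical(ff$core | ff$delayed, s)
    expect_false(any((ff$core & ff$salvageable) | (ff$core & ff$delayed) |
                       (ff$salvageable & ff$delayed)))
  }
})

test_that("mirroring is an exact involution that preserves volume", {
  m <- array(FALSE, dim = c(8L, 6L, 4L))
  m[6, 2, 3] <- TRUE
  mm <- mirror_homologue(m)
  expect_true(mm[3, 2, 3])   # 8 + 1 - 6
  expect_identical(sum(mm), sum(m))
  expect_identical(suppressWarnings(mirror_homologue(mm)), m)
  # a midline-touching mask warns about self-overlap
  m2 <- m; m2[4:5, 2, 3] <- TRUE
  expect_warning(mirror_homologue(m2), "overlap")
})

test_that("volume metrics and the inclusion rule follow the arithmetic", {
  sh <- c(50L, 20L, 10L)
  hemi <- array(FALSE, sh); hemi[seq_len(10000L)] <- TRUE
  acute <- array(FALSE, sh); acute[seq_len(100L)] <- TRUE
  f <- classify_fate(acute, array(FALSE, sh))
  vm <- volume_metrics(f, hemi, voxel_volume_ul = 0.0135)
  expect_equal(vm$hemisphere_fraction[vm$roi == "acute"], 0.01)
  expect_equal(vm$volume_ul[vm$roi == "acute"], 1.35)
  expect_false(attr(vm, "included"))   # 1.35 uL < 30 uL

  f0 <- classify_fate(array(FALSE, sh), array(FALSE, sh))
  vm0 <- volume_metrics(f0, hemi, 0.0135)
  expect_true(all(vm0$volume_ul == 0))
  expect_false(attr(vm0, "included"))
  expect_error(volume_metrics(f, array(FALSE, sh), 0.0135), "empty")

  # fractions of core + salvageable equal the acute fraction
  set.seed(35)
  a <- array(runif(prod(sh)) < 0.1, sh); s <- array(runif(prod(sh)) < 0.1, sh)
  fr <- classify_fate(a, s)
  vr <- volume_metrics(fr, hemi, 0.0135)
  expect_equal(vr$hemisphere_fraction[vr$roi == "core"] +
                 vr$hemisphere_fraction[vr$roi == "salvageable"],
               vr$hemisphere_fraction[vr$roi == "acute"])
})

test_that("volume change is the signed percent of the acute volume", {
  expect_equal(volume_change(100, 100), 0)
  expect_equal(volume_change(100, 50), -50)
  expect_equal(volume_change(80, 100), 25)
  expect_error(volume_change(0, 10), "positive")
})

test_that("planted lesions at 4 contralateral SDs are recovered with high Dice", {
  a <- make_atlas(c(24L, 24L, 8L))
  ph <- make_phantom(c(24L, 24L, 8L), lesion_spec(radii = c(4.5, 5, 2.5)))
  planted <- ph$lesion_truth$acute
  set.seed(36)
  for (s in 1:3) {
    map <- array(rnorm(prod(dim(a$labels)), 0.75e-3, 2e-5), dim = dim(a$labels))
    map[planted] <- rnorm(sum(planted), 0.75e-3 - 4 * 2e-5, 2e-5)
    rs <- reference_stats(map, a, "adc")
    m <- clean_mask(threshold_lesion(map, rs, a, "adc"),
                    min_cluster_voxels = 5L, closing_radius = 1L)
    expect_gt(dice(m, planted), 0.95)
  }
})

test_that("lesion location is the majority atlas compartment", {
  ph <- small_phantom()
  expect_equal(lesion_location(ph$lesion_truth$acute, ph), "subcortical")
  thal <- ph$labels == atlas_labels[["thalamus"]] & ph$hemisphere == 2L
  expect_equal(lesion_location(thal, ph), "diencephalic")
  cort <- ph$labels == atlas_labels[["s1fl"]] & ph$hemisphere == 2L
  expect_equal(lesion_location(cort, ph), "cortical")
})
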