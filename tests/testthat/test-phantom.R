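test_that("phantom_spec enforces construction invariants", {
  expect_error(phantom_spec(lattice_constant_nm = 18, filament_radius_nm = 10),
               "a > 2r")
  expect_error(phantom_spec(zdisk_csa_reduction = 1.2), "\\(-1, 1\\)")
  expect_error(phantom_spec(iband_width_nm = 1200, sarcomere_period_nm = 1300,
                            zdisk_thickness_nm = 200), "smaller than the period")
  expect_error(phantom_spec(filament_radius_nm = 4, voxel_nm = 10,
                            lattice_constant_nm = 45), "one voxel")
  expect_error(phantom_spec(lattice_constant_nm = 25, filament_radius_nm = 10,
                            zdisk_csa_reduction = 0.9), "overlap at the Z-disk")
})

test_that("zero CSA reduction builds straight filaments and equal sheet areas", {
  ph <- build_phantom(bundle_spec(delta = 0, voxel_nm = 10,
                                  myofibril_radius_nm = 120))
  gt <- ground_truth(ph)
  expect_lt(max(gt$filament_sagitta_nm), ph$spec$voxel_nm / 2)
  # Z-disk and A-band max-projection CSA agree (no taper)
  z <- sum(apply(ph$labels$zdisk$data == 1, c(2, 3), max))
  a <- sum(apply(ph$labels$aband$data == 1, c(2, 3), max))
  expect_lt(abs(z - a) / a, 0.05)   # one boundary-voxel ring
  expect_lt(abs(gt$csa_heterogeneity_pct), 3)
})

test_that("taper compresses the filament lattice toward the Z-disk", {
  ph <- build_phantom(bundle_spec(delta = 0.4, voxel_nm = 10,
                                  myofibril_radius_nm = 160))
  gt <- ground_truth(ph)
  lat <- gt$lattice_by_slab
  a <- ph$spec$lattice_constant_nm
  # A-band-center slabs carry the nominal lattice constant
  center <- lat$lattice_nm[which.max(lat$slab_center_nm)]
  expect_lt(abs(center - a) / a, 0.03)
  # the Z-end slab is compressed toward a * sqrt(1 - delta)
  zend <- lat$lattice_nm[which.min(lat$slab_center_nm)]
  expect_lt(zend, 0.88 * a)
  expect_gt(zend, sqrt(1 - 0.4) * a * 0.93)
  # outermost shell is displaced most, core stays straight
  outer <- gt$filament_sagitta_nm[gt$filament_shell == max(gt$filament_shell)]
  core <- gt$filament_sagitta_nm[gt$filament_shell == 0]
  expect_gt(min(outer), 10 * max(core))
})

test_that("organelle labels are mutually disjoint and mito configs differ", {
  spec <- phantom_spec(voxel_nm = 10, myofibril_radius_nm = 150,
                       sarcomere_period_nm = 1200, iband_width_nm = 100,
                       zdisk_thickness_nm = 80, mito_config = "grid",
                       n_periods = 2, lipid_droplet_radii_nm = 120)
  ph <- build_phantom(spec)
  overlap <- (ph$labels$filaments$data > 0) + ph$labels$zdisk$data +
    ph$labels$mito$data + ph$labels$srt$data + ph$labels$lipid$data
  expect_lte(max(overlap), 1L)
  for (nm in c("mito", "srt", "lipid"))
    expect_gt(sum(ph$labels[[nm]]$data), 0)

  # grid config: every mito voxel within W_I + 200 nm of a Z-disk voxel,
  # verified against Z-disk voxel positions directly (per-voxel oracle)
  mi <- which(ph$labels$mito$data == 1, arr.ind = TRUE)
  zi <- which(ph$labels$zdisk$data == 1, arr.ind = TRUE)
  set.seed(1)
  sub <- mi[sample(nrow(mi), 300), , drop = FALSE]
  dmin <- vapply(seq_len(nrow(sub)), function(r)
    sqrt(min(colSums((t(zi) - sub[r, ])^2))) * 10, numeric(1))
  expect_true(all(dmin <= spec$iband_width_nm + 200))
  expect_equal(ground_truth(ph)$z_adjacent_fraction, 1)

  # parallel config spans sarcomeres longitudinally
  php <- build_phantom(phantom_spec(voxel_nm = 10, myofibril_radius_nm = 150,
                                    sarcomere_period_nm = 1200,
                                    iband_width_nm = 100,
                                    zdisk_thickness_nm = 80,
                                    mito_config = "parallel", n_periods = 2))
  runs <- apply(php$labels$mito$data == 1, 1, sum)
  expect_true(all(runs > 0))   # tubes present on every slice
})

test_that("ground truth mitochondrial content equals manual voxel counting", {
  ph <- build_phantom(phantom_spec(voxel_nm = 10, myofibril_radius_nm = 120,
                                   sarcomere_period_nm = 1200,
                                   iband_width_nm = 100, zdisk_thickness_nm = 80,
                                   mito_config = "grid", n_periods = 1))
  gt <- ground_truth(ph)
  expect_equal(gt$mito_content,
               sum(ph$labels$mito$data == 1) / sum(ph$labels$cell$data == 1))
  expect_gt(gt$mito_content, 0)
})

test_that("grayscale rendering is deterministic and honors the stated SNR", {
  ph <- build_phantom(bundle_spec(delta = 0, voxel_nm = 10,
                                  myofibril_radius_nm = 100))
  clean <- render_grayscale(ph, snr = Inf)
  expect_true(all(clean$data >= 0 & clean$data <= 255))
  n1 <- render_grayscale(ph, snr = 5, seed = 11)
  n2 <- render_grayscale(ph, snr = 5, seed = 11)
  expect_identical(n1$data, n2$data)
  n3 <- render_grayscale(ph, snr = 5, seed = 12)
  expect_false(identical(n1$data, n3$data))
  # empirical contrast / noise SD within 10% of the requested SNR
  # (measure noise away from clip boundaries)
  mid <- clean$data > 20 & clean$data < 235
  noise_sd <- stats::sd((n1$data - clean$data)[mid])
  contrast <- 200 - 100
  expect_lt(abs(contrast / noise_sd - 5) / 5, 0.1)
  expect_error(render_grayscale(ph, snr = -1), "positive")
})

test_that("halving the voxel size leaves constructive ground truth stable", {
  gts <- lapply(c(10, 5), function(v) {
    spec <- phantom_spec(voxel_nm = v, myofibril_radius_nm = 140,
                         sarcomere_period_nm = 1200, iband_width_nm = 100,
                         zdisk_thickness_nm = 80, zdisk_csa_reduction = 0.3,
                         mito_config = "grid", n_periods = 1,
                         lipid_droplet_radii_nm = numeric(0),
                         sr_tube_radius_nm = 0)
    ground_truth(build_phantom(spec))
  })
  expect_lt(abs(gts[[1]]$csa_heterogeneity_pct - gts[[2]]$csa_heterogeneity_pct), 2)
  expect_lt(abs(gts[[1]]$mito_content - gts[[2]]$mito_content) /
              gts[[2]]$mito_content, 0.02)
})
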