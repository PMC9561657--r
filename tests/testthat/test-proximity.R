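test_that("distance field equals brute force exactly on sparse masks", {
  set.seed(42)
  m <- array(stats::runif(24^3) < 0.005, c(24, 24, 24))
  m[5, 5, 5] <- TRUE
  df <- distance_field(voxel_volume(m, 7, "binary"))
  expect_equal(df$data, brute_edt(m, 7), tolerance = 1e-9)
  expect_true(all(df$data[m] == 0))
})

test_that("distance field basics and errors", {
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  df <- distance_field(voxel_volume(m, 10, "binary"))
  expect_equal(df$data[5, 4, 4], 10)            # face-adjacent
  expect_equal(df$data[5, 5, 4], 10 * sqrt(2))  # edge-adjacent
  expect_error(distance_field(voxel_volume(array(0L, c(4, 4, 4)), 10, "binary")),
               "empty")
  # 1-Lipschitz between neighbors (bounded by the voxel diagonal)
  set.seed(3)
  m2 <- array(stats::runif(16^3) < 0.01, c(16, 16, 16)); m2[2, 2, 2] <- TRUE
  d2 <- distance_field(voxel_volume(m2, 10, "binary"))$data
  expect_lte(max(abs(d2[-1, , ] - d2[-16, , ])), 10 * sqrt(3) + 1e-9)
})

test_that("per-filament minimum distances match brute force on 64^3", {
  set.seed(9)
  vox <- 8
  lab <- array(0L, c(64, 64, 64))
  lab[10:55, 20:23, 20:23] <- 1L
  lab[10:55, 40:43, 28:31] <- 2L
  org <- array(FALSE, c(64, 64, 64))
  org[30:34, 30:33, 50:53] <- TRUE
  org[12:14, 21:22, 21:22] <- TRUE      # touches filament 1
  labv <- voxel_volume(lab, vox, "labels")
  field <- distance_field(voxel_volume(org, vox, "binary"))
  res <- min_distance_per_filament(labv, field)
  oi <- which(org, arr.ind = TRUE)
  for (id in 1:2) {
    fi <- which(lab == id, arr.ind = TRUE)
    bf <- min(vapply(seq_len(nrow(fi)), function(r)
      min(colSums((t(oi) - fi[r, ])^2)), numeric(1)))
    expect_equal(res$min_distance_nm[res$id == id], sqrt(bf) * vox,
                 tolerance = 1e-9)
  }
  expect_equal(res$min_distance_nm[res$id == 1], 0)  # shared boundary voxel
  expect_error(min_distance_per_filament(
    voxel_volume(lab[1:32, , ], vox, "labels"), field), "geometr")
})

test_that("constructed parallel-cylinder gap is recovered", {
  vox <- 10
  lab <- array(0L, c(40, 40, 40))
  org <- array(FALSE, c(40, 40, 40))
  lab[5:35, 10:12, 10:12] <- 1L        # filament block
  org[5:35, 21:23, 10:12] <- TRUE      # organelle block, gap 8 voxels = 80 nm
  res <- min_distance_per_filament(voxel_volume(lab, vox, "labels"),
                                   distance_field(voxel_volume(org, vox, "binary")))
  expect_equal(res$min_distance_nm, 80, tolerance = vox * sqrt(3))
})

test_that("proximity bins are half-open and exclude overlap", {
  expect_true(is.na(proximity_bin(0)))
  expect_equal(proximity_bin(c(0.1, 100, 100.1, 250)), c(1L, 1L, 2L, 3L))
})

test_that("mitochondrial partition matches constructed splits exactly", {
  vox <- 10
  zd <- array(FALSE, c(100, 20, 20)); zd[1:2, , ] <- TRUE
  mito <- array(FALSE, c(100, 20, 20))
  # threshold = 150 + 200 = 350 nm from the Z-disk sheet at slices 1:2;
  # distance of slice i is (i - 2) * 10 nm for i > 2
  mito[3:32, 5, 5] <- TRUE    # 30 voxels at 10..300 nm  (Z-adjacent)
  mito[38:100, 6, 6] <- TRUE  # 63 voxels at 360..980 nm (distal)
  mito[38:44, 7, 7] <- TRUE   # 7 voxels at 360..420 nm  (distal)
  part <- partition_mitochondria(voxel_volume(mito, vox, "binary"),
                                 voxel_volume(zd, vox, "binary"),
                                 iband_width_nm = 150)
  expect_equal(part$threshold_nm, 350)
  expect_equal(part$z_adjacent_voxels + part$non_adjacent_voxels,
               part$total_mito_voxels)
  expect_equal(part$z_adjacent_fraction, 30 / 100, tolerance = 0.01)
  # fraction is monotone non-decreasing in the threshold
  fr <- vapply(c(0, 100, 200, 400, 800), function(m)
    partition_mitochondria(voxel_volume(mito, vox, "binary"),
                           voxel_volume(zd, vox, "binary"),
                           iband_width_nm = 150, margin_nm = m)$z_adjacent_fraction,
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  # degenerate cases
  empty <- voxel_volume(array(0L, c(100, 20, 20)), vox, "binary")
  expect_error(partition_mitochondria(empty, empty, 150), "empty Z-disk")
  p0 <- partition_mitochondria(empty, voxel_volume(zd, vox, "binary"), 150)
  expect_true(p0$undefined)
  expect_true(is.na(p0$z_adjacent_fraction))
})

test_that("grid phantom mitochondria are fully Z-adjacent through the pipeline", {
  ph <- build_phantom(phantom_spec(voxel_nm = 10, myofibril_radius_nm = 120,
                                   sarcomere_period_nm = 1200,
                                   iband_width_nm = 100, zdisk_thickness_nm = 80,
                                   mito_config = "grid", n_periods = 1))
  part <- partition_mitochondria(ph$labels$mito, ph$labels$zdisk,
                                 iband_width_nm = ph$spec$iband_width_nm,
                                 cell = ph$labels$cell)
  expect_equal(part$z_adjacent_fraction, 1)
  expect_equal(part$mito_content, ground_truth(ph)$mito_content)
})

test_that("local thickness recovers analytic diameters", {
  vox <- 10
  # solid sphere, diameter 200 nm
  sph <- array(FALSE, c(30, 30, 30))
  co <- which(array(TRUE, c(30, 30, 30)), arr.ind = TRUE)
  sph[co[colSums((t(co) - 15)^2) <= 10^2, ]] <- TRUE
  lt <- local_thickness(voxel_volume(sph, vox, "binary"))
  expect_equal(lt$median_nm, 200, tolerance = vox * 1.5)
  # slab, thickness 120 nm
  slab <- array(FALSE, c(24, 30, 24)); slab[, 10:21, ] <- TRUE
  lts <- local_thickness(voxel_volume(slab, vox, "binary"))
  expect_equal(lts$median_nm, 120, tolerance = vox)
  expect_error(local_thickness(voxel_volume(array(0L, c(4, 4, 4)), vox, "binary")),
               "empty")
})

test_that("two-population tube diameters give the constructed median ratio", {
  vox <- 10
  dims <- c(80, 90, 40)
  m <- array(FALSE, dims)
  co2 <- as.matrix(expand.grid(j = 1:90, k = 1:40))
  small_r <- 6; big_r <- 6 * 2.45          # voxel radii: d and 2.45 d
  small <- co2[(co2[, 1] - 20)^2 + (co2[, 2] - 20)^2 <= small_r^2, ]
  big <- co2[(co2[, 1] - 60)^2 + (co2[, 2] - 20)^2 <= big_r^2, ]
  msk_small <- array(FALSE, dims); msk_big <- array(FALSE, dims)
  for (i in 1:80) {
    msk_small[cbind(i, small)] <- TRUE
    msk_big[cbind(i, big)] <- TRUE
  }
  m <- msk_small | msk_big
  lt <- local_thickness(voxel_volume(m, vox, "binary"))
  med <- function(sel) stats::median(lt$field$data[sel])
  ratio <- med(msk_big) / med(msk_small)
  expect_equal(ratio, 2.45, tolerance = 2.45 * 0.05)
})
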