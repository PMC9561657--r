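test_that("parameter constructors enforce their invariants", {
  expect_error(cylinder_template(outer_radius_nm = 25, mask_radius_nm = 20),
               "inner < outer")
  expect_error(cylinder_template(cylinder_length_nm = 0), "positive")
  expect_error(trace_params(min_continuation = 130, min_seed_correlation = 120),
               "min_continuation")
  expect_error(trace_params(direction_coefficient = 1.5), "\\[0, 1\\]")
})

test_that("orientation sampling covers the cap at the requested spacing", {
  dirs <- sample_orientations(15, 90)
  expect_true(all(abs(sqrt(rowSums(dirs^2)) - 1) < 1e-12))
  # nearest-neighbor angular spacing stays near the request
  gram <- dirs %*% t(dirs); diag(gram) <- -1
  nn <- acos(pmin(apply(gram, 1, max), 1)) * 180 / pi
  expect_lt(max(nn), 16)
  dirs20 <- sample_orientations(10, 20)
  expect_true(all(dirs20[, 1] >= cos(20 * pi / 180) - 1e-9))
})

test_that("constant volumes give a flagged all-zero field and empty trace set", {
  vol <- voxel_volume(array(100, c(40, 40, 40)), 5, "grayscale")
  fld <- cylinder_correlation(vol, cylinder_template(angular_sampling_deg = 30))
  expect_true(fld$degenerate)
  expect_true(all(fld$corr == 0))
  fs <- trace_lines(fld)
  expect_length(fs$filaments, 0)
  small <- voxel_volume(array(stats::runif(8^3) * 255, c(8, 8, 8)), 5, "grayscale")
  expect_error(cylinder_correlation(small), "smaller than the correlation template")
})

test_that("a single noiseless cylinder is found with the right orientation", {
  vox <- 5
  dims <- c(440, 33, 33)
  pts <- cbind(seq(100, 2100, by = vox), 80, 80)
  g <- array(100, dims)
  lab <- rasterize_filaments(make_fset(list(pts), vox, dims), dims, vox, 10)
  g[lab$data == 1] <- 200
  vol <- voxel_volume(g, vox, "grayscale")
  tmpl <- cylinder_template(outer_radius_nm = 10, mask_radius_nm = 20,
                            angular_sampling_deg = 15)
  fld <- cylinder_correlation(vol, tmpl, max_tilt_deg = 30)
  # on-axis argmax orientation within 5 degrees of the longitudinal axis
  axis_vox <- cbind(seq(30, 410, by = 20), 17, 17)
  odirs <- fld$directions[fld$orientation_idx[axis_vox], , drop = FALSE]
  expect_true(all(acos(pmin(abs(odirs[, 1]), 1)) * 180 / pi <= 5 + 1e-6))
  # on-axis correlation dominates off-axis
  expect_gt(min(fld$corr[axis_vox]),
            2 * max(fld$corr[cbind(seq(30, 410, by = 20), 8, 26)]))
  fs <- trace_lines(fld, trace_params(max_step_nm = 20))
  expect_length(fs$filaments, 1)
  expect_equal(fs$filaments[[1]]$length_nm, 2000, tolerance = 0.05)
  dev <- apply(fs$filaments[[1]]$points[, 2:3], 1,
               function(p) sqrt(sum((p - c(80, 80))^2)))
  expect_lt(mean(dev), vox)
})

test_that("a hexagonal seven-filament bundle traces one line per filament", {
  spec <- bundle_spec(delta = 0, myofibril_radius_nm = 70)
  ph <- build_phantom(spec)
  expect_equal(nrow(ph$filament_table), 7L)
  g <- render_grayscale(ph, snr = Inf)
  fld <- cylinder_correlation(g, bundle_template(spec), max_tilt_deg = 20)
  fs <- trace_lines(fld, bundle_trace_params(spec))
  expect_length(fs$filaments, 7)
  expect_true(all(vapply(fs$filaments, `[[`, numeric(1), "length_nm") >=
                    fs$params$min_length_nm))
  centers <- t(vapply(fs$filaments, function(f)
    colMeans(f$points[, 2:3]), numeric(2)))
  dmat <- as.matrix(stats::dist(centers)); diag(dmat) <- Inf
  expect_true(all(abs(apply(dmat, 1, min) - 45) <= 5))
  q <- trace_quality(fs, ph$centerlines)
  expect_equal(q$recall, 1)
  expect_equal(q$precision, 1)
})

test_that("in-plane lattice rotation does not change the filament count", {
  spec <- bundle_spec(delta = 0, myofibril_radius_nm = 70,
                      lattice_rotation_deg = 30)
  ph <- build_phantom(spec)
  g <- render_grayscale(ph, snr = Inf)
  fld <- cylinder_correlation(g, bundle_template(spec), max_tilt_deg = 20)
  fs <- trace_lines(fld, bundle_trace_params(spec))
  expect_length(fs$filaments, 7)   # within 5% of the unrotated count
})

test_that("pure noise stays below the seed threshold", {
  vox <- 8
  tmpl <- cylinder_template(outer_radius_nm = 10, mask_radius_nm = 20,
                            angular_sampling_deg = 25)
  set.seed(99)
  maxima <- vapply(1:20, function(i) {
    g <- array(pmin(pmax(stats::rnorm(26^3, 128, 30), 0), 255), c(26, 26, 26))
    fld <- cylinder_correlation(voxel_volume(g, vox, "grayscale"), tmpl)
    max(fld$corr)
  }, numeric(1))
  expect_gte(mean(maxima < 115), 0.95)
})

test_that("rasterization reproduces tube volumes and label bookkeeping", {
  vox <- 5
  dims <- c(120, 24, 24)
  pts <- cbind(seq(40, 540, by = vox), 60, 60)
  lab <- rasterize_filaments(make_fset(list(pts), vox, dims), dims, vox,
                             radius_nm = 10)
  analytic <- pi * 10^2 * (500 + 2 * 10)   # cylinder plus end caps
  expect_equal(sum(lab$data == 1) * vox^3, analytic, tolerance = 0.10)
  # empty set and two disjoint filaments
  empty <- rasterize_filaments(make_fset(list(), vox, dims), dims, vox, 10)
  expect_true(all(empty$data == 0))
  two <- rasterize_filaments(make_fset(list(pts, pts + rep(c(0, 0, -40), each = nrow(pts))),
                                       vox, dims), dims, vox, 10)
  expect_equal(sort(setdiff(unique(as.vector(two$data)), 0L)), c(1L, 2L))
  expect_error(rasterize_filaments(make_fset(list(pts + 2000), vox, dims),
                                   dims, vox, 10), "outside")
  expect_error(rasterize_filaments(make_fset(list(pts), vox, dims), dims, vox,
                                   radius_nm = 1), "half a voxel")
})

test_that("filament sets round-trip through JSON lines", {
  pts <- cbind(seq(0, 600, by = 10), 50, 50)
  fs <- make_fset(list(pts, pts + 20), 5, c(130, 30, 30))
  path <- file.path(withr::local_tempdir(), "fils.jsonl")
  write_filaments(fs, path)
  back <- read_filaments(path, voxel_nm = 5, dims = c(130, 30, 30))
  expect_length(back$filaments, 2)
  expect_equal(back$filaments[[1]]$points, fs$filaments[[1]]$points,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$filaments[[2]]$length_nm, fs$filaments[[2]]$length_nm)
})
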