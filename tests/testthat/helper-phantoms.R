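# Shared fixtures and independent oracles, built in code at test time.

# compact tracing phantom: short-period fibrillar bundle, no organelles
bundle_spec <- function(delta = 0, myofibril_radius_nm = 70, voxel_nm = 5, ...) {
  phantom_spec(voxel_nm = voxel_nm, myofibril_radius_nm = myofibril_radius_nm,
               zdisk_csa_reduction = delta,
               sarcomere_period_nm = 1200, iband_width_nm = 100,
               zdisk_thickness_nm = 80, mito_config = "none",
               sr_tube_radius_nm = 0, lipid_droplet_radii_nm = numeric(0),
               n_periods = 1, ...)
}

# template matched to the phantoms' rendered filament radius
bundle_template <- function(spec)
  cylinder_template(outer_radius_nm = spec$filament_radius_nm,
                    mask_radius_nm = 20, angular_sampling_deg = 12)

# tracing parameters for a 45-nm lattice: step cap below half the spacing
bundle_trace_params <- function(spec)
  trace_params(max_step_nm = spec$lattice_constant_nm / 2 - 2)

# recall/precision of traced centerlines against ground-truth centerlines,
# matching by median point-to-polyline distance at the given tolerance
trace_quality <- function(fset, centerlines, tol_nm = 20, subsample = 3L) {
  if (length(fset$filaments) == 0)
    return(list(recall = 0, precision = NA_real_, n_traces = 0))
  mm <- t(vapply(fset$filaments, function(f) {
    pts <- f$points[seq(1, nrow(f$points), by = subsample), , drop = FALSE]
    d <- vapply(centerlines, function(cl) {
      stats::median(vapply(seq_len(nrow(pts)), function(r)
        min(sqrt(colSums((t(cl) - pts[r, ])^2))), numeric(1)))
    }, numeric(1))
    c(which.min(d), min(d))
  }, numeric(2)))
  list(recall = length(unique(mm[mm[, 2] <= tol_nm, 1])) / length(centerlines),
       precision = mean(mm[, 2] <= tol_nm),
       n_traces = nrow(mm))
}

# brute-force Euclidean distance (nm) from every voxel to the nearest
# foreground voxel: explicit minimum over all mask voxels
brute_edt <- function(mask, voxel_nm) {
  src <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  I <- slice.index(mask, 1); J <- slice.index(mask, 2); K <- slice.index(mask, 3)
  best <- array(Inf, d)
  for (r in seq_len(nrow(src)))
    best <- pmin(best, (I - src[r, 1])^2 + (J - src[r, 2])^2 + (K - src[r, 3])^2)
  sqrt(best) * voxel_nm
}

# ideal hexagonal point-lattice image, constant a (nm), optional rotation
hex_image <- function(a, px, n = 256, rot_deg = 0) {
  img <- matrix(0, n, n)
  th <- rot_deg * pi / 180
  for (i in -60:60) for (j in -60:60) {
    y <- a * (i + j / 2); z <- a * sqrt(3) / 2 * j
    yr <- y * cos(th) - z * sin(th); zr <- y * sin(th) + z * cos(th)
    iy <- round(yr / px) + n / 2; iz <- round(zr / px) + n / 2
    if (iy >= 1 && iy <= n && iz >= 1 && iz <= n) img[iy, iz] <- 1
  }
  img
}

# wrap bare polylines (list of n x 3 nm matrices) as a filament_set
make_fset <- function(point_list, voxel_nm, dims) {
  fil <- lapply(seq_along(point_list), function(i) {
    p <- point_list[[i]]
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    list(id = i, points = p, correlations = rep(255, nrow(p)),
         length_nm = sum(seg))
  })
  structure(list(filaments = fil, params = NULL, voxel_nm = voxel_nm,
                 dims = dims), class = "filament_set")
}

# axis-aligned straight tube label volume (id 1), for closed-form checks
rasterize_rod <- function(length_nm, radius_nm, voxel_nm, bend_sagitta_nm = 0,
                          rotate_deg = 0) {
  x <- seq(0, length_nm, by = voxel_nm)
  y <- bend_sagitta_nm * (1 - (2 * x / length_nm - 1)^2)
  th <- rotate_deg * pi / 180
  margin <- 8 * voxel_nm
  pts <- cbind(margin + x * cos(th) - y * sin(th),
               margin + 2 * radius_nm + x * sin(th) + y * cos(th),
               margin + 2 * radius_nm)
  dims <- ceiling(apply(pts, 2, max) / voxel_nm) + round(margin / voxel_nm)
  rasterize_filaments(make_fset(list(pts), voxel_nm, dims),
                      dims = dims, voxel_nm = voxel_nm, radius_nm = radius_nm)
}
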