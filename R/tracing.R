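#' Hollow-cylinder template parameters
#'
#' Template used for normalized cross-correlation against myosin filaments:
#' a (hollow) cylinder of the filament's dimensions inside a cylindrical
#' correlation mask. Defaults follow the filament-segmentation protocol:
#' length 100 nm, outer radius 19 nm, inner radius 0, mask radius 20 nm,
#' angular sampling 5 (interpreted as degrees of maximum spacing between
#' sampled orientations on the hemisphere).
#'
#' @param cylinder_length_nm,outer_radius_nm,inner_radius_nm,mask_radius_nm
#'   template geometry, nm.
#' @param angular_sampling_deg maximum angular spacing of sampled
#'   orientations, degrees.
#' @return list of class `cylinder_template`.
#' @export
cylinder_template <- function(cylinder_length_nm = 100, outer_radius_nm = 19,
                              inner_radius_nm = 0, mask_radius_nm = 20,
                              angular_sampling_deg = 5) {
  if (!(inner_radius_nm < outer_radius_nm && outer_radius_nm <= mask_radius_nm))
    stop("require inner < outer <= mask radius")
  if (cylinder_length_nm <= 0) stop("cylinder length must be positive")
  structure(list(cylinder_length_nm = cylinder_length_nm,
                 outer_radius_nm = outer_radius_nm,
                 inner_radius_nm = inner_radius_nm,
                 mask_radius_nm = mask_radius_nm,
                 angular_sampling_deg = angular_sampling_deg),
            class = "cylinder_template")
}

#' Correlation-line tracing parameters
#'
#' Defaults follow the tracing protocol: minimum seed correlation 115 and
#' minimum continuation 80 (0-255 correlation scale), direction coefficient
#' 0.3, minimum distance 20 (interpreted here in nm), minimum length 500 nm,
#' search cone length 100 nm, half-angle 30 degrees, minimum step 10% of the
#' cone length.
#'
#' @param min_seed_correlation,min_continuation correlation thresholds
#'   (0-255).
#' @param direction_coefficient weight of the previous step direction
#'   against the local orientation field, in \[0, 1\].
#' @param min_distance_nm suppression distance between traces, nm.
#' @param min_length_nm minimum accepted trace length, nm.
#' @param search_cone_length_nm,search_cone_angle_deg search cone geometry.
#' @param min_step_fraction base step as a fraction of the cone length.
#' @param max_step_nm cap on the adaptively doubled step (default: the cone
#'   length). In dense lattices keep this below half the filament spacing so
#'   high-correlation steps cannot hop onto a neighboring filament.
#' @return list of class `trace_params`.
#' @export
trace_params <- function(min_seed_correlation = 115, min_continuation = 80,
                         direction_coefficient = 0.3, min_distance_nm = 20,
                         min_length_nm = 500, search_cone_length_nm = 100,
                         search_cone_angle_deg = 30, min_step_fraction = 0.10,
                         max_step_nm = search_cone_length_nm) {
  if (!(0 < min_continuation && min_continuation <= min_seed_correlation &&
        min_seed_correlation <= 255))
    stop("require 0 < min_continuation <= min_seed_correlation <= 255")
  if (direction_coefficient < 0 || direction_coefficient > 1)
    stop("direction coefficient must lie in [0, 1]")
  structure(list(min_seed_correlation = min_seed_correlation,
                 min_continuation = min_continuation,
                 direction_coefficient = direction_coefficient,
                 min_distance_nm = min_distance_nm,
                 min_length_nm = min_length_nm,
                 search_cone_length_nm = search_cone_length_nm,
                 search_cone_angle_deg = search_cone_angle_deg,
                 min_step_fraction = min_step_fraction,
                 max_step_nm = max_step_nm),
            class = "trace_params")
}

#' Quasi-uniform orientation sample on the (capped) hemisphere
#'
#' Fibonacci-spiral directions with approximately `spacing_deg` angular
#' spacing, restricted to tilts up to `max_tilt_deg` from the longitudinal
#' axis; the exact axis is always included. Orientations are axial
#' (sign-free).
#'
#' @param spacing_deg maximum angular spacing, degrees.
#' @param max_tilt_deg cap on the tilt from axis 1 (90 = full hemisphere).
#' @return n x 3 matrix of unit vectors (axial component first).
#' @export
sample_orientations <- function(spacing_deg = 5, max_tilt_deg = 90) {
  s <- spacing_deg * pi / 180
  cap <- max_tilt_deg * pi / 180
  area <- 2 * pi * (1 - cos(cap))
  n <- max(1L, ceiling(1.2 * area / s^2))
  if (n == 1L) return(matrix(c(1, 0, 0), 1, 3))
  i <- seq_len(n)
  x <- 1 - (1 - cos(cap)) * (i - 0.5) / n      # axial component
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - x^2, 0))
  rbind(c(1, 0, 0), cbind(x, r * cos(phi), r * sin(phi)))
}

# resample a polyline at roughly `spacing` intervals (keeps all vertices)
densify_polyline <- function(pts, spacing) {
  if (nrow(pts) < 2) return(pts)
  out <- list(pts[1, , drop = FALSE])
  for (s in seq_len(nrow(pts) - 1)) {
    a <- pts[s, ]; b <- pts[s + 1, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / spacing))
    tt <- seq_len(n) / n
    out[[s + 1]] <- cbind(a[1] + tt * (b[1] - a[1]),
                          a[2] + tt * (b[2] - a[2]),
                          a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

# trilinear interpolation of a 3D array at continuous 1-based voxel coords
interp3 <- function(arr, P) {
  d <- dim(arr)
  P[, 1] <- pmin(pmax(P[, 1], 1), d[1])
  P[, 2] <- pmin(pmax(P[, 2], 1), d[2])
  P[, 3] <- pmin(pmax(P[, 3], 1), d[3])
  i0 <- pmin(floor(P[, 1]), d[1] - 1); fi <- P[, 1] - i0
  j0 <- pmin(floor(P[, 2]), d[2] - 1); fj <- P[, 2] - j0
  k0 <- pmin(floor(P[, 3]), d[3] - 1); fk <- P[, 3] - k0
  lin <- function(i, j, k) arr[cbind(i, j, k)]
  v000 <- lin(i0, j0, k0);     v100 <- lin(i0 + 1, j0, k0)
  v010 <- lin(i0, j0 + 1, k0); v110 <- lin(i0 + 1, j0 + 1, k0)
  v001 <- lin(i0, j0, k0 + 1); v101 <- lin(i0 + 1, j0, k0 + 1)
  v011 <- lin(i0, j0 + 1, k0 + 1); v111 <- lin(i0 + 1, j0 + 1, k0 + 1)
  (v000 * (1 - fi) + v100 * fi) * (1 - fj) * (1 - fk) +
    (v010 * (1 - fi) + v110 * fi) * fj * (1 - fk) +
    (v001 * (1 - fi) + v101 * fi) * (1 - fj) * fk +
    (v011 * (1 - fi) + v111 * fi) * fj * fk
}

#' Cylinder correlation field
#'
#' Normalized cross-correlation of a grayscale volume against a (hollow)
#' cylindrical template over a quasi-uniform sample of orientations,
#' evaluated by FFT. Per voxel the maximum NCC over orientations (affinely
#' mapped to 0-255) and the argmax orientation are returned. Constant
#' volumes produce an all-zero field flagged `degenerate`.
#'
#' @param vol grayscale [voxel_volume()]; for good sampling of the template
#'   the voxel size should be at most half the outer radius.
#' @param tmpl a [cylinder_template()].
#' @param max_tilt_deg orientation cap passed to [sample_orientations()]
#'   (90 = full hemisphere; reduce when the fiber axis is known).
#' @param min_local_contrast windows whose local intensity SD falls below
#'   this fraction of the volume's dynamic range get correlation 0; this
#'   suppresses the unbounded NCC response to near-constant regions.
#' @return list of class `correlation_field`: `corr` (0-255 array),
#'   `orientation_idx` (int array), `directions`, `voxel_nm`, `degenerate`.
#' @export
cylinder_correlation <- function(vol, tmpl = cylinder_template(),
                                 max_tilt_deg = 90, min_local_contrast = 0.02) {
  assert_volume(vol, "grayscale")
  vox <- vol$voxel_nm
  d <- dim(vol$data)
  he <- ceiling((tmpl$cylinder_length_nm / 2 + tmpl$mask_radius_nm) / vox) + 1L
  if (any(d < 2 * he + 1))
    stop("volume smaller than the correlation template")
  if (stats::sd(vol$data) == 0) {
    return(structure(list(corr = array(0, d),
                          orientation_idx = array(1L, d),
                          directions = matrix(c(1, 0, 0), 1, 3),
                          voxel_nm = vox, degenerate = TRUE),
                     class = "correlation_field"))
  }
  pd <- vapply(d + 2L * he, function(x) stats::nextn(x, c(2, 3, 5)), numeric(1))
  # replicate-pad: a smooth continuation avoids spurious step-edge responses
  ix <- pmin(pmax(seq_len(pd[1]) - he, 1L), d[1])
  iy <- pmin(pmax(seq_len(pd[2]) - he, 1L), d[2])
  iz <- pmin(pmax(seq_len(pd[3]) - he, 1L), d[3])
  Ipad <- vol$data[ix, iy, iz]
  FI <- stats::fft(Ipad)
  FI2 <- stats::fft(Ipad^2)
  Np <- prod(pd)

  offs <- as.matrix(expand.grid(p1 = -he:he, p2 = -he:he, p3 = -he:he))
  onm <- offs * vox
  wrap <- function(p, n) ((p %% n) + n) %% n + 1L
  lin_idx <- wrap(offs[, 1], pd[1]) +
    pd[1] * (wrap(offs[, 2], pd[2]) - 1) +
    pd[1] * pd[2] * (wrap(offs[, 3], pd[3]) - 1)

  dirs <- sample_orientations(tmpl$angular_sampling_deg, max_tilt_deg)
  best <- array(-Inf, pd)
  bidx <- array(1L, pd)
  for (q in seq_len(nrow(dirs))) {
    u <- dirs[q, ]
    ax <- onm %*% u
    rad <- sqrt(pmax(rowSums(onm^2) - ax^2, 0))
    mask <- rad <= tmpl$mask_radius_nm & abs(ax) <= tmpl$cylinder_length_nm / 2
    val <- pmin(pmax((tmpl$outer_radius_nm + vox / 2 - rad) / vox, 0), 1)
    if (tmpl$inner_radius_nm > 0)
      val <- val * pmin(pmax((rad - tmpl$inner_radius_nm + vox / 2) / vox, 0), 1)
    val <- val * mask
    nm_ <- sum(mask)
    t0 <- (val - sum(val) / nm_) * mask
    t0 <- t0 / sqrt(sum(t0^2))

    Tarr <- array(0, pd); Tarr[lin_idx] <- t0
    Marr <- array(0, pd); Marr[lin_idx] <- as.numeric(mask)
    num <- Re(stats::fft(FI * Conj(stats::fft(Tarr)), inverse = TRUE)) / Np
    s1 <- Re(stats::fft(FI * Conj(stats::fft(Marr)), inverse = TRUE)) / Np
    s2 <- Re(stats::fft(FI2 * Conj(stats::fft(Marr)), inverse = TRUE)) / Np
    den <- sqrt(pmax(s2 - s1^2 / nm_, 0))
    den_floor <- min_local_contrast * sqrt(nm_) * diff(range(vol$data))
    ncc <- ifelse(den > den_floor, num / den, 0)
    upd <- ncc > best
    best[upd] <- ncc[upd]
    bidx[upd] <- q
  }
  sel1 <- seq_len(d[1]) + he; sel2 <- seq_len(d[2]) + he; sel3 <- seq_len(d[3]) + he
  corr <- pmin(pmax(best[sel1, sel2, sel3], 0), 1) * 255
  structure(list(corr = corr,
                 orientation_idx = bidx[sel1, sel2, sel3],
                 directions = dirs, voxel_nm = vox, degenerate = FALSE),
            class = "correlation_field")
}

# cone-sampled unit candidate directions around `center`
cone_dirs <- function(center, half_angle_deg, n_rings = 3L, n_az = 12L) {
  center <- center / sqrt(sum(center^2))
  ref <- if (abs(center[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- ref - sum(ref * center) * center
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(center[2] * b1[3] - center[3] * b1[2],
          center[3] * b1[1] - center[1] * b1[3],
          center[1] * b1[2] - center[2] * b1[1])
  out <- matrix(center, 1, 3)
  for (t in seq_len(n_rings)) {
    th <- half_angle_deg * pi / 180 * t / n_rings
    for (a in seq_len(n_az)) {
      phi <- 2 * pi * (a - 1) / n_az
      out <- rbind(out, cos(th) * center +
                     sin(th) * (cos(phi) * b1 + sin(phi) * b2))
    }
  }
  out
}

#' Trace filament centerlines through a correlation field
#'
#' Greedy bidirectional tracing: seeds are 26-neighborhood local maxima of
#' the correlation field at or above the seed threshold, visited in
#' decreasing correlation order (ties broken by voxel index). Each trace
#' steps within a search cone around the blended direction (previous step
#' weighted by the direction coefficient against the local orientation,
#' sign-aligned with travel), with the base step equal to the minimum step
#' fraction of the cone length, doubling up to the cone length while the
#' correlation stays at seed level. A trace stops when the best candidate
#' falls below the continuation threshold or leaves the volume. Seeds and
#' traces within the minimum distance of an accepted trace are suppressed,
#' and traces shorter than the minimum length are discarded.
#'
#' @param field a [cylinder_correlation()] result.
#' @param params a [trace_params()].
#' @return An object of class `filament_set`: list with `filaments` (each
#'   `id`, `points` n x 3 nm, `correlations`, `length_nm`), `params`,
#'   `voxel_nm`, `dims`.
#' @export
trace_lines <- function(field, params = trace_params()) {
  stopifnot(inherits(field, "correlation_field"))
  corr <- field$corr
  if (all(corr == 0) || isTRUE(field$degenerate))
    return(structure(list(filaments = list(), params = params,
                          voxel_nm = field$voxel_nm, dims = dim(corr)),
                     class = "filament_set"))
  vox <- field$voxel_nm
  d <- dim(corr)

  # 26-neighborhood local maxima at or above the seed threshold
  ismax <- corr >= params$min_seed_correlation
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    if (!any(ismax)) break
    sh <- array(-Inf, d)
    i_src <- max(1, 1 - di):min(d[1], d[1] - di)
    j_src <- max(1, 1 - dj):min(d[2], d[2] - dj)
    k_src <- max(1, 1 - dk):min(d[3], d[3] - dk)
    sh[i_src + di, j_src + dj, k_src + dk] <- corr[i_src, j_src, k_src]
    ismax <- ismax & (corr >= sh)
  }
  seeds <- which(ismax)
  seeds <- seeds[order(-corr[seeds], seeds)]

  claimed <- array(FALSE, d)
  rv <- params$min_distance_nm / vox
  reach <- ceiling(rv)
  stamp <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
  stamp <- stamp[rowSums(stamp^2) <= rv^2, , drop = FALSE]

  claim_points <- function(Pv) {
    iv <- round(Pv)
    for (s in seq_len(nrow(stamp))) {
      q <- sweep(iv, 2, stamp[s, ], "+")
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      if (any(ok)) claimed[q[ok, , drop = FALSE]] <<- TRUE
    }
  }

  step_base <- params$min_step_fraction * params$search_cone_length_nm
  max_steps <- 100000L

  trace_arm <- function(pos, dir) {
    pts <- matrix(numeric(0), 0, 3)
    cors <- numeric(0)
    step <- step_base
    for (it in seq_len(max_steps)) {
      vc <- round(pos / vox + 1)
      if (any(vc < 1) || any(vc > d)) break
      o <- field$directions[field$orientation_idx[vc[1], vc[2], vc[3]], ]
      if (sum(o * dir) < 0) o <- -o
      dc <- params$direction_coefficient
      blend <- dc * dir + (1 - dc) * o
      blend <- blend / sqrt(sum(blend^2))
      cand <- cone_dirs(blend, params$search_cone_angle_deg)
      P <- sweep(cand * step, 2, pos, "+")
      Pv <- P / vox + 1
      inside <- Pv[, 1] >= 1 & Pv[, 1] <= d[1] & Pv[, 2] >= 1 &
        Pv[, 2] <= d[2] & Pv[, 3] >= 1 & Pv[, 3] <= d[3]
      if (!any(inside)) break
      cv <- rep(-Inf, nrow(P))
      cv[inside] <- interp3(corr, Pv[inside, , drop = FALSE])
      b <- which.max(cv)
      if (cv[b] < params$min_continuation) break
      dir <- cand[b, ]
      pos <- P[b, ]
      pts <- rbind(pts, pos)
      cors <- c(cors, cv[b])
      step <- if (cv[b] >= params$min_seed_correlation)
        min(step * 2, params$max_step_nm) else step_base
    }
    list(pts = pts, cors = cors)
  }

  filaments <- list()
  fid <- 0L
  for (s in seeds) {
    i <- (s - 1) %% d[1] + 1
    j <- ((s - 1) %/% d[1]) %% d[2] + 1
    k <- (s - 1) %/% (d[1] * d[2]) + 1
    if (claimed[i, j, k]) next
    pos0 <- (c(i, j, k) - 1) * vox
    d0 <- field$directions[field$orientation_idx[i, j, k], ]
    fwd <- trace_arm(pos0, d0)
    bwd <- trace_arm(pos0, -d0)
    pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))), , drop = FALSE],
                 matrix(pos0, 1, 3), fwd$pts)
    cors <- c(rev(bwd$cors), corr[i, j, k], fwd$cors)
    if (nrow(pts) < 2) next
    seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                              pts[-nrow(pts), , drop = FALSE])^2))
    len <- sum(seglen)
    if (len < params$min_length_nm) next
    dense <- densify_polyline(pts, vox)
    Pv <- dense / vox + 1
    frac_claimed <- mean(claimed[round(Pv)])
    if (frac_claimed > 0.5) next
    fid <- fid + 1L
    colnames(pts) <- c("x_nm", "y_nm", "z_nm")
    filaments[[fid]] <- list(id = fid, points = pts, correlations = cors,
                             length_nm = len)
    claim_points(Pv)
  }
  structure(list(filaments = filaments, params = params, voxel_nm = vox,
                 dims = d), class = "filament_set")
}

#' @export
print.filament_set <- function(x, ...) {
  lens <- vapply(x$filaments, `[[`, numeric(1), "length_nm")
  cat(sprintf("<filament_set> %d filaments%s\n", length(x$filaments),
              if (length(lens)) sprintf(", length %.0f-%.0f nm (median %.0f)",
                                        min(lens), max(lens), stats::median(lens))
              else ""))
  invisible(x)
}

#' Rasterize traced filaments into a label volume
#'
#' Paints each polyline as a tube of the given radius carrying its filament
#' id; overlaps resolve to the earlier (higher-seed-correlation) id.
#'
#' @param fset a [trace_lines()] `filament_set`.
#' @param dims target volume dimensions (default: the traced volume's).
#' @param voxel_nm target voxel size (default: the traced volume's).
#' @param radius_nm tube radius; must be at least half a voxel.
#' @return A label [voxel_volume()].
#' @export
rasterize_filaments <- function(fset, dims = fset$dims, voxel_nm = fset$voxel_nm,
                                radius_nm = 10) {
  stopifnot(inherits(fset, "filament_set"))
  if (radius_nm < voxel_nm / 2) stop("radius must be at least half a voxel")
  lab <- array(0L, dims)
  rv <- radius_nm / voxel_nm
  reach <- ceiling(rv) + 1L
  offs <- as.matrix(expand.grid(-reach:reach, -reach:reach, -reach:reach))
  offs <- offs[rowSums(offs^2) <= (rv + 1)^2, , drop = FALSE]
  for (f in fset$filaments) {
    P <- densify_polyline(f$points, voxel_nm / 2)
    Pv <- P / voxel_nm + 1                    # continuous voxel coords
    iv <- round(Pv)
    if (any(iv < 1) || any(sweep(iv, 2, dims, ">")))
      stop("filament ", f$id, " polyline lies outside the target volume")
    for (s in seq_len(nrow(offs))) {
      q <- sweep(iv, 2, offs[s, ], "+")
      d2 <- rowSums((q - Pv)^2)               # voxel center to exact point
      ok <- d2 <= rv^2 & q[, 1] >= 1 & q[, 1] <= dims[1] &
        q[, 2] >= 1 & q[, 2] <= dims[2] & q[, 3] >= 1 & q[, 3] <= dims[3]
      if (!any(ok)) next
      lin <- q[ok, 1] + dims[1] * (q[ok, 2] - 1) + dims[1] * dims[2] * (q[ok, 3] - 1)
      free <- lab[lin] == 0L
      lab[lin[free]] <- f$id
    }
  }
  voxel_volume(lab, voxel_nm = voxel_nm, kind = "labels")
}

#' Write / read a filament set as JSON lines
#'
#' One filament per line: id, polyline points (nm), per-point correlations.
#'
#' @param fset a `filament_set`.
#' @param path output path (`.jsonl`).
#' @return `path` / a `filament_set`.
#' @export
write_filaments <- function(fset, path) {
  stopifnot(inherits(fset, "filament_set"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (f in fset$filaments) {
    writeLines(jsonlite::toJSON(list(id = f$id,
                                     points = unname(f$points),
                                     correlations = f$correlations,
                                     length_nm = f$length_nm),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_filaments
#' @param voxel_nm,dims geometry to attach on read.
#' @export
read_filaments <- function(path, voxel_nm = NA_real_, dims = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  fil <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    pts <- matrix(unlist(x$points), ncol = 3, byrow = FALSE)
    if (is.matrix(x$points)) pts <- x$points
    colnames(pts) <- c("x_nm", "y_nm", "z_nm")
    list(id = x$id, points = pts, correlations = x$correlations,
         length_nm = x$length_nm)
  })
  structure(list(filaments = fil, params = NULL, voxel_nm = voxel_nm,
                 dims = dims), class = "filament_set")
}
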