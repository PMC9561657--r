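#' Estimate the sarcomere period from a Z-disk mask
#'
#' Takes the per-slice Z-disk voxel count profile along the longitudinal
#' axis, finds the dominant peak of its autocorrelation (parabolically
#' refined), and locates the phase (position of the first Z-disk density
#' maximum) by circular averaging. Requires at least 3 Z-disks.
#'
#' @param zdisk binary Z-disk [voxel_volume()].
#' @return list: `period_nm`, `phase_nm` (center of the first Z-disk sheet).
#' @export
estimate_period <- function(zdisk) {
  assert_volume(zdisk, "binary")
  vox <- zdisk$voxel_nm
  prof <- apply(zdisk$data == 1, 1, sum)
  n <- length(prof)
  if (stats::sd(prof) == 0) stop("flat Z-disk profile: no periodicity")
  runs <- rle(prof > max(prof) / 2)
  if (sum(runs$values) < 3)
    stop("need at least 3 Z-disks along the longitudinal axis, found ",
         sum(runs$values))
  x <- prof - mean(prof)
  np <- stats::nextn(2L * n, 2)
  ac <- Re(stats::fft(Mod(stats::fft(c(x, rep(0, np - n))))^2, inverse = TRUE))[1:n]
  # skip the zero-lag peak: search beyond the first zero crossing
  lag0 <- which(ac < 0)[1]
  if (is.na(lag0)) stop("no periodicity detected in the Z-disk profile")
  search <- lag0:(floor(n * 2 / 3))
  pk <- search[which.max(ac[search])]
  # parabolic sub-sample refinement
  if (pk > 1 && pk < n - 1) {
    y1 <- ac[pk - 1]; y2 <- ac[pk]; y3 <- ac[pk + 1]
    denom <- y1 - 2 * y2 + y3
    shift <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
  } else shift <- 0
  period_vox <- (pk - 1) + shift
  period_nm <- period_vox * vox
  # phase by circular mean of the profile at the detected period
  ph <- Arg(sum(prof * exp(2i * pi * (seq_len(n) - 1) / period_vox)))
  z0 <- (ph / (2 * pi)) * period_vox
  z0 <- z0 %% period_vox
  list(period_nm = period_nm, phase_nm = z0 * vox)
}

# complete Z-disk center positions (nm) inside [0, extent)
period_z_centers <- function(extent_nm, period_nm, phase_nm) {
  k <- 0:floor((extent_nm - phase_nm) / period_nm)
  zc <- phase_nm + k * period_nm
  zc[zc >= 0 & zc < extent_nm]
}

#' Z-disk sheet areas per half sarcomere
#'
#' Groups the volume into sarcomere-length slabs centered on each Z-disk,
#' takes the maximum projection of the Z-disk mask along the longitudinal
#' axis per slab, and counts foreground pixels. Each Z-disk serves its two
#' flanking half sarcomeres, so every complete sarcomere yields two
#' half-sheet rows (interleaved duplication).
#'
#' @param zdisk binary Z-disk [voxel_volume()].
#' @param period_nm sarcomere period P (nm).
#' @param phase_nm center of the first Z-disk sheet (nm).
#' @return data.frame: `half_sheet`, `sarcomere`, `side` ("left"/"right" of
#'   the sarcomere's two Z-disks), `z_center_nm`, `z_area_vox`, `z_area_um2`.
#' @export
zdisk_sheet_areas <- function(zdisk, period_nm, phase_nm) {
  assert_volume(zdisk, "binary")
  vox <- zdisk$voxel_nm
  n1 <- dim(zdisk$data)[1]
  extent <- n1 * vox
  zc <- period_z_centers(extent, period_nm, phase_nm)
  if (length(zc) < 2) stop("fewer than two Z-disks: no complete sarcomere")
  zpos <- (seq_len(n1) - 1) * vox
  area_at <- vapply(zc, function(z) {
    sl <- which(zpos >= z - period_nm / 2 & zpos < z + period_nm / 2)
    sub <- zdisk$data[sl, , , drop = FALSE] == 1
    a <- sum(apply(sub, c(2, 3), max))
    if (a == 0) stop("sarcomere-length slab at ", z, " nm contains no Z-disk voxels")
    a
  }, numeric(1))
  ns <- length(zc) - 1                 # complete sarcomeres
  rows <- data.frame(
    half_sheet = seq_len(2 * ns),
    sarcomere = rep(seq_len(ns), each = 2),
    side = rep(c("left", "right"), ns),
    z_center_nm = as.vector(rbind(zc[seq_len(ns)], zc[seq_len(ns) + 1])),
    z_area_vox = as.vector(rbind(area_at[seq_len(ns)], area_at[seq_len(ns) + 1])))
  rows$z_area_um2 <- rows$z_area_vox * (vox / 1e3)^2
  rows
}

# mean filter over a (2w+1)^2 window with edge renormalization, via cumsums
box_mean <- function(x, w) {
  n1 <- nrow(x); n2 <- ncol(x)
  cs <- matrix(0, n1 + 1, n2 + 1)
  cs[-1, -1] <- t(apply(apply(x, 2, cumsum), 1, cumsum))
  i1 <- pmax(seq_len(n1) - w, 1); i2 <- pmin(seq_len(n1) + w, n1)
  j1 <- pmax(seq_len(n2) - w, 1); j2 <- pmin(seq_len(n2) + w, n2)
  S <- cs[i2 + 1, j2 + 1] - cs[i1, j2 + 1] - cs[i2 + 1, j1] + cs[i1, j1]
  cnt <- outer(i2 - i1 + 1, j2 - j1 + 1)
  S / cnt
}

# IsoData iterative-intermeans threshold on an 8-bit image
isodata_threshold <- function(img8) {
  v <- as.vector(img8)
  if (diff(range(v)) == 0) stop("single-valued image: threshold undefined")
  t_old <- -Inf
  t_new <- mean(v)
  while (abs(t_new - t_old) > 0.5) {
    t_old <- t_new
    lo <- v[v <= t_old]; hi <- v[v > t_old]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
  }
  t_new
}

#' A-band sheet areas per half sarcomere
#'
#' Per half-sarcomere slab: average projection along the longitudinal axis,
#' local-contrast normalization (per-pixel subtract local mean and divide by
#' local SD over a square window of radius P/4, clip at +/- `clip_sd` SD,
#' affinely stretched and centered to 8-bit), multiplication by the slab's
#' binarized maximum projection, and IsoData thresholding; the area is the
#' foreground pixel count. Works on binary masks and on grayscale
#' probability volumes alike.
#'
#' @param aband A-band [voxel_volume()] (binary mask or grayscale).
#' @param period_nm sarcomere period P (nm).
#' @param phase_nm Z-disk phase (nm).
#' @param window_radius_nm local-contrast window radius, default P/4.
#' @param clip_sd SD clip for the normalization, default 10.
#' @return data.frame: `half_sheet`, `sarcomere`, `side`, `a_area_vox`,
#'   `a_area_um2`.
#' @export
aband_sheet_areas <- function(aband, period_nm, phase_nm,
                              window_radius_nm = period_nm / 4, clip_sd = 10) {
  assert_volume(aband, c("binary", "grayscale"))
  vox <- aband$voxel_nm
  n1 <- dim(aband$data)[1]
  extent <- n1 * vox
  zc <- period_z_centers(extent, period_nm, phase_nm)
  if (length(zc) < 2) stop("fewer than two Z-disks: no complete sarcomere")
  zpos <- (seq_len(n1) - 1) * vox
  w <- max(1L, round(window_radius_nm / vox))
  ns <- length(zc) - 1
  rows <- lapply(seq_len(ns), function(k) {
    bounds <- c(zc[k], zc[k] + period_nm / 2, zc[k + 1])
    areas <- vapply(1:2, function(half) {
      sl <- which(zpos >= bounds[half] & zpos < bounds[half + 1])
      sub <- aband$data[sl, , , drop = FALSE]
      if (all(sub == 0)) stop("empty half-sarcomere slab at ", bounds[half], " nm")
      avg <- apply(sub, c(2, 3), mean)
      mx <- apply(sub, c(2, 3), max)
      mask <- mx > max(mx) / 2
      mu <- box_mean(avg, w)
      sdv <- sqrt(pmax(box_mean(avg^2, w) - mu^2, 0))
      nrm <- ifelse(sdv > 0, (avg - mu) / sdv, 0)
      nrm <- pmin(pmax(nrm, -clip_sd), clip_sd)
      img8 <- round((nrm + clip_sd) / (2 * clip_sd) * 255)
      img8 <- img8 * mask
      thr <- isodata_threshold(img8)
      sum(img8 > thr & mask)
    }, numeric(1))
    data.frame(half_sheet = c(2 * k - 1, 2 * k), sarcomere = k,
               side = c("left", "right"), a_area_vox = areas)
  })
  out <- do.call(rbind, rows)
  out$a_area_um2 <- out$a_area_vox * (vox / 1e3)^2
  out
}

#' Intrasarcomere CSA heterogeneity per half sarcomere sheet
#'
#' Combines paired Z-disk and A-band half-sheet areas into the percent CSA
#' difference 100 * (A - Z) / A per half sheet (positive when the Z-disk CSA
#' is reduced below the A-band CSA; negative values are allowed and flagged)
#' plus the raw Z/A ratio, and summarizes the cell as mean +/- SD.
#'
#' @param z_areas data.frame from [zdisk_sheet_areas()].
#' @param a_areas data.frame from [aband_sheet_areas()].
#' @return list of class `half_sheet_csa`: `table` (per half sheet),
#'   `mean_pct`, `sd_pct`, `n_half_sheets`, `any_inverted`.
#' @export
csa_heterogeneity <- function(z_areas, a_areas) {
  if (nrow(z_areas) != nrow(a_areas))
    stop("Z-disk and A-band half-sheet tables differ in length")
  if (any(a_areas$a_area_vox == 0)) stop("zero A-band area: percent difference undefined")
  tab <- data.frame(half_sheet = z_areas$half_sheet,
                    sarcomere = z_areas$sarcomere,
                    side = z_areas$side,
                    z_area_vox = z_areas$z_area_vox,
                    a_area_vox = a_areas$a_area_vox)
  tab$percent_difference <- 100 * (tab$a_area_vox - tab$z_area_vox) / tab$a_area_vox
  tab$za_ratio <- tab$z_area_vox / tab$a_area_vox
  structure(list(table = tab,
                 mean_pct = mean(tab$percent_difference),
                 sd_pct = stats::sd(tab$percent_difference),
                 n_half_sheets = nrow(tab),
                 any_inverted = any(tab$percent_difference < 0)),
            class = "half_sheet_csa")
}

#' @export
print.half_sheet_csa <- function(x, ...) {
  cat(sprintf("<half_sheet_csa> %d half sheets: %.1f +/- %.1f %% CSA difference%s\n",
              x$n_half_sheets, x$mean_pct, x$sd_pct,
              if (x$any_inverted) " (inverted sheets present)" else ""))
  invisible(x)
}

#' End-to-end CSA heterogeneity from masks
#'
#' Convenience wrapper: estimates (or accepts) the period and phase, computes
#' Z-disk and A-band half-sheet areas, and returns the heterogeneity summary.
#'
#' @param zdisk binary Z-disk [voxel_volume()].
#' @param aband A-band [voxel_volume()].
#' @param period_nm,phase_nm optional manual override of [estimate_period()].
#' @return A `half_sheet_csa` (see [csa_heterogeneity()]); the period and
#'   phase used are attached as attributes.
#' @export
sheet_csa <- function(zdisk, aband, period_nm = NULL, phase_nm = NULL) {
  if (is.null(period_nm)) {
    est <- estimate_period(zdisk)
    period_nm <- est$period_nm
    if (is.null(phase_nm)) phase_nm <- est$phase_nm
  } else if (is.null(phase_nm)) {
    # phase by circular averaging at the supplied period (no 3-Z-disk minimum)
    prof <- apply(zdisk$data == 1, 1, sum)
    pv <- period_nm / zdisk$voxel_nm
    ph <- Arg(sum(prof * exp(2i * pi * (seq_along(prof) - 1) / pv)))
    phase_nm <- (((ph / (2 * pi)) * pv) %% pv) * zdisk$voxel_nm
  }
  z <- zdisk_sheet_areas(zdisk, period_nm, phase_nm)
  a <- aband_sheet_areas(aband, period_nm, phase_nm)
  out <- csa_heterogeneity(z, a)
  attr(out, "period_nm") <- period_nm
  attr(out, "phase_nm") <- phase_nm
  out
}
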