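#' Exact Euclidean distance field to a binary mask
#'
#' Per-voxel exact Euclidean distance (nm, voxel center to voxel center) to
#' the nearest foreground voxel of `mask`, computed with a separable exact
#' squared-distance transform.
#'
#' @param mask a binary [voxel_volume()] with at least one foreground voxel.
#' @return A [voxel_volume()] of kind `"distance"` carrying the source mask
#'   dimensions; zero on source voxels.
#' @export
distance_field <- function(mask) {
  assert_volume(mask, "binary")
  m <- mask$data == 1
  if (!any(m)) stop("distance transform of an empty mask is undefined")
  d2 <- cpp_edt_sq(as.vector(m), dim(mask$data))
  voxel_volume(array(sqrt(d2) * mask$voxel_nm, dim(mask$data)),
               voxel_nm = mask$voxel_nm, kind = "distance")
}

#' Minimum organelle distance per filament
#'
#' For each filament id in a label volume, the minimum of a distance field
#' over the filament's voxels — the minimum voxel-center distance between the
#' filament and the distance field's source organelle.
#'
#' @param labels a label [voxel_volume()] of filament ids.
#' @param field a distance [voxel_volume()] from [distance_field()].
#' @return A data.frame with columns `id`, `min_distance_nm`, `n_voxels`.
#' @export
min_distance_per_filament <- function(labels, field) {
  assert_volume(labels, "labels")
  assert_volume(field, "distance")
  if (!identical(dim(labels$data), dim(field$data)) ||
      !isTRUE(all.equal(labels$voxel_nm, field$voxel_nm)))
    stop("label volume and distance field geometries do not match")
  idx <- which(labels$data > 0)
  if (length(idx) == 0L)
    return(data.frame(id = integer(0), min_distance_nm = numeric(0),
                      n_voxels = integer(0)))
  ids <- labels$data[idx]
  dmin <- tapply(field$data[idx], ids, min)
  nvox <- tapply(ids, ids, length)
  data.frame(id = as.integer(names(dmin)),
             min_distance_nm = as.numeric(dmin),
             n_voxels = as.integer(nvox), row.names = NULL)
}

#' Assign half-open proximity bins to distances
#'
#' Bins of the form (0, w], (w, 2w], ... nm; exact overlap (distance 0) is
#' excluded (`NA`), matching the organelle-overlap filter applied upstream.
#'
#' @param distance_nm numeric distances in nm.
#' @param width_nm bin width (default 100 nm).
#' @return Integer bin index (1 = within `width_nm`), `NA` for distance 0.
#' @export
proximity_bin <- function(distance_nm, width_nm = 100) {
  ifelse(distance_nm <= 0, NA_integer_, as.integer(ceiling(distance_nm / width_nm)))
}

#' Partition mitochondria into Z-disk-adjacent and distal compartments
#'
#' Mitochondrial voxels whose distance to the nearest Z-disk voxel is at most
#' `iband_width_nm + 200` nm are Z-adjacent. Also reports total mitochondrial
#' content as mitochondrial voxels over cell voxels when a cell mask is given.
#'
#' @param mito binary mitochondrial [voxel_volume()].
#' @param zdisk binary Z-disk [voxel_volume()] (non-empty).
#' @param iband_width_nm I-band width W_I, nm (measured on the raw data; an
#'   explicit input, never auto-estimated).
#' @param cell optional binary cell mask for the content denominator.
#' @param margin_nm margin added to W_I for the threshold (default 200 nm).
#' @return A list of class `mito_partition`: `threshold_nm`, voxel counts,
#'   `z_adjacent_fraction` (NA with `undefined = TRUE` if there are no
#'   mitochondrial voxels), `mito_content`.
#' @export
partition_mitochondria <- function(mito, zdisk, iband_width_nm, cell = NULL,
                                   margin_nm = 200) {
  assert_volume(mito, "binary")
  assert_volume(zdisk, "binary")
  if (!identical(dim(mito$data), dim(zdisk$data)))
    stop("mitochondrial and Z-disk masks do not share geometry")
  if (!any(zdisk$data == 1)) stop("empty Z-disk mask")
  thr <- iband_width_nm + margin_nm
  total <- sum(mito$data == 1)
  if (total == 0L) {
    zadj <- 0L
    frac <- NA_real_
  } else {
    dz <- distance_field(zdisk)
    zadj <- sum(dz$data[mito$data == 1] <= thr)
    frac <- zadj / total
  }
  content <- if (!is.null(cell)) {
    assert_volume(cell, "binary")
    total / sum(cell$data == 1)
  } else NA_real_
  structure(list(threshold_nm = thr,
                 z_adjacent_voxels = as.integer(zadj),
                 non_adjacent_voxels = as.integer(total - zadj),
                 total_mito_voxels = as.integer(total),
                 z_adjacent_fraction = frac,
                 undefined = total == 0L,
                 mito_content = content), class = "mito_partition")
}

#' @export
print.mito_partition <- function(x, ...) {
  cat(sprintf("<mito_partition> threshold %g nm: %d / %d voxels Z-adjacent (%s)\n",
              x$threshold_nm, x$z_adjacent_voxels, x$total_mito_voxels,
              if (x$undefined) "undefined fraction: no mitochondria"
              else sprintf("fraction %.3f", x$z_adjacent_fraction)))
  if (!is.na(x$mito_content))
    cat(sprintf("  mitochondrial content: %.3f of cell volume\n", x$mito_content))
  invisible(x)
}

#' Local thickness of a binary structure
#'
#' Per-voxel diameter (nm) of the largest inscribed sphere containing the
#' voxel (Hildebrand-Ruegsegger), computed from the exact Euclidean distance
#' transform of the foreground by painting spheres in decreasing radius
#' order. Used for mitochondrial diameter distributions.
#'
#' @param mask non-empty binary [voxel_volume()].
#' @return A list of class `local_thickness`: `field` (distance
#'   [voxel_volume()], nm, zero outside the mask), `median_nm`, `mean_nm`.
#' @export
local_thickness <- function(mask) {
  assert_volume(mask, "binary")
  m <- mask$data == 1
  if (!any(m)) stop("local thickness of an empty mask is undefined")
  # EDT of the foreground: distance to nearest background voxel
  d2 <- cpp_edt_sq(as.vector(!m), dim(mask$data))
  th <- cpp_local_thickness(sqrt(d2), as.vector(m), dim(mask$data))
  th <- array(th * mask$voxel_nm, dim(mask$data))
  vals <- th[m]
  structure(list(field = voxel_volume(th, mask$voxel_nm, "distance"),
                 median_nm = stats::median(vals),
                 mean_nm = mean(vals)), class = "local_thickness")
}

#' @export
print.local_thickness <- function(x, ...) {
  cat(sprintf("<local_thickness> median %.1f nm, mean %.1f nm\n",
              x$median_nm, x$mean_nm))
  invisible(x)
}
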