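#' Per-filament inertia geometry
#'
#' Second-moment (inertia) analysis of one filament in a label volume: unit
#' mass per voxel, moments about the centroid, eigenvalues sorted ascending
#' (nm^2). The moment about the *longest* principal axis (`I_long`, the
#' smallest eigenvalue for an elongated body) is the mean squared
#' perpendicular distance of filament mass from its best-fit line times the
#' voxel count — the basis of the deviation-from-linearity metric. The
#' largest eigenvalue is reported alongside.
#'
#' @param labels a label [voxel_volume()].
#' @param id filament id present in `labels`.
#' @return A list of class `filament_record`: `id`, `n_voxels`, `volume_nm3`,
#'   `centroid_nm`, `eigenvalues_nm2` (I1 <= I2 <= I3, per unit total mass
#'   times voxel count; see details), `axes` (columns = principal axes,
#'   longest first), `length_nm` (extent along the longest axis),
#'   `degenerate` flag for single-voxel filaments.
#' @export
filament_inertia <- function(labels, id) {
  assert_volume(labels, "labels")
  idx <- which(labels$data == id)
  if (length(idx) == 0L) stop("filament id ", id, " absent from label volume")
  vox <- labels$voxel_nm
  dims <- dim(labels$data)
  i <- (idx - 1) %% dims[1] + 1
  j <- ((idx - 1) %/% dims[1]) %% dims[2] + 1
  k <- (idx - 1) %/% (dims[1] * dims[2]) + 1
  pts <- cbind(i, j, k) * vox
  n <- nrow(pts)
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  S <- crossprod(rel)                      # second-moment matrix (sum r r^T)
  trS <- sum(diag(S))
  Itens <- diag(3) * trS - S               # inertia tensor, unit voxel mass
  eg <- eigen(Itens, symmetric = TRUE)     # values descending
  evals <- rev(eg$values)                  # I1 <= I2 <= I3
  evals[evals < 0] <- 0
  axes <- eg$vectors[, 3:1, drop = FALSE]  # longest principal axis first
  len <- if (n > 1) diff(range(rel %*% axes[, 1])) + vox else vox
  structure(list(id = id, n_voxels = n, volume_nm3 = n * vox^3,
                 centroid_nm = ctr, eigenvalues_nm2 = evals, axes = axes,
                 length_nm = len, degenerate = n == 1L),
            class = "filament_record")
}

#' Deviation from linearity of a filament
#'
#' The moment of inertia about the filament's longest principal axis divided
#' by its voxel volume: the mean squared perpendicular distance (nm^2) of
#' filament mass from its best-fit line. A straight solid rod of radius r
#' gives the cross-section floor r^2/2; curvature adds the squared deviation
#' of the centerline from the chord. Minimal for straight filaments and
#' strictly increasing with bending sagitta.
#'
#' The eigenvalue convention is switchable: `axis = "longest"` (default)
#' uses the moment about the longest principal axis (smallest eigenvalue),
#' which equals the deviation from the best-fit line; `axis = "largest"`
#' instead divides the largest eigenvalue by the volume.
#'
#' @param rec a [filament_inertia()] record.
#' @param axis `"longest"` (default) or `"largest"` eigenvalue convention.
#' @return Deviation from linearity, nm^2.
#' @export
linearity_deviation <- function(rec, axis = c("longest", "largest")) {
  axis <- match.arg(axis)
  stopifnot(inherits(rec, "filament_record"))
  if (rec$n_voxels == 0) stop("filament has zero volume")
  ev <- if (axis == "longest") rec$eigenvalues_nm2[1] else rec$eigenvalues_nm2[3]
  ev / rec$n_voxels
}

#' Morphometry table for all filaments in a label volume
#'
#' Runs [filament_inertia()] and [linearity_deviation()] for every label id.
#'
#' @inheritParams filament_inertia
#' @param lengths_nm optional named vector of trace polyline lengths (nm) by
#'   id; used in preference to the principal-axis voxel extent.
#' @return data.frame: `id`, `n_voxels`, `volume_nm3`, `length_nm`,
#'   `linearity_dev_nm2`, `linearity_dev_largest_nm2`, centroid columns.
#' @export
filament_morphometry <- function(labels, lengths_nm = NULL) {
  assert_volume(labels, "labels")
  vox <- labels$voxel_nm
  idx <- which(labels$data > 0)
  if (length(idx) == 0L) return(NULL)
  dims <- dim(labels$data)
  ids_all <- labels$data[idx]
  pts <- cbind((idx - 1) %% dims[1] + 1,
               ((idx - 1) %/% dims[1]) %% dims[2] + 1,
               (idx - 1) %/% (dims[1] * dims[2]) + 1) * vox
  rows <- lapply(split(seq_along(ids_all), ids_all), function(sel) {
    id <- ids_all[sel[1]]
    p <- pts[sel, , drop = FALSE]
    n <- nrow(p)
    ctr <- colMeans(p)
    rel <- sweep(p, 2, ctr)
    S <- crossprod(rel)
    Itens <- diag(3) * sum(diag(S)) - S
    eg <- eigen(Itens, symmetric = TRUE)
    evals <- pmax(rev(eg$values), 0)
    len <- if (n > 1) diff(range(rel %*% eg$vectors[, 3])) + vox else vox
    if (!is.null(lengths_nm) && !is.na(lengths_nm[as.character(id)]))
      len <- unname(lengths_nm[as.character(id)])
    data.frame(id = id, n_voxels = n, volume_nm3 = n * vox^3, length_nm = len,
               linearity_dev_nm2 = evals[1] / n,
               linearity_dev_largest_nm2 = evals[3] / n,
               centroid_x_nm = ctr[1], centroid_y_nm = ctr[2],
               centroid_z_nm = ctr[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter filaments for proximity analyses
#'
#' Keeps filaments longer than `min_length_nm` (strictly) that share no voxel
#' with any organelle mask — the inclusion rule for all filament-organelle
#' proximity statistics.
#'
#' @param morpho data.frame from [filament_morphometry()] (needs `id`,
#'   `length_nm`).
#' @param labels the filament label [voxel_volume()].
#' @param organelle_masks list of binary [voxel_volume()]s to test overlap
#'   against (may be empty).
#' @param min_length_nm length cutoff, default 1000 nm (filaments must be
#'   longer than 1 micrometer).
#' @return The filtered data.frame (possibly empty, with attribute
#'   `n_removed`).
#' @export
filter_filaments <- function(morpho, labels, organelle_masks = list(),
                             min_length_nm = 1000) {
  assert_volume(labels, "labels")
  keep <- morpho$length_nm > min_length_nm
  if (length(organelle_masks) > 0) {
    overlap_any <- array(FALSE, dim(labels$data))
    for (m in organelle_masks) {
      assert_volume(m, "binary")
      if (!identical(dim(m$data), dim(labels$data)))
        stop("organelle mask geometry does not match the label volume")
      overlap_any <- overlap_any | (m$data == 1)
    }
    touched <- unique(labels$data[overlap_any & labels$data > 0])
    keep <- keep & !(morpho$id %in% touched)
  }
  out <- morpho[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
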