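#' Construct a voxel volume
#'
#' A `voxel_volume` wraps a 3D array with its isotropic voxel size (nm) and a
#' semantic kind. Axis 1 is always the longitudinal (contractile) axis; axes
#' 2-3 span the muscle cross-section. Kinds:
#' \describe{
#'   \item{grayscale}{numeric intensities, 8-bit range \[0, 255\]}
#'   \item{binary}{values in \{0, 1\}}
#'   \item{labels}{non-negative integer instance labels, 0 = background}
#'   \item{distance}{non-negative distances in nm (derived volumes)}
#' }
#'
#' @param data 3D numeric/integer/logical array, at least 2 voxels per axis.
#' @param voxel_nm positive scalar, isotropic voxel edge length in nm.
#' @param kind one of `"grayscale"`, `"binary"`, `"labels"`, `"distance"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_nm, kind = c("grayscale", "binary", "labels", "distance")) {
  kind <- match.arg(kind)
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 2L))
    stop("volume must have at least 2 voxels per axis")
  if (!is.numeric(voxel_nm) || length(voxel_nm) != 1L || !is.finite(voxel_nm) || voxel_nm <= 0)
    stop("`voxel_nm` must be a positive scalar")
  validate_kind(data, kind)
  structure(list(data = data, voxel_nm = as.numeric(voxel_nm), kind = kind),
            class = "voxel_volume")
}

validate_kind <- function(data, kind) {
  rng <- range(data, finite = TRUE)
  switch(kind,
    binary = {
      u <- unique(as.vector(data))
      if (!all(u %in% c(0, 1)))
        stop("binary volume contains values other than {0, 1}: ",
             paste(utils::head(setdiff(u, c(0, 1)), 5), collapse = ", "))
    },
    labels = {
      if (rng[1] < 0) stop("label volume contains negative values")
      if (any(as.vector(data) %% 1 != 0)) stop("label volume contains non-integer values")
    },
    grayscale = {
      if (rng[1] < 0 || rng[2] > 255) stop("grayscale volume outside 8-bit range [0, 255]")
    },
    distance = {
      if (rng[1] < 0) stop("distance volume contains negative values")
    })
  invisible(TRUE)
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s, %d x %d x %d voxels @ %g nm (%.2f x %.2f x %.2f um)\n",
              x$kind, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$voxel_nm,
              dim(x$data)[1] * x$voxel_nm / 1e3,
              dim(x$data)[2] * x$voxel_nm / 1e3,
              dim(x$data)[3] * x$voxel_nm / 1e3))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' @rdname voxel_volume
#' @param x object to test or coerce.
#' @export
is_voxel_volume <- function(x) inherits(x, "voxel_volume")

assert_volume <- function(x, kind = NULL, what = deparse(substitute(x))) {
  if (!is_voxel_volume(x)) stop(what, " must be a voxel_volume")
  if (!is.null(kind) && !x$kind %in% kind)
    stop(what, " must have kind ", paste(kind, collapse = "/"), ", got ", x$kind)
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Load a voxel volume from a TIFF stack
#'
#' Reads a multi-page TIFF (one cross-sectional 2D slice per page, stacked
#' along the longitudinal axis). A JSON sidecar (`<path>.json`, written by
#' [save_volume()]) supplies `voxel_nm` and `kind` when present; arguments
#' override only if consistent.
#'
#' @param path path to a `.tif`/`.tiff` file.
#' @param voxel_nm isotropic voxel size in nm (required if no sidecar).
#' @param kind volume kind (required if no sidecar); values are validated.
#' @param transpose optional permutation of axes (e.g. `c(3, 1, 2)`) applied
#'   at load so that axis 1 is longitudinal; never inferred automatically.
#' @return A [voxel_volume()].
#' @export
load_volume <- function(path, voxel_nm = NULL, kind = NULL, transpose = NULL) {
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unknown volume file extension (expected .tif/.tiff): ", path)
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (!is.null(meta)) {
    if (is.null(voxel_nm)) voxel_nm <- meta$voxel_nm
    else if (!isTRUE(all.equal(as.numeric(voxel_nm), as.numeric(meta$voxel_nm))))
      stop("voxel_nm = ", voxel_nm, " conflicts with stored metadata (", meta$voxel_nm, " nm)")
    if (is.null(kind)) kind <- meta$kind
  }
  if (is.null(voxel_nm)) stop("`voxel_nm` required: no metadata sidecar found")
  if (is.null(kind)) stop("`kind` required: no metadata sidecar found")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  if (length(d2) != 2L) stop("expected single-channel TIFF pages")
  arr <- array(0, dim = c(length(pages), d2))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  if (!is.null(transpose)) arr <- aperm(arr, transpose)
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  voxel_volume(arr, voxel_nm = voxel_nm, kind = kind)
}

#' Save a voxel volume as a TIFF stack
#'
#' Writes one page per longitudinal slice plus a JSON metadata sidecar
#' (`<path>.json`) recording `voxel_nm` and `kind`. Grayscale and binary
#' volumes are stored 8-bit, label volumes 16-bit (labels must be < 65536).
#' Distance volumes are derived objects and are not file-backed.
#'
#' @param vol a [voxel_volume()] of kind grayscale, binary, or labels.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  assert_volume(vol)
  if (vol$kind == "distance")
    stop("distance volumes are derived in-memory objects; convert before saving")
  mx <- if (vol$kind == "labels") 65535 else 255
  bits <- if (vol$kind == "labels") 16L else 8L
  if (max(vol$data) > mx) stop("values exceed ", bits, "-bit storage range")
  n1 <- dim(vol$data)[1]
  pages <- lapply(seq_len(n1), function(i) vol$data[i, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(list(voxel_nm = vol$voxel_nm, kind = vol$kind,
                            dim = dim(vol$data)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save a result table
#'
#' Writes an analysis result table as CSV (UTF-8, header row) or JSON
#' depending on the file extension. Numeric columns survive a round trip at
#' double precision ([load_results()]).
#'
#' @param table a non-empty data.frame.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
save_results <- function(table, path) {
  if (!is.data.frame(table)) stop("`table` must be a data.frame")
  if (nrow(table) == 0L) stop("refusing to write an empty result table")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(table, con, row.names = FALSE)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(table, path, dataframe = "columns", digits = NA, na = "null")
  } else stop("unknown result table extension (expected .csv or .json): ", path)
  invisible(path)
}

#' @rdname save_results
#' @export
load_results <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else stop("unknown result table extension: ", path)
}
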