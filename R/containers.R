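# Core data containers: OCT volume, boundary set, pathology mask.

#' Construct an OCT volume
#'
#' @param data numeric 3D array `[depth_px, width_ascans, n_bscans]` of
#'   intensities in 0--255.
#' @param voxel_dims numeric length-3: (axial um/px, lateral um/px,
#'   inter-B-scan spacing um).
#' @return An `oct_volume` object.
#' @export
oct_volume <- function(data, voxel_dims) {
  stopifnot(length(dim(data)) == 3)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3 || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("voxel_dims must be 3 positive numbers (axial, lateral, bscan) in um")
  structure(list(data = data, voxel_dims = voxel_dims),
            class = "oct_volume")
}

#' @export
dim.oct_volume <- function(x) dim(x$data)

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume> %d depth px x %d A-scans x %d B-scans, voxel %s um\n",
              d[1], d[2], d[3], paste(signif(x$voxel_dims, 4), collapse = " x ")))
  invisible(x)
}

n_bscans <- function(volume) dim(volume$data)[3]
depth_px <- function(volume) dim(volume$data)[1]
width_ascans <- function(volume) dim(volume$data)[2]

#' Construct a boundary set
#'
#' Holds, per B-scan and per A-scan, the axial position (0-based row,
#' fractional values allowed) of each of the 12 named layer boundaries.
#'
#' @param positions numeric 3D array `[12, width_ascans, n_bscans]` with
#'   rownames `BOUNDARY_ORDER`.
#' @param voxel_dims voxel dimensions carried along for thickness
#'   conversions (um).
#' @return An `oct_boundary_set`.
#' @export
boundary_set <- function(positions, voxel_dims = NULL) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[1] == 12)
  if (is.null(dimnames(positions)[[1]]))
    dimnames(positions) <- list(BOUNDARY_ORDER, NULL, NULL)
  structure(list(positions = positions, voxel_dims = voxel_dims),
            class = "oct_boundary_set")
}

#' @export
print.oct_boundary_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<oct_boundary_set> 12 boundaries x %d A-scans x %d B-scans\n",
              d[2], d[3]))
  invisible(x)
}

#' Extract one boundary trace
#'
#' @param bs an `oct_boundary_set`.
#' @param boundary boundary name (one of `BOUNDARY_ORDER`).
#' @param bscan 0-based B-scan index.
#' @return Numeric vector of per-A-scan axial positions.
#' @export
boundary_positions <- function(bs, boundary, bscan) {
  stopifnot(boundary %in% BOUNDARY_ORDER)
  bs$positions[boundary, , bscan + 1L]
}

#' Check the anatomical depth-ordering invariant of a boundary set
#'
#' @param bs an `oct_boundary_set`.
#' @param tol tolerance in px.
#' @return TRUE if for every A-scan of every B-scan the 12 boundaries are in
#'   non-decreasing anatomical depth order within `tol`.
#' @export
boundaries_ordered <- function(bs, tol = 0.5) {
  p <- bs$positions
  all(apply(p, c(2, 3), function(v) all(diff(v) >= -tol)))
}

#' Construct a pathology mask
#'
#' @param mask logical 3D array, same shape as the volume data.
#' @param kind `"drusen"` or `"HIS"`.
#' @param voxel_dims voxel dimensions in um.
#' @return An `oct_mask`.
#' @export
oct_mask <- function(mask, kind = c("drusen", "HIS"), voxel_dims) {
  kind <- match.arg(kind)
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(mask = mask, kind = kind,
                 voxel_dims = as.numeric(voxel_dims)),
            class = "oct_mask")
}

#' @export
print.oct_mask <- function(x, ...) {
  cat(sprintf("<oct_mask> kind=%s, %d voxels set (%.4g mm^3)\n",
              x$kind, sum(x$mask), mask_volume(x)))
  invisible(x)
}

#' Physical volume of a pathology mask
#'
#' The number of set voxels multiplied by the physical voxel volume.
#'
#' @param mask an `oct_mask`.
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "oct_mask"))
  sum(mask$mask) * prod(mask$voxel_dims) / 1e9
}
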