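# The ten structural features of an eye: pathology volumes (HIS, drusen),
# boundary curviness (MZ-EZ, OPL-ONL) and mean / 70th-percentile thickness
# of the retina, the EZ-to-RBC complex and the RPE layer.

#' Default feature-extraction configuration
#'
#' @return Named list: curviness constants (`alpha`, `delta`), drusen
#'   detection (`ratio_threshold`, `dev_threshold_px`, `band_px`), thickness
#'   smoothing `sigma` (grid samples) and the complex upper boundary.
#' @export
feature_config <- function() {
  list(
    curviness = curviness_params(alpha = 3, delta = 5),
    drusen = list(ratio_threshold = 1.3, dev_threshold_px = 3, band_px = 3),
    his = list(min_component = 0),
    thickness = list(sigma = 2),
    complex_upper = "MZ-EZ"
  )
}

#' Construct a named ten-feature vector
#'
#' @param his_volume_mm3,drusen_volume_mm3 pathology volumes (mm^3).
#' @param curviness_mzez,curviness_oplonl boundary curviness scores.
#' @param retina_mean_um,retina_p70_um,complex_mean_um,complex_p70_um,rpe_mean_um,rpe_p70_um
#'   thickness statistics (um).
#' @return Named numeric vector of class `feature_vector`.
#' @export
feature_vector <- function(his_volume_mm3, drusen_volume_mm3, curviness_mzez,
                           curviness_oplonl, retina_mean_um, retina_p70_um,
                           complex_mean_um, complex_p70_um, rpe_mean_um,
                           rpe_p70_um) {
  v <- c(his_volume_mm3 = his_volume_mm3, drusen_volume_mm3 = drusen_volume_mm3,
         curviness_mzez = curviness_mzez, curviness_oplonl = curviness_oplonl,
         retina_mean_um = retina_mean_um, retina_p70_um = retina_p70_um,
         complex_mean_um = complex_mean_um, complex_p70_um = complex_p70_um,
         rpe_mean_um = rpe_mean_um, rpe_p70_um = rpe_p70_um)
  if (any(!is.finite(v))) stop("feature vector contains non-finite values")
  structure(v, class = c("feature_vector", "numeric"))
}

FEATURE_NAMES <- c("his_volume_mm3", "drusen_volume_mm3", "curviness_mzez",
                   "curviness_oplonl", "retina_mean_um", "retina_p70_um",
                   "complex_mean_um", "complex_p70_um", "rpe_mean_um",
                   "rpe_p70_um")

# intensities of all pixels in the half-open band [upper, lower) of one
# B-scan; rows satisfy upper <= r < lower (fractional bounds allowed)
band_values_bscan <- function(img, upper, lower) {
  d <- nrow(img); w <- ncol(img)
  rows0 <- seq_len(d) - 1L
  unlist(lapply(seq_len(w), function(j) {
    img[rows0 >= upper[j] & rows0 < lower[j], j]
  }), use.names = FALSE)
}

# logical band mask for one B-scan
band_mask_bscan <- function(d, w, upper, lower) {
  rows0 <- matrix(seq_len(d) - 1L, d, w)
  u <- matrix(upper, d, w, byrow = TRUE)
  l <- matrix(lower, d, w, byrow = TRUE)
  rows0 >= u & rows0 < l
}

#' Mean intensity of a named retinal layer
#'
#' @param volume an `oct_volume`.
#' @param boundaries an `oct_boundary_set`.
#' @param layer `"RNFL"`, `"RPE"`, `"retina"` or `"complex"`, or a character
#'   vector of two boundary names (upper, lower).
#' @return Arithmetic mean intensity over the half-open band across all
#'   B-scans.
#' @export
layer_mean_intensity <- function(volume, boundaries, layer) {
  bnd <- if (length(layer) == 2) layer else LAYER_BANDS[[layer]]
  if (is.null(bnd)) stop(sprintf("unknown layer '%s'", layer[1]))
  nb <- n_bscans(volume)
  vals <- unlist(lapply(seq_len(nb) - 1L, function(z) {
    band_values_bscan(volume$data[, , z + 1L],
                      boundary_positions(boundaries, bnd[1], z),
                      boundary_positions(boundaries, bnd[2], z))
  }), use.names = FALSE)
  if (length(vals) == 0)
    stop(sprintf("layer band %s-%s is empty (coincident boundaries)",
                 bnd[1], bnd[2]))
  mean(vals)
}

#' Detect hyper-reflective intra-retinal spots (HIS)
#'
#' HIS pixels live in the INL-to-ONL band (rows between the IPL-INL and
#' ONL-ELM boundaries) and are brighter than the reference threshold: the
#' mean intensity over the pooled union of the RNFL and RPE bands of the
#' whole volume.
#'
#' @param volume an `oct_volume`.
#' @param boundaries an `oct_boundary_set`.
#' @param config feature configuration (see [feature_config()]).
#' @return An `oct_mask` of kind `"HIS"`.
#' @export
detect_his <- function(volume, boundaries, config = feature_config()) {
  for (b in c("IPL-INL", "ONL-ELM", "ILM-RNFL", "RNFL-GCL", "IZ-RPE", "RBC"))
    if (any(is.na(boundaries$positions[b, , ])))
      stop(sprintf("detect_his: boundary %s missing", b))
  nb <- n_bscans(volume); d <- depth_px(volume); w <- width_ascans(volume)
  ref_vals <- unlist(lapply(seq_len(nb) - 1L, function(z) {
    img <- volume$data[, , z + 1L]
    c(band_values_bscan(img, boundary_positions(boundaries, "ILM-RNFL", z),
                        boundary_positions(boundaries, "RNFL-GCL", z)),
      band_values_bscan(img, boundary_positions(boundaries, "IZ-RPE", z),
                        boundary_positions(boundaries, "RBC", z)))
  }), use.names = FALSE)
  if (length(ref_vals) == 0) stop("detect_his: empty RNFL/RPE reference bands")
  threshold <- mean(ref_vals)
  mask <- array(FALSE, dim = dim(volume$data))
  for (z in seq_len(nb) - 1L) {
    band <- band_mask_bscan(d, w, boundary_positions(boundaries, "IPL-INL", z),
                            boundary_positions(boundaries, "ONL-ELM", z))
    mask[, , z + 1L] <- band & volume$data[, , z + 1L] > threshold
  }
  oct_mask(mask, "HIS", volume$voxel_dims)
}

#' Detect drusen (RPE detachment)
#'
#' Per B-scan, Bruch's membrane is estimated as a robust least-squares line
#' through the RBC boundary (columns where RBC rises more than
#' `dev_threshold_px` above the first fit are dropped and the line refit).
#' The ELM-to-BM thickness profile `T[i] = BM[i] - ONLELM[i]` is then fit
#' with a first-order polynomial; columns where `T` exceeds the fit by more
#' than `dev_threshold_px` are drusen candidates.  Candidate columns are
#' merged into maximal runs, and a run is confirmed when the mean intensity
#' of the `band_px` rows just above the detached RBC (bright RPE) exceeds
#' `ratio_threshold` times the mean of the `band_px` rows just above the
#' Bruch's-membrane baseline (hypo-reflective detachment interior).
#' Confirmed mask pixels are those between the detached RBC and the
#' baseline.
#'
#' @param volume an `oct_volume`.
#' @param boundaries an `oct_boundary_set`.
#' @param ratio_threshold intensity ratio confirming a detachment.
#' @param dev_threshold_px candidate threshold on the thickness residual, px.
#' @param band_px height of the intensity bands, px.
#' @return An `oct_mask` of kind `"drusen"`.
#' @export
detect_drusen <- function(volume, boundaries, ratio_threshold = 1.3,
                          dev_threshold_px = 3, band_px = 3) {
  for (b in c("ONL-ELM", "RBC"))
    if (any(is.na(boundaries$positions[b, , ])))
      stop(sprintf("detect_drusen: boundary %s missing", b))
  nb <- n_bscans(volume); d <- depth_px(volume); w <- width_ascans(volume)
  if (w < 2) stop("detect_drusen: volume too narrow for a line fit")
  mask <- array(FALSE, dim = dim(volume$data))
  rows0 <- seq_len(d) - 1L
  cols0 <- seq_len(w) - 1L
  for (z in seq_len(nb) - 1L) {
    img <- volume$data[, , z + 1L]
    rbc <- boundary_positions(boundaries, "RBC", z)
    elm <- boundary_positions(boundaries, "ONL-ELM", z)
    # Bruch's membrane baseline: line fit to RBC, refit without the columns
    # where RBC is elevated (detached RPE sits above the first fit)
    fit0 <- stats::lm.fit(cbind(1, cols0), rbc)
    flat <- (fit0$fitted.values - rbc) <= dev_threshold_px
    bcols <- if (any(flat)) cols0[flat] else cols0
    bfit <- stats::lm.fit(cbind(1, bcols), rbc[bcols + 1L])
    baseline <- bfit$coefficients[1] + bfit$coefficients[2] * cols0
    tt <- baseline - elm
    fit <- stats::lm.fit(cbind(1, cols0), tt)
    cand <- (tt - fit$fitted.values) > dev_threshold_px
    if (!any(cand)) next
    runs <- rle(cand)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      cs <- starts[k]:ends[k]
      upper_vals <- unlist(lapply(cs, function(j) {
        img[rows0 >= rbc[j] - band_px & rows0 < rbc[j], j]
      }), use.names = FALSE)
      lower_vals <- unlist(lapply(cs, function(j) {
        img[rows0 >= baseline[j] - band_px & rows0 < baseline[j], j]
      }), use.names = FALSE)
      if (length(upper_vals) == 0 || length(lower_vals) == 0) next
      ratio <- mean(upper_vals) / mean(lower_vals)
      if (!is.finite(ratio) || ratio <= ratio_threshold) next
      # delineate the full contiguous detachment: extend the confirmed run
      # outwards while the RBC still sits visibly above the BM baseline
      lo <- cs[1]
      while (lo > 1 && (baseline[lo - 1] - rbc[lo - 1]) > 0.5) lo <- lo - 1
      hi <- cs[length(cs)]
      while (hi < w && (baseline[hi + 1] - rbc[hi + 1]) > 0.5) hi <- hi + 1
      for (j in lo:hi) {
        rr <- rows0 >= rbc[j] & rows0 < baseline[j]
        mask[rr, j, z + 1L] <- TRUE
      }
    }
  }
  oct_mask(mask, "drusen", volume$voxel_dims)
}

#' Thickness map of a structure
#'
#' Per-(B-scan, A-scan) thickness in um between two boundaries, optionally
#' smoothed with a 2D Gaussian across the A-scan x B-scan grid (kernel
#' renormalised at the borders).
#'
#' @param boundaries an `oct_boundary_set` (must carry voxel dims).
#' @param upper,lower boundary names.
#' @param sigma Gaussian smoothing sigma in grid samples; 0 disables.
#' @return Matrix `[width_ascans, n_bscans]` of thickness in um with
#'   attribute `sigma`.
#' @export
thickness_profile <- function(boundaries, upper, lower, sigma = 2) {
  ax <- boundaries$voxel_dims[1]
  if (is.null(ax)) stop("boundary set carries no voxel dimensions")
  t_px <- boundaries$positions[lower, , ] - boundaries$positions[upper, , ]
  t_px <- as.matrix(t_px)
  if (any(t_px < 0)) {
    warning(sprintf("crossing boundaries %s/%s: thickness clamped at 0",
                    upper, lower))
    t_px[t_px < 0] <- 0
  }
  t_um <- t_px * ax
  if (sigma > 0) t_um <- gauss_smooth2d_renorm(t_um, sigma)
  attr(t_um, "sigma") <- sigma
  t_um
}

# 2D Gaussian smoothing with border renormalisation (separable; the valid
# window is a product set so separable renormalisation equals the 2D one)
gauss_smooth2d_renorm <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  sm1 <- function(x) {
    n <- length(x); r <- (length(k) - 1L) / 2L
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      wts <- k[j - i + r + 1L]
      out[i] <- sum(wts * x[j]) / sum(wts)
    }
    out
  }
  m2 <- apply(m, 2, sm1)
  if (is.null(dim(m2))) m2 <- matrix(m2, nrow = nrow(m))
  m3 <- t(apply(m2, 1, sm1))
  if (nrow(m) == 1) m3 <- matrix(m3, nrow = 1)
  if (ncol(m) == 1) m3 <- matrix(t(m3), ncol = 1)
  m3
}

#' Mean and 70th percentile of a thickness map
#'
#' The percentile uses linear interpolation between closest ranks,
#' `h = (n - 1) * 0.7 + 1`.
#'
#' @param tmap thickness matrix from [thickness_profile()].
#' @return Named numeric `c(mean, p70)` in um.
#' @export
thickness_stats <- function(tmap) {
  v <- as.numeric(tmap)
  if (length(v) == 0) stop("empty thickness map")
  c(mean = mean(v), p70 = as.numeric(stats::quantile(v, 0.7, type = 7)))
}

#' Extract the ten features of a volume
#'
#' @param volume an `oct_volume`.
#' @param boundaries an `oct_boundary_set` with all 12 boundaries.
#' @param config feature configuration, see [feature_config()].
#' @return A `feature_vector`.
#' @export
extract_features <- function(volume, boundaries, config = feature_config()) {
  nb <- n_bscans(volume)
  wrap <- function(feature, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("feature '%s': %s", feature, conditionMessage(e)), call. = FALSE))
  }
  his <- wrap("his_volume_mm3", detect_his(volume, boundaries, config))
  dru <- wrap("drusen_volume_mm3", detect_drusen(
    volume, boundaries,
    ratio_threshold = config$drusen$ratio_threshold,
    dev_threshold_px = config$drusen$dev_threshold_px,
    band_px = config$drusen$band_px))
  cv_of <- function(feature, given) {
    wrap(feature, mean(vapply(seq_len(nb) - 1L, function(z) {
      curviness(boundary_positions(boundaries, "RBC", z),
                boundary_positions(boundaries, given, z),
                config$curviness)
    }, numeric(1))))
  }
  sig <- config$thickness$sigma
  if (is.null(boundaries$voxel_dims)) boundaries$voxel_dims <- volume$voxel_dims
  r <- wrap("retina", thickness_stats(
    thickness_profile(boundaries, "ILM-RNFL", "RBC", sig)))
  cx <- wrap("complex", thickness_stats(
    thickness_profile(boundaries, config$complex_upper, "RBC", sig)))
  rp <- wrap("rpe", thickness_stats(
    thickness_profile(boundaries, "IZ-RPE", "RBC", sig)))
  feature_vector(
    his_volume_mm3 = mask_volume(his),
    drusen_volume_mm3 = mask_volume(dru),
    curviness_mzez = cv_of("curviness_mzez", "MZ-EZ"),
    curviness_oplonl = cv_of("curviness_oplonl", "OPL-ONL"),
    retina_mean_um = r[["mean"]], retina_p70_um = r[["p70"]],
    complex_mean_um = cx[["mean"]], complex_p70_um = cx[["p70"]],
    rpe_mean_um = rp[["mean"]], rpe_p70_um = rp[["p70"]]
  )
}
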