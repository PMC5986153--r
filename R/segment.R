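# Volume segmentation: the 12 boundaries are detected per B-scan in a fixed
# high-contrast-to-low-contrast sequence; the ILM-RNFL and RBC anchors define
# per-column regions of interest for all later, lower-contrast interfaces,
# and a cross-B-scan correction exploits the continuity of retinal tissue
# between adjacent B-scans.

#' Default segmentation configuration
#'
#' @return Named list of segmentation parameters: Canny settings, graph edge
#'   weights, ROI construction, curve fit and cross-B-scan correction.
#' @export
segmentation_config <- function() {
  list(
    canny = list(sigma = 1.5, q_low = 0.7, q_high = 0.9),
    # w_s deliberately small: drusen-elevated boundaries have steep shoulders
    # whose climb must not cost more than skipping the bump; w_p large enough
    # to pin the two anchors (topmost ILM-RNFL, bottommost RBC)
    weights = list(w_d = 1, w_s = 0.5, w_a = 5, w_p = 10),
    polarity = BOUNDARY_POLARITY,
    depth_fractions = BOUNDARY_DEPTH_FRACTION,
    roi = list(rbc_min_offset = 20, margin = 2, tol_frac = 0.12, min_tol = 4),
    # offset 0.5: the gradient ridge of a step sits half a pixel above the
    # first pixel of the layer below, which is the position convention
    fit = list(method = "spline", offset = 0.5),
    max_dev_px = 5
  )
}

# per-column ROI (inclusive 0-based row bounds) for one boundary given the
# boundaries already found in this B-scan
compute_roi <- function(bname, found, d, w, cfg) {
  if (bname == "ILM-RNFL")
    return(list(min = rep(0, w), max = rep(d - 1, w)))
  ilm <- found["ILM-RNFL", ]
  if (bname == "RBC") {
    lo <- if (all(is.na(ilm))) rep(0, w) else ilm + cfg$roi$rbc_min_offset
    return(list(min = pmin(lo, d - 1), max = rep(d - 1, w)))
  }
  rbc <- found["RBC", ]
  if (all(is.na(ilm)) || all(is.na(rbc)))
    return(list(min = rep(0, w), max = rep(d - 1, w)))
  span <- rbc - ilm
  nom <- ilm + cfg$depth_fractions[[bname]] * span
  tol <- pmax(cfg$roi$min_tol, cfg$roi$tol_frac * span)
  lo <- nom - tol; hi <- nom + tol
  idx <- match(bname, BOUNDARY_ORDER)
  m <- cfg$roi$margin
  for (k in seq_len(12)) {
    if (k == idx || all(is.na(found[k, ]))) next
    if (k < idx) lo <- pmax(lo, found[k, ] + m)
    else hi <- pmin(hi, found[k, ] - m)
  }
  bad <- lo > hi
  if (any(bad)) { lo[bad] <- nom[bad] - 1; hi[bad] <- nom[bad] + 1 }
  list(min = pmax(0, lo), max = pmin(d - 1, hi))
}

# detect a single boundary in one B-scan; returns positions or NULL.
# Hysteresis thresholds are taken from the gradient magnitudes of the NMS
# ridge pixels inside this boundary's ROI: boundary contrast spans a factor
# of ~5 across the 12 interfaces, so whole-B-scan thresholds would delete
# the faint ones before their dedicated search even starts.
detect_boundary_bscan <- function(bname, cz, found, d, w, cfg) {
  pol <- cfg$polarity[[bname]]
  cand <- if (pol == "positive") cz$nms & cz$gy > 0 else cz$nms & cz$gy < 0
  roi <- compute_roi(bname, found, d, w, cfg)
  rows0 <- matrix(seq_len(d) - 1L, d, w)
  lo <- matrix(roi$min, d, w, byrow = TRUE)
  hi <- matrix(roi$max, d, w, byrow = TRUE)
  in_roi <- rows0 >= lo & rows0 <= hi
  cand <- cand & in_roi
  if (!any(cand)) return(NULL)
  # thresholds from the ROI pixels whose gradient sign matches the target
  # polarity: they track the local noise floor of the relevant contrast
  # direction, so a faint target interface is not suppressed by a strong
  # opposite-polarity neighbour sharing the ROI
  pool <- in_roi & (if (pol == "positive") cz$gy > 0 else cz$gy < 0)
  th <- pmax(stats::quantile(cz$mag[pool], c(cfg$canny$q_low, cfg$canny$q_high),
                             names = FALSE), 1e-9)
  cand <- hysteresis_grow(cand & cz$mag >= th[2], cand & cz$mag >= th[1])
  groups <- group_edge_pixels(cand, collapse_runs = TRUE)
  if (length(groups) == 0) return(NULL)
  mg <- vapply(groups, function(g) {
    mean(abs(cz$gy[cbind(g$rows + 1L, g$cols + 1L)]))
  }, numeric(1))
  nonassoc <- 1 - mg / max(mg)
  row_pref <- switch(bname, "ILM-RNFL" = "top", "RBC" = "bottom", "none")
  reference <- if (!bname %in% c("ILM-RNFL", "RBC") && !all(is.na(found["RBC", ])))
    found["RBC", ] else NULL
  graph <- build_boundary_graph(groups, roi, reference, width = w,
                                weights = cfg$weights, nonassoc = nonassoc,
                                row_pref = row_pref, depth_px = d)
  sp <- shortest_boundary_path(graph)
  if (length(sp$groups) == 0) return(NULL)
  # reduce each chain to its per-column ridge pixel, then refine to sub-pixel
  sp$groups <- lapply(sp$groups, function(g) {
    mg <- cz$mag[cbind(g$rows + 1L, g$cols + 1L)]
    keep <- unlist(lapply(split(seq_along(g$cols), g$cols),
                          function(ii) ii[which.max(mg[ii])]), use.names = FALSE)
    g$rows <- subpixel_rows(g$rows[keep], g$cols[keep], cz$mag)
    g$cols <- g$cols[keep]
    g
  })
  pos <- reconstruct_boundary(sp$groups, w, cfg$fit)
  pmin(pmax(pos, 0), d - 1)
}

#' Segment all 12 retinal boundaries of a volume
#'
#' Boundaries are detected per B-scan in `DETECTION_SEQUENCE`; each ROI is
#' derived from the already detected boundaries (the ILM-RNFL / RBC anchors
#' plus anatomical depth fractions).  A boundary that yields no edge evidence
#' in a B-scan is filled from the nearest B-scan where it was recovered, with
#' a warning.  The anatomical depth ordering is enforced on the result.
#'
#' @param volume an `oct_volume`.
#' @param config segmentation configuration, see [segmentation_config()].
#' @return An `oct_boundary_set`.
#' @export
segment_volume <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- depth_px(volume); w <- width_ascans(volume); nb <- n_bscans(volume)
  pos <- array(NA_real_, dim = c(12, w, nb),
               dimnames = list(BOUNDARY_ORDER, NULL, NULL))
  for (z in seq_len(nb)) {
    img <- volume$data[, , z]
    cz <- canny_bscan(img, config$canny$sigma, config$canny$q_low,
                      config$canny$q_high)
    found <- matrix(NA_real_, 12, w, dimnames = list(BOUNDARY_ORDER, NULL))
    for (bname in DETECTION_SEQUENCE) {
      p <- detect_boundary_bscan(bname, cz, found, d, w, config)
      if (!is.null(p)) found[bname, ] <- p
    }
    pos[, , z] <- found
  }
  # fill boundaries missing in a B-scan from the nearest segmented neighbour
  for (bname in BOUNDARY_ORDER) {
    missing_z <- which(vapply(seq_len(nb), function(z) any(is.na(pos[bname, , z])),
                              logical(1)))
    if (length(missing_z) == 0) next
    have_z <- setdiff(seq_len(nb), missing_z)
    if (length(have_z) == 0) {
      warning(sprintf("boundary %s unrecoverable in every B-scan", bname))
      next
    }
    for (z in missing_z) {
      zn <- have_z[which.min(abs(have_z - z))]
      pos[bname, , z] <- pos[bname, , zn]
      warning(sprintf("boundary %s missing in B-scan %d; copied from B-scan %d",
                      bname, z - 1L, zn - 1L))
    }
  }
  # enforce anatomical ordering
  for (z in seq_len(nb)) {
    for (i in 2:12) {
      pos[i, , z] <- pmax(pos[i, , z], pos[i - 1, , z], na.rm = TRUE)
    }
  }
  boundary_set(pos, volume$voxel_dims)
}

#' Cross-B-scan correction of a boundary set
#'
#' Retinal tissue is continuous between adjacent B-scans, so a boundary
#' position deviating more than `max_dev_px` from the median of the same
#' boundary over the adjacent B-scan window (the B-scan and its neighbours)
#' is replaced by that median.  The correction is computed from the input
#' set everywhere (no sequential drift) and is the identity on
#' already-consistent sets and on single B-scan volumes.
#'
#' @param bs an `oct_boundary_set`.
#' @param max_dev_px tolerated deviation in px.
#' @return Corrected `oct_boundary_set`.
#' @export
refine_across_bscans <- function(bs, max_dev_px = 5) {
  p <- bs$positions
  nb <- dim(p)[3]
  if (nb < 2) return(bs)
  out <- p
  for (z in seq_len(nb)) {
    zs <- intersect((z - 1L):(z + 1L), seq_len(nb))
    stack <- p[, , zs, drop = FALSE]
    med <- apply(stack, c(1, 2), stats::median)
    dev <- abs(p[, , z] - med) > max_dev_px
    slice <- out[, , z]
    slice[dev] <- med[dev]
    out[, , z] <- slice
  }
  boundary_set(out, bs$voxel_dims)
}
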