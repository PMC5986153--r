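# Canny edge detection on B-scans.  No preinstalled R package provides it,
# and the edge map is the substrate of the boundary graph, so it is
# implemented here: separable Gaussian smoothing, central-difference
# gradients, 4-sector non-maximum suppression and percentile-based
# hysteresis.

# shift a matrix by (dr, dc) with replicate padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicate borders
gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  if (length(k) == 1) return(m)
  r <- (length(k) - 1L) / 2L
  tmp <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) tmp <- tmp + k[i] * shift_mat(m, i - r - 1L, 0L)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(tmp, 0L, i - r - 1L)
  out
}

# Full Canny analysis of one B-scan; returns the edge map together with the
# axial gradient (needed downstream for polarity selection and group
# strength).  Thresholds are the `q_low`/`q_high` quantiles of the non-zero
# gradient magnitudes of this B-scan.
canny_bscan <- function(img, sigma = 1.5, q_low = 0.7, q_high = 0.9) {
  sm <- gaussian_blur(img, sigma)
  gy <- (shift_mat(sm, -1L, 0L) - shift_mat(sm, 1L, 0L)) / 2   # d/drow (axial)
  gx <- (shift_mat(sm, 0L, -1L) - shift_mat(sm, 0L, 1L)) / 2   # d/dcol
  mag <- sqrt(gx^2 + gy^2)

  # non-maximum suppression in 4 quantised gradient directions
  ang <- atan2(gy, gx) %% pi
  sector <- round(ang / (pi / 4)) %% 4   # 0: grad horiz, 2: grad vertical
  n1 <- matrix(0, nrow(img), ncol(img)); n2 <- n1
  pick <- function(s, dr, dc, n1v, n2v) {
    w <- sector == s
    n1v[w] <- shift_mat(mag, dr, dc)[w]
    n2v[w] <- shift_mat(mag, -dr, -dc)[w]
    list(n1v, n2v)
  }
  for (sp in list(list(0, 0L, 1L), list(1, 1L, 1L),
                  list(2, 1L, 0L), list(3, 1L, -1L))) {
    res <- pick(sp[[1]], sp[[2]], sp[[3]], n1, n2)
    n1 <- res[[1]]; n2 <- res[[2]]
  }
  keep <- mag > 0 & mag >= n1 & mag > n2

  if (!any(mag > 0))
    return(list(edges = keep & FALSE, nms = keep, gy = gy, mag = mag))
  # quantiles over the whole B-scan: on clean images most pixels have zero
  # gradient, so the thresholds drop and weak interfaces survive
  th <- pmax(stats::quantile(mag, c(q_low, q_high), names = FALSE), 1e-9)
  edges <- hysteresis_grow(keep & mag >= th[2], keep & mag >= th[1])
  list(edges = edges, nms = keep, gy = gy, mag = mag)
}

# grow strong edge pixels into weak ones (8-connected) until fixpoint
hysteresis_grow <- function(strong, weak) {
  cur <- strong
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_mat(cur, dr, dc)
    }
    grown <- grown & weak
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

# parabolic sub-pixel refinement of ridge rows along the axial direction;
# returns fractional row positions (0-based in, 0-based out)
subpixel_rows <- function(rows0, cols0, mag) {
  d <- nrow(mag)
  r1 <- rows0 + 1L; c1 <- cols0 + 1L
  up <- mag[cbind(pmax(r1 - 1L, 1L), c1)]
  mid <- mag[cbind(r1, c1)]
  dn <- mag[cbind(pmin(r1 + 1L, d), c1)]
  den <- up - 2 * mid + dn
  delta <- ifelse(den < -1e-12, 0.5 * (up - dn) / den, 0)
  delta[abs(delta) > 1] <- 0
  rows0 + delta
}

#' Detect candidate edge pixels of one polarity
#'
#' Runs Canny edge detection on a B-scan and keeps only the edge pixels whose
#' axial intensity gradient sign matches `polarity`: `"positive"` edges go
#' dark-to-bright with increasing depth, `"negative"` the reverse.
#'
#' @param bscan numeric matrix `[depth_px, width_ascans]`, intensities 0--255.
#' @param polarity `"positive"` or `"negative"`.
#' @param sigma Gaussian smoothing sigma of the Canny detector (px).
#' @param q_low,q_high hysteresis thresholds as quantiles of the per-B-scan
#'   gradient magnitudes.
#' @param canny optional precomputed result of the internal Canny analysis
#'   (used by [segment_volume()] to avoid recomputation).
#' @return Logical matrix marking the retained edge pixels.
#' @export
detect_candidate_edges <- function(bscan, polarity = c("positive", "negative"),
                                   sigma = 1.5, q_low = 0.7, q_high = 0.9,
                                   canny = NULL) {
  polarity <- match.arg(polarity)
  if (length(bscan) == 0) stop("bscan must be non-empty")
  if (is.null(canny)) canny <- canny_bscan(bscan, sigma, q_low, q_high)
  if (polarity == "positive") canny$edges & canny$gy > 0
  else canny$edges & canny$gy < 0
}
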