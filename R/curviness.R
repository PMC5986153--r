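# Boundary curviness score: the height profile of a boundary relative to the
# RBC anchor is reduced to (a) the summed deviations from its first-order
# polynomial fit that exceed alpha and (b) the number of delta-significant
# peaks surviving local-extrema pruning; the score is their product.

#' Curviness parameters
#'
#' @param alpha deviation threshold in px: positions whose absolute deviation
#'   from the fitted line exceeds `alpha` are counted as curvy (default 3).
#' @param delta peak significance in px: adjacent local maxima/minima closer
#'   than `delta` in value are pruned away (default 5).
#' @return A `curviness_params` list.
#' @export
curviness_params <- function(alpha = 3, delta = 5) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (delta <= 0) stop("delta must be > 0")
  structure(list(alpha = alpha, delta = delta), class = "curviness_params")
}

#' Alternating local extrema of a series
#'
#' A value is a local maximum if it is greater than at least one neighbour
#' and not less than any neighbour (mirrored for minima); plateaus collapse
#' to a single extremum at the plateau's first index, series endpoints are
#' eligible, and the output strictly alternates max/min.
#'
#' @param x numeric series (length >= 3).
#' @return data.frame with columns `index` (0-based), `value`, `kind`
#'   (`"max"`/`"min"`); empty for constant series.
#' @export
alternating_extrema <- function(x) {
  if (length(x) < 3) stop("series must have length >= 3")
  r <- rle(x)
  v <- r$values
  nruns <- length(v)
  first_idx <- cumsum(c(0L, r$lengths[-nruns]))  # 0-based first index of run
  if (nruns == 1) return(data.frame(index = integer(0), value = numeric(0),
                                    kind = character(0)))
  kind <- character(nruns)
  for (i in seq_len(nruns)) {
    lo <- if (i > 1) v[i - 1] else NULL
    hi <- if (i < nruns) v[i + 1] else NULL
    up <- c(lo, hi)
    if (all(v[i] >= up) && any(v[i] > up)) kind[i] <- "max"
    else if (all(v[i] <= up) && any(v[i] < up)) kind[i] <- "min"
  }
  keep <- kind != ""
  out <- data.frame(index = first_idx[keep], value = v[keep], kind = kind[keep],
                    stringsAsFactors = FALSE)
  # collapse consecutive same-kind extrema to the more extreme one
  if (nrow(out) > 1) {
    repeat {
      same <- which(out$kind[-1] == out$kind[-nrow(out)])
      if (length(same) == 0) break
      i <- same[1]
      drop <- if (out$kind[i] == "max") {
        if (out$value[i] >= out$value[i + 1]) i + 1 else i
      } else {
        if (out$value[i] <= out$value[i + 1]) i + 1 else i
      }
      out <- out[-drop, ]
    }
  }
  rownames(out) <- NULL
  out
}

#' Prune insignificant extrema
#'
#' While any adjacent max/min pair differs by less than `delta`, the adjacent
#' pair with the smallest absolute difference (leftmost on ties) is removed.
#' The result alternates and all adjacent differences are >= `delta`.
#'
#' @param lmm alternating extrema (data.frame from [alternating_extrema()]).
#' @param delta significance threshold.
#' @return Pruned extrema data.frame.
#' @export
prune_extrema <- function(lmm, delta) {
  while (nrow(lmm) >= 2) {
    diffs <- abs(diff(lmm$value))
    if (all(diffs >= delta)) break
    j <- which.min(diffs)
    lmm <- lmm[-c(j, j + 1L), ]
  }
  rownames(lmm) <- NULL
  lmm
}

#' Curviness of a boundary relative to the RBC anchor
#'
#' Computes `NL = b_rbc - b_given`, fits a first-order polynomial `PNL1` to
#' `NL`, sums the deviations `|NL - PNL1|` exceeding `alpha` (`C1`), counts
#' the local maxima surviving delta-pruning of the extrema of `NL` (`C2`),
#' and returns `C = C1 * C2`.
#'
#' @param b_rbc,b_given numeric vectors of per-A-scan boundary positions
#'   (equal length >= 3).
#' @param params a [curviness_params()] list.
#' @return Non-negative curviness score.
#' @export
curviness <- function(b_rbc, b_given, params = curviness_params()) {
  if (length(b_rbc) != length(b_given))
    stop("boundaries must have equal length")
  nl <- as.numeric(b_rbc) - as.numeric(b_given)
  idx <- seq_along(nl) - 1
  fit <- stats::lm.fit(cbind(1, idx), nl)
  df <- abs(nl - fit$fitted.values)
  c1 <- sum(df[df > params$alpha])
  lmm <- alternating_extrema(nl)
  lmm <- prune_extrema(lmm, params$delta)
  c2 <- sum(lmm$kind == "max")
  c1 * c2
}
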