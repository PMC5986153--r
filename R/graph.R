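# Boundary detection as a shortest-path problem: Canny edge pixels are
# chained into 8-connected pixel groups; group end pixels become graph nodes
# between a virtual source (column -1) and sink (column `width`); edge
# weights combine the Euclidean gap between end pixels, slope similarity to a
# reference line and the group's non-associativity with the target boundary.

# 8-neighbour degree of every TRUE pixel
pixel_degree <- function(mask) {
  deg <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    deg <- deg + shift_mat_zero(mask, dr, dc)
  }
  deg
}

# shift with zero padding (logical -> integer)
shift_mat_zero <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# connected components (8-connectivity) of a logical mask; returns a list of
# linear-index vectors
components_of <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  vid <- integer(length(mask)); vid[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dim(mask))
  r <- coords[, 1]; cc <- coords[, 2]
  epairs <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    rr <- r + off[1]; c2 <- cc + off[2]
    ok <- rr >= 1 & rr <= nr & c2 >= 1 & c2 <= nc
    lin <- (c2 - 1L) * nr + rr
    ok[ok] <- mask[lin[ok]]
    if (any(ok))
      epairs <- c(epairs, rbind(vid[idx[ok]], vid[lin[ok]]))
  }
  if (length(epairs) == 0) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::make_graph(epairs, n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  unname(split(idx, memb))
}

make_group <- function(rows0, cols0) {
  li <- order(cols0, rows0)[1]; ri <- order(-cols0, rows0)[1]
  list(rows = rows0, cols = cols0,
       left = c(row = rows0[li], col = cols0[li]),
       right = c(row = rows0[ri], col = cols0[ri]),
       size = length(rows0))
}

#' Group edge pixels into 8-connected chains
#'
#' In the default pixel mode, junction pixels (8-neighbour degree >= 3) are
#' split off so that branching chains separate into simple arms; junction
#' pixels themselves form their own group(s).  With `collapse_runs = TRUE`,
#' vertical runs of edge pixels are treated as single super-pixels (runs in
#' adjacent columns connect when their row intervals touch within one row),
#' which keeps steep boundary segments -- where non-maximum suppression
#' leaves 2-3 pixels per column -- in one chain; run-level junctions
#' (>= 3 neighbouring runs) are split off analogously.  Each group records
#' its member pixels (0-based rows/cols) and its two end pixels (leftmost
#' and rightmost members).
#'
#' @param edge_map logical matrix of edge pixels.
#' @param collapse_runs collapse vertical runs before chaining (used by the
#'   segmentation stage).
#' @return List of pixel groups, each a list with `rows`, `cols`, `left`,
#'   `right` and `size`.
#' @export
group_edge_pixels <- function(edge_map, collapse_runs = FALSE) {
  if (!any(edge_map)) return(list())
  if (!collapse_runs) {
    deg <- pixel_degree(edge_map)
    junction <- edge_map & deg >= 3L
    comps <- c(components_of(edge_map & !junction), components_of(junction))
    return(lapply(comps, function(lin) {
      coords <- arrayInd(lin, dim(edge_map))
      make_group(coords[, 1] - 1L, coords[, 2] - 1L)
    }))
  }
  # enumerate vertical runs
  runs <- list()
  for (j in seq_len(ncol(edge_map))) {
    col <- edge_map[, j]
    if (!any(col)) next
    r <- rle(col)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      runs[[length(runs) + 1]] <- c(col = j, rmin = starts[k], rmax = ends[k])
  }
  nr <- length(runs)
  rcol <- vapply(runs, `[[`, 0, "col")
  rmin <- vapply(runs, `[[`, 0, "rmin")
  rmax <- vapply(runs, `[[`, 0, "rmax")
  # adjacency between runs in neighbouring columns (8-connectivity)
  epairs <- integer(0); deg <- integer(nr)
  ord <- order(rcol)
  for (a in seq_len(nr)) {
    nb <- which(rcol == rcol[a] + 1L & rmin <= rmax[a] + 1L & rmax >= rmin[a] - 1L)
    if (length(nb)) {
      epairs <- c(epairs, rbind(a, nb))
      deg[a] <- deg[a] + length(nb); deg[nb] <- deg[nb] + 1L
    }
  }
  junction <- deg >= 3L
  comp_groups <- function(sel) {
    if (!any(sel)) return(list())
    ids <- which(sel)
    remap <- integer(nr); remap[ids] <- seq_along(ids)
    if (length(epairs)) {
      em <- matrix(epairs, nrow = 2)
      kp <- sel[em[1, ]] & sel[em[2, ]]
      em <- em[, kp, drop = FALSE]
      g <- igraph::make_graph(as.vector(remap[em]), n = length(ids),
                              directed = FALSE)
      memb <- igraph::components(g)$membership
    } else memb <- seq_along(ids)
    lapply(split(ids, memb), function(rs) {
      rows0 <- unlist(lapply(rs, function(a) seq.int(rmin[a], rmax[a]))) - 1L
      cols0 <- rep.int(rcol[rs], rmax[rs] - rmin[rs] + 1L) - 1L
      make_group(rows0, cols0)
    })
  }
  unname(c(comp_groups(!junction), comp_groups(junction)))
}

#' Build the weighted boundary graph over pixel groups
#'
#' Nodes are the pixel groups plus a virtual source at column -1 and sink at
#' column `width`.  A directed edge runs from group A to group B whenever B
#' starts strictly right of A's right end; its weight is
#' `w_d * |gap|  +  w_s * |slope(gap) - slope(reference)|  +  w_a *
#' nonassoc(B)  +  w_p * rowpref(B)`.
#' Traversal within a group is free.  Terminal edges carry only the
#' horizontal distance (plus the target group's node terms); a direct
#' source-to-sink fallback edge of weight `w_d * (width + 1)` encodes "no
#' evidence".
#'
#' @param groups list of pixel groups from [group_edge_pixels()].
#' @param roi list with numeric vectors `min` and `max` (inclusive 0-based row
#'   bounds per column); groups with less than half of their pixels inside
#'   the ROI are excluded.
#' @param reference numeric vector of per-column reference positions (an
#'   already detected boundary), or `NULL` for a horizontal reference.
#' @param width number of A-scans.
#' @param weights list with `w_d`, `w_s`, `w_a`, `w_p`.
#' @param nonassoc numeric vector in `[0,1]`, one non-associativity score per
#'   group (0 = fully associated with the target boundary); default all 0.
#' @param row_pref `"none"`, `"top"` or `"bottom"`: depth preference used for
#'   the outermost anchor boundaries.
#' @param depth_px axial image size, needed for the depth preference.
#' @return A `boundary_graph` object.
#' @export
build_boundary_graph <- function(groups, roi, reference = NULL, width,
                                 weights = list(w_d = 1, w_s = 2, w_a = 5, w_p = 5),
                                 nonassoc = NULL, row_pref = "none",
                                 depth_px = NULL) {
  if (length(groups)) {
    frac_in <- vapply(groups, function(g) {
      mean(g$rows >= roi$min[g$cols + 1L] & g$rows <= roi$max[g$cols + 1L])
    }, numeric(1))
    keep <- frac_in >= 0.5
    groups <- groups[keep]
    if (!is.null(nonassoc)) nonassoc <- nonassoc[keep]
  }
  n <- length(groups)
  if (is.null(nonassoc)) nonassoc <- rep(0, max(n, 0))
  rp <- rep(0, max(n, 0))
  if (row_pref != "none" && n > 0) {
    if (is.null(depth_px)) stop("depth_px required for row preference")
    mr <- vapply(groups, function(g) mean(g$rows), numeric(1)) / depth_px
    rp <- if (row_pref == "top") mr else 1 - mr
  }
  # node terms are scaled by the group's column coverage so that a boundary
  # fragmented into many short chains pays the same total penalty as the
  # equivalent single full-width chain
  cover <- if (n > 0) vapply(groups, function(g)
    length(unique(g$cols)), numeric(1)) / width else numeric(0)
  node_term <- if (n > 0)
    (weights$w_a * nonassoc + weights$w_p * rp) * cover else numeric(0)

  ref_slope <- function(c1, c2) {
    if (is.null(reference)) return(0)
    (reference[c2 + 1L] - reference[c1 + 1L]) / (c2 - c1)
  }

  from <- integer(0); to <- integer(0); w <- numeric(0)
  if (n > 0) {
    for (i in seq_len(n)) {
      # source -> i and i -> sink
      from <- c(from, 0L); to <- c(to, i)
      w <- c(w, weights$w_d * (groups[[i]]$left[["col"]] + 1) + node_term[i])
      from <- c(from, i); to <- c(to, n + 1L)
      w <- c(w, weights$w_d * (width - groups[[i]]$right[["col"]]))
    }
    for (i in seq_len(n)) {
      a <- groups[[i]]
      for (j in seq_len(n)) {
        if (i == j) next
        b <- groups[[j]]
        dc <- b$left[["col"]] - a$right[["col"]]
        if (dc <= 0) next
        dr <- b$left[["row"]] - a$right[["row"]]
        gap <- sqrt(dc^2 + dr^2)
        slope <- dr / dc
        sl <- abs(slope - ref_slope(a$right[["col"]], b$left[["col"]]))
        from <- c(from, i); to <- c(to, j)
        w <- c(w, weights$w_d * gap + weights$w_s * sl + node_term[j])
      }
    }
  }
  # fallback: skip everything
  from <- c(from, 0L); to <- c(to, n + 1L)
  w <- c(w, weights$w_d * (width + 1))

  structure(list(groups = groups, edges = data.frame(from = from, to = to, w = w),
                 n = n, width = width, weights = weights,
                 nonassoc = nonassoc, reference = reference),
            class = "boundary_graph")
}

# TRUE if integer vector a is lexicographically smaller than b
lex_smaller <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) {
    d <- a[seq_len(k)] - b[seq_len(k)]
    nz <- which(d != 0)
    if (length(nz)) return(d[nz[1]] < 0)
  }
  length(a) < length(b)
}

#' Minimum-weight source-to-sink path through a boundary graph
#'
#' Dynamic programming over the left-to-right DAG; among equal-weight paths
#' the lexicographically smallest node sequence wins, so runs are
#' deterministic.
#'
#' @param graph a `boundary_graph`.
#' @return List with `groups` (the pixel groups on the optimal path, left to
#'   right; empty if the fallback skip edge wins), `node_ids` and `weight`.
#' @export
shortest_boundary_path <- function(graph) {
  n <- graph$n
  sink <- n + 1L
  # topological order: source, groups by left column, sink
  ord <- c(0L, if (n > 0) order(vapply(graph$groups, function(g) g$left[["col"]],
                                       numeric(1))) else integer(0), sink)
  edges <- graph$edges
  out <- split(seq_len(nrow(edges)), edges$from)
  dist <- rep(Inf, n + 2L); names(dist) <- as.character(0:(n + 1L))
  dist["0"] <- 0
  paths <- vector("list", n + 2L)
  paths[[1]] <- 0L
  eps <- 1e-9
  for (u in ord) {
    du <- dist[as.character(u)]
    if (!is.finite(du)) next
    ei <- out[[as.character(u)]]
    for (k in ei) {
      v <- edges$to[k]
      nd <- du + edges$w[k]
      cand <- c(paths[[u + 1L]], v)
      if (nd < dist[as.character(v)] - eps) {
        dist[as.character(v)] <- nd
        paths[[v + 1L]] <- cand
      } else if (nd <= dist[as.character(v)] + eps &&
                 lex_smaller(cand, paths[[v + 1L]])) {
        paths[[v + 1L]] <- cand
      }
    }
  }
  if (!is.finite(dist[as.character(sink)])) {
    covered <- sort(unique(unlist(lapply(graph$groups, function(g) g$cols))))
    gaps <- setdiff(seq_len(graph$width) - 1L, covered)
    stop(sprintf("boundary graph disconnected; uncovered columns: %s",
                 paste(utils::head(gaps, 10), collapse = ", ")))
  }
  ids <- setdiff(paths[[sink + 1L]], c(0L, sink))
  list(groups = graph$groups[ids], node_ids = ids,
       weight = unname(dist[as.character(sink)]))
}

#' Reconstruct a boundary trace from the pixel groups of a shortest path
#'
#' Per-column positions are the mean member-pixel row where the path has
#' evidence; gaps are filled by linear interpolation and the result is
#' smoothed with a cubic smoothing spline (smoothing chosen by generalised
#' cross-validation).
#'
#' @param path_groups list of pixel groups (ordered left to right).
#' @param width number of A-scans; output length.
#' @param fit list with `method` (`"spline"` or `"interp"`) and `offset`
#'   (additive sub-pixel calibration, px).
#' @return Numeric vector of per-A-scan axial positions (fractional).
#' @export
reconstruct_boundary <- function(path_groups, width,
                                 fit = list(method = "spline", offset = 0)) {
  if (length(path_groups) == 0) stop("path must be non-empty")
  sums <- numeric(width); cnt <- numeric(width)
  for (g in path_groups) {
    for (k in seq_along(g$cols)) {
      j <- g$cols[k] + 1L
      sums[j] <- sums[j] + g$rows[k]
      cnt[j] <- cnt[j] + 1
    }
  }
  has <- cnt > 0
  if (!any(has)) stop("path groups contain no pixels")
  x <- which(has) - 1L
  y <- sums[has] / cnt[has]
  xout <- seq_len(width) - 1L
  if (length(x) == 1) {
    pos <- rep(y, width)
  } else {
    pos <- stats::approx(x, y, xout = xout, rule = 2)$y
    method <- fit$method %||% "spline"
    if (method == "spline" && length(unique(x)) >= 4 && stats::var(y) > 0) {
      sm <- tryCatch(stats::smooth.spline(x, y), error = function(e) NULL)
      if (!is.null(sm)) pos <- stats::predict(sm, xout)$y
    }
  }
  pos + (fit$offset %||% 0)
}
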