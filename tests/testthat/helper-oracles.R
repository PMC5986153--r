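# Independent oracles: deliberately simple, brute-force implementations that
# share no code with the package internals they check.

# ---- curviness: straight-line implementation of the boundary-curviness
# algorithm (explicit least-squares formulas, neighbourhood scans, literal
# pruning loop) ----------------------------------------------------------

oracle_curviness <- function(b_rbc, b_given, alpha = 3, delta = 5) {
  nl <- b_rbc - b_given
  n <- length(nl)
  x <- seq_len(n) - 1
  # explicit first-order least squares
  sx <- sum(x); sy <- sum(nl); sxx <- sum(x^2); sxy <- sum(x * nl)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  inter <- (sy - slope * sx) / n
  df <- abs(nl - (inter + slope * x))
  c1 <- sum(df[df > alpha])

  lmm <- oracle_extrema(nl)
  repeat {
    if (nrow(lmm) < 2) break
    d <- abs(diff(lmm$value))
    if (all(d >= delta)) break
    j <- which(d == min(d))[1]          # leftmost smallest
    lmm <- lmm[-c(j, j + 1), , drop = FALSE]
  }
  c2 <- sum(lmm$kind == "max")
  c1 * c2
}

# local extrema by literal definition on the run-compressed series, endpoints
# eligible, plateau -> first index, then collapse same-kind neighbours
oracle_extrema <- function(nl) {
  n <- length(nl)
  # compress plateaus
  keep <- c(TRUE, nl[-1] != nl[-n])
  v <- nl[keep]; first_idx <- (which(keep) - 1)
  m <- length(v)
  out <- data.frame(index = numeric(0), value = numeric(0),
                    kind = character(0), stringsAsFactors = FALSE)
  if (m < 2) return(out)
  for (i in seq_len(m)) {
    nb <- c(if (i > 1) v[i - 1], if (i < m) v[i + 1])
    if (all(v[i] >= nb) && any(v[i] > nb))
      out <- rbind(out, data.frame(index = first_idx[i], value = v[i],
                                   kind = "max", stringsAsFactors = FALSE))
    else if (all(v[i] <= nb) && any(v[i] < nb))
      out <- rbind(out, data.frame(index = first_idx[i], value = v[i],
                                   kind = "min", stringsAsFactors = FALSE))
  }
  # collapse consecutive same-kind extrema (keep the more extreme, leftmost
  # on ties)
  i <- 1
  while (i < nrow(out)) {
    if (out$kind[i] == out$kind[i + 1]) {
      better <- if (out$kind[i] == "max") {
        if (out$value[i] >= out$value[i + 1]) i else i + 1
      } else {
        if (out$value[i] <= out$value[i + 1]) i else i + 1
      }
      out <- out[-setdiff(c(i, i + 1), better), , drop = FALSE]
      i <- max(1, i - 1)
    } else i <- i + 1
  }
  rownames(out) <- NULL
  out
}

# ---- shortest path: exhaustive enumeration over all simple source-to-sink
# paths of a boundary_graph ----------------------------------------------

oracle_shortest_path <- function(graph) {
  edges <- graph$edges
  sink <- graph$n + 1L
  best <- list(weight = Inf, path = NULL)
  recurse <- function(node, weight, path) {
    if (node == sink) {
      if (weight < best$weight - 1e-9 ||
          (abs(weight - best$weight) <= 1e-9 && lex_less(path, best$path))) {
        best$weight <<- weight; best$path <<- path
      }
      return()
    }
    out <- which(edges$from == node)
    for (k in out) {
      v <- edges$to[k]
      if (v %in% path) next
      recurse(v, weight + edges$w[k], c(path, v))
    }
  }
  recurse(0L, 0, 0L)
  best
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# random boundary-graph-shaped DAG with <= nmax group nodes
random_boundary_graph <- function(nmax = 12) {
  n <- sample.int(nmax, 1)
  groups <- lapply(seq_len(n), function(i) {
    c1 <- sample.int(40, 1) - 1L; c2 <- min(39L, c1 + sample.int(5, 1) - 1L)
    list(rows = c(0L, 0L), cols = c(c1, c2),
         left = c(row = sample.int(30, 1) - 1L, col = c1),
         right = c(row = sample.int(30, 1) - 1L, col = c2), size = 2L)
  })
  g <- build_boundary_graph(groups, roi = list(min = rep(0, 40), max = rep(40, 40)),
                            reference = NULL, width = 40,
                            nonassoc = runif(n), row_pref = "none")
  # perturb weights to exercise generic graphs
  g$edges$w <- g$edges$w + round(runif(nrow(g$edges), 0, 5), 2)
  g
}

# ---- rasterisation oracles ---------------------------------------------

# brute-force pixel membership of a semicircular/semielliptic bump
# detachment: pixel (r, c), 0-based, is drusen iff baseline - e(c) <= r <
# baseline with e(c) = h * sqrt(1 - ((c - centre)/radius)^2)
oracle_bump_count <- function(depth, width, baseline, center, radius, height) {
  cnt <- 0L
  for (cc in 0:(width - 1)) {
    u <- (cc - center) / radius
    if (abs(u) >= 1) next
    e <- height * sqrt(1 - u^2)
    for (r in 0:(depth - 1)) {
      if (r >= baseline - e && r < baseline) cnt <- cnt + 1L
    }
  }
  cnt
}

# ---- pixel chain oracle -------------------------------------------------

# exhaustive adjacency analysis: junction pixels are edge pixels with >= 3
# 8-neighbours; chains are the connected components of the non-junction
# pixels plus the components of the junction pixels
oracle_chain_count <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  adj <- function(i, j) max(abs(pts[i, ] - pts[j, ])) == 1
  deg <- vapply(seq_len(n), function(i)
    sum(vapply(seq_len(n), function(j) j != i && adj(i, j), logical(1))),
    numeric(1))
  junc <- deg >= 3
  comps_in <- function(sel) {
    ids <- which(sel)
    if (length(ids) == 0) return(0L)
    lab <- seq_along(ids)
    repeat {
      changed <- FALSE
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        if (a != b && adj(ids[a], ids[b]) && lab[b] > lab[a]) {
          lab[b] <- lab[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    length(unique(lab))
  }
  comps_in(!junc) + comps_in(junc)
}

# ---- smoothing oracle ---------------------------------------------------

# direct 2D Gaussian convolution with border renormalisation
oracle_gauss2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nrow(m) || jj < 1 || jj > ncol(m)) next
      wt <- k[di + r + 1] * k[dj + r + 1]
      num <- num + wt * m[ii, jj]; den <- den + wt
    }
    out[i, j] <- num / den
  }
  out
}

# ---- shared fixtures ----------------------------------------------------

tiny_phantom_spec <- function(...) {
  phantom_spec(n_bscans = 3, ...)
}

# a small, well-separated feature cohort for classifier tests
toy_cohort <- function(n = 15, seed = 99) {
  octretina:::with_seed(seed, {
    X <- rbind(
      cbind(rnorm(n, 0, .0001), rnorm(n, 0, .0001), abs(rnorm(n, 1, 1)),
            abs(rnorm(n, 1, 1)), rnorm(n, 545, 8), rnorm(n, 552, 8),
            rnorm(n, 117, 4), rnorm(n, 119, 4), rnorm(n, 39, 1.5), rnorm(n, 39, 1.5)),
      cbind(rnorm(n, 0, .0001), rnorm(n, .0065, .001), rnorm(n, 100, 25),
            rnorm(n, 480, 90), rnorm(n, 538, 8), rnorm(n, 545, 8),
            rnorm(n, 115, 4), rnorm(n, 117, 4), rnorm(n, 39, 1.5), rnorm(n, 39, 1.5)),
      cbind(rnorm(n, .0008, .0002), rnorm(n, 0, .0001), abs(rnorm(n, 5, 3)),
            rnorm(n, 1590, 200), rnorm(n, 590, 8), rnorm(n, 597, 8),
            rnorm(n, 115, 4), rnorm(n, 117, 4), rnorm(n, 39, 1.5), rnorm(n, 39, 1.5)))
    colnames(X) <- octretina:::FEATURE_NAMES
    labeled_cohort(X, rep(c("normal", "AMD", "DME"), each = n))
  })
}
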