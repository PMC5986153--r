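# Phantom SD-OCT volumes with fully known layer geometry and injected
# pathology.  The generator is the ground-truth oracle for every downstream
# stage: segmentation accuracy, pathology volume recovery and the end-to-end
# classification benchmark.

# fraction of the drusen elevation carried by each deformed surface: the RPE
# (and its lower edge RBC) rides the full bump, surfaces further up are
# displaced progressively less, so the ELM-to-RBC span thickens over drusen
DRUSEN_DAMPING <- c(
  "ONL-ELM" = 0.5, "ELM-MZ" = 0.6, "MZ-EZ" = 0.7,
  "EZ-OSL" = 0.8, "IZ-RPE" = 1.0, "RBC" = 1.0
)

default_layer_profile <- function() {
  data.frame(
    boundary = BOUNDARY_ORDER,
    depth = c(60, 75, 90, 105, 120, 135, 155, 162, 170, 180, 190, 200),
    # mean intensity of the layer immediately below each interface; the last
    # entry is the choroid below RBC.  Contrasts are graded so that each
    # interface is the strongest edge of its polarity inside its search ROI
    # (RBC in particular must beat EZ-OSL), and the choroid matches the
    # drusen-interior reflectivity so no spurious Bruch's-membrane edge
    # competes with the elevated RPE bottom over a bump.
    intensity = c(150, 100, 75, 40, 90, 40, 15, 70, 175, 65, 200, 65),
    stringsAsFactors = FALSE
  )
}

#' Specify a phantom SD-OCT volume
#'
#' A phantom is a stack of piecewise-constant B-scans: each retinal layer is a
#' horizontal band of constant mean intensity, optionally deformed by drusen
#' bumps (semi-elliptic sub-RPE elevations with a hypo-reflective interior),
#' decorated with hyper-reflective intra-retinal spots (bright discs in the
#' INL--ONL band), perturbed by sinusoidal boundary waves, and degraded with
#' additive Gaussian noise clipped to `[0, 255]`.
#'
#' @param width_ascans number of A-scans (columns) per B-scan.
#' @param depth_px axial size (rows) of each B-scan.
#' @param n_bscans number of B-scans in the stack.
#' @param voxel_dims numeric (axial um/px, lateral um/px, B-scan spacing um).
#' @param layer_profile data.frame with columns `boundary` (the 12 names in
#'   `BOUNDARY_ORDER`), `depth` (baseline axial position, px, strictly
#'   increasing) and `intensity` (mean intensity of the layer below the
#'   interface; the last row gives the choroid).
#' @param vitreous_intensity mean intensity above the ILM.
#' @param drusen_bumps list of bumps, each a list with `bscans` (0-based
#'   indices), `center` (A-scan), `radius` (px), `height` (px) and
#'   `intensity` (interior intensity of the detachment).
#' @param his_spots list of spots, each a list with `bscan`, `row`, `col`,
#'   `radius` (px) and `intensity`.
#' @param boundary_waves list of sinusoidal perturbations, each a list with
#'   `boundary`, `amplitude` (px), `period` (A-scans) and `phase` (radians).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed controlling the noise realisation.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(width_ascans = 128, depth_px = 256, n_bscans = 9,
                         voxel_dims = c(3.9, 11.6, 120),
                         layer_profile = default_layer_profile(),
                         vitreous_intensity = 20,
                         drusen_bumps = list(), his_spots = list(),
                         boundary_waves = list(),
                         noise_sd = 0, seed = 1L) {
  spec <- structure(list(
    width_ascans = as.integer(width_ascans), depth_px = as.integer(depth_px),
    n_bscans = as.integer(n_bscans), voxel_dims = as.numeric(voxel_dims),
    layer_profile = layer_profile, vitreous_intensity = vitreous_intensity,
    drusen_bumps = drusen_bumps, his_spots = his_spots,
    boundary_waves = boundary_waves, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  lp <- spec$layer_profile
  if (!identical(lp$boundary, BOUNDARY_ORDER))
    stop("layer_profile must list the 12 boundaries in anatomical order")
  if (any(diff(lp$depth) <= 0))
    stop("layer_profile depths must be strictly increasing in anatomical order")
  if (lp$depth[1] < 1 || lp$depth[12] >= spec$depth_px)
    stop("layer_profile depths must lie inside [1, depth_px)")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  for (k in seq_along(spec$drusen_bumps)) {
    b <- spec$drusen_bumps[[k]]
    if (b$height < 0)
      stop(sprintf("drusen bump %d: height must be >= 0", k))
    if (b$center - b$radius < 0 || b$center + b$radius >= spec$width_ascans)
      stop(sprintf("drusen bump %d: lateral extent outside image bounds", k))
    if (any(b$bscans < 0) || any(b$bscans >= spec$n_bscans))
      stop(sprintf("drusen bump %d: B-scan range outside volume", k))
  }
  for (k in seq_along(spec$his_spots)) {
    s <- spec$his_spots[[k]]
    if (s$bscan < 0 || s$bscan >= spec$n_bscans)
      stop(sprintf("HIS spot %d: B-scan index outside volume", k))
    if (s$row - s$radius < 0 || s$row + s$radius >= spec$depth_px ||
        s$col - s$radius < 0 || s$col + s$radius >= spec$width_ascans)
      stop(sprintf("HIS spot %d: disc outside image bounds", k))
  }
  for (k in seq_along(spec$boundary_waves)) {
    w <- spec$boundary_waves[[k]]
    if (!w$boundary %in% BOUNDARY_ORDER)
      stop(sprintf("boundary wave %d: unknown boundary '%s'", k, w$boundary))
    if (w$period <= 0) stop(sprintf("boundary wave %d: period must be > 0", k))
  }
  invisible(spec)
}

# semi-elliptic elevation profile of a bump at 0-based columns `cols`
bump_elevation <- function(bump, cols) {
  u <- (cols - bump$center) / bump$radius
  e <- numeric(length(cols))
  inside <- abs(u) < 1
  e[inside] <- bump$height * sqrt(1 - u[inside]^2)
  e
}

# Generative boundary surfaces of a phantom.  Returns the deformed positions
# (12 x width x n_bscans) and the flat RBC baseline (Bruch's membrane proxy).
phantom_surfaces <- function(spec) {
  w <- spec$width_ascans; nb <- spec$n_bscans
  lp <- spec$layer_profile
  cols <- seq_len(w) - 1L
  base <- matrix(rep(lp$depth, w), nrow = 12)
  pos <- array(0, dim = c(12, w, nb), dimnames = list(BOUNDARY_ORDER, NULL, NULL))
  baseline_rbc <- matrix(rep(lp$depth[12], w), nrow = w, ncol = nb)
  for (z in seq_len(nb)) {
    p <- base
    for (wv in spec$boundary_waves) {
      if (!is.null(wv$bscans) && !((z - 1L) %in% wv$bscans)) next
      i <- match(wv$boundary, BOUNDARY_ORDER)
      p[i, ] <- p[i, ] + wv$amplitude *
        sin(2 * pi * cols / wv$period + (wv$phase %||% 0))
    }
    for (b in spec$drusen_bumps) {
      if (!((z - 1L) %in% b$bscans)) next
      e <- bump_elevation(b, cols)
      for (nm in names(DRUSEN_DAMPING)) {
        i <- match(nm, BOUNDARY_ORDER)
        p[i, ] <- p[i, ] - DRUSEN_DAMPING[[nm]] * e
      }
    }
    if (any(apply(p, 2, function(v) any(diff(v) < 0.5))))
      stop("phantom geometry degenerate: deformed boundaries cross (check bump heights / wave amplitudes)")
    pos[, , z] <- p
  }
  list(positions = pos, baseline_rbc = baseline_rbc)
}

#' Generate a phantom volume with ground truth
#'
#' Rasterises the generative layer surfaces of `spec` into an 8-bit volume and
#' returns it together with the exact ground truth: boundary surfaces, drusen
#' and HIS masks, the flat RBC baseline, and the analytic feature vector.
#'
#' @param spec a `phantom_spec`.
#' @param label optional class label recorded in the ground truth
#'   (`"normal"`, `"AMD"` or `"DME"`).
#' @return List with elements `volume` (an `oct_volume`) and `truth` (an
#'   `oct_ground_truth` with fields `boundaries`, `drusen_mask`, `his_mask`,
#'   `baseline_rbc`, `true_features`, `label`, `spec`).
#' @export
generate_phantom <- function(spec, label = NA_character_) {
  validate_phantom_spec(spec)
  w <- spec$width_ascans; d <- spec$depth_px; nb <- spec$n_bscans
  surf <- phantom_surfaces(spec)
  pos <- surf$positions
  intens <- c(spec$vitreous_intensity, spec$layer_profile$intensity)
  rows0 <- seq_len(d) - 1L

  vol <- array(0, dim = c(d, w, nb))
  dmask <- array(FALSE, dim = c(d, w, nb))
  hmask <- array(FALSE, dim = c(d, w, nb))

  for (z in seq_len(nb)) {
    p <- pos[, , z]
    img <- vapply(seq_len(w), function(j) {
      intens[findInterval(rows0, p[, j]) + 1L]
    }, numeric(d))
    # drusen interior: rows between the elevated RBC and the flat baseline
    for (b in spec$drusen_bumps) {
      if (!((z - 1L) %in% b$bscans)) next
      cols <- seq_len(w) - 1L
      e <- bump_elevation(b, cols)
      for (j in which(e > 0)) {
        rbc_el <- p["RBC", j]
        b0 <- surf$baseline_rbc[j, z]
        rr <- rows0 >= rbc_el & rows0 < b0
        img[rr, j] <- b$intensity
        dmask[rr, j, z] <- TRUE
      }
    }
    for (s in spec$his_spots) {
      if (s$bscan != z - 1L) next
      for (j in seq.int(s$col - s$radius, s$col + s$radius)) {
        dy <- sqrt(s$radius^2 - (j - s$col)^2)
        rr <- rows0 >= s$row - dy & rows0 <= s$row + dy
        if (any(dmask[rr, j + 1L, z]))
          stop(sprintf("HIS spot at (%d,%d,%d) overlaps a drusen region",
                       s$bscan, s$row, s$col))
        img[rr, j + 1L] <- s$intensity
        hmask[rr, j + 1L, z] <- TRUE
      }
    }
    vol[, , z] <- img
  }

  if (spec$noise_sd > 0) {
    vol <- with_seed(spec$seed, {
      vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim = dim(vol))
    })
    vol[vol < 0] <- 0; vol[vol > 255] <- 255
  }

  volume <- oct_volume(vol, spec$voxel_dims)
  bs <- boundary_set(pos, spec$voxel_dims)
  truth <- structure(list(
    boundaries = bs,
    drusen_mask = oct_mask(dmask, "drusen", spec$voxel_dims),
    his_mask = oct_mask(hmask, "HIS", spec$voxel_dims),
    baseline_rbc = surf$baseline_rbc,
    true_features = NULL,
    label = label,
    spec = spec
  ), class = "oct_ground_truth")
  truth$true_features <- true_features(volume, truth)
  list(volume = volume, truth = truth)
}

# Analytic feature vector of a phantom: pathology volumes from the exact
# masks, curviness from the generative surfaces, thickness statistics from
# the raw (unsmoothed) generative bands.
true_features <- function(volume, truth) {
  bs <- truth$boundaries
  nb <- dim(bs$positions)[3]
  ax <- volume$voxel_dims[1]
  cv <- function(given) {
    mean(vapply(seq_len(nb) - 1L, function(z) {
      curviness(boundary_positions(bs, "RBC", z),
                boundary_positions(bs, given, z))
    }, numeric(1)))
  }
  tstats <- function(upper, lower) {
    t_um <- (bs$positions[lower, , ] - bs$positions[upper, , ]) * ax
    c(mean = mean(t_um), p70 = as.numeric(stats::quantile(t_um, 0.7, type = 7)))
  }
  r <- tstats("ILM-RNFL", "RBC"); cx <- tstats("MZ-EZ", "RBC")
  rp <- tstats("IZ-RPE", "RBC")
  feature_vector(
    his_volume_mm3 = mask_volume(truth$his_mask),
    drusen_volume_mm3 = mask_volume(truth$drusen_mask),
    curviness_mzez = cv("MZ-EZ"),
    curviness_oplonl = cv("OPL-ONL"),
    retina_mean_um = r[["mean"]], retina_p70_um = r[["p70"]],
    complex_mean_um = cx[["mean"]], complex_p70_um = cx[["p70"]],
    rpe_mean_um = rp[["mean"]], rpe_p70_um = rp[["p70"]]
  )
}

# ---- cohort generation ------------------------------------------------------

#' Default class archetypes for phantom cohorts
#'
#' Archetypes mirror the clinical phenotypes: AMD volumes carry drusen bumps
#' (which also make the MZ-EZ boundary curvy), DME volumes carry
#' hyper-reflective spots, a wavy OPL-ONL boundary and a thickened outer
#' retina, normal volumes carry neither.  Each entry holds the template
#' `phantom_spec` (the zero-jitter archetype) and a `sample` function drawing
#' a jittered spec.
#'
#' @param noise_sd noise level shared by all classes.
#' @return Named list of class templates for [phantom_cohort()].
#' @export
default_class_params <- function(noise_sd = 8) {
  jit <- function(mid, half, js) stats::runif(1, mid - half * js, mid + half * js)
  jit_int <- function(mid, half, js) as.integer(round(jit(mid, half, js)))

  jitter_common <- function(spec, js) {
    lp <- spec$layer_profile
    shift <- jit_int(0, 3, js)
    lp$depth <- lp$depth + shift
    lp$intensity <- pmin(255, pmax(0, lp$intensity +
      vapply(seq_len(12), function(i) jit(0, 5, js), numeric(1))))
    spec$layer_profile <- lp
    spec$vitreous_intensity <- pmax(0, spec$vitreous_intensity + jit(0, 4, js))
    spec
  }

  normal_base <- phantom_spec(noise_sd = noise_sd)

  amd_bumps <- list(
    list(bscans = 2:6, center = 45, radius = 14, height = 16, intensity = 65),
    list(bscans = 3:5, center = 95, radius = 11, height = 13, intensity = 65)
  )
  amd_base <- phantom_spec(noise_sd = noise_sd, drusen_bumps = amd_bumps)

  dme_outer_shift <- 11
  dme_profile <- default_layer_profile()
  dme_profile$depth[7:12] <- dme_profile$depth[7:12] + dme_outer_shift
  dme_base <- phantom_spec(
    noise_sd = noise_sd, layer_profile = dme_profile,
    boundary_waves = list(list(boundary = "OPL-ONL", amplitude = 6,
                               period = 32, phase = 0)),
    his_spots = list(
      list(bscan = 2, row = 125, col = 40, radius = 3, intensity = 205),
      list(bscan = 4, row = 132, col = 75, radius = 2, intensity = 205),
      list(bscan = 5, row = 120, col = 100, radius = 3, intensity = 205),
      list(bscan = 6, row = 140, col = 58, radius = 2, intensity = 205),
      list(bscan = 7, row = 128, col = 20, radius = 3, intensity = 205)
    )
  )

  list(
    normal = list(
      template = normal_base,
      sample = function(js) jitter_common(normal_base, js)
    ),
    AMD = list(
      template = amd_base,
      sample = function(js) {
        spec <- jitter_common(amd_base, js)
        choroid <- spec$layer_profile$intensity[12]
        spec$drusen_bumps <- lapply(amd_bumps, function(b) {
          b$center <- jit_int(b$center, 10, js)
          b$radius <- jit_int(b$radius, 3, js)
          b$height <- jit_int(b$height, 3, js)
          b$intensity <- choroid   # drusen interior tracks choroid reflectivity
          b
        })
        spec
      }
    ),
    DME = list(
      template = dme_base,
      sample = function(js) {
        spec <- jitter_common(dme_base, js)
        extra <- jit_int(0, 3, js)
        spec$layer_profile$depth[7:12] <- spec$layer_profile$depth[7:12] + extra
        spec$boundary_waves[[1]]$amplitude <- jit(6, 1, js)
        spec$boundary_waves[[1]]$period <- jit(32, 6, js)
        spec$boundary_waves[[1]]$phase <- jit(0, pi, js)
        spec$his_spots <- lapply(spec$his_spots, function(s) {
          s$row <- jit_int(s$row, 6, js); s$col <- jit_int(s$col, 10, js)
          s$intensity <- jit(s$intensity, 10, js)
          s
        })
        spec
      }
    )
  )
}

#' Generate a labelled cohort of phantom volumes
#'
#' @param n_per_class number of volumes per class (>= 1).
#' @param class_params named list of class templates as produced by
#'   [default_class_params()].
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param jitter_scale scale factor on all jitter ranges; 0 reproduces the
#'   class templates exactly.
#' @return List of `list(volume, truth)` pairs with a `provenance`
#'   attribute (data.frame of per-volume label and seed).
#' @export
phantom_cohort <- function(n_per_class, class_params = default_class_params(),
                           seed = 1L, jitter_scale = 1) {
  if (length(class_params) == 0) stop("class_params must name at least one class")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  labels <- names(class_params)
  out <- list(); prov <- list()
  seeds <- derive_seeds(seed, length(labels) * n_per_class)
  i <- 0L
  for (lab in labels) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      spec <- with_seed(seeds[i], {
        s <- class_params[[lab]]$sample(jitter_scale)
        s$seed <- sample.int(.Machine$integer.max, 1)
        s
      })
      validate_phantom_spec(spec)
      out[[i]] <- generate_phantom(spec, label = lab)
      prov[[i]] <- data.frame(index = i, label = lab, spec_seed = spec$seed)
    }
  }
  attr(out, "provenance") <- do.call(rbind, prov)
  out
}
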