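# File formats: multi-page TIFF volumes (minimal baseline codec: 8-bit
# grayscale, uncompressed, one strip per page -- no R TIFF package is
# available in the target environment), PNG B-scan directories, boundary
# sets as JSON and feature tables as CSV.

#' Write a volume as multi-page TIFF
#'
#' Baseline little-endian TIFF, 8-bit grayscale, one page per B-scan,
#' uncompressed.  A sidecar JSON (`<path>.json`) records the voxel
#' dimensions and optional metadata so that [read_volume()] can round-trip
#' the volume bit-exactly.
#'
#' @param volume an `oct_volume`.
#' @param path output file path.
#' @param sidecar write the sidecar JSON (default TRUE).
#' @param metadata extra fields stored in the sidecar (e.g. label, spec).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path, sidecar = TRUE, metadata = list()) {
  d <- dim(volume$data)
  h <- d[1]; w <- d[2]; np <- d[3]
  pages <- lapply(seq_len(np), function(z) {
    m <- round(volume$data[, , z])
    m[m < 0] <- 0; m[m > 255] <- 255
    as.raw(as.integer(t(m)))   # row-major
  })
  page_bytes <- h * w
  ifd_len <- 2 + 9 * 12 + 4
  data_off <- 8 + cumsum(c(0, rep(page_bytes, np - 1)))
  ifd0 <- 8 + np * page_bytes
  ifd_off <- ifd0 + (seq_len(np) - 1) * ifd_len

  con <- file(path, "wb"); on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd0), con, size = 4, endian = "little")
  for (z in seq_len(np)) writeBin(pages[[z]], con)
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3) {  # SHORT: value in first 2 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (z in seq_len(np)) {
    writeBin(9L, con, size = 2, endian = "little")
    entry(256, 4, 1, w)               # ImageWidth
    entry(257, 4, 1, h)               # ImageLength
    entry(258, 3, 1, 8)               # BitsPerSample
    entry(259, 3, 1, 1)               # Compression: none
    entry(262, 3, 1, 1)               # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[z])     # StripOffsets
    entry(277, 3, 1, 1)               # SamplesPerPixel
    entry(278, 4, 1, h)               # RowsPerStrip
    entry(279, 4, 1, page_bytes)      # StripByteCounts
    nxt <- if (z < np) ifd_off[z + 1] else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  if (sidecar) {
    side <- c(list(voxel_dims = volume$voxel_dims,
                   shape = c(depth_px = h, width_ascans = w, n_bscans = np)),
              metadata)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

read_tiff_volume <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  byte_order <- rawToChar(raw[1:2])
  en <- if (byte_order == "II") "little" else if (byte_order == "MM") "big"
        else stop("not a TIFF file: ", path)
  rint <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = en, signed = size == 4)
  if (rint(2, 2) != 42) stop("not a TIFF file: ", path)
  ifd <- rint(4, 4)
  pages <- list()
  while (ifd != 0) {
    nent <- rint(ifd, 2)
    tags <- list()
    for (e in seq_len(nent)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- rint(off, 2); type <- rint(off + 2, 2); count <- rint(off + 4, 4)
      tsz <- c(`1` = 1, `3` = 2, `4` = 4)[as.character(type)]
      if (is.na(tsz)) next
      vals <- if (tsz * count <= 4) rint(off + 8, tsz, count)
              else rint(rint(off + 8, 4), tsz, count)
      tags[[as.character(tag)]] <- vals
    }
    need <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF tag ", t, " missing")
        default
      } else v
    }
    w <- need(256); h <- need(257)
    if (need(259, 1) != 1) stop("only uncompressed TIFF is supported")
    if (any(need(258, 8) != 8)) stop("only 8-bit TIFF is supported")
    if (need(277, 1) != 1) stop("only single-sample (grayscale) TIFF is supported")
    offs <- need(273); cnts <- need(279)
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + cnts[i])]))
    m <- matrix(as.numeric(as.integer(bytes)), nrow = h, ncol = w, byrow = TRUE)
    pages[[length(pages) + 1]] <- m
    ifd <- rint(ifd + 2 + nent * 12, 4)
  }
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1)
    stop("inconsistent page shapes in ", path)
  array(unlist(pages), dim = c(shapes[[1]], length(pages)))
}

# natural sort: order by the first integer embedded in each file name
natural_order <- function(files) {
  base <- basename(files)
  num <- suppressWarnings(as.integer(gsub("\\D", "", base)))
  order(is.na(num), num, base)
}

read_png_dir <- function(path) {
  files <- list.files(path, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0) stop("no PNG files in ", path)
  files <- files[natural_order(files)]
  pages <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    round(m * 255)
  })
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1) stop("inconsistent PNG sizes in ", path)
  array(unlist(pages), dim = c(shapes[[1]], length(pages)))
}

#' Write a volume as a directory of PNG B-scans
#'
#' @param volume an `oct_volume`.
#' @param dir output directory (created if needed); files are
#'   `bscan_000.png`, ...
#' @return `dir`, invisibly.
#' @export
write_volume_png_dir <- function(volume, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (z in seq_len(n_bscans(volume))) {
    m <- round(volume$data[, , z])
    m[m < 0] <- 0; m[m > 255] <- 255
    png::writePNG(m / 255, file.path(dir, sprintf("bscan_%03d.png", z - 1)))
  }
  invisible(dir)
}

#' Read an OCT volume from disk
#'
#' Accepts a multi-page TIFF file or a directory of PNG B-scans (pages in
#' natural name order).  Voxel dimensions come from the `voxel_dims`
#' argument or from the sidecar JSON `<path>.json`; without either, reading
#' fails.
#'
#' @param path TIFF path or PNG directory.
#' @param voxel_dims numeric length-3 (axial um/px, lateral um/px, B-scan
#'   spacing um), or `NULL` to use the sidecar.
#' @return An `oct_volume`.
#' @export
read_volume <- function(path, voxel_dims = NULL) {
  data <- if (dir.exists(path)) read_png_dir(path) else read_tiff_volume(path)
  if (is.null(voxel_dims)) {
    side <- paste0(path, ".json")
    if (file.exists(side))
      voxel_dims <- as.numeric(jsonlite::read_json(side)$voxel_dims)
  }
  if (is.null(voxel_dims) || length(voxel_dims) != 3)
    stop("voxel_dims missing: supply them or provide the sidecar JSON ",
         paste0(path, ".json"))
  oct_volume(data, voxel_dims)
}

#' Serialise a boundary set to JSON
#'
#' Structure: `{metadata: {...}, bscans: {"0": {"ILM-RNFL": [...], ...}}}`
#' with 0-based B-scan keys and fractional positions.
#'
#' @param bs an `oct_boundary_set`.
#' @param path output path.
#' @param metadata extra metadata fields.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(bs, path, metadata = list()) {
  nb <- dim(bs$positions)[3]
  bscans <- lapply(seq_len(nb), function(z) {
    stats::setNames(lapply(BOUNDARY_ORDER, function(b) bs$positions[b, , z]),
                    BOUNDARY_ORDER)
  })
  names(bscans) <- as.character(seq_len(nb) - 1L)
  obj <- list(metadata = c(list(voxel_dims = bs$voxel_dims), metadata),
              bscans = bscans)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a boundary set from JSON
#'
#' @param path JSON path written by [write_boundaries()].
#' @return An `oct_boundary_set`.
#' @export
read_boundaries <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- as.character(sort(as.integer(names(obj$bscans))))
  nb <- length(keys)
  w <- length(obj$bscans[[keys[1]]][[BOUNDARY_ORDER[1]]])
  pos <- array(NA_real_, dim = c(12, w, nb),
               dimnames = list(BOUNDARY_ORDER, NULL, NULL))
  for (z in seq_len(nb))
    for (b in BOUNDARY_ORDER)
      pos[b, , z] <- obj$bscans[[keys[z]]][[b]]
  vd <- obj$metadata$voxel_dims
  boundary_set(pos, if (length(vd)) as.numeric(vd) else NULL)
}

#' Write / read a feature table
#'
#' Comma-separated, UTF-8, header row, `.` decimal; one row per volume with
#' an `id` column, the ten feature columns and an optional `label` column.
#'
#' @param df data.frame of features.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_features <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
}

#' Full pipeline configuration
#'
#' Nests the segmentation, feature and cross-validation defaults; every
#' value can be overridden from a YAML file via [load_config()].
#'
#' @return Named list of all pipeline parameters.
#' @export
pipeline_config <- function() {
  list(
    segmentation = segmentation_config(),
    features = feature_config(),
    cv = list(k = 15, repeats = 10, algorithm = "rf", seed = 7,
              n_classes = NULL),
    voxel_dims = NULL
  )
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [pipeline_config()]; everything else keeps its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- pipeline_config()
  if (!is.null(path)) cfg <- deep_merge(cfg, yaml::read_yaml(path))
  cfg
}

#' Save a pipeline configuration as YAML
#'
#' @param config configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
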