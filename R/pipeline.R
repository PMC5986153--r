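# End-to-end pipeline: segment -> refine -> features -> repeated k-fold CV.

#' Run the full phenotyping pipeline
#'
#' Each volume is segmented, cross-B-scan corrected and reduced to its ten
#' features; with labels attached, the feature table is evaluated under the
#' repeated stratified k-fold protocol.  A volume whose processing fails is
#' skipped with a named warning and listed in the result.
#'
#' @param volumes list of `oct_volume` objects, of `list(volume, truth)`
#'   pairs (e.g. from [phantom_cohort()]), or a character vector of file
#'   paths readable by [read_volume()].
#' @param labels class labels, one per volume; taken from phantom ground
#'   truth when `volumes` are phantom pairs and `labels` is `NULL`.
#' @param config pipeline configuration, see [pipeline_config()].
#' @param outdir optional directory: persists `features.csv`, per-volume
#'   boundary JSONs, the CV result and a run log.
#' @return List with `features` (data.frame), `cv` (a `cv_result` or
#'   `NULL`), `boundaries` (list of `oct_boundary_set`) and `failed`
#'   (character vector of failed volume ids).
#' @export
run_pipeline <- function(volumes, labels = NULL, config = pipeline_config(),
                         outdir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(volumes)) {
    ids <- basename(volumes)
    volumes <- lapply(volumes, read_volume, voxel_dims = config$voxel_dims)
  } else {
    ids <- sprintf("volume_%03d", seq_along(volumes))
  }
  if (length(volumes) && is.list(volumes[[1]]) &&
      !inherits(volumes[[1]], "oct_volume") && !is.null(volumes[[1]]$volume)) {
    if (is.null(labels))
      labels <- vapply(volumes, function(v) v$truth$label, character(1))
    volumes <- lapply(volumes, `[[`, "volume")
  }
  if (!is.null(labels) && length(labels) != length(volumes))
    stop("labels must match volumes")

  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  feats <- list(); bsets <- list(); failed <- character(0)
  log <- list()
  for (i in seq_along(volumes)) {
    ti <- proc.time()[["elapsed"]]
    res <- tryCatch({
      bs <- segment_volume(volumes[[i]], config$segmentation)
      bs <- refine_across_bscans(bs, config$segmentation$max_dev_px)
      fv <- extract_features(volumes[[i]], bs, config$features)
      list(bs = bs, fv = fv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("volume %s failed (%s); skipped", ids[i],
                      conditionMessage(res)))
      failed <- c(failed, ids[i])
      next
    }
    bsets[[ids[i]]] <- res$bs
    row <- data.frame(id = ids[i], t(unclass(res$fv)), check.names = FALSE)
    if (!is.null(labels)) row$label <- labels[i]
    feats[[length(feats) + 1]] <- row
    log[[length(log) + 1]] <- list(stage = "volume", id = ids[i],
                                   seconds = proc.time()[["elapsed"]] - ti)
    if (!is.null(outdir))
      write_boundaries(res$bs, file.path(outdir, paste0(ids[i], ".boundaries.json")))
  }
  if (length(feats) == 0) stop("no volume could be processed")
  features <- do.call(rbind, feats)

  cv <- NULL
  if (!is.null(labels)) {
    ok <- features$label
    if (length(unique(ok)) < 2)
      stop("cross-validation needs at least two classes; cohort has only: ",
           paste(unique(ok), collapse = ", "))
    cohort <- labeled_cohort(features, features$label, ids = features$id)
    cvc <- config$cv
    cv <- repeated_kfold_cv(cohort, k = cvc$k, repeats = cvc$repeats,
                            algorithm = cvc$algorithm, seed = cvc$seed,
                            n_classes = cvc$n_classes)
  }
  if (!is.null(outdir)) {
    write_features(features, file.path(outdir, "features.csv"))
    if (!is.null(cv))
      jsonlite::write_json(
        list(per_repeat = cv$per_repeat, aggregate = cv$aggregate,
             config = cv$config[c("k", "repeats", "algorithm", "seed",
                                  "n_classes")]),
        file.path(outdir, "cv_result.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
    cfg_path <- file.path(outdir, "config.yaml")
    save_config(config, cfg_path)
    log[[length(log) + 1]] <- list(
      stage = "total", seconds = proc.time()[["elapsed"]] - t0,
      config_hash = unname(tools::md5sum(cfg_path)), n_failed = length(failed))
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = features, cv = cv, boundaries = bsets, failed = failed)
}
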