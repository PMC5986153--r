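# Repeated stratified k-fold evaluation with per-fold hyperparameter tuning
# on an inner validation split, mirroring the evaluation protocol of the
# classification experiments (k = 15, 10 repetitions; every test fold holds
# at least one instance of each class).

#' Stratified fold assignment
#'
#' Each class is shuffled and dealt round-robin over the k folds, so
#' per-class fold sizes differ by at most one; with class counts equal to k
#' every fold receives exactly one instance of each class.
#'
#' @param labels factor or character vector.
#' @param k number of folds.
#' @param seed integer seed; assignment is deterministic given it.
#' @return Integer vector of fold indices (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  y <- factor(labels)
  cnt <- table(y)
  if (any(cnt < k)) {
    stop(sprintf(
      "class counts (%s) must all be >= k = %d; maximum feasible k is %d",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), k, min(cnt)))
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Tune hyperparameters on an inner validation split
#'
#' The training subset is split 80/20 per class (at least one validation
#' sample per class where possible); each grid point is fitted on the inner
#' training part and scored by validation accuracy.  The first grid point
#' attaining the maximum wins, so grids ordered smallest-model-first encode
#' the tie-breaking rule.
#'
#' @param cohort a `labeled_cohort` restricted to the training samples.
#' @param algorithm registry name.
#' @param grid list of parameter lists (see [default_grid()]).
#' @param seed integer seed for the split and the fits.
#' @return The chosen parameter list, with attribute `accuracy`.
#' @export
tune_hyperparams <- function(cohort, algorithm, grid, seed = 1L) {
  if (length(grid) == 0) stop("hyperparameter grid is empty")
  if (length(grid) == 1) return(grid[[1]])
  y <- factor(cohort$y)
  if (nlevels(droplevels(y)) < 2) stop("training subset must contain all classes")
  val_idx <- with_seed(seed, {
    unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      if (length(idx) < 2) return(integer(0))   # keep singletons in training
      sample(idx, max(1L, floor(0.2 * length(idx))))
    }))
  })
  if (length(val_idx) == 0) return(grid[[1]])   # too few samples to split
  tr_idx <- setdiff(seq_along(y), val_idx)
  tr <- labeled_cohort(cohort$X[tr_idx, , drop = FALSE], y[tr_idx],
                       cohort$ids[tr_idx])
  ntrees <- vapply(grid, function(g) g$ntree %||% NA_real_, numeric(1))
  if (algorithm == "rf" && !anyNA(ntrees)) {
    # forests are prefix-stable in ntree: fit the largest once
    full <- train_classifier(tr, algorithm, list(ntree = max(ntrees)),
                             seed = seed)
    acc <- vapply(ntrees, function(m) {
      sc <- predict_rf_scores(full$fit, cohort$X[val_idx, , drop = FALSE], m)
      pred <- full$levels[max.col(sc, ties.method = "first")]
      mean(pred == as.character(y[val_idx]))
    }, numeric(1))
  } else {
    acc <- vapply(seq_along(grid), function(g) {
      m <- train_classifier(tr, algorithm, grid[[g]], seed = seed + g)
      pred <- predict(m, cohort$X[val_idx, , drop = FALSE])
      mean(pred$class == y[val_idx])
    }, numeric(1))
  }
  best <- grid[[which.max(acc)]]
  attr(best, "accuracy") <- max(acc)
  attr(best, "val_ids") <- cohort$ids[val_idx]
  best
}

auc_rank <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics
#'
#' Binary mode (two levels in `truth`): sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, f1 `2PR/(P+R)` on the positive class and
#' accuracy, all in percent, plus the rank-based AUC of the positive-class
#' score.  Multi-class mode: overall accuracy plus one-vs-rest AUC per class
#' and their macro average; sensitivity/specificity/f1 are `NA`.
#'
#' @param truth,predictions factors over the same levels.
#' @param scores matrix of per-class scores (columns named by level), or
#'   `NULL` to omit AUC.
#' @param positive_class the positive level for binary reporting.
#' @return An `oct_metrics` list with fields `sensitivity`, `specificity`,
#'   `f1`, `accuracy` (percent), `auc`, and `auc_per_class` (multi-class).
#' @export
classification_metrics <- function(truth, predictions, scores = NULL,
                                   positive_class = NULL) {
  truth <- factor(truth)
  predictions <- factor(predictions, levels = levels(truth))
  if (length(truth) != length(predictions))
    stop("truth and predictions must have equal length")
  acc <- 100 * mean(predictions == truth)
  lv <- levels(truth)
  if (length(lv) == 2) {
    pos <- positive_class %||% lv[2]
    if (!pos %in% lv) stop("positive_class not among levels")
    neg <- setdiff(lv, pos)
    tp <- sum(truth == pos & predictions == pos)
    fn <- sum(truth == pos & predictions != pos)
    tn <- sum(truth == neg & predictions == neg)
    fp <- sum(truth == neg & predictions != neg)
    sens <- 100 * tp / (tp + fn)
    spec <- 100 * tn / (tn + fp)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- tp / (tp + fn)
    f1 <- if (is.na(prec) || prec + rec == 0) NA_real_
          else 100 * 2 * prec * rec / (prec + rec)
    auc <- if (!is.null(scores)) auc_rank(scores[, pos], truth == pos)
           else NA_real_
    structure(list(sensitivity = sens, specificity = spec, f1 = f1,
                   accuracy = acc, auc = auc, positive_class = pos),
              class = "oct_metrics")
  } else {
    aucs <- if (!is.null(scores)) {
      vapply(lv, function(l) auc_rank(scores[, l], truth == l), numeric(1))
    } else rep(NA_real_, length(lv))
    names(aucs) <- lv
    structure(list(sensitivity = NA_real_, specificity = NA_real_,
                   f1 = NA_real_, accuracy = acc,
                   auc = mean(aucs), auc_per_class = aucs),
              class = "oct_metrics")
  }
}

#' @export
print.oct_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %s  specificity %s  f1 %s  AUC %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.2f%%", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.2f%%", x$specificity)),
              ifelse(is.na(x$f1), "NA", sprintf("%.2f%%", x$f1)),
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition a fresh stratified fold assignment is drawn; within
#' each fold, hyperparameters are tuned on an inner 80/20 split of the
#' training folds, the model is refit on the whole training data and
#' evaluated on the held-out fold.  Metrics are pooled per repetition over
#' its k test folds and aggregated as mean (SD) over repetitions.
#'
#' @param cohort a `labeled_cohort`.
#' @param k number of folds (default 15).
#' @param repeats number of repetitions (default 10).
#' @param algorithm registry name (default `"rf"`).
#' @param grid hyperparameter grid; default [default_grid()] of the
#'   algorithm.
#' @param seed master seed; the whole experiment is reproducible from it.
#' @param n_classes 2 or 3: with 2 while the cohort has three labels,
#'   non-normal labels are collapsed into `"diseased"`.
#' @param positive_class positive level for binary metrics; defaults to
#'   `"diseased"` after collapsing, else the non-normal level.
#' @return A `cv_result`: per-repeat metrics, aggregate mean/SD, fold
#'   assignments and a per-fold data-access log (`train_ids`, `test_ids`).
#' @export
repeated_kfold_cv <- function(cohort, k = 15, repeats = 10, algorithm = "rf",
                              grid = default_grid(algorithm), seed = 1L,
                              n_classes = NULL, positive_class = NULL) {
  y <- factor(cohort$y)
  n_classes <- n_classes %||% nlevels(y)
  if (n_classes == 2 && nlevels(y) > 2) {
    y <- factor(ifelse(as.character(y) == "normal", "normal", "diseased"),
                levels = c("normal", "diseased"))
    positive_class <- positive_class %||% "diseased"
  } else if (nlevels(y) == 2 && is.null(positive_class)) {
    positive_class <- setdiff(levels(y), "normal")[1]
  }
  coh <- labeled_cohort(cohort$X, y, cohort$ids)
  rseeds <- derive_seeds(seed, repeats)
  per_repeat <- list(); access_log <- list()
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(coh$y, k, rseeds[r])
    pred <- factor(rep(NA_character_, length(coh$y)), levels = levels(coh$y))
    scores <- matrix(NA_real_, length(coh$y), nlevels(coh$y),
                     dimnames = list(NULL, levels(coh$y)))
    fold_log <- list()
    fseeds <- derive_seeds(rseeds[r], k)
    for (f in seq_len(k)) {
      te <- which(folds == f); tr <- which(folds != f)
      trc <- labeled_cohort(coh$X[tr, , drop = FALSE], coh$y[tr], coh$ids[tr])
      params <- tune_hyperparams(trc, algorithm, grid, seed = fseeds[f])
      model <- train_classifier(trc, algorithm, params, seed = fseeds[f] + 7L)
      p <- predict(model, coh$X[te, , drop = FALSE])
      pred[te] <- p$class
      scores[te, colnames(p$scores)] <- p$scores
      fold_log[[f]] <- list(train_ids = coh$ids[tr], test_ids = coh$ids[te],
                            params = params)
    }
    m <- classification_metrics(coh$y, pred, scores, positive_class)
    per_repeat[[r]] <- data.frame(
      repeat_i = r, sensitivity = m$sensitivity, specificity = m$specificity,
      f1 = m$f1, accuracy = m$accuracy, auc = m$auc)
    access_log[[r]] <- fold_log
  }
  pr <- do.call(rbind, per_repeat)
  agg <- lapply(c("sensitivity", "specificity", "f1", "accuracy", "auc"),
                function(col) list(mean = mean(pr[[col]]), sd = stats::sd(pr[[col]])))
  names(agg) <- c("sensitivity", "specificity", "f1", "accuracy", "auc")
  structure(list(per_repeat = pr, aggregate = agg,
                 config = list(k = k, repeats = repeats, algorithm = algorithm,
                               grid = grid, seed = seed, n_classes = n_classes,
                               positive_class = positive_class),
                 access_log = access_log),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  a <- x$aggregate
  fmt <- function(s) if (is.na(a[[s]]$mean)) "NA"
    else sprintf("%.2f (%.2f)", a[[s]]$mean, a[[s]]$sd)
  cat(sprintf("<cv_result> %s, %d-fold x %d repeats (%d-class)\n",
              x$config$algorithm, x$config$k, x$config$repeats,
              x$config$n_classes))
  cat(sprintf("  accuracy    %s\n  sensitivity %s\n  specificity %s\n  f1          %s\n  AUC         %s\n",
              fmt("accuracy"), fmt("sensitivity"), fmt("specificity"),
              fmt("f1"),
              if (is.na(a$auc$mean)) "NA"
              else sprintf("%.3f (%.3f)", a$auc$mean, a$auc$sd)))
  invisible(x)
}
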