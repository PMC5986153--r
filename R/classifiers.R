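# Classifier registry for the disease-classification experiments.  CART
# trees, bagged random forests, SAMME AdaBoost and Gaussian naive Bayes are
# implemented here; logistic regression is delegated to glmnet; the two SVM
# variants are least-squares SVMs (kernel ridge with a bias term), which
# preserve the tunable-kernel-scale contract without an external QP solver.

ALGORITHMS <- c("rf", "logistic", "svm_linear", "svm_rbf", "adaboost",
                "naive_bayes", "tree_regression", "tree_classification")

#' Assemble a labelled cohort
#'
#' @param features data.frame or matrix whose columns include the ten
#'   feature names; extra columns are ignored.
#' @param labels factor or character vector of class labels.
#' @param ids optional sample identifiers.
#' @return A `labeled_cohort` (list with `X`, `y`, `ids`).
#' @export
labeled_cohort <- function(features, labels, ids = NULL) {
  feats <- intersect(FEATURE_NAMES, colnames(features))
  if (length(feats) == 0) feats <- colnames(features)
  X <- as.matrix(as.data.frame(features)[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("cohort features contain missing values")
  y <- factor(labels)
  if (nrow(X) != length(y)) stop("features and labels length mismatch")
  ids <- ids %||% seq_len(nrow(X))
  structure(list(X = X, y = y, ids = ids), class = "labeled_cohort")
}

# ---- CART -------------------------------------------------------------------

# Weighted CART.  type "class": Gini impurity, grown in compiled code (the
# forest and the boosting loop fit hundreds of thousands of trees); type
# "reg": weighted variance, pure R (fit once per fold).  mtry features are
# drawn per node.
fit_cart <- function(X, y, type = c("class", "reg"), weights = NULL,
                     mtry = NULL, max_depth = Inf, min_split = 2L,
                     n_levels = NULL) {
  type <- match.arg(type)
  n <- nrow(X); p <- ncol(X)
  weights <- weights %||% rep(1, n)
  mtry <- mtry %||% p
  if (type == "class") {
    y <- as.integer(y)
    n_levels <- n_levels %||% max(y)
    tree <- cart_grow_class(X, y, weights, n_levels, mtry,
                            as.integer(min_split),
                            if (is.finite(max_depth)) as.integer(max_depth) else -1L)
    return(structure(list(cpp = tree, type = "class",
                          n_levels = n_levels, p = p),
                     class = "cart_tree"))
  }

  leaf <- function(idx) {
    list(leaf = TRUE, value = stats::weighted.mean(y[idx], weights[idx]))
  }

  best_split <- function(idx, feats) {
    best <- NULL
    for (f in feats) {
      x <- X[idx, f]
      o <- order(x)
      xs <- x[o]; ws <- weights[idx][o]
      if (xs[1] == xs[length(xs)]) next
      splittable <- which(xs[-length(xs)] < xs[-1])
      if (length(splittable) == 0) next
      yo <- y[idx][o]
      cw <- cumsum(ws); cy <- cumsum(ws * yo); cy2 <- cumsum(ws * yo^2)
      tw <- cw[length(xs)]; ty <- cy[length(xs)]; ty2 <- cy2[length(xs)]
      vl <- cy2 - cy^2 / pmax(cw, 1e-300)
      wr <- tw - cw
      vr <- (ty2 - cy2) - (ty - cy)^2 / pmax(wr, 1e-300)
      crit <- (vl + vr)[splittable]
      i <- splittable[which.min(crit)]
      val <- min(crit)
      if (is.null(best) || val < best$crit - 1e-12) {
        best <- list(crit = val, feature = f,
                     threshold = (xs[i] + xs[i + 1]) / 2)
      }
    }
    best
  }

  grow <- function(idx, depth) {
    if (length(idx) < min_split || depth >= max_depth) return(leaf(idx))
    if (stats::var(y[idx]) == 0) return(leaf(idx))
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    sp <- best_split(idx, feats)
    if (is.null(sp) && mtry < p) sp <- best_split(idx, seq_len(p))
    if (is.null(sp)) return(leaf(idx))
    go_left <- X[idx, sp$feature] <= sp$threshold
    if (all(go_left) || !any(go_left)) return(leaf(idx))
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         left = grow(idx[go_left], depth + 1),
         right = grow(idx[!go_left], depth + 1))
  }

  structure(list(root = grow(seq_len(n), 0), type = "reg", p = p),
            class = "cart_tree")
}

predict_cart <- function(tree, X) {
  if (tree$type == "class") return(cart_predict_class(tree$cpp, X))
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    go <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[go]); rec(node$right, idx[!go])
  }
  rec(tree$root, seq_len(n))
  out
}

# ---- fitting backends -------------------------------------------------------

# Every tree gets its own derived seed, so the first m trees of a forest are
# identical across ntree settings; hyperparameter tuning exploits this by
# fitting the largest forest once and scoring prefixes.
fit_rf <- function(X, y, ntree = 200, mtry = NULL) {
  n <- nrow(X)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  nl <- nlevels(y)
  tseeds <- sample.int(.Machine$integer.max, ntree)
  trees <- lapply(seq_len(ntree), function(i) {
    set.seed(tseeds[i])
    idx <- sample.int(n, n, replace = TRUE)
    fit_cart(X[idx, , drop = FALSE], y[idx], type = "class", mtry = mtry,
             n_levels = nl)
  })
  list(trees = trees)
}

predict_rf_scores <- function(fit, X, ntree = length(fit$trees)) {
  probs <- lapply(fit$trees[seq_len(ntree)], function(tr) predict_cart(tr, X))
  Reduce(`+`, probs) / length(probs)
}

fit_adaboost <- function(X, y, rounds = 100) {
  n <- nrow(X); K <- nlevels(y); yc <- as.integer(y)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    st <- fit_cart(X, y, type = "class", weights = w, max_depth = 1,
                   n_levels = K)
    pred <- max.col(predict_cart(st, X), ties.method = "first")
    miss <- pred != yc
    err <- sum(w[miss]) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, K = K)
}

fit_naive_bayes <- function(X, y) {
  K <- nlevels(y)
  stats_by <- lapply(seq_len(K), function(k) {
    Xi <- X[as.integer(y) == k, , drop = FALSE]
    mu <- colMeans(Xi)
    sd <- apply(Xi, 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-9] <- 1e-9
    list(mu = mu, sd = sd, prior = nrow(Xi) / nrow(X))
  })
  list(stats = stats_by, K = K)
}

fit_lssvm <- function(X, y, kernel = c("linear", "rbf"), kernel_scale = 1,
                      lambda = 0.1) {
  kernel <- match.arg(kernel)
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- scale(X, mu, sdv)
  n <- nrow(Xs); K <- nlevels(y)
  Y <- sapply(seq_len(K), function(k) ifelse(as.integer(y) == k, 1, -1))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = n)
  Km <- if (kernel == "linear") tcrossprod(Xs)
        else exp(-as.matrix(stats::dist(Xs))^2 / (2 * kernel_scale^2))
  A <- rbind(cbind(Km + lambda * diag(n), rep(1, n)), c(rep(1, n), 0))
  sol <- solve(A, rbind(Y, 0))
  list(alpha = sol[seq_len(n), , drop = FALSE], b = sol[n + 1, ],
       Xs = Xs, mu = mu, sdv = sdv, kernel = kernel,
       kernel_scale = kernel_scale)
}

fit_logistic <- function(X, y) {
  fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
  fit <- glmnet::glmnet(X, y, family = fam, alpha = 0,
                        lambda = c(1, 0.1, 0.01, 1e-3))
  list(fit = fit, family = fam)
}

# ---- registry ---------------------------------------------------------------

#' Train a disease classifier
#'
#' @param cohort a `labeled_cohort` (or list with `X` and `y`).
#' @param algorithm one of `"rf"`, `"logistic"`, `"svm_linear"`,
#'   `"svm_rbf"`, `"adaboost"`, `"naive_bayes"`, `"tree_regression"`,
#'   `"tree_classification"`.
#' @param params algorithm parameters (e.g. `ntree` for rf, `kernel_scale`
#'   for svm_rbf).
#' @param seed integer seed; fits are deterministic given it.
#' @return An `oct_model` exposing class predictions and per-class scores
#'   via [predict.oct_model()].
#' @export
train_classifier <- function(cohort, algorithm, params = list(), seed = 1L) {
  if (!algorithm %in% ALGORITHMS)
    stop(sprintf("unknown algorithm '%s'; available: %s", algorithm,
                 paste(ALGORITHMS, collapse = ", ")))
  X <- cohort$X; y <- droplevels(factor(cohort$y))
  if (nlevels(y) < 2) stop("cohort must contain at least 2 classes")
  fit <- with_seed(seed, switch(algorithm,
    rf = fit_rf(X, y, ntree = params$ntree %||% 200,
                mtry = params$mtry),
    logistic = fit_logistic(X, y),
    svm_linear = fit_lssvm(X, y, "linear",
                           lambda = params$lambda %||% 0.1),
    svm_rbf = fit_lssvm(X, y, "rbf",
                        kernel_scale = params$kernel_scale %||% 1,
                        lambda = params$lambda %||% 0.1),
    adaboost = fit_adaboost(X, y, rounds = params$rounds %||% 100),
    naive_bayes = fit_naive_bayes(X, y),
    tree_regression = fit_cart(X, as.numeric(as.integer(y)), type = "reg",
                               min_split = params$min_split %||% 5),
    tree_classification = fit_cart(X, y, type = "class",
                                   n_levels = nlevels(y))
  ))
  structure(list(algorithm = algorithm, fit = fit, levels = levels(y),
                 params = params, seed = seed),
            class = "oct_model")
}

#' Predict classes and per-class scores
#'
#' @param object an `oct_model`.
#' @param newdata feature matrix (or `labeled_cohort`).
#' @param ... unused.
#' @return List with `class` (factor) and `scores` (matrix, one column per
#'   class; rows sum to 1 where the backend yields probabilities).
#' @export
predict.oct_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_cohort")) newdata$X else as.matrix(newdata)
  lv <- object$levels; K <- length(lv)
  fit <- object$fit
  scores <- switch(object$algorithm,
    rf = predict_rf_scores(fit, X),
    logistic = {
      if (fit$family == "binomial") {
        p <- as.numeric(stats::predict(fit$fit, X, s = 1e-3, type = "response"))
        cbind(1 - p, p)
      } else {
        pr <- stats::predict(fit$fit, X, s = 1e-3, type = "response")
        pr[, , 1]
      }
    },
    svm_linear = , svm_rbf = {
      Xs <- scale(X, fit$mu, fit$sdv)
      Km <- if (fit$kernel == "linear") tcrossprod(Xs, fit$Xs)
            else {
              d2 <- outer(rowSums(Xs^2), rowSums(fit$Xs^2), `+`) -
                2 * tcrossprod(Xs, fit$Xs)
              exp(-pmax(d2, 0) / (2 * fit$kernel_scale^2))
            }
      raw <- Km %*% fit$alpha + matrix(fit$b, nrow(Xs), K, byrow = TRUE)
      # softmax for a probability-like score
      e <- exp(raw - apply(raw, 1, max))
      e / rowSums(e)
    },
    adaboost = {
      votes <- matrix(0, nrow(X), K)
      for (i in seq_along(fit$stumps)) {
        pr <- max.col(predict_cart(fit$stumps[[i]], X), ties.method = "first")
        votes[cbind(seq_len(nrow(X)), pr)] <-
          votes[cbind(seq_len(nrow(X)), pr)] + fit$alphas[i]
      }
      if (sum(fit$alphas) > 0) votes / sum(fit$alphas) else votes
    },
    naive_bayes = {
      ll <- sapply(fit$stats, function(s) {
        rowSums(sapply(seq_len(ncol(X)), function(j)
          stats::dnorm(X[, j], s$mu[j], s$sd[j], log = TRUE))) + log(s$prior)
      })
      if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(X))
      e <- exp(ll - apply(ll, 1, max))
      e / rowSums(e)
    },
    tree_regression = {
      v <- predict_cart(fit, X)
      sc <- sapply(seq_len(K), function(k) 1 - abs(v - k) / max(K - 1, 1))
      if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(X))
      pmax(sc, 0)
    },
    tree_classification = predict_cart(fit, X)
  )
  colnames(scores) <- lv
  cls <- factor(lv[max.col(scores, ties.method = "first")], levels = lv)
  list(class = cls, scores = scores)
}

#' Default hyperparameter grids
#'
#' Grids are ordered by tie preference: the smallest model (fewest trees,
#' largest kernel scale) comes first.
#'
#' @param algorithm registry name.
#' @return List of parameter lists.
#' @export
default_grid <- function(algorithm) {
  switch(algorithm,
    rf = lapply(c(50, 100, 200, 500), function(n) list(ntree = n)),
    svm_rbf = lapply(rev(10^seq(-1, 1, length.out = 5)),
                     function(s) list(kernel_scale = s)),
    list(list())
  )
}
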