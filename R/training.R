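# Per-side classifier training: univariate feature selection, grid-searched
# hyperparameters with seeded stratified 10-fold cross-validation, and a
# final refit on the full balanced dataset.

#' Hyperparameter grid for one algorithm
#'
#' The standard tuning grids: SVM (kernel linear/rbf, C in
#' \{0.1, 0.3, 0.6, 1, 3, 6, 10\}; 14 combinations), k-nearest neighbors
#' (k in \{3, 5, 10, 15, 20, 40\}, uniform/distance vote, four
#' neighbor-search strategies; 48 combinations), and random forest (50/
#' 100/200 trees, gini/entropy criterion, max depth \{5, 8, 11, 14\},
#' max features auto/sqrt/log2; 72 combinations).
#'
#' Two axes are carried for interface compatibility but cannot change a
#' fitted model: the kNN `algorithm` axis selects a neighbor-search
#' strategy (the exact-search implementation used here returns identical
#' predictions for all four), and the random-forest `criterion` axis is
#' fitted with the Gini impurity for both values (no installed backend
#' implements the information-gain criterion). `max_features = "auto"` is
#' a deprecated alias of `"sqrt"`.
#'
#' @param algo `"svm"`, `"knn"` or `"random_forest"`.
#' @return Data frame with one row per hyperparameter combination.
#' @export
#' @examples
#' nrow(default_grid("svm"))           # 14
#' nrow(default_grid("random_forest")) # 72
default_grid <- function(algo = c("svm", "knn", "random_forest")) {
  algo <- match.arg(algo)
  g <- switch(algo,
    svm = expand.grid(kernel = c("linear", "rbf"),
                      C = c(0.1, 0.3, 0.6, 1.0, 3, 6, 10),
                      stringsAsFactors = FALSE),
    knn = expand.grid(k = c(3L, 5L, 10L, 15L, 20L, 40L),
                      weights = c("uniform", "distance"),
                      algorithm = c("auto", "ball_tree", "kd_tree", "brute"),
                      stringsAsFactors = FALSE),
    random_forest = expand.grid(n_estimators = c(50L, 100L, 200L),
                                criterion = c("gini", "entropy"),
                                max_depth = c(5L, 8L, 11L, 14L),
                                max_features = c("auto", "sqrt", "log2"),
                                stringsAsFactors = FALSE)
  )
  g
}

#' Training configuration
#'
#' @param n_folds Cross-validation folds (default 10).
#' @param nf_max Maximum number of selected features (default 30).
#' @param seed Seed for fold assignment, subsampling and forest fitting.
#' @param select_in_fold Fit the feature selector inside each training
#'   fold (default `TRUE`; avoids selection leakage into the validation
#'   folds). `FALSE` reproduces the optimistic variant that selects once
#'   on the full dataset.
#' @param group_by_trial Keep all windows of one trial in the same fold
#'   (default `TRUE`): overlapping windows of a single propulsion are
#'   near-duplicates, and splitting them across folds inflates pooled CV
#'   accuracy. `FALSE` gives plain pooled stratified CV.
#' @param window_sweep_w,window_sweep_s Window sizes and steps evaluated by
#'   [window_sweep()].
#' @return A `training_config` list.
#' @export
training_config <- function(n_folds = 10L, nf_max = 30L, seed = 1L,
                            select_in_fold = TRUE, group_by_trial = TRUE,
                            window_sweep_w = c(10L, 20L, 30L),
                            window_sweep_s = c(3L, 5L)) {
  stopifnot(n_folds >= 2, nf_max >= 1)
  structure(list(n_folds = as.integer(n_folds), nf_max = as.integer(nf_max),
                 seed = as.integer(seed), select_in_fold = select_in_fold,
                 group_by_trial = group_by_trial,
                 window_sweep_w = as.integer(window_sweep_w),
                 window_sweep_s = as.integer(window_sweep_s)),
            class = "training_config")
}

#' Rank features by one-way ANOVA F-score
#'
#' Univariate F-statistic of each feature across the class labels,
#' vectorized over columns. Ranking is deterministic: ties (and constant
#' features, whose F is undefined) are broken by column-name order and
#' sorted last respectively.
#'
#' @param X Numeric feature matrix with column names.
#' @param y Factor of class labels.
#' @param k Number of features to keep; must not exceed `ncol(X)`.
#' @return Character vector of the top-`k` feature names, best first, with
#'   the F-scores attached as the `scores` attribute.
#' @export
select_features <- function(X, y, k = 30L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (k > ncol(X)) {
    stop("cannot select ", k, " features from ", ncol(X), " available")
  }
  if (is.null(colnames(X))) stop("feature matrix must have column names")
  n <- nrow(X)
  g <- nlevels(y)
  stopifnot(g >= 2, n > g)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (lev in levels(y)) {
    sel <- y == lev
    ng <- sum(sel)
    mg <- colMeans(X[sel, , drop = FALSE])
    ssb <- ssb + ng * (mg - grand)^2
    ssw <- ssw + colSums((X[sel, , drop = FALSE] -
                            rep(mg, each = ng))^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[!is.finite(f)] <- -Inf                   # constant features rank last
  ord <- order(-f, colnames(X))
  out <- colnames(X)[ord][seq_len(k)]
  attr(out, "scores") <- f[ord][seq_len(k)]
  out
}

# Seeded stratified fold assignment; with `groups`, whole groups are dealt
# round-robin to folds (by decreasing size) so that overlapping windows of
# one trial never straddle a fold boundary.
make_folds <- function(y, n_folds, seed, groups = NULL) {
  withr::local_seed(as.integer(seed))
  fold <- integer(length(y))
  if (is.null(groups)) {
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    ug <- sample(unique(groups))
    sizes <- table(groups)[as.character(ug)]
    ug <- ug[order(-as.integer(sizes))]
    load <- numeric(n_folds)
    for (g in ug) {
      f <- which.min(load)
      sel <- groups == g
      fold[sel] <- f
      load[f] <- load[f] + sum(sel)
    }
  }
  fold
}

# Standardized exact kNN with uniform or inverse-distance vote. Ties are
# broken deterministically by class-level order; a zero-distance neighbor
# decides a distance-weighted vote outright.
knn_predict <- function(Xtr, ytr, Xte, k, weights = "uniform") {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[scl == 0] <- 1
  Ztr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  Zte <- sweep(sweep(Xte, 2, ctr), 2, scl, "/")
  d2 <- outer(rowSums(Zte^2), rowSums(Ztr^2), "+") - 2 * Zte %*% t(Ztr)
  d2[d2 < 0] <- 0
  k <- min(k, nrow(Ztr))
  lv <- levels(ytr)
  pred <- character(nrow(Zte))
  for (i in seq_len(nrow(Zte))) {
    nn <- order(d2[i, ])[seq_len(k)]
    if (weights == "distance") {
      d <- sqrt(d2[i, nn])
      if (any(d == 0)) {
        w <- as.numeric(d == 0)
      } else {
        w <- 1 / d
      }
    } else {
      w <- rep(1, k)
    }
    votes <- vapply(lv, function(l) sum(w[ytr[nn] == l]), numeric(1))
    pred[i] <- lv[which.max(votes)]
  }
  factor(pred, levels = lv)
}

rf_mtry <- function(max_features, p) {
  switch(as.character(max_features),
         auto = ,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop("unknown max_features: ", max_features))
}

# Fit one algorithm/hyperparameter combination and predict new rows.
fit_predict <- function(algo, params, Xtr, ytr, Xte, seed = 1L) {
  fit <- fit_model(algo, params, Xtr, ytr, seed)
  predict_model(fit, Xte)
}

fit_model <- function(algo, params, Xtr, ytr, seed = 1L) {
  ytr <- droplevels(ytr)
  fit <- switch(algo,
    svm = e1071::svm(
      x = Xtr, y = ytr,
      kernel = if (params$kernel == "rbf") "radial" else "linear",
      cost = params$C, scale = apply(Xtr, 2, stats::sd) > 0),
    knn = list(Xtr = Xtr, ytr = ytr, k = params$k,
               weights = params$weights),
    random_forest = ranger::ranger(
      x = Xtr, y = ytr,
      num.trees = params$n_estimators,
      max.depth = params$max_depth,
      mtry = rf_mtry(params$max_features, ncol(Xtr)),
      splitrule = "gini",            # both criterion values fit with Gini
      seed = seed, num.threads = 1),
    stop("unknown algorithm: ", algo)
  )
  structure(list(algo = algo, fit = fit,
                 features = colnames(Xtr), classes = levels(ytr)),
            class = "propulse_fit")
}

predict_model <- function(model, X) {
  X <- X[, model$features, drop = FALSE]
  switch(model$algo,
    svm = stats::predict(model$fit, X),
    knn = knn_predict(model$fit$Xtr, model$fit$ytr, X,
                      model$fit$k, model$fit$weights),
    random_forest = stats::predict(model$fit, data = X,
                                   num.threads = 1)$predictions
  )
}

#' Exhaustive grid search with seeded stratified cross-validation
#'
#' Evaluates every hyperparameter combination of `grid` with `n_folds`
#' stratified cross-validation on `X`/`y` and returns the combination with
#' the highest mean validation accuracy. Feature selection (top
#' `cfg$nf_max` by F-score) is refitted inside each training fold by
#' default. The result is invariant to the row order of `grid`: ties in
#' accuracy are broken by the lexicographic parameter string.
#'
#' @param X Feature matrix (named columns).
#' @param y Factor of labels; every class must have at least `n_folds`
#'   members.
#' @param algo `"svm"`, `"knn"` or `"random_forest"`.
#' @param grid Hyperparameter data frame (default [default_grid()]).
#' @param cfg A [training_config()].
#' @param groups Optional trial index per row for trial-grouped folds
#'   (used when `cfg$group_by_trial` is `TRUE`).
#' @return List with `algo`, `best_params` (one-row data frame),
#'   `cv_accuracy`, and `results` (per-combination mean accuracies).
#' @export
grid_search <- function(X, y, algo = c("svm", "knn", "random_forest"),
                        grid = NULL, cfg = training_config(),
                        groups = NULL) {
  algo <- match.arg(algo)
  if (is.null(grid)) grid <- default_grid(algo)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (any(table(y) < cfg$n_folds)) {
    stop("configuration error: every class needs at least ", cfg$n_folds,
         " members for ", cfg$n_folds, "-fold CV")
  }
  if (!cfg$group_by_trial) groups <- NULL
  fold <- make_folds(y, cfg$n_folds, cfg$seed, groups)
  folds <- sort(unique(fold))
  # per-fold feature selection is independent of the hyperparameters
  sel <- lapply(folds, function(f) {
    if (cfg$select_in_fold) {
      select_features(X[fold != f, , drop = FALSE], y[fold != f],
                      min(cfg$nf_max, ncol(X)))
    } else {
      select_features(X, y, min(cfg$nf_max, ncol(X)))
    }
  })
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- grid[i, , drop = FALSE]
    fold_acc <- vapply(seq_along(folds), function(fi) {
      f <- folds[fi]
      tr <- fold != f
      feats <- sel[[fi]]
      pred <- fit_predict(algo, params,
                          X[tr, feats, drop = FALSE], y[tr],
                          X[!tr, feats, drop = FALSE],
                          seed = cfg$seed + i)
      mean(pred == y[!tr])
    }, numeric(1))
    acc[i] <- mean(fold_acc)
  }
  key <- apply(grid, 1, function(r) paste(trimws(format(r)), collapse = "|"))
  best <- order(-acc, key)[1]
  results <- cbind(grid, accuracy = acc)
  list(algo = algo, best_params = grid[best, , drop = FALSE],
       cv_accuracy = acc[best], results = results, n_eval = nrow(grid))
}

#' Train one side classifier
#'
#' Full training pipeline for one side: assemble the balanced labeled
#' dataset (unless one is supplied), grid-search each requested algorithm
#' with cross-validation, pick the best algorithm/hyperparameter
#' combination, select the final feature subset on the full dataset, and
#' refit.
#'
#' @param trials List of trials (`recording` + `annotations`), or a
#'   prebuilt `labeled_dataset` from [build_dataset()].
#' @param side `"left"` or `"right"`.
#' @param mode `"two-sensor"` or `"three-sensor"`.
#' @param params A [window_params()] (default window 30, step 5).
#' @param filt A [filter_spec()].
#' @param cfg A [training_config()].
#' @param algos Algorithms to search (default all three).
#' @param grids Optional named list of hyperparameter grids overriding
#'   [default_grid()] per algorithm.
#' @return A `side_model`: the fitted classifier plus its side, mode,
#'   algorithm, hyperparameters, selected feature names, CV accuracy,
#'   window/filter parameters, class counts and seed.
#' @export
train_side <- function(trials, side = c("left", "right"),
                       mode = c("two-sensor", "three-sensor"),
                       params = window_params(), filt = filter_spec(),
                       cfg = training_config(),
                       algos = c("svm", "knn", "random_forest"),
                       grids = NULL) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  if (inherits(trials, "labeled_dataset")) {
    ds <- trials
    side <- ds$side
    mode <- ds$mode
    params <- ds$params
  } else {
    ds <- build_dataset(trials, side, mode, params, filt, seed = cfg$seed)
  }
  searches <- lapply(algos, function(a) {
    grid_search(ds$X, ds$y, a,
                grid = if (!is.null(grids)) grids[[a]] else NULL,
                cfg = cfg, groups = ds$groups)
  })
  accs <- vapply(searches, `[[`, numeric(1), "cv_accuracy")
  best <- searches[[order(-accs, algos)[1]]]
  feats <- select_features(ds$X, ds$y, min(cfg$nf_max, ncol(ds$X)))
  fit <- fit_model(best$algo, best$best_params,
                   ds$X[, feats, drop = FALSE], ds$y, seed = cfg$seed)
  structure(list(
    side = side, mode = mode,
    algorithm = best$algo,
    hyperparameters = best$best_params,
    selected_features = as.character(feats),
    feature_scores = attr(feats, "scores"),
    cv_accuracy = best$cv_accuracy,
    cv_results = lapply(searches, `[[`, "results"),
    window_params = params, filter = filt,
    counts = ds$counts, seed = cfg$seed,
    cfg = cfg, fit = fit,
    classes = basic_labels(),
    package_version = as.character(utils::packageVersion("propulse"))),
    class = "side_model")
}

#' @export
print.side_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, as.character, character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf(
    "<side_model> %s classifier (%s): %s [%s]\n  w=%d s=%d, %d features, CV accuracy %.4f\n",
    x$side, x$mode, x$algorithm, hp, x$window_params$w, x$window_params$s,
    length(x$selected_features), x$cv_accuracy))
  invisible(x)
}

#' Predict basic gestures for a feature matrix
#'
#' @param model A `side_model`.
#' @param X Feature matrix containing (at least) the model's selected
#'   feature columns.
#' @return Factor of predictions (`forward`, `backward`, `dance`).
#' @export
predict_side <- function(model, X) {
  stopifnot(inherits(model, "side_model"))
  factor(as.character(predict_model(model$fit, as.matrix(X))),
         levels = basic_labels())
}

#' Sweep sliding-window parameters
#'
#' Re-runs [train_side()]'s grid search for every combination of window
#' size and step in the training configuration, producing an
#' algorithm-by-(w, s) accuracy table.
#'
#' @inheritParams train_side
#' @return Data frame with columns `algo`, `w`, `s`, `accuracy` (best CV
#'   accuracy of that algorithm's grid at those window parameters).
#' @export
window_sweep <- function(trials, side = c("left", "right"),
                         mode = c("two-sensor", "three-sensor"),
                         filt = filter_spec(), cfg = training_config(),
                         algos = c("svm", "knn", "random_forest"),
                         grids = NULL) {
  side <- match.arg(side)
  mode <- match.arg(mode)
  out <- list()
  for (w in cfg$window_sweep_w) {
    for (s in cfg$window_sweep_s) {
      ds <- build_dataset(trials, side, mode, window_params(w, s), filt,
                          seed = cfg$seed)
      for (a in algos) {
        gs <- grid_search(ds$X, ds$y, a,
                          grid = if (!is.null(grids)) grids[[a]] else NULL,
                          cfg = cfg, groups = ds$groups)
        out[[length(out) + 1L]] <-
          data.frame(algo = a, w = w, s = s, accuracy = gs$cv_accuracy)
      }
    }
  }
  do.call(rbind, out)
}
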