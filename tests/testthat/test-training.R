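# Feature selection, grid search with stratified CV, and side-model
# training.

test_that("F-score ranking matches the aov oracle and finds the signal", {
  withr::with_seed(21, {
    n <- 90
    y <- factor(rep(basic_labels(), each = 30), levels = basic_labels())
    X <- matrix(rnorm(n * 10), n, 10)
    colnames(X) <- sprintf("f%02d", 1:10)
    X[, 4] <- as.integer(y) * 3 + rnorm(n, 0, 0.1)  # the one real feature
  })
  ranked <- select_features(X, y, 10)
  expect_equal(ranked[1], "f04")
  # oracle: one-way ANOVA F statistic per column
  scores <- attr(ranked, "scores")
  for (j in c(1, 4, 7)) {
    f_ref <- anova(lm(X[, j] ~ y))[["F value"]][1]
    expect_equal(unname(scores[ranked == colnames(X)[j]]), f_ref,
                 tolerance = 1e-10)
  }
})

test_that("selection keeps everything at k = p and breaks ties by name", {
  withr::with_seed(22, {
    y <- factor(rep(basic_labels(), each = 10), levels = basic_labels())
    X <- matrix(rnorm(30 * 4), 30, 4)
    colnames(X) <- c("b", "a", "d", "c")
  })
  expect_setequal(select_features(X, y, 4), colnames(X))
  # duplicated columns have identical F: name order decides
  Xd <- cbind(X[, 1], X[, 1], X[, 1])
  colnames(Xd) <- c("z_dup", "a_dup", "m_dup")
  expect_equal(as.character(select_features(Xd, y, 3)),
               c("a_dup", "m_dup", "z_dup"))
  expect_error(select_features(X, y, 5), "cannot select")
})

test_that("default grids enumerate the full tuning space", {
  expect_equal(nrow(default_grid("svm")), 2 * 7)
  expect_equal(nrow(default_grid("knn")), 6 * 2 * 4)
  expect_equal(nrow(default_grid("random_forest")), 3 * 2 * 4 * 3)
})

test_that("grid search solves separable data and ignores grid order", {
  withr::with_seed(23, {
    y <- factor(rep(basic_labels(), each = 40), levels = basic_labels())
    X <- matrix(rnorm(120 * 6), 120, 6)
    X[, 1] <- X[, 1] + c(0, 20, 40)[as.integer(y)]
    colnames(X) <- sprintf("f%d", 1:6)
  })
  cfg <- training_config(n_folds = 10, nf_max = 6, seed = 3,
                         group_by_trial = FALSE)
  gs <- grid_search(X, y, "svm", cfg = cfg)
  expect_equal(gs$n_eval, 14)
  expect_equal(gs$cv_accuracy, 1.0)
  # shuffling the grid rows changes neither winner nor score
  grid <- default_grid("svm")
  gs2 <- grid_search(X, y, "svm", grid = grid[sample(nrow(grid)), ],
                     cfg = cfg)
  expect_equal(gs2$best_params$kernel, gs$best_params$kernel)
  expect_equal(gs2$best_params$C, gs$best_params$C)
  expect_equal(gs2$cv_accuracy, gs$cv_accuracy)
})

test_that("grid search rejects classes too small for the folds", {
  y <- factor(rep(basic_labels(), c(5, 40, 40)), levels = basic_labels())
  X <- matrix(rnorm(85 * 3), 85, 3)
  colnames(X) <- c("a", "b", "c")
  expect_error(grid_search(X, y, "svm", cfg = training_config(n_folds = 10)),
               "configuration error")
})

test_that("the in-package kNN agrees with class::knn for uniform weights", {
  withr::with_seed(24, {
    Xtr <- matrix(rnorm(60 * 4), 60, 4)
    ytr <- factor(rep(basic_labels(), each = 20), levels = basic_labels())
    Xtr <- Xtr + c(0, 3, 6)[as.integer(ytr)]
    Xte <- matrix(rnorm(15 * 4), 15, 4) + 3
  })
  # oracle works in the same standardized space the implementation uses
  ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, sd)
  Ztr <- scale(Xtr, ctr, scl); Zte <- scale(Xte, ctr, scl)
  ref <- class::knn(Ztr, Zte, ytr, k = 3)
  mine <- propulse:::knn_predict(Xtr, ytr, Xte, k = 3, weights = "uniform")
  expect_equal(as.character(mine), as.character(ref))
  # distance weighting: a coincident training point decides the vote
  Xte1 <- Xtr[1, , drop = FALSE]
  pred <- propulse:::knn_predict(Xtr, ytr, Xte1, k = 5, weights = "distance")
  expect_equal(as.character(pred), as.character(ytr[1]))
})

test_that("train_side is deterministic and annotates its configuration", {
  corpus <- tiny_corpus()
  cfg <- training_config(n_folds = 5, seed = 9)
  grids <- list(svm = data.frame(kernel = "rbf", C = c(1, 10)))
  m1 <- train_side(corpus, "right", params = window_params(30, 5),
                   cfg = cfg, algos = "svm", grids = grids)
  m2 <- train_side(corpus, "right", params = window_params(30, 5),
                   cfg = cfg, algos = "svm", grids = grids)
  expect_equal(m1$cv_accuracy, m2$cv_accuracy)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(m1$selected_features, m2$selected_features)
  expect_equal(m1$window_params$w, 30)
  expect_equal(m1$window_params$s, 5)
  expect_lte(length(m1$selected_features), 30)
  # identical predictions on the training corpus
  ds <- build_dataset(corpus, "right", "two-sensor", window_params(30, 5),
                      seed = 9)
  expect_identical(predict_side(m1, ds$X), predict_side(m2, ds$X))
  expect_gte(m1$cv_accuracy, 0.9)
})

test_that("random forest hyperparameters map onto the backend faithfully", {
  expect_equal(propulse:::rf_mtry("sqrt", 30), 5)
  expect_equal(propulse:::rf_mtry("auto", 30), 5)   # deprecated alias
  expect_equal(propulse:::rf_mtry("log2", 30), 4)
  withr::with_seed(25, {
    y <- factor(rep(basic_labels(), each = 30), levels = basic_labels())
    X <- matrix(rnorm(90 * 5), 90, 5)
    X[, 2] <- X[, 2] + c(0, 4, 8)[as.integer(y)]
    colnames(X) <- sprintf("f%d", 1:5)
  })
  # both criterion values are fitted with Gini: identical models
  p1 <- data.frame(n_estimators = 50L, criterion = "gini", max_depth = 8L,
                   max_features = "sqrt")
  p2 <- p1; p2$criterion <- "entropy"
  f1 <- propulse:::fit_model("random_forest", p1, X, y, seed = 4)
  f2 <- propulse:::fit_model("random_forest", p2, X, y, seed = 4)
  expect_identical(propulse:::predict_model(f1, X),
                   propulse:::predict_model(f2, X))
})
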