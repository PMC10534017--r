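# Classifier backends (L2 logistic via quasi-Newton, RBF SVM with Platt
# probabilities, probability random forest) and the four model variants:
# PI (clinical only), R (handcrafted radiomics only), DL (frozen encoder
# features + sigmoid head trained with Adam on binary cross-entropy) and
# MFC (all blocks).

#' Classifier specification
#'
#' @param kind `"logistic"`, `"svm"` or `"forest"`.
#' @param lambda L2 penalty weight of the logistic model (intercept
#'   unpenalized), fitted with the L-BFGS-B quasi-Newton solver.
#' @param cost,tolerance RBF-SVM cost and numeric tolerance (default 1e-3);
#'   scores are Platt-calibrated probabilities.
#' @param n_trees,depth Random forest size and maximum tree depth;
#'   `depth = NULL` selects the depth by the train-vs-test sweep of
#'   [select_forest_depth()].
#' @param seed Seed for stochastic backends.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("logistic", "svm", "forest"),
                            lambda = 1.0, cost = 1.0, tolerance = 1e-3,
                            n_trees = 200L, depth = 8L, seed = 1L) {
  kind <- match.arg(kind)
  if (tolerance <= 0) stop("svm tolerance must be > 0")
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(kind = kind, lambda = lambda, cost = cost,
                 tolerance = tolerance, n_trees = as.integer(n_trees),
                 depth = depth, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Random-forest depth sweep
#'
#' Implements the stated tuning procedure: grow forests of increasing
#' maximum depth on an internal stratified 70/30 split and keep the largest
#' depth before the train/test performance diverges (test AUC drops while
#' train AUC keeps rising).
#'
#' @param X Feature matrix. @param y Binary labels.
#' @param depths Candidate depths, increasing.
#' @param n_trees Forest size.
#' @param seed Seed for the split and forests.
#' @return The selected depth.
#' @export
select_forest_depth <- function(X, y, depths = c(2L, 3L, 5L, 8L, 12L),
                                n_trees = 200L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) return(depths[length(depths)])
  split <- stratified_split(y, train_frac = 0.7, seed = seed)
  tr <- split$train; te <- split$test
  if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
    return(depths[length(depths)])
  train_auc <- test_auc <- numeric(length(depths))
  for (i in seq_along(depths)) {
    fit <- ranger::ranger(y = factor(y[tr], levels = c(0, 1)),
                          x = as.data.frame(X[tr, , drop = FALSE]),
                          probability = TRUE, num.trees = n_trees,
                          max.depth = depths[i], seed = seed,
                          num.threads = 1)
    ptr <- predict(fit, as.data.frame(X[tr, , drop = FALSE]),
                   num.threads = 1)$predictions[, "1"]
    pte <- predict(fit, as.data.frame(X[te, , drop = FALSE]),
                   num.threads = 1)$predictions[, "1"]
    train_auc[i] <- roc_metrics(ptr, y[tr])$auc
    test_auc[i] <- roc_metrics(pte, y[te])$auc
  }
  for (i in seq_along(depths)[-1]) {
    if (test_auc[i] < test_auc[i - 1] && train_auc[i] >= train_auc[i - 1])
      return(depths[i - 1])
  }
  depths[which.max(test_auc)]
}

#' Construct a classifier backend
#'
#' @param spec A [classifier_spec()].
#' @return An unfitted classifier object; fit with [fit_classifier()].
#' @export
make_classifier <- function(spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  structure(list(spec = spec), class = c(paste0("clf_", spec$kind),
                                         "mfc_classifier"))
}

#' Fit a classifier
#'
#' @param clf Object from [make_classifier()].
#' @param X Numeric feature matrix (rows = samples).
#' @param y Binary labels (0/1).
#' @return A fitted classifier.
#' @export
fit_classifier <- function(clf, X, y) UseMethod("fit_classifier")

#' Predict scores in `[0, 1]`
#'
#' @param fitted A fitted classifier (or fitted variant bundle).
#' @param X New feature matrix.
#' @return Numeric vector of scores, one per row.
#' @export
predict_scores <- function(fitted, X) UseMethod("predict_scores")

.check_two_classes <- function(y) {
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; cannot fit")
}

#' @export
fit_classifier.clf_logistic <- function(clf, X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  .check_two_classes(y)
  lambda <- clf$spec$lambda
  p <- ncol(X)
  negloglik <- function(par) {
    eta <- par[1] + X %*% par[-1]
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      0.5 * lambda * sum(par[-1]^2)
  }
  grad <- function(par) {
    eta <- drop(par[1] + X %*% par[-1])
    r <- stats::plogis(eta) - y
    c(sum(r), drop(crossprod(X, r)) + lambda * par[-1])
  }
  fit <- optim(numeric(p + 1), negloglik, grad, method = "L-BFGS-B",
               control = list(maxit = 200))
  clf$coef <- fit$par
  clf$feature_names <- colnames(X)
  class(clf) <- c("fitted_logistic", class(clf))
  clf
}

#' @export
predict_scores.fitted_logistic <- function(fitted, X) {
  X <- as.matrix(X)
  unname(drop(stats::plogis(fitted$coef[1] + X %*% fitted$coef[-1])))
}

#' @export
fit_classifier.clf_svm <- function(clf, X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  .check_two_classes(y)
  fit <- with_seed(clf$spec$seed,
    e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
               cost = clf$spec$cost, tolerance = clf$spec$tolerance,
               probability = TRUE, scale = FALSE))
  clf$model <- fit
  class(clf) <- c("fitted_svm", class(clf))
  clf
}

#' @export
predict_scores.fitted_svm <- function(fitted, X) {
  pr <- predict(fitted$model, as.matrix(X), probability = TRUE)
  unname(attr(pr, "probabilities")[, "1"])
}

#' @export
fit_classifier.clf_forest <- function(clf, X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  .check_two_classes(y)
  depth <- clf$spec$depth
  if (is.null(depth))
    depth <- select_forest_depth(X, y, n_trees = clf$spec$n_trees,
                                 seed = clf$spec$seed)
  fit <- ranger::ranger(y = factor(y, levels = c(0, 1)),
                        x = as.data.frame(X), probability = TRUE,
                        num.trees = clf$spec$n_trees, max.depth = depth,
                        seed = clf$spec$seed, num.threads = 1)
  clf$model <- fit
  clf$depth <- depth
  class(clf) <- c("fitted_forest", class(clf))
  clf
}

#' @export
predict_scores.fitted_forest <- function(fitted, X) {
  unname(predict(fitted$model, as.data.frame(as.matrix(X)),
                 num.threads = 1)$predictions[, "1"])
}

#' Train the sigmoid head of the DL variant
#'
#' A single fully connected layer with sigmoid activation on top of the
#' frozen encoder's 512 deep features, trained by minibatch Adam on binary
#' cross-entropy.
#'
#' @param X Deep feature matrix. @param y Binary labels.
#' @param epochs,lr,batch Training schedule.
#' @param seed Seed for initialization and batch shuffling.
#' @return A fitted head of class `fitted_dl_head`.
#' @export
train_dl_head <- function(X, y, epochs = 50L, lr = 1e-3, batch = 8L,
                          seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  mw <- vw <- numeric(p); mb <- vb <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch)) {
        rows <- ord[start:min(start + batch - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        r <- stats::plogis(drop(Xb %*% w) + b) - y[rows]
        gw <- drop(crossprod(Xb, r)) / length(rows)
        gb <- mean(r)
        t <- t + 1
        mw <- beta1 * mw + (1 - beta1) * gw
        vw <- beta2 * vw + (1 - beta2) * gw^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        w <- w - lr * (mw / (1 - beta1^t)) / (sqrt(vw / (1 - beta2^t)) + eps)
        b <- b - lr * (mb / (1 - beta1^t)) / (sqrt(vb / (1 - beta2^t)) + eps)
      }
    }
  })
  structure(list(w = w, b = b), class = "fitted_dl_head")
}

#' @export
predict_scores.fitted_dl_head <- function(fitted, X) {
  unname(drop(stats::plogis(as.matrix(X) %*% fitted$w + fitted$b)))
}

.variant_blocks <- list(PI = "clinical", R = "handcrafted", DL = "deep",
                        MFC = c("handcrafted", "deep", "clinical"))

#' Model variant specification
#'
#' The four comparison models: `PI` uses only the clinical block, `R` only
#' the handcrafted radiomics block, `DL` the frozen-encoder deep block with
#' a sigmoid head, and `MFC` all blocks.
#'
#' @param name `"PI"`, `"R"`, `"DL"` or `"MFC"`.
#' @param classifier A [classifier_spec()] (ignored by `DL`).
#' @param head For `DL`: list of head-training settings
#'   (`epochs`, `lr`, `batch`).
#' @return A list of class `model_variant`.
#' @export
model_variant <- function(name = c("MFC", "PI", "R", "DL"),
                          classifier = classifier_spec(),
                          head = list(epochs = 50L, lr = 1e-3, batch = 8L)) {
  name <- match.arg(name)
  structure(list(name = name, blocks = .variant_blocks[[name]],
                 classifier = classifier, head = head),
            class = "model_variant")
}

# columns of a feature table belonging to the variant's blocks
.variant_columns <- function(table, variant) {
  blocks <- attr(table, "blocks")
  if (is.null(blocks)) stop("feature table has no 'blocks' attribute")
  missing <- setdiff(variant$blocks, unique(blocks))
  if (length(missing))
    stop("variant ", variant$name, " requires missing block(s): ",
         paste(missing, collapse = ", "))
  names(blocks)[blocks %in% variant$blocks]
}

#' Train a model variant on selected rows
#'
#' Runs the full fold-local pipeline on the training rows: restrict to the
#' variant's blocks, multicollinearity reduction, z-score fit, Gaussian
#' oversampling, then classifier (or Adam sigmoid-head) fitting. All
#' preprocessing statistics come from the training rows only.
#'
#' @param variant A [model_variant()].
#' @param table Feature table from [assemble_feature_blocks()].
#' @param labels Binary labels aligned with the table rows.
#' @param train_idx Row indices of the training set.
#' @param config A [fusion_config()].
#' @param seed Fold seed (oversampling noise, stochastic backends).
#' @param reduce Apply multicollinearity reduction (default TRUE).
#' @return A fitted bundle usable with [predict_scores()].
#' @export
train_variant <- function(variant, table, labels, train_idx,
                          config = fusion_config(), seed = 1L,
                          reduce = TRUE) {
  stopifnot(inherits(variant, "model_variant"))
  labels <- as.integer(labels)
  .check_two_classes(labels[train_idx])
  cols <- .variant_columns(table, variant)
  Xtr <- as.matrix(table[train_idx, cols, drop = FALSE])

  kept <- cols
  if (reduce && ncol(Xtr) > 1L) {
    red <- multicollinearity_reduce(Xtr, labels[train_idx], config)
    kept <- red$keep
    Xtr <- Xtr[, kept, drop = FALSE]
  }
  norm <- zscore_normalize(Xtr)
  os <- gaussian_oversample(norm$train, labels[train_idx], config, seed = seed)

  if (variant$name == "DL") {
    h <- variant$head
    model <- train_dl_head(os$table, os$labels, epochs = h$epochs,
                           lr = h$lr, batch = h$batch, seed = seed)
  } else {
    spec <- variant$classifier
    spec$seed <- seed
    model <- fit_classifier(make_classifier(spec), os$table, os$labels)
  }
  structure(list(variant = variant, kept = kept, center = norm$center,
                 scale = norm$scale, constant = norm$constant, model = model),
            class = "fitted_variant")
}

#' @export
predict_scores.fitted_variant <- function(fitted, X) {
  missing <- setdiff(fitted$kept, colnames(X))
  if (length(missing))
    stop("test rows are missing feature column(s): ",
         paste(head(missing, 5), collapse = ", "))
  A <- as.matrix(X[, fitted$kept, drop = FALSE])
  A <- sweep(sweep(A, 2, fitted$center[fitted$kept]), 2,
             fitted$scale[fitted$kept], `/`)
  A[, fitted$constant[fitted$kept]] <- 0
  unname(predict_scores(fitted$model, A))
}
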