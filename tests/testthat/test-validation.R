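test_that("stratified 70% splits reproduce the published fold compositions", {
  surgery <- c(rep(0L, 76), rep(1L, 7))
  sp <- stratified_split(surgery, 0.7, seed = 3)
  expect_equal(sum(surgery[sp$train] == 0), 53)
  expect_equal(sum(surgery[sp$train] == 1), 5)

  sbrt <- c(rep(0L, 75), rep(1L, 9))
  sp2 <- stratified_split(sbrt, 0.7, seed = 3)
  expect_equal(sum(sbrt[sp2$train] == 0), 52)
  expect_equal(sum(sbrt[sp2$train] == 1), 6)

  expect_error(stratified_split(surgery, 1.0, seed = 1), "empty test")
  expect_error(stratified_split(rep(1L, 10), 0.7, seed = 1), "both classes")
  expect_setequal(c(sp$train, sp$test), seq_along(surgery))
})

test_that("ROC metrics match hand-enumerated cases and tie conventions", {
  # pos {0.9, 0.8}, neg {0.7, 0.85}: 3 concordant of 4 pairs
  r <- roc_metrics(c(0.9, 0.8, 0.7, 0.85), c(1, 1, 0, 0))
  expect_equal(r$auc, 0.75)
  # reversed perfect ranking
  expect_equal(roc_metrics(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc, 0)
  # constant scores: AUC 1/2 by the tie convention
  expect_equal(roc_metrics(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)
  # all scores above threshold
  r2 <- roc_metrics(c(0.9, 0.8, 0.7), c(1, 0, 1), threshold = 0.5)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0)
  expect_error(roc_metrics(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the concordance oracle on random score sets", {
  set.seed(13)
  for (trial in 1:200) {
    n <- sample(4:30, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    scores <- if (runif(1) < 0.5) round(runif(n), 1) else runif(n)
    expect_equal(roc_metrics(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  for (trial in 1:20) {
    n <- 30
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    scores <- round(runif(n), 1)
    expect_equal(roc_metrics(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

toy_cv_dataset <- function(n = 30, seed = 5, signal = 2.5) {
  set.seed(seed)
  ids <- sprintf("p%02d", 1:n)
  y <- c(rep(0L, n - 8), rep(1L, 8))
  hc <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, paste0("hc", 1:5)))
  hc[, 2] <- hc[, 2] + signal * y
  cl <- data.frame(gender = sample(0:1, n, TRUE), age = runif(n, 50, 90),
                   tumor_volume_cc = runif(n, 1, 5),
                   cci = sample(0:5, n, TRUE), row.names = ids)
  tab <- assemble_feature_blocks(handcrafted = hc, clinical = cl)
  list(table = tab, labels = y[match(rownames(tab), ids)])
}

test_that("leave-one-out tests every sample once and finds planted signal", {
  ds <- toy_cv_dataset()
  res <- run_loocv(ds$table, ds$labels, model_variant("R"),
                   fusion_config(multiplicity = 1, noise_fraction = 0),
                   seed = 1)
  expect_equal(res$n_folds, nrow(ds$table))
  expect_length(res$scores, nrow(ds$table))
  expect_gt(res$auc, 0.8)
})

test_that("Monte-Carlo validation is deterministic and aggregates folds", {
  ds <- toy_cv_dataset()
  v <- model_variant("R")
  cfg <- fusion_config(multiplicity = 1, noise_fraction = 0)
  r1 <- run_mcrv(ds$table, ds$labels, v, n_folds = 8, seed = 4, config = cfg)
  r2 <- run_mcrv(ds$table, ds$labels, v, n_folds = 8, seed = 4, config = cfg)
  expect_identical(r1$per_fold$auc, r2$per_fold$auc)
  expect_equal(nrow(r1$per_fold), 8)
  expect_equal(unname(r1$mean["auc"]), mean(r1$per_fold$auc))
  expect_equal(nrow(r1$mean_roc), 101)
  expect_true(all(r1$mean_roc$tpr >= 0 & r1$mean_roc$tpr <= 1))
  r3 <- run_mcrv(ds$table, ds$labels, v, n_folds = 8, seed = 5, config = cfg)
  expect_false(identical(r1$per_fold$auc, r3$per_fold$auc))
})

test_that("model comparison t-test behaves on degenerate and shifted inputs", {
  a <- runif(100, 0.6, 0.9)
  same <- compare_models_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  shift <- compare_models_ttest(a, a - 0.1)
  expect_lt(shift$p, 0.05)
  expect_true(shift$significant)
  expect_error(compare_models_ttest(a[1], a[1]), "at least 2")
  expect_error(compare_models_ttest(a, a[1:50]), "equal-length")
  # two-sample mode tolerates different lengths
  two <- compare_models_ttest(a, runif(50, 0.1, 0.2), paired = FALSE)
  expect_true(two$significant)
})

test_that("fold-local preprocessing blocks the leakage sentinel", {
  # a feature equal to the label on held-out rows only (noise on training
  # rows of every fold) must not lift AUC above the null band
  set.seed(31)
  n <- 40
  ids <- sprintf("p%02d", 1:n)
  y <- c(rep(0L, 30), rep(1L, 10))
  hc <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, paste0("hc", 1:4)))
  cl <- data.frame(gender = sample(0:1, n, TRUE), age = runif(n, 50, 90),
                   tumor_volume_cc = runif(n, 1, 5),
                   cci = sample(0:5, n, TRUE), row.names = ids)
  cfg <- fusion_config(multiplicity = 1, noise_fraction = 0)
  v <- model_variant("R", classifier_spec("logistic"))

  n_folds <- 12
  base <- run_mcrv(assemble_feature_blocks(handcrafted = hc, clinical = cl),
                   y, v, n_folds = n_folds, seed = 2, config = cfg)
  aucs <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    fold_seed <- 2 + k
    sp <- stratified_split(y, 0.7, seed = fold_seed)
    sentinel <- rnorm(n)
    sentinel[sp$test] <- y[sp$test]   # informative on test rows only
    hc2 <- cbind(hc, hc5 = sentinel)
    tab <- assemble_feature_blocks(handcrafted = hc2, clinical = cl)
    fit <- train_variant(v, tab, y, sp$train, cfg, seed = fold_seed)
    sc <- predict_scores(fit, tab[sp$test, , drop = FALSE])
    aucs[k] <- roc_metrics(sc, y[sp$test])$auc
  }
  # exploiting the sentinel (a verbatim label copy) would push toward 1
  expect_lt(mean(aucs), mean(base$per_fold$auc) + 0.1)
  expect_lt(mean(aucs), 0.9)
})

test_that("reports write the expected tables and figure", {
  ds <- toy_cv_dataset()
  cfg <- fusion_config(multiplicity = 1, noise_fraction = 0)
  res <- list(
    "MFC (LR)" = run_mcrv(ds$table, ds$labels, model_variant("R"),
                          n_folds = 5, seed = 1, config = cfg),
    "PI (LR)" = run_mcrv(ds$table, ds$labels, model_variant("PI"),
                         n_folds = 5, seed = 1, config = cfg)
  )
  dir <- withr::local_tempdir()
  paths <- render_report(res, dir)
  tab <- read.csv(paths$metrics, check.names = FALSE)
  expect_equal(tab$metric, c("auc", "sensitivity", "specificity", "accuracy"))
  expect_equal(ncol(tab), 3)
  expect_true(all(grepl("\\d\\.\\d{3} ± \\d\\.\\d{3}", tab[["MFC (LR)"]])))
  pv <- read.csv(paths$p_values)
  expect_equal(nrow(pv), 1)
  expect_true(file.exists(paths$roc))
})
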