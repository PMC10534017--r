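make_table <- function(n = 20, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  X
}

test_that("z-score fit gives mean 0 / SD 1 and reuses training statistics", {
  X <- make_table(30, 4)
  hold <- make_table(5, 4, seed = 2)
  z <- zscore_normalize(X, hold)
  expect_lt(max(abs(colMeans(z$train))), 1e-9)
  expect_lt(max(abs(apply(z$train, 2, sd) - 1)), 1e-9)
  # held-out row equal to the training mean maps to 0
  row <- matrix(z$center, 1, dimnames = list("m", names(z$center)))
  expect_lt(max(abs(zscore_normalize(X, row)$apply)), 1e-12)
  # constant features flagged and zeroed
  Xc <- cbind(X, const = 5)
  zc <- zscore_normalize(Xc)
  expect_true(zc$constant["const"])
  expect_true(all(zc$train[, "const"] == 0))
})

test_that("oversampling multiplies rows, balances classes and adds calibrated noise", {
  X <- make_table(10, 3)
  y <- c(rep(0, 8), rep(1, 2))
  cfg <- fusion_config(multiplicity = 3, noise_fraction = 0, balance = FALSE)
  os <- gaussian_oversample(X, y, cfg, seed = 1)
  expect_equal(nrow(os$table), 30)
  expect_equal(sum(os$labels == 1), 6)
  expect_true(all(duplicated(os$table)[seq(2, 30, by = 3)]))  # exact copies

  bal <- gaussian_oversample(X, y, fusion_config(multiplicity = 1,
                                                 noise_fraction = 0),
                             seed = 1)
  expect_equal(sum(bal$labels == 1), sum(bal$labels == 0))

  # noisy copies center on the original row (CLT bound)
  one <- X[1, , drop = FALSE]
  Xrep <- X  # SD computed from the full table
  cfg2 <- fusion_config(multiplicity = 2, noise_fraction = 0.2,
                        balance = FALSE)
  reps <- 2000
  acc <- matrix(0, reps, 3)
  sds <- apply(X, 2, sd)
  for (i in seq_len(reps)) {
    os2 <- gaussian_oversample(X, y, cfg2, seed = 1000 + i)
    acc[i, ] <- os2$table[2, ]  # noisy copy of row 1
  }
  expect_true(all(abs(colMeans(acc) - X[1, ]) <
                    4 * 0.2 * sds / sqrt(reps)))
})

test_that("multicollinearity reduction keeps one representative per correlated subset", {
  set.seed(3)
  n <- 40
  A <- rnorm(n)
  B <- A + rnorm(n, sd = 0.01)   # |r| > 0.99
  C <- rnorm(n)                  # independent
  y <- as.integer(A + rnorm(n, sd = 0.5) > 0)
  X <- cbind(A = A, B = B, C = C)
  red <- multicollinearity_reduce(X, y, fusion_config())
  expect_length(red$keep, 2)
  expect_true("C" %in% red$keep)
  expect_true(any(c("A", "B") %in% red$keep))
  expect_equal(length(red$subsets), 1)

  # identical columns: exactly one kept
  X2 <- cbind(a = A, b = A)
  red2 <- multicollinearity_reduce(X2, y, fusion_config())
  expect_length(red2$keep, 1)

  # no correlation above threshold: everything kept, in order
  X3 <- make_table(50, 6, seed = 9)
  red3 <- multicollinearity_reduce(X3, sample(0:1, 50, TRUE), fusion_config())
  expect_identical(red3$keep, colnames(X3))

  # constant feature: kept and flagged
  X4 <- cbind(X, k = 1)
  red4 <- multicollinearity_reduce(X4, y, fusion_config())
  expect_true("k" %in% red4$keep)
  expect_identical(red4$constant_features, "k")
})

test_that("reduction matches exhaustive enumeration on random tables", {
  set.seed(11)
  thr <- 0.95
  for (trial in 1:40) {
    n <- 25; p <- 10
    base <- matrix(rnorm(n * 4), n, 4)
    X <- sapply(1:p, function(j) {
      src <- sample(1:4, 1)
      if (runif(1) < 0.5) base[, src] + rnorm(n, sd = 0.005)
      else rnorm(n)
    })
    colnames(X) <- paste0("f", 1:p)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    red <- multicollinearity_reduce(X, y, fusion_config())

    # oracle: explicit component growth + min-p representative
    C <- abs(cor(X))
    adj <- C > thr; diag(adj) <- FALSE
    comp <- rep(NA_integer_, p); cid <- 0
    for (s in 1:p) {
      if (!is.na(comp[s])) next
      cid <- cid + 1; frontier <- s; comp[s] <- cid
      while (length(frontier)) {
        nxt <- which(adj[frontier[1], ] & is.na(comp))
        comp[nxt] <- cid
        frontier <- c(frontier[-1], nxt)
      }
    }
    pv <- apply(X, 2, function(x)
      wilcox.test(x[y == 1], x[y == 0], exact = FALSE)$p.value)
    want <- sort(vapply(unique(comp), function(cc) {
      members <- which(comp == cc)
      members[which.min(pv[members])]
    }, integer(1)))
    expect_identical(red$keep, colnames(X)[want])
  }
})

test_that("reduction is idempotent and monotone in the threshold", {
  set.seed(21)
  X <- make_table(30, 8)
  X[, 2] <- X[, 1] + rnorm(30, sd = 0.01)
  X[, 5] <- -X[, 4] + rnorm(30, sd = 0.01)  # strong negative correlation
  y <- sample(0:1, 30, replace = TRUE)
  red <- multicollinearity_reduce(X, y, fusion_config())
  again <- multicollinearity_reduce(X[, red$keep], y, fusion_config())
  expect_identical(again$keep, red$keep)
  # negative correlation is treated by magnitude
  expect_false(all(c("f4", "f5") %in% red$keep))
  # lowering the threshold cannot increase the kept count
  for (thr in c(0.999, 0.99, 0.95, 0.8, 0.5)) {
    k <- length(multicollinearity_reduce(
      X, y, fusion_config(corr_threshold = thr))$keep)
    if (exists("prev_k")) expect_lte(k, prev_k)
    prev_k <- k
  }
})

test_that("block assembly orders columns, checks ids and counts match the design", {
  n <- 6
  ids <- sprintf("p%d", 1:n)
  hc <- matrix(rnorm(n * 105), n, 105,
               dimnames = list(ids, handcrafted_feature_names()))
  dp <- matrix(rnorm(n * 512), n, 512,
               dimnames = list(ids, sprintf("deep__f%03d", 1:512)))
  man <- data.frame(id = ids, cohort = "surgery", gender = 1, age = 70,
                    tumor_volume_cc = 2, cci = 3, dose_gy = NA,
                    n_fractions = NA, label = rep(c(0, 1), 3))
  tab <- assemble_feature_blocks(hc, dp, clinical_block(man))
  expect_equal(ncol(tab), 105 + 512 + 4)
  blocks <- attr(tab, "blocks")
  expect_equal(as.integer(table(blocks)[c("handcrafted", "deep", "clinical")]),
               c(105L, 512L, 4L))
  expect_identical(unname(blocks), rep(c("handcrafted", "deep", "clinical"),
                                       c(105, 512, 4)))

  man_sbrt <- man; man_sbrt$cohort <- "sbrt"
  man_sbrt$dose_gy <- 50; man_sbrt$n_fractions <- 5
  tab2 <- assemble_feature_blocks(hc, dp, clinical_block(man_sbrt))
  expect_equal(ncol(tab2), 623)

  # row order does not matter after id alignment
  tab3 <- assemble_feature_blocks(hc[n:1, ], dp, clinical_block(man))
  expect_equal(tab3, tab, ignore_attr = TRUE)

  bad <- hc; rownames(bad)[1] <- "zz"
  expect_error(assemble_feature_blocks(bad, dp, clinical_block(man)), "zz")
})
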