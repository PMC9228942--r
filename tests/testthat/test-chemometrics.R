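# PCA, PLS-DA, VIP, LDA thresholding, LOPO cross-validation, confusion
# metrics, and pixel classification.

test_that("PCA recovers the diagonal direction of two points", {
  x <- rbind(c(-1, -1), c(1, 1))
  m <- msi_pca(x, n_components = 1)
  expect_equal(abs(m$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(m$explained[1], 1, tolerance = 1e-12)
  # sign convention: the largest-magnitude loading element is positive
  expect_gt(max(m$loadings[, 1]), 0)
})

test_that("PCA matches a dense eigendecomposition and centers scores", {
  set.seed(21)
  x <- matrix(rnorm(60), 10, 6)
  m <- msi_pca(x, n_components = 5)
  xs <- apply_autoscale(x, m$scaling)
  eig <- eigen(cov(xs), symmetric = TRUE)
  for (j in 1:5) {
    v <- eig$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(m$loadings[, j], v, tolerance = 1e-8)
  }
  expect_equal(m$explained, eig$values[1:5] / sum(eig$values),
               tolerance = 1e-8)
  expect_equal(colMeans(m$scores), rep(0, 5), tolerance = 1e-9)
  expect_equal(crossprod(m$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(msi_pca(x, n_components = 10), "n_components")
})

test_that("score maps are centered and deterministic", {
  set.seed(22)
  obj <- toy_objects(matrix(rnorm(40), 8, 5),
                     rep(c("pathological", "healthy"), 4))
  m <- msi_pca(obj, n_components = 2)
  # a pixel equal to the training mean spectrum scores 0 on every component
  mean_px <- matrix(m$scaling$mean, 2, 5, byrow = TRUE)
  mat <- toy_matrix(mean_px)
  sm <- score_map(m, mat, 1)
  expect_equal(sm$score, c(0, 0), tolerance = 1e-12)
  # duplicate pixels give identical scores
  dup <- toy_matrix(matrix(rnorm(5), 2, 5, byrow = FALSE) * 0 +
                      matrix(rep(rnorm(5), each = 2), 2, 5))
  sm2 <- score_map(m, dup, 2)
  expect_equal(sm2$score[1], sm2$score[2])
  expect_error(score_map(m, toy_matrix(matrix(0, 2, 3)), 1),
               "variable count")
})

test_that("PLS-DA separates a 1-D ordered class perfectly with 1 LV", {
  obj <- toy_objects(matrix(c(1, 2, 3, 11, 12, 13), 6, 1),
                     rep(c("pathological", "healthy"), each = 3))
  m <- plsda(obj, n_lv = 1)
  pred <- predict(m, obj)
  expect_equal(pred$class, obj$class_label)
})

test_that("full-rank PLS equals least squares and scores are orthogonal", {
  set.seed(23)
  n <- 12; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  cls <- rep(c("pathological", "healthy"), each = n / 2)
  obj <- toy_objects(x, cls)
  m <- plsda(obj, n_lv = p)
  expect_equal(m$n_lv, p)
  pred <- predict(m, obj)$yhat

  xs <- apply_autoscale(x, m$scaling)
  y <- as.numeric(cls == "healthy")
  ols <- lm.fit(cbind(1, xs), y)
  expect_equal(pred, as.numeric(cbind(1, xs) %*% ols$coefficients),
               tolerance = 1e-8)

  # NIPALS deflation yields mutually orthogonal score vectors
  # (T = X W (P'W)^{-1} reconstructs the scores from the stored loadings)
  scores <- xs %*% m$W %*% solve(crossprod(m$P, m$W))
  g <- crossprod(scores)
  expect_equal(g - diag(diag(g)), matrix(0, p, p), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(plsda(toy_objects(x, rep("healthy", n)), 2),
               "both classes")
})

test_that("PLS with 1 LV ranks variables like |correlation with y|", {
  set.seed(24)
  n <- 30; p <- 8
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c(0, 1), each = n / 2)
  x[, 3] <- x[, 3] + 2 * y
  x[, 6] <- x[, 6] - 1 * y
  obj <- toy_objects(x, ifelse(y == 1, "healthy", "pathological"))
  m <- plsda(obj, n_lv = 1)
  xs <- apply_autoscale(x, m$scaling)
  r <- abs(as.numeric(cor(xs, y)))
  expect_equal(order(-abs(m$W[, 1])), order(-r))
})

test_that("the LDA threshold is the class-mean midpoint, affine-equivariant", {
  lab <- rep(c("pathological", "healthy"), each = 4)
  yhat <- c(-0.1, 0.1, 0, 0, 0.9, 1.1, 1, 1)
  l <- lda_threshold(yhat, lab)
  expect_equal(l$boundary, 0.5)
  l2 <- lda_threshold(3 * yhat + 2, lab)
  expect_equal(l2$boundary, 3 * 0.5 + 2)

  # grid oracle: the midpoint maximizes training accuracy for these data
  grid <- seq(-0.5, 1.5, by = 0.001)
  acc <- vapply(grid, function(g) mean((yhat > g) == (lab == "healthy")),
                numeric(1))
  expect_equal(mean((yhat > l$boundary) == (lab == "healthy")), max(acc))

  expect_error(lda_threshold(rep(1, 8), lab), "degenerate")
})

test_that("VIP identities hold on fitted models", {
  set.seed(25)
  x <- matrix(rnorm(100), 20, 5)
  obj <- toy_objects(x, rep(c("pathological", "healthy"), 10))
  m <- plsda(obj, n_lv = 3)
  expect_equal(sum(m$vip^2), 5, tolerance = 1e-6)
  expect_true(all(m$vip >= 0))

  # single-variable model: VIP is exactly 1
  m1 <- plsda(toy_objects(matrix(c(1:5, 11:15), 10, 1),
                          rep(c("pathological", "healthy"), each = 5)), 1)
  expect_equal(m1$vip, 1, tolerance = 1e-12)

  # a constant variable carries zero weight and zero VIP
  xz <- cbind(x, 7)
  mz <- plsda(toy_objects(xz, rep(c("pathological", "healthy"), 10)), 3)
  expect_equal(mz$vip[6], 0, tolerance = 1e-10)

  expect_equal(select_vip(m, threshold = 0), seq_len(5))
  expect_warning(sel <- select_vip(m, threshold = 99), "VIP threshold")
  expect_length(sel, 0)
})

test_that("LOPO CV bookkeeping: P folds, 2 held-out objects each, no leaks", {
  set.seed(26)
  P <- 5
  x <- matrix(rnorm(2 * P * 6), 2 * P, 6)
  x[, 1] <- x[, 1] + 4 * rep(c(0, 1), P)
  obj <- toy_objects(x, rep(c("pathological", "healthy"), P),
                     patient_id = rep(sprintf("pat%d", 1:P), each = 2))
  cv <- lopo_cv(obj, max_lv = 3)
  f1 <- cv$folds[cv$folds$n_lv == 1, ]
  expect_equal(nrow(f1), 2 * P)
  expect_equal(sort(unique(f1$patient_id)), sprintf("pat%d", 1:P))
  expect_equal(unname(table(f1$patient_id)), rep(2L, P), ignore_attr = TRUE)

  # ties in CV accuracy resolve to the smallest component count
  best <- max(cv$metrics$accuracy_cv)
  expect_equal(cv$optimal_nlv,
               min(cv$metrics$n_lv[cv$metrics$accuracy_cv == best]))

  bad <- obj
  bad$class_label[2] <- "pathological"
  expect_error(lopo_cv(bad, 2), "lacks both class")
  expect_error(lopo_cv(obj[obj$patient_id %in% c("pat1", "pat2"), ], 2),
               "at least 3 patients")
})

test_that("confusion metrics match hand arithmetic and flag degeneracies", {
  perfect <- list(TP = 7, TN = 7, FP = 0, FN = 0)
  expect_equal(unlist(confusion_metrics(perfect)), c(accuracy = 100,
                                                     sensitivity = 100,
                                                     specificity = 100))
  one_fp <- list(TP = 7, TN = 6, FP = 1, FN = 0)
  m <- confusion_metrics(one_fp)
  expect_equal(m$accuracy, 100 * 13 / 14)
  expect_equal(m$specificity, 100 * 6 / 7)
  expect_equal(m$sensitivity, 100)

  expect_warning(nd <- confusion_metrics(list(TP = 0, TN = 3, FP = 1,
                                              FN = 0)),
                 "sensitivity undefined")
  expect_true(is.nan(nd$sensitivity))
  expect_error(confusion_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "empty")

  cm <- confusion_counts(c("healthy", "healthy", "pathological"),
                         c("healthy", "pathological", "pathological"))
  expect_equal(unlist(cm), c(TP = 1L, TN = 1L, FP = 0L, FN = 1L))
})

test_that("pixel classification percent agrees with a brute-force recount", {
  set.seed(27)
  n <- 16; p <- 4
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + 3 * rep(c(0, 1), each = n / 2)
  obj <- toy_objects(x, rep(c("pathological", "healthy"), each = n / 2))
  m <- plsda(obj, n_lv = 2)

  # image whose pixels replicate a correctly classified training object
  px <- matrix(rep(x[n, ], each = 6), 6, p)
  mat <- toy_matrix(px)
  pc <- classify_pixels(m, mat, "healthy")
  expect_equal(pc$percent_correct, 100)

  set.seed(28)
  mixed <- toy_matrix(matrix(rnorm(10 * p), 10, p))
  pcm <- classify_pixels(m, mixed, "healthy", n_lv = 2)
  recount <- 100 * mean(predict(m, mixed$values, n_lv = 2)$class == "healthy")
  expect_equal(pcm$percent_correct, recount)

  # background pixels are no-calls and excluded from the denominator
  lbl <- toy_matrix(px, label = c(rep("tumor", 4), "background",
                                  "background"))
  pcb <- classify_pixels(m, lbl, "healthy")
  expect_equal(sum(is.na(pcb$map$class)), 2)
  expect_equal(pcb$percent_correct, 100)
})
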