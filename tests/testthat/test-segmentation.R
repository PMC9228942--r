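# Bisecting k-means, cluster masks, Pearson correlation, colocalization.

make_clouds <- function(n1 = 12, n2 = 9, sep = 50, seed = 31) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * 3), n1, 3),
             matrix(rnorm(n2 * 3), n2, 3) + sep)
  toy_matrix(x - min(x))
}

test_that("a split never increases the summed within-cluster scatter", {
  mat <- make_clouds(6, 6, sep = 4, seed = 30)
  seg <- bisecting_kmeans(mat, k = 2)
  parent <- seg$nodes$wcss[seg$nodes$node == 1]
  children <- sum(seg$nodes$wcss[!is.na(seg$nodes$parent)])
  expect_gte(parent, children - 1e-9)
})

test_that("well-separated clouds split exactly at k = 2", {
  mat <- make_clouds()
  seg <- bisecting_kmeans(mat, k = 2)
  cl <- seg$labels$cluster
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:12])), 1)
  expect_equal(length(unique(cl[13:21])), 1)
  expect_true(cl[1] != cl[13])
})

test_that("k = 1 yields one leaf holding the total scatter", {
  mat <- make_clouds()
  seg <- bisecting_kmeans(mat, k = 1)
  expect_equal(unique(seg$labels$cluster), 1L)
  scatter <- sum(sweep(mat$values, 2, colMeans(mat$values))^2)
  expect_equal(seg$total_wcss, scatter)
  expect_error(bisecting_kmeans(mat, k = 100), "exceeds")
})

test_that("k = 2 matches the exhaustive minimum-WCSS 2-partition", {
  set.seed(32)
  for (trial in 1:4) {
    n <- 8
    vals <- matrix(rnorm(n * 2, 5, 2), n, 2)
    mat <- toy_matrix(vals - min(vals))
    seg <- bisecting_kmeans(mat, k = 2)
    got <- sum(vapply(1:2, function(c) {
      sub <- mat$values[seg$labels$cluster == c, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
    # brute force over all 2^(n-1)-1 bipartitions
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
      a <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
      w <- sum(sweep(mat$values[a, , drop = FALSE], 2,
                     colMeans(mat$values[a, , drop = FALSE]))^2) +
        sum(sweep(mat$values[!a, , drop = FALSE], 2,
                  colMeans(mat$values[!a, , drop = FALSE]))^2)
      best <- min(best, w)
    }
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("total WCSS is non-increasing in k; masks complement", {
  mat <- make_clouds(n1 = 15, n2 = 15, sep = 3, seed = 33)
  w <- vapply(1:4, function(k) bisecting_kmeans(mat, k)$total_wcss,
              numeric(1))
  expect_true(all(diff(w) <= 1e-9))

  seg <- bisecting_kmeans(mat, k = 2)
  m1 <- cluster_mask(seg, 1)
  m2 <- cluster_mask(seg, 2)
  expect_equal(m1$mask + m2$mask, rep(1, 30))
  expect_error(cluster_mask(seg, 9), "not a leaf")

  segk1 <- bisecting_kmeans(mat, k = 1)
  expect_equal(cluster_mask(segk1, 1)$mask, rep(1, 30))
})

test_that("segmentation is invariant to pixel order and constant shifts", {
  mat <- make_clouds(seed = 34)
  seg <- bisecting_kmeans(mat, k = 2)

  perm <- sample(nrow(mat$values))
  matp <- msiclass:::new_msi_matrix(mat$values[perm, ],
                                    mat$index[perm, ], mat$mz)
  segp <- bisecting_kmeans(matp, k = 2)
  key <- paste(seg$labels$x, seg$labels$y)
  keyp <- paste(segp$labels$x, segp$labels$y)
  a <- seg$labels$cluster
  b <- segp$labels$cluster[match(key, keyp)]
  expect_true(all(a == b) || all(a == 3 - b))

  mats <- msiclass:::new_msi_matrix(mat$values + 7, mat$index, mat$mz)
  segs <- bisecting_kmeans(mats, k = 2)
  expect_true(all(seg$labels$cluster == segs$labels$cluster) ||
                all(seg$labels$cluster == 3 - segs$labels$cluster))
})

test_that("pearson matches cor() and flags constant input", {
  expect_equal(pearson(1:10, 1:10), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  set.seed(35)
  for (i in 1:5) {
    x <- rnorm(40); y <- rnorm(40)
    expect_equal(pearson(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_warning(r <- pearson(rep(1, 5), 1:5), "constant")
  expect_true(is.nan(r))
})

test_that("colocalization reports mask-aligned variables only", {
  set.seed(36)
  n <- 200
  mask01 <- rep(c(1, 0), each = n / 2)
  vals <- cbind(mask01 * 10 + 1,          # equals the mask -> r = 1
                rnorm(n))                 # independent noise
  mat <- toy_matrix(vals - min(vals))
  mask <- tibble::tibble(x = mat$index$x, y = mat$index$y, mask = mask01)
  hits <- colocalize(mat, mask, r_min = 0.5)
  expect_equal(hits$mz[1], mat$mz[1])
  expect_equal(hits$r[1], 1, tolerance = 1e-12)
  expect_false(mat$mz[2] %in% hits$mz)
  expect_true(all(diff(hits$r) <= 0))
})

test_that("a separated two-region image is recovered with high Dice", {
  cfg <- phantom_config(n_patients = 1L, grid = c(16L, 16L),
                        n_variables = 120L, n_discriminant = 10L,
                        fold_change = 3, noise_sd = 0.05,
                        tic_variation_cv = 0.1, patient_effect_sd = 0.1,
                        seed = 5)
  ph <- generate_phantom(cfg)
  mat <- preprocess(ph$images, preprocess_config(), masks = ph$masks)
  id <- "P01_pathological"
  seg <- bisecting_kmeans(subset_image(mat, id), k = 2)
  truth <- ph$masks[[id]]
  tt <- truth$label[match(paste(seg$labels$x, seg$labels$y),
                          paste(truth$x, truth$y))] == "tumor"
  d <- max(dice_coef(seg$labels$cluster == 1, tt),
           dice_coef(seg$labels$cluster == 2, tt))
  expect_gte(d, 0.95)
})
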