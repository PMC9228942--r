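# The preprocessing chain: normalization, baselines, binning, gating,
# filtering, log transform, auto-scaling.

test_that("TIC normalization equalizes row sums at the dataset mean", {
  m <- toy_matrix(rbind(c(1, 1), c(2, 2)))  # sums 2 and 4
  out <- normalize_tic(m)
  expect_equal(rowSums(out$values), c(3, 3))

  mz <- toy_matrix(rbind(c(1, 1), c(0, 0)))
  outz <- normalize_tic(mz)
  expect_equal(outz$values[2, ], c(0, 0))
  expect_equal(outz$flags$zero_rows, 2L)

  set.seed(3)
  mr <- toy_matrix(matrix(rexp(200), 20, 10))
  outr <- normalize_tic(mr)
  target <- mean(rowSums(mr$values))
  expect_equal(rowSums(outr$values) / target, rep(1, 20), tolerance = 1e-9)
})

test_that("RMS normalization equalizes per-row root mean square", {
  m <- toy_matrix(rbind(c(3, 4), c(3, 4)))
  out <- normalize_rms(m)
  # identical rows are a fixed point
  expect_equal(out$values, m$values)

  set.seed(4)
  mr <- toy_matrix(matrix(rexp(120), 12, 10))
  outr <- normalize_rms(mr)
  rms <- apply(outr$values, 1, function(v) sqrt(mean(v^2)))
  expect_equal(rms, rep(mean(apply(mr$values, 1, function(v)
    sqrt(mean(v^2)))), 12), tolerance = 1e-9)
})

test_that("top-hat baseline removal matches a naive sliding-window oracle", {
  expect_equal(tophat_baseline(rep(5, 100), sigma = 10), rep(0, 100))

  spike <- numeric(100); spike[50] <- 7
  expect_equal(tophat_baseline(spike, sigma = 20), spike)

  # Gaussian peaks on a linear ramp vs brute-force erosion/dilation
  n <- 300; s <- 15
  x <- seq_len(n)
  y <- 0.05 * x + 10 * exp(-(x - 80)^2 / 18) + 6 * exp(-(x - 200)^2 / 50)
  win <- function(i) max(1, i - s):min(n, i + s)
  ero <- vapply(x, function(i) min(y[win(i)]), numeric(1))
  opening <- vapply(x, function(i) max(ero[win(i)]), numeric(1))
  expect_equal(tophat_baseline(y, sigma = s), y - opening, tolerance = 1e-12)

  expect_error(tophat_baseline(1:10, sigma = 20), "larger than the spectrum")
})

test_that("AsLS agrees with a dense solver and removes smooth drift", {
  expect_equal(asls_baseline(numeric(50))$baseline, numeric(50))

  set.seed(5)
  n <- 200
  y <- 3 * exp(-(1:n - 60)^2 / 40) + exp(-(1:n) / 80) + abs(rnorm(n, 0, .02))
  got <- asls_baseline(y, p = 0.01, lambda = 1e4, iterations = 10)
  ref <- asls_dense_reference(y, p = 0.01, lambda = 1e4, iterations = 10)
  expect_equal(got$baseline, ref, tolerance = 1e-8)

  # a pure quadratic with no peaks is absorbed into the baseline (the
  # second-difference penalty only forces z toward a straight line as
  # lambda grows, so curvature tracking needs a moderate penalty)
  q <- (seq(-1, 1, length.out = 400))^2 * 50
  corr <- asls_baseline(q, p = 0.005, lambda = 1e2, iterations = 20)$corrected
  expect_lt(max(abs(corr)), 0.01 * diff(range(q)))

  expect_error(asls_baseline(c(1, NA, 3)), "non-finite")
})

test_that("AsLS drift recovery on a planted exponential baseline", {
  set.seed(6)
  n <- 500
  drift <- 20 * exp(-(1:n) / 150)
  peaks <- numeric(n)
  at <- seq(20, 480, by = 40)
  peaks[at] <- 100
  y <- drift + peaks
  fit <- asls_baseline(y, p = 0.005, lambda = 1e4, iterations = 20)
  off <- setdiff(1:n, at)
  # baseline tracks the planted drift off-peak within 2.5% of its amplitude
  expect_lt(max(abs(fit$baseline[off] - drift[off])), 0.5)
})

test_that("binning uses half-open max-in-bin semantics on a fixed grid", {
  img <- msi_image(matrix(c(2, 5), 1, 2), c(100.05, 100.15),
                   data.frame(x = 0L, y = 0L), "one",
                   mz_range = c(100, 100.2))
  out <- bin_peaks(list(img), bandwidth = 0.2)[[1]]
  expect_equal(length(out$mz), 1)
  expect_equal(as.numeric(out$intensities), 5)
  expect_equal(out$mz, 100.1)

  # a point exactly on a bin edge goes to the upper bin
  img2 <- msi_image(matrix(c(1, 9), 1, 2), c(100.05, 100.2),
                    data.frame(x = 0L, y = 0L), "edge",
                    mz_range = c(100, 100.4))
  out2 <- bin_peaks(list(img2), bandwidth = 0.2)[[1]]
  expect_equal(out2$mz, c(100.1, 100.3))
  expect_equal(as.numeric(out2$intensities), c(1, 9))

  # output variable count never exceeds ceil(range / bandwidth)
  img3 <- small_image(nchan = 50)
  out3 <- bin_peaks(list(img3), bandwidth = 0.7)[[1]]
  expect_lte(length(out3$mz), ceiling(diff(img3$mz_range) / 0.7) + 1)
})

test_that("jittered processed-mode axes bin like the unjittered truth", {
  # peaks sit on bin centers; per-pixel jitter below bandwidth/2 cannot
  # move a point out of its bin
  set.seed(2)
  n <- 4; nchan <- 10
  centers <- 100 + (seq_len(nchan) * 7 - 0.5) * 0.2  # every 7th bin center
  coords <- data.frame(x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L))
  vals <- matrix(runif(n * nchan, 1, 10), n, nchan)
  clean <- msi_image(vals, centers, coords, "clean",
                     mz_range = c(100, 100 + 0.2 * (7 * nchan + 1)))
  jit <- msi_image(lapply(seq_len(n), function(i) vals[i, ]),
                   lapply(seq_len(n), function(i)
                     centers + runif(nchan, -0.09, 0.09)),
                   coords, "jit",
                   mz_range = c(100, 100 + 0.2 * (7 * nchan + 1)))
  b1 <- unfold(bin_peaks(list(clean), 0.2))
  b2 <- unfold(bin_peaks(list(jit), 0.2))
  expect_equal(b1$mz, b2$mz)
  expect_equal(b1$values, b2$values, tolerance = 1e-12)
})

test_that("the MAD gate zeroes at-or-below threshold entries per spectrum", {
  m <- toy_matrix(matrix(c(1, 1, 1, 10), 1, 4))
  out <- mad_noise_gate(m)
  # MAD of (1,1,1,10) around median 1 is 0 -> strict > 0 keeps everything
  expect_equal(as.numeric(out$values), c(1, 1, 1, 10))

  # a constant positive row has MAD 0, so threshold 0 keeps everything:
  # the gate compares raw intensities, strictly, against 2.5 * MAD
  cm <- toy_matrix(matrix(5, 1, 6))
  expect_equal(as.numeric(mad_noise_gate(cm)$values), rep(5, 6))
  # ... and an entry exactly at the threshold is zeroed (strict "above"):
  # row has median 3, MAD 2, threshold 5; the 5 is dropped, the 9 survives
  at_thr <- c(1, 1, 1, 3, 3, 3, 5, 9)
  gated <- mad_noise_gate(toy_matrix(matrix(at_thr, 1, 8)))
  expect_equal(gated$flags$row_mad, 2)
  expect_equal(as.numeric(gated$values), c(0, 0, 0, 0, 0, 0, 0, 9))

  set.seed(8)
  big <- toy_matrix(matrix(rnorm(1e5), 1, 1e5))
  gated <- mad_noise_gate(big)
  expect_equal(gated$flags$row_mad, 0.6745, tolerance = 0.02)

  # gate never increases an entry
  r <- toy_matrix(matrix(abs(rnorm(200)), 10, 20))
  expect_true(all(mad_noise_gate(r)$values <= r$values))
})

test_that("pixel-fraction filter substitutes sparse columns by the minimum", {
  v <- matrix(0, 10, 2)
  v[1:3, 1] <- 5            # 30% nonzero -> substituted (min 0)
  v[1:4, 2] <- 7            # 40% nonzero -> kept
  out <- pixel_fraction_filter(toy_matrix(v), 0.35)
  expect_equal(out$values[, 1], rep(0, 10))
  expect_equal(out$values[, 2], v[, 2])
  expect_equal(out$flags$n_filtered, 1L)

  # brute-force recount: exactly the columns below the threshold change
  set.seed(9)
  w <- matrix(rbinom(600, 1, 0.4) * runif(600, 1, 5), 30, 20)
  outw <- pixel_fraction_filter(toy_matrix(w), 0.35)
  kept <- colMeans(w > 0) >= 0.35
  expect_equal(outw$flags$n_filtered, sum(!kept))
  for (j in which(kept)) expect_equal(outw$values[, j], w[, j])
  for (j in which(!kept)) expect_equal(outw$values[, j],
                                       rep(min(w[, j]), 30))
  # the filter never increases an entry
  expect_true(all(outw$values <= w))
})

test_that("log transform conventions and monotonicity", {
  m <- toy_matrix(matrix(c(0, exp(1) - 1), 1, 2))
  out <- log_transform(m, offset = 1)
  expect_equal(as.numeric(out$values), c(0, 1))

  set.seed(10)
  r <- toy_matrix(matrix(rexp(100), 10, 10))
  lr <- log_transform(r)
  o <- order(r$values)
  expect_true(all(diff(lr$values[o]) >= 0))

  neg <- toy_matrix(matrix(1, 2, 2))
  neg$values[1, 1] <- -1
  expect_error(log_transform(neg), "non-negative")
})

test_that("auto-scaling centers and scales with the n-1 convention", {
  p <- fit_autoscale(matrix(c(1, 3, 5, 5), 2, 2))
  expect_equal(p$mean, c(2, 5))
  expect_equal(p$sd, c(sqrt(2), 1))  # constant column -> divisor 1
  sc <- apply_autoscale(matrix(c(1, 3, 5, 5), 2, 2), p)
  expect_equal(sc[, 1], c(-1, 1) / sqrt(2))
  expect_equal(sc[, 2], c(0, 0))

  set.seed(12)
  x <- matrix(rnorm(80, 5, 3), 16, 5)
  ps <- fit_autoscale(x)
  xs <- apply_autoscale(x, ps)
  expect_equal(colMeans(xs), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(xs, 2, sd), rep(1, 5), tolerance = 1e-9)
})

test_that("the full chain is deterministic", {
  cfg <- phantom_config(n_patients = 2L, grid = c(6L, 6L),
                        n_variables = 40L, n_discriminant = 4L, seed = 3)
  ph <- generate_phantom(cfg)
  m1 <- preprocess(ph$images, preprocess_config())
  m2 <- preprocess(ph$images, preprocess_config())
  expect_identical(m1$values, m2$values)
  expect_identical(m1$mz, m2$mz)
})
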