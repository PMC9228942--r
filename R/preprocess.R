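# Spectral preprocessing chain: peak binning, TIC/RMS normalization,
# baseline removal (asymmetric least squares and morphological top-hat),
# MAD noise gating, pixel-fraction variable filtering, log transform and
# auto-scaling. The default supervised chain (see preprocess()) is
#   bin -> TIC -> AsLS -> MAD gate -> pixel-fraction filter -> log
# with auto-scaling fitted on the training object table only. Top-hat and
# RMS normalization belong to the vendor-side segmentation workflow and are
# exposed but not part of the default chain.

#' Preprocessing configuration
#'
#' @param normalization `"tic"`, `"rms"`, or `"none"`.
#' @param asls_p Asymmetry weight of the AsLS baseline (0 < p < 1); points
#'   above the running baseline get weight `p`, points below `1 - p`.
#' @param asls_lambda Smoothness penalty of the AsLS baseline.
#' @param asls_iterations Weight-update iterations.
#' @param tophat_sigma Structuring half-width, in channels, of the top-hat
#'   opening (element width `2 * sigma + 1`).
#' @param bin_bandwidth Peak-binning bin width in Da.
#' @param snr_multiplier Signal-to-noise gate: entries at or below
#'   `snr_multiplier * MAD` of their spectrum are zeroed.
#' @param min_pixel_fraction Variables with a nonzero signal in fewer than
#'   this fraction of pixels are replaced by their column minimum.
#' @param log_offset Constant added before the natural log; `NULL` means the
#'   smallest positive matrix entry (1 if none).
#' @param mad_scope `"pixel"` (per-spectrum MAD, default) or `"global"`.
#' @param fraction_scope `"dataset"` (default) or `"image"`: whether the
#'   pixel-fraction rule is evaluated across the merged matrix or per image.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(normalization = c("tic", "rms", "none"),
                              asls_p = 0.005, asls_lambda = 1e8,
                              asls_iterations = 20L, tophat_sigma = 20L,
                              bin_bandwidth = 0.2, snr_multiplier = 2.5,
                              min_pixel_fraction = 0.35, log_offset = NULL,
                              mad_scope = c("pixel", "global"),
                              fraction_scope = c("dataset", "image")) {
  normalization <- match.arg(normalization)
  mad_scope <- match.arg(mad_scope)
  fraction_scope <- match.arg(fraction_scope)
  stopifnot(asls_p > 0, asls_p < 1, asls_lambda > 0, asls_iterations >= 1,
            bin_bandwidth > 0, snr_multiplier >= 0,
            min_pixel_fraction >= 0, min_pixel_fraction <= 1)
  structure(list(normalization = normalization, asls_p = asls_p,
                 asls_lambda = asls_lambda,
                 asls_iterations = as.integer(asls_iterations),
                 tophat_sigma = as.integer(tophat_sigma),
                 bin_bandwidth = bin_bandwidth,
                 snr_multiplier = snr_multiplier,
                 min_pixel_fraction = min_pixel_fraction,
                 log_offset = log_offset, mad_scope = mad_scope,
                 fraction_scope = fraction_scope),
            class = "preprocess_config")
}

#' Bin peaks onto a shared m/z grid
#'
#' Fixed half-open bins `[m0 + k*bw, m0 + (k+1)*bw)` spanning the
#' acquisition range, with bin origin `m0` at the lower acquisition bound.
#' Per pixel and bin the intensity is the maximum raw intensity falling in
#' the bin; the recorded variable m/z is the bin center. Bins empty in every
#' pixel of every image are dropped.
#'
#' @param images List of [msi_image]s (continuous or processed).
#' @param bandwidth Bin width in Da (default 0.2).
#' @return List of continuous [msi_image]s on the identical m/z vector.
#' @export
bin_peaks <- function(images, bandwidth = 0.2) {
  stopifnot(bandwidth > 0, length(images) >= 1)
  m0 <- min(vapply(images, function(im) im$mz_range[1], numeric(1)))
  hi <- max(vapply(images, function(im) im$mz_range[2], numeric(1)))
  nbin <- max(1L, as.integer(floor((hi - m0) / bandwidth)) + 1L)

  bin_of <- function(mz) {
    b <- as.integer(floor((mz - m0) / bandwidth))
    pmin(pmax(b, 0L), nbin - 1L)
  }

  binned <- lapply(images, function(im) {
    n <- n_pixels(im)
    out <- matrix(0, n, nbin)
    if (im$continuous) {
      a <- bin_of(im$mz)
      for (b in unique(a)) {
        cols <- which(a == b)
        out[, b + 1L] <- if (length(cols) == 1L) im$intensities[, cols]
        else do.call(pmax, lapply(cols, function(j) im$intensities[, j]))
      }
    } else {
      for (i in seq_len(n)) {
        a <- bin_of(im$mz[[i]])
        v <- im$intensities[[i]]
        for (k in seq_along(a)) {
          b <- a[k] + 1L
          if (v[k] > out[i, b]) out[i, b] <- v[k]
        }
      }
    }
    out
  })

  nonempty <- Reduce(`|`, lapply(binned, function(m) colSums(m > 0) > 0))
  if (!any(nonempty)) abort("all bins are empty")
  centers <- m0 + (which(nonempty) - 0.5) * bandwidth
  lapply(seq_along(images), function(i) {
    im <- images[[i]]
    msi_image(binned[[i]][, nonempty, drop = FALSE], centers, im$coords,
              im$image_id, im$patient_id, im$class_label, im$polarity,
              mz_range = c(m0, hi))
  })
}

norm_rows <- function(mat, stat, tag) {
  s <- apply(mat$values, 1, stat)
  pos <- s > 0
  target <- mean(s[pos])
  values <- mat$values
  values[pos, ] <- values[pos, , drop = FALSE] * (target / s[pos])
  flags <- mat$flags
  flags$zero_rows <- which(!pos)
  new_msi_matrix(values, mat$index, mat$mz, c(mat$provenance, tag), flags)
}

#' Normalize spectra to a common total ion count
#'
#' Each pixel spectrum with a positive sum is rescaled so its total ion
#' count equals the mean pre-normalization row sum of the dataset; zero-sum
#' rows are left unchanged and recorded in `flags$zero_rows`.
#'
#' @param mat An `msi_matrix` (pre-log, non-negative).
#' @return The normalized `msi_matrix`.
#' @export
normalize_tic <- function(mat) norm_rows(mat, sum, "tic")

#' Normalize spectra to a common root mean square
#'
#' As [normalize_tic()] but rescaling each spectrum's root mean square to
#' the dataset mean RMS (the vendor convention for FT-ICR spectra).
#'
#' @inheritParams normalize_tic
#' @return The normalized `msi_matrix`.
#' @export
normalize_rms <- function(mat) {
  norm_rows(mat, function(v) sqrt(mean(v^2)), "rms")
}

#' Morphological top-hat baseline removal
#'
#' Subtracts the morphological opening (erosion then dilation with a flat
#' structuring element of width `2 * sigma + 1` channels, windows clipped at
#' the spectrum edges) from the spectrum.
#'
#' @param spectrum Numeric intensity vector.
#' @param sigma Structuring half-width in channels (default 20).
#' @return The baseline-corrected vector.
#' @export
tophat_baseline <- function(spectrum, sigma = 20L) {
  sigma <- as.integer(sigma)
  n <- length(spectrum)
  if (sigma < 1) abort("sigma must be >= 1")
  if (2L * sigma + 1L > n) {
    abort("structuring element is larger than the spectrum")
  }
  spectrum - running_window(running_window(spectrum, sigma, pmin),
                            sigma, pmax)
}

running_window <- function(v, s, reduce) {
  pad <- if (identical(reduce, pmin)) Inf else -Inf
  n <- length(v)
  out <- v
  for (k in seq_len(s)) {
    left <- c(rep(pad, k), v[seq_len(n - k)])
    right <- c(v[(k + 1):n], rep(pad, k))
    out <- reduce(out, left, right)
  }
  out
}

#' Asymmetric least squares (AsLS) baseline
#'
#' The baseline `z` minimizes `sum w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2`
#' where `d2` is the second difference; after each of `iterations` solves the
#' weights are reset to `p` where `y > z` and `1 - p` elsewhere (starting
#' from all ones). Defaults follow the standard chemometric setting
#' `p = 0.005`, `lambda = 1e8`, 20 iterations.
#'
#' @param spectrum Numeric intensity vector (length >= 3, finite).
#' @param p Asymmetry weight in (0, 1).
#' @param lambda Smoothness penalty (> 0).
#' @param iterations Weight-update count (>= 1).
#' @return A list with `baseline` and `corrected` (= spectrum - baseline).
#' @export
asls_baseline <- function(spectrum, p = 0.005, lambda = 1e8,
                          iterations = 20L) {
  if (any(!is.finite(spectrum))) abort("spectrum contains non-finite values")
  stopifnot(p > 0, p < 1, lambda > 0, iterations >= 1)
  z <- asls_baseline_cpp(as.numeric(spectrum), p, lambda,
                         as.integer(iterations))
  list(baseline = z, corrected = spectrum - z)
}

#' AsLS baseline correction of every pixel spectrum
#' @param mat An `msi_matrix`.
#' @inheritParams asls_baseline
#' @return The corrected `msi_matrix`.
#' @export
asls_correct <- function(mat, p = 0.005, lambda = 1e8, iterations = 20L) {
  if (any(!is.finite(mat$values))) abort("matrix contains non-finite values")
  stopifnot(p > 0, p < 1, lambda > 0, iterations >= 1)
  base <- asls_baseline_rows_cpp(mat$values, p, lambda,
                                 as.integer(iterations))
  new_msi_matrix(mat$values - base, mat$index, mat$mz,
                 c(mat$provenance,
                   sprintf("asls(p=%g, lambda=%g, iter=%d)", p, lambda,
                           as.integer(iterations))),
                 mat$flags)
}

#' MAD signal-to-noise gate
#'
#' Per pixel spectrum, the noise scale is the (raw, unscaled) median
#' absolute deviation of the row around its median; entries at or below
#' `snr_multiplier * MAD` are set to zero and entries strictly above are
#' kept. Per-row MADs are stored in `flags$row_mad`.
#'
#' @param mat A pre-log `msi_matrix`.
#' @param snr_multiplier MAD multiple (default 2.5).
#' @param scope `"pixel"` (per-row MAD) or `"global"` (one MAD for the whole
#'   matrix).
#' @return The gated `msi_matrix`.
#' @export
mad_noise_gate <- function(mat, snr_multiplier = 2.5,
                           scope = c("pixel", "global")) {
  scope <- match.arg(scope)
  stopifnot(snr_multiplier >= 0)
  v <- mat$values
  if (scope == "pixel") {
    med <- apply(v, 1, median)
    madv <- apply(abs(v - med), 1, median)
    thr <- snr_multiplier * madv
    v[v <= thr] <- 0   # thr recycles down columns: row-wise comparison
  } else {
    madv <- median(abs(v - median(v)))
    thr <- snr_multiplier * madv
    v[v <= thr] <- 0
  }
  flags <- mat$flags
  flags$row_mad <- madv
  new_msi_matrix(v, mat$index, mat$mz,
                 c(mat$provenance,
                   sprintf("mad_gate(%g, %s)", snr_multiplier, scope)),
                 flags)
}

#' Pixel-fraction variable filter
#'
#' Any variable with a nonzero signal in strictly fewer than `min_fraction`
#' of the pixels has its entire column replaced by the column minimum (the
#' convention for suppressing sparse variables while keeping the matrix
#' shape). Intended to run after [mad_noise_gate()].
#'
#' @param mat An `msi_matrix`.
#' @param min_fraction Fraction in `[0, 1]` (default 0.35).
#' @param scope `"dataset"` (fractions over the merged matrix, default) or
#'   `"image"` (evaluated and substituted per image).
#' @return The filtered `msi_matrix`; the number of substituted columns is
#'   recorded in the provenance and `flags$n_filtered`.
#' @export
pixel_fraction_filter <- function(mat, min_fraction = 0.35,
                                  scope = c("dataset", "image")) {
  scope <- match.arg(scope)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  v <- mat$values
  n_sub <- 0L
  apply_rule <- function(block) {
    frac <- colMeans(block > 0)
    low <- which(frac < min_fraction)
    for (j in low) block[, j] <- min(block[, j])
    list(block = block, n = length(low))
  }
  if (scope == "dataset") {
    r <- apply_rule(v)
    v <- r$block
    n_sub <- r$n
  } else {
    for (id in unique(mat$index$image_id)) {
      sel <- mat$index$image_id == id
      r <- apply_rule(v[sel, , drop = FALSE])
      v[sel, ] <- r$block
      n_sub <- n_sub + r$n
    }
  }
  flags <- mat$flags
  flags$n_filtered <- n_sub
  new_msi_matrix(v, mat$index, mat$mz,
                 c(mat$provenance,
                   sprintf("pixel_fraction(%g, %s): %d columns substituted",
                           min_fraction, scope, n_sub)),
                 flags)
}

#' Log transform
#'
#' Applies `log(value + offset)` entrywise. The default offset is the
#' smallest positive matrix entry (1 if the matrix is all zero), so zeros
#' map to a finite floor.
#'
#' @param mat A non-negative `msi_matrix`.
#' @param offset Positive constant; `NULL` for the default.
#' @return The transformed `msi_matrix`.
#' @export
log_transform <- function(mat, offset = NULL) {
  if (any(mat$values < 0)) abort("log transform requires non-negative values")
  if (is.null(offset)) {
    pos <- mat$values[mat$values > 0]
    offset <- if (length(pos)) min(pos) else 1
  }
  stopifnot(offset > 0)
  new_msi_matrix(log(mat$values + offset), mat$index, mat$mz,
                 c(mat$provenance, sprintf("log(+%g)", offset)), mat$flags)
}

#' Fit auto-scaling parameters
#'
#' Per-variable mean and standard deviation (denominator n - 1) learned on a
#' training object table; zero-variance variables get divisor 1. The same
#' parameters must be applied to test objects and to pixel rows when
#' projecting maps.
#'
#' @param objects An object table from [median_objects()] (training rows
#'   only), or a plain numeric matrix.
#' @return A list of class `autoscale` with `mean` and `sd`.
#' @export
fit_autoscale <- function(objects) {
  x <- spectra_of(objects)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = mu, sd = s), class = "autoscale")
}

#' Apply auto-scaling parameters
#' @param x A numeric matrix, object table, or `msi_matrix`.
#' @param params An `autoscale` object from [fit_autoscale()].
#' @return `x` with each variable centered and scaled by the training
#'   parameters, in the same container it came in.
#' @export
apply_autoscale <- function(x, params) {
  stopifnot(inherits(params, "autoscale"))
  scale_mat <- function(m) {
    if (ncol(m) != length(params$mean)) {
      abort("variable count does not match the scaling parameters")
    }
    sweep(sweep(m, 2, params$mean, "-"), 2, params$sd, "/")
  }
  if (inherits(x, "msi_matrix")) {
    new_msi_matrix(scale_mat(x$values), x$index, x$mz,
                   c(x$provenance, "autoscale"), x$flags)
  } else if (is.matrix(x)) {
    scale_mat(x)
  } else {
    x$spectrum <- scale_mat(x$spectrum)
    x
  }
}

# object-table / matrix polymorphism used across the modeling code
spectra_of <- function(objects) {
  if (is.matrix(objects)) objects
  else if (inherits(objects, "msi_matrix")) objects$values
  else objects$spectrum
}

#' Run the default preprocessing chain
#'
#' bin -> TIC normalize -> AsLS (per pixel, on binned values) -> MAD gate ->
#' pixel-fraction filter -> log, with every step logged in the provenance.
#' Auto-scaling is not part of this chain: it is fitted on training objects
#' only (see [fit_autoscale()]).
#'
#' @param images List of [msi_image]s.
#' @param config A [preprocess_config()].
#' @param masks Optional named list of masks passed to [unfold()].
#' @return A preprocessed `msi_matrix`.
#' @export
preprocess <- function(images, config = preprocess_config(), masks = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  mat <- unfold(bin_peaks(images, config$bin_bandwidth), masks = masks)
  mat <- switch(config$normalization,
                tic = normalize_tic(mat),
                rms = normalize_rms(mat),
                none = mat)
  mat <- asls_correct(mat, config$asls_p, config$asls_lambda,
                      config$asls_iterations)
  # AsLS residuals can dip below zero off-peak; the gate treats them as noise
  mat$values[mat$values < 0] <- 0
  mat <- mad_noise_gate(mat, config$snr_multiplier, config$mad_scope)
  mat <- pixel_fraction_filter(mat, config$min_pixel_fraction,
                               config$fraction_scope)
  log_transform(mat, config$log_offset)
}
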