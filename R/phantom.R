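# Synthetic MSI phantoms with the statistical structure the analysis
# assumes: paired pathological/healthy images per patient, delta-like ion
# channels, planted up/down-regulated discriminant ions, a smooth additive
# baseline drift, per-pixel multiplicative TIC variation, per-patient random
# effects, and additive truncated-Gaussian noise.

#' Phantom configuration
#'
#' @param n_patients Number of patients; each contributes one pathological
#'   and one healthy image.
#' @param grid Pixel grid `c(width, height)`.
#' @param mz_range Acquisition m/z range `c(low, high)` in Da.
#' @param polarity Ionization mode metadata.
#' @param n_variables Number of m/z channels (equally spaced across the
#'   range, so each lands in its own 0.2-Da bin). Only
#'   `signal_fraction * n_variables` of them are true ion channels; the rest
#'   carry baseline drift and noise only, emulating the noise floor that the
#'   MAD gate and pixel-fraction filter exist to remove.
#' @param signal_fraction Fraction of channels that are true ions
#'   (default 0.4).
#' @param n_discriminant Number of planted class-affected ion channels;
#'   directions alternate up/down in tumor.
#' @param fold_change Multiplicative effect on the tumor region mean of each
#'   discriminant channel (up: `*fold`, down: `/fold`).
#' @param tumor_geometry `"blob"` (disc covering most of the image),
#'   `"half"`, or `"annulus"` — the tumor region inside the pathological
#'   image; the rest of that image is adjacent non-tumor tissue; healthy
#'   images are homogeneous non-tumor.
#' @param baseline_amplitude,baseline_decay Additive smooth drift
#'   `amplitude * exp(-(mz - low) / decay)` shared by every pixel.
#' @param noise_sd Additive Gaussian noise sd, relative to each channel's
#'   region mean; intensities are truncated at zero.
#' @param tic_variation_cv Coefficient of variation of the per-pixel
#'   multiplicative log-normal TIC factor (mean 1).
#' @param patient_effect_sd Log-scale sd of the per-patient, per-channel
#'   multiplicative random effect (mean 1): each patient draws one channel
#'   multiplier vector shared by both of their images, emulating
#'   between-subject metabolome variability that survives TIC normalization.
#' @param mz_jitter Per-pixel uniform m/z jitter half-width in Da; > 0
#'   yields processed-mode images (exercises binning), 0 a shared axis.
#' @param seed Integer seed; the generator is bit-deterministic given it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 7L, grid = c(40L, 40L),
                           mz_range = c(300, 1000),
                           polarity = c("positive", "negative"),
                           n_variables = 500L, signal_fraction = 0.4,
                           n_discriminant = 25L,
                           fold_change = 3, tumor_geometry = c("blob",
                                                               "half",
                                                               "annulus"),
                           baseline_amplitude = 30, baseline_decay = 200,
                           noise_sd = 0.05, tic_variation_cv = 0.2,
                           patient_effect_sd = 0.1, mz_jitter = 0,
                           seed = 0L) {
  polarity <- match.arg(polarity)
  tumor_geometry <- match.arg(tumor_geometry)
  stopifnot(n_patients >= 1, all(grid >= 2), n_variables >= 1,
            signal_fraction > 0, signal_fraction <= 1,
            n_discriminant <= ceiling(signal_fraction * n_variables),
            fold_change > 0, noise_sd >= 0,
            tic_variation_cv >= 0, patient_effect_sd >= 0, mz_jitter >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 grid = as.integer(grid), mz_range = as.numeric(mz_range),
                 polarity = polarity, n_variables = as.integer(n_variables),
                 signal_fraction = signal_fraction,
                 n_discriminant = as.integer(n_discriminant),
                 fold_change = fold_change, tumor_geometry = tumor_geometry,
                 baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay, noise_sd = noise_sd,
                 tic_variation_cv = tic_variation_cv,
                 patient_effect_sd = patient_effect_sd,
                 mz_jitter = mz_jitter, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Named phantom scenarios
#'
#' `"separable"`: strong planted effects (fold 3, low noise) so the
#' downstream pipeline reaches perfect cross-validated classification —
#' the simulation analog of a cleanly separated two-class study.
#' `"noisy"`: moderate effects with class overlap, for power and robustness
#' checks. `"null"`: no planted effects at all (every between-class fold
#' change is 1), for specificity / false-positive checks, on a smaller grid
#' so repeated-seed suites stay cheap.
#'
#' @param name Scenario name.
#' @param seed Seed stored in the returned config.
#' @return A [phantom_config()].
#' @export
default_scenario <- function(name = c("separable", "noisy", "null"),
                             seed = 0L) {
  name <- match.arg(name)
  switch(name,
    separable = phantom_config(n_patients = 7L, grid = c(40L, 40L),
                               n_variables = 500L, n_discriminant = 25L,
                               fold_change = 3, noise_sd = 0.05,
                               tic_variation_cv = 0.2,
                               patient_effect_sd = 0.1, seed = seed),
    noisy = phantom_config(n_patients = 7L, grid = c(20L, 20L),
                           n_variables = 300L, n_discriminant = 15L,
                           fold_change = 1.3, noise_sd = 0.6,
                           tic_variation_cv = 0.3, patient_effect_sd = 0.4,
                           seed = seed),
    null = phantom_config(n_patients = 7L, grid = c(16L, 16L),
                          n_variables = 300L, n_discriminant = 0L,
                          fold_change = 1, noise_sd = 0.5,
                          tic_variation_cv = 0.3, patient_effect_sd = 0.3,
                          seed = seed))
}

tumor_region <- function(grid, geometry) {
  w <- grid[1]; h <- grid[2]
  gx <- rep(seq_len(w) - 1L, times = h)
  gy <- rep(seq_len(h) - 1L, each = w)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  inside <- switch(geometry,
    blob = {
      r <- 0.45 * min(w, h)
      (gx - cx)^2 + (gy - cy)^2 <= r^2
    },
    half = gx < w / 2,
    annulus = {
      d2 <- (gx - cx)^2 + (gy - cy)^2
      r_out <- 0.48 * min(w, h); r_in <- 0.22 * min(w, h)
      d2 <= r_out^2 & d2 >= r_in^2
    })
  if (!any(inside) || all(inside)) {
    abort("grid too small for the requested tumor geometry")
  }
  list(x = gx, y = gy, tumor = inside)
}

#' Generate an MSI phantom
#'
#' Per pixel, the intensity at channel `j` is
#' `baseline(mz_j) + patient_effect * tic_factor * region_mean_j + noise`,
#' truncated at zero. Region means differ between tumor and non-tumor only
#' on the planted discriminant channels, by the configured fold change.
#' Pathological images contain a tumor region plus adjacent non-tumor
#' tissue; healthy images are homogeneous non-tumor.
#'
#' @param config A [phantom_config()].
#' @return A list of class `msi_phantom`: `images` (list of [msi_image]),
#'   `manifest` (tibble), `masks` (named list of mask tibbles), and `truth`
#'   (discriminant channel table, per-patient effects, per-pixel TIC
#'   factors, region means).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  nv <- config$n_variables
  lo <- config$mz_range[1]; hi <- config$mz_range[2]
  mz <- lo + (seq_len(nv) - 0.5) * (hi - lo) / nv
  n_ion <- max(1L, round(config$signal_fraction * nv))
  ion <- sort(sample.int(nv, n_ion))
  # ion intensities with ~30% spread around 100; non-ion channels carry only
  # baseline drift and noise (the floor the MAD gate is meant to remove)
  base_mean <- numeric(nv)
  base_mean[ion] <- exp(rnorm(n_ion, log(100), 0.3))

  disc <- integer(0)
  direction <- character(0)
  if (config$n_discriminant > 0) {
    disc <- sort(sample(ion, config$n_discriminant))
    direction <- rep(c("up", "down"), length.out = length(disc))
  }
  tumor_mean <- base_mean
  tumor_mean[disc[direction == "up"]] <-
    tumor_mean[disc[direction == "up"]] * config$fold_change
  tumor_mean[disc[direction == "down"]] <-
    tumor_mean[disc[direction == "down"]] / config$fold_change

  baseline <- config$baseline_amplitude *
    exp(-(mz - lo) / config$baseline_decay)

  sdlog_pat <- config$patient_effect_sd
  patient_effect <- matrix(
    exp(rnorm(config$n_patients * nv, -sdlog_pat^2 / 2, sdlog_pat)),
    config$n_patients, nv)
  sdlog_tic <- sqrt(log(1 + config$tic_variation_cv^2))

  region <- tumor_region(config$grid, config$tumor_geometry)
  npx <- length(region$x)
  coords <- tibble::tibble(x = region$x, y = region$y)

  images <- list()
  masks <- list()
  manifest <- list()
  tic_factors <- list()
  for (p in seq_len(config$n_patients)) {
    for (cls in c("pathological", "healthy")) {
      id <- sprintf("P%02d_%s", p, cls)
      is_tumor <- if (cls == "pathological") region$tumor else
        rep(FALSE, npx)
      tic <- exp(rnorm(npx, -sdlog_tic^2 / 2, sdlog_tic))
      pe <- patient_effect[p, ]
      mu <- outer(rep(1, npx), base_mean * pe)
      if (any(is_tumor)) {
        mu[is_tumor, ] <- outer(rep(1, sum(is_tumor)), tumor_mean * pe)
      }
      signal <- tic * mu
      # one global noise scale relative to the mean ion intensity, so the
      # floor is present on empty channels too
      noise <- if (config$noise_sd > 0) {
        matrix(rnorm(npx * nv, 0,
                     config$noise_sd * mean(base_mean[ion])), npx, nv)
      } else 0
      intens <- pmax(sweep(signal + noise, 2, baseline, "+"), 0)
      if (config$mz_jitter > 0) {
        mzl <- lapply(seq_len(npx), function(i) {
          mz + runif(nv, -config$mz_jitter, config$mz_jitter)
        })
        il <- lapply(seq_len(npx), function(i) intens[i, ])
        img <- msi_image(il, mzl, coords, id, paste0("patient", p), cls,
                         config$polarity, mz_range = config$mz_range)
      } else {
        img <- msi_image(intens, mz, coords, id, paste0("patient", p), cls,
                         config$polarity, mz_range = config$mz_range)
      }
      images[[id]] <- img
      masks[[id]] <- tibble::tibble(
        x = coords$x, y = coords$y,
        label = ifelse(is_tumor, "tumor", "non-tumor"))
      manifest[[id]] <- tibble::tibble(
        image_id = id, patient_id = paste0("patient", p),
        class_label = cls, polarity = config$polarity)
      tic_factors[[id]] <- tic
    }
  }

  truth <- list(
    discriminant = tibble::tibble(
      channel = disc, mz = mz[disc], direction = direction,
      fold_change = ifelse(direction == "up", config$fold_change,
                           1 / config$fold_change)),
    patient_effects = `rownames<-`(patient_effect,
                                   paste0("patient",
                                          seq_len(config$n_patients))),
    tic_factors = tic_factors,
    ion_channels = ion, base_mean = base_mean, tumor_mean = tumor_mean,
    mz = mz, baseline = baseline)

  structure(list(images = unname(images), manifest = dplyr::bind_rows(manifest),
                 masks = masks, truth = truth, config = config),
            class = "msi_phantom")
}

#' @export
print.msi_phantom <- function(x, ...) {
  cat(sprintf(
    "<msi_phantom> %d patients x 2 images, %dx%d pixels, %d channels (%d discriminant)\n",
    x$config$n_patients, x$config$grid[1], x$config$grid[2],
    x$config$n_variables, x$config$n_discriminant))
  invisible(x)
}

#' Write a phantom to disk as imzML + manifest + masks
#'
#' Emits one imzML/ibd pair per image plus `manifest.tsv` and
#' `<image_id>_mask.tsv` files, so downstream runs exercise the real I/O
#' path.
#'
#' @param phantom An [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (im in phantom$images) {
    write_imzml(im, file.path(dir, paste0(im$image_id, ".imzML")))
    write_mask(phantom$masks[[im$image_id]],
               file.path(dir, paste0(im$image_id, "_mask.tsv")))
  }
  write_manifest(phantom$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
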