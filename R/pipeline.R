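# End-to-end orchestration: simulate or ingest -> preprocess -> PCA ->
# PLS-DA (full and VIP-reduced, leave-one-patient-out CV) -> pixel
# classification maps -> segmentation + colocalization -> annotation ->
# report. Configured from a list or a YAML file.

#' Run configuration
#'
#' @param scenario Phantom scenario name (see [default_scenario()]), or
#'   `NULL` to read data from `input_dir`.
#' @param input_dir Directory with imzML files, `manifest.tsv` and optional
#'   `*_mask.tsv` files (as written by [write_phantom()]).
#' @param test_patients Patient ids held out as the test set (may be empty).
#' @param preprocess A [preprocess_config()].
#' @param n_components PCA components for score maps.
#' @param max_lv,vip_threshold PLS-DA settings for [lopo_cv()].
#' @param segmentation_k Cluster counts for per-image segmentation.
#' @param r_min Colocalization threshold.
#' @param compound_table Optional path to a compound reference table for
#'   annotating reported ions.
#' @param tol_da Da tolerance for TOF-style annotation of binned ions.
#' @param seed Seed for the simulate branch.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, input_dir = NULL,
                       test_patients = character(),
                       preprocess = preprocess_config(),
                       n_components = 2L, max_lv = 5L, vip_threshold = 2,
                       segmentation_k = c(2L, 4L), r_min = 0.5,
                       compound_table = NULL, tol_da = 0.75, seed = 0L,
                       out_dir = NULL) {
  if (is.null(scenario) && is.null(input_dir)) {
    abort("config needs either a phantom scenario or an input directory")
  }
  structure(list(scenario = scenario, input_dir = input_dir,
                 test_patients = as.character(test_patients),
                 preprocess = preprocess, n_components = n_components,
                 max_lv = max_lv, vip_threshold = vip_threshold,
                 segmentation_k = segmentation_k, r_min = r_min,
                 compound_table = compound_table, tol_da = tol_da,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; the `preprocess` key
#' holds [preprocess_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, y$preprocess %||% list())
  y$preprocess <- NULL
  do.call(run_config, c(y, list(preprocess = pp)))
}

load_run_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    ph <- generate_phantom(default_scenario(config$scenario,
                                            seed = config$seed))
    list(images = ph$images, masks = ph$masks, truth = ph$truth)
  } else {
    manifest <- read_manifest(file.path(config$input_dir, "manifest.tsv"))
    images <- lapply(manifest$image_id, function(id) {
      read_imzml(file.path(config$input_dir, paste0(id, ".imzML")),
                 image_id = id)
    })
    images <- apply_manifest(images, manifest)
    masks <- list()
    for (i in seq_along(images)) {
      mp <- file.path(config$input_dir,
                      paste0(images[[i]]$image_id, "_mask.tsv"))
      if (file.exists(mp)) {
        masks[[images[[i]]$image_id]] <- read_mask(mp, images[[i]])
      }
    }
    list(images = images, masks = masks, truth = NULL)
  }
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), f)
  unname(tools::md5sum(f))
}

#' Run the full discrimination pipeline
#'
#' Executes preprocess -> object table -> PCA -> leave-one-patient-out
#' PLS-DA CV (full variables and VIP-reduced) -> test-set pixel
#' classification -> per-image bisecting k-means segmentation with Pearson
#' colocalization -> annotation of the reported ions, and assembles a
#' metrics table (training/CV/test by full/VIP) plus a discriminant-ion
#' report with modulation direction (sign of the tumor-minus-healthy
#' object-median difference).
#'
#' @param config A [run_config()], or a path to a YAML file.
#' @return A list of class `msi_run`; see the components in the examples of
#'   the package vignette. When `config$out_dir` is set, TSV/JSON artifacts
#'   are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  inputs <- load_run_inputs(config)
  images <- inputs$images
  manifest <- tibble::tibble(
    image_id = vapply(images, `[[`, character(1), "image_id"),
    patient_id = vapply(images, `[[`, character(1), "patient_id"),
    class_label = vapply(images, `[[`, character(1), "class_label"))
  patients <- unique(manifest$patient_id)
  if (length(config$test_patients)) {
    missing <- setdiff(config$test_patients, patients)
    if (length(missing)) {
      abort(sprintf("test patients not in the data: %s",
                    paste(missing, collapse = ", ")))
    }
    if (length(setdiff(patients, config$test_patients)) < 3) {
      abort("fewer than 3 training patients after the test split")
    }
  }

  mat <- preprocess(images, config$preprocess, masks = inputs$masks)
  objects <- median_objects(mat)
  train_obj <- objects[!(objects$patient_id %in% config$test_patients), ]
  test_obj <- objects[objects$patient_id %in% config$test_patients, ]

  pca <- msi_pca(train_obj, n_components = config$n_components)
  cv_full <- lopo_cv(train_obj, max_lv = config$max_lv)
  cv_vip <- lopo_cv(train_obj, max_lv = config$max_lv,
                    vip_threshold = config$vip_threshold)

  collect_metrics <- function(cv, label) {
    opt <- cv$metrics[cv$metrics$n_lv == cv$optimal_nlv, ]
    tibble::tibble(
      model = label,
      n_vars = if (is.null(cv$model$selected_variables)) ncol(objects$spectrum)
               else length(cv$model$selected_variables),
      n_lv = cv$optimal_nlv,
      split = c("training", "cv"),
      accuracy = c(opt$accuracy_train, opt$accuracy_cv),
      sensitivity = c(opt$sensitivity_train, opt$sensitivity_cv),
      specificity = c(opt$specificity_train, opt$specificity_cv))
  }
  metrics <- dplyr::bind_rows(collect_metrics(cv_full, "full"),
                              collect_metrics(cv_vip, "vip"))

  # pixel-level test metrics, per image, for both models
  pixel_maps <- list()
  if (nrow(test_obj)) {
    for (label in c("full", "vip")) {
      cv <- if (label == "full") cv_full else cv_vip
      for (id in test_obj$image_id) {
        sub <- subset_image(mat, id)
        truth <- test_obj$class_label[test_obj$image_id == id]
        pc <- classify_pixels(cv$model, sub, truth)
        pixel_maps[[paste(label, id, sep = ":")]] <- pc
      }
    }
    test_pixel <- dplyr::bind_rows(lapply(names(pixel_maps), function(k) {
      pc <- pixel_maps[[k]]
      tibble::tibble(model = sub(":.*", "", k), image_id = pc$image_id,
                     truth = pc$truth_label,
                     percent_correct = pc$percent_correct)
    }))
  } else {
    test_pixel <- tibble::tibble(model = character(), image_id = character(),
                                 truth = character(),
                                 percent_correct = numeric())
  }

  # per-image segmentation + colocalization on the preprocessed matrix
  segmentations <- list()
  coloc <- list()
  for (id in manifest$image_id) {
    sub <- subset_image(mat, id)
    for (k in config$segmentation_k) {
      seg <- bisecting_kmeans(sub, k = k)
      segmentations[[sprintf("%s:k%d", id, k)]] <- seg
      for (ci in seq_len(seg$k)) {
        hits <- colocalize(sub, cluster_mask(seg, ci), config$r_min)
        if (nrow(hits)) {
          coloc[[sprintf("%s:k%d:c%d", id, k, ci)]] <- dplyr::bind_cols(
            tibble::tibble(image_id = id, k = k, cluster = ci,
                           .rows = nrow(hits)), hits)
        }
      }
    }
  }
  coloc <- if (length(coloc)) dplyr::bind_rows(coloc) else
    tibble::tibble(image_id = character(), k = integer(), cluster = integer(),
                   mz = numeric(), r = numeric())

  # discriminant-ion report: VIP > threshold and/or colocalized ions, with
  # modulation direction from object-level medians (tumor minus healthy)
  vip_full <- vip_scores(cv_full$model, cv_full$model$n_lv_optimal)
  vip_idx <- which(vip_full > config$vip_threshold)
  med_diff <- colMeans(train_obj$spectrum[
    train_obj$class_label == "pathological", , drop = FALSE]) -
    colMeans(train_obj$spectrum[
      train_obj$class_label == "healthy", , drop = FALSE])
  coloc_mz <- unique(coloc$mz)
  report_idx <- sort(union(vip_idx, match(coloc_mz, mat$mz)))
  best_r <- vapply(mat$mz[report_idx], function(m) {
    rr <- coloc$r[coloc$mz == m]
    if (length(rr)) max(rr) else NA_real_
  }, numeric(1))
  ion_report <- tibble::tibble(
    mz = mat$mz[report_idx],
    vip = vip_full[report_idx],
    pearson_r = best_r,
    modulation = ifelse(med_diff[report_idx] > 0, "up", "down"))

  if (!is.null(config$compound_table)) {
    tab <- read_compound_table(config$compound_table)
    hits <- match_peaks(ion_report$mz, tab, tol_da = config$tol_da)
    ion_report$compound <- vapply(ion_report$mz, function(m) {
      h <- hits$name[hits$observed_mz == m]
      if (length(h)) h[1] else NA_character_
    }, character(1))
  }

  run <- structure(
    list(config = config, config_hash = config_hash(config),
         seed = config$seed, manifest = manifest,
         matrix = mat, objects = objects, pca = pca,
         cv_full = cv_full, cv_vip = cv_vip, metrics = metrics,
         test_pixel = test_pixel, pixel_maps = pixel_maps,
         segmentations = segmentations, colocalization = coloc,
         ion_report = ion_report, truth = inputs$truth),
    class = "msi_run")

  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(run$metrics, file.path(dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(run$test_pixel, file.path(dir, "test_pixel_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$colocalization, file.path(dir, "colocalization.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$ion_report, file.path(dir, "ion_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (k in names(run$segmentations)) {
    seg <- run$segmentations[[k]]
    write.table(seg$labels,
                file.path(dir, sprintf("segmentation_%s.tsv",
                                       gsub(":", "_", k))),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  meta <- c(sprintf("config_hash\t%s", run$config_hash),
            sprintf("seed\t%d", run$seed))
  writeLines(meta, file.path(dir, "run_metadata.tsv"))
  invisible(dir)
}

#' @export
print.msi_run <- function(x, ...) {
  cat(sprintf("<msi_run> %d images, %d patients (seed %d, config %s)\n",
              nrow(x$manifest), length(unique(x$manifest$patient_id)),
              x$seed, substr(x$config_hash, 1, 8)))
  print(x$metrics)
  invisible(x)
}

#' @export
glance.msi_run <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = c("full", "vip")),
                   dplyr::bind_rows(glance(x$cv_full), glance(x$cv_vip)))
}
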