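# Leave-one-patient-out cross-validation, confusion-matrix figures of
# merit, and per-pixel classification maps.

#' Confusion matrix counts
#'
#' Positive class = healthy: TP counts healthy objects classified healthy.
#'
#' @param truth,predicted Class label vectors.
#' @return A list of class `confusion` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  t1 <- code_y(truth) == 1
  p1 <- code_y(predicted) == 1
  structure(list(TP = sum(t1 & p1), TN = sum(!t1 & !p1),
                 FP = sum(!t1 & p1), FN = sum(t1 & !p1)),
            class = "confusion")
}

#' Classification figures of merit
#'
#' Accuracy `= 100 (TP + TN) / (TP + FP + TN + FN)`, sensitivity
#' `= 100 TP / (TP + FN)`, specificity `= 100 TN / (TN + FP)`, with the
#' healthy class as positive. Undefined denominators yield `NaN` with a
#' warning.
#'
#' @param cm A `confusion` object (or list with `TP`, `TN`, `FP`, `FN`).
#' @return A tibble with `accuracy`, `sensitivity`, `specificity` in percent.
#' @export
confusion_metrics <- function(cm) {
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  if (tot == 0) abort("empty confusion matrix")
  rate <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined: zero denominator", what))
      return(NaN)
    }
    100 * num / den
  }
  tibble::tibble(
    accuracy = 100 * (cm$TP + cm$TN) / tot,
    sensitivity = rate(cm$TP, cm$TP + cm$FN, "sensitivity"),
    specificity = rate(cm$TN, cm$TN + cm$FP, "specificity"))
}

#' Leave-one-patient-out cross-validation of PLS-DA
#'
#' One fold per patient: both of a patient's images (pathological and
#' healthy objects) are held out, the model — auto-scaling included — is
#' refitted on the remaining patients, and the held-out objects are
#' classified, for every component count `1..max_lv`. The optimal component
#' count maximizes CV accuracy, ties resolved toward fewer components. With
#' `vip_threshold` set, VIP selection is recomputed inside each training
#' fold (no leakage) before refitting on the reduced variable set.
#'
#' @param objects Object table from [median_objects()]; at least 3 patients,
#'   each with both class images.
#' @param max_lv Largest component count to evaluate.
#' @param vip_threshold Optional VIP cutoff (strict `>`) for per-fold
#'   variable selection.
#' @param vip_nlv Component count of the per-fold model from which VIP
#'   scores are computed (default `max_lv`, capped at the fold's rank).
#' @return An object of class `plsda_cv`: `metrics` (per-nLV training and
#'   CV accuracy/sensitivity/specificity), `optimal_nlv`, `folds` (per-fold
#'   held-out predictions), and the final model refitted on all objects at
#'   the optimal component count.
#' @export
lopo_cv <- function(objects, max_lv = 5L, vip_threshold = NULL,
                    vip_nlv = max_lv) {
  patients <- unique(objects$patient_id)
  if (length(patients) < 3) abort("need at least 3 patients")
  for (p in patients) {
    cls <- objects$class_label[objects$patient_id == p]
    if (!all(c("pathological", "healthy") %in% cls)) {
      abort(sprintf("patient '%s' lacks both class images", p))
    }
  }
  max_lv <- as.integer(max_lv)

  fit_fold <- function(train) {
    sel <- NULL
    if (!is.null(vip_threshold)) {
      full <- plsda(train, n_lv = min(vip_nlv, nrow(train) - 1L))
      sel <- select_vip(full, vip_threshold)
      if (!length(sel)) sel <- seq_len(ncol(train$spectrum))
      train$spectrum <- train$spectrum[, sel, drop = FALSE]
    }
    m <- plsda(train, n_lv = min(max_lv, nrow(train) - 1L))
    m$selected_variables <- sel
    m
  }

  folds <- lapply(patients, function(p) {
    train <- objects[objects$patient_id != p, ]
    test <- objects[objects$patient_id == p, ]
    m <- fit_fold(train)
    pred <- lapply(seq_len(max_lv), function(a) {
      predict(m, test, n_lv = min(a, m$n_lv))$class
    })
    tibble::tibble(patient_id = p,
                   image_id = rep(test$image_id, max_lv),
                   truth = rep(test$class_label, max_lv),
                   n_lv = rep(seq_len(max_lv), each = nrow(test)),
                   predicted = unlist(pred))
  })
  folds <- dplyr::bind_rows(folds)

  # training metrics from the all-object fit (resubstitution)
  full_model <- fit_fold(objects)
  metrics <- dplyr::bind_rows(lapply(seq_len(max_lv), function(a) {
    cvf <- folds[folds$n_lv == a, ]
    cv <- confusion_metrics(confusion_counts(cvf$truth, cvf$predicted))
    tr_pred <- predict(full_model, objects, n_lv = min(a, full_model$n_lv))
    tr <- confusion_metrics(confusion_counts(objects$class_label,
                                             tr_pred$class))
    tibble::tibble(n_lv = a,
                   accuracy_train = tr$accuracy, accuracy_cv = cv$accuracy,
                   sensitivity_train = tr$sensitivity,
                   sensitivity_cv = cv$sensitivity,
                   specificity_train = tr$specificity,
                   specificity_cv = cv$specificity)
  }))

  optimal <- metrics$n_lv[which.max(metrics$accuracy_cv)]  # ties -> fewest

  final <- full_model
  final$n_lv_optimal <- min(optimal, final$n_lv)

  structure(list(metrics = metrics, optimal_nlv = optimal, folds = folds,
                 model = final, vip_threshold = vip_threshold,
                 n_patients = length(patients),
                 n_objects = nrow(objects)),
            class = "plsda_cv")
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat(sprintf("<plsda_cv> %d patients, %d objects%s\n", x$n_patients,
              x$n_objects,
              if (!is.null(x$vip_threshold))
                sprintf(", VIP > %g selection per fold", x$vip_threshold)
              else ""))
  opt <- x$metrics[x$metrics$n_lv == x$optimal_nlv, ]
  cat(sprintf("optimal nLV = %d: CV accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$optimal_nlv, opt$accuracy_cv, opt$sensitivity_cv,
              opt$specificity_cv))
  invisible(x)
}

#' @export
tidy.plsda_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -"n_lv",
                      names_to = c("metric", "split"), names_sep = "_",
                      values_to = "value")
}

#' @export
glance.plsda_cv <- function(x, ...) {
  opt <- x$metrics[x$metrics$n_lv == x$optimal_nlv, ]
  tibble::tibble(optimal_nlv = x$optimal_nlv,
                 accuracy_cv = opt$accuracy_cv,
                 sensitivity_cv = opt$sensitivity_cv,
                 specificity_cv = opt$specificity_cv,
                 n_patients = x$n_patients, n_objects = x$n_objects)
}

#' Classify every pixel of one image
#'
#' Scores each tissue pixel with the PLS-DA regression vector and assigns a
#' class via the model's LDA threshold. Background-labeled pixels are
#' excluded from the percentage and rendered as no-call (`NA`).
#'
#' @param model A fitted [plsda] model.
#' @param mat A one-image `msi_matrix` preprocessed as the training data.
#' @param truth_label The image's true class (`"pathological"`/`"healthy"`).
#' @param n_lv Component count (default: the model's optimum if recorded,
#'   else all fitted components).
#' @return A list of class `pixel_classification`: `map` (tibble `x`, `y`,
#'   `yhat`, `class`), `percent_correct`, `truth_label`, `image_id`.
#' @export
classify_pixels <- function(model, mat, truth_label,
                            n_lv = model$n_lv_optimal %||% model$n_lv) {
  stopifnot(length(unique(mat$index$image_id)) == 1)
  tissue <- rep(TRUE, nrow(mat$values))
  if ("label" %in% names(mat$index)) {
    tissue <- is.na(mat$index$label) | mat$index$label != "background"
  }
  pred <- predict(model, mat$values, n_lv = n_lv)
  cls <- pred$class
  cls[!tissue] <- NA_character_
  pct <- 100 * sum(cls[tissue] == truth_label) / sum(tissue)
  structure(list(map = tibble::tibble(x = mat$index$x, y = mat$index$y,
                                      yhat = pred$yhat, class = cls),
                 percent_correct = pct, truth_label = truth_label,
                 image_id = mat$index$image_id[1]),
            class = "pixel_classification")
}

#' @export
print.pixel_classification <- function(x, ...) {
  cat(sprintf("<pixel_classification '%s'> truth %s: %.1f%% pixels correct\n",
              x$image_id, x$truth_label, x$percent_correct))
  invisible(x)
}
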