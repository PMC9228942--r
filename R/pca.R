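# Object-level principal component analysis and per-pixel score maps.

#' Principal component analysis of an object table
#'
#' Fits PCA on the auto-scaled training object table via singular value
#' decomposition. Sign convention: within each loading column the
#' largest-magnitude element is positive, so loadings are deterministic.
#'
#' @param objects Training object table from [median_objects()] (or a plain
#'   numeric matrix).
#' @param n_components Number of components to keep; at most
#'   `min(rows - 1, variables)`.
#' @param scaling Optional pre-fitted [fit_autoscale()] parameters; by
#'   default fitted on `objects`.
#' @return An object of class `msi_pca`: `loadings` (variables x
#'   components), `scores` (training objects x components), `explained`
#'   (variance fractions), `scaling`, and the training row info.
#' @export
msi_pca <- function(objects, n_components = 2L, scaling = NULL) {
  x <- spectra_of(objects)
  n <- nrow(x)
  if (n < 2) abort("PCA needs at least 2 objects")
  kmax <- min(n - 1L, ncol(x))
  if (n_components > kmax) {
    abort(sprintf("n_components must be <= %d for this table", kmax))
  }
  if (is.null(scaling)) scaling <- fit_autoscale(x)
  xs <- apply_autoscale(x, scaling)
  sv <- svd(xs, nu = n_components, nv = n_components)
  loadings <- sv$v
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- xs %*% loadings
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(n_components)]
  info <- if (is.matrix(objects)) NULL else
    objects[, intersect(c("image_id", "patient_id", "class_label"),
                        names(objects))]
  structure(list(loadings = loadings, scores = scores,
                 explained = explained, scaling = scaling, info = info),
            class = "msi_pca")
}

#' @export
print.msi_pca <- function(x, ...) {
  cat(sprintf("<msi_pca> %d components over %d variables\n",
              ncol(x$loadings), nrow(x$loadings)))
  cat("explained variance:",
      paste(sprintf("%.2f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.msi_pca <- function(x, ...) {
  tb <- tibble::tibble(component = seq_along(x$explained),
                       explained_variance = x$explained)
  if (!is.null(x$info)) {
    sc <- tibble::as_tibble(as.data.frame(x$scores))
    names(sc) <- paste0("PC", seq_len(ncol(x$scores)))
    attr(tb, "scores") <- dplyr::bind_cols(x$info, sc)
  }
  tb
}

#' Per-pixel PCA score map
#'
#' Applies a training loading column to every pixel of one image (scaled by
#' the training parameters) to build a score image.
#'
#' @param model An [msi_pca] model.
#' @param mat A one-image `msi_matrix`, preprocessed identically to the
#'   training objects.
#' @param component Component index.
#' @return A tibble `x`, `y`, `score`.
#' @export
score_map <- function(model, mat, component = 1L) {
  stopifnot(inherits(model, "msi_pca"))
  if (ncol(mat$values) != nrow(model$loadings)) {
    abort("matrix variable count does not match the PCA model")
  }
  if (component > ncol(model$loadings)) abort("component not in model")
  xs <- apply_autoscale(mat$values, model$scaling)
  tibble::tibble(x = mat$index$x, y = mat$index$y,
                 score = as.numeric(xs %*% model$loadings[, component]))
}
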