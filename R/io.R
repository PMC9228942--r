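# Region masks, sidecar manifests, and the unfolded pixels x variables
# matrix. Masks and manifests are tab-separated text, per the formats:
#   mask:     x <TAB> y <TAB> label
#   manifest: image_id <TAB> patient_id <TAB> class_label <TAB> polarity

#' Read a per-pixel region mask
#'
#' Reads a pathologist-style annotation table (`x`, `y`, `label`) and
#' restricts it to the coordinates of `image`; pixels absent from the table
#' are labeled `"background"`.
#'
#' @param path Tab-separated file with header `x`, `y`, `label`.
#' @param image The [msi_image] the mask annotates.
#' @return A tibble with one row per image pixel: `x`, `y`, `label`.
#' @export
read_mask <- function(path, image) {
  tab <- tibble::as_tibble(read.delim(path, sep = "\t",
                                      colClasses = c("integer", "integer",
                                                     "character")))
  stopifnot(all(c("x", "y", "label") %in% names(tab)))
  key <- paste(image$coords$x, image$coords$y)
  mkey <- paste(tab$x, tab$y)
  bad <- which(!(mkey %in% key))
  if (length(bad)) {
    abort(sprintf(
      "mask rows refer to coordinates absent from image '%s': %s",
      image$image_id,
      paste(sprintf("(%d, %d)", tab$x[bad], tab$y[bad]), collapse = ", ")))
  }
  label <- rep("background", length(key))
  label[match(mkey, key)] <- tab$label
  tibble::tibble(x = image$coords$x, y = image$coords$y, label = label)
}

#' Write a per-pixel region mask
#' @param mask Tibble with columns `x`, `y`, `label`.
#' @param path Output path (tab-separated text).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write.table(mask[, c("x", "y", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' imzML carries no class label or patient id; those live in a sidecar
#' manifest (one row per image).
#'
#' @param path Tab-separated file with header `image_id`, `patient_id`,
#'   `class_label`, `polarity`.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  tab <- tibble::as_tibble(read.delim(path, sep = "\t",
                                      colClasses = "character"))
  need <- c("image_id", "patient_id", "class_label", "polarity")
  if (!all(need %in% names(tab))) {
    abort(sprintf("manifest must have columns: %s", paste(need, collapse = ", ")))
  }
  tab
}

#' Write a sample manifest
#' @param manifest Tibble as returned by [read_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest[, c("image_id", "patient_id", "class_label", "polarity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach manifest metadata to images
#' @param images List of [msi_image]s.
#' @param manifest Tibble from [read_manifest()].
#' @return The list of images with patient ids and class labels filled in.
#' @export
apply_manifest <- function(images, manifest) {
  lapply(images, function(im) {
    i <- match(im$image_id, manifest$image_id)
    if (is.na(i)) abort(sprintf("image '%s' not in manifest", im$image_id))
    im$patient_id <- manifest$patient_id[i]
    im$class_label <- manifest$class_label[i]
    im$polarity <- manifest$polarity[i]
    im
  })
}

new_msi_matrix <- function(values, index, mz, provenance = character(),
                           flags = list()) {
  stopifnot(nrow(values) == nrow(index), ncol(values) == length(mz))
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    abort("variable m/z centers must be strictly increasing")
  }
  structure(list(values = values, index = tibble::as_tibble(index),
                 mz = as.numeric(mz), provenance = provenance, flags = flags),
            class = "msi_matrix")
}

#' @export
print.msi_matrix <- function(x, ...) {
  cat(sprintf("<msi_matrix> %d pixels x %d variables (%d images)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$index$image_id))))
  if (length(x$provenance)) {
    cat("provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Unfold binned images into a pixels-by-variables matrix
#'
#' Stacks images (already on a common binned m/z axis, see [bin_peaks()])
#' into one 2-D matrix with one row per pixel. Rows are ordered image by
#' image, then row-major by (y, x).
#'
#' @param images List of continuous [msi_image]s sharing one m/z vector.
#' @param masks Optional named list of mask tibbles (per image id, from
#'   [read_mask()]); adds a `label` column to the row index.
#' @return An `msi_matrix`: `values` (matrix), `index` (tibble with
#'   `image_id`, `patient_id`, `class_label`, `x`, `y` and optionally
#'   `label`), `mz`, and a `provenance` log.
#' @export
unfold <- function(images, masks = NULL) {
  stopifnot(length(images) >= 1)
  mz <- images[[1]]$mz
  for (im in images) {
    if (!im$continuous || length(im$mz) != length(mz) ||
        any(im$mz != mz)) {
      abort(sprintf(
        "image '%s' is not on the common variable grid of '%s'",
        im$image_id, images[[1]]$image_id))
    }
  }
  parts <- lapply(images, function(im) {
    ord <- order(im$coords$y, im$coords$x)
    idx <- tibble::tibble(
      image_id = im$image_id, patient_id = im$patient_id,
      class_label = im$class_label,
      x = im$coords$x[ord], y = im$coords$y[ord])
    if (!is.null(masks) && !is.null(masks[[im$image_id]])) {
      m <- masks[[im$image_id]]
      idx$label <- m$label[match(paste(idx$x, idx$y), paste(m$x, m$y))]
    }
    list(values = im$intensities[ord, , drop = FALSE], index = idx)
  })
  index <- dplyr::bind_rows(lapply(parts, `[[`, "index"))
  values <- do.call(rbind, lapply(parts, `[[`, "values"))
  new_msi_matrix(values, index, mz, provenance = "unfold")
}

#' Restrict an msi_matrix to one image
#' @param mat An `msi_matrix`.
#' @param image_id The image to keep.
#' @return An `msi_matrix` with only that image's rows.
#' @export
subset_image <- function(mat, image_id) {
  keep <- mat$index$image_id == image_id
  if (!any(keep)) abort(sprintf("image '%s' not present in matrix", image_id))
  new_msi_matrix(mat$values[keep, , drop = FALSE],
                 mat$index[keep, , drop = FALSE], mat$mz,
                 mat$provenance, mat$flags)
}

#' Median-spectrum object table
#'
#' Collapses each image to the per-variable median of its pixel spectra —
#' the "object" on which supervised models are trained. With an even pixel
#' count the median is the mean of the two central order statistics.
#' Background-labeled pixels (when the row index carries a `label` column)
#' are excluded from the medians.
#'
#' @param mat An `msi_matrix`.
#' @param exclude_background Drop rows labeled `"background"` before taking
#'   medians (default `TRUE`).
#' @return A tibble with one row per image: `image_id`, `patient_id`,
#'   `class_label`, and a matrix column `spectrum`; the variable m/z vector
#'   is attached as attribute `"mz"`.
#' @export
median_objects <- function(mat, exclude_background = TRUE) {
  idx <- mat$index
  keep <- rep(TRUE, nrow(idx))
  if (exclude_background && "label" %in% names(idx)) {
    keep <- is.na(idx$label) | idx$label != "background"
  }
  ids <- unique(idx$image_id)
  rows <- lapply(ids, function(id) {
    sel <- keep & idx$image_id == id
    if (!any(sel)) abort(sprintf("image '%s' has no tissue pixels", id))
    apply(mat$values[sel, , drop = FALSE], 2, median)
  })
  spectrum <- do.call(rbind, rows)
  info <- idx[match(ids, idx$image_id), c("image_id", "patient_id",
                                          "class_label")]
  out <- tibble::tibble(image_id = info$image_id,
                        patient_id = info$patient_id,
                        class_label = info$class_label,
                        spectrum = spectrum)
  attr(out, "mz") <- mat$mz
  out
}
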