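#' Construct an MSI image
#'
#' A single MALDI-MSI acquisition: a pixel grid with one mass spectrum per
#' pixel. Continuous images share one m/z axis across pixels (intensities
#' stored as a pixels-by-channels matrix); processed images carry a per-pixel
#' axis (both stored as lists of numeric vectors).
#'
#' Coordinates are 0-based (`x` = column, `y` = row); imzML's 1-based pixel
#' positions are shifted on read and restored on write.
#'
#' @param intensities For a continuous image, a numeric matrix with one row
#'   per pixel and one column per m/z channel; for a processed image, a list
#'   of numeric vectors (one per pixel).
#' @param mz For a continuous image, a strictly increasing numeric vector of
#'   m/z values (Da); for a processed image, a list of such vectors aligned
#'   with `intensities`.
#' @param coords Data frame with integer columns `x`, `y` (0-based), one row
#'   per pixel; coordinates must be unique.
#' @param image_id,patient_id Identifiers carried through the analysis.
#' @param class_label One of `"pathological"`, `"healthy"`, `"unknown"`.
#' @param polarity `"positive"` or `"negative"` ionization mode.
#' @param mz_range Acquisition m/z range `c(low, high)` in Da; defaults to
#'   the observed range.
#' @return An object of class `msi_image`.
#' @export
msi_image <- function(intensities, mz, coords, image_id,
                      patient_id = NA_character_,
                      class_label = c("unknown", "pathological", "healthy"),
                      polarity = c("positive", "negative"),
                      mz_range = NULL) {
  class_label <- match.arg(class_label)
  polarity <- match.arg(polarity)
  stopifnot(all(c("x", "y") %in% names(coords)))
  coords <- tibble::tibble(x = as.integer(coords$x),
                           y = as.integer(coords$y))
  if (anyDuplicated(paste(coords$x, coords$y)) > 0) {
    abort(sprintf("image '%s': duplicate pixel coordinates", image_id))
  }
  continuous <- is.matrix(intensities)
  if (continuous) {
    mz <- as.numeric(mz)
    if (nrow(intensities) != nrow(coords)) {
      abort("intensity rows must match pixel count")
    }
    if (ncol(intensities) != length(mz)) {
      abort("intensity columns must match m/z axis length")
    }
    check_axis(mz, "shared axis")
    if (any(intensities < 0)) abort("intensities must be non-negative")
  } else {
    stopifnot(is.list(intensities), is.list(mz))
    if (length(intensities) != nrow(coords) || length(mz) != nrow(coords)) {
      abort("per-pixel arrays must match pixel count")
    }
    for (i in seq_along(mz)) {
      if (length(mz[[i]]) != length(intensities[[i]])) {
        abort(sprintf("pixel %d: m/z and intensity lengths differ", i))
      }
      check_axis(mz[[i]], sprintf("pixel %d", i))
      if (any(intensities[[i]] < 0)) {
        abort(sprintf("pixel %d: intensities must be non-negative", i))
      }
    }
  }
  if (is.null(mz_range)) {
    allmz <- if (continuous) mz else unlist(mz)
    mz_range <- if (length(allmz)) range(allmz) else c(NA_real_, NA_real_)
  }
  structure(
    list(image_id = image_id, patient_id = patient_id,
         class_label = class_label, polarity = polarity,
         coords = coords, mz = mz, intensities = intensities,
         continuous = continuous, mz_range = as.numeric(mz_range)),
    class = "msi_image"
  )
}

check_axis <- function(mz, what) {
  if (length(mz) == 0) return(invisible(TRUE))
  if (any(!is.finite(mz))) abort(sprintf("%s: non-finite m/z values", what))
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    abort(sprintf("%s: m/z axis is not strictly increasing", what))
  }
  invisible(TRUE)
}

#' @export
print.msi_image <- function(x, ...) {
  nch <- if (x$continuous) length(x$mz) else
    sprintf("%d-%d (processed)", min(lengths(x$mz)), max(lengths(x$mz)))
  cat(sprintf(
    "<msi_image '%s'> %d pixels, %s channels, %s mode, %s/%s\n",
    x$image_id, nrow(x$coords), paste(nch, collapse = ""),
    if (x$continuous) "continuous" else "processed",
    x$class_label, x$polarity))
  invisible(x)
}

#' Number of pixels in an MSI image
#' @param image An [msi_image].
#' @return Integer pixel count.
#' @export
n_pixels <- function(image) nrow(image$coords)

# spectrum of pixel i as a numeric vector on the image's axis
pixel_spectrum <- function(image, i) {
  if (image$continuous) image$intensities[i, ] else image$intensities[[i]]
}
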