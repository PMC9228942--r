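# Shared fixtures, all generated in code. The separable-scenario run is
# expensive (full preprocessing of 22,400 spectra), so it is computed once
# per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

separable_fixture <- function() {
  cached("separable", {
    ph <- generate_phantom(default_scenario("separable", seed = 0))
    mat <- preprocess(ph$images, preprocess_config(), masks = ph$masks)
    list(phantom = ph, mat = mat, objects = median_objects(mat))
  })
}

# a small continuous image with reproducible pseudo-random intensities
small_image <- function(id = "img1", nx = 3, ny = 3, nchan = 5,
                        patient = "p1", class = "unknown", seed = 42) {
  set.seed(seed)
  coords <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L)
  msi_image(matrix(runif(nx * ny * nchan, 0, 10), nx * ny, nchan),
            mz = 100 + seq_len(nchan), coords = coords, image_id = id,
            patient_id = patient, class_label = class)
}

# msi_matrix straight from a values matrix (one image, row-major grid)
toy_matrix <- function(values, image_id = "img1", patient_id = "p1",
                       class_label = "unknown", label = NULL) {
  n <- nrow(values)
  idx <- tibble::tibble(image_id = image_id, patient_id = patient_id,
                        class_label = class_label,
                        x = seq_len(n) - 1L, y = 0L)
  if (!is.null(label)) idx$label <- label
  msiclass:::new_msi_matrix(values, idx, mz = 100 + seq_len(ncol(values)))
}

# object table with a given spectra matrix and labels
toy_objects <- function(spectra, class_label, patient_id = NULL) {
  n <- nrow(spectra)
  tibble::tibble(
    image_id = sprintf("img%02d", seq_len(n)),
    patient_id = patient_id %||% sprintf("pat%02d", seq_len(n)),
    class_label = class_label, spectrum = spectra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# map true phantom channel m/z values onto binned variable indices
nearest_variable <- function(mz_targets, mz_axis, tol = 0.11) {
  idx <- vapply(mz_targets, function(z) which.min(abs(mz_axis - z)), 1L)
  stopifnot(all(abs(mz_axis[idx] - mz_targets) <= tol))
  idx
}

# dense R reference for the AsLS baseline: identical iteration scheme,
# solved with base solve() on the explicit penalized system
asls_dense_reference <- function(y, p, lambda, iterations) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  z <- numeric(n)
  for (i in seq_len(iterations)) {
    z <- solve(diag(w) + P, w * y)
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}
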