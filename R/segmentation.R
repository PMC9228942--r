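# Unsupervised spatial segmentation of one image by bisecting k-means and
# Pearson colocalization of m/z variables with cluster masks.

# deterministic 2-means: centers seeded by farthest point from the leaf
# centroid, then farthest point from the first seed; Lloyd iterations to a
# 1e-8 centroid tolerance or 300 iterations
two_means <- function(x, tol = 1e-8, max_iter = 300L) {
  centroid <- colMeans(x)
  d0 <- rowSums(sweep(x, 2, centroid)^2)
  c1 <- x[which.max(d0), ]
  d1 <- rowSums(sweep(x, 2, c1)^2)
  c2 <- x[which.max(d1), ]
  assign <- rep(1L, nrow(x))
  for (it in seq_len(max_iter)) {
    da <- rowSums(sweep(x, 2, c1)^2)
    db <- rowSums(sweep(x, 2, c2)^2)
    assign <- ifelse(db < da, 2L, 1L)
    if (!any(assign == 2L) || all(assign == 2L)) break
    n1 <- colMeans(x[assign == 1L, , drop = FALSE])
    n2 <- colMeans(x[assign == 2L, , drop = FALSE])
    shift <- max(sum((n1 - c1)^2), sum((n2 - c2)^2))
    c1 <- n1; c2 <- n2
    if (shift < tol) break
  }
  assign
}

wcss_of <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(sweep(x, 2, colMeans(x))^2)
}

#' Bisecting k-means segmentation of one image
#'
#' Iteratively splits the leaf with the largest within-cluster sum of
#' squares (ties: larger pixel count, then lower node id) by deterministic
#' 2-means on the preprocessed pixel spectra (Euclidean distance) until `k`
#' leaves remain. Background-labeled pixels are excluded. The procedure is
#' fully deterministic; `seed` is accepted for interface stability only.
#'
#' @param mat A one-image `msi_matrix` (preprocessed).
#' @param k Number of leaf clusters.
#' @param seed Unused (deterministic initialization); kept so segmentation
#'   calls are reproducible by construction.
#' @param distance `"euclidean"` (default) or `"correlation"` (spectra are
#'   row-standardized first, so Euclidean distance orders like 1 - r).
#' @return An object of class `msi_segmentation`: `labels` (tibble `x`, `y`,
#'   `cluster`), `nodes` (split tree with per-node WCSS), `split_order`.
#' @export
bisecting_kmeans <- function(mat, k = 2L, seed = 0L,
                             distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  stopifnot(length(unique(mat$index$image_id)) == 1, k >= 1)
  tissue <- rep(TRUE, nrow(mat$values))
  if ("label" %in% names(mat$index)) {
    tissue <- is.na(mat$index$label) | mat$index$label != "background"
  }
  x <- mat$values[tissue, , drop = FALSE]
  if (distance == "correlation") {
    mu <- rowMeans(x)
    s <- sqrt(pmax(apply(x, 1, var), .Machine$double.eps))
    x <- (x - mu) / s
  }
  n <- nrow(x)
  if (k > n) abort(sprintf("k = %d exceeds the %d tissue pixels", k, n))

  nodes <- list(list(id = 1L, parent = NA_integer_,
                     pixels = seq_len(n), wcss = wcss_of(x), leaf = TRUE))
  split_order <- integer(0)
  next_id <- 2L
  while (sum(vapply(nodes, `[[`, logical(1), "leaf")) < k) {
    leaves <- Filter(function(nd) nd$leaf && length(nd$pixels) >= 2, nodes)
    if (!length(leaves)) break
    ord <- order(-vapply(leaves, `[[`, numeric(1), "wcss"),
                 -vapply(leaves, function(nd) length(nd$pixels), numeric(1)),
                 vapply(leaves, `[[`, integer(1), "id"))
    target <- leaves[[ord[1]]]
    sub <- x[target$pixels, , drop = FALSE]
    assign <- two_means(sub)
    if (length(unique(assign)) < 2) {
      # duplicate points: deterministic fallback split keeps the partition valid
      assign <- rep(1L, nrow(sub)); assign[1] <- 2L
    }
    for (child in 1:2) {
      px <- target$pixels[assign == child]
      nodes[[next_id]] <- list(id = next_id, parent = target$id,
                               pixels = px,
                               wcss = wcss_of(x[px, , drop = FALSE]),
                               leaf = TRUE)
      next_id <- next_id + 1L
    }
    nodes[[target$id]]$leaf <- FALSE
    split_order <- c(split_order, target$id)
  }

  leaf_ids <- vapply(Filter(function(nd) nd$leaf, nodes), `[[`,
                     integer(1), "id")
  cluster <- integer(n)
  for (ci in seq_along(leaf_ids)) {
    cluster[nodes[[leaf_ids[ci]]]$pixels] <- ci
  }
  labels <- tibble::tibble(x = mat$index$x[tissue], y = mat$index$y[tissue],
                           cluster = cluster)
  nodes_tb <- dplyr::bind_rows(lapply(nodes, function(nd) {
    tibble::tibble(node = nd$id, parent = nd$parent,
                   n_pixels = length(nd$pixels), wcss = nd$wcss,
                   leaf = nd$leaf,
                   cluster = if (nd$leaf) match(nd$id, leaf_ids)
                             else NA_integer_)
  }))
  structure(list(labels = labels, nodes = nodes_tb,
                 split_order = split_order, k = length(leaf_ids),
                 image_id = mat$index$image_id[1],
                 total_wcss = sum(nodes_tb$wcss[nodes_tb$leaf])),
            class = "msi_segmentation")
}

#' @export
print.msi_segmentation <- function(x, ...) {
  cat(sprintf("<msi_segmentation '%s'> k = %d, total WCSS %.4g\n",
              x$image_id, x$k, x$total_wcss))
  invisible(x)
}

#' Spatial indicator mask of one cluster
#' @param seg An [bisecting_kmeans()] result.
#' @param cluster_id Leaf cluster id (1..k).
#' @return A tibble `x`, `y`, `mask` with 1 for member pixels, 0 otherwise.
#' @export
cluster_mask <- function(seg, cluster_id) {
  if (!cluster_id %in% seg$labels$cluster) {
    abort(sprintf("cluster %s is not a leaf of this segmentation",
                  cluster_id))
  }
  tibble::tibble(x = seg$labels$x, y = seg$labels$y,
                 mask = as.numeric(seg$labels$cluster == cluster_id))
}

#' Sample Pearson correlation coefficient
#'
#' Computed from the textbook sums; constant input is undefined and returns
#' `NaN` with a warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 2).
#' @return The correlation in `[-1, 1]`, or `NaN`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) {
    warn("Pearson correlation undefined for constant input")
    return(NaN)
  }
  sum(xc * yc) / den
}

#' Ions colocalized with a cluster mask
#'
#' Per variable, the Pearson correlation between the cluster's spatial
#' indicator and the variable's intensity over the same pixels; hits whose
#' correlation reaches `r_min` are returned sorted by descending correlation.
#'
#' @param mat A one-image `msi_matrix` (same image the mask came from).
#' @param mask A [cluster_mask()] tibble.
#' @param r_min Correlation threshold (default 0.5, inclusive).
#' @return A tibble `mz`, `r` (and the mask's cluster if known), sorted by
#'   descending `r`.
#' @export
colocalize <- function(mat, mask, r_min = 0.5) {
  key <- paste(mat$index$x, mat$index$y)
  sel <- match(paste(mask$x, mask$y), key)
  if (anyNA(sel)) abort("mask coordinates are not all present in the matrix")
  v <- mat$values[sel, , drop = FALSE]
  m <- mask$mask
  r <- vapply(seq_len(ncol(v)), function(j) {
    if (var(v[, j]) == 0 || var(m) == 0) return(NA_real_)
    pearson(m, v[, j])
  }, numeric(1))
  hits <- tibble::tibble(mz = mat$mz, r = r)
  hits <- hits[!is.na(hits$r) & hits$r >= r_min, ]
  hits[order(-hits$r), ]
}
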