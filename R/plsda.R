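# PLS-DA: NIPALS PLS1 regression on a binary-coded class response, with
# classification by one-dimensional linear discriminant analysis of the
# predicted response. The positive class is "healthy" (y = 1,
# pathological = 0), matching the convention that sensitivity/specificity
# refer to the healthy class.

Y_CODING <- c(pathological = 0, healthy = 1)

code_y <- function(class_label) {
  bad <- setdiff(unique(class_label), names(Y_CODING))
  if (length(bad)) {
    abort(sprintf("unknown class labels: %s", paste(bad, collapse = ", ")))
  }
  unname(Y_CODING[class_label])
}

#' Fit a PLS-DA model
#'
#' NIPALS PLS1 on the auto-scaled spectra and the centered binary response.
#' Per component `a`: weight `w_a` proportional to `X' y` (unit norm),
#' scores `t_a = X w_a`, x-loading `p_a = X' t_a / (t_a' t_a)`, y-loading
#' `q_a = y' t_a / (t_a' t_a)`, then `X` and `y` are deflated. The
#' regression vector is `W (P' W)^{-1} q`. An LDA threshold (equal priors,
#' pooled variance) is fitted to the training predictions for every
#' component count `1..n_lv`.
#'
#' Component extraction stops early if the residual `X' y` is numerically
#' zero (the response is exhausted); the fitted `n_lv` reflects that.
#'
#' @param objects Training object table from [median_objects()]; both
#'   classes must be present.
#' @param n_lv Number of latent variables.
#' @param scaling Optional pre-fitted [fit_autoscale()] parameters.
#' @return An object of class `plsda` with weights `W`, x-loadings `P`,
#'   y-loadings `q`, per-component score norms, regression vectors and LDA
#'   parameters for each component count, VIP scores, and the scaling.
#' @export
plsda <- function(objects, n_lv = 2L, scaling = NULL) {
  x <- spectra_of(objects)
  y <- code_y(objects$class_label)
  if (length(unique(y)) < 2) abort("training set must contain both classes")
  n_lv <- as.integer(n_lv)
  stopifnot(n_lv >= 1)
  if (is.null(scaling)) scaling <- fit_autoscale(x)
  xs <- apply_autoscale(x, scaling)
  ybar <- mean(y)
  yc <- y - ybar

  p <- ncol(xs)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0)
  q <- numeric(0); tt <- numeric(0)
  Xa <- xs; ya <- yc
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- Xa %*% w
    t2 <- sum(t_a^2)
    if (t2 < 1e-12) break
    p_a <- crossprod(Xa, t_a) / t2
    q_a <- sum(ya * t_a) / t2
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - q_a * t_a
    W <- cbind(W, w); P <- cbind(P, p_a)
    q <- c(q, q_a); tt <- c(tt, t2)
  }
  if (ncol(W) == 0) abort("no PLS component could be extracted")
  n_lv <- ncol(W)

  # regression vector and LDA threshold for every component count 1..n_lv
  coefs <- vector("list", n_lv)
  lda <- vector("list", n_lv)
  for (a in seq_len(n_lv)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    b <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
    coefs[[a]] <- as.numeric(b)
    yhat <- as.numeric(xs %*% b) + ybar
    lda[[a]] <- lda_threshold(yhat, objects$class_label)
  }

  model <- structure(
    list(n_lv = n_lv, W = W, P = P, q = q, t2 = tt,
         coef = coefs[[n_lv]], coefs = coefs, ybar = ybar,
         scaling = scaling, lda = lda[[n_lv]], ldas = lda,
         selected_variables = NULL),
    class = "plsda")
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d latent variables, %d variables\n",
              x$n_lv, nrow(x$W)))
  invisible(x)
}

#' One-dimensional Gaussian LDA threshold
#'
#' Linear discriminant analysis of the predicted PLS response: per-class
#' means and pooled variance, equal priors. With equal priors the decision
#' boundary reduces to the midpoint of the class means; classification
#' assigns the nearest class mean.
#'
#' @param predictions Numeric predicted responses for the training objects.
#' @param labels Class labels (`"pathological"` / `"healthy"`).
#' @return A list of class `lda1d`: class means, pooled variance, boundary.
#' @export
lda_threshold <- function(predictions, labels) {
  y <- code_y(labels)
  if (length(unique(y)) < 2) abort("both classes required")
  m0 <- mean(predictions[y == 0])
  m1 <- mean(predictions[y == 1])
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  ss <- sum((predictions[y == 0] - m0)^2) + sum((predictions[y == 1] - m1)^2)
  pooled <- if (n0 + n1 > 2) ss / (n0 + n1 - 2) else 0
  if (pooled == 0 && m0 == m1) {
    abort("degenerate LDA: equal class means with zero pooled variance")
  }
  structure(list(mean_pathological = m0, mean_healthy = m1,
                 pooled_var = pooled, boundary = (m0 + m1) / 2,
                 priors = c(pathological = 0.5, healthy = 0.5)),
            class = "lda1d")
}

classify_lda <- function(lda, yhat) {
  ifelse(abs(yhat - lda$mean_healthy) < abs(yhat - lda$mean_pathological),
         "healthy", "pathological")
}

#' Predict class membership for new objects
#'
#' @param object A fitted [plsda] model.
#' @param newdata Object table, `msi_matrix`, or numeric matrix on the same
#'   variables (same preprocessing as training). If the model was fitted on
#'   a VIP-reduced variable set, `newdata` must carry the full variable set
#'   and is subset internally.
#' @param n_lv Component count to predict with (default: the fitted count).
#' @param ... Unused.
#' @return A tibble with `yhat` (predicted response) and `class`.
#' @export
predict.plsda <- function(object, newdata, n_lv = object$n_lv, ...) {
  x <- spectra_of(newdata)
  if (!is.null(object$selected_variables) &&
      ncol(x) != nrow(object$W)) {
    x <- x[, object$selected_variables, drop = FALSE]
  }
  if (ncol(x) != length(object$scaling$mean)) {
    abort("newdata variable count does not match the model")
  }
  stopifnot(n_lv >= 1, n_lv <= object$n_lv)
  xs <- apply_autoscale(x, object$scaling)
  yhat <- as.numeric(xs %*% object$coefs[[n_lv]]) + object$ybar
  tibble::tibble(yhat = yhat,
                 class = classify_lda(object$ldas[[n_lv]], yhat))
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` with
#' `SSY_a = q_a^2 t_a' t_a` and `p` the variable count; the squared scores
#' satisfy `sum_j VIP_j^2 = p`.
#'
#' @param model A fitted [plsda] model.
#' @param n_lv Component count to accumulate over (default: all fitted).
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model, n_lv = model$n_lv) {
  stopifnot(inherits(model, "plsda"), n_lv >= 1, n_lv <= model$n_lv)
  p <- nrow(model$W)
  a <- seq_len(n_lv)
  ssy <- model$q[a]^2 * model$t2[a]
  wn <- sweep(model$W[, a, drop = FALSE], 2,
              sqrt(colSums(model$W[, a, drop = FALSE]^2)), "/")
  as.numeric(sqrt(p * (wn^2 %*% ssy) / sum(ssy)))
}

#' Select variables by VIP score
#'
#' Indices of variables with VIP strictly greater than the threshold, in
#' variable order. Refitting on the reduced set is the caller's
#' responsibility (see [lopo_cv()] for leakage-free per-fold selection).
#'
#' @param model A fitted [plsda] model.
#' @param threshold VIP cutoff (default 2, strict `>`).
#' @return Integer vector of variable indices (empty with a warning if no
#'   variable passes).
#' @export
select_vip <- function(model, threshold = 2) {
  idx <- which(model$vip > threshold)
  if (!length(idx)) warn("no variable exceeds the VIP threshold")
  idx
}

#' @export
glance.plsda <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, n_vars = nrow(x$W),
                 n_selected = length(x$selected_variables %||% integer(0)),
                 boundary = x$lda$boundary)
}

#' @export
tidy.plsda <- function(x, ...) {
  tibble::tibble(variable = seq_len(nrow(x$W)),
                 coefficient = x$coef, vip = x$vip)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
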