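#' Principal component analysis by singular value decomposition
#'
#' Intended for autoscaled data; `center = TRUE` (the default) removes column
#' means so the decomposition is a PCA even on raw input. Components are
#' ordered by decreasing variance and the sign of each loading column is fixed
#' so that its largest-magnitude entry is positive, making results
#' deterministic.
#'
#' @param matrix numeric samples x variables matrix.
#' @param n_components number of components to retain; at most
#'   `min(nrow - 1, ncol)`. Default: all.
#' @param center subtract column means before decomposition (default TRUE).
#' @return Object of class `pca_model`: `loadings` (variables x components,
#'   orthonormal columns), `scores` (samples x components),
#'   `explained_variance_pct`, `center`.
#' @export
pca_fit <- function(matrix, n_components = NULL, center = TRUE) {
  if (!is.matrix(matrix) || nrow(matrix) < 2)
    stop("pca_fit needs a matrix with at least 2 rows")
  max_comp <- min(nrow(matrix) - 1, ncol(matrix))
  n_components <- n_components %||% max_comp
  if (n_components < 1 || n_components > max_comp)
    stop("n_components must be between 1 and ", max_comp)
  ctr <- if (center) colMeans(matrix) else rep(0, ncol(matrix))
  xc <- sweep(matrix, 2, ctr)
  total_var <- sum(xc^2)
  if (total_var == 0)
    stop("matrix has zero variance after centering; explained variance undefined")
  sv <- svd(xc)
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive in every column
  flip <- vapply(k, function(j) {
    lj <- loadings[, j]
    sign(lj[which.max(abs(lj))])
  }, 0)
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- xc %*% loadings
  expl <- 100 * sv$d[k]^2 / total_var
  dimnames(loadings) <- list(colnames(matrix), paste0("PC", k))
  dimnames(scores) <- list(rownames(matrix), paste0("PC", k))
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_pct = expl, center = ctr),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components over %d variables\n",
              ncol(x$loadings), nrow(x$loadings)))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", utils::head(x$explained_variance_pct, 5)),
            collapse = ", "),
      if (length(x$explained_variance_pct) > 5) "..." else "", "\n")
  invisible(x)
}

#' PCA of SOM neuron weights with class annotation
#'
#' Interprets a trained self-organizing map by running PCA on its
#' neurons x variables weight matrix (mean-centered; the weights already live
#' in autoscaled data space, so no re-scaling is applied) and annotating every
#' neuron by the class membership of the samples it won: `"class_a"`,
#' `"class_b"`, `"mixed"`, or `"empty"` (the black-circle convention for
#' neurons that attracted no sample).
#'
#' @param som_model a trained [som_fit()] model.
#' @param labels factor with two levels for the samples the SOM was trained
#'   on, in training order.
#' @param n_components components to retain (default 2).
#' @return List with `pca` (a `pca_model` over neurons) and `annotation`
#'   (factor per neuron: class_a / class_b / mixed / empty).
#' @export
pca_on_som_weights <- function(som_model, labels, n_components = 2) {
  if (!inherits(som_model, "som_model"))
    stop("som_model must be a trained som_model")
  labels <- as.factor(labels)
  if (length(labels) != length(som_model$assignments))
    stop("labels length must match the number of training samples")
  pca <- pca_fit(som_model$weights, n_components = n_components, center = TRUE)
  lv <- levels(labels)
  annotation <- vapply(seq_len(nrow(som_model$weights)), function(j) {
    cls <- unique(labels[som_model$assignments == j])
    if (!length(cls)) "empty"
    else if (length(cls) > 1) "mixed"
    else if (cls == lv[1]) "class_a" else "class_b"
  }, "")
  list(pca = pca,
       annotation = factor(annotation,
                           levels = c("class_a", "class_b", "mixed", "empty")))
}
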