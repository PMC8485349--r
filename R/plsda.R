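# Lean PLS1 core used by both the user-facing model and the CV engine.
# X must already be column-centered/scaled, y centered. Returns weights W,
# loadings P, score matrix TT, y-loadings q, regression vector b, and the
# per-LV explained sums of squares.
pls1_core <- function(X, y, n_lv) {
  p <- ncol(X)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  TT <- matrix(0, nrow(X), n_lv); q <- numeric(n_lv)
  ssx_lv <- numeric(n_lv); ssy_lv <- numeric(n_lv)
  Xa <- X; ya <- y
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14)
      stop("PLS component ", a, " degenerate: no remaining covariance with the class")
    w <- w / nw
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    pl <- crossprod(Xa, t_) / tt
    qa <- sum(ya * t_) / tt
    Xa <- Xa - t_ %*% t(pl)
    ya <- ya - qa * t_
    W[, a] <- w; P[, a] <- pl; TT[, a] <- t_; q[a] <- qa
    ssx_lv[a] <- tt * sum(pl^2)
    ssy_lv[a] <- qa^2 * tt
  }
  b <- W %*% solve(crossprod(P, W), q)
  list(W = W, P = P, TT = TT, q = q, b = b, ssx_lv = ssx_lv, ssy_lv = ssy_lv)
}

# Wold VIP: VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )
vip_from_core <- function(core) {
  ssy <- core$ssy_lv
  if (sum(ssy) <= 0)
    stop("degenerate model: no class-membership variance explained; VIP undefined")
  wn2 <- sweep(core$W, 2, sqrt(colSums(core$W^2)), "/")^2
  sqrt(nrow(core$W) * as.numeric(wn2 %*% ssy) / sum(ssy))
}

#' Fit a two-class PLS-DA model
#'
#' PLS1 regression of a symmetric class indicator (class a = -1,
#' class b = +1, centered) on the autoscaled abundance matrix, by the NIPALS
#' algorithm. Scaling is done internally (training column means and standard
#' deviations are stored and reused for prediction), so `matrix` should be
#' raw or consistently pre-treated data. Positive coefficients read as
#' association with class b — with class b the later timepoint, up-regulation
#' with aging.
#'
#' @param matrix numeric samples x variables matrix.
#' @param labels factor with exactly two levels present.
#' @param n_lv number of latent variables, at most `min(n - 1, p)`.
#' @param scale autoscale columns internally (default TRUE); set FALSE if the
#'   matrix is already autoscaled.
#' @return Object of class `plsda_model`: weights/loadings/scores, y
#'   loadings, `coefficients` (on the scaled scale), `vip`,
#'   `explained_x_pct`, `explained_y_pct` (per LV), class coding and scaling
#'   parameters, plus in-sample `fitted_decision` and `fitted_class`.
#' @export
plsda_fit <- function(matrix, labels, n_lv = 2, scale = TRUE) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2)
    stop("labels must contain exactly two classes (got ",
         nlevels(labels), ")")
  n <- nrow(matrix); p <- ncol(matrix)
  if (length(labels) != n) stop("labels length must match rows of matrix")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop("n_lv must be between 1 and min(n-1, p) = ", min(n - 1, p))
  ctr <- colMeans(matrix)
  scl <- if (scale) apply(matrix, 2, stats::sd) else rep(1, p)
  if (any(scl == 0))
    stop("cannot scale constant column(s): ",
         paste(colnames(matrix)[scl == 0] %||% which(scl == 0), collapse = ", "))
  X <- sweep(sweep(matrix, 2, ctr), 2, scl, "/")
  y_raw <- ifelse(labels == levels(labels)[2], 1, -1)
  y_mean <- mean(y_raw)
  core <- pls1_core(X, y_raw - y_mean, n_lv)
  ssy_tot <- sum((y_raw - y_mean)^2)
  fitted <- as.numeric(X %*% core$b) + y_mean
  model <- structure(list(
    n_lv = n_lv,
    x_weights = core$W, x_loadings = core$P, x_scores = core$TT,
    y_loadings = core$q,
    coefficients = stats::setNames(as.numeric(core$b),
                                   colnames(matrix)),
    intercept = y_mean,
    vip = stats::setNames(vip_from_core(core), colnames(matrix)),
    explained_x_pct = 100 * core$ssx_lv / sum(X^2),
    explained_y_pct = 100 * core$ssy_lv / ssy_tot,
    class_levels = levels(labels),
    x_center = ctr, x_scale = scl,
    fitted_decision = fitted,
    fitted_class = decision_to_class(fitted, levels(labels))$class),
    class = "plsda_model")
  dimnames(model$x_weights) <- dimnames(model$x_loadings) <-
    list(colnames(matrix), paste0("LV", seq_len(n_lv)))
  model
}

# decision > 0 -> class b; exact ties assigned to class a and flagged
decision_to_class <- function(decision, class_levels) {
  cls <- factor(ifelse(decision > 0, class_levels[2], class_levels[1]),
                levels = class_levels)
  list(class = cls, tie = decision == 0)
}

#' Predict classes from a PLS-DA model
#'
#' New samples are scaled with the training scaling parameters; the decision
#' value is the predicted class indicator, thresholded at zero. An exact tie
#' (decision value 0) is deterministically assigned to class a and flagged.
#'
#' @param model a [plsda_fit()] model.
#' @param new_matrix samples x variables matrix with the training columns.
#' @return List: `class` (factor), `decision` (numeric), `tie` (logical).
#' @export
plsda_predict <- function(model, new_matrix) {
  stopifnot(inherits(model, "plsda_model"))
  if (is.null(dim(new_matrix))) new_matrix <- matrix(new_matrix, nrow = 1)
  if (ncol(new_matrix) != length(model$x_center))
    stop("column mismatch: model has ", length(model$x_center),
         " variables, new data has ", ncol(new_matrix))
  if (!is.null(colnames(new_matrix)) && !is.null(names(model$coefficients)) &&
      !identical(colnames(new_matrix), names(model$coefficients)))
    stop("column names of new data do not match training variables")
  X <- sweep(sweep(new_matrix, 2, model$x_center), 2, model$x_scale, "/")
  decision <- as.numeric(X %*% model$coefficients) + model$intercept
  c(decision_to_class(decision, model$class_levels),
    list(decision = decision))
}

#' Variable importance in projection
#'
#' Standard Wold VIP scores of a fitted PLS-DA model:
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja/||w_a||)^2 / sum_a SSY_a )`, where
#' `SSY_a` is the class-membership variance explained by latent variable a.
#' The mean of squared VIPs over variables is identically 1.
#'
#' @param model a [plsda_fit()] model.
#' @return Named numeric vector of VIP scores (>= 0).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  model$vip
}

#' Coefficient-based direction calls
#'
#' @param model a [plsda_fit()] model.
#' @return data.frame: `variable`, `coefficient`, `call` ("up_in_class_b" for
#'   positive coefficients, "down_in_class_b" for negative).
#' @export
coefficient_report <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  data.frame(variable = names(model$coefficients),
             coefficient = as.numeric(model$coefficients),
             call = ifelse(model$coefficients >= 0,
                           "up_in_class_b", "down_in_class_b"),
             stringsAsFactors = FALSE)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d LVs, %d variables, classes %s vs %s\n",
              x$n_lv, length(x$coefficients),
              x$class_levels[1], x$class_levels[2]))
  cat(sprintf("  X variance explained: %.2f%%; class membership: %.2f%%\n",
              sum(x$explained_x_pct), sum(x$explained_y_pct)))
  invisible(x)
}
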