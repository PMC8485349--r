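#' Repeated leave-more-out cross-validation scheme
#'
#' Each repeat partitions the samples at random into `n_groups` disjoint
#' cancellation groups of about `1/n_groups` of the samples; every group is
#' held out once while the model is refit on the rest. The whole procedure is
#' repeated `n_repeats` times with fresh random partitions.
#'
#' @param n_groups cancellation groups per repeat (default 5, i.e. 20% test).
#' @param n_repeats number of repeats (default 1000).
#' @param seed integer seed; partitions are deterministic given the seed.
#' @return Object of class `cv_scheme` with `test_fraction = 1/n_groups`.
#' @export
cv_scheme <- function(n_groups = 5, n_repeats = 1000, seed = 1) {
  if (n_groups < 2) stop_field("n_groups", "must be >= 2")
  if (n_repeats < 1) stop_field("n_repeats", "must be >= 1")
  structure(list(n_groups = as.integer(n_groups),
                 test_fraction = 1 / n_groups,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

# Random partition of n samples into k disjoint, covering groups; when n is
# not divisible by k, the remainder is distributed one per group, largest
# groups first.
make_folds <- function(n, k) {
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  split(sample.int(n), rep(seq_len(k), times = sizes))
}

#' Classification performance metrics for a two-class problem
#'
#' Accuracy, non-error rate (mean of class-conditional accuracies), and
#' per-class sensitivity, specificity and precision from the 2x2 confusion
#' table. Metrics whose denominator class is absent are `NA`.
#'
#' @param true,predicted factors of equal length over the same two levels.
#' @return Object of class `classification_metrics`: `accuracy_pct`,
#'   `ner_pct`, named vectors `sensitivity`, `specificity`, `precision`
#'   (fractions), and the `confusion` table (rows = true).
#' @export
classification_metrics <- function(true, predicted) {
  true <- as.factor(true)
  predicted <- factor(predicted, levels = levels(true))
  if (length(true) != length(predicted))
    stop("true and predicted labels must have equal length")
  if (nlevels(true) != 2) stop("expected exactly two classes")
  conf <- table(true = true, predicted = predicted)
  lv <- levels(true)
  per_class_acc <- diag(conf) / rowSums(conf)
  per_class_acc[rowSums(conf) == 0] <- NA
  sens <- per_class_acc
  spec <- rev(per_class_acc)
  names(spec) <- lv
  prec <- diag(conf) / colSums(conf)
  prec[colSums(conf) == 0] <- NA
  structure(list(accuracy_pct = 100 * sum(diag(conf)) / length(true),
                 ner_pct = 100 * mean(per_class_acc),
                 sensitivity = sens, specificity = spec, precision = prec,
                 confusion = conf),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, non-error rate %.2f%%\n",
              x$accuracy_pct, x$ner_pct))
  print(x$confusion)
  invisible(x)
}

#' Repeated leave-more-out cross-validation of a PLS-DA model
#'
#' For each repeat, the samples are partitioned into the scheme's
#' cancellation groups; each group is predicted by a PLS-DA model fit on the
#' remaining samples, with autoscaling and class-indicator centering
#' recomputed on the training portion only (no information leaks from the
#' held-out group). Each sample is predicted exactly once per repeat; metrics
#' are computed per repeat from the pooled out-of-fold predictions and then
#' averaged over repeats. A repeat whose partition leaves a training fold
#' with a single class is redrawn (an error is raised after `max_redraws`
#' failed draws). Deterministic given the scheme seed.
#'
#' @param matrix raw samples x variables matrix.
#' @param labels two-level factor.
#' @param n_lv latent variables (capped per fold at the training rank).
#' @param scheme a [cv_scheme()].
#' @param max_redraws redraw budget for degenerate partitions.
#' @return Object of class `cv_metrics`: mean and sd of accuracy % and
#'   non-error rate %, mean per-class sensitivity/specificity/precision,
#'   `per_repeat` accuracy vector, `n_redraws`.
#' @export
repeated_cv <- function(matrix, labels, n_lv, scheme = cv_scheme(),
                        max_redraws = 100) {
  stopifnot(inherits(scheme, "cv_scheme"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("labels must contain exactly two classes")
  y <- ifelse(labels == levels(labels)[2], 1, -1)
  n <- nrow(matrix)
  if (n < scheme$n_groups)
    stop("fewer samples (", n, ") than cancellation groups (", scheme$n_groups, ")")
  nr <- scheme$n_repeats
  acc <- ner <- numeric(nr)
  sens_a <- sens_b <- prec_a <- prec_b <- numeric(nr)
  redraws <- 0L
  with_seed(scheme$seed, {
    for (r in seq_len(nr)) {
      repeat {
        folds <- make_folds(n, scheme$n_groups)
        ok <- all(vapply(folds, function(f)
          any(y[-f] > 0) && any(y[-f] < 0), TRUE))
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > max_redraws)
          stop("could not draw a partition with two-class training folds ",
               "after ", max_redraws, " attempts")
      }
      pred <- numeric(n)
      for (f in folds) {
        tr <- matrix[-f, , drop = FALSE]
        ytr <- y[-f]
        ctr <- colMeans(tr)
        xc <- sweep(tr, 2, ctr)
        scl <- sqrt(colSums(xc^2) / (nrow(tr) - 1))
        scl[scl == 0] <- Inf        # constant-in-fold columns contribute 0
        Xtr <- sweep(xc, 2, scl, "/")
        ym <- mean(ytr)
        A <- min(n_lv, nrow(tr) - 1, ncol(tr))
        core <- pls1_core(Xtr, ytr - ym, A)
        Xte <- sweep(sweep(matrix[f, , drop = FALSE], 2, ctr), 2, scl, "/")
        pred[f] <- as.numeric(Xte %*% core$b) + ym
      }
      pc <- ifelse(pred > 0, 1, -1)       # ties -> class a
      tb <- y > 0
      tp <- sum(pc > 0 & tb);  fn <- sum(pc < 0 & tb)
      tn <- sum(pc < 0 & !tb); fp <- sum(pc > 0 & !tb)
      acc[r] <- (tp + tn) / n
      sb <- tp / (tp + fn); sa <- tn / (tn + fp)
      ner[r] <- (sa + sb) / 2
      sens_a[r] <- sa; sens_b[r] <- sb
      prec_a[r] <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
      prec_b[r] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    }
  })
  lv <- levels(labels)
  structure(list(
    accuracy_pct = 100 * mean(acc), accuracy_sd_pct = 100 * stats::sd(acc),
    ner_pct = 100 * mean(ner), ner_sd_pct = 100 * stats::sd(ner),
    sensitivity = stats::setNames(c(mean(sens_a), mean(sens_b)), lv),
    specificity = stats::setNames(c(mean(sens_b), mean(sens_a)), lv),
    precision = stats::setNames(c(mean(prec_a, na.rm = TRUE),
                                  mean(prec_b, na.rm = TRUE)), lv),
    per_repeat = 100 * acc,
    n_redraws = redraws,
    n_lv = n_lv, scheme = scheme),
    class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("repeated CV (%d repeats, %d groups): accuracy %.2f%% (sd %.2f), NER %.2f%%\n",
              x$scheme$n_repeats, x$scheme$n_groups,
              x$accuracy_pct, x$accuracy_sd_pct, x$ner_pct))
  invisible(x)
}

#' Choose the number of latent variables by cross-validation
#'
#' Evaluates [repeated_cv()] for 1..`max_lv` latent variables (same scheme,
#' hence identical partitions, for a fair comparison) and returns the count
#' with the highest mean CV accuracy; ties go to the fewest latent variables.
#'
#' @param matrix,labels,scheme as in [repeated_cv()].
#' @param max_lv largest latent-variable count to try.
#' @return List: `best_n_lv`, `accuracy_pct` (per candidate count).
#' @export
select_n_lv <- function(matrix, labels, scheme = cv_scheme(), max_lv = 3) {
  max_lv <- min(max_lv, nrow(matrix) - 1, ncol(matrix))
  accs <- vapply(seq_len(max_lv), function(a)
    repeated_cv(matrix, labels, a, scheme)$accuracy_pct, 0)
  list(best_n_lv = which.max(accs), accuracy_pct = accs)
}

#' VIP-driven backward elimination of variables
#'
#' The biomarker-selection engine: starting from all variables, repeatedly
#' (1) cross-validate the PLS-DA model on the current variable set,
#' (2) compute VIP scores on the full-data fit, and (3) remove the single
#' variable with the lowest VIP (ties broken by first index), continuing
#' until one variable remains. The returned selection is the step with the
#' highest mean CV accuracy; ties go to the model with fewest variables.
#' The latent-variable count is selected once on the full variable set by
#' [select_n_lv()] and capped by the shrinking variable count
#' (`reselect_lv = TRUE` re-selects it at every step, at `max_lv` times the
#' CV cost). The CV partitions are re-seeded identically at every step, so
#' refitting the selected set with the same scheme reproduces the logged
#' metrics exactly.
#'
#' @param matrix raw samples x variables matrix (>= 2 variables).
#' @param labels two-level factor.
#' @param scheme a [cv_scheme()].
#' @param max_lv largest latent-variable count considered.
#' @param reselect_lv re-run LV selection at every elimination step.
#' @return Object of class `selection_trace`: `trace` (data.frame, one row
#'   per step: `step`, `n_vars`, `n_lv`, `cv_accuracy_pct`, `cv_ner_pct`,
#'   `removed`, `removed_vip`), `selected_set`, `best_n_lv`, `cv_metrics`
#'   (of the selected step), `final_model` (full-data PLS-DA refit on the
#'   selected set), `fitting_metrics`.
#' @export
backward_eliminate <- function(matrix, labels, scheme = cv_scheme(),
                               max_lv = 3, reselect_lv = FALSE) {
  p <- ncol(matrix)
  if (p < 2) stop("backward elimination needs at least 2 variables")
  vars <- colnames(matrix) %||% sprintf("V%d", seq_len(p))
  colnames(matrix) <- vars
  labels <- droplevels(as.factor(labels))
  n_lv_full <- select_n_lv(matrix, labels, scheme, max_lv)$best_n_lv

  cur <- vars
  steps <- vector("list", p)
  cvs <- vector("list", p)
  step_sets <- vector("list", p)
  for (s in seq_len(p)) {
    A <- if (reselect_lv && length(cur) > 1)
      select_n_lv(matrix[, cur, drop = FALSE], labels, scheme,
                  min(max_lv, length(cur)))$best_n_lv
    else min(n_lv_full, length(cur))
    cv <- repeated_cv(matrix[, cur, drop = FALSE], labels, A, scheme)
    fit <- plsda_fit(matrix[, cur, drop = FALSE], labels, n_lv = A)
    vip <- vip_scores(fit)
    if (!all(is.finite(vip))) stop("non-finite VIP at step ", s)
    step_sets[[s]] <- cur
    cvs[[s]] <- cv
    if (length(cur) > 1) {
      drop_idx <- which.min(vip)            # ties: first index
      steps[[s]] <- data.frame(step = s, n_vars = length(cur), n_lv = A,
                               cv_accuracy_pct = cv$accuracy_pct,
                               cv_ner_pct = cv$ner_pct,
                               removed = cur[drop_idx],
                               removed_vip = vip[[drop_idx]],
                               stringsAsFactors = FALSE)
      cur <- cur[-drop_idx]
    } else {
      steps[[s]] <- data.frame(step = s, n_vars = 1L, n_lv = A,
                               cv_accuracy_pct = cv$accuracy_pct,
                               cv_ner_pct = cv$ner_pct,
                               removed = NA_character_,
                               removed_vip = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  trace <- do.call(rbind, steps)
  rownames(trace) <- NULL
  best <- which(trace$cv_accuracy_pct == max(trace$cv_accuracy_pct))
  best <- best[which.min(trace$n_vars[best])]    # ties: fewest variables
  selected_set <- step_sets[[best]]
  final_model <- plsda_fit(matrix[, selected_set, drop = FALSE], labels,
                           n_lv = trace$n_lv[best])
  structure(list(trace = trace,
                 selected_set = selected_set,
                 best_n_lv = trace$n_lv[best],
                 cv_metrics = cvs[[best]],
                 final_model = final_model,
                 fitting_metrics = classification_metrics(
                   labels, final_model$fitted_class),
                 all_vars = vars),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("backward elimination: %d -> %d variables, %d LVs\n",
              length(x$all_vars), length(x$selected_set), x$best_n_lv))
  cat(sprintf("  best CV accuracy %.2f%% (fitting %.2f%%)\n",
              x$cv_metrics$accuracy_pct, x$fitting_metrics$accuracy_pct))
  invisible(x)
}

#' Write a selection trace as TSV
#'
#' @param trace a `selection_trace`.
#' @param path TSV path (one row per elimination step).
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  utils::write.table(trace$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
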