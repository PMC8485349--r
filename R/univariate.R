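#' Fold-change and t-test screening of protein abundances
#'
#' For every protein, a two-sided two-sample t-test between the two classes
#' on raw abundances, plus the fold change `FC = mean(class_b) / mean(class_a)`.
#' A protein is flagged as dysregulated when `p < p_threshold` AND
#' (`FC > fc_upper` OR `FC < fc_lower`); both threshold comparisons are
#' strict, and no multiple-testing correction is applied. Student's pooled-
#' variance test is the default; Welch's test is available via
#' `var_equal = FALSE`.
#'
#' @param matrix numeric samples x proteins matrix, raw positive abundances.
#' @param labels factor of length `nrow(matrix)` with exactly two levels;
#'   the first level is class a (earlier timepoint), the second class b.
#' @param p_threshold significance threshold for the t-test.
#' @param fc_upper,fc_lower strict fold-change thresholds for up/down calls
#'   (defaults 1.3 and 0.769).
#' @param var_equal pooled-variance Student's t-test (default) or Welch.
#' @return data.frame of class `univariate_screen`: `protein_id`, `p_value`,
#'   `fold_change`, `direction` ("up"/"down"/"unchanged"), `significant`.
#' @export
ttest_fc_screen <- function(matrix, labels, p_threshold = 0.05,
                            fc_upper = 1.3, fc_lower = 0.769,
                            var_equal = TRUE) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  ia <- labels == levels(labels)[1]
  ib <- labels == levels(labels)[2]
  na <- sum(ia); nb <- sum(ib)
  if (na < 2 || nb < 2)
    stop("each class needs at least 2 samples (got ", na, " and ", nb, ")")
  xa <- matrix[ia, , drop = FALSE]
  xb <- matrix[ib, , drop = FALSE]
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(sweep(xa, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(xb, 2, mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (mb - ma) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0 & mb == ma] <- 1
  fc <- mb / ma
  direction <- ifelse(fc > fc_upper, "up",
                      ifelse(fc < fc_lower, "down", "unchanged"))
  res <- data.frame(protein_id = colnames(matrix) %||% seq_len(ncol(matrix)),
                    p_value = p, fold_change = fc, direction = direction,
                    significant = p < p_threshold & direction != "unchanged",
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("univariate_screen", "data.frame")
  attr(res, "thresholds") <- c(p = p_threshold, fc_upper = fc_upper,
                               fc_lower = fc_lower)
  res
}

#' Correlate protein abundances with phenotype variables
#'
#' Pearson correlation of each protein with each phenotype variable at the
#' biological-sample level (technical replicates averaged). The p-value comes
#' from the t transform `t = r * sqrt(n-2) / sqrt(1-r^2)` with `n-2` degrees
#' of freedom, two-sided. Zero-variance vectors yield `NA` with a warning.
#'
#' @param dataset an [abundance_dataset()].
#' @param phenotypes data.frame with `animal_id`, `timepoint` and numeric
#'   phenotype columns, one row per biological sample.
#' @param p_threshold significance flag threshold (default 0.05).
#' @return Object of class `correlation_matrix`: matrices `r`, `p`,
#'   `significant` (proteins x phenotypes) and `n`, the number of paired
#'   biological samples.
#' @export
correlate_with_phenotypes <- function(dataset, phenotypes, p_threshold = 0.05) {
  stopifnot(inherits(dataset, "abundance_dataset"))
  key_d <- paste(dataset$metadata$animal_id, dataset$metadata$timepoint)
  key_p <- paste(phenotypes$animal_id, phenotypes$timepoint)
  shared <- intersect(unique(key_d), key_p)
  if (length(shared) < 3)
    stop("need at least 3 paired biological samples (found ", length(shared), ")")
  agg <- t(vapply(shared, function(k)
    colMeans(dataset$values[key_d == k, , drop = FALSE]),
    numeric(ncol(dataset$values))))
  phen <- phenotypes[match(shared, key_p),
                     vapply(phenotypes, is.numeric, TRUE) &
                       !(names(phenotypes) %in% c("animal_id", "timepoint", "tech_rep")),
                     drop = FALSE]
  n <- length(shared)
  r <- suppressWarnings(stats::cor(agg, as.matrix(phen)))
  zero_var <- apply(agg, 2, stats::sd) == 0
  zero_var_ph <- apply(as.matrix(phen), 2, stats::sd) == 0
  if (any(zero_var) || any(zero_var_ph))
    warning("zero-variance vector(s); correlations reported as NA")
  r[zero_var, ] <- NA
  r[, zero_var_ph] <- NA
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  structure(list(r = r, p = p, significant = !is.na(p) & p < p_threshold,
                 n = n),
            class = "correlation_matrix")
}

#' Shear-force two-way ANOVA with per-animal tenderization differences
#'
#' Analyzes replicate-level Warner-Bratzler shear (WBS) force records with a
#' two-way fixed-effects ANOVA (animal, days of aging, and their interaction),
#' follows up significant effects with Tukey HSD comparisons, and reports the
#' per-animal DWBS — the difference between the mean shear force at the later
#' and the earlier aging day — together with its pooled standard deviation.
#' Lower force means more tender meat; a negative average DWBS quantifies
#' tenderization over aging.
#'
#' @param records data.frame with columns `animal`, `day` (two levels) and
#'   `value` (force, N); optionally `gender` and `replicate`. At least two
#'   replicates per animal x day cell, no empty cells.
#' @param p_threshold significance level for the omnibus tests (default 0.05).
#' @return Object of class `anova_result`: `anova_table` (F and p for animal,
#'   days, interaction), `dwbs` (per-animal difference and pooled sd),
#'   `avg_dwbs`, and `tukey` (list of Tukey HSD tables for significant
#'   effects, or NULL).
#' @export
wbs_anova <- function(records, p_threshold = 0.05) {
  need <- c("animal", "day", "value")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  records$animal <- factor(records$animal)
  records$day <- factor(records$day)
  if (nlevels(records$day) != 2)
    stop("expected exactly two aging days, got ", nlevels(records$day))
  cell <- table(records$animal, records$day)
  if (any(cell == 0))
    stop("empty animal x day cell(s): ",
         paste(which(cell == 0, arr.ind = TRUE), collapse = ", "))
  if (any(cell < 2))
    stop("need >= 2 replicates per animal x day cell")

  day_lo <- levels(records$day)[1]
  day_hi <- levels(records$day)[2]
  per_animal <- do.call(rbind, lapply(levels(records$animal), function(a) {
    v1 <- records$value[records$animal == a & records$day == day_lo]
    v2 <- records$value[records$animal == a & records$day == day_hi]
    pooled_sd <- sqrt(((length(v1) - 1) * stats::var(v1) +
                       (length(v2) - 1) * stats::var(v2)) /
                      (length(v1) + length(v2) - 2))
    data.frame(animal = a, dwbs = mean(v2) - mean(v1), pooled_sd = pooled_sd,
               stringsAsFactors = FALSE)
  }))

  constant <- stats::var(records$value) == 0
  if (constant) {
    atab <- data.frame(term = c("animal", "days", "animal:days"),
                       F = NA_real_, p = NA_real_)
    tukey <- NULL
  } else {
    fit <- stats::aov(value ~ animal * day, data = records)
    s <- summary(fit)[[1]]
    atab <- data.frame(term = c("animal", "days", "animal:days"),
                       F = s[["F value"]][1:3], p = s[["Pr(>F)"]][1:3])
    sig <- atab$term[!is.na(atab$p) & atab$p < p_threshold]
    tukey <- NULL
    if (length(sig)) {
      th <- stats::TukeyHSD(fit)
      keep <- intersect(c("animal", "day"),
                        sub("days", "day", sub(":.*", "", sig)))
      tukey <- th[names(th) %in% keep]
      if (!length(tukey)) tukey <- th["animal:day"]
    }
  }
  structure(list(anova_table = atab,
                 dwbs = per_animal,
                 avg_dwbs = mean(per_animal$dwbs),
                 tukey = tukey),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA on shear force (animal, days, interaction)\n")
  print(x$anova_table, row.names = FALSE)
  cat(sprintf("Average DWBS: %.4g\n", x$avg_dwbs))
  invisible(x)
}
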