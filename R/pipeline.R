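#' Configuration for a full comparison run
#'
#' Bundles the stage parameters of [run_comparison()]. SOM defaults follow
#' the analysis protocol: a 10x10 grid with 300 epochs when the comparison
#' spans three or more timepoints (the general comparison), an 8x8 grid with
#' 200 epochs for pairwise comparisons.
#'
#' @param som_rows,som_cols,som_epochs SOM grid and training length;
#'   `NULL` = choose by design.
#' @param cv_repeats repeats of the leave-more-out CV (default 1000).
#' @param cv_groups cancellation groups (default 5).
#' @param max_lv largest latent-variable count considered.
#' @param p_threshold,fc_upper,fc_lower univariate screening thresholds.
#' @param seed master seed; per-stage seeds are derived from it, so stages
#'   are independently re-runnable.
#' @return Object of class `comparison_config`.
#' @export
comparison_config <- function(som_rows = NULL, som_cols = NULL,
                              som_epochs = NULL,
                              cv_repeats = 1000, cv_groups = 5,
                              max_lv = 3,
                              p_threshold = 0.05,
                              fc_upper = 1.3, fc_lower = 0.769,
                              seed = 1) {
  structure(list(som_rows = som_rows, som_cols = som_cols,
                 som_epochs = som_epochs,
                 cv_repeats = cv_repeats, cv_groups = cv_groups,
                 max_lv = max_lv, p_threshold = p_threshold,
                 fc_upper = fc_upper, fc_lower = fc_lower,
                 seed = as.integer(seed)),
            class = "comparison_config")
}

#' Run the full analysis for one comparison
#'
#' Executes the complete pipeline for a two-class timepoint comparison:
#' subset, autoscale, univariate fold-change + t-test screen, PCA, SOM with
#' PCA-on-weights interpretation, and PLS-DA backward elimination with
#' repeated leave-more-out cross-validation. Fully reproducible from the
#' config seed; when `out_dir` is given, all artifacts (panels, trace, SOM
#' model, top map, summary JSON) are written there.
#'
#' @param dataset an [abundance_dataset()].
#' @param design a [comparison_design()].
#' @param config a [comparison_config()].
#' @param out_dir optional directory for artifacts.
#' @return Object of class `comparison_report`: `design`, `univariate`
#'   (screen table), `univariate_panel`, `multivariate_panel` (selected
#'   variables with coefficient and VIP), `overlap` (panel intersection),
#'   `pca`, `som`, `top_map`, `som_weight_pca`, `selection` (the trace),
#'   `cv_metrics`, `fitting_metrics`, `provenance`.
#' @export
run_comparison <- function(dataset, design, config = comparison_config(),
                           out_dir = NULL) {
  stopifnot(inherits(dataset, "abundance_dataset"),
            inherits(design, "comparison_design"),
            inherits(config, "comparison_config"))
  run_stage <- function(stage, fn) {
    tryCatch(fn, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  sub <- run_stage("subset", subset_for_design(dataset, design))
  scaled <- run_stage("autoscale", autoscale(sub$values))

  uni <- run_stage("univariate",
    ttest_fc_screen(sub$values, sub$labels,
                    p_threshold = config$p_threshold,
                    fc_upper = config$fc_upper, fc_lower = config$fc_lower))
  pca <- run_stage("pca", pca_fit(scaled$values))

  pairwise <- length(c(design$class_a, design$class_b)) < 3
  som_cfg <- som_config(
    rows = config$som_rows %||% (if (pairwise) 8 else 10),
    cols = config$som_cols %||% (if (pairwise) 8 else 10),
    epochs = config$som_epochs %||% (if (pairwise) 200 else 300),
    seed = derive_seed(config$seed, 2L))
  som <- run_stage("som", som_fit(scaled$values, som_cfg))
  tmap <- run_stage("top_map", top_map(som, sub$labels))
  wpca <- run_stage("som_weight_pca", pca_on_som_weights(som, sub$labels))

  scheme <- cv_scheme(n_groups = config$cv_groups,
                      n_repeats = config$cv_repeats,
                      seed = derive_seed(config$seed, 3L))
  sel <- run_stage("backward_elimination",
                   backward_eliminate(sub$values, sub$labels, scheme,
                                      max_lv = config$max_lv))

  uni_panel <- uni$protein_id[uni$significant]
  multi_panel <- data.frame(
    protein_id = sel$selected_set,
    coefficient = as.numeric(sel$final_model$coefficients),
    vip = as.numeric(sel$final_model$vip),
    stringsAsFactors = FALSE)
  report <- structure(list(
    design = design,
    n_samples = nrow(sub$values),
    univariate = uni,
    univariate_panel = uni_panel,
    multivariate_panel = multi_panel,
    overlap = intersect(uni_panel, multi_panel$protein_id),
    pca = pca,
    som = som, top_map = tmap, som_weight_pca = wpca,
    selection = sel,
    cv_metrics = sel$cv_metrics,
    fitting_metrics = sel$fitting_metrics,
    protein_universe = colnames(dataset$values),
    provenance = list(seed = config$seed,
                      som_seed = som_cfg$seed, cv_seed = scheme$seed,
                      cv_repeats = config$cv_repeats,
                      som_grid = c(som_cfg$rows, som_cfg$cols),
                      som_epochs = som_cfg$epochs,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "comparison_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison '%s' (%s vs %s), %d samples\n", x$design$name,
              x$design$label_a, x$design$label_b, x$n_samples))
  cat(sprintf("  univariate panel: %d proteins; multivariate panel: %d proteins (overlap %d)\n",
              length(x$univariate_panel), nrow(x$multivariate_panel),
              length(x$overlap)))
  cat(sprintf("  selected model: %d LVs, CV accuracy %.2f%%, fitting %.2f%%\n",
              x$selection$best_n_lv, x$cv_metrics$accuracy_pct,
              x$fitting_metrics$accuracy_pct))
  invisible(x)
}

#' Write the artifacts of a comparison report
#'
#' @param report a `comparison_report`.
#' @param out_dir directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$univariate,
                     file.path(out_dir, "univariate_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$multivariate_panel,
                     file.path(out_dir, "multivariate_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_selection_trace(report$selection,
                        file.path(out_dir, "selection_trace.tsv"))
  utils::write.table(report$top_map, file.path(out_dir, "top_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_som(report$som, file.path(out_dir, "som_model.json"))
  jsonlite::write_json(list(
    design = unclass(report$design),
    n_samples = report$n_samples,
    univariate_panel = report$univariate_panel,
    multivariate_panel = report$multivariate_panel$protein_id,
    overlap = report$overlap,
    best_n_lv = report$selection$best_n_lv,
    cv_accuracy_pct = report$cv_metrics$accuracy_pct,
    cv_ner_pct = report$cv_metrics$ner_pct,
    fitting_accuracy_pct = report$fitting_metrics$accuracy_pct,
    provenance = report$provenance),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Cross-design overlap summary of biomarker panels
#'
#' Computes the pairwise and higher-order intersections of the multivariate
#' panels of several comparison reports (the Venn counts across designs).
#'
#' @param reports named list of `comparison_report` objects (>= 2) over the
#'   same protein universe, or a named list of character vectors (panels).
#' @return Object of class `overlap_summary`: data.frame `table` with one
#'   row per design combination (`designs`, `n_overlap`) and `members`, the
#'   corresponding protein lists.
#' @export
overlap_summary <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports")
  panels <- lapply(reports, function(r) {
    if (inherits(r, "comparison_report")) r$multivariate_panel$protein_id
    else as.character(r)
  })
  if (is.null(names(panels)) || any(!nzchar(names(panels))))
    names(panels) <- paste0("panel", seq_along(panels))
  universes <- lapply(reports, function(r)
    if (inherits(r, "comparison_report")) r$protein_universe else NULL)
  universes <- Filter(Negate(is.null), universes)
  if (length(universes) > 1 &&
      !all(vapply(universes[-1], identical, TRUE, universes[[1]])))
    stop("reports have mismatched protein universes")
  k <- length(panels)
  combos <- unlist(lapply(2:k, function(m)
    utils::combn(k, m, simplify = FALSE)), recursive = FALSE)
  members <- lapply(combos, function(idx) Reduce(intersect, panels[idx]))
  tab <- data.frame(
    designs = vapply(combos, function(idx)
      paste(names(panels)[idx], collapse = "&"), ""),
    n_overlap = lengths(members),
    stringsAsFactors = FALSE)
  names(members) <- tab$designs
  sizes <- data.frame(designs = names(panels),
                      n_overlap = lengths(panels),
                      stringsAsFactors = FALSE)
  structure(list(table = rbind(sizes, tab), members = members,
                 panels = panels),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
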