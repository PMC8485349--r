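#' Construct an abundance dataset
#'
#' The universal input of the pipeline: a samples x proteins matrix of
#' positive abundances (arbitrary intensity units) together with per-sample
#' metadata. Rows are individual measurements, i.e. technical replicates of
#' biological samples.
#'
#' @param values numeric matrix, samples in rows, proteins in columns; must
#'   carry unique row names (sample ids) and column names (protein ids).
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `animal_id`, `gender`, `timepoint`, `tech_rep`, in the same
#'   order as the rows of `values`.
#' @return An object of class `abundance_dataset` with elements `values` and
#'   `metadata`.
#' @export
abundance_dataset <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("values", "must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_field("values", "must have sample row names and protein column names")
  if (anyDuplicated(rownames(values)))
    stop_field("values", paste("duplicate sample ids:",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")))
  if (anyDuplicated(colnames(values)))
    stop_field("values", paste("duplicate protein ids:",
      paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", ")))
  if (!all(is.finite(values)))
    stop_field("values", "all abundances must be finite")
  req <- c("sample_id", "animal_id", "gender", "timepoint", "tech_rep")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop_field("metadata", paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(metadata) != nrow(values))
    stop_field("metadata", sprintf("has %d rows but matrix has %d samples",
                                   nrow(metadata), nrow(values)))
  if (!identical(as.character(metadata$sample_id), rownames(values)))
    stop_field("metadata", "sample_id column must match matrix row names in order")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  structure(list(values = values, metadata = metadata),
            class = "abundance_dataset")
}

#' @export
print.abundance_dataset <- function(x, ...) {
  tp <- table(x$metadata$timepoint)
  cat(sprintf("abundance_dataset: %d samples x %d proteins\n",
              nrow(x$values), ncol(x$values)))
  cat("  timepoints:", paste(sprintf("%s=%d", names(tp), tp), collapse = ", "), "\n")
  cat(sprintf("  animals: %d, technical replicates per biological sample: %s\n",
              length(unique(x$metadata$animal_id)),
              paste(sort(unique(table(paste(x$metadata$animal_id,
                                            x$metadata$timepoint)))), collapse = "/")))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write an abundance dataset to TSV files
#'
#' Values are printed at full double precision (17 significant digits) so
#' that a write/read cycle round-trips bit-for-bit.
#'
#' @param dataset an [abundance_dataset()].
#' @param matrix_path,metadata_path output file paths (tab-separated, UTF-8).
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, matrix_path, metadata_path) {
  stopifnot(inherits(dataset, "abundance_dataset"))
  vals <- dataset$values
  header <- paste(c("sample_id", colnames(vals)), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i)
    paste(c(rownames(vals)[i], fmt_num(vals[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), matrix_path, useBytes = TRUE)
  utils::write.table(dataset$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Read an abundance dataset from TSV files
#'
#' @param matrix_path TSV with a `sample_id` column followed by one numeric
#'   column per protein.
#' @param metadata_path TSV with columns `sample_id`, `animal_id`, `gender`,
#'   `timepoint`, `tech_rep`.
#' @return An [abundance_dataset()].
#' @export
read_dataset <- function(matrix_path, metadata_path) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character")
  if (names(raw)[1] != "sample_id")
    stop("matrix file must have 'sample_id' as its first column")
  ids <- raw[[1]]
  prot <- names(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(prot),
                 dimnames = list(ids, prot))
  for (j in seq_along(prot)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) & !is.na(raw[[j + 1]]) & raw[[j + 1]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric abundance at row '%s', column '%s': '%s'",
                   ids[bad[1]], prot[j], raw[[j + 1]][bad[1]]))
    vals[, j] <- v
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  extra_m <- setdiff(ids, meta$sample_id)
  extra_d <- setdiff(meta$sample_id, ids)
  if (length(extra_m) || length(extra_d))
    stop("sample sets differ between matrix and metadata; ",
         if (length(extra_m)) paste("missing from metadata:",
                                    paste(extra_m, collapse = ", ")) else "",
         if (length(extra_d)) paste(" missing from matrix:",
                                    paste(extra_d, collapse = ", ")) else "")
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  abundance_dataset(vals, meta)
}

#' Write / read a phenotype table
#'
#' One row per biological sample (animal x timepoint), one column per
#' phenotype variable. Values printed at full precision.
#'
#' @param phenotypes data.frame as produced by [synthesize_phenotypes()].
#' @param path TSV file path.
#' @return `write_phenotypes` the table invisibly; `read_phenotypes` the table.
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- phenotypes
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(phenotypes)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Define a two-class comparison between timepoint groups
#'
#' A comparison contrasts two disjoint sets of timepoint labels, e.g. early
#' aging (`t0` vs `t12`) or general aging (`t0` vs `t12`+`t26`).
#'
#' @param name label for the comparison.
#' @param class_a,class_b character vectors of timepoint labels; disjoint and
#'   non-empty. `class_b` is conventionally the later timepoint(s), so that
#'   positive PLS-DA coefficients read as up-regulation with aging.
#' @return An object of class `comparison_design`.
#' @export
comparison_design <- function(name, class_a, class_b) {
  if (!length(class_a) || !length(class_b))
    stop_field("class_a/class_b", "both classes must be non-empty")
  if (length(intersect(class_a, class_b)))
    stop_field("class_a/class_b", paste("timepoints in both classes:",
      paste(intersect(class_a, class_b), collapse = ", ")))
  structure(list(name = name,
                 class_a = as.character(class_a),
                 class_b = as.character(class_b),
                 label_a = paste(class_a, collapse = "+"),
                 label_b = paste(class_b, collapse = "+")),
            class = "comparison_design")
}

#' The four standard aging comparisons
#'
#' Early (`t0` vs `t12`), late (`t12` vs `t26`), long (`t0` vs `t26`) and
#' general (`t0` vs `t12`+`t26`) aging.
#'
#' @return Named list of [comparison_design()] objects.
#' @export
standard_designs <- function() {
  list(early   = comparison_design("early",   "t0",  "t12"),
       late    = comparison_design("late",    "t12", "t26"),
       long    = comparison_design("long",    "t0",  "t26"),
       general = comparison_design("general", "t0",  c("t12", "t26")))
}

#' Subset a dataset for a two-class comparison
#'
#' @param dataset an [abundance_dataset()].
#' @param design a [comparison_design()].
#' @return List with `values` (rows restricted to the two classes), `labels`
#'   (factor with the class-a label first), and the matching `metadata`.
#' @export
subset_for_design <- function(dataset, design) {
  stopifnot(inherits(dataset, "abundance_dataset"),
            inherits(design, "comparison_design"))
  tp <- dataset$metadata$timepoint
  unknown <- setdiff(c(design$class_a, design$class_b), unique(tp))
  if (length(unknown))
    stop("timepoints not present in dataset: ", paste(unknown, collapse = ", "))
  keep <- tp %in% c(design$class_a, design$class_b)
  labels <- factor(ifelse(tp[keep] %in% design$class_a,
                          design$label_a, design$label_b),
                   levels = c(design$label_a, design$label_b))
  list(values = dataset$values[keep, , drop = FALSE],
       labels = labels,
       metadata = dataset$metadata[keep, , drop = FALSE])
}

#' Autoscale a matrix
#'
#' Centers every column to mean zero and scales it to unit sample standard
#' deviation (n-1 denominator), the standard pre-treatment before PCA,
#' SOM and PLS-DA in chemometrics. The column means and standard deviations
#' are retained so the identical transform can be applied to new samples
#' (e.g. cross-validation test folds).
#'
#' @param matrix numeric matrix with at least two rows and no constant column.
#' @return Object of class `scaled_matrix`: `values`, `center`, `scale`.
#' @export
autoscale <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) < 2)
    stop("autoscale needs a matrix with at least 2 rows")
  ctr <- colMeans(matrix)
  sds <- apply(matrix, 2, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const))
    stop("cannot autoscale constant column(s): ",
         paste(colnames(matrix)[const] %||% const, collapse = ", "))
  vals <- sweep(sweep(matrix, 2, ctr, "-"), 2, sds, "/")
  structure(list(values = vals, center = ctr, scale = sds),
            class = "scaled_matrix")
}

#' Apply a stored autoscaling to new data
#'
#' @param scaling a `scaled_matrix` (or anything with `center` and `scale`).
#' @param newdata matrix with the same columns as the training matrix.
#' @return Scaled numeric matrix.
#' @export
apply_scaling <- function(scaling, newdata) {
  if (ncol(newdata) != length(scaling$center))
    stop("column mismatch: new data has ", ncol(newdata), " columns, scaling has ",
         length(scaling$center))
  sweep(sweep(newdata, 2, scaling$center, "-"), 2, scaling$scale, "/")
}
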