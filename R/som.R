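#' Configuration of a Kohonen self-organizing map
#'
#' Batch-trained SOM on a hexagonal grid with toroidal boundary (left/right
#' and top/bottom edges wrap around). Grid dimensions must be even so the
#' hexagonal lattice closes consistently on the torus. The learning rate
#' decreases linearly from `lr_start` to `lr_end` over the epochs, and the
#' Gaussian neighborhood radius shrinks linearly from `neighborhood_start`
#' to zero, so the final epochs correct only the winning neuron.
#'
#' @param rows,cols grid dimensions; even integers >= 2.
#' @param epochs number of training cycles (>= 1).
#' @param lr_start,lr_end learning-rate schedule endpoints,
#'   `lr_start > lr_end > 0`; defaults 0.5 and 0.01.
#' @param neighborhood_start initial neighborhood radius in grid units;
#'   default half the larger grid dimension.
#' @param seed integer seed for the random weight initialization.
#' @return Object of class `som_config`.
#' @export
som_config <- function(rows = 10, cols = 10, epochs = 300,
                       lr_start = 0.5, lr_end = 0.01,
                       neighborhood_start = max(rows, cols) / 2,
                       seed = 1) {
  if (rows < 2 || cols < 2 || rows %% 2 != 0 || cols %% 2 != 0)
    stop_field("rows/cols", "grid dimensions must be even and >= 2 for a hexagonal torus")
  if (epochs < 1) stop_field("epochs", "must be >= 1")
  if (!(lr_start > lr_end && lr_end > 0))
    stop_field("lr_start/lr_end", "need lr_start > lr_end > 0")
  if (neighborhood_start < 0)
    stop_field("neighborhood_start", "must be >= 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 epochs = as.integer(epochs),
                 lr_start = lr_start, lr_end = lr_end,
                 neighborhood_start = neighborhood_start,
                 topology = "hexagonal", boundary = "toroidal",
                 seed = as.integer(seed)),
            class = "som_config")
}

# Neurons are indexed row-major: neuron (r, c) [0-based] has index r*cols+c+1.
# Hexagonal layout is pointy-top "odd-r" offset: odd rows are shifted right.
# Cube coordinates turn offset positions into a lattice where the hex grid
# distance is (|dx|+|dy|+|dz|)/2.
hex_cube <- function(r, c) {
  x <- c - (r - (r %% 2)) / 2
  z <- r
  cbind(x = x, y = -x - z, z = z)
}

hex_cube_dist <- function(a, b) {
  (abs(a[, 1] - b[, 1]) + abs(a[, 2] - b[, 2]) + abs(a[, 3] - b[, 3])) / 2
}

#' Hexagonal distance between neurons on a toroidal grid
#'
#' Lattice (step-count) distance between two neurons of a hexagonal grid
#' whose boundaries wrap in both directions, computed by the minimal-image
#' rule: the smallest hexagonal distance over the nine wrapped copies of the
#' target neuron. Symmetric, and zero iff the neurons coincide.
#'
#' @param rows,cols grid dimensions (even).
#' @param i,j neuron indices in 1..rows*cols (row-major); vectorized.
#' @return Numeric distance(s) in grid units.
#' @export
hex_toroidal_distance <- function(rows, cols, i, j) {
  n <- rows * cols
  if (any(i < 1 | i > n) || any(j < 1 | j > n))
    stop("neuron index out of grid (1..", n, ")")
  ri <- (i - 1) %/% cols; ci <- (i - 1) %% cols
  rj <- (j - 1) %/% cols; cj <- (j - 1) %% cols
  a <- hex_cube(ri, ci)
  best <- rep(Inf, length(i))
  for (dr in c(-rows, 0, rows)) for (dc in c(-cols, 0, cols)) {
    b <- hex_cube(rj + dr, cj + dc)
    best <- pmin(best, hex_cube_dist(a, b))
  }
  best
}

# All-pairs neuron distance matrix for a rows x cols hexagonal torus.
hex_dist_matrix <- function(rows, cols) {
  n <- rows * cols
  idx <- seq_len(n)
  ii <- rep(idx, times = n)
  jj <- rep(idx, each = n)
  matrix(hex_toroidal_distance(rows, cols, ii, jj), n, n)
}

#' Train a batch self-organizing map
#'
#' Batch Kohonen algorithm: every epoch assigns each sample to its winning
#' neuron (minimum Euclidean distance over the weight vectors, ties broken by
#' the lowest neuron index) and then moves every neuron toward the
#' neighborhood-kernel-weighted mean of the samples, blended with the current
#' weights by the epoch's learning rate:
#' `w_new = (1 - alpha) * w_old + alpha * target`. The kernel is Gaussian in
#' hexagonal-toroidal grid distance, `h = exp(-d^2 / (2 sigma^2))`, with
#' `sigma` shrinking linearly to zero (winner-only in the final epoch).
#' Neurons receiving no kernel mass in an epoch keep their weights. Training
#' is deterministic given the config seed.
#'
#' @param matrix autoscaled samples x variables matrix; all finite, >= 1 row.
#' @param config a [som_config()].
#' @return Object of class `som_model`: `weights` (neurons x variables),
#'   `assignments` (winning neuron per sample, recomputed after the last
#'   update), `qe_trace` (quantization error per epoch: mean Euclidean
#'   distance from each sample to its winner at the start of the epoch),
#'   `grid` (rows, cols), `config`.
#' @export
som_fit <- function(matrix, config = som_config()) {
  stopifnot(inherits(config, "som_config"))
  if (!is.matrix(matrix) || nrow(matrix) == 0)
    stop("som_fit needs a non-empty numeric matrix")
  if (!all(is.finite(matrix)))
    stop("som_fit input must be finite")
  n <- nrow(matrix); p <- ncol(matrix)
  nn <- config$rows * config$cols
  D2 <- hex_dist_matrix(config$rows, config$cols)^2
  x2 <- rowSums(matrix^2)

  W <- with_seed(config$seed,
                 matrix(stats::rnorm(nn * p), nn, p))
  qe <- numeric(config$epochs)
  denom <- max(1L, config$epochs - 1L)
  for (e in seq_len(config$epochs)) {
    frac <- (e - 1) / denom
    alpha <- config$lr_start + (config$lr_end - config$lr_start) * frac
    sigma <- config$neighborhood_start * (1 - frac)
    d2 <- outer(x2, rowSums(W^2), "+") - 2 * matrix %*% t(W)
    winners <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(sqrt(pmax(d2[cbind(seq_len(n), winners)], 0)))
    H <- if (sigma > 0) exp(-D2 / (2 * sigma^2)) else (D2 == 0) * 1
    K <- H[, winners, drop = FALSE]            # neurons x samples
    mass <- rowSums(K)
    target <- K %*% matrix
    upd <- mass > 1e-12
    target[upd, ] <- target[upd, , drop = FALSE] / mass[upd]
    target[!upd, ] <- W[!upd, , drop = FALSE]
    W <- (1 - alpha) * W + alpha * target
  }
  d2 <- outer(x2, rowSums(W^2), "+") - 2 * matrix %*% t(W)
  winners <- max.col(-d2, ties.method = "first")
  dimnames(W) <- list(sprintf("n%03d", seq_len(nn)), colnames(matrix))
  structure(list(weights = W, assignments = winners, qe_trace = qe,
                 grid = c(rows = config$rows, cols = config$cols),
                 config = config),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d hexagonal toroidal grid, %d epochs\n",
              x$grid["rows"], x$grid["cols"], x$config$epochs))
  cat(sprintf("  final quantization error: %.4f\n",
              x$qe_trace[length(x$qe_trace)]))
  invisible(x)
}

#' Per-neuron occupancy summary (top map)
#'
#' Summarizes which samples each neuron of a trained map attracted: counts
#' per class, emptiness, majority class and purity.
#'
#' @param som_model a trained [som_fit()] model.
#' @param labels factor (any number of levels) for the training samples, in
#'   training order.
#' @return data.frame of class `top_map`, one row per neuron: `neuron`,
#'   `row`, `col`, one count column per class, `n`, `empty`, `majority`,
#'   `purity`.
#' @export
top_map <- function(som_model, labels) {
  if (!inherits(som_model, "som_model")) stop("need a trained som_model")
  labels <- as.factor(labels)
  if (length(labels) != length(som_model$assignments))
    stop("labels length (", length(labels), ") must match sample count (",
         length(som_model$assignments), ")")
  nn <- nrow(som_model$weights)
  cols <- som_model$grid["cols"]
  counts <- matrix(0L, nn, nlevels(labels),
                   dimnames = list(NULL, levels(labels)))
  tab <- table(som_model$assignments, labels)
  counts[as.integer(rownames(tab)), ] <- as.integer(tab)
  n <- rowSums(counts)
  majority <- ifelse(n == 0, NA, levels(labels)[max.col(counts, "first")])
  out <- data.frame(neuron = seq_len(nn),
                    row = (seq_len(nn) - 1) %/% cols + 1,
                    col = (seq_len(nn) - 1) %% cols + 1,
                    counts, n = n, empty = n == 0,
                    majority = majority,
                    purity = ifelse(n == 0, NA,
                                    apply(counts, 1, max) / pmax(n, 1)),
                    check.names = FALSE)
  class(out) <- c("top_map", "data.frame")
  out
}

#' Serialize / restore a SOM model as JSON text
#'
#' @param som_model a trained model.
#' @param path JSON file path.
#' @return `write_som` the path invisibly; `read_som` a `som_model`.
#' @export
write_som <- function(som_model, path) {
  stopifnot(inherits(som_model, "som_model"))
  obj <- list(grid = as.list(som_model$grid),
              config = unclass(som_model$config),
              weights = som_model$weights,
              assignments = som_model$assignments,
              qe_trace = som_model$qe_trace,
              variable_ids = colnames(som_model$weights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$weights)
  dimnames(W) <- list(sprintf("n%03d", seq_len(nrow(W))), obj$variable_ids)
  cfg <- do.call(som_config, obj$config[c("rows", "cols", "epochs", "lr_start",
                                          "lr_end", "neighborhood_start", "seed")])
  structure(list(weights = W, assignments = obj$assignments,
                 qe_trace = obj$qe_trace,
                 grid = c(rows = cfg$rows, cols = cfg$cols),
                 config = cfg),
            class = "som_model")
}
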