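# Shared fixtures, all generated in code.

# Independent-groups null design: each animal contributes exactly one
# biological sample, so the two classes are independent and a two-sample
# t-test's assumptions hold. Built entirely from the generator's surface.
null_groups_spec <- function(seed, n_per_group = 8, n_proteins = 137) {
  disc <- rbind(
    data.frame(animal = seq_len(n_per_group), timepoint = "t12"),
    data.frame(animal = n_per_group + seq_len(n_per_group), timepoint = "t0"))
  synthetic_spec(n_animals = 2 * n_per_group,
                 genders = rep(c("F", "M"), n_per_group),
                 timepoints = c("t0", "t12"), n_tech_reps = 1,
                 n_proteins = n_proteins, n_discriminant = 0,
                 discarded_samples = disc, seed = seed)
}

# Strongly separable two-class dataset: large planted fold changes, low noise.
separable_fixture <- function(seed, n_proteins = 30, n_discriminant = 6,
                              fc = 6) {
  out <- synthesize(synthetic_spec(n_proteins = n_proteins,
                                   n_discriminant = n_discriminant,
                                   planted_fc = fc,
                                   biological_cv = 0.1, technical_cv = 0.03,
                                   seed = seed))
  subset_for_design(out$dataset, standard_designs()$long)
}

# Breadth-first-search all-pairs distances over the wrapped hexagonal
# adjacency graph (odd-r offset neighbor tables), independent of the
# cube-coordinate arithmetic used by hex_toroidal_distance().
bfs_hex_distances <- function(rows, cols) {
  n <- rows * cols
  nb_even <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(-1, -1), c(1, -1))
  nb_odd  <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(-1, 1), c(1, 1))
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% cols
    c <- (i - 1) %% cols
    nb <- if (r %% 2 == 0) nb_even else nb_odd
    rr <- (r + nb[, 1]) %% rows
    cc <- (c + nb[, 2]) %% cols
    adj[[i]] <- rr * cols + cc + 1
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (w in adj[[v]]) if (!is.finite(D[s, w])) {
        D[s, w] <- D[s, v] + 1
        q <- c(q, w)
      }
    }
  }
  D
}

# Replicate seed for with_seed-protected expressions inside tests.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
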