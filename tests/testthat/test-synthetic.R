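test_that("the default design yields 69 rows split 24/21/24 across timepoints", {
  out <- synthesize(synthetic_spec())
  expect_equal(nrow(out$dataset$values), 69)
  tp <- table(out$dataset$metadata$timepoint)
  expect_equal(as.integer(tp[c("t0", "t12", "t26")]), c(24, 21, 24))
  # the discarded biological sample is a female at the second timepoint
  gone <- setdiff(
    paste(rep(sprintf("a%02d", 1:8), each = 3), c("t0", "t12", "t26")),
    unique(paste(out$dataset$metadata$animal_id, out$dataset$metadata$timepoint)))
  expect_equal(gone, "a01 t12")
})

test_that("identical spec and seed give bit-identical output", {
  a <- synthesize(synthetic_spec(seed = 42))
  b <- synthesize(synthetic_spec(seed = 42))
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth$log_fc, b$truth$log_fc)
  c <- synthesize(synthetic_spec(seed = 43))
  expect_false(identical(a$dataset$values, c$dataset$values))
})

test_that("no effects and zero CVs give constant protein columns", {
  out <- synthesize(synthetic_spec(n_discriminant = 0, biological_cv = 0,
                                   technical_cv = 0, n_proteins = 10))
  expect_true(all(apply(out$dataset$values, 2, stats::sd) == 0))
  expect_true(all(out$dataset$values > 0))
})

test_that("planted fold changes are recovered empirically at large n", {
  # Monte-Carlo check of the generator against its own stated model
  spec <- synthetic_spec(n_animals = 200, n_proteins = 10, n_discriminant = 2,
                         planted_fc = 2, seed = 3,
                         discarded_samples = data.frame(animal = integer(),
                                                        timepoint = character()))
  out <- synthesize(spec)
  md <- out$dataset$metadata
  for (prot in c("P001", "P002")) {
    ratio <- mean(out$dataset$values[md$timepoint == "t26", prot]) /
      mean(out$dataset$values[md$timepoint == "t0", prot])
    expect_lt(abs(ratio - 2), 0.2)
  }
  # unplanted protein: ratio near 1
  r0 <- mean(out$dataset$values[md$timepoint == "t26", "P005"]) /
    mean(out$dataset$values[md$timepoint == "t0", "P005"])
  expect_lt(abs(r0 - 1), 0.1)
})

test_that("ground truth discriminant sets equal proteins with nonzero log FC", {
  out <- synthesize(synthetic_spec(n_discriminant = 6, seed = 5))
  for (ct in colnames(out$truth$log_fc)) {
    expect_identical(out$truth$discriminant[[ct]],
                     rownames(out$truth$log_fc)[out$truth$log_fc[, ct] != 0])
  }
  # early-onset proteins discriminate t0 vs t12; late-onset ones do not
  expect_true("P001" %in% out$truth$discriminant$t0_vs_t12)
  expect_false("P002" %in% out$truth$discriminant$t0_vs_t12)
  expect_true("P002" %in% out$truth$discriminant$t12_vs_t26)
  # every planted protein discriminates the long contrast
  expect_true(all(sprintf("P%03d", 1:6) %in% out$truth$discriminant$t0_vs_t26))
})

test_that("technical variance is smaller than biological variance in aggregate", {
  out <- synthesize(synthetic_spec(seed = 8))
  md <- out$dataset$metadata
  logv <- log(out$dataset$values)
  bio <- paste(md$animal_id, md$timepoint)
  # mean within-biological-sample variance vs between-biological-sample variance
  tech_var <- mean(vapply(unique(bio), function(b)
    mean(apply(logv[bio == b, , drop = FALSE], 2, stats::var)), 0))
  bio_means <- t(vapply(unique(bio), function(b)
    colMeans(logv[bio == b, , drop = FALSE]), numeric(ncol(logv))))
  bio_var <- mean(apply(bio_means, 2, stats::var))
  expect_lt(tech_var, bio_var)
})

test_that("spec validation errors name the offending field", {
  expect_error(synthetic_spec(technical_cv = 0.4, biological_cv = 0.3),
               "technical_cv")
  expect_error(synthetic_spec(n_discriminant = 200), "n_discriminant")
  expect_error(synthetic_spec(planted_fc = -1), "planted_fc")
  expect_error(synthetic_spec(genders = c("F", "M")), "genders")
  expect_error(synthetic_spec(gender_affected = list(proteins = c(1, 1),
                                                     fc = 2)),
               "gender_affected")
  expect_error(synthetic_spec(
    discarded_samples = data.frame(animal = 99, timepoint = "t12")),
    "discarded_samples")
})

test_that("gender effects shift the flagged proteins between genders", {
  spec <- synthetic_spec(n_animals = 40, n_proteins = 10, n_discriminant = 0,
                         gender_affected = list(proteins = 3, fc = 2),
                         seed = 12,
                         discarded_samples = data.frame(animal = integer(),
                                                        timepoint = character()))
  out <- synthesize(spec)
  md <- out$dataset$metadata
  ratio <- mean(out$dataset$values[md$gender == "F", "P003"]) /
    mean(out$dataset$values[md$gender == "M", "P003"])
  expect_gt(ratio, 1.5)
})

test_that("a perfect phenotype link is an affine transform of its protein", {
  spec <- synthetic_spec(
    phenotype_links = data.frame(phenotype = "tenderness", protein = "P004",
                                 r = 1),
    seed = 4)
  out <- synthesize(spec)
  ph <- synthesize_phenotypes(out$dataset, spec)
  key <- paste(out$dataset$metadata$animal_id, out$dataset$metadata$timepoint)
  x <- vapply(unique(key), function(k)
    mean(log(out$dataset$values[key == k, "P004"])), 0)
  expect_equal(abs(cor(x, ph$tenderness)), 1, tolerance = 1e-12)
  expect_equal(nrow(ph), 23)  # one row per surviving biological sample
})

test_that("r = 0 links are null-distributed and disjoint links stay uncorrelated", {
  # oracle: under the null the 97.5% quantile of |r| at n biological samples
  # is the value solving the two-sided t-transform test at p = 0.05
  n_bio <- 23
  tcrit <- stats::qt(0.975, n_bio - 2)
  r_crit <- tcrit / sqrt(n_bio - 2 + tcrit^2)
  hits <- vapply(1:200, function(s) {
    spec <- synthetic_spec(
      phenotype_links = data.frame(phenotype = "score", protein = "P001", r = 0),
      seed = s)
    out <- synthesize(spec)
    ph <- synthesize_phenotypes(out$dataset, spec)
    key <- paste(out$dataset$metadata$animal_id, out$dataset$metadata$timepoint)
    x <- vapply(unique(key), function(k)
      mean(log(out$dataset$values[key == k, "P001"])), 0)
    abs(cor(x, ph$score)) < r_crit
  }, TRUE)
  expect_gt(mean(hits), 0.90)   # nominal 95%, binomial tolerance at 200 runs

  spec <- synthetic_spec(
    phenotype_links = data.frame(phenotype = c("ph1", "ph2"),
                                 protein = c("P001", "P050"),
                                 r = c(0.9, 0.9)),
    seed = 77)
  out <- synthesize(spec)
  ph <- synthesize_phenotypes(out$dataset, spec)
  # block-diagonal structure: the two phenotypes track disjoint proteins
  expect_lt(abs(cor(ph$ph1, ph$ph2)), r_crit * 1.5)
})

test_that("phenotype links to unknown proteins are rejected", {
  spec <- synthetic_spec(
    phenotype_links = data.frame(phenotype = "x", protein = "P999", r = 0.5))
  out <- synthesize(spec)
  expect_error(synthesize_phenotypes(out$dataset, spec), "unknown protein")
  expect_error(synthesize_phenotypes(out$dataset, synthetic_spec()),
               "no phenotype_links")
})

test_that("spec and ground truth serialize to plain text and back", {
  spec <- synthetic_spec(n_proteins = 12, n_discriminant = 3, seed = 6)
  path <- tempfile(fileext = ".json")
  write_spec(spec, path)
  spec2 <- read_spec(path)
  expect_equal(spec2$n_proteins, 12)
  expect_identical(synthesize(spec)$dataset$values,
                   synthesize(spec2)$dataset$values)
  out <- synthesize(spec)
  tsv <- tempfile(fileext = ".tsv")
  write_ground_truth(out$truth, tsv)
  gt <- read.delim(tsv, check.names = FALSE)
  expect_equal(gt$t0_vs_t26, unname(out$truth$log_fc[, "t0_vs_t26"]))
})
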