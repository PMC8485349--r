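#' Specify a synthetic abundance study
#'
#' Defines the design and ground truth of a simulated label-free proteomics
#' study: animals measured at ordered timepoints, each biological sample
#' quantified in several technical replicates, with a planted subset of
#' timepoint-discriminant proteins, an optional gender effect, and phenotype
#' variables linearly coupled to chosen proteins.
#'
#' Abundances are log-normal: effects are additive on the log scale and
#' exponentiated. `biological_cv` is the total biological coefficient of
#' variation, split evenly between a persistent animal effect and
#' per-biological-sample variation; `technical_cv` acts independently on every
#' technical replicate and must be smaller than `biological_cv`.
#'
#' Planted proteins follow step trajectories: an "early" protein shifts at the
#' second timepoint and stays shifted, a "late" protein shifts only at the last
#' timepoint. Onsets alternate across the planted proteins so that every
#' pairwise contrast has truly discriminant proteins.
#'
#' @param n_animals number of animals (biological subjects).
#' @param genders character vector of length `n_animals` ("F"/"M"); default
#'   half heifers, half bulls.
#' @param timepoints ordered character vector of timepoint labels.
#' @param n_tech_reps technical replicates per biological sample.
#' @param n_proteins number of protein variables.
#' @param n_discriminant number of planted timepoint-affected proteins.
#' @param planted_fc multiplicative fold change (relative to the first
#'   timepoint) for planted proteins; scalar or vector of length
#'   `n_discriminant`; all entries finite and positive.
#' @param biological_cv,technical_cv coefficients of variation on the natural
#'   scale; `technical_cv < biological_cv`.
#' @param gender_affected optional list with `proteins` (indices) and `fc`
#'   (fold change of females relative to males, recycled).
#' @param phenotype_links optional data.frame with columns `phenotype`,
#'   `protein` (id or index) and `r` (target Pearson correlation).
#' @param discarded_samples data.frame with columns `animal` (index) and
#'   `timepoint`: biological samples removed from the output (all their
#'   technical replicates). Default: the first female animal at the second
#'   timepoint, the study's one discarded sample.
#' @param seed integer; all randomness flows from explicit seeds, never
#'   global state.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_animals = 8,
                           genders = rep(c("F", "M"), each = ceiling(n_animals / 2))[seq_len(n_animals)],
                           timepoints = c("t0", "t12", "t26"),
                           n_tech_reps = 3,
                           n_proteins = 137,
                           n_discriminant = min(20, n_proteins),
                           planted_fc = 2,
                           biological_cv = 0.30,
                           technical_cv = 0.10,
                           gender_affected = NULL,
                           phenotype_links = NULL,
                           discarded_samples = NULL,
                           seed = 1) {
  if (n_animals < 1) stop_field("n_animals", "must be >= 1")
  if (length(genders) != n_animals)
    stop_field("genders", "must have one entry per animal")
  if (!all(genders %in% c("F", "M")))
    stop_field("genders", "entries must be 'F' or 'M'")
  if (length(timepoints) < 1 || anyDuplicated(timepoints))
    stop_field("timepoints", "must be non-empty and unique")
  if (n_tech_reps < 1) stop_field("n_tech_reps", "must be >= 1")
  if (n_proteins < 1) stop_field("n_proteins", "must be >= 1")
  if (n_discriminant < 0 || n_discriminant > n_proteins)
    stop_field("n_discriminant", "must be between 0 and n_proteins")
  planted_fc <- rep_len(as.numeric(planted_fc),
                        max(n_discriminant, length(planted_fc)))
  if (n_discriminant > 0) planted_fc <- planted_fc[seq_len(n_discriminant)]
  if (n_discriminant > 0 && (!all(is.finite(planted_fc)) || any(planted_fc <= 0)))
    stop_field("planted_fc", "entries must be finite and positive")
  if (!is.finite(biological_cv) || biological_cv < 0)
    stop_field("biological_cv", "must be a finite non-negative number")
  if (!is.finite(technical_cv) || technical_cv < 0)
    stop_field("technical_cv", "must be a finite non-negative number")
  if (biological_cv > 0 && technical_cv >= biological_cv)
    stop_field("technical_cv", "must be smaller than biological_cv")
  if (!is.null(gender_affected)) {
    if (!is.list(gender_affected) || is.null(gender_affected$proteins))
      stop_field("gender_affected", "must be a list with 'proteins' and 'fc'")
    if (anyDuplicated(gender_affected$proteins))
      stop_field("gender_affected", "protein indices must be unique")
    if (any(gender_affected$proteins < 1 | gender_affected$proteins > n_proteins))
      stop_field("gender_affected", "protein index out of range")
    gender_affected$fc <- rep_len(gender_affected$fc %||% 1.5,
                                  length(gender_affected$proteins))
    if (any(!is.finite(gender_affected$fc) | gender_affected$fc <= 0))
      stop_field("gender_affected", "fold changes must be finite and positive")
  }
  if (!is.null(phenotype_links)) {
    phenotype_links <- as.data.frame(phenotype_links, stringsAsFactors = FALSE)
    need <- c("phenotype", "protein", "r")
    if (!all(need %in% names(phenotype_links)))
      stop_field("phenotype_links", "needs columns phenotype, protein, r")
    if (any(abs(phenotype_links$r) > 1))
      stop_field("phenotype_links", "target r must lie in [-1, 1]")
    if (anyDuplicated(phenotype_links$phenotype))
      stop_field("phenotype_links", "phenotype names must be unique")
  }
  if (is.null(discarded_samples)) {
    if (length(timepoints) >= 2 && any(genders == "F")) {
      discarded_samples <- data.frame(animal = which(genders == "F")[1],
                                      timepoint = timepoints[2],
                                      stringsAsFactors = FALSE)
    } else {
      discarded_samples <- data.frame(animal = integer(), timepoint = character())
    }
  } else {
    discarded_samples <- as.data.frame(discarded_samples, stringsAsFactors = FALSE)
    if (!all(c("animal", "timepoint") %in% names(discarded_samples)))
      stop_field("discarded_samples", "needs columns animal, timepoint")
    if (any(discarded_samples$animal < 1 | discarded_samples$animal > n_animals))
      stop_field("discarded_samples", "animal index out of range")
    if (!all(discarded_samples$timepoint %in% timepoints))
      stop_field("discarded_samples", "unknown timepoint")
  }
  structure(list(n_animals = n_animals, genders = genders,
                 timepoints = timepoints, n_tech_reps = n_tech_reps,
                 n_proteins = n_proteins, n_discriminant = n_discriminant,
                 planted_fc = if (n_discriminant) planted_fc else numeric(),
                 biological_cv = biological_cv, technical_cv = technical_cv,
                 gender_affected = gender_affected,
                 phenotype_links = phenotype_links,
                 discarded_samples = discarded_samples,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Log-scale timepoint effect matrix (proteins x timepoints) implied by a spec.
# Planted proteins occupy the first n_discriminant columns of the matrix;
# onsets alternate early (second timepoint onward) / late (last timepoint).
planted_effects <- function(spec) {
  p <- spec$n_proteins
  tps <- spec$timepoints
  beta <- matrix(0, p, length(tps),
                 dimnames = list(protein_ids(spec), tps))
  if (spec$n_discriminant == 0 || length(tps) < 2) return(beta)
  onset2 <- length(tps) >= 3
  for (j in seq_len(spec$n_discriminant)) {
    lfc <- log(spec$planted_fc[j])
    if (onset2 && j %% 2 == 0) {
      beta[j, length(tps)] <- lfc                # late onset
    } else {
      beta[j, -1] <- lfc                         # early onset, sustained
    }
  }
  beta
}

protein_ids <- function(spec) sprintf("P%03d", seq_len(spec$n_proteins))

# All two-class contrasts implied by the timepoints: every ordered pair
# (earlier vs later) plus first-vs-rest when there are >= 3 timepoints.
spec_contrasts <- function(spec) {
  tps <- spec$timepoints
  out <- list()
  for (i in seq_along(tps)) for (j in seq_along(tps)) if (i < j) {
    out[[paste0(tps[i], "_vs_", tps[j])]] <- list(a = tps[i], b = tps[j])
  }
  if (length(tps) >= 3)
    out[[paste0(tps[1], "_vs_", paste(tps[-1], collapse = "."))]] <-
      list(a = tps[1], b = tps[-1])
  out
}

#' Generate a synthetic abundance dataset with ground truth
#'
#' Draws one dataset from the model described in [synthetic_spec()]:
#' `abundance = exp(baseline + animal effect + timepoint effect +
#' gender effect + biological noise + technical noise)`. Identical spec and
#' seed give bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `dataset` (an [abundance_dataset()]) and `truth`, the
#'   ground-truth object: `log_fc` (proteins x contrasts true log fold
#'   change), `discriminant` (protein ids with non-zero log FC, per
#'   contrast), `effects` (proteins x timepoints log effects), and the
#'   gender/phenotype design.
#' @export
synthesize <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_proteins
  tps <- spec$timepoints
  prot <- protein_ids(spec)
  beta <- planted_effects(spec)

  # log-normal: a CV of c corresponds to log-sd sqrt(log(1+c^2)); the
  # biological variance is split evenly between animal and sample levels
  sd_bio_tot <- sqrt(log1p(spec$biological_cv^2))
  sd_anim <- sd_bio_tot / sqrt(2)
  sd_bsam <- sd_bio_tot / sqrt(2)
  sd_tech <- sqrt(log1p(spec$technical_cv^2))

  keep <- expand.grid(tech_rep = seq_len(spec$n_tech_reps),
                      timepoint = tps,
                      animal = seq_len(spec$n_animals),
                      stringsAsFactors = FALSE)
  disc <- spec$discarded_samples
  if (nrow(disc)) {
    drop <- paste(keep$animal, keep$timepoint) %in%
      paste(disc$animal, disc$timepoint)
    keep <- keep[!drop, , drop = FALSE]
  }
  keep <- keep[order(keep$animal, match(keep$timepoint, tps), keep$tech_rep), ]
  n <- nrow(keep)

  vals <- with_seed(spec$seed, {
    base <- stats::runif(p, 9, 14)                       # log intensity units
    anim_eff <- matrix(stats::rnorm(spec$n_animals * p, 0, sd_anim),
                       spec$n_animals, p)
    bio_eff <- array(stats::rnorm(spec$n_animals * length(tps) * p, 0, sd_bsam),
                     dim = c(spec$n_animals, length(tps), p))
    tech_eff <- matrix(stats::rnorm(n * p, 0, sd_tech), n, p)
    gend <- rep(0, p)
    if (!is.null(spec$gender_affected))
      gend[spec$gender_affected$proteins] <- log(spec$gender_affected$fc)
    lv <- matrix(0, n, p)
    for (i in seq_len(n)) {
      a <- keep$animal[i]
      ti <- match(keep$timepoint[i], tps)
      lv[i, ] <- base + anim_eff[a, ] + beta[, ti] +
        (if (spec$genders[a] == "F") gend else 0) +
        bio_eff[a, ti, ] + tech_eff[i, ]
    }
    exp(lv)
  })

  ids <- sprintf("a%02d_%s_r%d", keep$animal, keep$timepoint, keep$tech_rep)
  dimnames(vals) <- list(ids, prot)
  meta <- data.frame(sample_id = ids,
                     animal_id = sprintf("a%02d", keep$animal),
                     gender = spec$genders[keep$animal],
                     timepoint = keep$timepoint,
                     tech_rep = keep$tech_rep,
                     stringsAsFactors = FALSE)
  dataset <- abundance_dataset(vals, meta)

  contrasts <- spec_contrasts(spec)
  log_fc <- sapply(contrasts, function(ct) {
    rowMeans(beta[, ct$b, drop = FALSE]) - rowMeans(beta[, ct$a, drop = FALSE])
  })
  if (is.null(dim(log_fc))) log_fc <- matrix(log_fc, ncol = length(contrasts),
                                             dimnames = list(prot, names(contrasts)))
  discr <- apply(log_fc, 2, function(z) prot[z != 0], simplify = FALSE)
  truth <- structure(list(log_fc = log_fc,
                          discriminant = discr,
                          effects = beta,
                          gender_affected = spec$gender_affected,
                          phenotype_links = spec$phenotype_links),
                     class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate phenotype variables linked to proteins
#'
#' Produces one phenotype value per biological sample (animal x timepoint).
#' Each phenotype is built as `r * z(protein) + sqrt(1 - r^2) * noise`, where
#' `z(protein)` is the standardized biological-level log abundance (technical
#' replicates averaged on the log scale), so the achieved Pearson correlation
#' with its linked protein approaches the target `r` at large n.
#'
#' @param dataset an [abundance_dataset()].
#' @param spec the [synthetic_spec()] holding `phenotype_links`.
#' @param seed optional integer; default derives from the spec seed.
#' @return data.frame: `animal_id`, `timepoint`, one column per phenotype.
#' @export
synthesize_phenotypes <- function(dataset, spec, seed = NULL) {
  stopifnot(inherits(dataset, "abundance_dataset"),
            inherits(spec, "synthetic_spec"))
  links <- spec$phenotype_links
  if (is.null(links) || !nrow(links))
    stop("spec has no phenotype_links")
  prot <- colnames(dataset$values)
  ref <- ifelse(suppressWarnings(!is.na(as.integer(links$protein))),
                prot[as.integer(links$protein)], as.character(links$protein))
  unknown <- which(is.na(ref) | !(ref %in% prot))
  if (length(unknown))
    stop("phenotype link to unknown protein: ",
         paste(links$protein[unknown], collapse = ", "))

  key <- paste(dataset$metadata$animal_id, dataset$metadata$timepoint, sep = "|")
  bio <- unique(key)
  logv <- log(dataset$values)
  out <- data.frame(animal_id = sub("\\|.*", "", bio),
                    timepoint = sub(".*\\|", "", bio),
                    stringsAsFactors = FALSE)
  n <- length(bio)
  with_seed(seed %||% derive_seed(spec$seed, 1L), {
    for (k in seq_len(nrow(links))) {
      x <- vapply(bio, function(b) mean(logv[key == b, ref[k]]), 0)
      z <- as.numeric(scale(x))
      r <- links$r[k]
      noise <- if (abs(r) < 1) stats::rnorm(n) else rep(0, n)
      out[[as.character(links$phenotype[k])]] <- r * z + sqrt(max(0, 1 - r^2)) * noise
    }
  })
  rownames(out) <- NULL
  out
}

#' Write / read a synthetic spec as plain-text configuration
#'
#' @param spec a [synthetic_spec()].
#' @param path JSON file path.
#' @return `write_spec` the path invisibly; `read_spec` the spec.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synthetic_spec, x[setdiff(names(x), character())])
}

#' Write ground truth as TSV
#'
#' @param truth ground-truth object from [synthesize()].
#' @param path TSV file path; one row per protein, one column of true log
#'   fold change per contrast.
#' @export
write_ground_truth <- function(truth, path) {
  df <- data.frame(protein_id = rownames(truth$log_fc),
                   truth$log_fc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
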