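# Synthetic shape populations with known ground truth.
#
# The stated world: a healthy population plus two syndromic populations
# (synA, synB) separable by region-specific smooth shape offsets, with
# within-class individual variation as smooth Gaussian fields. Surgery
# displaces chosen regions toward (or away from) the healthy mean with a
# known completeness parameter alpha. Every generator is a pure function of
# its spec, including the seed.

#' Specify a synthetic shape population
#'
#' Defaults are the package's stated world: 3 classes, region-specific class
#' offsets of 10 mm against 1 mm of smooth individual variation (a strong,
#' clearly separable syndromic signature), healthy class with zero offset by
#' convention.
#'
#' @param n_per_class named integer vector of subjects per class.
#' @param region_effects per-class list: `list(regions = <ids>, effect_mm = <x>)`.
#'   The healthy class must have zero offset (omit it or give effect 0).
#' @param individual_sd within-class variation scale, mm (mean per-vertex
#'   displacement norm of the individual smooth field).
#' @param seed integer seed.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_per_class = c(healthy = 30, synA = 30, synB = 30),
                            region_effects = list(
                              synA = list(regions = c(4, 5, 7), effect_mm = 10),
                              synB = list(regions = c(1, 2, 3), effect_mm = 10)),
                            individual_sd = 1,
                            seed = 1) {
  if (any(n_per_class < 1)) .stopf("n_per_class must be >= 1 for every class")
  if (is.null(names(n_per_class))) .stopf("n_per_class must be named by class")
  for (cl in names(region_effects)) {
    re <- region_effects[[cl]]
    if (!is.finite(re$effect_mm)) .stopf("effect size for %s not finite", cl)
    if (re$effect_mm != 0 && !length(re$regions))
      .stopf("class %s has an effect size but no regions", cl)
  }
  if (!is.null(region_effects$healthy) && region_effects$healthy$effect_mm != 0)
    .stopf("healthy class must have zero class-offset by convention")
  structure(list(n_per_class = n_per_class,
                 class_names = names(n_per_class),
                 region_effects = region_effects,
                 individual_sd = individual_sd, seed = seed),
            class = "population_spec")
}

## Deterministic class-offset field: a fixed smooth signature per class,
## confined to the designated regions by the 2-ring blend mask, rescaled so
## the RMS per-vertex displacement norm over the designated region vertices
## equals effect_mm. >= 90% of the field's squared norm lies inside the
## regions. The signature depends only on the class identity (its name and
## region_effects entry, which may carry an explicit `coef` 16 x 3 matrix),
## never on the population seed: two cohorts drawn with different seeds
## sample the same class distributions.
class_offset_field <- function(template, class_name, region_effect, seed = NULL) {
  N <- nrow(template$mesh$vertices)
  if (is.null(region_effect) || region_effect$effect_mm == 0)
    return(matrix(0, N, 3))
  coef <- region_effect$coef
  if (is.null(coef)) {
    stream <- sum(utf8ToInt(class_name) * seq_len(nchar(class_name)))
    coef <- .with_seed(.child_seed(97, stream), matrix(rnorm(16 * 3), 16, 3))
  }
  f <- .smooth_field(template, coef)
  w <- blend_weights(template, region_effect$regions)
  f <- f * w
  inside <- template$partition$labels %in% region_effect$regions
  rms <- sqrt(mean(rowSums(f[inside, , drop = FALSE]^2)))
  if (rms < 1e-9) .stopf("degenerate class offset field for %s", class_name)
  f * (region_effect$effect_mm / rms)
}

#' Sample a synthetic population of corresponded meshes
#'
#' Each subject is `template + class offset field + individual smooth
#' Gaussian field`. Deterministic given the spec's seed.
#'
#' @param spec a `population_spec`.
#' @param template a `shape_template` from [make_template()].
#' @return list of `synthetic_subject` objects, each with `subject_id`,
#'   `class_label`, `mesh`, and a `truth` record of its generating
#'   coefficients.
#' @export
sample_population <- function(spec, template) {
  stopifnot(inherits(spec, "population_spec"))
  tv <- template$mesh$vertices
  offsets <- lapply(spec$class_names, function(cl)
    class_offset_field(template, cl, spec$region_effects[[cl]], spec$seed))
  names(offsets) <- spec$class_names
  subjects <- list()
  k <- 0L
  for (cl in spec$class_names) {
    off <- offsets[[cl]]
    for (i in seq_len(spec$n_per_class[[cl]])) {
      k <- k + 1L
      indiv <- .with_seed(.child_seed(spec$seed, 1000 + k),
                          .random_smooth_field(template, spec$individual_sd))
      mesh <- corresponded_mesh(tv + off + indiv, template$mesh$faces,
                                template_id = template$mesh$template_id,
                                validate = FALSE)
      subjects[[k]] <- structure(
        list(subject_id = sprintf("%s_%03d", cl, i), class_label = cl,
             mesh = mesh, augmented = FALSE,
             truth = list(class_offset_rms = sqrt(mean(rowSums(off^2))),
                          individual_sd = spec$individual_sd)),
        class = "synthetic_subject")
    }
  }
  subjects
}

#' Specify a simulated surgical intervention
#'
#' @param target_regions region ids the procedure acts on (non-empty).
#' @param alpha completeness: 0 = no change, 1 = the region's deviation from
#'   the healthy mean fully removed, > 1 = overcorrection past the healthy
#'   mean (as seen at the nose/upper lip in practice).
#' @param direction_mode `"toward_healthy"`, `"away_from_healthy"`, or
#'   `"random"` (a random smooth field of matched norm).
#' @param noise_sd residual surgical noise, mm.
#' @param seed integer seed.
#' @return an object of class `surgery_spec`.
#' @export
surgery_spec <- function(target_regions, alpha = 0.8,
                         direction_mode = c("toward_healthy",
                                            "away_from_healthy", "random"),
                         noise_sd = 0, seed = 1) {
  direction_mode <- match.arg(direction_mode)
  if (!length(target_regions)) .stopf("target_regions must be non-empty")
  if (alpha < 0) .stopf("completeness alpha must be >= 0")
  structure(list(target_regions = target_regions, alpha = alpha,
                 direction_mode = direction_mode, noise_sd = noise_sd,
                 seed = seed),
            class = "surgery_spec")
}

#' Simulate surgery on a synthetic subject
#'
#' On the target regions, vertices move by `alpha` times the difference to
#' the healthy mean (toward mode), its negation (away mode), or a random
#' smooth field of matched norm, plus smooth surgical noise. Non-target
#' regions are untouched except for the 2-ring boundary blend. The ground
#' truth (alpha, mode, targets) is recorded on the returned subject.
#'
#' @param subject a `synthetic_subject` (preoperative).
#' @param spec a `surgery_spec`.
#' @param healthy_mean_mesh the healthy population mean `corresponded_mesh`.
#' @param template the shared `shape_template`.
#' @return the postoperative `synthetic_subject`.
#' @export
apply_surgery <- function(subject, spec, healthy_mean_mesh, template) {
  stopifnot(inherits(spec, "surgery_spec"))
  pre <- subject$mesh
  check_correspondence(pre, template)
  check_correspondence(healthy_mean_mesh, template)
  w <- blend_weights(template, spec$target_regions)
  diff <- healthy_mean_mesh$vertices - pre$vertices
  move <- switch(spec$direction_mode,
    toward_healthy = spec$alpha * diff * w,
    away_from_healthy = -spec$alpha * diff * w,
    random = {
      target_norm <- sqrt(sum((spec$alpha * diff * w)^2))
      f <- .with_seed(.child_seed(spec$seed, 7), .random_smooth_field(template, 1)) * w
      nf <- sqrt(sum(f^2))
      if (nf < 1e-12) f else f * (target_norm / nf)
    })
  noise <- if (spec$noise_sd > 0) {
    .with_seed(.child_seed(spec$seed, 11),
               .random_smooth_field(template, spec$noise_sd)) * w
  } else 0
  post_mesh <- corresponded_mesh(pre$vertices + move + noise,
                                 pre$faces, template_id = pre$template_id,
                                 validate = FALSE)
  post <- subject
  post$mesh <- post_mesh
  post$truth$surgery <- list(alpha = spec$alpha, mode = spec$direction_mode,
                             target_regions = spec$target_regions,
                             noise_sd = spec$noise_sd)
  post
}

# ---- latent-space fixtures -------------------------------------------------

#' Specify a latent-space Gaussian fixture
#'
#' A stand-in for encoder output: per-class Gaussians in an R x d latent
#' layout, for testing the statistics and outcome stages without training.
#'
#' @param means named list of class mean vectors (length R*d each).
#' @param covariances named list of symmetric positive-definite covariance
#'   matrices, same names as `means`.
#' @param n_per_class named integer vector.
#' @param R,d latent layout (regions x per-region width).
#' @param seed integer seed.
#' @export
latent_fixture_spec <- function(means, covariances, n_per_class,
                                R = 15, d = 5, seed = 1) {
  p <- R * d
  for (cl in names(means)) {
    if (length(means[[cl]]) != p) .stopf("mean for %s must have length %d", cl, p)
    S <- covariances[[cl]]
    if (is.null(S) || nrow(S) != p || any(abs(S - t(S)) > 1e-8))
      .stopf("covariance for %s must be symmetric %d x %d", cl, p, p)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      .stopf("covariance for %s is not positive-definite", cl)
  }
  structure(list(means = means, covariances = covariances,
                 n_per_class = n_per_class, R = R, d = d, seed = seed),
            class = "latent_fixture_spec")
}

#' Draw a latent-vector table from a Gaussian fixture
#'
#' @param spec a `latent_fixture_spec`.
#' @return data.frame with `subject_id`, `class_label`, and latent columns
#'   `z_001 ... z_{R*d}`; deterministic given the spec's seed.
#' @export
sample_latent_fixture <- function(spec) {
  stopifnot(inherits(spec, "latent_fixture_spec"))
  p <- spec$R * spec$d
  .with_seed(spec$seed, {
    rows <- lapply(names(spec$means), function(cl) {
      n <- spec$n_per_class[[cl]]
      L <- chol(spec$covariances[[cl]])
      Z <- matrix(rnorm(n * p), n, p) %*% L
      Z <- sweep(Z, 2, spec$means[[cl]], "+")
      data.frame(subject_id = sprintf("%s_%03d", cl, seq_len(n)),
                 class_label = cl, Z, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    names(out)[-(1:2)] <- sprintf("z_%03d", seq_len(p))
    rownames(out) <- NULL
    out
  })
}

# ---- manifests -------------------------------------------------------------

#' Write a population manifest CSV
#'
#' Columns: subject_id, class_label, mesh_path, stage (pre/post),
#' procedure_label, augmented.
#' @param rows data.frame with those columns.
#' @param path output CSV.
#' @export
write_manifest <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population manifest CSV
#' @param path manifest CSV path.
#' @export
read_manifest <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Vertex-wise mean mesh of a set of subjects
#' @param subjects list of `synthetic_subject`.
#' @param class_label optional class filter.
#' @param template the shared `shape_template`.
#' @return a `corresponded_mesh`.
#' @export
mean_mesh <- function(subjects, template, class_label = NULL) {
  if (!is.null(class_label))
    subjects <- Filter(function(s) s$class_label == class_label, subjects)
  if (!length(subjects)) .stopf("no subjects to average")
  V <- Reduce(`+`, lapply(subjects, function(s) s$mesh$vertices))
  corresponded_mesh(V / length(subjects), template$mesh$faces,
                    template_id = template$mesh$template_id, validate = FALSE)
}
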