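# Shared fixtures, built in code and memoized for the whole test run.
# The heavyweight fixture (fix_trained) generates a 3-class cohort,
# augments it, trains the toy autoencoder and fits the latent Gaussians
# once; several test files and the acceptance suite reuse it.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

# coarse template: 162 vertices, used for cheap geometry tests
fix_template2 <- function() .memo("tpl2", function() make_template(2, seed = 1))

# working template: 642 vertices, used for population-level fixtures
fix_template3 <- function() .memo("tpl3", function() make_template(3, seed = 1))

# the stated-world cohort: 30 per class, 10 mm class effects, 1 mm
# individual variation (defaults of population_spec)
fix_population <- function() .memo("pop", function() {
  sample_population(population_spec(seed = 11), fix_template3())
})

# full trained stack on the augmented cohort (100 per class)
fix_trained <- function() .memo("trained", function() {
  tpl <- fix_template3()
  subs <- fix_population()
  aug <- augment_population(subs, 100, tpl, k = 128, seed = 12,
                            classes = c("healthy", "synA", "synB"))
  model <- sdvae_train(lapply(aug, `[[`, "mesh"), tpl,
                       sdvae_config(epochs = 30, seed = 5))
  latents <- sdvae_encode_table(model, aug)
  dists <- fit_class_distributions(latents, layout = model$layout)
  list(template = tpl, subjects = subs, augmented = aug, model = model,
       latents = latents, dists = dists,
       healthy_mean = mean_mesh(subs, tpl, "healthy"),
       projection = lda_fit_project(latents))
})

# hand-built class_distribution for worked metric examples: R regions of
# width d, every regional block (mean, cov) as given; the global covariance
# is the block-diagonal replication of the regional one
make_plain_dist <- function(mean_r, cov_r, R = 1) {
  d <- length(mean_r)
  cov_r <- as.matrix(cov_r)
  G <- matrix(0, R * d, R * d)
  for (r in seq_len(R)) {
    idx <- ((r - 1) * d + 1):(r * d)
    G[idx, idx] <- cov_r
  }
  structure(list(class = "healthy", n = 2,
                 mean = rep(mean_r, R),
                 cov = G,
                 shrinkage = 0,
                 regional = replicate(R, list(mean = mean_r,
                                              cov = as.matrix(cov_r),
                                              shrinkage = 0),
                                      simplify = FALSE),
                 layout = latent_layout(R, d)),
            class = "class_distribution")
}

# random symmetric positive-definite matrix
random_spd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.1
}
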