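# Synthetic template, population generator and simulated surgery:
# determinism, geometry counts, class-signature locality and the
# completeness ground truth.

test_that("template construction is deterministic with the stated counts", {
  t1 <- make_template(2, seed = 3)
  t2 <- make_template(2, seed = 3)
  expect_identical(t1$mesh$vertices, t2$mesh$vertices)
  expect_identical(t1$partition$labels, t2$partition$labels)
  # icosphere subdivision formula: 10 * 4^n + 2 vertices, 20 * 4^n faces
  t3 <- make_template(3, seed = 1)
  expect_identical(nrow(t3$mesh$vertices), 642L)
  expect_identical(nrow(t3$mesh$faces), 1280L)
  expect_identical(nrow(t1$mesh$vertices), 162L)
})

test_that("every region is non-empty and contiguous on the surface graph", {
  tpl <- fix_template3()
  g <- cranioshape:::mesh_graph(tpl$mesh)
  for (r in seq_len(n_regions(tpl$partition))) {
    members <- region_vertices(tpl$partition, r) + 1L
    expect_gt(length(members), 0)
    expect_equal(
      igraph::components(igraph::induced_subgraph(g, members))$no, 1)
  }
})

test_that("population generator honours its degenerate limits", {
  tpl <- fix_template2()
  # no individual variation: all subjects of a class identical
  spec0 <- population_spec(n_per_class = c(healthy = 3, synA = 3, synB = 2),
                           individual_sd = 0, seed = 5)
  subs <- sample_population(spec0, tpl)
  a <- Filter(function(s) s$class_label == "synA", subs)
  expect_equal(a[[1]]$mesh$vertices, a[[2]]$mesh$vertices, tolerance = 1e-14)
  # healthy with zero offset and zero sd is the template exactly
  h <- subs[[1]]
  expect_equal(h$mesh$vertices, tpl$mesh$vertices, tolerance = 1e-12)
})

test_that("class separation dominates individual variation (30 per class)", {
  subs <- fix_population()
  labs <- vapply(subs, function(s) s$class_label, character(1))
  V <- lapply(subs, function(s) s$mesh$vertices)
  rmsd <- function(i, j) sqrt(mean(rowSums((V[[i]] - V[[j]])^2)))
  set.seed(1)
  intra <- replicate(60, {
    cl <- sample(unique(labs), 1)
    ij <- sample(which(labs == cl), 2)
    rmsd(ij[1], ij[2])
  })
  inter <- replicate(60, {
    cls <- sample(unique(labs), 2)
    rmsd(sample(which(labs == cls[1]), 1), sample(which(labs == cls[2]), 1))
  })
  expect_gt(mean(inter), mean(intra))
})

test_that("class offset fields stay >= 90% within their designated regions", {
  tpl <- fix_template3()
  spec <- population_spec(seed = 11)
  for (cl in c("synA", "synB")) {
    re <- spec$region_effects[[cl]]
    off <- cranioshape:::class_offset_field(tpl, cl, re)
    inside <- tpl$partition$labels %in% re$regions
    expect_gte(sum(off[inside, ]^2) / sum(off^2), 0.90)
  }
})

test_that("generators are pure functions of their spec", {
  tpl <- fix_template2()
  spec <- population_spec(n_per_class = c(healthy = 2, synA = 2, synB = 2),
                          seed = 9)
  s1 <- sample_population(spec, tpl)
  s2 <- sample_population(spec, tpl)
  expect_identical(s1[[4]]$mesh$vertices, s2[[4]]$mesh$vertices)
})

test_that("surgery completeness alpha is the exact ground truth on targets", {
  tpl <- fix_template3()
  subs <- fix_population()
  hm <- mean_mesh(subs, tpl, "healthy")
  pa <- Filter(function(s) s$class_label == "synA", subs)[[1]]

  # alpha = 0, no noise: identity
  post0 <- apply_surgery(pa, surgery_spec(c(4, 5), alpha = 0), hm, tpl)
  expect_equal(post0$mesh$vertices, pa$mesh$vertices, tolerance = 1e-14)

  # alpha = 1, all regions targeted: the healthy mean exactly (full blend)
  post1 <- apply_surgery(pa, surgery_spec(1:15, alpha = 1), hm, tpl)
  expect_lt(max(abs(post1$mesh$vertices - hm$vertices)), 1e-9)

  # toward_healthy, noise-free: post distance = (1 - alpha) * pre distance
  # at full-weight (interior) vertices, for every alpha in [0, 1]
  w <- blend_weights(tpl, c(4, 5, 7))
  interior <- w == 1
  d_pre <- sqrt(rowSums((pa$mesh$vertices - hm$vertices)^2))
  for (alpha in c(0.25, 0.5, 0.8, 1)) {
    post <- apply_surgery(pa, surgery_spec(c(4, 5, 7), alpha = alpha), hm, tpl)
    d_post <- sqrt(rowSums((post$mesh$vertices - hm$vertices)^2))
    expect_equal(d_post[interior], (1 - alpha) * d_pre[interior],
                 tolerance = 1e-9)
  }

  # away_from_healthy: target-region vertices move away from the healthy mean
  away <- apply_surgery(pa, surgery_spec(c(4, 5, 7), alpha = 0.5,
                                         direction_mode = "away_from_healthy"),
                        hm, tpl)
  d_away <- sqrt(rowSums((away$mesh$vertices - hm$vertices)^2))
  expect_true(all(d_away[interior] > d_pre[interior]))

  expect_error(surgery_spec(integer(0)), "non-empty")
  expect_error(surgery_spec(1, alpha = -0.1), "alpha")
})

test_that("latent fixture sampling matches its Gaussian spec", {
  p <- 4   # R = 2 regions of width 2, small for a fast Monte-Carlo check
  mu <- list(healthy = rep(0, p), synA = c(3, 0, -2, 1))
  S <- list(healthy = diag(p), synA = 0.5 * diag(p))
  spec <- latent_fixture_spec(mu, S, c(healthy = 5000, synA = 5000),
                              R = 2, d = 2, seed = 21)
  tab <- sample_latent_fixture(spec)
  expect_identical(nrow(tab), 10000L)
  Z <- latent_matrix(tab[tab$class_label == "synA", ])
  se <- sqrt(0.5 / 5000)
  expect_true(all(abs(colMeans(Z) - mu$synA) < 3 * se))
  # determinism and the near-degenerate limit
  expect_identical(sample_latent_fixture(spec), tab)
  tiny <- latent_fixture_spec(mu, lapply(S, function(x) x * 1e-12),
                              c(healthy = 3, synA = 3), R = 2, d = 2, seed = 2)
  tt <- sample_latent_fixture(tiny)
  expect_lt(max(abs(latent_matrix(tt[4:6, ]) -
                    matrix(mu$synA, 3, p, byrow = TRUE))), 1e-4)
  # non-PD covariance is refused
  bad <- S; bad$healthy[1, 1] <- -1
  expect_error(latent_fixture_spec(mu, bad, c(healthy = 2, synA = 2),
                                   R = 2, d = 2), "positive-definite")
})
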