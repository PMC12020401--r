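# Gaussian class fits, Mahalanobis geometry, QDA classification, the
# confusion/precision accounting and the LDA manifold projection.

test_that("class fitting handles degenerate and well-sampled classes", {
  # two identical rows: mean is that row, covariance is the ridge floor
  tab <- data.frame(class_label = c("h", "h"),
                    z_001 = c(1, 1), z_002 = c(2, 2),
                    z_003 = c(0, 0), z_004 = c(-1, -1))
  d <- fit_class_distributions(tab, layout = latent_layout(2, 2))
  expect_equal(d$h$mean, c(z_001 = 1, z_002 = 2, z_003 = 0, z_004 = -1))
  expect_equal(d$h$cov, diag(d$h$shrinkage, 4), ignore_attr = TRUE)
  expect_gt(min(eigen(d$h$cov, symmetric = TRUE)$values), 0)
  # a 1-row class is refused
  bad <- rbind(tab, data.frame(class_label = "x", z_001 = 0, z_002 = 0,
                               z_003 = 0, z_004 = 0))
  expect_error(fit_class_distributions(bad, layout = latent_layout(2, 2)),
               "need >= 2")

  # large-sample fixture: recovered mean within 3 standard errors
  spec <- latent_fixture_spec(list(g = c(2, -1, 0, 3)),
                              list(g = diag(c(4, 1, 1, 2))),
                              c(g = 4000), R = 2, d = 2, seed = 13)
  fit <- fit_class_distributions(sample_latent_fixture(spec),
                                 layout = latent_layout(2, 2))
  se <- sqrt(c(4, 1, 1, 2) / 4000)
  expect_true(all(abs(fit$g$mean - c(2, -1, 0, 3)) < 3 * se))

  # the per-region covariance equals the block of the subset columns
  Z <- latent_matrix(sample_latent_fixture(spec))
  S2 <- cov(Z[, 3:4])
  expect_equal(fit$g$regional[[2]]$cov,
               S2 + diag(fit$g$regional[[2]]$shrinkage * sum(diag(S2)) / 2, 2),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Mahalanobis distance is calibrated in healthy SD units", {
  # identity covariance reduces to Euclidean: the 3-4-5 triangle
  expect_equal(latent_mahalanobis(c(0, 0), c(3, 4), diag(2)), 5)
  # variance 4 on the first axis: points 2 apart on it are 1 SD apart
  expect_equal(latent_mahalanobis(c(0, 0), c(2, 0), diag(c(4, 1))), 1)
  expect_error(latent_mahalanobis(c(0, 0, 0), c(1, 0), diag(2)), "mismatch")
})

test_that("Mahalanobis agrees with an eigen-whitening oracle and is a metric", {
  set.seed(31)
  for (i in 1:25) {
    S <- random_spd(5)
    z1 <- rnorm(5); z2 <- rnorm(5); z3 <- rnorm(5)
    # oracle: whiten by explicit eigendecomposition, take Euclidean norm
    e <- eigen(S, symmetric = TRUE)
    W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    oracle <- sqrt(sum((W %*% (z1 - z2))^2))
    d12 <- latent_mahalanobis(z1, z2, S)
    expect_equal(d12, oracle, tolerance = 1e-8)
    # metric axioms on random triples
    expect_equal(d12, latent_mahalanobis(z2, z1, S), tolerance = 1e-12)
    expect_equal(latent_mahalanobis(z1, z1, S), 0)
    expect_lte(d12, latent_mahalanobis(z1, z3, S) +
                    latent_mahalanobis(z3, z2, S) + 1e-12)
    # scale equivariance: z -> c z, S -> c^2 S leaves the distance unchanged
    expect_equal(latent_mahalanobis(3 * z1, 3 * z2, 9 * S), d12,
                 tolerance = 1e-10)
  }
})

test_that("whitening is norm-consistent with the distance", {
  set.seed(32)
  d <- make_plain_dist(c(1, -2, 0), random_spd(3))
  for (i in 1:10) {
    z <- rnorm(3)
    w <- whiten_latent(z, d)
    expect_equal(sqrt(sum(w^2)), latent_mahalanobis(z, d$mean, d),
                 tolerance = 1e-8)
  }
  expect_equal(whiten_latent(d$mean, d), c(0, 0, 0))
  id <- make_plain_dist(c(1, 1), diag(2))
  expect_equal(whiten_latent(c(3, 0), id), c(2, -1))
})

test_that("QDA maximizes the Gaussian posterior with calibrated boundaries", {
  dists <- list(a = make_plain_dist(c(0, 0), diag(2)),
                b = make_plain_dist(c(4, 0), diag(2)))
  # at a class mean with equal priors and covariances, that class wins
  pr <- qda_predict(dists, c(0, 0))
  expect_identical(pr$label, "a")
  expect_equal(sum(pr$posterior), 1, tolerance = 1e-12)

  # 1-dim closed form: N(0, 1) vs N(3, 4); the decision boundary solves
  # -x^2/2 - log(1) = -(x-3)^2/8 - log(2), a quadratic with a root between
  # the means at x = (-3 + sqrt(9 + 3*(9/2 - 4*log(2)))) / 3
  d1 <- list(lo = make_plain_dist(0, matrix(1)),
             hi = make_plain_dist(3, matrix(4)))
  disc <- function(x) (-x^2 / 2) - (-(x - 3)^2 / 8 - log(2))
  root <- uniroot(disc, c(0, 3), tol = 1e-12)$root
  expect_identical(qda_predict(d1, root - 1e-6)$label, "lo")
  expect_identical(qda_predict(d1, root + 1e-6)$label, "hi")

  # posteriors over random inputs always normalize
  set.seed(5)
  tab <- matrix(rnorm(20), 10, 2)
  colnames(tab) <- c("z_001", "z_002")
  res <- qda_predict(dists, tab)
  expect_equal(rowSums(as.matrix(res[, -1])), rep(1, 10), tolerance = 1e-12)
})

test_that("QDA matches MASS::qda on a well-conditioned fixture", {
  skip_if_not_installed("MASS")
  set.seed(77)
  n <- 120
  Z <- rbind(matrix(rnorm(n * 4), ncol = 4),
             matrix(rnorm(n * 4, mean = 2), ncol = 4),
             matrix(rnorm(n * 4, sd = 2), ncol = 4))
  lab <- rep(c("p", "q", "r"), each = n)
  tab <- data.frame(class_label = lab, Z)
  names(tab)[-1] <- sprintf("z_%03d", 1:4)
  dists <- fit_class_distributions(tab, layout = latent_layout(2, 2))
  mine <- qda_predict(dists, tab)$label
  ref <- as.character(stats::predict(MASS::qda(Z, grouping = lab,
                                               prior = rep(1 / 3, 3)))$class)
  expect_gt(mean(mine == ref), 0.98)
})

test_that("confusion counts and precision follow the TP/(TP+FP) definition", {
  cm <- confusion_and_precision(c("a", "a", "b"), c("a", "a", "b"))
  expect_equal(unname(cm$precision), c(1, 1))
  # 9 true-A predicted A, 1 true-B predicted A: precision(A) = 0.9
  cm2 <- confusion_and_precision(c(rep("A", 9), "B"), rep("A", 10))
  expect_equal(cm2$precision[["A"]], 0.9)
  expect_true(is.na(cm2$precision[["B"]]))   # never predicted: flagged, not 0
  expect_identical(cm2$undefined, "B")

  # random labels vs a brute-force pair-counting oracle
  set.seed(9)
  tru <- sample(c("x", "y", "z"), 60, replace = TRUE)
  prd <- sample(c("x", "y", "z"), 60, replace = TRUE)
  cm3 <- confusion_and_precision(tru, prd)
  for (ti in c("x", "y", "z")) for (pj in c("x", "y", "z"))
    expect_identical(cm3$counts[ti, pj], sum(tru == ti & prd == pj))
  expect_identical(sum(cm3$counts), 60L)
  ok <- !is.na(cm3$precision)
  expect_true(all(cm3$precision[ok] >= 0 & cm3$precision[ok] <= 1))
  expect_error(confusion_and_precision("a", c("a", "b")), "length")
  expect_error(confusion_and_precision("a", "q", classes = c("a", "b")),
               "outside")
})

test_that("LDA projects to exactly 2D, deterministically, without refitting", {
  set.seed(41)
  n <- 50
  Z <- rbind(matrix(rnorm(n * 6), ncol = 6),
             sweep(matrix(rnorm(n * 6), ncol = 6), 2, c(8, 0, 0, 0, 0, 0), `+`),
             sweep(matrix(rnorm(n * 6), ncol = 6), 2, c(0, 8, 0, 0, 0, 0), `+`))
  lab <- rep(c("g1", "g2", "g3"), each = n)
  tab <- data.frame(class_label = lab, Z)
  names(tab)[-1] <- sprintf("z_%03d", 1:6)
  proj <- lda_fit_project(tab)
  expect_identical(dim(proj$axes), c(6L, 2L))
  XY <- project_latents(proj, tab)
  expect_identical(dim(XY), c(150L, 2L))
  # well-separated classes: projected means farther apart than twice the
  # mean within-class 2D scatter radius
  means <- lapply(unique(lab), function(g) colMeans(XY[lab == g, ]))
  scatter <- mean(vapply(unique(lab), function(g)
    mean(sqrt(rowSums(sweep(XY[lab == g, ], 2,
                            colMeans(XY[lab == g, ]))^2))), numeric(1)))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gt(sqrt(sum((means[[i]] - means[[j]])^2)), 2 * scatter)
  # projecting the same point twice is identical, and projection is frozen
  expect_identical(project_latents(proj, Z[1, ]),
                   project_latents(proj, Z[1, ]))
  manual <- (Z[1, ] - proj$center) %*% proj$axes
  expect_equal(unname(project_latents(proj, Z[1, ])), manual,
               tolerance = 1e-12)
  # two classes: one discriminant axis plus a declared zero second axis
  proj2 <- lda_fit_project(tab[lab != "g3", ])
  expect_identical(dim(proj2$axes), c(6L, 2L))
  expect_true(all(proj2$axes[, 2] == 0))
  expect_error(lda_fit_project(tab[lab == "g1", ]), ">= 2 classes")
})
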