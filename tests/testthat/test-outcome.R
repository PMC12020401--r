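# The regional outcome metric: versors, worked cases, monotonicity in
# surgical completeness, sign correctness and cohort summaries.

test_that("versors are unit length with flagged degeneracies", {
  id2 <- make_plain_dist(c(0, 0), diag(2))
  # zero movement: flagged null versor, no error
  s0 <- surgical_versor(c(1, 2), c(1, 2), id2)
  expect_true(s0$null)
  expect_equal(s0$v, c(0, 0))
  # identity covariance: plain normalized difference
  s1 <- surgical_versor(c(0, 0), c(0, 3), id2)
  expect_equal(s1$v, c(0, 1))
  # healthy versor: mu = 0, pre = (4, 0) points back to the mean
  v1 <- healthy_versor(c(4, 0), id2)
  expect_equal(v1$v, c(-1, 0))
  expect_true(healthy_versor(c(0, 0), id2)$null)
  # unit norm on random nondegenerate inputs
  set.seed(3)
  for (i in 1:10) {
    d <- make_plain_dist(rnorm(3), random_spd(3))
    s <- surgical_versor(rnorm(3), rnorm(3), d)
    expect_equal(sqrt(sum(s$v^2)), 1, tolerance = 1e-12)
  }
})

test_that("the regional metric reproduces its worked cases", {
  hd <- make_plain_dist(c(0, 0), diag(2))
  lay <- latent_layout(1, 2)
  # movement straight toward the mean, halving the distance: 2 -> 1
  p1 <- surgical_pair("p1", "op", c(2, 0), c(1, 0), lay)
  o1 <- regional_metric(p1, 1, hd)
  expect_equal(o1$magnitude, 1)
  expect_equal(o1$proximity, 1)
  expect_equal(o1$alignment, 1)
  expect_equal(o1$m, 1)
  # movement straight away: 2 -> 3 gives -1/3
  p2 <- surgical_pair("p2", "op", c(2, 0), c(3, 0), lay)
  o2 <- regional_metric(p2, 1, hd)
  expect_equal(o2$alignment, -1)
  expect_equal(o2$m, -1 / 3)
  # no movement: m = 0 by convention, flagged
  p3 <- surgical_pair("p3", "op", c(2, 0), c(2, 0), lay)
  o3 <- regional_metric(p3, 1, hd)
  expect_equal(o3$m, 0)
  expect_true("no_movement" %in% o3$flags)
  # post exactly at the healthy mean: denominator floored and flagged
  p4 <- surgical_pair("p4", "op", c(2, 0), c(0, 0), hd$layout)
  o4 <- regional_metric(p4, 1, hd, eps = 1e-6)
  expect_true("denominator_floored" %in% o4$flags)
  expect_equal(o4$m, 2 / 1e-6)
  # the alternative product reading stays available behind the switch
  expect_equal(regional_metric(p2, 1, hd, form = "product")$m, -3)
})

test_that("m_r increases strictly with completeness and flips sign when adverse", {
  hd <- make_plain_dist(c(0, 0, 0), diag(3))
  lay <- latent_layout(1, 3)
  z_pre <- c(4, 0, 0)
  ms <- vapply(c(0.2, 0.4, 0.6, 0.8), function(alpha) {
    z_post <- (1 - alpha) * z_pre    # ideal noise-free ray toward the mean
    regional_metric(surgical_pair("p", "op", z_pre, z_post, lay), 1, hd)$m
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_equal(ms, (c(0.2, 0.4, 0.6, 0.8) / (1 - c(0.2, 0.4, 0.6, 0.8))),
               tolerance = 1e-12)
  adverse <- regional_metric(
    surgical_pair("p", "op", z_pre, 1.5 * z_pre, lay), 1, hd)
  expect_lt(adverse$m, 0)
})

test_that("the metric is invariant under common invertible linear maps", {
  set.seed(12)
  d <- 5
  S <- random_spd(d)
  mu <- rnorm(d)
  hd <- make_plain_dist(mu, S)
  lay <- latent_layout(1, d)
  z_pre <- rnorm(d); z_post <- rnorm(d)
  base <- regional_metric(surgical_pair("p", "op", z_pre, z_post, lay), 1, hd)
  for (i in 1:5) {
    A <- matrix(rnorm(d * d), d)
    hd2 <- make_plain_dist(as.numeric(A %*% mu), A %*% S %*% t(A))
    tr <- regional_metric(surgical_pair("p", "op", as.numeric(A %*% z_pre),
                                        as.numeric(A %*% z_post), lay), 1, hd2)
    expect_equal(tr$magnitude, base$magnitude, tolerance = 1e-8)
    expect_equal(tr$proximity, base$proximity, tolerance = 1e-8)
    expect_equal(tr$alignment, base$alignment, tolerance = 1e-8)
    expect_equal(tr$m, base$m, tolerance = 1e-8)
  }
})

test_that("patient assessment ties regions, globals and 2D coordinates together", {
  fx <- fix_trained()
  tpl <- fx$template
  pa <- Filter(function(s) s$class_label == "synA", fx$subjects)[[2]]
  z_pre <- sdvae_encode(fx$model, pa$mesh)

  # post = pre: every m_r zero, 2D coordinates coincide
  pair0 <- surgical_pair(pa$subject_id, "none", z_pre, z_pre)
  rep0 <- assess_patient(pair0, fx$dists, fx$projection)
  expect_true(all(vapply(rep0$regional, `[[`, numeric(1), "m") == 0))
  expect_equal(rep0$coords_2d$pre, rep0$coords_2d$post)
  expect_equal(rep0$global_d_pre, rep0$global_d_post)

  # toward-healthy surgery on regions {4, 5}: positive m there, near-zero
  # elsewhere, and the global distance shrinks
  post <- apply_surgery(pa, surgery_spec(c(4, 5), alpha = 0.5, seed = 2),
                        fx$healthy_mean, tpl)
  pair <- surgical_pair(pa$subject_id, "midface", z_pre,
                        sdvae_encode(fx$model, post$mesh))
  rep1 <- assess_patient(pair, fx$dists, fx$projection)
  m <- vapply(rep1$regional, `[[`, numeric(1), "m")
  expect_true(all(m[c(4, 5)] > 0))
  expect_lt(rep1$global_d_post, rep1$global_d_pre)
  # arrow endpoints equal the frozen projection of the pair's latents
  expect_equal(unname(rep1$coords_2d$pre),
               as.numeric(project_latents(fx$projection, pair$z_pre)),
               tolerance = 1e-12)
})

test_that("cohort summaries aggregate by procedure and region faithfully", {
  fx <- fix_trained()
  tpl <- fx$template
  synA <- Filter(function(s) s$class_label == "synA", fx$subjects)[1:6]
  make_reports <- function(alpha, label, subjects) {
    lapply(seq_along(subjects), function(i) {
      s <- subjects[[i]]
      post <- apply_surgery(s, surgery_spec(c(4, 5), alpha = alpha,
                                            seed = 100 + i),
                            fx$healthy_mean, tpl)
      pair <- surgical_pair(s$subject_id, label,
                            sdvae_encode(fx$model, s$mesh),
                            sdvae_encode(fx$model, post$mesh))
      assess_patient(pair, fx$dists, fx$projection)
    })
  }
  reps_lo <- make_reports(0.3, "partial", synA[1:3])
  reps_hi <- make_reports(0.8, "full", synA[4:6])

  # single report: medians equal that report's m_r values
  s1 <- cohort_summary(reps_lo[1])
  expect_equal(s1$median,
               vapply(reps_lo[[1]]$regional, `[[`, numeric(1), "m"))

  tab <- cohort_summary(c(reps_lo, reps_hi))
  expect_identical(sort(unique(tab$procedure)), c("full", "partial"))
  for (r in c(4, 5)) {
    lo <- tab$median[tab$procedure == "partial" & tab$region == r]
    hi <- tab$median[tab$procedure == "full" & tab$region == r]
    expect_gt(hi, lo)         # higher completeness, higher median m_r
  }
  # a procedure that never touches a region leaves its median |m_r| small
  untouched <- setdiff(1:15, c(4, 5))
  hi_m <- tab[tab$procedure == "full" & tab$region %in% c(4, 5), "median"]
  for (r in untouched) {
    expect_lt(abs(tab$median[tab$procedure == "full" & tab$region == r]),
              0.25 * min(hi_m))
  }
  # long export carries one row per patient x region
  long <- outcome_long(c(reps_lo, reps_hi))
  expect_identical(nrow(long), 6L * 15L)
})
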