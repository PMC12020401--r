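# Regional surgical-outcome metric.
#
# For each anatomic region r, surgery moves the regional latent subset from
# z_pre^r to z_post^r. In the whitened geometry of the healthy distribution
# (mu_H^r, Sigma_H^r) the metric is
#
#   m_r = [ dM(z_pre^r, z_post^r) / max(dM(z_post^r, mu_H^r), eps) ]
#         * <s_hat_r, v_hat_H^r>
#
# where s_hat_r is the unit direction (versor) of the surgical movement and
# v_hat_H^r the versor from the preoperative point toward the healthy mean.
# Large positive m_r: a substantial movement, in the correct direction,
# ending close to the center of the healthy distribution. Negative m_r:
# movement away from the healthy population. Versors and the inner product
# live in the whitened regional space so that directions and distances
# share one geometry.

#' Bundle a pre/post-operative latent pair
#'
#' @param patient_id identifier.
#' @param procedure procedure label (e.g. monobloc, bipartition, LeFortIII).
#' @param z_pre,z_post `latent_vector`s (or bare numerics) sharing a layout.
#' @param layout a `latent_layout`, required if bare numerics are given.
#' @return object of class `surgical_pair`.
#' @export
surgical_pair <- function(patient_id, procedure, z_pre, z_post, layout = NULL) {
  get_vals <- function(z) if (inherits(z, "latent_vector")) z$values else as.numeric(z)
  get_lay <- function(z) if (inherits(z, "latent_vector")) z$layout else layout
  lay <- get_lay(z_pre)
  if (is.null(lay)) .stopf("layout required for bare numeric latents")
  vp <- get_vals(z_pre); vq <- get_vals(z_post)
  if (length(vp) != lay$width || length(vq) != lay$width)
    .stopf("latents do not share the %d-wide layout", lay$width)
  structure(list(patient_id = patient_id, procedure = procedure,
                 z_pre = vp, z_post = vq, layout = lay),
            class = "surgical_pair")
}

## Unit vector with degeneracy flag; the null versor is all zeros.
.versor <- function(v, tol = 1e-12) {
  nrm <- sqrt(sum(v^2))
  if (nrm < tol) list(v = v * 0, null = TRUE, norm = 0)
  else list(v = v / nrm, null = FALSE, norm = nrm)
}

#' Versor of the surgical movement in region r
#'
#' Unit direction of (whitened z_post^r - whitened z_pre^r); a zero
#' movement yields a flagged null versor, never an error.
#'
#' @param z_pre_r,z_post_r regional latent subsets (width d).
#' @param healthy_dist a `class_distribution` (its regional block `region`
#'   is used) or an explicit d x d covariance.
#' @param region region id when `healthy_dist` is a fitted distribution.
#' @return list with unit vector `v` and logical `null`.
#' @export
surgical_versor <- function(z_pre_r, z_post_r, healthy_dist, region = NULL) {
  wp <- whiten_latent(z_pre_r, healthy_dist, region)
  wq <- whiten_latent(z_post_r, healthy_dist, region)
  .versor(wq - wp)
}

#' Versor toward the healthy mean in region r
#'
#' Unit direction of the ideal trajectory from the preoperative point to
#' the center of the healthy distribution: -(whitened z_pre^r) normalized.
#'
#' @inheritParams surgical_versor
#' @export
healthy_versor <- function(z_pre_r, healthy_dist, region = NULL) {
  wp <- whiten_latent(z_pre_r, healthy_dist, region)
  .versor(-wp)
}

#' Regional outcome metric m_r
#'
#' @param pair a `surgical_pair`.
#' @param r region id.
#' @param healthy_dist the healthy `class_distribution` (regional block r
#'   is used).
#' @param eps denominator floor in SD units (default 1e-6); a postoperative
#'   point essentially at the healthy mean floors the denominator and sets
#'   the `denominator_floored` flag.
#' @param form `"ratio"` (default; movement magnitude over residual
#'   distance) or `"product"` for the alternative reading.
#' @return object of class `regional_outcome`: `m`, `magnitude`
#'   (= dM(pre, post)), `proximity` (= dM(post, mu_H)), `alignment` in
#'   [-1, 1], and `flags`.
#' @export
regional_metric <- function(pair, r, healthy_dist, eps = 1e-6,
                            form = c("ratio", "product")) {
  form <- match.arg(form)
  stopifnot(inherits(pair, "surgical_pair"))
  idx <- latent_subset(pair$layout, r)
  wp <- whiten_latent(pair$z_pre[idx], healthy_dist, r)
  wq <- whiten_latent(pair$z_post[idx], healthy_dist, r)
  magnitude <- sqrt(sum((wq - wp)^2))   # = dM(z_pre^r, z_post^r)
  proximity <- sqrt(sum(wq^2))          # = dM(z_post^r, mu_H^r)
  s_hat <- .versor(wq - wp)
  v_hat <- .versor(-wp)
  flags <- character(0)
  if (s_hat$null) flags <- c(flags, "no_movement")
  if (v_hat$null) flags <- c(flags, "pre_at_healthy_mean")
  alignment <- if (s_hat$null || v_hat$null) 0
               else max(-1, min(1, sum(s_hat$v * v_hat$v)))
  if (s_hat$null) {
    m <- 0
  } else {
    denom <- proximity
    if (denom < eps) { denom <- eps; flags <- c(flags, "denominator_floored") }
    m <- switch(form,
                ratio = (magnitude / denom) * alignment,
                product = magnitude * proximity * alignment)
  }
  structure(list(region = r, m = m, magnitude = magnitude,
                 proximity = proximity, alignment = alignment,
                 form = form, flags = flags),
            class = "regional_outcome")
}

#' Full per-patient outcome report
#'
#' One `regional_outcome` per region, the global pre/post 2D manifold
#' coordinates under a frozen LDA projection, and the global Mahalanobis
#' distances to the healthy mean before and after surgery.
#'
#' @param pair a `surgical_pair`.
#' @param dists named list of `class_distribution` including `"healthy"`.
#' @param projection a fitted `manifold_projection`, or `NULL` to skip 2D
#'   coordinates.
#' @param eps,form passed to [regional_metric()].
#' @return object of class `outcome_report`.
#' @export
assess_patient <- function(pair, dists, projection = NULL,
                           eps = 1e-6, form = "ratio") {
  healthy <- dists[["healthy"]]
  if (is.null(healthy)) .stopf("no 'healthy' class distribution supplied")
  if (healthy$layout$width != pair$layout$width)
    .stopf("latent layout mismatch between pair and distributions")
  regions <- lapply(seq_len(pair$layout$R), function(r)
    regional_metric(pair, r, healthy, eps = eps, form = form))
  d_pre <- latent_mahalanobis(pair$z_pre, healthy$mean, healthy)
  d_post <- latent_mahalanobis(pair$z_post, healthy$mean, healthy)
  coords <- if (!is.null(projection)) {
    xy <- project_latents(projection, rbind(pair$z_pre, pair$z_post))
    list(pre = xy[1, ], post = xy[2, ])
  } else NULL
  structure(list(patient_id = pair$patient_id, procedure = pair$procedure,
                 regional = regions, global_d_pre = d_pre,
                 global_d_post = d_post, coords_2d = coords),
            class = "outcome_report")
}

#' Flatten outcome reports to a long table
#'
#' One row per patient x region: patient, procedure, region, m, magnitude,
#' proximity, alignment, flags (";"-joined). The export format used for
#' boxplots.
#'
#' @param reports list of `outcome_report`.
#' @return data.frame in long format.
#' @export
outcome_long <- function(reports) {
  do.call(rbind, lapply(reports, function(rep) {
    do.call(rbind, lapply(rep$regional, function(ro)
      data.frame(patient_id = rep$patient_id, procedure = rep$procedure,
                 region = ro$region, m = ro$m, magnitude = ro$magnitude,
                 proximity = ro$proximity, alignment = ro$alignment,
                 flags = paste(ro$flags, collapse = ";"),
                 stringsAsFactors = FALSE)))
  }))
}

#' Per-procedure, per-region cohort summary
#'
#' Groups the regional metric by procedure label and region and returns
#' median, quartiles, extremes, group size and flag count - the table
#' behind the regional boxplot.
#'
#' @param reports list of `outcome_report` (>= 1).
#' @return data.frame: procedure, region, n, median, q1, q3, min, max,
#'   n_flagged.
#' @export
cohort_summary <- function(reports) {
  if (!length(reports)) .stopf("no reports to summarize")
  long <- outcome_long(reports)
  groups <- unique(long[, c("procedure", "region")])
  groups <- groups[order(groups$region, groups$procedure), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- long[long$procedure == groups$procedure[i] &
              long$region == groups$region[i], ]
    qs <- stats::quantile(g$m, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(procedure = groups$procedure[i], region = groups$region[i],
               n = nrow(g), median = qs[2], q1 = qs[1], q3 = qs[3],
               min = min(g$m), max = max(g$m),
               n_flagged = sum(nzchar(g$flags)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export an outcome report as JSON
#'
#' @param report an `outcome_report`.
#' @param path output path.
#' @export
write_outcome_json <- function(report, path) {
  x <- list(patient_id = report$patient_id, procedure = report$procedure,
            global_d_pre = report$global_d_pre,
            global_d_post = report$global_d_post,
            coords_2d = report$coords_2d,
            regional = lapply(report$regional, function(ro)
              list(region = ro$region, m = ro$m, magnitude = ro$magnitude,
                   proximity = ro$proximity, alignment = ro$alignment,
                   flags = as.list(ro$flags))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
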