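# Per-class Gaussian models in latent space.
#
# Classes (healthy, synA, synB, ...) are modelled as Gaussians with their
# own covariance, both globally (width R*d) and per region (width d, on the
# latent subset z_r). Distances are Mahalanobis under the healthy
# covariance: dM = 1 means one standard deviation of the healthy
# distribution. Classification is QDA on the class Gaussians; LDA is used
# only to project to 2D for manifold visualization, never to compute the
# outcome metric.

#' Extract the latent matrix from a latent table
#'
#' @param latents data.frame with `z_###` columns (as produced by
#'   [sdvae_encode_table()] / [sample_latent_fixture()]) or a bare matrix.
#' @return numeric matrix, one row per subject.
#' @export
latent_matrix <- function(latents) {
  if (is.matrix(latents)) return(latents)
  zc <- grep("^z_", names(latents), value = TRUE)
  if (!length(zc)) .stopf("no z_ columns in latent table")
  as.matrix(latents[, zc, drop = FALSE])
}

## Ridge-regularized covariance: S + eps * (tr(S)/p) * I, with the scale
## falling back to 1 for degenerate (zero-variance) classes and eps
## escalated x10 until the result is numerically PD.
.reg_cov <- function(S, eps) {
  p <- ncol(S)
  scale <- sum(diag(S)) / p
  if (!is.finite(scale) || scale < 1e-12) scale <- 1
  repeat {
    Sr <- S + diag(eps * scale, p)
    ev <- eigen((Sr + t(Sr)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0) return(list(cov = (Sr + t(Sr)) / 2, eps = eps))
    eps <- eps * 10
  }
}

#' Fit per-class global and per-region Gaussian distributions
#'
#' Sample means and ridge-regularized covariances (`S + eps * tr(S)/p * I`;
#' `eps` is escalated automatically, and recorded, if the result is not
#' positive-definite).
#'
#' @param latents latent table or matrix (see [latent_matrix()]).
#' @param labels class label per row (taken from the table's `class_label`
#'   column if missing).
#' @param layout a `latent_layout`; defaults to 15 x 5 if the width is 75,
#'   otherwise must be supplied.
#' @param shrinkage ridge intensity `eps` (default 1e-6) or `"auto"`
#'   (same starting point, escalation always applies).
#' @return named list of `class_distribution` objects (class ->
#'   mean/cov/regional blocks/shrinkage used).
#' @export
fit_class_distributions <- function(latents, labels = NULL, layout = NULL,
                                    shrinkage = 1e-6) {
  Z <- latent_matrix(latents)
  if (is.null(labels)) {
    if (!is.data.frame(latents) || is.null(latents$class_label))
      .stopf("labels missing and latent table has no class_label column")
    labels <- latents$class_label
  }
  if (length(labels) != nrow(Z)) .stopf("labels length != number of rows")
  p <- ncol(Z)
  if (is.null(layout)) {
    if (p == 75) layout <- latent_layout(15, 5)
    else .stopf("layout must be supplied for latent width %d", p)
  }
  if (layout$width != p) .stopf("layout width %d != latent width %d", layout$width, p)
  eps0 <- if (identical(shrinkage, "auto")) 1e-6 else as.numeric(shrinkage)
  if (eps0 < 0 || eps0 > 1) .stopf("shrinkage must be in [0,1] or 'auto'")

  out <- lapply(sort(unique(labels)), function(cl) {
    Zi <- Z[labels == cl, , drop = FALSE]
    if (nrow(Zi) < 2L) .stopf("class %s has %d row(s); need >= 2", cl, nrow(Zi))
    mu <- colMeans(Zi)
    Sg <- .reg_cov(stats::cov(Zi), eps0)
    regional <- lapply(seq_len(layout$R), function(r) {
      idx <- latent_subset(layout, r)
      Sr <- .reg_cov(stats::cov(Zi[, idx, drop = FALSE]), eps0)
      list(mean = mu[idx], cov = Sr$cov, shrinkage = Sr$eps)
    })
    structure(list(class = cl, n = nrow(Zi), mean = mu, cov = Sg$cov,
                   shrinkage = Sg$eps, regional = regional, layout = layout),
              class = "class_distribution")
  })
  stats::setNames(out, sort(unique(labels)))
}

## Resolve (mean, cov) for a distribution argument: a class_distribution
## (global or regional via `region`), or an explicit covariance matrix
## (mean taken as 0 unless given).
.dist_params <- function(dist, region = NULL, mean = NULL) {
  if (inherits(dist, "class_distribution")) {
    if (is.null(region)) list(mean = dist$mean, cov = dist$cov)
    else {
      if (region < 1 || region > dist$layout$R) .stopf("unknown region %d", region)
      dist$regional[[region]][c("mean", "cov")]
    }
  } else {
    S <- as.matrix(dist)
    list(mean = if (is.null(mean)) rep(0, ncol(S)) else mean, cov = S)
  }
}

#' Mahalanobis distance between two latent vectors
#'
#' `dM(z1, z2) = sqrt((z1 - z2)' Sigma^-1 (z1 - z2))` under the given
#' distribution's covariance: the distance in standard deviations of that
#' distribution. `dM = 1` means the two vectors sit one SD apart.
#'
#' @param z1,z2 numeric vectors of equal length.
#' @param dist a `class_distribution` or an explicit covariance matrix.
#' @param region optional region id: use the regional block
#'   `(mu_r, Sigma_r)` of a fitted distribution.
#' @param squared return the squared distance.
#' @return nonnegative scalar.
#' @export
latent_mahalanobis <- function(z1, z2, dist, region = NULL, squared = FALSE) {
  pars <- .dist_params(dist, region)
  z1 <- as.numeric(z1); z2 <- as.numeric(z2)
  if (length(z1) != length(z2) || length(z1) != ncol(pars$cov))
    .stopf("dimension mismatch: vectors %d/%d, covariance %d",
           length(z1), length(z2), ncol(pars$cov))
  diff <- z1 - z2
  Lc <- tryCatch(chol(pars$cov),
                 error = function(e) .stopf("covariance not positive-definite"))
  q <- sum(backsolve(Lc, diff, transpose = TRUE)^2)
  if (squared) q else sqrt(q)
}

#' Whiten a latent vector under a class distribution
#'
#' `w = Sigma^-1/2 (z - mu)` (symmetric inverse square root); the Euclidean
#' norm of `w` equals the Mahalanobis distance of `z` to the mean, so
#' directions and distances share one geometry.
#'
#' @inheritParams latent_mahalanobis
#' @param z latent vector (global or regional width).
#' @return whitened numeric vector.
#' @export
whiten_latent <- function(z, dist, region = NULL) {
  pars <- .dist_params(dist, region)
  z <- as.numeric(z)
  if (length(z) != ncol(pars$cov))
    .stopf("dimension mismatch: vector %d, covariance %d", length(z), ncol(pars$cov))
  as.numeric(.spd_power(pars$cov, -0.5) %*% (z - pars$mean))
}

#' Classify a latent vector with quadratic discriminant analysis
#'
#' Label = argmax over classes of Gaussian log-density plus log prior;
#' ties are broken by class-name order. Priors default to uniform
#' (augmented class sizes reflect augmentation policy, not prevalence).
#'
#' @param dists named list of `class_distribution` (>= 2 classes).
#' @param z latent vector, or a matrix/latent table of rows to classify.
#' @param priors named numeric vector of priors, or `NULL` for uniform.
#' @param region optional region id for regional (d-wide) classification.
#' @return for one vector: list(label, posterior); for several rows: a
#'   data.frame of labels with posterior columns.
#' @export
qda_predict <- function(dists, z, priors = NULL, region = NULL) {
  if (length(dists) < 2L) .stopf("need >= 2 fitted classes")
  cls <- sort(names(dists))
  if (is.null(priors)) priors <- stats::setNames(rep(1 / length(cls), length(cls)), cls)
  priors <- priors / sum(priors)
  pre <- lapply(cls, function(cl) {
    pars <- .dist_params(dists[[cl]], region)
    Lc <- chol(pars$cov)
    list(mean = pars$mean, Lc = Lc, logdet = 2 * sum(log(diag(Lc))),
         logprior = log(priors[[cl]]))
  })
  names(pre) <- cls
  score_one <- function(zv) {
    lp <- vapply(cls, function(cl) {
      pp <- pre[[cl]]
      diff <- zv - pp$mean
      q <- sum(backsolve(pp$Lc, diff, transpose = TRUE)^2)
      -0.5 * (length(zv) * log(2 * pi) + pp$logdet + q) + pp$logprior
    }, numeric(1))
    post <- exp(lp - max(lp)); post <- post / sum(post)
    list(label = cls[which.max(lp)], posterior = post)
  }
  if (is.data.frame(z) || is.matrix(z)) {
    Z <- latent_matrix(z)
    res <- apply(Z, 1, score_one)
    data.frame(label = vapply(res, `[[`, character(1), "label"),
               do.call(rbind, lapply(res, `[[`, "posterior")),
               stringsAsFactors = FALSE)
  } else score_one(as.numeric(z))
}

#' Confusion matrix and per-class precision
#'
#' Precision = TP / (TP + FP) per class; classes that were never predicted
#' have undefined precision and are flagged (`NA`), not zero-filled.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param classes optional fitted class set; labels outside it are an error.
#' @return object of class `confusion_matrix` with `counts` (rows = true,
#'   columns = predicted) and `precision`.
#' @export
confusion_and_precision <- function(true_labels, predicted_labels,
                                    classes = NULL) {
  if (length(true_labels) != length(predicted_labels))
    .stopf("label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(true_labels, predicted_labels)))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(bad)) .stopf("label(s) outside fitted class set: %s",
                          paste(bad, collapse = ", "))
  counts <- table(factor(true_labels, classes), factor(predicted_labels, classes))
  tp <- diag(counts)
  pred_tot <- colSums(counts)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, NA_real_)
  structure(list(counts = unclass(counts),
                 precision = stats::setNames(as.numeric(precision), classes),
                 undefined = classes[pred_tot == 0]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(x$counts)
  cat("per-class precision:\n")
  print(round(x$precision, 4))
  invisible(x)
}

#' Fit an LDA projection to 2D and project points
#'
#' Discriminant axes are fitted on labelled data only; any new
#' (pre/postoperative) points are projected with the frozen transform,
#' never refitting. Three or more classes give exactly 2 axes; two classes
#' give the single discriminant axis padded with a zero second axis.
#'
#' @param latents latent table or matrix of labelled training rows.
#' @param labels class labels (or taken from the table).
#' @param ridge within-class scatter ridge (relative to `tr(Sw)/p`).
#' @return object of class `manifold_projection` with `axes` (p x 2),
#'   `center`, per-class 2D means and 2 x 2 covariances for contour
#'   drawing. Use [project_latents()] to apply it.
#' @export
lda_fit_project <- function(latents, labels = NULL, ridge = 1e-8) {
  Z <- latent_matrix(latents)
  if (is.null(labels)) labels <- latents$class_label
  cls <- sort(unique(labels))
  C <- length(cls)
  if (C < 2L) .stopf("need >= 2 classes for a discriminant projection")
  p <- ncol(Z)
  center <- colMeans(Z)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in cls) {
    Zi <- Z[labels == cl, , drop = FALSE]
    mu <- colMeans(Zi)
    Sw <- Sw + crossprod(sweep(Zi, 2, mu))
    Sb <- Sb + nrow(Zi) * tcrossprod(mu - center)
  }
  Sw <- Sw / max(1, nrow(Z) - C)
  Sw <- Sw + diag(ridge * max(sum(diag(Sw)) / p, 1e-12), p)
  W <- .spd_power(Sw, -0.5)
  M <- W %*% Sb %*% W
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_axes <- min(C - 1L, 2L)
  axes <- W %*% e$vectors[, seq_len(n_axes), drop = FALSE]
  axes <- sweep(axes, 2, sqrt(colSums(axes^2)), "/")
  # deterministic sign: largest-|loading| coordinate positive
  for (j in seq_len(n_axes)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  if (n_axes < 2L) axes <- cbind(axes, 0)   # declared zero second axis
  proj <- structure(list(axes = axes, center = center, classes = cls),
                    class = "manifold_projection")
  XY <- project_latents(proj, Z)
  proj$class_means_2d <- lapply(stats::setNames(cls, cls), function(cl)
    colMeans(XY[labels == cl, , drop = FALSE]))
  proj$class_cov_2d <- lapply(stats::setNames(cls, cls), function(cl)
    stats::cov(XY[labels == cl, , drop = FALSE]))
  proj
}

#' Project latent rows with a fitted manifold projection
#'
#' @param projection a `manifold_projection`.
#' @param latents latent table, matrix, vector, or `latent_vector`.
#' @return n x 2 matrix of 2D coordinates (columns LD1, LD2).
#' @export
project_latents <- function(projection, latents) {
  if (inherits(latents, "latent_vector")) latents <- latents$values
  Z <- if (is.numeric(latents) && is.null(dim(latents)))
    matrix(latents, 1) else latent_matrix(latents)
  if (ncol(Z) != nrow(projection$axes))
    .stopf("latent width %d != projection input width %d",
           ncol(Z), nrow(projection$axes))
  XY <- sweep(Z, 2, projection$center) %*% projection$axes
  colnames(XY) <- c("LD1", "LD2")
  XY
}
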