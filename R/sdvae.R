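# Region-disentangled mesh autoencoder at toy scale.
#
# Each of the R anatomic regions has its own encoder/decoder pair acting on
# that region's centered vertex block; the R per-region codes (width d)
# concatenate into one R*d latent whose subsets control one region each.
# The maps are linear with a diagonal-Gaussian posterior whose mean is used
# at inference, so encoding is deterministic. Training minimizes
#   reconstruction + beta * (code ridge from the unit-Gaussian prior
#   divergence) per region by exact alternating least squares: every epoch
# performs one exact code update and one exact decoder update, so the loss
# is non-increasing by construction. The swap-consistency penalty of the
# swap-disentanglement idea is evaluated on mesh hybrids each epoch; with
# per-region maps it is near zero by construction and is monitored, not
# optimized.

#' Latent layout descriptor
#'
#' @param R number of regions; @param d per-region latent width.
#' @return object of class `latent_layout` with total width `R * d`.
#' @export
latent_layout <- function(R = 15, d = 5) {
  R <- as.integer(R); d <- as.integer(d)
  structure(list(R = R, d = d, width = R * d), class = "latent_layout")
}

#' Indices of region r's latent subset
#'
#' The R*d latent is tiled by R disjoint d-wide subsets in region-id order.
#'
#' @param layout a `latent_layout`.
#' @param r region id.
#' @return integer indices (1-based) of subset `z_r`.
#' @export
latent_subset <- function(layout, r) {
  if (r < 1 || r > layout$R) .stopf("unknown region id %d", r)
  ((r - 1) * layout$d + 1):(r * layout$d)
}

#' Autoencoder configuration
#'
#' @param R regions (default 15); @param d per-region width (default 5):
#'   the default latent is 75-dimensional, split into 5-wide regional
#'   subsets.
#' @param beta weight of the unit-Gaussian prior divergence (default 1e-3).
#' @param gamma weight attached to the swap-consistency penalty in the
#'   logged total loss (default 1).
#' @param epochs alternating-least-squares iterations (default 50).
#' @param n_swap_monitor mesh-hybrid pairs used to evaluate the swap
#'   penalty each epoch.
#' @param seed integer seed for parameter initialization.
#' @return object of class `sdvae_config`.
#' @export
sdvae_config <- function(R = 15, d = 5, beta = 1e-3, gamma = 1,
                         epochs = 50, n_swap_monitor = 4, seed = 1) {
  if (any(c(beta, gamma) < 0)) .stopf("loss weights must be >= 0")
  if (epochs < 1) .stopf("epochs must be >= 1")
  R <- as.integer(R); d <- as.integer(d)
  structure(list(R = R, d = d, beta = beta, gamma = gamma, epochs = epochs,
                 n_swap_monitor = n_swap_monitor, seed = seed),
            class = "sdvae_config")
}

## Column indices of region r's (x, y, z) block in the flattened 3N layout.
.region_cols <- function(template, r) {
  vr <- region_vertices(template$partition, r)     # 0-based
  as.vector(rbind(3 * vr + 1, 3 * vr + 2, 3 * vr + 3))
}

## Flatten meshes to an n x 3N matrix (vertex-major: x1 y1 z1 x2 ...).
.flatten_meshes <- function(meshes) {
  do.call(rbind, lapply(meshes, function(m) as.vector(t(m$vertices))))
}

#' Swap one region's surface between two corresponded meshes
#'
#' Returns a hybrid with region `r` taken from B and everything else from A,
#' blended smoothly over a 2-ring boundary zone. Vertices beyond the 2-ring
#' are bit-identical to A.
#'
#' @param meshA,meshB `corresponded_mesh` objects on the template.
#' @param r region id.
#' @param template the shared `shape_template`.
#' @return the hybrid `corresponded_mesh`.
#' @export
region_swap <- function(meshA, meshB, r, template) {
  check_correspondence(meshA, template)
  check_correspondence(meshB, template)
  if (length(r) != 1L || r < 1 || r > n_regions(template$partition))
    .stopf("unknown region id: %s", as.character(r))
  w <- blend_weights(template, r)
  V <- meshA$vertices + w * (meshB$vertices - meshA$vertices)
  corresponded_mesh(V, meshA$faces, template_id = meshA$template_id,
                    validate = FALSE)
}

#' Train the toy region-disentangled autoencoder
#'
#' @param meshes list of >= 2 `corresponded_mesh` training meshes.
#' @param template the shared `shape_template`.
#' @param config an `sdvae_config`; its `R` must match the template's
#'   partition.
#' @return object of class `sdvae_model` with per-region encoder/decoder
#'   matrices, per-vertex normalization statistics, and a per-epoch training
#'   log (`recon`, `kl`, `swap`, `total`).
#' @export
sdvae_train <- function(meshes, template, config = sdvae_config()) {
  if (length(meshes) < 2L) .stopf("need >= 2 training meshes")
  if (config$R != n_regions(template$partition))
    .stopf("config has R = %d but template has %d regions",
           config$R, n_regions(template$partition))
  for (m in meshes) check_correspondence(m, template)
  n <- length(meshes)
  X <- .flatten_meshes(meshes)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  R <- config$R; d <- config$d; beta <- config$beta
  cols <- lapply(seq_len(R), function(r) .region_cols(template, r))

  # fixed monitoring set for the swap-consistency penalty: hybrid meshes do
  # not depend on the parameters, so they are built once
  mon <- .with_seed(.child_seed(config$seed, 3), {
    np <- min(config$n_swap_monitor, n - 1L)
    lapply(seq_len(np), function(j) {
      ab <- sample(n, 2L); r <- sample(R, 1L)
      list(a = ab[1], b = ab[2], r = r)
    })
  })
  mon_X <- do.call(rbind, lapply(mon, function(p) {
    h <- region_swap(meshes[[p$a]], meshes[[p$b]], p$r, template)
    as.vector(t(h$vertices))
  }))
  mon_Xc <- sweep(mon_X, 2, mu)

  decoders <- .with_seed(.child_seed(config$seed, 5),
    lapply(seq_len(R), function(r)
      matrix(rnorm(length(cols[[r]]) * d, sd = 0.01), length(cols[[r]]), d)))
  encoders <- vector("list", R)
  log_rows <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    recon_sse <- 0; kl_sum <- 0
    for (r in seq_len(R)) {
      Xr <- Xc[, cols[[r]], drop = FALSE]
      D <- decoders[[r]]
      # exact code update under the ridge induced by the prior divergence
      G <- crossprod(D) + diag(0.5 * beta, d)
      E <- solve(G, t(D))                      # d x p_r encoder
      Z <- Xr %*% t(E)
      recon_sse <- recon_sse + sum((Xr - Z %*% t(D))^2)
      kl_sum <- kl_sum + 0.5 * sum(Z^2)
      # exact decoder update given the codes
      ZtZ <- crossprod(Z) + diag(1e-10, d)
      decoders[[r]] <- t(solve(ZtZ, crossprod(Z, Xr)))
      encoders[[r]] <- E
    }
    recon <- recon_sse / (n * ncol(Xc))          # per-coordinate MSE, mm^2
    kl <- kl_sum / n
    # swap-consistency: hybrid latents vs the composite of the parents'
    Efull <- .encoder_matrix(encoders, cols, ncol(Xc), R, d)
    z_mon <- mon_Xc %*% t(Efull)
    z_all <- Xc %*% t(Efull)
    z_exp <- t(vapply(seq_along(mon), function(j) {
      p <- mon[[j]]
      comp <- z_all[p$a, ]
      idx <- ((p$r - 1) * d + 1):(p$r * d)
      comp[idx] <- z_all[p$b, idx]
      comp
    }, numeric(R * d)))
    swap_pen <- mean((z_mon - z_exp)^2)
    total <- recon + beta * kl + config$gamma * swap_pen
    if (!is.finite(total))
      .stopf("training diverged at epoch %d (non-finite loss)", epoch)
    log_rows[[epoch]] <- data.frame(epoch = epoch, recon = recon, kl = kl,
                                    swap = swap_pen, total = total)
  }

  structure(list(encoders = encoders, decoders = decoders, mu = mu,
                 region_cols = cols, template_id = template$mesh$template_id,
                 faces = template$mesh$faces,
                 layout = latent_layout(R, d), config = config,
                 log = do.call(rbind, log_rows)),
            class = "sdvae_model")
}

## Assemble the block-sparse full encoder (R*d x 3N) from per-region maps.
.encoder_matrix <- function(encoders, cols, p_total, R, d) {
  Efull <- matrix(0, R * d, p_total)
  for (r in seq_len(R))
    Efull[((r - 1) * d + 1):(r * d), cols[[r]]] <- encoders[[r]]
  Efull
}

#' @export
print.sdvae_model <- function(x, ...) {
  cat(sprintf("sdvae_model: %d x %d latent on template '%s'; final loss %.4g after %d epochs\n",
              x$layout$R, x$layout$d, x$template_id,
              x$log$total[nrow(x$log)], nrow(x$log)))
  invisible(x)
}

#' Encode a mesh to its region-partitioned latent vector
#'
#' Posterior mean, no sampling: two calls on the same mesh agree exactly.
#'
#' @param model an `sdvae_model`.
#' @param mesh a `corresponded_mesh` on the model's template.
#' @return a `latent_vector` (values of length R*d plus layout).
#' @export
sdvae_encode <- function(model, mesh) {
  if (mesh$template_id != model$template_id ||
      3L * nrow(mesh$vertices) != length(model$mu))
    .stopf("mesh is not on the model's template")
  xc <- as.vector(t(mesh$vertices)) - model$mu
  d <- model$layout$d
  vals <- numeric(model$layout$width)
  for (r in seq_len(model$layout$R)) {
    vals[((r - 1) * d + 1):(r * d)] <-
      model$encoders[[r]] %*% xc[model$region_cols[[r]]]
  }
  if (!all(is.finite(vals))) .stopf("non-finite latent values")
  structure(list(values = vals, layout = model$layout),
            class = "latent_vector")
}

#' Decode a latent vector back to a mesh
#'
#' The regions tile the vertex set, so each region's decoder reconstructs
#' its own vertex block; the all-zeros latent decodes to the training mean
#' shape.
#'
#' @param model an `sdvae_model`.
#' @param latent a `latent_vector` (or bare numeric of matching width).
#' @return a `corresponded_mesh` on the model's template.
#' @export
sdvae_decode <- function(model, latent) {
  vals <- if (inherits(latent, "latent_vector")) latent$values else latent
  if (length(vals) != model$layout$width)
    .stopf("latent width %d does not match model layout %d",
           length(vals), model$layout$width)
  d <- model$layout$d
  x <- model$mu
  for (r in seq_len(model$layout$R)) {
    idx <- ((r - 1) * d + 1):(r * d)
    x[model$region_cols[[r]]] <- x[model$region_cols[[r]]] +
      model$decoders[[r]] %*% vals[idx]
  }
  corresponded_mesh(matrix(x, ncol = 3, byrow = TRUE), model$faces,
                    template_id = model$template_id, validate = FALSE)
}

#' Encode a list of subjects into a latent table
#'
#' @param model an `sdvae_model`.
#' @param subjects list of `synthetic_subject` (or bare meshes with labels
#'   `NA`).
#' @return data.frame: subject_id, class_label, stage, z_001..z_{R*d}.
#' @export
sdvae_encode_table <- function(model, subjects) {
  rows <- lapply(subjects, function(s) {
    mesh <- if (inherits(s, "corresponded_mesh")) s else s$mesh
    z <- sdvae_encode(model, mesh)$values
    data.frame(subject_id = if (is.list(s) && !is.null(s$subject_id)) s$subject_id else NA,
               class_label = if (is.list(s) && !is.null(s$class_label)) s$class_label else NA,
               stage = if (is.list(s) && !is.null(s$stage)) s$stage else "pre",
               t(z), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:3)] <- sprintf("z_%03d", seq_len(model$layout$width))
  rownames(out) <- NULL
  out
}

#' Save / load a trained model checkpoint
#'
#' Single-file archive with parameters, config, normalization statistics
#' and template id.
#' @param model an `sdvae_model`; @param path checkpoint path.
#' @export
sdvae_save <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname sdvae_save
#' @export
sdvae_load <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sdvae_model")) .stopf("not an sdvae_model checkpoint")
  m
}
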