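# Spectral mesh interpolation for data augmentation.
#
# New same-class meshes are synthesized by blending the Laplacian-eigenbasis
# coefficients of corresponded mesh pairs. The basis is the first k
# eigenpairs of the template's uniform (combinatorial) graph Laplacian
# L = D - A, whose null space is the constant vector on a connected mesh.

#' Truncated Laplacian eigenbasis of a template
#'
#' @param template a `shape_template`.
#' @param k number of eigenpairs, `1 <= k <= N`.
#' @return object of class `spectral_basis` with orthonormal `eigenvectors`
#'   (N x k) and nondecreasing nonnegative `eigenvalues` (length k).
#' @export
laplacian_basis <- function(template, k = 128) {
  mesh <- template$mesh
  N <- nrow(mesh$vertices)
  if (k < 1 || k > N) .stopf("k must be in 1..%d", N)
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no != 1L) .stopf("template mesh is disconnected")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  L <- diag(rowSums(A)) - A
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(e$values)                 # ascending: smooth modes first
  vecs <- e$vectors[, ord[seq_len(k)], drop = FALSE]
  vals <- pmax(e$values[ord[seq_len(k)]], 0)
  # fix signs for reproducibility: largest-|entry| component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(eigenvectors = vecs, eigenvalues = vals,
                 laplacian_kind = "uniform_graph",
                 template_id = mesh$template_id, n_vertices = N),
            class = "spectral_basis")
}

#' Interpolate two corresponded meshes in a spectral basis
#'
#' Each coordinate channel of both meshes is projected onto the basis; the
#' in-basis coefficients and the out-of-basis residual are blended linearly
#' with the same weight, then reconstructed. `lambda = 0` returns mesh A,
#' `lambda = 1` mesh B; with the full basis, `lambda = 0.5` is the
#' vertex-wise midpoint.
#'
#' @param meshA,meshB `corresponded_mesh` objects on the basis's template.
#' @param lambda blend weight in `[0, 1]`.
#' @param basis a `spectral_basis` from [laplacian_basis()].
#' @return the interpolated `corresponded_mesh`.
#' @export
spectral_interpolate <- function(meshA, meshB, lambda, basis) {
  stopifnot(inherits(basis, "spectral_basis"))
  if (lambda < 0 || lambda > 1) .stopf("lambda must be in [0, 1]")
  if (meshA$template_id != meshB$template_id ||
      nrow(meshA$vertices) != basis$n_vertices ||
      nrow(meshB$vertices) != basis$n_vertices)
    .stopf("meshes and basis are not on the same template")
  U <- basis$eigenvectors
  cA <- crossprod(U, meshA$vertices)     # k x 3 spectral coefficients
  cB <- crossprod(U, meshB$vertices)
  rA <- meshA$vertices - U %*% cA        # out-of-basis residual
  rB <- meshB$vertices - U %*% cB
  V <- U %*% ((1 - lambda) * cA + lambda * cB) + (1 - lambda) * rA + lambda * rB
  corresponded_mesh(V, meshA$faces, template_id = meshA$template_id,
                    validate = FALSE)
}

## Band energy of a mesh's coordinates above basis column `from` (1-based):
## squared norm of the projection onto eigenvectors from..k.
.high_band_energy <- function(mesh, basis, from) {
  U <- basis$eigenvectors[, from:ncol(basis$eigenvectors), drop = FALSE]
  sum(crossprod(U, mesh$vertices)^2)
}

#' Augment a population by within-class spectral interpolation
#'
#' New subjects are synthesized from uniformly drawn same-class pairs with
#' `lambda ~ Uniform(lambda_range)`, inherit the class label, and are
#' flagged `augmented`. Pairing never mixes classes.
#'
#' @param subjects list of `synthetic_subject`.
#' @param n_target requested total per class (named vector, or a single
#'   number applied to every augmented class).
#' @param template the shared `shape_template`.
#' @param k basis size (default 128, capped at N).
#' @param lambda_range blend-weight interval (default `c(0.2, 0.8)`;
#'   mid-range weights avoid near-duplicates).
#' @param classes classes to augment; defaults to all non-healthy classes
#'   present (healthy augmentation is supported but off by default).
#' @param seed integer seed.
#' @return the input list plus the new augmented subjects.
#' @export
augment_population <- function(subjects, n_target, template, k = 128,
                               lambda_range = c(0.2, 0.8), classes = NULL,
                               seed = 1) {
  labs <- vapply(subjects, function(s) s$class_label, character(1))
  if (is.null(classes)) {
    classes <- if (!is.null(names(n_target))) names(n_target)
               else setdiff(unique(labs), "healthy")
  }
  if (length(n_target) == 1L && is.null(names(n_target)))
    n_target <- stats::setNames(rep(n_target, length(classes)), classes)
  basis <- laplacian_basis(template, min(k, nrow(template$mesh$vertices)))
  out <- subjects
  idx <- length(subjects)
  for (cl in classes) {
    members <- which(labs == cl)
    need <- n_target[[cl]] - length(members)
    if (need <= 0) next
    if (length(members) < 2L)
      .stopf("class %s has %d subject(s); need >= 2 to augment", cl, length(members))
    draws <- .with_seed(.child_seed(seed, 500 + match(cl, classes)), {
      pairs <- t(replicate(need, sample(members, 2L)))
      lam <- runif(need, lambda_range[1], lambda_range[2])
      list(pairs = pairs, lam = lam)
    })
    for (j in seq_len(need)) {
      a <- subjects[[draws$pairs[j, 1]]]; b <- subjects[[draws$pairs[j, 2]]]
      m <- spectral_interpolate(a$mesh, b$mesh, draws$lam[j], basis)
      idx <- idx + 1L
      out[[idx]] <- structure(
        list(subject_id = sprintf("%s_aug%03d", cl, j), class_label = cl,
             mesh = m, augmented = TRUE,
             truth = list(parents = c(a$subject_id, b$subject_id),
                          lambda = draws$lam[j])),
        class = "synthetic_subject")
    }
  }
  out
}
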