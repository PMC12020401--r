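# Synthetic head template: anisotropically scaled subdivided icosphere with
# a face-side (nasal) protrusion, partitioned into R contiguous anatomic
# regions by geodesic growing from fixed anchor directions.

.DEFAULT_REGION_NAMES <- c(
  "frontal", "supraorbital", "orbits", "nose", "central_midface",
  "nasolabial", "upper_lip", "lower_lip", "chin", "cheek_left",
  "cheek_right", "ear_left", "ear_right", "temporal", "cranium")

## Unit icosahedron (12 vertices, 20 faces, 0-based indices).
.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  list(vertices = v, faces = f)
}

## One 4-to-1 subdivision step with midpoints pushed back to the unit sphere.
.subdivide_sphere <- function(v, f) {
  n <- nrow(v)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e1 <- key(f[, 1], f[, 2]); e2 <- key(f[, 2], f[, 3]); e3 <- key(f[, 3], f[, 1])
  all_keys <- unique(c(e1, e2, e3))
  mid_id <- stats::setNames(seq_along(all_keys) + n - 1L, all_keys)
  ab <- do.call(rbind, strsplit(all_keys, " "))
  ia <- as.integer(ab[, 1]) + 1L; ib <- as.integer(ab[, 2]) + 1L
  mids <- (v[ia, , drop = FALSE] + v[ib, , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  m1 <- mid_id[e1]; m2 <- mid_id[e2]; m3 <- mid_id[e3]
  nf <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
              cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  list(vertices = rbind(v, mids), faces = unname(nf))
}

## Unit icosphere after n subdivision steps: 10*4^n + 2 vertices, 20*4^n faces.
.icosphere <- function(n_subdivisions) {
  s <- .icosahedron()
  for (i in seq_len(n_subdivisions)) s <- .subdivide_sphere(s$vertices, s$faces)
  s
}

## 15 fixed anchor directions, biased toward the face (+y hemisphere) so the
## facial subunits are smaller than the cranial ones. Deterministic.
.anchor_directions <- function(R) {
  i <- seq_len(R)
  golden <- pi * (3 - sqrt(5))
  # Fibonacci lattice on the sphere, rotated so the densest arc faces +y
  z <- 1 - 2 * (i - 0.5) / R
  rad <- sqrt(pmax(0, 1 - z^2))
  th <- golden * i
  dirs <- cbind(rad * cos(th), rad * sin(th), z)
  dirs[order(-dirs[, 2]), , drop = FALSE]
}

#' Build the synthetic head template
#'
#' A closed head-like surface: a subdivided icosphere scaled anisotropically
#' to head proportions (mm) with a smooth face-side protrusion emulating the
#' nose/midface, partitioned into `R` contiguous anatomic regions by
#' geodesic growing from fixed anchor directions. Deterministic given
#' `seed` (the seed only perturbs anchor tie-breaking jitter).
#'
#' @param n_subdivisions icosphere subdivision depth (>= 1). The default 4
#'   gives 2562 vertices; tests use 2-3 for speed.
#' @param seed integer seed.
#' @param R number of anatomic regions (default 15, matching the 75 = 15 x 5
#'   latent layout used downstream).
#' @param region_names optional character vector of length `R`.
#' @return a `shape_template`.
#' @export
make_template <- function(n_subdivisions = 4, seed = 1, R = 15,
                          region_names = NULL) {
  if (n_subdivisions < 1) .stopf("n_subdivisions must be >= 1")
  if (is.null(region_names)) {
    region_names <- if (R == 15) .DEFAULT_REGION_NAMES
                    else sprintf("region_%02d", seq_len(R))
  }
  if (length(region_names) != R) .stopf("need %d region names", R)
  s <- .icosphere(n_subdivisions)
  u <- s$vertices                       # unit directions, kept for fields
  # head proportions: half-axes in mm (x right, y forward/face, z up)
  v <- cbind(u[, 1] * 75, u[, 2] * 95, u[, 3] * 88)
  # smooth nasal protrusion around the +y pole
  face_dir <- c(0, 1, 0)
  ang <- acos(pmin(1, pmax(-1, u %*% face_dir)))
  bump <- 18 * exp(-(ang / 0.45)^2)
  v <- v + u * as.vector(bump)
  mesh <- corresponded_mesh(v, s$faces,
                            template_id = sprintf("synthhead-s%d-r%d", n_subdivisions, R))
  labels <- .grow_regions(mesh, u, R, seed)
  shape_template(mesh, region_partition(labels, region_names))
}

## Geodesic Voronoi labelling from anchor vertices, with a cleanup pass that
## re-attaches any stray components so every region is contiguous in the
## vertex-adjacency graph.
.grow_regions <- function(mesh, unit_dirs, R, seed) {
  dirs <- .anchor_directions(R)
  jit <- .with_seed(.child_seed(seed, 1), matrix(rnorm(R * 3, sd = 1e-3), R))
  dirs <- dirs + jit
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # anchor vertex: template vertex whose direction is closest to each anchor
  anchors <- apply(dirs %*% t(unit_dirs), 1, which.max)
  g <- mesh_graph(mesh)
  ends_of <- igraph::ends(g, igraph::E(g))
  elen <- sqrt(rowSums((mesh$vertices[ends_of[, 1], ] - mesh$vertices[ends_of[, 2], ])^2))
  D <- igraph::distances(g, v = anchors, weights = elen)
  labels <- apply(D, 2, which.min)
  labels[anchors] <- seq_len(R)         # anchors keep their own region
  .reattach_strays(g, labels, anchors)
}

.reattach_strays <- function(g, labels, anchors) {
  adj <- igraph::as_adj_list(g)
  for (pass in 1:10) {
    changed <- FALSE
    for (r in seq_along(anchors)) {
      members <- which(labels == r)
      sub <- igraph::induced_subgraph(g, members)
      comp <- igraph::components(sub)
      if (comp$no <= 1L) next
      keep <- comp$membership[match(anchors[r], members)]
      if (is.na(keep)) keep <- which.max(comp$csize)
      stray <- members[comp$membership != keep]
      for (v in stray) {
        nb_lab <- labels[as.integer(adj[[v]])]
        nb_lab <- nb_lab[nb_lab != r]
        if (length(nb_lab)) {
          labels[v] <- sort(nb_lab)[ceiling(length(nb_lab) / 2)]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  labels
}

# ---- smooth displacement fields -------------------------------------------
# Low-order polynomial harmonics on the template's unit directions: a 16-
# function basis (monomials of degree <= 3 in the direction components),
# columns standardized to unit RMS. Spatially smooth by construction.

.field_basis <- function(template) {
  v <- template$mesh$vertices
  u <- v / sqrt(rowSums(v^2))
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  B <- cbind(1, x, y, z, x * y, x * z, y * z, x^2, y^2, z^2,
             x^3, y^3, z^3, x^2 * y, y^2 * z, z^2 * x)
  sweep(B, 2, sqrt(colMeans(B^2)), "/")
}

## field = B %*% coef (coef: 16 x 3), one smooth 3D displacement per vertex.
.smooth_field <- function(template, coef) .field_basis(template) %*% coef

## Random smooth field with mean per-vertex displacement norm = scale_mm.
## Individual-variation fields use only the degree <= 1 sub-basis (12 dof):
## within-class variation must remain estimable from cohorts of a few tens
## of subjects, so its intrinsic dimension is kept below the smallest
## class size the package is exercised at.
.random_smooth_field <- function(template, scale_mm) {
  coef <- rbind(matrix(rnorm(4 * 3), 4, 3), matrix(0, 12, 3))
  f <- .smooth_field(template, coef)
  rms <- sqrt(mean(rowSums(f^2)))
  if (rms < 1e-12) return(f * 0)
  f * (scale_mm / rms)
}

#' Smooth region blending weights
#'
#' Weight 1 on the given region set, decaying geometrically over `rings`
#' graph rings outside it (2-ring falloff by default), 0 beyond. Used to
#' confine class signatures and surgical moves to their regions without
#' tearing artifacts at region borders.
#'
#' @param template a `shape_template`.
#' @param regions region ids (1-based).
#' @param rings falloff width in graph rings (default 2).
#' @param decay per-ring weight multiplier (default 1/5; keeps >= 90% of a
#'   masked field's squared norm inside its regions even on coarse meshes).
#' @return numeric vector of length N in `[0, 1]`.
#' @export
blend_weights <- function(template, regions, rings = 2, decay = 1 / 5) {
  labels <- template$partition$labels
  inside <- which(labels %in% regions)
  if (!length(inside)) .stopf("empty target region set")
  g <- mesh_graph(template$mesh)
  hop <- igraph::distances(g, v = inside, weights = NA)
  dmin <- apply(hop, 2, min)
  w <- ifelse(dmin <= rings, decay^dmin, 0)
  as.numeric(w)
}
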