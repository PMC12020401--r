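# Corresponded triangle meshes, anatomic region partitions, and the
# template that ties them together.
#
# Every mesh handled by this package is assumed to be in dense point
# correspondence with a template: vertex i has the same anatomical meaning
# in every mesh, and the face list is shared verbatim. Correspondence is
# established upstream (nonrigid registration is deliberately out of scope);
# here it is only *validated*, topologically.

#' Construct a corresponded triangle mesh
#'
#' A `corresponded_mesh` is an N x 3 vertex matrix (coordinates in mm) plus
#' an M x 3 face matrix of 0-based vertex indices, tagged with the id of the
#' correspondence template it lives on.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 0-based vertex index triples.
#' @param template_id character identifier of the correspondence template.
#' @param validate run full invariant checks (finite coordinates, every
#'   vertex used, connected surface). Disable only in tight inner loops on
#'   meshes already known valid.
#' @return an object of class `corresponded_mesh`.
#' @export
corresponded_mesh <- function(vertices, faces, template_id = "template",
                              validate = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) .stopf("vertices must be N x 3, got %d columns", ncol(vertices))
  mesh <- structure(list(vertices = vertices, faces = faces,
                         template_id = template_id),
                    class = "corresponded_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.corresponded_mesh <- function(x, ...) {
  cat(sprintf("corresponded_mesh: %d vertices, %d faces, template '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$template_id))
  invisible(x)
}

#' Validate mesh invariants
#'
#' Checks finiteness of coordinates, face index range, that every vertex is
#' referenced by at least one face, and that the face edge graph is connected.
#'
#' @param mesh a `corresponded_mesh`.
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) .stopf("mesh has non-finite vertex coordinates")
  if (nrow(f) < 1L) .stopf("mesh has no faces")
  if (min(f) < 0L || max(f) >= nrow(v))
    .stopf("face indices out of range [0, %d]", nrow(v) - 1L)
  used <- sort(unique(as.vector(f)))
  if (length(used) != nrow(v))
    .stopf("%d vertices are not referenced by any face", nrow(v) - length(used))
  g <- mesh_graph(mesh)
  if (igraph::components(g)$no != 1L)
    .stopf("mesh surface is not connected")
  invisible(mesh)
}

## Undirected edge graph of the triangulation (0-based vertex i -> node i+1).
mesh_graph <- function(mesh) {
  f <- mesh$faces + 1L
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Check that a mesh matches a template's topology
#'
#' Correspondence contract: identical vertex count and identical face list.
#' A mismatch signals broken correspondence and is always an error.
#'
#' @param mesh a `corresponded_mesh`.
#' @param template a `shape_template` (see [shape_template()]).
#' @return the mesh, invisibly.
#' @export
check_correspondence <- function(mesh, template) {
  tm <- template$mesh
  if (nrow(mesh$vertices) != nrow(tm$vertices))
    .stopf("correspondence broken: mesh has %d vertices, template %d",
           nrow(mesh$vertices), nrow(tm$vertices))
  if (nrow(mesh$faces) != nrow(tm$faces) || !all(mesh$faces == tm$faces))
    .stopf("correspondence broken: face list differs from template")
  invisible(mesh)
}

#' Construct an anatomic region partition
#'
#' Assigns every template vertex to exactly one of R named anatomic
#' subunits (orbits, nose, upper lip, ...). Region ids are 1-based.
#'
#' @param labels integer vector, one region id in `1..R` per vertex.
#' @param region_names character vector of R region names.
#' @return an object of class `region_partition`.
#' @export
region_partition <- function(labels, region_names) {
  labels <- as.integer(labels)
  R <- length(region_names)
  if (R < 2L) .stopf("a partition needs at least 2 regions")
  if (any(labels < 1L | labels > R)) .stopf("region labels outside 1..%d", R)
  counts <- tabulate(labels, nbins = R)
  if (any(counts == 0L))
    .stopf("empty region(s): %s", paste(which(counts == 0L), collapse = ", "))
  structure(list(labels = labels, region_names = as.character(region_names)),
            class = "region_partition")
}

#' Number of regions in a partition
#' @param partition a `region_partition`.
#' @export
n_regions <- function(partition) length(partition$region_names)

#' Vertex indices of one region
#'
#' @param partition a `region_partition`.
#' @param r region id in `1..R`.
#' @return 0-based vertex indices carrying label `r`.
#' @export
region_vertices <- function(partition, r) {
  if (length(r) != 1L || is.na(r) || r < 1 || r > n_regions(partition))
    .stopf("unknown region id: %s", as.character(r))
  which(partition$labels == as.integer(r)) - 1L
}

#' Bundle a mesh and its partition into a template
#'
#' @param mesh the template `corresponded_mesh`.
#' @param partition a `region_partition` over the template's vertices.
#' @return an object of class `shape_template`.
#' @export
shape_template <- function(mesh, partition) {
  if (length(partition$labels) != nrow(mesh$vertices))
    .stopf("partition length %d != vertex count %d",
           length(partition$labels), nrow(mesh$vertices))
  structure(list(mesh = mesh, partition = partition), class = "shape_template")
}

#' @export
print.shape_template <- function(x, ...) {
  cat(sprintf("shape_template '%s': %d vertices, %d faces, %d regions\n",
              x$mesh$template_id, nrow(x$mesh$vertices), nrow(x$mesh$faces),
              n_regions(x$partition)))
  invisible(x)
}

#' Per-vertex displacement magnitudes between two corresponded meshes
#'
#' Entry i is the Euclidean distance (mm) moved by vertex i, the quantity
#' rendered as a postoperative change heatmap.
#'
#' @param pre,post `corresponded_mesh` objects on the same template.
#' @return numeric vector of length N, all entries >= 0.
#' @export
vertex_displacements <- function(pre, post) {
  if (pre$template_id != post$template_id ||
      nrow(pre$vertices) != nrow(post$vertices))
    .stopf("meshes are not on the same template")
  sqrt(rowSums((post$vertices - pre$vertices)^2))
}

# ---- file formats ----------------------------------------------------------
# ASCII PLY: element vertex with x y z properties; element face with a
# vertex_indices list. Wavefront OBJ: v/f records, 1-based indices converted
# on load. Both are minimal, portable dialects; no normals, colors or UVs.

#' Write a corresponded mesh to PLY or OBJ
#'
#' Coordinates are written with enough digits for a lossless round trip at
#' 1e-6 mm. Meshes violating their invariants (non-finite coordinates) are
#' refused.
#'
#' @param mesh a `corresponded_mesh`.
#' @param path output file path.
#' @param format `"ply"` (ASCII) or `"obj"`; default inferred from the
#'   file extension.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj")) .stopf("unknown mesh format '%s'", ext)
    format <- ext
  }
  if (!all(is.finite(mesh$vertices)))
    .stopf("refusing to write mesh with non-finite coordinates")
  v <- mesh$vertices; f <- mesh$faces
  vs <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  if (format == "ply") {
    lines <- c(
      "ply", "format ascii 1.0",
      sprintf("comment template %s", mesh$template_id),
      sprintf("element vertex %d", nrow(v)),
      "property double x", "property double y", "property double z",
      sprintf("element face %d", nrow(f)),
      "property list uchar int vertex_indices",
      "end_header",
      vs,
      sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]))
  } else {
    lines <- c(sprintf("# template %s", mesh$template_id),
               paste("v", vs),
               sprintf("f %d %d %d", f[, 1] + 1L, f[, 2] + 1L, f[, 3] + 1L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a corresponded mesh from PLY or OBJ
#'
#' The loaded mesh is validated against the template's topology: vertex
#' count and face list must match exactly (broken correspondence is an
#' error, not a warning).
#'
#' @param path file path (ASCII PLY or OBJ).
#' @param template a `shape_template` to validate against, or `NULL` to
#'   skip correspondence checking.
#' @return a `corresponded_mesh`.
#' @export
read_mesh <- function(path, template = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
                 ply = .read_ply(path),
                 obj = .read_obj(path),
                 .stopf("unknown mesh format '%s'", ext))
  if (!is.null(template)) {
    mesh$template_id <- template$mesh$template_id
    check_correspondence(mesh, template)
  }
  validate_mesh(mesh)
  mesh
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    .stopf("not an ASCII PLY file: %s", path)
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) .stopf("PLY header without end_header: %s", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format ascii", hdr))) .stopf("only ASCII PLY is supported")
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr, value = TRUE)[1]))
  tid <- sub("^comment template ", "", grep("^comment template ", hdr, value = TRUE)[1])
  if (is.na(nv) || is.na(nf)) .stopf("PLY header missing vertex/face counts")
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) .stopf("truncated PLY body")
  vtxt <- scan(text = body[seq_len(nv)], quiet = TRUE)
  v <- matrix(vtxt, ncol = 3, byrow = TRUE)
  ftxt <- scan(text = body[nv + seq_len(nf)], quiet = TRUE)
  fm <- matrix(ftxt, ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3)) .stopf("only triangle faces are supported")
  corresponded_mesh(v, fm[, 2:4],
                    template_id = if (length(tid) && !is.na(tid)) tid else "template")
}

.read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  tid <- sub("^# template ", "", grep("^# template ", lines, value = TRUE)[1])
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  if (!length(vlines) || !length(flines)) .stopf("no v/f records in OBJ: %s", path)
  v <- matrix(scan(text = sub("^v ", "", vlines), quiet = TRUE),
              ncol = 3, byrow = TRUE)
  # strip any texture/normal slashes (f a/b/c style) down to the vertex index
  ftok <- sub("/.*$", "", unlist(strsplit(sub("^f ", "", flines), "\\s+")))
  fm <- matrix(as.integer(ftok), ncol = 3, byrow = TRUE) - 1L
  corresponded_mesh(v, fm,
                    template_id = if (length(tid) && !is.na(tid)) tid else "template")
}

#' Write a region partition as a sidecar CSV
#'
#' Columns `vertex_index` (0-based), `region_id` (1-based), `region_name`.
#' Kept separate from the mesh file for PLY/OBJ dialect portability.
#'
#' @param partition a `region_partition`.
#' @param path output CSV path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(vertex_index = seq_along(partition$labels) - 1L,
                   region_id = partition$labels,
                   region_name = partition$region_names[partition$labels])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a region partition from its sidecar CSV
#' @param path CSV with columns vertex_index, region_id, region_name.
#' @return a `region_partition`.
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("vertex_index", "region_id", "region_name")
  if (!all(req %in% names(df))) .stopf("partition CSV needs columns %s",
                                       paste(req, collapse = ", "))
  df <- df[order(df$vertex_index), ]
  R <- max(df$region_id)
  nm <- character(R)
  nm[df$region_id] <- df$region_name
  region_partition(df$region_id, nm)
}
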