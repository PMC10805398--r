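#' Triangle mesh container
#'
#' A minimal triangle-mesh class used throughout the package: vertex
#' coordinates in millimetres and counter-clockwise oriented faces. Closed
#' (watertight) genus-zero meshes are the working assumption of the
#' parameterization stage; [validate_mesh()] checks and, where possible,
#' repairs a mesh towards that contract.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices,
#'   counter-clockwise when seen from outside.
#' @param validate if `TRUE`, run [validate_mesh()] on the result.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices` and `faces`.
#' @examples
#' m <- triangle_mesh(
#'   vertices = rbind(c(0, 0, 1), c(1, 0, -1), c(-1, 1, -1), c(-1, -1, -1)),
#'   faces = rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
#' )
#' euler_characteristic(m)
#' @export
triangle_mesh <- function(vertices, faces, validate = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop_subshape("mesh_invalid", "vertices must be N x 3")
  if (ncol(faces) != 3L) stop_subshape("mesh_invalid", "faces must be M x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_subshape("mesh_invalid", "face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  if (validate) m <- validate_mesh(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  chi <- tryCatch(euler_characteristic(x), error = function(e) NA_integer_)
  if (!is.na(chi)) cat(sprintf(", Euler characteristic %d", chi))
  cat("\n")
  invisible(x)
}

# Undirected edge table: one row per undirected edge, columns (lo, hi).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

#' Euler characteristic of a mesh
#'
#' `V - E + F`; equals 2 for a closed genus-zero surface.
#' @param mesh a [triangle_mesh()].
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Total surface area of a mesh
#' @param mesh a [triangle_mesh()].
#' @return total triangle area (mm^2).
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  0.5 * row_norms(vcross(a, b))
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  normalize_rows(vcross(a, b))
}

# Signed volume via the divergence theorem; positive for outward orientation.
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p3[, 2] * p2[, 3]) -
      p2[, 1] * (p1[, 2] * p3[, 3] - p3[, 2] * p1[, 3]) +
      p3[, 1] * (p1[, 2] * p2[, 3] - p2[, 2] * p1[, 3])) / 6
}

#' Validate (and repair) a triangle mesh
#'
#' Checks the closed genus-zero contract the downstream stages rely on:
#' every edge shared by exactly two faces, consistent counter-clockwise
#' (outward) orientation, Euler characteristic 2, and no zero-area faces.
#' Two repairs are attempted before failing: duplicate vertices are merged
#' (coordinates equal within `tol` mm) and face orientation is made globally
#' consistent by propagation, flipped outward if the signed volume is
#' negative.
#'
#' @param mesh a [triangle_mesh()].
#' @param tol vertex-merge tolerance in mm.
#' @return the repaired `triangle_mesh`.
#' @export
validate_mesh <- function(mesh, tol = 1e-9) {
  mesh <- merge_duplicate_vertices(mesh, tol)
  f <- mesh$faces
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop_subshape("mesh_degenerate", "mesh has degenerate faces (repeated vertex index)")

  # edge-manifold / watertight: every undirected edge on exactly 2 faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L)) {
    bad <- sum(cnt != 2L)
    stop_subshape("mesh_not_watertight",
      sprintf("mesh is not watertight/manifold: %d edge(s) not shared by exactly 2 faces", bad))
  }

  mesh$faces <- orient_faces(mesh)
  if (mesh_signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]

  chi <- euler_characteristic(mesh)
  if (chi != 2L)
    stop_subshape("mesh_not_genus0",
      sprintf("mesh is not genus 0: Euler characteristic V-E+F = %d != 2", chi))
  if (any(face_areas(mesh) <= 0))
    stop_subshape("mesh_degenerate", "mesh has zero-area faces")
  mesh
}

merge_duplicate_vertices <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  idx <- match(key, key)           # first occurrence of each coordinate
  if (all(idx == seq_len(nrow(v)))) return(mesh)
  keep <- sort(unique(idx))
  remap <- integer(nrow(v))
  remap[keep] <- seq_along(keep)
  f <- matrix(remap[idx[mesh$faces]], ncol = 3L)
  # drop faces that became degenerate by the merge
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  triangle_mesh(v[keep, , drop = FALSE], f[ok, , drop = FALSE])
}

# Make face windings globally consistent by breadth-first propagation across
# shared edges. Assumes edge-manifold input.
orient_faces <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  # directed-edge -> face lookup over undirected keys
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nf), times = 3L)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ord <- order(key)
  key_s <- key[ord]; fid_s <- fid[ord]
  # pairs of faces sharing each edge
  first <- !duplicated(key_s)
  fa <- fid_s[first]
  fb <- fid_s[!first]
  adj <- vector("list", nf)
  for (i in seq_along(fa)) {
    adj[[fa[i]]] <- c(adj[[fa[i]]], fb[i])
    adj[[fb[i]]] <- c(adj[[fb[i]]], fa[i])
  }
  visited <- rep(FALSE, nf)
  out <- f
  queue <- 1L
  visited[1L] <- TRUE
  dir_key <- function(face) paste(face, face[c(2, 3, 1)])
  while (length(queue)) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    cur_dir <- dir_key(out[cur, ])
    for (nb in adj[[cur]]) {
      if (visited[nb]) next
      # consistent orientation: shared edge traversed in opposite directions
      nb_face <- out[nb, ]
      nb_dir <- dir_key(nb_face)
      nb_rev <- paste(nb_face[c(2, 3, 1)], nb_face)
      if (any(nb_dir %in% cur_dir)) out[nb, ] <- nb_face[c(1, 3, 2)]
      else if (!any(nb_rev %in% cur_dir)) next  # not actually edge-adjacent
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  if (!all(visited))
    stop_subshape("mesh_disconnected", "mesh has more than one connected component")
  out
}

# Per-vertex outward normals (area-weighted average of face normals).
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], mesh$faces[, j])
      n[as.integer(rownames(acc)), k] <- n[as.integer(rownames(acc)), k] + acc
    }
  }
  normalize_rows(n)
}
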