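#' Discrete mean curvature of a closed mesh
#'
#' Cotangent-Laplacian mean-curvature normal over mixed Voronoi areas
#' (Meyer's discretization). The sign convention is taken against the
#' outward vertex normal, so a sphere of radius r with outward orientation
#' gets `H = 1/r` everywhere. Vertices whose incident triangles are nearly
#' degenerate (minimum angle below `degenerate_angle` degrees) are flagged
#' and receive the average of their one-ring neighbours instead.
#'
#' @param mesh a closed, consistently oriented [triangle_mesh()].
#' @param degenerate_angle minimum triangle angle (degrees) below which a
#'   vertex value is replaced by its one-ring average.
#' @return numeric vector of per-vertex mean curvature (1/mm), with a
#'   logical attribute `"flagged"` marking the replaced vertices.
#' @export
mean_curvature <- function(mesh, degenerate_angle = 0.5) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)

  # per-corner cotangents and angles
  corner <- function(i, j, k) {
    a <- v[f[, j], , drop = FALSE] - v[f[, i], , drop = FALSE]
    b <- v[f[, k], , drop = FALSE] - v[f[, i], , drop = FALSE]
    dotab <- rowSums(a * b)
    crossn <- row_norms(vcross(a, b))
    list(cot = dotab / pmax(crossn, 1e-300), angle = atan2(crossn, dotab))
  }
  c1 <- corner(1, 2, 3)
  c2 <- corner(2, 3, 1)
  c3 <- corner(3, 1, 2)

  # mixed Voronoi area per vertex (Meyer et al.)
  area_f <- face_areas(mesh)
  amix <- numeric(nv)
  ang <- cbind(c1$angle, c2$angle, c3$angle)
  cot <- cbind(c1$cot, c2$cot, c3$cot)
  obtuse_face <- apply(ang > pi / 2, 1, any)
  for (j in 1:3) {
    jj <- c(2, 3, 1)[j]
    kk <- c(3, 1, 2)[j]
    # Voronoi area at corner j: (1/8)(|e_jk|^2 cot_k + |e_jjj|^2 cot_jj)
    ejk <- v[f[, kk], , drop = FALSE] - v[f[, j], , drop = FALSE]
    ejj <- v[f[, jj], , drop = FALSE] - v[f[, j], , drop = FALSE]
    avor <- (rowSums(ejk * ejk) * cot[, jj] + rowSums(ejj * ejj) * cot[, kk]) / 8
    acorner <- ifelse(!obtuse_face, avor,
                      ifelse(ang[, j] > pi / 2, area_f / 2, area_f / 4))
    s <- rowsum(acorner, f[, j])
    amix[as.integer(rownames(s))] <- amix[as.integer(rownames(s))] + s
  }

  # mean curvature normal: K_i = (1/(2 A_i)) sum_j (cot a + cot b)(v_i - v_j)
  K <- matrix(0, nv, 3L)
  add_edge <- function(i, j, w) {
    d <- v[f[, i], , drop = FALSE] - v[f[, j], , drop = FALSE]
    for (k in 1:3) {
      s <- rowsum(w * d[, k], f[, i])
      K[as.integer(rownames(s)), k] <<- K[as.integer(rownames(s)), k] + s
      s <- rowsum(w * (-d[, k]), f[, j])
      K[as.integer(rownames(s)), k] <<- K[as.integer(rownames(s)), k] + s
    }
  }
  # edge (1,2) is opposite corner 3, etc.; each face contributes one cot per edge
  add_edge(1, 2, c3$cot)
  add_edge(2, 3, c1$cot)
  add_edge(3, 1, c2$cot)
  K <- K / (2 * pmax(amix, 1e-300))

  n_out <- vertex_normals(mesh)
  H <- 0.5 * rowSums(K * n_out)

  # flag vertices touching nearly degenerate triangles
  min_ang <- rep(Inf, nv)
  fmin <- apply(ang, 1, min)
  for (j in 1:3) {
    sp <- split(fmin, f[, j])
    mn <- vapply(sp, min, 0)
    idx <- as.integer(names(mn))
    min_ang[idx] <- pmin(min_ang[idx], mn)
  }
  flagged <- min_ang < degenerate_angle * pi / 180
  if (any(flagged)) {
    e <- mesh_edges(mesh)
    nbr <- c(split(e[, 2], e[, 1]), split(e[, 1], e[, 2]))
    for (i in which(flagged)) {
      nb <- unique(c(unlist(nbr[names(nbr) == as.character(i)])))
      nb <- setdiff(nb, which(flagged))
      if (length(nb)) H[i] <- mean(H[nb])
    }
  }
  attr(H, "flagged") <- flagged
  H
}
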