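#' Conformal grid container
#'
#' Fixed-resolution parameter-domain grid carrying resampled 3D positions,
#' the conformal factor (local area-distortion density) and mean curvature.
#' The parameter domain is the rectangle `[0,1] x [0,2*pi)` with `u` running
#' along the structure's long axis and `v` periodic around it; grids are
#' sampled at `u_i = (i - 0.5)/nu` (midpoint rule in u) and
#' `v_j = 2*pi*(j-1)/nv`.
#'
#' @param positions numeric array `nu x nv x 3` of 3D positions (mm).
#' @param lambda numeric `nu x nv` matrix, conformal factor
#'   `sqrt(det g)` of the first fundamental form per unit parameter area;
#'   strictly positive.
#' @param H numeric `nu x nv` matrix of mean curvature (1/mm).
#' @param periodic_v logical; `TRUE` for tube topology.
#' @param metadata named list of provenance (cut choice, seam rule,
#'   lambda normalization).
#' @return an object of class `conformal_grid`.
#' @export
conformal_grid <- function(positions, lambda, H, periodic_v = TRUE,
                           metadata = list()) {
  dims <- dim(lambda)
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3] == 3L,
            all(dim(positions)[1:2] == dims), all(dim(H) == dims))
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop_subshape("grid_invalid", "conformal factor must be finite and > 0 everywhere")
  if (any(!is.finite(H)))
    stop_subshape("grid_invalid", "mean curvature must be finite")
  structure(list(dims = dims, positions = positions, lambda = lambda, H = H,
                 periodic_v = isTRUE(periodic_v), metadata = metadata),
            class = "conformal_grid")
}

#' @export
print.conformal_grid <- function(x, ...) {
  cat(sprintf("conformal_grid: %d x %d nodes (%d total), periodic_v = %s\n",
              x$dims[1], x$dims[2], prod(x$dims), x$periodic_v))
  cat(sprintf("  lambda in [%.4g, %.4g], H in [%.4g, %.4g] mm^-1\n",
              min(x$lambda), max(x$lambda), min(x$H), max(x$H)))
  invisible(x)
}

# parameter-grid sample coordinates
grid_u <- function(nu) (seq_len(nu) - 0.5) / nu
grid_v <- function(nv) 2 * pi * (seq_len(nv) - 1) / nv

#' Surface area implied by a conformal grid
#'
#' `sum(lambda) * du * dv`; reproduces the mesh surface area to within the
#' resampling error.
#' @param grid a [conformal_grid()].
#' @return area (mm^2).
#' @export
grid_area <- function(grid) {
  du <- 1 / grid$dims[1]
  dv <- 2 * pi / grid$dims[2]
  sum(grid$lambda) * du * dv
}

# cotangent weight sparse Laplacian (positive semi-definite, L = D - W)
cot_laplacian <- function(v, f, clamp = FALSE) {
  cot_at <- function(i, j, k) {
    a <- v[f[, j], , drop = FALSE] - v[f[, i], , drop = FALSE]
    b <- v[f[, k], , drop = FALSE] - v[f[, i], , drop = FALSE]
    rowSums(a * b) / pmax(row_norms(vcross(a, b)), 1e-300)
  }
  # edge (j,k) opposite corner i contributes cot_i / 2
  ii <- c(f[, 2], f[, 3], f[, 1])
  jj <- c(f[, 3], f[, 1], f[, 2])
  ww <- 0.5 * c(cot_at(1, 2, 3), cot_at(2, 3, 1), cot_at(3, 1, 2))
  if (clamp) ww <- pmax(ww, 1e-8)
  n <- nrow(v)
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

# solve L x = 0 with Dirichlet values at `fixed` (named vector index -> value)
solve_harmonic <- function(L, fixed_idx, fixed_val) {
  n <- nrow(L)
  free <- setdiff(seq_len(n), fixed_idx)
  rhs <- -L[free, fixed_idx, drop = FALSE] %*% fixed_val
  x <- numeric(n)
  x[fixed_idx] <- fixed_val
  x[free] <- as.numeric(Matrix::solve(L[free, free], rhs))
  x
}

#' Conformal tube parameterization of a genus-zero mesh
#'
#' Maps a closed genus-zero, tube-like mesh onto the fixed parameter grid.
#' The surface is cut at the two extremal vertices along its first principal
#' axis (their vertex stars are removed, leaving an open tube with two
#' boundary loops); `u` is the discrete harmonic function with boundary
#' values 0 and 1 on the two loops; `v` is the conjugate-style periodic
#' coordinate obtained by cutting the tube along the shortest geodesic
#' between the loops and solving a second harmonic problem with a `2*pi`
#' jump across the seam. Positions are resampled at the regular grid by
#' barycentric interpolation in the parameter plane; the conformal factor is
#' the area element `sqrt(det g)` of the resampled immersion and mean
#' curvature is interpolated from [mean_curvature()] of the input mesh.
#'
#' @param mesh a closed genus-zero [triangle_mesh()].
#' @param dims grid dimensions `c(nu, nv)`; the default `c(100, 150)` gives
#'   the standard 15,000-vertex grid.
#' @param periodic_v must be `TRUE` (tube topology is the only supported
#'   domain).
#' @return a [conformal_grid()].
#' @export
conformal_parameterize <- function(mesh, dims = c(100L, 150L), periodic_v = TRUE) {
  if (!periodic_v) stop_subshape("bad_argument", "only periodic_v = TRUE is supported")
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 4L))
    stop_subshape("bad_argument", "dims must be two integers >= 4")
  mesh <- validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  H_closed <- mean_curvature(mesh)

  # cut points: extremal vertices along the first principal axis
  ctr <- colMeans(v)
  pc <- eigen(stats::cov(v), symmetric = TRUE)$vectors[, 1]
  if (pc[which.max(abs(pc))] < 0) pc <- -pc   # deterministic sign
  proj <- as.numeric((v - rep(ctr, each = nrow(v))) %*% pc)
  # extremal vertex; near-ties resolved toward the principal axis, then by index
  axial_pick <- function(cand) {
    d2 <- rowSums(((v[cand, , drop = FALSE] - rep(ctr, each = length(cand))) -
                     outer(proj[cand], pc))^2)
    cand[which.min(d2)[1]]
  }
  tol <- 1e-7 * diff(range(proj))
  p0 <- axial_pick(which(proj <= min(proj) + tol))
  p1 <- axial_pick(which(proj >= max(proj) - tol))

  # remove the two pole stars -> open tube
  keep_f <- !(rowSums(matrix(f %in% c(p0, p1), ncol = 3L)) > 0)
  fo <- f[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(fo)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  fo <- matrix(remap[fo], ncol = 3L)
  vo <- v[used, , drop = FALSE]
  Ho <- H_closed[used]

  # boundary loops of the open tube
  e <- rbind(fo[, c(1, 2)], fo[, c(2, 3)], fo[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)[key]
  bnd <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))[cnt == 1, , drop = FALSE])
  if (nrow(bnd) == 0L)
    stop_subshape("parameterization_failed", "cutting produced no boundary")
  gb <- igraph::graph_from_edgelist(bnd, directed = FALSE)
  comp <- igraph::components(gb)
  loop_ids <- which(comp$csize > 1)
  if (length(loop_ids) != 2L)
    stop_subshape("parameterization_failed",
      sprintf("principal-axis cut yields %d boundary component(s), expected 2 (non-tube-like input)",
              length(loop_ids)))
  memb <- comp$membership
  loop0 <- which(memb == loop_ids[1])
  loop1 <- which(memb == loop_ids[2])
  # loop0 = the loop around p0 (u = 0 end)
  if (mean(proj[used[loop0]]) > mean(proj[used[loop1]])) {
    tmp <- loop0; loop0 <- loop1; loop1 <- tmp
  }

  # harmonic u with Dirichlet 0/1 on the loops
  L <- cot_laplacian(vo, fo)
  u_coord <- solve_harmonic(L, c(loop0, loop1),
                            c(rep(0, length(loop0)), rep(1, length(loop1))))

  # seam: shortest geodesic between the loops
  eu <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  wts <- row_norms(vo[eu[, 1], , drop = FALSE] - vo[eu[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(eu, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = wts)
  s0 <- min(loop0)
  d_to_loop1 <- igraph::distances(g, v = s0, to = loop1)[1, ]
  s1 <- loop1[which.min(d_to_loop1)[1]]
  seam <- as.integer(igraph::shortest_paths(g, from = s0, to = s1)$vpath[[1]])

  cutres <- cut_mesh_along_path(vo, fo, seam)
  v_coord <- solve_seam_harmonic(vo, cutres, seam)

  res <- resample_param_grid(vo, fo, cutres, u_coord, v_coord, Ho, dims)
  lambda <- grid_lambda(res$positions)
  conformal_grid(res$positions, lambda, res$H, periodic_v = TRUE,
    metadata = list(
      cut_vertices = c(p0, p1),
      seam_length = length(seam),
      flipped_param_triangles = res$n_flipped,
      u_axis = "first principal axis, low -> high projection",
      lambda_def = "sqrt(det g) of the resampled immersion per unit parameter area"))
}

# Cut an open mesh along a vertex path. Returns new faces plus the duplicate
# map: faces on the "right" of the path (by face orientation) reference
# duplicated vertex indices nv + k.
cut_mesh_along_path <- function(v, f, path) {
  nv <- nrow(v)
  seam_edges <- cbind(path[-length(path)], path[-1])
  seam_key <- c(paste(seam_edges[, 1], seam_edges[, 2]),
                paste(seam_edges[, 2], seam_edges[, 1]))
  f_new <- f
  dup_of <- integer(0)           # original index per duplicate
  for (p in path) {
    inc <- which(f_new[, 1] == p | f_new[, 2] == p | f_new[, 3] == p)
    if (!length(inc)) next
    # fan adjacency: faces share a NON-seam edge incident to p
    other <- lapply(inc, function(fi) setdiff(f[fi, ], p))
    edges_ok <- lapply(seq_along(inc), function(k) {
      x <- other[[k]]
      x[!(paste(p, x) %in% seam_key)]
    })
    adj <- matrix(FALSE, length(inc), length(inc))
    for (a in seq_along(inc)) for (b in seq_along(inc)) {
      if (a < b && length(intersect(edges_ok[[a]], edges_ok[[b]])))
        adj[a, b] <- adj[b, a] <- TRUE
    }
    comp <- rep(0L, length(inc))
    cid <- 0L
    for (a in seq_along(inc)) {
      if (comp[a] > 0L) next
      cid <- cid + 1L
      queue <- a
      comp[a] <- cid
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        nb <- which(adj[cur, ] & comp == 0L)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
    if (cid < 2L) next
    # the component containing the LEFT face of a seam edge at p keeps p;
    # left face of directed seam edge (a,b) = face containing (a,b) in order
    left_comp <- NA_integer_
    for (se in seq_len(nrow(seam_edges))) {
      a <- seam_edges[se, 1]; b <- seam_edges[se, 2]
      if (a != p && b != p) next
      for (k in seq_along(inc)) {
        tri <- f[inc[k], ]
        nxt <- tri[c(2, 3, 1)]
        if (any(tri == a & nxt == b)) { left_comp <- comp[k]; break }
      }
      if (!is.na(left_comp)) break
    }
    if (is.na(left_comp)) left_comp <- 1L
    for (ci in setdiff(seq_len(cid), left_comp)) {
      dup_of <- c(dup_of, p)
      newid <- nv + length(dup_of)
      for (k in which(comp == ci)) {
        row <- f_new[inc[k], ]
        row[f[inc[k], ] == p] <- newid
        f_new[inc[k], ] <- row
      }
    }
  }
  list(faces = f_new, dup_of = dup_of, n_orig = nv)
}

# harmonic v with +2*pi jump on the duplicated (right) side
solve_seam_harmonic <- function(vo, cutres, seam) {
  nv <- cutres$n_orig
  nd <- length(cutres$dup_of)
  vall <- rbind(vo, vo[cutres$dup_of, , drop = FALSE])
  L <- cot_laplacian(vall, cutres$faces)
  n <- nv + nd
  # v_full = P w + c with w over original vertices; dup rows add 2*pi
  Pi <- c(seq_len(nv), cutres$dup_of)
  P <- Matrix::sparseMatrix(i = seq_len(n), j = Pi, x = 1, dims = c(n, nv))
  cvec <- c(rep(0, nv), rep(2 * pi, nd))
  A <- Matrix::t(P) %*% L %*% P
  b <- -as.numeric(Matrix::t(P) %*% (L %*% cvec))
  # gauge: fix v = 0 at the first seam vertex
  fix <- seam[1]
  free <- setdiff(seq_len(nv), fix)
  w <- numeric(nv)
  w[free] <- as.numeric(Matrix::solve(A[free, free], b[free] - A[free, fix] * 0))
  as.numeric(P %*% w + cvec)
}

# locate regular grid nodes in the (u, v) triangulation and interpolate
resample_param_grid <- function(vo, fo, cutres, u_coord, v_coord, Ho, dims) {
  nu <- dims[1]; nv_grid <- dims[2]
  fc <- cutres$faces
  base <- c(seq_len(cutres$n_orig), cutres$dup_of)   # 3D/H source per cut vertex
  uu <- u_coord[base]
  vv <- v_coord

  # orientation fix: parameter triangles should be positively oriented
  tu <- cbind(uu[fc[, 1]], uu[fc[, 2]], uu[fc[, 3]])
  tv <- cbind(vv[fc[, 1]], vv[fc[, 2]], vv[fc[, 3]])
  sgn <- (tu[, 2] - tu[, 1]) * (tv[, 3] - tv[, 1]) -
         (tu[, 3] - tu[, 1]) * (tv[, 2] - tv[, 1])
  if (mean(sgn < 0) > 0.5) {
    vv <- -vv
    tv <- -tv
    sgn <- -sgn
  }
  n_flipped <- sum(sgn <= 0)
  if (n_flipped > 0.02 * length(sgn))
    stop_subshape("parameterization_failed",
      sprintf("parameter map not injective: %d flipped parameter triangle(s)", n_flipped))
  vv <- vv - floor(min(vv) / (2 * pi)) * 2 * pi

  ug <- grid_u(nu)
  vg <- grid_v(nv_grid)
  pos <- array(NA_real_, c(nu, nv_grid, 3L))
  Hg <- matrix(NA_real_, nu, nv_grid)

  locate_with_offset <- function(off) {
    t_v <- tv + off
    vmin <- pmin(t_v[, 1], t_v[, 2], t_v[, 3]); vmax <- pmax(t_v[, 1], t_v[, 2], t_v[, 3])
    umin <- pmin(tu[, 1], tu[, 2], tu[, 3]);   umax <- pmax(tu[, 1], tu[, 2], tu[, 3])
    for (tri in seq_len(nrow(fc))) {
      iu <- which(ug >= umin[tri] - 1e-12 & ug <= umax[tri] + 1e-12)
      if (!length(iu)) next
      iv <- which(vg >= vmin[tri] - 1e-12 & vg <= vmax[tri] + 1e-12)
      if (!length(iv)) next
      need <- which(is.na(Hg[iu, iv, drop = FALSE]), arr.ind = TRUE)
      if (!length(need)) next
      gi <- iu[need[, 1]]; gj <- iv[need[, 2]]
      px <- ug[gi]; py <- vg[gj]
      x1 <- tu[tri, 1]; y1 <- t_v[tri, 1]
      x2 <- tu[tri, 2]; y2 <- t_v[tri, 2]
      x3 <- tu[tri, 3]; y3 <- t_v[tri, 3]
      den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
      if (abs(den) < 1e-300) next
      w1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / den
      w2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / den
      w3 <- 1 - w1 - w2
      inside <- w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9
      if (!any(inside)) next
      vidx <- fc[tri, ]
      for (kk in which(inside)) {
        wts <- c(w1[kk], w2[kk], w3[kk])
        p3 <- wts %*% vo[base[vidx], , drop = FALSE]
        pos[gi[kk], gj[kk], ] <<- p3
        Hg[gi[kk], gj[kk]] <<- sum(wts * Ho[base[vidx]])
      }
    }
  }
  for (off in c(0, -2 * pi, 2 * pi)) {
    if (!anyNA(Hg)) break
    locate_with_offset(off)
  }

  # fall back to nearest parameter-plane vertex for any uncovered node
  miss <- which(is.na(Hg), arr.ind = TRUE)
  if (nrow(miss)) {
    for (r in seq_len(nrow(miss))) {
      du_ <- uu - ug[miss[r, 1]]
      dv_ <- abs(vv - vg[miss[r, 2]])
      dv_ <- pmin(dv_, 2 * pi - dv_)
      k <- which.min(du_^2 + dv_^2)
      pos[miss[r, 1], miss[r, 2], ] <- vo[base[k], ]
      Hg[miss[r, 1], miss[r, 2]] <- Ho[base[k]]
    }
  }
  list(positions = pos, H = Hg, n_flipped = n_flipped)
}

# conformal factor from the resampled immersion: sqrt(det g)
grid_lambda <- function(pos) {
  nu <- dim(pos)[1]; nv <- dim(pos)[2]
  du <- 1 / nu; dv <- 2 * pi / nv
  Xu <- array(0, dim(pos)); Xv <- array(0, dim(pos))
  for (k in 1:3) {
    m <- pos[, , k]
    Xu[, , k] <- rbind((m[2, ] - m[1, ]) / du,
                       (m[3:nu, ] - m[1:(nu - 2), ]) / (2 * du),
                       (m[nu, ] - m[nu - 1, ]) / du)
    Xv[, , k] <- (m[, c(2:nv, 1)] - m[, c(nv, 1:(nv - 1))]) / (2 * dv)
  }
  E <- apply(Xu * Xu, c(1, 2), sum)
  Fm <- apply(Xu * Xv, c(1, 2), sum)
  G <- apply(Xv * Xv, c(1, 2), sum)
  detg <- pmax(E * G - Fm^2, 1e-300)
  sqrt(detg)
}

#' Conformal representation channels
#'
#' Returns the conformal factor and mean curvature of a grid as the two
#' registration channels, each standardized to zero mean and unit variance
#' over the grid (the standardization constants are recorded in metadata so
#' the transform is invertible).
#'
#' @param grid a [conformal_grid()].
#' @return a list of class `conformal_representation` with elements
#'   `lambda` and `H` (standardized `nu x nv` matrices), `dims`,
#'   `periodic_v`, and `metadata` carrying the raw means/sds.
#' @export
conformal_representation <- function(grid) {
  stopifnot(inherits(grid, "conformal_grid"))
  if (any(!is.finite(grid$lambda)) || any(!is.finite(grid$H)))
    stop_subshape("grid_invalid", "non-finite lambda or H")
  std <- function(m) {
    s <- stats::sd(m)
    if (s == 0) s <- 1
    list(img = (m - mean(m)) / s, mean = mean(m), sd = s)
  }
  sl <- std(grid$lambda)
  sh <- std(grid$H)
  structure(list(lambda = sl$img, H = sh$img, dims = grid$dims,
                 periodic_v = grid$periodic_v,
                 metadata = list(lambda_mean = sl$mean, lambda_sd = sl$sd,
                                 H_mean = sh$mean, H_sd = sh$sd)),
            class = "conformal_representation")
}
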