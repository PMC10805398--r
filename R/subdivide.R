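#' Loop subdivision of a closed triangle mesh
#'
#' Standard Loop scheme for closed meshes: each edge gains a new vertex at
#' `3/8 (a + b) + 1/8 (c + d)` (edge endpoints a, b; opposite vertices c, d),
#' and each original vertex of valence n is moved to
#' `(1 - n beta) v + beta * sum(neighbours)` with
#' `beta = (1/n) (5/8 - (3/8 + 1/4 cos(2 pi / n))^2)`.
#' Each level multiplies the face count by 4 and preserves closedness and
#' genus.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param levels non-negative integer number of subdivision levels.
#' @return the subdivided `triangle_mesh`.
#' @export
loop_subdivide <- function(mesh, levels = 1L) {
  levels <- as.integer(levels)
  if (levels < 0L) stop_subshape("bad_argument", "levels must be >= 0")
  for (i in seq_len(levels)) mesh <- loop_once(mesh)
  mesh
}

loop_once <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  nf <- nrow(f)

  # undirected edges with the two opposite vertices
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to   <- c(f[, 2], f[, 3], f[, 1])
  he_opp  <- c(f[, 3], f[, 1], f[, 2])
  lo <- pmin(he_from, he_to)
  hi <- pmax(he_from, he_to)
  key <- paste(lo, hi)
  eid <- match(key, unique(key))
  ne <- max(eid)
  ends <- matrix(0L, ne, 2L)
  ends[eid, 1L] <- lo
  ends[eid, 2L] <- hi
  opp <- matrix(NA_integer_, ne, 2L)
  first <- !duplicated(eid)
  opp[eid[first], 1L] <- he_opp[first]
  opp[eid[!first], 2L] <- he_opp[!first]
  if (anyNA(opp))
    stop_subshape("mesh_not_watertight", "Loop subdivision requires a closed mesh")

  edge_pts <- 0.375 * (v[ends[, 1], ] + v[ends[, 2], ]) +
              0.125 * (v[opp[, 1], ] + v[opp[, 2], ])

  # even (original) vertex update
  val <- tabulate(c(ends[, 1], ends[, 2]), nbins = nv)
  beta <- (1 / val) * (5 / 8 - (3 / 8 + 0.25 * cos(2 * pi / val))^2)
  nbr_sum <- matrix(0, nv, 3L)
  for (k in 1:3) {
    s1 <- rowsum(v[ends[, 2], k], ends[, 1])
    nbr_sum[as.integer(rownames(s1)), k] <- nbr_sum[as.integer(rownames(s1)), k] + s1
    s2 <- rowsum(v[ends[, 1], k], ends[, 2])
    nbr_sum[as.integer(rownames(s2)), k] <- nbr_sum[as.integer(rownames(s2)), k] + s2
  }
  v_new <- (1 - val * beta) * v + beta * nbr_sum

  # face split: edge ids per corner edge of each face
  e12 <- eid[seq_len(nf)]
  e23 <- eid[nf + seq_len(nf)]
  e31 <- eid[2L * nf + seq_len(nf)]
  ev <- nv + seq_len(ne)            # edge-vertex indices
  f_new <- rbind(
    cbind(f[, 1], nv + e12, nv + e31),
    cbind(f[, 2], nv + e23, nv + e12),
    cbind(f[, 3], nv + e31, nv + e23),
    cbind(nv + e12, nv + e23, nv + e31)
  )
  triangle_mesh(rbind(v_new, edge_pts), f_new)
}

#' Simplify a mesh by quadric-error edge collapse
#'
#' Progressive simplification: each vertex carries the sum of the squared
#' point-to-plane quadrics of its incident faces; the cheapest valid edge is
#' collapsed repeatedly (each collapse removes two faces) until the face
#' budget is reached. Candidate positions are the two endpoints, the
#' midpoint, and the quadric-optimal point; collapses that would break local
#' manifoldness (link condition) or flip face normals are rejected. If no
#' valid collapse remains before the target is reached the achieved count is
#' reported in a warning.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param target_face_count requested face count (>= 100, < current count).
#' @return the simplified `triangle_mesh` (face count within 2 of target
#'   unless collapse stopped early).
#' @export
simplify_mesh <- function(mesh, target_face_count) {
  nf0 <- nrow(mesh$faces)
  if (target_face_count >= nf0) {
    if (target_face_count == nf0) return(mesh)
    stop_subshape("bad_argument", "target_face_count must be <= current face count")
  }
  if (target_face_count < 100)
    stop_subshape("bad_argument", "target_face_count must be >= 100")

  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)
  alive_f <- rep(TRUE, nrow(f))
  alive_v <- rep(TRUE, nv)

  # per-vertex incident faces
  vfaces <- vector("list", nv)
  for (j in 1:3) {
    sp <- split(seq_len(nrow(f)), f[, j])
    for (nm in names(sp)) {
      i <- as.integer(nm)
      vfaces[[i]] <- c(vfaces[[i]], sp[[nm]])
    }
  }

  # fundamental quadrics (4x4 per vertex, stored as 10 unique entries)
  quadric_of_face <- function(fi) {
    p <- v[f[fi, ], , drop = FALSE]
    n <- vcross(p[2, , drop = FALSE] - p[1, , drop = FALSE],
                p[3, , drop = FALSE] - p[1, , drop = FALSE])
    a2 <- sum(n * n)
    if (a2 < 1e-30) return(numeric(10))
    n <- n / sqrt(a2)
    d <- -sum(n * p[1, ])
    q <- c(n[1], n[2], n[3], d)
    w <- sqrt(a2) / 2          # area-weighted quadrics
    w * c(q[1] * q, q[2] * q[2:4], q[3] * q[3:4], q[4] * q[4])
  }
  Q <- matrix(0, nv, 10L)
  for (fi in seq_len(nrow(f))) {
    qf <- quadric_of_face(fi)
    for (j in f[fi, ]) Q[j, ] <- Q[j, ] + qf
  }
  q_eval <- function(q, p) {
    x <- p[1]; y <- p[2]; z <- p[3]
    q[1] * x * x + 2 * q[2] * x * y + 2 * q[3] * x * z + 2 * q[4] * x +
      q[5] * y * y + 2 * q[6] * y * z + 2 * q[7] * y +
      q[8] * z * z + 2 * q[9] * z + q[10]
  }
  q_optimal <- function(q) {
    A <- matrix(c(q[1], q[2], q[3], q[2], q[5], q[6], q[3], q[6], q[8]), 3, 3)
    b <- -c(q[4], q[7], q[9])
    p <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(p) || any(!is.finite(p))) NULL else p
  }

  edge_list <- mesh_edges(mesh)
  ne <- nrow(edge_list)
  e1 <- edge_list[, 1]; e2 <- edge_list[, 2]
  cost <- rep(NA_real_, ne)
  pos <- matrix(NA_real_, ne, 3L)
  alive_e <- rep(TRUE, ne)

  edge_cost <- function(i) {
    q <- Q[e1[i], ] + Q[e2[i], ]
    cands <- rbind(v[e1[i], ], v[e2[i], ], 0.5 * (v[e1[i], ] + v[e2[i], ]))
    p_opt <- q_optimal(q)
    if (!is.null(p_opt)) cands <- rbind(cands, p_opt)
    costs <- apply(cands, 1, q_eval, q = q)
    k <- which.min(costs)
    list(cost = costs[k], pos = cands[k, ])
  }
  for (i in seq_len(ne)) {
    ec <- edge_cost(i)
    cost[i] <- ec$cost
    pos[i, ] <- ec$pos
  }

  nf_alive <- nf0
  while (nf_alive > target_face_count + 1L) {
    active <- which(alive_e & !is.na(cost))
    if (!length(active)) break
    collapsed <- FALSE
    ord <- active[order(cost[active])]
    for (i in ord) {
      a <- e1[i]; b <- e2[i]
      if (!alive_v[a] || !alive_v[b]) { alive_e[i] <- FALSE; next }
      fa <- vfaces[[a]][alive_f[vfaces[[a]]]]
      fb <- vfaces[[b]][alive_f[vfaces[[b]]]]
      shared <- intersect(fa, fb)
      if (length(shared) != 2L) { alive_e[i] <- FALSE; next }
      # link condition: common neighbours of a and b == opposite vertices of shared faces
      na_ <- setdiff(unique(as.vector(f[fa, ])), c(a, b))
      nb_ <- setdiff(unique(as.vector(f[fb, ])), c(a, b))
      opp2 <- setdiff(unique(as.vector(f[shared, ])), c(a, b))
      if (!setequal(intersect(na_, nb_), opp2)) next
      newp <- pos[i, ]
      # normal-flip rejection on surviving faces around a and b
      surv <- setdiff(union(fa, fb), shared)
      flip <- FALSE
      for (fi in surv) {
        tri <- f[fi, ]
        p_old <- v[tri, , drop = FALSE]
        p_new <- p_old
        p_new[tri == a | tri == b, ] <- rep(newp, each = sum(tri == a | tri == b))
        n_old <- vcross(p_old[2, , drop = FALSE] - p_old[1, , drop = FALSE],
                        p_old[3, , drop = FALSE] - p_old[1, , drop = FALSE])
        n_new <- vcross(p_new[2, , drop = FALSE] - p_new[1, , drop = FALSE],
                        p_new[3, , drop = FALSE] - p_new[1, , drop = FALSE])
        if (sum(n_old * n_new) <= 1e-12 * sqrt(sum(n_old^2) * sum(n_new^2))) { flip <- TRUE; break }
      }
      if (flip) next

      # perform collapse: b -> a at newp
      v[a, ] <- newp
      Q[a, ] <- Q[a, ] + Q[b, ]
      alive_v[b] <- FALSE
      alive_f[shared] <- FALSE
      nf_alive <- nf_alive - 2L
      f[f == b] <- a
      vfaces[[a]] <- unique(c(fa, fb))
      alive_e[i] <- FALSE
      # re-point edges of b at a, drop the ones that degenerate
      e1[e1 == b & alive_e] <- a
      e2[e2 == b & alive_e] <- a
      alive_e[alive_e & e1 == e2] <- FALSE
      # refresh costs of surviving edges around a
      for (t in which(alive_e & (e1 == a | e2 == a))) {
        if (!alive_v[e1[t]] || !alive_v[e2[t]]) { alive_e[t] <- FALSE; next }
        ec <- edge_cost(t)
        cost[t] <- ec$cost
        pos[t, ] <- ec$pos
      }
      collapsed <- TRUE
      break
    }
    if (!collapsed) break
  }

  if (nf_alive > target_face_count + 2L)
    warning(sprintf("simplification stopped early at %d faces (target %d)",
                    nf_alive, target_face_count))

  keep_f <- f[alive_f, , drop = FALSE]
  keep_v <- which(alive_v)
  remap <- integer(nrow(v))
  remap[keep_v] <- seq_along(keep_v)
  triangle_mesh(v[keep_v, , drop = FALSE],
                matrix(remap[keep_f], ncol = 3L))
}
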