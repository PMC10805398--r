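# Analytic mesh primitives used as oracles across the suite.

octahedron_mesh <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  subshape::triangle_mesh(v, f, validate = TRUE)
}

icosahedron_mesh <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  subshape::triangle_mesh(v, f, validate = TRUE)
}

# midpoint-subdivide and project to the unit sphere
icosphere_mesh <- function(subdivisions = 3, radius = 1) {
  m <- icosahedron_mesh()
  for (s in seq_len(subdivisions)) {
    v <- m$vertices; f <- m$faces
    nf <- nrow(f); nv <- nrow(v)
    he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    eid <- match(key, unique(key))
    ne <- max(eid)
    mids <- matrix(0, ne, 3)
    mids[eid, ] <- (v[he[, 1], ] + v[he[, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    e12 <- eid[seq_len(nf)]; e23 <- eid[nf + seq_len(nf)]; e31 <- eid[2 * nf + seq_len(nf)]
    f2 <- rbind(cbind(f[, 1], nv + e12, nv + e31),
                cbind(f[, 2], nv + e23, nv + e12),
                cbind(f[, 3], nv + e31, nv + e23),
                cbind(nv + e12, nv + e23, nv + e31))
    m <- subshape::triangle_mesh(rbind(v, mids), f2)
  }
  m$vertices <- radius * m$vertices / sqrt(rowSums(m$vertices^2))
  m
}

# capped cylinder of radius r, length L along z, closed with pole fans
cylinder_mesh <- function(r = 1, L = 4, n_ring = 48, n_len = 40) {
  zs <- seq(-L / 2, L / 2, length.out = n_len)
  th <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  v <- do.call(rbind, lapply(zs, function(z) cbind(r * cos(th), r * sin(th), z)))
  idx <- function(i, j) (i - 1) * n_ring + ((j - 1) %% n_ring) + 1
  f <- list()
  for (i in seq_len(n_len - 1)) {
    for (j in seq_len(n_ring)) {
      a <- idx(i, j); b <- idx(i, j + 1); c <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      f[[length(f) + 1]] <- rbind(c(a, b, d), c(a, d, c))
    }
  }
  np <- nrow(v)
  v <- rbind(v, c(0, 0, -L / 2), c(0, 0, L / 2))
  for (j in seq_len(n_ring)) {
    f[[length(f) + 1]] <- rbind(c(np + 1, idx(1, j + 1), idx(1, j)),
                                c(np + 2, idx(n_len, j), idx(n_len, j + 1)))
  }
  subshape::triangle_mesh(v, do.call(rbind, f), validate = TRUE)
}

torus_mesh <- function(R = 2, r = 0.5, n_u = 24, n_v = 16) {
  us <- seq(0, 2 * pi, length.out = n_u + 1)[-(n_u + 1)]
  vs <- seq(0, 2 * pi, length.out = n_v + 1)[-(n_v + 1)]
  v <- do.call(rbind, lapply(us, function(u) {
    cbind((R + r * cos(vs)) * cos(u), (R + r * cos(vs)) * sin(u), r * sin(vs))
  }))
  idx <- function(i, j) ((i - 1) %% n_u) * n_v + ((j - 1) %% n_v) + 1
  f <- list()
  for (i in seq_len(n_u)) for (j in seq_len(n_v)) {
    a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i, j + 1); d <- idx(i + 1, j + 1)
    f[[length(f) + 1]] <- rbind(c(a, b, d), c(a, d, c))
  }
  subshape::triangle_mesh(v, do.call(rbind, f))
}
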