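#' Radial distance map
#'
#' Thickness surrogate: for each iso-parametric ring `u = const` the
#' medial-axis point is taken as the ring's 3D centroid (on tube-like
#' surfaces the iso-parametric curve is perpendicular to the medial axis,
#' so the centroid lies on the axis); `RD(u, v)` is the Euclidean distance
#' from the node to its ring centroid, in mm.
#'
#' @param grid a [conformal_grid()].
#' @return `nu x nv` matrix of radial distances (mm).
#' @export
radial_distance <- function(grid) {
  stopifnot(inherits(grid, "conformal_grid"))
  pos <- grid$positions
  nu <- dim(pos)[1]
  RD <- matrix(0, nu, dim(pos)[2])
  for (i in seq_len(nu)) {
    ring <- pos[i, , ]
    if (nrow(unique(round(ring, 9))) < 3L)
      stop_subshape("degenerate_ring",
        sprintf("iso-parametric ring u index %d has fewer than 3 distinct positions", i))
    ctr <- colMeans(ring)
    RD[i, ] <- sqrt(colSums((t(ring) - ctr)^2))
  }
  RD
}

#' Tensor-based morphometry map (det J)
#'
#' Local area change of the registration at each node: values below 1 are
#' contraction (atrophy-like), above 1 expansion.
#'
#' @param J_field `nu x nv x 2 x 2` Jacobian array (from [jacobian_field()]
#'   or a [fluid_register()] result's `$jacobian`).
#' @return `nu x nv` matrix of Jacobian determinants.
#' @export
tbm <- function(J_field) {
  if (inherits(J_field, "deformation_field")) J_field <- J_field$jacobian
  d <- det_j(J_field)
  if (any(d <= 0))
    stop_subshape("registration_failed",
      sprintf("det J <= 0 at %d node(s): registration invariant violated", sum(d <= 0)))
  d
}

#' Multivariate tensor-based morphometry (log-Euclidean deformation tensor)
#'
#' `S = J J^T` is symmetric positive definite; its matrix logarithm `L`
#' (via eigendecomposition) is vectorized as `(L11, sqrt(2) L12, L22)`.
#' The `sqrt(2)` off-diagonal scaling makes the Euclidean norm of the
#' 3-vector equal the Frobenius norm of `L`, i.e. the Log-Euclidean metric
#' on deformation tensors.
#'
#' @param J_field `nu x nv x 2 x 2` Jacobian array or a `deformation_field`.
#' @return `nu x nv x 3` array.
#' @export
mtbm <- function(J_field) {
  if (inherits(J_field, "deformation_field")) J_field <- J_field$jacobian
  a <- J_field[, , 1, 1]; b <- J_field[, , 1, 2]
  cc <- J_field[, , 2, 1]; d <- J_field[, , 2, 2]
  if (any(a * d - b * cc <= 0))
    stop_subshape("registration_failed", "det J <= 0: deformation tensor not SPD")
  # S = J J^T, symmetric 2x2
  s11 <- a * a + b * b
  s12 <- a * cc + b * d
  s22 <- cc * cc + d * d
  # eigendecomposition of symmetric 2x2 in closed form
  tr <- s11 + s22
  diff <- s11 - s22
  disc <- sqrt(pmax(diff^2 + 4 * s12^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (any(l2 <= 0))
    stop_subshape("registration_failed", "deformation tensor not SPD within tolerance")
  # eigenvector for l1: (s12, l1 - s11) unless s12 ~ 0
  ex <- ifelse(abs(s12) > 1e-300, s12, 1)
  ey <- ifelse(abs(s12) > 1e-300, l1 - s11, 0)
  nrm <- sqrt(ex^2 + ey^2)
  ex <- ex / nrm; ey <- ey / nrm
  g1 <- log(l1); g2 <- log(l2)
  L11 <- g1 * ex^2 + g2 * ey^2
  L12 <- (g1 - g2) * ex * ey
  L22 <- g1 * ey^2 + g2 * ex^2
  out <- array(0, c(dim(a), 3L))
  out[, , 1] <- L11
  out[, , 2] <- sqrt(2) * L12
  out[, , 3] <- L22
  out
}

#' Multivariate morphometry statistics
#'
#' Per-vertex 4-vector combining the radial thickness measure with the
#' tangential deformation tensor: channel order
#' `(RD, mTBM1, mTBM2, mTBM3)`.
#'
#' @param RD `nu x nv` radial-distance matrix.
#' @param mTBM `nu x nv x 3` log-Euclidean tensor array.
#' @return `nu x nv x 4` array; channel 1 equals `RD` bitwise.
#' @export
mms <- function(RD, mTBM) {
  stopifnot(all(dim(RD) == dim(mTBM)[1:2]), dim(mTBM)[3] == 3L)
  out <- array(0, c(dim(RD), 4L))
  out[, , 1] <- RD
  out[, , 2:4] <- mTBM
  out
}

#' Full per-vertex feature set of a registered subject
#'
#' Convenience wrapper computing RD on the subject grid and TBM/mTBM/MMS
#' from the deformation that registers the subject to the template.
#'
#' @param grid subject [conformal_grid()].
#' @param deformation a [fluid_register()] result, or `NULL` for an
#'   identity deformation (e.g. surfaces constructed in correspondence).
#' @return an object of class `vertex_features`: list with `RD`, `TBM`,
#'   `mTBM`, `MMS`.
#' @export
vertex_features <- function(grid, deformation = NULL) {
  RD <- radial_distance(grid)
  J <- if (is.null(deformation)) {
    J0 <- array(0, c(dim(RD), 2L, 2L))
    J0[, , 1, 1] <- 1
    J0[, , 2, 2] <- 1
    J0
  } else if (inherits(deformation, "deformation_field")) {
    deformation$jacobian
  } else deformation
  TBM <- tbm(J)
  mT <- mtbm(J)
  structure(list(RD = RD, TBM = TBM, mTBM = mT, MMS = mms(RD, mT)),
            class = "vertex_features")
}

#' @export
print.vertex_features <- function(x, ...) {
  cat(sprintf("vertex_features: %d x %d grid\n", dim(x$RD)[1], dim(x$RD)[2]))
  cat(sprintf("  RD [%.2f, %.2f] mm; TBM [%.3f, %.3f]; |mTBM| max %.3f\n",
              min(x$RD), max(x$RD), min(x$TBM), max(x$TBM),
              max(sqrt(apply(x$mTBM^2, c(1, 2), sum)))))
  invisible(x)
}

#' Export feature maps as long-format table
#'
#' @param features a [vertex_features()] object.
#' @param subject subject identifier recycled into the first column.
#' @return data.frame with columns subject, u, v, channel, value.
#' @export
features_long <- function(features, subject = "S001") {
  dims <- dim(features$RD)
  grids <- expand.grid(u = seq_len(dims[1]), v = seq_len(dims[2]))
  chans <- list(RD = features$RD, TBM = features$TBM,
                mTBM1 = features$mTBM[, , 1], mTBM2 = features$mTBM[, , 2],
                mTBM3 = features$mTBM[, , 3])
  do.call(rbind, lapply(names(chans), function(nm) {
    data.frame(subject = subject, u = grids$u, v = grids$v, channel = nm,
               value = as.vector(chans[[nm]]))
  }))
}
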