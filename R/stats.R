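#' Assemble a cohort feature array
#'
#' Stacks per-subject feature maps into the subjects x vertices x channels
#' array the statistical operations work on.
#'
#' @param features_list list of [vertex_features()] objects (one per
#'   subject) or of plain matrices/arrays.
#' @param channel `"RD"`, `"TBM"`, `"mTBM"` or `"MMS"`.
#' @return numeric array `subjects x vertices x channels` with attribute
#'   `"channel_kind"`.
#' @export
stack_features <- function(features_list, channel = c("MMS", "RD", "TBM", "mTBM")) {
  channel <- match.arg(channel)
  get1 <- function(f) {
    m <- if (inherits(f, "vertex_features")) f[[channel]] else f
    if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
    matrix(m, nrow = prod(dim(m)[1:2]), ncol = dim(m)[3])
  }
  mats <- lapply(features_list, get1)
  V <- nrow(mats[[1]]); C <- ncol(mats[[1]])
  out <- array(0, c(length(mats), V, C))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  attr(out, "channel_kind") <- channel
  out
}

as_feature_array <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L)
    stop_subshape("bad_argument", "features must be subjects x vertices x channels")
  x
}

check_two_groups <- function(labels, n) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop_subshape("bad_argument", "exactly two groups required")
  if (length(labels) != n)
    stop_subshape("bad_argument", "labels length must match subject count")
  if (any(table(labels) < 2L))
    stop_subshape("bad_argument", "each group needs >= 2 subjects")
  labels
}

#' Vertex-wise two-sample t statistics
#'
#' Pooled-variance two-sample t per vertex for a univariate channel
#' (RD or TBM), group 1 minus group 2. Vertices with zero pooled variance
#' get statistic 0 and are flagged in the `"zero_variance"` attribute.
#'
#' @param x subjects x vertices matrix (or subjects x vertices x 1 array).
#' @param labels two-level factor; the first level is group 1 (reference).
#' @return numeric vector of t statistics with attribute `"zero_variance"`.
#' @export
vertex_t_stat <- function(x, labels) {
  x <- as_feature_array(x)
  if (dim(x)[3] != 1L)
    stop_subshape("bad_argument", "t statistics need a univariate channel")
  labels <- check_two_groups(labels, dim(x)[1])
  m <- x[, , 1, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(x)[1])
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(m[g1, , drop = FALSE])
  m2 <- colMeans(m[!g1, , drop = FALSE])
  ss1 <- colSums(m[g1, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(m[!g1, , drop = FALSE]^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  zero <- denom <= 0 | !is.finite(denom)
  t <- ifelse(zero, 0, (m1 - m2) / ifelse(zero, 1, denom))
  attr(t, "zero_variance") <- zero
  t
}

# ---- batched symmetric quadratic forms q = b' S^{-1} b, d in 1..4 --------
# S given as list S[[j]][[k]] (j <= k) of per-vertex vectors; b as list.
spd_quadform <- function(d, S, b) {
  if (d == 1L) {
    return(list(q = b[[1]]^2 / S[[1]][[1]], det = S[[1]][[1]]))
  }
  if (d == 2L) {
    det <- S[[1]][[1]] * S[[2]][[2]] - S[[1]][[2]]^2
    q <- (b[[1]]^2 * S[[2]][[2]] - 2 * b[[1]] * b[[2]] * S[[1]][[2]] +
            b[[2]]^2 * S[[1]][[1]]) / det
    return(list(q = q, det = det))
  }
  if (d == 3L) {
    s11 <- S[[1]][[1]]; s12 <- S[[1]][[2]]; s13 <- S[[1]][[3]]
    s22 <- S[[2]][[2]]; s23 <- S[[2]][[3]]; s33 <- S[[3]][[3]]
    A11 <- s22 * s33 - s23^2
    A12 <- -(s12 * s33 - s13 * s23)
    A13 <- s12 * s23 - s13 * s22
    A22 <- s11 * s33 - s13^2
    A23 <- -(s11 * s23 - s12 * s13)
    A33 <- s11 * s22 - s12^2
    det <- s11 * A11 + s12 * A12 + s13 * A13
    b1 <- b[[1]]; b2 <- b[[2]]; b3 <- b[[3]]
    q <- (b1 * (A11 * b1 + A12 * b2 + A13 * b3) +
          b2 * (A12 * b1 + A22 * b2 + A23 * b3) +
          b3 * (A13 * b1 + A23 * b2 + A33 * b3)) / det
    return(list(q = q, det = det))
  }
  # d == 4: 2x2 block inversion, all entries elementwise vectors
  a11 <- S[[1]][[1]]; a12 <- S[[1]][[2]]; a22 <- S[[2]][[2]]
  b11 <- S[[1]][[3]]; b12 <- S[[1]][[4]]
  b21 <- S[[2]][[3]]; b22 <- S[[2]][[4]]
  d11 <- S[[3]][[3]]; d12 <- S[[3]][[4]]; d22 <- S[[4]][[4]]
  detA <- a11 * a22 - a12^2
  # y = A^{-1} b1
  y1 <- (a22 * b[[1]] - a12 * b[[2]]) / detA
  y2 <- (-a12 * b[[1]] + a11 * b[[2]]) / detA
  # C = A^{-1} B (2x2)
  c11 <- (a22 * b11 - a12 * b21) / detA
  c12 <- (a22 * b12 - a12 * b22) / detA
  c21 <- (-a12 * b11 + a11 * b21) / detA
  c22 <- (-a12 * b12 + a11 * b22) / detA
  # E = D - B' A^{-1} B
  e11 <- d11 - (b11 * c11 + b21 * c21)
  e12 <- d12 - (b11 * c12 + b21 * c22)
  e22 <- d22 - (b12 * c12 + b22 * c22)
  detE <- e11 * e22 - e12^2
  # r = b2 - B' y
  r1 <- b[[3]] - (b11 * y1 + b21 * y2)
  r2 <- b[[4]] - (b12 * y1 + b22 * y2)
  q <- b[[1]] * y1 + b[[2]] * y2 +
    (r1^2 * e22 - 2 * r1 * r2 * e12 + r2^2 * e11) / detE
  list(q = q, det = detA * detE)
}

# Hotelling T2 from per-group moment sums (all arguments per-vertex vectors
# inside lists); ridge-regularizes singular pooled covariances
t2_from_moments <- function(d, n1, n2, sum1, sum2, cross_total) {
  n <- n1 + n2
  m1 <- lapply(sum1, function(s) s / n1)
  m2 <- lapply(sum2, function(s) s / n2)
  S <- vector("list", d)
  tr <- 0
  for (j in seq_len(d)) {
    S[[j]] <- vector("list", d)
    for (k in j:d) {
      S[[j]][[k]] <- (cross_total[[j]][[k]] - n1 * m1[[j]] * m1[[k]] -
                        n2 * m2[[j]] * m2[[k]]) / (n - 2)
    }
    tr <- tr + S[[j]][[j]]
  }
  b <- lapply(seq_len(d), function(j) m1[[j]] - m2[[j]])
  res <- spd_quadform(d, S, b)
  bad <- !is.finite(res$q) | res$det <= 0
  if (any(bad)) {
    ridge <- 1e-8 * tr / d
    Sr <- S
    for (j in seq_len(d)) Sr[[j]][[j]] <- S[[j]][[j]] + ridge
    res2 <- spd_quadform(d, Sr, b)
    res$q[bad] <- res2$q[bad]
  }
  q <- res$q
  q[!is.finite(q)] <- 0
  (n1 * n2 / n) * q
}

#' Vertex-wise Hotelling's T-squared statistics
#'
#' Two-sample Hotelling's T2 per vertex for multivariate channels (mTBM or
#' MMS), with pooled covariance; a ridge of `1e-8 * trace(S)/d` is added
#' where the pooled covariance is singular. For a univariate channel the
#' statistic reduces to `t^2`.
#'
#' @param x subjects x vertices x channels array.
#' @param labels two-level factor; first level is group 1.
#' @return numeric vector of T2 values.
#' @export
vertex_hotelling_t2 <- function(x, labels) {
  x <- as_feature_array(x)
  d <- dim(x)[3]
  labels <- check_two_groups(labels, dim(x)[1])
  n1 <- sum(labels == levels(labels)[1]); n2 <- dim(x)[1] - n1
  if (n1 + n2 - 2 <= d)
    stop_subshape("bad_argument", "need n1 + n2 - 2 > channels for Hotelling's T2")
  g1 <- labels == levels(labels)[1]
  V <- dim(x)[2]
  chan <- function(j) matrix(x[, , j], dim(x)[1], V)
  sum1 <- lapply(seq_len(d), function(j) colSums(chan(j)[g1, , drop = FALSE]))
  sum2 <- lapply(seq_len(d), function(j) colSums(chan(j)[!g1, , drop = FALSE]))
  cross <- vector("list", d)
  for (j in seq_len(d)) {
    cross[[j]] <- vector("list", d)
    for (k in j:d) cross[[j]][[k]] <- colSums(chan(j) * chan(k))
  }
  t2_from_moments(d, n1, n2, sum1, sum2, cross)
}

#' Permutation test with count-based global correction
#'
#' Vertex-wise two-group permutation test preserving the spatial dependence
#' structure: each permutation applies one shared label shuffle to all
#' vertices. The per-vertex p value is the fraction of permuted statistics
#' at least as large as the observed one (absolute value for t, raw value
#' for T2). The global multiple-comparison correction counts, for the
#' observed data and for every permutation (leave-self-in), how many
#' vertices are significant at `alpha`; the corrected global p is the
#' fraction of permutations whose count strictly exceeds the observed
#' "real effect" count. A global p of 0 is reported as `< 1/n_perm` by the
#' print method.
#'
#' @param x subjects x vertices (x channels) feature array.
#' @param labels two-level factor; first level is group 1 (reference).
#' @param stat `"auto"` (t for 1 channel, Hotelling otherwise), `"t"` or
#'   `"hotelling"`.
#' @param n_perm number of label shuffles (>= 100).
#' @param alpha uncorrected vertex-level threshold.
#' @param seed integer seed for the shuffles.
#' @param shuffle_hook optional `function(perm_index, permuted_labels)`
#'   called once per permutation with the shared label vector (test
#'   instrumentation).
#' @param keep_perm_stats if `TRUE` the full `n_perm x vertices` permuted
#'   statistic matrix is attached to the result (diagnostics).
#' @return an object of class `stat_map`; see Details.
#' @details The returned list has elements `statistic`, `p_vertex`
#'   (multiples of `1/n_perm`), `sig_mask`, `real_effect`, `p_global`,
#'   `n_perm`, `alpha`, `seed`, `stat_kind`, `perm_counts`.
#' @export
permutation_test <- function(x, labels, stat = c("auto", "t", "hotelling"),
                             n_perm = 10000L, alpha = 0.05, seed = 1L,
                             shuffle_hook = NULL, keep_perm_stats = FALSE) {
  stat <- match.arg(stat)
  x <- as_feature_array(x)
  n <- dim(x)[1]; V <- dim(x)[2]; d <- dim(x)[3]
  labels <- check_two_groups(labels, n)
  if (n_perm < 100L) stop_subshape("bad_argument", "n_perm must be >= 100")
  if (stat == "auto") stat <- if (d == 1L) "t" else "hotelling"
  if (stat == "t" && d != 1L)
    stop_subshape("bad_argument", "t statistics need a univariate channel")
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- n - n1
  if (lchoose(n, n1) < log(n_perm))
    warning("n_perm exceeds the number of distinct permutations; proceeding with sampling")

  obs <- if (stat == "t") abs(vertex_t_stat(x, labels))
         else vertex_hotelling_t2(x, labels)

  # one shared shuffle per permutation
  perm_idx <- with_seed(seed, {
    replicate(n_perm, sample.int(n, n1), simplify = FALSE)
  })
  if (!is.null(shuffle_hook)) {
    for (b in seq_len(n_perm)) {
      pl <- rep(levels(labels)[2], n)
      pl[perm_idx[[b]]] <- levels(labels)[1]
      shuffle_hook(b, factor(pl, levels = levels(labels)))
    }
  }
  Ind <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) Ind[perm_idx[[b]], b] <- 1

  perm_stat <- permuted_statistics(x, Ind, n1, n2, stat)   # n_perm x V

  p_vertex <- colSums(sweep(perm_stat, 2, obs, ">=")) / n_perm
  sig_mask <- p_vertex < alpha
  real_effect <- sum(sig_mask)

  # leave-self-in permutation p-maps and their significant counts
  thr <- alpha * n_perm
  counts <- integer(n_perm)
  for (v in seq_len(V)) {
    cnt_ge <- n_perm - rank(perm_stat[, v], ties.method = "min") + 1
    counts <- counts + (cnt_ge < thr)
  }
  p_global <- sum(counts > real_effect) / n_perm

  out <- list(statistic = obs, p_vertex = p_vertex, sig_mask = sig_mask,
              real_effect = real_effect, p_global = p_global,
              n_perm = as.integer(n_perm), alpha = alpha, seed = seed,
              stat_kind = stat, perm_counts = counts,
              group1 = levels(labels)[1], group2 = levels(labels)[2])
  if (keep_perm_stats) out$perm_stats <- perm_stat
  structure(out, class = "stat_map")
}

# vectorized permuted statistics from moment sums; returns n_perm x V
permuted_statistics <- function(x, Ind, n1, n2, stat) {
  n <- dim(x)[1]; V <- dim(x)[2]; d <- dim(x)[3]
  n_perm <- ncol(Ind)
  if (stat == "t") {
    m <- x[, , 1]
    tot <- colSums(m); tot2 <- colSums(m^2)
    S1 <- crossprod(Ind, m)                     # n_perm x V group-1 sums
    SS1 <- crossprod(Ind, m^2)
    m1 <- S1 / n1
    m2 <- sweep(-S1, 2, tot, "+") / n2
    ss1 <- SS1 - n1 * m1^2
    ss2 <- sweep(-SS1, 2, tot2, "+") - n2 * m2^2
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    denom <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
    tt <- abs(m1 - m2) / denom
    tt[!is.finite(tt)] <- 0
    return(tt)
  }
  # Hotelling: per-channel sums and fixed total crossproducts
  tots <- lapply(seq_len(d), function(j) colSums(x[, , j]))
  S1 <- lapply(seq_len(d), function(j) crossprod(Ind, x[, , j]))  # n_perm x V
  cross <- vector("list", d)
  for (j in seq_len(d)) {
    cross[[j]] <- vector("list", d)
    for (k in j:d) {
      cij <- colSums(x[, , j] * x[, , k])
      cross[[j]][[k]] <- matrix(cij, n_perm, V, byrow = TRUE)
    }
  }
  sum1 <- S1
  sum2 <- lapply(seq_len(d), function(j) sweep(-S1[[j]], 2, tots[[j]], "+"))
  out <- t2_from_moments(d, n1, n2, sum1, sum2, cross)
  matrix(out, n_perm, V)
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map (%s): %d vertices, %d permutations, alpha = %g\n",
              x$stat_kind, length(x$statistic), x$n_perm, x$alpha))
  pg <- if (x$p_global == 0) sprintf("< %g", 1 / x$n_perm) else format(x$p_global)
  cat(sprintf("  real effect: %d significant vertex(es); global corrected p = %s\n",
              x$real_effect, pg))
  invisible(x)
}

#' @export
summary.stat_map <- function(object, ...) {
  out <- data.frame(
    stat_kind = object$stat_kind,
    n_vertices = length(object$statistic),
    n_perm = object$n_perm,
    alpha = object$alpha,
    real_effect = object$real_effect,
    sig_fraction = mean(object$sig_mask),
    p_global = object$p_global)
  class(out) <- c("summary.stat_map", "data.frame")
  out
}

#' Atrophy/expansion direction map
#'
#' Labels each significant vertex by the sign of the group-1 minus group-2
#' mean difference of a univariate measure: positive (reference group
#' larger) is atrophy of group 2, negative is expansion. Non-significant
#' vertices are `"none"`.
#'
#' @param x subjects x vertices matrix (univariate channel, RD or TBM).
#' @param labels two-level factor used for `stat_map`.
#' @param stat_map a [permutation_test()] result on the same cohort.
#' @return character vector with levels atrophy/expansion/none.
#' @export
direction_map <- function(x, labels, stat_map) {
  x <- as_feature_array(x)
  if (dim(x)[3] != 1L)
    stop_subshape("bad_argument", "direction maps are defined for univariate measures")
  labels <- check_two_groups(labels, dim(x)[1])
  m <- x[, , 1]
  g1 <- labels == levels(labels)[1]
  md <- colMeans(m[g1, , drop = FALSE]) - colMeans(m[!g1, , drop = FALSE])
  out <- rep("none", length(md))
  sig <- stat_map$sig_mask
  zero_sig <- sig & md == 0
  if (any(zero_sig)) {
    warning(sprintf("%d significant vertex(es) with exactly zero mean difference; labelled 'none'",
                    sum(zero_sig)))
  }
  out[sig & md > 0] <- "atrophy"
  out[sig & md < 0] <- "expansion"
  out
}

#' Vertex-wise clinical correlation maps
#'
#' Pearson correlation between a per-subject univariate feature map and a
#' clinical score, with the two-sided parametric p value per vertex and an
#' uncorrected significance mask.
#'
#' @param x subjects x vertices matrix of feature values.
#' @param scores numeric per-subject score vector (non-constant, >= 3
#'   subjects).
#' @param alpha uncorrected threshold for the mask.
#' @return list with `r`, `p`, `mask`.
#' @export
clinical_correlation <- function(x, scores, alpha = 0.05) {
  x <- as_feature_array(x)[, , 1]
  n <- nrow(x)
  if (n < 3L) stop_subshape("bad_argument", "need >= 3 subjects")
  if (length(scores) != n) stop_subshape("bad_argument", "scores length mismatch")
  if (stats::sd(scores) == 0)
    stop_subshape("bad_argument", "constant score vector")
  r <- suppressWarnings(as.vector(stats::cor(scores, x)))
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, mask = p < alpha)
}
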