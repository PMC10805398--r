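#' Registration parameters
#'
#' Numerics of the viscous-fluid mutual-information registration. The
#' defaults follow common fluid-registration practice: 32 histogram bins,
#' a Gaussian fluid kernel of 2 grid cells, a 3-level coarse-to-fine
#' pyramid, and regridding when the incremental Jacobian determinant drops
#' below 0.5.
#'
#' @param bins joint-histogram bin count (>= 8).
#' @param sigma_fluid Gaussian smoothing width of the velocity field (grid
#'   cells; > 0).
#' @param step time-step scale; the update is additionally normalized so
#'   the largest per-iteration displacement is at most 0.5 grid cell.
#' @param max_iter maximum iterations per pyramid level.
#' @param levels multiresolution pyramid depth (1 = single scale).
#' @param regrid_threshold minimum incremental `det J` before the flow is
#'   composed into the total deformation and restarted (in (0, 1)).
#' @param tol relative MI change treated as convergence.
#' @return a list of class `registration_params`.
#' @export
registration_params <- function(bins = 32L, sigma_fluid = 2.0, step = 1.0,
                                max_iter = 200L, levels = 3L,
                                regrid_threshold = 0.5, tol = 1e-5) {
  if (bins < 8L) stop_subshape("bad_argument", "bins must be >= 8")
  if (sigma_fluid <= 0) stop_subshape("bad_argument", "sigma_fluid must be > 0")
  if (regrid_threshold <= 0 || regrid_threshold >= 1)
    stop_subshape("bad_argument", "regrid_threshold must be in (0, 1)")
  structure(list(bins = as.integer(bins), sigma_fluid = sigma_fluid,
                 step = step, max_iter = as.integer(max_iter),
                 levels = as.integer(levels),
                 regrid_threshold = regrid_threshold, tol = tol),
            class = "registration_params")
}

#' Mutual information between two images
#'
#' Plug-in estimate `MI = H(A) + H(B) - H(A, B)` in bits from a joint
#' histogram with `bins^2` cells filled with linear (partial-volume)
#' weights: each sample distributes its mass over the two nearest bin
#' centres along each axis.
#'
#' @param imageA,imageB equal-shaped numeric matrices/arrays.
#' @param bins histogram bin count per axis.
#' @return MI in bits (non-negative up to floating error). A constant image
#'   yields 0 with a warning (degenerate entropy).
#' @export
mutual_information <- function(imageA, imageB, bins = 32L) {
  a <- as.vector(imageA); b <- as.vector(imageB)
  if (length(a) != length(b)) stop_subshape("bad_argument", "images must have equal shape")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_subshape("bad_argument", "images must be finite")
  if (max(a) == min(a) || max(b) == min(b)) {
    warning("constant image: MI = 0 (degenerate entropy)")
    return(0)
  }
  P <- joint_histogram(a, b, bins)
  joint_mi(P)
}

# linear (partial-volume) joint histogram, normalized to sum 1
joint_histogram <- function(a, b, bins, ra = range(a), rb = range(b)) {
  sa <- (a - ra[1]) / (ra[2] - ra[1]) * (bins - 1)   # in [0, bins-1]
  sb <- (b - rb[1]) / (rb[2] - rb[1]) * (bins - 1)
  sa <- pmin(pmax(sa, 0), bins - 1)
  sb <- pmin(pmax(sb, 0), bins - 1)
  ia <- pmin(floor(sa), bins - 2); fa <- sa - ia
  ib <- pmin(floor(sb), bins - 2); fb <- sb - ib
  idx <- function(i, j) i + 1L + bins * j             # 1-based linear index
  P <- numeric(bins * bins)
  add <- function(i, j, w) {
    t <- rowsum(w, idx(i, j))
    P[as.integer(rownames(t))] <<- P[as.integer(rownames(t))] + t
  }
  add(ia, ib, (1 - fa) * (1 - fb))
  add(ia + 1, ib, fa * (1 - fb))
  add(ia, ib + 1, (1 - fa) * fb)
  add(ia + 1, ib + 1, fa * fb)
  matrix(P / length(a), bins, bins)
}

joint_mi <- function(P) {
  pa <- rowSums(P); pb <- colSums(P)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  max(ent(pa) + ent(pb) - ent(P), 0)
}

#' Deformation Jacobians from a displacement field
#'
#' `J = I + grad(u)` by central differences: periodic wrap along v, one-sided
#' differences at the u edges.
#'
#' @param displacement `nu x nv x 2` array (grid-cell units; component 1
#'   along u, component 2 along v).
#' @return `nu x nv x 2 x 2` array of Jacobian matrices.
#' @export
jacobian_field <- function(displacement) {
  nu <- dim(displacement)[1]; nv <- dim(displacement)[2]
  J <- array(0, c(nu, nv, 2L, 2L))
  for (k in 1:2) {
    m <- displacement[, , k]
    du <- rbind(m[2, ] - m[1, ],
                (m[3:nu, ] - m[1:(nu - 2), ]) / 2,
                m[nu, ] - m[nu - 1, ])
    dv <- (m[, c(2:nv, 1)] - m[, c(nv, 1:(nv - 1))]) / 2
    J[, , k, 1] <- du
    J[, , k, 2] <- dv
  }
  J[, , 1, 1] <- J[, , 1, 1] + 1
  J[, , 2, 2] <- J[, , 2, 2] + 1
  J
}

det_j <- function(J) J[, , 1, 1] * J[, , 2, 2] - J[, , 1, 2] * J[, , 2, 1]

# bilinear sampling of image `img` at (x + u); periodic in v, clamped in u
warp_image <- function(img, disp) {
  nu <- nrow(img); nv <- ncol(img)
  xi <- matrix(seq_len(nu), nu, nv) + disp[, , 1]
  yj <- matrix(seq_len(nv), nu, nv, byrow = TRUE) + disp[, , 2]
  xi <- pmin(pmax(xi, 1), nu)
  i0 <- pmin(floor(xi), nu - 1); fx <- xi - i0
  j0f <- floor(yj); fy <- yj - j0f
  j0 <- ((as.integer(j0f) - 1L) %% nv) + 1L
  j1 <- (j0 %% nv) + 1L
  g <- function(ii, jj) matrix(img[cbind(as.integer(ii), as.integer(jj))], nu, nv)
  g(i0, j0) * (1 - fx) * (1 - fy) + g(i0 + 1, j0) * fx * (1 - fy) +
    g(i0, j1) * (1 - fx) * fy + g(i0 + 1, j1) * fx * fy
}

# image gradient (periodic v, one-sided u edges)
image_gradient <- function(img) {
  nu <- nrow(img); nv <- ncol(img)
  gu <- rbind(img[2, ] - img[1, ],
              (img[3:nu, ] - img[1:(nu - 2), ]) / 2,
              img[nu, ] - img[nu - 1, ])
  gv <- (img[, c(2:nv, 1)] - img[, c(nv, 1:(nv - 1))]) / 2
  list(gu = gu, gv = gv)
}

# smooth (Parzen-style) MI gradient wrt the warped image intensities:
# derivative of the linear intensity-bin weights times the spatial image
# gradient gives a kink-free ascent direction even at integer alignment
mi_intensity_gradient <- function(tmpl, warped, bins, rt, rw) {
  n <- length(tmpl)
  P <- joint_histogram(as.vector(tmpl), as.vector(warped), bins, rt, rw)
  pw <- colSums(P)
  Lmat <- matrix(0, bins, bins)
  pos <- P > 0
  Lmat[pos] <- log2(P[pos] / pw[col(P)[pos]])
  st <- (as.vector(tmpl) - rt[1]) / (rt[2] - rt[1]) * (bins - 1)
  sw <- (as.vector(warped) - rw[1]) / (rw[2] - rw[1]) * (bins - 1)
  st <- pmin(pmax(st, 0), bins - 1); sw <- pmin(pmax(sw, 0), bins - 1)
  it <- pmin(floor(st), bins - 2); ft <- st - it
  iw <- pmin(floor(sw), bins - 2)
  look <- function(i, j) Lmat[cbind(i + 1L, j + 1L)]
  dMI_ds <- (1 - ft) * (look(it, iw + 1) - look(it, iw)) +
            ft * (look(it + 1, iw + 1) - look(it + 1, iw))
  dscale <- (bins - 1) / (rw[2] - rw[1])
  matrix(dMI_ds * dscale / n, nrow(tmpl), ncol(tmpl))
}

# hard bin index (1..bins) per pixel for the partial-volume histogram
hard_bins <- function(img, bins, rng = range(img)) {
  s <- (as.vector(img) - rng[1]) / max(rng[2] - rng[1], 1e-300) * bins
  b <- pmin(pmax(floor(s), 0), bins - 1) + 1L
  matrix(as.integer(b), nrow(img), ncol(img))
}

# bilinear spatial weights of x + u over the 4 neighbouring pixels
# (periodic in v, clamped in u)
pv_neighbours <- function(disp) {
  nu <- dim(disp)[1]; nv <- dim(disp)[2]
  xi <- matrix(seq_len(nu), nu, nv) + disp[, , 1]
  yj <- matrix(seq_len(nv), nu, nv, byrow = TRUE) + disp[, , 2]
  xi <- pmin(pmax(xi, 1), nu)
  i0 <- pmin(floor(xi), nu - 1); fx <- xi - i0
  j0f <- floor(yj); fy <- yj - j0f
  j0 <- ((as.integer(j0f) - 1L) %% nv) + 1L
  j1 <- (j0 %% nv) + 1L
  list(i0 = matrix(as.integer(i0), nu, nv), j0 = matrix(j0, nu, nv),
       j1 = matrix(j1, nu, nv), fx = fx, fy = fy)
}

# partial-volume joint histogram between hard-binned template pixels and the
# hard-binned moving image sampled at x + u with bilinear spatial weights
pv_joint_histogram <- function(t_bin, s_bin, nb, bins) {
  P <- numeric(bins * bins)
  acc <- function(si, w) {
    idx <- t_bin + bins * (si - 1L)
    t <- rowsum(as.vector(w), as.vector(idx))
    P[as.integer(rownames(t))] <<- P[as.integer(rownames(t))] + t
  }
  s00 <- matrix(s_bin[cbind(as.vector(nb$i0), as.vector(nb$j0))], nrow(t_bin))
  s10 <- matrix(s_bin[cbind(as.vector(nb$i0 + 1L), as.vector(nb$j0))], nrow(t_bin))
  s01 <- matrix(s_bin[cbind(as.vector(nb$i0), as.vector(nb$j1))], nrow(t_bin))
  s11 <- matrix(s_bin[cbind(as.vector(nb$i0 + 1L), as.vector(nb$j1))], nrow(t_bin))
  acc(s00, (1 - nb$fx) * (1 - nb$fy))
  acc(s10, nb$fx * (1 - nb$fy))
  acc(s01, (1 - nb$fx) * nb$fy)
  acc(s11, nb$fx * nb$fy)
  list(P = matrix(P / length(t_bin), bins, bins),
       s00 = s00, s10 = s10, s01 = s01, s11 = s11)
}


# separable Gaussian smoothing; periodic in v, reflected in u
gauss_smooth <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  nu <- nrow(img); nv <- ncol(img)
  # u direction with reflection padding
  up <- rbind(img[pmin(r:1, nu), , drop = FALSE], img,
              img[pmax(nu - (1:r) + 1, 1), , drop = FALSE])
  sm <- matrix(0, nu, nv)
  for (t in -r:r) sm <- sm + k[t + r + 1] * up[(r + 1 + t):(r + nu + t), , drop = FALSE]
  # v direction periodic
  out <- matrix(0, nu, nv)
  for (t in -r:r) {
    cols <- ((seq_len(nv) - 1 + t) %% nv) + 1
    out <- out + k[t + r + 1] * sm[, cols, drop = FALSE]
  }
  out
}

# compose displacement fields: total'(x) = inner(x) + outer(x + inner(x))
compose_displacement <- function(outer_disp, inner_disp) {
  out <- inner_disp
  for (k in 1:2) out[, , k] <- inner_disp[, , k] + warp_image(outer_disp[, , k], inner_disp)
  out
}

# downsample a matrix by 2 (mean of 2x2 blocks; v length must stay even-safe)
downsample2 <- function(img) {
  nu <- nrow(img); nv <- ncol(img)
  nu2 <- floor(nu / 2); nv2 <- floor(nv / 2)
  img <- img[seq_len(2 * nu2), seq_len(2 * nv2), drop = FALSE]
  0.25 * (img[seq(1, 2 * nu2, 2), seq(1, 2 * nv2, 2)] +
          img[seq(2, 2 * nu2, 2), seq(1, 2 * nv2, 2)] +
          img[seq(1, 2 * nu2, 2), seq(2, 2 * nv2, 2)] +
          img[seq(2, 2 * nu2, 2), seq(2, 2 * nv2, 2)])
}

# upsample a displacement field to dims `todims` (bilinear, periodic v),
# scaling the displacement magnitudes with the grid refinement
upsample_disp <- function(disp, todims) {
  nu0 <- dim(disp)[1]; nv0 <- dim(disp)[2]
  nu1 <- todims[1]; nv1 <- todims[2]
  su <- nu1 / nu0; sv <- nv1 / nv0
  xi <- (seq_len(nu1) - 0.5) / su + 0.5
  yj <- (seq_len(nv1) - 0.5) / sv + 0.5
  out <- array(0, c(nu1, nv1, 2L))
  for (k in 1:2) {
    m <- disp[, , k]
    x <- pmin(pmax(xi, 1), nu0)
    i0 <- pmin(floor(x), nu0 - 1); fx <- x - i0
    j0f <- floor(yj); fy <- yj - j0f
    j0 <- ((as.integer(j0f) - 1L) %% nv0) + 1L
    j1 <- (j0 %% nv0) + 1L
    g <- function(ii, jj) outer(seq_len(nu1), seq_len(nv1), function(a, b) m[cbind(ii[a], jj[b])])
    val <- g(as.integer(i0), j0) * outer(1 - fx, 1 - fy) +
           g(as.integer(i0) + 1L, j0) * outer(fx, 1 - fy) +
           g(as.integer(i0), j1) * outer(1 - fx, fy) +
           g(as.integer(i0) + 1L, j1) * outer(fx, fy)
    out[, , k] <- val * (if (k == 1) su else sv)
  }
  out
}

#' Viscous-fluid registration of conformal representations
#'
#' Registers a subject's two-channel (conformal factor, mean curvature)
#' representation to the template's by gradient ascent on the summed
#' per-channel mutual information. Each iteration computes the analytic
#' histogram-based MI gradient ("force"), smooths it with a Gaussian of
#' width `sigma_fluid` (the fluid approximation of the viscous solve),
#' and takes an explicit Euler step normalized so the largest update is at
#' most half a grid cell; steps that decrease MI are rejected with step
#' halving. When the incremental deformation's `det J` drops below
#' `regrid_threshold` the flow is composed into the total displacement and
#' restarted (regridding). A coarse-to-fine pyramid handles large
#' displacements. The u-component of the displacement is zeroed on the
#' first and last grid rows (cut points correspond by construction).
#'
#' @param subject_rep,template_rep [conformal_representation()] objects on
#'   identical grids.
#' @param params a [registration_params()] list.
#' @param seed unused placeholder for interface symmetry (the algorithm is
#'   deterministic); kept so pipeline seed plumbing is uniform.
#' @return an object of class `deformation_field`: list with `displacement`
#'   (`nu x nv x 2`, grid-cell units), `jacobian` (`nu x nv x 2 x 2`),
#'   `mi_trace` (accepted-step MI values), `converged`, `params`.
#' @export
fluid_register <- function(subject_rep, template_rep, params = registration_params(),
                           seed = NULL) {
  stopifnot(inherits(subject_rep, "conformal_representation"),
            inherits(template_rep, "conformal_representation"))
  if (!all(subject_rep$dims == template_rep$dims))
    stop_subshape("bad_argument", "representations must share grid dims")
  ch_s <- list(subject_rep$lambda, subject_rep$H)
  ch_t <- list(template_rep$lambda, template_rep$H)
  dims <- subject_rep$dims

  # pyramid (coarsest first)
  pyr_s <- list(ch_s); pyr_t <- list(ch_t)
  for (l in seq_len(params$levels - 1L)) {
    ch_s <- lapply(ch_s, downsample2)
    ch_t <- lapply(ch_t, downsample2)
    if (any(dim(ch_s[[1]]) < 8)) break
    pyr_s <- c(list(ch_s), pyr_s)
    pyr_t <- c(list(ch_t), pyr_t)
  }

  disp <- NULL
  mi_trace <- numeric(0)
  mi_seg <- integer(0)
  converged <- FALSE
  for (lev in seq_along(pyr_s)) {
    S <- pyr_s[[lev]]; Tm <- pyr_t[[lev]]
    d <- dim(S[[1]])
    disp <- if (is.null(disp)) array(0, c(d, 2L)) else upsample_disp(disp, d)
    res <- fluid_level(S, Tm, disp, params)
    disp <- res$disp
    off <- if (length(mi_seg)) max(mi_seg) else 0L
    mi_trace <- c(mi_trace, res$mi_trace)
    mi_seg <- c(mi_seg, res$mi_seg + off)
    converged <- res$converged
  }

  J <- jacobian_field(disp)
  dj <- det_j(J)
  if (any(dj <= 0))
    stop_subshape("registration_failed",
      sprintf("non-positive det J at %d node(s) after registration", sum(dj <= 0)))
  structure(list(displacement = disp, jacobian = J, mi_trace = mi_trace,
                 mi_segment = mi_seg, converged = converged, params = params),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  dj <- det_j(x$jacobian)
  cat(sprintf("deformation_field: %d x %d grid, converged = %s\n",
              dim(x$displacement)[1], dim(x$displacement)[2], x$converged))
  cat(sprintf("  max |displacement| %.3f cells, det J in [%.3f, %.3f], final MI %.4f bits\n",
              max(abs(x$displacement)), min(dj), max(dj),
              if (length(x$mi_trace)) x$mi_trace[length(x$mi_trace)] else NA))
  invisible(x)
}

fluid_level <- function(S, Tm, disp0, params) {
  bins <- min(params$bins, max(8L, floor(sqrt(length(S[[1]])))))
  t_bins <- lapply(Tm, hard_bins, bins = bins)
  t_rng <- lapply(Tm, range)
  s_rng <- lapply(S, range)
  total <- disp0                  # accumulated (regridded) displacement
  incr <- array(0, dim(disp0))    # current incremental flow
  S_cur <- lapply(S, warp_image, disp = total)
  s_bins <- mapply(hard_bins, S_cur, s_rng, MoreArgs = list(bins = bins),
                   SIMPLIFY = FALSE)
  # dispersion-corrected MI: the partial-volume histogram loses a little
  # entropy sharpness at fractional displacements regardless of alignment;
  # the template self-pair at the same displacement measures exactly that
  # loss, so adding it back leaves a metric whose gains reflect alignment
  # only (and which is exact, with zero correction, at zero displacement)
  self_mi0 <- vapply(t_bins, function(tb) {
    nb0 <- pv_neighbours(array(0, dim(disp0)))
    joint_mi(pv_joint_histogram(tb, tb, nb0, bins)$P)
  }, 0)
  total_mi <- function(d) {
    nb <- pv_neighbours(d)
    mi <- 0
    for (c in seq_along(S)) {
      h <- pv_joint_histogram(t_bins[[c]], s_bins[[c]], nb, bins)
      hs <- pv_joint_histogram(t_bins[[c]], t_bins[[c]], nb, bins)
      mi <- mi + joint_mi(h$P) + (self_mi0[c] - joint_mi(hs$P))
    }
    mi
  }
  cur_mi <- total_mi(incr)
  mi_trace <- cur_mi
  seg <- 1L
  mi_seg <- seg
  step <- params$step
  n_bad <- 0L
  converged <- FALSE

  for (it in seq_len(params$max_iter)) {
    # force: smooth Parzen-style MI gradient (progress itself is measured
    # on the partial-volume histogram, which is exact at alignment)
    fu <- matrix(0, nrow(S[[1]]), ncol(S[[1]]))
    fv <- fu
    for (c in seq_along(S)) {
      W <- warp_image(S_cur[[c]], incr)
      gI <- mi_intensity_gradient(Tm[[c]], W, bins, t_rng[[c]], s_rng[[c]])
      gW <- image_gradient(W)
      fu <- fu + gI * gW$gu
      fv <- fv + gI * gW$gv
    }
    vu <- gauss_smooth(fu, params$sigma_fluid)
    vv <- gauss_smooth(fv, params$sigma_fluid)
    vu[1, ] <- 0; vu[nrow(vu), ] <- 0     # cut points fixed in u
    vmax <- max(abs(c(vu, vv)))
    if (vmax < 1e-12) { converged <- TRUE; break }
    scale <- step * min(1, 0.5 / vmax)
    cand <- incr
    cand[, , 1] <- incr[, , 1] + scale * vu
    cand[, , 2] <- incr[, , 2] + scale * vv
    new_mi <- total_mi(cand)
    if (new_mi > cur_mi + 1e-12) {
      rel <- (new_mi - cur_mi) / max(abs(cur_mi), 1e-12)
      incr <- cand
      cur_mi <- new_mi
      mi_trace <- c(mi_trace, cur_mi)
      mi_seg <- c(mi_seg, seg)
      n_bad <- 0L
      step <- min(step * 1.2, params$step * 4)
      dj <- det_j(jacobian_field(incr))
      if (min(dj) < params$regrid_threshold) {
        total <- compose_displacement(total, incr)
        S_cur <- lapply(S, warp_image, disp = total)
        s_bins <- mapply(hard_bins, S_cur, s_rng, MoreArgs = list(bins = bins),
                         SIMPLIFY = FALSE)
        incr <- array(0, dim(incr))
        djt <- det_j(jacobian_field(total))
        if (any(djt <= 0))
          stop_subshape("registration_failed",
                        "non-positive det J after regridding")
        cur_mi <- total_mi(incr)
        seg <- seg + 1L
      }
      if (rel < params$tol) { converged <- TRUE; break }
    } else {
      step <- step / 2
      n_bad <- n_bad + 1L
      if (n_bad >= 10L) { converged <- TRUE; break }
    }
  }
  list(disp = compose_displacement(total, incr), mi_trace = mi_trace,
       mi_seg = mi_seg, converged = converged)
}
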