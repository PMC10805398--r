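#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic cohort of subcortical-like surfaces: a template
#' shape, per-group sample sizes, localized radial group effects with known
#' ground truth, smooth per-subject shape noise, and clinical scores
#' correlated with the realized deformation.
#'
#' @param structure_kind `"hippocampus_like"` (tube swept along a C-shaped
#'   centerline) or `"amygdala_like"` (smoothed superellipsoid).
#' @param n_per_group named integer vector of group sizes (>= 2 each); the
#'   first group is the reference (no implanted effect).
#' @param effect_regions list of regions, each a list with elements
#'   `u = c(u0, u1)` (within `[0,1]`), `v = c(v0, v1)` (radians, may wrap),
#'   `delta` (radial offset magnitude, mm) and `sign` (`"atrophy"` shrinks
#'   the radius, `"expansion"` grows it). The offset is full strength in the
#'   region core and tapers to zero at the edges with a raised-cosine
#'   falloff.
#' @param noise_sd standard deviation (mm) of the smooth per-subject radial
#'   noise field (low-order harmonics, bands <= 8 in u and v).
#' @param score_spec list of per-score specs `list(name, mean, sd, rho)`;
#'   `rho` is the target correlation with the subject's realized mean
#'   radial deformation inside the effect regions.
#' @param grid_dims grid dimensions `c(nu, nv)`.
#' @param seed integer seed controlling all randomness of the cohort.
#' @param taper_frac fraction of each region side used for the raised-cosine
#'   falloff (default 0.25).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(structure_kind = c("hippocampus_like", "amygdala_like"),
                              n_per_group = c(HC = 30L, PD = 30L),
                              effect_regions = list(),
                              noise_sd = 0.3,
                              score_spec = list(),
                              grid_dims = c(100L, 150L),
                              seed = 1L,
                              taper_frac = 0.25) {
  structure_kind <- match.arg(structure_kind)
  if (length(n_per_group) < 2L || any(n_per_group < 2L))
    stop_subshape("bad_config", "need >= 2 groups with n >= 2 each")
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("group", seq_along(n_per_group))
  if (noise_sd < 0) stop_subshape("bad_config", "noise_sd must be >= 0")
  for (r in effect_regions) {
    if (!all(c("u", "v", "delta", "sign") %in% names(r)))
      stop_subshape("bad_config", "each region needs u, v, delta, sign")
    if (r$u[1] < 0 || r$u[2] > 1 || r$u[1] >= r$u[2])
      stop_subshape("bad_config", "region u range must be inside [0, 1]")
    if (!r$sign %in% c("atrophy", "expansion"))
      stop_subshape("bad_config", "region sign must be 'atrophy' or 'expansion'")
    if (r$delta < 0) stop_subshape("bad_config", "delta is a magnitude; use sign")
  }
  structure(list(structure_kind = structure_kind,
                 n_per_group = as.integer(round(n_per_group)) |>
                   stats::setNames(names(n_per_group)),
                 effect_regions = effect_regions, noise_sd = noise_sd,
                 score_spec = score_spec, grid_dims = as.integer(grid_dims),
                 seed = as.integer(seed), taper_frac = taper_frac),
            class = "simulation_config")
}

# Analytic template geometry: centerline, cross-section frame and base
# radius function r0(u, v). Radii in mm.
template_geometry <- function(kind, seed = 1L) {
  # small deterministic harmonic perturbation so different seeds give
  # slightly different but equally valid templates
  pert <- with_seed(seed * 7919L + 13L, {
    list(a = rnorm(3, 0, 0.1), ph = runif(3, 0, 2 * pi))
  })
  if (kind == "hippocampus_like") {
    Rc <- 18                      # centerline arc radius (mm)
    phi0 <- -1.05; phi1 <- 1.05   # C-shaped sweep (rad)
    centerline <- function(u) {
      phi <- phi0 + (phi1 - phi0) * u
      cbind(Rc * sin(phi), 0, -Rc * cos(phi) + Rc)
    }
    frame <- function(u) {
      phi <- phi0 + (phi1 - phi0) * u
      list(N = cbind(sin(phi), 0, -cos(phi)),                      # in-plane radial
           B = cbind(0, 1, 0)[rep(1, length(u)), , drop = FALSE]) # out-of-plane
    }
    radius <- function(u, v) {
      base <- 4.6 * sin(pi * u)^0.6 * (1 + 0.18 * sin(pi * u))
      ell <- 1 + 0.18 * cos(2 * v)
      p <- 1 + pert$a[1] * sin(2 * pi * u + pert$ph[1]) * sin(v + pert$ph[2])
      base * ell * p
    }
    min_radius_limit <- Rc * (phi1 - phi0)  # curvature guard scale
  } else {
    a <- 9                        # half-length along the long axis (mm)
    centerline <- function(u) cbind(a * (2 * u - 1), 0, 0)
    frame <- function(u) list(N = cbind(0, 1, 0)[rep(1, length(u)), , drop = FALSE],
                              B = cbind(0, 0, 1)[rep(1, length(u)), , drop = FALSE])
    radius <- function(u, v) {
      p_exp <- 2.5
      s <- (1 - abs(2 * u - 1)^p_exp)^(1 / p_exp)
      b <- 7; cc <- 5.5
      ell <- sqrt((b * cos(v))^2 + (cc * sin(v))^2)
      p <- 1 + pert$a[2] * sin(2 * pi * u + pert$ph[2]) * sin(v + pert$ph[3])
      s * ell * p
    }
    min_radius_limit <- Inf
  }
  list(kind = kind, centerline = centerline, frame = frame, radius = radius,
       min_radius_limit = min_radius_limit)
}

# evaluate a radial template/subject surface on the parameter grid;
# radial_extra is an nu x nv matrix added to the base radius.
eval_radial_surface <- function(geom, nu, nv, radial_extra = NULL) {
  us <- grid_u(nu)
  vs <- grid_v(nv)
  C <- geom$centerline(us)
  fr <- geom$frame(us)
  pos <- array(0, c(nu, nv, 3L))
  r <- outer(us, vs, geom$radius)
  if (!is.null(radial_extra)) r <- r + radial_extra
  if (any(r <= 0.05))
    stop_subshape("self_intersection",
      "radial offsets drive the surface through its medial axis (radius <= 0.05 mm)")
  cosv <- cos(vs); sinv <- sin(vs)
  for (k in 1:3) {
    pos[, , k] <- C[, k] + r * (outer(fr$N[, k], cosv) + outer(fr$B[, k], sinv))
  }
  list(positions = pos, radius = r)
}

# closed mesh from a radial grid: nu rings of nv vertices plus two poles
radial_grid_mesh <- function(geom, pos) {
  nu <- dim(pos)[1]; nv <- dim(pos)[2]
  v <- matrix(aperm(pos, c(2, 1, 3)), ncol = 3L)   # ring-major: (i-1)*nv + j
  idx <- function(i, j) (i - 1L) * nv + ((j - 1L) %% nv) + 1L
  i <- rep(seq_len(nu - 1L), each = nv)
  j <- rep(seq_len(nv), times = nu - 1L)
  a <- idx(i, j); b <- idx(i, j + 1L); cc <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
  f <- rbind(cbind(a, b, d), cbind(a, d, cc))
  poles <- geom$centerline(c(0, 1))
  np <- nu * nv
  v <- rbind(v, poles)
  j <- seq_len(nv)
  f <- rbind(f,
             cbind(np + 1L, idx(1L, j + 1L), idx(1L, j)),
             cbind(np + 2L, idx(nu, j), idx(nu, j + 1L)))
  validate_mesh(triangle_mesh(v, f))
}

# H of a parametric surface by finite-difference fundamental forms
parametric_mean_curvature <- function(posfun, us, vs, h = 1e-4) {
  P  <- posfun(us, vs)
  Pu1 <- posfun(us + h, vs); Pu0 <- posfun(us - h, vs)
  Pv1 <- posfun(us, vs + h); Pv0 <- posfun(us, vs - h)
  Xu <- (Pu1 - Pu0) / (2 * h); Xv <- (Pv1 - Pv0) / (2 * h)
  Xuu <- (Pu1 - 2 * P + Pu0) / h^2
  Xvv <- (Pv1 - 2 * P + Pv0) / h^2
  Puv1 <- posfun(us + h, vs + h); Puv2 <- posfun(us - h, vs - h)
  Puv3 <- posfun(us + h, vs - h); Puv4 <- posfun(us - h, vs + h)
  Xuv <- (Puv1 + Puv2 - Puv3 - Puv4) / (4 * h^2)
  dot <- function(A, B) apply(A * B, c(1, 2), sum)
  E <- dot(Xu, Xu); Fm <- dot(Xu, Xv); G <- dot(Xv, Xv)
  nrm <- array(0, dim(P))
  cr <- function(A, B, k1, k2) A[, , k1] * B[, , k2] - A[, , k2] * B[, , k1]
  nrm[, , 1] <- cr(Xu, Xv, 2, 3); nrm[, , 2] <- cr(Xu, Xv, 3, 1); nrm[, , 3] <- cr(Xu, Xv, 1, 2)
  nlen <- sqrt(dot(nrm, nrm))
  for (k in 1:3) nrm[, , k] <- nrm[, , k] / pmax(nlen, 1e-300)
  L <- dot(Xuu, nrm); M <- dot(Xuv, nrm); N <- dot(Xvv, nrm)
  Hm <- (E * N - 2 * Fm * M + G * L) / (2 * pmax(E * G - Fm^2, 1e-300))
  # orient against the outward normal (outward = away from the centerline)
  Hm
}

# conformal grid of a radial surface with analytic positions
radial_surface_grid <- function(geom, nu, nv, radial_extra = NULL) {
  ev <- eval_radial_surface(geom, nu, nv, radial_extra)
  interp_extra <- function(us, vs) {
    if (is.null(radial_extra)) return(0)
    # bilinear interpolation of the extra radial field (periodic in v)
    gu <- grid_u(nu); gv <- grid_v(nv)
    ui <- pmin(pmax((us - gu[1]) / (gu[2] - gu[1]) + 1, 1), nu)
    vi <- (vs - gv[1]) / (gv[2] - gv[1]) + 1
    u0 <- pmin(floor(ui), nu - 1); fu <- ui - u0
    v0 <- floor(vi); fv <- vi - v0
    vwrap <- function(i) ((as.integer(i) - 1L) %% nv) + 1L
    outer_idx <- function(uu, vv) radial_extra[cbind(rep(uu, length(vv)),
                                                     rep(vwrap(vv), each = length(uu)))]
    m00 <- matrix(outer_idx(u0, v0), length(us), length(vs))
    m10 <- matrix(outer_idx(u0 + 1, v0), length(us), length(vs))
    m01 <- matrix(outer_idx(u0, v0 + 1), length(us), length(vs))
    m11 <- matrix(outer_idx(u0 + 1, v0 + 1), length(us), length(vs))
    FU <- matrix(fu, length(us), length(vs))
    FV <- matrix(fv, length(us), length(vs), byrow = TRUE)
    m00 * (1 - FU) * (1 - FV) + m10 * FU * (1 - FV) +
      m01 * (1 - FU) * FV + m11 * FU * FV
  }
  posfun <- function(us, vs) {
    C <- geom$centerline(us)
    fr <- geom$frame(us)
    r <- outer(us, vs, geom$radius) + interp_extra(us, vs)
    out <- array(0, c(length(us), length(vs), 3L))
    for (k in 1:3) {
      out[, , k] <- C[, k] + r * (outer(fr$N[, k], cos(vs)) + outer(fr$B[, k], sin(vs)))
    }
    out
  }
  H <- parametric_mean_curvature(posfun, grid_u(nu), grid_v(nv))
  lambda <- grid_lambda(ev$positions)
  conformal_grid(ev$positions, lambda, H, periodic_v = TRUE,
                 metadata = list(analytic = TRUE, kind = geom$kind))
}

#' Analytic template surface
#'
#' Builds a smooth, closed, genus-zero template mesh of the requested kind
#' together with its exact parameterization as a [conformal_grid()]
#' (positions known in closed form; curvature from the parametric
#' fundamental forms).
#'
#' @param kind `"hippocampus_like"` or `"amygdala_like"`.
#' @param grid_dims `c(nu, nv)` grid dimensions.
#' @param seed integer; seeds a small deterministic harmonic perturbation of
#'   the template shape.
#' @return list with elements `mesh` ([triangle_mesh()]) and `grid`
#'   ([conformal_grid()]).
#' @examples
#' tpl <- make_template_surface("hippocampus_like", c(40, 60), seed = 1)
#' euler_characteristic(tpl$mesh)
#' @export
make_template_surface <- function(kind = c("hippocampus_like", "amygdala_like"),
                                  grid_dims = c(100L, 150L), seed = 1L) {
  kind <- match.arg(kind)
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 2L || any(grid_dims < 8L))
    stop_subshape("bad_argument", "grid_dims must be two integers >= 8")
  geom <- template_geometry(kind, seed)
  ev <- eval_radial_surface(geom, grid_dims[1], grid_dims[2])
  mesh <- radial_grid_mesh(geom, ev$positions)
  grid <- radial_surface_grid(geom, grid_dims[1], grid_dims[2])
  list(mesh = mesh, grid = grid, geometry = geom)
}

# smooth radial noise field: low-order separable harmonics, sd = noise_sd
smooth_noise_field <- function(nu, nv, noise_sd, max_band = 8L) {
  if (noise_sd == 0) return(matrix(0, nu, nv))
  us <- grid_u(nu); vs <- grid_v(nv)
  field <- matrix(0, nu, nv)
  for (k in 0:max_band) {
    bu <- if (k == 0) rep(1, nu) else cos(k * pi * us)
    for (l in 0:max_band) {
      if (k == 0 && l == 0) next   # no global size term
      w <- 1 / (1 + k + l)
      if (l == 0) {
        field <- field + rnorm(1, 0, w) * outer(bu, rep(1, nv))
      } else {
        field <- field + rnorm(1, 0, w) * outer(bu, cos(l * vs)) +
                         rnorm(1, 0, w) * outer(bu, sin(l * vs))
      }
    }
  }
  # taper to zero over the outer 12% of u so the pinched pole ends stay
  # intact, then rescale to the requested grid-wide sd
  ramp <- pmin(1, pmin(us, 1 - us) / 0.12)
  taper <- 0.5 * (1 - cos(pi * ramp))
  field <- field * taper
  field * (noise_sd / stats::sd(as.vector(field)))
}

# raised-cosine region weight on the parameter grid (v may wrap)
region_weight <- function(region, nu, nv, taper_frac = 0.25) {
  us <- grid_u(nu); vs <- grid_v(nv)
  taper1d <- function(x, lo, hi, frac) {
    w <- numeric(length(x))
    len <- hi - lo
    t <- frac * len
    core_lo <- lo + t; core_hi <- hi - t
    w[x >= core_lo & x <= core_hi] <- 1
    ramp_in <- x >= lo & x < core_lo
    w[ramp_in] <- 0.5 * (1 - cos(pi * (x[ramp_in] - lo) / t))
    ramp_out <- x > core_hi & x <= hi
    w[ramp_out] <- 0.5 * (1 - cos(pi * (hi - x[ramp_out]) / t))
    w
  }
  wu <- taper1d(us, region$u[1], region$u[2], taper_frac)
  v0 <- region$v[1] %% (2 * pi); v1 <- region$v[2] %% (2 * pi)
  if (v1 <= v0) {  # wrapping region: evaluate on unwrapped copy
    vshift <- ifelse(vs < v0, vs + 2 * pi, vs)
    wv <- taper1d(vshift, v0, v1 + 2 * pi, taper_frac)
  } else {
    wv <- taper1d(vs, v0, v1, taper_frac)
  }
  outer(wu, wv)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Each subject is the template deformed by (a) a smooth radial noise field
#' and (b), for non-reference groups, the configured radial effects with a
#' raised-cosine falloff. Clinical scores are drawn with the configured
#' correlation to the subject's realized mean deformation inside the effect
#' regions.
#'
#' @param config a [simulation_config()].
#' @param meshes if `TRUE` (default) build a closed mesh per subject; the
#'   analytic per-subject [conformal_grid()]s are always returned.
#' @return an object of class `synthetic_cohort`: list with `meshes`,
#'   `grids`, `labels` (factor), `scores` (data.frame), and `truth` (list
#'   with `effect_mask`, `true_delta`, `deformation` per subject means,
#'   `config`).
#' @export
simulate_cohort <- function(config, meshes = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  nu <- config$grid_dims[1]; nv <- config$grid_dims[2]
  geom <- template_geometry(config$structure_kind, config$seed)

  true_delta <- matrix(0, nu, nv)
  for (r in config$effect_regions) {
    s <- if (r$sign == "atrophy") -1 else 1
    true_delta <- true_delta + s * r$delta * region_weight(r, nu, nv, config$taper_frac)
  }
  effect_mask <- abs(true_delta) > 0

  labels <- factor(rep(names(config$n_per_group), config$n_per_group),
                   levels = names(config$n_per_group))
  n_total <- length(labels)
  ref_group <- names(config$n_per_group)[1]

  subj <- with_seed(config$seed, {
    lapply(seq_len(n_total), function(i) {
      noise <- smooth_noise_field(nu, nv, config$noise_sd)
      extra <- noise + if (labels[i] == ref_group) 0 else true_delta
      list(extra = extra)
    })
  })

  grids <- lapply(subj, function(s) radial_surface_grid(geom, nu, nv, s$extra))
  mesh_list <- if (meshes) {
    lapply(subj, function(s) {
      ev <- eval_radial_surface(geom, nu, nv, s$extra)
      radial_grid_mesh(geom, ev$positions)
    })
  } else NULL

  # realized mean deformation inside the effect regions
  defo <- vapply(subj, function(s) {
    if (any(effect_mask)) mean(s$extra[effect_mask]) else mean(s$extra)
  }, 0)

  scores <- data.frame(subject = sprintf("S%03d", seq_len(n_total)),
                       group = labels)
  if (length(config$score_spec)) {
    zdef <- as.vector(scale(defo))
    scores_draw <- with_seed(config$seed + 1L, {
      lapply(config$score_spec, function(sp) {
        eps <- rnorm(n_total)
        sp$mean + sp$sd * (sp$rho * zdef + sqrt(1 - sp$rho^2) * eps)
      })
    })
    for (k in seq_along(config$score_spec)) {
      scores[[config$score_spec[[k]]$name]] <- scores_draw[[k]]
    }
  }

  structure(list(meshes = mesh_list, grids = grids, labels = labels,
                 scores = scores,
                 truth = list(effect_mask = effect_mask, true_delta = true_delta,
                              deformation = defo, config = config)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("synthetic_cohort: %s, %s subjects (%s), grid %d x %d\n",
              cfg$structure_kind, length(x$labels),
              paste(sprintf("%s=%d", names(cfg$n_per_group), cfg$n_per_group),
                    collapse = ", "),
              cfg$grid_dims[1], cfg$grid_dims[2]))
  cat(sprintf("  %d effect region(s), noise sd %.3g mm, %d truth-mask node(s)\n",
              length(cfg$effect_regions), cfg$noise_sd, sum(x$truth$effect_mask)))
  invisible(x)
}

# run-length encode a logical vector (column-major over the grid)
rle_encode <- function(mask) {
  r <- rle(as.vector(mask))
  list(lengths = r$lengths, values = r$values, dims = dim(mask))
}

#' Write a synthetic cohort to disk
#'
#' Meshes as binary PLY, ground truth as JSON (masks run-length encoded),
#' scores and labels as TSV.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$meshes)) {
    for (i in seq_along(cohort$meshes)) {
      write_mesh(cohort$meshes[[i]], file.path(dir, sprintf("subject_%03d.ply", i)))
    }
  }
  truth <- list(
    effect_mask = rle_encode(cohort$truth$effect_mask),
    true_delta = as.vector(cohort$truth$true_delta),
    dims = dim(cohort$truth$true_delta),
    labels = as.character(cohort$labels),
    deformation = cohort$truth$deformation)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(cohort$scores, file.path(dir, "scores.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
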