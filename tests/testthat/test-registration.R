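# smooth test warp with fixed u-boundary, amplitude in grid cells
make_warp <- function(nu, nv, amp = 2.0) {
  us <- matrix(seq(0, 1, length.out = nu), nu, nv)
  vs <- matrix(seq(0, 2 * pi, length.out = nv + 1)[seq_len(nv)], nu, nv,
               byrow = TRUE)
  w <- array(0, c(nu, nv, 2L))
  w[, , 1] <- amp * sin(pi * us) * sin(vs)
  w[, , 2] <- amp * sin(pi * us) * cos(2 * vs)
  w[1, , 1] <- 0
  w[nu, , 1] <- 0
  w
}

textured_rep <- function(seed = 11L) {
  cfg <- simulation_config(n_per_group = c(HC = 2L, PD = 2L), noise_sd = 0.35,
                           grid_dims = c(40L, 60L), seed = seed)
  co <- cached_cohort(paste0("reg", seed), cfg)
  conformal_representation(co$grids[[1]])
}

warped_copy <- function(rep, w) {
  out <- rep
  out$lambda <- subshape:::warp_image(rep$lambda, w)
  out$H <- subshape:::warp_image(rep$H, w)
  out
}

test_that("mutual information satisfies its information-theoretic identities", {
  set.seed(1)
  # bin-centre-aligned image: the partial-volume histogram is exact and
  # the identity MI(X, X) = H(X) holds to floating precision
  X <- matrix(round(runif(10000) * 31) / 31, 100, 100)
  P <- subshape:::joint_histogram(as.vector(X), as.vector(X), 32)
  pa <- rowSums(P)
  hx <- -sum(pa[pa > 0] * log2(pa[pa > 0]))
  expect_equal(mutual_information(X, X, 32), hx, tolerance = 1e-9)
  Y <- matrix(runif(10000), 100, 100)
  expect_lt(mutual_information(X, Y, 32), 0.05)
  expect_warning(mi0 <- mutual_information(matrix(1, 10, 10), Y[1:10, 1:10]),
                 "constant")
  expect_equal(mi0, 0)
})

test_that("MI of the printed 2x2 joint table is 0.278 bits", {
  # joint counts {(0,0): 40, (0,1): 10, (1,0): 10, (1,1): 40}
  a <- rep(c(0, 0, 1, 1), times = c(40, 10, 10, 40))
  b <- rep(c(0, 1, 0, 1), times = c(40, 10, 10, 40))
  expect_equal(mutual_information(a, b, bins = 2L), 0.278, tolerance = 5e-4)
})

test_that("Jacobian fields match closed forms", {
  d0 <- array(0, c(20, 30, 2))
  J <- jacobian_field(d0)
  expect_true(all(abs(subshape:::det_j(J) - 1) < 1e-12))

  a <- 1.1
  d1 <- array(0, c(20, 30, 2))
  d1[, , 1] <- (a - 1) * matrix(1:20, 20, 30)
  d1[, , 2] <- (a - 1) * matrix(1:30, 20, 30, byrow = TRUE)
  dj <- subshape:::det_j(jacobian_field(d1))
  expect_true(all(abs(dj[2:19, 2:29] - a^2) < 1e-6))

  # smooth analytic warp: central differences against the true derivatives
  nu <- 100; nv <- 150
  iu <- matrix(seq_len(nu), nu, nv)
  jv <- matrix(seq_len(nv), nu, nv, byrow = TRUE)
  d2 <- array(0, c(nu, nv, 2))
  d2[, , 1] <- 1e-3 * iu^2 + 0.5 * sin(2 * pi * jv / nv)
  d2[, , 2] <- 0.8 * cos(2 * pi * jv / nv) + 2e-3 * iu^2
  J2 <- jacobian_field(d2)
  expect_equal(J2[2:(nu - 1), , 1, 1], 1 + 2e-3 * iu[2:(nu - 1), ],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(J2[, , 1, 2], 0.5 * (2 * pi / nv) * cos(2 * pi * jv / nv),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(J2[, , 2, 2], 1 - 0.8 * (2 * pi / nv) * sin(2 * pi * jv / nv),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("registering a representation to itself is an exact fixed point", {
  rep <- textured_rep()
  df <- fluid_register(rep, rep, registration_params(levels = 2L, max_iter = 50L))
  expect_true(all(df$displacement == 0))
  expect_true(all(abs(subshape:::det_j(df$jacobian) - 1) < 1e-6))
  expect_true(df$converged)
})

test_that("a known smooth warp is recovered to sub-cell accuracy", {
  rep <- textured_rep()
  w <- make_warp(40, 60, amp = 2.0)
  subj <- warped_copy(rep, w)
  df <- fluid_register(subj, rep,
                       registration_params(levels = 3L, max_iter = 200L))
  eu <- df$displacement[, , 1] + subshape:::warp_image(w[, , 1], df$displacement)
  ev <- df$displacement[, , 2] + subshape:::warp_image(w[, , 2], df$displacement)
  expect_lt(mean(sqrt(eu^2 + ev^2)), 0.5)
  expect_true(all(subshape:::det_j(df$jacobian) > 0))
  # ascent contract: monotone within each metric segment, net gain overall
  mono <- tapply(df$mi_trace, df$mi_segment,
                 function(x) all(diff(x) >= -1e-9))
  expect_true(all(mono))
  last_seg <- df$mi_trace[df$mi_segment == max(df$mi_segment)]
  expect_gte(last_seg[length(last_seg)], last_seg[1])
})

test_that("forward and backward registrations approximately invert", {
  rep <- textured_rep()
  w <- make_warp(40, 60, amp = 1.5)
  subj <- warped_copy(rep, w)
  p <- registration_params(levels = 2L, max_iter = 120L)
  ab <- fluid_register(subj, rep, p)
  ba <- fluid_register(rep, subj, p)
  comp <- subshape:::compose_displacement(ba$displacement, ab$displacement)
  expect_lt(mean(sqrt(comp[, , 1]^2 + comp[, , 2]^2)), 1)
})

test_that("registration parameter validation", {
  expect_error(registration_params(bins = 4), class = "bad_argument")
  expect_error(registration_params(sigma_fluid = 0), class = "bad_argument")
  expect_error(registration_params(regrid_threshold = 1.2), class = "bad_argument")
})
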