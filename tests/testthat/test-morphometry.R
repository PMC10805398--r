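# analytic straight elliptic tube as a conformal_grid
tube_grid <- function(nu = 20, nv = 36, a = 3, b = 3, L = 10) {
  us <- subshape:::grid_u(nu)
  vs <- subshape:::grid_v(nv)
  pos <- array(0, c(nu, nv, 3))
  pos[, , 1] <- outer(rep(1, nu), a * cos(vs))
  pos[, , 2] <- outer(rep(1, nu), b * sin(vs))
  pos[, , 3] <- outer(L * us, rep(1, nv))
  conformal_grid(pos, subshape:::grid_lambda(pos), matrix(1 / (2 * a), nu, nv))
}

identity_J <- function(nu, nv) {
  J <- array(0, c(nu, nv, 2, 2))
  J[, , 1, 1] <- 1
  J[, , 2, 2] <- 1
  J
}

test_that("radial distance equals the tube radius and is rigid-motion invariant", {
  g <- tube_grid(a = 3, b = 3)
  RD <- radial_distance(g)
  expect_true(all(abs(RD - 3) < 1e-9))

  g2 <- g
  for (k in 1:3) g2$positions[, , k] <- g$positions[, , k] + c(10, 10, 10)[k]
  expect_equal(radial_distance(g2), RD, tolerance = 1e-12)

  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g3 <- g
  pts <- matrix(aperm(g$positions, c(3, 1, 2)), nrow = 3)
  rot <- R %*% pts
  g3$positions <- aperm(array(rot, c(3, dim(g$positions)[1:2])), c(2, 3, 1))
  expect_equal(radial_distance(g3), RD, tolerance = 1e-9)
})

test_that("elliptic rings reproduce the analytic point-to-centre distances", {
  g <- tube_grid(a = 2, b = 1)
  RD <- radial_distance(g)
  vs <- subshape:::grid_v(36)
  expected <- sqrt((2 * cos(vs))^2 + sin(vs)^2)
  for (i in c(1, 10, 20)) {
    expect_equal(unname(RD[i, ]), expected, tolerance = 1e-9)
  }
  expect_true(min(RD) > 0.99 && max(RD) < 2.01)
})

test_that("degenerate rings raise a structured error", {
  g <- tube_grid()
  g$positions[5, , 1] <- 0
  g$positions[5, , 2] <- 0   # ring collapses to a point on the axis
  expect_error(radial_distance(g), class = "degenerate_ring")
})

test_that("TBM is det J with its closed forms", {
  J <- identity_J(10, 12)
  expect_true(all(tbm(J) == 1))
  Js <- J
  Js[, , 1, 1] <- 1.2
  Js[, , 2, 2] <- 1.2
  expect_true(all(abs(tbm(Js) - 1.44) < 1e-6))
  set.seed(4)
  Jr <- array(rnorm(10 * 12 * 4, sd = 0.2), c(10, 12, 2, 2))
  Jr[, , 1, 1] <- Jr[, , 1, 1] + 1.5
  Jr[, , 2, 2] <- Jr[, , 2, 2] + 1.5
  oracle <- Jr[, , 1, 1] * Jr[, , 2, 2] - Jr[, , 1, 2] * Jr[, , 2, 1]
  expect_identical(tbm(Jr), oracle)
  Jbad <- J
  Jbad[3, 3, 1, 1] <- -1
  expect_error(tbm(Jbad), class = "registration_failed")
})

test_that("mTBM is the isometric vectorization of log(J J^T)", {
  J <- identity_J(5, 6)
  expect_true(all(mtbm(J) == 0))

  Je <- identity_J(5, 6)
  Je[, , 1, 1] <- exp(1)
  Je[, , 2, 2] <- exp(1)
  m <- mtbm(Je)
  expect_equal(m[, , 1], matrix(2, 5, 6), tolerance = 1e-12)
  expect_equal(m[, , 2], matrix(0, 5, 6), tolerance = 1e-12)
  expect_equal(m[, , 3], matrix(2, 5, 6), tolerance = 1e-12)

  set.seed(7)
  Jr <- array(rnorm(5 * 6 * 4, sd = 0.3), c(5, 6, 2, 2))
  Jr[, , 1, 1] <- Jr[, , 1, 1] + 1.4
  Jr[, , 2, 2] <- Jr[, , 2, 2] + 1.4
  m <- mtbm(Jr)
  for (i in 1:5) for (j in 1:6) {
    Jm <- matrix(Jr[i, j, , ], 2, 2)
    S <- Jm %*% t(Jm)
    e <- eigen(S, symmetric = TRUE)
    L <- e$vectors %*% diag(log(e$values)) %*% t(e$vectors)
    # vector norm equals the Frobenius norm of the matrix log
    expect_equal(sqrt(sum(m[i, j, ]^2)), sqrt(sum(L^2)), tolerance = 1e-10)
    # log-det identity: det(J)^2 = exp(L11 + L22)
    expect_equal(det(Jm)^2, exp(m[i, j, 1] + m[i, j, 3]), tolerance = 1e-8)
  }
})

test_that("MMS concatenates RD and mTBM bitwise in the right order", {
  g <- tube_grid()
  RD <- radial_distance(g)
  set.seed(2)
  Jr <- identity_J(20, 36)
  Jr[, , 1, 2] <- rnorm(20 * 36, sd = 0.1)
  mT <- mtbm(Jr)
  M <- mms(RD, mT)
  expect_equal(dim(M)[3], 4L)
  expect_identical(M[, , 1], RD)
  expect_identical(M[, , 2:4], mT)

  vf <- vertex_features(g, NULL)
  expect_true(all(vf$TBM == 1))
  expect_identical(vf$MMS[, , 1], vf$RD)
  lg <- features_long(vf, "S007")
  expect_equal(nrow(lg), 20 * 36 * 5)
  expect_setequal(unique(lg$channel), c("RD", "TBM", "mTBM1", "mTBM2", "mTBM3"))
})
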