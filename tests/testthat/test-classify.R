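test_that("patch layouts honour their contracts", {
  lay <- generate_patches(c(100L, 150L))
  expect_equal(nrow(lay), 1008L)
  expect_true(all(lay$u0 >= 1 & lay$u0 + lay$side - 1 <= 100))
  expect_identical(lay, generate_patches(c(100L, 150L)))

  one <- generate_patches(c(30L, 30L), n_patches = 1L, side = 30L,
                          periodic_v = FALSE)
  expect_equal(one$u0, 1L)
  expect_equal(one$v0, 1L)
  expect_error(generate_patches(c(10L, 40L), side = 20L), class = "bad_argument")
})

test_that("patch extraction flattens and round-trips blocks exactly", {
  set.seed(1)
  A <- array(rnorm(40 * 60 * 4), c(40, 60, 4))
  lay <- generate_patches(c(40L, 60L), 12L, side = 8L, seed = 2)
  pm <- extract_patch_features(A, lay)
  expect_equal(ncol(pm), 8 * 8 * 4)
  for (p in c(1, 7, 12)) {
    ui <- lay$u0[p] + 0:7
    vi <- ((lay$v0[p] + 0:7 - 1) %% 60) + 1
    expect_identical(subshape:::unflatten_patch(pm[p, ], 8, 4), A[ui, vi, ])
  }
  const <- array(2.5, c(40, 60, 4))
  pmc <- extract_patch_features(const, lay)
  expect_true(all(pmc == 2.5))
  side30 <- generate_patches(c(100L, 150L), 3L, side = 30L, seed = 1)
  expect_equal(ncol(extract_patch_features(array(0, c(100, 150, 4)), side30)),
               3600L)
})

test_that("sparse encoding solves the LASSO to proximal-gradient accuracy", {
  set.seed(9)
  # one-hot recovery at vanishing penalty (well-conditioned dictionary:
  # in the heavily over-complete regime the near-zero-penalty problem is
  # numerically degenerate for any solver)
  D1 <- matrix(rnorm(60 * 20), 60, 20)
  D1 <- sweep(D1, 2, sqrt(colSums(D1^2)), "/")
  z <- sparse_encode(matrix(D1[, 7], 1), D1, gamma = 1e-8)
  expect_lt(max(abs(z - replace(rep(0, 20), 7, 1))), 1e-4)
  D <- matrix(rnorm(30 * 50), 30, 50)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  # null threshold
  x <- D[, 3] + 0.1 * D[, 9]
  gbig <- max(abs(crossprod(D, x))) * 1.0001
  expect_true(all(sparse_encode(matrix(x, 1), D, gamma = gbig) == 0))
  # objective matches an independent FISTA solver
  X <- matrix(rnorm(5 * 30), 5, 30)
  Z <- sparse_encode(X, D, gamma = 0.2)
  L <- max(eigen(crossprod(D), symmetric = TRUE, only.values = TRUE)$values)
  fista <- function(xv) {
    z <- rep(0, 50); y <- z; tk <- 1
    for (i in 1:30000) {
      zn <- y + crossprod(D, xv - D %*% y) / L
      zn <- sign(zn) * pmax(abs(zn) - 0.2 / L, 0)
      tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
      y <- zn + ((tk - 1) / tn) * (zn - z)
      z <- zn; tk <- tn
    }
    z
  }
  obj <- function(z, xv) 0.5 * sum((xv - D %*% z)^2) + 0.2 * sum(abs(z))
  for (i in 1:5) {
    expect_lt(abs(obj(Z[i, ], X[i, ]) - obj(fista(X[i, ]), X[i, ])), 1e-5)
  }
})

test_that("SCC recovers a planted dictionary", {
  set.seed(5)
  m <- 60; k <- 40; n <- 500
  Dtrue <- matrix(rnorm(m * k), m, k)
  Dtrue <- sweep(Dtrue, 2, sqrt(colSums(Dtrue^2)), "/")
  Ztrue <- sapply(seq_len(n), function(i) {
    z <- rep(0, k); z[sample(k, 3)] <- rnorm(3); z
  })
  X <- t(Dtrue %*% Ztrue)
  dict <- scc_learn(X, k = k, gamma = 0.1, epochs = 10, seed = 3)
  Z <- sparse_encode(X, dict, debias = TRUE)
  relerr <- sqrt(sum((X - Z %*% t(dict$atoms))^2)) / sqrt(sum(X^2))
  expect_lt(relerr, 0.1)
  expect_true(all(abs(colSums(dict$atoms^2) - 1) < 1e-9))
  # held-out objective descent: epoch 5 not above epoch 1
  expect_lte(dict$objective[6], dict$objective[2] + 1e-6)
  # epochs = 0 returns the (normalized) initialization deterministically
  d0a <- scc_learn(X, k = k, gamma = 0.1, epochs = 0, seed = 3)
  d0b <- scc_learn(X, k = k, gamma = 0.1, epochs = 0, seed = 3)
  expect_identical(d0a$atoms, d0b$atoms)
  expect_warning(scc_learn(X[1:50, ], k = 10, gamma = 100, epochs = 1, seed = 1),
                 "dead dictionary")
})

test_that("max pooling matches brute-force nested loops", {
  expect_equal(max_pool(matrix(c(1, 3, 2, 4), 2, 2)), matrix(4, 1, 1))
  expect_true(all(max_pool(matrix(7, 5, 5)) == 7))
  set.seed(6)
  M <- matrix(rnorm(63), 7, 9)
  brute <- function(m, w = 2, s = 2) {
    ro <- seq(1, nrow(m), s); co <- seq(1, ncol(m), s)
    o <- matrix(0, length(ro), length(co))
    for (a in seq_along(ro)) for (b in seq_along(co)) {
      o[a, b] <- max(m[ro[a]:min(ro[a] + w - 1, nrow(m)),
                       co[b]:min(co[b] + w - 1, ncol(m))])
    }
    o
  }
  expect_identical(max_pool(M), brute(M))
  expect_warning(big <- max_pool(matrix(1, 1, 1), window = 5), "window")
  expect_identical(big, matrix(1, 1, 1))
})

test_that("subject vectors have the pooled dimensions", {
  set.seed(3)
  codes <- matrix(rnorm(1008 * 256), 1008, 256)
  v <- subject_vector(codes)
  expect_length(v, 504 * 128)
  vg <- subject_vector(codes, pooling = "global")
  expect_length(vg, 256)
  expect_equal(unname(vg), apply(codes, 2, max), ignore_attr = TRUE)
  # a dominant one-hot code survives pooling in its atom's column block
  codes2 <- matrix(0, 10, 6)
  codes2[5, 4] <- 99
  pooled <- max_pool(codes2)
  expect_true(any(pooled == 99))
  expect_equal(max(subject_vector(codes2)), 99)
})

test_that("GentleBoost separates blobs and reduces to the optimal stump", {
  set.seed(7)
  X <- rbind(cbind(rnorm(50, -3), rnorm(50)), cbind(rnorm(50, 3), rnorm(50)))
  y <- c(rep(-1, 50), rep(1, 50))
  gb <- gentleboost_train(X, y, n_rounds = 20, max_depth = 2)
  expect_equal(mean(predict(gb, X) != y), 0)

  set.seed(8)
  Xs <- matrix(rnorm(40), 20, 2)
  ys <- sign(rnorm(20)); ys[ys == 0] <- 1
  gb1 <- gentleboost_train(Xs, ys, n_rounds = 1, max_depth = 1)
  f1 <- predict(gb1, Xs, type = "score")
  w0 <- rep(1 / 20, 20)
  best <- NULL
  for (j in 1:2) for (thr in sort(Xs[, j])) {
    left <- Xs[, j] < thr + 1e-12
    if (all(left) || !any(left)) next
    aL <- weighted.mean(ys[left], w0[left])
    aR <- weighted.mean(ys[!left], w0[!left])
    pred <- ifelse(left, aL, aR)
    sse <- sum(w0 * (ys - pred)^2)
    if (is.null(best) || sse < best$sse) best <- list(sse = sse, pred = pred)
  }
  expect_lt(max(abs(f1 - best$pred)), 1e-10)
  # weight update direction: misclassified points gain weight
  w_after <- exp(-ys * f1)
  mis <- predict(gb1, Xs) != ys
  expect_gt(min(w_after[mis]), max(w_after[!mis]) - 1e-12)
  expect_error(gentleboost_train(Xs, rep(1, 20)), class = "bad_argument")
  expect_error(gentleboost_train(Xs, c(rep(1, 19), -1)), class = "bad_argument")
})

test_that("fold allocation gives near-equal folds (311 -> 31/32)", {
  f <- cv_folds(311, 10, seed = 2)
  expect_setequal(as.integer(table(f)), c(rep(31L, 9), 32L))
  expect_identical(f, cv_folds(311, 10, seed = 2))
  expect_error(cv_folds(5, 10), class = "bad_argument")
})

test_that("a perfectly separable cohort yields perfect CV metrics", {
  set.seed(11)
  base <- array(rnorm(12 * 12 * 4, sd = 0.05), c(12, 12, 4))
  mms_list <- lapply(1:20, function(i) {
    off <- if (i <= 10) 0 else 5
    base + off + array(rnorm(12 * 12 * 4, sd = 0.05), c(12, 12, 4))
  })
  labels <- factor(rep(c("HC", "PD"), each = 10))
  lay <- generate_patches(c(12L, 12L), 6L, side = 4L, seed = 1)
  cv <- cross_validate(mms_list, labels, lay, k = 8, gamma = 0.15, epochs = 1,
                       n_rounds = 10, max_depth = 1, k_folds = 5, seed = 3)
  expect_equal(unname(cv$mean_metrics), rep(1, 5), tolerance = 1e-12)
  expect_true(all(vapply(cv$confusions, function(tb) sum(diag(tb)) == sum(tb), TRUE)))
  # determinism of the full report
  cv2 <- cross_validate(mms_list, labels, lay, k = 8, gamma = 0.15, epochs = 1,
                        n_rounds = 10, max_depth = 1, k_folds = 5, seed = 3)
  expect_identical(cv2$fold_metrics, cv$fold_metrics)
})
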