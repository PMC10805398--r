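test_that("the two-sample t statistic matches the hand formula and is antisymmetric", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  lab <- factor(c("a", "a", "a", "b", "b", "b"))
  t1 <- vertex_t_stat(x, lab)
  expect_equal(as.vector(t1), -3.674235, tolerance = 1e-6)
  lab2 <- factor(c("b", "b", "b", "a", "a", "a"), levels = c("a", "b"))
  expect_equal(as.vector(vertex_t_stat(x, lab2)), 3.674235, tolerance = 1e-6)

  xs <- array(c(x, x), c(6, 2, 1))
  xs[4:6, , 1] <- xs[1:3, , 1]
  t0 <- vertex_t_stat(xs, lab)
  expect_true(all(t0 == 0))
})

test_that("Hotelling's T2 reduces to t^2 and matches dense algebra", {
  set.seed(2)
  lab <- factor(rep(c("a", "b"), each = 10))
  X1 <- array(rnorm(20 * 50), c(20, 50, 1))
  expect_equal(vertex_hotelling_t2(X1, lab),
               unname(vertex_t_stat(X1, lab))^2, tolerance = 1e-10,
               ignore_attr = TRUE)
  for (d in 2:4) {
    set.seed(d)
    X <- array(rnorm(20 * 30 * d), c(20, 30, d))
    T2 <- vertex_hotelling_t2(X, lab)
    brute <- sapply(1:30, function(v) {
      x1 <- X[1:10, v, , drop = FALSE][, 1, ]
      x2 <- X[11:20, v, , drop = FALSE][, 1, ]
      dd <- colMeans(x1) - colMeans(x2)
      S <- (cov(x1) * 9 + cov(x2) * 9) / 18
      (10 * 10 / 20) * as.numeric(t(dd) %*% solve(S) %*% dd)
    })
    expect_equal(T2, brute, tolerance = 1e-10)
  }
  expect_error(vertex_hotelling_t2(array(rnorm(4 * 2 * 4), c(4, 2, 4)),
                                   factor(c("a", "a", "b", "b"))),
               class = "bad_argument")
})

test_that("permutations share one shuffle across vertices and match a direct recompute", {
  set.seed(4)
  X <- array(rnorm(20 * 25), c(20, 25, 1))
  lab <- factor(rep(c("g1", "g2"), each = 10))
  seen <- list()
  sm <- permutation_test(X, lab, n_perm = 120, seed = 5,
                         shuffle_hook = function(b, pl) seen[[b]] <<- pl,
                         keep_perm_stats = TRUE)
  expect_length(seen, 120)
  expect_true(all(vapply(seen, function(pl) sum(pl == "g1") == 10L, TRUE)))
  for (b in c(3, 57, 120)) {
    direct <- abs(vertex_t_stat(X, seen[[b]]))
    expect_equal(sm$perm_stats[b, ], as.vector(direct), tolerance = 1e-12)
  }
  # p values are exact multiples of 1/n_perm
  expect_true(all(abs(sm$p_vertex * 120 - round(sm$p_vertex * 120)) < 1e-9))
  sm2 <- permutation_test(X, lab, n_perm = 120, seed = 5)
  expect_identical(sm2$p_vertex, sm$p_vertex)
  expect_identical(sm2$p_global, sm$p_global)
})

test_that("a strong implanted effect drives the corrected global p to zero", {
  set.seed(6)
  X <- array(rnorm(30 * 60), c(30, 60, 1))
  X[16:30, 1:20, 1] <- X[16:30, 1:20, 1] + 3
  lab <- factor(rep(c("g1", "g2"), each = 15))
  sm <- permutation_test(X, lab, n_perm = 200, seed = 2)
  expect_equal(sm$p_global, 0)
  expect_output(print(sm), "< 0.005")
  expect_gt(sum(sm$sig_mask[1:20]), 15)
  s <- summary(sm)
  expect_equal(s$real_effect, sm$real_effect)
})

test_that("direction maps label atrophy/expansion symmetrically", {
  co <- cached_cohort("dir", atrophy_config(seed = 21L))
  arr <- stack_features(lapply(co$grids, radial_distance), "RD")
  sm <- permutation_test(arr, co$labels, n_perm = 200, seed = 3)
  dm <- direction_map(arr, co$labels, sm)
  truth <- as.vector(co$truth$effect_mask)
  expect_gt(sum(dm[truth] == "atrophy"), 0.5 * sum(truth))
  expect_lte(sum(dm[truth] == "expansion"), 3)

  # negating the group difference flips every label
  arr_neg <- arr
  arr_neg[co$labels == "PD", , ] <- arr[co$labels == "PD", , ] +
    2 * (matrix(colMeans(arr[co$labels == "HC", , 1]) -
                  colMeans(arr[co$labels == "PD", , 1]),
                sum(co$labels == "PD"), dim(arr)[2], byrow = TRUE))
  dm2 <- direction_map(arr_neg, co$labels, sm)
  swapped <- ifelse(dm == "atrophy", "expansion",
                    ifelse(dm == "expansion", "atrophy", "none"))
  expect_identical(dm2, swapped)

  # nothing significant -> all none
  null_map <- sm
  null_map$sig_mask[] <- FALSE
  expect_true(all(direction_map(arr, co$labels, null_map) == "none"))
})

test_that("clinical correlation maps hit their analytic null level", {
  set.seed(8)
  n <- 20
  X <- matrix(rnorm(n * 10000), n, 10000)
  scores <- rnorm(n)
  cc <- clinical_correlation(X, scores)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(mean(cc$mask) - 0.05), 3 * se)
  # perfect correlation at a constructed vertex
  X[, 1] <- scores
  cc2 <- clinical_correlation(X, scores)
  expect_equal(cc2$r[1], 1, tolerance = 1e-12)
  expect_lt(cc2$p[1], 1e-20)
  # antisymmetry under score negation
  cc3 <- clinical_correlation(X, -scores)
  expect_equal(cc3$r, -cc2$r, tolerance = 1e-12)
  expect_error(clinical_correlation(X, rep(1, n)), class = "bad_argument")
})
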