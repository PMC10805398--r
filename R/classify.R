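#' Random square patch layout on the parameter grid
#'
#' Draws `n_patches` square windows with top-left corners uniform over the
#' valid grid positions. Windows may overlap; along the periodic v axis
#' they may wrap. The same layout is used for every subject.
#'
#' @param grid_dims `c(nu, nv)`.
#' @param n_patches number of windows (default 1008).
#' @param side window side in vertices (typically 20 to 30).
#' @param seed integer seed.
#' @param periodic_v whether v windows may wrap.
#' @return an object of class `patch_layout`: data.frame with columns
#'   `u0`, `v0`, `side` plus attributes.
#' @export
generate_patches <- function(grid_dims, n_patches = 1008L, side = 30L,
                             seed = 1L, periodic_v = TRUE) {
  nu <- grid_dims[1]; nv <- grid_dims[2]
  if (side > nu)
    stop_subshape("bad_argument", "patch side exceeds grid extent in u")
  if (!periodic_v && side > nv)
    stop_subshape("bad_argument", "patch side exceeds grid extent in v")
  max_u <- nu - side + 1L
  max_v <- if (periodic_v) nv else nv - side + 1L
  layout <- with_seed(seed, {
    data.frame(u0 = sample.int(max_u, n_patches, replace = TRUE),
               v0 = sample.int(max_v, n_patches, replace = TRUE),
               side = as.integer(side))
  })
  structure(layout, class = c("patch_layout", "data.frame"),
            grid_dims = as.integer(grid_dims), periodic_v = periodic_v,
            seed = as.integer(seed))
}

#' Extract per-patch feature rows from an MMS grid
#'
#' Each row is the row-major flattening of one `side x side x channels`
#' block (channel index fastest, then v, then u); v indices wrap on
#' periodic grids.
#'
#' @param mms_array `nu x nv x channels` feature array (typically MMS).
#' @param layout a [generate_patches()] layout on the same grid dims.
#' @return `n_patches x (side^2 * channels)` matrix.
#' @export
extract_patch_features <- function(mms_array, layout) {
  if (length(dim(mms_array)) == 2L) dim(mms_array) <- c(dim(mms_array), 1L)
  dims <- attr(layout, "grid_dims")
  if (!all(dim(mms_array)[1:2] == dims))
    stop_subshape("bad_argument", "layout and feature grid dims disagree")
  nu <- dims[1]; nv <- dims[2]; ch <- dim(mms_array)[3]
  side <- layout$side[1]
  m <- side * side * ch
  out <- matrix(0, nrow(layout), m)
  for (p in seq_len(nrow(layout))) {
    ui <- layout$u0[p] + 0:(side - 1)
    vi <- ((layout$v0[p] + 0:(side - 1) - 1L) %% nv) + 1L
    block <- mms_array[ui, vi, , drop = FALSE]
    # row-major: u slowest, then v, channel fastest
    out[p, ] <- as.vector(aperm(block, c(3, 2, 1)))
  }
  out
}

# inverse of the patch flattening (testing aid)
unflatten_patch <- function(row, side, channels) {
  aperm(array(row, c(channels, side, side)), c(3, 2, 1))
}

soft_threshold <- function(x, g) sign(x) * pmax(abs(x) - g, 0)

# fast approximate single-sample coordinate descent for the streaming
# dictionary updates: coordinates are restricted to the atoms initially
# correlated with the sample (|D'x| > gamma); exact batch solves are used
# everywhere codes are consumed downstream
stream_code <- function(D, x, gamma, passes) {
  k <- ncol(D)
  Cx <- as.vector(crossprod(D, x))
  cand <- which(abs(Cx) > gamma)
  z <- matrix(0, k, 1)
  if (!length(cand)) return(z)
  G <- crossprod(D[, cand, drop = FALSE])
  zc <- numeric(length(cand))
  Gz <- numeric(length(cand))
  dg <- pmax(diag(G), 1e-12)
  for (pass in seq_len(passes)) {
    changed <- FALSE
    for (a in seq_along(cand)) {
      rho <- Cx[cand[a]] - Gz[a] + dg[a] * zc[a]
      zn <- soft_threshold(rho, gamma) / dg[a]
      if (zn != zc[a]) {
        Gz <- Gz + G[, a] * (zn - zc[a])
        zc[a] <- zn
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  z[cand, 1] <- zc
  z
}

# batch coordinate-descent LASSO: minimize 0.5||x - D z||^2 + gamma ||z||_1
# for all columns of X (m x B) at once, working in the covariance space
# (G = D'D, C = D'X) so per-coordinate cost is O(k B) not O(m B);
# returns k x B codes
cd_lasso_batch <- function(D, X, gamma, max_pass = 100L, tol = 1e-6,
                           Z = NULL) {
  k <- ncol(D)
  B <- ncol(X)
  G <- crossprod(D)                  # k x k, diag = 1 for unit atoms
  Cm <- crossprod(D, X)              # k x B
  dg <- pmax(diag(G), 1e-12)
  if (is.null(Z)) Z <- matrix(0, k, B)
  GZ <- G %*% Z
  x2 <- 0.5 * colSums(X^2)
  objective <- function() {
    x2 - colSums(Z * Cm) + 0.5 * colSums(Z * GZ) + gamma * colSums(abs(Z))
  }
  obj <- objective()
  for (pass in seq_len(max_pass)) {
    for (j in seq_len(k)) {
      zj <- Z[j, ]
      rho <- Cm[j, ] - GZ[j, ] + dg[j] * zj
      znew <- soft_threshold(rho, gamma) / dg[j]
      dz <- znew - zj
      upd <- which(dz != 0)
      if (length(upd)) {
        GZ[, upd] <- GZ[, upd] + G[, j] %o% dz[upd]
        Z[j, upd] <- znew[upd]
      }
    }
    obj_new <- objective()
    if (max(obj - obj_new) <= tol * max(1, max(abs(obj)))) break
    obj <- obj_new
  }
  Z
}

#' Sparse codes of patch rows under a dictionary
#'
#' Coordinate-descent LASSO solve `min 0.5 ||x - D z||^2 + gamma ||z||_1`
#' per patch, run to a tight relative objective tolerance (1e-8).
#'
#' @param patch_matrix P x m matrix of patch rows.
#' @param dictionary an [scc_learn()] dictionary (or plain m x k matrix).
#' @param gamma sparsity weight; defaults to the dictionary's training
#'   value.
#' @param debias if `TRUE`, refit the non-zero coefficients of each code by
#'   least squares on their support, removing the deliberate l1 shrinkage
#'   (the support itself is still selected by the LASSO).
#' @param tol relative objective tolerance of the coordinate-descent solve.
#' @param max_pass cap on coordinate-descent passes.
#' @return P x k code matrix with attribute `"density"` (fraction of
#'   non-zero coefficients).
#' @export
sparse_encode <- function(patch_matrix, dictionary, gamma = NULL,
                          debias = FALSE, tol = 1e-8, max_pass = 500L) {
  D <- if (inherits(dictionary, "scc_dictionary")) dictionary$atoms else dictionary
  if (is.null(gamma)) {
    gamma <- if (inherits(dictionary, "scc_dictionary")) dictionary$gamma else
      stop_subshape("bad_argument", "gamma required for a plain matrix dictionary")
  }
  if (ncol(patch_matrix) != nrow(D))
    stop_subshape("bad_argument", "patch length and dictionary atom length disagree")
  Z <- cd_lasso_batch(D, t(patch_matrix), gamma, max_pass = max_pass, tol = tol)
  codes <- t(Z)
  if (debias) {
    for (i in seq_len(nrow(codes))) {
      s <- which(codes[i, ] != 0)
      if (!length(s)) next
      Ds <- D[, s, drop = FALSE]
      codes[i, s] <- tryCatch(qr.solve(Ds, patch_matrix[i, ]),
                              error = function(e) codes[i, s])
    }
  }
  attr(codes, "density") <- mean(codes != 0)
  codes
}

#' Learn an over-complete dictionary by Stochastic Coordinate Coding
#'
#' Online dictionary learning: samples are streamed in shuffled order (in
#' small mini-batches); for each batch a few coordinate-descent passes
#' update the sparse codes, then only the dictionary columns appearing in
#' the codes' support receive a stochastic gradient step (learning rate
#' decaying with each atom's update count) and are renormalized to unit
#' length. A fixed held-out batch tracks the LASSO objective across
#' epochs.
#'
#' @param patch_matrix P x m matrix (rows = training patches).
#' @param k number of atoms (k > m gives the over-complete regime).
#' @param gamma sparsity weight (> 0).
#' @param epochs passes over the data; `epochs = 0` returns the normalized
#'   random initialization.
#' @param seed integer seed (initialization and shuffling).
#' @param cd_passes coordinate-descent passes per sample during training.
#' @param batch_size samples per stochastic update (1 = pure streaming,
#'   the default; small mini-batches trade recovery quality for speed).
#' @return an object of class `scc_dictionary`: list with unit-norm `atoms`
#'   (m x k), `gamma`, `epochs`, `seed`, `objective` (held-out objective
#'   per epoch, epoch 0 first).
#' @export
scc_learn <- function(patch_matrix, k, gamma = 0.15, epochs = 10L, seed = 1L,
                      cd_passes = 12L, batch_size = 1L) {
  if (gamma <= 0) stop_subshape("bad_argument", "gamma must be > 0")
  X <- as.matrix(patch_matrix)
  P <- nrow(X); m <- ncol(X)
  res <- with_seed(seed, {
    # initialize atoms from jittered random training samples (falling back
    # to pure noise atoms when P < k); a standard warm start that speeds up
    # convergence of online dictionary learning considerably
    pick <- sample.int(P, min(P, k))
    D <- matrix(rnorm(m * k, 0, 0.05), m, k)
    D[, seq_along(pick)] <- D[, seq_along(pick)] + t(X[pick, , drop = FALSE])
    nrm <- sqrt(colSums(D^2))
    D <- sweep(D, 2, pmax(nrm, 1e-12), "/")
    hold <- sample.int(P, min(P, 128L))
    list(D = D, hold = hold, perms = replicate(max(epochs, 0),
                                               sample.int(P), simplify = FALSE))
  })
  D <- res$D
  Xh <- t(X[res$hold, , drop = FALSE])
  holdout_obj <- function(D) {
    Z <- cd_lasso_batch(D, Xh, gamma, max_pass = 50L)
    mean(0.5 * colSums((Xh - D %*% Z)^2) + gamma * colSums(abs(Z)))
  }
  objective <- holdout_obj(D)
  counts <- rep(0, k)
  if (epochs > 0) {
    for (e in seq_len(epochs)) {
      ord <- res$perms[[e]]
      starts <- seq(1L, P, by = batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + batch_size - 1L, P)]
        Xb <- t(X[idx, , drop = FALSE])
        Z <- if (length(idx) == 1L) {
          stream_code(D, Xb[, 1], gamma, cd_passes)
        } else {
          cd_lasso_batch(D, Xb, gamma, max_pass = cd_passes, tol = 0)
        }
        used <- which(rowSums(Z != 0) > 0)
        if (!length(used)) next
        R <- Xb - D %*% Z
        usage <- rowSums(Z != 0)
        grad <- sweep(R %*% t(Z), 2, pmax(usage, 1), "/")   # m x k
        counts[used] <- counts[used] + usage[used]
        lr <- 1 / (1 + counts[used] / 50)
        D[, used] <- D[, used] + sweep(grad[, used, drop = FALSE], 2, lr, "*")
        nrm <- sqrt(colSums(D[, used, drop = FALSE]^2))
        D[, used] <- sweep(D[, used, drop = FALSE], 2, pmax(nrm, 1e-12), "/")
      }
      objective <- c(objective, holdout_obj(D))
    }
  }
  dead <- counts == 0 & epochs > 0
  if (epochs > 0 && all(counts == 0))
    warning("gamma so large that all training codes are zero (dead dictionary)")
  structure(list(atoms = D, gamma = gamma, epochs = as.integer(epochs),
                 seed = as.integer(seed), objective = objective,
                 atom_update_counts = counts),
            class = "scc_dictionary")
}

#' @export
print.scc_dictionary <- function(x, ...) {
  cat(sprintf("scc_dictionary: %d atoms of length %d (gamma = %g, %d epoch(s))\n",
              ncol(x$atoms), nrow(x$atoms), x$gamma, x$epochs))
  cat(sprintf("  held-out objective %.4g -> %.4g\n",
              x$objective[1], x$objective[length(x$objective)]))
  invisible(x)
}

#' Max pooling of a matrix
#'
#' Sliding maximum over `window x window` blocks with the given stride;
#' edge windows are truncated, so the output is `ceiling(dim/stride)`.
#'
#' @param m numeric matrix.
#' @param window pooling window (default 2).
#' @param stride pooling stride (default 2).
#' @return pooled matrix.
#' @export
max_pool <- function(m, window = 2L, stride = 2L) {
  m <- as.matrix(m)
  if (window > nrow(m) && window > ncol(m)) {
    warning("pooling window exceeds input extent; returning input unchanged")
    return(m)
  }
  ro <- seq(1L, nrow(m), by = stride)
  co <- seq(1L, ncol(m), by = stride)
  out <- matrix(-Inf, length(ro), length(co))
  for (a in seq_along(ro)) {
    ri <- ro[a]:min(ro[a] + window - 1L, nrow(m))
    for (b in seq_along(co)) {
      ci <- co[b]:min(co[b] + window - 1L, ncol(m))
      out[a, b] <- max(m[ri, ci])
    }
  }
  out
}

#' Pooled per-subject classifier input vector
#'
#' Default configuration arranges one subject's sparse codes as the
#' `P x k` patch-code matrix, applies 2 x 2 max pooling with stride 2 and
#' flattens; the `"global"` configuration takes the per-atom maximum over
#' all patches (a k-vector).
#'
#' @param codes P x k sparse-code matrix for one subject.
#' @param pooling `"patch_matrix"` (default) or `"global"`.
#' @param window,stride pooling geometry for the default configuration.
#' @return numeric vector with attribute `"pooling"`.
#' @export
subject_vector <- function(codes, pooling = c("patch_matrix", "global"),
                           window = 2L, stride = 2L) {
  pooling <- match.arg(pooling)
  v <- if (pooling == "global") apply(codes, 2, max)
       else as.vector(max_pool(codes, window, stride))
  attr(v, "pooling") <- pooling
  v
}

#' Train a GentleBoost tree ensemble
#'
#' GentleBoost with regression trees as weak learners: weights start
#' uniform; each round fits a depth-limited regression tree minimizing the
#' weighted squared error to the labels, adds its prediction to the
#' ensemble score, multiplies the weights by `exp(-y * f(x))` and
#' renormalizes. Prediction is the sign of the accumulated score.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels in `{-1, +1}`.
#' @param n_rounds boosting rounds.
#' @param max_depth weak-learner tree depth (1 = stumps).
#' @param seed kept for interface uniformity (the fit is deterministic).
#' @return an object of class `gentleboost`.
#' @export
gentleboost_train <- function(X, y, n_rounds = 100L, max_depth = 3L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)))
    stop_subshape("bad_argument", "y must be in {-1, +1}")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop_subshape("bad_argument", "need >= 2 samples per class")
  n <- nrow(X)
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  w <- rep(1 / n, n)
  trees <- vector("list", n_rounds)
  Fscore <- numeric(n)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2L,
                               minbucket = 1L, xval = 0L, maxsurrogate = 0L,
                               maxcompete = 0L)
  dfit <- df
  dfit$.y <- y
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dfit, weights = w * n, method = "anova",
                        control = ctrl)
    f <- as.numeric(predict(fit, df))
    f <- pmin(pmax(f, -1), 1)
    trees[[r]] <- fit
    Fscore <- Fscore + f
    w <- w * exp(-y * f)
    s <- sum(w)
    if (s <= 0 || !is.finite(s)) break
    w <- w / s
    trees_used <- r
  }
  structure(list(trees = trees[!vapply(trees, is.null, TRUE)],
                 n_rounds = n_rounds, max_depth = max_depth,
                 feature_names = names(df), train_score = Fscore),
            class = "gentleboost")
}

#' @export
predict.gentleboost <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  nd <- as.data.frame(as.matrix(newdata))
  names(nd) <- object$feature_names
  sc <- rowSums(vapply(object$trees,
                       function(tr) pmin(pmax(as.numeric(predict(tr, nd)), -1), 1),
                       numeric(nrow(nd))))
  if (type == "score") sc else ifelse(sc >= 0, 1, -1)
}

#' Random fold allocation
#'
#' Unstratified allocation of `n` subjects into `k` folds whose sizes
#' differ by at most one.
#'
#' @param n number of subjects.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) per subject.
#' @export
cv_folds <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop_subshape("bad_argument", "need n >= k")
  base <- n %/% k
  extra <- n %% k
  with_seed(seed, {
    sizes <- rep(base, k) + as.integer(seq_len(k) %in% sample.int(k, extra))
    sample(rep(seq_len(k), times = sizes))
  })
}

confusion_metrics <- function(truth, pred) {
  TP <- sum(truth == 1 & pred == 1)
  TN <- sum(truth == -1 & pred == -1)
  FP <- sum(truth == -1 & pred == 1)
  FN <- sum(truth == 1 & pred == -1)
  safe <- function(a, b) if (b == 0) NA_real_ else a / b
  c(ACC = (TP + TN) / length(truth),
    SEN = safe(TP, TP + FN), SPE = safe(TN, TN + FP),
    PPV = safe(TP, TP + FP), NPV = safe(TN, TN + FN))
}

#' Cross-validated MMS classification pipeline
#'
#' 10-fold cross-validation of the patch / sparse-coding / pooling /
#' GentleBoost pipeline on per-subject MMS grids. Within each fold the
#' dictionary is learned on training-fold patches only (no leakage), all
#' subjects are encoded under it, pooled subject vectors are built, and a
#' GentleBoost ensemble is trained on the training subjects. The positive
#' class is the second factor level of `labels`.
#'
#' @param mms_list list of per-subject `nu x nv x 4` MMS arrays (or any
#'   equal-shaped feature arrays).
#' @param labels two-level factor.
#' @param layout a [generate_patches()] layout.
#' @param k dictionary atoms.
#' @param gamma sparsity weight.
#' @param epochs SCC epochs per fold.
#' @param n_rounds,max_depth GentleBoost configuration.
#' @param k_folds number of folds.
#' @param seed seed controlling folds and dictionary initialization.
#' @param pooling subject-vector pooling configuration
#'   (see [subject_vector()]).
#' @param max_train_patches optional cap on the number of training patches
#'   fed to the dictionary learner per fold (random subsample).
#' @param encode_tol coordinate-descent tolerance used when encoding
#'   subjects inside the cross-validation loop.
#' @return an object of class `cv_report`: per-fold metrics and confusion
#'   matrices, their unweighted means, fold assignment, configuration.
#' @export
cross_validate <- function(mms_list, labels, layout, k = 32L, gamma = 0.15,
                           epochs = 5L, n_rounds = 50L, max_depth = 3L,
                           k_folds = 10L, seed = 1L,
                           pooling = c("patch_matrix", "global"),
                           max_train_patches = Inf, encode_tol = 1e-6) {
  pooling <- match.arg(pooling)
  labels <- check_two_groups(labels, length(mms_list))
  n <- length(mms_list)
  y <- ifelse(labels == levels(labels)[2], 1, -1)   # positive = second level
  patches <- lapply(mms_list, extract_patch_features, layout = layout)
  folds <- cv_folds(n, k_folds, seed)

  fold_metrics <- matrix(NA_real_, k_folds, 5L,
                         dimnames = list(NULL, c("ACC", "SEN", "SPE", "PPV", "NPV")))
  confusions <- vector("list", k_folds)
  preds <- numeric(n)
  for (fd in seq_len(k_folds)) {
    tr <- which(folds != fd)
    te <- which(folds == fd)
    train_patches <- do.call(rbind, patches[tr])
    # standardize on training statistics only: center each patch dimension
    # and scale so the mean training patch norm is 1 (gamma is then a
    # fraction of a typical atom correlation)
    mu <- colMeans(train_patches)
    ctp <- sweep(train_patches, 2, mu)
    scl <- mean(sqrt(rowSums(ctp^2)))
    if (scl <= 0) scl <- 1
    dtrain <- ctp / scl
    if (nrow(dtrain) > max_train_patches) {
      keep <- with_seed(seed + 1000L + fd,
                        sample.int(nrow(dtrain), max_train_patches))
      dtrain <- dtrain[keep, , drop = FALSE]
    }
    dict <- scc_learn(dtrain, k = k, gamma = gamma, epochs = epochs,
                      seed = seed + fd)
    vecs <- lapply(patches, function(pm) {
      pm_std <- sweep(pm, 2, mu) / scl
      subject_vector(sparse_encode(pm_std, dict, tol = encode_tol,
                                   max_pass = 100L),
                     pooling = pooling)
    })
    Xall <- do.call(rbind, vecs)
    if (length(unique(y[tr])) < 2L) {
      warning(sprintf("fold %d has a single training class; metrics NA", fd))
      next
    }
    model <- gentleboost_train(Xall[tr, , drop = FALSE], y[tr],
                               n_rounds = n_rounds, max_depth = max_depth)
    pr <- predict(model, Xall[te, , drop = FALSE])
    preds[te] <- pr
    fold_metrics[fd, ] <- confusion_metrics(y[te], pr)
    confusions[[fd]] <- table(truth = factor(y[te], c(-1, 1)),
                              pred = factor(pr, c(-1, 1)))
  }
  nas <- is.na(fold_metrics)
  if (any(nas))
    warning("some fold metrics are undefined (single-class fold); excluded from means")
  means <- colMeans(fold_metrics, na.rm = TRUE)
  structure(list(fold_metrics = fold_metrics, mean_metrics = means,
                 confusions = confusions, folds = folds, predictions = preds,
                 labels = labels, seed = as.integer(seed),
                 config = list(k = k, gamma = gamma, epochs = epochs,
                               n_rounds = n_rounds, max_depth = max_depth,
                               k_folds = k_folds, pooling = pooling,
                               n_patches = nrow(layout), side = layout$side[1])),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("cv_report: %d-fold CV, %d subjects, %d patches (side %d), k = %d\n",
              cfg$k_folds, length(x$folds), cfg$n_patches, cfg$side, cfg$k))
  cat("  mean metrics:\n")
  print(round(x$mean_metrics, 4))
  invisible(x)
}

#' Patch-size model-selection sweep
#'
#' Runs the cross-validated pipeline over a range of patch sides and
#' reports the mean accuracy per side, mirroring the usual patch-size
#' selection procedure (accuracy plateaus once the windows are large
#' enough).
#'
#' @param mms_list,labels as in [cross_validate()].
#' @param sides integer vector of window sides.
#' @param n_patches windows per layout.
#' @param seed seed shared across sides.
#' @param ... further arguments passed to [cross_validate()].
#' @return data.frame with columns `side` and `ACC`.
#' @export
patch_size_sweep <- function(mms_list, labels, sides = c(20L, 25L, 30L),
                             n_patches = 1008L, seed = 1L, ...) {
  dims <- dim(mms_list[[1]])[1:2]
  acc <- vapply(sides, function(s) {
    layout <- generate_patches(dims, n_patches = n_patches, side = s, seed = seed)
    rep <- cross_validate(mms_list, labels, layout, seed = seed, ...)
    unname(rep$mean_metrics["ACC"])
  }, 0)
  data.frame(side = sides, ACC = acc)
}
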