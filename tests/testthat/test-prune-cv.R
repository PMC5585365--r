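# Cost-complexity pruning sequences and cross-validated subtree selection.

test_that("a single-split tree prunes in one step at alpha = gain", {
  co <- make_cohort(data.frame(x = 1:10), as.integer(1:10 >= 5))
  tr <- grow_tree(co, grow_params(min_split = 2, min_leaf = 1))
  path <- cost_complexity_path(tr)
  expect_equal(path$alphas, c(0, 2.4), tolerance = 1e-12)
  expect_equal(path$n_leaves, c(2, 1))
  expect_equal(n_leaves(prune_at(path, 1)), 2)
  expect_equal(n_leaves(prune_at(path, 2.4)), 1)
})

test_that("a root-only tree yields the single-element path", {
  co <- make_cohort(data.frame(x = rnorm(10)), rep(0L, 10))
  path <- cost_complexity_path(grow_tree(co, grow_params(min_split = 2,
                                                         min_leaf = 1)))
  expect_equal(path$alphas, 0)
  expect_equal(path$n_leaves, 1)
})

test_that("pruning sequences are strictly nested with increasing alphas", {
  for (seed in 1:8) {
    co <- random_cohort(n = 150, p = 4, seed = 100 + seed)
    path <- cost_complexity_path(grow_tree(co, grow_params(
      min_split = 10, min_leaf = 3, cp = 0.003)))
    K <- length(path$alphas)
    expect_true(all(diff(path$alphas) > 0))
    expect_true(all(diff(path$n_leaves) < 0))
    expect_equal(path$n_leaves[K], 1)
    for (k in seq_len(K - 1)) {
      # each later collapse mask contains the earlier one (nesting)
      expect_true(all(path$leaf_flags[[k]] <= path$leaf_flags[[k + 1]]))
    }
  }
})

test_that("pruned subtrees are cost-complexity optimal (brute-force check)", {
  for (seed in 1:5) {
    co <- random_cohort(n = 60, p = 2, seed = 200 + seed)
    params <- grow_params(min_split = 8, min_leaf = 3, cp = 0.005)
    tr <- grow_tree(co, params)
    path <- cost_complexity_path(tr)
    X <- as.matrix(co$data)
    otree <- oracle_grow(X, co$outcome, 8, 3, 30, 0.005)
    for (alpha in c(path$alphas + 1e-6, path$alphas[-1] - 1e-6)) {
      mine <- prune_at(path, alpha)
      best <- oracle_prune_at(otree, alpha)
      pred_o <- vapply(seq_len(co$n), function(i)
        oracle_predict1(best, X[i, ]), 0)
      expect_equal(predict(mine, co), pred_o, tolerance = 1e-9)
    }
  }
})

test_that("CV selection prefers the null tree on pure-noise outcomes", {
  hits <- 0
  for (seed in 1:40) {
    set.seed(3000 + seed)
    X <- data.frame(x1 = rnorm(300), x2 = rnorm(300), x3 = rnorm(300))
    y <- rbinom(300, 1, 0.34)
    co <- make_cohort(X, y)
    tr <- select_subtree_cv(co, grow_params(seed = seed))
    hits <- hits + (n_leaves(tr) == 1)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("CV selection keeps both planted splits under strong signal", {
  hits <- 0
  for (seed in 1:40) {
    set.seed(4000 + seed)
    X <- data.frame(x1 = runif(300, 10, 150), x2 = runif(300, 18, 45))
    y <- rbinom(300, 1, ifelse(X$x1 >= 78 & X$x2 < 31.5, 0.9, 0.1))
    co <- make_cohort(X, y)
    tr <- select_subtree_cv(co, grow_params(seed = seed))
    vars <- tr$covariates[tr$nodes[tr$nodes[, "var"] != 0, "var"]]
    hits <- hits + (all(c("x1", "x2") %in% vars))
  }
  expect_gte(hits / 40, 0.9)
})

test_that("leave-one-out selection matches an exhaustive manual computation", {
  # 12-row fixture, one covariate; v_folds = n is exact LOO
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  y <- c(0, 0, 1, 0, 0, 0, 1, 1, 0, 1, 1, 1)
  co <- make_cohort(data.frame(x = x), as.integer(y))
  params <- grow_params(min_split = 4, min_leaf = 2, cp = 0.01,
                        v_folds = 12, seed = 1)
  mine <- select_subtree_cv(co, params)

  # manual oracle: the package's own full-data path supplies the candidate
  # alphas; everything else (fold trees, pruning, errors) is brute force
  full_path <- cost_complexity_path(grow_tree(co, params))
  K <- length(full_path$alphas)
  rep_alpha <- c(if (K > 1) sqrt(full_path$alphas[-K] *
                                 full_path$alphas[-1]), Inf)
  sqerr <- matrix(NA_real_, 12, K)
  for (i in 1:12) {
    ot <- oracle_grow(matrix(x[-i], ncol = 1), y[-i], 4, 2, 30, 0.01)
    for (k in seq_len(K)) {
      pt <- oracle_prune_at(ot, min(rep_alpha[k], 1e9))
      sqerr[i, k] <- (y[i] - oracle_predict1(pt, x[i]))^2
    }
  }
  cv <- colMeans(sqerr)
  cand <- which(cv <= min(cv) + 1e-12)
  k_star <- cand[which.min(full_path$n_leaves[cand])]
  expect_equal(attr(mine, "selected_alpha"), full_path$alphas[k_star])
  manual_tree <- rert:::extract_subtree(full_path$tree,
                                        full_path$leaf_flags[[k_star]])
  expect_equal(predict(mine, co), predict(manual_tree, co))
  expect_equal(attr(mine, "cptable")$cv_error, cv, tolerance = 1e-12)
})

test_that("selection refuses impossible fold counts", {
  co <- make_cohort(data.frame(x = 1:5), c(0L, 1L, 0L, 1L, 0L))
  expect_error(select_subtree_cv(co, grow_params(min_split = 2, min_leaf = 1,
                                                 v_folds = 10)),
               "smaller than v_folds")
})
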