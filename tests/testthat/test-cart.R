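# Tree growing: impurity, split search, prediction, conservation identities.

small_params <- function(...) {
  grow_params(min_split = 2, min_leaf = 1, cp = 0.01, ...)
}

test_that("node impurity is the sum of squared deviations n*p*(1-p)", {
  expect_equal(node_impurity(c(0, 0, 0, 0)), 0)
  expect_equal(node_impurity(c(1, 0)), 0.5)
  expect_equal(node_impurity(c(1, 1, 1, 0, 0)), 1.2)
  # agrees with the direct definition on random multisets
  set.seed(1)
  for (r in 1:20) {
    y <- rbinom(sample(2:40, 1), 1, runif(1))
    expect_equal(node_impurity(y), sum((y - mean(y))^2), tolerance = 1e-12)
  }
  expect_error(node_impurity(integer(0)), "empty")
  expect_error(node_impurity(c(0, 2)), "0/1")
})

test_that("best split on a step function lands at the midpoint with full gain", {
  co <- make_cohort(data.frame(x = 1:10), as.integer(1:10 >= 5))
  sp <- best_split(co, small_params())
  expect_equal(sp$covariate, "x")
  expect_equal(sp$threshold, 4.5, ignore_attr = TRUE)
  expect_equal(sp$gain, 2.4, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("constant outcomes and duplicate covariates follow the contracts", {
  co0 <- make_cohort(data.frame(x = 1:10), rep(0L, 10))
  expect_null(best_split(co0, small_params()))
  # two identical covariates: tie goes to the first in schema order
  co2 <- make_cohort(data.frame(a = 1:10, b = 1:10), as.integer(1:10 >= 5))
  sp <- best_split(co2, small_params())
  expect_equal(sp$covariate, "a")
})

test_that("grown trees recover a planted two-threshold interaction exactly", {
  g <- expand.grid(x1 = seq(10, 150, by = 7), x2 = seq(18, 45, by = 3))
  y <- as.integer(g$x1 >= 78 & g$x2 < 31.5)
  co <- make_cohort(g, y)
  tr <- grow_tree(co, grow_params(min_split = 10, min_leaf = 5, cp = 0.01))
  expect_equal(n_leaves(tr), 3)
  # recovered cutpoints within half a grid spacing of the planted ones
  nd <- tr$nodes
  thr <- nd[nd[, "var"] != 0, "threshold"]
  vars <- tr$covariates[nd[nd[, "var"] != 0, "var"]]
  expect_lte(abs(thr[vars == "x1"] - 78), 3.5)
  expect_lte(abs(thr[vars == "x2"] - 31.5), 1.5)
  expect_equal(predict(tr, co), y, tolerance = 1e-12) # leaves pure
})

test_that("single-class cohorts give a root-only tree, not an error", {
  co <- make_cohort(data.frame(x = rnorm(5)), rep(1L, 5))
  tr <- grow_tree(co, small_params())
  expect_equal(n_leaves(tr), 1)
  expect_equal(unname(predict(tr, co)), rep(1, 5))
})

test_that("leaf frequencies conserve the positive count and impurity budget", {
  for (seed in 1:10) {
    co <- random_cohort(n = 120, p = 4, seed = seed)
    tr <- grow_tree(co, grow_params(min_split = 10, min_leaf = 3, cp = 0.005))
    nd <- tr$nodes
    leaves <- nd[, "var"] == 0
    # sum over leaves of n * yhat = total positives, exactly
    expect_equal(sum(nd[leaves, "n"] * nd[leaves, "yhat"]), sum(co$outcome),
                 tolerance = 1e-9)
    # complete data: root impurity = sum of leaf impurities + split gains
    expect_equal(unname(nd[1, "impurity"]),
                 sum(nd[leaves, "impurity"]) + sum(nd[!leaves, "gain"]),
                 tolerance = 1e-9)
    # every accepted split strictly decreased impurity
    expect_true(all(nd[!leaves, "gain"] > 0))
    # re-predicting the training rows averages to the prevalence
    expect_equal(mean(predict(tr, co)), mean(co$outcome), tolerance = 1e-12)
  }
})

test_that("missing values route with the majority of observed cases", {
  x <- c(1:10, NA, NA, NA)
  y <- as.integer(c(1:10 >= 5, 1, 1, 1))
  co <- make_cohort(data.frame(x = x), y)
  tr <- grow_tree(co, small_params())
  sp <- rert:::root_split(tr)
  # 4 observed go left, 6 observed go right -> missing follow right
  expect_equal(sp$surrogate_direction, "right")
  nd <- tr$nodes
  expect_equal(nd[nd[, "parent"] == 1, "n"], c(4, 9), ignore_attr = TRUE)
  # a record missing x predicts as the majority-direction child subtree
  expect_equal(predict(tr, data.frame(x = NA_real_)),
               predict(tr, data.frame(x = 100)))
})

test_that("nominal covariates split by level subsets via the mean ordering", {
  # planted: levels {2, 5} are high-risk, {1, 3, 4} low-risk
  set.seed(9)
  lev <- sample(1:5, 300, replace = TRUE)
  y <- rbinom(300, 1, ifelse(lev %in% c(2, 5), 0.9, 0.1))
  sch <- list(g = covariate_spec("g", "nominal", levels = paste0("L", 1:5)))
  co <- cohort(data.frame(g = as.numeric(lev)), sch, y,
               rep("all", 300))
  tr <- grow_tree(co, grow_params())
  sp <- rert:::root_split(tr)
  expect_equal(sp$form, "level-subset")
  expect_setequal(setdiff(1:5, sp$left_levels), c(2, 5))
})

test_that("prediction demands the tree's covariates and ignores extras", {
  co <- make_cohort(data.frame(x = 1:10), as.integer(1:10 >= 5))
  tr <- grow_tree(co, small_params())
  expect_error(predict(tr, data.frame(z = 1)), "lacks covariate")
  expect_equal(unname(predict(tr, data.frame(x = c(2, 9), extra = 0))),
               c(0, 1))
})

test_that("identical cohort, params and seed give bit-identical trees", {
  co <- default_study_emulator(seed = 5, n = 150)
  t1 <- grow_tree(co, grow_params(seed = 3))
  t2 <- grow_tree(co, grow_params(seed = 3))
  expect_identical(tree_to_json(t1), tree_to_json(t2))
})

test_that("trees serialize to JSON and back without loss", {
  co <- default_study_emulator(seed = 8, n = 200)
  tr <- grow_tree(co, grow_params())
  back <- tree_from_json(tree_to_json(tr))
  expect_equal(back$nodes, tr$nodes, tolerance = 1e-12)
  expect_identical(back$covariates, tr$covariates)
  expect_equal(predict(back, co), predict(tr, co), tolerance = 1e-12)
})
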