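# Cost-complexity (weakest-link) pruning and cross-validated subtree
# selection.  The collapse sequence itself is computed in compiled code; R
# handles fold bookkeeping and the selection rule.

PRUNE_TOL <- 1e-9

#' Weakest-link cost-complexity pruning sequence
#'
#' Repeatedly collapses the internal node(s) with the smallest link strength
#' `g(t) = (I(t) - sum of leaf impurities below t) / (leaves below t - 1)`,
#' recording the successive strengths as the alpha sequence.  The first entry
#' (alpha 0) is the grown tree with any zero-strength links already
#' collapsed; the last is the root-only tree.  Subtrees are strictly nested.
#'
#' @param tree a `rert_tree`.
#' @return a `rert_cp_path`: list with `alphas` (strictly increasing, from
#'   0), `n_leaves`, `leaf_flags` (logical collapse masks over the grown
#'   tree's nodes) and the grown tree.
#' @export
cost_complexity_path <- function(tree) {
  stopifnot(inherits(tree, "rert_tree"))
  cp <- cp_path_cpp(tree$nodes)
  structure(list(alphas = cp$alphas, n_leaves = cp$n_leaves,
                 leaf_flags = lapply(seq_along(cp$alphas),
                                     function(k) cp$flags[k, ]),
                 tree = tree),
            class = "rert_cp_path")
}

#' @export
print.rert_cp_path <- function(x, ...) {
  cat("<rert_cp_path>\n")
  print(data.frame(alpha = x$alphas, n_leaves = x$n_leaves,
                   row.names = NULL))
  invisible(x)
}

#' Extract the pruned subtree for a given complexity penalty
#' @param path a `rert_cp_path`.
#' @param alpha penalty; the subtree optimal for this alpha is returned.
#' @return a `rert_tree`.
#' @export
prune_at <- function(path, alpha) {
  k <- max(which(path$alphas <= alpha + PRUNE_TOL))
  extract_subtree(path$tree, path$leaf_flags[[k]])
}

#' Cross-validated subtree selection
#'
#' Grows the full tree, computes its pruning sequence, estimates the
#' cross-validated squared error of each alpha with outcome-stratified folds
#' (fold trees are grown and pruned independently, held-out rows scored at
#' the geometric-mean representative alpha of each interval), and returns the
#' subtree at the alpha minimizing CV error.  Equal CV errors go to the
#' smaller subtree, then the smaller alpha index.
#'
#' @param x a `rert_cohort` with both outcome classes present.
#' @param params a [grow_params()]; `v_folds` and `seed` drive the folds.
#' @return a `rert_tree` with attribute `cptable` (alpha, leaf count, CV
#'   error and its standard error per pruning step) and `selected_alpha`.
#' @export
select_subtree_cv <- function(x, params = grow_params()) {
  stopifnot(inherits(x, "rert_cohort"))
  check_two_classes(x, "cross-validated selection")
  if (x$n < params$v_folds) {
    stop("n = ", x$n, " is smaller than v_folds = ", params$v_folds,
         call. = FALSE)
  }
  full <- grow_tree(x, params)
  path <- cost_complexity_path(full)
  K <- length(path$alphas)
  # representative alpha per interval [alpha_k, alpha_{k+1})
  rep_alpha <- c(if (K > 1) sqrt(path$alphas[-K] * path$alphas[-1]), Inf)

  fold <- stratified_folds(x$outcome, params$v_folds, params$seed)
  sqerr <- matrix(NA_real_, x$n, K)
  cm <- cohort_matrix(x)
  for (f in seq_len(params$v_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    ftree <- grow_tree(x, params, rows = train)
    fpath <- cp_path_cpp(ftree$nodes)
    Xtest <- cm$X[test, , drop = FALSE]
    for (k in seq_len(K)) {
      kk <- max(which(fpath$alphas <= rep_alpha[k] + PRUNE_TOL))
      pred <- predict_tree_cpp(ftree$nodes, Xtest,
                               as.integer(fpath$flags[kk, ]))
      sqerr[test, k] <- (x$outcome[test] - pred)^2
    }
  }
  cv_err <- colMeans(sqerr)
  cv_se <- apply(sqerr, 2, sd) / sqrt(x$n)
  best <- min(cv_err)
  cand <- which(cv_err <= best + 1e-12)
  k_sel <- cand[which.min(path$n_leaves[cand])] # ties: fewer leaves, then
  # smaller index (which.min returns the first minimum)
  out <- extract_subtree(full, path$leaf_flags[[k_sel]])
  attr(out, "cptable") <- data.frame(alpha = path$alphas,
                                     n_leaves = path$n_leaves,
                                     cv_error = cv_err, cv_se = cv_se)
  attr(out, "selected_alpha") <- path$alphas[k_sel]
  out
}
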