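# Independent reference implementations used as oracles.  These are written
# from the definitions (direct sums, exhaustive enumeration, O(n^2) pair
# scans) and deliberately share no code with the package internals.

# --- exhaustive CART reference (complete data, numeric covariates) --------

oracle_impurity <- function(y) sum((y - mean(y))^2)

# Exhaustive search over all covariates and all midpoint thresholds.
# Ties (within 1e-9) keep the earlier covariate, then the smaller threshold.
oracle_best_split <- function(X, y, min_leaf, cp_abs) {
  best <- NULL
  best_gain <- 0
  I0 <- oracle_impurity(y)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    mids <- (u[-length(u)] + u[-1]) / 2
    for (t in mids) {
      L <- X[, j] < t
      if (sum(L) < min_leaf || sum(!L) < min_leaf) next
      gain <- I0 - oracle_impurity(y[L]) - oracle_impurity(y[!L])
      if (gain > best_gain + 1e-9) {
        best_gain <- gain
        best <- list(var = j, threshold = t, gain = gain)
      }
    }
  }
  if (is.null(best) || best$gain < cp_abs - 1e-12) return(NULL)
  best
}

oracle_grow <- function(X, y, min_split = 20, min_leaf = 7, max_depth = 30,
                        cp = 0.01) {
  cp_abs <- cp * oracle_impurity(y)
  rec <- function(idx, depth) {
    yy <- y[idx]
    node <- list(n = length(idx), n_pos = sum(yy), yhat = mean(yy),
                 impurity = oracle_impurity(yy))
    if (length(idx) >= min_split && depth < max_depth &&
        node$n_pos > 0 && node$n_pos < node$n) {
      sp <- oracle_best_split(X[idx, , drop = FALSE], yy, min_leaf, cp_abs)
      if (!is.null(sp)) {
        node$var <- sp$var
        node$threshold <- sp$threshold
        L <- X[idx, sp$var] < sp$threshold
        node$left <- rec(idx[L], depth + 1)
        node$right <- rec(idx[!L], depth + 1)
      }
    }
    node
  }
  rec(seq_along(y), 0)
}

# Preorder (var, threshold, n, n_pos) flattening for split-for-split
# comparison.
oracle_flatten <- function(node) {
  if (is.null(node$var)) {
    return(data.frame(var = 0, threshold = NA_real_, n = node$n,
                      n_pos = node$n_pos))
  }
  rbind(data.frame(var = node$var, threshold = node$threshold, n = node$n,
                   n_pos = node$n_pos),
        oracle_flatten(node$left), oracle_flatten(node$right))
}

tree_flatten <- function(tree) {
  nd <- tree$nodes
  data.frame(var = nd[, "var"], threshold = nd[, "threshold"],
             n = nd[, "n"], n_pos = nd[, "n_pos"], row.names = NULL)
}

# All pruned subtrees of an oracle tree (brute-force enumeration), each as a
# list(tree, n_leaves, train_err_sum).  A pruned subtree is obtained by
# collapsing any antichain of internal nodes.
oracle_all_subtrees <- function(node) {
  if (is.null(node$var)) {
    return(list(list(tree = node, n_leaves = 1,
                     sse = node$impurity)))
  }
  collapsed <- node
  collapsed$var <- collapsed$left <- collapsed$right <-
    collapsed$threshold <- NULL
  out <- list(list(tree = collapsed, n_leaves = 1, sse = node$impurity))
  for (ls in oracle_all_subtrees(node$left)) {
    for (rs in oracle_all_subtrees(node$right)) {
      t2 <- node
      t2$left <- ls$tree
      t2$right <- rs$tree
      out <- c(out, list(list(tree = t2, n_leaves = ls$n_leaves + rs$n_leaves,
                              sse = ls$sse + rs$sse)))
    }
  }
  out
}

# Smallest subtree minimizing sse + alpha * n_leaves (the cost-complexity
# optimum, by full enumeration).
oracle_prune_at <- function(node, alpha) {
  subs <- oracle_all_subtrees(node)
  cost <- vapply(subs, function(s) s$sse + alpha * s$n_leaves, 0)
  leaves <- vapply(subs, function(s) s$n_leaves, 0)
  cand <- which(cost <= min(cost) + 1e-9)
  subs[[cand[which.min(leaves[cand])]]]$tree
}

oracle_predict1 <- function(node, x) {
  while (!is.null(node$var)) {
    node <- if (x[node$var] < node$threshold) node$left else node$right
  }
  node$yhat
}

# --- AUC / DeLong oracles -------------------------------------------------

# AUC by O(n_pos * n_neg) pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# DeLong variance of AUC_a - AUC_b via explicit O(n^2) placement values.
oracle_delong <- function(sa, sb, labels) {
  place <- function(s) {
    pos <- s[labels == 1]
    neg <- s[labels == 0]
    v10 <- apply(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)),
                 1, mean)
    v01 <- apply(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)),
                 2, mean)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- place(sa)
  pb <- place(sb)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  var_diff <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
       z = (pa$auc - pb$auc) / sqrt(var_diff))
}

# Trapezoid area under a ROC curve object.
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

# --- small cohort builders ------------------------------------------------

# Numeric-only cohort from a matrix/data.frame of quantitative covariates.
make_cohort <- function(X, y, stratum = NULL) {
  X <- as.data.frame(X)
  schema <- lapply(names(X), function(nm) covariate_spec(nm, "quantitative"))
  names(schema) <- names(X)
  cohort(X, schema, y, stratum %||% rep("all", length(y)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_cohort <- function(n, p, seed, prevalence = 0.4,
                          discrete = FALSE) {
  set.seed(seed)
  X <- if (discrete) {
    matrix(sample(1:6, n * p, replace = TRUE) + 0, n, p)
  } else {
    matrix(round(rnorm(n * p), 2), n, p)
  }
  colnames(X) <- paste0("x", seq_len(p))
  y <- rbinom(n, 1, prevalence)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  make_cohort(X, y)
}
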