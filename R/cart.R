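# Regression trees on a 0/1 outcome: growing, prediction, serialization.
# Each leaf predicts the relative frequency of positives among its members.

#' Growing parameters for regression trees
#'
#' Defaults follow the common recursive-partitioning conventions: a node is
#' eligible to split from 20 members, children keep at least 7, and a split
#' must reduce impurity by at least `cp` times the root impurity.
#'
#' @param min_split smallest node eligible to split.
#' @param min_leaf smallest allowed child (counted on observed values of the
#'   split covariate).
#' @param max_depth maximum tree depth (root at depth 0).
#' @param cp complexity floor: minimum impurity decrease expressed as a
#'   fraction of the root impurity.
#' @param v_folds folds for cross-validated subtree selection.
#' @param seed integer seed for fold assignment.
#' @return a `grow_params` object.
#' @export
grow_params <- function(min_split = 20, min_leaf = 7, max_depth = 30,
                        cp = 0.01, v_folds = 10, seed = 1) {
  stopifnot(min_leaf >= 1, min_split >= 2 * min_leaf, max_depth >= 1,
            cp >= 0, v_folds >= 2)
  structure(list(min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 cp = cp, v_folds = as.integer(v_folds),
                 seed = as.integer(seed)),
            class = "grow_params")
}

#' Squared-error impurity of a 0/1 multiset
#'
#' Returns the sum of squared deviations from the node mean, which for a
#' binary outcome equals `n * p * (1 - p)` with `p` the positive fraction.
#'
#' @param y vector of 0/1 values (no missing).
#' @return nonnegative impurity.
#' @export
node_impurity <- function(y) {
  if (length(y) == 0) stop("impurity of an empty node is undefined",
                           call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("y must be 0/1 with no missing values", call. = FALSE)
  }
  s <- sum(y)
  n <- length(y)
  s - s * s / n
}

new_tree <- function(nodes, cohort, params) {
  structure(list(nodes = nodes,
                 covariates = names(cohort$schema),
                 schema = cohort$schema,
                 params = params),
            class = "rert_tree")
}

#' Grow an unpruned regression tree
#'
#' Recursive partitioning with squared-error impurity: at each node the split
#' maximizing the observed-value impurity decrease is taken, thresholds at
#' midpoints of consecutive distinct observed values, nominal covariates via
#' the within-level-mean ordering.  Cases missing the split covariate follow
#' the child holding the majority of observed members (direction frozen at
#' fit time).  Equal-gain ties go to the covariate earlier in schema order,
#' then the smaller threshold.  A single-class cohort yields a root-only tree.
#'
#' @param x a `rert_cohort`.
#' @param params a [grow_params()].
#' @param rows optional integer row indices to grow on (default all rows).
#' @return a `rert_tree`.
#' @export
grow_tree <- function(x, params = grow_params(), rows = NULL) {
  stopifnot(inherits(x, "rert_cohort"), inherits(params, "grow_params"))
  cm <- cohort_matrix(x)
  rows <- if (is.null(rows)) seq_len(x$n) else as.integer(rows)
  nodes <- grow_tree_cpp(cm$X, x$outcome, cm$kind, rows,
                         params$min_split, params$min_leaf, params$max_depth,
                         params$cp, length(cm$kind))
  new_tree(nodes, x, params)
}

#' Best single split of a cohort (or return NULL)
#'
#' Searches all covariates under the stated tie rules and returns the
#' accepted root split, or `NULL` when no admissible split exists (node too
#' small, pure outcome, best gain below the complexity floor, or all
#' covariates entirely missing).
#'
#' @inheritParams grow_tree
#' @return a list with `covariate`, `form` (`"threshold"` or
#'   `"level-subset"`), `threshold` or `left_levels`, `surrogate_direction`
#'   and `gain`, or `NULL`.
#' @export
best_split <- function(x, params = grow_params(), rows = NULL) {
  p1 <- params
  p1$max_depth <- 1L
  tr <- grow_tree(x, p1, rows)
  if (nrow(tr$nodes) == 1) return(NULL)
  split_info(tr, 1L)
}

split_info <- function(tree, i) {
  nd <- tree$nodes
  v <- nd[i, "var"]
  if (v == 0) return(NULL)
  nominal <- nd[i, "nominal"] == 1
  list(covariate = tree$covariates[v],
       form = if (nominal) "level-subset" else "threshold",
       threshold = if (nominal) NA_real_ else unname(nd[i, "threshold"]),
       left_levels = if (nominal) which(bitwAnd(
         as.integer(nd[i, "mask"]), bitwShiftL(1L, 0:30)) != 0),
       surrogate_direction = c("left", "right")[nd[i, "miss_dir"]],
       gain = unname(nd[i, "gain"]))
}

#' Predict event probabilities from a tree
#'
#' Routes records through the split rules; records missing a split covariate
#' follow the stored surrogate direction.  Returns the leaf relative
#' frequency for each row.
#'
#' @param object a `rert_tree`.
#' @param newdata a `rert_cohort` or a data.frame encoded like its `data`.
#' @param ... unused.
#' @return numeric vector of predictions in `[0, 1]`.
#' @export
predict.rert_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "rert_cohort")) {
    if (!all(object$covariates %in% names(newdata$schema))) {
      stop("cohort lacks covariate(s) the tree splits on", call. = FALSE)
    }
    X <- cohort_matrix(newdata)$X[, object$covariates, drop = FALSE]
  } else {
    if (!all(object$covariates %in% names(newdata))) {
      stop("newdata lacks covariate(s): ",
           paste(setdiff(object$covariates, names(newdata)), collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(newdata[object$covariates])
    storage.mode(X) <- "double"
  }
  predict_tree_cpp(object$nodes, X, integer(nrow(object$nodes)))
}

#' Number of leaves of a tree
#' @param tree a `rert_tree`.
#' @return integer leaf count.
#' @export
n_leaves <- function(tree) sum(tree$nodes[, "var"] == 0)

# leaf rows in preorder = left-to-right display order
leaf_ids <- function(tree) which(tree$nodes[, "var"] == 0)

root_split <- function(tree) split_info(tree, 1L)

# Materialize the subtree implied by leaf_flag (1 = collapse to leaf) into a
# standalone tree with preorder-renumbered nodes.
extract_subtree <- function(tree, leaf_flag) {
  nd <- tree$nodes
  keep <- logical(nrow(nd))
  order_new <- integer(0)
  walk <- function(i) {
    keep[i] <<- TRUE
    order_new <<- c(order_new, i)
    if (nd[i, "var"] != 0 && !leaf_flag[i]) {
      walk(nd[i, "left"])
      walk(nd[i, "right"])
    }
  }
  walk(1L)
  remap <- integer(nrow(nd))
  remap[order_new] <- seq_along(order_new)
  out <- nd[order_new, , drop = FALSE]
  for (k in seq_len(nrow(out))) {
    old <- order_new[k]
    if (nd[old, "var"] != 0 && !leaf_flag[old]) {
      out[k, "left"] <- remap[nd[old, "left"]]
      out[k, "right"] <- remap[nd[old, "right"]]
    } else {
      out[k, c("left", "right")] <- 0
      out[k, c("var", "mask", "nominal", "miss_dir", "gain")] <- 0
      out[k, "threshold"] <- NA_real_
    }
    out[k, "parent"] <- if (k == 1) 0 else remap[nd[old, "parent"]]
  }
  tr <- tree
  tr$nodes <- out
  tr
}

split_label <- function(tree, i) {
  s <- split_info(tree, i)
  if (is.null(s)) return("<leaf>")
  if (s$form == "threshold") {
    sprintf("%s >= %s", s$covariate, format(s$threshold, digits = 6))
  } else {
    lv <- tree$schema[[s$covariate]]$levels
    sprintf("%s in {%s}", s$covariate,
            paste(lv[s$left_levels], collapse = ","))
  }
}

#' @export
print.rert_tree <- function(x, ...) {
  nd <- x$nodes
  cat("<rert_tree>", nrow(nd), "nodes,", n_leaves(x), "leaves, n =",
      nd[1, "n"], "\n")
  rec <- function(i, prefix) {
    if (nd[i, "var"] == 0) {
      cat(sprintf("%s* yhat = %.3f (n = %d, pos = %d)\n", prefix,
                  nd[i, "yhat"], as.integer(nd[i, "n"]),
                  as.integer(nd[i, "n_pos"])))
    } else {
      lab <- split_label(x, i)
      miss <- c("left", "right")[nd[i, "miss_dir"]]
      cat(sprintf("%s%s  [no -> left | missing -> %s]\n", prefix, lab, miss))
      rec(nd[i, "left"], paste0(prefix, "  "))
      rec(nd[i, "right"], paste0(prefix, "  "))
    }
  }
  rec(1L, "")
  invisible(x)
}

#' Serialize a tree to JSON
#'
#' Captures nodes (splits, counts, leaf frequencies), covariate names and
#' growing parameters; [tree_from_json()] restores an identical tree.
#'
#' @param tree a `rert_tree`.
#' @return a JSON string.
#' @export
tree_to_json <- function(tree) {
  nd <- as.data.frame(tree$nodes)
  lev <- lapply(tree$schema, function(s) s$levels %||% character(0))
  kind <- vapply(tree$schema, `[[`, "", "kind")
  jsonlite::toJSON(list(nodes = nd, covariates = tree$covariates,
                        kinds = kind, levels = lev,
                        params = unclass(tree$params)),
                   digits = NA, auto_unbox = TRUE)
}

#' Restore a tree serialized by [tree_to_json()]
#' @param json JSON string or file path.
#' @return a `rert_tree`.
#' @export
tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  nodes <- as.matrix(x$nodes)
  dimnames(nodes) <- list(NULL, colnames(nodes))
  schema <- lapply(seq_along(x$covariates), function(i) {
    nm <- x$covariates[i]
    covariate_spec(nm, x$kinds[[i]],
                   levels = if (length(x$levels[[nm]])) unlist(x$levels[[nm]]))
  })
  names(schema) <- x$covariates
  p <- x$params
  structure(list(nodes = nodes, covariates = x$covariates, schema = schema,
                 params = grow_params(p$min_split, p$min_leaf, p$max_depth,
                                      p$cp, p$v_folds, p$seed)),
            class = "rert_tree")
}
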