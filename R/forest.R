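# Random forest of regression trees with Total Decrease in Node Impurity
# (TDNI) relative variable importance — the driver-screening step.

#' Random-forest parameters
#'
#' @param n_trees number of bootstrap trees (the screening runs described in
#'   the package documentation use 10000; simulations use fewer).
#' @param mtry covariates sampled without replacement at every split;
#'   `NULL` means the regression-forest convention `max(1, floor(p / 3))`.
#' @param min_leaf smallest allowed child in the unpruned trees.
#' @param seed integer seed.
#' @return a `forest_params` object.
#' @export
forest_params <- function(n_trees = 10000, mtry = NULL, min_leaf = 5,
                          seed = 1) {
  stopifnot(n_trees >= 1, min_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "forest_params")
}

#' Grow a random forest
#'
#' `n_trees` unpruned regression trees, each on an (unstratified) bootstrap
#' sample of the cohort rows, with `mtry` covariates sampled uniformly at
#' every split.  Used for importance screening, not prediction.
#'
#' @param x a `rert_cohort` with both outcome classes present.
#' @param params a [forest_params()].
#' @param bootstrap set `FALSE` to grow every tree on the original rows
#'   (test hook; with `mtry = p` and `n_trees = 1` this reduces to a single
#'   unpruned [grow_tree()]).
#' @return a `rert_forest`: per-tree node matrices plus the per-tree summed
#'   impurity decreases attributed to each covariate.
#' @export
grow_forest <- function(x, params = forest_params(), bootstrap = TRUE) {
  stopifnot(inherits(x, "rert_cohort"), inherits(params, "forest_params"))
  check_two_classes(x)
  cm <- cohort_matrix(x)
  p <- length(cm$kind)
  mtry <- params$mtry %||% max(1L, p %/% 3L)
  if (mtry < 1 || mtry > p) {
    stop("mtry must lie in [1, ", p, "]", call. = FALSE)
  }
  res <- with_seed(params$seed,
    grow_forest_cpp(cm$X, x$outcome, cm$kind, params$n_trees, mtry,
                    2L * params$min_leaf, params$min_leaf, 30L, bootstrap))
  colnames(res$gains) <- cm$names
  structure(list(trees = res$trees, gains = res$gains,
                 covariates = cm$names, params = params, mtry = mtry),
            class = "rert_forest")
}

#' @export
print.rert_forest <- function(x, ...) {
  cat("<rert_forest>", length(x$trees), "trees, mtry =", x$mtry, "\n")
  invisible(x)
}

#' Total Decrease in Node Impurity importance
#'
#' Raw TDNI of covariate j is the mean over trees of the summed impurity
#' decreases of all splits on j; relative importance rescales so the top
#' covariate sits at 100.  A forest of root-only trees yields all-zero
#' importance with a warning.
#'
#' @param forest a `rert_forest`.
#' @return a `rert_importance` data.frame with columns `covariate`,
#'   `raw_tdni` and `relative`, sorted by descending importance; attribute
#'   `degenerate` flags the all-zero case.
#' @export
tdni_importance <- function(forest) {
  stopifnot(inherits(forest, "rert_forest"))
  raw <- colMeans(forest$gains)
  degenerate <- all(raw == 0)
  rel <- if (degenerate) {
    warning("all trees are root-only; importance is undefined (reported 0)")
    raw
  } else {
    100 * raw / max(raw)
  }
  out <- data.frame(covariate = names(raw), raw_tdni = unname(raw),
                    relative = unname(rel), row.names = NULL)
  out <- out[order(-out$relative, out$covariate), ]
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  class(out) <- c("rert_importance", "data.frame")
  out
}

#' Screen covariates by relative importance
#'
#' @param importance a `rert_importance` table.
#' @param cutoff driver threshold on the 0-100 relative scale (the screening
#'   rule used throughout the package documentation is 60).
#' @return character vector of covariates with `relative >= cutoff` and
#'   nonzero raw TDNI, in descending importance order.
#' @export
select_drivers <- function(importance, cutoff = 60) {
  stopifnot(inherits(importance, "rert_importance"))
  sel <- importance$relative >= cutoff & importance$raw_tdni > 0
  importance$covariate[sel]
}
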