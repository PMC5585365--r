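# The representative-regression-tree (RERT) procedure: B stratified-bootstrap
# cross-validated trees, each scored by AUC on the data it was selected for;
# the best performer is the representative tree.  Honest performance comes
# from nested cross-validation in which the whole selection is rerun per fold.

#' RERT parameters
#'
#' @param n_boot number of bootstrap candidates B (the procedure's reference
#'   run uses 1000).
#' @param grow a [grow_params()] for candidate growing/pruning.
#' @param eval_folds folds of the nested honest evaluation.
#' @param seed integer master seed; all bootstrap draws and fold assignments
#'   derive from it via [derive_seed()].
#' @param nested compute nested cross-validated scores (can be disabled for
#'   selection-only experiments).
#' @return a `rert_params` object.
#' @export
rert_params <- function(n_boot = 1000, grow = grow_params(), eval_folds = 10,
                        seed = 1, nested = TRUE) {
  stopifnot(n_boot >= 1, eval_folds >= 2, inherits(grow, "grow_params"))
  structure(list(n_boot = as.integer(n_boot), grow = grow,
                 eval_folds = as.integer(eval_folds),
                 seed = as.integer(seed), nested = isTRUE(nested)),
            class = "rert_params")
}

#' Stratified bootstrap of a cohort
#'
#' Draws, within each stratum of size `n_s`, exactly `n_s` rows with
#' replacement, so stratum counts are preserved on every draw.
#'
#' @param x a `rert_cohort`.
#' @param seed optional seed (caller-managed RNG when `NULL`).
#' @return integer row indices of length `n`.
#' @export
stratified_bootstrap <- function(x, seed = NULL) {
  stopifnot(inherits(x, "rert_cohort"))
  with_seed(seed, {
    idx <- integer(0)
    for (s in unique(x$stratum)) {
      rows <- which(x$stratum == s)
      idx <- c(idx, sample(rows, length(rows), replace = TRUE))
    }
    idx
  })
}

# One full B-candidate selection on `x`; scores candidates on all rows of
# `x`.  Returns the winner and the ensemble bookkeeping.
rert_select <- function(x, params, base_seed) {
  B <- params$n_boot
  aucs <- numeric(B)
  summaries <- vector("list", B)
  best <- NULL
  n_resampled <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      sub_seed <- derive_seed(base_seed, b, attempt)
      idx <- stratified_bootstrap(x, seed = sub_seed)
      if (length(unique(x$outcome[idx])) == 2) break
      attempt <- attempt + 1L
      n_resampled <- n_resampled + 1L
      if (attempt > 1000L) {
        stop("all bootstrap candidates degenerate (single-class samples)",
             call. = FALSE)
      }
    }
    samp <- cohort_subset(x, idx)
    gp <- params$grow
    gp$seed <- derive_seed(base_seed, b, attempt, 1L)
    tree <- select_subtree_cv(samp, gp)
    scores <- predict(tree, x)
    auc <- tryCatch(roc_auc(scores, x$outcome)$auc, error = function(e) 0.5)
    aucs[b] <- auc
    rs <- root_split(tree)
    summaries[[b]] <- data.frame(
      b = b, auc = auc, n_leaves = n_leaves(tree),
      root_covariate = if (is.null(rs)) NA_character_ else rs$covariate,
      root_threshold = if (is.null(rs)) NA_real_ else rs$threshold,
      stringsAsFactors = FALSE)
    better <- is.null(best) ||
      auc > best$auc + 1e-12 ||
      (abs(auc - best$auc) <= 1e-12 && n_leaves(tree) < best$leaves)
    if (better) {
      best <- list(tree = tree, auc = auc, leaves = n_leaves(tree), b = b)
    }
  }
  list(tree = best$tree, auc = best$auc, b = best$b, aucs = aucs,
       summaries = do.call(rbind, summaries), n_resampled = n_resampled)
}

#' Fit a representative regression tree
#'
#' Draws `n_boot` histotype-stratified bootstrap samples, grows and
#' CV-prunes a tree on each, scores every candidate by AUC on the full
#' cohort, and returns the best performer (ties: fewer leaves, then lower
#' replicate index).  Bootstrap samples with a single outcome class are
#' resampled under an incremented sub-seed so the ensemble always has
#' exactly `n_boot` members.  When `params$nested` is `TRUE`, honest
#' out-of-fold scores are additionally computed by rerunning the entire
#' selection inside each of `eval_folds` outcome-stratified folds.
#'
#' @param x a `rert_cohort` with both outcome classes present.
#' @param params a [rert_params()].
#' @return a `rert_fit` with elements `representative` (the selected
#'   `rert_tree`), `selection_auc` (its apparent full-cohort AUC),
#'   `ensemble_aucs`, `candidate_summaries`, `cv_scores` (one nested
#'   out-of-fold prediction per row, or `NULL`) and `cv_auc`.
#' @export
fit_rert <- function(x, params = rert_params()) {
  stopifnot(inherits(x, "rert_cohort"), inherits(params, "rert_params"))
  check_two_classes(x)
  sel <- rert_select(x, params, params$seed)

  cv_scores <- NULL
  cv_auc <- NA_real_
  if (params$nested) {
    fold <- stratified_folds(x$outcome, params$eval_folds,
                             derive_seed(params$seed, 999983L))
    cv_scores <- numeric(x$n)
    for (f in seq_len(params$eval_folds)) {
      test <- which(fold == f)
      train_cohort <- cohort_subset(x, which(fold != f))
      check_two_classes(train_cohort, "nested evaluation")
      fsel <- rert_select(train_cohort, params,
                          derive_seed(params$seed, 500009L, f))
      cv_scores[test] <- predict(fsel$tree, cohort_subset(x, test))
    }
    cv_auc <- roc_auc(cv_scores, x$outcome)$auc
  }

  structure(list(representative = sel$tree, selection_auc = sel$auc,
                 selection_b = sel$b, ensemble_aucs = sel$aucs,
                 candidate_summaries = sel$summaries,
                 n_resampled = sel$n_resampled,
                 cv_scores = cv_scores, cv_auc = cv_auc,
                 outcome = x$outcome, params = params),
            class = "rert_fit")
}

#' @export
print.rert_fit <- function(x, ...) {
  cat("<rert_fit> B =", length(x$ensemble_aucs), "candidates\n")
  cat(sprintf("selection AUC (apparent): %.3f at b = %d, %d leaves\n",
              x$selection_auc, x$selection_b, n_leaves(x$representative)))
  if (!is.null(x$cv_scores)) {
    cat(sprintf("nested %d-fold CV AUC (honest): %.3f\n",
                x$params$eval_folds, x$cv_auc))
  }
  cat(sprintf("ensemble AUC: median %.3f, IQR [%.3f, %.3f]\n",
              median(x$ensemble_aucs),
              quantile(x$ensemble_aucs, 0.25),
              quantile(x$ensemble_aucs, 0.75)))
  invisible(x)
}

#' Agreement among high-AUC candidates
#'
#' Among candidates whose apparent AUC exceeds `auc_floor`, reports the
#' modal root covariate, the fraction of candidates sharing it, and the
#' interquartile range of their root thresholds — the stability summary
#' motivating the choice of a single representative tree.
#'
#' @param fit a `rert_fit`.
#' @param auc_floor AUC threshold (default 0.80).
#' @return a `rert_consensus` list; `empty = TRUE` when no candidate clears
#'   the floor.
#' @export
consensus_report <- function(fit, auc_floor = 0.80) {
  stopifnot(inherits(fit, "rert_fit"))
  cs <- fit$candidate_summaries
  hi <- cs[cs$auc > auc_floor, , drop = FALSE]
  if (nrow(hi) == 0) {
    return(structure(list(empty = TRUE, auc_floor = auc_floor,
                          n_candidates = 0L),
                     class = "rert_consensus"))
  }
  roots <- ifelse(is.na(hi$root_covariate), "<leaf>", hi$root_covariate)
  tab <- sort(table(roots), decreasing = TRUE)
  modal <- names(tab)[1]
  thr <- hi$root_threshold[roots == modal & !is.na(hi$root_threshold)]
  iqr <- if (length(thr)) unname(quantile(thr, c(0.25, 0.75)))
         else c(NA_real_, NA_real_)
  structure(list(empty = FALSE, auc_floor = auc_floor,
                 n_candidates = nrow(hi), modal_root = modal,
                 agreement = unname(tab[1]) / nrow(hi),
                 threshold_iqr = iqr),
            class = "rert_consensus")
}

#' @export
print.rert_consensus <- function(x, ...) {
  if (x$empty) {
    cat("<rert_consensus> no candidate above AUC", x$auc_floor, "\n")
    return(invisible(x))
  }
  cat("<rert_consensus>", x$n_candidates, "candidates above AUC",
      x$auc_floor, "\n")
  cat(sprintf("modal root: %s (agreement %.2f)\n", x$modal_root,
              x$agreement))
  if (!anyNA(x$threshold_iqr)) {
    cat(sprintf("root threshold IQR: [%.3f, %.3f]\n",
                x$threshold_iqr[1], x$threshold_iqr[2]))
  }
  invisible(x)
}
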