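# End-to-end two-step run (importance screening -> representative tree),
# table/figure export, and the annotated DOT flow-chart.

#' Export a tree as a DOT flow-chart
#'
#' Internal nodes are labeled with their split condition ("covariate >=
#' threshold", no-branch to the left) and the missing-value direction;
#' leaves are numbered left-to-right and labeled with their relative
#' frequency and size.  The edge into a leaf is colored red when the leaf
#' frequency reaches `risk_threshold`, green otherwise; leaf boxes are
#' filled the same way.
#'
#' @param tree a `rert_tree`.
#' @param risk_threshold operating point for the red/green coloring
#'   (typically the Youden threshold of the honest CV scores).
#' @return DOT digraph text (invisibly writable with [writeLines()]).
#' @export
export_flowchart <- function(tree, risk_threshold = 0.5) {
  stopifnot(inherits(tree, "rert_tree"))
  nd <- tree$nodes
  lines <- c("digraph rert {",
             "  node [shape=box, fontname=\"Helvetica\"];")
  leaf_no <- 0L
  emit <- function(i) {
    if (nd[i, "var"] == 0) {
      leaf_no <<- leaf_no + 1L
      col <- if (nd[i, "yhat"] >= risk_threshold) "red" else "green"
      lines <<- c(lines, sprintf(
        "  n%d [label=\"Leaf %d\\nyhat = %s\\nn = %d\", style=filled, fillcolor=%s];",
        i, leaf_no, format(round(nd[i, "yhat"], 3)), as.integer(nd[i, "n"]),
        if (col == "red") "\"#f4cccc\"" else "\"#d9ead3\""))
    } else {
      miss <- c("left", "right")[nd[i, "miss_dir"]]
      lines <<- c(lines, sprintf(
        "  n%d [label=\"%s\\n(missing -> %s)\"];",
        i, gsub("\"", "'", split_label(tree, i)), miss))
      for (side in c("left", "right")) {
        ch <- nd[i, side]
        lab <- if (side == "left") "no" else "yes"
        col <- if (nd[ch, "var"] == 0) {
          if (nd[ch, "yhat"] >= risk_threshold) "red" else "green"
        } else "black"
        lines <<- c(lines, sprintf(
          "  n%d -> n%d [label=\"%s\", color=%s];", i, ch, lab, col))
        emit(ch)
      }
    }
  }
  emit(1L)
  paste(c(lines, "}"), collapse = "\n")
}

svg_importance_chart <- function(importance, path) {
  imp <- importance[order(importance$relative), ]
  k <- nrow(imp)
  bar_h <- 18
  gap <- 8
  left <- 130
  width <- 460
  height <- k * (bar_h + gap) + 40
  lines <- c(sprintf(
    "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\">",
    left + width + 60, height),
    "<style>text{font-family:Helvetica;font-size:12px;}</style>")
  for (i in seq_len(k)) {
    y <- 20 + (k - i) * (bar_h + gap)
    w <- imp$relative[i] / 100 * width
    lines <- c(lines,
      sprintf("<text x=\"%d\" y=\"%.0f\" text-anchor=\"end\">%s</text>",
              left - 6, y + bar_h - 4, imp$covariate[i]),
      sprintf(paste0("<rect x=\"%d\" y=\"%.0f\" width=\"%.2f\" ",
                     "height=\"%d\" fill=\"#4f81bd\"/>"),
              left, y, max(w, 0.5), bar_h),
      sprintf("<text x=\"%.2f\" y=\"%.0f\">%.1f</text>",
              left + w + 4, y + bar_h - 4, imp$relative[i]))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

method_scores <- function(x, method, rert_fit_obj, grow, seed) {
  n <- x$n
  switch(method,
    he4 = list(scores = x$data$he4, labels = x$outcome,
               keep = !is.na(x$data$he4)),
    ca125 = list(scores = x$data$ca125, labels = x$outcome,
                 keep = !is.na(x$data$ca125)),
    clinical_stage = list(scores = x$data$clinical_stage, labels = x$outcome,
                          keep = !is.na(x$data$clinical_stage)),
    logistic = {
      lb <- logistic_baseline(x)
      keep <- rep(FALSE, n)
      keep[lb$rows_used] <- TRUE
      sc <- rep(NA_real_, n)
      sc[lb$rows_used] <- lb$scores
      list(scores = sc, labels = x$outcome, keep = keep)
    },
    single_cv_tree = {
      # honest out-of-fold scores of a single CV-pruned tree
      fold <- stratified_folds(x$outcome, grow$v_folds,
                               derive_seed(seed, 424243L))
      sc <- numeric(n)
      for (f in seq_len(grow$v_folds)) {
        train <- cohort_subset(x, which(fold != f))
        gp <- grow
        gp$seed <- derive_seed(seed, 424243L, f)
        tr <- select_subtree_cv(train, gp)
        sc[fold == f] <- predict(tr, cohort_subset(x, which(fold == f)))
      }
      list(scores = sc, labels = x$outcome, keep = rep(TRUE, n))
    },
    rert = list(scores = rert_fit_obj$cv_scores, labels = x$outcome,
                keep = rep(TRUE, n)),
    stop("unknown comparator '", method, "'", call. = FALSE))
}

metric_rows <- c("ROC-AUC", "Threshold (Youden Index)", "Specificity",
                 "Sensitivity", "Accuracy", "PPV", "NPV")

metrics_column <- function(m) {
  c(m$auc, m$threshold, m$specificity, m$sensitivity, m$accuracy, m$ppv,
    m$npv)
}

#' Run the full two-step procedure and write its artifacts
#'
#' Step (i): random-forest importance screening with TDNI.  Step (ii):
#' representative-tree selection from a histotype-stratified bootstrap
#' ensemble with nested-CV honest scores.  Writes, under `out_dir`:
#' `importance.csv`, `importance.svg`, `rert_model.json`, `metrics.csv`
#' (one Youden-point column per method), `auc_comparisons.csv` (pairwise
#' DeLong tests of the representative tree against each comparator),
#' `rert_tree.dot`, and `run_manifest.json` recording every seed and
#' parameter.  Any stage error removes partial outputs.
#'
#' @param x a `rert_cohort`.
#' @param out_dir output directory (created if needed).
#' @param forest a [forest_params()].
#' @param rert a [rert_params()] (must have `nested = TRUE` for the metrics
#'   table).
#' @param comparators subset of `c("clinical_stage", "ca125", "he4",
#'   "logistic", "single_cv_tree")`.
#' @param driver_cutoff relative-importance screening threshold.
#' @return (invisibly) a list with the fitted objects and artifact paths.
#' @export
run_two_step <- function(x, out_dir,
                         forest = forest_params(),
                         rert = rert_params(),
                         comparators = c("clinical_stage", "ca125", "he4",
                                         "logistic", "single_cv_tree"),
                         driver_cutoff = 60) {
  stopifnot(inherits(x, "rert_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c(
    importance = "importance.csv", plot = "importance.svg",
    model = "rert_model.json", metrics = "metrics.csv",
    comparisons = "auc_comparisons.csv", flowchart = "rert_tree.dot",
    manifest = "run_manifest.json"))
  names(paths) <- c("importance", "plot", "model", "metrics", "comparisons",
                    "flowchart", "manifest")
  written <- character(0)
  stage <- "setup"
  on.exit(if (stage != "done") unlink(written), add = TRUE)
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  fr <- run_stage("importance", {
    fo <- grow_forest(x, forest)
    imp <- tdni_importance(fo)
    write.csv(imp, paths["importance"], row.names = FALSE)
    written <- c(written, paths["importance"])
    svg_importance_chart(imp, paths["plot"])
    written <- c(written, paths["plot"])
    list(forest = fo, importance = imp,
         drivers = select_drivers(imp, driver_cutoff))
  })

  fit <- run_stage("rert", {
    if (!rert$nested) stop("nested evaluation required for the metrics table")
    f <- fit_rert(x, rert)
    writeLines(as.character(jsonlite::toJSON(list(
      representative = jsonlite::fromJSON(tree_to_json(f$representative)),
      selection_auc = f$selection_auc,
      selection_b = f$selection_b,
      ensemble_aucs = f$ensemble_aucs,
      consensus = unclass(consensus_report(f)),
      cv_auc = f$cv_auc,
      cv_scores = f$cv_scores), digits = NA, auto_unbox = TRUE)),
      paths["model"])
    written <- c(written, paths["model"])
    f
  })

  tabs <- run_stage("metrics", {
    methods <- c(comparators, "rert")
    cols <- list()
    scores <- list()
    for (m in methods) {
      ms <- method_scores(x, m, fit, rert$grow, rert$seed)
      scores[[m]] <- ms
      rep <- metrics_report(ms$scores[ms$keep], ms$labels[ms$keep])
      cols[[m]] <- metrics_column(rep)
    }
    tab <- data.frame(Metric = metric_rows, check.names = FALSE)
    for (m in methods) tab[[m]] <- cols[[m]]
    write.csv(tab, paths["metrics"], row.names = FALSE)
    written <- c(written, paths["metrics"])

    cmp <- do.call(rbind, lapply(comparators, function(m) {
      keep <- scores[[m]]$keep
      dt <- delong_test(fit$cv_scores[keep], scores[[m]]$scores[keep],
                        x$outcome[keep])
      data.frame(method_a = "rert", method_b = m, auc_a = dt$auc_a,
                 auc_b = dt$auc_b, z = dt$statistic, p_value = dt$p_value,
                 test = "delong")
    }))
    write.csv(cmp, paths["comparisons"], row.names = FALSE)
    written <- c(written, paths["comparisons"])
    list(metrics = tab, comparisons = cmp)
  })

  run_stage("flowchart", {
    thr <- youden_threshold(fit$cv_scores, x$outcome)$threshold
    writeLines(export_flowchart(fit$representative, risk_threshold = thr),
               paths["flowchart"])
    written <- c(written, paths["flowchart"])
  })

  run_stage("manifest", {
    manifest <- list(
      package_version = as.character(utils::packageVersion("rert")),
      n = x$n, prevalence = mean(x$outcome),
      forest_params = unclass(forest), rert_params = list(
        n_boot = rert$n_boot, eval_folds = rert$eval_folds,
        seed = rert$seed, grow = unclass(rert$grow)),
      driver_cutoff = driver_cutoff, comparators = comparators,
      drivers = fr$drivers)
    writeLines(as.character(jsonlite::toJSON(manifest, digits = NA,
                                             auto_unbox = TRUE)),
               paths["manifest"])
    written <- c(written, paths["manifest"])
  })
  stage <- "done"
  invisible(list(forest = fr$forest, importance = fr$importance,
                 drivers = fr$drivers, fit = fit,
                 metrics = tabs$metrics, comparisons = tabs$comparisons,
                 paths = paths))
}
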