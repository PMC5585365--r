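# Nonparametric association tests, Pearson correlation and the logistic
# baseline.  Missing values are excluded from every test.

#' Association test between a covariate and a grouping variable
#'
#' A quantitative covariate against a 2-level grouping uses the
#' Wilcoxon-Mann-Whitney test (exact enumeration when both groups have at
#' most 8 observations and no ties; tie-corrected normal approximation
#' without continuity correction otherwise); more than 2 groups uses
#' Kruskal-Wallis.  Two categorical variables use Pearson's chi-squared
#' without continuity correction.  Rows missing either variable are dropped.
#'
#' @param x a `rert_cohort`.
#' @param covariate name of the covariate under test.
#' @param group_by name of the grouping covariate, or `"outcome"` /
#'   `"stratum"`.
#' @return list with `statistic`, `p_value`, `method` and `n_used`.
#' @export
assoc_tests <- function(x, covariate, group_by) {
  stopifnot(inherits(x, "rert_cohort"))
  get_col <- function(nm) {
    if (nm == "outcome") return(list(v = x$outcome, kind = "binary"))
    if (nm == "stratum") {
      return(list(v = match(x$stratum, sort(unique(x$stratum))),
                  kind = "nominal"))
    }
    if (!nm %in% names(x$schema)) {
      stop("unknown covariate '", nm, "'", call. = FALSE)
    }
    list(v = x$data[[nm]], kind = x$schema[[nm]]$kind)
  }
  cv <- get_col(covariate)
  gv <- get_col(group_by)
  keep <- !is.na(cv$v) & !is.na(gv$v)
  v <- cv$v[keep]
  g <- gv$v[keep]
  groups <- sort(unique(g))
  sizes <- table(g)
  if (length(groups) < 2 || any(sizes < 2)) {
    small <- if (length(groups) < 2) "fewer than 2 groups remain" else
      paste0("group '", names(sizes)[which.min(sizes)],
             "' has fewer than 2 non-missing observations")
    stop("association test impossible: ", small, call. = FALSE)
  }

  if (cv$kind == "quantitative") {
    if (length(groups) == 2) {
      a <- v[g == groups[1]]
      b <- v[g == groups[2]]
      exact <- length(a) <= 8 && length(b) <= 8 &&
        !any(duplicated(c(a, b)))
      ht <- suppressWarnings(
        wilcox.test(a, b, exact = exact, correct = FALSE))
      method <- if (exact) "wilcoxon-exact" else "wilcoxon-normal"
    } else {
      ht <- kruskal.test(v, factor(g))
      method <- "kruskal-wallis"
    }
  } else {
    ht <- suppressWarnings(chisq.test(table(v, g), correct = FALSE))
    method <- "chi-squared"
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, n_used = length(v))
}

#' Pearson correlation with t-distribution p-value
#'
#' Pairwise deletion of missing values; requires at least 3 complete pairs.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p_value`, `n_used`; zero variance in either
#'   vector yields `rho = NA` with `flag = "degenerate"`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = length(x),
                flag = "degenerate"))
  }
  ht <- cor.test(x, y, method = "pearson")
  list(rho = unname(ht$estimate), p_value = ht$p.value, n_used = length(x))
}

#' Main-effects logistic-regression baseline
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of the outcome
#' on the selected covariates, with listwise deletion of incomplete rows
#' (the linear model cannot route missing values the way the trees do).
#' Quasi-separation and non-convergence are detected and flagged, never
#' silent.
#'
#' @param x a `rert_cohort`.
#' @param covariates covariate names (default: all).
#' @return list with `scores` (fitted probabilities for retained rows),
#'   `rows_used` (their indices), `n_dropped`, `labels` (their outcomes),
#'   `model` (the `glm` fit), and logical flags `converged`, `separation`.
#' @export
logistic_baseline <- function(x, covariates = NULL) {
  stopifnot(inherits(x, "rert_cohort"))
  check_two_classes(x, "logistic regression")
  covariates <- covariates %||% names(x$schema)
  stopifnot(all(covariates %in% names(x$schema)))
  df <- x$data[covariates]
  for (nm in covariates) {
    if (x$schema[[nm]]$kind == "nominal") df[[nm]] <- factor(df[[nm]])
  }
  df$.y <- x$outcome
  keep <- which(complete.cases(df))
  if (length(unique(x$outcome[keep])) < 2) {
    stop("both classes must survive listwise deletion", call. = FALSE)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = df[keep, , drop = FALSE]),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  list(scores = unname(fit$fitted.values), rows_used = keep,
       n_dropped = x$n - length(keep), labels = x$outcome[keep],
       model = fit, converged = fit$converged, separation = sep)
}
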