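# Paired AUC-comparison tests: DeLong (placement-value covariance) and a
# stratified paired bootstrap.

# Midrank placement values: for each positive, the fraction of negatives it
# outscores (ties half); and symmetrically for negatives.
placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Both score vectors are evaluated on the same labels (paired design).  AUCs
#' and their covariance are estimated from midrank placement values; the
#' difference is referred to a standard normal, two-sided.
#'
#' @param scores_a,scores_b paired risk scores.
#' @param labels shared 0/1 labels, both classes present.
#' @return a `rert_auc_comparison`: `auc_a`, `auc_b`, `statistic` (z),
#'   `p_value`, `var_diff`, `method = "delong"`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  var_diff <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0 || m == 1 || n == 1) {
    if (abs(d) < 1e-12) {
      z <- 0
      p <- 1
    } else {
      stop("degenerate DeLong variance with unequal AUCs", call. = FALSE)
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, statistic = z,
                 p_value = p, var_diff = var_diff, method = "delong"),
            class = "rert_auc_comparison")
}

#' Bootstrap test for two correlated AUCs
#'
#' Stratified (by label) paired bootstrap of rows; the observed AUC
#' difference is referred to a normal with the bootstrap standard deviation
#' of the difference, two-sided.
#'
#' @param scores_a,scores_b paired risk scores.
#' @param labels shared 0/1 labels.
#' @param n_rep bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return a `rert_auc_comparison` with `method = "bootstrap"`.
#' @export
bootstrap_auc_test <- function(scores_a, scores_b, labels, n_rep = 2000,
                               seed = 1) {
  stopifnot(n_rep >= 100, length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  labels <- as.integer(labels)
  ipos <- which(labels == 1)
  ineg <- which(labels == 0)
  if (!length(ipos) || !length(ineg)) {
    stop("both classes must be present", call. = FALSE)
  }
  auc_of <- function(s, idx) {
    lab <- labels[idx]
    r <- rank(s[idx], ties.method = "average")
    np <- sum(lab == 1)
    nn <- sum(lab == 0)
    (sum(r[lab == 1]) - np * (np + 1) / 2) / (np * nn)
  }
  d_obs <- roc_auc(scores_a, labels)$auc - roc_auc(scores_b, labels)$auc
  d_boot <- with_seed(seed, vapply(seq_len(n_rep), function(r) {
    idx <- c(sample(ipos, length(ipos), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
    auc_of(scores_a, idx) - auc_of(scores_b, idx)
  }, 0))
  s <- sd(d_boot)
  if (s <= 0) {
    z <- if (abs(d_obs) < 1e-12) 0 else Inf * sign(d_obs)
    p <- if (abs(d_obs) < 1e-12) 1 else 0
  } else {
    z <- d_obs / s
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = roc_auc(scores_a, labels)$auc,
                 auc_b = roc_auc(scores_b, labels)$auc,
                 statistic = z, p_value = p, n_rep = n_rep,
                 method = "bootstrap"),
            class = "rert_auc_comparison")
}

#' @export
print.rert_auc_comparison <- function(x, ...) {
  cat(sprintf("<%s AUC comparison> AUC_a = %.4f, AUC_b = %.4f, z = %.3f, p = %.4g\n",
              x$method, x$auc_a, x$auc_b, x$statistic, x$p_value))
  invisible(x)
}
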