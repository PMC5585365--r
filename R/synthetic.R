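# Synthetic clinical cohorts with the structure of a preoperative
# endometrial-carcinoma dataset: 11 mixed-type covariates, right-skewed
# correlated serum biomarkers, covariate-specific MCAR missingness, a
# histotype stratum, and an outcome planted by a threshold-interaction tree.

#' Planted outcome tree mirroring the package's reference flow-chart
#'
#' Root split on serum HE4 at 78 pmol/L; on the high-HE4 side, advanced
#' clinical stage gives very high risk, otherwise BMI at 31.5 and a second
#' HE4 cut at 135 separate the remaining leaves.  Leaf probabilities follow
#' the reference flow-chart's printed leaf frequencies {0.07, 0.95, 0.04,
#' 0.90}; the one interior leaf the chart does not print is calibrated so
#' the expected outcome prevalence equals 99/293 (see the methods vignette).
#'
#' With `hard = TRUE` the leaves become deterministic {0, 1}: the outcome is
#' 1 exactly when (HE4 >= 78 and advanced clinical stage) or (HE4 >= 135 and
#' BMI < 31.5) — the planted-recovery benchmark, usually combined with
#' label noise.
#'
#' @param hard logical; deterministic leaves for recovery experiments.
#' @return a nested planted-tree list (`var`/`threshold`/`left`/`right`
#'   internal nodes, `p` leaves; numeric routing is `value < threshold` to
#'   the left, binary covariates split at 0.5).
#' @export
default_planted_tree <- function(hard = FALSE) {
  leaf <- function(p) list(p = p)
  node <- function(var, threshold, left, right) {
    list(var = var, threshold = threshold, left = left, right = right)
  }
  if (hard) {
    node("he4", 78,
         leaf(0),
         node("clinical_stage", 0.5,
              node("bmi", 31.5,
                   node("he4", 135, leaf(0), leaf(1)),
                   leaf(0)),
              leaf(1)))
  } else {
    node("he4", 78,
         leaf(0.07),
         node("clinical_stage", 0.5,
              node("bmi", 31.5,
                   node("he4", 135, leaf(0.4888), leaf(0.90)),
                   leaf(0.04)),
              leaf(0.95)))
  }
}

# Marginal families fitted to the reference cohort's summary table: medians
# and upper percentiles for the biomarkers (log-normal), category counts for
# the rest.
default_marginals <- function() {
  list(
    he4 = list(dist = "lognormal", meanlog = log(76), sdlog = 0.834,
               units = "pmol/L"),
    ca125 = list(dist = "lognormal", meanlog = log(17.3), sdlog = 1.313,
                 units = "U/mL"),
    age = list(dist = "normal", mean = 63, sd = 9, min = 18,
               units = "years"),
    bmi = list(dist = "normal", mean = 27, sd = 5.5, min = 13,
               units = "kg/m2"),
    children = list(dist = "poisson", lambda = 1.8),
    menopause = list(dist = "bernoulli", p = 257 / 292),
    contraception = list(dist = "bernoulli", p = 13 / 206),
    hrt = list(dist = "bernoulli", p = 41 / 264),
    hypertension = list(dist = "bernoulli", p = 150 / 293),
    grading = list(dist = "categorical",
                   levels = c("Hyperplasia", "G1", "G2", "G3"),
                   probs = c(6, 82, 91, 87) / 266),
    clinical_stage = list(dist = "bernoulli", p = 44 / 290,
                          levels = c("early", "advanced")))
}

# Per-covariate MCAR missing rates from the reference cohort's missing
# counts (out of 293).
default_missing_rates <- function() {
  c(he4 = 0, ca125 = 0, age = 0, bmi = 14 / 293, children = 0,
    menopause = 1 / 293, contraception = 87 / 293, hrt = 29 / 293,
    hypertension = 0, grading = 27 / 293, clinical_stage = 3 / 293)
}

#' Configuration for the synthetic-cohort generator
#'
#' @param n cohort size.
#' @param planted_tree outcome-generating tree ([default_planted_tree()]).
#' @param marginals per-covariate distribution specs.
#' @param biomarker_corr target Pearson correlation of log-HE4 and log-CA125
#'   (imposed exactly through a Gaussian copula on the log scale).
#' @param missing_rates named per-covariate MCAR missing probabilities.
#' @param label_noise probability of flipping each generated outcome.
#' @param stratum_probs named histotype proportions.
#' @param prevalence_target expected outcome prevalence of the default
#'   configuration (documentation/validation; the planted tree and marginals
#'   determine the realized value).
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n = 293,
                             planted_tree = default_planted_tree(),
                             marginals = default_marginals(),
                             biomarker_corr = 0.49,
                             missing_rates = default_missing_rates(),
                             label_noise = 0,
                             stratum_probs = c(endometrioid = 254,
                                               non_endometrioid = 39) / 293,
                             prevalence_target = 99 / 293,
                             seed = 1) {
  stopifnot(n >= 1, label_noise >= 0, label_noise < 1,
            abs(biomarker_corr) < 1,
            all(missing_rates >= 0), all(missing_rates < 1))
  check_planted(planted_tree, names(marginals))
  structure(list(n = as.integer(n), planted_tree = planted_tree,
                 marginals = marginals, biomarker_corr = biomarker_corr,
                 missing_rates = missing_rates, label_noise = label_noise,
                 stratum_probs = stratum_probs / sum(stratum_probs),
                 prevalence_target = prevalence_target,
                 seed = as.integer(seed)),
            class = "generator_config")
}

check_planted <- function(node, known) {
  if (!is.null(node$p)) {
    stopifnot(node$p >= 0, node$p <= 1)
    return(invisible(TRUE))
  }
  if (!node$var %in% known) {
    stop("planted tree references unknown covariate '", node$var, "'",
         call. = FALSE)
  }
  check_planted(node$left, known)
  check_planted(node$right, known)
}

planted_leaf_prob <- function(node, row) {
  while (is.null(node$p)) {
    node <- if (row[[node$var]] < node$threshold) node$left else node$right
  }
  node$p
}

draw_marginal <- function(spec, n) {
  switch(spec$dist,
    lognormal = stop("biomarkers are drawn jointly", call. = FALSE),
    normal = pmax(spec$min %||% -Inf, rnorm(n, spec$mean, spec$sd)),
    poisson = rpois(n, spec$lambda),
    bernoulli = rbinom(n, 1, spec$p),
    categorical = sample.int(length(spec$probs), n, replace = TRUE,
                             prob = spec$probs),
    stop("unknown marginal family '", spec$dist, "'", call. = FALSE))
}

#' Generate a synthetic cohort
#'
#' Covariates are drawn from the configured marginals, the two serum
#' biomarkers jointly log-normal at the configured log-scale correlation.
#' The outcome of each row is Bernoulli with the planted tree's leaf
#' probability (evaluated on the complete, pre-missingness covariates), then
#' flipped with probability `label_noise`.  Missingness is applied
#' completely at random per covariate; outcome and stratum are never
#' missing.
#'
#' @param config a [generator_config()].
#' @return a `rert_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mg <- config$marginals
  n <- config$n
  with_seed(config$seed, {
    # correlated log-normal biomarkers via a Gaussian copula on log scale
    rho <- config$biomarker_corr
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cols <- list()
    for (nm in names(mg)) {
      cols[[nm]] <- if (mg[[nm]]$dist == "lognormal") {
        z <- if (nm == names(mg)[1]) z1 else z2
        exp(mg[[nm]]$meanlog + mg[[nm]]$sdlog * z)
      } else {
        draw_marginal(mg[[nm]], n)
      }
    }
    df <- as.data.frame(cols, check.names = FALSE)

    p_leaf <- vapply(seq_len(n),
                     function(i) planted_leaf_prob(config$planted_tree,
                                                   df[i, , drop = FALSE]),
                     0)
    y <- rbinom(n, 1, p_leaf)
    if (config$label_noise > 0) {
      flip <- rbinom(n, 1, config$label_noise) == 1
      y[flip] <- 1L - y[flip]
    }
    stratum <- sample(names(config$stratum_probs), n, replace = TRUE,
                      prob = config$stratum_probs)
    for (nm in names(config$missing_rates)) {
      r <- config$missing_rates[[nm]]
      if (r > 0 && nm %in% names(df)) {
        df[[nm]][runif(n) < r] <- NA
      }
    }
    cohort(df, generator_schema(mg), y, stratum)
  })
}

generator_schema <- function(marginals) {
  specs <- lapply(names(marginals), function(nm) {
    m <- marginals[[nm]]
    switch(m$dist,
      bernoulli = covariate_spec(nm, "binary",
                                 levels = m$levels %||% c("no", "yes")),
      categorical = covariate_spec(nm, "ordered", levels = m$levels),
      covariate_spec(nm, "quantitative", units = m$units %||% ""))
  })
  names(specs) <- names(marginals)
  specs
}

#' Default study emulator
#'
#' The fixed published configuration: n = 293, the calibrated planted tree
#' of [default_planted_tree()], reference-table marginals, log-scale
#' biomarker correlation 0.49, reference-table missing rates, no extra label
#' noise.  This synthetic cohort emulates the structure of the study data it
#' stands in for; it is not that data.
#'
#' @param seed integer seed.
#' @param n cohort size (default 293).
#' @return a `rert_cohort`.
#' @export
default_study_emulator <- function(seed = 1, n = 293) {
  generate_cohort(generator_config(n = n, seed = seed))
}

#' Planted-recovery benchmark configuration
#'
#' A synthetic benchmark for parameter-recovery experiments: the
#' deterministic planted rule of `default_planted_tree(hard = TRUE)`
#' (outcome 1 iff HE4 >= 78 with advanced clinical stage, or HE4 >= 135
#' with BMI < 31.5) plus independent label noise.  Unlike the study
#' emulator, the covariate marginals here are chosen for identifiability,
#' not realism: the planted rule admits several equivalent tree
#' representations (rooting at either HE4 cut, or on clinical stage), so
#' recovering "the" planted root requires marginals under which the HE4-78
#' cut is the unique dominant first split.  The benchmark therefore enriches
#' advanced clinical stage (0.7) and tightens the HE4 spread (sdlog 0.35);
#' the methods vignette derives the resulting impurity-gain ordering.
#'
#' @param n cohort size.
#' @param label_noise outcome flip probability (default 0.1).
#' @param seed integer seed.
#' @return a [generator_config()].
#' @export
recovery_benchmark_config <- function(n = 300, label_noise = 0.1, seed = 1) {
  mg <- default_marginals()
  mg$clinical_stage$p <- 0.7
  mg$he4$sdlog <- 0.35
  generator_config(n = n, planted_tree = default_planted_tree(hard = TRUE),
                   marginals = mg, label_noise = label_noise, seed = seed)
}

# Closed-form expected prevalence of a planted tree under the default
# independent marginals (biomarker copula does not matter: only one
# biomarker enters the tree).  Used to calibrate the unprinted leaf.
planted_prevalence <- function(planted_tree, marginals = default_marginals(),
                               label_noise = 0) {
  p_interval <- function(nm, lo, hi) {
    m <- marginals[[nm]]
    cdf <- switch(m$dist,
      lognormal = function(q) plnorm(q, m$meanlog, m$sdlog),
      normal = function(q) pnorm(q, m$mean, m$sd),
      poisson = function(q) ppois(q - 1e-9, m$lambda),
      bernoulli = function(q) ifelse(q <= 0, 0, ifelse(q <= 1, 1 - m$p, 1)),
      categorical = function(q) sum(m$probs[seq_len(max(0, min(floor(q),
                                    length(m$probs))))]))
    cdf(hi) - cdf(lo)
  }
  rec <- function(node, lo, hi) {
    if (!is.null(node$p)) {
      prob <- prod(vapply(names(lo), function(nm) {
        p_interval(nm, lo[[nm]], hi[[nm]])
      }, 0))
      return(prob * node$p)
    }
    lo_l <- lo; hi_l <- hi; lo_r <- lo; hi_r <- hi
    hi_l[[node$var]] <- min(hi[[node$var]], node$threshold)
    lo_r[[node$var]] <- max(lo[[node$var]], node$threshold)
    if (lo_l[[node$var]] >= hi_l[[node$var]]) left <- 0
    else left <- rec(node$left, lo_l, hi_l)
    if (lo_r[[node$var]] >= hi_r[[node$var]]) right <- 0
    else right <- rec(node$right, lo_r, hi_r)
    left + right
  }
  vars <- planted_vars(planted_tree)
  lo <- as.list(stats::setNames(rep(-Inf, length(vars)), vars))
  hi <- as.list(stats::setNames(rep(Inf, length(vars)), vars))
  prev <- rec(planted_tree, lo, hi)
  prev * (1 - label_noise) + (1 - prev) * label_noise
}

planted_vars <- function(node) {
  if (!is.null(node$p)) return(character(0))
  unique(c(node$var, planted_vars(node$left), planted_vars(node$right)))
}
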