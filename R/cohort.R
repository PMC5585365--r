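# Cohort data model: mixed-type preoperative covariates, a binary outcome
# (1 = surgically advanced disease) and a non-missing stratum label.

MISSING_SENTINELS <- c("", "na", "nan")

#' Declare one covariate of a cohort schema
#'
#' @param name column name, unique within a schema.
#' @param kind one of `"quantitative"`, `"binary"`, `"ordered"` (ordered
#'   categorical, split on level index) or `"nominal"` (unordered
#'   categorical, split on level subsets).
#' @param levels ordered character vector of category labels; required for
#'   the categorical kinds, forbidden for `"quantitative"`. Binary
#'   covariates default to `c("0", "1")`.
#' @param units free-text measurement units (documentation only).
#' @return a `covariate_spec` object.
#' @export
covariate_spec <- function(name, kind, levels = NULL, units = "") {
  kind <- match.arg(kind, c("quantitative", "binary", "ordered", "nominal"))
  if (kind == "quantitative" && !is.null(levels)) {
    stop("quantitative covariate '", name, "' must not declare levels",
         call. = FALSE)
  }
  if (kind == "binary" && is.null(levels)) levels <- c("0", "1")
  if (kind != "quantitative") {
    if (is.null(levels) || length(levels) < 2) {
      stop("categorical covariate '", name, "' needs >= 2 levels",
           call. = FALSE)
    }
    if (kind == "binary" && length(levels) != 2) {
      stop("binary covariate '", name, "' needs exactly 2 levels",
           call. = FALSE)
    }
    if (length(levels) > 31) {
      stop("covariate '", name, "' has more than 31 levels", call. = FALSE)
    }
  }
  structure(list(name = name, kind = kind,
                 levels = if (!is.null(levels)) as.character(levels),
                 units = units),
            class = "covariate_spec")
}

validate_schema <- function(schema) {
  if (!length(schema)) stop("schema is empty", call. = FALSE)
  if (!all(vapply(schema, inherits, TRUE, "covariate_spec"))) {
    stop("schema must be a list of covariate_spec objects", call. = FALSE)
  }
  nm <- vapply(schema, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate covariate names in schema",
                              call. = FALSE)
  names(schema) <- nm
  schema
}

#' Construct a cohort from already-encoded columns
#'
#' Columns are stored numerically: quantitative values as doubles, binary as
#' 0/1, categorical kinds as 1-based level indices; `NA` is the missing
#' marker.  The outcome must be 0/1 with no missing values and the stratum
#' label must be non-missing.
#'
#' @param data data.frame of covariate columns matching `schema`.
#' @param schema list of [covariate_spec()] entries.
#' @param outcome integer vector in `{0, 1}`.
#' @param stratum character vector of stratum labels (e.g. histotype).
#' @return a `rert_cohort` object.
#' @export
cohort <- function(data, schema, outcome, stratum) {
  schema <- validate_schema(schema)
  nm <- names(schema)
  if (!all(nm %in% names(data))) {
    stop("data lacks covariate column(s): ",
         paste(setdiff(nm, names(data)), collapse = ", "), call. = FALSE)
  }
  data <- data[nm]
  n <- nrow(data)
  if (n < 1) stop("cohort must have at least one row", call. = FALSE)
  outcome <- as.integer(outcome)
  if (length(outcome) != n || anyNA(outcome) || !all(outcome %in% 0:1)) {
    stop("outcome must be a complete 0/1 vector of length n", call. = FALSE)
  }
  stratum <- as.character(stratum)
  if (length(stratum) != n || anyNA(stratum)) {
    stop("stratum labels must be non-missing", call. = FALSE)
  }
  for (s in schema) {
    x <- data[[s$name]]
    if (!is.numeric(x)) stop("column '", s$name, "' is not numeric encoded",
                             call. = FALSE)
    if (s$kind != "quantitative") {
      L <- length(s$levels)
      ok <- is.na(x) | (x == floor(x) &
                          x >= ifelse(s$kind == "binary", 0, 1) &
                          x <= ifelse(s$kind == "binary", 1, L))
      if (!all(ok)) stop("column '", s$name, "' has values outside its levels",
                         call. = FALSE)
    } else if (any(is.infinite(x), na.rm = TRUE)) {
      stop("column '", s$name, "' has non-finite values", call. = FALSE)
    }
  }
  structure(list(data = data, schema = schema, outcome = outcome,
                 stratum = stratum, n = n),
            class = "rert_cohort")
}

parse_covariate <- function(raw, spec, colname) {
  raw <- trimws(raw)
  miss <- tolower(raw) %in% MISSING_SENTINELS
  out <- rep(NA_real_, length(raw))
  if (spec$kind == "quantitative") {
    val <- suppressWarnings(as.numeric(raw))
    out[!miss] <- val[!miss]           # unparseable cells stay missing
    out[is.infinite(out)] <- NA_real_
  } else {
    idx <- match(raw, spec$levels)
    if (spec$kind == "binary") {
      idx <- idx - 1                   # binary stored as 0/1
      num <- suppressWarnings(as.numeric(raw))
      idx[is.na(idx) & num %in% c(0, 1)] <- num[is.na(idx) & num %in% c(0, 1)]
    }
    out[!miss] <- idx[!miss]
  }
  out
}

#' Load a cohort from a CSV file
#'
#' Columns are keyed by header name (file column order is irrelevant).  Empty
#' cells, `"NA"` and `"NaN"` (case-insensitive) and unparseable cells become
#' the missing marker.  The outcome is mapped through `outcome_map` and must
#' land in `{0, 1}` with no missing values; the stratum must be non-missing.
#'
#' @param path CSV file with a header row.
#' @param schema list of [covariate_spec()] (or path handled by
#'   [read_schema()]).
#' @param outcome_name,stratum_name column names of outcome and stratum.
#' @param outcome_map named vector mapping raw outcome labels to 0/1, e.g.
#'   `c("I" = 0, ">I" = 1)`. `NULL` means the column is already 0/1.
#' @return a `rert_cohort`.
#' @export
load_cohort <- function(path, schema, outcome_name, stratum_name,
                        outcome_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema)) schema <- read_schema(schema)
  schema <- validate_schema(schema)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE,
             na.strings = NULL, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot read '", path, "': ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(raw) == 0) stop("input file '", path, "' has no data rows",
                           call. = FALSE)
  need <- c(names(schema), outcome_name, stratum_name)
  if (!all(need %in% names(raw))) {
    stop("missing column(s) in '", path, "': ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(
    lapply(schema, function(s) parse_covariate(raw[[s$name]], s, s$name)),
    check.names = FALSE)
  names(data) <- names(schema)

  oraw <- trimws(raw[[outcome_name]])
  if (!is.null(outcome_map)) {
    mapped <- unname(outcome_map[oraw])
    mapped[is.na(mapped) & oraw %in% c("0", "1")] <-
      as.numeric(oraw[is.na(mapped) & oraw %in% c("0", "1")])
  } else {
    mapped <- suppressWarnings(as.numeric(oraw))
  }
  bad <- which(is.na(mapped) | !(mapped %in% c(0, 1)))
  if (length(bad)) {
    stop("outcome column '", outcome_name, "' row ", bad[1],
         " has value '", oraw[bad[1]], "' outside {0,1}", call. = FALSE)
  }
  straw <- trimws(raw[[stratum_name]])
  if (any(tolower(straw) %in% MISSING_SENTINELS)) {
    stop("stratum column '", stratum_name, "' has missing values",
         call. = FALSE)
  }
  cohort(data, schema, as.integer(mapped), straw)
}

#' Read a covariate schema from YAML or JSON
#'
#' The file maps covariate name to `kind`, optional `levels` and `units`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a named list of [covariate_spec()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_schema(lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    covariate_spec(nm, s$kind, levels = unlist(s$levels) %||% NULL,
                   units = s$units %||% "")
  }))
}

#' Write a schema to YAML
#' @param schema list of [covariate_spec()].
#' @param path output file.
#' @export
write_schema <- function(schema, path) {
  schema <- validate_schema(schema)
  out <- lapply(schema, function(s) {
    x <- list(kind = s$kind)
    if (!is.null(s$levels)) x$levels <- as.list(s$levels)
    if (nzchar(s$units)) x$units <- s$units
    x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a cohort back to CSV with level labels restored
#'
#' Missing values are written as empty cells, so [load_cohort()] on the
#' result round-trips to an identical cohort.
#'
#' @param x a `rert_cohort`.
#' @param path output CSV path.
#' @param outcome_name,stratum_name column names used in the file.
#' @export
write_cohort <- function(x, path, outcome_name = "outcome",
                         stratum_name = "stratum") {
  stopifnot(inherits(x, "rert_cohort"))
  out <- lapply(x$schema, function(s) {
    v <- x$data[[s$name]]
    if (s$kind == "quantitative") {
      ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE,
                                  scientific = FALSE))
    } else if (s$kind == "binary") {
      ifelse(is.na(v), "", s$levels[v + 1])
    } else {
      ifelse(is.na(v), "", s$levels[v])
    }
  })
  df <- as.data.frame(out, check.names = FALSE)
  df[[outcome_name]] <- x$outcome
  df[[stratum_name]] <- x$stratum
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-covariate missing-value counts
#'
#' @param x a `rert_cohort`.
#' @return named integer vector, one nonnegative count per covariate
#'   (outcome and stratum are never missing by construction).
#' @export
summarize_missingness <- function(x) {
  stopifnot(inherits(x, "rert_cohort"))
  vapply(x$data, function(col) sum(is.na(col)), 0L)
}

#' Row subset of a cohort
#' @param x a `rert_cohort`.
#' @param idx integer row indices (duplicates allowed, e.g. bootstrap).
#' @return a `rert_cohort` with the selected rows.
#' @export
cohort_subset <- function(x, idx) {
  stopifnot(inherits(x, "rert_cohort"))
  cohort(x$data[idx, , drop = FALSE], x$schema,
         x$outcome[idx], x$stratum[idx])
}

# Numeric fitting view: matrix of encoded covariates plus the nominal flag
# the grower needs.
cohort_matrix <- function(x) {
  m <- as.matrix(x$data)
  storage.mode(m) <- "double"
  kind <- ifelse(vapply(x$schema, `[[`, "", "kind") == "nominal", 1L, 0L)
  list(X = m, kind = kind, names = names(x$schema))
}

check_two_classes <- function(x, what = "fitting") {
  if (length(unique(x$outcome)) < 2) {
    stop("both outcome classes must be present for ", what, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.rert_cohort <- function(x, ...) {
  cat("<rert_cohort> n =", x$n,
      "| positives =", sum(x$outcome),
      sprintf("(%.1f%%)", 100 * mean(x$outcome)), "\n")
  cat("covariates:", paste(names(x$schema), collapse = ", "), "\n")
  st <- table(x$stratum)
  cat("strata:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  miss <- summarize_missingness(x)
  if (any(miss > 0)) {
    mm <- miss[miss > 0]
    cat("missing:", paste(sprintf("%s=%d", names(mm), mm), collapse = ", "),
        "\n")
  }
  invisible(x)
}
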