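#' Observational study tables
#'
#' An `obs_table` holds the study units of an observational comparison: a unit
#' id, a binary treatment indicator, a continuous outcome and a covariate
#' table of numeric and categorical columns, with the original missingness
#' recorded as a logical mask. Downstream matching requires an imputed table
#' (see [impute_two_step()]).
#'
#' @param data A data frame.
#' @param treatment Name of the binary treatment column (values 0/1).
#' @param outcome Name of the numeric outcome column.
#' @param id Name of the unit-id column, or `NULL` to use row numbers.
#' @param covariates Character vector of covariate columns; default: every
#'   remaining column.
#' @return An object of class `obs_table`: a list with elements `id`, `z`,
#'   `y`, `x` (covariate data frame), `types` (named `"numeric"` or
#'   `"categorical"`), and `miss` (logical matrix marking missing cells).
#' @export
as_obs_table <- function(data, treatment = "treatment", outcome = "outcome",
                         id = NULL, covariates = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(treatment, outcome))
    if (!col %in% names(data))
      stop("schema error: required column '", col, "' not found")
  if (!is.null(id) && !id %in% names(data))
    stop("schema error: id column '", id, "' not found")

  z <- data[[treatment]]
  if (!all(z %in% c(0, 1)))
    stop("validation error: treatment column must be binary 0/1; found ",
         paste(setdiff(unique(z), c(0, 1)), collapse = ", "))
  z <- as.integer(z)
  if (sum(z) == 0L || sum(z) == length(z))
    stop("validation error: need at least one treated and one control unit")

  y <- as.numeric(data[[outcome]])
  ids <- if (is.null(id)) as.character(seq_len(nrow(data)))
         else as.character(data[[id]])
  if (anyDuplicated(ids)) stop("validation error: unit ids must be unique")

  if (is.null(covariates))
    covariates <- setdiff(names(data), c(treatment, outcome, id))
  if (length(covariates) == 0L)
    stop("schema error: at least one covariate column is required")
  x <- data[, covariates, drop = FALSE]
  types <- vapply(x, function(v) if (is.numeric(v)) "numeric" else "categorical",
                  character(1))
  for (j in which(types == "categorical")) x[[j]] <- as.factor(x[[j]])
  miss <- as.matrix(as.data.frame(lapply(x, is.na)))
  dimnames(miss) <- list(NULL, names(x))

  structure(list(id = ids, z = z, y = y, x = x, types = types, miss = miss),
            class = "obs_table")
}

#' Read a delimited study table
#'
#' Reads a comma-separated file with a header row; empty strings and `"NA"`
#' both denote missing values.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_obs_table
#' @return An [as_obs_table()] object.
#' @export
load_table <- function(path, treatment = "treatment", outcome = "outcome",
                       id = "id", covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!is.null(id) && !id %in% names(df)) id <- NULL
  as_obs_table(df, treatment = treatment, outcome = outcome, id = id,
               covariates = covariates)
}

#' Write an observational table to CSV
#'
#' @param table An `obs_table`.
#' @param path Output path.
#' @export
write_obs_table <- function(table, path) {
  df <- data.frame(id = table$id, treatment = table$z, outcome = table$y,
                   table$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.obs_table <- function(x, ...) {
  cat("obs_table:", length(x$z), "units (", sum(x$z), "treated,",
      sum(1 - x$z), "control ),", ncol(x$x), "covariates\n")
  nm <- sum(colSums(x$miss) > 0)
  if (nm > 0) cat("  covariates with missing entries:", nm, "\n")
  invisible(x)
}

#' Two-step missing-covariate handling
#'
#' For every covariate with at least one missing entry, (i) a binary indicator
#' `<covariate>_missing` is appended marking the missing cells, and (ii) the
#' missing entries are imputed with the mean of the non-missing entries
#' (numeric covariates) or the modal level (categorical covariates; the mean
#' is undefined for unordered categories). Matching on the covariates together
#' with the indicators balances both the observed values and the pattern of
#' missingness. Covariates without missing entries are untouched and receive
#' no indicator. The operation is idempotent.
#'
#' @param table An `obs_table`.
#' @return An `obs_table` with no missing covariate cells.
#' @export
impute_two_step <- function(table) {
  stopifnot(inherits(table, "obs_table"))
  x <- table$x
  types <- table$types
  miss_cols <- names(x)[colSums(table$miss) > 0]
  for (nm in miss_cols) {
    v <- x[[nm]]
    isna <- is.na(v)
    if (all(isna))
      stop("covariate '", nm, "' has all entries missing; cannot impute")
    if (types[[nm]] == "numeric") {
      v[isna] <- mean(v[!isna])
    } else {
      tab <- table(v[!isna])
      v[isna] <- names(tab)[which.max(tab)]
    }
    x[[nm]] <- v
    ind <- paste0(nm, "_missing")
    x[[ind]] <- as.numeric(isna)
    types[[ind]] <- "numeric"
  }
  miss <- as.matrix(as.data.frame(lapply(x, is.na)))
  dimnames(miss) <- list(NULL, names(x))
  structure(list(id = table$id, z = table$z, y = table$y, x = x,
                 types = types, miss = miss),
            class = "obs_table")
}

#' Generate a synthetic observational fixture
#'
#' Emulates the shape of a mid-sized clinical observational cohort: an
#' approximately 1:3 treated:control ratio, a few dozen covariates mixing
#' binary indicators, small categorical factors and continuous measurements,
#' sparse missingness in a handful of covariates, and treatment assignment
#' mildly dependent on the covariates. The generator is a pure function of its
#' arguments: the same arguments and seed always give a byte-identical table.
#'
#' @param n_treated,n_control Positive unit counts.
#' @param p Number of covariates.
#' @param missing_rate Fraction of cells set missing in the covariates chosen
#'   to carry missingness; `0 <= missing_rate < 1`.
#' @param seed Integer seed.
#' @return An `obs_table` with `n_treated + n_control` units.
#' @export
generate_fixture <- function(n_treated, n_control, p = 31,
                             missing_rate = 0.02, seed = 1) {
  stopifnot(n_treated >= 1, n_control >= 1, p >= 1,
            missing_rate >= 0, missing_rate < 1)
  n <- n_treated + n_control
  with_seed(seed, {
    kinds <- rep(c("binary", "continuous", "categorical"), length.out = p)
    x <- vector("list", p)
    names(x) <- sprintf("x%02d", seq_len(p))
    for (j in seq_len(p)) {
      x[[j]] <- switch(kinds[j],
        binary      = rbinom(n, 1, runif(1, 0.2, 0.8)),
        continuous  = rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2)),
        categorical = factor(sample(LETTERS[1:sample(3:5, 1)], n,
                                    replace = TRUE)))
    }
    x <- as.data.frame(x)
    # treatment leans on the first few covariates so matching has work to do
    std <- function(v) {
      v <- as.numeric(v)
      if (sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, length(v))
    }
    lp <- 0.5 * std(x[[1]]) + if (p >= 2) 0.3 * std(x[[2]]) else 0
    treated <- sample(n, n_treated, prob = plogis_safe(lp))
    z <- integer(n); z[treated] <- 1L
    y <- rnorm(n, mean = 0.1 + 0.15 * z, sd = 0.7)
    if (missing_rate > 0) {
      carriers <- seq_len(p)[seq_len(p) %% 7 == 3]   # a few covariates
      if (length(carriers) == 0) carriers <- 1L
      for (j in carriers) {
        holes <- runif(n) < missing_rate
        x[[j]][holes] <- NA
      }
    }
    df <- data.frame(id = sprintf("u%04d", seq_len(n)), treatment = z,
                     outcome = y, x, check.names = FALSE)
    as_obs_table(df, id = "id")
  })
}

plogis_safe <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))
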