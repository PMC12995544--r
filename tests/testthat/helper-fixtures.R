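# Small programmatic fixtures.

# An obs_table of matched pairs built from explicit outcomes and shared
# covariates: y_t / y_c are per-pair treated and control outcomes, x an
# optional data frame of per-pair covariates (shared within the pair).
make_pairs <- function(y_t, y_c, x = NULL) {
  I <- length(y_t)
  stopifnot(length(y_c) == I)
  df <- data.frame(id = paste0("p", rep(seq_len(I), each = 2), ".",
                               rep(1:2, I)),
                   treatment = rep(c(1L, 0L), I),
                   outcome = as.vector(rbind(y_t, y_c)))
  if (!is.null(x)) df <- cbind(df, x[rep(seq_len(I), each = 2), ,
                                     drop = FALSE])
  if (is.null(x)) df$x1 <- 0   # at least one covariate
  rownames(df) <- NULL
  tab <- as_obs_table(df, id = "id")
  sets <- data.frame(set = rep(seq_len(I), each = 2),
                     unit = seq_len(2 * I),
                     role = rep(c("treated", "control"), I))
  list(table = tab, sample = htesens:::new_matched_sample(sets, tab))
}

# A matched sample with explicit per-set member outcomes (first member
# treated), for variable-ratio structures.
make_sets <- function(outcomes_list, x = NULL) {
  n <- lengths(outcomes_list)
  I <- length(n)
  unit <- 0L
  rows <- list()
  for (i in seq_len(I)) {
    for (j in seq_len(n[i])) {
      unit <- unit + 1L
      rows[[unit]] <- data.frame(id = paste0("s", i, ".", j),
                                 treatment = as.integer(j == 1),
                                 outcome = outcomes_list[[i]][j],
                                 set = i)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(x)) df <- cbind(df, x[df$set, , drop = FALSE])
  else df$x1 <- 0
  rownames(df) <- NULL
  tab <- as_obs_table(df, id = "id",
                      covariates = setdiff(names(df),
                                           c("id", "treatment", "outcome",
                                             "set")))
  sets <- data.frame(set = df$set, unit = seq_len(nrow(df)),
                     role = ifelse(df$treatment == 1, "treated", "control"))
  list(table = tab, sample = htesens:::new_matched_sample(sets, tab))
}

write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

dist_from_matrix <- function(m) {
  htesens:::new_distance_matrix(m, seq_len(nrow(m)),
                                nrow(m) + seq_len(ncol(m)))
}
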