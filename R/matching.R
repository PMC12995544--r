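#' Expand covariates to a numeric matrix
#'
#' Categorical covariates are expanded to one 0/1 indicator per level before
#' any distance computation, mirroring the indicator coding conventional in
#' matched observational studies. Numeric covariates pass through unchanged.
#'
#' @param table An imputed `obs_table`.
#' @return A numeric matrix with one row per unit.
#' @export
expand_covariates <- function(table) {
  stopifnot(inherits(table, "obs_table"))
  cols <- list()
  for (nm in names(table$x)) {
    v <- table$x[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      v <- as.factor(v)
      for (lev in levels(v))
        cols[[paste0(nm, ".", lev)]] <- as.numeric(v == lev)
    }
  }
  do.call(cbind, cols)
}

new_distance_matrix <- function(d, treated_idx, control_idx) {
  structure(d, treated_idx = treated_idx, control_idx = control_idx,
            class = c("distance_matrix", "matrix"))
}

restore_dist <- function(d, template) {
  new_distance_matrix(unclass(d), attr(template, "treated_idx"),
                      attr(template, "control_idx"))
}

#' Rank-based Mahalanobis distance between treated and control units
#'
#' Every (expanded) covariate is replaced by its average ranks over all units;
#' distances are squared Mahalanobis distances on the ranks, using the rank
#' covariance matrix. Ranking makes the distance invariant under strictly
#' monotone transformations of any single covariate and limits the influence
#' of outliers. A singular rank covariance is regularized by adding
#' `1e-6 * trace/p` to the diagonal; zero-variance rank columns are dropped
#' with a warning.
#'
#' @param table An imputed `obs_table` (no missing covariate cells).
#' @return A `distance_matrix`: rows index treated units, columns controls;
#'   attributes `treated_idx` / `control_idx` hold the unit row indices.
#' @export
rank_mahalanobis <- function(table) {
  if (any(table$miss)) stop("impute covariates before computing distances")
  X <- expand_covariates(table)
  R <- apply(X, 2, avg_rank)
  keep <- apply(R, 2, function(col) var(col) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance covariate columns: ",
            paste(colnames(R)[!keep], collapse = ", "))
    R <- R[, keep, drop = FALSE]
  }
  S <- cov(R)
  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv)) {
    S <- S + diag(1e-6 * sum(diag(S)) / ncol(S), ncol(S))
    inv <- solve(S)
  }
  ti <- which(table$z == 1L)
  ci <- which(table$z == 0L)
  Rt <- R[ti, , drop = FALSE]
  Rc <- R[ci, , drop = FALSE]
  # squared Mahalanobis via the quadratic expansion
  A <- Rt %*% inv
  qt <- rowSums(A * Rt)
  qc <- rowSums((Rc %*% inv) * Rc)
  d <- outer(qt, qc, "+") - 2 * A %*% t(Rc)
  d[d < 0] <- 0   # numerical noise
  dimnames(d) <- list(table$id[ti], table$id[ci])
  new_distance_matrix(d, ti, ci)
}

#' Propensity scores from a main-effects logistic model
#'
#' Fits treatment on the expanded covariates with a logistic link. Under
#' perfect separation (or non-convergence) the fit falls back to a
#' ridge-penalized logistic regression, with a warning.
#'
#' @param table An imputed `obs_table`.
#' @param ridge_lambda Penalty used by the fallback fit.
#' @return Numeric vector of fitted treatment probabilities, one per unit.
#' @export
propensity_scores <- function(table, ridge_lambda = 0.01) {
  X <- expand_covariates(table)
  z <- table$z
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(z ~ ., data = data.frame(z = z, X, check.names = TRUE),
        family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  fv <- as.numeric(fitted(fit))
  separated <- separated || !fit$converged ||
    any(fv < 1e-8 | fv > 1 - 1e-8)   # quiet separation
  if (!separated) return(fv)
  warning("separation detected in the propensity model; ",
          "falling back to a ridge-penalized fit")
  keep <- apply(X, 2, var) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  co <- ridge_logistic(Xs, z, lambda = ridge_lambda)
  as.numeric(plogis_safe(co$intercept + Xs %*% co$beta))
}

# Ridge-penalized logistic regression by penalized IRLS (intercept unpenalized).
ridge_logistic <- function(X, z, lambda, maxit = 100, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  b <- rep(0, p); b0 <- qnorm(mean(z)) # rough start
  for (it in seq_len(maxit)) {
    eta <- as.vector(b0 + X %*% b)
    mu <- plogis_safe(eta)
    w <- pmax(mu * (1 - mu), 1e-8)
    u <- eta + (z - mu) / w
    Xw <- cbind(1, X) * sqrt(w)
    uw <- u * sqrt(w)
    P <- diag(c(0, rep(n * lambda, p)))
    new <- solve(crossprod(Xw) + P, crossprod(Xw, uw))
    if (max(abs(new - c(b0, b))) < tol) break
    b0 <- new[1]; b <- new[-1]
  }
  list(intercept = b0, beta = b)
}

#' Soft propensity caliper
#'
#' Entries whose treated-control propensity-score gap exceeds the caliper
#' width are penalized proportionally to the excess gap (a soft caliper, which
#' preserves feasibility): the entry is increased by
#' `penalty * (gap - width) / width`.
#'
#' @param dist A `distance_matrix`.
#' @param scores Propensity scores for all units (as from
#'   [propensity_scores()]).
#' @param width Caliper width on the propensity scale; default 0.2 standard
#'   deviations of the scores.
#' @param penalty Nonnegative penalty multiplier.
#' @return The penalized `distance_matrix`.
#' @export
apply_caliper <- function(dist, scores, width = NULL, penalty = 1000) {
  ti <- attr(dist, "treated_idx"); ci <- attr(dist, "control_idx")
  if (is.null(width)) width <- 0.2 * sd(scores)
  stopifnot(width > 0, penalty >= 0)
  gap <- abs(outer(scores[ti], scores[ci], "-"))
  excess <- pmax(gap - width, 0)
  restore_dist(unclass(dist) + penalty * excess / width, dist)
}

#' Almost-exact matching penalties
#'
#' Adds a large penalty, per disagreeing key, to every treated-control entry
#' that disagrees on any of the designated covariates, so that exact matches
#' on those covariates are strictly preferred whenever feasible.
#'
#' @param dist A `distance_matrix`.
#' @param table The `obs_table` the distances came from.
#' @param exact_keys Covariate names to match exactly when possible.
#' @param penalty Additive penalty per disagreeing key; default
#'   `1000 * max(finite entries)`, which dominates any total distance.
#' @return The penalized `distance_matrix`.
#' @export
apply_almost_exact <- function(dist, table, exact_keys, penalty = NULL) {
  stopifnot(all(exact_keys %in% names(table$x)))
  d <- unclass(dist)
  if (is.null(penalty)) {
    mx <- max(d[is.finite(d)], 0)
    penalty <- 1000 * max(mx, 1)
  }
  ti <- attr(dist, "treated_idx"); ci <- attr(dist, "control_idx")
  for (key in exact_keys) {
    v <- as.character(table$x[[key]])
    dis <- outer(v[ti], v[ci], "!=")
    d <- d + penalty * dis
  }
  restore_dist(d, dist)
}

# Solve a (possibly rectangular, rows <= cols) assignment problem, treating
# non-finite entries as forbidden. Returns the column index per row.
lsap_solve <- function(cost) {
  finite <- cost[is.finite(cost)]
  if (length(finite) == 0) stop("assignment infeasible: no finite entries")
  big <- (max(finite, 0) + 1) * (nrow(cost) + 1)
  m <- cost
  m[!is.finite(m)] <- big
  sol <- as.integer(clue::solve_LSAP(m))
  attr(sol, "forbidden") <- !is.finite(cost[cbind(seq_len(nrow(cost)), sol)])
  sol
}

new_matched_sample <- function(sets_df, table, constraints = list()) {
  sets_df <- sets_df[order(sets_df$set, sets_df$role != "treated"), ]
  rownames(sets_df) <- NULL
  I <- length(unique(sets_df$set))
  ids <- if (is.null(table)) as.character(sets_df$unit)
         else table$id[sets_df$unit]
  treated <- sets_df$unit[sets_df$role == "treated"]
  ctrl_split <- split(sets_df$unit[sets_df$role == "control"],
                      sets_df$set[sets_df$role == "control"])
  ctrl_split <- ctrl_split[order(as.integer(names(ctrl_split)))]
  sets_list <- Map(function(t, cs) list(treated = t, controls = cs),
                   treated, ctrl_split)
  structure(list(sets = sets_df, I = I, ids = ids,
                 sets_list = unname(sets_list),
                 constraints = constraints),
            class = "matched_sample")
}

#' @export
print.matched_sample <- function(x, ...) {
  ni <- table(x$sets$set)
  cat("matched_sample:", x$I, "sets;",
      sum(x$sets$role == "control"), "controls; set sizes",
      paste(range(ni), collapse = "-"), "\n")
  invisible(x)
}

# List of per-set member indices: list(treated = row, controls = rows).
ms_sets <- function(sample) sample$sets_list

#' Optimal pair matching
#'
#' Matches each treated unit to a distinct control so that the total matched
#' distance is minimal over all such assignments (a minimum-cost bipartite
#' assignment). Infinite entries are forbidden pairings.
#'
#' @param dist A `distance_matrix`.
#' @param table The `obs_table` the distances came from (for provenance and
#'   balance devices).
#' @param balance_keys Optional categorical covariates put under near-fine
#'   balance (see Details).
#' @param balance_penalty Penalty per balance-violating absorption; default
#'   `100 * max(finite entries)`.
#' @details Near-fine balance is implemented by augmenting the assignment
#'   problem with surplus-absorbing extra rows, one per excess control in each
#'   category of the (interacted) balance keys: absorbing a control from a
#'   surplus category is free, absorbing from elsewhere costs a penalty, so
#'   the matched controls' marginal category counts are pushed toward the
#'   treated counts without sacrificing feasibility.
#' @return A `matched_sample` with all set sizes equal to 2.
#' @export
pair_match <- function(dist, table = NULL, balance_keys = NULL,
                       balance_penalty = NULL) {
  match_core(dist, table, min_c = 1L, max_c = 1L, balance_keys = balance_keys,
             balance_penalty = balance_penalty)
}

#' Optimal variable-ratio matching
#'
#' Each treated unit receives between `min_controls` and `max_controls`
#' controls, every control is used at most once, and the total matched
#' distance is minimal subject to the constraints. When the control supply is
#' short of `I * max_controls`, all controls are used and the matching ratios
#' adapt; with `min_controls = max_controls = 1` the result equals
#' [pair_match()] exactly.
#'
#' @inheritParams pair_match
#' @param min_controls,max_controls Controls per treated unit (`min >= 1`,
#'   `max >= min`).
#' @return A `matched_sample`.
#' @export
variable_ratio_match <- function(dist, table = NULL, min_controls = 1L,
                                 max_controls = 1L, balance_keys = NULL,
                                 balance_penalty = NULL) {
  match_core(dist, table, min_c = as.integer(min_controls),
             max_c = as.integer(max_controls), balance_keys = balance_keys,
             balance_penalty = balance_penalty)
}

match_core <- function(dist, table, min_c, max_c, balance_keys = NULL,
                       balance_penalty = NULL) {
  stopifnot(min_c >= 1L, max_c >= min_c)
  ti <- attr(dist, "treated_idx"); ci <- attr(dist, "control_idx")
  d <- unclass(dist)
  TT <- nrow(d); C <- ncol(d)
  if (C < TT * min_c)
    stop("infeasible control supply: need at least ", TT * min_c,
         " controls for ", TT, " treated units, have ", C)

  n_slots <- TT * max_c
  slot_treated <- rep(seq_len(TT), each = max_c)
  slot_required <- rep(seq_len(max_c), times = TT) <= min_c
  n_dummy <- max(0L, n_slots - C)

  finite <- d[is.finite(d)]
  if (length(finite) == 0) {
    stop("matching infeasible for treated units: ",
         paste(rownames(d), collapse = ", "))
  }
  mx <- max(finite, 0)

  cost <- matrix(Inf, n_slots, C + n_dummy)
  cost[, seq_len(C)] <- d[slot_treated, , drop = FALSE]
  if (n_dummy > 0)
    cost[!slot_required, C + seq_len(n_dummy)] <- 0

  extra_cat <- character(0)
  if (!is.null(balance_keys) && C > n_slots) {
    stopifnot(!is.null(table), all(balance_keys %in% names(table$x)))
    if (is.null(balance_penalty)) balance_penalty <- 100 * max(mx, 1)
    cat_all <- interaction(table$x[balance_keys], drop = TRUE)
    tcat <- table(cat_all[ti]); ccat <- table(cat_all[ci])
    levs <- levels(cat_all)
    desired <- as.numeric(tcat[levs]) * (n_slots / TT)
    desired[is.na(desired)] <- 0
    have <- as.numeric(ccat[levs]); have[is.na(have)] <- 0
    surplus <- pmax(round(have - desired), 0)
    n_extra <- C - n_slots
    e <- surplus
    while (sum(e) > n_extra) e[which.max(e)] <- e[which.max(e)] - 1
    extra_cat <- rep(levs, times = e)
    if (length(extra_cat) < n_extra)
      extra_cat <- c(extra_cat, rep(NA_character_,
                                    n_extra - length(extra_cat)))
    ctrl_cat <- as.character(cat_all[ci])
    extra_cost <- matrix(0, length(extra_cat), C + n_dummy)
    for (r in seq_along(extra_cat)) {
      if (!is.na(extra_cat[r]))
        extra_cost[r, seq_len(C)] <-
          ifelse(ctrl_cat == extra_cat[r], 0, balance_penalty)
    }
    cost <- rbind(cost, extra_cost)
  }

  sol <- lsap_solve(cost)
  slot_cols <- sol[seq_len(n_slots)]
  is_real <- slot_cols <= C
  bad <- is_real & !is.finite(d[cbind(slot_treated, pmin(slot_cols, C))])
  if (any(bad)) {
    labs <- if (is.null(table)) as.character(ti[slot_treated[bad]])
            else table$id[ti[slot_treated[bad]]]
    stop("matching infeasible for treated units: ",
         paste(unique(labs), collapse = ", "))
  }

  sets <- data.frame(set = integer(0), unit = integer(0),
                     role = character(0))
  for (t in seq_len(TT)) {
    cols <- slot_cols[slot_treated == t]
    ctrls <- ci[cols[cols <= C]]
    sets <- rbind(sets,
                  data.frame(set = t, unit = c(ti[t], ctrls),
                             role = c("treated", rep("control",
                                                     length(ctrls)))))
  }
  new_matched_sample(sets, table,
                     constraints = list(min_controls = min_c,
                                        max_controls = max_c,
                                        balance_keys = balance_keys))
}

#' Fine-balance deviation of a categorical covariate
#'
#' Compares the marginal category counts of a covariate between the treated
#' units and their matched controls. For variable-ratio samples each control
#' contributes weight `1/(n_i - 1)` so control counts are on the treated
#' scale.
#'
#' @param sample A `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param key A categorical (or discrete) covariate name.
#' @return Named numeric vector of per-category absolute count deviations.
#' @export
evaluate_fine_balance <- function(sample, table, key) {
  v <- as.character(table$x[[key]])
  sets <- ms_sets(sample)
  tvals <- vapply(sets, function(s) v[s$treated], character(1))
  cvals <- unlist(lapply(sets, function(s) v[s$controls]))
  cwts <- unlist(lapply(sets, function(s)
    rep(1 / length(s$controls), length(s$controls))))
  levs <- sort(unique(c(tvals, cvals)))
  tc <- vapply(levs, function(l) sum(tvals == l), numeric(1))
  cc <- vapply(levs, function(l) sum(cwts[cvals == l]), numeric(1))
  abs(tc - cc)
}

#' Standardized mean differences before and after matching
#'
#' For each expanded covariate, reports
#' `(mean treated - mean control) / SD_pooled`, where the pooled SD comes from
#' the unmatched groups so the before and after columns share a scale. For
#' variable-ratio samples, matched controls are weighted by `1/(n_i - 1)`.
#'
#' @param table An imputed `obs_table`.
#' @param sample Optional `matched_sample` for the after-matching column.
#' @return A data frame with columns `covariate`, `before`, `after` (NA when
#'   no sample is given) and `zero_sd` flag.
#' @export
standardized_differences <- function(table, sample = NULL) {
  X <- expand_covariates(table)
  zt <- table$z == 1L
  sd_pool <- sqrt((apply(X[zt, , drop = FALSE], 2, var) +
                   apply(X[!zt, , drop = FALSE], 2, var)) / 2)
  zero <- sd_pool == 0 | !is.finite(sd_pool)
  denom <- ifelse(zero, 1, sd_pool)
  before <- (colMeans(X[zt, , drop = FALSE]) -
             colMeans(X[!zt, , drop = FALSE])) / denom
  before[zero] <- 0
  after <- rep(NA_real_, ncol(X))
  if (!is.null(sample)) {
    sets <- ms_sets(sample)
    tu <- vapply(sets, function(s) s$treated, numeric(1))
    cu <- unlist(lapply(sets, function(s) s$controls))
    cw <- unlist(lapply(sets, function(s)
      rep(1 / length(s$controls), length(s$controls))))
    cw <- cw / sum(cw)
    after <- (colMeans(X[tu, , drop = FALSE]) -
              colSums(X[cu, , drop = FALSE] * cw)) / denom
    after[zero] <- 0
  }
  data.frame(covariate = colnames(X), before = before, after = after,
             zero_sd = zero, row.names = NULL)
}

exact_on_keys <- function(table, keys, units) {
  # TRUE iff all units share identical values on every key
  for (key in keys) {
    v <- as.character(table$x[[key]])[units]
    if (length(unique(v)) > 1) return(FALSE)
  }
  TRUE
}

#' Rematch inexactly matched pairs within subgroups
#'
#' Pairs already exactly matched on `selected_keys` are kept. The treated and
#' control units of the remaining (inexact) pairs are pooled and re-paired by
#' optimal assignment restricted to exact agreement on `selected_keys`; units
#' that cannot be re-paired exactly are dropped. The number of exactly matched
#' pairs never decreases.
#'
#' @param sample A pair-matched `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param selected_keys Covariates (e.g. the splitting variables of a fitted
#'   regression tree) defining the subgroups.
#' @return A `matched_sample` of pairs, all exactly matched on
#'   `selected_keys`; attribute `n_dropped` counts discarded units.
#' @export
rematch_inexact <- function(sample, table, selected_keys) {
  sets <- ms_sets(sample)
  if (any(vapply(sets, function(s) length(s$controls), numeric(1)) != 1))
    stop("rematch_inexact requires a pair matching")
  exact <- vapply(sets, function(s)
    exact_on_keys(table, selected_keys, c(s$treated, s$controls)), logical(1))

  keep <- sets[exact]
  pool_t <- vapply(sets[!exact], function(s) s$treated, numeric(1))
  pool_c <- vapply(sets[!exact], function(s) s$controls, numeric(1))
  n_new <- 0L
  new_pairs <- list()
  if (length(pool_t) > 0) {
    dist_full <- rank_mahalanobis(table)
    ti <- attr(dist_full, "treated_idx"); ci <- attr(dist_full, "control_idx")
    d <- unclass(dist_full)[match(pool_t, ti), match(pool_c, ci),
                            drop = FALSE]
    for (key in selected_keys) {
      v <- as.character(table$x[[key]])
      d[outer(v[pool_t], v[pool_c], "!=")] <- Inf
    }
    if (any(is.finite(d))) {
      sol <- lsap_solve(d)
      ok <- !attr(sol, "forbidden")
      for (r in which(ok)) {
        n_new <- n_new + 1L
        new_pairs[[n_new]] <- list(treated = pool_t[r],
                                   controls = pool_c[sol[r]])
      }
    }
  }
  all_sets <- c(keep, new_pairs)
  sets_df <- do.call(rbind, lapply(seq_along(all_sets), function(i)
    data.frame(set = i,
               unit = c(all_sets[[i]]$treated, all_sets[[i]]$controls),
               role = c("treated", "control"))))
  out <- new_matched_sample(sets_df, table, constraints = sample$constraints)
  attr(out, "n_dropped") <- 2L * (length(pool_t) - n_new)
  out
}

#' Export a matched sample as a data frame
#'
#' @param x A `matched_sample`.
#' @param ... Unused.
#' @return Data frame with columns `set_index`, `unit_id`, `role`.
#' @export
as.data.frame.matched_sample <- function(x, ...) {
  data.frame(set_index = x$sets$set, unit_id = x$ids, role = x$sets$role)
}
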