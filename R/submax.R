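#' Contrast family over binary effect modifiers
#'
#' For `L` binary modifiers the family contains `K = 2L + 1` comparisons: the
#' overall comparison (all matched sets) and, per modifier, its two
#' complementary subpopulations. A matched set belongs to a modifier
#' comparison only if it is exactly matched on that modifier (all members
#' share the value); sets inexactly matched on some modifier still contribute
#' to the comparisons defined by the modifiers they are exact on, and to the
#' overall comparison.
#'
#' @param sample A `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param modifier_keys Names of binary covariates (at most two observed
#'   levels each).
#' @return A `contrast_family`: `K`, `L`, `labels`, `members` (list of
#'   set-index vectors), and `groups`/`cmat` describing the induced
#'   subgroup-level contrast vectors over the `2^L` modifier combinations.
#' @export
build_contrasts <- function(sample, table, modifier_keys = character(0)) {
  sets <- ms_sets(sample)
  I <- length(sets)
  L <- length(modifier_keys)

  set_val <- function(key) {
    v <- as.character(table$x[[key]])
    vapply(sets, function(s) {
      vals <- unique(v[c(s$treated, s$controls)])
      if (length(vals) == 1) vals else NA_character_
    }, character(1))
  }
  vals <- lapply(modifier_keys, set_val)
  names(vals) <- modifier_keys
  levs <- lapply(seq_along(modifier_keys), function(l) {
    u <- sort(unique(as.character(table$x[[modifier_keys[l]]])))
    if (length(u) > 2)
      stop("modifier '", modifier_keys[l], "' is not binary")
    u
  })

  members <- list(seq_len(I))
  labels <- "overall"
  for (l in seq_len(L)) {
    for (v in levs[[l]]) {
      members <- c(members, list(which(!is.na(vals[[l]]) & vals[[l]] == v)))
      labels <- c(labels, paste0(modifier_keys[l], "=", v))
    }
  }
  if (any(lengths(members) == 0))
    stop("empty comparison: ", paste(labels[lengths(members) == 0],
                                     collapse = ", "))

  # subgroup-level representation over the modifier combinations
  groups <- if (L == 0) data.frame(row.names = 1) else
    rev(expand.grid(rev(setNames(levs, modifier_keys)),
                    stringsAsFactors = FALSE))
  G <- nrow(groups)
  cmat <- matrix(0L, length(members), G,
                 dimnames = list(labels, NULL))
  cmat[1, ] <- 1L
  k <- 1L
  for (l in seq_len(L)) for (v in levs[[l]]) {
    k <- k + 1L
    cmat[k, groups[[modifier_keys[l]]] == v] <- 1L
  }

  structure(list(K = length(members), L = L, labels = labels,
                 members = members, groups = groups, cmat = cmat,
                 modifier_keys = modifier_keys),
            class = "contrast_family")
}

#' @export
print.contrast_family <- function(x, ...) {
  cat("contrast_family: K =", x$K, "comparisons over L =", x$L,
      "modifiers\n")
  for (k in seq_len(x$K))
    cat(sprintf("  %-24s %d sets\n", x$labels[k], length(x$members[[k]])))
  invisible(x)
}

#' Studentized worst-case deviates of a contrast family
#'
#' For each comparison `k`, `D_k = (T_k - theta_k) / sigma_k`, where `T_k`
#' sums the weighted treated psi-scores over the comparison's member sets and
#' `(theta_k, sigma_k)` are the worst-case null moments at `gamma`.
#'
#' @param scores A `set_scores` object.
#' @param family A `contrast_family` over the same matched sets.
#' @param gamma Sensitivity parameter, `>= 1`.
#' @param direction `"upper"` or `"lower"` tail.
#' @return A `deviate_vector`: `D`, `D_max`, per-comparison `T`, `theta`,
#'   `sigma`, plus the per-set worst-case moments used (for the correlation).
#' @export
deviates <- function(scores, family, gamma = 1,
                     direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "lower") -1 else 1
  mom <- set_moments(scores, gamma, direction)
  w <- scores$w
  qt <- sgn * vapply(scores$q, function(q) q[1], numeric(1))
  Tk <- vapply(family$members, function(m) sum(w[m] * qt[m]), numeric(1))
  th <- vapply(family$members, function(m) sum(w[m] * mom[m, "mu"]),
               numeric(1))
  s2 <- vapply(family$members, function(m) sum(w[m]^2 * mom[m, "v"]),
               numeric(1))
  if (any(s2 <= 0)) stop("degenerate comparison (zero worst-case variance)")
  D <- (Tk - th) / sqrt(s2)
  structure(list(D = setNames(D, family$labels), D_max = max(D),
                 T = Tk, theta = th, sigma = sqrt(s2), gamma = gamma,
                 direction = direction, set_var = w^2 * mom[, "v"],
                 family = family),
            class = "deviate_vector")
}

#' Correlation matrix of the contrast deviates
#'
#' `rho(k, k') = sum over shared member sets of w_i^2 v_i / (sigma_k
#' sigma_k')`, with `v_i` the per-set worst-case variance; unit diagonal,
#' entries in `[0, 1]` for nonnegative weights.
#'
#' @inheritParams deviates
#' @return A `K x K` correlation matrix.
#' @export
deviate_correlation <- function(scores, family, gamma = 1,
                                direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  mom <- set_moments(scores, gamma, direction)
  sv <- scores$w^2 * mom[, "v"]
  K <- family$K
  sig <- vapply(family$members, function(m) sqrt(sum(sv[m])), numeric(1))
  rho <- diag(1, K)
  for (k in seq_len(K - 1)) for (j in (k + 1):K) {
    shared <- intersect(family$members[[k]], family$members[[j]])
    rho[k, j] <- rho[j, k] <- sum(sv[shared]) / (sig[k] * sig[j])
  }
  dimnames(rho) <- list(family$labels, family$labels)
  rho
}

#' Critical value for the maximum of correlated normal deviates
#'
#' The `1 - alpha` quantile of the maximum of a zero-mean unit-variance
#' normal vector with correlation `rho`, found by bracketing root search on
#' the multivariate-normal rectangle probability (tolerance 1e-4).
#'
#' @param rho Positive semidefinite correlation matrix.
#' @param alpha Level in (0, 1).
#' @return The critical value `kappa`.
#' @export
critical_value <- function(rho, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  rho <- as.matrix(rho)
  ev <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("correlation matrix is not positive semidefinite ",
         "(smallest eigenvalue ", signif(ev, 3), ")")
  K <- nrow(rho)
  if (K == 1) return(qnorm(1 - alpha))
  f <- function(k) mvn_rect(rep(k, K), rho) - (1 - alpha)
  lo <- qnorm(1 - alpha); hi <- qnorm(1 - alpha / K) + 0.5
  while (f(hi) < 0) hi <- hi + 0.5
  uniroot(f, c(lo, hi), tol = 1e-4)$root
}

#' Maximum-deviate (submax) test
#'
#' Rejects the sharp null of no effect in the whole population, at sensitivity
#' parameter `gamma`, if the maximum studentized deviate exceeds the critical
#' value of the maximum of the correlated normal vector.
#'
#' @param dev A `deviate_vector`.
#' @param rho The matching correlation matrix.
#' @param alpha Level.
#' @return List with `D_max`, `kappa`, `pvalue` (`1 - P(max <= D_max)`) and
#'   `reject`.
#' @export
submax_test <- function(dev, rho, alpha = 0.05) {
  stopifnot(length(dev$D) == nrow(rho))
  p <- 1 - mvn_rect(rep(dev$D_max, nrow(rho)), rho)
  kappa <- critical_value(rho, alpha)
  list(D_max = dev$D_max, kappa = kappa, pvalue = p,
       reject = dev$D_max >= kappa)
}

# Local rejection of the subfamily J: max_{k in J} D_k >= kappa(rho_J),
# decided through one rectangle probability; Slepian-type bounds (valid for
# nonnegative correlations) avoid most MVN evaluations.
reject_subfamily <- function(D, rho, J, alpha, use_bounds) {
  u <- max(D[J])
  m <- length(J)
  if (m == 1) return(pnorm(u) >= 1 - alpha)
  pu <- pnorm(u)
  if (use_bounds) {
    if (pu < 1 - alpha) return(FALSE)       # P(all <= u) <= Phi(u)
    if (pu^m >= 1 - alpha) return(TRUE)     # P(all <= u) >= Phi(u)^m
  }
  mvn_rect(rep(u, m), rho[J, J, drop = FALSE]) >= 1 - alpha
}

#' Closed testing over the submax comparisons
#'
#' For each subset `J` of comparisons, `H_J` is rejected locally if
#' `max_{k in J} D_k` reaches the critical value of the `|J|`-dimensional
#' normal maximum with the corresponding correlation submatrix; the closure
#' principle then yields familywise-valid rejections. Full enumeration is used
#' for `K <= 15`; for larger families singletons are rejected by the
#' conservative sufficient rule `D_k >= kappa(full family)` (the critical
#' value of any subfamily cannot exceed the full family's).
#'
#' @inheritParams submax_test
#' @return List with `rejected` (named logical per comparison),
#'   `any_rejection`, and (when enumerated) the per-subset table.
#' @export
closed_testing_submax <- function(dev, rho, alpha = 0.05) {
  D <- dev$D
  K <- length(D)
  use_bounds <- min(rho) >= 0
  if (K > 15) {
    kappa <- critical_value(rho, alpha)
    rejected <- D >= kappa
    return(list(rejected = rejected, any_rejection = any(rejected),
                table = NULL, reduced = TRUE))
  }
  full <- seq_len(K)
  if (!reject_subfamily(D, rho, full, alpha, use_bounds)) {
    rejected <- setNames(rep(FALSE, K), names(D))
    return(list(rejected = rejected, any_rejection = FALSE, table = NULL,
                reduced = FALSE))
  }
  masks <- subset_masks(K)
  local <- logical(length(masks))
  closed <- logical(length(masks))
  sizes <- vapply(masks, function(m) length(mask_members(m, K)), integer(1))
  for (m in masks[order(sizes, decreasing = TRUE)]) {
    ok_sup <- TRUE
    for (j in 0:(K - 1L)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(m, bit) == 0 && !closed[bitwOr(m, bit)]) {
        ok_sup <- FALSE; break
      }
    }
    if (!ok_sup) { closed[m] <- FALSE; next }  # some superset already failed
    local[m] <- reject_subfamily(D, rho, mask_members(m, K), alpha,
                                 use_bounds)
    closed[m] <- local[m]
  }
  rejected <- vapply(seq_len(K), function(k)
    closed[bitwShiftL(1L, k - 1L)], logical(1))
  names(rejected) <- names(D)
  tab <- data.frame(
    subset = vapply(masks, function(m) format_subset(mask_members(m, K)),
                    character(1)),
    size = sizes, max_D = vapply(masks, function(m)
      max(D[mask_members(m, K)]), numeric(1)),
    reject_closed = closed)
  list(rejected = rejected, any_rejection = any(closed), table = tab,
       reduced = FALSE)
}

#' Sensitivity values over a Gamma grid
#'
#' Applies a rejection-producing analysis at each grid value and reports, per
#' hypothesis, the smallest `gamma` at which the rejection is lost (1 if never
#' rejected; `Inf`, flagged censored, if rejected at every grid point).
#' Exploits monotonicity: once lost, a hypothesis is not re-examined.
#'
#' @param reject_at Function of `gamma` returning a named logical vector of
#'   rejections.
#' @param gamma_grid Increasing grid starting at 1.
#' @return Data frame `hypothesis`, `sensitivity_value`, `censored`.
#' @export
sensitivity_value <- function(reject_at, gamma_grid) {
  stopifnot(all(diff(gamma_grid) > 0), gamma_grid[1] >= 1)
  rej <- reject_at(gamma_grid[1])
  vals <- ifelse(rej, Inf, gamma_grid[1])
  alive <- rej
  for (gamma in gamma_grid[-1]) {
    if (!any(alive)) break
    rej <- reject_at(gamma)
    lost <- alive & !rej
    vals[lost] <- gamma
    alive <- alive & rej
  }
  data.frame(hypothesis = names(rej), sensitivity_value = unname(vals),
             censored = !is.finite(unname(vals)), row.names = NULL)
}

#' Submax sensitivity analysis of a matched sample
#'
#' For each `gamma` in the grid, computes the studentized deviates of the
#' contrast family, their correlation, the maximum-deviate test and closed
#' testing; reports a per-gamma table (deviates, maximum, p-value, critical
#' value) and per-comparison sensitivity values. Two-sided analyses run both
#' tails at `alpha / 2` and reject if either rejects.
#'
#' @param sample A `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param modifier_keys Binary effect modifiers defining the contrasts.
#' @param gamma_grid Increasing grid of sensitivity parameters.
#' @param config A [score_config()].
#' @param alpha Familywise level.
#' @param side `"upper"`, `"lower"` or `"two"`.
#' @return A `submax_result`.
#' @export
submax_analyze <- function(sample, table, modifier_keys, gamma_grid = 1,
                           config = score_config(), alpha = 0.05,
                           side = c("upper", "two", "lower")) {
  side <- match.arg(side)
  family <- build_contrasts(sample, table, modifier_keys)
  scores <- set_scores(sample, table$y, config)
  dirs <- switch(side, upper = "upper", lower = "lower",
                 two = c("upper", "lower"))
  lvl <- if (side == "two") alpha / 2 else alpha

  rows <- list(); rej_rows <- list()
  for (gi in seq_along(gamma_grid)) {
    gamma <- gamma_grid[gi]
    rej <- setNames(rep(FALSE, family$K), family$labels)
    row <- NULL
    for (dd in dirs) {
      dv <- deviates(scores, family, gamma, dd)
      rho <- deviate_correlation(scores, family, gamma, dd)
      ct <- closed_testing_submax(dv, rho, lvl)
      rej <- rej | ct$rejected
      if (dd == dirs[1]) {
        st <- submax_test(dv, rho, lvl)
        row <- data.frame(gamma = gamma, t(dv$D), D_max = dv$D_max,
                          kappa = st$kappa, pvalue = st$pvalue)
        names(row) <- c("gamma", family$labels, "D_max", "kappa", "pvalue")
      }
    }
    rows[[gi]] <- row
    rej_rows[[gi]] <- rej
  }
  rej <- do.call(rbind, rej_rows)
  structure(list(family = family, scores = scores,
                 table = do.call(rbind, rows), rejections = rej,
                 sensitivity_values =
                   sensitivity_from_rejections(gamma_grid, rej),
                 alpha = alpha, side = side, gamma_grid = gamma_grid),
            class = "submax_result")
}

#' @export
print.submax_result <- function(x, ...) {
  cat("submax sensitivity analysis: K =", x$family$K, "comparisons;",
      x$side, "tests at alpha =", x$alpha, "\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat("sensitivity values:\n")
  print(x$sensitivity_values, row.names = FALSE)
  invisible(x)
}

#' The submax+ pipeline: CART-seeded submax
#'
#' Pair-matches the sample, fits the regression tree of absolute within-pair
#' differences on the potential effect modifiers, takes the tree's splitting
#' variables (dichotomized at the tree's split points), rebuilds the matched
#' sample by variable-ratio matching with almost-exact matching on those
#' variables, and runs the submax analysis over the induced contrast family.
#' When the tree selects no variable the analysis reduces to the overall-only
#' comparison (`K = 1`).
#'
#' @inheritParams hsr_pipeline
#' @param min_controls,max_controls Variable-ratio bounds for the rematch.
#' @return A `submax_result` (with the tree attached as attribute `tree`).
#' @export
submax_plus_pipeline <- function(table, pem_keys, gamma_grid = 1,
                                 config = score_config(), alpha = 0.05,
                                 side = "upper", min_controls = 1,
                                 max_controls = 3, tree_control = list(),
                                 match_args = list()) {
  table <- impute_two_step(table)
  d <- rank_mahalanobis(table)
  ps <- propensity_scores(table)
  d0 <- apply_caliper(d, ps, width = match_args$caliper_width,
                      penalty = match_args$caliper_penalty %||% 1000)
  pairs <- pair_match(apply_almost_exact(d0, table, pem_keys), table)
  pd <- pair_differences(pairs, table, pem_keys)
  tree <- do.call(fit_tree, c(list(records = pd), tree_control))
  keys <- dichotomize_at_splits(table, tree)
  table2 <- keys$table
  d2 <- rank_mahalanobis(table2)
  d2 <- apply_caliper(d2, propensity_scores(table2),
                      width = match_args$caliper_width,
                      penalty = match_args$caliper_penalty %||% 1000)
  if (length(keys$keys) > 0)
    d2 <- apply_almost_exact(d2, table2, keys$keys)
  vs <- variable_ratio_match(d2, table2, min_controls, max_controls,
                             balance_keys = match_args$balance_keys)
  out <- submax_analyze(vs, table2, keys$keys, gamma_grid, config, alpha,
                        side)
  attr(out, "tree") <- tree
  out
}

# Turn the tree's splitting variables into binary covariates cut at the
# tree's split points (numeric splits; binary variables pass through).
dichotomize_at_splits <- function(table, tree) {
  if (length(tree$vars) == 0) return(list(table = table, keys = character(0)))
  keys <- character(0)
  for (v in tree$vars) {
    pts <- tree$split_points$point[tree$split_points$var == v]
    x <- table$x[[v]]
    if (!is.numeric(x) || length(unique(x)) <= 2) {
      keys <- c(keys, v)
      next
    }
    cutpt <- pts[which(!is.na(pts))[1]]
    nm <- paste0(v, "_ge", signif(cutpt, 4))
    table$x[[nm]] <- as.numeric(x >= cutpt)
    table$types[[nm]] <- "numeric"
    table$miss <- cbind(table$miss, matrix(FALSE, nrow(table$miss), 1,
                                           dimnames = list(NULL, nm)))
    keys <- c(keys, nm)
  }
  list(table = table, keys = keys)
}
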