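#' Truncated product combination of p-values
#'
#' Combines p-values by the product of those falling at or below the
#' truncation threshold (empty product = 1). The null distribution of the
#' product statistic `W` under independent uniform p-values has the closed
#' form, conditioning on the binomial count of truncated p-values,
#' \deqn{P(W \le w) = \sum_{k\ge1} \binom{L}{k} \tau^k (1-\tau)^{L-k} F_k(w/\tau^k),}
#' where \eqn{F_k(x) = x \sum_{s<k} (-\ln x)^s/s!} is the distribution of a
#' product of `k` uniforms (and 1 for `x >= 1`). The p-value of `W = 1` is
#' exactly 1.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha_tilde Truncation threshold in (0, 1]; default 0.05.
#' @return List with `W` (the product statistic), `alpha_tilde`, and `pvalue`.
#' @export
truncated_product <- function(pvals, alpha_tilde = 0.05) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals)))
    stop("p-values must lie in [0, 1]")
  stopifnot(alpha_tilde > 0, alpha_tilde <= 1)
  small <- pvals[pvals <= alpha_tilde]
  W <- if (length(small) == 0) 1 else prod(small)
  list(W = W, alpha_tilde = alpha_tilde,
       pvalue = truncated_product_pvalue(W, length(pvals), alpha_tilde))
}

#' @rdname truncated_product
#' @param w Observed product statistic in (0, 1].
#' @param L Number of combined p-values.
#' @export
truncated_product_pvalue <- function(w, L, alpha_tilde = 0.05) {
  tau <- alpha_tilde
  if (w >= 1) return(1)
  if (w <= 0) return(0)
  total <- 0
  for (k in seq_len(L)) {
    x <- w / tau^k
    Fk <- if (x >= 1) 1 else {
      s <- 0:(k - 1)
      x * sum((-log(x))^s / factorial(s))
    }
    total <- total + choose(L, k) * tau^k * (1 - tau)^(L - k) * Fk
  }
  min(max(total, 0), 1)
}

#' Per-subgroup worst-case p-values
#'
#' For each subgroup of the partition, computes the weighted M-statistic and
#' its worst-case normal-approximation p-value at the given `gamma`.
#' Two-sided p-values are twice the smaller one-sided p-value, capped at 1.
#'
#' @param scores A `set_scores` object.
#' @param partition A `subgroup_partition` over the same matched sets.
#' @param gamma Sensitivity parameter, `>= 1`.
#' @param side `"upper"`, `"lower"` or `"two"`.
#' @return Named numeric vector of p-values, one per subgroup.
#' @export
subgroup_pvalues <- function(scores, partition, gamma = 1,
                             side = c("two", "upper", "lower")) {
  side <- match.arg(side)
  vapply(seq_len(partition$G), function(g) {
    idx <- which(partition$group == g)
    t_obs <- m_statistic(scores, idx)
    p_up <- pvalue_upper(t_obs,
                         worstcase_moments(scores, idx, gamma, "upper"))
    if (side == "upper") return(p_up)
    p_lo <- pvalue_upper(-t_obs,
                         worstcase_moments(scores, idx, gamma, "lower"))
    if (side == "lower") return(p_lo)
    min(1, 2 * min(p_up, p_lo))
  }, numeric(1), USE.NAMES = FALSE) -> p
  setNames(p, partition$labels)
}

subset_masks <- function(G) seq_len(2^G - 1L)

mask_members <- function(mask, G) which(bitwAnd(mask, bitwShiftL(1L, 0:(G - 1L))) > 0)

#' Closed testing over a family of subgroup hypotheses
#'
#' Evaluates every nonempty intersection hypothesis of `G` subgroup
#' hypotheses with the supplied p-value function and applies the closure
#' principle: a hypothesis is rejected if and only if it and every
#' intersection containing it have p-values at or below `alpha`. This controls
#' the familywise error rate in the strong sense.
#'
#' @param intersection_p Function taking an integer vector (subset of
#'   `1..G`) and returning its intersection p-value.
#' @param G Number of elementary hypotheses (`G <= 20`).
#' @param alpha Significance level.
#' @return List with `table` (subset, size, p, reject_local, reject_closed)
#'   and `rejected_singletons` (integer indices).
#' @export
closed_testing <- function(intersection_p, G, alpha = 0.05) {
  if (G > 20) stop("G too large for full closure; consider the submax family")
  masks <- subset_masks(G)
  sizes <- vapply(masks, function(m) length(mask_members(m, G)), integer(1))
  p <- vapply(masks, function(m) intersection_p(mask_members(m, G)),
              numeric(1))
  local <- p <= alpha
  closed <- logical(length(masks))
  for (m in masks[order(sizes, decreasing = TRUE)]) {
    if (!local[m]) { closed[m] <- FALSE; next }
    ok <- TRUE
    for (j in 0:(G - 1L)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(m, bit) == 0 && !closed[bitwOr(m, bit)]) { ok <- FALSE; break }
    }
    closed[m] <- ok
  }
  singles <- vapply(seq_len(G), function(g) closed[bitwShiftL(1L, g - 1L)],
                    logical(1))
  tab <- data.frame(
    subset = vapply(masks, function(m)
      format_subset(mask_members(m, G)), character(1)),
    size = sizes, p = p, reject_local = local, reject_closed = closed)
  list(table = tab, rejected_singletons = which(singles))
}

# Intersection p-value function built from per-subgroup p-values via the
# truncated product (Table-2-style testing).
tpm_intersection <- function(pvals, alpha_tilde = 0.05) {
  function(subset) truncated_product(pvals[subset], alpha_tilde)$pvalue
}

#' The HSR sensitivity-analysis pipeline
#'
#' Runs the full chain on a matched pair sample: within-pair differences for
#' pairs exact on the potential effect modifiers, a regression tree on the
#' absolute differences, rematching of inexact pairs on the tree's splitting
#' covariates, subgroup partition from the tree leaves, and, for each value of
#' `gamma` in the grid, per-subgroup worst-case p-values, truncated-product
#' intersection p-values and closed testing. Per-hypothesis sensitivity values
#' (the smallest `gamma` at which rejection is lost) are reported.
#'
#' @param sample A pair-matched `matched_sample`.
#' @param table The underlying `obs_table`.
#' @param pem_keys Potential effect modifiers.
#' @param gamma_grid Increasing grid of sensitivity parameters starting at 1.
#' @param config A [score_config()].
#' @param alpha Familywise level.
#' @param alpha_tilde Truncation threshold.
#' @param side Sidedness of the subgroup tests.
#' @param tree_control List of [fit_tree()] controls.
#' @return An object of class `hsr_result`: the tree, partition, rematched
#'   sample, per-gamma p-value table (`sensitivity_table`), closed-testing
#'   rejections per gamma and per-hypothesis sensitivity values.
#' @export
hsr_analyze <- function(sample, table, pem_keys, gamma_grid = 1,
                        config = score_config(), alpha = 0.05,
                        alpha_tilde = 0.05, side = "two",
                        tree_control = list()) {
  pd <- pair_differences(sample, table, pem_keys)
  tree <- do.call(fit_tree, c(list(records = pd), tree_control))
  if (length(tree$vars) > 0) {
    sample <- rematch_inexact(sample, table, tree$vars)
  }
  partition <- partition_from_tree(sample, table, tree)
  scores <- set_scores(sample, table$y, config)
  G <- partition$G

  rows <- list()
  rejections <- list()
  for (gi in seq_along(gamma_grid)) {
    gamma <- gamma_grid[gi]
    p <- subgroup_pvalues(scores, partition, gamma, side)
    ct <- closed_testing(tpm_intersection(p, alpha_tilde), G, alpha)
    rows[[gi]] <- data.frame(gamma = gamma, t(ct$table$p))
    names(rows[[gi]]) <- c("gamma", ct$table$subset)
    rejections[[gi]] <- ct$table$reject_closed
  }
  sens_tab <- do.call(rbind, rows)
  rej <- do.call(rbind, rejections)
  colnames(rej) <- names(rows[[1]])[-1]
  sens_values <- sensitivity_from_rejections(gamma_grid, rej)

  structure(list(tree = tree, partition = partition, sample = sample,
                 scores = scores, sensitivity_table = sens_tab,
                 rejections = rej, sensitivity_values = sens_values,
                 alpha = alpha, side = side),
            class = "hsr_result")
}

#' @rdname hsr_analyze
#' @param match_args List of arguments passed through to the matching step
#'   (`balance_keys`, `caliper`-related settings).
#' @details `hsr_pipeline()` additionally performs the optimal pair matching:
#'   rank-based Mahalanobis distances, a soft propensity caliper, almost-exact
#'   matching on the potential effect modifiers and optional near-fine
#'   balance.
#' @export
hsr_pipeline <- function(table, pem_keys, gamma_grid = 1,
                         config = score_config(), alpha = 0.05,
                         alpha_tilde = 0.05, side = "two",
                         tree_control = list(), match_args = list()) {
  table <- impute_two_step(table)
  d <- rank_mahalanobis(table)
  ps <- propensity_scores(table)
  d <- apply_caliper(d, ps, width = match_args$caliper_width,
                     penalty = match_args$caliper_penalty %||% 1000)
  d <- apply_almost_exact(d, table, pem_keys)
  sample <- pair_match(d, table, balance_keys = match_args$balance_keys)
  hsr_analyze(sample, table, pem_keys, gamma_grid, config, alpha,
              alpha_tilde, side, tree_control)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-hypothesis sensitivity value: the first gamma on the grid at which the
# closed-testing rejection is lost (1 if never rejected; Inf, flagged
# censored, if rejected throughout).
sensitivity_from_rejections <- function(gamma_grid, rej) {
  vals <- vapply(seq_len(ncol(rej)), function(j) {
    lost <- which(!rej[, j])
    if (length(lost) == 0) Inf else gamma_grid[min(lost)]
  }, numeric(1))
  data.frame(hypothesis = colnames(rej), sensitivity_value = vals,
             censored = !is.finite(vals), row.names = NULL)
}

#' @export
print.hsr_result <- function(x, ...) {
  cat("HSR sensitivity analysis:", x$partition$G, "subgroups from",
      length(x$tree$vars), "tree-selected covariates;",
      x$sample$I, "matched pairs\n")
  cat("sensitivity values (alpha =", x$alpha, "):\n")
  print(x$sensitivity_values, row.names = FALSE)
  invisible(x)
}
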