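#' Configuration of the weighted M-statistic
#'
#' The statistic sums, over matched sets, weighted psi-scores of scaled
#' within-set outcome differences. `inner` and `outer` are the trimming
#' parameters of the ramp [psi()]; `lambda` is the quantile of the pooled
#' absolute treated-control differences used as the scale `s`; the weight
#' scheme is either constant (the default, and the scheme all headline results
#' use) or the sampling-rank `ustat` weights indexed by `(m, m_lo, m_hi)`.
#'
#' @param inner Nonnegative trimming start.
#' @param outer Trimming cap, `> inner` (may be `Inf`: identity psi).
#' @param lambda Quantile in (0,1) for the scale.
#' @param weights `"constant"` or `"ustat"`.
#' @param m,m_lo,m_hi The u-statistic weight indices, `1 <= m_lo <= m_hi <= m`.
#' @return A `score_config` list.
#' @export
score_config <- function(inner = 0, outer = 3, lambda = 0.5,
                         weights = c("constant", "ustat"),
                         m = 20, m_lo = 12, m_hi = 19) {
  weights <- match.arg(weights)
  stopifnot(inner >= 0, outer > inner, lambda > 0, lambda < 1)
  if (weights == "ustat") stopifnot(1 <= m_lo, m_lo <= m_hi, m_hi <= m)
  structure(list(inner = inner, outer = outer, lambda = lambda,
                 weights = weights, m = m, m_lo = m_lo, m_hi = m_hi),
            class = "score_config")
}

#' Scale of the outcome differences
#'
#' The scale `s` is the `lambda`-quantile (linear interpolation between order
#' statistics) of the absolute treated-control outcome differences pooled over
#' all within-set treated-control member pairs.
#'
#' @param sample A `matched_sample`.
#' @param y Outcome vector for all units of the underlying table.
#' @param lambda Quantile in (0,1).
#' @return A positive scalar; ties throughout the outcomes (s = 0) are an
#'   error advising the identity fallback `s = 1`.
#' @export
scale_s <- function(sample, y, lambda = 0.5) {
  sets <- ms_sets(sample)
  diffs <- unlist(lapply(sets, function(s)
    abs(y[s$treated] - y[s$controls])))
  s <- as.numeric(quantile(diffs, lambda, type = 7))
  if (s <= 0)
    stop("scale s = 0 (outcomes tied at the chosen quantile); ",
         "consider the identity fallback s = 1")
  s
}

#' Trimmed ramp psi function
#'
#' The odd, nondecreasing score function
#' `psi(y) = sign(y) * min(max(|y| - inner, 0), outer - inner)`. With
#' `inner = 0, outer = Inf` this is the identity, recovering the permutational
#' t-test when combined with constant weights.
#'
#' @param y Numeric input.
#' @param inner,outer Trimming parameters, `0 <= inner < outer`.
#' @return psi evaluated elementwise; bounded by `outer - inner`.
#' @export
psi <- function(y, inner = 0, outer = 3) {
  stopifnot(inner >= 0, outer > inner)
  sign(y) * pmin(pmax(abs(y) - inner, 0), outer - inner)
}

#' Per-set psi-scores and weights
#'
#' For each member `j` of matched set `i` computes
#' `q_ij = sum_l psi((R_ij - R_il)/s)`; within a pair the two scores are
#' antisymmetric and within any set they sum to zero. Weights follow the
#' configured scheme.
#'
#' @param sample A `matched_sample`.
#' @param y Outcome vector for all units of the underlying table.
#' @param config A [score_config()].
#' @param s Optional pre-computed scale (computed once globally otherwise).
#' @return A `set_scores` object: per-set `q` vectors (treated member first),
#'   weights `w`, and the scale `s`.
#' @export
set_scores <- function(sample, y, config = score_config(), s = NULL) {
  sets <- ms_sets(sample)
  if (is.null(s)) s <- scale_s(sample, y, config$lambda)
  q <- lapply(sets, function(st) {
    r <- c(y[st$treated], y[st$controls])
    vapply(seq_along(r), function(j)
      sum(psi((r[j] - r) / s, config$inner, config$outer)), numeric(1))
  })
  w <- if (config$weights == "constant") rep(1, length(sets))
       else ustat_weights(sample, y, config$m, config$m_lo, config$m_hi)
  structure(list(q = q, w = w, s = s, I = length(sets)),
            class = "set_scores")
}

# Sampling-rank u-statistic weights: w_i is the probability that, given set i
# is included in an m-sample (with replacement) from the sets' absolute
# treated-minus-mean-control differences, its magnitude rank falls in
# positions m_lo..m_hi.
ustat_weights <- function(sample, y, m, m_lo, m_hi) {
  sets <- ms_sets(sample)
  d <- vapply(sets, function(s)
    abs(y[s$treated] - mean(y[s$controls])), numeric(1))
  qq <- avg_rank(d) / length(d)
  vapply(qq, function(u)
    sum(choose(m - 1, (m_lo:m_hi) - 1) * u^((m_lo:m_hi) - 1) *
          (1 - u)^(m - (m_lo:m_hi))), numeric(1))
}

#' Weighted M-statistic over a subgroup of matched sets
#'
#' `T_g = sum_{i in s_g} w_i q_{i,treated}`.
#'
#' @param scores A `set_scores` object.
#' @param subset Integer indices of the contributing matched sets; default all.
#' @return The statistic value.
#' @export
m_statistic <- function(scores, subset = seq_len(scores$I)) {
  if (length(subset) == 0) stop("empty subgroup")
  qt <- vapply(scores$q[subset], function(q) q[1], numeric(1))
  sum(scores$w[subset] * qt)
}

# Per-set worst-case mean and variance of the treated member's q at a given
# gamma. For each set, the adverse distribution puts probability
# gamma/(a*gamma + n - a) on each of the a largest q and 1/(a*gamma + n - a)
# on the rest; a is chosen to maximize the mean (ties: larger second moment).
set_worstcase <- function(q, gamma) {
  n <- length(q)
  qs <- sort(q, decreasing = TRUE)
  cq <- cumsum(qs); cq2 <- cumsum(qs^2)
  tq <- cq[n]; tq2 <- cq2[n]
  a <- seq_len(n - 1)
  denom <- a * gamma + n - a
  mu <- (gamma * cq[a] + (tq - cq[a])) / denom
  nu <- (gamma * cq2[a] + (tq2 - cq2[a])) / denom
  best <- which(mu > max(mu) - 1e-12)
  pick <- best[which.max(nu[best])]
  c(mu = mu[pick], v = nu[pick] - mu[pick]^2)
}

# Vectorized over sets; direction "lower" negates the scores.
set_moments <- function(scores, gamma, direction = "upper") {
  sgn <- if (direction == "lower") -1 else 1
  t(vapply(scores$q, function(q) set_worstcase(sgn * q, gamma), numeric(2)))
}

#' Worst-case null moments of the M-statistic under the Gamma model
#'
#' Computes the expectation and standard deviation of the subgroup statistic
#' under the most adverse allocation of an unobserved covariate consistent
#' with the sensitivity parameter `gamma`, under the sharp null. At
#' `gamma = 1` these equal the uniform-randomization moments.
#'
#' @inheritParams m_statistic
#' @param gamma Sensitivity parameter, `>= 1`.
#' @param direction `"upper"` (default) or `"lower"` tail.
#' @return List with `theta` (worst-case mean), `sigma` (worst-case SD),
#'   `gamma`, `direction`.
#' @export
worstcase_moments <- function(scores, subset = seq_len(scores$I), gamma = 1,
                              direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (gamma < 1) stop("gamma must be >= 1")
  if (length(subset) == 0) stop("empty subgroup")
  mom <- set_moments(scores, gamma, direction)[subset, , drop = FALSE]
  w <- scores$w[subset]
  list(theta = sum(w * mom[, "mu"]),
       sigma = sqrt(sum(w^2 * mom[, "v"])),
       gamma = gamma, direction = direction)
}

#' Normal-approximation worst-case p-value
#'
#' One minus the standard normal distribution function at
#' `(T - theta) / sigma`; for the lower tail pass a statistic and null
#' computed with `direction = "lower"` (sign-reversed scores).
#'
#' @param t Observed statistic (from [m_statistic()]; negate for lower tail).
#' @param null Worst-case moments from [worstcase_moments()].
#' @return p-value in `[0, 1]`.
#' @export
pvalue_upper <- function(t, null) {
  if (null$sigma <= 0) {
    warning("degenerate null (sigma = 0)")
    return(if (t <= null$theta) 1 else 0)
  }
  1 - pnorm((t - null$theta) / null$sigma)
}

#' Exact worst-case tail probability by enumeration (test oracle)
#'
#' Maximizes `P(T >= t)` over all binary configurations of the unobserved
#' covariate, with within-set treatment probabilities proportional to
#' `gamma^u`, by exhaustive enumeration. Intended as an oracle on tiny
#' instances (at most 14 members in total).
#'
#' @inheritParams worstcase_moments
#' @param t Threshold.
#' @return The exact maximal tail probability.
#' @export
exact_worstcase_tail <- function(scores, subset = seq_len(scores$I),
                                 gamma = 1, t = 0) {
  qs <- scores$q[subset]
  ws <- scores$w[subset]
  sizes <- lengths(qs)
  if (sum(sizes) > 14) stop("instance too large for enumeration (> 14 members)")

  # per set: list of candidate outcome distributions, one per u-configuration
  per_set <- lapply(seq_along(qs), function(i) {
    n <- sizes[i]
    u_grid <- as.matrix(expand.grid(rep(list(0:1), n)))
    lapply(seq_len(nrow(u_grid)), function(r) {
      pr <- gamma^u_grid[r, ]
      list(val = ws[i] * qs[[i]], p = pr / sum(pr))
    })
  })
  combos <- expand.grid(lapply(per_set, seq_along))
  best <- 0
  for (r in seq_len(nrow(combos))) {
    dist <- list(val = 0, p = 1)
    for (i in seq_along(per_set)) {
      d2 <- per_set[[i]][[combos[r, i]]]
      dist <- list(val = as.vector(outer(dist$val, d2$val, "+")),
                   p = as.vector(outer(dist$p, d2$p, "*")))
    }
    best <- max(best, sum(dist$p[dist$val >= t - 1e-12]))
  }
  best
}
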