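# Independent brute-force oracles used to check the analytic implementations.

# Worst-case mean/second-moment of one matched set's treated psi-score by
# exhaustive enumeration over all binary unobserved-covariate configurations
# (treatment probabilities proportional to gamma^u within the set).
oracle_set_worstcase <- function(q, gamma) {
  n <- length(q)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    u <- as.integer(intToBits(mask))[seq_len(n)]
    p <- gamma^u / sum(gamma^u)
    mu <- sum(p * q)
    nu <- sum(p * q^2)
    if (is.null(best) || mu > best$mu + 1e-12 ||
        (abs(mu - best$mu) <= 1e-12 && nu > best$nu + 1e-12))
      best <- list(mu = mu, nu = nu)
  }
  best
}

oracle_worstcase_moments <- function(scores, gamma, subset = seq_len(scores$I)) {
  mus <- vs <- numeric(length(subset))
  for (k in seq_along(subset)) {
    b <- oracle_set_worstcase(scores$q[[subset[k]]], gamma)
    mus[k] <- b$mu
    vs[k] <- b$nu - b$mu^2
  }
  w <- scores$w[subset]
  list(theta = sum(w * mus), sigma = sqrt(sum(w^2 * vs)))
}

# Uniform-randomization (gamma = 1) moments by direct averaging over members.
oracle_uniform_moments <- function(scores, subset = seq_len(scores$I)) {
  mus <- vapply(scores$q[subset], mean, numeric(1))
  nus <- vapply(scores$q[subset], function(q) mean(q^2), numeric(1))
  w <- scores$w[subset]
  list(theta = sum(w * mus), sigma = sqrt(sum(w^2 * (nus - mus^2))))
}

# Minimum total cost of a pair assignment by enumerating all injections of
# treated rows into control columns (rows <= 6).
oracle_pair_match_cost <- function(d) {
  stopifnot(nrow(d) <= 6)
  best <- Inf
  recurse <- function(row, used, total) {
    if (total >= best) return()
    if (row > nrow(d)) { best <<- min(best, total); return() }
    for (j in setdiff(seq_len(ncol(d)), used))
      if (is.finite(d[row, j])) recurse(row + 1, c(used, j), total + d[row, j])
  }
  recurse(1, integer(0), 0)
  best
}

total_match_cost <- function(sample, d) {
  ti <- attr(d, "treated_idx"); ci <- attr(d, "control_idx")
  sum(vapply(htesens:::ms_sets(sample), function(s)
    sum(unclass(d)[match(s$treated, ti), match(s$controls, ci)]), numeric(1)))
}

# Fake set_scores object for direct statistical checks.
fake_scores <- function(q, w = rep(1, length(q)), s = 1) {
  structure(list(q = q, w = w, s = s, I = length(q)), class = "set_scores")
}
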