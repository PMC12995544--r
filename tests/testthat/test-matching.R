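test_that("rank-based Mahalanobis distance: zero for identical units, 1-D closed form", {
  tab <- as_obs_table(data.frame(treatment = c(1, 0, 0, 1),
                                 outcome = rnorm(4),
                                 a = c(3, 3, 8, 8), b = c(1, 1, 2, 2)))
  d <- rank_mahalanobis(tab)
  expect_equal(unclass(d)[1, 1], 0)   # identical covariates
  expect_equal(unclass(d)[2, 2], 0)

  # one covariate: squared Mahalanobis on ranks = (rank diff)^2 / var(ranks)
  tab1 <- as_obs_table(data.frame(treatment = c(1, 0, 1, 0),
                                  outcome = rnorm(4),
                                  a = c(10, 2, 5, 7)))
  d1 <- unclass(rank_mahalanobis(tab1))
  r <- rank(tab1$x$a)                 # 4 1 2 3
  v <- var(r)
  expect_equal(d1[1, 1], (r[1] - r[2])^2 / v)
  expect_equal(d1[2, 2], (r[3] - r[4])^2 / v)
})

test_that("distances are invariant under strictly monotone covariate transforms", {
  set.seed(11)
  base <- data.frame(treatment = rep(c(1, 0), each = 5), outcome = rnorm(10),
                     a = rnorm(10), b = runif(10))
  d0 <- rank_mahalanobis(as_obs_table(base))
  tr <- base
  tr$a <- exp(tr$a)            # strictly increasing
  tr$b <- tr$b^3
  expect_equal(unclass(rank_mahalanobis(as_obs_table(tr))), unclass(d0))
})

test_that("propensity scores: intercept-only fit gives the treated fraction; independence gives near-constant scores", {
  tab <- as_obs_table(data.frame(treatment = rep(c(1, 0, 0, 0), 5),
                                 outcome = rnorm(20), a = rep(2, 20)))
  expect_equal(propensity_scores(tab), rep(0.25, 20), tolerance = 1e-9)

  set.seed(21)
  n <- 5000
  tab2 <- as_obs_table(data.frame(treatment = rbinom(n, 1, 0.3),
                                  outcome = rnorm(n), a = rnorm(n)))
  ps <- propensity_scores(tab2)
  expect_lt(max(abs(ps - mean(tab2$z))), 0.05)
})

test_that("perfect separation triggers the ridge fallback", {
  tab <- as_obs_table(data.frame(treatment = rep(c(1, 0), each = 10),
                                 outcome = rnorm(20),
                                 a = rep(c(1, 0), each = 10) + 0,
                                 b = rnorm(20)))
  expect_warning(ps <- propensity_scores(tab), "ridge")
  expect_true(all(ps > 0 & ps < 1))
})

test_that("soft caliper penalizes only gaps beyond the width, proportionally", {
  d <- dist_from_matrix(matrix(1, 2, 2))
  scores <- c(0.5, 0.5, 0.5 - 0.05, 0.5 - 0.2)  # treated then controls
  out <- unclass(apply_caliper(d, scores, width = 0.1, penalty = 1000))
  expect_equal(out[1, 1], 1)                     # gap 0.05 < width
  expect_equal(out[1, 2], 1 + 1000)              # gap = 2 * width
  out0 <- unclass(apply_caliper(d, scores, width = 0.1, penalty = 0))
  expect_equal(out0, unclass(d))
})

test_that("almost-exact penalties add per disagreeing key and enforce exactness when feasible", {
  tab <- as_obs_table(data.frame(
    treatment = c(1, 1, 1, 0, 0, 0), outcome = rnorm(6),
    k1 = c("a", "b", "a", "a", "b", "a"),
    k2 = c(0, 1, 0, 0, 1, 1), k3 = c(1, 1, 1, 1, 1, 1)))
  d <- dist_from_matrix(matrix(1, 3, 3))
  attr(d, "treated_idx") <- 1:3; attr(d, "control_idx") <- 4:6
  out <- unclass(apply_almost_exact(d, tab, c("k1", "k2", "k3"),
                                    penalty = 100))
  expect_equal(out[1, 1], 1)            # agree on all keys
  expect_equal(out[1, 2], 1 + 2 * 100)  # disagrees on k1 and k2

  # with a dominant penalty, the all-exact assignment beats any mismatch:
  # brute-force over all 3x3 assignments
  base <- matrix(c(5, 1, 1, 1, 5, 1, 1, 1, 5), 3, 3)
  dd <- dist_from_matrix(base)
  attr(dd, "treated_idx") <- 1:3; attr(dd, "control_idx") <- 4:6
  pen <- apply_almost_exact(dd, tab, "k1", penalty = NULL)
  m <- pair_match(pen, tab)
  profs <- vapply(htesens:::ms_sets(m), function(s)
    as.character(tab$x$k1[s$treated]) == as.character(tab$x$k1[s$controls]),
    logical(1))
  expect_true(all(profs))   # exact on k1 despite larger base distance
})

test_that("pair matching attains the brute-force minimum", {
  d <- dist_from_matrix(matrix(c(1, 10, 10, 1), 2, 2, byrow = TRUE))
  m <- pair_match(d)
  expect_equal(total_match_cost(m, d), 2)

  d2 <- dist_from_matrix(matrix(c(1, 2, 1, 100), 2, 2, byrow = TRUE))
  m2 <- pair_match(d2)
  expect_equal(total_match_cost(m2, d2), 3)  # (t1,c2) + (t2,c1)

  set.seed(31)
  for (rep in 1:20) {
    nt <- sample(2:6, 1); nc <- nt + sample(0:3, 1)
    dm <- matrix(round(runif(nt * nc, 0, 20), 2), nt, nc)
    dm[runif(nt * nc) < 0.1] <- Inf
    d3 <- dist_from_matrix(dm)
    oracle <- oracle_pair_match_cost(dm)
    if (!is.finite(oracle)) {
      expect_error(pair_match(d3), "infeasible")
    } else {
      expect_equal(total_match_cost(pair_match(d3), d3), oracle,
                   tolerance = 1e-9)
    }
  }
})

test_that("an all-forbidden instance is reported infeasible", {
  d <- dist_from_matrix(matrix(Inf, 2, 3))
  expect_error(pair_match(d), "infeasible")
})

test_that("variable-ratio matching selects nearest controls and respects supply", {
  # 1 treated, 3 controls, exactly 2 each: enumerate all 3 choose 2 subsets
  dm <- matrix(c(4, 1, 2.5), 1, 3)
  d <- dist_from_matrix(dm)
  m <- variable_ratio_match(d, min_controls = 2, max_controls = 2)
  got <- sort(htesens:::ms_sets(m)[[1]]$controls)
  subsets <- combn(3, 2)
  costs <- apply(subsets, 2, function(j) sum(dm[1, j]))
  expect_equal(got, 1 + sort(subsets[, which.min(costs)]))  # controls offset

  # 2 treated, 2 controls, min 1 max 2: controls cannot be shared -> pairs
  d2 <- dist_from_matrix(matrix(c(1, 2, 3, 4), 2, 2))
  m2 <- variable_ratio_match(d2, min_controls = 1, max_controls = 2)
  expect_equal(vapply(htesens:::ms_sets(m2), function(s)
    length(s$controls), numeric(1)), c(1, 1))

  expect_error(variable_ratio_match(d2, min_controls = 2, max_controls = 2),
               "infeasible control supply")
})

test_that("variable-ratio matching with min = max = 1 equals pair matching", {
  set.seed(41)
  for (rep in 1:10) {
    nt <- sample(2:5, 1); nc <- nt + sample(1:4, 1)
    d <- dist_from_matrix(matrix(runif(nt * nc, 0, 10), nt, nc))
    a <- pair_match(d)
    b <- variable_ratio_match(d, min_controls = 1, max_controls = 1)
    expect_equal(total_match_cost(a, d), total_match_cost(b, d),
                 tolerance = 1e-9)
    expect_identical(a$sets, b$sets)
  }
})

test_that("fine-balance deviations count category mismatches on the treated scale", {
  df <- data.frame(id = letters[1:4], treatment = c(1, 0, 1, 0),
                   outcome = c(1, 0, 2, 1), g = c("A", "A", "A", "B"))
  tab <- as_obs_table(df, id = "id")
  sets <- data.frame(set = c(1, 1, 2, 2), unit = 1:4,
                     role = c("treated", "control", "treated", "control"))
  s <- htesens:::new_matched_sample(sets, tab)
  dev <- evaluate_fine_balance(s, tab, "g")
  expect_equal(unname(dev[c("A", "B")]), c(1, 1))

  # exactly balanced pairs give all-zero deviations, invariant to relabeling
  df2 <- df; df2$g <- c("A", "A", "B", "B")
  tab2 <- as_obs_table(df2, id = "id")
  s2 <- htesens:::new_matched_sample(sets, tab2)
  expect_true(all(evaluate_fine_balance(s2, tab2, "g") == 0))
  df3 <- df2; df3$g <- c("Z", "Z", "Q", "Q")   # relabeled
  tab3 <- as_obs_table(df3, id = "id")
  expect_equal(sort(unname(evaluate_fine_balance(
    htesens:::new_matched_sample(sets, tab3), tab3, "g"))),
    sort(unname(evaluate_fine_balance(s2, tab2, "g"))))
})

test_that("near-fine balance steers unmatched-control surplus toward balance", {
  # 2 treated (both category A), 6 controls: 2 A's far away, 4 B's close.
  # Without balance the cheap B's are taken; with balance the A's are.
  df <- data.frame(treatment = c(1, 1, rep(0, 6)), outcome = rnorm(8),
                   g = c("A", "A", "A", "A", "B", "B", "B", "B"),
                   z1 = c(0, 1, 5, 6, 0.1, 0.9, 1.1, 0.05))
  tab <- as_obs_table(df)
  d <- rank_mahalanobis(tab)
  plain <- pair_match(d, tab)
  bal <- pair_match(d, tab, balance_keys = "g")
  dev_plain <- sum(evaluate_fine_balance(plain, tab, "g"))
  dev_bal <- sum(evaluate_fine_balance(bal, tab, "g"))
  expect_lt(dev_bal, dev_plain)
  expect_equal(dev_bal, 0)
})

test_that("standardized differences use the before-matching pooled SD", {
  df <- data.frame(treatment = rep(c(1, 0), each = 4), outcome = rnorm(8),
                   a = c(2, 2, 4, 4, 1, 1, 3, 3))
  tab <- as_obs_table(df)
  sd_pool <- sqrt((var(c(2, 2, 4, 4)) + var(c(1, 1, 3, 3))) / 2)
  bal <- standardized_differences(tab)
  expect_equal(bal$before[bal$covariate == "a"], 1 / sd_pool)

  # constant covariate: flagged, reported 0
  df$c0 <- 5
  bal2 <- standardized_differences(as_obs_table(df))
  expect_true(bal2$zero_sd[bal2$covariate == "c0"])
  expect_equal(bal2$before[bal2$covariate == "c0"], 0)

  # matching exactly on the covariate zeroes the after column
  sets <- data.frame(set = rep(1:4, each = 2),
                     unit = c(1, 5, 2, 6, 3, 7, 4, 8),
                     role = rep(c("treated", "control"), 4))
  tab3 <- as_obs_table(data.frame(treatment = rep(c(1, 0), each = 4),
                                  outcome = rnorm(8),
                                  a = c(1, 2, 3, 4, 1, 2, 3, 4)))
  bal3 <- standardized_differences(tab3,
                                   htesens:::new_matched_sample(sets, tab3))
  expect_equal(bal3$after[bal3$covariate == "a"], 0)
})

test_that("rematching inexact pairs recovers cross-exact pairs and never loses exact ones", {
  # 6 pairs: 3 exact on the key; 3 inexact of which 2 can be cross-repaired
  df <- data.frame(
    id = paste0("u", 1:12),
    treatment = rep(c(1, 0), 6),
    outcome = rnorm(12),
    k = c("A", "A",  "B", "B",  "A", "A",      # exact pairs 1-3
          "A", "B",  "B", "A",  "A", "C"),     # inexact pairs 4-6
    noise = rnorm(12))
  tab <- as_obs_table(df, id = "id")
  sets <- data.frame(set = rep(1:6, each = 2), unit = 1:12,
                     role = rep(c("treated", "control"), 6))
  s <- htesens:::new_matched_sample(sets, tab)
  out <- rematch_inexact(s, tab, "k")
  expect_equal(out$I, 5L)                      # 3 exact + 2 recovered
  exact <- vapply(htesens:::ms_sets(out), function(st)
    as.character(tab$x$k[st$treated]) == as.character(tab$x$k[st$controls]),
    logical(1))
  expect_true(all(exact))
  expect_equal(attr(out, "n_dropped"), 2L)

  # already all-exact: unchanged
  df2 <- df; df2$k <- rep(c("A", "A"), 6)
  tab2 <- as_obs_table(df2, id = "id")
  s2 <- htesens:::new_matched_sample(sets, tab2)
  out2 <- rematch_inexact(s2, tab2, "k")
  expect_equal(out2$I, 6L)

  # two inexact pairs with swapped profiles become exact after rematch
  df3 <- data.frame(id = paste0("v", 1:4), treatment = rep(c(1, 0), 2),
                    outcome = rnorm(4), k = c("A", "B", "B", "A"),
                    noise = rnorm(4))
  tab3 <- as_obs_table(df3, id = "id")
  s3 <- htesens:::new_matched_sample(
    data.frame(set = c(1, 1, 2, 2), unit = 1:4,
               role = rep(c("treated", "control"), 2)), tab3)
  out3 <- rematch_inexact(s3, tab3, "k")
  expect_equal(out3$I, 2L)
  exact3 <- vapply(htesens:::ms_sets(out3), function(st)
    as.character(tab3$x$k[st$treated]) == as.character(tab3$x$k[st$controls]),
    logical(1))
  expect_true(all(exact3))
})
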