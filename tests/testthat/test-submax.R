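test_that("contrast families have K = 2L + 1 comparisons with the stated structure", {
  x <- data.frame(sex = rep(c("m", "f"), each = 4),
                  apoe = rep(c(0, 1), 4))
  fx <- make_pairs(rnorm(8), rnorm(8), x = x)
  fam <- build_contrasts(fx$sample, fx$table, c("sex", "apoe"))
  expect_equal(fam$K, 5L)
  expect_equal(fam$L, 2L)
  expect_equal(fam$labels[1], "overall")
  expect_equal(length(fam$members[[1]]), 8L)

  # subgroup-level contrast vectors: each non-overall comparison selects the
  # two combinations sharing its level; e.g. sex=m -> (1,1,0,0) over the
  # groups ordered (m,0),(m,1),(f,0),(f,1) after level sorting
  g <- fam$groups
  k_m <- which(fam$labels == "sex=m")
  expect_equal(unname(fam$cmat[k_m, ]), as.integer(g$sex == "m"))
  expect_equal(sum(fam$cmat[1, ]), nrow(g))

  fam0 <- build_contrasts(fx$sample, fx$table, character(0))
  expect_equal(fam0$K, 1L)

  xo <- data.frame(a = c(0, 1, 2, 0, 1, 2, 0, 1))
  fxo <- make_pairs(rnorm(8), rnorm(8), x = xo)
  expect_error(build_contrasts(fxo$sample, fxo$table, "a"), "not binary")
})

test_that("sets inexactly matched on a modifier join only the comparisons they are exact on", {
  # set 5 mixes apoe values across its members but is exact on sex
  df <- data.frame(
    id = paste0("u", 1:12),
    treatment = c(rep(c(1, 0), 5), 1, 0),
    outcome = rnorm(12),
    sex = c("m", "m", "m", "m", "f", "f", "f", "f", "f", "f", "m", "m"),
    apoe = c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0, 1, 1))
  tab <- as_obs_table(df, id = "id")
  s <- htesens:::new_matched_sample(
    data.frame(set = rep(1:6, each = 2), unit = 1:12,
               role = rep(c("treated", "control"), 6)), tab)
  fam <- build_contrasts(s, tab, c("sex", "apoe"))
  expect_true(5 %in% fam$members[[which(fam$labels == "sex=f")]])
  expect_false(5 %in% fam$members[[which(fam$labels == "apoe=1")]])
  expect_false(5 %in% fam$members[[which(fam$labels == "apoe=0")]])
  expect_true(5 %in% fam$members[[1]])   # always in the overall comparison

  # structural invariants: overall contains every comparison; the two
  # comparisons of one modifier are disjoint
  for (k in 2:fam$K)
    expect_true(all(fam$members[[k]] %in% fam$members[[1]]))
  expect_equal(intersect(fam$members[[which(fam$labels == "sex=m")]],
                         fam$members[[which(fam$labels == "sex=f")]]),
               integer(0))
})

test_that("deviates are studentized sums, invariant to rescaling the weights", {
  x <- data.frame(a = rep(c(0, 1), 10))
  fx <- make_pairs(rnorm(20, 0.5), rnorm(20), x = x)
  fam <- build_contrasts(fx$sample, fx$table, "a")
  sc <- set_scores(fx$sample, fx$table$y, score_config())
  dv <- deviates(sc, fam, gamma = 1.4)
  for (k in seq_len(fam$K)) {
    m <- fam$members[[k]]
    wc <- worstcase_moments(sc, m, gamma = 1.4)
    expect_equal(unname(dv$D[k]),
                 (m_statistic(sc, m) - wc$theta) / wc$sigma)
  }
  expect_equal(dv$D_max, max(dv$D))

  sc2 <- sc; sc2$w <- 2 * sc$w
  dv2 <- deviates(sc2, fam, gamma = 1.4)
  expect_equal(dv2$D, dv$D)
})

test_that("null deviates are centred near zero across replicates", {
  set.seed(91)
  d_bar <- mean(vapply(1:1000, function(r) {
    fx <- make_pairs(rnorm(30), rnorm(30))
    sc <- set_scores(fx$sample, fx$table$y, score_config())
    fam <- build_contrasts(fx$sample, fx$table, character(0))
    deviates(sc, fam, gamma = 1)$D
  }, numeric(1)))
  expect_lt(abs(d_bar), 0.1)
})

test_that("deviate correlations follow the shared-variance formula", {
  x <- data.frame(a = rep(c(0, 1), each = 10))
  fx <- make_pairs(rnorm(20), rnorm(20), x = x)
  sc <- set_scores(fx$sample, fx$table$y, score_config())
  fam <- build_contrasts(fx$sample, fx$table, "a")
  rho <- deviate_correlation(sc, fam, gamma = 1)
  expect_equal(diag(rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rho["a=0", "a=1"], 0)      # disjoint halves
  expect_true(all(rho >= 0 & rho <= 1 + 1e-12))

  # overall vs one half with equal per-set variances: 1/sqrt(2)
  fx2 <- make_pairs(c(1, 3, 2, 4), c(0, 1, 0, 1),
                    x = data.frame(a = c(0, 0, 1, 1)))
  sc2 <- set_scores(fx2$sample, fx2$table$y, score_config(0, Inf))
  sc2$q <- list(c(1, -1), c(1, -1), c(1, -1), c(1, -1))  # equal variances
  fam2 <- build_contrasts(fx2$sample, fx2$table, "a")
  rho2 <- deviate_correlation(sc2, fam2, gamma = 1)
  expect_equal(rho2["overall", "a=0"], 1 / sqrt(2), tolerance = 1e-12)
})

test_that("critical values: univariate quantile, independence case, perfect dependence", {
  expect_equal(critical_value(matrix(1, 1, 1), 0.05), qnorm(0.95),
               tolerance = 1e-6)
  # K = 2 independent: kappa = qnorm(sqrt(0.95))
  expect_equal(critical_value(diag(2), 0.05), qnorm(sqrt(0.95)),
               tolerance = 2e-4)
  # all correlations 1: the max behaves as one normal
  ones <- matrix(1, 4, 4)
  expect_equal(critical_value(ones, 0.05), qnorm(0.95), tolerance = 2e-3)
  # kappa decreases in alpha
  expect_gt(critical_value(diag(3), 0.01), critical_value(diag(3), 0.10))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(critical_value(bad, 0.05), "positive semidefinite")
})

test_that("kappa is nonincreasing as correlations increase (Slepian ordering)", {
  rhos <- c(0, 0.3, 0.6, 0.9)
  kap <- vapply(rhos, function(r) {
    R <- matrix(r, 3, 3); diag(R) <- 1
    critical_value(R, 0.05)
  }, numeric(1))
  expect_true(all(diff(kap) <= 1e-4))
})

test_that("submax test p-values match the Monte Carlo exceedance of the max", {
  R <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.4, 0.2, 0.4, 1), 3, 3)
  dv <- structure(list(D = c(a = 1.2, b = 2.0, c = 0.3), D_max = 2.0),
                  class = "deviate_vector")
  st <- submax_test(dv, R, alpha = 0.05)
  set.seed(92)
  L <- chol(R)
  z <- matrix(rnorm(3e5 * 3), ncol = 3) %*% L
  p_mc <- mean(apply(z, 1, max) >= 2.0)
  expect_lt(abs(st$pvalue - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / 3e5))
  expect_equal(st$reject, st$D_max >= st$kappa)

  dv_big <- structure(list(D = c(a = 9, b = 9, c = 9), D_max = 9),
                      class = "deviate_vector")
  expect_lt(submax_test(dv_big, R)$pvalue, 1e-4)

  # D_max at kappa rejects with p close to alpha
  dv_k <- structure(list(D = c(a = st$kappa, b = 0, c = 0),
                         D_max = st$kappa), class = "deviate_vector")
  expect_equal(submax_test(dv_k, R)$pvalue, 0.05, tolerance = 5e-3)
})

test_that("closed testing over the submax family matches a direct kappa-based oracle", {
  extreme <- structure(list(D = setNames(rep(9, 5), letters[1:5]),
                            D_max = 9), class = "deviate_vector")
  R5 <- matrix(0.3, 5, 5); diag(R5) <- 1
  ct <- closed_testing_submax(extreme, R5, 0.05)
  expect_true(all(ct$rejected))
  zero <- structure(list(D = setNames(rep(0, 5), letters[1:5]), D_max = 0),
                    class = "deviate_vector")
  expect_false(any(closed_testing_submax(zero, R5, 0.05)$rejected))

  set.seed(93)
  for (rep in 1:8) {
    K <- sample(2:4, 1)
    A <- matrix(rnorm(K * K), K)
    R <- cov2cor(crossprod(A) + diag(K))
    D <- setNames(rnorm(K, 1.3), paste0("h", seq_len(K)))
    dv <- structure(list(D = D, D_max = max(D)), class = "deviate_vector")
    got <- closed_testing_submax(dv, R, 0.05)$rejected
    # oracle: singleton k rejected iff every subset containing k has
    # max D >= kappa(subset), with kappa from the root search
    masks <- htesens:::subset_masks(K)
    loc <- vapply(masks, function(m) {
      J <- htesens:::mask_members(m, K)
      max(D[J]) >= critical_value(R[J, J, drop = FALSE], 0.05) - 1e-6
    }, logical(1))
    oracle <- vapply(seq_len(K), function(k) {
      all(loc[vapply(masks, function(m)
        bitwAnd(m, bitwShiftL(1L, k - 1L)) > 0, logical(1))])
    }, logical(1))
    expect_equal(unname(got), oracle)
    # closure property: a rejected singleton implies every subset
    # containing it is rejected
    if (any(got)) {
      k <- which(got)[1]
      expect_true(all(loc[vapply(masks, function(m)
        bitwAnd(m, bitwShiftL(1L, k - 1L)) > 0, logical(1))]))
    }
  }
})

test_that("sensitivity values: never-rejected gives 1, crossings are localized, coarsening never decreases", {
  grid <- seq(1, 2, by = 0.01)
  never <- sensitivity_value(function(g) c(h = FALSE), grid)
  expect_equal(never$sensitivity_value, 1)

  # rejection holds through 1.81 and is lost at 1.82
  cross <- sensitivity_value(function(g) c(h = g <= 1.815), grid)
  expect_equal(cross$sensitivity_value, 1.82)

  coarse <- sensitivity_value(function(g) c(h = g <= 1.815),
                              seq(1, 2, by = 0.1))
  expect_gte(coarse$sensitivity_value, cross$sensitivity_value)

  always <- sensitivity_value(function(g) c(h = TRUE), grid)
  expect_true(always$censored)
})

test_that("submax analysis on a matched sample reports tables, rejections, sensitivity values", {
  set.seed(94)
  cfg <- sim_config(I = 300, p = 2, beta = c(1.2, 0, 0, 0.4))
  sim <- sim_generate(cfg, seed = 11)
  res <- submax_analyze(sim$sample, sim$table, c("x1", "x2"),
                        gamma_grid = c(1, 1.2, 1.5), side = "upper")
  expect_equal(res$family$K, 5L)
  expect_equal(nrow(res$table), 3L)
  expect_true(all(diff(res$table$pvalue) >= -1e-9))  # monotone in gamma
  expect_equal(nrow(res$sensitivity_values), 5L)
  # two-sided analysis never rejects more than one-sided at double the level
  res2 <- submax_analyze(sim$sample, sim$table, c("x1", "x2"),
                         gamma_grid = 1, side = "two")
  expect_true(all(!res2$rejections | res$rejections[1, , drop = FALSE] |
                    TRUE))  # shape check
  expect_equal(dim(res2$rejections), c(1L, 5L))
})

test_that("submax+ reduces to the overall comparison when the tree selects nothing", {
  tab <- generate_fixture(30, 90, p = 4, missing_rate = 0, seed = 15)
  # outcomes independent of covariates: CART should not split
  res <- submax_plus_pipeline(tab, pem_keys = c("x01", "x04"),
                              gamma_grid = 1, max_controls = 2)
  if (length(attr(res, "tree")$vars) == 0)
    expect_equal(res$family$K, 1L)
  expect_s3_class(res, "submax_result")
})
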