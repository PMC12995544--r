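#' Simulation configuration
#'
#' Describes the paired randomized design used to benchmark the procedures:
#' `I` matched pairs; `p` Bernoulli(1/2) covariates shared within each pair
#' (so pairs are exactly matched by construction); control responses standard
#' normal; treated response equal to control plus the subgroup effect
#' `beta_g`; treatment position randomized within each pair. The first one
#' (G = 2) or two (G = 4) covariates are the true effect modifiers defining
#' the subgroups; the remaining covariates carry no effect.
#'
#' @param I Number of matched pairs.
#' @param p Number of covariates (`p >= log2(G)`).
#' @param beta Per-subgroup additive effects; length 2 or 4 (a power of 2).
#' @param reps Replicates for [sim_study()].
#' @param alpha Level used by all procedures.
#' @param gamma_grid Sensitivity parameters to evaluate.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(I = 200, p = 4, beta = c(1.2, 0, 0, 0.4), reps = 100,
                       alpha = 0.05, gamma_grid = 1, seed = 1) {
  G <- length(beta)
  stopifnot(G %in% c(2, 4), p >= log2(G), I >= 2)
  structure(list(I = I, p = p, beta = beta, G = G, reps = reps,
                 alpha = alpha, gamma_grid = gamma_grid, seed = seed),
            class = "sim_config")
}

#' Generate one replicate of the paired design
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this replicate.
#' @return List with `table` (an `obs_table` of `2I` units), `sample` (the
#'   `I` matched pairs) and `truth` (`modifiers`: names of the true effect
#'   modifiers; `group`: subgroup index per pair; `beta`; `false_null_groups`).
#' @export
sim_generate <- function(config, seed = config$seed) {
  I <- config$I; p <- config$p; beta <- config$beta; G <- config$G
  with_seed(seed, {
    x <- matrix(rbinom(I * p, 1, 0.5), I, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    group <- if (G == 2) x[, 1] + 1L
             else 2L * x[, 1] + x[, 2] + 1L
    rc <- matrix(rnorm(2 * I), I, 2)
    rt <- rc + beta[group]
    z1 <- rbinom(I, 1, 0.5)             # position of the treated unit
    r1 <- ifelse(z1 == 1, rt[, 1], rc[, 1])
    r2 <- ifelse(z1 == 1, rc[, 2], rt[, 2])
    df <- data.frame(
      id = paste0("p", rep(seq_len(I), each = 2), ".", rep(1:2, I)),
      treatment = as.vector(rbind(z1, 1L - z1)),
      outcome = as.vector(rbind(r1, r2)),
      x[rep(seq_len(I), each = 2), , drop = FALSE])
    table <- as_obs_table(df, id = "id")
    sets <- data.frame(set = rep(seq_len(I), each = 2),
                       unit = seq_len(2 * I),
                       role = ifelse(table$z == 1, "treated", "control"))
    sample <- new_matched_sample(sets, table)
    truth <- list(modifiers = paste0("x", seq_len(log2(G))),
                  group = group, beta = beta,
                  false_null_groups = which(beta != 0))
    list(table = table, sample = sample, truth = truth, config = config)
  })
}

#' Run one method variant on a simulated replicate
#'
#' Variants: `"hsr"` (CART subgroups + truncated-product closed testing),
#' `"submax"` (all covariates as modifiers), `"submax_plus"` (CART-selected
#' covariates), `"submax_best"` (the true modifiers), `"submax_worst"` (all
#' covariates except the true modifiers). Since the design randomizes
#' treatment within exactly matched pairs, the generated pairs are analyzed
#' directly. Tests are one-sided (upper) at level `alpha`, the direction of a
#' nonnegative treatment effect.
#'
#' @param variant One of the five method names.
#' @param sim A replicate from [sim_generate()].
#' @param gamma Sensitivity parameter.
#' @param alpha Level for closed testing.
#' @param config A [score_config()] for the test statistics.
#' @return List with `hypotheses` (label, false-null flag, rejected flag per
#'   tested singleton hypothesis) and `identified` (covariate names declared
#'   effect modifiers).
#' @export
run_variant <- function(variant, sim, gamma = 1, alpha = 0.05,
                        config = score_config()) {
  truth <- sim$truth
  p <- sim$config$p
  all_keys <- paste0("x", seq_len(p))
  switch(variant,
    submax = run_submax_variant(sim, all_keys, gamma, alpha, config),
    submax_best = run_submax_variant(sim, truth$modifiers, gamma, alpha,
                                     config),
    submax_worst = run_submax_variant(sim, setdiff(all_keys,
                                                   truth$modifiers),
                                      gamma, alpha, config),
    submax_plus = run_submax_variant(sim, cart_selected(sim), gamma, alpha,
                                     config),
    hsr = run_hsr_variant(sim, all_keys, gamma, alpha, config),
    stop("unknown variant: ", variant))
}

cart_selected <- function(sim, tree_control = list()) {
  pd <- pair_differences(sim$sample, sim$table,
                         paste0("x", seq_len(sim$config$p)))
  tree <- do.call(fit_tree, c(list(records = pd), tree_control))
  tree$vars
}

# A subpopulation is a false null iff it contains any pair from a subgroup
# with a nonzero effect.
subpop_false_null <- function(members, truth) {
  vapply(members, function(m)
    any(truth$group[m] %in% truth$false_null_groups), logical(1))
}

run_submax_variant <- function(sim, keys, gamma, alpha, config) {
  family <- build_contrasts(sim$sample, sim$table, keys)
  scores <- set_scores(sim$sample, sim$table$y, config)
  dv <- deviates(scores, family, gamma, "upper")
  rho <- deviate_correlation(scores, family, gamma, "upper")
  ct <- closed_testing_submax(dv, rho, alpha)
  hyp <- data.frame(label = family$labels,
                    false_null = subpop_false_null(family$members,
                                                   sim$truth),
                    rejected = unname(ct$rejected))
  # a covariate is identified if a rejected subpopulation is defined by it
  def_key <- c(NA, rep(keys, each = 2))[seq_len(family$K)]
  identified <- unique(def_key[!is.na(def_key) & ct$rejected])
  list(hypotheses = hyp, identified = identified,
       any_rejection = ct$any_rejection)
}

run_hsr_variant <- function(sim, keys, gamma, alpha, config,
                            alpha_tilde = 0.05) {
  pd <- pair_differences(sim$sample, sim$table, keys)
  tree <- fit_tree(pd)
  scores <- set_scores(sim$sample, sim$table$y, config)
  if (length(tree$vars) == 0) {
    # no split: a single overall hypothesis
    t_obs <- m_statistic(scores)
    pv <- pvalue_upper(t_obs, worstcase_moments(scores, gamma = gamma))
    hyp <- data.frame(label = "overall",
                      false_null = any(sim$truth$beta != 0),
                      rejected = pv <= alpha)
    return(list(hypotheses = hyp, identified = character(0),
                any_rejection = pv <= alpha))
  }
  partition <- partition_from_tree(sim$sample, sim$table, tree)
  pvals <- subgroup_pvalues(scores, partition, gamma, side = "upper")
  ct <- closed_testing(tpm_intersection(pvals, alpha_tilde), partition$G,
                       alpha)
  members <- lapply(seq_len(partition$G),
                    function(g) which(partition$group == g))
  leaf_rej <- seq_len(partition$G) %in% ct$rejected_singletons
  global_rej <- ct$table$reject_closed[ct$table$size == partition$G]
  hyp <- data.frame(
    label = c(partition$labels, "overall"),
    false_null = c(subpop_false_null(members, sim$truth),
                   any(sim$truth$beta != 0)),
    rejected = c(leaf_rej, global_rej))
  identified <- hsr_identified(tree, partition, ct)
  list(hypotheses = hyp, identified = identified,
       any_rejection = any(ct$table$reject_closed))
}

# HSR effect-modifier rule: a covariate is identified if the tree splits on
# it and the hypothesis of one of the split's child nodes (the intersection of
# the leaves under the child) is rejected by closed testing.
hsr_identified <- function(tree, partition, ct) {
  prim <- primary_splits(tree$fit)
  closed <- ct$table$reject_closed
  names(closed) <- ct$table$subset
  leaves <- tree$leaves
  is_desc <- function(leaf, node) {
    while (leaf >= node) {
      if (leaf == node) return(TRUE)
      leaf <- leaf %/% 2L
    }
    FALSE
  }
  ident <- character(0)
  for (r in seq_len(nrow(prim))) {
    for (child in c(2L * prim$node[r], 2L * prim$node[r] + 1L)) {
      under <- which(vapply(leaves, is_desc, logical(1), node = child))
      if (length(under) == 0) next
      if (closed[[format_subset(under)]]) {
        ident <- c(ident, prim$var[r])
        break
      }
    }
  }
  unique(ident)
}

#' Evaluation metrics: F1 score and true positive rate
#'
#' `F1 = 2TP / (2TP + FP + FN)`, `TPR = TP / (TP + FN)`; undefined
#' denominators are reported as 0 with a flag.
#'
#' @param rejected Logical vector: which tested hypotheses were rejected.
#' @param false_null Logical vector: which tested hypotheses are false nulls.
#' @return List with `TP`, `FP`, `FN`, `F1`, `TPR`, `undefined`.
#' @export
power_metrics <- function(rejected, false_null) {
  tp <- sum(rejected & false_null)
  fp <- sum(rejected & !false_null)
  fn <- sum(!rejected & false_null)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  tpr <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(TP = tp, FP = fp, FN = fn, F1 = f1, TPR = tpr,
       undefined = (tp + fn == 0))
}

#' @rdname power_metrics
#' @param identified Character vector of covariates declared effect modifiers.
#' @param true_modifiers Character vector of the true effect modifiers.
#' @param all_covariates All candidate covariate names.
#' @export
modifier_metrics <- function(identified, true_modifiers, all_covariates) {
  stopifnot(all(identified %in% all_covariates))
  rejected <- all_covariates %in% identified
  false_null <- all_covariates %in% true_modifiers
  power_metrics(rejected, false_null)
}

#' Replicated simulation study
#'
#' Repeats the paired design `reps` times and, for every variant and every
#' `gamma` in the grid, averages the F1 score and TPR for statistical power
#' (hypothesis rejection) and for effect-modifier identification.
#'
#' @param config A [sim_config()].
#' @param variants Method variants to run.
#' @param score_cfg A [score_config()].
#' @return Tidy data frame: `variant`, `gamma`, `metric`, `mean`, `mc_se`,
#'   `reps`.
#' @export
sim_study <- function(config,
                      variants = c("hsr", "submax", "submax_plus",
                                   "submax_best", "submax_worst"),
                      score_cfg = score_config()) {
  acc <- list()
  for (r in seq_len(config$reps)) {
    sim <- sim_generate(config, seed = config$seed + r)
    for (v in variants) {
      for (gamma in config$gamma_grid) {
        res <- run_variant(v, sim, gamma, config$alpha, score_cfg)
        pm <- power_metrics(res$hypotheses$rejected,
                            res$hypotheses$false_null)
        mm <- modifier_metrics(res$identified, sim$truth$modifiers,
                               paste0("x", seq_len(config$p)))
        acc[[length(acc) + 1]] <- data.frame(
          variant = v, gamma = gamma, rep = r,
          power_f1 = pm$F1, power_tpr = pm$TPR,
          modifier_f1 = mm$F1, modifier_tpr = mm$TPR,
          any_rejection = res$any_rejection)
      }
    }
  }
  long <- do.call(rbind, acc)
  metrics <- c("power_f1", "power_tpr", "modifier_f1", "modifier_tpr",
               "any_rejection")
  out <- list()
  for (m in metrics) {
    ag <- aggregate(long[[m]],
                    by = list(variant = long$variant, gamma = long$gamma),
                    FUN = function(v) c(mean = mean(v),
                                        se = sd(v) / sqrt(length(v))))
    out[[m]] <- data.frame(variant = ag$variant, gamma = ag$gamma,
                           metric = m, mean = ag$x[, "mean"],
                           mc_se = ag$x[, "se"], reps = config$reps)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
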