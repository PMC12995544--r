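---
title: "Sensitivity analysis for heterogeneous treatment effects in matched observational studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity analysis for heterogeneous treatment effects in matched observational studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htesens)
```

## The problem

In an observational comparison of a treated and a control group, matching on
observed covariates removes overt bias, but an unobserved covariate can still
distort both the estimated overall treatment effect and, more subtly, the
apparent *heterogeneity* of the effect across subgroups: the bias need not be
the same in every subgroup. `htesens` implements a family of procedures that
(i) discover or accept candidate subgroups, (ii) test sharp null hypotheses of
no treatment effect within subgroups, and (iii) quantify how strong an
unobserved confounder would have to be to overturn each conclusion.

The sensitivity model is Rosenbaum's: two units with identical observed
covariates may differ in their odds of treatment by at most a factor
$\Gamma \ge 1$. At $\Gamma = 1$ treatment is effectively randomized within
matched sets; larger $\Gamma$ admits progressively stronger unmeasured
confounding. For each $\Gamma$ the package computes the *worst-case* null
distribution of the test statistic over all allocations of the unobserved
covariate consistent with $\Gamma$, and reports the corresponding worst-case
p-value. The *sensitivity value* of a conclusion is the smallest $\Gamma$ at
which the test stops rejecting at level $\alpha$.

## Matched samples

Matched sets are built by minimum-total-distance assignment
(`pair_match()`, `variable_ratio_match()`), with the devices customary in this
design:

* **Rank-based Mahalanobis distance** (`rank_mahalanobis()`): covariates are
  replaced by average ranks before the Mahalanobis form, making the distance
  robust to outliers and invariant under monotone transformations of single
  covariates. Categorical covariates are expanded to one indicator per level.
  We report squared distances; only the ordering of assignments matters to the
  optimizer. A singular rank covariance is regularized by adding
  $10^{-6}\,\mathrm{tr}(S)/p$ to the diagonal.
* **Soft propensity caliper** (`apply_caliper()`): entries whose
  propensity-score gap exceeds the caliper width are penalized proportionally
  to the excess, `penalty * (gap - width) / width`. A soft caliper preserves
  feasibility where a hard exclusion may not. The default width is 0.2 SD of
  the estimated scores, a common convention. The propensity model is a
  main-effects logistic regression; under (possibly quiet) separation it falls
  back to a ridge-penalized fit.
* **Almost-exact matching** (`apply_almost_exact()`): a penalty of
  1000 times the largest finite distance per disagreeing key dominates any
  total distance, so exact matches on the designated covariates are taken
  whenever feasible.
* **Near-fine balance**: when more controls are available than will be
  matched, the assignment problem is augmented with surplus-absorbing extra
  rows, one per excess control in each category of the balance key; absorbing
  a control from a surplus category is free, absorbing from elsewhere is
  penalized. This pushes the matched controls' marginal category counts
  toward the treated counts without hard constraints;
  `evaluate_fine_balance()` reports the residual deviation.

The assignment itself is solved as a linear sum assignment problem (the
Hungarian method via `clue::solve_LSAP`), which for these bipartite problems
attains the same optimum as the network-flow formulations used elsewhere in
the matching literature. Variable-ratio matching expands each treated unit
into `max_controls` slots (the first `min_controls` of which must take real
controls) and pads with zero-cost dummy columns when controls are scarce, so
the ratios adapt to supply.

Missing covariate entries are handled before matching by the two-step rule
(`impute_two_step()`): add a missingness indicator per affected covariate,
then impute the mean of the observed entries (the modal level for categorical
covariates, where a mean is undefined — the source procedure describes means
for numerically coded covariates and is silent on unordered categories).
Matching then balances observed values and missingness patterns jointly.

## Weighted M-statistics and the worst-case null

Within subgroup $s_g$ the test statistic is the weighted M-statistic
$$T_g = \sum_{i \in s_g} w_i \sum_j Z_{ij} q_{ij}, \qquad
  q_{ij} = \sum_l \psi\{(R_{ij} - R_{il})/s\},$$
with $\psi$ the odd trimmed ramp
$\psi(y) = \mathrm{sign}(y)\min\{\max(|y| - \texttt{inner}, 0),
\texttt{outer} - \texttt{inner}\}$ and $s$ the $\lambda$-quantile (linear
interpolation) of the pooled absolute treated–control differences, computed
once per matched sample. Defaults: `inner = 0`, `outer = 3`,
$\lambda = 1/2$ — trimming appropriate for long-tailed outcomes. With
`inner = 0`, `outer = Inf` and constant weights the statistic reduces to the
permutational t-test. We use the un-normalized ramp: any positive rescaling
of $\psi$ rescales $T$, $\theta_\Gamma$ and $\sigma_\Gamma$ together and
leaves every p-value unchanged. Constant weights are the default; a
sampling-rank u-statistic weighting indexed by $(m, \underline m, \bar m)$ is
available behind the same seam (`score_config(weights = "ustat")`) and is
deliberately isolated so it can be swapped without touching other modules.

For a set of size $n_i$, sorting its scores in decreasing order, the
worst-case allocation at $\Gamma$ puts probability
$\Gamma/(a\Gamma + n_i - a)$ on each of the $a$ largest scores and
$1/(a\Gamma + n_i - a)$ on the rest; $a \in \{1, \dots, n_i - 1\}$ is chosen
to maximize the mean, breaking ties toward the larger second moment (the
conservative choice). Summing per-set means and variances gives
$(\theta_\Gamma, \sigma_\Gamma)$ and the normal-approximation worst-case
p-value $1 - \Phi\{(T_g - \theta_\Gamma)/\sigma_\Gamma\}$. Lower-tail tests
negate the scores; two-sided p-values double the smaller one-sided p-value
(capped at 1). An exhaustive enumeration oracle
(`exact_worstcase_tail()`, feasible to 14 members) backs the implementation
in the test suite.

## HSR: tree-discovered subgroups with truncated-product closed testing

The pipeline (`hsr_pipeline()` / `hsr_analyze()`):

1. optimal pair matching, almost exact on the declared potential effect
   modifiers;
2. for pairs exact on all modifiers, within-pair differences $Y_i$; a
   least-squares regression tree of $|Y_i|$ on the modifiers
   (`fit_tree()`, via `rpart` with cost-complexity pruning and **no**
   cross-validation, so fits are deterministic). Because the tree sees only
   $|Y_i|$, whose distribution is unaffected by within-pair treatment
   labels under the sharp null, subsequent inference on the signed
   differences remains valid without sample splitting;
3. pairs inexact on the full modifier set are rematched exactly on the
   tree-selected covariates (`rematch_inexact()`), enlarging the testable
   sample without degrading balance;
4. per-leaf worst-case p-values; intersections tested by the truncated
   product $W = \prod_g P_g^{\chi(P_g \le \tilde\alpha)}$ with
   $\tilde\alpha = 0.05$, whose null distribution has the closed form
   (conditioning on the binomial count of truncated p-values)
   $$P(W \le w) = \sum_{k \ge 1} \binom{L}{k} \tilde\alpha^k
     (1-\tilde\alpha)^{L-k} F_k(w/\tilde\alpha^k), \quad
     F_k(x) = x\sum_{s<k} (-\ln x)^s/s!,$$
   cross-checked against Monte Carlo in the tests. The truncated-product
   null treats the subgroup p-values as independent, which holds under the
   sharp null because the subgroups partition disjoint matched sets;
5. closed testing over the full intersection lattice (guarded to
   $G \le 20$): a subgroup hypothesis is rejected only if every
   intersection containing it is rejected, controlling the familywise error
   rate in the strong sense.

Tree controls default to the conventional recursive-partitioning values
(`minsplit = 20`, `minbucket = 7`, `cp = 0.01`, `maxdepth = 30`); the source
procedure names the tool but not its settings, so these defaults are our
choice and are exposed. Split-gain ties resolve to the first (lowest-index)
covariate, for determinism.

## Submax and submax+: maximum deviates over contrast families

Given $L$ binary modifiers, `build_contrasts()` forms $K = 2L + 1$
comparisons: the whole population plus the two subpopulations per modifier. A
matched set joins a modifier's comparisons only if all its members agree on
that modifier; sets inexact on one modifier still contribute to the others
and to the overall comparison — membership is resolved at the set level, not
through a complete cross-classification. For each comparison,
$D_{\Gamma k} = (\sum T - \theta_{\Gamma k})/\sigma_{\Gamma k}$; the vector
of deviates is asymptotically normal with correlation
$\rho_{kk'} = \sum_{i \in \mathcal S_k \cap \mathcal S_{k'}} w_i^2 v_i /
(\sigma_{\Gamma k}\sigma_{\Gamma k'})$, $v_i$ the per-set worst-case
variance. The global test rejects when
$D_{\Gamma\max} = \max_k D_{\Gamma k}$ exceeds $\kappa_{\Gamma,\alpha}$, the
$1-\alpha$ quantile of the maximum of the correlated normal vector. Closed
testing re-evaluates $\kappa$ on each subfamily's correlation submatrix and
rejects $H_{\mathcal J}$ when $\max_{k \in \mathcal J} D_{\Gamma k}$ reaches
it; two-sided analyses run both tails at $\alpha/2$.

*Numerical choices.* Rectangle probabilities of the multivariate normal come
from `mvtnorm`: the deterministic TVPACK algorithm up to dimension 3, and
quasi-Monte Carlo integration under a fixed internal seed (absolute tolerance
$10^{-5}$) beyond, so reported critical values are reproducible.
`critical_value()` brackets and root-solves to a $10^{-4}$ tolerance on
$\kappa$. Rejection decisions inside closed testing avoid the root search:
$D_{\max} \ge \kappa$ iff $P(\text{all} \le D_{\max}) \ge 1 - \alpha$, one
rectangle probability per subfamily, with Slepian-type bounds
($\Phi(u)$ from above, $\Phi(u)^{|\mathcal J|}$ from below, valid for the
nonnegative correlations that arise here) short-circuiting most evaluations.
Full closure is enumerated for $K \le 15$; beyond that, singletons are
rejected by the conservative sufficient rule $D_k \ge \kappa(\text{full
family})$, valid because a subfamily's critical value never exceeds the full
family's.

`submax_plus_pipeline()` ("submax+") seeds the contrast family with the
covariates the regression tree splits on, dichotomized at the tree's split
points, and rebuilds the matched sample by variable-ratio matching with
almost-exact matching on those covariates. If the tree selects nothing the
analysis degrades gracefully to the overall comparison ($K = 1$).

Whether the scale $s$ and weights are recomputed within each comparison or
once globally is not fixed by the sources; we compute them once per matched
sample, so all comparisons share one scale.

## Amplification

A one-dimensional $\Gamma$ is hard to interpret; `gamma_of()`, `delta_of()`
and `amplification_curve()` map it to pairs $(\Lambda, \Delta)$ — an
unobserved covariate multiplying the treatment odds by $\Lambda$ and the
outcome odds by $\Delta$ — through
$\Gamma = (\Lambda\Delta + 1)/(\Lambda + \Delta)$. For example,
$\Gamma = 1.25$ corresponds to a confounder that doubles both odds. The map
round-trips to machine precision and CLI output rounds to the conventional
two decimals for $\Gamma$, one for $\Lambda, \Delta$.

## The simulation framework

`sim_generate()` draws the benchmark design: $I$ matched pairs; $p$
Bernoulli(1/2) covariates shared within a pair (so pairs are exactly matched
by construction and the matching step can be bypassed); control responses
$N(0,1)$; treated response shifted by the subgroup effect $\beta_g$, with
subgroups defined by the first one ($G = 2$) or two ($G = 4$) covariates;
treatment position randomized within the pair. Non-modifier covariates are
pure noise — they influence neither outcome nor assignment. Effect vectors
such as $\beta = (1.2, 0, 0, 0.4)$ give one strong, one weak and two null
subgroups. `run_variant()` dispatches the five benchmarked procedures (HSR,
submax on all covariates, submax+ on tree-selected covariates, and the
submax oracles using exactly the true or exactly the non-true modifiers),
and `sim_study()` averages F1 and true-positive rates for hypothesis
rejection and for effect-modifier identification over replicates, with
per-replicate seeds `seed + r`.

Two scoring conventions deserve mention. First, the tested hypotheses scored
for power are the singleton hypotheses each procedure evaluates by closed
testing: the $K$ comparisons for the submax family, and the tree leaves plus
the global intersection for HSR (the leaves are what HSR's closed testing
can reject). A hypothesis is a false null when its subpopulation contains any
pair with $\beta_g \ne 0$. A consequence worth knowing: under
$\beta = (1.2, 0, 0, 0.4)$ *every* subpopulation tested by the "worst"
oracle contains affected pairs, so at $\Gamma = 1$ that oracle cannot commit
a false positive and its power-F1 can match or exceed the "best" oracle's;
the benchmarks separate as $\Gamma$ grows and diluted effects lose
significance first. The modifier-identification metrics separate the oracles
at every $\Gamma$ (the worst oracle's TPR is identically zero by
construction). Second, simulation tests are one-sided (upper) at
$\alpha = 0.05$, the direction of a nonnegative effect.

### What the generators do and do not emulate

`generate_fixture()` produces an observational cohort of the shape typical
in this literature — roughly 1:3 treated:control, a few dozen covariates
mixing binary, categorical and continuous types, sparse missingness,
treatment mildly dependent on covariates — so every matching and pipeline
function is exercisable without restricted data. Neither generator emulates
longitudinal measurement, informatively missing outcomes, clustered
recruitment, or covariate distributions of any particular cohort; passing
tests demonstrate the procedures' operating characteristics under the stated
designs, not performance on any specific real dataset.

### Problem sizes used in the checks

The shipped test suite and the acceptance script run the familywise-error
simulation at 1000 replicates of $I = 200$ pairs with $p = 4$ covariates,
and the large-effect recovery at 200 replicates of $I = 600$ — sizes chosen
so the whole suite completes in a few minutes on one core while keeping
Monte Carlo error well inside the asserted margins (3 binomial standard
errors where rates are compared).

## Known limitations

* Worst-case p-values are normal approximations; exact tail enumeration is
  available only as a small-sample oracle. Very small subgroups (a handful of
  sets) should be interpreted cautiously.
* Tree routing supports numeric and categorical primary splits but not
  surrogate splits; matched sets must have complete modifier values.
* The near-fine-balance device is a soft penalty: it reduces, but does not
  guarantee to minimize, marginal imbalance.
* Closed testing enumerates $2^K - 1$ subfamilies; beyond $K = 15$ the
  conservative reduced rule is used.
* The truncated-product intersection tests assume independent subgroup
  p-values, exact under the sharp null across disjoint matched sets but not
  under alternatives.
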