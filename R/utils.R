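#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm quantile rnorm runif rbinom glm binomial
#'   predict cov var sd uniroot complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head combn
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# P(X_k <= upper_k for all k) for a zero-mean unit-variance normal vector with
# correlation matrix `corr`. Deterministic: TVPACK in low dimension, otherwise
# quasi-Monte Carlo integration run under a fixed local seed so repeated calls
# agree to the stated tolerance.
mvn_rect <- function(upper, corr, abseps = 1e-5) {
  k <- length(upper)
  if (k == 1L) return(pnorm(upper))
  corr <- (corr + t(corr)) / 2
  if (k <= 3L) {
    val <- mvtnorm::pmvnorm(lower = rep(-Inf, k), upper = upper, corr = corr,
                            algorithm = mvtnorm::TVPACK(abseps = abseps))
  } else {
    val <- with_seed(190451L, mvtnorm::pmvnorm(
      lower = rep(-Inf, k), upper = upper, corr = corr,
      algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = 50000L)))
  }
  min(max(as.numeric(val), 0), 1)
}

# Average ranks with ties, as used throughout the matching distances.
avg_rank <- function(x) rank(x, ties.method = "average")

format_subset <- function(idx) paste0("H{", paste(idx, collapse = ","), "}")
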