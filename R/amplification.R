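#' Amplification of the sensitivity parameter
#'
#' Rosenbaum's sensitivity parameter \eqn{\Gamma} bounds the ratio of treatment
#' odds between two units with identical observed covariates. A single
#' \eqn{\Gamma} can be reinterpreted ("amplified") as a curve of pairs
#' \eqn{(\Lambda, \Delta)} with \eqn{\Lambda > 1} the factor by which an
#' unobserved covariate multiplies the odds of treatment and \eqn{\Delta > 1}
#' the factor by which it multiplies the odds of a positive response, linked by
#' \deqn{\Gamma = (\Lambda\Delta + 1) / (\Lambda + \Delta).}
#' For example \eqn{\Gamma = 1.25} corresponds to an unobserved covariate that
#' doubles the odds of treatment and doubles the odds of raising the outcome.
#'
#' @param lambda Treatment-odds multiplier \eqn{\Lambda > 1}.
#' @param delta Outcome-odds multiplier \eqn{\Delta > 1}.
#' @return `gamma_of()` returns the implied \eqn{\Gamma \ge 1}.
#' @examples
#' gamma_of(2, 2)            # 1.25
#' delta_of(1.25, 2)         # 2
#' amplification_curve(1.25, c(2, 3))
#' @export
gamma_of <- function(lambda, delta) {
  if (any(lambda <= 1) || any(delta <= 1))
    stop("amplification requires lambda > 1 and delta > 1")
  (lambda * delta + 1) / (lambda + delta)
}

#' @rdname gamma_of
#' @param gamma Sensitivity parameter \eqn{\Gamma \ge 1}.
#' @return `delta_of()` returns the \eqn{\Delta} solving the amplification
#'   identity for the given \eqn{(\Gamma, \Lambda)}; requires
#'   \eqn{\Lambda > \Gamma}.
#' @export
delta_of <- function(gamma, lambda) {
  if (any(gamma < 1)) stop("gamma must be >= 1")
  if (any(lambda <= gamma))
    stop("no finite amplification: lambda must exceed gamma")
  (gamma * lambda - 1) / (lambda - gamma)
}

#' @rdname gamma_of
#' @param lambda_grid Increasing grid of \eqn{\Lambda} values, all `> gamma`.
#' @return `amplification_curve()` returns a data frame with columns `lambda`,
#'   `delta`, `gamma`; each row satisfies the identity exactly.
#' @export
amplification_curve <- function(gamma, lambda_grid) {
  if (any(lambda_grid <= gamma))
    stop("all grid values must exceed gamma")
  data.frame(lambda = lambda_grid,
             delta = delta_of(gamma, lambda_grid),
             gamma = gamma)
}
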