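#' Detectable odds ratio for allele-score MR with a binary outcome
#'
#' Normal approximation to the Wald test of the score coefficient in a
#' case-control design: the smallest detectable log OR at significance
#' \eqn{\alpha} and the target power is
#' \deqn{b = (z_{1-\alpha/2} + z_{power}) / \sqrt{N R^2 \phi (1 - \phi)}}
#' where \eqn{N} is the total sample size, \eqn{R^2} the fraction of
#' exposure variance explained by the instrument, and
#' \eqn{\phi = n_{cases}/N} the case fraction. Both the protective
#' (\eqn{e^{-b}}) and risk (\eqn{e^{+b}}) bounds are returned.
#'
#' @param n_cases,n_controls sample sizes.
#' @param r2 instrument variance explained, in (0, 1).
#' @param alpha two-sided significance level (default 0.05).
#' @param target_power desired power (default 0.8).
#' @return named numeric \code{c(protective = , risk = )}.
#' @examples
#' detectableOR(5133, 5984, r2 = 0.03)["protective"]  # ~0.74
#' detectableOR(5133, 5984, r2 = 0.05)["protective"]  # ~0.79
#' @export
detectableOR <- function(n_cases, n_controls, r2, alpha = 0.05,
                         target_power = 0.8) {
    stopifnot(n_cases > 0, n_controls > 0, r2 > 0, r2 < 1,
              alpha > 0, alpha < 1, target_power > 0, target_power < 1)
    n <- n_cases + n_controls
    phi <- n_cases / n
    b <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(target_power)) /
        sqrt(n * r2 * phi * (1 - phi))
    c(protective = exp(-b), risk = exp(b))
}

#' Power to detect a given odds ratio
#'
#' Inverse of [detectableOR()]:
#' \deqn{power = \Phi(|\ln OR| \sqrt{N R^2 \phi (1-\phi)} - z_{1-\alpha/2})}
#'
#' @inheritParams detectableOR
#' @param or_alt alternative odds ratio (> 0, != 1 for non-null power).
#' @return the power fraction.
#' @export
powerAtOR <- function(n_cases, n_controls, r2, or_alt, alpha = 0.05) {
    stopifnot(n_cases > 0, n_controls > 0, r2 > 0, r2 < 1,
              alpha > 0, alpha < 1, or_alt > 0)
    n <- n_cases + n_controls
    phi <- n_cases / n
    stats::pnorm(abs(log(or_alt)) * sqrt(n * r2 * phi * (1 - phi)) -
                 stats::qnorm(1 - alpha / 2))
}
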