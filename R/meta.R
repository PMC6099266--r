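#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools k independent log-OR estimates with the method-of-moments
#' between-stratum variance: fixed-effect weights \eqn{w_i = 1/se_i^2},
#' Cochran's \eqn{Q = \sum w_i (\theta_i - \bar\theta_{FE})^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))},
#' random-effects weights \eqn{w^*_i = 1/(se_i^2 + \tau^2)}, pooled estimate
#' \eqn{\sum w^* \theta / \sum w^*} with SE \eqn{(\sum w^*)^{-1/2}} and a
#' z-based 95\% CI. Heterogeneity is summarized by
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q)} with a Higgins-Thompson confidence
#' interval ([i2ConfidenceInterval()]) and a \eqn{\chi^2_{k-1}} p-value.
#'
#' @param log_or numeric vector of log odds ratios, or a list of
#'   \linkS4class{CausalEstimate} objects (corrected SEs used).
#' @param se positive standard errors, same length (ignored for a list
#'   input).
#' @return A \linkS4class{MetaResult}. With \code{k = 1} the single estimate
#'   is returned (tau2 = Q = I2 = 0) with a warning; \code{k = 0} is an
#'   error.
#' @examples
#' # pooling two printed oropharyngeal estimates via their CIs:
#' se1 <- seFromCI(0.98, c(0.67, 1.44))
#' se2 <- seFromCI(0.92, c(0.64, 1.34))
#' oddsRatio(dlRandomEffects(log(c(0.98, 0.92)), c(se1, se2)))  # 0.948
#' @export
dlRandomEffects <- function(log_or, se = NULL) {
    if (is.list(log_or)) {
        ests <- log_or
        se <- vapply(ests, seCorrected, numeric(1))
        log_or <- vapply(ests, logOR, numeric(1))
    }
    k <- length(log_or)
    if (k == 0L) stop("no estimates to pool")
    if (length(se) != k || any(!is.finite(se)) || any(se <= 0))
        stop("se must be positive and parallel to log_or")
    z <- stats::qnorm(0.975)
    if (k == 1L) {
        warning("single estimate: returning it unpooled")
        return(new("MetaResult", pooled_log_or = log_or, pooled_se = se,
                   ci95 = exp(log_or + c(-1, 1) * z * se), tau2 = 0,
                   q = 0, df = 0L, i2 = 0, i2_ci = c(NA_real_, NA_real_),
                   p_het = NA_real_))
    }
    w <- 1 / se^2
    theta_fe <- sum(w * log_or) / sum(w)
    q <- sum(w * (log_or - theta_fe)^2)
    df <- k - 1L
    c_dl <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df) / c_dl)
    wr <- 1 / (se^2 + tau2)
    pooled <- sum(wr * log_or) / sum(wr)
    pooled_se <- 1 / sqrt(sum(wr))
    i2 <- if (q > 0) max(0, (q - df) / q) else 0
    new("MetaResult", pooled_log_or = pooled, pooled_se = pooled_se,
        ci95 = exp(pooled + c(-1, 1) * z * pooled_se), tau2 = tau2,
        q = q, df = df, i2 = i2,
        i2_ci = i2ConfidenceInterval(q, k),
        p_het = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Higgins-Thompson confidence interval for I2
#'
#' Test-based interval on \eqn{\ln H} with \eqn{H = \sqrt{Q/(k-1)}}
#' (truncated below at 1): for \eqn{Q > k},
#' \eqn{se(\ln H) = \frac{1}{2}(\ln Q - \ln(k-1)) / (\sqrt{2Q} -
#' \sqrt{2k-3})}; otherwise \eqn{se(\ln H) = \sqrt{\frac{1}{2(k-2)} (1 -
#' \frac{1}{3(k-2)^2})}} (defined for k > 2; for k = 2 with small Q the SE is
#' unavailable and \code{c(NA, NA)} is returned). The H interval is
#' transformed to the \eqn{I^2 = (H^2-1)/H^2} scale and truncated to [0, 1].
#'
#' @param q Cochran's Q.
#' @param k number of pooled estimates (>= 2).
#' @return numeric (lower, upper) on the I2 scale.
#' @export
i2ConfidenceInterval <- function(q, k) {
    if (k < 2L) stop("I2 interval needs k >= 2")
    z <- stats::qnorm(0.975)
    h <- max(1, sqrt(q / (k - 1)))
    se_ln_h <- if (q > k) {
        0.5 * (log(q) - log(k - 1)) / (sqrt(2 * q) - sqrt(2 * k - 3))
    } else if (k > 2L) {
        sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
    } else NA_real_
    if (is.na(se_ln_h)) return(c(NA_real_, NA_real_))
    hb <- exp(log(h) + c(-1, 1) * z * se_ln_h)
    hb <- pmax(hb, 1)
    i2 <- (hb^2 - 1) / hb^2
    pmin(pmax(i2, 0), 1)
}

#' Back-derive a log-OR standard error from a printed CI
#'
#' For a symmetric-on-log 95\% CI, \code{se = (ln upper - ln lower) /
#' (2 * 1.96)}; lets printed (OR, lower, upper) triples feed
#' [dlRandomEffects()] for summary-level pooling.
#'
#' @param or_point the printed odds ratio.
#' @param ci numeric (lower, upper), both positive.
#' @param level confidence level of the printed interval (default 0.95).
#' @return the standard error on the log-OR scale; warns when the point lies
#'   outside the interval.
#' @export
seFromCI <- function(or_point, ci, level = 0.95) {
    if (length(ci) != 2L || ci[1] <= 0 || ci[1] >= ci[2])
        stop("ci must be (lower, upper) with 0 < lower < upper")
    if (or_point < ci[1] || or_point > ci[2])
        warning("point estimate outside its confidence interval")
    z <- stats::qnorm(1 - (1 - level) / 2)
    (log(ci[2]) - log(ci[1])) / (2 * z)
}
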