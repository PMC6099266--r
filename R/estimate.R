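#' Analysis specification for causal-OR estimation
#'
#' @param site_filter which cases enter the fit: \code{"combined"} (all
#'   cases), \code{"oral"} or \code{"oropharyngeal"} (that site's cases);
#'   controls are shared across site analyses.
#' @param stratum a stratum label, or \code{"all"} for the whole cohort.
#' @param covariates character vector of colData columns adjusted for;
#'   \code{NULL} (default) means age band, sex and every principal-component
#'   column present.
#' @param bootstrap_reps number of parametric bootstrap replicates B for the
#'   weight-imprecision correction (default 1000).
#' @param seed seed for the bootstrap draws.
#' @return a list-like \code{AnalysisSpec}.
#' @export
AnalysisSpec <- function(site_filter = c("combined", "oral",
                                         "oropharyngeal"),
                         stratum = "all", covariates = NULL,
                         bootstrap_reps = 1000L, seed = 1L) {
    structure(list(site_filter = match.arg(site_filter),
                   stratum = stratum, covariates = covariates,
                   bootstrap_reps = as.integer(bootstrap_reps),
                   seed = as.integer(seed)),
              class = "AnalysisSpec")
}

.default_covariates <- function(cohort) {
    cd <- colnames(colData(cohort))
    c(intersect(c("age_band", "sex"), cd),
      grep("^pc[0-9]+$", cd, value = TRUE))
}

## Subset by site/stratum, align scores, drop incomplete rows and build the
## logistic design matrix (intercept, score, covariate dummies).
.prep_design <- function(cohort, scores, spec) {
    cd <- colData(cohort)
    site <- as.character(cd$site)
    keep <- switch(spec$site_filter,
        combined = rep(TRUE, ncol(cohort)),
        oral = site %in% c("oral", "control"),
        oropharyngeal = site %in% c("oropharyngeal", "control"))
    if (!identical(spec$stratum, "all"))
        keep <- keep & as.character(cd$stratum) == spec$stratum
    covars <- if (is.null(spec$covariates)) .default_covariates(cohort)
              else spec$covariates
    missing_cov <- setdiff(covars, colnames(cd))
    if (length(missing_cov))
        stop("covariates absent from colData: ",
             paste(missing_cov, collapse = ", "))
    s <- scores[colnames(cohort)]
    df <- as.data.frame(cd[, covars, drop = FALSE])
    ok <- keep & !is.na(s) & stats::complete.cases(df)
    label <- paste(spec$site_filter,
                   if (identical(spec$stratum, "all")) "all strata"
                   else spec$stratum, sep = " | ")
    y <- as.integer(cd$case[ok])
    if (sum(y) == 0L || sum(1L - y) == 0L)
        stop("need at least one case and one control after filtering (",
             label, ")")
    df <- droplevels(as.data.frame(lapply(df[ok, , drop = FALSE],
        function(v) if (is.character(v)) factor(v) else v),
        stringsAsFactors = FALSE))
    X <- if (ncol(df)) stats::model.matrix(~ ., data = df)
         else matrix(1, nrow = sum(ok), dimnames = list(NULL, "(Intercept)"))
    X <- cbind(X[, 1, drop = FALSE], score = s[colnames(cohort)][ok],
               X[, -1, drop = FALSE])
    list(y = y, X = X, label = label,
         n_cases = sum(y), n_controls = sum(1L - y), keep = ok)
}

## IRLS logistic fit on an explicit design matrix; returns the score
## coefficient and its information-matrix SE. `start` warm-starts IRLS
## (used by the bootstrap, whose replicates perturb the fit only slightly).
.fit_logistic <- function(y, X, label, start = NULL) {
    fit <- suppressWarnings(stats::glm.fit(
        x = X, y = y, family = stats::binomial(), start = start,
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    if (!fit$converged)
        stop("logistic fit did not converge (", label, ")")
    if (any(is.na(fit$coefficients)))
        stop("rank-deficient design (", label, ")")
    if (any(abs(fit$coefficients) > 20))
        stop("perfect or quasi-perfect separation detected (", label, ")")
    w <- fit$weights
    info <- crossprod(X * sqrt(w))
    vc <- tryCatch(chol2inv(chol(info)),
                   error = function(e) stop("singular information matrix (",
                                            label, ")"))
    list(log_or = unname(fit$coefficients["score"]),
         se = sqrt(vc[2, 2]), coefficients = fit$coefficients)
}

#' Causal odds ratio per SD of exposure by allele-score logistic regression
#'
#' Fits case status on the relative-exposure score plus covariates by
#' maximum-likelihood logistic regression; the score coefficient is the
#' causal log OR per SD of the (log-scale) exposure, with its standard error
#' from the information matrix and a Wald CI and p-value. Use
#' [bootstrapWeightCorrection()] for the SE correction accounting for
#' instrument-weight imprecision.
#'
#' @param cohort an \linkS4class{MRCohort}.
#' @param scores named numeric score vector from [relativeExposure()];
#'   computed from the cohort's own weights when \code{NULL}.
#' @param spec an [AnalysisSpec()].
#' @return A \linkS4class{CausalEstimate} (with
#'   \code{se_corrected = se_naive}).
#' @export
fitCausalLogistic <- function(cohort, scores = NULL, spec = AnalysisSpec()) {
    if (is.null(scores)) scores <- relativeExposure(cohort)
    prep <- .prep_design(cohort, scores, spec)
    if (stats::var(prep$X[, "score"]) == 0)
        stop("score has zero variance (", prep$label, ")")
    fit <- .fit_logistic(prep$y, prep$X, prep$label)
    .CausalEstimate(label = prep$label, log_or = fit$log_or,
                    se_naive = fit$se, se_corrected = fit$se,
                    pvalue = 2 * stats::pnorm(-abs(fit$log_or / fit$se)),
                    n_cases = prep$n_cases, n_controls = prep$n_controls)
}

#' Bootstrap correction for instrument-weight imprecision
#'
#' The GWAS betas entering the score are estimates; ignoring their standard
#' errors understates the uncertainty of the causal OR. This parametric
#' bootstrap draws \eqn{\beta^*_{jb} \sim N(\beta_j, SE_j)} independently
#' across variants for \eqn{b = 1..B}, rebuilds the score and refits the
#' logistic model each time, and inflates the SE:
#' \code{se_corrected = sqrt(se_naive^2 + var_b(log-OR*))} (default), or
#' uses the replicate SD alone with \code{method = "replicate-sd"}. The
#' point estimate remains the original-weight fit; CI and p-value are
#' recomputed from the corrected SE.
#'
#' @param cohort an \linkS4class{MRCohort}.
#' @param weights a \linkS4class{VariantWeights}; defaults to the cohort's.
#' @param spec an [AnalysisSpec()]; \code{spec$bootstrap_reps} and
#'   \code{spec$seed} drive the bootstrap.
#' @param method \code{"variance-add"} (default) or \code{"replicate-sd"}.
#' @param impute_missing passed to [relativeExposure()].
#' @return A \linkS4class{CausalEstimate} with \code{se_corrected >=
#'   se_naive} under the default method.
#' @export
bootstrapWeightCorrection <- function(cohort, weights = NULL,
                                      spec = AnalysisSpec(),
                                      method = c("variance-add",
                                                 "replicate-sd"),
                                      impute_missing = FALSE) {
    method <- match.arg(method)
    if (is.null(weights)) weights <- variantWeights(cohort)
    B <- spec$bootstrap_reps
    if (B < 2L) stop("bootstrap correction needs at least 2 replicates")
    d <- dosages(cohort)
    scores <- relativeExposure(d, weights, impute_missing = impute_missing)
    prep <- .prep_design(cohort, scores, spec)
    fit0 <- .fit_logistic(prep$y, prep$X, prep$label)
    dkeep <- d[match(weights$rsid, rownames(d)), prep$keep, drop = FALSE]
    if (impute_missing && anyNA(dkeep))
        for (j in seq_len(nrow(dkeep))) {
            nas <- is.na(dkeep[j, ])
            if (any(nas)) dkeep[j, nas] <- 2 * weights$eaf[j]
        }
    X <- prep$X
    thetas <- .with_seed(spec$seed, {
        vapply(seq_len(B), function(b) {
            bstar <- stats::rnorm(nrow(weights), weights$beta, weights$se)
            X[, "score"] <- as.numeric(crossprod(dkeep, bstar))
            tryCatch(.fit_logistic(prep$y, X, prep$label,
                                   start = fit0$coefficients)$log_or,
                     error = function(e) NA_real_)
        }, numeric(1))
    })
    dropped <- sum(is.na(thetas))
    if (dropped > 0) {
        if (dropped > 0.1 * B)
            stop(dropped, "/", B, " bootstrap replicates failed (",
                 prep$label, ")")
        warning(dropped, " bootstrap replicates dropped (non-convergence)")
        thetas <- thetas[!is.na(thetas)]
    }
    vb <- stats::var(thetas)
    se_corr <- switch(method,
        `variance-add` = if (vb == 0) fit0$se else sqrt(fit0$se^2 + vb),
        `replicate-sd` = sqrt(vb))
    .CausalEstimate(label = prep$label, log_or = fit0$log_or,
                    se_naive = fit0$se, se_corrected = se_corr,
                    pvalue = 2 * stats::pnorm(-abs(fit0$log_or / se_corr)),
                    n_cases = prep$n_cases, n_controls = prep$n_controls)
}

#' Per-stratum causal estimates
#'
#' Repeats [fitCausalLogistic()] (or, with \code{bootstrap = TRUE},
#' [bootstrapWeightCorrection()]) within each stratum of the cohort, each fit
#' adjusted for that stratum's own covariate values (including its
#' region-specific principal components). Strata with no cases or no
#' controls after site filtering are skipped with a warning.
#'
#' @param cohort an \linkS4class{MRCohort}.
#' @param scores optional precomputed scores.
#' @param spec an [AnalysisSpec()]; its \code{stratum} field is ignored.
#' @param bootstrap apply the weight-imprecision correction per stratum.
#' @return named list of \linkS4class{CausalEstimate}, one per stratum.
#' @export
estimateAllStrata <- function(cohort, scores = NULL, spec = AnalysisSpec(),
                              bootstrap = FALSE) {
    strata <- unique(as.character(colData(cohort)$stratum))
    if (length(strata) == 0L) stop("cohort has no strata")
    if (is.null(scores)) scores <- relativeExposure(cohort)
    out <- list()
    for (st in strata) {
        sp <- spec; sp$stratum <- st
        est <- tryCatch(
            if (bootstrap) bootstrapWeightCorrection(cohort, spec = sp)
            else fitCausalLogistic(cohort, scores, sp),
            error = function(e) {
                warning("stratum ", st, " skipped: ", conditionMessage(e))
                NULL
            })
        if (!is.null(est)) out[[st]] <- est
    }
    out
}
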