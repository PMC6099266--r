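#' @rdname CausalEstimate-class
#' @param object,x a \linkS4class{CausalEstimate} or \linkS4class{MetaResult}.
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' @rdname CausalEstimate-class
#' @export
setMethod("oddsRatio", "CausalEstimate", function(object) exp(object@log_or))

#' @rdname MetaResult-class
#' @export
setMethod("oddsRatio", "MetaResult", function(object)
    exp(object@pooled_log_or))

#' @rdname CausalEstimate-class
#' @export
setGeneric("logOR", function(object) standardGeneric("logOR"))

#' @rdname CausalEstimate-class
#' @export
setMethod("logOR", "CausalEstimate", function(object) object@log_or)

#' @rdname MetaResult-class
#' @export
setMethod("logOR", "MetaResult", function(object) object@pooled_log_or)

#' @rdname CausalEstimate-class
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

#' @rdname CausalEstimate-class
#' @export
setMethod("confint95", "CausalEstimate", function(object) object@ci95)

#' @rdname MetaResult-class
#' @export
setMethod("confint95", "MetaResult", function(object) object@ci95)

#' @rdname CausalEstimate-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname CausalEstimate-class
#' @export
setMethod("pValue", "CausalEstimate", function(object) object@pvalue)

#' @rdname CausalEstimate-class
#' @export
setGeneric("seNaive", function(object) standardGeneric("seNaive"))

#' @rdname CausalEstimate-class
#' @export
setMethod("seNaive", "CausalEstimate", function(object) object@se_naive)

#' @rdname CausalEstimate-class
#' @export
setGeneric("seCorrected", function(object) standardGeneric("seCorrected"))

#' @rdname CausalEstimate-class
#' @export
setMethod("seCorrected", "CausalEstimate", function(object)
    object@se_corrected)

#' @rdname MetaResult-class
#' @export
setGeneric("heterogeneity", function(object) standardGeneric("heterogeneity"))

#' @rdname MetaResult-class
#' @export
setMethod("heterogeneity", "MetaResult", function(object)
    c(tau2 = object@tau2, Q = object@q, df = object@df,
      I2 = object@i2, I2_lower = object@i2_ci[1], I2_upper = object@i2_ci[2],
      p_het = object@p_het))

#' Dosage matrix of a cohort
#' @param object an \linkS4class{MRCohort}.
#' @return numeric matrix, variants x samples, effect-allele scale.
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "MRCohort", function(object) assay(object, "dosage"))

#' Instrument weights carried by a cohort
#' @param object an \linkS4class{MRCohort}.
#' @export
setGeneric("variantWeights", function(object)
    standardGeneric("variantWeights"))

#' @rdname variantWeights
#' @export
setMethod("variantWeights", "MRCohort", function(object) {
    rd <- rowData(object)
    new("VariantWeights", rd[, .vw_required])
})

setMethod("show", "CausalEstimate", function(object) {
    cat("CausalEstimate:", object@label, "\n")
    cat(sprintf("  OR per SD exposure: %.3f [%.3f, %.3f], p = %.3g\n",
                exp(object@log_or), object@ci95[1], object@ci95[2],
                object@pvalue))
    cat(sprintf("  log OR %.4f; SE naive %.4f, corrected %.4f\n",
                object@log_or, object@se_naive, object@se_corrected))
    cat(sprintf("  %d cases / %d controls\n",
                object@n_cases, object@n_controls))
})

setMethod("show", "MetaResult", function(object) {
    cat("MetaResult (DerSimonian-Laird random effects)\n")
    cat(sprintf("  pooled OR: %.3f [%.3f, %.3f]\n",
                exp(object@pooled_log_or), object@ci95[1], object@ci95[2]))
    i2ci <- if (anyNA(object@i2_ci)) "" else
        sprintf(" [%.0f%%, %.0f%%]", 100 * object@i2_ci[1],
                100 * object@i2_ci[2])
    cat(sprintf("  tau2 = %.4g; Q = %.3f (df %d, p_het = %.3g); I2 = %.0f%%%s\n",
                object@tau2, object@q, object@df, object@p_het,
                100 * object@i2, i2ci))
})

setMethod("show", "MRCohort", function(object) {
    callNextMethod()
    cd <- colData(object)
    cat(sprintf("cases: %d  controls: %d  strata: %s\n",
                sum(cd$case), sum(!cd$case),
                paste(sort(unique(as.character(cd$stratum))),
                      collapse = ", ")))
})

#' @rdname CausalEstimate-class
#' @param row.names,optional,... passed through (see [base::as.data.frame]).
#' @export
as.data.frame.CausalEstimate <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    data.frame(label = x@label, log_or = x@log_or, or = exp(x@log_or),
               se_naive = x@se_naive, se_corrected = x@se_corrected,
               ci_lower = x@ci95[1], ci_upper = x@ci95[2],
               pvalue = x@pvalue, n_cases = x@n_cases,
               n_controls = x@n_controls, stringsAsFactors = FALSE)
}

#' Bind a list of CausalEstimate objects into a data.frame
#' @param estimates list of \linkS4class{CausalEstimate}.
#' @export
estimateTable <- function(estimates) {
    if (is(estimates, "CausalEstimate")) estimates <- list(estimates)
    do.call(rbind, lapply(estimates, as.data.frame))
}
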