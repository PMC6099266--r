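.sim_config_from_list <- function(lst) {
    if (is.null(lst)) lst <- list()
    args <- list()
    if (!is.null(lst$weights)) args$weights <- readVariantWeights(lst$weights)
    if (!is.null(lst$strata))
        args$strata <- do.call(rbind, lapply(lst$strata, function(s)
            data.frame(stratum = s$stratum, n_cases = as.integer(s$n_cases),
                       n_controls = as.integer(s$n_controls),
                       stringsAsFactors = FALSE)))
    for (f in c("causal_log_or", "noise_sd", "oral_fraction",
                "structure_stratum", "structure_log_or", "subpop_fraction",
                "n_pcs", "alpha", "pop_mult", "seed"))
        if (!is.null(lst[[f]])) args[[f]] <- lst[[f]]
    if (!is.null(lst$structure_scenario))
        args$structure_scenario <- isTRUE(lst$structure_scenario)
    if (!is.null(lst$eaf_shift)) args$eaf_shift <- unlist(lst$eaf_shift)
    if (!is.null(lst$confounder_effects))
        args$confounder_effects <- unlist(lst$confounder_effects)
    do.call(SimulationConfig, args)
}

.meta_as_list <- function(m) {
    h <- heterogeneity(m)
    list(pooled_or = unname(exp(m@pooled_log_or)),
         pooled_log_or = m@pooled_log_or, pooled_se = m@pooled_se,
         ci_lower = m@ci95[1], ci_upper = m@ci95[2],
         tau2 = unname(h["tau2"]), q = unname(h["Q"]),
         df = as.integer(h["df"]), i2 = unname(h["I2"]),
         i2_lower = unname(h["I2_lower"]), i2_upper = unname(h["I2_upper"]),
         p_het = unname(h["p_het"]))
}

#' Run the full genetic-risk-score MR pipeline from a config
#'
#' Orchestrates score construction, per-stratum causal estimation with
#' bootstrap weight correction, random-effects pooling per cancer site
#' (oral, oropharyngeal, combined — controls shared across site analyses),
#' leave-one-out and all-subsets sensitivity analyses, instrument-confounder
#' balance diagnostics, the power table, an optional rerun excluding a named
#' stratum, and an optional second cohort pooled with the first by a
#' second-level meta-analysis. Every random stage records its seed in the
#' report, so identical configs and seeds give identical reports.
#'
#' @param config a YAML file path or an equivalent nested list. Recognized
#'   top-level fields: \code{seed}; \code{input} (either
#'   \code{simulate: true} with \code{sim:} overrides for
#'   [SimulationConfig()], or \code{weights}/\code{genotypes}/
#'   \code{phenotypes} paths for [readCohort()]); \code{covariates};
#'   \code{bootstrap} (replicates, 0 disables correction); \code{sites};
#'   \code{sensitivity} (\code{leave_one_out}, \code{all_subsets});
#'   \code{balance_covariates}; \code{exclude_stratum}; \code{power}
#'   (\code{r2} grid, \code{alpha}, \code{target_power});
#'   \code{second_cohort} (a second \code{input}-style block); and
#'   \code{out_dir}.
#' @param out_dir output directory (overrides the config field); when given,
#'   a machine-readable \code{report.json}, TSV tables and a plain-text
#'   summary are written there. On a stage failure partial outputs are kept
#'   under \code{<out_dir>/failed/} and the error names the stage.
#' @return the report, invisibly when written to disk.
#' @export
runPipeline <- function(config, out_dir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(out_dir)) out_dir <- config$out_dir
    seed <- as.integer(config$seed %||% 1L)
    stage <- "setup"
    report <- list(seed = seed)
    on_fail <- function(e) {
        if (!is.null(out_dir)) {
            fdir <- file.path(out_dir, "failed")
            dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
            jsonlite::write_json(report, file.path(fdir, "partial.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 force = TRUE)
        }
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
    }
    tryCatch({
        stage <- "input"
        cohort <- .pipeline_cohort(config$input, seed)
        weights <- variantWeights(cohort)
        scores <- relativeExposure(cohort)
        stage <- "estimation"
        B <- as.integer(config$bootstrap %||% 1000L)
        sites <- unlist(config$sites %||%
                        c("oral", "oropharyngeal", "combined"))
        site_results <- list()
        for (site in sites) {
            spec <- AnalysisSpec(site_filter = site,
                                 covariates = config$covariates,
                                 bootstrap_reps = max(B, 2L), seed = seed)
            ests <- estimateAllStrata(cohort, scores, spec,
                                      bootstrap = B > 0L)
            pooled <- dlRandomEffects(ests)
            res <- list(strata = lapply(ests, function(e)
                            as.list(as.data.frame(e))),
                        pooled = .meta_as_list(pooled))
            excl <- config$exclude_stratum
            if (!is.null(excl) && excl %in% names(ests) &&
                length(ests) > 2L)
                res$pooled_excluding <- c(list(excluded = excl),
                    .meta_as_list(dlRandomEffects(ests[names(ests) !=
                                                       excl])))
            site_results[[site]] <- res
        }
        report$sites <- site_results
        stage <- "sensitivity"
        sens_cfg <- config$sensitivity %||% list(leave_one_out = TRUE,
                                                 all_subsets = TRUE)
        spec_comb <- AnalysisSpec(site_filter = "combined",
                                  covariates = config$covariates,
                                  bootstrap_reps = max(B, 2L), seed = seed)
        sens <- list()
        if (isTRUE(sens_cfg$leave_one_out))
            sens$leave_one_out <- leaveOneOut(cohort, weights, spec_comb)
        if (isTRUE(sens_cfg$all_subsets))
            sens$all_subsets <- allSubsets(cohort, weights, spec_comb)
        report$sensitivity <- sens
        stage <- "balance"
        bal_covs <- unlist(config$balance_covariates %||%
                           c("sex", "smoking", "alcohol", "stratum"))
        cd <- colData(cohort)
        bal <- lapply(bal_covs, function(cv)
            confounderBalance(scores, as.character(cd[[cv]]))$p_value)
        names(bal) <- bal_covs
        report$balance <- list(
            p_raw = bal,
            p_bonferroni = lapply(bal, function(p)
                min(1, p * length(bal))))
        stage <- "power"
        pw <- config$power %||% list()
        r2_grid <- unlist(pw$r2 %||% c(0.03, 0.05))
        nca <- sum(cd$case); nco <- sum(!cd$case)
        report$power <- lapply(r2_grid, function(r2) {
            det <- detectableOR(nca, nco, r2,
                                alpha = pw$alpha %||% 0.05,
                                target_power = pw$target_power %||% 0.8)
            list(r2 = r2, n_cases = nca, n_controls = nco,
                 protective_or = unname(det["protective"]),
                 risk_or = unname(det["risk"]))
        })
        stage <- "second_cohort"
        if (!is.null(config$second_cohort)) {
            cohort2 <- .pipeline_cohort(config$second_cohort, seed + 1L)
            report$second_cohort <- list(seed = seed + 1L)
            meta2 <- list()
            for (site in sites) {
                spec2 <- AnalysisSpec(site_filter = site,
                                      covariates = config$covariates,
                                      bootstrap_reps = max(B, 2L),
                                      seed = seed + 1L)
                e2 <- if (B > 0L) bootstrapWeightCorrection(cohort2,
                          spec = spec2)
                      else fitCausalLogistic(cohort2, spec = spec2)
                pooled1 <- report$sites[[site]]$pooled
                meta2[[site]] <- .meta_as_list(dlRandomEffects(
                    c(pooled1$pooled_log_or, logOR(e2)),
                    c(pooled1$pooled_se, seCorrected(e2))))
            }
            report$second_cohort$pooled_across_cohorts <- meta2
        }
        stage <- "report"
        if (!is.null(out_dir)) {
            dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
            jsonlite::write_json(report, file.path(out_dir, "report.json"),
                                 auto_unbox = TRUE, digits = NA,
                                 force = TRUE)
            for (site in sites) {
                tab <- do.call(rbind, lapply(
                    report$sites[[site]]$strata, as.data.frame))
                utils::write.table(tab,
                    file.path(out_dir, paste0("estimates_", site, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
            }
            if (!is.null(sens$leave_one_out))
                utils::write.table(sens$leave_one_out,
                    file.path(out_dir, "leave_one_out.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
            if (!is.null(sens$all_subsets))
                utils::write.table(sens$all_subsets,
                    file.path(out_dir, "all_subsets.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
            writeLines(.summary_text(report),
                       file.path(out_dir, "summary.txt"))
            return(invisible(report))
        }
        report
    }, error = on_fail)
}

.pipeline_cohort <- function(input, seed) {
    if (is.null(input) || isTRUE(input$simulate)) {
        cfg <- .sim_config_from_list(input$sim)
        simulateCohort(cfg, seed = input$sim$seed %||% seed)
    } else {
        w <- readVariantWeights(input$weights)
        readCohort(input$genotypes, input$phenotypes, w)
    }
}

.summary_text <- function(report) {
    out <- c(sprintf("grsmr pipeline report (seed %d)", report$seed))
    for (site in names(report$sites)) {
        p <- report$sites[[site]]$pooled
        out <- c(out, sprintf(
            "%s: pooled OR %.3f [%.3f, %.3f], I2 %.0f%%, p_het %.3g",
            site, p$pooled_or, p$ci_lower, p$ci_upper, 100 * p$i2,
            p$p_het))
    }
    if (!is.null(report$balance))
        out <- c(out, paste("balance p (raw):",
            paste(sprintf("%s=%.3g", names(report$balance$p_raw),
                          unlist(report$balance$p_raw)), collapse = "  ")))
    for (pw in report$power)
        out <- c(out, sprintf(
            "power: R2=%.2f -> detectable protective OR %.2f",
            pw$r2, pw$protective_or))
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
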