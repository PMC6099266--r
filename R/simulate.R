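## Marginal covariate frequencies of the emulated consortium (all-participant
## column of the cohort summary table); missing is generated as NA.
.age_levels <- c("<=50", "50-60", "60-70", ">=70")
.age_probs <- c(2217, 3443, 3348, 2108) / 11116
.sex_male_prob <- 7680 / 11117
.smoking_levels <- c("never", "previous", "current", NA)
.smoking_probs <- c(3302, 3655, 3300, 860) / 11117
.alcohol_levels <- c("never", "ever", NA)
.alcohol_probs <- c(1825, 8422, 870) / 11117

.default_strata <- function()
    data.frame(stratum = c("Europe", "North America", "South America"),
               n_cases = c(2323L, 2254L, 556L),
               n_controls = c(2928L, 2329L, 727L),
               stringsAsFactors = FALSE)

#' @rdname SimulationConfig-class
#' @param weights instrument weights (default: the packaged 25OHD set).
#' @param strata data.frame with columns \code{stratum}, \code{n_cases},
#'   \code{n_controls}; defaults to the three-region consortium composition
#'   totalling 11,117 participants.
#' @param causal_log_or causal effect of the exposure on the outcome, log OR
#'   per SD (default 0, the null).
#' @param noise_sd SD of the non-genetic exposure component; \code{NA}
#'   (default) picks \code{sqrt(1 - R2)} so the exposure has unit variance.
#' @param confounder_effects named numeric of log-OR effects on the outcome,
#'   names of the form \code{"covariate:level"} (e.g.
#'   \code{c("smoking:current" = 0.7)}). Confounders are drawn independently
#'   of genotype, so instrument-confounder balance has a true null.
#' @param oral_fraction fraction of cases labelled oral (default 0.526, the
#'   remainder oropharyngeal).
#' @param structure_scenario enable the latent-subpopulation artifact: within
#'   \code{structure_stratum} a fraction \code{subpop_fraction} of
#'   individuals draw genotypes at EAFs shifted so the stratum-level mean EAF
#'   moves by \code{eaf_shift}, and carry \code{structure_log_or} on the
#'   outcome logit — allele frequency then co-varies with outcome risk
#'   within the stratum, producing a spurious stratum-specific causal OR.
#' @param structure_stratum,eaf_shift,structure_log_or,subpop_fraction see
#'   \code{structure_scenario}.
#' @param n_pcs number of principal-component covariates (default 15).
#' @param alpha baseline outcome logit in the simulated source population.
#' @param pop_mult source-population oversampling factor for retrospective
#'   case-control sampling.
#' @param seed default seed used by [simulateCohort()].
#' @return A \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(weights = vitaminDWeights(),
                             strata = .default_strata(),
                             causal_log_or = 0,
                             noise_sd = NA_real_,
                             confounder_effects = numeric(0),
                             oral_fraction = 0.526,
                             structure_scenario = FALSE,
                             structure_stratum = "South America",
                             eaf_shift = c(rs4588 = 0.10, rs4423214 = 0.10),
                             structure_log_or = log(5),
                             subpop_fraction = 0.5,
                             n_pcs = 15L,
                             alpha = stats::qlogis(0.15),
                             pop_mult = 4,
                             seed = 1L) {
    new("SimulationConfig", weights = weights, strata = strata,
        causal_log_or = causal_log_or, noise_sd = noise_sd,
        confounder_effects = confounder_effects,
        oral_fraction = oral_fraction,
        structure_scenario = structure_scenario,
        structure_stratum = structure_stratum,
        eaf_shift = eaf_shift, structure_log_or = structure_log_or,
        subpop_fraction = subpop_fraction,
        n_pcs = as.integer(n_pcs), alpha = alpha, pop_mult = pop_mult,
        impute_missing = FALSE, seed = as.integer(seed))
}

## Run expr under a pinned, seeded RNG, restoring global RNG state after.
.with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    expr
}

#' Simulate a case-control cohort with the structure the analysis assumes
#'
#' Generates, per stratum, a source population of
#' \code{pop_mult * (n_cases + n_controls)} individuals: genotypes drawn
#' Binomial(2, EAF) independently across variants (Hardy-Weinberg, linkage
#' equilibrium); a standardized log-scale exposure
#' \eqn{x_i = \sum_j \beta_j g_{ij} - E[\sum_j \beta_j g_{ij}] + \epsilon_i}
#' with the noise SD chosen so \eqn{Var(x) = 1} (the instrument then explains
#' \eqn{\sum_j \beta_j^2 2 p_j (1-p_j)} of the exposure variance); outcome
#' drawn from \eqn{logit P(case) = \alpha + \theta x + } confounder and
#' structure terms; then the configured numbers of cases and controls are
#' sampled retrospectively (log ORs are invariant to outcome-dependent
#' sampling up to the intercept). Cases are labelled oral or oropharyngeal
#' per \code{oral_fraction}; principal components are standard normal with
#' stratum-specific mean offsets on PC1; sex, age band, smoking and alcohol
#' are drawn from the consortium's marginal frequencies, independent of
#' genotype.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer; overrides \code{config@seed}. The RNG kind is pinned,
#'   so the same config and seed reproduce the cohort exactly.
#' @return An \linkS4class{MRCohort}; \code{colData} carries the latent
#'   \code{exposure} for validation.
#' @examples
#' cfg <- SimulationConfig(strata = data.frame(
#'     stratum = "Europe", n_cases = 200L, n_controls = 250L))
#' cohort <- simulateCohort(cfg, seed = 7)
#' @export
simulateCohort <- function(config, seed = config@seed) {
    validObject(config)
    .with_seed(as.integer(seed), .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
    w <- config@weights
    k <- nrow(w)
    r2 <- expectedInstrumentR2(w)
    noise_sd <- if (is.na(config@noise_sd)) sqrt(max(0, 1 - r2))
                else config@noise_sd
    center <- 2 * sum(w$beta * w$eaf)
    strata <- config@strata
    out <- vector("list", nrow(strata))
    for (si in seq_len(nrow(strata))) {
        st <- strata$stratum[si]
        ncase <- strata$n_cases[si]; nctrl <- strata$n_controls[si]
        npop <- ceiling(config@pop_mult * (ncase + nctrl))
        structured <- config@structure_scenario &&
            st == config@structure_stratum
        sub <- if (structured)
            stats::rbinom(npop, 1L, config@subpop_fraction) else
            integer(npop)
        g <- matrix(0, nrow = k, ncol = npop,
                    dimnames = list(w$rsid, NULL))
        for (j in seq_len(k)) {
            p <- rep(w$eaf[j], npop)
            if (structured) {
                shift <- config@eaf_shift[w$rsid[j]]
                if (!is.na(shift) && shift != 0)
                    p[sub == 1L] <- w$eaf[j] + shift / config@subpop_fraction
            }
            g[j, ] <- stats::rbinom(npop, 2L, p)
        }
        score <- as.numeric(crossprod(g, w$beta))
        x <- score - center + stats::rnorm(npop, 0, noise_sd)
        age <- sample(.age_levels, npop, replace = TRUE, prob = .age_probs)
        sex <- ifelse(stats::runif(npop) < .sex_male_prob, "male", "female")
        smoking <- sample(.smoking_levels, npop, replace = TRUE,
                          prob = .smoking_probs)
        alcohol <- sample(.alcohol_levels, npop, replace = TRUE,
                          prob = .alcohol_probs)
        eta <- config@alpha + config@causal_log_or * x
        if (length(config@confounder_effects)) {
            covs <- list(sex = sex, age_band = age, smoking = smoking,
                         alcohol = alcohol)
            for (nm in names(config@confounder_effects)) {
                parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
                if (length(parts) != 2L || !parts[1] %in% names(covs))
                    stop("confounder_effects names must be 'covariate:level'",
                         " over sex/age_band/smoking/alcohol; got ", nm)
                hit <- !is.na(covs[[parts[1]]]) & covs[[parts[1]]] == parts[2]
                eta[hit] <- eta[hit] + config@confounder_effects[[nm]]
            }
        }
        if (structured) eta[sub == 1L] <- eta[sub == 1L] +
            config@structure_log_or
        y <- stats::rbinom(npop, 1L, stats::plogis(eta))
        cases_avail <- which(y == 1L); ctrls_avail <- which(y == 0L)
        if (length(cases_avail) < ncase || length(ctrls_avail) < nctrl)
            stop("stratum ", st, ": source population yielded ",
                 length(cases_avail), " cases / ", length(ctrls_avail),
                 " controls but ", ncase, "/", nctrl, " requested; ",
                 "adjust alpha or increase pop_mult")
        pick <- c(sample(cases_avail, ncase), sample(ctrls_avail, nctrl))
        case <- c(rep(TRUE, ncase), rep(FALSE, nctrl))
        site <- rep("control", ncase + nctrl)
        site[seq_len(ncase)] <- ifelse(
            stats::runif(ncase) < config@oral_fraction,
            "oral", "oropharyngeal")
        n <- ncase + nctrl
        pcs <- matrix(stats::rnorm(n * config@n_pcs), nrow = n)
        pcs[, 1] <- pcs[, 1] + 0.5 * (si - 1)
        colnames(pcs) <- paste0("pc", seq_len(config@n_pcs))
        ph <- data.frame(
            id = sprintf("%s_%06d", gsub("[^A-Za-z]", "", st), pick),
            case = case, site = site, stratum = st,
            sex = sex[pick], age_band = age[pick],
            smoking = smoking[pick], alcohol = alcohol[pick],
            pcs, exposure = x[pick],
            stringsAsFactors = FALSE, check.names = FALSE)
        rownames(ph) <- ph$id
        d <- g[, pick, drop = FALSE]
        colnames(d) <- ph$id
        out[[si]] <- list(d = d, ph = ph)
    }
    dosage <- do.call(cbind, lapply(out, `[[`, "d"))
    ph <- do.call(rbind, lapply(out, `[[`, "ph"))
    cohort <- MRCohort(dosage, ph, w)
    metadata(cohort)$config <- config
    cohort
}

.fixture_env <- new.env(parent = emptyenv())

#' Packaged small-cohort fixture
#'
#' A ~2,000-participant three-region cohort (Europe 418/527, North America
#' 406/419, South America 100/130) regenerated deterministically from an
#' embedded configuration and fixed seed, for fast examples and tests. The
#' result is cached within the session; independent calls (and fresh
#' sessions) produce identical cohorts because the RNG kind is pinned.
#'
#' @return list with elements \code{cohort} (an \linkS4class{MRCohort}) and
#'   \code{config} (the embedded \linkS4class{SimulationConfig}).
#' @export
packagedFixture <- function() {
    if (is.null(.fixture_env$fixture)) {
        config <- SimulationConfig(
            strata = data.frame(
                stratum = c("Europe", "North America", "South America"),
                n_cases = c(418L, 406L, 100L),
                n_controls = c(527L, 419L, 130L),
                stringsAsFactors = FALSE),
            seed = 1907L)
        .fixture_env$fixture <- list(cohort = simulateCohort(config),
                                     config = config)
    }
    .fixture_env$fixture
}
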