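## End-to-end orchestration: module discovery on the discovery cohort,
## meta-gene summarization, phenotype screens, classifier training with CV
## and external validation, per-grade stratification, multivariate models,
## module sparsification per validation cohort, and optional enrichment /
## TF screens. Module discovery runs only on the discovery cohort; the
## validation cohorts receive gene lists and recompute their own
## meta-genes.

#' Run the full meta-gene recurrence pipeline
#'
#' @param discovery discovery cohort (\code{SummarizedExperiment} from
#'   \code{\link{makeCohort}}).
#' @param validation named list of validation cohorts (possibly empty).
#' @param gmt optional gene-set library for enrichment and the TF screen.
#' @param power soft threshold; NULL selects by scale-free fit.
#' @param candidates candidate powers for automatic selection.
#' @param minSize,deepSplit tree-cut parameters.
#' @param alpha module recurrence-screen t-test threshold.
#' @param qAlpha enrichment q threshold for the TF screen.
#' @param folds CV folds (>= 2).
#' @param seed master seed (fold assignment and any other randomness).
#' @param sparsifyThreshold,sparsifyCap sparsification parameters.
#' @param covariates covariates for the multivariate models (intersected
#'   with each cohort's available columns).
#' @return a report list: \code{partition}, \code{power}, \code{metagenes},
#'   \code{associations}, \code{significantModules},
#'   \code{predictiveModule}, \code{cv}, \code{external},
#'   \code{byGrade}, \code{multivariate}, \code{sparsification},
#'   \code{enrichment}, \code{tfMarkers}, \code{manifest}.
#' @export
runPipeline <- function(discovery, validation = list(), gmt = NULL,
                        power = NULL, candidates = 1:12, minSize = 20L,
                        deepSplit = 2L, alpha = 0.05, qAlpha = 0.05,
                        folds = 10L, seed = 1L, sparsifyThreshold = 0.90,
                        sparsifyCap = 100L,
                        covariates = c("who_grade", "simpson_grade")) {
    if (folds < 2L) stop("folds must be >= 2")
    xd <- .exprs(discovery)
    pd <- .pheno(discovery)

    disc <- discoverModules(xd, power = power, candidates = candidates,
                            minSize = minSize, deepSplit = deepSplit)
    part <- disc$partition
    labs <- setdiff(unique(moduleLabels(part)), "unassigned")
    if (length(labs) == 0L) stop("no modules detected in discovery cohort")
    moduleGenes <- stats::setNames(
        lapply(labs, function(m) moduleGenes(part, m)), labs)

    mg <- computeMetagenes(xd, moduleGenes)
    sc <- metageneScores(mg)

    assoc <- lapply(labs, function(m) {
        tt <- recurrenceTTest(sc[m, ], pd, unit = m)
        an <- gradeAnova(sc[m, ], pd, unit = m)
        tc <- tryCatch(ttrCorrelation(sc[m, ], pd, unit = m),
                       error = function(e) NULL)
        list(ttest = tt, anova = an, ttr = tc)
    })
    names(assoc) <- labs
    ttP <- vapply(assoc, function(a) a$ttest$p.value, numeric(1L))
    sig <- labs[ttP < alpha]
    if (length(sig) == 0L) {
        warning("no module passes the recurrence t-test screen; ",
                "carrying the best-p module forward")
        sig <- labs[which.min(ttP)]
    }
    predictive <- sig[which.min(ttP[sig])]

    cv <- crossValidate(xd, pd, moduleGenes[sig], k = folds, seed = seed)

    external <- byGrade <- multivariate <- list()
    for (v in names(validation)) {
        external[[v]] <- evaluateExternal(discovery, validation[[v]],
                                          moduleGenes[sig])
        cvv <- intersect(covariates,
                         colnames(.pheno(validation[[v]])))
        cvv <- cvv[vapply(cvv, function(cc) {
            vals <- .pheno(validation[[v]])[[cc]]
            length(unique(vals[!is.na(vals)])) > 1L
        }, logical(1L))]
        if (length(cvv))
            multivariate[[v]] <- evaluateExternal(
                validation[[v]], validation[[v]], moduleGenes[predictive],
                covariates = cvv)$model
        byGrade[[v]] <- lapply(
            sort(unique(.pheno(validation[[v]])$who_grade)), function(g)
                tryCatch(stratifiedByGrade(validation[[v]],
                                           moduleGenes = moduleGenes[sig],
                                           grade = g),
                         error = function(e) conditionMessage(e)))
        names(byGrade[[v]]) <- paste0("grade",
            sort(unique(.pheno(validation[[v]])$who_grade)))
    }
    # discovery-cohort multivariate model (module + WHO grade)
    multivariate[["discovery"]] <- {
        X <- data.frame(t(sc[predictive, , drop = FALSE]),
                        who_grade = as.numeric(pd$who_grade))
        suppressWarnings(fitLogistic(pd$recurrence, X))
    }

    sparsification <- list()
    if (length(validation) >= 1L) {
        traces <- lapply(validation, function(vc)
            tryCatch(sparsifyModule(vc, moduleGenes[[predictive]],
                                    threshold = sparsifyThreshold,
                                    cap = sparsifyCap),
                     error = function(e) NULL))
        traces <- Filter(Negate(is.null), traces)
        sparsification$traces <- traces
        if (length(traces) >= 1L && length(validation) >= 2L)
            sparsification$crossCohort <- evaluateSparseCrossCohort(
                lapply(traces, sparseGenes), validation,
                moduleGenes[[predictive]])
    }

    enrichment <- tfMarkers <- NULL
    if (!is.null(gmt)) {
        enrichment <- lapply(moduleGenes[sig], overrepresentationTest,
                             library = gmt, universe = rownames(xd))
        if (length(validation) >= 1L)
            tfMarkers <- tfMarkerScreen(enrichment[[predictive]],
                                        validation, qAlpha = qAlpha,
                                        pAlpha = alpha)
    }

    list(partition = part, power = disc$power, fits = disc$fits,
         metagenes = mg, associations = assoc, significantModules = sig,
         predictiveModule = predictive, cv = cv, external = external,
         byGrade = byGrade, multivariate = multivariate,
         sparsification = sparsification, enrichment = enrichment,
         tfMarkers = tfMarkers,
         manifest = list(seed = seed, folds = folds, alpha = alpha,
                         qAlpha = qAlpha, minSize = minSize,
                         deepSplit = deepSplit, power = disc$power,
                         sparsifyThreshold = sparsifyThreshold,
                         sparsifyCap = sparsifyCap))
}

#' Serialize a pipeline report's headline numbers as JSON
#'
#' Flattens the quantitative core of a \code{\link{runPipeline}} report
#' (module sizes, screen p-values, AUCs, odds ratios, sparse-set sizes)
#' for machine reading.
#'
#' @param report list from \code{\link{runPipeline}}.
#' @param path output path; NULL returns the JSON string.
#' @return the JSON string, invisibly if written to a file.
#' @export
reportJSON <- function(report, path = NULL) {
    sizes <- moduleSizes(report$partition)
    out <- list(
        power = report$power,
        moduleSizes = as.list(sizes),
        significantModules = report$significantModules,
        predictiveModule = report$predictiveModule,
        recurrenceTTestP = lapply(report$associations,
                                  function(a) a$ttest$p.value),
        cvAUC = report$cv$roc$auc, cvAUCse = report$cv$roc$se,
        externalAUC = lapply(report$external, function(e) e$roc$auc),
        sparseSizes = lapply(report$sparsification$traces,
                             function(tr) length(sparseGenes(tr))),
        seed = report$manifest$seed)
    js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    if (!is.null(path)) {
        writeLines(js, path)
        return(invisible(js))
    }
    js
}
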