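## Logistic recurrence classifier, ROC/AUC with DeLong variance, paired
## DeLong curve comparison, stratified cross-validation with strict
## per-fold meta-gene recomputation, external validation, and per-grade
## stratification. ROC machinery delegates to pROC (DeLong structural
## components); the pipeline logic around it is package-specific.

#' Fit a logistic recurrence model
#'
#' Maximum-likelihood logistic regression (IRLS via \code{stats::glm}) of a
#' binary outcome on meta-genes and/or covariates, with Wald confidence
#' intervals and odds ratios. Non-convergence and complete separation are
#' detected and flagged, never silently returned.
#'
#' @param y binary outcome (0/1), both classes present.
#' @param X data.frame or matrix of regressors (columns named).
#' @return object of class \code{mm_logistic}: coefficients, covariance,
#'   odds ratios with 95\% CI, Wald p-values, \code{converged} and
#'   \code{separation} flags.
#' @export
fitLogistic <- function(y, X) {
    X <- as.data.frame(X)
    y <- as.numeric(y)
    stopifnot(all(y %in% 0:1), nrow(X) == length(y))
    if (length(unique(y)) < 2L) stop("single-class outcome")
    if (length(y) <= ncol(X) + 1L) stop("more regressors than samples allow")
    sep <- FALSE
    fit <- withCallingHandlers(
        stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    co <- summary(fit)$coefficients
    est <- co[, "Estimate"]; se <- co[, "Std. Error"]
    if (sep || !fit$converged)
        warning("separation or non-convergence detected; ",
                "coefficients are the last IRLS iterate")
    out <- list(coefficients = est, se = se, vcov = stats::vcov(fit),
                or = exp(est), orCI = cbind(lower = exp(est - 1.96 * se),
                                            upper = exp(est + 1.96 * se)),
                p = co[, "Pr(>|z|)"],
                converged = fit$converged, separation = sep,
                terms = colnames(X), glm = fit)
    class(out) <- "mm_logistic"
    out
}

#' @export
print.mm_logistic <- function(x, ...) {
    cat("Logistic model (", length(x$terms), " regressor(s))",
        if (x$separation) " [SEPARATION FLAGGED]", "\n", sep = "")
    tab <- data.frame(coef = x$coefficients, OR = x$or,
                      CI.lo = x$orCI[, 1L], CI.hi = x$orCI[, 2L], p = x$p)
    print(round(tab, 4))
    invisible(x)
}

#' Predict recurrence probabilities
#'
#' @param m an \code{mm_logistic} model.
#' @param X regressor data.frame/matrix with the model's columns.
#' @return per-sample probabilities in (0,1).
#' @export
predictProb <- function(m, X) {
    stopifnot(inherits(m, "mm_logistic"))
    X <- as.data.frame(X)
    miss <- setdiff(m$terms, colnames(X))
    if (length(miss)) stop("missing regressor(s): ",
                           paste(miss, collapse = ", "))
    beta <- m$coefficients
    lp <- beta[["(Intercept)"]] +
        as.matrix(X[, m$terms, drop = FALSE]) %*% beta[m$terms]
    stats::plogis(drop(lp))
}

.proc <- function(scores, labels) {
    if (length(unique(labels)) < 2L) stop("both outcome classes required")
    pROC::roc(response = labels, predictor = as.numeric(scores),
              levels = c(0, 1), direction = "<", quiet = TRUE)
}

#' ROC curve and AUC with DeLong standard error
#'
#' AUC equals the Mann-Whitney statistic with half credit for ties; the
#' standard error comes from DeLong's structural-components variance. The
#' score direction is fixed (higher score predicts the positive class), so
#' AUC below 0.5 is reported as-is.
#'
#' @param scores numeric predictor.
#' @param labels binary labels (0/1).
#' @return object of class \code{mm_roc}: \code{auc}, \code{se},
#'   \code{curve} (FPR/TPR/threshold, (0,0) to (1,1)), \code{nPos},
#'   \code{nNeg}.
#' @export
rocAuc <- function(scores, labels) {
    r <- .proc(scores, labels)
    curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                        threshold = r$thresholds)
    curve <- curve[order(curve$fpr, curve$tpr), ]
    rownames(curve) <- NULL
    v <- withCallingHandlers(
        pROC::var(r, method = "delong"),
        warning = function(w) {
            # a degenerate curve (AUC exactly 1) has zero DeLong variance;
            # SE = 0 is the correct report, no need to warn per call
            if (grepl("AUC == 1", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    out <- list(auc = as.numeric(pROC::auc(r)),
                se = sqrt(v),
                curve = curve,
                nPos = sum(labels == 1), nNeg = sum(labels == 0))
    class(out) <- "mm_roc"
    out
}

#' @export
print.mm_roc <- function(x, ...) {
    cat(sprintf("ROC: AUC = %.3f +/- %.3f (%d pos / %d neg)\n",
                x$auc, x$se, x$nPos, x$nNeg))
    invisible(x)
}

#' Paired DeLong test between two correlated ROC curves
#'
#' DeLong's (1988) comparison of two AUCs computed from different scores on
#' the same samples, via placement values; two-sided p from the normal
#' approximation. Scores that induce identical rank orders give z = 0,
#' p = 1 exactly.
#'
#' @param scores1,scores2 paired score vectors on the same samples.
#' @param labels binary labels (0/1).
#' @return object of class \code{mm_delong}: \code{auc1}, \code{auc2},
#'   \code{diff}, \code{varDiff}, \code{z}, \code{p.value}.
#' @export
delongTest <- function(scores1, scores2, labels) {
    if (length(scores1) != length(scores2) ||
        length(scores1) != length(labels))
        stop("scores and labels must be paired (equal lengths)")
    r1 <- .proc(scores1, labels); r2 <- .proc(scores2, labels)
    a1 <- as.numeric(pROC::auc(r1)); a2 <- as.numeric(pROC::auc(r2))
    if (identical(rank(as.numeric(scores1)), rank(as.numeric(scores2)))) {
        out <- list(auc1 = a1, auc2 = a2, diff = 0, varDiff = 0, z = 0,
                    p.value = 1)
        class(out) <- "mm_delong"
        return(out)
    }
    tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    z <- unname(tst$statistic)
    p <- tst$p.value
    if (!is.finite(z)) { z <- 0; p <- 1 }   # zero-variance difference
    out <- list(auc1 = a1, auc2 = a2, diff = a1 - a2,
                varDiff = if (z != 0) ((a1 - a2) / z)^2 else 0,
                z = z, p.value = p)
    class(out) <- "mm_delong"
    out
}

#' @export
print.mm_delong <- function(x, ...) {
    cat(sprintf("DeLong: AUC1 = %.3f, AUC2 = %.3f, z = %.3f, p = %.4g\n",
                x$auc1, x$auc2, x$z, x$p.value))
    invisible(x)
}

#' Deterministic stratified fold assignment
#'
#' Shuffles each outcome class with the given seed and deals samples
#' round-robin, so fold class proportions match the cohort as closely as
#' integer counts allow.
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id (1..k) per sample.
#' @export
makeStratifiedFolds <- function(y, k, seed = 1L) {
    stopifnot(k >= 2L, k <= length(y))
    set.seed(seed)
    fold <- integer(length(y))
    for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Stratified k-fold cross-validation of the meta-gene classifier
#'
#' Per fold: module meta-genes are fitted on the training samples only
#' (PC1 loadings, gene centers/scales from training), held-out samples are
#' projected onto the training components, a logistic model is fitted on
#' the training scores and applied to the held-out scores; the ROC is
#' computed on the pooled out-of-fold probabilities. The
#' \code{"whole-cohort"} compatibility mode computes meta-genes once on all
#' samples (loadings see the held-out data) and cross-validates only the
#' logistic coefficients.
#'
#' @param x genes x samples matrix or cohort.
#' @param pheno phenotype table (ignored if \code{x} is a cohort).
#' @param moduleGenes named list of module gene vectors.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param metageneMode \code{"per-fold"} (strict, default) or
#'   \code{"whole-cohort"}.
#' @return list with \code{roc} (pooled out-of-fold \code{mm_roc}),
#'   \code{probs}, \code{folds}, \code{labels}.
#' @export
crossValidate <- function(x, pheno = NULL, moduleGenes, k = 10L, seed = 1L,
                          metageneMode = c("per-fold", "whole-cohort")) {
    metageneMode <- match.arg(metageneMode)
    x0 <- .exprs(x)
    ph <- .pheno(x, pheno)
    ph <- ph[match(colnames(x0), ph$sample_id), , drop = FALSE]
    y <- ph$recurrence
    if (k < 2L) stop("k must be >= 2")
    if (min(table(y)) < k)
        warning("a class has fewer samples than folds; ",
                "stratification degrades")
    folds <- makeStratifiedFolds(y, k, seed)
    probs <- rep(NA_real_, length(y))
    wholeScores <- if (metageneMode == "whole-cohort")
        t(metageneScores(computeMetagenes(x0, moduleGenes))) else NULL
    for (f in sort(unique(folds))) {
        tr <- folds != f; te <- !tr
        if (length(unique(y[tr])) < 2L)
            stop("outcome class absent from training fold ", f)
        if (metageneMode == "per-fold") {
            mgTrain <- suppressMessages(
                computeMetagenes(x0[, tr, drop = FALSE], moduleGenes))
            strain <- as.data.frame(t(metageneScores(mgTrain)))
            stest <- as.data.frame(t(projectMetagenes(
                x0[, te, drop = FALSE], mgTrain)))
        } else {
            strain <- as.data.frame(wholeScores[tr, , drop = FALSE])
            stest <- as.data.frame(wholeScores[te, , drop = FALSE])
        }
        m <- suppressWarnings(fitLogistic(y[tr], strain))
        probs[te] <- predictProb(m, stest)
    }
    list(roc = rocAuc(probs, y), probs = probs, folds = folds, labels = y)
}

.checkModuleCoverage <- function(x, moduleGenes, maxMissing = 0.5) {
    for (m in names(moduleGenes)) {
        frac <- mean(!moduleGenes[[m]] %in% rownames(x))
        if (frac > maxMissing)
            stop("module ", m, ": ", round(100 * frac),
                 "% of genes missing from cohort (limit ",
                 round(100 * maxMissing), "%)")
        if (frac > 0)
            message("module ", m, ": ",
                    sum(!moduleGenes[[m]] %in% rownames(x)),
                    " gene(s) missing from cohort, dropped")
    }
    lapply(moduleGenes, intersect, y = rownames(x))
}

#' External validation of the meta-gene classifier
#'
#' Module gene lists transfer between cohorts; meta-genes are recomputed as
#' PC1 within each cohort (the orientation rule makes signs comparable).
#' The logistic model is fitted on the training cohort's meta-genes (plus
#' optional ordinal covariates) and applied to the test cohort's
#' meta-genes; the ROC is computed on the test cohort. With covariates the
#' result reports the module terms' odds ratios and p-values within the
#' multivariate fit.
#'
#' @param train,test cohorts (\code{SummarizedExperiment}) or matrices.
#' @param moduleGenes named list of module gene vectors.
#' @param covariates character subset of \code{c("who_grade",
#'   "simpson_grade")}, encoded as numeric ordinals; samples missing a
#'   covariate are dropped from that model with a message.
#' @param trainPheno,testPheno phenotype tables when matrices are given.
#' @param maxMissing maximum tolerated fraction of module genes absent
#'   from either cohort.
#' @return list with \code{roc} (test-cohort \code{mm_roc}), \code{model}
#'   (fitted on train), \code{trainScores}, \code{testScores},
#'   \code{testProbs}.
#' @export
evaluateExternal <- function(train, test, moduleGenes, covariates = NULL,
                             trainPheno = NULL, testPheno = NULL,
                             maxMissing = 0.5) {
    xtr <- .exprs(train); xte <- .exprs(test)
    ptr <- .pheno(train, trainPheno); pte <- .pheno(test, testPheno)
    ptr <- ptr[match(colnames(xtr), ptr$sample_id), , drop = FALSE]
    pte <- pte[match(colnames(xte), pte$sample_id), , drop = FALSE]
    mgl <- .checkModuleCoverage(xtr, moduleGenes, maxMissing)
    mgl <- .checkModuleCoverage(xte, mgl, maxMissing)
    str <- as.data.frame(t(metageneScores(computeMetagenes(xtr, mgl))))
    ste <- as.data.frame(t(metageneScores(computeMetagenes(xte, mgl))))
    keepTr <- rep(TRUE, nrow(str)); keepTe <- rep(TRUE, nrow(ste))
    for (cv in covariates) {
        str[[cv]] <- as.numeric(ptr[[cv]])
        ste[[cv]] <- as.numeric(pte[[cv]])
        keepTr <- keepTr & !is.na(str[[cv]])
        keepTe <- keepTe & !is.na(ste[[cv]])
    }
    if (any(!keepTr) || any(!keepTe))
        message(sum(!keepTr) + sum(!keepTe),
                " sample(s) dropped for missing covariate(s)")
    m <- fitLogistic(ptr$recurrence[keepTr], str[keepTr, , drop = FALSE])
    pr <- predictProb(m, ste[keepTe, , drop = FALSE])
    list(roc = rocAuc(pr, pte$recurrence[keepTe]), model = m,
         trainScores = str, testScores = ste, testProbs = pr)
}

#' Classifier performance within one WHO-grade stratum
#'
#' Meta-genes and the logistic model come from the full cohort; evaluation
#' is restricted to the samples of the requested grade.
#'
#' @param x cohort or genes x samples matrix.
#' @param pheno phenotype table when a matrix is given.
#' @param moduleGenes named list of module gene vectors.
#' @param grade WHO grade value to stratify on.
#' @param model optional prefitted \code{mm_logistic}; default: fitted on
#'   the full cohort's meta-genes.
#' @return \code{mm_roc} for the stratum.
#' @export
stratifiedByGrade <- function(x, pheno = NULL, moduleGenes, grade,
                              model = NULL) {
    x0 <- .exprs(x)
    ph <- .pheno(x, pheno)
    ph <- ph[match(colnames(x0), ph$sample_id), , drop = FALSE]
    if (!grade %in% ph$who_grade)
        stop("WHO grade ", grade, " absent from cohort")
    sc <- as.data.frame(t(metageneScores(computeMetagenes(x0, moduleGenes))))
    if (is.null(model))
        model <- suppressWarnings(fitLogistic(ph$recurrence, sc))
    pr <- predictProb(model, sc)
    sel <- ph$who_grade == grade & !is.na(ph$who_grade)
    if (length(unique(ph$recurrence[sel])) < 2L)
        stop("single-class stratum for WHO grade ", grade,
             " (recurrence labels are rare in small strata)")
    rocAuc(pr[sel], ph$recurrence[sel])
}
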