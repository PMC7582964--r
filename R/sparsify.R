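## Module sparsification: rank module genes by individual predictive AUC,
## iteratively remove the top-ranked genes while recomputing the remaining
## module's meta-gene, and stop when the meta-gene AUC falls below a
## retention fraction of the full-module AUC (or a removal cap / module
## exhaustion). The removed genes form the "sparse module".

.foldAUC <- function(a) pmax(a, 1 - a)

#' Individual predictive AUC of each module gene
#'
#' Per-gene recurrence AUC, with a paired DeLong test of the gene against
#' the module meta-gene. For ranking, AUCs are direction-folded
#' (max(AUC, 1 - AUC)), since module genes may correlate negatively with
#' the meta-gene; the unfolded AUC is reported alongside. Ties in the
#' folded AUC are broken lexicographically by gene id.
#'
#' @param x genes x samples matrix or cohort.
#' @param genes module gene list.
#' @param pheno phenotype table when a matrix is given.
#' @param metagene optional per-sample meta-gene scores for the DeLong
#'   comparison; computed from \code{genes} if omitted.
#' @return data.frame sorted by descending folded AUC: gene, auc (folded),
#'   aucRaw, delongP.
#' @export
perGeneAuc <- function(x, genes, pheno = NULL, metagene = NULL) {
    x0 <- .exprs(x)
    ph <- .pheno(x, pheno)
    ph <- ph[match(colnames(x0), ph$sample_id), , drop = FALSE]
    y <- ph$recurrence
    if (length(unique(y)) < 2L) stop("both outcome classes required")
    absent <- setdiff(genes, rownames(x0))
    if (length(absent))
        message(length(absent), " gene(s) absent from matrix, skipped")
    genes <- intersect(genes, rownames(x0))
    if (is.null(metagene))
        metagene <- metageneScores(
            computeMetagenes(x0, list(module = genes)))["module", ]
    rows <- lapply(genes, function(g) {
        r <- rocAuc(x0[g, ], y)
        dl <- delongTest(x0[g, ], metagene, y)
        data.frame(gene = g, auc = .foldAUC(r$auc), aucRaw = r$auc,
                   delongP = dl$p.value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$auc, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Greedy module sparsification
#'
#' Removes module genes in descending order of individual (folded) AUC —
#' the static ranking from \code{\link{perGeneAuc}} unless \code{rerank}
#' re-ranks the survivors after every removal — recomputing the remaining
#' module's first-PC meta-gene and its AUC after each removal. Stops when
#' the meta-gene AUC drops below \code{threshold} times the full-module
#' AUC, after \code{cap} removals, or when fewer than 2 genes remain. The
#' sparse module is the ordered set of removed genes up to and including
#' the removal that crosses the threshold (\code{inclusive = FALSE}
#' excludes the crossing removal).
#'
#' @param x genes x samples matrix or cohort.
#' @param genes module gene list (>= 3 genes).
#' @param pheno phenotype table when a matrix is given.
#' @param threshold retention fraction of the full-module AUC (default
#'   0.90).
#' @param cap maximum removals (default 100).
#' @param rerank recompute the per-gene ranking among survivors after each
#'   removal instead of using the static full-module ranking.
#' @param inclusive include the threshold-crossing removal in the sparse
#'   set (default TRUE).
#' @param minFullAUC minimum folded full-module AUC below which the module
#'   is considered non-predictive and sparsification undefined.
#' @return a \code{\link{SparsificationTrace-class}}.
#' @export
sparsifyModule <- function(x, genes, pheno = NULL, threshold = 0.90,
                           cap = 100L, rerank = FALSE, inclusive = TRUE,
                           minFullAUC = 0.55) {
    x0 <- .exprs(x)
    ph <- .pheno(x, pheno)
    ph <- ph[match(colnames(x0), ph$sample_id), , drop = FALSE]
    y <- ph$recurrence
    genes <- intersect(genes, rownames(x0))
    if (length(genes) < 3L) stop("module needs >= 3 genes")
    metaAuc <- function(gs) {
        sc <- metageneScores(suppressMessages(
            computeMetagenes(x0, list(module = gs))))["module", ]
        .foldAUC(rocAuc(sc, y)$auc)
    }
    fullAUC <- metaAuc(genes)
    if (fullAUC <= minFullAUC)
        stop("module not predictive (folded AUC ", round(fullAUC, 3),
             " <= ", minFullAUC, "); sparsification undefined")
    floorAUC <- threshold * fullAUC
    ranking <- perGeneAuc(x0, genes, ph)$gene
    remaining <- genes
    removed <- character(0); aucTrace <- numeric(0)
    termination <- "exhausted"
    while (length(removed) < cap && length(remaining) > 2L) {
        nxt <- if (rerank && length(removed))
            perGeneAuc(x0, remaining, ph)$gene[1L]
        else ranking[length(removed) + 1L]
        remaining <- setdiff(remaining, nxt)
        removed <- c(removed, nxt)
        aucTrace <- c(aucTrace, metaAuc(remaining))
        if (aucTrace[length(aucTrace)] < floorAUC) {
            termination <- "threshold"
            break
        }
    }
    if (termination != "threshold" && length(removed) >= cap)
        termination <- "cap"
    sparse <- if (termination == "threshold" && !inclusive)
        removed[-length(removed)] else removed
    new("SparsificationTrace", removed = removed, aucTrace = aucTrace,
        fullAUC = fullAUC, threshold = threshold, cap = as.integer(cap),
        sparseSet = sparse, termination = termination)
}

#' Cross-cohort evaluation of sparse modules
#'
#' For every (sparse set, cohort) pair: recompute the sparse set's
#' meta-gene in that cohort, its recurrence AUC, and a paired DeLong test
#' against the full module's meta-gene in the same cohort; also reports
#' pairwise overlap counts between sparse sets.
#'
#' @param sparseSets named list of sparse gene sets (typically one per
#'   cohort they were derived on).
#' @param cohorts named list of cohorts (\code{SummarizedExperiment}).
#' @param fullModule the full module gene list.
#' @return list with \code{performance} (data.frame: sparseSet, cohort,
#'   auc, fullAuc, delongP, nGenes) and \code{overlap} (matrix of pairwise
#'   intersection sizes).
#' @export
evaluateSparseCrossCohort <- function(sparseSets, cohorts, fullModule) {
    stopifnot(length(cohorts) >= 2L, length(sparseSets) >= 1L)
    if (is.null(names(sparseSets)))
        names(sparseSets) <- sprintf("sparse%d", seq_along(sparseSets))
    if (is.null(names(cohorts)))
        names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
    rows <- list()
    for (ci in names(cohorts)) {
        x0 <- .exprs(cohorts[[ci]])
        ph <- .pheno(cohorts[[ci]])
        y <- ph[match(colnames(x0), ph$sample_id), "recurrence"]
        full <- metageneScores(suppressMessages(computeMetagenes(
            x0, list(full = intersect(fullModule, rownames(x0))))))["full", ]
        for (si in names(sparseSets)) {
            gs <- intersect(sparseSets[[si]], rownames(x0))
            flagged <- length(gs) < 2L
            sc <- if (flagged) {
                message("sparse set ", si, " has < 2 genes in ", ci,
                        "; single-gene score used (flagged)")
                x0[gs, ]
            } else metageneScores(suppressMessages(computeMetagenes(
                x0, list(s = gs))))["s", ]
            a <- .foldAUC(rocAuc(sc, y)$auc)
            dl <- delongTest(sc, full, y)
            rows[[paste(si, ci)]] <- data.frame(
                sparseSet = si, cohort = ci, nGenes = length(gs),
                auc = a, fullAuc = .foldAUC(dl$auc2), delongP = dl$p.value,
                flagged = flagged, stringsAsFactors = FALSE)
        }
    }
    ov <- outer(seq_along(sparseSets), seq_along(sparseSets),
                Vectorize(function(i, j)
                    length(intersect(sparseSets[[i]], sparseSets[[j]]))))
    dimnames(ov) <- list(names(sparseSets), names(sparseSets))
    perf <- do.call(rbind, rows)
    rownames(perf) <- NULL
    list(performance = perf, overlap = ov)
}
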