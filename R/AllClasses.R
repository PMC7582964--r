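#' @import methods
NULL

#' Gene-to-module partition
#'
#' Result of hybrid adaptive tree cutting of a co-expression dendrogram.
#' Every gene carries exactly one label; genes not absorbed by any module
#' carry the reserved label \code{"unassigned"}. Named modules are ordered by
#' size (largest first) and mapped onto the conventional WGCNA color
#' sequence (\code{turquoise}, \code{blue}, \code{brown}, ...).
#'
#' @slot labels named character vector, gene id -> module label.
#' @slot params list of tree-cut parameters used (minSize, deepSplit,
#'   maxHeight, pamStage).
#' @export
setClass("ModulePartition",
    representation(labels = "character", params = "list"))

setValidity("ModulePartition", function(object) {
    lab <- object@labels
    if (length(lab) == 0L) return("empty partition")
    if (is.null(names(lab)) || anyDuplicated(names(lab)))
        return("labels must be uniquely named by gene id")
    if (any(is.na(lab) | lab == ""))
        return("every gene must carry a label ('unassigned' is the reserved label)")
    TRUE
})

#' Module meta-genes (first-principal-component summaries)
#'
#' Per-module first principal component scores across samples, each scaled
#' to unit variance and oriented so that the meta-gene correlates positively
#' with the mean of the module genes' standardized expression. Stores the
#' per-gene centering/scaling and PC loadings so that new samples can be
#' projected onto a previously fitted meta-gene (used by strict
#' cross-validation).
#'
#' @slot scores numeric matrix, modules x samples; unit variance per row.
#' @slot varExplained named numeric, proportion of (standardized) module
#'   variance captured by the first component.
#' @slot loadings list per module: \code{genes}, \code{center}, \code{scale},
#'   \code{w} (unit loading vector), \code{sdRaw} (training score scale).
#' @slot dropped list per module of genes dropped (zero variance / absent).
#' @export
setClass("MetageneSet",
    representation(scores = "matrix", varExplained = "numeric",
                   loadings = "list", dropped = "list"))

setValidity("MetageneSet", function(object) {
    s <- object@scores
    if (is.null(rownames(s)) || is.null(colnames(s)))
        return("scores must have module rownames and sample colnames")
    if (anyDuplicated(rownames(s))) return("duplicate module labels")
    v <- apply(s, 1L, stats::var)
    if (any(abs(v - 1) > 1e-6))
        return("meta-gene scores must have unit variance per module")
    if (!setequal(rownames(s), names(object@varExplained)))
        return("varExplained must be named by module")
    TRUE
})

#' Trace of greedy module sparsification
#'
#' Record of iteratively removing a module's most individually predictive
#' genes (descending single-gene AUC) while recomputing the meta-gene of the
#' remaining genes, until the meta-gene AUC falls below a retention fraction
#' of the full-module AUC, a removal cap is reached, or the module is
#' exhausted. The removed genes up to the stopping point form the sparse
#' module.
#'
#' @slot removed ordered character vector of removed gene ids.
#' @slot aucTrace numeric, meta-gene AUC after each removal.
#' @slot fullAUC numeric(1), AUC of the intact module meta-gene.
#' @slot threshold numeric(1), retention fraction in (0,1].
#' @slot cap integer(1), maximum number of removals.
#' @slot sparseSet character, the sparse-module gene set.
#' @slot termination one of "threshold", "cap", "exhausted".
#' @export
setClass("SparsificationTrace",
    representation(removed = "character", aucTrace = "numeric",
                   fullAUC = "numeric", threshold = "numeric",
                   cap = "integer", sparseSet = "character",
                   termination = "character"))

setValidity("SparsificationTrace", function(object) {
    if (length(object@removed) != length(object@aucTrace))
        return("removed and aucTrace lengths differ")
    if (length(object@removed) > object@cap)
        return("trace longer than cap")
    if (!all(object@sparseSet %in% object@removed))
        return("sparse set must be a subset of removed genes")
    if (object@threshold <= 0 || object@threshold > 1)
        return("threshold must lie in (0, 1]")
    if (!object@termination %in% c("threshold", "cap", "exhausted"))
        return("unknown termination reason")
    TRUE
})

setMethod("show", "ModulePartition", function(object) {
    sz <- moduleSizes(object)
    cat("ModulePartition over", length(object@labels), "genes\n")
    n.un <- sum(object@labels == "unassigned")
    named <- sz[names(sz) != "unassigned"]
    cat(" ", length(named), "modules:",
        paste0(names(named), " (", named, ")", collapse = ", "), "\n")
    cat("  unassigned:", n.un, "\n")
})

setMethod("show", "MetageneSet", function(object) {
    cat("MetageneSet:", nrow(object@scores), "modules x",
        ncol(object@scores), "samples\n")
    cat("  variance explained:",
        paste0(names(object@varExplained), "=",
               sprintf("%.2f", object@varExplained), collapse = ", "), "\n")
})

setMethod("show", "SparsificationTrace", function(object) {
    cat("SparsificationTrace:", length(object@removed), "removals,",
        "full AUC", sprintf("%.3f", object@fullAUC), "\n")
    cat("  sparse module:", length(object@sparseSet), "genes;",
        "termination:", object@termination, "\n")
})

#' @describeIn ModulePartition-class gene -> module label vector
#' @param x a \code{ModulePartition}
#' @export
moduleLabels <- function(x) {
    stopifnot(is(x, "ModulePartition"))
    x@labels
}

#' @describeIn ModulePartition-class module sizes, largest first
#' @export
moduleSizes <- function(x) {
    stopifnot(is(x, "ModulePartition"))
    tab <- table(x@labels)
    named <- sort(tab[names(tab) != "unassigned"], decreasing = TRUE)
    out <- as.integer(named)
    names(out) <- names(named)
    if ("unassigned" %in% names(tab))
        out <- c(out, unassigned = as.integer(tab[["unassigned"]]))
    out
}

#' @describeIn ModulePartition-class gene ids belonging to one module
#' @param module module label
#' @export
moduleGenes <- function(x, module) {
    stopifnot(is(x, "ModulePartition"))
    names(x@labels)[x@labels == module]
}

#' @describeIn MetageneSet-class modules x samples score matrix
#' @param x a \code{MetageneSet}
#' @export
metageneScores <- function(x) {
    stopifnot(is(x, "MetageneSet"))
    x@scores
}

#' @describeIn MetageneSet-class per-module proportion of variance explained
#' @export
varExplained <- function(x) {
    stopifnot(is(x, "MetageneSet"))
    x@varExplained
}

#' @describeIn SparsificationTrace-class the sparse-module gene set
#' @param x a \code{SparsificationTrace}
#' @export
sparseGenes <- function(x) {
    stopifnot(is(x, "SparsificationTrace"))
    x@sparseSet
}
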