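## First-principal-component module summaries ("meta-genes") and module
## membership (kME). Meta-genes are recomputed within each cohort from the
## module gene lists; loadings are retained so strict cross-validation can
## project held-out samples onto training-only components.

.fitMetagene <- function(xm) {
    # xm: module genes x samples, already restricted to usable genes
    center <- rowMeans(xm)
    scl <- apply(xm, 1L, stats::sd)
    z <- (xm - center) / scl
    sv <- svd(z, nu = 1L, nv = 1L)
    w <- sv$u[, 1L]
    raw <- drop(crossprod(z, w))          # sample scores along PC1
    sdRaw <- stats::sd(raw)
    score <- raw / sdRaw
    # orient positively against the mean standardized module profile
    sgn <- if (stats::cor(score, colMeans(z)) < 0) -1 else 1
    list(score = sgn * score,
         varExplained = sv$d[1L]^2 / sum(sv$d^2),
         loading = list(genes = rownames(xm), center = center, scale = scl,
                        w = sgn * w, sdRaw = sdRaw))
}

#' Compute module meta-genes (first principal components)
#'
#' Per module: member gene rows are standardized (mean 0, sd 1 across
#' samples), the first principal component's sample scores are scaled to
#' unit variance, and the sign is chosen so the meta-gene correlates
#' positively with the mean standardized module profile (making signs
#' comparable across cohorts). Zero-variance genes are dropped from the
#' PCA with a message; a module reduced below 2 genes is an error.
#'
#' @param x genes x samples matrix or cohort.
#' @param partition a \code{\link{ModulePartition-class}}, or a named list
#'   of module gene vectors (gene lists transferred from a discovery
#'   cohort).
#' @param modules optional subset of module labels to summarize; default:
#'   all named modules (never \code{"unassigned"}).
#' @return a \code{\link{MetageneSet-class}}.
#' @export
computeMetagenes <- function(x, partition, modules = NULL) {
    x0 <- .exprs(x)
    geneLists <- if (is(partition, "ModulePartition")) {
        labs <- setdiff(unique(partition@labels), "unassigned")
        stats::setNames(lapply(labs, function(m) moduleGenes(partition, m)),
                        labs)
    } else {
        stopifnot(is.list(partition), !is.null(names(partition)))
        partition
    }
    if (!is.null(modules)) geneLists <- geneLists[modules]
    if (length(geneLists) == 0L) stop("no modules to summarize")

    scores <- matrix(NA_real_, nrow = length(geneLists), ncol = ncol(x0),
                     dimnames = list(names(geneLists), colnames(x0)))
    ve <- stats::setNames(numeric(length(geneLists)), names(geneLists))
    loadings <- dropped <- stats::setNames(vector("list", length(geneLists)),
                                           names(geneLists))
    for (m in names(geneLists)) {
        genes <- geneLists[[m]]
        absent <- setdiff(genes, rownames(x0))
        present <- intersect(genes, rownames(x0))
        xm <- x0[present, , drop = FALSE]
        zeroVar <- present[apply(xm, 1L, stats::sd) == 0]
        usable <- setdiff(present, zeroVar)
        drop <- c(absent, zeroVar)
        if (length(drop))
            message("module ", m, ": ", length(drop),
                    " gene(s) dropped (absent or zero variance)")
        if (length(usable) < 2L)
            stop("module ", m, " has fewer than 2 usable genes")
        fit <- .fitMetagene(x0[usable, , drop = FALSE])
        scores[m, ] <- fit$score
        ve[m] <- fit$varExplained
        loadings[[m]] <- fit$loading
        dropped[[m]] <- drop
    }
    new("MetageneSet", scores = scores, varExplained = ve,
        loadings = loadings, dropped = dropped)
}

#' Project new samples onto previously fitted meta-genes
#'
#' Standardizes the new samples' module genes with the training centers and
#' scales, projects onto the stored loading vectors, and applies the
#' training score scale. Used by strict cross-validation, where held-out
#' samples must not influence loading estimation.
#'
#' @param x genes x samples matrix of the new samples.
#' @param mg a fitted \code{\link{MetageneSet-class}}.
#' @return modules x samples score matrix on the training scale.
#' @export
projectMetagenes <- function(x, mg) {
    stopifnot(is(mg, "MetageneSet"))
    x0 <- .exprs(x)
    out <- matrix(NA_real_, nrow = nrow(mg@scores), ncol = ncol(x0),
                  dimnames = list(rownames(mg@scores), colnames(x0)))
    for (m in rownames(mg@scores)) {
        ld <- mg@loadings[[m]]
        miss <- setdiff(ld$genes, rownames(x0))
        if (length(miss)) stop("module ", m, " gene(s) absent: ",
                               paste(utils::head(miss, 5L), collapse = ", "))
        z <- (x0[ld$genes, , drop = FALSE] - ld$center) / ld$scale
        out[m, ] <- drop(crossprod(z, ld$w)) / ld$sdRaw
    }
    out
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module
#' meta-gene. Zero-variance genes get NA with a message.
#'
#' @param x genes x samples matrix or cohort.
#' @param mg a \code{\link{MetageneSet-class}} on the same samples.
#' @param genes optional gene subset (default: all genes in \code{x}).
#' @return genes x modules correlation matrix in [-1, 1].
#' @export
computeKME <- function(x, mg, genes = NULL) {
    stopifnot(is(mg, "MetageneSet"))
    x0 <- .exprs(x)
    if (!identical(colnames(x0), colnames(mg@scores)))
        stop("samples of expression and meta-genes differ")
    if (!is.null(genes)) x0 <- x0[intersect(genes, rownames(x0)), ,
                                  drop = FALSE]
    v <- apply(x0, 1L, stats::sd)
    kme <- matrix(NA_real_, nrow = nrow(x0), ncol = nrow(mg@scores),
                  dimnames = list(rownames(x0), rownames(mg@scores)))
    ok <- v > 0
    if (any(!ok)) message(sum(!ok), " zero-variance gene(s): kME is NA")
    if (any(ok))
        kme[ok, ] <- stats::cor(t(x0[ok, , drop = FALSE]), t(mg@scores))
    kme
}
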