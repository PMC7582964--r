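## Normalization and cohort merging. The canonical chain is
## log2 -> quantile -> merge -> batch-correct; each function stamps the
## matrix with stage metadata and refuses to run after a later stage.

.stageOrder <- c(log2 = 1L, quantile = 2L, merge = 3L, batch = 4L)

.stageCheck <- function(x, stage) {
    done <- attr(x, "stages")
    if (any(.stageOrder[done] > .stageOrder[[stage]]))
        stop("preprocessing stage '", stage, "' requested after later ",
             "stage(s): ", paste(done, collapse = " -> "))
    invisible(NULL)
}

.stageStamp <- function(x, stage, from = NULL) {
    attr(x, "stages") <- c(attr(from, "stages"), stage)
    x
}

#' Elementwise log2 transform
#'
#' @param x genes x samples numeric matrix on linear scale.
#' @param offset non-negative pseudocount added before the log.
#' @return log2(x + offset), same dimnames.
#' @export
log2Transform <- function(x, offset = 0) {
    x0 <- .exprs(x)
    .stageCheck(x0, "log2")
    if (offset < 0) stop("offset must be non-negative")
    bad <- which(x0 + offset <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        off <- apply(utils::head(bad, 5L), 1L, function(i)
            paste0(rownames(x0)[i[1L]], "/", colnames(x0)[i[2L]]))
        stop("non-positive value(s) after offset at: ",
             paste(off, collapse = ", "),
             if (nrow(bad) > 5L) paste0(" (+", nrow(bad) - 5L, " more)"))
    }
    .stageStamp(log2(x0 + offset), "log2", x0)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) onto the common distribution of per-rank
#' cross-sample means; ties within a column receive the mean of the
#' reference values at their tied ranks. Delegates to
#' \code{limma::normalizeQuantiles} (ties = TRUE), the standard microarray
#' implementation of exactly this convention.
#'
#' @param x genes x samples matrix, no missing values.
#' @return normalized matrix; after normalization all column-sorted value
#'   vectors are identical.
#' @export
quantileNormalize <- function(x) {
    x0 <- .exprs(x)
    .stageCheck(x0, "quantile")
    if (ncol(x0) < 2L) {
        warning("single-sample matrix: quantile normalization is a no-op")
        return(.stageStamp(x0, "quantile", x0))
    }
    out <- limma::normalizeQuantiles(x0, ties = TRUE)
    dimnames(out) <- dimnames(x0)
    .stageStamp(out, "quantile", x0)
}

#' Per-array median scaling
#'
#' Divides each sample by the 50th percentile of its own values, an
#' alternative array-level normalization offered for fidelity with cohorts
#' preprocessed that way; not part of the default chain.
#'
#' @param x genes x samples matrix (linear or log scale as the caller
#'   intends).
#' @return scaled matrix.
#' @export
medianScale <- function(x) {
    x0 <- .exprs(x)
    med <- apply(x0, 2L, stats::median)
    if (any(med == 0)) stop("zero median in sample(s): ",
                            paste(colnames(x0)[med == 0], collapse = ", "))
    sweep(x0, 2L, med, "/")
}

#' Merge cohorts on their shared gene universe
#'
#' Restricts all matrices to the intersection of gene ids, concatenates
#' samples, and attaches batch labels. Duplicate sample ids across cohorts
#' are suffixed with their batch label.
#'
#' @param xs list of genes x samples matrices.
#' @param batches one label per cohort (defaults to list names or B1..Bk).
#' @return merged matrix with attribute \code{"batch"} giving the
#'   per-sample cohort label.
#' @export
mergeCohorts <- function(xs, batches = NULL) {
    stopifnot(is.list(xs), length(xs) >= 1L)
    xs <- lapply(xs, .exprs)
    for (x in xs) .stageCheck(x, "merge")
    if (is.null(batches))
        batches <- if (!is.null(names(xs))) names(xs)
                   else sprintf("B%d", seq_along(xs))
    stopifnot(length(batches) == length(xs))
    common <- Reduce(intersect, lapply(xs, rownames))
    if (length(common) == 0L) stop("empty gene intersection across cohorts")
    dropped <- sum(vapply(xs, nrow, 1L)) - length(common) * length(xs)
    if (dropped > 0L)
        message(dropped, " gene row(s) outside the intersection dropped")
    parts <- Map(function(x, b) {
        x <- x[common, , drop = FALSE]
        colnames(x) <- paste0(colnames(x), "")
        x
    }, xs, batches)
    ids <- unlist(lapply(parts, colnames), use.names = FALSE)
    lab <- rep(batches, vapply(parts, ncol, 1L))
    if (anyDuplicated(ids)) {
        message("duplicate sample ids across cohorts suffixed with batch")
        ids <- ifelse(ids %in% ids[duplicated(ids)] | duplicated(ids),
                      paste0(ids, ".", lab), ids)
    }
    out <- do.call(cbind, parts)
    colnames(out) <- ids
    attr(out, "batch") <- stats::setNames(lab, ids)
    .stageStamp(out, "merge", xs[[1L]])
}

#' Batch-effect correction
#'
#' Aligns per-gene batch means to the pooled mean and batch variances to
#' the pooled variance. \code{"eb-shrinkage"} (default) uses the parametric
#' empirical-Bayes model of \code{sva::ComBat}, shrinking per-gene batch
#' location/scale estimates toward across-gene priors; \code{"location-scale"}
#' is the transparent per-gene standardize-and-restore fallback, which
#' leaves the pooled per-gene mean unchanged.
#'
#' @param x genes x samples matrix (or merged matrix carrying a
#'   \code{"batch"} attribute).
#' @param batches per-sample batch labels; taken from \code{attr(x,
#'   "batch")} when omitted.
#' @param mode \code{"eb-shrinkage"} or \code{"location-scale"}.
#' @return corrected matrix.
#' @export
batchCorrect <- function(x, batches = NULL,
                         mode = c("eb-shrinkage", "location-scale")) {
    mode <- match.arg(mode)
    x0 <- .exprs(x)
    .stageCheck(x0, "batch")
    if (is.null(batches)) batches <- attr(x0, "batch")
    if (is.null(batches)) stop("batch labels required")
    batches <- as.character(batches)
    stopifnot(length(batches) == ncol(x0))
    tab <- table(batches)
    if (length(tab) < 2L) stop("need >= 2 batches")
    if (any(tab < 2L))
        stop("batch(es) with a single sample: ",
             paste(names(tab)[tab < 2L], collapse = ", "))
    if (mode == "eb-shrinkage") {
        out <- suppressMessages(sva::ComBat(dat = x0, batch = batches))
        dimnames(out) <- dimnames(x0)
        return(.stageStamp(out, "batch", x0))
    }
    out <- x0
    pooledMean <- rowMeans(x0)
    pooledSD <- apply(x0, 1L, stats::sd)
    nSkipped <- 0L
    for (b in names(tab)) {
        j <- which(batches == b)
        bm <- rowMeans(x0[, j, drop = FALSE])
        bs <- apply(x0[, j, drop = FALSE], 1L, stats::sd)
        zero <- bs == 0 | pooledSD == 0
        nSkipped <- nSkipped + sum(zero)
        ratio <- ifelse(zero, 1, pooledSD / bs)
        out[, j] <- (x0[, j, drop = FALSE] - bm) * ratio + pooledMean
    }
    if (nSkipped > 0L)
        message("scale step skipped for ", nSkipped,
                " zero-variance gene-batch combination(s)")
    # location-scale recentres every batch on the pooled mean, so the
    # pooled per-gene mean is preserved exactly
    attr(out, "batch") <- stats::setNames(batches, colnames(out))
    .stageStamp(out, "batch", x0)
}
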