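## Weighted co-expression network construction: soft-thresholded Pearson
## adjacency, scale-free power selection, topological overlap, average-
## linkage clustering and hybrid adaptive tree cut.

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned: a_ij = |cor(x_i, x_j)|^power; signed: a_ij =
#' ((1 + cor)/2)^power. The diagonal is forced to 1.
#'
#' @param x genes x samples matrix (>= 3 samples).
#' @param power natural-number soft threshold.
#' @param signMode \code{"unsigned"} (default, the historical convention)
#'   or \code{"signed"}.
#' @param zeroVariance \code{"error"} (default) or \code{"drop"} genes with
#'   zero variance.
#' @return symmetric adjacency matrix in [0,1] with attributes
#'   \code{"power"} and \code{"signMode"}.
#' @export
adjacencyMatrix <- function(x, power = 6L,
                            signMode = c("unsigned", "signed"),
                            zeroVariance = c("error", "drop")) {
    signMode <- match.arg(signMode)
    zeroVariance <- match.arg(zeroVariance)
    x0 <- .exprs(x)
    if (ncol(x0) < 3L) stop("need >= 3 samples")
    if (power < 1 || power != round(power)) stop("power must be a natural number")
    v <- apply(x0, 1L, stats::var)
    if (any(v == 0)) {
        bad <- rownames(x0)[v == 0]
        if (zeroVariance == "error")
            stop("zero-variance gene(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
        message(length(bad), " zero-variance gene(s) dropped")
        x0 <- x0[v > 0, , drop = FALSE]
    }
    r <- stats::cor(t(x0))
    a <- if (signMode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
    diag(a) <- 1
    attr(a, "power") <- as.integer(power)
    attr(a, "signMode") <- signMode
    a
}

.scaleFreeFit <- function(k, nBins = 10L) {
    # equal-width binning of connectivity, log10(p(k)) regressed on
    # log10(mean k per bin); scale-free topology shows a straight line
    # with negative slope
    k <- k[k > 0]
    if (length(k) < nBins) return(c(r2 = NA_real_, slope = NA_real_))
    br <- seq(min(k), max(k), length.out = nBins + 1L)
    br[1L] <- br[1L] - 1e-9
    bin <- cut(k, br, labels = FALSE)
    freq <- tabulate(bin, nBins) / length(k)
    meanK <- vapply(seq_len(nBins), function(b)
        if (freq[b] > 0) mean(k[bin == b]) else NA_real_, numeric(1L))
    ok <- freq > 0 & meanK > 0
    if (sum(ok) < 3L) return(c(r2 = NA_real_, slope = NA_real_))
    fit <- stats::lm(log10(freq[ok]) ~ log10(meanK[ok]))
    c(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power, builds the adjacency, computes per-gene
#' connectivity k_i = sum_{j != i} a_ij, and regresses the log-binned
#' degree distribution; returns the lowest candidate whose fit reaches the
#' target r-squared with a negative slope. If no candidate reaches the
#' target, the candidate maximizing r-squared is returned flagged
#' \code{targetMet = FALSE} (never silently picked).
#'
#' @param x genes x samples matrix.
#' @param candidates ascending natural-number candidate powers.
#' @param targetR2 scale-free fit target (default 0.9).
#' @param signMode passed to \code{\link{adjacencyMatrix}}.
#' @param nBins equal-width connectivity bins for the degree regression.
#' @return list with \code{power}, \code{targetMet}, and \code{fits} (a
#'   data.frame of power, r2, slope, meanConnectivity).
#' @export
pickSoftThreshold <- function(x, candidates = 1:20, targetR2 = 0.9,
                              signMode = c("unsigned", "signed"),
                              nBins = 10L) {
    signMode <- match.arg(signMode)
    stopifnot(length(candidates) >= 1L, !is.unsorted(candidates))
    x0 <- .exprs(x)
    r <- stats::cor(t(x0))
    base <- if (signMode == "unsigned") abs(r) else (1 + r) / 2
    diag(base) <- 0     # exclude self from connectivity
    fits <- t(vapply(candidates, function(b) {
        k <- rowSums(base^b)
        f <- .scaleFreeFit(k, nBins)
        c(power = b, f, meanConnectivity = mean(k))
    }, numeric(4L)))
    fits <- as.data.frame(fits)
    hit <- which(!is.na(fits$r2) & fits$r2 >= targetR2 & fits$slope < 0)
    if (length(hit)) {
        list(power = as.integer(fits$power[hit[1L]]), targetMet = TRUE,
             fits = fits)
    } else {
        best <- which.max(ifelse(is.na(fits$r2), -Inf, fits$r2))
        warning("scale-free target r2 >= ", targetR2,
                " not met; best candidate returned flagged")
        list(power = as.integer(fits$power[best]), targetMet = FALSE,
             fits = fits)
    }
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
#' with k_i = sum_{u != i} a_iu, for i != j; diagonal 1. Similarity grows
#' with shared neighborhood, not just the direct edge.
#'
#' @param a symmetric adjacency in [0,1] with unit diagonal.
#' @return TOM matrix; \code{1 - TOM} is the clustering dissimilarity.
#' @export
topologicalOverlap <- function(a) {
    stopifnot(is.matrix(a), nrow(a) == ncol(a))
    if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
    if (any(a < -1e-12 | a > 1 + 1e-12)) stop("adjacency entries outside [0,1]")
    k <- rowSums(a) - diag(a)
    L <- a %*% a                      # L_ij includes u = i and u = j terms
    num <- L - 2 * a + a              # subtract a_ii*a_ij + a_ij*a_jj, add a_ij
    den <- outer(k, k, pmin) + 1 - a
    tom <- num / den
    diag(tom) <- 1
    dimnames(tom) <- dimnames(a)
    tom
}

#' Average-linkage dendrogram of a dissimilarity matrix
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (typically
#'   \code{1 - TOM}).
#' @return an \code{hclust} tree (merge heights non-decreasing).
#' @export
clusterDendrogram <- function(d) {
    stopifnot(is.matrix(d), nrow(d) == ncol(d))
    if (anyNA(d)) stop("NaN/NA dissimilarity")
    if (max(abs(d - t(d))) > 1e-10) stop("dissimilarity must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("dissimilarity diagonal must be zero")
    stats::hclust(stats::as.dist(d), method = "average")
}

.wgcnaColors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                  "black", "pink", "magenta", "purple", "greenyellow",
                  "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                  "grey60", "lightgreen", "lightyellow", "royalblue")

## leaf sets for every internal node of an hclust tree
.nodeLeaves <- function(hc) {
    n <- length(hc$height)
    leaves <- vector("list", n)
    for (i in seq_len(n)) {
        kids <- hc$merge[i, ]
        leaves[[i]] <- c(if (kids[1L] < 0) -kids[1L] else leaves[[kids[1L]]],
                         if (kids[2L] < 0) -kids[2L] else leaves[[kids[2L]]])
    }
    leaves
}

#' Hybrid adaptive tree cut
#'
#' Two-stage dynamic-hybrid module detection. Stage 1 walks the dendrogram
#' from the root and accepts a branch as a candidate cluster only when its
#' internal merge heights are tight: the branch top must fall below a
#' core-scatter bound interpolated between the dendrogram's low reference
#' height and the cut height, with \code{deepSplit} (0 = conservative ..
#' 4 = aggressive) moving the bound upward. Branches joining above the
#' bound keep splitting, so loose chains of stragglers peel off instead of
#' being absorbed. Surviving branches of size >= \code{minSize} become
#' modules; everything else is pooled.
#' Stage 2 (\code{pamStage = TRUE}, the default) assigns each pooled gene
#' to the module with the smallest average dissimilarity, provided it is
#' strictly closer to that module than to any other; remaining genes are
#' labelled \code{"unassigned"}. Modules are ordered by size and named by
#' the conventional color sequence (turquoise, blue, ...).
#'
#' @param dend \code{hclust} tree from \code{\link{clusterDendrogram}}.
#' @param d the dissimilarity matrix the tree was built on (used by the
#'   assignment stage).
#' @param minSize minimum module size (>= 2).
#' @param deepSplit split aggressiveness, integer 0-4.
#' @param maxHeight cut height as a fraction of the dendrogram height
#'   range.
#' @param pamStage logical; run the stage-2 nearest-module assignment.
#' @return a \code{\link{ModulePartition-class}} object.
#' @export
cutModules <- function(dend, d, minSize = 20L, deepSplit = 2L,
                       maxHeight = 0.99, pamStage = TRUE) {
    stopifnot(inherits(dend, "hclust"))
    if (minSize < 2L) stop("minSize must be >= 2")
    if (!deepSplit %in% 0:4) stop("deepSplit must be an integer in 0..4")
    genes <- dend$labels
    if (is.null(genes)) genes <- as.character(seq_along(dend$order))
    stopifnot(nrow(d) == length(genes))
    if (!is.null(rownames(d))) d <- d[genes, genes]

    h <- dend$height
    rng <- max(h) - min(h)
    labels <- rep("unassigned", length(genes))
    names(labels) <- genes

    if (rng == 0) {
        # degenerate flat tree: everything is one module
        labels[] <- .wgcnaColors[1L]
        return(new("ModulePartition", labels = labels,
                   params = list(minSize = minSize, deepSplit = deepSplit,
                                 maxHeight = maxHeight, pamStage = pamStage)))
    }
    cutAbs <- min(h) + maxHeight * rng
    ref <- stats::quantile(h, 0.05, names = FALSE)
    # core-scatter bound between the reference and cut heights, widened by
    # deepSplit (after the dynamic-hybrid convention)
    coreFrac <- 0.64 + deepSplit * (0.96 - 0.64) / 4
    scatterAbs <- ref + coreFrac * (cutAbs - ref)
    leaves <- .nodeLeaves(dend)

    # a straggler joining a tight branch far above the branch's own top is
    # peeled off rather than absorbed
    minGap <- (1 - coreFrac) * (cutAbs - ref) / 2
    nodeHeight <- function(k) if (k < 0) 0 else h[k]

    clusters <- list()
    descend <- function(node) {
        if (node < 0) { clusters[[length(clusters) + 1L]] <<- -node; return() }
        kids <- dend$merge[node, ]
        gap <- h[node] - max(nodeHeight(kids[1L]), nodeHeight(kids[2L]))
        sizes <- vapply(kids, function(k)
            if (k < 0) 1L else length(leaves[[k]]), 1L)
        # the gap rule only peels stragglers (sub-minSize side branches);
        # it never splits two well-formed sub-branches
        straggler <- min(sizes) < minSize && gap > minGap
        if (h[node] <= scatterAbs && h[node] <= cutAbs && !straggler) {
            clusters[[length(clusters) + 1L]] <<- leaves[[node]]
        } else {
            descend(kids[1L]); descend(kids[2L])
        }
    }
    descend(length(h))

    cores <- Filter(function(cl) length(cl) >= minSize, clusters)
    if (length(cores)) {
        cores <- cores[order(vapply(cores, length, 1L), decreasing = TRUE)]
        nm <- c(.wgcnaColors,
                sprintf("M%d", seq_len(max(0L, length(cores) -
                                              length(.wgcnaColors)))))
        for (i in seq_along(cores)) labels[cores[[i]]] <- nm[i]
        if (pamStage) {
            un <- which(labels == "unassigned")
            if (length(un)) {
                avg <- vapply(seq_along(cores), function(i)
                    rowMeans(d[un, cores[[i]], drop = FALSE]),
                    numeric(length(un)))
                avg <- matrix(avg, nrow = length(un))
                for (r in seq_along(un)) {
                    o <- order(avg[r, ])
                    if (length(cores) == 1L ||
                        avg[r, o[1L]] < avg[r, o[2L]])
                        labels[un[r]] <- nm[o[1L]]
                }
            }
        }
    }
    new("ModulePartition", labels = labels,
        params = list(minSize = as.integer(minSize),
                      deepSplit = as.integer(deepSplit),
                      maxHeight = maxHeight, pamStage = pamStage))
}

#' Discover modules from an expression matrix in one call
#'
#' Convenience chain: pick the soft threshold (unless \code{power} is
#' given), build the adjacency and TOM, cluster 1 - TOM, and cut modules.
#'
#' @param x genes x samples matrix or cohort.
#' @param power soft threshold; \code{NULL} selects it by scale-free fit.
#' @param candidates candidate powers for automatic selection.
#' @param signMode network sign mode.
#' @param minSize,deepSplit,maxHeight,pamStage tree-cut parameters.
#' @param targetR2 scale-free fit target.
#' @return list with \code{partition}, \code{power}, \code{fits} (NULL if
#'   power was given), \code{dendrogram}, and \code{dissimilarity}.
#' @export
discoverModules <- function(x, power = NULL, candidates = 1:12,
                            signMode = c("unsigned", "signed"),
                            minSize = 20L, deepSplit = 2L, maxHeight = 0.99,
                            pamStage = TRUE, targetR2 = 0.9) {
    signMode <- match.arg(signMode)
    x0 <- .exprs(x)
    fits <- NULL
    if (is.null(power)) {
        pk <- pickSoftThreshold(x0, candidates, targetR2, signMode)
        power <- pk$power
        fits <- pk$fits
    }
    a <- adjacencyMatrix(x0, power, signMode)
    tom <- topologicalOverlap(a)
    diss <- 1 - tom
    diag(diss) <- 0
    dend <- clusterDendrogram(diss)
    part <- cutModules(dend, diss, minSize = minSize, deepSplit = deepSplit,
                       maxHeight = maxHeight, pamStage = pamStage)
    list(partition = part, power = as.integer(power), fits = fits,
         dendrogram = dend, dissimilarity = diss)
}
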