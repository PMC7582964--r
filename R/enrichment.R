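## Local over-representation analysis over GMT gene-set libraries:
## hypergeometric upper-tail p-values with Benjamini-Hochberg adjustment.
## Gene symbols are matched case-insensitively.

#' Gene-set over-representation test
#'
#' For each library term: with N universe genes, K term genes in the
#' universe, m module genes and k overlapping genes, the one-sided p-value
#' is P(X >= k) for X ~ Hypergeometric(N, K, m) (Fisher's exact
#' over-representation). Benjamini-Hochberg q-values are computed across
#' all terms of the library; results are ranked by q, then p, then term.
#'
#' @param moduleGenes character vector of module gene symbols.
#' @param library named list of term gene sets (see \code{\link{readGmt}}).
#' @param universe background gene list (e.g. all genes on the platform);
#'   must cover the module genes.
#' @return data.frame: term, k (overlap), m (module size in universe),
#'   K (term size in universe), N, p, q, overlapGenes.
#' @export
overrepresentationTest <- function(moduleGenes, library, universe) {
    uni <- unique(toupper(universe))
    mod <- unique(toupper(moduleGenes))
    if (!all(mod %in% uni))
        stop("module genes outside the universe: ",
             paste(utils::head(setdiff(mod, uni), 5L), collapse = ", "))
    mod <- intersect(mod, uni)
    if (length(mod) == 0L) stop("empty module-universe intersection")
    N <- length(uni); m <- length(mod)
    rows <- lapply(names(library), function(term) {
        tg <- intersect(unique(toupper(library[[term]])), uni)
        K <- length(tg)
        hit <- intersect(mod, tg)
        k <- length(hit)
        p <- if (K == 0L) 1 else
            stats::phyper(k - 1L, K, N - K, m, lower.tail = FALSE)
        data.frame(term = term, k = k, m = m, K = K, N = N, p = p,
                   overlapGenes = paste(sort(hit), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$q, out$p, out$term),
               c("term", "k", "m", "K", "N", "p", "q", "overlapGenes")]
    rownames(out) <- NULL
    out
}

#' Rank enrichment results
#'
#' Top terms by ascending q (ties broken by p, then term name);
#' \code{by = "neglog10q"} additionally attaches -log10(q) for plotting.
#'
#' @param results data.frame from \code{\link{overrepresentationTest}}.
#' @param topN how many terms to keep.
#' @param by \code{"q"} or \code{"neglog10q"}.
#' @return ranked subset of \code{results}.
#' @export
rankTerms <- function(results, topN = 5L, by = c("q", "neglog10q")) {
    by <- match.arg(by)
    if (nrow(results) == 0L) stop("empty results")
    if (topN <= 0L) stop("topN must be positive")
    out <- results[order(results$q, results$p, results$term), , drop = FALSE]
    out <- utils::head(out, topN)
    if (by == "neglog10q") out$neglog10q <- -log10(out$q)
    rownames(out) <- NULL
    out
}
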