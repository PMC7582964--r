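# Independent oracle implementations used across tests. These stay
# deliberately naive (loops, pair counting) so they cannot share a defect
# with the vectorized implementations they check.

# AUC by explicit positive-negative pair counting, ties get half credit
pairCountAUC <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (a in pos) for (b in neg)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}

# topological overlap by the literal triple-loop formula
bruteTOM <- function(a) {
    n <- nrow(a)
    k <- rowSums(a) - diag(a)
    tom <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        s <- 0
        for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
        tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    tom
}

# adjusted Rand index between two label vectors
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# minimal phenotype table around a recurrence vector
mkPheno <- function(y, ids = sprintf("S%03d", seq_along(y)), grade = NULL) {
    data.frame(sample_id = ids, recurrence = y,
               who_grade = if (is.null(grade)) rep(1L, length(y)) else grade,
               stringsAsFactors = FALSE)
}

# gene x sample matrix with named dims from a bare numeric matrix
named <- function(m, gp = "g", sp = "s") {
    dimnames(m) <- list(sprintf("%s%03d", gp, seq_len(nrow(m))),
                        sprintf("%s%03d", sp, seq_len(ncol(m))))
    m
}
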