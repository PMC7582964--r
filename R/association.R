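## Phenotype association screens: recurrence t-tests, WHO-grade ANOVA,
## time-to-recurrence correlation, the transcription-factor marker screen,
## and the intra-chromosomal distance / co-expression analysis.

.assocResult <- function(unit, test, statistic, p, groups = NULL,
                         direction = NA_character_, extra = list()) {
    out <- c(list(unit = unit, test = test, statistic = statistic,
                  p.value = p, groups = groups, direction = direction),
             extra)
    class(out) <- "mm_assoc"
    out
}

#' @export
print.mm_assoc <- function(x, ...) {
    cat(x$test, "for", x$unit, ": statistic =",
        sprintf("%.4g", x$statistic), ", p =", sprintf("%.4g", x$p.value),
        if (!is.na(x$direction)) paste0(", direction ", x$direction), "\n")
    invisible(x)
}

#' Recurrent vs non-recurrent two-sample t-test
#'
#' Two-sided Welch test by default (pooled-variance optional). Degenerate
#' input with zero variance in both groups and equal means is reported as
#' t = 0, p = 1 by convention.
#'
#' @param values named per-sample scores (e.g. a meta-gene row).
#' @param pheno phenotype table with \code{recurrence}; or a bare 0/1
#'   vector aligned with \code{values}.
#' @param unit label for the tested unit.
#' @param varEqual pooled-variance Student test instead of Welch.
#' @return an association result with group means, sizes, and the
#'   direction of the recurrent group ("up"/"down").
#' @export
recurrenceTTest <- function(values, pheno, unit = "module",
                            varEqual = FALSE) {
    y <- if (is.data.frame(pheno)) {
        if (!is.null(names(values)))
            pheno <- pheno[match(names(values), pheno$sample_id), ,
                           drop = FALSE]
        pheno$recurrence
    } else pheno
    stopifnot(length(y) == length(values), all(y %in% 0:1))
    g1 <- values[y == 1]; g0 <- values[y == 0]
    if (length(g1) < 2L || length(g0) < 2L)
        stop("both outcome groups need >= 2 samples")
    groups <- list(recurrent = c(n = length(g1), mean = mean(g1)),
                   nonrecurrent = c(n = length(g0), mean = mean(g0)))
    if (stats::sd(g1) == 0 && stats::sd(g0) == 0) {
        if (mean(g1) == mean(g0)) {
            message("zero variance in both groups with equal means: p = 1")
            return(.assocResult(unit, "t-test", 0, 1, groups, "none"))
        }
        stop("zero variance in both groups with unequal means")
    }
    tt <- stats::t.test(g1, g0, var.equal = varEqual)
    dir <- if (mean(g1) > mean(g0)) "up" else "down"
    .assocResult(unit, "t-test", unname(tt$statistic), tt$p.value, groups,
                 dir, list(df = unname(tt$parameter)))
}

#' One-way ANOVA across WHO grades
#'
#' Fixed-effects F test of per-sample scores across WHO grades. Requires at
#' least two grades with >= 2 samples each. A fully degenerate input (all
#' values equal) is reported as F = 0, p = 1.
#'
#' @param values named per-sample scores.
#' @param pheno phenotype table with \code{who_grade}, or a bare grade
#'   vector.
#' @param unit label for the tested unit.
#' @return an association result with per-grade means and sizes.
#' @export
gradeAnova <- function(values, pheno, unit = "module") {
    g <- if (is.data.frame(pheno)) {
        if (!is.null(names(values)))
            pheno <- pheno[match(names(values), pheno$sample_id), ,
                           drop = FALSE]
        pheno$who_grade
    } else pheno
    stopifnot(length(g) == length(values))
    keep <- !is.na(g)
    g <- factor(g[keep]); v <- values[keep]
    tab <- table(g)
    if (length(tab) < 2L) stop("need >= 2 WHO grades present")
    if (any(tab < 2L)) stop("every grade needs >= 2 samples")
    groups <- lapply(split(v, g), function(z) c(n = length(z),
                                                mean = mean(z)))
    if (stats::var(v) == 0)
        return(.assocResult(unit, "ANOVA", 0, 1, groups))
    fit <- stats::anova(stats::lm(v ~ g))
    .assocResult(unit, "ANOVA", fit$`F value`[1L], fit$`Pr(>F)`[1L], groups,
                 extra = list(df = unname(fit$Df)))
}

#' Correlation of meta-gene expression with time to recurrence
#'
#' Pearson correlation over recurrent samples with observed time to
#' recurrence. \code{"year-binned"} (default) averages the score within
#' integer years of time-to-recurrence (bins holding >= \code{minBinN}
#' samples) and correlates the bin means against the bin years, matching
#' the usual presentation of such trends; \code{"per-sample"} correlates
#' raw values.
#'
#' @param values named per-sample scores.
#' @param pheno phenotype table with \code{recurrence} and
#'   \code{time_to_recurrence}.
#' @param mode \code{"year-binned"} or \code{"per-sample"}.
#' @param minBinN minimum samples per year bin.
#' @param unit label for the tested unit.
#' @return association result with estimate \code{rho}.
#' @export
ttrCorrelation <- function(values, pheno,
                           mode = c("year-binned", "per-sample"),
                           minBinN = 3L, unit = "module") {
    mode <- match.arg(mode)
    if (!is.null(names(values)))
        pheno <- pheno[match(names(values), pheno$sample_id), , drop = FALSE]
    use <- pheno$recurrence == 1 & !is.na(pheno$time_to_recurrence)
    if (sum(use) < 3L) stop("need >= 3 recurrent samples with ",
                            "time_to_recurrence")
    t0 <- pheno$time_to_recurrence[use]; v0 <- values[use]
    if (mode == "year-binned") {
        yr <- round(t0)
        keep <- yr %in% as.numeric(names(which(table(yr) >= minBinN)))
        if (length(unique(yr[keep])) < 3L)
            stop("fewer than 3 usable year bins")
        t0 <- sort(unique(yr[keep]))
        v0 <- vapply(t0, function(yy) mean(v0[keep][yr[keep] == yy]),
                     numeric(1L))
    }
    ct <- stats::cor.test(v0, t0, method = "pearson")
    .assocResult(unit, "Pearson", unname(ct$statistic), ct$p.value,
                 direction = if (ct$estimate >= 0) "positive" else "negative",
                 extra = list(rho = unname(ct$estimate), n = length(v0),
                              mode = mode))
}

#' Transcription-factor marker screen
#'
#' Keeps transcription factors whose regulon term is enriched in the module
#' (q < \code{qAlpha}) and whose own expression separates recurrent from
#' non-recurrent tumors (t-test p < \code{pAlpha}) in every supplied
#' cohort with a consistent direction. WHO-grade ANOVA p-values per cohort
#' are reported alongside. TF symbols are matched case-insensitively; TFs
#' absent from any cohort's matrix are excluded with a message.
#'
#' @param enrich data.frame from \code{\link{overrepresentationTest}} whose
#'   \code{term} column holds TF gene symbols.
#' @param cohorts list of cohorts (or of \code{list(expr =, pheno =)}).
#' @param qAlpha,pAlpha significance thresholds (default 0.05 each).
#' @return data.frame of retained TFs: term, q, direction, per-cohort
#'   t-test and grade-ANOVA p-values.
#' @export
tfMarkerScreen <- function(enrich, cohorts, qAlpha = 0.05, pAlpha = 0.05) {
    if (length(cohorts) == 0L) stop("empty cohort list")
    getXP <- function(ch) {
        if (is(ch, "SummarizedExperiment"))
            list(x = .exprs(ch), p = .pheno(ch))
        else list(x = .exprs(ch$expr), p = ch$pheno)
    }
    parsed <- lapply(cohorts, getXP)
    cand <- enrich$term[enrich$q < qAlpha]
    rows <- list()
    for (tf in cand) {
        ok <- TRUE; dirs <- character(0)
        tp <- gp <- numeric(length(parsed))
        for (i in seq_along(parsed)) {
            x <- parsed[[i]]$x
            hit <- which(toupper(rownames(x)) == toupper(tf))
            if (length(hit) != 1L) {
                message("TF ", tf, " unresolved in cohort ", i, "; excluded")
                ok <- FALSE; break
            }
            tt <- recurrenceTTest(x[hit, ], parsed[[i]]$p, unit = tf)
            an <- gradeAnova(x[hit, ], parsed[[i]]$p, unit = tf)
            tp[i] <- tt$p.value; gp[i] <- an$p.value
            dirs <- c(dirs, tt$direction)
        }
        if (!ok) next
        if (all(tp < pAlpha) && length(unique(dirs)) == 1L)
            rows[[tf]] <- data.frame(
                term = tf, q = enrich$q[match(tf, enrich$term)],
                direction = dirs[1L],
                t(stats::setNames(tp, sprintf("ttest_p_cohort%d",
                                              seq_along(tp)))),
                t(stats::setNames(gp, sprintf("anova_p_cohort%d",
                                              seq_along(gp)))),
                stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(term = character(0), q = numeric(0),
                          direction = character(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$q), , drop = FALSE]
}

#' Intra-chromosomal gene distance vs co-expression
#'
#' Over all gene pairs sharing a chromosome within the given subset:
#' Pearson correlation between genomic separation |start_i - start_j| and
#' expression correlation cor(x_i, x_j). Significance by permutation of
#' the gene-to-position assignment (seeded).
#'
#' @param x genes x samples matrix or cohort.
#' @param genes gene subset (e.g. one module's genes).
#' @param ann annotation data.frame from \code{\link{readGeneAnnotation}}.
#' @param nPerm number of position permutations.
#' @param seed permutation seed.
#' @return association result with estimate \code{rho} and a two-sided
#'   permutation p-value.
#' @export
linkageDistanceCorrelation <- function(x, genes, ann, nPerm = 1000L,
                                       seed = 1L) {
    x0 <- .exprs(x)
    genes <- intersect(genes, intersect(rownames(x0), ann$gene_id))
    ann <- ann[match(genes, ann$gene_id), , drop = FALSE]
    chrTab <- table(ann$chromosome)
    if (!any(chrTab >= 2L)) stop("no intra-chromosomal pair")
    r <- stats::cor(t(x0[genes, , drop = FALSE]))
    pairStat <- function(chrom, start) {
        ii <- jj <- integer(0)
        for (ch in names(chrTab)) {
            idx <- which(chrom == ch)
            if (length(idx) < 2L) next
            cmb <- utils::combn(idx, 2L)
            ii <- c(ii, cmb[1L, ]); jj <- c(jj, cmb[2L, ])
        }
        stats::cor(abs(start[ii] - start[jj]), r[cbind(ii, jj)])
    }
    obs <- pairStat(ann$chromosome, ann$start)
    set.seed(seed)
    perm <- vapply(seq_len(nPerm), function(i) {
        o <- sample(length(genes))
        pairStat(ann$chromosome[o], ann$start[o])
    }, numeric(1L))
    p <- (1 + sum(abs(perm) >= abs(obs))) / (nPerm + 1)
    .assocResult("gene-linkage", "permutation-Pearson", obs, p,
                 direction = if (obs >= 0) "positive" else "negative",
                 extra = list(rho = obs, nPerm = nPerm))
}
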