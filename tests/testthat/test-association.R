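test_that("recurrence t-test matches the closed-form Welch oracle", {
    g0 <- c(0.1, 0.2, 0.3, 0.4); g1 <- c(1.1, 1.3, 1.2, 1.4)
    y <- c(rep(0, 4), rep(1, 4))
    res <- recurrenceTTest(c(g0, g1), mkPheno(y))
    # independent closed-form Welch computation
    v0 <- sum((g0 - mean(g0))^2) / 3; v1 <- sum((g1 - mean(g1))^2) / 3
    se <- sqrt(v0 / 4 + v1 / 4)
    tW <- (mean(g1) - mean(g0)) / se
    dfW <- (v0 / 4 + v1 / 4)^2 /
        ((v0 / 4)^2 / 3 + (v1 / 4)^2 / 3)
    expect_equal(res$statistic, tW, tolerance = 1e-12)
    expect_equal(res$p.value, 2 * pt(-abs(tW), dfW), tolerance = 1e-12)
    expect_equal(res$direction, "up")
})

test_that("degenerate and invalid t-test inputs are handled per convention", {
    y <- c(0, 0, 0, 1, 1, 1)
    res <- recurrenceTTest(rep(c(1, 2, 3), 2), mkPheno(y))
    expect_equal(res$p.value, 1, tolerance = 1e-12)
    resc <- suppressMessages(recurrenceTTest(rep(5, 6), mkPheno(y)))
    expect_equal(resc$p.value, 1)
    expect_equal(resc$statistic, 0)
    expect_error(recurrenceTTest(1:5, mkPheno(c(1, 0, 0, 0, 0))),
                 ">= 2 samples")
})

test_that("grade ANOVA matches the hand-computed F", {
    v <- c(1, 2, 3, 4, 5, 6)
    g <- c(1, 1, 2, 2, 3, 3)
    res <- gradeAnova(v, mkPheno(rep(0, 6), grade = g))
    expect_equal(res$statistic, 16)       # MSB 8 / MSW 0.5, worked by hand
    expect_equal(res$p.value, pf(16, 2, 3, lower.tail = FALSE),
                 tolerance = 1e-12)
    # equal groups: F = 0, p = 1
    res0 <- gradeAnova(rep(c(1, 2), 3), mkPheno(rep(0, 6), grade = g))
    expect_equal(res0$statistic, 0)
    expect_equal(res0$p.value, 1)
    expect_error(gradeAnova(1:4, mkPheno(rep(0, 4), grade = rep(1, 4))),
                 ">= 2 WHO grades")
})

test_that("association tests are order- and shift-invariant", {
    set.seed(3)
    v <- rnorm(40); y <- rbinom(40, 1, 0.5); g <- sample(1:3, 40, TRUE)
    o <- sample(40)
    t1 <- recurrenceTTest(v, mkPheno(y)); t2 <- recurrenceTTest(v[o], mkPheno(y[o]))
    expect_equal(t1$p.value, t2$p.value, tolerance = 1e-12)
    t3 <- recurrenceTTest(v + 100, mkPheno(y))
    expect_equal(t1$statistic, t3$statistic, tolerance = 1e-8)
    a1 <- gradeAnova(v, mkPheno(y, grade = g))
    a2 <- gradeAnova(v + 100, mkPheno(y, grade = g))
    expect_equal(a1$statistic, a2$statistic, tolerance = 1e-8)
})

test_that("time-to-recurrence correlation hits both exact limits", {
    n <- 30
    ph <- mkPheno(rep(1, n))
    ph$time_to_recurrence <- runif(n, 1, 10)
    res <- ttrCorrelation(ph$time_to_recurrence, ph, mode = "per-sample")
    expect_equal(res$rho, 1)
    resn <- ttrCorrelation(-ph$time_to_recurrence, ph, mode = "per-sample")
    expect_equal(resn$rho, -1)
    expect_equal(resn$direction, "negative")
    ph2 <- mkPheno(c(1, 1, 0)); ph2$time_to_recurrence <- c(1, 2, NA)
    expect_error(ttrCorrelation(1:3, ph2), ">= 3 recurrent")
})

test_that("planted negative TTR dependence is detected with high power", {
    hits <- vapply(1:40, function(s) {
        spec <- syntheticCohortSpec(nSamples = 200, moduleSizes = 4,
                                    nNoiseGenes = 0, predictiveModule = 1,
                                    beta1 = 2, ttrSlope = 0.35, seed = 100 + s)
        sim <- simulateCohort(spec)
        res <- ttrCorrelation(sim$truth$factors[1L, ], sim$pheno,
                              mode = "per-sample")
        res$rho < 0 && res$p.value < 0.05
    }, logical(1L))
    expect_gte(mean(hits), 0.9)
})

test_that("TF marker screen applies the q, p and direction AND-rules", {
    mkcoh <- function(seed, tfUp = 1.5) {
        set.seed(seed)
        n <- 60
        y <- rep(c(0, 1), each = n / 2)
        x <- named(matrix(rnorm(5 * n), 5, n))
        rownames(x) <- c("FOXM1", "SUZ12", "RUNX1", "OTHER1", "OTHER2")
        x["FOXM1", ] <- x["FOXM1", ] + tfUp * y       # up in recurrent
        x["RUNX1", ] <- x["RUNX1", ] - tfUp * y       # down in recurrent
        list(expr = x, pheno = mkPheno(y, ids = colnames(x),
                                       grade = sample(1:3, n, TRUE)))
    }
    cohorts <- list(mkcoh(1), mkcoh(2))
    enrich <- data.frame(term = c("FOXM1", "RUNX1", "SUZ12", "BADQ"),
                         q = c(0.01, 0.02, 0.03, 0.2))
    res <- suppressMessages(tfMarkerScreen(enrich, cohorts))
    expect_setequal(res$term, c("FOXM1", "RUNX1"))
    expect_equal(res$direction[res$term == "FOXM1"], "up")
    expect_equal(res$direction[res$term == "RUNX1"], "down")
    # differential in only one cohort -> excluded
    oneSided <- list(mkcoh(1), mkcoh(3, tfUp = 0))
    res2 <- suppressMessages(tfMarkerScreen(
        data.frame(term = "FOXM1", q = 0.01), oneSided))
    expect_false("FOXM1" %in% res2$term)
    expect_error(tfMarkerScreen(enrich, list()), "empty cohort")
})

test_that("linkage analysis finds planted distance-decaying co-expression", {
    set.seed(12)
    n <- 80; p <- 24
    pos <- sort(sample.int(2e6, p))
    f <- rnorm(n)
    # co-expression decays deterministically with genomic separation
    x <- named(matrix(NA_real_, p, n))
    for (i in seq_len(p)) {
        w <- exp(-pos[i] / 8e5)
        x[i, ] <- w * f + sqrt(1 - w^2) * rnorm(n)
    }
    ann <- data.frame(gene_id = rownames(x), chromosome = "chr1",
                      start = pos)
    res <- linkageDistanceCorrelation(x, rownames(x), ann, nPerm = 1000,
                                      seed = 5)
    expect_lt(res$rho, 0)
    expect_lte(res$p.value, 0.005)
    # reproducible under a fixed seed
    res2 <- linkageDistanceCorrelation(x, rownames(x), ann, nPerm = 1000,
                                       seed = 5)
    expect_identical(res$p.value, res2$p.value)
    # all genes on distinct chromosomes: no usable pair
    ann2 <- data.frame(gene_id = rownames(x),
                       chromosome = sprintf("chr%d", seq_len(p)),
                       start = pos)
    expect_error(linkageDistanceCorrelation(x, rownames(x), ann2),
                 "no intra-chromosomal")
})
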