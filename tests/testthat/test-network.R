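test_that("adjacency matches a direct double-loop correlation oracle", {
    set.seed(1)
    x <- named(matrix(rnorm(50), 5, 10))
    a <- adjacencyMatrix(x, power = 6)
    for (i in 1:5) for (j in 1:5) {
        want <- if (i == j) 1 else abs(cor(x[i, ], x[j, ]))^6
        expect_equal(a[i, j], want, tolerance = 1e-12)
    }
    # identical rows give adjacency 1 at any power
    x2 <- rbind(x, g999 = x[1, ] )
    a2 <- adjacencyMatrix(x2, power = 9)
    expect_equal(a2["g001", "g999"], 1)
    # signed mode and the 0.5^6 spot value
    expect_equal(0.5^6, 0.015625)
    s <- adjacencyMatrix(x, power = 2, signMode = "signed")
    expect_equal(s[1, 2], ((1 + cor(x[1, ], x[2, ])) / 2)^2,
                 tolerance = 1e-12)
    # zero-variance handling
    x3 <- x; x3[2, ] <- 5
    expect_error(adjacencyMatrix(x3), "zero-variance")
    expect_equal(nrow(suppressMessages(
        adjacencyMatrix(x3, zeroVariance = "drop"))), 4L)
})

test_that("adjacency and TOM are symmetric, unit-diagonal, in [0,1]", {
    set.seed(2)
    for (rep in 1:5) {
        x <- named(matrix(rnorm(80), 8, 10))
        a <- adjacencyMatrix(x, power = sample(1:8, 1))
        expect_lt(max(abs(a - t(a))), 1e-12)
        expect_true(all(diag(a) == 1))
        expect_true(all(a >= 0 & a <= 1))
        tom <- topologicalOverlap(a)
        expect_lt(max(abs(tom - t(tom))), 1e-12)
        expect_true(all(diag(tom) == 1))
        expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    }
})

test_that("TOM of a complete graph is all ones; zero overlap gives zero", {
    a <- matrix(1, 5, 5)
    expect_equal(topologicalOverlap(a), matrix(1, 5, 5),
                 ignore_attr = TRUE)
    # two genes with no edge and no shared neighbor
    a2 <- diag(4)
    a2[3, 4] <- a2[4, 3] <- 0.9
    expect_equal(topologicalOverlap(a2)[1, 2], 0)
})

test_that("scale-free power selection behaves on modular vs noise data", {
    spec <- syntheticCohortSpec(nSamples = 120, moduleSizes = c(40, 30),
                                nNoiseGenes = 20, loadings = 1, sigma = 0.3,
                                seed = 8)
    sim <- simulateCohort(spec)
    ps <- suppressWarnings(pickSoftThreshold(sim$expr, candidates = 1:12))
    expect_true(is.data.frame(ps$fits) && nrow(ps$fits) == 12L)
    expect_true(ps$power %in% 1:12)
    # pure noise is not scale-free: flagged, never silently picked
    noise <- named(matrix(rnorm(100 * 60), 100, 60))
    expect_warning(pn <- pickSoftThreshold(noise, candidates = 1:10),
                   "not met")
    expect_false(pn$targetMet)
    # a single candidate that fits is returned directly
    one <- suppressWarnings(pickSoftThreshold(sim$expr, candidates = 6))
    expect_equal(one$power, 6L)
})

test_that("average linkage reproduces the hand-worked 3-point heights", {
    d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    d["a", "b"] <- d["b", "a"] <- 0.2
    d["a", "c"] <- d["c", "a"] <- 0.4
    d["b", "c"] <- d["c", "b"] <- 0.6
    hc <- clusterDendrogram(d)
    expect_equal(hc$height, c(0.2, 0.5))    # (0.4 + 0.6) / 2
    # block construction: first merges near 0.1, last near 0.9
    n <- 10
    db <- matrix(0.9, 2 * n, 2 * n)
    db[1:n, 1:n] <- 0.1; db[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0.1
    diag(db) <- 0
    dimnames(db) <- list(sprintf("g%02d", 1:(2 * n)),
                         sprintf("g%02d", 1:(2 * n)))
    hb <- clusterDendrogram(db)
    expect_equal(max(hb$height), 0.9)
    expect_equal(min(hb$height), 0.1)
    expect_error(clusterDendrogram(matrix(c(0, NaN, NaN, 0), 2, 2)), "NaN|NA")
})

test_that("tree cut recovers planted blocks and isolates noise without PAM", {
    spec <- syntheticCohortSpec(nSamples = 150, moduleSizes = c(50, 50),
                                nNoiseGenes = 0, loadings = 1, sigma = 0.2,
                                baselineSD = 0, seed = 13)
    sim <- simulateCohort(spec)
    res <- discoverModules(sim$expr, power = 6)
    sz <- moduleSizes(res$partition)
    expect_equal(unname(sz[c("turquoise", "blue")]), c(50L, 50L))
    expect_equal(ari(moduleLabels(res$partition)[names(sim$truth$labels)],
                     sim$truth$labels), 1)
    # noise genes stay unassigned when the PAM stage is off
    spec2 <- syntheticCohortSpec(nSamples = 150, moduleSizes = 30,
                                 nNoiseGenes = 30, loadings = 1, sigma = 0.2,
                                 seed = 14)
    sim2 <- simulateCohort(spec2)
    r2 <- discoverModules(sim2$expr, power = 6, pamStage = FALSE)
    lab2 <- moduleLabels(r2$partition)
    noise <- names(sim2$truth$labels)[sim2$truth$labels == "noise"]
    expect_gt(mean(lab2[noise] == "unassigned"), 0.8)
    planted <- setdiff(names(lab2), noise)
    expect_gt(mean(lab2[planted] == "turquoise"), 0.95)
})

test_that("tree cut is deterministic, permutation-stable and validates input", {
    spec <- syntheticCohortSpec(nSamples = 100, moduleSizes = c(25, 25),
                                nNoiseGenes = 10, loadings = 1, sigma = 0.3,
                                seed = 21)
    sim <- simulateCohort(spec)
    r1 <- discoverModules(sim$expr, power = 6)
    r2 <- discoverModules(sim$expr, power = 6)
    expect_identical(moduleLabels(r1$partition), moduleLabels(r2$partition))
    perm <- sample(nrow(sim$expr))
    r3 <- discoverModules(sim$expr[perm, ], power = 6)
    expect_equal(ari(moduleLabels(r1$partition),
                     moduleLabels(r3$partition)[names(moduleLabels(r1$partition))]),
                 1)
    expect_error(cutModules(r1$dendrogram, r1$dissimilarity, minSize = 1),
                 "minSize")
    # mutually identical genes collapse into a single module
    flat <- named(matrix(rep(rnorm(20), each = 6), 6, 20))
    rf <- discoverModules(flat + 1e-9, power = 2, minSize = 3)
    expect_equal(length(setdiff(unique(moduleLabels(rf$partition)),
                                "unassigned")), 1L)
})

test_that("random TOMs match the brute-force triple-loop formula", {
    set.seed(33)
    for (rep in 1:3) {
        n <- 6
        r <- matrix(runif(n * n), n, n)
        a <- (r + t(r)) / 2
        diag(a) <- 1
        expect_lt(max(abs(topologicalOverlap(a) - bruteTOM(a))), 1e-12)
    }
})
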