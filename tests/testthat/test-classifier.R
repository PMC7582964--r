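test_that("logistic arithmetic and null behavior are exact", {
    # hand-set coefficients: beta0 = -1, beta1 = 2, x = 0.5 -> p = 0.5
    m <- list(coefficients = c("(Intercept)" = -1, x = 2), terms = "x")
    class(m) <- "mm_logistic"
    expect_equal(unname(predictProb(m, data.frame(x = 0.5))), 0.5)
    m0 <- list(coefficients = c("(Intercept)" = 0, x = 0), terms = "x")
    class(m0) <- "mm_logistic"
    expect_equal(unname(predictProb(m0, data.frame(x = c(-3, 0, 7)))),
                 rep(0.5, 3))
    mInf <- list(coefficients = c("(Intercept)" = 30, x = 0), terms = "x")
    class(mInf) <- "mm_logistic"
    expect_true(all(predictProb(mInf, data.frame(x = rnorm(5))) > 0.999))
    # null regressor: CI covers zero
    set.seed(8)
    X <- data.frame(x = rnorm(1000))
    y <- rbinom(1000, 1, 0.4)
    f <- fitLogistic(y, X)
    ci <- log(f$orCI["x", ])
    expect_true(ci[1] < 0 && ci[2] > 0)
    expect_error(fitLogistic(rep(1, 10), data.frame(x = rnorm(10))),
                 "single-class")
})

test_that("complete separation is flagged, not silently returned", {
    X <- data.frame(x = c(-3, -2, -1, 1, 2, 3))
    y <- c(0, 0, 0, 1, 1, 1)
    expect_warning(f <- fitLogistic(y, X), "separation|converge")
    expect_true(f$separation)
})

test_that("maximum likelihood matches a generic optimizer on toy data", {
    set.seed(21)
    X <- data.frame(x = rnorm(80))
    y <- rbinom(80, 1, plogis(0.3 + 1.2 * X$x))
    f <- fitLogistic(y, X)
    nll <- function(b) -sum(y * (b[1] + b[2] * X$x) -
                            log1p(exp(b[1] + b[2] * X$x)))
    opt <- optim(c(0, 0), nll, method = "BFGS")
    expect_equal(unname(f$coefficients), opt$par, tolerance = 1e-5)
})

test_that("AUC edge cases and complement/transform invariances hold", {
    expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
    expect_equal(rocAuc(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
    expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
    set.seed(4)
    s <- rnorm(50); y <- rbinom(50, 1, 0.5)
    expect_equal(rocAuc(s, y)$auc + rocAuc(-s, y)$auc, 1)
    expect_equal(rocAuc(exp(2 * s), y)$auc, rocAuc(s, y)$auc)
    r <- rocAuc(s, y)
    expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
    expect_equal(tail(r$curve$fpr, 1), 1); expect_equal(tail(r$curve$tpr, 1), 1)
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_error(rocAuc(s, rep(1, 50)), "both outcome classes")
})

test_that("DeLong test is exact under rank identity and tracks a bootstrap", {
    set.seed(9)
    y <- rbinom(120, 1, 0.5); s <- rnorm(120)
    d0 <- delongTest(s, s, y)
    expect_identical(c(d0$z, d0$p.value, d0$diff), c(0, 1, 0))
    dmono <- delongTest(s, exp(s) + 2, y)   # rank-preserving transform
    expect_identical(c(dmono$z, dmono$p.value), c(0, 1))
    expect_error(delongTest(s, s[-1], y[-1]), "paired")

    # stratified-bootstrap oracle for the two-sided p on correlated scores
    fastAUC <- function(s, y) {
        n1 <- sum(y); r <- rank(s)
        (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * (sum(y == 0)))
    }
    set.seed(77)
    devs <- replicate(8, {
        n <- 300
        z <- rnorm(n); y <- rbinom(n, 1, plogis(z))
        s1 <- z + rnorm(n, 0, 0.8); s2 <- z + rnorm(n, 0, 1.1)
        dl <- delongTest(s1, s2, y)
        ip <- which(y == 1); ineg <- which(y == 0)
        d <- replicate(4000, {
            i <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
            fastAUC(s1[i], y[i]) - fastAUC(s2[i], y[i])
        })
        pBoot <- 2 * min(mean(d <= 0), mean(d >= 0))
        abs(min(pBoot, 1) - dl$p.value)
    })
    expect_lt(median(devs), 0.05)
})

test_that("stratified folds are deterministic, balanced and exhaustive", {
    y <- rbinom(100, 1, 0.3)
    f1 <- makeStratifiedFolds(y, 10, seed = 3)
    f2 <- makeStratifiedFolds(y, 10, seed = 3)
    expect_identical(f1, f2)
    expect_setequal(unique(f1), 1:10)
    perFold <- table(f1, y)
    expect_lte(diff(range(perFold[, 2])), 1)   # positives spread evenly
    # leave-one-out partition property: every sample scored exactly once
    set.seed(31)
    yb <- rep(c(0, 1), 5)
    x <- named(matrix(rnorm(40) + 2 * rep(yb, each = 4), 4, 10))
    cv <- suppressWarnings(crossValidate(
        x, mkPheno(yb, ids = colnames(x)), list(m = rownames(x)),
        k = 10, seed = 1))
    expect_false(anyNA(cv$probs))
    expect_equal(length(cv$probs), 10L)
})

test_that("cross-validated AUC recovers the theoretical factor AUC", {
    spec <- syntheticCohortSpec(nSamples = 500, moduleSizes = 40,
                                nNoiseGenes = 10, loadings = 1, sigma = 0.4,
                                predictiveModule = 1, beta1 = 2, seed = 41)
    sim <- simulateCohort(spec)
    ml <- list(m = names(sim$truth$labels)[sim$truth$labels == "module1"])
    cv <- crossValidate(sim$expr, sim$pheno, ml, k = 10, seed = 2)
    expect_lt(abs(cv$roc$auc - theoreticalAUC(spec)), 0.05)
    # determinism under the seed
    cv2 <- crossValidate(sim$expr, sim$pheno, ml, k = 10, seed = 2)
    expect_identical(cv$folds, cv2$folds)
    expect_identical(cv$roc$auc, cv2$roc$auc)
})

test_that("external validation transfers gene lists across cohorts", {
    mk <- function(seed) syntheticCohortSpec(
        nSamples = 250, moduleSizes = c(30, 25), nNoiseGenes = 15,
        loadings = 1, sigma = 0.5, beta1 = 2, seed = seed)
    sims <- simulateMultiCohort(list(mk(1), mk(2)))
    ml <- list(m = names(sims[[1]]$truth$labels)[
        sims[[1]]$truth$labels == "module2"])
    ev <- evaluateExternal(sims[[1]]$cohort, sims[[2]]$cohort, ml)
    cv <- crossValidate(sims[[1]]$expr, sims[[1]]$pheno, ml, k = 10,
                        seed = 1)
    expect_lt(abs(ev$roc$auc - cv$roc$auc), 0.06)
    # resubstitution identity: test == train
    evSelf <- evaluateExternal(sims[[1]]$cohort, sims[[1]]$cohort, ml)
    sc <- evSelf$testScores$m
    expect_equal(evSelf$roc$auc,
                 rocAuc(sc, sims[[1]]$pheno$recurrence)$auc)
    # too many missing module genes are rejected
    small <- sims[[2]]$expr[!grepl("MOD2", rownames(sims[[2]]$expr)) |
                            seq_len(nrow(sims[[2]]$expr)) %% 7 == 0, ]
    expect_error(suppressMessages(evaluateExternal(
        sims[[1]]$cohort, makeCohort(small, sims[[2]]$pheno), ml)),
        "missing from cohort")
})

test_that("multivariate models report the module term within the fit", {
    spec <- syntheticCohortSpec(nSamples = 300, moduleSizes = 25,
                                nNoiseGenes = 5, loadings = 1, beta1 = 2,
                                predictiveModule = 1, seed = 51)
    sim <- simulateCohort(spec)
    ml <- list(m = names(sim$truth$labels)[sim$truth$labels == "module1"])
    ev <- evaluateExternal(sim$cohort, sim$cohort, ml,
                           covariates = "who_grade")
    expect_true(all(c("m", "who_grade") %in% names(ev$model$or)))
    expect_lt(ev$model$p["m"], 0.05)
    expect_true(all(ev$model$orCI[, "lower"] <= ev$model$orCI[, "upper"]))
})

test_that("grade-stratified evaluation restricts to the stratum", {
    spec <- syntheticCohortSpec(nSamples = 600, moduleSizes = 25,
                                nNoiseGenes = 5, loadings = 1, beta1 = 2,
                                gradeSlope = 0,   # grade independent of f
                                predictiveModule = 1, seed = 61)
    sim <- simulateCohort(spec)
    ml <- list(m = names(sim$truth$labels)[sim$truth$labels == "module1"])
    overall <- rocAuc(metageneScores(computeMetagenes(sim$expr, ml))["m", ],
                      sim$pheno$recurrence)$auc
    for (g in 1:2) {
        r <- stratifiedByGrade(sim$cohort, moduleGenes = ml, grade = g)
        expect_lt(abs(r$auc - overall), 0.12)
    }
    expect_error(stratifiedByGrade(sim$cohort, moduleGenes = ml, grade = 9),
                 "absent")
    ph2 <- sim$pheno; ph2$recurrence[ph2$who_grade == 1] <- 0
    expect_error(stratifiedByGrade(sim$expr, ph2, ml, grade = 1),
                 "single-class stratum")
})
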