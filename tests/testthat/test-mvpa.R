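test_that("LDA training computes regularized pooled covariance", {
    # two classes constructed so that the pooled covariance is the identity
    x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) + 5
    cl <- c(1, 1, 2, 2)
    m <- ldaTrain(x, cl, regFraction = 0.01)
    expect_equal(m@covReg, 1.01 * diag(2), ignore_attr = TRUE)
    expect_equal(unname(m@means), rbind(c(5, 5), c(5, 5)))
    # with zero within-class noise, class means equal the patterns
    bp <- separatedBetas(nRuns = 3)
    m2 <- ldaTrain(bp)
    expect_equal(unname(m2@means), unname(betaMatrix(bp)[1:4, ]),
                 tolerance = 0.01)
    # pooled covariance equals the explicit per-class oracle
    set.seed(1)
    x3 <- matrix(rnorm(60), 12, 5)
    cl3 <- rep(1:3, each = 4)
    m3 <- ldaTrain(x3, cl3, regFraction = 0)
    expect_equal(m3@covReg, oraclePooledCov(x3, cl3), tolerance = 1e-12)
    expect_error(ldaTrain(x3[1:4, ], rep(1, 4)), "2 classes")
    expect_error(ldaTrain(x3[1:3, ], c(1, 1, 2)), "2 observations")
})

test_that("LDA classification is maximum likelihood with shared covariance", {
    bp <- separatedBetas(nRuns = 3)
    m <- ldaTrain(bp)
    # a pattern equal to a class mean goes to that class
    pred <- ldaClassify(m, m@means)
    expect_equal(as.character(pred), m@labels)
    expect_error(ldaClassify(m, matrix(0, 1, 3)), "feature count")
    # exact tie breaks to the lowest class index (symmetric construction)
    mt <- new("LDAModel", means = rbind(c(1, 0), c(-1, 0), c(0, 3)),
              covReg = diag(2), labels = c("a", "b", "c"),
              regFraction = 0.01)
    expect_equal(as.character(ldaClassify(mt, c(0, 0))), "a")
})

test_that("LDA predictions agree with the brute-force likelihood oracle", {
    set.seed(2)
    for (i in 1:10) {
        K <- sample(2:4, 1); p <- sample(2:8, 1)
        x <- matrix(rnorm(6 * K * p, sd = 2), 6 * K, p)
        cl <- rep(seq_len(K), 6)
        m <- ldaTrain(x, cl)
        xt <- matrix(rnorm(5 * p), 5, p)
        expect_equal(as.integer(ldaClassify(m, xt)),
                     oracleLdaPredict(m@means, m@covReg, xt))
    }
})

test_that("leave-one-run-out accuracy matches an independent reimplementation", {
    set.seed(3)
    gt <- makeGroundTruth(20, vCommon = 1, vSpecific = 1, vRun = 0.3,
                          vTrial = 1, d = 3, geometry = "random", seed = 4)
    bp <- simulateBetas(gt, 6, seed = 5)
    res <- crossvalAccuracy(bp)
    expect_equal(res@nTest, 24L)
    expect_equal(accuracy(res),
                 oracleCrossval(betaMatrix(bp),
                                conditionLabels(bp), runLabels(bp)))
    # noiseless well-separated patterns are classified perfectly
    expect_equal(accuracy(crossvalAccuracy(separatedBetas())), 1)
})

test_that("accuracy z-transform follows the binomial approximation", {
    expect_equal(accuracyToZ(0.25, 32, 0.25), 0)
    expect_equal(accuracyToZ(0.375, 32, 0.25), 1.633, tolerance = 1e-3)
    expect_equal(accuracyToZ(0.5, 32, 0.25), 3.266, tolerance = 1e-3)
    expect_equal(accuracyThreshold(1.64, 32, 0.25), 37.5)
    expect_equal(accuracyThreshold(0, 32, 0.25), 25)
    expect_equal(accuracyThreshold(1.64, 128, 0.25),
                 floor(1000 * (0.25 + 1.64 * sqrt(0.25 * 0.75 / 128))) / 10)
})

test_that("voxel permutation leaves accuracy unchanged", {
    set.seed(6)
    gt <- makeGroundTruth(30, vCommon = 1, vSpecific = 2, vRun = 0.3,
                          vTrial = 1, d = 3, geometry = "random", seed = 7)
    bp <- simulateBetas(gt, 5, seed = 8)
    perm <- sample(30)
    bpPerm <- BetaPatterns(SummarizedExperiment::assay(bp)[perm, ],
                           conditionLabels(bp), runLabels(bp))
    expect_equal(accuracy(crossvalAccuracy(bp)),
                 accuracy(crossvalAccuracy(bpPerm)))
})

test_that("accuracy increases with the specific-to-noise ratio", {
    set.seed(9)
    ratios <- c(0.05, 0.3, 1.2)
    meanAcc <- vapply(ratios, function(r) {
        mean(vapply(1:15, function(i) {
            gt <- makeGroundTruth(40, vCommon = 1, vSpecific = r, vRun = 0.2,
                                  vTrial = 1, d = 3, geometry = "random")
            accuracy(crossvalAccuracy(simulateBetas(gt, 8)))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(meanAcc) > 0))
})

test_that("behavioural LDA handles all seven feature combinations", {
    sch <- makeSchedule(seed = 10)
    rec <- simulateBehavior(sch, mtMeans = c(900, 1100, 1300, 1500),
                            mtSd = 20, seed = 11)
    # strongly separated MTs classify near perfectly
    expect_gt(accuracy(behavioralClassifier(rec, "MT")), 0.9)
    combos <- list("MT", "force", "error",
                   c("MT", "force"), c("MT", "error"), c("force", "error"),
                   c("MT", "force", "error"))
    accs <- vapply(combos, function(f)
        accuracy(suppressWarnings(behavioralClassifier(rec, f))),
        numeric(1))
    expect_length(accs, 7)
    expect_true(all(accs >= 0 & accs <= 1))
    # a constant feature is dropped with a warning
    rec0 <- rec; rec0$error <- FALSE
    expect_warning(behavioralClassifier(rec0, c("MT", "error")), "constant")
    # indistinguishable conditions stay near chance on average
    set.seed(12)
    nullAcc <- mean(vapply(1:20, function(i) {
        r <- simulateBehavior(sch, mtMeans = 1200, mtSd = 100,
                              forceMeans = 4, errorRate = 0.1)
        accuracy(behavioralClassifier(r))
    }, numeric(1)))
    expect_lt(abs(nullAcc - 0.25), 0.08)
})
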