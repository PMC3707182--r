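test_that("the canonical HRF has the standard double-gamma shape", {
    TRfine <- 0.01
    h <- canonicalHrf(TRfine)
    t <- seq(0, 32, by = TRfine)
    expect_gt(sum(h) * TRfine, 0)                 # positive integral
    peak <- t[which.max(h)]
    expect_gte(peak, 5); expect_lte(peak, 6)       # response peak ~5-6 s
    expect_equal(length(canonicalHrf(2.72)), length(seq(0, 32, 2.72)))
    # truncation: support ends at `length`
    expect_equal(length(canonicalHrf(1, length = 20)), 21)
    # undershoot: negative lobe peaking near 15-16 s
    expect_lt(h[which(abs(t - 15.5) < TRfine / 2)], 0)
})

test_that("the canonical design has one convolved regressor per condition-run", {
    sch <- makeSchedule(nRuns = 2, seed = 1)
    X <- buildDesign(sch)
    expect_equal(ncol(X@X), 2 * 4 + 2)            # 4 conditions x 2 runs + 2 intercepts
    expect_equal(nrow(X@X), 2 * 110)
    # single-trial regressor support: starts at onset, lasts ~ boxcar + hrf
    sch1 <- new("TrialSchedule",
                trials = data.frame(run = 1L, trial = 1L, condition = 1L,
                                    onset = 27, duration = 13.5),
                nRuns = 1L, nConditions = 1L, nVolumes = 110L, TR = 2.72)
    X1 <- buildDesign(sch1)
    reg <- X1@X[, 1]
    volTimes <- (0:109) * 2.72
    expect_true(all(abs(reg[volTimes < 27]) < 1e-6))
    active <- which(abs(reg) > 1e-3 * max(reg))
    expect_lt(volTimes[min(active)] - 27, 2 * 2.72)
    expect_lt(volTimes[max(active)], 27 + 13.5 + 32 + 2.72)
    # overlapping trials are rejected by the schedule class
    expect_error(new("TrialSchedule",
                     trials = data.frame(run = 1L, trial = 1:2,
                                         condition = 1:2, onset = c(0, 5),
                                         duration = 13.5),
                     nRuns = 1L, nConditions = 2L, nVolumes = 110L,
                     TR = 2.72),
                 "overlap")
})

test_that("high-pass filtering removes drift and keeps fast signal", {
    TR <- 2.72; n <- 110
    # constant series becomes zero
    const <- matrix(5, n, 3); attr(const, "TR") <- TR
    expect_lt(max(abs(highpassFilter(const))), 1e-9)
    # pure linear drift: residual power < 1% of input power
    drift <- matrix(seq(-1, 1, length.out = n), n, 1)
    fd <- highpassFilter(drift, TR = TR)
    expect_lt(sum(fd^2) / sum(drift^2), 0.01)
    # signal well above the cutoff is untouched within 1%
    fast <- matrix(sin(2 * pi * 0.1 * (1:n) * TR), n, 1)   # 0.1 Hz >> 1/128
    ff <- highpassFilter(fast, TR = TR)
    expect_lt(sum((ff - fast)^2) / sum(fast^2), 0.01)
    expect_error(highpassFilter(matrix(0, 4, 1), TR = TR), "8 volumes")
})

test_that("beta estimation matches the normal-equations oracle", {
    sch <- makeSchedule(nRuns = 3, seed = 2)
    gt <- makeGroundTruth(25, vCommon = 2, vSpecific = 1, vRun = 0.5,
                          vTrial = 0.5, d = 3, geometry = "random", seed = 3)
    runs <- simulateTimeseries(gt, sch, noiseSd = 1, seed = 4)
    design <- buildDesign(sch)
    bp <- estimateBetas(runs, design, highpass = FALSE)
    B <- oracleOls(design@X, do.call(rbind, runs))
    task <- !is.na(design@labels$condition)
    expect_equal(unname(betaMatrix(bp)), unname(B[task, ]),
                 tolerance = 1e-8)
})

test_that("noiseless simulation round-trips through the GLM exactly", {
    sch <- makeSchedule(nRuns = 2, seed = 5)
    gt <- makeGroundTruth(30, vCommon = 4, vSpecific = 2, vRun = 0,
                          vTrial = 0, d = 3, geometry = "random", seed = 6)
    runs <- simulateTimeseries(gt, sch, noiseSd = 0)
    bp <- estimateBetas(runs, buildDesign(sch))
    true <- t(t(gt@specific) + gt@common)
    est <- betaMatrix(bp)
    err <- max(abs(est - true[as.integer(conditionLabels(bp)), ]))
    expect_lt(err / sqrt(mean(true^2)), 1e-8)
})

test_that("robust regression down-weights an artifactual volume", {
    set.seed(7)
    sch <- makeSchedule(nRuns = 2, seed = 8)
    gt <- makeGroundTruth(40, vCommon = 2, vSpecific = 1, vRun = 0,
                          vTrial = 0, d = 3, geometry = "random", seed = 9)
    runs <- simulateTimeseries(gt, sch, noiseSd = 0.5)
    runs[[1]][40, ] <- runs[[1]][40, ] + rnorm(40, 0, 50)   # artifact volume
    design <- buildDesign(sch)
    true <- t(t(gt@specific) + gt@common)
    sqErr <- function(bp) {
        est <- betaMatrix(bp)
        sum((est - true[as.integer(conditionLabels(bp)), ])^2)
    }
    eOls <- sqErr(estimateBetas(runs, design, robust = FALSE))
    eRob <- sqErr(estimateBetas(runs, design, robust = TRUE))
    expect_lt(eRob, eOls)
})

test_that("filtering commutes with fitting", {
    # residualizing data and design against the same basis before OLS
    # equals projecting out the basis from the fit
    set.seed(10)
    sch <- makeSchedule(nRuns = 2, seed = 11)
    gt <- makeGroundTruth(10, vCommon = 1, vSpecific = 1, vRun = 0.2,
                          vTrial = 0.2, d = 2, geometry = "random", seed = 12)
    runs <- simulateTimeseries(gt, sch, noiseSd = 1, drift = 2)
    design <- buildDesign(sch)
    bp1 <- estimateBetas(runs, design, highpass = TRUE)
    runsF <- lapply(runs, highpassFilter)
    bp2 <- estimateBetas(runsF, design, highpass = TRUE)
    expect_equal(betaMatrix(bp1), betaMatrix(bp2), tolerance = 1e-8)
})

test_that("FIR regressors tile the post-onset window", {
    sch1 <- new("TrialSchedule",
                trials = data.frame(run = 1L, trial = 1L, condition = 1L,
                                    onset = 13.5, duration = 13.5),
                nRuns = 1L, nConditions = 1L, nVolumes = 30L, TR = 2.72)
    X <- buildFirDesign(sch1, nBins = 9)
    task <- which(!is.na(X@labels$condition))
    expect_length(task, 9)
    M <- X@X[, task]
    # disjoint single-TR support
    expect_true(all(colSums(M) == 1))
    expect_true(all(rowSums(M) <= 1))
    # the 9 bins together form a 9-TR boxcar after onset
    volTimes <- (0:29) * 2.72
    box <- as.numeric(volTimes >= 13.5 & volTimes < 13.5 + 9 * 2.72)
    expect_equal(unname(rowSums(M)), box)
})

test_that("FIR estimates reproduce the HRF-convolved response per bin", {
    sch <- makeSchedule(nRuns = 2, seed = 13)
    gt <- makeGroundTruth(12, vCommon = 0, vSpecific = 4, vRun = 0,
                          vTrial = 0, d = 3, geometry = "random", seed = 14)
    runs <- simulateTimeseries(gt, sch, noiseSd = 0)
    fir <- estimateBetas(runs, buildFirDesign(sch), highpass = FALSE)
    beta <- S4Vectors::metadata(fir)$allBetas
    lab <- S4Vectors::metadata(fir)$labels
    # for a condition-run, the FIR curve scaled by the voxel pattern should
    # approximate the convolved boxcar sampled per TR (FIR bins average the
    # response over each TR, so compare against bin-averaged predictions)
    sel <- which(lab$condition == 1 & lab$run == 1)
    v <- which.max(abs(gt@specific[1, ]))
    firCurve <- beta[sel, v][order(lab$bin[sel])]
    expect_equal(which.max(abs(firCurve)), which.max(firCurve))
    # peak of the FIR response lies 2-4 TRs after onset (boxcar + HRF lag)
    expect_true(which.max(firCurve) %in% 3:6)
    # and the response returns toward baseline by bin 9 relative to peak
    expect_lt(abs(firCurve[9]), max(firCurve))
})

test_that("temporal components recover a single shared time course", {
    sch <- makeSchedule(nRuns = 2, seed = 15)
    gt <- makeGroundTruth(15, vCommon = 0, vSpecific = 3, vRun = 0,
                          vTrial = 0, d = 3, geometry = "random", seed = 16)
    runs <- simulateTimeseries(gt, sch, noiseSd = 0)
    fir <- estimateBetas(runs, buildFirDesign(sch), highpass = FALSE)
    tc <- temporalComponents(fir, 4)
    # orthonormal, ordered components
    expect_equal(crossprod(tc@timecourses), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(tc@singularValues) <= 1e-8))
    # noiseless data share one underlying time course: the first component
    # dominates
    expect_gt(tc@singularValues[1]^2 / sum(tc@singularValues^2), 0.95)
})

test_that("time-course normalization is scale invariant", {
    set.seed(17)
    s <- matrix(rnorm(27), 9, 3)
    n1 <- normalizeTimecourse(s)
    expect_equal(normalizeTimecourse(100 * s), n1, tolerance = 1e-12)
    # single series: unit norm output
    v <- rnorm(9)
    expect_equal(sqrt(sum(normalizeTimecourse(v)^2)), 1, tolerance = 1e-12)
    # identical series stay identical
    m <- cbind(v, v)
    nm <- normalizeTimecourse(m)
    expect_equal(nm[, 1], nm[, 2], ignore_attr = TRUE)
    expect_error(normalizeTimecourse(matrix(0, 9, 2)), "zero-norm")
})
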