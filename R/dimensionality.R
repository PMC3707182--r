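#' @include AllClasses.R
NULL

## Projector onto the top-d pattern components of the training class
## means: center the K x p class-mean matrix by its grand mean and take
## the top-d right singular vectors (ordered by singular value, i.e. by
## the between-class signal each component carries).
componentProjector <- function(d) {
    force(d)
    function(xtr, classes) {
        classes <- as.factor(classes)
        M <- do.call(rbind, lapply(levels(classes), function(l)
            colMeans(xtr[classes == l, , drop = FALSE])))
        M <- sweep(M, 2L, colMeans(M))
        sv <- svd(M, nu = 0, nv = d)
        sv$v[, seq_len(d), drop = FALSE]
    }
}

#' Cross-validated accuracy using the top spatial pattern components
#'
#' Per cross-validation fold, the training-fold class means are centered
#' by their grand mean and decomposed by SVD; training and test patterns
#' are projected onto the `d` most informative pattern components (largest
#' singular values) and classified with the regularized LDA in that
#' subspace.  For K classes the centered class-mean matrix has rank at
#' most K - 1, so d ranges over 1..K-1 (1--3 for four sequences).
#'
#' @param betas A [BetaPatterns-class].
#' @param d Number of pattern components to use.
#' @param regFraction Regularization fraction.
#' @return A [ClassifierResult-class].
#' @export
reducedDimAccuracy <- function(betas, d, regFraction = 0.01) {
    stopifnot(is(betas, "BetaPatterns"))
    K <- nlevels(conditionLabels(betas))
    d <- as.integer(d)
    if (d >= K) stop("d must be smaller than the number of classes (", K, ")")
    if (d < 1L) stop("d must be at least 1")
    crossvalMatrix(betaMatrix(betas), conditionLabels(betas),
                   runLabels(betas), regFraction,
                   projector = componentProjector(d))
}

#' Regular-simplex activity patterns
#'
#' K patterns forming a regular simplex embedded in a random (K-1)-
#' dimensional subspace of voxel space, centered at zero: all pairwise
#' distances are equal and the nonzero eigenvalues of the Gram matrix are
#' equal, the idealised geometry of fully distinct ("evenly spaced")
#' condition patterns.
#'
#' @param K Number of patterns (default 4).
#' @param nVoxels Number of voxels (>= K - 1).
#' @param scale Root-mean-square norm of the patterns.
#' @param seed Optional RNG seed.
#' @return K x nVoxels matrix.
#' @export
evenlySpacedPatterns <- function(K = 4, nVoxels, scale = 1, seed = NULL) {
    stopifnot(nVoxels >= K - 1L)
    if (!is.null(seed)) set.seed(seed)
    Q <- qr.Q(qr(matrix(stats::rnorm(nVoxels * (K - 1L)), nVoxels, K - 1L)))
    simplexCoords(K) %*% t(Q) * scale * sqrt(nVoxels)
}

#' Simulated accuracy curves over pattern-component dimensionality
#'
#' Predicts the accuracy profile across 1-, 2- and 3-component classifiers
#' under an assumed pattern geometry, calibrated so that the mean
#' simulated accuracy of the `matchDim`-component classifier equals an
#' observed accuracy.  Calibration is a bisection on a scalar multiplying
#' the specific-pattern norms (accuracy is monotone in signal scale);
#' simulations reuse a fixed set of random draws across bisection steps so
#' the calibrated quantity is deterministic.
#'
#' @param geometry Pattern geometry: `"random"`, `"evenly_spaced"` or
#'   `"scaled_1d"`.
#' @param dTrue True dimensionality of the generating patterns (forced to
#'   K - 1 for `evenly_spaced`, 1 for `scaled_1d`).
#' @param nVoxels,nRuns Simulated data size.
#' @param matchAccuracy Observed accuracy to match, in (chance, 1\].
#' @param matchDim Classifier dimensionality at which to match (1..K-1).
#' @param nSims Simulated datasets per bisection evaluation and per
#'   reported point.
#' @param nConditions Number of classes.
#' @param vTrial Trial-noise variance (the signal scale is calibrated
#'   against it).
#' @param tol Matching tolerance on accuracy (default 0.005).
#' @param maxIter Maximum bisection iterations (default 40).
#' @param seed Optional RNG seed.
#' @return List with `accuracy` (named vector over d = 1..K-1), `nTest`
#'   per simulated dataset, `achieved` (calibrated accuracy at
#'   `matchDim`), and `scale` (the calibrated signal multiplier).
#' @export
simulateAccuracyCurves <- function(geometry = c("random", "evenly_spaced",
                                                "scaled_1d"),
                                   dTrue = 3, nVoxels = 60, nRuns = 8,
                                   matchAccuracy, matchDim = 3, nSims = 50,
                                   nConditions = 4, vTrial = 1, tol = 0.005,
                                   maxIter = 40, seed = NULL) {
    geometry <- match.arg(geometry)
    if (geometry == "evenly_spaced") dTrue <- nConditions - 1L
    if (geometry == "scaled_1d") dTrue <- 1L
    K <- nConditions
    chance <- 1 / K
    dims <- seq_len(K - 1L)
    if (!is.null(seed)) set.seed(seed)
    simSeeds <- sample.int(.Machine$integer.max, nSims)

    simAcc <- function(s, d) {
        mean(vapply(seq_len(nSims), function(i) {
            gt <- makeGroundTruth(nVoxels, vCommon = 0,
                                  vSpecific = s^2 * vTrial, vRun = 0,
                                  vTrial = vTrial, d = dTrue,
                                  geometry = geometry,
                                  nConditions = K, seed = simSeeds[i])
            accuracy(reducedDimAccuracy(simulateBetas(gt, nRuns), d))
        }, numeric(1)))
    }

    if (matchAccuracy <= chance) {
        warning("matchAccuracy is at or below chance; returning a flat ",
                "chance curve")
        out <- stats::setNames(rep(chance, K - 1L), paste0("d", dims))
        return(list(accuracy = out, nTest = K * nRuns, achieved = chance,
                    scale = 0))
    }
    stopifnot(matchAccuracy <= 1, matchDim %in% dims)

    lo <- 0; hi <- 1
    while (simAcc(hi, matchDim) < matchAccuracy && hi < 64) hi <- hi * 2
    achieved <- NA_real_; s <- hi
    for (iter in seq_len(maxIter)) {
        s <- (lo + hi) / 2
        achieved <- simAcc(s, matchDim)
        if (abs(achieved - matchAccuracy) <= tol) break
        if (achieved < matchAccuracy) lo <- s else hi <- s
    }
    acc <- vapply(dims, function(d) simAcc(s, d), numeric(1))
    list(accuracy = stats::setNames(acc, paste0("d", dims)),
         nTest = K * nRuns, achieved = achieved, scale = s)
}
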