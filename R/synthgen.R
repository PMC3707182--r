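#' @include AllClasses.R
NULL

## Regular simplex with K vertices in K-1 dimensions, centered at zero,
## scaled so the mean squared vertex norm is 1.
simplexCoords <- function(K) {
    C <- diag(K) - 1 / K
    sv <- svd(C)
    X <- sv$u[, seq_len(K - 1L), drop = FALSE] %*%
        diag(sv$d[seq_len(K - 1L)], K - 1L)
    X / sqrt(mean(rowSums(X^2)))
}

#' Construct ground-truth voxel patterns
#'
#' Builds the generative pattern model used by all simulations.  The common
#' pattern is drawn i.i.d. Gaussian per voxel with variance `vCommon`.  The
#' condition-specific patterns live in a random `d`-dimensional subspace of
#' voxel space (spanned by orthonormal directions) with latent coordinates
#' set by `geometry`:
#' \describe{
#'   \item{random}{independent standard-normal coordinates per condition —
#'     unique but unstructured patterns.}
#'   \item{evenly_spaced}{a regular simplex: all pairwise distances equal
#'     (requires `d = nConditions - 1`).}
#'   \item{scaled_1d}{all patterns are scalar multiples of one voxel vector,
#'     with equally spaced centered scale factors (requires `d = 1`).}
#' }
#' Coordinates are scaled so the expected voxel-wise variance of the
#' specific component, averaged over conditions, equals `vSpecific`.
#'
#' @param nVoxels Number of voxels (>= nConditions).
#' @param vCommon,vSpecific,vRun,vTrial Component variances per voxel.
#' @param d Dimensionality of the specific patterns, 1--3 for 4 conditions.
#' @param geometry `"random"`, `"evenly_spaced"` or `"scaled_1d"`.
#' @param nConditions Number of conditions (default 4).
#' @param seed Optional RNG seed.
#' @return A [PatternGroundTruth-class].
#' @export
makeGroundTruth <- function(nVoxels, vCommon = 100, vSpecific = 1,
                            vRun = 1, vTrial = 1, d = 3,
                            geometry = c("random", "evenly_spaced",
                                         "scaled_1d"),
                            nConditions = 4, seed = NULL) {
    geometry <- match.arg(geometry)
    stopifnot(vCommon >= 0, vSpecific >= 0, vRun >= 0, vTrial >= 0,
              nVoxels >= nConditions)
    d <- as.integer(d)
    if (d < 1L || d > nConditions - 1L)
        stop("d must lie in 1..", nConditions - 1L)
    if (geometry == "evenly_spaced" && d != nConditions - 1L)
        stop("evenly_spaced geometry requires d = nConditions - 1")
    if (geometry == "scaled_1d" && d != 1L)
        stop("scaled_1d geometry requires d = 1")
    if (!is.null(seed)) set.seed(seed)

    common <- stats::rnorm(nVoxels, 0, sqrt(vCommon))

    ## orthonormal basis of the specific subspace, scaled to unit
    ## per-voxel mean square per direction
    B <- qr.Q(qr(matrix(stats::rnorm(nVoxels * d), nVoxels, d)))
    B <- t(B) * sqrt(nVoxels)                       # d x voxels

    C <- switch(geometry,
        random = matrix(stats::rnorm(nConditions * d), nConditions, d),
        evenly_spaced = simplexCoords(nConditions),
        scaled_1d = matrix(seq(-1, 1, length.out = nConditions) -
                               mean(seq(-1, 1, length.out = nConditions)),
                           nConditions, 1L))
    msq <- mean(rowSums(C^2))
    if (vSpecific > 0 && msq > 0) {
        C <- C * sqrt(vSpecific / msq)
    } else {
        C[] <- 0
    }
    specific <- C %*% B                             # conditions x voxels

    new("PatternGroundTruth", common = common, specific = specific,
        vCommon = vCommon, vSpecific = vSpecific, vRun = vRun,
        vTrial = vTrial, d = d, geometry = geometry)
}

#' Simulate run-wise activation patterns directly
#'
#' Draws condition x run x voxel activation estimates from the generative
#' model, bypassing the time-series level: each observation is
#' common + specific(condition) + run effect (drawn once per run, shared by
#' all conditions in that run) + independent noise with variance `vTrial`.
#'
#' @param gt A [PatternGroundTruth-class].
#' @param nRuns Number of runs (>= 2).
#' @param seed Optional RNG seed.
#' @return A [BetaPatterns-class].
#' @export
simulateBetas <- function(gt, nRuns = 8, seed = NULL) {
    stopifnot(is(gt, "PatternGroundTruth"), nRuns >= 2)
    if (!is.null(seed)) set.seed(seed)
    V <- nVoxels(gt)
    K <- nrow(gt@specific)
    condition <- rep(seq_len(K), nRuns)
    run <- rep(seq_len(nRuns), each = K)
    runEff <- matrix(stats::rnorm(nRuns * V, 0, sqrt(gt@vRun)), nRuns, V)
    betas <- matrix(0, V, K * nRuns)
    for (j in seq_len(K * nRuns)) {
        betas[, j] <- gt@common + gt@specific[condition[j], ] +
            runEff[run[j], ] +
            stats::rnorm(V, 0, sqrt(gt@vTrial))
    }
    BetaPatterns(betas, condition = factor(condition), run = run)
}

#' Simulate BOLD time series from the generative pattern model
#'
#' Each trial contributes its condition's true pattern (common + specific +
#' run effect + an independent per-trial pattern perturbation with variance
#' `vTrial`) multiplied by a 13.5 s boxcar convolved with the canonical
#' double-gamma HRF, plus i.i.d. Gaussian measurement noise per volume and
#' voxel and an optional low-frequency drift.
#'
#' @param gt A [PatternGroundTruth-class].
#' @param schedule A [TrialSchedule-class].
#' @param noiseSd Standard deviation of the additive volume noise.
#' @param drift Amplitude of a per-run linear drift (0 disables).
#' @param seed Optional RNG seed.
#' @return List of volumes x voxels matrices, one per run, with the TR as
#'   attribute `TR`.
#' @export
simulateTimeseries <- function(gt, schedule, noiseSd = 1, drift = 0,
                               seed = NULL) {
    stopifnot(is(gt, "PatternGroundTruth"), is(schedule, "TrialSchedule"))
    if (!is.null(seed)) set.seed(seed)
    V <- nVoxels(gt)
    TR <- schedule@TR
    nVol <- schedule@nVolumes
    runs <- vector("list", schedule@nRuns)
    for (r in seq_len(schedule@nRuns)) {
        runEff <- stats::rnorm(V, 0, sqrt(gt@vRun))
        tr <- schedule@trials[schedule@trials$run == r, ]
        Y <- matrix(0, nVol, V)
        for (i in seq_len(nrow(tr))) {
            reg <- convolvedBoxcar(tr$onset[i], tr$duration[i], nVol, TR)
            pat <- gt@common + gt@specific[tr$condition[i], ] + runEff +
                stats::rnorm(V, 0, sqrt(gt@vTrial))
            Y <- Y + outer(reg, pat)
        }
        if (noiseSd > 0)
            Y <- Y + matrix(stats::rnorm(nVol * V, 0, noiseSd), nVol, V)
        if (drift != 0)
            Y <- Y + outer(seq(-drift, drift, length.out = nVol),
                           rep(1, V))
        attr(Y, "TR") <- TR
        runs[[r]] <- Y
    }
    runs
}

#' Simulate per-trial behavioural records
#'
#' Generates the behavioural table that accompanies a scanning session:
#' per trial, the movement time (Gaussian around the condition mean), peak
#' force per finger, and an error flag.  Defaults mirror trained/untrained
#' performance during scanning (MT 1209 vs 1341 ms, peak force about 4.4
#' vs 4.0 N, error rate about 12%).
#'
#' @param schedule A [TrialSchedule-class].
#' @param mtMeans Mean MT (ms) per condition (recycled).
#' @param mtSd MT standard deviation (ms).
#' @param forceMeans Mean peak force (N) per condition (recycled).
#' @param forceSd Peak-force standard deviation (N).
#' @param errorRate Error probability per trial, in \[0, 1\] (recycled per
#'   condition).
#' @param seed Optional RNG seed.
#' @return data.frame with one row per trial: `run`, `trial`, `condition`,
#'   `MT_ms`, `force1`..`force5`, `error`.
#' @export
simulateBehavior <- function(schedule, mtMeans = c(1209, 1209, 1341, 1341),
                             mtSd = 150, forceMeans = 4.2, forceSd = 0.5,
                             errorRate = 0.12, seed = NULL) {
    stopifnot(is(schedule, "TrialSchedule"),
              all(errorRate >= 0 & errorRate <= 1))
    if (!is.null(seed)) set.seed(seed)
    tr <- schedule@trials
    K <- schedule@nConditions
    mtMeans <- rep_len(mtMeans, K)
    forceMeans <- rep_len(forceMeans, K)
    errorRate <- rep_len(errorRate, K)
    n <- nrow(tr)
    mt <- stats::rnorm(n, mtMeans[tr$condition], mtSd)
    forces <- matrix(stats::rnorm(5L * n, rep(forceMeans[tr$condition],
                                              each = 5L), forceSd),
                     n, 5L, byrow = TRUE)
    colnames(forces) <- paste0("force", 1:5)
    err <- stats::runif(n) < errorRate[tr$condition]
    cbind(data.frame(run = tr$run, trial = tr$trial,
                     condition = tr$condition, MT_ms = pmax(mt, 1)),
          as.data.frame(forces), data.frame(error = err))
}
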