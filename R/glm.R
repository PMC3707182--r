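#' @include AllClasses.R
NULL

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peaking about 5--6 s after
#' onset, undershoot peaking about 15--16 s, undershoot ratio 1/6),
#' truncated at 32 s, sampled on a regular grid.
#'
#' @param TR Sampling interval in seconds.
#' @param length Support of the response in seconds (default 32; the
#'   response is 0 beyond this).
#' @param peak,undershoot Shape parameters of the two gamma densities.
#' @param ratio Undershoot amplitude relative to the response.
#' @return Numeric vector of the response sampled at `0, TR, 2 TR, ...`.
#' @export
canonicalHrf <- function(TR, length = 32, peak = 6, undershoot = 16,
                         ratio = 1 / 6) {
    stopifnot(TR > 0)
    t <- seq(0, length, by = TR)
    stats::dgamma(t, peak, 1) - ratio * stats::dgamma(t, undershoot, 1)
}

## One trial's regressor sampled at volume acquisition times (v - 1) * TR.
## The boxcar * HRF convolution has the closed form H(t - onset) -
## H(t - onset - duration), with H the integral of the double-gamma
## response (a difference of gamma CDFs), so no numerical convolution is
## needed.
convolvedBoxcar <- function(onset, duration, nVolumes, TR, peak = 6,
                            undershoot = 16, ratio = 1 / 6) {
    volTimes <- (seq_len(nVolumes) - 1L) * TR
    H <- function(u)
        stats::pgamma(pmax(u, 0), peak, 1) -
            ratio * stats::pgamma(pmax(u, 0), undershoot, 1)
    H(volTimes - onset) - H(volTimes - onset - duration)
}

#' Build a canonical GLM design
#'
#' One regressor per condition per run: a boxcar of the trial duration at
#' each of that condition's trial onsets, convolved with the canonical
#' double-gamma HRF and sampled at volume times, plus an intercept per run.
#'
#' @param schedule A [TrialSchedule-class].
#' @return A [DesignMatrix-class] spanning all runs (volumes stacked run by
#'   run).
#' @export
buildDesign <- function(schedule) {
    stopifnot(is(schedule, "TrialSchedule"))
    K <- schedule@nConditions
    R <- schedule@nRuns
    nVol <- schedule@nVolumes
    cols <- list(); labels <- list()
    for (r in seq_len(R)) {
        tr <- schedule@trials[schedule@trials$run == r, ]
        for (k in seq_len(K)) {
            tk <- tr[tr$condition == k, ]
            reg <- rep(0, nVol)
            for (i in seq_len(nrow(tk)))
                reg <- reg + convolvedBoxcar(tk$onset[i], tk$duration[i],
                                             nVol, schedule@TR)
            cols[[length(cols) + 1L]] <- list(run = r, col = reg)
            labels[[length(labels) + 1L]] <-
                data.frame(regressor = sprintf("cond%d.run%d", k, r),
                           condition = k, run = r, bin = NA_integer_)
        }
    }
    assembleDesign(cols, labels, R, nVol)
}

#' Build a finite-impulse-response GLM design
#'
#' For each condition and run, `nBins` regressors, one per TR after trial
#' onset: bin k of a trial covers the k-th TR-wide window after the trial's
#' onset.  With the default 9 bins the model spans 9 TRs of response,
#' estimating the trial time course without assuming an HRF shape.
#'
#' @param schedule A [TrialSchedule-class].
#' @param nBins Number of FIR bins (default 9).
#' @return A [DesignMatrix-class] with a `bin` label per regressor.
#' @export
buildFirDesign <- function(schedule, nBins = 9) {
    stopifnot(is(schedule, "TrialSchedule"), nBins >= 1)
    K <- schedule@nConditions
    R <- schedule@nRuns
    nVol <- schedule@nVolumes
    TR <- schedule@TR
    volTimes <- (seq_len(nVol) - 1L) * TR
    cols <- list(); labels <- list()
    for (r in seq_len(R)) {
        tr <- schedule@trials[schedule@trials$run == r, ]
        for (k in seq_len(K)) {
            tk <- tr[tr$condition == k, ]
            for (b in seq_len(nBins)) {
                reg <- rep(0, nVol)
                for (i in seq_len(nrow(tk))) {
                    lo <- tk$onset[i] + (b - 1L) * TR
                    reg <- reg + as.numeric(volTimes >= lo - 1e-9 &
                                            volTimes < lo + TR - 1e-9)
                }
                cols[[length(cols) + 1L]] <- list(run = r, col = reg)
                labels[[length(labels) + 1L]] <-
                    data.frame(regressor = sprintf("cond%d.run%d.bin%d",
                                                   k, r, b),
                               condition = k, run = r, bin = b)
            }
        }
    }
    assembleDesign(cols, labels, R, nVol)
}

assembleDesign <- function(cols, labels, R, nVol) {
    nTask <- length(cols)
    X <- matrix(0, R * nVol, nTask + R)
    for (j in seq_len(nTask)) {
        r <- cols[[j]]$run
        X[((r - 1L) * nVol + 1L):(r * nVol), j] <- cols[[j]]$col
    }
    for (r in seq_len(R))
        X[((r - 1L) * nVol + 1L):(r * nVol), nTask + r] <- 1
    labels <- do.call(rbind, labels)
    labels <- rbind(labels,
                    data.frame(regressor = sprintf("intercept.run%d",
                                                   seq_len(R)),
                               condition = NA_integer_,
                               run = seq_len(R), bin = NA_integer_))
    new("DesignMatrix", X = X, labels = labels,
        volumeRun = rep(seq_len(R), each = nVol))
}

## Discrete cosine basis of all frequencies below `cutoff` (Hz), excluding
## the constant; frequency of DCT component k over N volumes is
## k / (2 N TR).
dctDriftBasis <- function(nVolumes, TR, cutoff = 1 / 128) {
    kMax <- floor(2 * nVolumes * TR * cutoff)
    if (kMax < 1L) return(NULL)
    n <- seq_len(nVolumes) - 0.5
    sapply(seq_len(kMax), function(k)
        cos(pi * k * n / nVolumes) * sqrt(2 / nVolumes))
}

#' High-pass filter a run by discrete-cosine residualisation
#'
#' Removes, from every voxel's time series, the projection onto a
#' discrete-cosine basis of all frequencies below the cutoff, including
#' the constant.  Applied identically to data and design before fitting,
#' so filtering commutes with estimation.
#'
#' @param run Volumes x voxels matrix (a single run).
#' @param TR Repetition time in seconds (taken from `attr(run, "TR")` if
#'   missing).
#' @param cutoff Cutoff frequency in Hz (default 1/128).
#' @return Filtered matrix of the same shape.
#' @export
highpassFilter <- function(run, TR = attr(run, "TR"), cutoff = 1 / 128) {
    run <- as.matrix(run)
    if (nrow(run) < 8L) stop("run must have at least 8 volumes")
    if (is.null(TR)) stop("TR must be supplied")
    B <- cbind(rep(1, nrow(run)), dctDriftBasis(nrow(run), TR, cutoff))
    out <- run - B %*% qr.solve(B, run)
    attr(out, "TR") <- TR
    out
}

#' Estimate activation patterns from BOLD runs
#'
#' Per-voxel least squares of the (high-pass filtered) time series on the
#' (identically filtered) design.  With `robust = TRUE`, volumes are
#' down-weighted by a Tukey bisquare function of their standardized
#' cross-voxel mean squared residual (weights shared across voxels, two
#' reweighting iterations), protecting the estimates against artifactual
#' volumes.
#'
#' @param runs List of volumes x voxels matrices, one per run.
#' @param design A [DesignMatrix-class] spanning the same runs.
#' @param robust Use iteratively reweighted least squares.
#' @param highpass Apply the 1/128 Hz high-pass filter to data and design
#'   (default TRUE).
#' @param cutoff High-pass cutoff in Hz.
#' @return A [BetaPatterns-class] holding the task-regressor coefficients
#'   (intercepts and, for FIR designs, the full bin grid are kept in
#'   `metadata()$allBetas` with their labels).
#' @export
estimateBetas <- function(runs, design, robust = FALSE, highpass = TRUE,
                          cutoff = 1 / 128) {
    stopifnot(is(design, "DesignMatrix"), is.list(runs))
    TR <- attr(runs[[1L]], "TR")
    Y <- do.call(rbind, lapply(runs, as.matrix))
    stopifnot(nrow(Y) == nrow(design@X))
    X <- design@X
    if (highpass) {
        for (r in unique(design@volumeRun)) {
            sel <- design@volumeRun == r
            Y[sel, ] <- highpassFilter(Y[sel, , drop = FALSE], TR = TR,
                                       cutoff = cutoff)
            X[sel, ] <- highpassFilter(X[sel, , drop = FALSE], TR = TR,
                                       cutoff = cutoff)
        }
        ## run intercepts are absorbed by the filter; refit them so the
        ## design stays full rank
        for (r in unique(design@volumeRun))
            X[design@volumeRun == r,
              which(is.na(design@labels$condition) & design@labels$run == r)] <- 1
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
    beta <- qr.coef(qrX, Y)
    if (robust) {
        ## Volume weights: Tukey bisquare of the volume's cross-voxel mean
        ## squared residual, standardized as the excess ratio over the
        ## median msr.  The window (c = 40, i.e. zero weight beyond ~40x
        ## the median) is wide because a gross artifact contaminates the
        ## initial fit and inflates the residuals of clean task volumes by
        ## up to several-fold; only clearly artifactual volumes should be
        ## suppressed.  Two reweighting iterations.
        cWin <- 40
        for (iter in 1:2) {
            res <- Y - X %*% beta
            msr <- rowMeans(res^2)
            med <- stats::median(msr)
            u <- if (med > 0) pmax(msr / med - 1, 0) else rep(0, length(msr))
            w <- ifelse(u >= cWin, 0, (1 - (u / cWin)^2)^2)
            sw <- sqrt(w)
            qrW <- qr(X * sw)
            if (qrW$rank < ncol(X)) stop("weighted design is rank deficient")
            beta <- qr.coef(qrW, Y * sw)
        }
    }
    task <- !is.na(design@labels$condition)
    lab <- design@labels[task, ]
    if (all(is.na(lab$bin))) {
        bp <- BetaPatterns(t(beta[task, , drop = FALSE]),
                           condition = factor(lab$condition), run = lab$run)
    } else {
        ## FIR design: return bin-1 grid as the pattern currency, keep all
        ## bins in metadata for temporal analyses
        first <- task & design@labels$bin %in% c(NA_integer_, 1L)
        lab1 <- design@labels[first, ]
        bp <- BetaPatterns(t(beta[first, , drop = FALSE]),
                           condition = factor(lab1$condition),
                           run = lab1$run)
    }
    S4Vectors::metadata(bp)$allBetas <- beta
    S4Vectors::metadata(bp)$labels <- design@labels
    bp
}

## Extract the FIR coefficient array (bins x observations x voxels) from
## the metadata of a BetaPatterns estimated with a FIR design.
firArray <- function(bp) {
    beta <- S4Vectors::metadata(bp)$allBetas
    lab <- S4Vectors::metadata(bp)$labels
    task <- !is.na(lab$condition) & !is.na(lab$bin)
    if (!any(task)) stop("no FIR regressors found; use buildFirDesign()")
    lab <- lab[task, ]
    beta <- beta[task, , drop = FALSE]
    bins <- sort(unique(lab$bin))
    obs <- unique(lab[, c("condition", "run")])
    arr <- array(NA_real_, c(length(bins), nrow(obs), ncol(beta)))
    for (i in seq_len(nrow(obs))) {
        sel <- lab$condition == obs$condition[i] & lab$run == obs$run[i]
        arr[, i, ] <- beta[sel, ][order(lab$bin[sel]), ]
    }
    attr(arr, "obs") <- obs
    arr
}

#' Temporal components of the FIR response
#'
#' Reorganizes FIR estimates as bins x (observations by voxels), removes
#' the per-bin mean, and takes a singular value decomposition.  The
#' returned component time courses are shared across voxels; the weight of
#' each component for every voxel and condition-run observation can be
#' used as classifier input in place of canonical-HRF betas.
#'
#' @param firBetas A [BetaPatterns-class] estimated with [buildFirDesign()].
#' @param nComponents Number of components to return.
#' @return A [TemporalComponents-class].
#' @export
temporalComponents <- function(firBetas, nComponents = 4) {
    arr <- firArray(firBetas)
    nBins <- dim(arr)[1L]; nObs <- dim(arr)[2L]; V <- dim(arr)[3L]
    if (V < 2L) stop("at least 2 voxels required")
    M <- matrix(arr, nBins, nObs * V)
    M <- M - rowMeans(M)
    if (max(abs(M)) == 0) stop("degenerate (all-zero) FIR input")
    nComponents <- min(nComponents, nBins, ncol(M))
    sv <- svd(M, nu = nComponents, nv = nComponents)
    w <- t(sv$v[, seq_len(nComponents), drop = FALSE] *
               rep(sv$d[seq_len(nComponents)], each = nrow(sv$v)))
    new("TemporalComponents",
        timecourses = sv$u[, seq_len(nComponents), drop = FALSE],
        singularValues = sv$d[seq_len(nComponents)],
        weights = array(w, c(nComponents, nObs, V)))
}

#' Normalize time courses by the L2 norm of their average
#'
#' Divides every series by the L2 norm of the mean series of the set, so
#' that time courses from regions with different overall response
#' amplitudes become comparable; the operation is invariant to a common
#' rescaling of all inputs.
#'
#' @param series Matrix with one series per column (time in rows), or a
#'   single numeric vector.
#' @return Object of the same shape.
#' @export
normalizeTimecourse <- function(series) {
    m <- as.matrix(series)
    avg <- rowMeans(m)
    nrm <- sqrt(sum(avg^2))
    if (nrm == 0) stop("zero-norm average series")
    out <- m / nrm
    if (is.vector(series)) drop(out) else out
}
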