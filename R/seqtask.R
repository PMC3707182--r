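#' @include AllClasses.R
NULL

## A run of more than three neighbouring digits means four consecutive
## positions stepping by +1 (ascending) or -1 (descending).
hasLongNeighbourRun <- function(s) {
    d <- diff(s)
    for (i in seq_len(length(d) - 2L)) {
        w <- d[i:(i + 2L)]
        if (all(w == 1L) || all(w == -1L)) return(TRUE)
    }
    FALSE
}

## All permutations of 1..5, as a 120 x 5 integer matrix.
allPermutations5 <- function() {
    out <- matrix(0L, 120L, 5L)
    k <- 0L
    rec <- function(prefix, rest) {
        if (length(rest) == 0L) {
            k <<- k + 1L
            out[k, ] <<- prefix
            return(invisible())
        }
        for (j in seq_along(rest))
            rec(c(prefix, rest[j]), rest[-j])
    }
    rec(integer(0), 1:5)
    out
}

validPermutationPool <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            p <- allPermutations5()
            cache <<- p[!apply(p, 1L, hasLongNeighbourRun), , drop = FALSE]
        }
        cache
    }
})

#' Check a finger sequence against the task constraints
#'
#' A valid sequence uses each of the five fingers exactly once and contains
#' no ascending or descending run of more than three neighbouring digits.
#'
#' @param sequence Integer vector of length 5.
#' @return Logical scalar.
#' @examples
#' isValidSequence(c(3, 2, 5, 1, 4))  # TRUE
#' isValidSequence(1:5)               # FALSE: ascending run of 5 neighbours
#' @export
isValidSequence <- function(sequence) {
    length(sequence) == 5L && setequal(sequence, 1:5) &&
        !hasLongNeighbourRun(as.integer(sequence))
}

#' Draw a pool of valid finger sequences
#'
#' Draws `nSequences` distinct sequences uniformly from the set of all
#' permutations of 1..5 satisfying the neighbour-run constraint (114 of the
#' 120 permutations).
#'
#' @param nSequences Number of sequences to draw.
#' @param seed Optional RNG seed.
#' @return A [SequenceSet-class].
#' @examples
#' pool <- generateSequencePool(12, seed = 1)
#' @export
generateSequencePool <- function(nSequences, seed = NULL) {
    valid <- validPermutationPool()
    if (nSequences > nrow(valid))
        stop("nSequences exceeds the number of valid sequences (",
             nrow(valid), ")")
    if (nSequences < 1L) stop("nSequences must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    SequenceSet(valid[sample.int(nrow(valid), nSequences), , drop = FALSE])
}

#' Randomly partition a sequence pool into equal groups
#'
#' Mirrors the experimental assignment of a 12-sequence pool to trained,
#' untrained-test and untrained-scan sets of four.
#'
#' @param pool A [SequenceSet-class].
#' @param nGroups Number of groups; must divide the pool size.
#' @param seed Optional RNG seed.
#' @return List of [SequenceSet-class] objects forming a partition of `pool`.
#' @export
splitPool <- function(pool, nGroups, seed = NULL) {
    n <- nSequences(pool)
    if (n %% nGroups != 0L)
        stop("pool size (", n, ") is not divisible by nGroups (", nGroups, ")")
    if (!is.null(seed)) set.seed(seed)
    idx <- sample.int(n)
    per <- n %/% nGroups
    lapply(seq_len(nGroups), function(g)
        pool[sort(idx[((g - 1L) * per + 1L):(g * per)])])
}

#' @rdname seqrep-generics
#' @export
setMethod("transitions", "SequenceSet", function(x) {
    s <- x@sequences
    as.vector(t(matrix(paste(s[, -5L], s[, -1L], sep = ">"),
                       nrow = nrow(s))))
})

#' Percentage of shared digit transitions between sequence sets
#'
#' Each five-press sequence contains four ordered digit transitions.  The
#' overlap is the percentage of the probe set's transitions (counted per
#' occurrence) that occur anywhere in the reference set.
#'
#' @param reference,probe [SequenceSet-class] objects.
#' @return Percentage in \[0, 100\].
#' @examples
#' a <- SequenceSet(rbind(c(1, 3, 5, 2, 4)))
#' b <- SequenceSet(rbind(c(1, 3, 5, 4, 2)))
#' transitionOverlap(a, b)  # 50: transitions 1>3 and 3>5 are shared
#' @export
transitionOverlap <- function(reference, probe) {
    stopifnot(is(reference, "SequenceSet"), is(probe, "SequenceSet"))
    100 * mean(transitions(probe) %in% transitions(reference))
}

#' Monte-Carlo mean transition overlap between trained and untrained sets
#'
#' Repeatedly draws a pool of 12 valid sequences, splits it at random into
#' three sets of four (trained, untrained-test, untrained-scan), and
#' computes the percentage of the untrained-scan set's 16 transitions that
#' occur anywhere in the trained set.
#'
#' @param nSims Number of Monte-Carlo pools.
#' @param poolSize,nGroups Pool size and number of groups.
#' @param seed Optional RNG seed.
#' @return Mean overlap percentage across pools.
#' @export
simulateTransitionOverlap <- function(nSims = 2000, poolSize = 12,
                                      nGroups = 3, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    valid <- validPermutationPool()
    mean(vapply(seq_len(nSims), function(i) {
        pool <- SequenceSet(valid[sample.int(nrow(valid), poolSize), ,
                                  drop = FALSE])
        groups <- splitPool(pool, nGroups)
        transitionOverlap(groups[[1L]], groups[[nGroups]])
    }, numeric(1)))
}

## ---------------------------------------------------------------------------
## Force traces and press detection
## ---------------------------------------------------------------------------

#' Detect key presses in a five-finger force trace
#'
#' A press is recognised at the first sample where one finger's force
#' reaches `pressThreshold` (2.5 N) while all other fingers are strictly
#' below `otherThreshold` (2.2 N).  A finger cannot re-trigger until its
#' force has fallen below `otherThreshold` again; a force of exactly 2.2 N
#' on another finger blocks the press.
#'
#' @param trace List with elements `time` (seconds, uniform sampling) and
#'   `forces` (samples x 5 matrix, Newtons), as produced by
#'   [simulateForceTrace()].
#' @param pressThreshold,otherThreshold Detection thresholds in Newtons.
#' @return data.frame with columns `finger` and `onset` (s), ordered by
#'   onset.
#' @export
detectPresses <- function(trace, pressThreshold = 2.5, otherThreshold = 2.2) {
    f <- trace$forces
    if (is.null(f) || nrow(f) == 0L) stop("empty force trace")
    stopifnot(ncol(f) == 5L, length(trace$time) == nrow(f), all(f >= 0))
    armed <- rep(TRUE, 5L)
    finger <- integer(0)
    onset <- numeric(0)
    for (i in seq_len(nrow(f))) {
        armed <- armed | f[i, ] < otherThreshold
        for (k in 1:5) {
            if (armed[k] && f[i, k] >= pressThreshold &&
                all(f[i, -k] < otherThreshold)) {
                finger <- c(finger, k)
                onset <- c(onset, trace$time[i])
                armed[k] <- FALSE
            }
        }
    }
    data.frame(finger = finger, onset = onset)
}

#' Simulate an isometric force trace for one trial
#'
#' Generates a five-channel force trace in which each press is a smooth
#' bump that reaches the 2.5 N detection threshold exactly at its nominal
#' onset, peaks near `peakForce`, and stays above 2.2 N for `pressDuration`
#' seconds (so overlapping presses cannot double-trigger under the
#' detection rule).
#'
#' @param sequence Integer vector of fingers, in press order.
#' @param onsets Press onsets in seconds (non-decreasing, spaced by more
#'   than `pressDuration`).
#' @param peakForce Peak force in Newtons (> 2.5).
#' @param pressDuration Time above 2.2 N per press, seconds.
#' @param fs Sampling rate, Hz (default 200: 5 ms resolution).
#' @param noiseSd Standard deviation of non-negative baseline noise (kept
#'   below threshold; values are clipped at 0).
#' @param seed Optional RNG seed.
#' @return List with `time` and `forces`, the [detectPresses()] input.
#' @export
simulateForceTrace <- function(sequence, onsets, peakForce = 4.5,
                               pressDuration = 0.2, fs = 200,
                               noiseSd = 0, seed = NULL) {
    stopifnot(length(sequence) == length(onsets), peakForce > 2.6,
              !is.unsorted(onsets))
    if (any(diff(onsets) <= pressDuration))
        stop("onsets must be spaced by more than pressDuration")
    if (!is.null(seed)) set.seed(seed)
    tEnd <- max(onsets) + pressDuration + 0.3
    time <- seq(0, tEnd, by = 1 / fs)
    forces <- matrix(0, length(time), 5L)
    for (j in seq_along(sequence)) {
        ph <- (time - onsets[j]) / pressDuration
        active <- ph >= 0 & ph <= 1
        ## bump floor of 2.6 N leaves a 0.1 N margin above both thresholds,
        ## so sub-threshold measurement noise cannot move a detected onset
        forces[active, sequence[j]] <-
            2.6 + (peakForce - 2.6) * sin(pi * ph[active])
    }
    if (noiseSd > 0)
        forces <- forces + matrix(abs(stats::rnorm(length(forces), 0, noiseSd)),
                                  nrow(forces))
    list(time = time, forces = forces)
}

#' Movement time of a completed sequence
#'
#' Time from the first to the fifth press onset, in milliseconds.  Onset-
#' based timing is invariant to release dynamics.
#'
#' @param presses data.frame from [detectPresses()].
#' @return Movement time in ms.
#' @export
movementTime <- function(presses) {
    if (nrow(presses) < 5L)
        stop(errorCondition(
            sprintf("incomplete trial: %d of 5 presses detected",
                    nrow(presses)),
            class = c("incompleteTrial", "error", "condition")))
    1000 * (presses$onset[5L] - presses$onset[1L])
}

## ---------------------------------------------------------------------------
## Sequence-specific learning test
## ---------------------------------------------------------------------------

#' Test for a sequence-specific learning advantage
#'
#' Regresses each subject's post-test trained-minus-untrained MT difference
#' on the corresponding pre-test difference and tests whether the intercept
#' differs from zero: a non-zero intercept is a sequence-specific advantage
#' that is not explained by pre-existing differences between the sequence
#' sets.
#'
#' @param preDiff,postDiff Per-subject paired MT differences (ms).
#' @return List with `intercept` (ms), `se`, `t` (n - 2 degrees of
#'   freedom), `p` (two-sided) and `df`.
#' @export
sequenceSpecificTest <- function(preDiff, postDiff) {
    stopifnot(length(preDiff) == length(postDiff))
    n <- length(preDiff)
    if (n < 3L) stop("at least 3 subjects required")
    fit <- stats::lm(postDiff ~ preDiff)
    cf <- summary(fit)$coefficients
    est <- unname(cf[1L, 1L]); se <- unname(cf[1L, 2L])
    if (se == 0) {         # exact fit: define t = 0 for a zero intercept
        tval <- if (est == 0) 0 else sign(est) * Inf
        pval <- if (est == 0) 1 else 0
    } else {
        tval <- unname(cf[1L, 3L]); pval <- unname(cf[1L, 4L])
    }
    list(intercept = est, se = se, t = tval, p = pval, df = n - 2L)
}
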