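#' @include AllClasses.R
NULL

#' Build a run-structured trial schedule
#'
#' Constructs the scanning schedule of the experiment: per run, randomly
#' ordered trials of 13.5 s (equal numbers per condition) with randomly
#' interspersed rest phases of the same length, on a fixed 13.5 s slot
#' grid.  Defaults follow the scanning design: 8 runs of 110 volumes at
#' TR 2.72 s, 16 trials per run (4 conditions x 4 trials) plus 4 rest
#' phases.
#'
#' @param nRuns Number of runs.
#' @param nConditions Number of sequence conditions.
#' @param trialsPerCondition Trials per condition per run.
#' @param nRest Rest phases per run.
#' @param trialDuration Trial (and rest) duration in seconds.
#' @param TR Repetition time in seconds.
#' @param nVolumes Volumes per run (after discarding initial volumes).
#' @param seed Optional RNG seed controlling trial order.
#' @return A [TrialSchedule-class].
#' @export
makeSchedule <- function(nRuns = 8, nConditions = 4, trialsPerCondition = 4,
                         nRest = 4, trialDuration = 13.5, TR = 2.72,
                         nVolumes = 110, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nTrials <- nConditions * trialsPerCondition
    nSlots <- nTrials + nRest
    if (nSlots * trialDuration > nVolumes * TR + 1e-9)
        stop("schedule does not fit into the run: ", nSlots, " slots of ",
             trialDuration, " s exceed ", nVolumes * TR, " s")
    rows <- lapply(seq_len(nRuns), function(r) {
        slots <- sample(c(rep(seq_len(nConditions), trialsPerCondition),
                          rep(NA_integer_, nRest)))
        keep <- !is.na(slots)
        data.frame(run = r, trial = seq_len(sum(keep)),
                   condition = slots[keep],
                   onset = (which(keep) - 1L) * trialDuration,
                   duration = trialDuration)
    })
    new("TrialSchedule", trials = do.call(rbind, rows),
        nRuns = as.integer(nRuns), nConditions = as.integer(nConditions),
        nVolumes = as.integer(nVolumes), TR = TR)
}
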