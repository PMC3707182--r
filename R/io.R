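#' @include AllClasses.R
NULL

#' Write and read BIDS-style events tables
#'
#' One `events.tsv` per run with columns `onset`, `duration`,
#' `trial_type`, the standard sidecar layout for task fMRI.
#'
#' @param schedule A [TrialSchedule-class].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return `writeEventsTsv` returns the written paths invisibly;
#'   `readEventsTsv` returns a [TrialSchedule-class].
#' @export
writeEventsTsv <- function(schedule, dir, prefix = "run") {
    stopifnot(is(schedule, "TrialSchedule"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(schedule@nRuns)
    for (r in seq_len(schedule@nRuns)) {
        tr <- schedule@trials[schedule@trials$run == r, ]
        paths[r] <- file.path(dir, sprintf("%s-%02d_events.tsv", prefix, r))
        utils::write.table(
            data.frame(onset = tr$onset, duration = tr$duration,
                       trial_type = sprintf("seq%d", tr$condition)),
            paths[r], sep = "\t", row.names = FALSE, quote = FALSE)
    }
    invisible(paths)
}

#' @rdname writeEventsTsv
#' @param paths Character vector of `events.tsv` paths, one per run, in
#'   run order.
#' @param TR,nVolumes Acquisition parameters of the runs.
#' @export
readEventsTsv <- function(paths, TR = 2.72, nVolumes = 110) {
    rows <- lapply(seq_along(paths), function(r) {
        ev <- utils::read.delim(paths[r])
        data.frame(run = r, trial = seq_len(nrow(ev)),
                   condition = as.integer(factor(ev$trial_type)),
                   onset = ev$onset, duration = ev$duration)
    })
    trials <- do.call(rbind, rows)
    new("TrialSchedule", trials = trials,
        nRuns = length(paths),
        nConditions = length(unique(trials$condition)),
        nVolumes = as.integer(nVolumes), TR = TR)
}

#' Write and read behavioural records as tab-separated tables
#'
#' One row per trial: subject, run, trial, sequence condition, movement
#' time, peak force per finger, error flag.
#'
#' @param records Behavioural data.frame (see [simulateBehavior()]).
#' @param path Output TSV path.
#' @param subject Subject identifier written with the records.
#' @return `writeBehavioralRecords` returns `path` invisibly;
#'   `readBehavioralRecords` returns the data.frame.
#' @export
writeBehavioralRecords <- function(records, path, subject = 1L) {
    out <- cbind(subject = subject, records)
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname writeBehavioralRecords
#' @export
readBehavioralRecords <- function(path) {
    utils::read.delim(path)
}

#' Write and read 4-D BOLD runs as NIfTI
#'
#' Serializes simulated runs to one 4-D NIfTI file per run; voxels are
#' unpacked onto the given sheet/grid geometry.
#'
#' @param runs List of volumes x voxels matrices (see
#'   [simulateTimeseries()]).
#' @param geometry A [VoxelGeometry-class] describing the voxel layout.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Written paths, invisibly.
#' @export
writeBoldNifti <- function(runs, geometry, dir, prefix = "bold") {
    stopifnot(is(geometry, "VoxelGeometry"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    co <- coordinates(geometry)
    nx <- length(unique(co[, 1L])); ny <- length(unique(co[, 2L]))
    TR <- attr(runs[[1L]], "TR")
    paths <- character(length(runs))
    for (r in seq_along(runs)) {
        Y <- runs[[r]]
        arr <- array(t(Y), c(nx, ny, 1L, nrow(Y)))
        img <- RNifti::asNifti(arr)
        if (!is.null(TR)) RNifti::pixdim(img)[4L] <- TR
        paths[r] <- file.path(dir, sprintf("%s-%02d.nii", prefix, r))
        RNifti::writeNifti(img, paths[r])
    }
    invisible(paths)
}

#' @rdname writeBoldNifti
#' @param paths NIfTI paths, one per run.
#' @export
readBoldNifti <- function(paths) {
    lapply(paths, function(p) {
        img <- RNifti::readNifti(p)
        d <- dim(img)
        Y <- t(matrix(img, prod(d[1:3]), d[4L]))
        attr(Y, "TR") <- RNifti::pixdim(img)[4L]
        Y
    })
}

#' Write activation estimates as NIfTI plus a label table
#'
#' One volume per condition-run estimate, with a TSV table mapping volume
#' index to condition and run.
#'
#' @param betas A [BetaPatterns-class].
#' @param geometry A [VoxelGeometry-class].
#' @param path Output NIfTI path (the label table gets the same path with
#'   extension `.tsv`).
#' @return The NIfTI path, invisibly.
#' @export
writeBetasNifti <- function(betas, geometry, path) {
    stopifnot(is(betas, "BetaPatterns"), is(geometry, "VoxelGeometry"),
              nVoxels(betas) == nVoxels(geometry))
    co <- coordinates(geometry)
    nx <- length(unique(co[, 1L])); ny <- length(unique(co[, 2L]))
    B <- SummarizedExperiment::assay(betas, "betas")
    arr <- array(B, c(nx, ny, 1L, ncol(B)))
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    utils::write.table(
        data.frame(volume = seq_len(ncol(B)),
                   condition = as.character(conditionLabels(betas)),
                   run = runLabels(betas)),
        sub("\\.nii(\\.gz)?$", ".tsv", path),
        sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Serialize and restore ground-truth parameters
#'
#' Writes the generative parameters (not the realized patterns) of a
#' [PatternGroundTruth-class] to a YAML config file, and rebuilds an
#' equivalent ground truth from one.
#'
#' @param gt A [PatternGroundTruth-class].
#' @param path Config file path.
#' @param seed Seed used when rebuilding the patterns.
#' @return `writeGroundTruthConfig` returns `path` invisibly;
#'   `readGroundTruthConfig` returns a [PatternGroundTruth-class].
#' @export
writeGroundTruthConfig <- function(gt, path) {
    stopifnot(is(gt, "PatternGroundTruth"))
    yaml::write_yaml(list(nVoxels = nVoxels(gt),
                          nConditions = nrow(gt@specific),
                          vCommon = gt@vCommon, vSpecific = gt@vSpecific,
                          vRun = gt@vRun, vTrial = gt@vTrial,
                          d = gt@d, geometry = gt@geometry), path)
    invisible(path)
}

#' @rdname writeGroundTruthConfig
#' @export
readGroundTruthConfig <- function(path, seed = NULL) {
    p <- yaml::read_yaml(path)
    makeGroundTruth(p$nVoxels, vCommon = p$vCommon,
                    vSpecific = p$vSpecific, vRun = p$vRun,
                    vTrial = p$vTrial, d = p$d, geometry = p$geometry,
                    nConditions = p$nConditions, seed = seed)
}
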