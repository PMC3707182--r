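#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## SequenceSet
## ---------------------------------------------------------------------------

#' Set of five-finger movement sequences
#'
#' A `SequenceSet` holds ordered finger sequences, each a permutation of the
#' digits 1--5 (1 = thumb, 5 = little finger).  Valid sequences contain no
#' ascending or descending run of more than three neighbouring digits
#' (1-2-3-4 anywhere is forbidden, 1-2-3 is allowed).
#'
#' @slot sequences Integer matrix, one row per sequence, five columns.
#'
#' @seealso [generateSequencePool()], [splitPool()], [transitionOverlap()]
#' @export
setClass("SequenceSet", representation(sequences = "matrix"))

setValidity("SequenceSet", function(object) {
    s <- object@sequences
    if (ncol(s) != 5L)
        return("sequences must have 5 columns")
    if (nrow(s) == 0L)
        return("SequenceSet must contain at least one sequence")
    if (!all(apply(s, 1L, function(x) setequal(x, 1:5))))
        return("every sequence must be a permutation of 1..5")
    if (any(apply(s, 1L, hasLongNeighbourRun)))
        return("sequences must not contain a run of more than 3 neighbouring digits")
    if (anyDuplicated(apply(s, 1L, paste, collapse = "")))
        return("sequences within a set must be distinct")
    TRUE
})

#' @rdname SequenceSet-class
#' @param sequences Integer matrix (rows = sequences) or list of integer
#'   vectors of length 5.
#' @export
SequenceSet <- function(sequences) {
    if (is.list(sequences))
        sequences <- do.call(rbind, sequences)
    sequences <- matrix(as.integer(sequences), nrow = nrow(sequences))
    new("SequenceSet", sequences = sequences)
}

#' @rdname seqrep-generics
#' @export
setMethod("sequences", "SequenceSet", function(x) x@sequences)

#' @rdname seqrep-generics
#' @export
setMethod("nSequences", "SequenceSet", function(x) nrow(x@sequences))

#' @rdname seqrep-generics
#' @export
setMethod("length", "SequenceSet", function(x) nrow(x@sequences))

#' @describeIn SequenceSet-class Subset a sequence set.
#' @param x,i A `SequenceSet` and row index.
#' @export
setMethod("[", "SequenceSet", function(x, i) {
    SequenceSet(x@sequences[i, , drop = FALSE])
})

setMethod("show", "SequenceSet", function(object) {
    cat("SequenceSet with", nSequences(object), "sequences\n")
    n <- min(6L, nSequences(object))
    lab <- apply(object@sequences[seq_len(n), , drop = FALSE], 1L,
                 paste, collapse = "-")
    cat(" ", paste(lab, collapse = "  "),
        if (nSequences(object) > n) "..." else "", "\n")
})

## ---------------------------------------------------------------------------
## TrialSchedule
## ---------------------------------------------------------------------------

#' Run-structured trial schedule
#'
#' Describes the timing of an imaging session: per run, an ordered list of
#' trials (condition, onset, duration) plus interspersed rest phases, the
#' number of volumes per run and the repetition time (TR).
#'
#' @slot trials data.frame with columns `run`, `trial`, `condition`,
#'   `onset` (s, within run) and `duration` (s).
#' @slot nRuns,nConditions,nVolumes Integer scalars.
#' @slot TR Repetition time in seconds.
#'
#' @seealso [makeSchedule()]
#' @export
setClass("TrialSchedule",
         representation(trials = "data.frame", nRuns = "integer",
                        nConditions = "integer", nVolumes = "integer",
                        TR = "numeric"))

setValidity("TrialSchedule", function(object) {
    tr <- object@trials
    need <- c("run", "trial", "condition", "onset", "duration")
    if (!all(need %in% names(tr)))
        return(paste("trials must have columns", paste(need, collapse = ", ")))
    if (object@TR <= 0)
        return("TR must be positive")
    for (r in seq_len(object@nRuns)) {
        t_r <- tr[tr$run == r, ]
        t_r <- t_r[order(t_r$onset), ]
        if (nrow(t_r) > 1L &&
            any(t_r$onset[-1L] < (t_r$onset + t_r$duration)[-nrow(t_r)] - 1e-9))
            return("trials within a run must not overlap")
        if (any(t_r$onset + t_r$duration > object@nVolumes * object@TR + 1e-9))
            return("trials must end before the end of the run")
    }
    TRUE
})

setMethod("show", "TrialSchedule", function(object) {
    cat("TrialSchedule:", object@nRuns, "runs x", object@nVolumes,
        "volumes (TR", object@TR, "s),",
        sum(object@trials$run == 1L), "trials/run,",
        object@nConditions, "conditions\n")
})

## ---------------------------------------------------------------------------
## PatternGroundTruth
## ---------------------------------------------------------------------------

#' Generative description of voxel activity patterns
#'
#' The generative model behind all simulations: each condition's true
#' activity pattern is the sum of a pattern component common to all
#' conditions and a condition-specific component of controlled
#' dimensionality and geometry.  Observed patterns add a run-common effect
#' (drawn once per run) and independent trial noise.  All components are
#' parameterised by their expected voxel-wise variance.
#'
#' @slot common Numeric vector, the common pattern (one value per voxel).
#' @slot specific Numeric matrix, conditions x voxels, the sequence-specific
#'   patterns.
#' @slot vCommon,vSpecific,vRun,vTrial Component variances (signal^2 units).
#' @slot d Dimensionality of the specific patterns (1--3 for 4 conditions).
#' @slot geometry One of `"random"`, `"evenly_spaced"`, `"scaled_1d"`.
#'
#' @seealso [makeGroundTruth()], [simulateBetas()], [simulateTimeseries()]
#' @export
setClass("PatternGroundTruth",
         representation(common = "numeric", specific = "matrix",
                        vCommon = "numeric", vSpecific = "numeric",
                        vRun = "numeric", vTrial = "numeric",
                        d = "integer", geometry = "character"))

setValidity("PatternGroundTruth", function(object) {
    if (length(object@common) != ncol(object@specific))
        return("common and specific patterns must have equal voxel counts")
    v <- c(object@vCommon, object@vSpecific, object@vRun, object@vTrial)
    if (any(v < 0)) return("variances must be non-negative")
    if (!object@geometry %in% c("random", "evenly_spaced", "scaled_1d"))
        return("unknown geometry")
    TRUE
})

setMethod("show", "PatternGroundTruth", function(object) {
    cat("PatternGroundTruth:", ncol(object@specific), "voxels,",
        nrow(object@specific), "conditions, geometry", object@geometry,
        "(d =", paste0(object@d, ")\n"))
    cat("  variances: common", object@vCommon, "specific", object@vSpecific,
        "run", object@vRun, "trial", object@vTrial, "\n")
})

#' @rdname seqrep-generics
#' @export
setMethod("nVoxels", "PatternGroundTruth", function(x) length(x@common))

## ---------------------------------------------------------------------------
## BetaPatterns
## ---------------------------------------------------------------------------

#' Condition-by-run activation estimates
#'
#' The universal currency between the GLM and all pattern analyses: one
#' activation estimate (GLM regression coefficient) per condition per run
#' per voxel.  Stored as a [SummarizedExperiment::SummarizedExperiment-class]
#' with voxels as rows and condition-run estimates as columns; `colData`
#' carries the `condition` and `run` labels, forming a complete grid.
#'
#' @seealso [estimateBetas()], [simulateBetas()], [crossvalAccuracy()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("BetaPatterns", contains = "SummarizedExperiment")

setValidity("BetaPatterns", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("condition", "run") %in% names(cd)))
        return("colData must contain 'condition' and 'run'")
    if (!all(is.finite(SummarizedExperiment::assay(object))))
        return("activation estimates must be finite")
    grid <- table(cd$condition, cd$run)
    if (!all(grid == 1L))
        return("every condition must appear exactly once in every run")
    TRUE
})

#' @rdname BetaPatterns-class
#' @param betas Numeric matrix, voxels x (condition-run) observations.
#' @param condition Factor or vector of condition labels, one per column.
#' @param run Integer vector of run labels, one per column.
#' @export
BetaPatterns <- function(betas, condition, run) {
    condition <- as.factor(condition)
    run <- as.integer(run)
    colnames(betas) <- paste0(condition, ".run", run)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(betas = betas),
        colData = S4Vectors::DataFrame(condition = condition, run = run))
    new("BetaPatterns", se)
}

#' @rdname seqrep-generics
#' @export
setMethod("conditionLabels", "BetaPatterns", function(x)
    SummarizedExperiment::colData(x)$condition)

#' @rdname seqrep-generics
#' @export
setMethod("runLabels", "BetaPatterns", function(x)
    SummarizedExperiment::colData(x)$run)

#' @rdname seqrep-generics
#' @export
setMethod("betaMatrix", "BetaPatterns", function(x)
    t(SummarizedExperiment::assay(x, "betas")))

#' @rdname seqrep-generics
#' @export
setMethod("nVoxels", "BetaPatterns", function(x) nrow(x))

setMethod("show", "BetaPatterns", function(object) {
    cat("BetaPatterns:", nrow(object), "voxels,",
        nlevels(conditionLabels(object)), "conditions x",
        length(unique(runLabels(object))), "runs\n")
})

## ---------------------------------------------------------------------------
## DesignMatrix
## ---------------------------------------------------------------------------

#' GLM design matrix
#'
#' Volumes x regressors matrix together with the regressor labels
#' (condition, run, and FIR bin where applicable) and the run membership of
#' every volume (used for run-wise high-pass filtering and intercepts).
#'
#' @slot X Numeric matrix, volumes x regressors.
#' @slot labels data.frame with one row per regressor: `regressor`,
#'   `condition`, `run`, `bin` (`NA` for intercepts and canonical designs).
#' @slot volumeRun Integer vector assigning each volume (row) to a run.
#'
#' @seealso [buildDesign()], [buildFirDesign()], [estimateBetas()]
#' @export
setClass("DesignMatrix",
         representation(X = "matrix", labels = "data.frame",
                        volumeRun = "integer"))

setValidity("DesignMatrix", function(object) {
    if (nrow(object@labels) != ncol(object@X))
        return("one label row per regressor required")
    if (length(object@volumeRun) != nrow(object@X))
        return("volumeRun must have one entry per volume")
    if (any(colSums(abs(object@X)) == 0))
        return("design contains an all-zero regressor")
    if (anyDuplicated(object@labels$regressor))
        return("regressor labels must be unique")
    TRUE
})

setMethod("show", "DesignMatrix", function(object) {
    cat("DesignMatrix:", nrow(object@X), "volumes x", ncol(object@X),
        "regressors (", sum(!is.na(object@labels$condition)),
        "task,", sum(is.na(object@labels$condition)), "intercept )\n")
})

## ---------------------------------------------------------------------------
## TemporalComponents
## ---------------------------------------------------------------------------

#' Temporal components of the trial response
#'
#' Result of a singular value decomposition of FIR time courses: orthonormal
#' component time courses (one value per post-onset TR bin), their singular
#' values, and the weight of each component for every voxel and every
#' condition-run observation.
#'
#' @slot timecourses Matrix, bins x components, orthonormal columns ordered
#'   by decreasing singular value.
#' @slot singularValues Numeric vector.
#' @slot weights Array, components x observations x voxels.
#'
#' @seealso [temporalComponents()]
#' @export
setClass("TemporalComponents",
         representation(timecourses = "matrix", singularValues = "numeric",
                        weights = "array"))

setValidity("TemporalComponents", function(object) {
    tc <- object@timecourses
    if (ncol(tc) != length(object@singularValues))
        return("one singular value per component required")
    if (is.unsorted(rev(object@singularValues)))
        return("components must be ordered by decreasing singular value")
    g <- crossprod(tc)
    if (max(abs(g - diag(ncol(tc)))) > 1e-6)
        return("component time courses must be orthonormal")
    TRUE
})

setMethod("show", "TemporalComponents", function(object) {
    cat("TemporalComponents:", ncol(object@timecourses), "components over",
        nrow(object@timecourses), "bins; singular values",
        paste(signif(object@singularValues, 3), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## LDAModel
## ---------------------------------------------------------------------------

#' Regularized linear discriminant model
#'
#' Class means and a pooled within-class covariance estimated from training
#' folds, regularized by adding a fraction of the mean diagonal element to
#' the diagonal.
#'
#' @slot means Matrix, classes x features.
#' @slot covReg Regularized pooled within-class covariance.
#' @slot labels Character vector of class labels.
#' @slot regFraction Regularization fraction (default 0.01).
#'
#' @seealso [ldaTrain()], [ldaClassify()]
#' @export
setClass("LDAModel",
         representation(means = "matrix", covReg = "matrix",
                        labels = "character", regFraction = "numeric"))

setValidity("LDAModel", function(object) {
    if (nrow(object@means) != length(object@labels))
        return("one mean per class required")
    if (ncol(object@covReg) != ncol(object@means) ||
        nrow(object@covReg) != ncol(object@means))
        return("covariance dimension must match feature count")
    if (max(abs(object@covReg - t(object@covReg))) > 1e-8)
        return("covariance must be symmetric")
    ev <- tryCatch(min(eigen(object@covReg, symmetric = TRUE,
                             only.values = TRUE)$values),
                   error = function(e) -Inf)
    if (ev <= 0)
        return("regularized covariance must be positive definite")
    TRUE
})

setMethod("show", "LDAModel", function(object) {
    cat("LDAModel:", length(object@labels), "classes,",
        ncol(object@means), "features, regularization",
        object@regFraction, "\n")
})

## ---------------------------------------------------------------------------
## ClassifierResult
## ---------------------------------------------------------------------------

#' Cross-validated classification result
#'
#' @slot accuracy Proportion correct over all cross-validated test
#'   classifications.
#' @slot nTest Total number of test classifications.
#' @slot z Accuracy z-transformed via the normal approximation to the
#'   binomial distribution.
#' @slot chance Chance level (1 / number of classes for balanced designs).
#' @slot predictions data.frame with one row per test pattern: `run`,
#'   `condition`, `predicted`, `correct`.
#'
#' @seealso [crossvalAccuracy()], [accuracyToZ()]
#' @export
setClass("ClassifierResult",
         representation(accuracy = "numeric", nTest = "integer",
                        z = "numeric", chance = "numeric",
                        predictions = "data.frame"))

setValidity("ClassifierResult", function(object) {
    if (object@accuracy < 0 || object@accuracy > 1)
        return("accuracy must lie in [0, 1]")
    if (nrow(object@predictions) > 0) {
        acc <- mean(object@predictions$correct)
        if (abs(acc - object@accuracy) > 1e-9)
            return("accuracy must equal the proportion of correct predictions")
    }
    zz <- accuracyToZ(object@accuracy, object@nTest, object@chance)
    if (abs(zz - object@z) > 1e-9)
        return("z must be consistent with accuracyToZ")
    TRUE
})

#' @rdname seqrep-generics
#' @export
setMethod("accuracy", "ClassifierResult", function(x) x@accuracy)

#' @rdname seqrep-generics
#' @export
setMethod("zScore", "ClassifierResult", function(x) x@z)

#' @rdname seqrep-generics
#' @export
setMethod("foldPredictions", "ClassifierResult", function(x) x@predictions)

setMethod("show", "ClassifierResult", function(object) {
    cat(sprintf("ClassifierResult: accuracy %.1f%% (chance %.1f%%, n = %d, z = %.2f)\n",
                100 * object@accuracy, 100 * object@chance,
                object@nTest, object@z))
})

## ---------------------------------------------------------------------------
## VarianceComponents
## ---------------------------------------------------------------------------

#' Voxel-by-voxel variances of pattern components
#'
#' Method-of-moments estimates of the variance (across voxels) of the
#' common, sequence-specific, run-common and trial-noise pattern
#' components.  Negative raw estimates are clipped to zero; the unclipped
#' values are retained in `unclipped`.
#'
#' @slot vCommon,vSpecific,vRun,vTrial Clipped variance estimates.
#' @slot unclipped Named numeric vector of the raw (possibly negative)
#'   estimates.
#'
#' @seealso [decomposePatterns()], [specificToNoiseRatio()]
#' @export
setClass("VarianceComponents",
         representation(vCommon = "numeric", vSpecific = "numeric",
                        vRun = "numeric", vTrial = "numeric",
                        unclipped = "numeric"))

setValidity("VarianceComponents", function(object) {
    v <- c(object@vCommon, object@vSpecific, object@vRun, object@vTrial)
    if (any(v < 0)) return("clipped variances must be non-negative")
    if (length(object@unclipped) != 4L)
        return("unclipped must hold the four raw estimates")
    TRUE
})

#' @rdname seqrep-generics
#' @export
setMethod("varianceTable", "VarianceComponents", function(x) {
    data.frame(component = c("common", "specific", "run", "trial"),
               variance = c(x@vCommon, x@vSpecific, x@vRun, x@vTrial),
               unclipped = unname(x@unclipped))
})

setMethod("show", "VarianceComponents", function(object) {
    cat("VarianceComponents (voxel-by-voxel):\n")
    cat(sprintf("  common %.4g  specific %.4g  run %.4g  trial %.4g\n",
                object@vCommon, object@vSpecific, object@vRun, object@vTrial))
    if (object@vTrial > 0)
        cat(sprintf("  ratios to noise: common %.3g, specific %.3g\n",
                    object@vCommon / object@vTrial,
                    object@vSpecific / object@vTrial))
})

## ---------------------------------------------------------------------------
## VoxelGeometry, Neighborhoods, AccuracyMap
## ---------------------------------------------------------------------------

#' Spatial layout of voxels
#'
#' Voxel coordinates (mm) on a 2-D sheet or 3-D grid, plus a positive area
#' weight per voxel (cm^2) used to measure suprathreshold surface area.
#' An abstracted stand-in for a cortical surface mesh: mesh-derived node
#' coordinates plug into the same interface.
#'
#' @slot coords Numeric matrix, voxels x 2 (sheet) or voxels x 3 (grid).
#' @slot areas Numeric vector of per-voxel areas (cm^2).
#'
#' @seealso [sheetGeometry()], [buildNeighborhoods()]
#' @export
setClass("VoxelGeometry",
         representation(coords = "matrix", areas = "numeric"))

setValidity("VoxelGeometry", function(object) {
    if (length(object@areas) != nrow(object@coords))
        return("one area per voxel required")
    if (any(object@areas <= 0)) return("areas must be positive")
    if (anyDuplicated(object@coords)) return("coordinates must be unique")
    TRUE
})

#' @rdname seqrep-generics
#' @export
setMethod("coordinates", "VoxelGeometry", function(x) x@coords)

#' @rdname seqrep-generics
#' @export
setMethod("voxelAreas", "VoxelGeometry", function(x) x@areas)

#' @rdname seqrep-generics
#' @export
setMethod("nVoxels", "VoxelGeometry", function(x) nrow(x@coords))

setMethod("show", "VoxelGeometry", function(object) {
    cat("VoxelGeometry:", nrow(object@coords), "voxels in",
        ncol(object@coords), "dimensions, total area",
        signif(sum(object@areas), 4), "cm^2\n")
})

#' Searchlight neighbourhoods
#'
#' For each center voxel, the indices of its `p` nearest voxels by
#' Euclidean distance (ties broken by voxel index), plus the achieved
#' radius.
#'
#' @slot index Integer matrix, centers x p.
#' @slot radius Numeric vector, achieved radius per center.
#' @slot p Neighbourhood size.
#'
#' @seealso [buildNeighborhoods()], [searchlightMap()]
#' @export
setClass("Neighborhoods",
         representation(index = "matrix", radius = "numeric", p = "integer"))

setValidity("Neighborhoods", function(object) {
    if (ncol(object@index) != object@p)
        return("every neighbourhood must contain exactly p voxels")
    if (length(object@radius) != nrow(object@index))
        return("one radius per center required")
    TRUE
})

setMethod("show", "Neighborhoods", function(object) {
    cat("Neighborhoods:", nrow(object@index), "centers, p =", object@p,
        ", median radius", signif(stats::median(object@radius), 3), "\n")
})

#' Searchlight accuracy map
#'
#' Per-voxel cross-validated classification accuracy (and its z transform)
#' assigned to each searchlight center, aligned with a [VoxelGeometry-class].
#'
#' @slot accuracy,z Numeric vectors, one value per center.
#' @slot nTest Number of test classifications per center.
#' @slot geometry The underlying [VoxelGeometry-class].
#'
#' @seealso [searchlightMap()], [suprathresholdArea()], [groupMapTest()]
#' @export
setClass("AccuracyMap",
         representation(accuracy = "numeric", z = "numeric",
                        nTest = "integer", geometry = "VoxelGeometry"))

setValidity("AccuracyMap", function(object) {
    if (any(object@accuracy < 0 | object@accuracy > 1))
        return("accuracies must lie in [0, 1]")
    if (length(object@accuracy) != nVoxels(object@geometry))
        return("map must be aligned to the geometry")
    if (length(object@z) != length(object@accuracy))
        return("one z per accuracy required")
    TRUE
})

#' @rdname seqrep-generics
#' @export
setMethod("accuracy", "AccuracyMap", function(x) x@accuracy)

#' @rdname seqrep-generics
#' @export
setMethod("zScore", "AccuracyMap", function(x) x@z)

setMethod("show", "AccuracyMap", function(object) {
    cat(sprintf("AccuracyMap: %d centers, mean accuracy %.1f%%, max %.1f%%\n",
                length(object@accuracy), 100 * mean(object@accuracy),
                100 * max(object@accuracy)))
})
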