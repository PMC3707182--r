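#' @include AllClasses.R
NULL

#' Experiment configuration
#'
#' Assembles and validates the parameters of an end-to-end synthetic
#' experiment: cohort size, run structure, and the generative pattern
#' parameters for the two condition sets.  The trained set defaults to
#' evenly spaced specific patterns with higher specific variance, the
#' untrained set to random geometry with lower specific variance — the
#' representational difference that training is expected to produce.
#'
#' @param nSubjects Cohort size (default 16, matching a random-effects
#'   analysis of that size).
#' @param nRuns,nConditions Imaging runs and sequence conditions.
#' @param sheet Sheet dimensions `c(nx, ny)` of the voxel geometry.
#' @param searchlightP Searchlight neighbourhood size.
#' @param vCommon,vRun,vTrial Shared component variances.
#' @param trained,untrained Lists with elements `geometry`, `d`,
#'   `vSpecific` for the two condition sets.
#' @param noiseSd Volume noise of the simulated time series.
#' @param nVolumes,TR,trialsPerCondition,nRest Schedule parameters.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return Named list of validated parameters (class `ExperimentConfig`).
#' @export
experimentConfig <- function(nSubjects = 16, nRuns = 8, nConditions = 4,
                             sheet = c(12, 12), searchlightP = 60,
                             vCommon = 100, vRun = 1, vTrial = 1,
                             trained = list(geometry = "evenly_spaced",
                                            d = 3, vSpecific = 0.6),
                             untrained = list(geometry = "random",
                                              d = 3, vSpecific = 0.25),
                             noiseSd = 1, nVolumes = 110, TR = 2.72,
                             trialsPerCondition = 4, nRest = 4,
                             seed = 1) {
    cfg <- list(nSubjects = as.integer(nSubjects),
                nRuns = as.integer(nRuns),
                nConditions = as.integer(nConditions),
                sheet = as.integer(sheet), searchlightP = as.integer(searchlightP),
                vCommon = vCommon, vRun = vRun, vTrial = vTrial,
                trained = trained, untrained = untrained,
                noiseSd = noiseSd, nVolumes = as.integer(nVolumes),
                TR = TR, trialsPerCondition = as.integer(trialsPerCondition),
                nRest = as.integer(nRest), seed = as.integer(seed))
    stopifnot(cfg$nSubjects >= 2, cfg$nRuns >= 2, cfg$nConditions >= 2,
              prod(cfg$sheet) >= cfg$searchlightP,
              cfg$vCommon >= 0, cfg$vRun >= 0, cfg$vTrial >= 0,
              cfg$trained$vSpecific >= 0, cfg$untrained$vSpecific >= 0)
    class(cfg) <- "ExperimentConfig"
    cfg
}

#' Run an end-to-end synthetic experiment
#'
#' Wires the full analysis for a simulated cohort: for every subject and
#' condition set, generate ground-truth patterns and BOLD runs, estimate
#' betas with the GLM, classify with cross-validated LDA (full pattern and
#' 1-, 2-, 3-component classifiers), run a searchlight, and decompose the
#' pattern variance; then compare the two condition sets at the group
#' level (accuracy contrast and a permutation-cluster map test).
#' Deterministic given the config seed.
#'
#' @param config An [experimentConfig()] list.
#' @param outDir Optional directory; if given, tidy result tables are
#'   written as TSV files (`accuracy.tsv`, `dimensionality.tsv`,
#'   `components.tsv`, `group.tsv`).
#' @param searchlight Run the per-subject searchlight (the slowest stage;
#'   default TRUE).
#' @return List with tidy data.frames `accuracy`, `dimensionality`,
#'   `components`, the group-level test results `group`, and (if run)
#'   per-subject searchlight maps.
#' @export
runExperiment <- function(config = experimentConfig(), outDir = NULL,
                          searchlight = TRUE) {
    stopifnot(inherits(config, "ExperimentConfig"))
    set.seed(config$seed)
    subjSeeds <- matrix(sample.int(.Machine$integer.max,
                                   config$nSubjects * 2L),
                        config$nSubjects, 2L)
    geometry <- sheetGeometry(config$sheet[1L], config$sheet[2L])
    V <- nVoxels(geometry)
    nb <- if (searchlight) buildNeighborhoods(geometry, config$searchlightP)
    sets <- list(trained = config$trained, untrained = config$untrained)
    dims <- seq_len(config$nConditions - 1L)

    accRows <- list(); dimRows <- list(); compRows <- list()
    maps <- list(trained = list(), untrained = list())
    for (s in seq_len(config$nSubjects)) {
        for (ci in seq_along(sets)) {
            setName <- names(sets)[ci]
            p <- sets[[ci]]
            seed_sc <- subjSeeds[s, ci]
            schedule <- makeSchedule(nRuns = config$nRuns,
                                     nConditions = config$nConditions,
                                     trialsPerCondition = config$trialsPerCondition,
                                     nRest = config$nRest, TR = config$TR,
                                     nVolumes = config$nVolumes,
                                     seed = seed_sc)
            gt <- makeGroundTruth(V, vCommon = config$vCommon,
                                  vSpecific = p$vSpecific,
                                  vRun = config$vRun,
                                  vTrial = config$vTrial, d = p$d,
                                  geometry = p$geometry,
                                  nConditions = config$nConditions)
            runs <- simulateTimeseries(gt, schedule,
                                       noiseSd = config$noiseSd)
            betas <- estimateBetas(runs, buildDesign(schedule))

            res <- crossvalAccuracy(betas)
            accRows[[length(accRows) + 1L]] <-
                data.frame(subject = s, conditionSet = setName,
                           accuracy = accuracy(res), nTest = res@nTest,
                           z = zScore(res))
            for (d in dims) {
                rd <- reducedDimAccuracy(betas, d)
                dimRows[[length(dimRows) + 1L]] <-
                    data.frame(subject = s, conditionSet = setName,
                               dimension = d, accuracy = accuracy(rd),
                               z = zScore(rd))
            }
            ## clipping warnings are expected for null-like data; the raw
            ## estimates are preserved in the components table
            vc <- suppressWarnings(decomposePatterns(betas))
            vt <- varianceTable(vc)
            compRows[[length(compRows) + 1L]] <-
                cbind(data.frame(subject = s, conditionSet = setName),
                      vt[, c("component", "variance")],
                      ratioToNoise = if (vc@vTrial > 0)
                          vt$variance / vc@vTrial else NA_real_)
            if (searchlight)
                maps[[setName]][[s]] <- searchlightMap(betas, nb, geometry)
        }
    }
    accuracyTab <- do.call(rbind, accRows)
    dimTab <- do.call(rbind, dimRows)
    compTab <- do.call(rbind, compRows)

    accT <- accuracyTab$accuracy[accuracyTab$conditionSet == "trained"]
    accU <- accuracyTab$accuracy[accuracyTab$conditionSet == "untrained"]
    tt <- stats::t.test(accT, accU, paired = TRUE)
    group <- list(accuracyContrast = data.frame(
        meanTrained = mean(accT), meanUntrained = mean(accU),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value))
    if (searchlight) {
        group$mapTest <- groupMapTest(maps$trained, maps$untrained,
                                      geometry = geometry,
                                      nPerm = 500,
                                      seed = config$seed + 1L)
    }

    out <- list(accuracy = accuracyTab, dimensionality = dimTab,
                components = compTab, group = group,
                maps = if (searchlight) maps)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(accuracyTab, file.path(outDir, "accuracy.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        utils::write.table(dimTab, file.path(outDir, "dimensionality.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        utils::write.table(compTab, file.path(outDir, "components.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        gm <- group$accuracyContrast
        if (!is.null(group$mapTest))
            gm <- cbind(gm, nClusters = nrow(group$mapTest$clusters),
                        minClusterP = if (nrow(group$mapTest$clusters))
                            min(group$mapTest$clusters$p) else NA_real_)
        utils::write.table(gm, file.path(outDir, "group.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    out
}

#' Null-calibration accuracy through the full GLM + LDA pipeline
#'
#' Repeatedly simulates datasets with a common pattern, run effects and
#' noise but zero sequence-specific variance, runs each through the
#' time-series simulation, GLM estimation and leave-one-run-out
#' regularized LDA, and returns the per-dataset accuracies.  With no
#' specific signal, the mean accuracy calibrates to chance (25% for four
#' conditions).
#'
#' @param nSims Number of simulated datasets.
#' @param nVoxels,nRuns,nConditions Dataset size.
#' @param vCommon,vRun,vTrial,noiseSd Generative parameters (specific
#'   variance is fixed at 0).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `nSims` accuracies.
#' @export
nullGlmAccuracy <- function(nSims = 200, nVoxels = 160, nRuns = 8,
                            nConditions = 4, vCommon = 100, vRun = 1,
                            vTrial = 1, noiseSd = 1, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    simSeeds <- sample.int(.Machine$integer.max, nSims)
    vapply(seq_len(nSims), function(i) {
        set.seed(simSeeds[i])
        schedule <- makeSchedule(nRuns = nRuns, nConditions = nConditions)
        gt <- makeGroundTruth(nVoxels, vCommon = vCommon, vSpecific = 0,
                              vRun = vRun, vTrial = vTrial, d = 1,
                              geometry = "random",
                              nConditions = nConditions)
        runs <- simulateTimeseries(gt, schedule, noiseSd = noiseSd)
        betas <- estimateBetas(runs, buildDesign(schedule))
        accuracy(crossvalAccuracy(betas))
    }, numeric(1))
}
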