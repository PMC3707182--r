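#' @include AllClasses.R
NULL

#' Decompose activation patterns into variance components
#'
#' Method-of-moments estimator of the voxel-by-voxel variance of the four
#' pattern components in the generative model
#' \eqn{b_{ir} = common + specific_i + run_r + noise_{ir}}.
#' With \eqn{m(i,r;j,r')} the mean over voxels of the raw product
#' \eqn{b_{ir} \cdot b_{jr'}} (no grand-mean removal: the common component
#' is itself a parameter of interest and would be absorbed by centering),
#' the four moment averages
#' \deqn{m_{i\ne j, r\ne r'} = v_c,\quad m_{i=j, r\ne r'} = v_c + v_s,}
#' \deqn{m_{i\ne j, r=r'} = v_c + v_r,\quad m_{i=j, r=r'} = v_c + v_s + v_r + v_t}
#' are solved linearly for the component variances.  Negative estimates
#' are clipped to zero with a warning; the raw values are kept in the
#' result.
#'
#' @param x A [BetaPatterns-class] with at least 2 conditions and 2 runs.
#' @param ... Ignored.
#' @return A [VarianceComponents-class].
#' @export
setMethod("decomposePatterns", "BetaPatterns", function(x, ...) {
    cond <- as.integer(conditionLabels(x))
    run <- runLabels(x)
    if (length(unique(cond)) < 2L) stop("at least 2 conditions required")
    if (length(unique(run)) < 2L) stop("at least 2 runs required")
    B <- SummarizedExperiment::assay(x, "betas")       # voxels x obs
    M <- crossprod(B) / nrow(B)                        # obs x obs moments
    sameCond <- outer(cond, cond, "==")
    sameRun <- outer(run, run, "==")

    m <- c(diffDiff = mean(M[!sameCond & !sameRun]),
           sameDiff = mean(M[sameCond & !sameRun]),
           diffSame = mean(M[!sameCond & sameRun]),
           sameSame = mean(M[sameCond & sameRun]))
    raw <- c(common = unname(m["diffDiff"]),
             specific = unname(m["sameDiff"] - m["diffDiff"]),
             run = unname(m["diffSame"] - m["diffDiff"]),
             trial = unname(m["sameSame"] - m["sameDiff"] -
                                m["diffSame"] + m["diffDiff"]))
    clipped <- pmax(raw, 0)
    if (any(raw < 0))
        warning("negative variance estimate(s) clipped to zero: ",
                paste(names(raw)[raw < 0], collapse = ", "))
    new("VarianceComponents", vCommon = clipped[["common"]],
        vSpecific = clipped[["specific"]], vRun = clipped[["run"]],
        vTrial = clipped[["trial"]], unclipped = raw)
})

#' @describeIn specificToNoiseRatio Ratio of the sequence-specific (and
#'   common) component variance to the trial-noise variance; classification
#'   accuracy relates tightly to the specific-to-noise ratio.
#' @return Named vector with elements `specific` and `common`.
#' @export
setMethod("specificToNoiseRatio", "VarianceComponents", function(x, ...) {
    if (x@vTrial <= 0) stop("trial-noise variance is zero; ratio undefined")
    c(specific = x@vSpecific / x@vTrial, common = x@vCommon / x@vTrial)
})
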