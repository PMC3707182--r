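#' @include AllClasses.R
NULL

#' Regular 2-D sheet geometry
#'
#' A rectangular sheet of voxels with constant spacing, the abstracted
#' stand-in for a flattened cortical surface patch.  Areas default to the
#' square of the spacing, converted to cm^2.
#'
#' @param nx,ny Sheet dimensions in voxels.
#' @param spacing Voxel spacing in mm (default 2.3, the in-plane
#'   resolution of the scanning protocol).
#' @return A [VoxelGeometry-class].
#' @export
sheetGeometry <- function(nx, ny, spacing = 2.3) {
    coords <- as.matrix(expand.grid(x = (seq_len(nx) - 1L) * spacing,
                                    y = (seq_len(ny) - 1L) * spacing))
    new("VoxelGeometry", coords = coords,
        areas = rep(spacing^2 / 100, nrow(coords)))
}

#' Searchlight neighbourhoods of fixed voxel count
#'
#' For every voxel (taken as a searchlight center), selects the `p`
#' nearest voxels by Euclidean distance, growing a circular region until
#' it contains exactly `p` voxels; ties at the boundary break by voxel
#' index.  The achieved radius is recorded per center.
#'
#' @param geometry A [VoxelGeometry-class].
#' @param p Neighbourhood size (default 160).
#' @return A [Neighborhoods-class].
#' @export
buildNeighborhoods <- function(geometry, p = 160) {
    stopifnot(is(geometry, "VoxelGeometry"))
    n <- nVoxels(geometry)
    if (n < p) stop("geometry has fewer than p = ", p, " voxels")
    co <- coordinates(geometry)
    index <- matrix(0L, n, p)
    radius <- numeric(n)
    for (i in seq_len(n)) {
        d <- sqrt(colSums((t(co) - co[i, ])^2))
        ord <- order(d, seq_len(n))[seq_len(p)]
        index[i, ] <- ord
        radius[i] <- d[ord[p]]
    }
    new("Neighborhoods", index = index, radius = radius, p = as.integer(p))
}

#' Searchlight classification accuracy map
#'
#' Runs the leave-one-run-out regularized LDA within every searchlight
#' neighbourhood and assigns the cross-validated accuracy (and its z
#' transform) to the neighbourhood's center, producing a map of where and
#' how well the conditions are represented.
#'
#' @param betas A [BetaPatterns-class] aligned with the geometry (one row
#'   per voxel).
#' @param neighborhoods A [Neighborhoods-class].
#' @param geometry The [VoxelGeometry-class] the neighbourhoods were built
#'   on.
#' @param regFraction Regularization fraction.
#' @return An [AccuracyMap-class].
#' @export
searchlightMap <- function(betas, neighborhoods, geometry,
                           regFraction = 0.01) {
    stopifnot(is(betas, "BetaPatterns"), is(neighborhoods, "Neighborhoods"),
              is(geometry, "VoxelGeometry"),
              nVoxels(betas) == nVoxels(geometry))
    x <- betaMatrix(betas)
    cl <- conditionLabels(betas)
    rn <- runLabels(betas)
    nC <- nrow(neighborhoods@index)
    acc <- numeric(nC); nTest <- integer(nC)
    for (i in seq_len(nC)) {
        res <- crossvalMatrix(x[, neighborhoods@index[i, ], drop = FALSE],
                              cl, rn, regFraction)
        acc[i] <- res@accuracy
        nTest[i] <- res@nTest
    }
    chance <- 1 / nlevels(cl)
    new("AccuracyMap", accuracy = acc,
        z = mapply(accuracyToZ, acc, nTest,
                   MoreArgs = list(chance = chance)),
        nTest = nTest, geometry = geometry)
}

#' Select the most activated voxels
#'
#' Indices of the `n` largest activations, ties broken by voxel index.
#' Used to restrict a region of interest to its most activated part; since
#' pattern analyses are independent of the mean activity level, the
#' selection does not bias them under the null hypothesis.
#'
#' @param activation Numeric vector of per-voxel activation.
#' @param n Number of voxels to keep (default 800).
#' @return Integer vector of voxel indices, sorted.
#' @export
selectTopActive <- function(activation, n = 800) {
    if (length(activation) < n)
        stop("fewer than n = ", n, " voxels available")
    sort(order(-activation, seq_along(activation))[seq_len(n)])
}

#' ROI accuracy by random-subspace averaging
#'
#' Draws random groups of `subsetSize` voxels from a region of interest
#' (without replacement within each draw), computes the cross-validated
#' LDA accuracy for each group, and averages over draws.  Averaging over
#' random subspaces stabilises ROI accuracy estimates.
#'
#' @param roiBetas A [BetaPatterns-class] restricted to the ROI voxels.
#' @param subsetSize Voxels per draw (default 160).
#' @param nDraws Number of draws (default 5000).
#' @param regFraction Regularization fraction.
#' @param seed Optional RNG seed.
#' @return Mean accuracy over draws.
#' @export
roiRandomSubspaceAccuracy <- function(roiBetas, subsetSize = 160,
                                      nDraws = 5000, regFraction = 0.01,
                                      seed = NULL) {
    stopifnot(is(roiBetas, "BetaPatterns"))
    V <- nVoxels(roiBetas)
    if (V < subsetSize)
        stop("ROI has fewer than subsetSize = ", subsetSize, " voxels")
    if (!is.null(seed)) set.seed(seed)
    x <- betaMatrix(roiBetas)
    cl <- conditionLabels(roiBetas)
    rn <- runLabels(roiBetas)
    if (V == subsetSize)
        return(crossvalMatrix(x, cl, rn, regFraction)@accuracy)
    mean(vapply(seq_len(nDraws), function(i) {
        sel <- sample.int(V, subsetSize)
        crossvalMatrix(x[, sel, drop = FALSE], cl, rn, regFraction)@accuracy
    }, numeric(1)))
}

#' Cortical area exceeding an accuracy threshold
#'
#' Sum of the per-voxel area weights over all map locations with accuracy
#' strictly above the threshold — the amount of cortex encoding the
#' conditions better than the given criterion.
#'
#' @param map An [AccuracyMap-class].
#' @param thresholdAcc Accuracy threshold in \[0, 1\] (e.g. the 37.5%
#'   within-subject criterion as 0.375).
#' @return Area in cm^2.
#' @export
suprathresholdArea <- function(map, thresholdAcc) {
    stopifnot(is(map, "AccuracyMap"))
    sum(voxelAreas(map@geometry)[map@accuracy > thresholdAcc])
}

## Edge list connecting voxels closer than `linkDistance`.
geometryEdges <- function(geometry, linkDistance = NULL) {
    co <- coordinates(geometry)
    if (is.null(linkDistance)) {
        d1 <- sqrt(colSums((t(co[-1L, , drop = FALSE]) - co[1L, ])^2))
        linkDistance <- min(d1) * 1.01
    }
    n <- nrow(co)
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n - 1L)) {
        d <- sqrt(colSums((t(co[(i + 1L):n, , drop = FALSE]) - co[i, ])^2))
        j <- which(d <= linkDistance)
        from <- c(from, rep(i, length(j)))
        to <- c(to, i + j)
    }
    cbind(from, to)
}

## Connected suprathreshold clusters; returns per-cluster area (cm^2).
clusterAreas <- function(above, edges, areas) {
    idx <- which(above)
    if (length(idx) == 0L) return(numeric(0))
    keep <- above[edges[, 1L]] & above[edges[, 2L]]
    g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(above) -
                                         igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    tapply(areas[idx], comp[idx], sum)
}

#' Group-level map contrast with permutation cluster inference
#'
#' One-sample t test per voxel across subject maps (optionally of a paired
#' contrast between two map sets), thresholded at the cluster-forming
#' criterion, with family-wise error over clusters controlled by a
#' sign-flip permutation null of the maximum suprathreshold cluster area.
#'
#' @param maps Subjects x voxels matrix of per-subject map values (e.g.
#'   z-transformed accuracies), or a list of [AccuracyMap-class] objects
#'   (their z maps are used).
#' @param contrastMaps Optional second set of the same shape; if given,
#'   the paired difference `maps - contrastMaps` is tested.
#' @param geometry The [VoxelGeometry-class] of the maps.
#' @param clusterFormingP Uncorrected one-sided p for the cluster-forming
#'   t threshold (default 0.002; with 15 residual degrees of freedom this
#'   is t > 3.39).
#' @param nPerm Number of sign-flip permutations (default 1000; fewer than
#'   100 triggers a warning).
#' @param alternative Direction of the test: `"greater"` (default),
#'   `"less"`, or `"two.sided"`.
#' @param seed Optional RNG seed for the permutations.
#' @return List with `t` (per-voxel t values), `df`, `tCrit`, `clusters`
#'   (data.frame: cluster id, area, familywise p), and `maxAreaNull` (the
#'   permutation distribution).
#' @export
groupMapTest <- function(maps, contrastMaps = NULL, geometry,
                         clusterFormingP = 0.002, nPerm = 1000,
                         alternative = c("greater", "less", "two.sided"),
                         seed = NULL) {
    alternative <- match.arg(alternative)
    if (is.list(maps) && !is.matrix(maps))
        maps <- do.call(rbind, lapply(maps, zScore))
    if (!is.null(contrastMaps)) {
        if (is.list(contrastMaps) && !is.matrix(contrastMaps))
            contrastMaps <- do.call(rbind, lapply(contrastMaps, zScore))
        stopifnot(all(dim(maps) == dim(contrastMaps)))
        maps <- maps - contrastMaps
    }
    stopifnot(is(geometry, "VoxelGeometry"),
              ncol(maps) == nVoxels(geometry))
    n <- nrow(maps)
    if (n < 2L) stop("at least 2 subjects required")
    if (nPerm < 100L) warning("fewer than 100 permutations")
    if (!is.null(seed)) set.seed(seed)
    df <- n - 1L
    tCrit <- if (alternative == "two.sided")
        stats::qt(1 - clusterFormingP / 2, df)
    else stats::qt(1 - clusterFormingP, df)

    ss <- colSums(maps^2)
    tFromFlips <- function(flips) {     # flips: vector of +-1 per subject
        m <- drop(flips %*% maps) / n
        v <- (ss - n * m^2) / df
        m / sqrt(pmax(v, .Machine$double.eps) / n)
    }
    above <- function(tv) switch(alternative,
                                 greater = tv > tCrit,
                                 less = tv < -tCrit,
                                 two.sided = abs(tv) > tCrit)
    edges <- geometryEdges(geometry)
    areas <- voxelAreas(geometry)

    tObs <- tFromFlips(rep(1, n))
    obsAreas <- clusterAreas(above(tObs), edges, areas)

    maxNull <- vapply(seq_len(nPerm), function(i) {
        ca <- clusterAreas(above(tFromFlips(sample(c(-1, 1), n,
                                                   replace = TRUE))),
                           edges, areas)
        if (length(ca) == 0L) 0 else max(ca)
    }, numeric(1))

    clusters <- if (length(obsAreas) == 0L) {
        data.frame(cluster = integer(0), area = numeric(0), p = numeric(0))
    } else {
        data.frame(cluster = seq_along(obsAreas),
                   area = as.numeric(obsAreas),
                   p = vapply(as.numeric(obsAreas), function(a)
                       (1 + sum(maxNull >= a)) / (1 + nPerm), numeric(1)))
    }
    list(t = tObs, df = df, tCrit = tCrit, clusters = clusters,
         maxAreaNull = maxNull)
}
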