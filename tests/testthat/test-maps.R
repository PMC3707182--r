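test_that("neighbourhoods contain the p nearest voxels", {
    geo <- sheetGeometry(8, 8, spacing = 1)
    nb <- buildNeighborhoods(geo, p = 64)
    # p = all voxels: every neighbourhood is the full set
    expect_true(all(apply(nb@index, 1, sort) == 1:64))
    nb2 <- buildNeighborhoods(geo, p = 12)
    expect_true(all(rowSums(!is.na(nb2@index)) == 12))
    # neighbours are closer than non-neighbours
    co <- coordinates(geo)
    for (i in c(1, 28, 64)) {
        d <- sqrt(colSums((t(co) - co[i, ])^2))
        expect_lte(max(d[nb2@index[i, ]]), min(d[-nb2@index[i, ]]))
    }
    expect_error(buildNeighborhoods(geo, p = 100), "fewer than")
})

test_that("achieved searchlight radius matches the disc-area prediction", {
    geo <- sheetGeometry(30, 30, spacing = 1)
    nb <- buildNeighborhoods(geo, p = 160)
    center <- which(coordinates(geo)[, 1] == 15 &
                        coordinates(geo)[, 2] == 15)
    # a disc holding 160 unit cells has radius sqrt(160 / pi) ~ 7.14
    expect_equal(nb@radius[center], sqrt(160 / pi), tolerance = 0.05)
})

test_that("searchlight assigns local accuracy to the center", {
    set.seed(1)
    geo <- sheetGeometry(8, 8, spacing = 1)
    nb <- buildNeighborhoods(geo, p = 9)
    # plant discriminative signal in a corner patch (voxels with x,y < 3)
    co <- coordinates(geo)
    patch <- which(co[, 1] < 3 & co[, 2] < 3)
    betas <- matrix(rnorm(64 * 32, sd = 1), 64, 32)
    cond <- rep(1:4, 8); run <- rep(1:8, each = 4)
    signal <- matrix(rnorm(length(patch) * 4, sd = 4), 4, length(patch))
    for (j in seq_len(32)) {
        betas[patch, j] <- betas[patch, j] + signal[cond[j], ]
    }
    bp <- BetaPatterns(betas, cond, run)
    m <- searchlightMap(bp, nb, geo)
    expect_true(which.max(accuracy(m)) %in%
                    which(co[, 1] < 4 & co[, 2] < 4))
    # center value depends only on its neighbourhood's voxels
    out <- setdiff(1:64, nb@index[1, ])
    betas2 <- betas
    betas2[out, ] <- matrix(rnorm(length(out) * 32, sd = 9), length(out))
    m2 <- searchlightMap(BetaPatterns(betas2, cond, run), nb, geo)
    expect_equal(accuracy(m2)[1], accuracy(m)[1])
    # permuting voxels together with the geometry leaves the map aligned
    # (tie-free coordinates, so neighbourhoods are permutation covariant)
    coJ <- co + matrix(runif(128, 0, 0.01), 64)
    geoJ <- new("VoxelGeometry", coords = coJ, areas = voxelAreas(geo))
    mJ <- searchlightMap(bp, buildNeighborhoods(geoJ, p = 9), geoJ)
    perm <- sample(64)
    geoP <- new("VoxelGeometry", coords = coJ[perm, ],
                areas = voxelAreas(geoJ)[perm])
    mP <- searchlightMap(BetaPatterns(betas[perm, ], cond, run),
                         buildNeighborhoods(geoP, p = 9), geoP)
    expect_equal(accuracy(mP), accuracy(mJ)[perm])
})

test_that("null searchlight maps average to chance", {
    set.seed(2)
    geo <- sheetGeometry(6, 6, spacing = 1)
    nb <- buildNeighborhoods(geo, p = 8)
    accs <- vapply(1:8, function(i) {
        gt <- makeGroundTruth(36, vCommon = 1, vSpecific = 0, vRun = 0.3,
                              vTrial = 1, d = 1, geometry = "random")
        mean(accuracy(searchlightMap(simulateBetas(gt, 8), nb, geo)))
    }, numeric(1))
    expect_lt(abs(mean(accs) - 0.25), 0.03)
})

test_that("top-active voxel selection is order- and shift-invariant", {
    a <- c(5, 1, 9, 7, 3)
    expect_equal(selectTopActive(a, 5), 1:5)
    expect_equal(selectTopActive(a, 2), c(3, 4))
    expect_equal(selectTopActive(a + 100, 2), selectTopActive(a, 2))
    # strictly decreasing activations select the first n
    expect_equal(selectTopActive(10:1, 4), 1:4)
    # ties break by index
    expect_equal(selectTopActive(c(1, 1, 1, 0), 2), c(1, 2))
    expect_error(selectTopActive(a, 6), "fewer")
})

test_that("random-subspace ROI accuracy reduces to direct accuracy", {
    set.seed(3)
    gt <- makeGroundTruth(30, vCommon = 1, vSpecific = 1.5, vRun = 0.3,
                          vTrial = 1, d = 3, geometry = "random")
    bp <- simulateBetas(gt, 6)
    direct <- accuracy(crossvalAccuracy(bp))
    expect_equal(roiRandomSubspaceAccuracy(bp, subsetSize = 30, nDraws = 3),
                 direct)
    a1 <- roiRandomSubspaceAccuracy(bp, subsetSize = 10, nDraws = 25,
                                    seed = 4)
    a2 <- roiRandomSubspaceAccuracy(bp, subsetSize = 10, nDraws = 25,
                                    seed = 4)
    expect_identical(a1, a2)
    expect_error(roiRandomSubspaceAccuracy(bp, subsetSize = 31), "fewer")
})

test_that("suprathreshold area sums the areas above threshold", {
    geo <- sheetGeometry(4, 4, spacing = 10)   # 1 cm^2 per voxel
    acc <- seq(0, 0.6, length.out = 16)
    map <- new("AccuracyMap", accuracy = acc,
               z = accuracyToZ(acc, 32, 0.25), nTest = rep(32L, 16),
               geometry = geo)
    expect_equal(suprathresholdArea(map, 1), 0)
    expect_equal(suprathresholdArea(map, -0.01), 16)
    expect_equal(suprathresholdArea(map, 0.375), sum(acc > 0.375))
})

test_that("group map test finds planted effects and not null ones", {
    set.seed(5)
    geo <- sheetGeometry(8, 8, spacing = 10)
    # identical maps with zero contrast: no clusters at all
    flat <- matrix(1, 8, 64)
    g0 <- groupMapTest(flat, contrastMaps = flat, geometry = geo,
                       nPerm = 120)
    expect_equal(nrow(g0$clusters), 0)
    # cluster-forming threshold reproduces the t(15) > 3.39 criterion
    g1 <- groupMapTest(matrix(rnorm(16 * 64), 16, 64), geometry = geo,
                       nPerm = 120, seed = 6)
    expect_equal(g1$tCrit, 3.39, tolerance = 0.005)
    expect_equal(g1$df, 15)
    # a strong planted effect in a block reaches cluster significance
    maps <- matrix(rnorm(16 * 64), 16, 64)
    block <- which(coordinates(geo)[, 1] < 40 & coordinates(geo)[, 2] < 40)
    maps[, block] <- maps[, block] + 3
    g2 <- groupMapTest(maps, geometry = geo, nPerm = 200, seed = 7)
    expect_gt(nrow(g2$clusters), 0)
    expect_lt(min(g2$clusters$p), 0.05)
    expect_warning(groupMapTest(maps, geometry = geo, nPerm = 50, seed = 8),
                   "100 permutations")
})
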