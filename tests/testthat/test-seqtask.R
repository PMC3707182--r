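test_that("sequence validity matches the task constraints", {
    expect_true(isValidSequence(c(3, 2, 5, 1, 4)))
    expect_false(isValidSequence(1:5))       # ascending run of 5 neighbours
    expect_false(isValidSequence(c(5, 4, 3, 2, 1)))
    expect_false(isValidSequence(c(1, 2, 3, 4, 5)[c(5, 1, 2, 3, 4)]))  # 1-2-3-4
    expect_true(isValidSequence(c(1, 2, 3, 5, 4)))  # runs of 3 are allowed
    expect_false(isValidSequence(c(1, 2, 3, 4)))    # wrong length
    expect_false(isValidSequence(c(1, 1, 2, 3, 4)))
})

test_that("the valid sequence pool matches exhaustive enumeration", {
    oracle <- oracleValidPerms()
    expect_equal(nrow(oracle), 114)
    # the pool can supply exactly that many distinct sequences, no more
    full <- generateSequencePool(114, seed = 1)
    expect_equal(nSequences(full), 114)
    expect_error(generateSequencePool(115), "exceeds")
    # and every drawn sequence is in the oracle set
    key <- function(m) apply(m, 1, paste, collapse = "")
    expect_true(all(key(sequences(full)) %in% key(oracle)))
})

test_that("pool draws are uniform over the valid set", {
    set.seed(42)
    counts <- table(replicate(3000, paste(sequences(
        generateSequencePool(1))[1, ], collapse = "")))
    # all 114 sequences appear, and a chi-squared test finds no bias
    expect_gte(length(counts), 100)
    cs <- chisq.test(as.vector(counts),
                     p = rep(1 / length(counts), length(counts)))
    expect_gt(cs$p.value, 0.001)
})

test_that("splitPool partitions the pool into disjoint groups", {
    pool <- generateSequencePool(12, seed = 7)
    groups <- splitPool(pool, 3, seed = 8)
    expect_length(groups, 3)
    expect_true(all(vapply(groups, nSequences, integer(1)) == 4L))
    key <- function(ss) apply(sequences(ss), 1, paste, collapse = "")
    all_keys <- unlist(lapply(groups, key))
    expect_setequal(all_keys, key(pool))
    expect_equal(anyDuplicated(all_keys), 0L)
    # identity partition and determinism
    one <- splitPool(groups[[1]], 1)
    expect_setequal(key(one[[1]]), key(groups[[1]]))
    expect_identical(lapply(splitPool(pool, 3, seed = 9), sequences),
                     lapply(splitPool(pool, 3, seed = 9), sequences))
    expect_error(splitPool(pool, 5), "divisible")
})

test_that("transition overlap counts shared ordered transitions", {
    a <- SequenceSet(rbind(c(1, 3, 5, 2, 4)))
    b <- SequenceSet(rbind(c(1, 3, 5, 4, 2)))
    expect_equal(transitionOverlap(a, b), 50)     # 1>3, 3>5 shared
    expect_equal(transitionOverlap(a, a), 100)
    pool <- generateSequencePool(12, seed = 3)
    groups <- splitPool(pool, 3, seed = 4)
    ov <- transitionOverlap(groups[[1]], groups[[3]])
    expect_gte(ov, 0); expect_lte(ov, 100)
    # every sequence contributes exactly 4 transitions over 5 distinct digits
    expect_length(transitions(pool), 4 * 12)
    expect_true(all(apply(sequences(pool), 1,
                          function(s) length(unique(s))) == 5))
})

test_that("press detection follows the two-threshold rule", {
    # single finger ramp: press at the first sample reaching 2.5 N
    time <- seq(0, 1, by = 0.005)
    f <- matrix(0, length(time), 5)
    f[, 2] <- 5 * time                       # reaches 2.5 N at t = 0.5
    pr <- detectPresses(list(time = time, forces = f))
    expect_equal(nrow(pr), 1)
    expect_equal(pr$finger, 2)
    expect_equal(pr$onset, 0.5)
    # another finger held at 2.3 N blocks the press until it releases
    f2 <- f
    f2[, 3] <- ifelse(time < 0.7, 2.3, 0)
    pr2 <- detectPresses(list(time = time, forces = f2))
    expect_equal(nrow(pr2), 1)
    expect_equal(pr2$onset, 0.7)             # first sample after release
    # a tie at exactly 2.2 N also blocks
    f3 <- f
    f3[, 4] <- 2.2
    expect_equal(nrow(detectPresses(list(time = time, forces = f3))), 0)
    expect_error(detectPresses(list(time = numeric(0),
                                    forces = matrix(0, 0, 5))), "empty")
})

test_that("generated force traces round-trip through press detection", {
    onsets <- c(0.30, 0.60, 0.90, 1.20, 1.50)
    seqs <- c(3, 2, 5, 1, 4)
    tr <- simulateForceTrace(seqs, onsets)
    pr <- detectPresses(tr)
    expect_equal(pr$finger, seqs)
    expect_equal(pr$onset, onsets, tolerance = 1e-9)
    expect_equal(movementTime(pr), 1200)
    # identical events under added sub-threshold noise
    set.seed(5)
    noisy <- tr
    noisy$forces <- pmax(noisy$forces +
        matrix(runif(length(tr$forces), -0.09, 0.09), nrow(tr$forces)), 0)
    expect_equal(detectPresses(noisy), pr)
})

test_that("movement time spans first to fifth press onset", {
    pr <- data.frame(finger = 1:5, onset = c(0, 0.1, 0.2, 0.3, 0.4))
    expect_equal(movementTime(pr), 400)
    expect_equal(movementTime(data.frame(finger = 1:5, onset = rep(1, 5))), 0)
    expect_error(movementTime(pr[1:3, ]), class = "incompleteTrial")
})

test_that("sequence-specific learning test recovers an injected advantage", {
    # a flat zero post-difference gives a zero intercept and t
    r0 <- sequenceSpecificTest(c(-10, 0, 10, 25), rep(0, 4))
    expect_equal(r0$intercept, 0)
    expect_equal(r0$t, 0)
    # injected 237 ms advantage at zero pre-difference, small noise
    set.seed(11)
    pre <- rnorm(16, 0, 50)
    post <- 237 + 0.3 * pre + rnorm(16, 0, 20)
    r <- sequenceSpecificTest(pre, post)
    expect_equal(r$intercept, 237, tolerance = 0.1)
    expect_equal(r$df, 14)
    expect_lt(r$p, 0.001)
    # t statistic equals the closed-form OLS oracle
    X <- cbind(1, pre)
    bhat <- drop(oracleOls(X, matrix(post)))
    res <- post - X %*% bhat
    s2 <- sum(res^2) / (16 - 2)
    se <- sqrt(s2 * solve(crossprod(X))[1, 1])
    expect_equal(r$t, unname(bhat[1] / se), tolerance = 1e-10)
    expect_error(sequenceSpecificTest(1:2, 1:2), "3 subjects")
})

test_that("Monte-Carlo transition overlap sits near the printed value", {
    ov <- simulateTransitionOverlap(400, seed = 20)
    expect_gt(ov, 50); expect_lt(ov, 66)
})
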