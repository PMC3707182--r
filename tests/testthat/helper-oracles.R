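# Independent oracles used across tests.  These deliberately use different
# code paths (string matching, explicit solve(), per-class loops) from the
# package implementation.

# Enumerate the valid permutations of 1..5 by string matching against the
# forbidden neighbour runs.
oracleValidPerms <- function() {
    g <- expand.grid(rep(list(1:5), 5))
    g <- g[apply(g, 1, function(x) length(unique(x)) == 5), ]
    strs <- apply(g, 1, paste, collapse = "")
    forbidden <- c("1234", "2345", "4321", "5432")
    keep <- !vapply(strs, function(s)
        any(vapply(forbidden, grepl, logical(1), x = s)), logical(1))
    unname(as.matrix(g[keep, ]))
}

# Closed-form OLS via the normal equations.
oracleOls <- function(X, Y) {
    solve(crossprod(X), crossprod(X, Y))
}

# Pooled within-class covariance by an explicit per-class loop.
oraclePooledCov <- function(x, classes) {
    classes <- as.factor(classes)
    S <- matrix(0, ncol(x), ncol(x))
    for (l in levels(classes)) {
        xl <- x[classes == l, , drop = FALSE]
        ctr <- sweep(xl, 2, colMeans(xl))
        S <- S + crossprod(ctr)
    }
    S / (nrow(x) - nlevels(classes))
}

# Brute-force Gaussian likelihood classification: evaluate the full
# quadratic form per class with solve(), equal priors, first argmax.
oracleLdaPredict <- function(means, covReg, x) {
    Sinv <- solve(covReg)
    apply(x, 1, function(v) {
        ll <- apply(means, 1, function(m)
            -0.5 * drop(t(v - m) %*% Sinv %*% (v - m)))
        which.max(ll)
    })
}

# Independent leave-one-run-out cross-validation with the same
# regularization rule, written as a standalone loop.
oracleCrossval <- function(x, classes, runs, regFraction = 0.01) {
    classes <- as.integer(as.factor(classes))
    K <- max(classes)
    correct <- 0L; total <- 0L
    for (r in sort(unique(runs))) {
        tr <- runs != r
        means <- do.call(rbind, lapply(seq_len(K), function(k)
            colMeans(x[tr & classes == k, , drop = FALSE])))
        S <- oraclePooledCov(x[tr, , drop = FALSE], classes[tr])
        Sreg <- S + regFraction * mean(diag(S)) * diag(ncol(x))
        pred <- oracleLdaPredict(means, Sreg, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == classes[!tr])
        total <- total + sum(!tr)
    }
    correct / total
}

# Small helper: a well-separated, almost-noiseless pattern set (a trace of
# within-class jitter keeps the pooled covariance positive definite).
separatedBetas <- function(nRuns = 4, nVoxels = 8, K = 4, sep = 10,
                           jitter = 1e-3) {
    patterns <- diag(K) * sep
    patterns <- cbind(patterns, matrix(0, K, nVoxels - K))
    condition <- rep(seq_len(K), nRuns)
    run <- rep(seq_len(nRuns), each = K)
    b <- t(patterns[condition, ])
    b <- b + matrix(sin(seq_len(length(b))), nrow(b)) * jitter
    BetaPatterns(b, condition = condition, run = run)
}
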