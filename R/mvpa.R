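#' @include AllClasses.R
NULL

#' Train a regularized linear discriminant model
#'
#' Computes the mean activation vector for each class over the training
#' observations and the pooled within-class covariance of the residuals
#' (denominator: observations minus classes), regularized by adding a
#' fraction of the mean diagonal element to every diagonal element:
#' \eqn{\Sigma_{reg} = \Sigma + f \cdot \overline{diag(\Sigma)} \cdot I}.
#'
#' @param x Observations x features matrix, or a [BetaPatterns-class]
#'   (voxels become features).
#' @param classes Class label per observation (taken from the condition
#'   labels of a `BetaPatterns` if missing).
#' @param regFraction Regularization fraction (default 0.01, i.e. 1% of
#'   the diagonal mean).
#' @return An [LDAModel-class].
#' @export
ldaTrain <- function(x, classes = NULL, regFraction = 0.01) {
    if (is(x, "BetaPatterns")) {
        if (is.null(classes)) classes <- conditionLabels(x)
        x <- betaMatrix(x)
    }
    classes <- as.factor(classes)
    stopifnot(nrow(x) == length(classes))
    K <- nlevels(classes)
    if (K < 2L) stop("at least 2 classes required")
    if (any(table(classes) < 2L))
        stop("at least 2 observations per class required")
    means <- do.call(rbind, lapply(levels(classes), function(l)
        colMeans(x[classes == l, , drop = FALSE])))
    rownames(means) <- levels(classes)
    resid <- x - means[as.integer(classes), , drop = FALSE]
    Sigma <- crossprod(resid) / (nrow(x) - K)
    dm <- mean(diag(Sigma))
    if (dm + max(abs(Sigma)) == 0)
        stop("within-class covariance is exactly zero; cannot regularize")
    covReg <- Sigma + regFraction * dm * diag(ncol(x))
    new("LDAModel", means = means, covReg = covReg,
        labels = levels(classes), regFraction = regFraction)
}

#' Classify patterns with a trained LDA model
#'
#' Assigns each test pattern to the class with the highest Gaussian
#' log-likelihood under the shared regularized covariance and equal class
#' priors — equivalently, the class with minimal Mahalanobis distance.
#' Exact ties break deterministically to the lowest class index.
#'
#' @param model An [LDAModel-class].
#' @param x Test patterns, observations x features matrix (or a single
#'   pattern vector), or a [BetaPatterns-class].
#' @return Factor of predicted class labels.
#' @export
ldaClassify <- function(model, x) {
    if (is(x, "BetaPatterns")) x <- betaMatrix(x)
    if (is.vector(x)) x <- matrix(x, nrow = 1L)
    if (ncol(x) != ncol(model@means))
        stop("test feature count (", ncol(x),
             ") does not match the model (", ncol(model@means), ")")
    U <- chol(model@covReg)
    ## linear discriminant: score_k = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2
    W <- backsolve(U, forwardsolve(t(U), t(model@means)))   # S^-1 mu_k
    scores <- x %*% W -
        matrix(colSums(t(model@means) * W) / 2, nrow(x),
               length(model@labels), byrow = TRUE)
    idx <- apply(scores, 1L, which.max)   # ties break to the lowest index
    factor(model@labels[idx], levels = model@labels)
}

#' Accuracy z-transform via the normal approximation to the binomial
#'
#' \eqn{z = (acc - chance) / \sqrt{chance (1 - chance) / n}}.
#'
#' @param accuracy Proportion correct in \[0, 1\].
#' @param nTest Number of test classifications.
#' @param chance Chance level in (0, 1).
#' @return z score.
#' @examples
#' accuracyToZ(0.375, 32, 0.25)  # ~1.63, the within-subject threshold pair
#' @export
accuracyToZ <- function(accuracy, nTest, chance = 0.25) {
    stopifnot(accuracy >= 0, accuracy <= 1, nTest >= 1,
              chance > 0, chance < 1)
    (accuracy - chance) / sqrt(chance * (1 - chance) / nTest)
}

#' Accuracy corresponding to a critical z value
#'
#' Inverts [accuracyToZ()]: the accuracy (in percent, truncated to one
#' decimal place) that a given z criterion corresponds to.  With the
#' standard design (32 cross-validated classifications, chance 25%),
#' z = 1.64 corresponds to 37.5%.
#'
#' @param zCrit Critical z value (> 0 for a suprachance threshold).
#' @param nTest Number of test classifications.
#' @param chance Chance level in (0, 1).
#' @return Accuracy threshold in percent, truncated to one decimal.
#' @export
accuracyThreshold <- function(zCrit, nTest, chance = 0.25) {
    stopifnot(nTest >= 1, chance > 0, chance < 1)
    acc <- 100 * (chance + zCrit * sqrt(chance * (1 - chance) / nTest))
    floor(acc * 10) / 10
}

#' Leave-one-run-out cross-validated classification accuracy
#'
#' For each run in turn, trains the regularized LDA on all other runs and
#' classifies the held-out run's patterns; accuracy is the proportion
#' correct over all classes x runs test classifications.
#'
#' @param betas A [BetaPatterns-class].
#' @param regFraction Regularization fraction passed to [ldaTrain()].
#' @return A [ClassifierResult-class].
#' @export
crossvalAccuracy <- function(betas, regFraction = 0.01) {
    stopifnot(is(betas, "BetaPatterns"))
    crossvalMatrix(betaMatrix(betas), conditionLabels(betas),
                   runLabels(betas), regFraction)
}

## Core leave-one-run-out loop on a plain matrix (obs x features).
crossvalMatrix <- function(x, classes, runs, regFraction = 0.01,
                           projector = NULL) {
    classes <- as.factor(classes)
    uRuns <- sort(unique(runs))
    if (length(uRuns) < 2L) stop("at least 2 runs required")
    preds <- vector("list", length(uRuns))
    for (i in seq_along(uRuns)) {
        test <- runs == uRuns[i]
        xtr <- x[!test, , drop = FALSE]
        xte <- x[test, , drop = FALSE]
        if (!is.null(projector)) {
            P <- projector(xtr, classes[!test])
            xtr <- xtr %*% P
            xte <- xte %*% P
        }
        model <- ldaTrain(xtr, classes[!test], regFraction)
        pred <- ldaClassify(model, xte)
        preds[[i]] <- data.frame(run = uRuns[i],
                                 condition = as.character(classes[test]),
                                 predicted = as.character(pred),
                                 correct = as.character(pred) ==
                                     as.character(classes[test]))
    }
    preds <- do.call(rbind, preds)
    acc <- mean(preds$correct)
    chance <- 1 / nlevels(classes)
    new("ClassifierResult", accuracy = acc, nTest = nrow(preds),
        z = accuracyToZ(acc, nrow(preds), chance), chance = chance,
        predictions = preds)
}

#' Cross-validated LDA on behavioural features
#'
#' Computes, per condition and run, the average movement time, the average
#' peak force (mean over fingers), and the error rate; z-standardizes each
#' feature across all condition-runs; and submits the selected features to
#' the same leave-one-run-out LDA used for voxel patterns.  Used to check
#' whether pattern-based classification could be explained by behavioural
#' differences between sequences.
#'
#' @param records Behavioural data.frame from [simulateBehavior()] (or the
#'   same layout read from disk).
#' @param features Character subset of `c("MT", "force", "error")`.
#' @param regFraction Regularization fraction.
#' @return A [ClassifierResult-class].
#' @export
behavioralClassifier <- function(records, features = c("MT", "force",
                                                       "error"),
                                 regFraction = 0.01) {
    features <- match.arg(features, several.ok = TRUE)
    agg <- stats::aggregate(
        cbind(MT = records$MT_ms,
              force = rowMeans(records[, paste0("force", 1:5)]),
              error = as.numeric(records$error)),
        by = list(condition = records$condition, run = records$run),
        FUN = mean)
    grid <- table(agg$condition, agg$run)
    if (!all(grid == 1L))
        stop("records must cover the complete condition x run grid")
    feat <- as.matrix(agg[, features, drop = FALSE])
    keep <- apply(feat, 2L, stats::sd) > 0
    if (!all(keep)) {
        warning("dropping constant feature(s): ",
                paste(colnames(feat)[!keep], collapse = ", "))
        feat <- feat[, keep, drop = FALSE]
    }
    if (ncol(feat) == 0L) stop("no non-constant features left")
    feat <- scale(feat)
    crossvalMatrix(feat, factor(agg$condition), agg$run, regFraction)
}
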