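## Permutation tests of genomic-signal reliance and the learning curve.

## strain-level genomic profile matrix of a dataset (one row per strain)
.strainProfiles <- function(data) {
    strains <- unique(data@strain)
    first <- match(strains, data@strain)
    P <- data@x[first, data@genomicFeatures, drop = FALSE]
    rownames(P) <- strains
    P
}

.permutedPC <- function(bundle, data, xg, rowsIdx) {
    x <- data@x
    x[, colnames(xg)] <- xg[rowsIdx, , drop = FALSE]
    ## targets and condition features are untouched by construction; the
    ## condition block is still the original slice of data@x
    cor(predictVmax(bundle, x), data@y)
}

.permResult <- function(mode, orig, nullPC, seed) {
    qs <- unname(quantile(nullPC, c(0.025, 0.975)))
    new("PermutationTestResult", mode = mode, originalPC = orig,
        nullPC = nullPC, lower = qs[1], upper = qs[2],
        outside95 = orig > qs[2] || orig < qs[1], seed = seed)
}

#' Feature-permutation test of genomic-signal reliance
#'
#' Per replicate, the strain-level values of every genomic feature are
#' independently permuted across the test strains (each strain keeps one
#' value per feature, broadcast to its condition rows), destroying the
#' alignment between genome and strain while condition features and targets
#' stay untouched. The model's Pearson correlation on the intact test set
#' is compared with the empirical 95\% interval of the permuted-set
#' correlations; a model that relies on genomic signal lands above the
#' 97.5th percentile.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param test an \linkS4class{AssembledDataset} of test rows (>= 2 strains
#'   recommended).
#' @param nReps number of replicates (published protocol: 1000).
#' @param seed RNG seed; the full null distribution is reproducible.
#' @return A \linkS4class{PermutationTestResult}.
#' @export
featurePermutationTest <- function(bundle, test, nReps = 1000, seed = 1) {
    stopifnot(is(bundle, "ModelBundle"), is(test, "AssembledDataset"))
    if (nReps < 1) stop("nReps must be >= 1")
    orig <- cor(predictVmax(bundle, test), test@y)
    gf <- test@genomicFeatures
    if (!length(gf))
        return(.permResult("feature_permute", orig, rep(orig, nReps), seed))
    P <- .strainProfiles(test)
    rowsIdx <- match(test@strain, rownames(P))
    nS <- nrow(P); nF <- ncol(P)
    set.seed(seed)
    nullPC <- vapply(seq_len(nReps), function(r) {
        perm <- vapply(seq_len(nF), function(j) sample.int(nS), integer(nS))
        xg <- matrix(P[cbind(as.vector(perm),
                             rep(seq_len(nF), each = nS))], nS, nF,
                     dimnames = dimnames(P))
        .permutedPC(bundle, test, xg, rowsIdx)
    }, numeric(1))
    .permResult("feature_permute", orig, nullPC, seed)
}

#' Profile-switch test of genomic-signal reliance
#'
#' Per replicate, whole genomic profiles are switched between test strains
#' by one random permutation (every feature moves together), so the
#' relationships between genomic features are kept intact while the
#' genome-to-strain assignment is destroyed.
#'
#' @inheritParams featurePermutationTest
#' @return A \linkS4class{PermutationTestResult}.
#' @export
profileSwitchTest <- function(bundle, test, nReps = 1000, seed = 1) {
    stopifnot(is(bundle, "ModelBundle"), is(test, "AssembledDataset"))
    if (nReps < 1) stop("nReps must be >= 1")
    orig <- cor(predictVmax(bundle, test), test@y)
    gf <- test@genomicFeatures
    if (!length(gf))
        return(.permResult("profile_switch", orig, rep(orig, nReps), seed))
    P <- .strainProfiles(test)
    rowsIdx <- match(test@strain, rownames(P))
    nS <- nrow(P)
    set.seed(seed)
    nullPC <- vapply(seq_len(nReps), function(r) {
        xg <- P[sample.int(nS), , drop = FALSE]
        rownames(xg) <- rownames(P)
        .permutedPC(bundle, test, xg, rowsIdx)
    }, numeric(1))
    .permResult("profile_switch", orig, nullPC, seed)
}

#' Learning curve over training-set size
#'
#' For each requested size, draws random strain subsets of the training
#' data, trains a forest with fixed hyperparameters, and evaluates on the
#' fixed test set; reports per-size mean scores.
#'
#' @param train,test \linkS4class{AssembledDataset}s.
#' @param sizes strictly increasing strain counts, each <= the number of
#'   training strains.
#' @param repsPerSize random subsets per size (>= 1).
#' @param params hyperparameters (default: the representation's preset).
#' @param seed RNG seed.
#' @return data.frame with columns \code{size}, \code{pearson},
#'   \code{explainedVariance}, \code{rmse} (means over repetitions);
#'   per-repetition scores in \code{attr(, "replicates")}.
#' @export
learningCurve <- function(train, test, sizes, repsPerSize = 1,
                          params = presetParams(train@representation),
                          seed = 1) {
    stopifnot(is(train, "AssembledDataset"), is(test, "AssembledDataset"))
    sizes <- as.integer(sizes)
    if (is.unsorted(sizes, strictly = TRUE))
        stop("sizes must be strictly increasing")
    strains <- unique(train@strain)
    if (max(sizes) > length(strains))
        stop("size exceeds the number of training strains")
    if (repsPerSize < 1) stop("repsPerSize must be >= 1")
    set.seed(seed)
    reps <- do.call(rbind, lapply(sizes, function(sz) {
        do.call(rbind, lapply(seq_len(repsPerSize), function(r) {
            sub <- subsetStrains(train,
                                 if (sz == length(strains)) strains
                                 else sample(strains, sz))
            ev <- evaluateModel(trainModel(sub, params, seed = seed), test)
            data.frame(size = sz, rep = r, pearson = ev$pearson,
                       explainedVariance = ev$explainedVariance,
                       rmse = ev$rmse)
        }))
    }))
    out <- do.call(rbind, lapply(split(reps, reps$size), function(d)
        data.frame(size = d$size[1], pearson = mean(d$pearson),
                   explainedVariance = mean(d$explainedVariance),
                   rmse = mean(d$rmse))))
    out <- out[order(out$size), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "replicates") <- reps
    out
}
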