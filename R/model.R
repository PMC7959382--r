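## Random-forest regression of Vmax: strain-level splitting, randomized
## grid search over the published candidate grid, training, evaluation.

#' Strain-level train/test split
#'
#' Partitions strains uniformly at random so that all measurements of a
#' strain fall on one side. The training set holds
#' \code{ceiling(fraction * n)} strains — 257 of 342 at the default 0.75.
#'
#' @param strainIds character vector of strain ids (n >= 2).
#' @param fraction training fraction in (0, 1); default 0.75.
#' @param seed RNG seed.
#' @return A \linkS4class{TrainTestSplit}.
#' @examples
#' sp <- splitByStrain(sprintf("S%03d", 1:342), seed = 1)
#' length(trainStrains(sp))  # 257
#' @export
splitByStrain <- function(strainIds, fraction = 0.75, seed = 1) {
    stopifnot(length(strainIds) >= 2, !anyDuplicated(strainIds))
    if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
    nTrain <- ceiling(fraction * length(strainIds))
    set.seed(seed)
    tr <- sample(strainIds, nTrain)
    new("TrainTestSplit", train = sort(tr, method = "radix"),
        test = sort(setdiff(strainIds, tr), method = "radix"),
        fraction = fraction, seed = seed)
}

#' Restrict an AssembledDataset to a strain subset
#'
#' @param data an \linkS4class{AssembledDataset}.
#' @param strains strain ids to keep.
#' @return The row-subset \linkS4class{AssembledDataset}.
#' @export
subsetStrains <- function(data, strains) {
    stopifnot(is(data, "AssembledDataset"))
    keep <- data@strain %in% strains
    new("AssembledDataset", x = data@x[keep, , drop = FALSE],
        y = data@y[keep], strain = data@strain[keep],
        condition = data@condition[keep],
        genomicFeatures = data@genomicFeatures,
        representation = data@representation)
}

#' The published hyperparameter candidate grid
#'
#' Number of trees \{10, 50, 100, ..., 750\}, maximum depth \{unlimited,
#' 10, 20, ..., 150\}, minimum samples to split \{2, 4, ..., 16\}, minimum
#' samples per leaf \{1, ..., 9\}, out-of-bag scoring \{on, off\}: 36864
#' combinations in total, explored by \code{nDraws} random draws under
#' 3-fold cross-validation.
#'
#' @param nDraws randomized draws to evaluate.
#' @param seed search seed.
#' @return A \linkS4class{HyperparameterGrid}.
#' @export
hyperparameterGrid <- function(nDraws = 100, seed = 1) {
    new("HyperparameterGrid",
        nTrees = c(10, seq(50, 750, by = 50)),
        maxDepth = c(NA, seq(10, 150, by = 10)),
        minSplit = seq(2, 16, by = 2),
        minLeaf = 1:9,
        oob = c(TRUE, FALSE),
        cvFolds = 3, nDraws = nDraws, seed = seed)
}

#' @rdname hyperparameterGrid
#' @param grid a \linkS4class{HyperparameterGrid}.
#' @export
gridSize <- function(grid) {
    length(grid@nTrees) * length(grid@maxDepth) * length(grid@minSplit) *
        length(grid@minLeaf) * length(grid@oob)
}

## decode mixed-radix combination index (1-based) into a parameter list
.gridCombination <- function(grid, idx) {
    dims <- c(length(grid@nTrees), length(grid@maxDepth),
              length(grid@minSplit), length(grid@minLeaf),
              length(grid@oob))
    i <- idx - 1L
    pick <- integer(5)
    for (d in seq_len(5)) {
        pick[d] <- i %% dims[d]
        i <- i %/% dims[d]
    }
    list(nTrees = grid@nTrees[pick[1] + 1L],
         maxDepth = grid@maxDepth[pick[2] + 1L],
         minSplit = grid@minSplit[pick[3] + 1L],
         minLeaf = grid@minLeaf[pick[4] + 1L],
         oob = grid@oob[pick[5] + 1L])
}

#' Published per-representation optimal hyperparameters
#'
#' The optima identified by the randomized 3-fold cross-validated search
#' for each representation, shipped as presets so the 36864-combination
#' search can be skipped: gene 450 trees / unlimited depth / split 2 /
#' leaf 1 / OOB on; pfam 650 / 70 / 6 / 4 / off; 8-mer 650 / 110 / 4 / 2 /
#' off; 9-mer 550 / 120 / 4 / 1 / off.
#'
#' @param representation one of \code{"gene"}, \code{"pfam"},
#'   \code{"kmer8"}, \code{"kmer9"}.
#' @return named list with \code{nTrees}, \code{maxDepth} (NA = unlimited),
#'   \code{minSplit}, \code{minLeaf}, \code{oob}.
#' @export
presetParams <- function(representation = c("gene", "pfam", "kmer8",
                                            "kmer9")) {
    representation <- match.arg(representation)
    switch(representation,
        gene = list(nTrees = 450, maxDepth = NA, minSplit = 2,
                    minLeaf = 1, oob = TRUE),
        pfam = list(nTrees = 650, maxDepth = 70, minSplit = 6,
                    minLeaf = 4, oob = FALSE),
        kmer8 = list(nTrees = 650, maxDepth = 110, minSplit = 4,
                     minLeaf = 2, oob = FALSE),
        kmer9 = list(nTrees = 550, maxDepth = 120, minSplit = 4,
                     minLeaf = 1, oob = FALSE))
}

## one ranger fit with the sklearn-equivalent settings: all features
## considered at every split (max_features = all), bootstrap sampling with
## replacement, minimum node size to attempt a split, minimum leaf size,
## depth cap (NA = unlimited)
.fitForest <- function(x, y, params, seed) {
    ranger::ranger(x = x, y = y,
                   num.trees = params$nTrees,
                   mtry = ncol(x),
                   min.node.size = params$minSplit,
                   min.bucket = params$minLeaf,
                   max.depth = if (is.na(params$maxDepth)) 0
                               else params$maxDepth,
                   replace = TRUE, sample.fraction = 1,
                   oob.error = isTRUE(params$oob),
                   num.threads = 1, seed = seed, verbose = FALSE)
}

#' Randomized 3-fold cross-validated hyperparameter search
#'
#' Draws \code{grid@nDraws} distinct combinations uniformly from the
#' candidate grid and scores each by 3-fold cross-validation on the
#' training rows (coefficient of determination on held-out folds); returns
#' the best combination by mean CV score.
#'
#' @param train an \linkS4class{AssembledDataset} (training rows).
#' @param grid a \linkS4class{HyperparameterGrid}.
#' @return named list of chosen hyperparameters (as
#'   \code{\link{presetParams}}), with the mean CV score in
#'   \code{attr(, "cvScore")}.
#' @export
tuneHyperparameters <- function(train, grid) {
    stopifnot(is(train, "AssembledDataset"), is(grid, "HyperparameterGrid"))
    n <- nrow(train@x)
    if (!n) stop("empty training set")
    total <- gridSize(grid)
    if (grid@nDraws > total)
        stop("nDraws exceeds the grid size (", total, ")")
    set.seed(grid@seed)
    draws <- sample.int(total, grid@nDraws)
    folds <- sample(rep(seq_len(grid@cvFolds), length.out = n))
    best <- NULL; bestScore <- -Inf
    for (d in draws) {
        p <- .gridCombination(grid, d)
        scores <- vapply(seq_len(grid@cvFolds), function(f) {
            ho <- folds == f
            fit <- .fitForest(train@x[!ho, , drop = FALSE], train@y[!ho],
                              p, seed = grid@seed)
            pred <- predict(fit, data = train@x[ho, , drop = FALSE],
                            num.threads = 1)$predictions
            1 - sum((train@y[ho] - pred)^2) /
                sum((train@y[ho] - mean(train@y[ho]))^2)
        }, numeric(1))
        sc <- mean(scores)
        if (sc > bestScore) { bestScore <- sc; best <- p }
    }
    attr(best, "cvScore") <- bestScore
    best
}

#' Train a random-forest Vmax regressor
#'
#' Fits a \pkg{ranger} regression forest with the given hyperparameters
#' (all features considered at every split, bootstrap sampling with
#' replacement, fixed seed), and flattens the fitted trees — children,
#' split features, thresholds, leaf values, and per-node training covers —
#' for exact TreeSHAP attribution.
#'
#' @param train an \linkS4class{AssembledDataset}.
#' @param params hyperparameters (a \code{\link{presetParams}}-shaped list);
#'   defaults to the preset of the dataset's representation.
#' @param seed forest seed.
#' @return A \linkS4class{ModelBundle}.
#' @export
trainModel <- function(train, params = presetParams(train@representation),
                       seed = 1) {
    stopifnot(is(train, "AssembledDataset"))
    if (nrow(train@x) < 2) stop("need at least 2 training rows")
    fit <- .fitForest(train@x, train@y, params, seed)
    forest <- .flattenForest(fit, colnames(train@x))
    forest$covers <- treeCoversCpp(forest, train@x)
    new("ModelBundle", representation = train@representation, fit = fit,
        params = params, predictors = colnames(train@x),
        trainStrains = sort(unique(train@strain), method = "radix"),
        forest = forest, seed = seed)
}

#' Predict Vmax for new rows
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param data an \linkS4class{AssembledDataset} or a numeric matrix with
#'   the bundle's predictor columns.
#' @return numeric vector of predicted Vmax (h^-1).
#' @export
predictVmax <- function(bundle, data) {
    stopifnot(is(bundle, "ModelBundle"))
    x <- if (is(data, "AssembledDataset")) data@x else data
    if (!identical(colnames(x), bundle@predictors)) {
        if (!all(bundle@predictors %in% colnames(x)))
            stop("data lacks predictors the model was trained on")
        x <- x[, bundle@predictors, drop = FALSE]
    }
    predict(bundle@fit, data = x, num.threads = 1)$predictions
}

#' Evaluate predictions on a test set
#'
#' Pearson correlation, explained variance (1 - var(residual)/var(actual))
#' and root-mean-square error between predicted and actual Vmax.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param test an \linkS4class{AssembledDataset} with >= 2 rows.
#' @return named list: \code{pearson}, \code{explainedVariance},
#'   \code{rmse}, plus the \code{predicted} and \code{actual} vectors.
#' @export
evaluateModel <- function(bundle, test) {
    stopifnot(is(test, "AssembledDataset"))
    if (nrow(test@x) < 2) stop("need >= 2 test rows to evaluate")
    if (length(intersect(bundle@trainStrains, unique(test@strain))))
        stop("strain leakage: test rows contain training strains")
    pred <- predictVmax(bundle, test)
    list(pearson = cor(pred, test@y),
         explainedVariance = 1 - var(test@y - pred) / var(test@y),
         rmse = sqrt(mean((test@y - pred)^2)),
         predicted = pred, actual = test@y)
}
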