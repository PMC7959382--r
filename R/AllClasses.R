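#' @import methods
#' @importFrom stats coef cor lm poly predict quantile rbinom rnorm
#'   runif sd uniroot var approx setNames
#' @importFrom utils head read.table write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib acidforest, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Experimental conditions
## ---------------------------------------------------------------------------

#' The 12 experimental conditions
#'
#' Acidification assays are run under 12 condition combinations:
#' temperature (25, 30, 40 C) x plate volume (lowwell \code{LW} 200 ul,
#' deepwell \code{DW} 2000 ul) x yeast-extract supplementation
#' (\code{YE} with, \code{NY} without). Condition identifiers follow the
#' \code{VOL_YEAST_TEMP} pattern, e.g. \code{"DW_YE_30"}.
#'
#' @return A data.frame with columns \code{condition}, \code{temperature}
#'   (numeric, C), \code{volume} (\code{"LW"}/\code{"DW"}) and \code{yeast}
#'   (\code{"NY"}/\code{"YE"}), one row per condition (12 rows).
#' @examples
#' conditionGrid()
#' @export
conditionGrid <- function() {
    g <- expand.grid(temperature = c(25, 30, 40),
                     yeast = c("NY", "YE"),
                     volume = c("LW", "DW"),
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[, c("volume", "yeast", "temperature")]
    g$condition <- paste(g$volume, g$yeast, g$temperature, sep = "_")
    rownames(g) <- NULL
    g[, c("condition", "temperature", "volume", "yeast")]
}

#' @rdname conditionGrid
#' @export
conditionIds <- function() conditionGrid()$condition

## ---------------------------------------------------------------------------
## Kinetics
## ---------------------------------------------------------------------------

#' CalibrationModel: degree-4 hue-to-pH calibration
#'
#' Stores the coefficients of a least-squares degree-4 polynomial mapping
#' scanner hue to pH, together with the hue and pH ranges spanned by the
#' calibration pairs, the fit RMSE, and a flag for monotonicity of the
#' polynomial over the fitted hue range (checked numerically). Non-monotone
#' fits are flagged, not rejected, because real dye curves can wiggle at the
#' edges of the usable range.
#'
#' @slot coefficients numeric(5), c0..c4 so that
#'   \code{pH = c0 + c1*h + c2*h^2 + c3*h^3 + c4*h^4}.
#' @slot hueRange numeric(2), hue range covered by the calibration pairs.
#' @slot phRange numeric(2), pH range covered by the calibration pairs.
#' @slot rmse numeric(1), residual RMSE of the fit.
#' @slot monotone logical(1), whether the polynomial is strictly monotone
#'   over \code{hueRange}.
#' @export
setClass("CalibrationModel",
    representation(coefficients = "numeric", hueRange = "numeric",
                   phRange = "numeric", rmse = "numeric",
                   monotone = "logical"),
    validity = function(object) {
        if (length(object@coefficients) != 5L)
            return("calibration must have exactly 5 coefficients (degree 4)")
        if (any(!is.finite(object@coefficients)))
            return("calibration coefficients must be finite")
        if (length(object@hueRange) != 2L || diff(object@hueRange) < 0)
            return("hueRange must be c(min, max)")
        TRUE
    })

#' PhCurve: one strain x condition kinetic time series
#'
#' A single acidification curve: pH (or raw scanner hue) sampled at uniform
#' time spacing, by default every 6 minutes (0.1 h).
#'
#' @slot strain character(1) strain identifier.
#' @slot condition character(1), one of \code{conditionIds()}.
#' @slot times numeric, hours, strictly increasing, uniform spacing.
#' @slot values numeric, same length as \code{times}.
#' @slot valueKind character(1), \code{"pH"} or \code{"hue"}.
#' @export
setClass("PhCurve",
    representation(strain = "character", condition = "character",
                   times = "numeric", values = "numeric",
                   valueKind = "character"),
    validity = function(object) {
        if (length(object@times) != length(object@values))
            return("times and values must have equal length")
        if (length(object@times) >= 2) {
            dt <- diff(object@times)
            if (any(dt <= 0)) return("times must be strictly increasing")
            if (max(dt) - min(dt) > 1e-6 * max(dt))
                return("times must be uniformly spaced")
        }
        if (!object@valueKind %in% c("pH", "hue"))
            return("valueKind must be 'pH' or 'hue'")
        if (!object@condition %in% conditionIds())
            return(sprintf("unknown condition '%s'", object@condition))
        TRUE
    })

#' Construct a PhCurve
#'
#' @param strain strain id.
#' @param condition condition id (see \code{\link{conditionGrid}}).
#' @param times sampling times in hours (uniform spacing).
#' @param values pH or hue values.
#' @param valueKind \code{"pH"} (default) or \code{"hue"}.
#' @return A \linkS4class{PhCurve}.
#' @export
phCurve <- function(strain, condition, times, values, valueKind = "pH") {
    new("PhCurve", strain = as.character(strain),
        condition = as.character(condition),
        times = as.numeric(times), values = as.numeric(values),
        valueKind = valueKind)
}

#' PhenotypeTable: Vmax per strain per condition
#'
#' A strains x 12-conditions matrix of maximum hourly acidification rates
#' (h^-1). Rates are negative (the pH drops); \code{NA} marks missing
#' strain x condition measurements.
#'
#' @slot mat numeric matrix, rownames = strain ids, colnames =
#'   \code{conditionIds()}; non-missing entries are <= 0.
#' @export
setClass("PhenotypeTable",
    representation(mat = "matrix"),
    validity = function(object) {
        m <- object@mat
        if (is.null(rownames(m))) return("strain ids (rownames) required")
        if (anyDuplicated(rownames(m))) return("duplicate strain ids")
        if (!identical(colnames(m), conditionIds()))
            return("columns must be the 12 condition ids, in canonical order")
        v <- m[!is.na(m)]
        if (length(v) && any(v > 0))
            return("non-missing Vmax values must be <= 0 (acidification)")
        TRUE
    })

#' Construct a PhenotypeTable from a matrix
#'
#' @param mat numeric matrix of Vmax values (h^-1, <= 0 or NA), rownames =
#'   strain ids. Columns are matched to \code{conditionIds()} by name.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
phenotypeTable <- function(mat) {
    if (is.null(colnames(mat)) || !all(conditionIds() %in% colnames(mat)))
        stop("matrix must have the 12 condition columns (see conditionIds())")
    new("PhenotypeTable", mat = mat[, conditionIds(), drop = FALSE])
}

## ---------------------------------------------------------------------------
## Features
## ---------------------------------------------------------------------------

.REPRESENTATIONS <- c("gene", "pfam", "kmer8", "kmer9")

#' FeatureMatrix: strains x genomic features, one representation
#'
#' Holds one of the four genomic representations: gene presence/absence
#' (binary), Pfam domain copy numbers, or canonical 8-/9-mer counts.
#' Columns whose value profiles are identical across all strains may be
#' collapsed into single comma-named columns; \code{collapseMap} records
#' the membership of each collapsed column.
#'
#' @slot representation one of \code{"gene"}, \code{"pfam"}, \code{"kmer8"},
#'   \code{"kmer9"}.
#' @slot mat numeric matrix of non-negative values; rownames = strain ids,
#'   colnames = feature ids (comma-joined when collapsed).
#' @slot subspecies character vector named by strain (e.g. \code{"lactis"} /
#'   \code{"cremoris"}); may be empty strings when unknown.
#' @slot collapseMap named list mapping each collapsed column name to the
#'   original feature ids it represents.
#' @export
setClass("FeatureMatrix",
    representation(representation = "character", mat = "matrix",
                   subspecies = "character", collapseMap = "list"),
    validity = function(object) {
        if (!object@representation %in% .REPRESENTATIONS)
            return(sprintf("representation must be one of %s",
                           paste(.REPRESENTATIONS, collapse = ", ")))
        m <- object@mat
        if (is.null(rownames(m))) return("strain ids (rownames) required")
        if (anyDuplicated(rownames(m))) return("duplicate strain ids")
        if (ncol(m) && is.null(colnames(m))) return("feature ids required")
        if (ncol(m) && anyDuplicated(colnames(m)))
            return("duplicate feature ids")
        if (length(m) && (any(is.na(m)) || any(m < 0)))
            return("feature values must be non-negative and non-missing")
        if (object@representation == "gene" && length(m) &&
            !all(m %in% c(0, 1)))
            return("gene representation must be binary 0/1")
        if (length(object@subspecies) &&
            !setequal(names(object@subspecies), rownames(m)))
            return("subspecies must be named by the strain ids")
        TRUE
    })

#' Construct a FeatureMatrix
#'
#' @param mat numeric matrix (strains x features).
#' @param representation one of \code{"gene"}, \code{"pfam"}, \code{"kmer8"},
#'   \code{"kmer9"}.
#' @param subspecies optional character vector named by strain id.
#' @param collapseMap optional named list (collapsed id -> original ids).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
featureMatrix <- function(mat, representation,
                          subspecies = character(), collapseMap = list()) {
    if (length(subspecies) && !is.null(rownames(mat)))
        subspecies <- subspecies[rownames(mat)]
    new("FeatureMatrix", representation = representation, mat = mat,
        subspecies = subspecies, collapseMap = collapseMap)
}

#' AssembledDataset: model-ready rows of (strain, condition)
#'
#' One row per non-missing strain x condition Vmax measurement. Predictors
#' are the genomic features of one representation plus the three condition
#' features: \code{Temperature} (numeric C), \code{Volume} (1 = deepwell)
#' and \code{Yeast} (1 = yeast extract added). Predictor columns are sorted
#' by name so that fitted models are invariant to input column order.
#'
#' @slot x numeric predictor matrix (rows x predictors, column-sorted).
#' @slot y numeric target Vmax (h^-1) per row.
#' @slot strain character strain id per row.
#' @slot condition character condition id per row.
#' @slot genomicFeatures character, names of the genomic predictor columns.
#' @slot representation the representation tag of the genomic features.
#' @export
setClass("AssembledDataset",
    representation(x = "matrix", y = "numeric", strain = "character",
                   condition = "character", genomicFeatures = "character",
                   representation = "character"),
    validity = function(object) {
        n <- nrow(object@x)
        if (length(object@y) != n || length(object@strain) != n ||
            length(object@condition) != n)
            return("x, y, strain, condition must agree in length")
        cn <- colnames(object@x)
        if (!identical(cn, sort(cn, method = "radix")))
            return("predictor columns must be sorted by name")
        cond <- c("Temperature", "Volume", "Yeast")
        if (!all(cond %in% colnames(object@x)))
            return("condition predictors Temperature/Volume/Yeast required")
        if (!all(object@genomicFeatures %in% colnames(object@x)))
            return("genomicFeatures must be predictor columns")
        if (any(object@genomicFeatures %in% cond))
            return("genomic features may not be named like condition features")
        TRUE
    })

## ---------------------------------------------------------------------------
## Model
## ---------------------------------------------------------------------------

#' TrainTestSplit: strain-level 75/25 partition
#'
#' @slot train character, training strain ids.
#' @slot test character, test strain ids.
#' @slot fraction numeric(1), training fraction; |train| = ceiling(fraction*n).
#' @slot seed numeric(1).
#' @export
setClass("TrainTestSplit",
    representation(train = "character", test = "character",
                   fraction = "numeric", seed = "numeric"),
    validity = function(object) {
        if (length(intersect(object@train, object@test)))
            return("train and test strains must be disjoint")
        n <- length(object@train) + length(object@test)
        if (length(object@train) != ceiling(object@fraction * n))
            return("|train| must equal ceiling(fraction * n)")
        TRUE
    })

#' HyperparameterGrid: the randomized-search candidate grid
#'
#' Candidate sets mirror the published grid: number of trees
#' \{10, 50, 100, ..., 750\}; maximum depth \{unlimited, 10, 20, ..., 150\};
#' minimum samples to split a node \{2, 4, ..., 16\}; minimum samples per
#' leaf \{1, ..., 9\}; out-of-bag scoring on/off. 16 x 16 x 8 x 9 x 2 =
#' 36864 combinations, explored by randomized draws with 3-fold CV.
#'
#' @slot nTrees integer candidates for the number of trees.
#' @slot maxDepth numeric candidates; \code{NA} = unlimited.
#' @slot minSplit integer candidates for min samples to split.
#' @slot minLeaf integer candidates for min samples per leaf.
#' @slot oob logical candidates for out-of-bag scoring.
#' @slot cvFolds integer(1), cross-validation folds (3).
#' @slot nDraws integer(1), randomized draws to evaluate.
#' @slot seed numeric(1), search seed.
#' @export
setClass("HyperparameterGrid",
    representation(nTrees = "numeric", maxDepth = "numeric",
                   minSplit = "numeric", minLeaf = "numeric",
                   oob = "logical", cvFolds = "numeric",
                   nDraws = "numeric", seed = "numeric"),
    validity = function(object) {
        if (object@nDraws < 1) return("nDraws must be >= 1")
        if (object@cvFolds < 2) return("cvFolds must be >= 2")
        if (any(object@nTrees < 1)) return("nTrees candidates must be >= 1")
        TRUE
    })

#' ModelBundle: a fitted random-forest Vmax regressor
#'
#' Wraps a fitted \pkg{ranger} forest with its hyperparameters, the
#' representation tag, the ordered predictor names, the training strain set,
#' and a flattened copy of the tree structures (children, split features,
#' thresholds, leaf values and per-node training covers) used for exact
#' TreeSHAP attribution.
#'
#' @slot representation representation tag of the genomic features.
#' @slot fit the fitted \code{ranger} object.
#' @slot params named list of hyperparameters used.
#' @slot predictors ordered predictor names the forest was fitted on.
#' @slot trainStrains strain ids seen during training.
#' @slot forest internal flattened forest (list of integer/double vectors).
#' @slot seed numeric(1) forest seed.
#' @export
setClass("ModelBundle",
    representation(representation = "character", fit = "ANY",
                   params = "list", predictors = "character",
                   trainStrains = "character", forest = "list",
                   seed = "numeric"))

#' PermutationTestResult: genomic-signal permutation null
#'
#' @slot mode \code{"feature_permute"} or \code{"profile_switch"}.
#' @slot originalPC Pearson correlation on the intact test set.
#' @slot nullPC Pearson correlations over the permuted replicates.
#' @slot lower,upper empirical 2.5th / 97.5th percentiles of \code{nullPC}.
#' @slot outside95 logical; TRUE iff \code{originalPC} falls outside
#'   [lower, upper].
#' @slot seed numeric(1).
#' @export
setClass("PermutationTestResult",
    representation(mode = "character", originalPC = "numeric",
                   nullPC = "numeric", lower = "numeric", upper = "numeric",
                   outside95 = "logical", seed = "numeric"),
    validity = function(object) {
        if (!object@mode %in% c("feature_permute", "profile_switch"))
            return("mode must be feature_permute or profile_switch")
        out <- object@originalPC > object@upper ||
               object@originalPC < object@lower
        if (!identical(out, object@outside95))
            return("outside95 inconsistent with null percentiles")
        TRUE
    })

## ---------------------------------------------------------------------------
## Synthetic population
## ---------------------------------------------------------------------------

#' SyntheticTruth: ground truth of a generated population
#'
#' @slot clade character \code{"A"}/\code{"B"} per strain (named).
#' @slot presence binary matrix strains x gene families (all families).
#' @slot causal data.frame of planted causal genes: columns \code{block},
#'   \code{gene}, \code{effect}, \code{tagKmer}.
#' @slot noise numeric matrix strains x conditions of the noise draws.
#' @slot targetVmax the PhenotypeTable-shaped matrix of target Vmax values
#'   before any curve synthesis (NA where masked missing).
#' @export
setClass("SyntheticTruth",
    representation(clade = "character", presence = "matrix",
                   causal = "data.frame", noise = "matrix",
                   targetVmax = "matrix"))

#' SimConfig: parameters of the synthetic population generator
#'
#' See \code{\link{simConfig}} for field semantics and defaults.
#'
#' @slot nStrains integer, number of strains (>= 2).
#' @slot cladeFraction fraction of strains in clade A.
#' @slot nCoreGenes integer, gene families present in every strain.
#' @slot nAccessoryGenes integer, clade-structured accessory families.
#' @slot accessoryPresenceProb numeric c(A=, B=) presence probability of each
#'   accessory family per clade.
#' @slot causalBlocks list of causal blocks (see \code{\link{causalBlock}}).
#' @slot conditionEffects list of condition effect sizes (see
#'   \code{\link{simConfig}}).
#' @slot baseSpeed baseline acidification speed (h^-1, positive scale).
#' @slot clipRange numeric(2), speed clipped into this range before negation.
#' @slot noiseSd measurement noise SD (h^-1).
#' @slot missingRate probability a strain x condition measurement is absent.
#' @slot geneLengthRange integer(2), gene length range in bp.
#' @slot mutationRate per-base substitution probability per strain.
#' @slot seed integer master seed; fully determines all outputs.
#' @export
setClass("SimConfig",
    representation(nStrains = "numeric", cladeFraction = "numeric",
                   nCoreGenes = "numeric", nAccessoryGenes = "numeric",
                   accessoryPresenceProb = "numeric", causalBlocks = "list",
                   conditionEffects = "list", baseSpeed = "numeric",
                   clipRange = "numeric", noiseSd = "numeric",
                   missingRate = "numeric", geneLengthRange = "numeric",
                   mutationRate = "numeric", seed = "numeric"),
    validity = function(object) {
        probs <- c(object@cladeFraction, object@accessoryPresenceProb,
                   object@missingRate, object@mutationRate)
        if (object@nStrains < 2) return("nStrains must be >= 2")
        if (any(probs < 0 | probs > 1))
            return("probabilities must lie in [0, 1]")
        if (object@noiseSd < 0) return("noiseSd must be >= 0")
        if (length(object@clipRange) != 2L ||
            object@clipRange[1] > object@clipRange[2])
            return("clipRange must be c(lower, upper) with lower <= upper")
        if (length(object@geneLengthRange) != 2L ||
            object@geneLengthRange[1] < 20 ||
            diff(object@geneLengthRange) < 0)
            return("geneLengthRange must be c(lo, hi) with lo >= 20")
        if (!setequal(names(object@accessoryPresenceProb), c("A", "B")))
            return("accessoryPresenceProb must be named c(A=, B=)")
        for (b in object@causalBlocks) {
            if (b$effect < 0) return("causal effects must be >= 0")
            if (!is.na(b$tagKmer) && !identical(b$tagKmer, "AUTO") &&
                !grepl("^[ACGT]{9}$", b$tagKmer))
                return("tagKmer must be a 9-mer over ACGT (or AUTO)")
            if (!setequal(names(b$carrierProb), c("A", "B")))
                return("carrierProb must be named c(A=, B=)")
        }
        TRUE
    })

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "CalibrationModel", function(object) {
    cat("CalibrationModel (degree-4 hue -> pH)\n")
    cat("  coefficients:", signif(object@coefficients, 4), "\n")
    cat(sprintf("  hue range [%.2f, %.2f], pH range [%.2f, %.2f]\n",
                object@hueRange[1], object@hueRange[2],
                object@phRange[1], object@phRange[2]))
    cat(sprintf("  fit RMSE %.4g; monotone over range: %s\n",
                object@rmse, object@monotone))
})

setMethod("show", "PhCurve", function(object) {
    cat(sprintf("PhCurve %s | %s: %d points (%s), t = %.1f..%.1f h\n",
                object@strain, object@condition, length(object@times),
                object@valueKind,
                if (length(object@times)) min(object@times) else NA,
                if (length(object@times)) max(object@times) else NA))
})

setMethod("show", "PhenotypeTable", function(object) {
    m <- object@mat
    cat(sprintf("PhenotypeTable: %d strains x %d conditions, %d missing\n",
                nrow(m), ncol(m), sum(is.na(m))))
    if (sum(!is.na(m)))
        cat(sprintf("  Vmax range [%.3f, %.3f] h^-1\n",
                    min(m, na.rm = TRUE), max(m, na.rm = TRUE)))
})

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf("FeatureMatrix [%s]: %d strains x %d features",
                object@representation, nrow(object@mat), ncol(object@mat)))
    if (length(object@collapseMap))
        cat(sprintf(" (%d collapsed)", length(object@collapseMap)))
    cat("\n")
})

setMethod("show", "AssembledDataset", function(object) {
    cat(sprintf(
        "AssembledDataset [%s]: %d rows (%d strains), %d predictors (%d genomic + 3 condition)\n",
        object@representation, nrow(object@x),
        length(unique(object@strain)), ncol(object@x),
        length(object@genomicFeatures)))
})

setMethod("show", "TrainTestSplit", function(object) {
    cat(sprintf("TrainTestSplit: %d train / %d test strains (fraction %.2f, seed %d)\n",
                length(object@train), length(object@test),
                object@fraction, object@seed))
})

setMethod("show", "ModelBundle", function(object) {
    p <- object@params
    cat(sprintf("ModelBundle [%s]: %d trees, depth %s, minSplit %s, minLeaf %s\n",
                object@representation, p$nTrees,
                ifelse(is.na(p$maxDepth), "unlimited", p$maxDepth),
                p$minSplit, p$minLeaf))
    cat(sprintf("  %d predictors, %d training strains\n",
                length(object@predictors), length(object@trainStrains)))
})

setMethod("show", "PermutationTestResult", function(object) {
    cat(sprintf("PermutationTestResult [%s]: original PC %.3f, null 95%% [%.3f, %.3f] (%d reps)\n",
                object@mode, object@originalPC, object@lower, object@upper,
                length(object@nullPC)))
    cat(sprintf("  outside 95%% interval: %s\n", object@outside95))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d strains (clade A fraction %.2f), %d core + %d accessory genes, %d causal blocks, seed %d\n",
                object@nStrains, object@cladeFraction, object@nCoreGenes,
                object@nAccessoryGenes, length(object@causalBlocks),
                object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d strains, %d gene families, %d causal genes\n",
                length(object@clade), ncol(object@presence),
                nrow(object@causal)))
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Accessors for acidforest objects
#'
#' \code{strainIds} returns strain identifiers; \code{featureIds} the feature
#' column names of a \linkS4class{FeatureMatrix}; \code{vmaxMatrix} the
#' numeric Vmax matrix of a \linkS4class{PhenotypeTable}; \code{featureValues}
#' the numeric matrix of a \linkS4class{FeatureMatrix}; \code{collapseMap}
#' the collapsed-column membership map; \code{subspecies} the per-strain
#' subspecies labels; \code{representation} the representation tag (\code{representationOf}).
#'
#' @param x an acidforest object.
#' @return See the description for each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))
#' @rdname accessors
#' @export
setMethod("strainIds", "FeatureMatrix", function(x) rownames(x@mat))
#' @rdname accessors
#' @export
setMethod("strainIds", "PhenotypeTable", function(x) rownames(x@mat))
#' @rdname accessors
#' @export
setMethod("strainIds", "SyntheticTruth", function(x) names(x@clade))
#' @rdname accessors
#' @export
setMethod("strainIds", "AssembledDataset", function(x) unique(x@strain))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setMethod("featureIds", "FeatureMatrix", function(x) colnames(x@mat))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@mat)

#' @rdname accessors
#' @export
setGeneric("vmaxMatrix", function(x) standardGeneric("vmaxMatrix"))
#' @rdname accessors
#' @export
setMethod("vmaxMatrix", "PhenotypeTable", function(x) x@mat)

#' @rdname accessors
#' @export
setGeneric("collapseMap", function(x) standardGeneric("collapseMap"))
#' @rdname accessors
#' @export
setMethod("collapseMap", "FeatureMatrix", function(x) x@collapseMap)

#' @rdname accessors
#' @export
setGeneric("subspecies", function(x) standardGeneric("subspecies"))
#' @rdname accessors
#' @export
setMethod("subspecies", "FeatureMatrix", function(x) x@subspecies)

#' @rdname accessors
#' @export
setGeneric("representationOf", function(x) standardGeneric("representationOf"))
#' @rdname accessors
#' @export
setMethod("representationOf", "FeatureMatrix", function(x) x@representation)
#' @rdname accessors
#' @export
setMethod("representationOf", "ModelBundle", function(x) x@representation)
#' @rdname accessors
#' @export
setMethod("representationOf", "AssembledDataset", function(x) x@representation)

#' @rdname accessors
#' @export
setGeneric("trainStrains", function(x) standardGeneric("trainStrains"))
#' @rdname accessors
#' @export
setMethod("trainStrains", "TrainTestSplit", function(x) x@train)
#' @rdname accessors
#' @export
setMethod("trainStrains", "ModelBundle", function(x) x@trainStrains)

#' @rdname accessors
#' @export
setGeneric("testStrains", function(x) standardGeneric("testStrains"))
#' @rdname accessors
#' @export
setMethod("testStrains", "TrainTestSplit", function(x) x@test)

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setMethod("modelParams", "ModelBundle", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))
#' @rdname accessors
#' @export
setMethod("nullDistribution", "PermutationTestResult", function(x) x@nullPC)

#' @rdname accessors
#' @export
setGeneric("outside95", function(x) standardGeneric("outside95"))
#' @rdname accessors
#' @export
setMethod("outside95", "PermutationTestResult", function(x) x@outside95)

#' @rdname accessors
#' @export
setGeneric("cladeOf", function(x) standardGeneric("cladeOf"))
#' @rdname accessors
#' @export
setMethod("cladeOf", "SyntheticTruth", function(x) x@clade)

#' @rdname accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))
#' @rdname accessors
#' @export
setMethod("presenceMatrix", "SyntheticTruth", function(x) x@presence)

#' @rdname accessors
#' @export
setGeneric("causalFeatures", function(x) standardGeneric("causalFeatures"))
#' @rdname accessors
#' @export
setMethod("causalFeatures", "SyntheticTruth", function(x) x@causal)
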