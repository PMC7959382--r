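## TreeSHAP feature importance, k-mer/domain -> gene mapping, and the
## cross-representation consensus report.

## flatten a fitted ranger forest into parallel arrays (absolute node ids)
.flattenForest <- function(fit, predictors) {
    nt <- fit$num.trees
    cl <- vector("list", nt); cr <- cl; fv <- cl; th <- cl; va <- cl
    treeStart <- integer(nt); off <- 0L
    for (t in seq_len(nt)) {
        ti <- ranger::treeInfo(fit, t)
        leaf <- ti$terminal
        treeStart[t] <- off
        cl[[t]] <- ifelse(leaf, -1L, ti$leftChild + off)
        cr[[t]] <- ifelse(leaf, -1L, ti$rightChild + off)
        fv[[t]] <- ifelse(leaf, -1L, ti$splitvarID)
        th[[t]] <- ifelse(leaf, 0, ti$splitval)
        va[[t]] <- ifelse(leaf, ti$prediction, 0)
        off <- off + nrow(ti)
    }
    list(treeStart = treeStart,
         childLeft = as.integer(unlist(cl, use.names = FALSE)),
         childRight = as.integer(unlist(cr, use.names = FALSE)),
         feature = as.integer(unlist(fv, use.names = FALSE)),
         threshold = as.numeric(unlist(th, use.names = FALSE)),
         value = as.numeric(unlist(va, use.names = FALSE)),
         predictors = predictors)
}

treeCoversCpp <- function(forest, x)
    .cppTreeCovers(forest$treeStart, forest$childLeft, forest$childRight,
                   forest$feature, forest$threshold, x)

## predictions by walking the flattened trees; used to assert the split
## convention against the fitting library
.forestPredict <- function(bundle, x)
    .cppForestPredict(bundle@forest$treeStart, bundle@forest$childLeft,
                      bundle@forest$childRight, bundle@forest$feature,
                      bundle@forest$threshold, bundle@forest$value, x)

#' TreeSHAP values for a set of rows
#'
#' Exact path-dependent TreeSHAP over the bundle's forest: per row and
#' feature, the Shapley value of the game whose coalition value is the
#' forest's conditional expectation, with off-coalition branches averaged by
#' training-cover weights. Satisfies local accuracy: base value + row sum of
#' SHAP values = model prediction.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param x numeric matrix with the bundle's predictor columns.
#' @return numeric matrix (rows x predictors) with attribute
#'   \code{baseValue}.
#' @export
shapValues <- function(bundle, x) {
    stopifnot(is(bundle, "ModelBundle"))
    if (!identical(colnames(x), bundle@predictors))
        x <- x[, bundle@predictors, drop = FALSE]
    f <- bundle@forest
    phi <- .cppTreeShap(f$treeStart, f$childLeft, f$childRight, f$feature,
                        f$threshold, f$value, f$covers, x)
    colnames(phi) <- bundle@predictors
    phi
}

#' SHAP feature-importance table
#'
#' Computes TreeSHAP values for the given rows (by convention the test set)
#' and ranks features by mean absolute SHAP value. The direction summary
#' reports whether higher feature values push predictions toward faster
#' acidification: because Vmax is negative, a negative SHAP value means
#' "toward faster acidification", so a feature whose value correlates
#' negatively with its SHAP values is labelled \code{"faster"}.
#'
#' @param bundle a \linkS4class{ModelBundle}.
#' @param data an \linkS4class{AssembledDataset} (typically the test rows).
#' @param topN number of top features to return (default 20).
#' @param nRows optionally explain only a random subset of rows of this
#'   size (TreeSHAP cost grows with rows x trees x leaves x depth^2).
#' @param seed seed for the row subsample.
#' @return data.frame with columns \code{feature}, \code{meanAbsShap},
#'   \code{direction} (\code{"faster"}/\code{"slower"}/\code{"n/a"}) and
#'   \code{rank}; the full SHAP matrix, base value, explained row indices
#'   and matching predictions are in attributes \code{shap},
#'   \code{baseValue}, \code{rows}, \code{predictions}.
#' @export
computeImportances <- function(bundle, data, topN = 20, nRows = NULL,
                               seed = 1) {
    stopifnot(is(bundle, "ModelBundle"), is(data, "AssembledDataset"))
    if (!nrow(data@x)) stop("no rows to explain")
    rows <- seq_len(nrow(data@x))
    if (!is.null(nRows) && nRows < length(rows)) {
        set.seed(seed)
        rows <- sort(sample(rows, nRows))
    }
    x <- data@x[rows, bundle@predictors, drop = FALSE]
    phi <- shapValues(bundle, x)
    meanAbs <- colMeans(abs(phi))
    dirCor <- vapply(seq_len(ncol(x)), function(j) {
        if (sd(x[, j]) == 0 || sd(phi[, j]) == 0) return(NA_real_)
        cor(x[, j], phi[, j])
    }, numeric(1))
    direction <- ifelse(is.na(dirCor), "n/a",
                        ifelse(dirCor < 0, "faster", "slower"))
    ord <- order(meanAbs, decreasing = TRUE)
    out <- data.frame(feature = colnames(x)[ord],
                      meanAbsShap = unname(meanAbs[ord]),
                      direction = direction[ord],
                      rank = seq_along(ord),
                      stringsAsFactors = FALSE)[seq_len(min(topN,
                                                            ncol(x))), ]
    rownames(out) <- NULL
    attr(out, "shap") <- phi
    attr(out, "baseValue") <- attr(phi, "baseValue")
    attr(out, "rows") <- rows
    attr(out, "predictions") <- predictVmax(bundle, x)
    out
}

#' Map a k-mer to the genes it occurs in
#'
#' Exact substring search for the k-mer and its reverse complement in every
#' gene sequence of every strain, reporting per gene the number of strains
#' whose copy contains it. Gene annotations in published importance tables
#' are restricted to genes hit in more than 40 strains; the threshold is
#' configurable.
#'
#' @param kmer a k-mer over A/C/G/T.
#' @param geneSeqs named list: strain -> \code{DNAStringSet} of gene
#'   sequences with locus-tag names \code{<strain>_<family>} (as produced
#'   by \code{\link{generatePopulation}}), or any names resolvable by
#'   \code{geneOf}.
#' @param minStrains report only genes hit in strictly more than this many
#'   strains (default 40; use 0 for all hits).
#' @param geneOf function mapping sequence names to gene ids; default
#'   strips the \code{<strain>_} prefix.
#' @return data.frame with columns \code{gene}, \code{nStrains}, ordered by
#'   decreasing strain count.
#' @export
mapKmerToGenes <- function(kmer, geneSeqs, minStrains = 40,
                           geneOf = function(nm) sub("^[^_]*_", "", nm)) {
    if (!grepl("^[ACGT]+$", kmer))
        stop("k-mer must be over the alphabet {A,C,G,T}")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(kmer)))
    counts <- new.env(parent = emptyenv())
    for (s in names(geneSeqs)) {
        seqs <- geneSeqs[[s]]
        if (!is(seqs, "DNAStringSet"))
            seqs <- Biostrings::DNAStringSet(seqs)  # names preserved
        hit <- Biostrings::vcountPattern(kmer, seqs, fixed = TRUE) > 0
        if (rc != kmer)
            hit <- hit | Biostrings::vcountPattern(rc, seqs,
                                                   fixed = TRUE) > 0
        for (g in unique(geneOf(names(seqs)[hit])))
            assign(g, (if (exists(g, counts)) get(g, counts) else 0L) + 1L,
                   counts)
    }
    genes <- ls(counts)
    n <- vapply(genes, get, integer(1), envir = counts)
    keep <- n > minStrains
    out <- data.frame(gene = genes[keep], nStrains = unname(n[keep]),
                      stringsAsFactors = FALSE)
    out[order(-out$nStrains, out$gene), , drop = FALSE]
}

#' Map a Pfam domain accession to the genes carrying it
#'
#' @param accession domain accession as it appears in the hit table
#'   (version retained, e.g. \code{"PF02502.13"}).
#' @param pfamTable a data.frame from \code{\link{readPfamScan}} or a path.
#' @param minOccurrences report only genes accounting for strictly more
#'   than this many hits (default 10; use 0 for all).
#' @param geneOf function mapping sequence ids to gene ids; default strips
#'   the \code{<strain>_} prefix.
#' @return data.frame with columns \code{gene}, \code{occurrences}, ordered
#'   by decreasing occurrence count.
#' @export
mapDomainToGenes <- function(accession, pfamTable, minOccurrences = 10,
                             geneOf = function(nm) sub("^[^_]*_", "", nm)) {
    if (is.character(pfamTable) && length(pfamTable) == 1L)
        pfamTable <- readPfamScan(pfamTable)
    hits <- pfamTable[pfamTable$hmm_acc == accession, , drop = FALSE]
    if (!nrow(hits))
        return(data.frame(gene = character(), occurrences = integer(),
                          stringsAsFactors = FALSE))
    tab <- table(geneOf(hits$seq_id))
    keep <- tab > minOccurrences
    out <- data.frame(gene = names(tab)[keep],
                      occurrences = as.integer(tab[keep]),
                      stringsAsFactors = FALSE)
    out[order(-out$occurrences, out$gene), , drop = FALSE]
}

## resolve one (possibly comma-joined) feature id of a representation to
## gene-level entity labels
.resolveFeature <- function(feature, rep, kmerMaps, domainMaps,
                            collapseMap) {
    condFeatures <- c("Temperature", "Volume", "Yeast")
    if (feature %in% condFeatures) return(feature)
    parts <- if (!is.null(collapseMap[[feature]])) collapseMap[[feature]]
             else strsplit(feature, ",", fixed = TRUE)[[1]]
    out <- unlist(lapply(parts, function(p) {
        if (rep == "gene") return(p)
        if (rep == "pfam") {
            m <- domainMaps[[p]]
            if (!is.null(m) && nrow(m)) return(m$gene)
            return(p)
        }
        m <- kmerMaps[[p]]
        if (!is.null(m) && nrow(m)) return(m$gene)
        p
    }), use.names = FALSE)
    unique(out)
}

#' Cross-representation consensus of important features
#'
#' Expands collapsed feature ids, resolves k-mers and Pfam domains to gene
#' labels via the supplied maps, groups by gene-level entity, and flags as
#' consensus the entities implicated by at least two representations.
#'
#' @param importances named list (representation -> importance table from
#'   \code{\link{computeImportances}}); at least two entries.
#' @param kmerMaps named list (k-mer -> \code{\link{mapKmerToGenes}} result).
#' @param domainMaps named list (accession ->
#'   \code{\link{mapDomainToGenes}} result).
#' @param collapseMaps named list (representation -> collapse map of the
#'   matrix the model was trained on).
#' @return data.frame with columns \code{entity}, \code{nRepresentations},
#'   \code{representations} (comma-joined), \code{features} (the
#'   implicating features, \code{rep:feature}), \code{consensus} (logical),
#'   ordered by decreasing support.
#' @export
buildConsensus <- function(importances, kmerMaps = list(),
                           domainMaps = list(), collapseMaps = list()) {
    stopifnot(length(importances) >= 2, !is.null(names(importances)))
    entity <- list()
    for (rep in names(importances)) {
        tab <- importances[[rep]]
        if (is.null(tab) || !nrow(tab)) next
        cm <- collapseMaps[[rep]]
        for (i in seq_len(nrow(tab))) {
            feats <- .resolveFeature(tab$feature[i], rep, kmerMaps,
                                     domainMaps,
                                     if (is.null(cm)) list() else cm)
            for (e in feats) {
                cur <- entity[[e]]
                if (is.null(cur)) cur <- list(reps = character(),
                                              features = character())
                cur$reps <- union(cur$reps, rep)
                cur$features <- union(cur$features,
                                      paste(rep, tab$feature[i],
                                            sep = ":"))
                entity[[e]] <- cur
            }
        }
    }
    if (!length(entity))
        return(data.frame(entity = character(),
                          nRepresentations = integer(),
                          representations = character(),
                          features = character(), consensus = logical(),
                          stringsAsFactors = FALSE))
    out <- data.frame(
        entity = names(entity),
        nRepresentations = vapply(entity, function(e) length(e$reps),
                                  integer(1)),
        representations = vapply(entity, function(e)
            paste(sort(e$reps), collapse = ","), character(1)),
        features = vapply(entity, function(e)
            paste(e$features, collapse = "; "), character(1)),
        stringsAsFactors = FALSE)
    out$consensus <- out$nRepresentations >= 2L
    out <- out[order(-out$nRepresentations, out$entity), , drop = FALSE]
    rownames(out) <- NULL
    out
}
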