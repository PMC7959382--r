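## Top-level pipeline: featurize -> assemble -> split -> train -> evaluate
## -> signal tests -> importance -> consensus, with full seed provenance.

## build the four (unprocessed) feature matrices of a simulated population
.simulatedMatrices <- function(genomes, truth, representations) {
    strains <- strainIds(truth)
    sub <- setNames(ifelse(truth@clade == "A", "lactis", "cremoris"),
                    strains)
    out <- list()
    if ("gene" %in% representations)
        out$gene <- featureMatrix(truth@presence + 0, "gene",
                                  subspecies = sub)
    if ("pfam" %in% representations) {
        doms <- .domainAssignment(colnames(truth@presence), truth@causal)
        pres <- truth@presence
        tab <- do.call(rbind, lapply(strains, function(s) {
            fams <- colnames(pres)[pres[s, ] == 1L]
            do.call(rbind, lapply(fams, function(g)
                data.frame(seq_id = paste(s, g, sep = "_"),
                           hmm_acc = doms[[g]]$hmm_acc,
                           hmm_name = doms[[g]]$hmm_name,
                           stringsAsFactors = FALSE)))
        }))
        g2s <- geneToStrainFromLocus(tab$seq_id)
        ## include empty strains so every strain has a row
        g2s <- c(g2s, setNames(strains, paste0(strains, "_core0000")))
        out$pfam <- buildDomainMatrix(tab, g2s, subspecies = sub)
        attr(out$pfam, "pfamTable") <- tab
    }
    if ("kmer8" %in% representations)
        out$kmer8 <- buildKmerMatrix(genomes, 8L, subspecies = sub)
    if ("kmer9" %in% representations)
        out$kmer9 <- buildKmerMatrix(genomes, 9L, subspecies = sub)
    out
}

#' Run the full genotype-to-phenotype pipeline
#'
#' Either simulates a population from \code{config} or reads feature and
#' phenotype matrices from \code{inputDir} (semicolon dialect, file names
#' \code{gene_matrix.txt}, \code{pfam_matrix.txt}, \code{kmer8_matrix.txt},
#' \code{kmer9_matrix.txt}, \code{phenotype_matrix.txt}); then for each
#' representation prunes (0.98) and collapses features, assembles the
#' dataset, splits strains 75/25, trains a forest (preset hyperparameters
#' or randomized search), evaluates on the held-out strains, optionally
#' runs both permutation signal tests, computes SHAP importances, and
#' builds the cross-representation consensus.
#'
#' @param config a \linkS4class{SimConfig} (used when \code{inputDir} is
#'   NULL).
#' @param inputDir optional directory of input matrices.
#' @param representations which representations to run.
#' @param search run the randomized grid search (default: use presets).
#' @param nDraws randomized-search draws when \code{search = TRUE}.
#' @param splitSeed,forestSeed,searchSeed,permSeed seeds for the split, the
#'   forest, the search and the permutation tests.
#' @param signalTests representations to run the permutation tests for
#'   (published protocol: gene and Pfam; k-mer models are heavy).
#' @param permReps permutation replicates (published protocol: 1000).
#' @param importanceRows rows of the test set to explain with TreeSHAP
#'   (NULL = all; the default keeps large forests tractable).
#' @param topN top features per importance table.
#' @return A report list: \code{scores}, \code{models}, \code{importances},
#'   \code{signal}, \code{consensus}, \code{split}, \code{provenance}.
#' @export
runPipeline <- function(config = simConfig(), inputDir = NULL,
                        representations = c("gene", "pfam", "kmer8",
                                            "kmer9"),
                        search = FALSE, nDraws = 30, splitSeed = 1,
                        forestSeed = 1, searchSeed = 1, permSeed = 1,
                        signalTests = c("gene", "pfam"), permReps = 1000,
                        importanceRows = 150, topN = 20) {
    representations <- match.arg(representations, several.ok = TRUE)
    genomes <- NULL; truth <- NULL; pfamTable <- NULL
    if (is.null(inputDir)) {
        pop <- generatePopulation(config)
        genomes <- pop$genomes; truth <- pop$truth
        phen <- generatePhenotypes(truth, config)
        mats <- .simulatedMatrices(genomes, truth, representations)
        pfamTable <- attr(mats$pfam, "pfamTable")
    } else {
        read1 <- function(name, rep) {
            p <- file.path(inputDir, name)
            if (!file.exists(p))
                stop("featurize stage: missing input file ", p)
            readMatrixFile(p, rep)
        }
        mats <- setNames(lapply(representations, function(rep)
            read1(sprintf("%s_matrix.txt", rep), rep)), representations)
        pp <- file.path(inputDir, "phenotype_matrix.txt")
        if (!file.exists(pp))
            stop("phenotype stage: missing input file ", pp)
        phen <- readPhenotypeFile(pp)
        ## tolerate strain subsets: inner join on strain id
        common <- intersect(rownames(vmaxMatrix(phen)),
                            rownames(featureValues(mats[[1]])))
        phen <- phenotypeTable(vmaxMatrix(phen)[common, , drop = FALSE])
    }

    phStrains <- strainIds(phen)
    split <- splitByStrain(phStrains, 0.75, seed = splitSeed)
    report <- list(split = split, scores = list(), models = list(),
                   importances = list(), signal = list())

    for (rep in representations) {
        fm <- collapseIdentical(pruneFeatures(mats[[rep]], 0.98))
        ds <- assembleDataset(fm, phen)
        tr <- subsetStrains(ds, trainStrains(split))
        te <- subsetStrains(ds, testStrains(split))
        params <- if (search)
            tuneHyperparameters(tr, hyperparameterGrid(nDraws, searchSeed))
        else presetParams(rep)
        bundle <- trainModel(tr, params, seed = forestSeed)
        report$models[[rep]] <- bundle
        report$scores[[rep]] <- evaluateModel(bundle, te)[
            c("pearson", "explainedVariance", "rmse")]
        report$importances[[rep]] <-
            computeImportances(bundle, te, topN = topN,
                               nRows = importanceRows, seed = permSeed)
        report$collapseMaps[[rep]] <- collapseMap(fm)
        if (rep %in% signalTests) {
            report$signal[[rep]] <- list(
                feature_permute = featurePermutationTest(
                    bundle, te, nReps = permReps, seed = permSeed),
                profile_switch = profileSwitchTest(
                    bundle, te, nReps = permReps, seed = permSeed))
        }
    }

    ## consensus across representations, resolving k-mers/domains to genes
    kmerMaps <- list(); domainMaps <- list()
    if (!is.null(genomes)) {
        for (rep in intersect(c("kmer8", "kmer9"), representations)) {
            feats <- report$importances[[rep]]$feature
            km <- unique(unlist(lapply(feats, function(f)
                strsplit(f, ",", fixed = TRUE)[[1]])))
            km <- km[grepl("^[ACGT]+$", km)]
            for (k in km)
                kmerMaps[[k]] <- mapKmerToGenes(
                    k, genomes, minStrains = max(1, length(phStrains) %/% 5))
        }
    }
    if (!is.null(pfamTable) && "pfam" %in% representations) {
        feats <- report$importances[["pfam"]]$feature
        accs <- unique(unlist(strsplit(feats, ",", fixed = TRUE)))
        accs <- accs[grepl("^PF", accs)]
        for (a in accs)
            domainMaps[[a]] <- mapDomainToGenes(a, pfamTable,
                                                minOccurrences = 10)
    }
    if (length(report$importances) >= 2)
        report$consensus <- buildConsensus(report$importances, kmerMaps,
                                           domainMaps, report$collapseMaps)

    report$provenance <- list(
        seeds = c(split = splitSeed, forest = forestSeed,
                  search = searchSeed, perm = permSeed,
                  sim = if (is.null(inputDir)) config@seed else NA),
        search = search, permReps = permReps,
        importanceRows = importanceRows,
        representations = representations,
        packageVersion = as.character(utils::packageVersion("acidforest")),
        rangerVersion = as.character(utils::packageVersion("ranger")))
    report
}

#' Re-run the published protocol on the deposited input matrices
#'
#' Given a directory holding the deposited model inputs — the four
#' semicolon-separated feature matrices (gene, Pfam, 8-mer, 9-mer; 343
#' lines each) and the phenotype matrix — re-runs the published protocol:
#' 75/25 strain split, the printed per-representation hyperparameters,
#' evaluation on the held-out strains, and the SHAP rank of the yeast
#' feature. The split seed is not part of the publication, so scores vary
#' with it by a few hundredths.
#'
#' @param dir directory containing the files.
#' @param files named character vector mapping representations (and
#'   \code{phenotypes}) to file names within \code{dir}.
#' @param splitSeed strain-split seed.
#' @param importanceRows test rows to explain for the yeast-rank check.
#' @return list per representation: \code{pearson},
#'   \code{explainedVariance}, \code{rmse}, \code{yeastRank}.
#' @export
reproducePublishedModels <- function(dir,
        files = c(gene = "gene_matrix.txt", pfam = "pfam_matrix.txt",
                  kmer8 = "kmer8_matrix.txt", kmer9 = "kmer9_matrix.txt",
                  phenotypes = "phenotype_matrix.txt"),
        splitSeed = 1, importanceRows = 150) {
    reps <- setdiff(names(files), "phenotypes")
    missing <- files[!file.exists(file.path(dir, files))]
    if (length(missing))
        stop("deposited input files not found under ", dir, ": ",
             paste(missing, collapse = ", "),
             " (these supplementary matrices must be downloaded separately)")
    phen <- readPhenotypeFile(file.path(dir, files[["phenotypes"]]))
    out <- list()
    for (rep in reps) {
        fm <- readMatrixFile(file.path(dir, files[[rep]]), rep)
        common <- intersect(strainIds(phen), strainIds(fm))
        ph <- phenotypeTable(vmaxMatrix(phen)[common, , drop = FALSE])
        ds <- assembleDataset(fm, ph)
        split <- splitByStrain(common, 0.75, seed = splitSeed)
        bundle <- trainModel(subsetStrains(ds, trainStrains(split)),
                             presetParams(rep), seed = 1)
        te <- subsetStrains(ds, testStrains(split))
        ev <- evaluateModel(bundle, te)
        imp <- computeImportances(bundle, te, topN = 20,
                                  nRows = importanceRows)
        out[[rep]] <- list(pearson = ev$pearson,
                           explainedVariance = ev$explainedVariance,
                           rmse = ev$rmse,
                           yeastRank = match("Yeast", imp$feature))
    }
    out
}
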