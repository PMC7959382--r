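## Synthetic strain populations: clade-structured gene content with planted
## causal blocks, condition-dependent Vmax phenotypes, kinetic curves, and
## all standard input file formats. The generator emulates a two-subspecies
## dairy Lactococcus collection assayed under 12 conditions.

.NUC <- c("A", "C", "G", "T")

#' Define a planted causal block
#'
#' A causal block is a set of gene families that always co-occur (an
#' operon-like unit). Carrying the block adds \code{effect} h^-1 to a
#' strain's acidification speed. Optionally a 9-mer tag is planted once in
#' each of the block's gene sequences and nowhere else in the population,
#' so that k-mer representations can recover the block.
#'
#' @param genes character, gene family ids of the block.
#' @param carrierProb named numeric \code{c(A=, B=)}: per-clade probability
#'   that a strain carries the block.
#' @param effect non-negative Vmax magnitude (h^-1) added when present.
#' @param tagKmer \code{TRUE} to auto-pick a unique 9-mer, \code{NA} for no
#'   tag, or an explicit 9-mer string.
#' @return list usable in \code{simConfig(causalBlocks = ...)}.
#' @export
causalBlock <- function(genes, carrierProb, effect, tagKmer = TRUE) {
    list(genes = as.character(genes),
         carrierProb = carrierProb[c("A", "B")],
         effect = effect,
         tagKmer = if (isTRUE(tagKmer)) "AUTO"
                   else if (identical(tagKmer, FALSE)) NA_character_
                   else as.character(tagKmer))
}

.defaultCausalBlocks <- function() list(
    causalBlock(c("cauA_1", "cauA_2", "cauA_3"),
                carrierProb = c(A = 0.70, B = 0.35), effect = 0.15),
    causalBlock(c("cauB_1", "cauB_2"),
                carrierProb = c(A = 0.30, B = 0.60), effect = 0.15))

.defaultConditionEffects <- function() list(
    ## speed shift (h^-1) per temperature, per clade; 30 C optimal for both
    tempEffect = list(A = c("25" = -0.06, "30" = 0, "40" = -0.20),
                      B = c("25" = -0.06, "30" = 0, "40" = -0.30)),
    ## at 40 C, yeast extract rescues clade A (subsp. lactis-like) only
    temp40YeastRescue = c(A = 0.16, B = 0.02),
    yeastEffect = 0.10,
    volumeEffect = 0.05)

#' Configuration of the synthetic population generator
#'
#' Defaults emulate the study design: a two-subspecies collection (clade A ~
#' subsp. lactis, clade B ~ subsp. cremoris) assayed under 12 conditions,
#' two planted operon-like causal blocks of effect 0.15 h^-1, measurement
#' noise SD 0.03 h^-1, ~19\% missing strain x condition measurements, and
#' speeds clipped to the observed phenotype range so emitted Vmax lies in
#' [-0.96, -0.05] h^-1. Gene count and length are scaled down from real
#' genomes to keep simulated populations light; see the package vignette.
#'
#' @param nStrains number of strains (>= 2).
#' @param cladeFraction fraction of strains in clade A.
#' @param nCoreGenes gene families present in every strain.
#' @param nAccessoryGenes clade-structured accessory families.
#' @param accessoryPresenceProb named \code{c(A=, B=)} per-clade presence
#'   probability of each accessory family.
#' @param causalBlocks list of \code{\link{causalBlock}} definitions.
#' @param conditionEffects list with \code{tempEffect} (per-clade named
#'   vectors over "25"/"30"/"40"), \code{temp40YeastRescue} (per-clade bonus
#'   applied at 40 C with yeast extract), \code{yeastEffect} and
#'   \code{volumeEffect} (deepwell minus lowwell), all in h^-1.
#' @param baseSpeed baseline acidification speed b0 (h^-1).
#' @param clipRange \code{c(lower, upper)}: speed clipped to this range
#'   before negation.
#' @param noiseSd measurement noise SD (h^-1).
#' @param missingRate probability a strain x condition measurement is absent
#'   (missing completely at random).
#' @param geneLengthRange \code{c(lo, hi)} gene length in bp (lo >= 20).
#' @param mutationRate per-base substitution probability per strain copy.
#' @param seed master seed; fully determines all generator outputs.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nStrains = 10, seed = 7)
#' @export
simConfig <- function(nStrains = 200,
                      cladeFraction = 0.67,
                      nCoreGenes = 150,
                      nAccessoryGenes = 100,
                      accessoryPresenceProb = c(A = 0.65, B = 0.25),
                      causalBlocks = .defaultCausalBlocks(),
                      conditionEffects = .defaultConditionEffects(),
                      baseSpeed = 0.35,
                      clipRange = c(0.05, 0.96),
                      noiseSd = 0.03,
                      missingRate = 0.19,
                      geneLengthRange = c(240, 600),
                      mutationRate = 0.005,
                      seed = 1) {
    new("SimConfig", nStrains = nStrains, cladeFraction = cladeFraction,
        nCoreGenes = nCoreGenes, nAccessoryGenes = nAccessoryGenes,
        accessoryPresenceProb = accessoryPresenceProb[c("A", "B")],
        causalBlocks = causalBlocks, conditionEffects = conditionEffects,
        baseSpeed = baseSpeed, clipRange = clipRange, noiseSd = noiseSd,
        missingRate = missingRate, geneLengthRange = geneLengthRange,
        mutationRate = mutationRate, seed = seed)
}

.randSeq <- function(len) paste(sample(.NUC, len, replace = TRUE),
                                collapse = "")

.revcompChar <- function(x) chartr("ACGT", "TGCA",
                                   vapply(strsplit(x, NULL),
                                          function(s) paste(rev(s),
                                                            collapse = ""),
                                          character(1)))

.containsKmer <- function(seqs, kmer) {
    rc <- .revcompChar(kmer)
    any(grepl(kmer, seqs, fixed = TRUE) | grepl(rc, seqs, fixed = TRUE))
}

## deterministic speed surface: strains x 12 conditions, positive scale
.speedSurface <- function(clade, presence, causal, noise, config) {
    cg <- conditionGrid()
    ce <- config@conditionEffects
    n <- length(clade)
    speed <- matrix(config@baseSpeed, n, 12L,
                    dimnames = list(names(clade), cg$condition))
    ## planted causal effects (block presence is shared by its genes)
    if (nrow(causal)) {
        for (b in unique(causal$block)) {
            rows <- causal[causal$block == b, ]
            carrier <- presence[, rows$gene[1]]
            speed <- speed + outer(carrier * rows$effect[1], rep(1, 12L))
        }
    }
    for (j in seq_len(12L)) {
        tE <- vapply(clade, function(cl)
            ce$tempEffect[[cl]][[as.character(cg$temperature[j])]],
            numeric(1))
        speed[, j] <- speed[, j] + tE
        if (cg$yeast[j] == "YE") {
            speed[, j] <- speed[, j] + ce$yeastEffect
            if (cg$temperature[j] == 40)
                speed[, j] <- speed[, j] +
                    unname(ce$temp40YeastRescue[clade])
        }
        if (cg$volume[j] == "DW")
            speed[, j] <- speed[, j] + ce$volumeEffect
    }
    speed <- speed + noise
    pmin(pmax(speed, config@clipRange[1]), config@clipRange[2])
}

#' Generate a clade-structured synthetic strain population
#'
#' Draws clade assignments, gene content (core families in every strain,
#' accessory families by per-clade probability, causal blocks by per-clade
#' carrier probability), per-strain gene sequences (shared reference per
#' family with per-strain substitutions; planted 9-mer tags kept
#' mutation-free and guaranteed unique to their block), measurement noise,
#' the target Vmax surface, and the missing-data mask. All outputs are
#' fully determined by the config (including its seed).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{genomes} (named list: strain ->
#'   \code{DNAStringSet} of gene contigs, names = locus tags
#'   \code{<strain>_<family>}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @export
generatePopulation <- function(config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    n <- config@nStrains
    strains <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))
    clade <- setNames(rep("B", n), strains)
    clade[seq_len(round(config@cladeFraction * n))] <- "A"

    coreIds <- sprintf("core%04d", seq_len(config@nCoreGenes))
    accIds <- sprintf("acc%04d", seq_len(config@nAccessoryGenes))
    causalGenes <- unlist(lapply(config@causalBlocks, `[[`, "genes"))
    if (anyDuplicated(causalGenes))
        stop("causal gene ids duplicated across blocks")
    if (length(intersect(causalGenes, c(coreIds, accIds))))
        stop("causal gene ids collide with core/accessory ids")
    famIds <- c(coreIds, accIds, causalGenes)

    ## reference sequence per family
    lens <- sample(seq(config@geneLengthRange[1], config@geneLengthRange[2]),
                   length(famIds), replace = TRUE)
    names(lens) <- famIds
    refs <- setNames(vapply(lens, .randSeq, character(1)), famIds)

    ## plant tag 9-mers: unique to the block, absent from all other refs
    tagOf <- setNames(rep(NA_character_, length(famIds)), famIds)
    tagPos <- setNames(rep(NA_integer_, length(famIds)), famIds)
    usedTags <- character()
    for (bi in seq_along(config@causalBlocks)) {
        b <- config@causalBlocks[[bi]]
        if (is.na(b$tagKmer)) next
        tag <- b$tagKmer
        if (identical(tag, "AUTO")) {
            repeat {
                tag <- paste(sample(.NUC, 9L, replace = TRUE), collapse = "")
                if (!.containsKmer(unname(refs), tag) &&
                    !tag %in% usedTags) break
            }
        } else if (.containsKmer(unname(refs[setdiff(famIds, b$genes)]), tag))
            stop("supplied tagKmer occurs in non-causal gene sequences")
        usedTags <- c(usedTags, tag)
        for (g in b$genes) {
            pos <- max(1L, lens[[g]] %/% 2L)
            substr(refs[[g]], pos, pos + 8L) <- tag
            tagOf[[g]] <- tag
            tagPos[[g]] <- pos
        }
        config@causalBlocks[[bi]]$tagKmer <- tag
    }

    ## presence matrix
    presence <- matrix(0L, n, length(famIds),
                       dimnames = list(strains, famIds))
    presence[, coreIds] <- 1L
    pAcc <- config@accessoryPresenceProb[clade]
    for (g in accIds)
        presence[, g] <- rbinom(n, 1L, pAcc)
    for (b in config@causalBlocks) {
        carrier <- rbinom(n, 1L, b$carrierProb[clade])
        presence[, b$genes] <- carrier
    }

    ## per-strain mutated gene copies; tag regions are mutation-free and
    ## mutations may not create a planted tag elsewhere
    refChars <- lapply(refs, function(s) strsplit(s, NULL)[[1]])
    genomes <- vector("list", n)
    names(genomes) <- strains
    for (i in seq_len(n)) {
        fams <- famIds[presence[i, ] == 1L]
        seqs <- vapply(fams, function(g) {
            ref <- refChars[[g]]
            protect <- if (!is.na(tagPos[[g]]))
                seq(tagPos[[g]], tagPos[[g]] + 8L) else integer()
            repeat {
                s <- ref
                mut <- which(runif(length(s)) < config@mutationRate)
                mut <- setdiff(mut, protect)
                if (length(mut))
                    s[mut] <- vapply(s[mut], function(b0)
                        sample(setdiff(.NUC, b0), 1L), character(1))
                out <- paste(s, collapse = "")
                ## reject mutants that spawn a foreign tag k-mer
                bad <- FALSE
                for (tg in usedTags)
                    if (!identical(tg, tagOf[[g]]) &&
                        .containsKmer(out, tg)) { bad <- TRUE; break }
                if (!bad) return(out)
            }
        }, character(1))
        names(seqs) <- paste(strains[i], fams, sep = "_")
        genomes[[i]] <- Biostrings::DNAStringSet(seqs)
    }

    noise <- matrix(rnorm(n * 12L, 0, config@noiseSd), n, 12L,
                    dimnames = list(strains, conditionIds()))
    causal <- do.call(rbind, lapply(seq_along(config@causalBlocks),
        function(bi) {
            b <- config@causalBlocks[[bi]]
            data.frame(block = bi, gene = b$genes, effect = b$effect,
                       tagKmer = b$tagKmer, stringsAsFactors = FALSE)
        }))
    if (is.null(causal))
        causal <- data.frame(block = integer(), gene = character(),
                             effect = numeric(), tagKmer = character(),
                             stringsAsFactors = FALSE)

    target <- -.speedSurface(clade, presence, causal, noise, config)
    mask <- matrix(runif(n * 12L) < config@missingRate, n, 12L)
    target[mask] <- NA_real_

    truth <- new("SyntheticTruth", clade = clade, presence = presence,
                 causal = causal, noise = noise, targetVmax = target)
    list(genomes = genomes, truth = truth)
}

#' Generate the phenotype table of a synthetic population
#'
#' Deterministically recomputes the Vmax surface from the truth object:
#' Vmax(strain, condition) = -clip(b0 + sum(block effects x presence) +
#' temperature effect + yeast effect + volume effect + noise, lower, upper),
#' with entries masked missing as drawn during population generation. All
#' non-missing values are negative.
#'
#' @param truth a \linkS4class{SyntheticTruth} from
#'   \code{\link{generatePopulation}}.
#' @param config the same \linkS4class{SimConfig}.
#' @return A \linkS4class{PhenotypeTable}.
#' @export
generatePhenotypes <- function(truth, config) {
    stopifnot(is(truth, "SyntheticTruth"), is(config, "SimConfig"))
    causal <- truth@causal
    ## block effects/tags may have been resolved during generation
    v <- -.speedSurface(truth@clade, truth@presence, causal, truth@noise,
                        config)
    v[is.na(truth@targetVmax)] <- NA_real_
    phenotypeTable(v)
}

#' The built-in monotone hue-to-pH calibration used for simulation
#'
#' A fixed, strictly monotone polynomial mapping hue in [20, 120] to pH in
#' about [4.0, 6.6], standing in for a real dye calibration when simulating
#' scanner hue curves.
#'
#' @return A \linkS4class{CalibrationModel} with zero residual RMSE.
#' @export
defaultCalibration <- function() {
    ## pH = 4 + 2.6*(0.2 s + 0.8 s^2), s = (hue - 20)/100, expanded in hue
    s0 <- -20 / 100
    c0 <- 4 + 2.6 * (0.2 * s0 + 0.8 * s0^2)
    c1 <- 2.6 * (0.2 / 100 + 1.6 * s0 / 100)
    c2 <- 2.6 * 0.8 / 100^2
    new("CalibrationModel", coefficients = c(c0, c1, c2, 0, 0),
        hueRange = c(20, 120), phRange = c(4, 6.6), rmse = 0,
        monotone = TRUE)
}

#' Simulate hue/pH calibration pairs
#'
#' Samples hue values across the calibration range and reports their pH
#' (from \code{calib}) with optional measurement noise — the input expected
#' by \code{\link{fitHueCalibration}}.
#'
#' @param n number of pairs.
#' @param noiseSd pH measurement noise SD.
#' @param seed RNG seed.
#' @param calib source \linkS4class{CalibrationModel}.
#' @return data.frame with columns \code{hue}, \code{ph}.
#' @export
simulateCalibrationPairs <- function(n = 25, noiseSd = 0.01, seed = 1,
                                     calib = defaultCalibration()) {
    set.seed(seed)
    hue <- seq(calib@hueRange[1], calib@hueRange[2], length.out = n)
    data.frame(hue = hue,
               ph = .polyEval(calib@coefficients, hue) + rnorm(n, 0, noiseSd))
}

## vectorized monotone inverse of a calibration (pH -> hue) via a fine grid
.inverseHueFun <- function(calib) {
    grid <- seq(calib@hueRange[1], calib@hueRange[2], length.out = 8192L)
    phg <- .polyEval(calib@coefficients, grid)
    if (phg[1] > phg[length(phg)]) { grid <- rev(grid); phg <- rev(phg) }
    function(ph) approx(phg, grid, xout = ph, rule = 2)$y
}

#' Synthesize kinetic curves matching target Vmax values
#'
#' For every non-missing strain x condition entry, emits a sigmoidal pH
#' decline \code{pH(t) = pEnd + (p0 - pEnd) / (1 + exp(r (t - tMid)))} with
#' the steepness r solved (by root finding) so that the maximum-negative
#' sliding-window slope equals the target Vmax; a zero target yields a flat
#' curve at \code{p0}. When a calibration is supplied, matching hue curves
#' are produced by inverting it.
#'
#' @param phenotypes a \linkS4class{PhenotypeTable} of target Vmax values.
#' @param calib optional \linkS4class{CalibrationModel} for hue variants.
#' @param durationH assay duration in hours (sampling every 0.1 h).
#' @param p0,pEnd initial and final pH of the sigmoid.
#' @param windowPoints window used when matching the target (default 10).
#' @return list with \code{ph} (list of pH \linkS4class{PhCurve}s) and, when
#'   \code{calib} is given, \code{hue} (matching hue curves).
#' @export
generatePhCurves <- function(phenotypes, calib = NULL, durationH = 12,
                             p0 = 6.5, pEnd = 4.3, windowPoints = 10L) {
    stopifnot(is(phenotypes, "PhenotypeTable"))
    pm <- phenotypes@mat
    times <- seq(0, durationH, by = 0.1)
    tMid <- durationH / 2
    slopeOf <- function(r) {
        ph <- pEnd + (p0 - pEnd) / (1 + exp(r * (times - tMid)))
        min(windowSlopes(times, ph, windowPoints))
    }
    rMax <- 200
    maxReach <- slopeOf(rMax)
    invHue <- if (!is.null(calib)) .inverseHueFun(calib)
    phCurves <- list(); hueCurves <- list()
    obs <- which(!is.na(pm), arr.ind = TRUE)
    for (idx in seq_len(nrow(obs))) {
        target <- pm[obs[idx, 1], obs[idx, 2]]
        if (!is.finite(target) || target > 0)
            stop("target Vmax must be finite and <= 0")
        if (target == 0) {
            ph <- rep(p0, length(times))
        } else {
            if (target < maxReach)
                stop(sprintf(
                    "target Vmax %.3f more negative than achievable (%.3f) given p0 - pEnd and duration",
                    target, maxReach))
            r <- uniroot(function(r) slopeOf(r) - target,
                         lower = 1e-4, upper = rMax, tol = 1e-9)$root
            ph <- pEnd + (p0 - pEnd) / (1 + exp(r * (times - tMid)))
        }
        strain <- rownames(pm)[obs[idx, 1]]
        cond <- colnames(pm)[obs[idx, 2]]
        key <- paste(strain, cond, sep = ".")
        phCurves[[key]] <- phCurve(strain, cond, times, ph, "pH")
        if (!is.null(calib))
            hueCurves[[key]] <- phCurve(strain, cond, times, invHue(ph),
                                        "hue")
    }
    out <- list(ph = phCurves)
    if (!is.null(calib)) out$hue <- hueCurves
    out
}

#' Strain of a locus tag
#'
#' Synthetic locus tags have the form \code{<strain>_<family>} with
#' underscore-free strain ids; this helper recovers the strain.
#'
#' @param loci character vector of locus tags.
#' @return character vector of strain ids, named by locus tag.
#' @export
geneToStrainFromLocus <- function(loci)
    setNames(sub("_.*$", "", loci), loci)

## deterministic synthetic Pfam accessions: one per family, plus one shared
## accession per causal block (always co-occurring, operon-like)
.domainAssignment <- function(famIds, causal) {
    doms <- lapply(seq_along(famIds), function(i)
        c(acc = sprintf("PF9%04d.1", i), name = sprintf("SynDom_%04d", i)))
    names(doms) <- famIds
    out <- lapply(doms, function(d)
        data.frame(hmm_acc = d[["acc"]], hmm_name = d[["name"]],
                   stringsAsFactors = FALSE))
    if (nrow(causal)) {
        for (b in unique(causal$block)) {
            genes <- causal$gene[causal$block == b]
            for (g in genes)
                out[[g]] <- rbind(out[[g]], data.frame(
                    hmm_acc = sprintf("PF8%03d.1", b),
                    hmm_name = sprintf("SynBlock_%03d", b),
                    stringsAsFactors = FALSE))
        }
    }
    out
}

#' Write the synthetic population as standard input files
#'
#' Writes, under \code{outdir}: per-strain multi-contig FASTA files
#' (\code{genomes/<strain>.fasta}), a Roary-style
#' \code{gene_presence_absence.csv} (gene group, annotation, one locus-tag
#' column per strain), a pfam_scan-style hit table \code{pfam_hits.txt}
#' (each gene family carries one synthetic accession, plus a shared
#' accession per causal block), the four processed feature matrices
#' (pruned at 0.98 and collapsed) and the phenotype matrix in the semicolon
#' dialect. All file contents are fully determined by the inputs.
#'
#' @param genomes,truth from \code{\link{generatePopulation}}.
#' @param phenotypes a \linkS4class{PhenotypeTable}.
#' @param outdir output directory (created if needed).
#' @param writeKmerMatrices write the 8-/9-mer matrices (the slowest part);
#'   default TRUE.
#' @return named character vector of the written paths.
#' @export
emitInputFiles <- function(genomes, truth, phenotypes, outdir,
                           writeKmerMatrices = TRUE) {
    stopifnot(is(truth, "SyntheticTruth"), is(phenotypes, "PhenotypeTable"))
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outdir)
    strains <- strainIds(truth)
    stopifnot(identical(sort(names(genomes)), sort(strains)))
    sub <- setNames(ifelse(truth@clade == "A", "lactis", "cremoris"),
                    strains)
    paths <- c()

    gdir <- file.path(outdir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    for (s in strains) {
        p <- file.path(gdir, paste0(s, ".fasta"))
        Biostrings::writeXStringSet(genomes[[s]], p)
        paths[paste0("fasta_", s)] <- p
    }

    ## Roary-style table
    pres <- truth@presence
    roary <- data.frame(Gene = colnames(pres),
                        Annotation = "hypothetical protein",
                        check.names = FALSE, stringsAsFactors = FALSE)
    for (s in strains)
        roary[[s]] <- ifelse(pres[s, ] == 1L,
                             paste(s, colnames(pres), sep = "_"), "")
    p <- file.path(outdir, "gene_presence_absence.csv")
    write.table(roary, p, sep = ",", qmethod = "double", row.names = FALSE,
                quote = TRUE)
    paths["roary"] <- p

    ## pfam_scan-style hits: one line per (gene copy, assigned domain)
    doms <- .domainAssignment(colnames(pres), truth@causal)
    hitLines <- unlist(lapply(strains, function(s) {
        fams <- colnames(pres)[pres[s, ] == 1L]
        unlist(lapply(fams, function(g) {
            d <- doms[[g]]
            sprintf("%s 1 50 %s %s", paste(s, g, sep = "_"),
                    d$hmm_acc, d$hmm_name)
        }), use.names = FALSE)
    }), use.names = FALSE)
    p <- file.path(outdir, "pfam_hits.txt")
    writeLines(c("# <seq id> <aln start> <aln end> <hmm acc> <hmm name>",
                 hitLines), p)
    paths["pfam"] <- p

    ## processed feature matrices + phenotypes (semicolon dialect)
    process <- function(fm) collapseIdentical(pruneFeatures(fm, 0.98))
    gm <- process(featureMatrix(pres + 0, "gene", subspecies = sub))
    p <- file.path(outdir, "gene_matrix.txt")
    writeMatrixFile(gm, p); paths["gene_matrix"] <- p
    pf <- process(buildDomainMatrix(
        readPfamScan(file.path(outdir, "pfam_hits.txt")),
        geneToStrainFromLocus(
            unlist(lapply(strains, function(s)
                paste(s, colnames(pres)[pres[s, ] == 1L], sep = "_")))),
        subspecies = sub))
    p <- file.path(outdir, "pfam_matrix.txt")
    writeMatrixFile(pf, p); paths["pfam_matrix"] <- p
    if (writeKmerMatrices) {
        for (k in c(8L, 9L)) {
            km <- process(buildKmerMatrix(genomes, k, subspecies = sub))
            p <- file.path(outdir, sprintf("kmer%d_matrix.txt", k))
            writeMatrixFile(km, p)
            paths[sprintf("kmer%d_matrix", k)] <- p
        }
    }
    p <- file.path(outdir, "phenotype_matrix.txt")
    writePhenotypeFile(phenotypes, p); paths["phenotypes"] <- p
    paths
}
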