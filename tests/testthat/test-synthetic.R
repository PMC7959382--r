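## The synthetic population generator: determinism, planted signal,
## phenotype surface, curve synthesis, emitted file formats.

test_that("the same config reproduces every output bit for bit", {
    cfg <- smallConfig(seed = 42)
    a <- generatePopulation(cfg)
    b <- generatePopulation(cfg)
    expect_identical(lapply(a$genomes, as.character),
                     lapply(b$genomes, as.character))
    expect_identical(presenceMatrix(a$truth), presenceMatrix(b$truth))
    expect_identical(a$truth@noise, b$truth@noise)
    expect_identical(vmaxMatrix(generatePhenotypes(a$truth, cfg)),
                     vmaxMatrix(generatePhenotypes(b$truth, cfg)))
    ## a different seed changes the sequences
    c2 <- generatePopulation(smallConfig(seed = 43))
    expect_false(identical(lapply(a$genomes, as.character),
                           lapply(c2$genomes, as.character)))
})

test_that("carrier probability 1 plants the tag k-mer in every strain", {
    cfg <- smallConfig(seed = 5,
        causalBlocks = list(causalBlock(c("cauX_1", "cauX_2"),
                                        carrierProb = c(A = 1, B = 1),
                                        effect = 0.1)))
    pop <- generatePopulation(cfg)
    tag <- unique(causalFeatures(pop$truth)$tagKmer)
    expect_match(tag, "^[ACGT]{9}$")
    hits <- vapply(pop$genomes, function(g) {
        s <- as.character(g)
        any(grepl(tag, s, fixed = TRUE))
    }, logical(1))
    expect_true(all(hits))
})

test_that("tag k-mers occur only in carrier strains and only in causal
           genes", {
    cfg <- smallConfig(seed = 8)
    pop <- generatePopulation(cfg)
    causal <- causalFeatures(pop$truth)
    pres <- presenceMatrix(pop$truth)
    for (b in unique(causal$block)) {
        genes <- causal$gene[causal$block == b]
        tag <- causal$tagKmer[causal$block == b][1]
        rc <- chartr("ACGT", "TGCA",
                     paste(rev(strsplit(tag, NULL)[[1]]), collapse = ""))
        carriers <- rownames(pres)[pres[, genes[1]] == 1]
        for (s in strainIds(pop$truth)) {
            seqs <- as.character(pop$genomes[[s]])
            inCausal <- grepl(paste(genes, collapse = "|"), names(seqs))
            hit <- grepl(tag, seqs, fixed = TRUE) |
                   grepl(rc, seqs, fixed = TRUE)
            if (s %in% carriers) {
                expect_true(all(hit[inCausal]))
            }
            expect_false(any(hit[!inCausal]))
        }
    }
})

test_that("clade-specific accessory probabilities separate the clades by
           clustering", {
    cfg <- simConfig(nStrains = 100, nCoreGenes = 10, nAccessoryGenes = 40,
                     accessoryPresenceProb = c(A = 0.9, B = 0.1),
                     geneLengthRange = c(60, 120), seed = 17)
    pop <- generatePopulation(cfg)
    pres <- presenceMatrix(pop$truth)
    acc <- pres[, grepl("^acc", colnames(pres)), drop = FALSE]
    cl <- cutree(hclust(dist(acc), method = "ward.D2"), k = 2)
    tab <- table(cl, cladeOf(pop$truth))
    purity <- sum(apply(tab, 1, max)) / sum(tab)
    expect_gte(purity, 0.95)
})

test_that("the degenerate phenotype model is exactly the baseline", {
    zeroCE <- list(tempEffect = list(A = c("25" = 0, "30" = 0, "40" = 0),
                                     B = c("25" = 0, "30" = 0, "40" = 0)),
                   temp40YeastRescue = c(A = 0, B = 0),
                   yeastEffect = 0, volumeEffect = 0)
    cfg <- smallConfig(seed = 3, causalBlocks = list(),
                       conditionEffects = zeroCE, baseSpeed = 0.5,
                       noiseSd = 0, missingRate = 0)
    pop <- generatePopulation(cfg)
    m <- vmaxMatrix(generatePhenotypes(pop$truth, cfg))
    expect_true(all(m == -0.5))
})

test_that("default bounds keep Vmax inside the observed extremes", {
    cfg <- simConfig(seed = 2, nCoreGenes = 20, nAccessoryGenes = 20,
                     geneLengthRange = c(60, 120))
    pop <- generatePopulation(cfg)
    m <- vmaxMatrix(generatePhenotypes(pop$truth, cfg))
    expect_gte(min(m, na.rm = TRUE), -0.96)
    expect_lte(max(m, na.rm = TRUE), -0.05)
    ## missingness close to the configured rate
    expect_equal(mean(is.na(m)), 0.19, tolerance = 0.05)
})

test_that("ordinary least squares recovers the planted effects", {
    ## moderate condition effects so no value is clipped; the OLS oracle
    ## then sees the uncensored linear model
    ce <- list(tempEffect = list(A = c("25" = -0.04, "30" = 0, "40" = -0.06),
                                 B = c("25" = -0.04, "30" = 0, "40" = -0.10)),
               temp40YeastRescue = c(A = 0.03, B = 0),
               yeastEffect = 0.08, volumeEffect = 0.04)
    cfg <- simConfig(nStrains = 200, nCoreGenes = 10, nAccessoryGenes = 20,
                     conditionEffects = ce, baseSpeed = 0.45,
                     noiseSd = 0.03, missingRate = 0,
                     geneLengthRange = c(60, 120), seed = 23)
    pop <- generatePopulation(cfg)
    m <- vmaxMatrix(generatePhenotypes(pop$truth, cfg))
    expect_true(all(m > -0.96 & m < -0.05))   # nothing clipped
    pres <- presenceMatrix(pop$truth)
    causal <- causalFeatures(pop$truth)
    blocks <- unique(causal$block)
    long <- data.frame(
        speed = -as.vector(m),
        cond = rep(colnames(m), each = nrow(m)),
        clade = rep(cladeOf(pop$truth), times = ncol(m)))
    for (b in blocks)
        long[[paste0("blk", b)]] <-
            rep(pres[, causal$gene[causal$block == b][1]],
                times = ncol(m))
    fit <- lm(speed ~ blk1 + blk2 + cond * clade, data = long)
    sm <- summary(fit)$coefficients
    for (b in blocks) {
        est <- sm[paste0("blk", b), "Estimate"]
        se <- sm[paste0("blk", b), "Std. Error"]
        eff <- causal$effect[causal$block == b][1]
        expect_lt(abs(est - eff), 3 * se)
    }
})

test_that("synthesized curves reproduce their target Vmax in closed loop", {
    m <- matrix(NA_real_, 1, 12, dimnames = list("sZ", conditionIds()))
    m[1, "DW_YE_30"] <- -0.5
    m[1, "LW_NY_25"] <- -0.05
    m[1, "DW_NY_40"] <- -0.96
    out <- generatePhCurves(phenotypeTable(m), calib = defaultCalibration())
    for (cv in out$ph) {
        target <- m[1, cv@condition]
        expect_equal(computeVmax(cv), target, tolerance = 0.01)
    }
    ## hue variants: hue -> pH -> Vmax round trip within 2%
    cal <- defaultCalibration()
    for (cv in out$hue) {
        target <- m[1, cv@condition]
        back <- computeVmax(hueToPh(cal, cv))
        expect_equal(back, target, tolerance = abs(0.02 * target))
    }
})

test_that("flat curves and unachievable targets behave as contracted", {
    m <- matrix(NA_real_, 1, 12, dimnames = list("sZ", conditionIds()))
    m[1, "DW_YE_30"] <- 0
    flat <- generatePhCurves(phenotypeTable(m))$ph[[1]]
    expect_true(all(flat@values == 6.5))
    expect_identical(computeVmax(flat), 0)
    m[1, "DW_YE_30"] <- -50
    expect_error(generatePhCurves(phenotypeTable(m)), "achievable")
})

test_that("emitted files round-trip through the standard parsers", {
    cfg <- simConfig(nStrains = 8, nCoreGenes = 6, nAccessoryGenes = 6,
                     geneLengthRange = c(60, 120), missingRate = 0.1,
                     seed = 31)
    pop <- generatePopulation(cfg)
    phen <- generatePhenotypes(pop$truth, cfg)
    out <- tempfile("simpop")
    paths <- emitInputFiles(pop$genomes, pop$truth, phen, out)

    ## Roary round trip: parsed presence equals the truth matrix
    gm <- buildGeneMatrix(paths[["roary"]])
    pres <- presenceMatrix(pop$truth)
    expect_identical(featureValues(gm)[rownames(pres), colnames(pres)] + 0L,
                     pres)

    ## FASTA round trip: tag k-mers found exactly in carrier strains
    causal <- causalFeatures(pop$truth)
    tag <- causal$tagKmer[1]
    carriers <- rownames(pres)[pres[, causal$gene[1]] == 1]
    for (s in strainIds(pop$truth)) {
        g <- Biostrings::readDNAStringSet(paths[[paste0("fasta_", s)]])
        found <- canonicalKmer(tag) %in% names(countCanonicalKmers(g, 9))
        expect_identical(found, s %in% carriers)
    }

    ## pfam hits: parseable, strains resolvable, matrix matches presence
    ## times domain assignment (every family has its own accession)
    hits <- readPfamScan(paths[["pfam"]])
    dm <- buildDomainMatrix(hits, geneToStrainFromLocus(hits$seq_id))
    ownAcc <- sprintf("PF9%04d.1", seq_len(ncol(pres)))
    common <- intersect(rownames(pres), rownames(featureValues(dm)))
    expect_identical(
        unname(featureValues(dm)[common, ownAcc] > 0),
        unname(pres[common, ] == 1L))

    ## semicolon matrices and phenotypes round-trip
    gm2 <- readMatrixFile(paths[["gene_matrix"]], "gene")
    f2 <- tempfile()
    writeMatrixFile(gm2, f2)
    expect_identical(readLines(paths[["gene_matrix"]]), readLines(f2))
    pt <- readPhenotypeFile(paths[["phenotypes"]])
    expect_equal(vmaxMatrix(pt), vmaxMatrix(phen), tolerance = 1e-6)
})

test_that("a minimal two-strain population still emits parseable files", {
    cfg <- simConfig(nStrains = 2, nCoreGenes = 3, nAccessoryGenes = 2,
                     geneLengthRange = c(60, 100), missingRate = 0,
                     seed = 1)
    pop <- generatePopulation(cfg)
    phen <- generatePhenotypes(pop$truth, cfg)
    out <- tempfile("minpop")
    paths <- emitInputFiles(pop$genomes, pop$truth, phen, out,
                            writeKmerMatrices = FALSE)
    expect_s4_class(buildGeneMatrix(paths[["roary"]]), "FeatureMatrix")
    expect_s4_class(readPhenotypeFile(paths[["phenotypes"]]),
                    "PhenotypeTable")
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(nStrains = 1), "nStrains")
    expect_error(simConfig(noiseSd = -1), "noiseSd")
    expect_error(simConfig(geneLengthRange = c(5, 50)), "geneLengthRange")
    expect_error(simConfig(causalBlocks = list(
        causalBlock("x", c(A = .5, B = .5), effect = -1))), "effect")
    ## causal ids colliding with generated family ids
    cfg <- smallConfig(causalBlocks = list(
        causalBlock("core0001", c(A = .5, B = .5), effect = .1)))
    expect_error(generatePopulation(cfg), "collide")
})
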