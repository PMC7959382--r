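## Canonical k-mers, Roary/pfam_scan parsing, pruning, collapsing,
## dataset assembly, pangenome categories.

test_that("canonical k-mer counting follows the alphabetically-first rule", {
    ## 10 A's, k=9: two windows, both AAAAAAAAA (revcomp TTTTTTTTT is later)
    expect_identical(countCanonicalKmers(c(c1 = "AAAAAAAAAA"), 9),
                     c(AAAAAAAAA = 2L))
    expect_identical(canonicalKmer(c("TTTTTTTTT", "ACGT", "GGGG")),
                     c("AAAAAAAAA", "ACGT", "CCCC"))
    expect_error(canonicalKmer("ACGN"), "alphabet")
})

test_that("counts are strand-symmetric and match the naive oracle", {
    set.seed(5)
    for (rep in 1:5) {
        s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
        rc <- chartr("ACGT", "TGCA",
                     paste(rev(strsplit(s, NULL)[[1]]), collapse = ""))
        for (k in c(5, 9)) {
            a <- countCanonicalKmers(s, k)
            b <- countCanonicalKmers(rc, k)
            expect_identical(a, b)
            oracle <- naiveCanonicalCounts(s, k)
            expect_identical(a[order(names(a))], oracle)
        }
    }
})

test_that("windows with ambiguous bases are skipped and contigs are not
           joined", {
    ## ACGTNACGT k=3: windows with N dropped
    got <- countCanonicalKmers(c(c1 = "ACGTNACGT"), 3)
    expect_identical(got, naiveCanonicalCounts("ACGTNACGT", 3))
    ## two contigs: no window spans the boundary
    two <- countCanonicalKmers(c(c1 = "AAAC", c2 = "GTTT"), 4)
    expect_identical(two, naiveCanonicalCounts(c("AAAC", "GTTT"), 4))
    expect_false("ACGT" %in% names(two))
})

test_that("degenerate k values behave as specified", {
    expect_length(countCanonicalKmers(c(c1 = "ACGT"), 9), 0L)
    expect_error(countCanonicalKmers(c(c1 = "ACGT"), 0), "k must be")
})

test_that("distinct canonical k-mer ceilings match closed forms", {
    ## odd k: 4^k / 2; even k: (4^k - 4^(k/2))/2 + 4^(k/2)
    expect_identical(nCanonicalKmers(9), 131072L)
    expect_identical(nCanonicalKmers(8), 32896L)
    expect_identical(nCanonicalKmers(3), 32L)
    expect_identical(nCanonicalKmers(2), 10L)
})

test_that("total canonical counts equal the number of valid windows", {
    set.seed(9)
    contigs <- vapply(c(300, 120, 50), function(L)
        paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
        character(1))
    for (k in c(4, 9)) {
        total <- sum(countCanonicalKmers(contigs, k))
        expect_identical(total,
                         sum(pmax(0L, nchar(contigs) - as.integer(k) + 1L)))
    }
})

test_that("gene matrix encodes presence from Roary-style cells", {
    d <- data.frame(Gene = paste0("g", 1:4),
                    Annotation = "hyp",
                    sA = c("sA_1", "sA_2", "", "sA_4"),
                    sB = c("sB_1", "", "sB_3", "sB_4"),
                    sC = c("sC_1", "sC_2\tsC_9", "sC_3", "sC_4"),
                    stringsAsFactors = FALSE, check.names = FALSE)
    fm <- buildGeneMatrix(d)
    m <- featureValues(fm)
    expect_equal(dim(m), c(3L, 4L))
    expect_equal(sum(m), 10)
    ## paralog cell (two tab-joined locus tags) still 1
    expect_equal(m["sC", "g2"], 1)
    expect_error(buildGeneMatrix(rbind(d, d[1, ])), "duplicated")
})

test_that("domain matrix counts copy numbers per strain", {
    tab <- data.frame(
        seq_id = c("sA_g1", "sA_g2", "sA_g2", "sB_g1"),
        hmm_acc = c("PF00001.1", "PF00001.1", "PF00002.3", "PF00001.1"),
        hmm_name = c("DomA", "DomA", "DomB", "DomA"),
        stringsAsFactors = FALSE)
    g2s <- geneToStrainFromLocus(c("sA_g1", "sA_g2", "sB_g1", "sB_g2"))
    fm <- buildDomainMatrix(tab, g2s)
    m <- featureValues(fm)
    expect_equal(m["sA", "PF00001.1"], 2)
    expect_equal(m["sB", "PF00002.3"], 0)
    expect_error(buildDomainMatrix(tab, g2s[-1]), "no strain mapping")
    ## empty table: all-zero matrix, and nothing survives pruning
    empty <- buildDomainMatrix(tab[0, ], g2s)
    expect_equal(ncol(featureValues(empty)), 0L)
})

test_that("pruning applies the strict more-than-98% rule at n = 100", {
    mk <- function(npresent) c(rep(1, npresent), rep(0, 100 - npresent))
    m <- cbind(p100 = mk(100), p99 = mk(99), p98 = mk(98), p50 = mk(50),
               p2 = mk(2), p1 = mk(1))
    rownames(m) <- sprintf("s%03d", 1:100)
    fm <- pruneFeatures(featureMatrix(m, "gene"), 0.98)
    expect_identical(featureIds(fm), c("p98", "p50", "p2"))
    ## idempotent
    expect_identical(featureValues(pruneFeatures(fm, 0.98)),
                     featureValues(fm))
    expect_error(pruneFeatures(fm, 0.4), "threshold")
})

test_that("collapsing merges exactly the identical profiles", {
    m <- cbind(A = c(1, 0, 1), B = c(1, 0, 1), C = c(0, 1, 1),
               D = c(1, 1, 1))
    rownames(m) <- c("s1", "s2", "s3")
    fm <- collapseIdentical(featureMatrix(m, "gene"))
    expect_identical(featureIds(fm), c("A,B", "C", "D"))
    expect_identical(collapseMap(fm), list("A,B" = c("A", "B")))
    ## all-distinct matrix unchanged
    fm2 <- collapseIdentical(featureMatrix(m[, c("A", "C", "D")], "gene"))
    expect_identical(featureIds(fm2), c("A", "C", "D"))
    expect_length(collapseMap(fm2), 0L)
})

test_that("collapsing matches a set-partition oracle on random matrices", {
    set.seed(21)
    for (rep in 1:5) {
        base <- matrix(rbinom(8 * 6, 3, 0.4), 8, 6)
        dup <- base[, sample(6, 10, replace = TRUE), drop = FALSE]
        colnames(dup) <- sprintf("f%02d", seq_len(ncol(dup)))
        rownames(dup) <- sprintf("s%d", 1:8)
        fm <- collapseIdentical(featureMatrix(dup, "pfam"))
        ## oracle: number of distinct column profiles
        profiles <- apply(dup, 2, paste, collapse = "|")
        expect_equal(ncol(featureValues(fm)), length(unique(profiles)))
        ## every original id in exactly one group
        groups <- lapply(featureIds(fm), function(id)
            collapseMap(fm)[[id]] %||% id)
        expect_setequal(unlist(groups), colnames(dup))
        expect_equal(anyDuplicated(unlist(groups)), 0L)
        ## collapsed columns keep their value vector
        for (i in seq_along(groups))
            for (g in groups[[i]])
                expect_identical(unname(featureValues(fm)[, i]),
                                 unname(dup[, g]))
    }
})

test_that("prune-then-collapse equals collapse-then-prune on binary data", {
    set.seed(33)
    m <- matrix(rbinom(200 * 30, 1, runif(30, 0.01, 0.99)), 200, 30,
                byrow = TRUE)
    m <- cbind(m, m[, 1:5])  # planted duplicates
    colnames(m) <- sprintf("g%02d", seq_len(ncol(m)))
    rownames(m) <- sprintf("s%03d", 1:200)
    fm <- featureMatrix(m, "gene")
    a <- collapseIdentical(pruneFeatures(fm, 0.98))
    b <- pruneFeatures(collapseIdentical(fm), 0.98)
    expect_identical(featureValues(a), featureValues(b))
})

test_that("dataset assembly broadcasts genomes over condition rows", {
    m <- cbind(g1 = c(1, 0), g2 = c(0, 1), g3 = c(1, 1))
    rownames(m) <- c("sA", "sB")
    pm <- matrix(-0.3, 2, 12, dimnames = list(c("sA", "sB"),
                                              conditionIds()))
    pm["sB", "DW_YE_40"] <- NA
    ds <- assembleDataset(featureMatrix(m, "gene"), phenotypeTable(pm))
    expect_equal(nrow(ds@x), 23L)
    expect_equal(ncol(ds@x), 3L + 3L)
    ## broadcast: genomic values constant within strain
    for (s in c("sA", "sB"))
        expect_equal(nrow(unique(ds@x[ds@strain == s,
                                      c("g1", "g2", "g3"), drop = FALSE])),
                     1L)
    ## condition encoding
    i <- which(ds@strain == "sA" & ds@condition == "DW_YE_40")
    expect_equal(unname(ds@x[i, c("Temperature", "Volume", "Yeast")]),
                 c(40, 1, 1))
    ## strain order invariance
    ds2 <- assembleDataset(featureMatrix(m[2:1, ], "gene"),
                           phenotypeTable(pm))
    expect_identical(ds2@x, ds@x)
    ## strains missing from the feature matrix are an error
    expect_error(assembleDataset(featureMatrix(m[1, , drop = FALSE],
                                               "gene"),
                                 phenotypeTable(pm)), "absent")
})

test_that("pangenome categories follow the presence-fraction thresholds", {
    mk <- function(p, n = 10) c(rep(1, p), rep(0, n - p))
    m <- cbind(all10 = mk(10), in9 = mk(9), in1 = mk(1))
    rownames(m) <- sprintf("s%02d", 1:10)
    ps <- pangenomeSummary(featureMatrix(m, "gene"))
    expect_equal(ps["core", "count"], 1L)       # 10/10
    expect_equal(ps["shell", "count"], 1L)      # 0.9 -> shell
    expect_equal(ps["cloud", "count"], 1L)      # 0.1 -> cloud
    expect_equal(ps["total", "count"], 3L)

    ## random matrix against brute-force classification
    set.seed(44)
    n <- 120
    m2 <- vapply(runif(60), function(p) rbinom(n, 1, p), integer(n))
    colnames(m2) <- sprintf("g%02d", 1:60)
    rownames(m2) <- sprintf("s%03d", 1:n)
    ps2 <- pangenomeSummary(featureMatrix(m2, "gene"))
    p <- colMeans(m2)
    expect_equal(ps2["core", "count"], sum(p >= 0.99))
    expect_equal(ps2["soft_core", "count"], sum(p >= 0.95 & p < 0.99))
    expect_equal(ps2["shell", "count"], sum(p >= 0.15 & p < 0.95))
    expect_equal(ps2["cloud", "count"], sum(p < 0.15))
    expect_equal(ps2["total", "count"], 60L)
    expect_equal(sum(ps2[c("core", "soft_core", "shell", "cloud"),
                         "percent"]), 100, tolerance = 0.01)
    expect_error(pangenomeSummary(featureMatrix(m2 * 2, "pfam")),
                 "binary")
})
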