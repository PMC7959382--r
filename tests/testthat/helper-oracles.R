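## Independent brute-force oracles and small shared fixtures.

## all-windows OLS slope enumeration (lm per window) -- independent of
## windowSlopes()'s vectorized implementation
bruteVmax <- function(times, values, w = 10L) {
    n <- length(times)
    slopes <- vapply(seq_len(n - w + 1L), function(i) {
        idx <- i:(i + w - 1L)
        unname(coef(lm(values[idx] ~ times[idx]))[2])
    }, numeric(1))
    m <- min(slopes)
    if (m >= 0) 0 else m
}

## naive canonical k-mer counting: enumerate windows, skip non-ACGT,
## canonicalize by string reversal + complement
naiveCanonicalCounts <- function(contigs, k) {
    revcomp <- function(s) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(s, NULL)[[1]]),
                                        collapse = ""))
    counts <- list()
    for (s in contigs) {
        if (nchar(s) < k) next
        for (i in 1:(nchar(s) - k + 1)) {
            km <- substr(s, i, i + k - 1)
            if (grepl("[^ACGT]", km)) next
            rc <- revcomp(km)
            canon <- if (km <= rc) km else rc
            counts[[canon]] <- (counts[[canon]] %||% 0L) + 1L
        }
    }
    unlist(counts)[order(names(unlist(counts)))]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## cover-weighted conditional expectation of one tree over a flattened
## forest; exhaustive-subset Shapley values (oracle for TreeSHAP)
treeValueOracle <- function(fo, root, xrow, S) {
    rec <- function(nd) {
        i1 <- nd + 1L
        f <- fo$feature[i1]
        if (f < 0L) return(fo$value[i1])
        l <- fo$childLeft[i1]; r <- fo$childRight[i1]
        if ((f + 1L) %in% S) {
            if (xrow[f + 1L] <= fo$threshold[i1]) rec(l) else rec(r)
        } else {
            (fo$covers[l + 1L] * rec(l) + fo$covers[r + 1L] * rec(r)) /
                fo$covers[i1]
        }
    }
    rec(root)
}

bruteShapley <- function(fo, xrow, M) {
    phi <- numeric(M)
    for (t in seq_along(fo$treeStart)) {
        root <- fo$treeStart[t]
        for (i in seq_len(M)) {
            others <- setdiff(seq_len(M), i)
            for (sz in 0:length(others)) {
                subs <- if (sz == 0) list(integer())
                        else utils::combn(others, sz, simplify = FALSE)
                w <- factorial(sz) * factorial(M - sz - 1) / factorial(M)
                for (S in subs)
                    phi[i] <- phi[i] +
                        w * (treeValueOracle(fo, root, xrow, c(S, i)) -
                             treeValueOracle(fo, root, xrow, S))
            }
        }
    }
    phi / length(fo$treeStart)
}

## a small, fast population for unit tests
smallConfig <- function(seed = 11, ...) {
    simConfig(nStrains = 30, nCoreGenes = 12, nAccessoryGenes = 15,
              geneLengthRange = c(60, 150), seed = seed, ...)
}

## quick RF params for tests that only need a working forest
fastParams <- list(nTrees = 50, maxDepth = NA, minSplit = 2, minLeaf = 1,
                   oob = FALSE)

## a null-scenario config: zero planted effects AND clade-symmetric
## condition effects, so the genome carries no information about Vmax
## (clade-specific temperature responses would otherwise leak phenotype
## signal into clade-correlated accessory genes)
nullSignalConfig <- function(seed, nStrains = 60) {
    symCE <- list(
        tempEffect = list(A = c("25" = -0.06, "30" = 0, "40" = -0.25),
                          B = c("25" = -0.06, "30" = 0, "40" = -0.25)),
        temp40YeastRescue = c(A = 0.05, B = 0.05),
        yeastEffect = 0.10, volumeEffect = 0.05)
    simConfig(nStrains = nStrains, nCoreGenes = 12, nAccessoryGenes = 20,
              geneLengthRange = c(60, 120),
              causalBlocks = list(causalBlock(
                  "cauN_1", carrierProb = c(A = .5, B = .5), effect = 0)),
              conditionEffects = symCE, seed = seed)
}
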