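## Genomic feature representations: canonical k-mers, gene presence/absence,
## Pfam domain copy numbers; pruning, collapsing, dataset assembly.

## cache of canonical k-mer lookup tables, keyed by k
.kmerCache <- new.env(parent = emptyenv())

.canonicalTable <- function(k) {
    key <- as.character(k)
    tab <- .kmerCache[[key]]
    if (!is.null(tab)) return(tab)
    all <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(all)))
    canon <- ifelse(all <= rc, all, rc)
    levels <- sort(unique(canon), method = "radix")
    tab <- list(all = all, canonical = canon,
                index = match(canon, levels), levels = levels)
    .kmerCache[[key]] <- tab
    tab
}

#' Canonical form of k-mers
#'
#' Because assembled contigs may come from either DNA strand, a k-mer and
#' its reverse complement are treated as one feature, represented by
#' whichever of the two sequences comes alphabetically first.
#'
#' @param kmers character vector of equal-length sequences over A/C/G/T.
#' @return character vector of canonical representatives.
#' @examples
#' canonicalKmer(c("TTTTTTTTT", "ACGT"))  # "AAAAAAAAA", "ACGT"
#' @export
canonicalKmer <- function(kmers) {
    if (!length(kmers)) return(character())
    if (any(!grepl("^[ACGT]+$", kmers)))
        stop("k-mers must be over the alphabet {A,C,G,T}")
    rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    ifelse(kmers <= rc, kmers, rc)
}

#' Number of distinct canonical k-mers
#'
#' Counted by exhaustive enumeration of all 4^k k-mers followed by
#' canonicalization. For odd k this is 4^k / 2 (no palindromes); for even k,
#' (4^k - 4^(k/2)) / 2 + 4^(k/2).
#'
#' @param k k-mer length (kept small; the table is 4^k entries).
#' @return integer(1).
#' @export
nCanonicalKmers <- function(k) length(.canonicalTable(k)$levels)

#' Count canonical k-mers of a genome
#'
#' Every length-k window over unambiguous (A/C/G/T) bases of every contig is
#' counted under the canonical representative of the (k-mer,
#' reverse-complement) pair; windows containing ambiguous bases are skipped,
#' and no window spans a contig boundary.
#'
#' @param genome a \code{Biostrings::DNAStringSet} (multi-contig) or a
#'   character vector of contig sequences.
#' @param k k-mer length (>= 1).
#' @return named integer vector of counts over the canonical k-mers observed
#'   (zero-count k-mers omitted), names sorted.
#' @examples
#' countCanonicalKmers(c(contig1 = "AAAAAAAAAA"), k = 9)  # AAAAAAAAA: 2
#' @export
countCanonicalKmers <- function(genome, k) {
    if (k <= 0) stop("k must be >= 1")
    if (!is(genome, "DNAStringSet"))
        genome <- Biostrings::DNAStringSet(as.character(genome))
    tab <- .canonicalTable(k)
    raw <- Biostrings::oligonucleotideFrequency(genome, width = k,
                                                simplify.as = "collapsed")
    out <- drop(rowsum(as.numeric(raw), tab$index, reorder = TRUE))
    names(out) <- tab$levels
    out <- out[out > 0]
    storage.mode(out) <- "integer"
    out
}

#' Build a canonical k-mer count FeatureMatrix for a strain collection
#'
#' @param genomes named list of per-strain genomes (each a
#'   \code{DNAStringSet} or character vector of contigs).
#' @param k 8 or 9 (the two standard representations).
#' @param subspecies optional character vector named by strain.
#' @return A \linkS4class{FeatureMatrix} with representation \code{"kmer8"}
#'   or \code{"kmer9"} containing every canonical k-mer observed in at least
#'   one strain.
#' @export
buildKmerMatrix <- function(genomes, k, subspecies = character()) {
    stopifnot(length(genomes) > 0, !is.null(names(genomes)))
    if (!k %in% c(8, 9))
        stop("the k-mer representations use k = 8 or 9; for other k use countCanonicalKmers")
    tab <- .canonicalTable(k)
    U <- length(tab$levels)
    n <- length(genomes)
    mat <- matrix(0L, n, U, dimnames = list(names(genomes), tab$levels))
    for (i in seq_len(n)) {
        g <- genomes[[i]]
        if (!is(g, "DNAStringSet"))
            g <- Biostrings::DNAStringSet(as.character(g))
        raw <- Biostrings::oligonucleotideFrequency(g, width = k,
                                                    simplify.as = "collapsed")
        mat[i, ] <- as.integer(rowsum(raw, tab$index, reorder = TRUE))
    }
    mat <- mat[, colSums(mat) > 0, drop = FALSE]
    rep <- if (k == 8) "kmer8" else "kmer9"
    featureMatrix(mat, rep, subspecies = subspecies)
}

## Metadata columns of a full Roary gene_presence_absence.csv; the compact
## dialect written by emitInputFiles uses only Gene + Annotation.
.ROARY_META <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
                 "No. sequences", "Avg sequences per isolate", "Genome Fragment",
                 "Order within Fragment", "Accessory Fragment",
                 "Accessory Order with Fragment", "QC", "Min group size nuc",
                 "Max group size nuc", "Avg group size nuc")

#' Build the gene presence/absence FeatureMatrix from a Roary-style table
#'
#' A cell is 1 iff the strain's column for that gene group is non-empty;
#' cells holding several locus tags (paralogs) still map to 1. Known Roary
#' metadata columns are dropped; all remaining columns are taken as strains.
#'
#' @param roary path to a \code{gene_presence_absence.csv}-style file, or an
#'   equivalent data.frame (first column = gene group names).
#' @param subspecies optional character vector named by strain.
#' @return A \linkS4class{FeatureMatrix} with representation \code{"gene"}
#'   (strains x gene groups).
#' @export
buildGeneMatrix <- function(roary, subspecies = character()) {
    d <- if (is.character(roary) && length(roary) == 1L)
        read.table(roary, header = TRUE, sep = ",", quote = "\"",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "")
    else as.data.frame(roary, check.names = FALSE,
                       stringsAsFactors = FALSE)
    genes <- as.character(d[[1]])
    if (anyDuplicated(genes)) stop("duplicated gene-group names")
    strainCols <- setdiff(names(d)[-1], .ROARY_META)
    if (!length(strainCols)) stop("no strain columns found in Roary table")
    present <- vapply(strainCols, function(s) {
        v <- d[[s]]
        as.integer(!(is.na(v) | trimws(as.character(v)) == ""))
    }, integer(length(genes)))
    mat <- t(present)              # strains x genes
    colnames(mat) <- genes
    rownames(mat) <- strainCols
    featureMatrix(mat, "gene", subspecies = subspecies)
}

#' Read a pfam_scan-style domain hit table
#'
#' Accepts both full \code{pfam_scan.pl} output (15 whitespace-delimited
#' columns, \code{#} comments) and the compact 5-column dialect written by
#' \code{\link{emitInputFiles}} (seq id, alignment start, alignment end,
#' hmm accession, hmm name).
#'
#' @param path file path.
#' @return data.frame with columns \code{seq_id}, \code{hmm_acc} (version
#'   retained, e.g. \code{"PF02502.13"}), \code{hmm_name}.
#' @export
readPfamScan <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines))
        return(data.frame(seq_id = character(), hmm_acc = character(),
                          hmm_name = character(), stringsAsFactors = FALSE))
    fields <- strsplit(trimws(lines), "\\s+")
    ncols <- lengths(fields)
    accCol <- if (all(ncols >= 7) &&
                  all(grepl("^PF", vapply(fields, `[`, "", 6L)))) 6L else 4L
    data.frame(seq_id = vapply(fields, `[`, "", 1L),
               hmm_acc = vapply(fields, `[`, "", accCol),
               hmm_name = vapply(fields, `[`, "", accCol + 1L),
               stringsAsFactors = FALSE)
}

#' Build the Pfam domain copy-number FeatureMatrix
#'
#' Each cell counts the domain hits of one accession across all genes of a
#' strain (copy number). Accession versions are retained.
#'
#' @param pfamTable a data.frame as returned by \code{\link{readPfamScan}},
#'   or a path to a pfam_scan-style file.
#' @param geneToStrain named character vector mapping each sequence id
#'   (locus tag) to its strain; every strain in this map gets a row, so
#'   strains without hits appear as all-zero rows.
#' @param subspecies optional character vector named by strain.
#' @return A \linkS4class{FeatureMatrix} with representation \code{"pfam"}.
#' @export
buildDomainMatrix <- function(pfamTable, geneToStrain,
                              subspecies = character()) {
    if (is.character(pfamTable) && length(pfamTable) == 1L)
        pfamTable <- readPfamScan(pfamTable)
    stopifnot(!is.null(names(geneToStrain)))
    strains <- sort(unique(unname(geneToStrain)), method = "radix")
    unmapped <- setdiff(pfamTable$seq_id, names(geneToStrain))
    if (length(unmapped))
        stop("sequence ids with no strain mapping: ",
             paste(head(unmapped, 5), collapse = ", "))
    accs <- sort(unique(pfamTable$hmm_acc), method = "radix")
    mat <- matrix(0L, length(strains), length(accs),
                  dimnames = list(strains, accs))
    if (nrow(pfamTable)) {
        st <- unname(geneToStrain[pfamTable$seq_id])
        tt <- table(factor(st, levels = strains),
                    factor(pfamTable$hmm_acc, levels = accs))
        mat[] <- as.integer(tt)
    }
    featureMatrix(mat, "pfam", subspecies = subspecies)
}

#' Prune near-constant features
#'
#' A feature is removed iff it is present (value > 0) in more than
#' \code{threshold} of the strains, or absent (value == 0) in more than
#' \code{threshold} of the strains — strictly "more than", so at the default
#' 0.98 with 100 strains a feature present in 99 strains is removed while
#' one present in 98 is kept. Pruning is idempotent.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param threshold fraction in (0.5, 1); default 0.98.
#' @return The pruned \linkS4class{FeatureMatrix}.
#' @export
pruneFeatures <- function(fm, threshold = 0.98) {
    stopifnot(is(fm, "FeatureMatrix"))
    if (threshold <= 0.5 || threshold >= 1)
        stop("threshold must lie in (0.5, 1)")
    if (!ncol(fm@mat)) return(fm)
    pres <- colMeans(fm@mat > 0)
    keep <- !(pres > threshold | (1 - pres) > threshold)
    fm@mat <- fm@mat[, keep, drop = FALSE]
    fm@collapseMap <- fm@collapseMap[
        intersect(names(fm@collapseMap), colnames(fm@mat))]
    fm
}

#' Collapse features with identical strain profiles
#'
#' Feature columns whose value vectors are identical across all strains
#' (always co-occurring) are merged into a single column named by
#' comma-joining the original ids in stable input order. The collapse map
#' records membership; already-collapsed inputs are expanded first so every
#' original id appears in exactly one entry.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @return The collapsed \linkS4class{FeatureMatrix}.
#' @export
collapseIdentical <- function(fm) {
    stopifnot(is(fm, "FeatureMatrix"))
    m <- fm@mat
    if (ncol(m) < 2L) return(fm)
    keys <- vapply(seq_len(ncol(m)),
                   function(j) paste(m[, j], collapse = ","), character(1))
    grp <- match(keys, unique(keys))
    expand <- function(id)
        if (!is.null(fm@collapseMap[[id]])) fm@collapseMap[[id]] else id
    members <- unname(lapply(split(colnames(m), grp),
                             function(ids) unlist(lapply(ids, expand),
                                                  use.names = FALSE)))
    first <- which(!duplicated(grp))
    newNames <- vapply(members, paste, character(1), collapse = ",")
    out <- m[, first, drop = FALSE]
    colnames(out) <- newNames
    multi <- lengths(members) > 1L
    cmap <- members[multi]
    names(cmap) <- newNames[multi]
    fm@mat <- out
    fm@collapseMap <- cmap
    fm
}

#' Assemble the model-ready dataset
#'
#' One row per non-missing strain x condition Vmax measurement. A strain's
#' genomic feature values are broadcast across its rows; three condition
#' predictors are added: \code{Temperature} (numeric 25/30/40),
#' \code{Volume} (1 = deepwell) and \code{Yeast} (1 = yeast extract).
#' Predictor columns are sorted by name.
#'
#' @param fm a \linkS4class{FeatureMatrix} whose strains are a superset of
#'   the phenotype strains.
#' @param phenotypes a \linkS4class{PhenotypeTable}.
#' @return An \linkS4class{AssembledDataset}.
#' @export
assembleDataset <- function(fm, phenotypes) {
    stopifnot(is(fm, "FeatureMatrix"), is(phenotypes, "PhenotypeTable"))
    pm <- phenotypes@mat
    missing <- setdiff(rownames(pm), rownames(fm@mat))
    if (length(missing))
        stop("phenotype strains absent from the feature matrix: ",
             paste(head(missing, 5), collapse = ", "))
    cg <- conditionGrid()
    obs <- which(!is.na(pm), arr.ind = TRUE)
    obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
    strain <- rownames(pm)[obs[, 1]]
    cond <- colnames(pm)[obs[, 2]]
    ci <- match(cond, cg$condition)
    condX <- cbind(Temperature = cg$temperature[ci],
                   Volume = as.numeric(cg$volume[ci] == "DW"),
                   Yeast = as.numeric(cg$yeast[ci] == "YE"))
    gx <- fm@mat[strain, , drop = FALSE]
    x <- cbind(gx, condX)
    x <- x[, sort(colnames(x), method = "radix"), drop = FALSE]
    rownames(x) <- NULL
    gf <- colnames(fm@mat)
    new("AssembledDataset", x = x, y = unname(pm[obs]), strain = strain,
        condition = cond, genomicFeatures = if (is.null(gf)) character()
                                            else gf,
        representation = fm@representation)
}

#' Pangenome category summary
#'
#' Classifies gene families of an (unpruned) presence/absence matrix by
#' presence fraction p: core p >= 0.99; soft core 0.95 <= p < 0.99; shell
#' 0.15 <= p < 0.95; cloud p < 0.15. Exact-boundary genes go to the higher
#' category.
#'
#' @param fm a binary \linkS4class{FeatureMatrix} (representation
#'   \code{"gene"}).
#' @return data.frame with rows core / soft_core / shell / cloud / total and
#'   columns \code{count}, \code{percent}.
#' @export
pangenomeSummary <- function(fm) {
    stopifnot(is(fm, "FeatureMatrix"))
    if (!all(fm@mat %in% c(0, 1))) stop("presence matrix must be binary")
    p <- colMeans(fm@mat > 0)
    cat_ <- cut(p, breaks = c(-Inf, 0.15, 0.95, 0.99, Inf),
                labels = c("cloud", "shell", "soft_core", "core"),
                right = FALSE)
    counts <- table(factor(cat_, levels = c("core", "soft_core", "shell",
                                            "cloud")))
    total <- sum(counts)
    out <- data.frame(count = as.integer(counts),
                      percent = if (total) 100 * as.integer(counts) / total
                                else rep(0, 4),
                      row.names = names(counts))
    rbind(out, total = data.frame(count = total,
                                  percent = if (total) 100 else 0))
}
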