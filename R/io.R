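## Readers/writers for the semicolon-separated matrix dialects used for the
## model input files: feature matrices (strain id; subspecies; features...)
## and the phenotype matrix (strain id; 12 Vmax columns).

#' Read / write a feature matrix in the semicolon dialect
#'
#' The dialect has a header line and one line per strain; fields are
#' semicolon-separated. Column 1 holds the strain id, column 2 the
#' subspecies annotation, and the remaining columns integer feature values.
#' A header cell may hold several comma-joined feature ids when columns with
#' identical profiles were collapsed; on reading these become single columns
#' and the membership is recorded in the collapse map. \code{writeMatrixFile}
#' and \code{readMatrixFile} are exact inverses of each other.
#'
#' @param path file path.
#' @param representation representation tag to attach on read
#'   (\code{"gene"}, \code{"pfam"}, \code{"kmer8"}, \code{"kmer9"}).
#' @return \code{readMatrixFile}: a \linkS4class{FeatureMatrix}.
#' @export
readMatrixFile <- function(path, representation) {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("matrix file needs a header and >= 1 strain")
    rows <- strsplit(lines, ";", fixed = TRUE)
    nc <- lengths(rows)
    if (length(unique(nc)) != 1L)
        stop("ragged matrix file: rows have differing column counts")
    header <- rows[[1L]]
    if (nc[1L] < 2L) stop("matrix file needs >= 2 columns")
    body <- rows[-1L]
    strains <- vapply(body, `[`, "", 1L)
    if (anyDuplicated(strains)) stop("duplicate strain ids in matrix file")
    sub <- setNames(vapply(body, `[`, "", 2L), strains)
    featNames <- header[-(1:2)]
    mat <- matrix(0, length(body), length(featNames),
                  dimnames = list(strains, featNames))
    if (length(featNames)) {
        vals <- vapply(body, function(r) {
            v <- suppressWarnings(as.numeric(r[-(1:2)]))
            if (any(is.na(v))) stop("non-numeric feature value in matrix file")
            if (any(v != trunc(v))) stop("feature values must be integers")
            v
        }, numeric(length(featNames)))
        mat[] <- t(vals)
    }
    cmap <- strsplit(featNames[grepl(",", featNames, fixed = TRUE)], ",",
                     fixed = TRUE)
    names(cmap) <- featNames[grepl(",", featNames, fixed = TRUE)]
    featureMatrix(mat, representation, subspecies = sub, collapseMap = cmap)
}

#' @rdname readMatrixFile
#' @param fm a \linkS4class{FeatureMatrix} to write.
#' @export
writeMatrixFile <- function(fm, path) {
    stopifnot(is(fm, "FeatureMatrix"))
    m <- fm@mat
    sub <- if (length(fm@subspecies)) unname(fm@subspecies[rownames(m)])
           else rep("", nrow(m))
    header <- paste(c("strain", "subspecies", colnames(m)), collapse = ";")
    bodyVals <- apply(m, 1L, function(v)
        paste(format(v, scientific = FALSE, trim = TRUE), collapse = ";"))
    body <- if (ncol(m)) paste(rownames(m), sub, bodyVals, sep = ";")
            else paste(rownames(m), sub, sep = ";")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read / write a phenotype matrix in the semicolon dialect
#'
#' 13 semicolon-separated columns: strain id then the 12 condition columns
#' (named as in \code{conditionIds()}, e.g. \code{DW_YE_25}). Empty fields
#' mark missing measurements. Arbitrary condition header names are accepted
#' via \code{conditionMap}, a named character vector translating file header
#' names to canonical condition ids.
#'
#' @param path file path.
#' @param conditionMap optional named character vector: file header name ->
#'   canonical condition id.
#' @return \code{readPhenotypeFile}: a \linkS4class{PhenotypeTable}.
#' @export
readPhenotypeFile <- function(path, conditionMap = NULL) {
    d <- read.table(path, header = TRUE, sep = ";", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "",
                    colClasses = "character")
    if (ncol(d) != 13L)
        stop(sprintf("phenotype file must have 13 columns, found %d", ncol(d)))
    strains <- d[[1L]]
    if (anyDuplicated(strains)) stop("duplicate strain ids in phenotype file")
    hdr <- names(d)[-1L]
    if (!is.null(conditionMap)) {
        mapped <- unname(conditionMap[hdr])
        if (any(is.na(mapped)))
            stop("conditionMap does not cover headers: ",
                 paste(hdr[is.na(mapped)], collapse = ", "))
        hdr <- mapped
    }
    if (!setequal(hdr, conditionIds()))
        stop("phenotype columns do not match the 12 conditions; ",
             "supply conditionMap to translate the headers")
    mat <- vapply(seq_along(hdr),
                  function(j) suppressWarnings(as.numeric(d[[j + 1L]])),
                  numeric(length(strains)))
    if (length(strains) == 1L) mat <- matrix(mat, nrow = 1L)
    colnames(mat) <- hdr
    rownames(mat) <- strains
    phenotypeTable(mat)
}

#' @rdname readPhenotypeFile
#' @param table a \linkS4class{PhenotypeTable} to write.
#' @export
writePhenotypeFile <- function(table, path) {
    stopifnot(is(table, "PhenotypeTable"))
    m <- table@mat
    fmt <- function(v) ifelse(is.na(v),
                              "",
                              format(v, scientific = FALSE, trim = TRUE))
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], fmt(m[i, ])), collapse = ";"), character(1))
    writeLines(c(paste(c("strain", colnames(m)), collapse = ";"), body), path)
    invisible(path)
}
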