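## Readers and writers for the three tabular inputs and the tabular outputs.
## Dialect: TSV, UTF-8, "\n" line endings; the expression matrix has a header
## row of sample ids and gene ids in column 1 (the shape of deposited
## gradient FPKM matrices); gzip is accepted transparently.

#' Read a genes-by-samples expression matrix
#'
#' Reads a delimited text file (optionally gzipped) whose first row is a
#' header of sample ids and whose first column holds gene ids, and returns a
#' validated [ExpressionGradient-class].  Rows are kept in file order.
#' Duplicate gene ids, non-numeric cells, missing values (empty or
#' \code{"NA"}) and negative values are hard errors: the method assumes an
#' already-quantified, complete FPKM-scale matrix and fails loudly rather
#' than imputing.
#'
#' @param path path to the matrix file; \code{.gz} is handled transparently.
#' @param delimiter field separator, default tab.
#' @return an [ExpressionGradient-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t3\t2\t1"), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path, delimiter = "\t") {
    if (!file.exists(path))
        stop("expression matrix file not found: ", path)
    df <- utils::read.table(path, sep = delimiter, header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "", comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("expression matrix needs a gene id column and >= 1 sample column")
    geneIds <- df[[1L]]
    dup <- geneIds[duplicated(geneIds)]
    if (length(dup))
        stop("duplicate gene id: ", dup[1L])
    raw <- as.matrix(df[, -1L, drop = FALSE])
    if (any(is.na(raw)) || any(trimws(raw) == ""))
        stop("missing value in expression matrix (empty or NA cell)")
    vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
    if (anyNA(vals)) {
        bad <- raw[is.na(vals)][1L]
        stop("non-numeric expression value: '", bad, "'")
    }
    if (any(vals < 0))
        stop("negative expression value: ", min(vals))
    ExpressionGradient(vals, geneIds = geneIds,
                       sampleIds = colnames(df)[-1L])
}

#' Write an expression matrix
#'
#' Inverse of [readExpressionMatrix()]: TSV with a header of sample ids and
#' gene ids in the first column.  Reading the written file back yields
#' identical ids and values (for the written decimal representation).
#'
#' @param x an [ExpressionGradient-class].
#' @param path output path; a \code{.gz} suffix writes gzipped.
#' @param idColumn name for the gene-id header cell.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "gene_id") {
    stopifnot(methods::is(x, "ExpressionGradient"))
    m <- SummarizedExperiment::assay(x, "exprs")
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    lines <- c(paste(c(idColumn, colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i) {
                   paste(c(rownames(m)[i],
                           format(m[i, ], trim = TRUE, scientific = FALSE)),
                         collapse = "\t")
               }, character(1)))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

#' Read a transcription-factor family table
#'
#' Two-column headerless TSV: gene id, family name.  A gene listed under two
#' distinct families is a hard error (each gene must map to exactly one
#' family); a repeated identical assignment is collapsed.
#'
#' @param path path to the table (optionally gzipped).
#' @return a [TFFamilyAnnotation-class].
#' @examples
#' f <- tempfile()
#' writeLines("LOC_Os09g12750\tG2-like", f)
#' readFamilyTable(f)
#' @export
readFamilyTable <- function(path) {
    if (!file.exists(path))
        stop("family table not found: ", path)
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) != 2L)
        stop("family table must have exactly two columns (gene_id, family)")
    df <- unique(df)
    if (any(df[[2L]] == "" | is.na(df[[2L]])))
        stop("empty family name in family table")
    dup <- df[[1L]][duplicated(df[[1L]])]
    if (length(dup))
        stop("conflicting assignment: gene ", dup[1L],
             " is listed under more than one family")
    a <- df[[2L]]
    names(a) <- df[[1L]]
    TFFamilyAnnotation(a)
}

#' Read a guide-gene list
#'
#' Two-column headerless TSV: symbol, gene id.  Order is preserved; symbols
#' need not be unique, gene ids must be.
#'
#' @param path path to the list (optionally gzipped).
#' @return a [GuideGeneSet-class].
#' @examples
#' readGuideList(system.file("extdata", "guide_genes.tsv",
#'                           package = "guideCoex"))
#' @export
readGuideList <- function(path) {
    if (!file.exists(path))
        stop("guide list not found: ", path)
    df <- tryCatch(
        utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE),
        error = function(e) stop("guide list is empty or unreadable: ", path))
    if (ncol(df) != 2L)
        stop("guide list must have exactly two columns (symbol, gene_id)")
    GuideGeneSet(symbol = df[[1L]], geneId = df[[2L]])
}

#' Write a correlation table
#'
#' Long-format TSV with header \code{guide_id}, \code{gene_id}, \code{r}
#' (6 decimal places, rounded half to even), \code{defined}
#' (\code{true}/\code{false}); undefined coefficients print an empty
#' \code{r} field.  Rows are ordered by guide (table order), then gene.
#'
#' @param table a [CorrelationTable-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCorrelationTable <- function(table, path) {
    stopifnot(methods::is(table, "CorrelationTable"))
    r <- table@r
    rv <- as.vector(t(r))
    long <- data.frame(
        guide_id = rep(rownames(r), each = ncol(r)),
        gene_id  = rep(colnames(r), times = nrow(r)),
        r        = ifelse(is.na(rv), "", sprintf("%.6f", round(rv, 6L))),
        defined  = ifelse(is.na(rv), "false", "true"),
        stringsAsFactors = FALSE)
    writeTsv(long, path)
}

#' Write family rankings
#'
#' TSV with header \code{guide_id}, \code{rank}, \code{family},
#' \code{member_count}; one block per guide in input order.
#'
#' @param rankings a list of [FamilyRanking-class] objects.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFamilyRankings <- function(rankings, path) {
    rows <- lapply(rankings, function(fr) {
        stopifnot(methods::is(fr, "FamilyRanking"))
        if (!nrow(fr@ranking)) return(NULL)
        data.frame(guide_id = fr@guideId,
                   rank = seq_len(nrow(fr@ranking)),
                   family = fr@ranking$family,
                   member_count = fr@ranking$count,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(
        data.frame(guide_id = character(), rank = integer(),
                   family = character(), member_count = integer()))))
    writeTsv(out, path)
}

#' Write a Venn region table
#'
#' TSV with header \code{region} (guide ids joined by \code{&}) and
#' \code{count} (families exclusive to that region).
#'
#' @param result a [SharedFamilyResult-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeVennTable <- function(result, path) {
    stopifnot(methods::is(result, "SharedFamilyResult"))
    writeTsv(result@vennCounts, path)
}

#' Write a candidate report
#'
#' TSV with header \code{tf_id}, \code{n_negative},
#' \code{negative_partners}, \code{positive_partners} (partner guide lists
#' semicolon-joined).
#'
#' @param candidates data.frame as returned by [selectNegativeCandidates()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCandidateReport <- function(candidates, path) {
    writeTsv(candidates, path)
}

## TSV writer used by every tabular output: header, UTF-8, "\n" endings.
writeTsv <- function(df, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    lines <- paste(names(df), collapse = "\t")
    if (nrow(df)) {
        body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
        lines <- c(lines, body)
    }
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
    invisible(path)
}
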