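## Guide-vs-all Pearson screening.  The coefficient itself comes from
## stats::cor; this module owns the undefined-value contract (zero-variance
## profiles yield NA, never 0) and the threshold semantics.

#' Sample Pearson correlation with an explicit undefined case
#'
#' Standard sample Pearson coefficient, symmetric in its arguments.
#' Returns \code{NA} (undefined) when either vector has zero variance:
#' the coefficient is mathematically undefined there, and treating it as 0
#' would corrupt downstream sign statistics.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a single numeric in [-1, 1], or \code{NA} if undefined.
#' @examples
#' pearsonCorrelation(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' pearsonCorrelation(c(5, 5, 5), c(1, 2, 3))        # NA: zero variance
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("at least 3 paired observations are required")
    if (anyNA(x) || anyNA(y))
        stop("missing values are not allowed")
    if (sd(x) == 0 || sd(y) == 0)
        return(NA_real_)
    stats::cor(x, y, method = "pearson")
}

#' Correlate every guide gene against every gene of the matrix
#'
#' Computes the sample Pearson coefficient of each guide's expression
#' profile against every gene in the matrix (guides included as columns,
#' so \code{r(g, g) = 1} for every non-constant guide).  Zero-variance
#' profiles yield undefined (\code{NA}) entries; their count is reported
#' via \code{message()}.
#'
#' @param matrix an [ExpressionGradient-class].
#' @param guides a [GuideGeneSet-class]; every guide id must be present in
#'   the matrix (a missing id is an error naming it).
#' @param logTransform apply \code{log2(x + 1)} to the whole matrix before
#'   correlating (default \code{FALSE}: coefficients are computed on the
#'   values as read).
#' @return a [CorrelationTable-class] (guides x genes).
#' @examples
#' m <- ExpressionGradient(rbind(G1 = c(1, 2, 3, 4), t1 = c(1, 3, 2, 4)),
#'                         sampleIds = paste0("s", 1:4))
#' g <- GuideGeneSet("G1", "G1")
#' corValues(correlateGuides(m, g))
#' @export
correlateGuides <- function(matrix, guides, logTransform = FALSE) {
    stopifnot(methods::is(matrix, "ExpressionGradient"),
              methods::is(guides, "GuideGeneSet"))
    m <- SummarizedExperiment::assay(matrix, "exprs")
    missing <- setdiff(guideIds(guides), rownames(m))
    if (length(missing))
        stop("guide gene id not found in expression matrix: ",
             paste(missing, collapse = ", "))
    if (logTransform) m <- log2(m + 1)
    constant <- apply(m, 1L, sd) == 0
    if (any(constant))
        message(sum(constant),
                " zero-variance gene(s) have undefined correlations")
    gm <- m[guideIds(guides), , drop = FALSE]
    r <- suppressWarnings(stats::cor(t(gm), t(m), method = "pearson"))
    r[, constant] <- NA_real_
    r[constant[guideIds(guides)], ] <- NA_real_
    ## guard against floating excursions beyond [-1, 1]
    r[!is.na(r) & r > 1] <- 1
    r[!is.na(r) & r < -1] <- -1
    rownames(r) <- guideIds(guides)
    colnames(r) <- rownames(m)
    methods::new("CorrelationTable", r = r, nSamples = ncol(m))
}

#' Select genes passing a correlation threshold for one guide
#'
#' Applies a [ThresholdSpec-class] to one guide's row of the correlation
#' table.  In absolute mode \code{|r|} is compared with \code{tau}; in
#' positive/negative mode only coefficients of that sign are eligible and
#' their magnitude is compared.  Strict means \code{>}, non-strict
#' \code{>=}.  The guide itself is always excluded, and undefined
#' coefficients never pass.
#'
#' @param table a [CorrelationTable-class].
#' @param spec a [ThresholdSpec-class].
#' @param guide a guide id present in the table.
#' @return character vector of gene ids, in table column order.
#' @examples
#' r <- matrix(c(1, 0.9, 0.7, -0.85), nrow = 1,
#'             dimnames = list("G", c("G", "g1", "g2", "g3")))
#' tab <- new("CorrelationTable", r = r, nSamples = 11L)
#' filterByThreshold(tab, thresholdSpec(0.8), "G")                     # g1, g3
#' filterByThreshold(tab, thresholdSpec(0.8, mode = "negative"), "G")  # g3
#' @export
filterByThreshold <- function(table, spec, guide) {
    stopifnot(methods::is(table, "CorrelationTable"),
              methods::is(spec, "ThresholdSpec"))
    if (!guide %in% rownames(table@r))
        stop("unknown guide: ", guide)
    rv <- structure(as.vector(table@r[guide, , drop = FALSE]),
                    names = colnames(table@r))
    rv <- rv[names(rv) != guide]
    eligible <- switch(spec@mode,
                       absolute = !is.na(rv),
                       positive = !is.na(rv) & rv > 0,
                       negative = !is.na(rv) & rv < 0)
    mag <- abs(rv)
    pass <- eligible &
        (if (spec@strict) mag > spec@tau else mag >= spec@tau)
    names(rv)[which(pass)]
}
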