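#' @rdname GuideGeneSet-class
#' @param object,x an object.
#' @export
setGeneric("guideIds", function(object) standardGeneric("guideIds"))

#' @rdname GuideGeneSet-class
#' @export
setGeneric("guideSymbols", function(object) standardGeneric("guideSymbols"))

#' @rdname TFFamilyAnnotation-class
#' @export
setGeneric("familyAssignments",
           function(object) standardGeneric("familyAssignments"))

#' @rdname CorrelationTable-class
#' @export
setGeneric("corValues", function(object) standardGeneric("corValues"))

#' @rdname CorrelationTable-class
#' @export
setGeneric("numSamples", function(object) standardGeneric("numSamples"))

#' @rdname CoexNetwork-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname CoexNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname ThresholdSpec-class
#' @export
setGeneric("thresholdUsed", function(object) standardGeneric("thresholdUsed"))

#' @rdname FamilyRanking-class
#' @export
setGeneric("familyCounts", function(object) standardGeneric("familyCounts"))

#' @rdname SharedFamilyResult-class
#' @export
setGeneric("sharedFamilies", function(object) standardGeneric("sharedFamilies"))

#' @rdname SharedFamilyResult-class
#' @export
setGeneric("vennCounts", function(object) standardGeneric("vennCounts"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

## ---- accessors -------------------------------------------------------------

#' @rdname GuideGeneSet-class
#' @export
setMethod("guideIds", "GuideGeneSet", function(object) object@geneId)

#' @rdname GuideGeneSet-class
#' @export
setMethod("guideSymbols", "GuideGeneSet", function(object) object@symbol)

#' @rdname GuideGeneSet-class
#' @export
setMethod("length", "GuideGeneSet", function(x) length(x@geneId))

#' @rdname TFFamilyAnnotation-class
#' @export
setMethod("familyAssignments", "TFFamilyAnnotation",
          function(object) object@assignments)

#' @rdname TFFamilyAnnotation-class
#' @param x a \code{TFFamilyAnnotation}.
#' @export
setMethod("length", "TFFamilyAnnotation",
          function(x) length(x@assignments))

#' Look up the family of one or more genes
#'
#' @param object a [TFFamilyAnnotation-class].
#' @param geneIds character vector of gene ids.
#' @return character vector of family names, \code{NA} where unannotated.
#' @export
familyOf <- function(object, geneIds) {
    stopifnot(methods::is(object, "TFFamilyAnnotation"))
    unname(object@assignments[geneIds])
}

#' @rdname CorrelationTable-class
#' @export
setMethod("corValues", "CorrelationTable", function(object) object@r)

#' @rdname CorrelationTable-class
#' @export
setMethod("numSamples", "CorrelationTable", function(object) object@nSamples)

#' @rdname CorrelationTable-class
#' @export
setMethod("guideIds", "CorrelationTable",
          function(object) rownames(object@r))

#' @rdname CoexNetwork-class
#' @export
setMethod("networkNodes", "CoexNetwork", function(object) object@nodes)

#' @rdname CoexNetwork-class
#' @export
setMethod("networkEdges", "CoexNetwork", function(object) object@edges)

#' @rdname CoexNetwork-class
#' @export
setMethod("thresholdUsed", "CoexNetwork", function(object) object@threshold)

#' @rdname FamilyRanking-class
#' @export
setMethod("familyCounts", "FamilyRanking", function(object) object@ranking)

#' @rdname FamilyRanking-class
#' @export
setMethod("thresholdUsed", "FamilyRanking", function(object) object@threshold)

#' @rdname FamilyRanking-class
#' @export
setMethod("guideIds", "FamilyRanking", function(object) object@guideId)

#' @rdname SharedFamilyResult-class
#' @export
setMethod("sharedFamilies", "SharedFamilyResult",
          function(object) object@intersection)

#' @rdname SharedFamilyResult-class
#' @export
setMethod("vennCounts", "SharedFamilyResult",
          function(object) object@vennCounts)

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedTruth", "SyntheticTruth", function(object) object@truth)

## ---- show methods ----------------------------------------------------------

setMethod("show", "GuideGeneSet", function(object) {
    cat(sprintf("GuideGeneSet with %d guide gene(s)\n", length(object)))
    cat(paste0("  ", object@symbol, " (", object@geneId, ")\n"), sep = "")
})

setMethod("show", "TFFamilyAnnotation", function(object) {
    fam <- table(object@assignments)
    cat(sprintf("TFFamilyAnnotation: %d gene(s) in %d family/ies\n",
                length(object), length(fam)))
    if (length(fam)) {
        top <- sort(fam, decreasing = TRUE)
        top <- utils::head(top, 5L)
        cat(sprintf("  %s (%d)\n", names(top), as.integer(top)), sep = "")
    }
})

setMethod("show", "ThresholdSpec", function(object) {
    cat(sprintf("ThresholdSpec: %s %s %.3g (%s mode)\n",
                if (object@mode == "absolute") "|r|" else "r",
                if (object@strict) ">" else ">=",
                object@tau, object@mode))
})

setMethod("show", "CorrelationTable", function(object) {
    cat(sprintf(
        "CorrelationTable: %d guide(s) x %d gene(s) over %d samples (%d undefined)\n",
        nrow(object@r), ncol(object@r), object@nSamples, sum(is.na(object@r))))
})

setMethod("show", "FamilyRanking", function(object) {
    cat(sprintf("FamilyRanking for guide %s (%d family/ies):\n",
                object@guideId, nrow(object@ranking)))
    if (nrow(object@ranking))
        cat(sprintf("  %d. %s (%d)\n", seq_len(nrow(object@ranking)),
                    object@ranking$family, object@ranking$count), sep = "")
})

setMethod("show", "SharedFamilyResult", function(object) {
    cat(sprintf("SharedFamilyResult over %d guide(s)\n",
                length(object@perGuideTop)))
    cat("  intersection:",
        if (length(object@intersection))
            paste(object@intersection, collapse = ", ") else "(empty)", "\n")
})

setMethod("show", "CoexNetwork", function(object) {
    nd <- object@nodes
    cat(sprintf(
        "CoexNetwork: %d guide(s), %d TF(s), %d edge(s) (%d positive, %d negative)\n",
        sum(nd$type == "guide"), sum(nd$type == "tf"), nrow(object@edges),
        sum(object@edges$sign == "positive"),
        sum(object@edges$sign == "negative")))
    cat(sprintf("  threshold: tau=%.3g (%s, %s); TF family: %s\n",
                object@threshold@tau, object@threshold@mode,
                if (object@threshold@strict) "strict" else "non-strict",
                object@familyFilter))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d planted gene(s)\n", nrow(object@truth)))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d sections, %d anchor(s), %d planted, %d background (noiseSd=%.3g, seed=%d)\n",
        object@nSections, nrow(object@anchors), nrow(object@planted),
        object@nBackground, object@noiseSd, object@seed))
})

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    cat(sprintf("  matrix:   %s\n  guides:   %s\n  families: %s\n  outDir:   %s\n",
                object@matrixPath, object@guidesPath, object@familiesPath,
                object@outDir))
    cat(sprintf("  family screen: |r| %s %.3g; network: |r| %s %.3g; topK=%d\n",
                if (object@familyThreshold@strict) ">" else ">=",
                object@familyThreshold@tau,
                if (object@networkThreshold@strict) ">" else ">=",
                object@networkThreshold@tau, object@topK))
    cat(sprintf("  network family: %s; minNegativePartners=%d; log2: %s\n",
                object@networkFamily, object@minNegativePartners,
                object@logTransform))
})
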