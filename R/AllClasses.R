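#' @import methods
#' @importFrom stats cor rnorm runif sd setNames
#' @importFrom utils read.table write.table packageVersion head combn
#' @importFrom tools md5sum
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

#' Gradient expression matrix container
#'
#' An \code{ExpressionGradient} holds a genes-by-samples matrix of
#' nonnegative expression values (FPKM scale) over an ordered series of
#' samples, e.g. consecutive sections of a developing leaf from immature
#' base to mature tip.  It extends
#' \linkS4class{SummarizedExperiment} with a single assay named
#' \code{"exprs"}; the sample order of the columns is meaningful and is
#' preserved by all operations.
#'
#' Validity requires: unique, non-empty gene identifiers as rownames; at
#' least 3 samples (a Pearson coefficient over fewer points is not
#' informative); no missing and no negative values.
#'
#' @seealso [readExpressionMatrix()], [correlateGuides()]
#' @export
setClass("ExpressionGradient", contains = "SummarizedExperiment")

setValidity("ExpressionGradient", function(object) {
    if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'exprs' is required")
    m <- SummarizedExperiment::assay(object, "exprs")
    if (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == ""))
        return("gene identifiers (rownames) must be non-empty")
    if (anyDuplicated(rownames(m)))
        return(sprintf("duplicate gene id: %s",
                       rownames(m)[anyDuplicated(rownames(m))]))
    if (ncol(m) < 3L)
        return("at least 3 samples are required")
    if (anyNA(m))
        return("missing values are not allowed in the expression matrix")
    if (any(m < 0))
        return("negative expression values are not allowed")
    TRUE
})

#' Construct an ExpressionGradient from a matrix
#'
#' @param values numeric matrix, genes in rows, ordered samples in columns.
#' @param geneIds character vector of unique gene identifiers; defaults to
#'   \code{rownames(values)}.
#' @param sampleIds character vector of sample identifiers; defaults to
#'   \code{colnames(values)}.
#' @return a validated [ExpressionGradient-class] object.
#' @examples
#' m <- matrix(1:12, nrow = 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ExpressionGradient(m)
#' @export
ExpressionGradient <- function(values, geneIds = rownames(values),
                               sampleIds = colnames(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    rownames(values) <- geneIds
    colnames(values) <- sampleIds
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    methods::new("ExpressionGradient", se)
}

#' Ordered set of guide genes
#'
#' Guide genes are genes of known function (e.g. photoperiodic flowering-time
#' regulators) used as anchors to find co-expressed, putatively
#' co-functional genes.  Symbols need not be unique; gene identifiers must
#' be.
#'
#' @slot symbol character vector of gene symbols.
#' @slot geneId character vector of unique gene identifiers.
#' @export
setClass("GuideGeneSet",
         representation(symbol = "character", geneId = "character"))

setValidity("GuideGeneSet", function(object) {
    if (length(object@geneId) == 0L)
        return("guide set must be nonempty")
    if (length(object@symbol) != length(object@geneId))
        return("symbol and geneId must have equal length")
    if (anyDuplicated(object@geneId))
        return(sprintf("duplicate guide gene_id: %s",
                       object@geneId[anyDuplicated(object@geneId)]))
    if (anyNA(object@geneId) || any(object@geneId == ""))
        return("guide gene ids must be non-empty")
    TRUE
})

#' Construct a GuideGeneSet
#'
#' @param symbol character vector of gene symbols (need not be unique).
#' @param geneId character vector of unique gene identifiers, same length.
#' @return a [GuideGeneSet-class].
#' @examples
#' GuideGeneSet(c("Hd3a", "RFT1"), c("LOC_Os06g06320", "LOC_Os06g06300"))
#' @export
GuideGeneSet <- function(symbol, geneId) {
    methods::new("GuideGeneSet", symbol = as.character(symbol),
                 geneId = as.character(geneId))
}

#' Transcription-factor family annotation
#'
#' Maps each transcription-factor gene id to exactly one family name
#' (e.g. \code{"G2-like"}, \code{"MYB"}, \code{"bHLH"}).
#'
#' @slot assignments named character vector: names are gene ids, values are
#'   family names.
#' @export
setClass("TFFamilyAnnotation",
         representation(assignments = "character"))

setValidity("TFFamilyAnnotation", function(object) {
    a <- object@assignments
    if (length(a) > 0L) {
        if (is.null(names(a)) || any(names(a) == ""))
            return("assignments must be named by gene id")
        if (anyDuplicated(names(a)))
            return(sprintf("conflicting assignment: gene %s listed more than once",
                           names(a)[anyDuplicated(names(a))]))
        if (anyNA(a) || any(a == ""))
            return("family names must be non-empty")
    }
    TRUE
})

#' Construct a TFFamilyAnnotation
#'
#' @param assignments named character vector mapping gene id to family name.
#' @return a [TFFamilyAnnotation-class].
#' @examples
#' TFFamilyAnnotation(c(LOC_Os09g12750 = "G2-like"))
#' @export
TFFamilyAnnotation <- function(assignments = character()) {
    methods::new("TFFamilyAnnotation", assignments = assignments)
}

#' Correlation screening threshold
#'
#' Describes how a Pearson coefficient is compared against a cutoff
#' \code{tau}: in \code{"absolute"} mode \code{|r|} is compared, in
#' \code{"positive"}/\code{"negative"} mode only coefficients of that sign
#' pass.  \code{strict} selects \code{>} (the default, matching a
#' "greater than" reading) versus \code{>=}.
#'
#' @slot tau numeric cutoff in (0, 1].
#' @slot mode one of \code{"absolute"}, \code{"positive"}, \code{"negative"}.
#' @slot strict logical; strict inequality if \code{TRUE}.
#' @export
setClass("ThresholdSpec",
         representation(tau = "numeric", mode = "character",
                        strict = "logical"))

setValidity("ThresholdSpec", function(object) {
    if (length(object@tau) != 1L || is.na(object@tau) ||
        object@tau <= 0 || object@tau > 1)
        return("tau must be a single value in (0, 1]")
    if (length(object@mode) != 1L ||
        !object@mode %in% c("absolute", "positive", "negative"))
        return("mode must be one of 'absolute', 'positive', 'negative'")
    if (length(object@strict) != 1L || is.na(object@strict))
        return("strict must be TRUE or FALSE")
    TRUE
})

#' Construct a ThresholdSpec
#'
#' @param tau numeric cutoff in (0, 1].
#' @param mode comparison mode; see [ThresholdSpec-class].
#' @param strict logical, use strict inequality (default \code{TRUE}).
#' @return a [ThresholdSpec-class].
#' @examples
#' thresholdSpec(0.8)                      # the family-screening cutoff
#' thresholdSpec(0.6)                      # the network cutoff
#' thresholdSpec(0.8, mode = "negative")   # negative co-expression only
#' @export
thresholdSpec <- function(tau, mode = c("absolute", "positive", "negative"),
                          strict = TRUE) {
    mode <- match.arg(mode)
    methods::new("ThresholdSpec", tau = as.numeric(tau), mode = mode,
                 strict = strict)
}

#' Guide-by-gene Pearson correlation table
#'
#' Holds the sample Pearson coefficient between every guide gene and every
#' gene of the expression matrix (guides included as columns).  Pairs where
#' either profile has zero variance are mathematically undefined and stored
#' as \code{NA}; they never pass a threshold downstream.
#'
#' @slot r numeric matrix, guides in rows, genes in columns; defined entries
#'   lie in [-1, 1], undefined entries are \code{NA}.
#' @slot nSamples integer, number of samples the coefficients were computed
#'   over.
#' @export
setClass("CorrelationTable",
         representation(r = "matrix", nSamples = "integer"))

setValidity("CorrelationTable", function(object) {
    r <- object@r
    if (is.null(rownames(r)) || is.null(colnames(r)))
        return("r must have guide rownames and gene colnames")
    if (anyDuplicated(rownames(r)) || anyDuplicated(colnames(r)))
        return("guide and gene ids must be unique")
    fin <- r[!is.na(r)]
    if (length(fin) && (any(fin < -1 - 1e-12) || any(fin > 1 + 1e-12)))
        return("defined correlations must lie in [-1, 1]")
    if (length(object@nSamples) != 1L || object@nSamples < 3L)
        return("nSamples must be a single integer >= 3")
    TRUE
})

#' Per-guide transcription-factor family ranking
#'
#' Families of the annotated TFs passing the screening threshold for one
#' guide, ordered by member count descending with lexicographic tie-break.
#'
#' @slot guideId the guide gene id.
#' @slot ranking data.frame with columns \code{family}, \code{count}.
#' @slot threshold the [ThresholdSpec-class] used for the screen.
#' @slot nUnannotated number of co-expressed genes without a family
#'   assignment (ignored by the ranking).
#' @slot tieTruncated \code{TRUE} if a tie at the top-k boundary was cut.
#' @export
setClass("FamilyRanking",
         representation(guideId = "character", ranking = "data.frame",
                        threshold = "ThresholdSpec",
                        nUnannotated = "integer", tieTruncated = "logical"))

setValidity("FamilyRanking", function(object) {
    rk <- object@ranking
    if (!all(c("family", "count") %in% names(rk)))
        return("ranking must have columns 'family' and 'count'")
    if (nrow(rk)) {
        if (any(rk$count <= 0)) return("counts must be strictly positive")
        ord <- order(-rk$count, rk$family)
        if (!identical(ord, seq_len(nrow(rk))))
            return("ranking must be ordered by count desc, family asc")
    }
    TRUE
})

#' Top-family intersection (Venn) result
#'
#' @slot perGuideTop named list: guide id -> character vector of its top-k
#'   family names.
#' @slot intersection families present in every guide's top-k set.
#' @slot vennCounts data.frame with columns \code{region} (guide ids joined
#'   by \code{"&"}) and \code{count} (families exclusive to that region);
#'   one row per nonempty guide subset.
#' @export
setClass("SharedFamilyResult",
         representation(perGuideTop = "list", intersection = "character",
                        vennCounts = "data.frame"))

setValidity("SharedFamilyResult", function(object) {
    tops <- object@perGuideTop
    if (length(tops)) {
        inAll <- vapply(tops, function(s) all(object@intersection %in% s),
                        logical(1))
        if (!all(inAll))
            return("intersection must be contained in every top set")
        if (sum(object@vennCounts$count) !=
            length(unique(unlist(tops, use.names = FALSE))))
            return("venn region counts must sum to the size of the union")
    }
    TRUE
})

#' Sign-stratified bipartite co-expression network
#'
#' Edges connect guide genes to transcription factors whose correlation
#' passes the network threshold; every edge carries the coefficient and its
#' sign.  The network is bipartite: guide-guide and TF-TF edges are never
#' emitted.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}
#'   (\code{"guide"} or \code{"tf"}) and \code{family} (\code{NA} when
#'   unannotated).
#' @slot edges data.frame with columns \code{guide}, \code{tf}, \code{r},
#'   \code{sign} (\code{"positive"}/\code{"negative"}).
#' @slot threshold the [ThresholdSpec-class] the edges passed.
#' @slot familyFilter the family the TF pool was restricted to, or
#'   \code{"all"}.
#' @export
setClass("CoexNetwork",
         representation(nodes = "data.frame", edges = "data.frame",
                        threshold = "ThresholdSpec",
                        familyFilter = "character"))

setValidity("CoexNetwork", function(object) {
    nd <- object@nodes; ed <- object@edges
    if (!all(c("id", "type", "family") %in% names(nd)))
        return("nodes must have columns id, type, family")
    if (!all(c("guide", "tf", "r", "sign") %in% names(ed)))
        return("edges must have columns guide, tf, r, sign")
    if (anyDuplicated(nd$id)) return("duplicate node id")
    if (nrow(ed)) {
        if (!all(ed$guide %in% nd$id[nd$type == "guide"]))
            return("edge guide endpoint missing from nodes")
        if (!all(ed$tf %in% nd$id[nd$type == "tf"]))
            return("edge tf endpoint missing from nodes")
        if (anyDuplicated(paste(ed$guide, ed$tf, sep = "\r")))
            return("duplicate (guide, tf) edge")
        if (!all(ed$sign == ifelse(ed$r > 0, "positive", "negative")))
            return("edge sign inconsistent with r")
    }
    orphan <- setdiff(nd$id[nd$type == "tf"], ed$tf)
    if (length(orphan)) return("orphan TF node without edges")
    TRUE
})

#' Planted-correlation ground truth for a synthetic dataset
#'
#' @slot truth data.frame with one row per planted gene: \code{geneId},
#'   \code{anchorId}, \code{targetRho}, \code{family}, \code{realizedR}
#'   (the sample correlation actually realized against its anchor).
#' @export
setClass("SyntheticTruth", representation(truth = "data.frame"))

setValidity("SyntheticTruth", function(object) {
    need <- c("geneId", "anchorId", "targetRho", "family", "realizedR")
    if (!all(need %in% names(object@truth)))
        return(paste("truth must have columns:", paste(need, collapse = ", ")))
    if (anyNA(object@truth$realizedR))
        return("realizedR must be defined for all planted genes")
    TRUE
})

#' Synthetic gradient-transcriptome specification
#'
#' Describes a simulated developmental-gradient dataset: anchor (guide)
#' profiles over \code{nSections} ordered samples, genes planted at target
#' correlations to anchors, and a background of independent-noise genes.
#'
#' @slot nSections number of ordered samples (default 11, one per leaf
#'   section of the gradient design the generator emulates).
#' @slot anchors data.frame with columns \code{anchorId}, \code{kind}
#'   (\code{"increasing"}, \code{"decreasing"} or \code{"peaked"}),
#'   \code{amplitude}.
#' @slot planted data.frame with columns \code{geneId}, \code{anchorId},
#'   \code{targetRho} in [-1, 1], \code{family}.
#' @slot nBackground number of background genes.
#' @slot backgroundFamilies families cycled over the annotated part of the
#'   background (half the background stays unannotated).
#' @slot noiseSd standard deviation of the noise term on the standardized
#'   scale (1 preserves the target correlation in expectation).
#' @slot seed root random seed; per-gene substreams are derived from it by a
#'   stable hash of the gene id.
#' @export
setClass("SyntheticSpec",
         representation(nSections = "integer", anchors = "data.frame",
                        planted = "data.frame", nBackground = "integer",
                        backgroundFamilies = "character", noiseSd = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    if (object@nSections < 3L) return("nSections must be >= 3")
    if (!all(c("anchorId", "kind", "amplitude") %in% names(object@anchors)))
        return("anchors needs columns anchorId, kind, amplitude")
    if (!all(object@anchors$kind %in% c("increasing", "decreasing", "peaked")))
        return("unknown anchor profile kind")
    if (!all(c("geneId", "anchorId", "targetRho", "family") %in%
             names(object@planted)))
        return("planted needs columns geneId, anchorId, targetRho, family")
    if (nrow(object@planted)) {
        if (any(abs(object@planted$targetRho) > 1))
            return("|targetRho| must be <= 1")
        if (!all(object@planted$anchorId %in% object@anchors$anchorId))
            return("planted gene references unknown anchor")
    }
    ids <- c(object@anchors$anchorId, object@planted$geneId)
    if (anyDuplicated(ids))
        return(sprintf("duplicate gene id in spec: %s",
                       ids[anyDuplicated(ids)]))
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    TRUE
})

#' Pipeline configuration
#'
#' Bundles the input paths and the tunable parameters of the full analysis.
#' Defaults mirror the two-threshold screening design: family ranking at
#' \code{|r| > 0.8}, network at \code{|r| > 0.6}, top 5 families per guide.
#'
#' @slot matrixPath,guidesPath,familiesPath,outDir file paths.
#' @slot familyThreshold [ThresholdSpec-class] for the family screen.
#' @slot networkThreshold [ThresholdSpec-class] for the network.
#' @slot topK number of top families per guide.
#' @slot networkFamily family the network TF pool is restricted to
#'   (\code{"all"} for no restriction).
#' @slot minNegativePartners minimum negative edges to nominate a candidate.
#' @slot vennGuides \code{"all"}, or a character vector of guide symbols or
#'   ids to restrict the top-family intersection to (e.g.
#'   \code{c("OsGI", "Ghd7", "OsMADS14", "Hd3a")}).
#' @slot logTransform apply log2(x+1) before correlating.
#' @export
setClass("PipelineConfig",
         representation(matrixPath = "character", guidesPath = "character",
                        familiesPath = "character", outDir = "character",
                        familyThreshold = "ThresholdSpec",
                        networkThreshold = "ThresholdSpec",
                        topK = "integer", networkFamily = "character",
                        minNegativePartners = "integer",
                        vennGuides = "character", logTransform = "logical"))

setValidity("PipelineConfig", function(object) {
    if (object@topK < 1L) return("topK must be >= 1")
    if (object@minNegativePartners < 1L)
        return("minNegativePartners must be >= 1")
    if (length(object@vennGuides) == 0L || anyNA(object@vennGuides) ||
        any(object@vennGuides == ""))
        return("vennGuides must be 'all' or a nonempty set of guide names")
    TRUE
})
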