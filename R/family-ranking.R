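## Family-abundance ranking among strongly co-expressed TFs, and the
## top-family intersection across guides (the Venn step).

#' Rank TF families by abundance among a set of co-expressed genes
#'
#' Counts family members among the given genes and returns the \code{topK}
#' most abundant families, ordered by member count descending with
#' lexicographic tie-break on the family name.  Genes absent from the
#' annotation are ignored (their count is recorded in the result and
#' reported via \code{message()}).  When a tie straddles the \code{topK}
#' boundary the lexicographically first families are kept up to exactly
#' \code{topK} and the truncation is flagged — the rule is arbitrary but
#' deterministic, which reproducibility requires.
#'
#' @param coexpressed character vector of gene ids (e.g. the output of
#'   [filterByThreshold()]).
#' @param annotation a [TFFamilyAnnotation-class].
#' @param topK maximum number of families to return (default 5, the usual
#'   "top five most abundant families" summary).
#' @param guideId optional guide id recorded in the result.
#' @param threshold optional [ThresholdSpec-class] recorded in the result.
#' @return a [FamilyRanking-class].
#' @examples
#' ann <- TFFamilyAnnotation(c(t1 = "MYB", t2 = "MYB", t3 = "MYB",
#'                             t4 = "bHLH", t5 = "bHLH", t6 = "NAC"))
#' familyCounts(rankFamilies(paste0("t", 1:6), ann, topK = 2))
#' @export
rankFamilies <- function(coexpressed, annotation, topK = 5L,
                         guideId = NA_character_,
                         threshold = thresholdSpec(0.8)) {
    stopifnot(methods::is(annotation, "TFFamilyAnnotation"), topK >= 1L)
    coexpressed <- unique(as.character(coexpressed))
    fams <- familyOf(annotation, coexpressed)
    nUnannotated <- sum(is.na(fams))
    if (nUnannotated)
        message(nUnannotated, " co-expressed gene(s) lack a family ",
                "annotation and are ignored")
    fams <- fams[!is.na(fams)]
    if (!length(fams)) {
        return(methods::new("FamilyRanking", guideId = guideId,
                            ranking = data.frame(family = character(),
                                                 count = integer()),
                            threshold = threshold,
                            nUnannotated = as.integer(nUnannotated),
                            tieTruncated = FALSE))
    }
    tab <- table(fams)
    df <- data.frame(family = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$family), , drop = FALSE]
    rownames(df) <- NULL
    truncated <- FALSE
    if (nrow(df) > topK) {
        if (df$count[topK] == df$count[topK + 1L]) {
            truncated <- TRUE
            message("tie at the top-", topK, " boundary truncated ",
                    "lexicographically")
        }
        df <- df[seq_len(topK), , drop = FALSE]
    }
    methods::new("FamilyRanking", guideId = guideId, ranking = df,
                 threshold = threshold,
                 nUnannotated = as.integer(nUnannotated),
                 tieTruncated = truncated)
}

#' Intersect top-ranked families across guides
#'
#' Computes the families shared by every guide's top-k set, together with
#' the full Venn decomposition: for each nonempty subset of guides, the
#' number of families found in exactly those guides' top sets.  Region
#' counts therefore partition the union of all top sets.
#'
#' @param rankings a nonempty list of [FamilyRanking-class] objects (or,
#'   alternatively, a named list of character vectors of family names).
#' @return a [SharedFamilyResult-class].
#' @examples
#' ann <- TFFamilyAnnotation(c(a = "MYB", b = "MYB", c = "bHLH", d = "NAC"))
#' r1 <- rankFamilies(c("a", "c"), ann, topK = 2, guideId = "G1")
#' r2 <- rankFamilies(c("b", "d"), ann, topK = 2, guideId = "G2")
#' sharedFamilies(sharedTopFamilies(list(r1, r2)))  # "MYB"
#' @export
sharedTopFamilies <- function(rankings) {
    if (!length(rankings))
        stop("at least one ranking is required")
    if (methods::is(rankings[[1L]], "FamilyRanking")) {
        tops <- lapply(rankings, function(fr) fr@ranking$family)
        names(tops) <- vapply(rankings, function(fr) fr@guideId, character(1))
    } else {
        tops <- lapply(rankings, as.character)
    }
    if (is.null(names(tops)) || any(is.na(names(tops))) ||
        anyDuplicated(names(tops)))
        names(tops) <- paste0("guide", seq_along(tops))
    inter <- Reduce(intersect, tops)
    allFams <- sort(unique(unlist(tops, use.names = FALSE)))
    n <- length(tops)
    ## membership signature of each family -> venn region
    regions <- character(0)
    if (length(allFams)) {
        member <- vapply(tops, function(s) allFams %in% s,
                         logical(length(allFams)))
        member <- matrix(member, nrow = length(allFams),
                         dimnames = list(allFams, names(tops)))
        regions <- apply(member, 1L, function(row)
            paste(names(tops)[row], collapse = "&"))
    }
    ## enumerate all 2^n - 1 regions in a stable order (by subset size,
    ## then guide order), including empty ones
    subsets <- unlist(lapply(seq_len(n), function(k)
        utils::combn(names(tops), k, FUN = function(s)
            paste(s, collapse = "&"), simplify = FALSE)),
        use.names = FALSE)
    counts <- vapply(subsets, function(s) sum(regions == s), integer(1))
    venn <- data.frame(region = subsets, count = counts,
                       stringsAsFactors = FALSE)
    methods::new("SharedFamilyResult", perGuideTop = tops,
                 intersection = as.character(inter), vennCounts = venn)
}
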