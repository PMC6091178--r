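## Sign-stratified bipartite guide-TF network at the network threshold,
## per-TF sign classification, candidate selection, and Cytoscape-compatible
## exports (SIF, GraphML).

#' Build a guide-TF co-expression network
#'
#' Emits one edge per (guide, TF) pair whose defined correlation passes the
#' threshold.  The TF pool is the annotated genes of the requested family
#' (or all annotated genes for \code{family = "all"}); guide self-pairs are
#' excluded.  The network is bipartite by construction — guide-guide and
#' TF-TF relations are not represented.  TFs without a passing edge do not
#' appear as nodes.
#'
#' @param table a [CorrelationTable-class].
#' @param annotation a [TFFamilyAnnotation-class] defining the TF pool.
#' @param family a family name, or \code{"all"}; an unknown family is an
#'   error listing the available families.
#' @param spec the network [ThresholdSpec-class]
#'   (default \code{|r| > 0.6}, strict).
#' @return a [CoexNetwork-class].
#' @examples
#' r <- matrix(c(0.7, -0.65, 0.1, 0.3, -0.61, 0.2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("G1", "G2"), c("t1", "t2", "t3")))
#' ann <- TFFamilyAnnotation(c(t1 = "G2-like", t2 = "G2-like", t3 = "MYB"))
#' tab <- new("CorrelationTable", r = r, nSamples = 11L)
#' buildNetwork(tab, ann, family = "all", spec = thresholdSpec(0.6))
#' @export
buildNetwork <- function(table, annotation, family = "all",
                         spec = thresholdSpec(0.6)) {
    stopifnot(methods::is(table, "CorrelationTable"),
              methods::is(annotation, "TFFamilyAnnotation"),
              methods::is(spec, "ThresholdSpec"))
    if (!ncol(table@r))
        stop("correlation table is empty")
    assignments <- familyAssignments(annotation)
    if (!identical(family, "all")) {
        avail <- sort(unique(assignments))
        if (!family %in% assignments)
            stop("unknown family '", family, "'; available: ",
                 paste(avail, collapse = ", "))
        assignments <- assignments[assignments == family]
    }
    guides <- rownames(table@r)
    pool <- intersect(colnames(table@r), names(assignments))
    pool <- setdiff(pool, guides)
    edges <- list()
    for (g in guides) {
        hits <- filterByThreshold(table, spec, g)
        hits <- intersect(hits, pool)
        if (length(hits))
            edges[[g]] <- data.frame(
                guide = g, tf = hits, r = unname(table@r[g, hits]),
                stringsAsFactors = FALSE)
    }
    ed <- do.call(rbind, c(edges, list(
        data.frame(guide = character(), tf = character(), r = numeric()))))
    rownames(ed) <- NULL
    ed$sign <- ifelse(ed$r > 0, "positive", "negative")
    tfs <- sort(unique(ed$tf))
    nodes <- data.frame(
        id = c(guides, tfs),
        type = c(rep("guide", length(guides)), rep("tf", length(tfs))),
        family = c(unname(familyAssignments(annotation)[guides]),
                   unname(familyAssignments(annotation)[tfs])),
        stringsAsFactors = FALSE)
    methods::new("CoexNetwork", nodes = nodes, edges = ed, threshold = spec,
                 familyFilter = if (identical(family, "all")) "all" else family)
}

#' Classify TF nodes by the sign of their edges
#'
#' Each TF node is classified as \code{positive} or \code{negative} by the
#' majority sign of its edges; an exact tie is classified \code{mixed} and
#' reported via \code{message()}.  This turns the per-edge sign structure
#' into per-gene counts ("how many TFs are positively vs negatively
#' co-expressed with the guides").
#'
#' @param net a [CoexNetwork-class].
#' @return a list with \code{positive}, \code{negative}, \code{mixed}
#'   (integer counts) and \code{perTF}, a data.frame with columns
#'   \code{tf_id}, \code{n_positive}, \code{n_negative}, \code{class},
#'   ordered by \code{tf_id}.
#' @export
countEdgeSigns <- function(net) {
    stopifnot(methods::is(net, "CoexNetwork"))
    ed <- net@edges
    tfs <- sort(unique(ed$tf))
    if (!length(tfs)) {
        return(list(positive = 0L, negative = 0L, mixed = 0L,
                    perTF = data.frame(tf_id = character(),
                                       n_positive = integer(),
                                       n_negative = integer(),
                                       class = character())))
    }
    np <- vapply(tfs, function(t)
        sum(ed$tf == t & ed$sign == "positive"), integer(1))
    nn <- vapply(tfs, function(t)
        sum(ed$tf == t & ed$sign == "negative"), integer(1))
    cls <- ifelse(np > nn, "positive", ifelse(nn > np, "negative", "mixed"))
    if (any(cls == "mixed"))
        message(sum(cls == "mixed"),
                " TF(s) with tied edge signs classified as mixed")
    list(positive = sum(cls == "positive"),
         negative = sum(cls == "negative"),
         mixed = sum(cls == "mixed"),
         perTF = data.frame(tf_id = tfs, n_positive = unname(np),
                            n_negative = unname(nn), class = unname(cls),
                            stringsAsFactors = FALSE))
}

#' Select candidate negative regulators
#'
#' Nominates TFs negatively co-expressed with at least
#' \code{minNegativePartners} guide genes — under the guide-gene logic, a
#' TF anti-correlated with several flowering-promoting regulators is a
#' candidate repressor of the process.  Results are sorted by the number of
#' negative partners descending, then TF id.
#'
#' @param net a [CoexNetwork-class].
#' @param minNegativePartners minimum number of negative edges (default 2).
#' @return a data.frame with columns \code{tf_id}, \code{n_negative},
#'   \code{negative_partners}, \code{positive_partners} (semicolon-joined
#'   guide ids, each list sorted).
#' @export
selectNegativeCandidates <- function(net, minNegativePartners = 2L) {
    stopifnot(methods::is(net, "CoexNetwork"), minNegativePartners >= 1L)
    ed <- net@edges
    tfs <- sort(unique(ed$tf[ed$sign == "negative"]))
    rows <- lapply(tfs, function(t) {
        negs <- sort(ed$guide[ed$tf == t & ed$sign == "negative"])
        poss <- sort(ed$guide[ed$tf == t & ed$sign == "positive"])
        if (length(negs) < minNegativePartners) return(NULL)
        data.frame(tf_id = t, n_negative = length(negs),
                   negative_partners = paste(negs, collapse = ";"),
                   positive_partners = paste(poss, collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(
        data.frame(tf_id = character(), n_negative = integer(),
                   negative_partners = character(),
                   positive_partners = character()))))
    out <- out[order(-out$n_negative, out$tf_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Export a network in Cytoscape SIF format
#'
#' One line per edge: \code{guide_id<TAB>pos|neg<TAB>tf_id}, sorted by
#' (guide id, tf id); byte-for-byte deterministic.
#'
#' @param net a [CoexNetwork-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportSIF <- function(net, path) {
    stopifnot(methods::is(net, "CoexNetwork"))
    ed <- net@edges
    ed <- ed[order(ed$guide, ed$tf, method = "radix"), , drop = FALSE]
    con <- file(path, "wb")
    on.exit(close(con))
    if (nrow(ed))
        writeLines(paste(ed$guide,
                         ifelse(ed$sign == "positive", "pos", "neg"),
                         ed$tf, sep = "\t"),
                   con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

#' Read a SIF file back into an edge table
#'
#' Companion to [exportSIF()] for round-trip checks and interchange.
#'
#' @param path a SIF file written by [exportSIF()].
#' @return data.frame with columns \code{guide}, \code{tf}, \code{sign}.
#' @export
readSIF <- function(path) {
    if (!file.exists(path)) stop("SIF file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(data.frame(guide = character(), tf = character(),
                          sign = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L))
        stop("malformed SIF line")
    data.frame(guide = vapply(parts, `[[`, "", 1L),
               tf = vapply(parts, `[[`, "", 3L),
               sign = ifelse(vapply(parts, `[[`, "", 2L) == "pos",
                             "positive", "negative"),
               stringsAsFactors = FALSE)
}

#' Export a network as GraphML
#'
#' GraphML 1.0 with node attributes \code{type} (\code{guide}/\code{tf})
#' and \code{family}, and edge attributes \code{r} (6 decimal places) and
#' \code{sign}.  Element ordering is deterministic: guide nodes in network
#' order, TF nodes sorted by id, edges sorted by (guide id, tf id).
#'
#' @param net a [CoexNetwork-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
exportGraphML <- function(net, path) {
    stopifnot(methods::is(net, "CoexNetwork"))
    doc <- xml2::xml_new_root(
        "graphml",
        xmlns = "http://graphml.graphdrawing.org/xmlns")
    keys <- list(c("d_type", "node", "type"),
                 c("d_family", "node", "family"),
                 c("d_r", "edge", "r"),
                 c("d_sign", "edge", "sign"))
    for (k in keys)
        xml2::xml_add_child(doc, "key", id = k[1L], `for` = k[2L],
                            attr.name = k[3L], attr.type = "string")
    graph <- xml2::xml_add_child(doc, "graph", id = "coex",
                                 edgedefault = "undirected")
    nd <- net@nodes
    nd <- rbind(nd[nd$type == "guide", , drop = FALSE],
                nd[nd$type == "tf", , drop = FALSE][
                    order(nd$id[nd$type == "tf"], method = "radix"), ,
                    drop = FALSE])
    for (i in seq_len(nrow(nd))) {
        node <- xml2::xml_add_child(graph, "node", id = nd$id[i])
        xml2::xml_add_child(node, "data", nd$type[i], key = "d_type")
        xml2::xml_add_child(node, "data",
                            if (is.na(nd$family[i])) "" else nd$family[i],
                            key = "d_family")
    }
    ed <- net@edges
    ed <- ed[order(ed$guide, ed$tf, method = "radix"), , drop = FALSE]
    for (i in seq_len(nrow(ed))) {
        edge <- xml2::xml_add_child(graph, "edge",
                                    source = ed$guide[i], target = ed$tf[i])
        xml2::xml_add_child(edge, "data",
                            sprintf("%.6f", round(ed$r[i], 6L)), key = "d_r")
        xml2::xml_add_child(edge, "data", ed$sign[i], key = "d_sign")
    }
    xml2::write_xml(doc, path)
    invisible(path)
}
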