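## Synthetic gradient-transcriptome generator with planted correlation
## structure, plus recovery scoring.  A single root seed drives per-gene
## substreams derived by a stable hash of the gene id, so adding a gene to a
## spec never perturbs the profiles of the others.

## Deterministic 31-bit polynomial hash of an id string, mixed with the root
## seed.  Kept in double precision well below 2^53; result fits a 32-bit
## integer seed.
stableSeed <- function(seed, id) {
    h <- 0
    for (b in utf8ToInt(id)) h <- (h * 131 + b) %% 2147483647
    as.integer((h + (seed %% 2147483647) * 10007) %% 2147483647)
}

#' Generate an anchor expression profile over the gradient
#'
#' Produces a nonnegative, non-constant profile of the requested shape over
#' \code{nSections} ordered samples: \code{"increasing"} profiles are
#' strictly monotone increasing (expression accumulating towards the mature
#' end of the gradient), \code{"decreasing"} is exactly the reverse of the
#' \code{"increasing"} profile for the same arguments, and \code{"peaked"}
#' is unimodal with a single interior maximum.  A small seeded jitter
#' (bounded by a third of the deterministic step, so shape contracts are
#' preserved) keeps distinct anchors from being perfectly collinear.
#'
#' @param kind \code{"increasing"}, \code{"decreasing"} or \code{"peaked"}.
#' @param nSections number of ordered samples (>= 3).
#' @param amplitude approximate dynamic range of the profile (FPKM scale).
#' @param seed integer seed for the jitter.
#' @return numeric vector of length \code{nSections}.
#' @examples
#' generateAnchorProfile("increasing", 11, 50, seed = 1)
#' @export
generateAnchorProfile <- function(kind, nSections, amplitude, seed = 1L) {
    if (nSections < 3L) stop("nSections must be >= 3")
    if (amplitude <= 0) stop("amplitude must be positive")
    if (kind == "decreasing")
        return(rev(generateAnchorProfile("increasing", nSections, amplitude,
                                         seed)))
    n <- nSections
    if (kind == "increasing") {
        base <- seq(amplitude * 0.05, amplitude, length.out = n)
        step <- base[2L] - base[1L]
    } else if (kind == "peaked") {
        peak <- 1L + ((seed %% (n - 2L)) + 1L)  # interior index in 2..(n-1)
        base <- amplitude * (1 - abs(seq_len(n) - peak) / n)
        step <- amplitude / n
    } else {
        stop("invalid profile kind: ", kind)
    }
    set.seed(stableSeed(seed, paste0("profile:", n, ":", amplitude)))
    base + stats::runif(n, 0, step / 3)
}

#' Plant a gene at a target correlation to an anchor
#'
#' Returns \code{y = shift(rho * z + sqrt(1 - rho^2) * noiseSd * eps)}
#' where \code{z} is the sample-standardized anchor, \code{eps} is
#' independent standard Gaussian noise, and \code{shift} subtracts the
#' minimum so all values are nonnegative (a location shift, which leaves
#' the correlation unchanged).  With \code{noiseSd = 1} the population
#' correlation with the anchor equals \code{targetRho} exactly; at
#' \code{|targetRho| = 1} the noise term vanishes and the sample
#' correlation is exactly \code{sign(targetRho)}.
#'
#' @param anchor numeric, non-constant anchor profile.
#' @param targetRho target correlation in [-1, 1].
#' @param noiseSd standard deviation multiplier of the noise term
#'   (default 1, which preserves the target in expectation).
#' @param seed integer seed for the noise draw.
#' @return numeric vector, same length as \code{anchor}.
#' @examples
#' a <- generateAnchorProfile("increasing", 11, 50)
#' y <- plantCorrelatedGene(a, 1)
#' pearsonCorrelation(a, y)  # exactly 1
#' @export
plantCorrelatedGene <- function(anchor, targetRho, noiseSd = 1, seed = 1L) {
    if (abs(targetRho) > 1) stop("|targetRho| must be <= 1")
    if (noiseSd < 0) stop("noiseSd must be nonnegative")
    if (sd(anchor) == 0) stop("anchor profile is constant")
    if (targetRho == 0 && noiseSd == 0)
        stop("degenerate plant: targetRho = 0 with noiseSd = 0")
    z <- (anchor - mean(anchor)) / sd(anchor)
    if (abs(targetRho) == 1) {
        y <- targetRho * z
    } else {
        set.seed(seed)
        eps <- stats::rnorm(length(anchor))
        y <- targetRho * z + sqrt(1 - targetRho^2) * noiseSd * eps
    }
    y - min(y)
}

#' Construct a SyntheticSpec
#'
#' @param anchors data.frame with columns \code{anchorId}, \code{kind},
#'   \code{amplitude}.
#' @param planted data.frame with columns \code{geneId}, \code{anchorId},
#'   \code{targetRho}, \code{family}.
#' @param nSections number of ordered samples (default 11, the gradient
#'   design the generator emulates).
#' @param nBackground number of background noise genes.
#' @param backgroundFamilies family names cycled over the background genes
#'   (empty for an unannotated background).
#' @param noiseSd noise standard deviation on the standardized scale.
#' @param seed root seed.
#' @return a [SyntheticSpec-class].
#' @seealso [defaultSyntheticSpec()] for the standard simulation design.
#' @export
syntheticSpec <- function(anchors, planted, nSections = 11L,
                          nBackground = 0L, backgroundFamilies = character(),
                          noiseSd = 1, seed = 1L) {
    methods::new("SyntheticSpec",
                 nSections = as.integer(nSections),
                 anchors = as.data.frame(anchors),
                 planted = as.data.frame(planted),
                 nBackground = as.integer(nBackground),
                 backgroundFamilies = as.character(backgroundFamilies),
                 noiseSd = as.numeric(noiseSd),
                 seed = as.integer(seed))
}

#' The default synthetic study design
#'
#' Emulates the structure of the motivating guide-gene screen: 8 anchor
#' (guide) genes over 11 gradient sections with mixed monotone and peaked
#' shapes, one dominant planted family ("G2-like") contributing a strong
#' positive (rho = 0.95) and a strong negative (rho = -0.95) partner per
#' anchor, a weaker "MYB" partner (rho = 0.7) per anchor, and 200
#' background genes of independent unit-variance noise spread over six
#' decoy families.
#'
#' @param seed root seed.
#' @return a [SyntheticSpec-class].
#' @examples
#' defaultSyntheticSpec(seed = 7)
#' @export
defaultSyntheticSpec <- function(seed = 1L) {
    kinds <- rep(c("increasing", "decreasing", "peaked"), length.out = 8L)
    anchors <- data.frame(
        anchorId = sprintf("anchor%02d", 1:8),
        kind = kinds,
        amplitude = rep(c(50, 80, 120, 60), length.out = 8L),
        stringsAsFactors = FALSE)
    planted <- do.call(rbind, lapply(1:8, function(i) {
        data.frame(
            geneId = sprintf("planted%02d_%s", i, c("pos", "neg", "weak")),
            anchorId = anchors$anchorId[i],
            targetRho = c(0.95, -0.95, 0.7),
            family = c("G2-like", "G2-like", "MYB"),
            stringsAsFactors = FALSE)
    }))
    syntheticSpec(anchors, planted, nSections = 11L, nBackground = 200L,
                  backgroundFamilies = c("AP2", "bHLH", "bZIP", "MYB",
                                         "NAC", "WRKY"),
                  noiseSd = 1, seed = seed)
}

#' Generate a complete synthetic dataset
#'
#' Realizes a [SyntheticSpec-class] into the objects the pipeline consumes:
#' an [ExpressionGradient-class] containing anchor, planted and background
#' genes; the anchors as a [GuideGeneSet-class]; a
#' [TFFamilyAnnotation-class] covering planted and background genes; and a
#' [SyntheticTruth-class] recording, for every planted gene, its anchor,
#' target correlation, family and the sample correlation actually realized.
#' The same spec (including seed) always yields bit-identical output.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a list with elements \code{matrix}, \code{guides},
#'   \code{families}, \code{truth} and \code{backgroundIds}.
#' @examples
#' ds <- generateDataset(defaultSyntheticSpec(seed = 7))
#' dim(ds$matrix)
#' @export
generateDataset <- function(spec) {
    stopifnot(methods::is(spec, "SyntheticSpec"))
    methods::validObject(spec)
    n <- spec@nSections
    profiles <- list()
    for (i in seq_len(nrow(spec@anchors))) {
        a <- spec@anchors[i, ]
        profiles[[a$anchorId]] <- generateAnchorProfile(
            a$kind, n, a$amplitude, seed = stableSeed(spec@seed, a$anchorId))
    }
    plantedRows <- list()
    realized <- numeric(nrow(spec@planted))
    for (i in seq_len(nrow(spec@planted))) {
        p <- spec@planted[i, ]
        y <- plantCorrelatedGene(profiles[[p$anchorId]], p$targetRho,
                                 noiseSd = spec@noiseSd,
                                 seed = stableSeed(spec@seed, p$geneId))
        plantedRows[[p$geneId]] <- y
        realized[i] <- pearsonCorrelation(profiles[[p$anchorId]], y)
    }
    bgIds <- if (spec@nBackground > 0L)
        sprintf("background%04d", seq_len(spec@nBackground)) else character()
    bgRows <- lapply(bgIds, function(id) {
        set.seed(stableSeed(spec@seed, id))
        x <- stats::rnorm(n) * max(spec@noiseSd, .Machine$double.eps)
        x - min(x)
    })
    names(bgRows) <- bgIds
    allRows <- c(profiles, plantedRows, bgRows)
    m <- do.call(rbind, allRows)
    rownames(m) <- names(allRows)
    colnames(m) <- sprintf("section_%02d", seq_len(n))
    guides <- GuideGeneSet(symbol = spec@anchors$anchorId,
                           geneId = spec@anchors$anchorId)
    fam <- spec@planted$family
    names(fam) <- spec@planted$geneId
    if (length(bgIds) && length(spec@backgroundFamilies)) {
        bgFam <- rep(spec@backgroundFamilies, length.out = length(bgIds))
        names(bgFam) <- bgIds
        fam <- c(fam, bgFam)
    }
    truth <- methods::new("SyntheticTruth", truth = data.frame(
        geneId = spec@planted$geneId,
        anchorId = spec@planted$anchorId,
        targetRho = spec@planted$targetRho,
        family = spec@planted$family,
        realizedR = realized,
        stringsAsFactors = FALSE))
    list(matrix = ExpressionGradient(m),
         guides = guides,
         families = TFFamilyAnnotation(fam),
         truth = truth,
         backgroundIds = bgIds)
}

#' Write a synthetic dataset as pipeline input files
#'
#' Emits \code{matrix.tsv}, \code{guides.tsv} and \code{families.tsv} in
#' exactly the formats the readers accept, plus \code{truth.tsv} with the
#' planted ground truth.
#'
#' @param dataset list as returned by [generateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the four paths.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(matrix = file.path(dir, "matrix.tsv"),
               guides = file.path(dir, "guides.tsv"),
               families = file.path(dir, "families.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeExpressionMatrix(dataset$matrix, paths[["matrix"]])
    writeTsvNoHeader(data.frame(guideSymbols(dataset$guides),
                                guideIds(dataset$guides)), paths[["guides"]])
    a <- familyAssignments(dataset$families)
    writeTsvNoHeader(data.frame(names(a), unname(a)), paths[["families"]])
    writeTsv(plantedTruth(dataset$truth), paths[["truth"]])
    invisible(paths)
}

writeTsvNoHeader <- function(df, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (nrow(df))
        writeLines(enc2utf8(do.call(paste, c(lapply(df, as.character),
                                             sep = "\t"))),
                   con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

#' Score recovery of planted structure from a network
#'
#' Compares a [CoexNetwork-class] built from a synthetic dataset against
#' the dataset's [SyntheticTruth-class].  Sensitivity is the fraction of
#' planted genes whose \code{|targetRho|} passes the network threshold that
#' appear in the network; it is \code{NA} (not applicable) when no planted
#' gene passes.  Sign accuracy is the fraction of recovered planted genes
#' whose edge sign to their own anchor (falling back to the majority sign
#' over all their edges) matches \code{sign(targetRho)}.  Specificity is
#' the fraction of background genes absent from the network.
#'
#' @param truth a [SyntheticTruth-class].
#' @param net a [CoexNetwork-class] built from the same dataset.
#' @param backgroundIds character vector of background gene ids (from
#'   [generateDataset()]).
#' @return list with numeric elements \code{sensitivity},
#'   \code{specificity}, \code{signAccuracy} (each possibly \code{NA} when
#'   not applicable).
#' @export
scoreRecovery <- function(truth, net, backgroundIds = character()) {
    stopifnot(methods::is(truth, "SyntheticTruth"),
              methods::is(net, "CoexNetwork"))
    tt <- plantedTruth(truth)
    spec <- net@threshold
    tau <- spec@tau
    passes <- if (spec@strict) abs(tt$targetRho) > tau
              else abs(tt$targetRho) >= tau
    ed <- net@edges
    inNet <- tt$geneId %in% ed$tf
    sensitivity <- if (any(passes)) mean(inNet[passes]) else NA_real_
    recovered <- which(inNet)
    signAccuracy <- if (length(recovered)) {
        ok <- vapply(recovered, function(i) {
            own <- ed$sign[ed$tf == tt$geneId[i] & ed$guide == tt$anchorId[i]]
            s <- if (length(own)) own[1L] else {
                signs <- ed$sign[ed$tf == tt$geneId[i]]
                if (sum(signs == "positive") > sum(signs == "negative"))
                    "positive"
                else if (sum(signs == "negative") > sum(signs == "positive"))
                    "negative"
                else "mixed"
            }
            s == ifelse(tt$targetRho[i] > 0, "positive", "negative")
        }, logical(1))
        mean(ok)
    } else NA_real_
    specificity <- if (length(backgroundIds))
        mean(!backgroundIds %in% ed$tf) else NA_real_
    list(sensitivity = sensitivity, specificity = specificity,
         signAccuracy = signAccuracy)
}
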