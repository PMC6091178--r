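## Orchestration: correlate -> rank families -> intersect -> network ->
## candidates -> export, from a single declarative YAML config, with a
## machine-readable run manifest.  Outputs are staged in a temporary
## directory and moved into place only on success, so a failed run leaves
## no partial outputs.

configKeys <- c("matrix", "guides", "families", "out_dir",
                "family_tau", "network_tau", "strict", "top_k",
                "network_family", "min_negative_partners", "venn_guides",
                "log_transform")

#' Construct a pipeline configuration
#'
#' Defaults mirror the two-threshold screening design: TF-family ranking
#' from genes at \code{|r| > 0.8}, network edges at \code{|r| > 0.6}, both
#' strict; top 5 families per guide; network restricted to the
#' \code{"G2-like"} family; candidates need at least 2 negative guide
#' partners (the weakest reading of "negatively co-expressed with many
#' regulators" — raise it for stricter shortlists).
#'
#' @param matrixPath,guidesPath,familiesPath input file paths.
#' @param outDir output directory (created if needed).
#' @param familyTau cutoff for the family-ranking screen (default 0.8).
#' @param networkTau cutoff for the network (default 0.6).
#' @param strict use strict inequality for both thresholds (default TRUE).
#' @param topK families kept per guide (default 5).
#' @param networkFamily family restriction for the network, or
#'   \code{"all"}.
#' @param minNegativePartners candidate cutoff (default 2).
#' @param vennGuides \code{"all"} or a character vector of guide symbols or
#'   ids to restrict the top-family intersection to.
#' @param logTransform apply log2(x+1) before correlating (default FALSE).
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(matrixPath, guidesPath, familiesPath, outDir,
                           familyTau = 0.8, networkTau = 0.6, strict = TRUE,
                           topK = 5L, networkFamily = "G2-like",
                           minNegativePartners = 2L, vennGuides = "all",
                           logTransform = FALSE) {
    methods::new("PipelineConfig",
                 matrixPath = matrixPath, guidesPath = guidesPath,
                 familiesPath = familiesPath, outDir = outDir,
                 familyThreshold = thresholdSpec(familyTau, strict = strict),
                 networkThreshold = thresholdSpec(networkTau, strict = strict),
                 topK = as.integer(topK),
                 networkFamily = networkFamily,
                 minNegativePartners = as.integer(minNegativePartners),
                 vennGuides = as.character(vennGuides),
                 logTransform = logTransform)
}

#' Read and validate a pipeline configuration file
#'
#' The config is a flat YAML mapping.  Recognized keys: \code{matrix},
#' \code{guides}, \code{families}, \code{out_dir} (required paths), and the
#' optional parameters \code{family_tau}, \code{network_tau},
#' \code{strict}, \code{top_k}, \code{network_family},
#' \code{min_negative_partners}, \code{venn_guides},
#' \code{log_transform}, with the defaults of [pipelineConfig()].  Unknown
#' keys are an error naming the key, so typos never silently fall back to a
#' default.
#'
#' @param path path to the YAML config file.
#' @return a validated [PipelineConfig-class].
#' @export
validateConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    if (!is.list(raw)) stop("config must be a YAML mapping")
    unknown <- setdiff(names(raw), configKeys)
    if (length(unknown))
        stop("unknown config key: ", paste(unknown, collapse = ", "))
    required <- c("matrix", "guides", "families", "out_dir")
    miss <- setdiff(required, names(raw))
    if (length(miss))
        stop("missing required config key: ", paste(miss, collapse = ", "))
    getOr <- function(key, default)
        if (key %in% names(raw)) raw[[key]] else default
    pipelineConfig(
        matrixPath = raw$matrix, guidesPath = raw$guides,
        familiesPath = raw$families, outDir = raw$out_dir,
        familyTau = getOr("family_tau", 0.8),
        networkTau = getOr("network_tau", 0.6),
        strict = getOr("strict", TRUE),
        topK = getOr("top_k", 5L),
        networkFamily = getOr("network_family", "G2-like"),
        minNegativePartners = getOr("min_negative_partners", 2L),
        vennGuides = getOr("venn_guides", "all"),
        logTransform = getOr("log_transform", FALSE))
}

withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full guide-gene co-expression pipeline
#'
#' Executes every stage on the configured inputs and writes to the output
#' directory: \code{correlations.tsv}, \code{family_rankings.tsv},
#' \code{venn.tsv}, \code{network.sif}, \code{network.graphml},
#' \code{candidates.tsv} and \code{manifest.json}.  Any stage error aborts
#' with a stage-labeled message and leaves no partial outputs (files are
#' staged in a temporary directory and moved on success).  Identical
#' inputs and config produce identical analysis outputs; the manifest
#' additionally records a timestamp.
#'
#' @param config a [PipelineConfig-class].
#' @param quiet suppress progress messages on standard error.
#' @return invisibly, the run manifest as a named list (config echo, input
#'   checksums, per-stage counts, package version, timestamp).
#' @export
runPipeline <- function(config, quiet = FALSE) {
    stopifnot(methods::is(config, "PipelineConfig"))
    methods::validObject(config)
    note <- function(...) if (!quiet) message(...)
    withStage <- if (quiet) {
        function(stage, expr) suppressMessages(
            tryCatch(expr, error = function(e)
                stop("[stage: ", stage, "] ", conditionMessage(e),
                     call. = FALSE)))
    } else withStage
    stage <- file.path(tempfile("guidecoex_stage"))
    dir.create(stage, recursive = TRUE)
    on.exit(unlink(stage, recursive = TRUE), add = TRUE)

    note("reading inputs")
    mat <- withStage("read expression matrix",
                     readExpressionMatrix(config@matrixPath))
    guides <- withStage("read guide list", readGuideList(config@guidesPath))
    ann <- withStage("read family table",
                     readFamilyTable(config@familiesPath))

    note("correlating ", length(guides), " guides against ",
         nrow(mat), " genes")
    tab <- withStage("correlate guides",
                     correlateGuides(mat, guides,
                                     logTransform = config@logTransform))
    withStage("write correlations",
              writeCorrelationTable(tab, file.path(stage,
                                                   "correlations.tsv")))
    zeroVar <- sum(apply(is.na(corValues(tab)), 2L, all))

    note("ranking TF families per guide (|r| screen at tau=",
         config@familyThreshold@tau, ")")
    screenHits <- withStage("family screen",
        lapply(stats::setNames(guideIds(guides), guideIds(guides)),
               function(g) filterByThreshold(tab, config@familyThreshold, g)))
    rankings <- withStage("rank families", lapply(guideIds(guides),
        function(g) rankFamilies(screenHits[[g]], ann, topK = config@topK,
                                 guideId = g,
                                 threshold = config@familyThreshold)))
    withStage("write family rankings",
              writeFamilyRankings(rankings,
                                  file.path(stage, "family_rankings.tsv")))

    vennSel <- seq_along(rankings)
    if (!identical(config@vennGuides, "all")) {
        keep <- guideSymbols(guides) %in% config@vennGuides |
            guideIds(guides) %in% config@vennGuides
        if (!any(keep))
            stop("[stage: intersect families] no guide matches venn_guides",
                 call. = FALSE)
        vennSel <- which(keep)
    }
    shared <- withStage("intersect families",
                        sharedTopFamilies(rankings[vennSel]))
    withStage("write venn table",
              writeVennTable(shared, file.path(stage, "venn.tsv")))

    note("building network (family=", config@networkFamily, ", tau=",
         config@networkThreshold@tau, ")")
    net <- withStage("build network",
                     buildNetwork(tab, ann, family = config@networkFamily,
                                  spec = config@networkThreshold))
    signs <- withStage("count edge signs", countEdgeSigns(net))
    cands <- withStage("select candidates",
                       selectNegativeCandidates(
                           net, config@minNegativePartners))
    withStage("export network", {
        exportSIF(net, file.path(stage, "network.sif"))
        exportGraphML(net, file.path(stage, "network.graphml"))
    })
    withStage("write candidates",
              writeCandidateReport(cands, file.path(stage,
                                                    "candidates.tsv")))

    manifest <- list(
        config = list(
            matrix = config@matrixPath, guides = config@guidesPath,
            families = config@familiesPath, out_dir = config@outDir,
            family_tau = config@familyThreshold@tau,
            network_tau = config@networkThreshold@tau,
            strict = config@familyThreshold@strict,
            top_k = config@topK,
            network_family = config@networkFamily,
            min_negative_partners = config@minNegativePartners,
            venn_guides = config@vennGuides,
            log_transform = config@logTransform),
        input_md5 = as.list(tools::md5sum(c(config@matrixPath,
                                            config@guidesPath,
                                            config@familiesPath))),
        counts = list(
            genes_read = nrow(mat),
            samples = ncol(mat),
            guides = length(guides),
            zero_variance_genes = zeroVar,
            genes_passing_family_screen = lapply(screenHits, length),
            shared_families = sharedFamilies(shared),
            network_nodes = nrow(networkNodes(net)),
            network_tf_nodes = sum(networkNodes(net)$type == "tf"),
            network_edges = nrow(networkEdges(net)),
            tf_positive = signs$positive,
            tf_negative = signs$negative,
            tf_mixed = signs$mixed,
            candidates = nrow(cands)),
        version = as.character(utils::packageVersion("guideCoex")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
    for (f in list.files(stage))
        file.copy(file.path(stage, f), file.path(config@outDir, f),
                  overwrite = TRUE)
    note("done: ", nrow(networkEdges(net)), " edges, ", nrow(cands),
         " candidate(s); outputs in ", config@outDir)
    invisible(manifest)
}
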