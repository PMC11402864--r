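## End-to-end pipeline: parse release -> high-confidence filter -> five
## evidence channels -> merged associations -> bipartite network.

#' Run configuration
#'
#' Validated bundle of the tunable thresholds. Defaults reproduce the
#' headline settings: hit-call threshold 0.9, open burst interval (-3, 3),
#' high-relevance filter at Level 5 with coverage at least 0.4.
#'
#' @param hitcThreshold inclusive winning-model hit-call threshold.
#' @param burstBounds open interval of burst Z-scores, default `c(-3, 3)`.
#' @param minLevel inclusive relevance-level filter threshold (1..5).
#' @param minCoverage inclusive coverage filter threshold in \[0, 1\].
#' @param woeRule cumulative weight-of-evidence rule (see
#'   [cumulativeWoe()]).
#' @param pathEdges `"all"` or `"adjacent"` KERs for path checks.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(hitcThreshold = 0.9, burstBounds = c(-3, 3),
                      minLevel = 5L, minCoverage = 0.4,
                      woeRule = c("mean", "min", "majority"),
                      pathEdges = c("all", "adjacent")) {
    woeRule <- match.arg(woeRule)
    pathEdges <- match.arg(pathEdges)
    if (hitcThreshold < 0 || hitcThreshold > 1)
        stop("hitcThreshold must be in [0, 1]")
    if (length(burstBounds) != 2L || burstBounds[1] >= burstBounds[2])
        stop("burstBounds must be an increasing pair")
    if (!(minLevel %in% 1:5)) stop("minLevel must be in 1..5")
    if (minCoverage < 0 || minCoverage > 1)
        stop("minCoverage must be in [0, 1]")
    cfg <- list(hitcThreshold = hitcThreshold, burstBounds = burstBounds,
                minLevel = as.integer(minLevel),
                minCoverage = minCoverage, woeRule = woeRule,
                pathEdges = pathEdges)
    class(cfg) <- "runConfig"
    cfg
}

.WORLD_FILES <- c(
    aopwiki_xml = "aopwiki.xml", toxcast_hits = "toxcast_hits.csv",
    cytotox = "cytotox.csv", assay_annotations = "assay_annotations.tsv",
    endpoint_genes = "endpoint_genes.tsv", ke_genes = "ke_genes.tsv",
    endpoint_ke_whitelist = "endpoint_ke_whitelist.tsv",
    ctd_cg = "ctd_cg.tsv", ctd_cp = "ctd_cp.tsv", ctd_cd = "ctd_cd.tsv",
    ctd_gd = "ctd_gd.tsv", go_obo = "go.obo",
    phenotype_whitelist = "phenotype_whitelist.tsv",
    disease_ke_map = "disease_ke_map.tsv", deduct = "deduct.tsv",
    deduct_ke_map = "deduct_ke_map.tsv", neurotoxkb = "neurotoxkb.tsv",
    neurotoxkb_ke_map = "neurotoxkb_ke_map.tsv",
    cas_synonyms = "cas_synonyms.tsv",
    stressor_names = "stressor_names.tsv", sectors = "sectors.tsv",
    disease_classes = "disease_classes.tsv")

#' Resolve pipeline input paths
#'
#' Accepts a [SyntheticWorld-class], a directory laid out with the standard
#' file names, or a named list of paths.
#'
#' @param x world, directory or named list.
#' @return named list of file paths.
#' @export
resolveInputs <- function(x) {
    if (is(x, "SyntheticWorld")) return(worldPaths(x))
    if (is.character(x) && length(x) == 1L && dir.exists(x)) {
        p <- as.list(file.path(x, .WORLD_FILES))
        names(p) <- names(.WORLD_FILES)
        return(p)
    }
    if (is.list(x)) return(x)
    stop("cannot resolve pipeline inputs from ", class(x)[1])
}

#' Run the full association-and-network pipeline
#'
#' Parses the release, applies the high-confidence filter, derives
#' chemical-KE associations from all five evidence channels (with CAS
#' canonicalization applied to every chemical column first), merges them
#' and builds the bipartite stressor-AOP network.
#'
#' @param inputs a [SyntheticWorld-class], input directory or named path
#'   list (see [resolveInputs()]).
#' @param config a [runConfig()].
#' @param overrides optional manual-curation override table (see
#'   [filterHighConfidence()]).
#' @return list with elements `aopset`, `accepted`, `rejections`,
#'   `associations`, `discardedBursts`, `network`, `counters`.
#' @examples
#' w <- generateWorld(worldConfig(seed = 7, n_aops = 8), tempfile())
#' res <- suppressWarnings(suppressMessages(runPipeline(w)))
#' res$network
#' @export
runPipeline <- function(inputs, config = runConfig(), overrides = NULL) {
    stopifnot(inherits(config, "runConfig"))
    p <- resolveInputs(inputs)
    miss <- vapply(p, function(f) !file.exists(f), logical(1))
    if (any(miss))
        stop("missing input file(s): ",
             paste(unlist(p[miss]), collapse = ", "))

    syn <- readTsv(p$cas_synonyms)
    nrm <- function(df, col = "chemical") .normalize_col(df, col, syn)

    aopset <- parseAopWikiXml(p$aopwiki_xml)
    fh <- filterHighConfidence(aopset, overrides = overrides,
                               pathEdges = config$pathEdges)

    hits <- nrm(utils::read.csv(p$toxcast_hits, stringsAsFactors = FALSE,
                                colClasses = c(chemical = "character")))
    cytotox <- nrm(utils::read.csv(p$cytotox, stringsAsFactors = FALSE,
                                   colClasses = c(chemical = "character")))
    ke <- keyEvents(aopset)
    tox <- toxcastChannel(
        hits, cytotox,
        endpointGenes = readTsv(p$endpoint_genes),
        keGenes = readTsv(p$ke_genes),
        whitelist = readTsv(p$endpoint_ke_whitelist),
        keLevels = ke[, c("ke_id", "biological_level")],
        hitcThreshold = config$hitcThreshold,
        burstBounds = config$burstBounds)

    tetramers <- buildCgpdTetramers(
        nrm(readTsv(p$ctd_cg)), nrm(readTsv(p$ctd_cp)),
        nrm(readTsv(p$ctd_cd)), readTsv(p$ctd_gd))
    keProc <- do.call(rbind, lapply(seq_len(nrow(ke)), function(i) {
        pr <- ke$process_ids[[i]]
        if (!length(pr)) return(NULL)
        data.frame(ke_id = ke$ke_id[i], process_id = pr,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(keProc))
        keProc <- data.frame(ke_id = character(0),
                             process_id = character(0),
                             stringsAsFactors = FALSE)
    goNb <- if (nrow(tetramers)) expandGoNeighbors(
        unique(tetramers$phenotype), parseObo(p$go_obo)) else list()
    ctd <- mapCtdToKes(tetramers, goNb, keProc,
                       phenotypeWhitelist = readTsv(p$phenotype_whitelist),
                       diseaseKeMap = readTsv(p$disease_ke_map))

    ded <- mapCuratedEndpoints(nrm(readTsv(p$deduct)),
                               readTsv(p$deduct_ke_map), "deduct")
    ntx <- mapCuratedEndpoints(nrm(readTsv(p$neurotoxkb)),
                               readTsv(p$neurotoxkb_ke_map), "neurotoxkb")
    stressorMap <- nrm(readTsv(p$stressor_names))
    swk <- aopwikiStressorChannel(aopset, stressorMap)

    merged <- mergeChannels(list(tox$associations, ctd, ded, ntx, swk))
    network <- buildNetwork(merged, fh$accepted,
                            sectorTable = readTsv(p$sectors),
                            diseaseMap = readTsv(p$disease_classes),
                            pathEdges = config$pathEdges)
    counters <- c(
        aops_parsed = nrow(aops(aopset)),
        aops_accepted = nrow(aops(fh$accepted)),
        aops_rejected = nrow(fh$rejections),
        hits_read = nrow(hits),
        bursts_discarded = nrow(tox$discardedBursts),
        tetramers = nrow(tetramers),
        associations = nrow(merged),
        association_pairs = nrow(associationPairs(merged)),
        links = nrow(links(network)),
        deduct_unmapped = attr(ded, "unmapped"),
        neurotoxkb_unmapped = attr(ntx, "unmapped"),
        stressor_unresolved = attr(swk, "unresolved"))
    list(aopset = aopset, accepted = fh$accepted,
         rejections = fh$rejections, associations = merged,
         discardedBursts = tox$discardedBursts, network = network,
         counters = counters)
}

#' Load a curated high-confidence release from plain tables
#'
#' Rebuilds an [AopSet-class] from exported definition tables of a curated
#' release: an AOP table (AOP id, its KE/MIE/AO membership and KER list), a
#' KE table and a KER table. Intended for reproducing published networks
#' from supplementary material; accepts TSV/CSV (and XLSX sheets when the
#' readxl package is available). Multi-valued cells use `;` separators.
#'
#' @param aopTable path or data.frame with columns `aop_id`, `ke_ids`,
#'   `mie_ids`, `ao_ids`, `ker_ids`.
#' @param keTable path or data.frame with columns `ke_id` and optional
#'   `title`, `biological_level`.
#' @param kerTable path or data.frame with `ker_id`, `upstream_ke`,
#'   `downstream_ke` and optional `adjacency`, `woe`.
#' @return an [AopSet-class].
#' @export
loadCuratedRelease <- function(aopTable, keTable, kerTable) {
    rd <- function(x) {
        if (is.data.frame(x)) return(x)
        ext <- tolower(tools::file_ext(x))
        if (ext == "xlsx") {
            if (!requireNamespace("readxl", quietly = TRUE))
                stop("reading xlsx requires the readxl package")
            as.data.frame(readxl::read_excel(x))
        } else if (ext == "csv") {
            utils::read.csv(x, stringsAsFactors = FALSE)
        } else readTsv(x)
    }
    ap <- rd(aopTable); ke <- rd(keTable); kr <- rd(kerTable)
    splitcol <- function(x) strsplit(ifelse(is.na(x) | x == "", "", x),
                                     ";", fixed = TRUE)
    ap2 <- data.frame(aop_id = ap$aop_id, stringsAsFactors = FALSE)
    if (!is.null(ap$title)) ap2$title <- ap$title
    ap2$ke_ids <- splitcol(ap$ke_ids)
    ap2$mie_ids <- splitcol(ap$mie_ids)
    ap2$ao_ids <- splitcol(ap$ao_ids)
    ap2$ker_ids <- splitcol(ap$ker_ids)
    makeAopSet(ap2, ke, kr)
}

#' Load a chemical-KE association table from a plain file
#'
#' Expects at least `chemical` and `ke_id` columns; missing `channel`,
#' `direction`, `evidence` columns are filled with `"unspecified"`/empty.
#'
#' @param path TSV/CSV (or XLSX sheet if readxl is available).
#' @return association data.frame.
#' @export
loadAssociationTable <- function(path) {
    ext <- tolower(tools::file_ext(path))
    df <- if (ext == "xlsx") {
        if (!requireNamespace("readxl", quietly = TRUE))
            stop("reading xlsx requires the readxl package")
        as.data.frame(readxl::read_excel(path))
    } else if (ext == "csv") {
        utils::read.csv(path, stringsAsFactors = FALSE)
    } else readTsv(path)
    if (!all(c("chemical", "ke_id") %in% names(df)))
        stop("association table needs chemical and ke_id columns")
    if (is.null(df$channel)) df$channel <- "unspecified"
    if (is.null(df$direction)) df$direction <- "unspecified"
    if (is.null(df$evidence)) df$evidence <- ""
    df[, c("chemical", "ke_id", "channel", "direction", "evidence")]
}
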