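#' @import methods
NULL

#' Typed view of an AOP-Wiki release
#'
#' An `AopSet` holds the parsed content of an AOP-Wiki project-download XML
#' file (or a synthetic release in the same dialect): one row per adverse
#' outcome pathway (AOP), one row per key event (KE) and one row per key
#' event relationship (KER), together with any quarantined dangling
#' references.
#'
#' @slot aops `data.frame` with columns `aop_id`, `title`, `saaop_status`,
#'   `oecd_status` and list-columns `ke_ids`, `mie_ids`, `ao_ids`, `ker_ids`,
#'   `stressor_names`, `applicability`. Roles (MIE/AO) are defined per AOP:
#'   the same KE may be an MIE in one AOP and an intermediate event in
#'   another.
#' @slot keyEvents `data.frame` with columns `ke_id`, `title`,
#'   `biological_level`, `action`, `object_name` and list-columns
#'   `object_ids`, `process_ids`.
#' @slot relationships `data.frame` with columns `ker_id`, `upstream_ke`,
#'   `downstream_ke`, `adjacency`, `woe`, `quantitative_understanding`.
#'   Direction is upstream to downstream.
#' @slot quarantined `data.frame` of dangling references found during
#'   parsing (columns `context`, `ref_type`, `ref_id`); these are recorded,
#'   not silently dropped.
#'
#' @seealso [parseAopWikiXml()], [filterHighConfidence()], [makeAopSet()]
#' @export
setClass("AopSet", representation(
    aops = "data.frame",
    keyEvents = "data.frame",
    relationships = "data.frame",
    quarantined = "data.frame"
))

.BIO_LEVELS <- c("molecular", "cellular", "tissue", "organ", "individual",
                 "population", "unspecified")
.ADJACENCY <- c("adjacent", "non-adjacent", "unspecified")
.WOE <- c("High", "Moderate", "Low", "unspecified")
.REJECTION_REASONS <- c("archived", "unknown_ke_title", "no_kes", "no_kers",
                        "disconnected", "no_mie", "no_ao", "no_mie_ao_path",
                        "override")
.CHANNELS <- c("toxcast", "ctd_phenotype", "ctd_disease", "deduct",
               "neurotoxkb", "aopwiki_stressor")

setValidity("AopSet", function(object) {
    msg <- character(0)
    ke <- object@keyEvents
    if (anyDuplicated(ke$ke_id))
        msg <- c(msg, "duplicated ke_id in keyEvents")
    bad <- setdiff(unique(ke$biological_level), .BIO_LEVELS)
    if (length(bad))
        msg <- c(msg, paste0("invalid biological_level: ",
                             paste(bad, collapse = ", ")))
    kr <- object@relationships
    if (nrow(kr)) {
        if (any(kr$upstream_ke == kr$downstream_ke))
            msg <- c(msg, "KER with identical upstream and downstream KE")
        miss <- setdiff(unique(c(kr$upstream_ke, kr$downstream_ke)), ke$ke_id)
        if (length(miss))
            msg <- c(msg, paste0("KER endpoints missing from keyEvents: ",
                                 paste(miss, collapse = ", ")))
    }
    ap <- object@aops
    if (nrow(ap)) {
        if (anyDuplicated(ap$aop_id))
            msg <- c(msg, "duplicated aop_id")
        for (i in seq_len(nrow(ap))) {
            kes <- ap$ke_ids[[i]]
            if (!all(ap$mie_ids[[i]] %in% kes) || !all(ap$ao_ids[[i]] %in% kes))
                msg <- c(msg, paste0(ap$aop_id[i],
                                     ": MIE/AO ids not a subset of ke_ids"))
            if (!all(kes %in% ke$ke_id))
                msg <- c(msg, paste0(ap$aop_id[i],
                                     ": ke_ids missing from keyEvents"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Bipartite stressor-AOP network
#'
#' Links chemicals (stressors) to AOPs that share at least one associated
#' key event. Each link carries the set of shared KEs, a coverage score in
#' (0, 1] (fraction of the AOP's KEs associated with the chemical) and a
#' relevance level in 1..5.
#'
#' @slot links `data.frame` with columns `chemical`, `aop_id`, `n_shared`,
#'   `coverage`, `level` and list-column `shared_kes`, sorted by
#'   (`chemical`, `aop_id`).
#' @slot chemicalAnnotations `data.frame` (`chemical`, `sector`), restricted
#'   to chemicals present in `links`.
#' @slot aopAnnotations `data.frame` (`aop_id`, `disease_class`), one row per
#'   AOP present in `links`; unmapped AOPs are labelled `"unclassified"`.
#' @slot metadata `list` of run counters (e.g. sector-annotated chemicals
#'   without any association).
#'
#' @seealso [buildNetwork()], [filterLinks()], [summarizeNetwork()]
#' @export
setClass("StressorAopNetwork", representation(
    links = "data.frame",
    chemicalAnnotations = "data.frame",
    aopAnnotations = "data.frame",
    metadata = "list"
))

setValidity("StressorAopNetwork", function(object) {
    lk <- object@links
    msg <- character(0)
    if (nrow(lk)) {
        if (any(lk$n_shared < 1)) msg <- c(msg, "link with empty shared KE set")
        if (any(lk$coverage <= 0 | lk$coverage > 1))
            msg <- c(msg, "coverage outside (0, 1]")
        if (!all(lk$level %in% 1:5)) msg <- c(msg, "level outside 1..5")
        if (anyDuplicated(paste(lk$chemical, lk$aop_id)))
            msg <- c(msg, "duplicated (chemical, aop_id) link")
    }
    if (length(msg)) msg else TRUE
})

#' Seeded synthetic pipeline world
#'
#' Holds the on-disk input tables produced by [generateWorld()] together
#' with the ground-truth manifest of planted rejections, cytotoxicity
#' bursts and stressor-AOP links, against which end-to-end pipeline runs
#' are checked.
#'
#' @slot dir directory the world was written to.
#' @slot paths named list of file paths (XML release, assay tables, CTD-like
#'   tables, curated maps, ontology, manifest).
#' @slot manifest list with elements `rejections`, `bursts`, `links`
#'   (data.frames of planted truth).
#' @slot config the [worldConfig()] list used for generation.
#'
#' @seealso [generateWorld()], [runPipeline()]
#' @export
setClass("SyntheticWorld", representation(
    dir = "character",
    paths = "list",
    manifest = "list",
    config = "list"
))
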