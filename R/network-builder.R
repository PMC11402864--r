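## Bipartite stressor-AOP network: coverage scores, five-level relevance
## classification, sector/disease annotation, filtering and summaries.

#' Coverage score of a stressor-AOP link
#'
#' Fraction of the AOP's KEs that are associated with the chemical:
#' `|associated KEs of the AOP| / |KEs of the AOP|`, a value in (0, 1] for
#' any emitted link. A coverage threshold of 0.4 means at least 40% of the
#' AOP's KEs are linked with the stressor.
#'
#' @param assocKes character vector, the chemical's associated KE ids.
#' @param aopKes character vector, the AOP's full KE set (nonempty).
#' @return numeric scalar in \[0, 1\].
#' @export
coverageScore <- function(assocKes, aopKes) {
    if (!length(aopKes)) stop("AOP has an empty KE set")
    length(intersect(unique(assocKes), unique(aopKes))) /
        length(unique(aopKes))
}

#' Five-level relevance of a stressor-AOP link
#'
#' Evaluated top-down, mutually exclusive, so every link receives exactly
#' one level:
#' \itemize{
#'   \item Level 5: at least one associated MIE and one associated AO, with
#'     a directed path from some associated MIE to some associated AO over
#'     the AOP's KERs;
#'   \item Level 4: associated MIE and AO, but no such path;
#'   \item Level 3: at least one associated MIE, no associated AO;
#'   \item Level 2: at least one associated AO, no associated MIE;
#'   \item Level 1: only intermediate KEs (neither MIE nor AO) associated.
#' }
#' The path may traverse unassociated KEs; only its endpoints must be
#' associated.
#'
#' @param assocKes associated KE ids of the chemical within this AOP.
#' @param mieIds,aoIds the AOP's MIE and AO sets.
#' @param kers data.frame of the AOP's KERs (`upstream_ke`,
#'   `downstream_ke`).
#' @return integer level in 1..5.
#' @export
classifyLevel <- function(assocKes, mieIds, aoIds, kers) {
    if (!length(assocKes)) stop("classifyLevel requires >= 1 shared KE")
    am <- intersect(assocKes, mieIds)
    aa <- intersect(assocKes, aoIds)
    if (length(am) && length(aa)) {
        if (hasMieAoPath(am, aa, kers)) 5L else 4L
    } else if (length(am)) 3L
    else if (length(aa)) 2L
    else 1L
}

#' Build the bipartite stressor-AOP network
#'
#' Links every chemical to every accepted AOP sharing at least one
#' associated KE; each link carries its shared-KE set, coverage score and
#' relevance level. Chemicals without any association to an accepted AOP
#' (and AOPs without any link) are absent from the network; sector-annotated
#' chemicals without associations are counted in `metadata`.
#'
#' @param associations association data.frame (canonical CAS).
#' @param aopset accepted [AopSet-class] (post high-confidence filter).
#' @param sectorTable optional data.frame (`sector`, `chemical`).
#' @param diseaseMap optional data.frame (`aop_id`, `disease_class`); AOPs
#'   not covered get `"unclassified"`.
#' @param pathEdges passed to the level-5 path check (`"all"` or
#'   `"adjacent"`).
#' @return a [StressorAopNetwork-class].
#' @export
buildNetwork <- function(associations, aopset, sectorTable = NULL,
                         diseaseMap = NULL, pathEdges = "all") {
    stopifnot(is(aopset, "AopSet"))
    ap <- aops(aopset); kr <- relationships(aopset)
    pairs <- associationPairs(associations)
    recs <- list()
    for (i in seq_len(nrow(ap))) {
        kes <- ap$ke_ids[[i]]
        if (!length(kes)) stop(ap$aop_id[i], " has an empty KE set")
        sub <- pairs[pairs$ke_id %in% kes, , drop = FALSE]
        if (!nrow(sub)) next
        edges <- .aop_edges(ap[i, , drop = FALSE], kr, pathEdges = pathEdges)
        for (chem in unique(sub$chemical)) {
            shared <- sort(unique(sub$ke_id[sub$chemical == chem]))
            recs[[length(recs) + 1L]] <- data.frame(
                chemical = chem, aop_id = ap$aop_id[i],
                n_shared = length(shared),
                coverage = length(shared) / length(kes),
                level = classifyLevel(shared, ap$mie_ids[[i]],
                                      ap$ao_ids[[i]], edges),
                shared = paste(shared, collapse = ";"),
                stringsAsFactors = FALSE)
        }
    }
    lk <- if (length(recs)) do.call(rbind, recs) else
        data.frame(chemical = character(0), aop_id = character(0),
                   n_shared = integer(0), coverage = numeric(0),
                   level = integer(0), shared = character(0),
                   stringsAsFactors = FALSE)
    lk <- lk[order(lk$chemical, lk$aop_id), , drop = FALSE]
    lk$shared_kes <- strsplit(lk$shared, ";", fixed = TRUE)
    lk$shared <- NULL
    rownames(lk) <- NULL

    meta <- list()
    chemAnn <- data.frame(chemical = character(0), sector = character(0),
                          stringsAsFactors = FALSE)
    if (!is.null(sectorTable) && nrow(sectorTable)) {
        inNet <- sectorTable$chemical %in% lk$chemical
        meta$sector_chemicals_without_links <-
            length(unique(sectorTable$chemical[!inNet]))
        chemAnn <- unique(sectorTable[inNet, c("chemical", "sector"),
                                      drop = FALSE])
        chemAnn <- chemAnn[order(chemAnn$chemical, chemAnn$sector), ,
                           drop = FALSE]
        rownames(chemAnn) <- NULL
    }
    aopsIn <- sort(unique(lk$aop_id))
    aopAnn <- data.frame(aop_id = aopsIn,
                         disease_class = rep("unclassified",
                                             length(aopsIn)),
                         stringsAsFactors = FALSE)
    if (!is.null(diseaseMap) && nrow(diseaseMap)) {
        idx <- match(aopAnn$aop_id, diseaseMap$aop_id)
        hit <- !is.na(idx)
        aopAnn$disease_class[hit] <- diseaseMap$disease_class[idx[hit]]
    }
    new("StressorAopNetwork", links = lk, chemicalAnnotations = chemAnn,
        aopAnnotations = aopAnn, metadata = meta)
}

#' Filter stressor-AOP links by relevance level and coverage
#'
#' Both thresholds are inclusive ("at least"): a link is kept iff
#' `level >= minLevel` and `coverage >= minCoverage`. Annotations are
#' restricted to the surviving chemicals/AOPs. Filtering is idempotent.
#'
#' @param network a [StressorAopNetwork-class].
#' @param minLevel integer in 1..5 (default 5).
#' @param minCoverage numeric in \[0, 1\] (default 0.4).
#' @return a filtered [StressorAopNetwork-class].
#' @export
filterLinks <- function(network, minLevel = 5, minCoverage = 0.4) {
    stopifnot(is(network, "StressorAopNetwork"))
    if (!(minLevel %in% 1:5)) stop("minLevel must be in 1..5")
    if (minCoverage < 0 || minCoverage > 1)
        stop("minCoverage must be in [0, 1]")
    lk <- network@links
    lk <- lk[lk$level >= minLevel & lk$coverage >= minCoverage, ,
             drop = FALSE]
    rownames(lk) <- NULL
    ca <- network@chemicalAnnotations
    ca <- ca[ca$chemical %in% lk$chemical, , drop = FALSE]
    rownames(ca) <- NULL
    aa <- network@aopAnnotations
    aa <- aa[aa$aop_id %in% lk$aop_id, , drop = FALSE]
    rownames(aa) <- NULL
    new("StressorAopNetwork", links = lk, chemicalAnnotations = ca,
        aopAnnotations = aa, metadata = network@metadata)
}

#' Summarize a stressor-AOP network
#'
#' Counts of links, distinct chemicals and distinct AOPs, grouped by
#' relevance level (all five levels always reported, zeros included), by
#' priority use sector, or by disease class.
#'
#' @param network a [StressorAopNetwork-class].
#' @param by one of `"level"`, `"sector"`, `"disease"`.
#' @return data.frame with columns `group`, `n_links`, `n_chemicals`,
#'   `n_aops`.
#' @export
summarizeNetwork <- function(network, by = c("level", "sector", "disease")) {
    by <- match.arg(by)
    lk <- network@links
    tally <- function(groups, sub_fun) {
        do.call(rbind, lapply(groups, function(g) {
            s <- sub_fun(g)
            data.frame(group = as.character(g), n_links = nrow(s),
                       n_chemicals = length(unique(s$chemical)),
                       n_aops = length(unique(s$aop_id)),
                       stringsAsFactors = FALSE)
        }))
    }
    out <- switch(by,
        level = tally(1:5, function(g)
            lk[lk$level == g, , drop = FALSE]),
        sector = {
            ca <- network@chemicalAnnotations
            groups <- sort(unique(ca$sector))
            tally(groups, function(g)
                lk[lk$chemical %in% ca$chemical[ca$sector == g], ,
                   drop = FALSE])
        },
        disease = {
            aa <- network@aopAnnotations
            groups <- sort(unique(aa$disease_class))
            tally(groups, function(g)
                lk[lk$aop_id %in% aa$aop_id[aa$disease_class == g], ,
                   drop = FALSE])
        })
    if (is.null(out))
        out <- data.frame(group = character(0), n_links = integer(0),
                          n_chemicals = integer(0), n_aops = integer(0),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Restrict a network to the chemicals of one priority use sector
#'
#' @param network a [StressorAopNetwork-class].
#' @param sector sector name as used in the sector table.
#' @return a [StressorAopNetwork-class] containing only links whose chemical
#'   is annotated to `sector`.
#' @export
sectorSubnetwork <- function(network, sector) {
    ca <- network@chemicalAnnotations
    chems <- unique(ca$chemical[ca$sector == sector])
    lk <- network@links
    lk <- lk[lk$chemical %in% chems, , drop = FALSE]
    rownames(lk) <- NULL
    aa <- network@aopAnnotations
    aa <- aa[aa$aop_id %in% lk$aop_id, , drop = FALSE]
    rownames(aa) <- NULL
    new("StressorAopNetwork", links = lk,
        chemicalAnnotations = ca[ca$chemical %in% chems, , drop = FALSE],
        aopAnnotations = aa, metadata = network@metadata)
}
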