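## Five evidence channels linking chemicals (CAS) to key events:
## high-throughput assay hit calls (ToxCast-like), CTD-like CGPD-tetramers
## (phenotype and disease routes), two curated endpoint resources, and
## AOP-Wiki stressor records.

.empty_assoc <- function() {
    data.frame(chemical = character(0), ke_id = character(0),
               channel = character(0), direction = character(0),
               evidence = character(0), stringsAsFactors = FALSE)
}

.assoc <- function(chemical, ke_id, channel, direction = "unspecified",
                   evidence = "") {
    if (!length(chemical)) return(.empty_assoc())
    df <- data.frame(chemical = chemical, ke_id = ke_id, channel = channel,
                     direction = direction, evidence = evidence,
                     stringsAsFactors = FALSE)
    df <- unique(df)
    df[order(df$chemical, df$ke_id, df$channel, df$evidence), , drop = FALSE]
}

#' Canonicalize CAS registry numbers through a synonym map
#'
#' Old identifiers are resolved transitively through the old-to-new synonym
#' map (a chain A->B, B->C resolves A to C). Identifiers absent from the map
#' pass through unchanged. A cyclic synonym chain is an error.
#'
#' @param chemicals character vector of CAS identifiers.
#' @param synonymMap data.frame with columns `old`, `new`.
#' @param collapse if `TRUE` (default) duplicates after mapping are removed.
#' @return character vector of canonical CAS identifiers.
#' @export
normalizeCas <- function(chemicals, synonymMap, collapse = TRUE) {
    if (is.null(synonymMap) || !nrow(synonymMap)) {
        out <- chemicals
    } else {
        map <- stats::setNames(as.character(synonymMap$new),
                               as.character(synonymMap$old))
        resolve <- function(x) {
            seen <- character(0)
            while (x %in% names(map)) {
                if (x %in% seen)
                    stop("cyclic CAS synonym chain: ",
                         paste(c(seen, x), collapse = " -> "))
                seen <- c(seen, x)
                x <- map[[x]]
            }
            x
        }
        out <- vapply(as.character(chemicals), resolve, character(1),
                      USE.NAMES = FALSE)
    }
    if (collapse) unique(out) else out
}

.normalize_col <- function(df, col, synonymMap) {
    if (nrow(df))
        df[[col]] <- normalizeCas(df[[col]], synonymMap, collapse = FALSE)
    df
}

#' Filter active assay hit calls and assign response direction
#'
#' Keeps records with winning-model hit call `hitc >= threshold` (inclusive)
#' and labels the response `activatory` when the winning model's `top`
#' parameter is positive, `inhibitory` when negative, `unspecified` when
#' zero or missing (missing `top` on an active hit warns).
#'
#' @param hits data.frame with columns `chemical`, `endpoint_id`, `hitc`,
#'   `top` and (for downstream burst filtering) `neg_log_ac50`.
#' @param hitcThreshold inclusive activity threshold, default 0.9.
#' @return the active subset of `hits` with a `direction` column added.
#' @export
toxcastActive <- function(hits, hitcThreshold = 0.9) {
    stopifnot(hitcThreshold >= 0, hitcThreshold <= 1)
    act <- hits[!is.na(hits$hitc) & hits$hitc >= hitcThreshold, ,
                drop = FALSE]
    if (any(is.na(act$top)))
        warning(sum(is.na(act$top)),
                " active hit(s) lack a winning-model top value; ",
                "direction set to unspecified")
    act$direction <- ifelse(is.na(act$top), "unspecified",
                     ifelse(act$top > 0, "activatory",
                     ifelse(act$top < 0, "inhibitory", "unspecified")))
    rownames(act) <- NULL
    act
}

#' Cytotoxicity-burst Z-score
#'
#' For each hit, `z = (neg_log_ac50 - cytotox_median_log) / global_mad`,
#' where `cytotox_median_log` is the chemical's median -log10 AC50 across
#' cytotoxicity assays and `global_mad` is the global cytotoxicity MAD
#' shared by all chemicals. A hit is a cytotoxicity-associated burst when
#' its Z-score lies strictly between the burst bounds (default -3 and +3);
#' z equal to a bound is kept as target-specific activity.
#'
#' @param negLogAc50 numeric vector, -log10 AC50 of the hit.
#' @param cytotoxMedianLog numeric vector (recycled), the chemical's
#'   cytotoxicity median; `NA` means the chemical has no cytotoxicity
#'   profile, in which case the hit is kept (`burst = FALSE`) with a
#'   warning and `z = NA`.
#' @param globalMad positive scalar, the global cytotoxicity MAD.
#' @param bounds length-2 numeric, the open burst interval, default
#'   `c(-3, 3)`.
#' @return data.frame with columns `z`, `burst`.
#' @export
cytotoxBurstZ <- function(negLogAc50, cytotoxMedianLog, globalMad,
                          bounds = c(-3, 3)) {
    if (!is.numeric(globalMad) || length(globalMad) != 1L ||
        is.na(globalMad) || globalMad <= 0)
        stop("globalMad must be a positive scalar")
    stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
    z <- (negLogAc50 - cytotoxMedianLog) / globalMad
    noprof <- is.na(cytotoxMedianLog)
    if (any(noprof))
        warning(sum(noprof), " hit(s) from chemicals without a ",
                "cytotoxicity profile; kept (burst = FALSE)")
    burst <- !is.na(z) & z > bounds[1] & z < bounds[2]
    data.frame(z = z, burst = burst)
}

#' Candidate endpoint-to-KE mappings by gene overlap
#'
#' A candidate `(endpoint, KE)` pair exists iff the endpoint's gene set and
#' the KE's annotated gene set intersect (case-insensitive on symbols).
#' Candidates are then restricted to a curated whitelist, the reproducible
#' stand-in for manual filtering on assay-endpoint descriptions. Only KEs at
#' the molecular or cellular level of biological organization are eligible;
#' pass `keLevels` to enforce this.
#'
#' @param endpointGenes data.frame (`endpoint_id`, `gene`).
#' @param keGenes data.frame (`ke_id`, `gene`).
#' @param whitelist data.frame (`endpoint_id`, `ke_id`) of curated retained
#'   pairs, or `NULL`/empty to retain all candidates (with a prominent
#'   warning).
#' @param keLevels optional data.frame (`ke_id`, `biological_level`);
#'   KEs outside molecular/cellular are removed before matching.
#' @return data.frame (`endpoint_id`, `ke_id`) of retained pairs.
#' @export
mapEndpointsToKes <- function(endpointGenes, keGenes, whitelist = NULL,
                              keLevels = NULL) {
    if (!is.null(keLevels)) {
        ok <- keLevels$ke_id[keLevels$biological_level %in%
                             c("molecular", "cellular")]
        keGenes <- keGenes[keGenes$ke_id %in% ok, , drop = FALSE]
    }
    if (!nrow(endpointGenes) || !nrow(keGenes))
        return(data.frame(endpoint_id = character(0), ke_id = character(0),
                          stringsAsFactors = FALSE))
    eg <- unique(data.frame(endpoint_id = endpointGenes$endpoint_id,
                            gene = toupper(endpointGenes$gene),
                            stringsAsFactors = FALSE))
    kg <- unique(data.frame(ke_id = keGenes$ke_id,
                            gene = toupper(keGenes$gene),
                            stringsAsFactors = FALSE))
    cand <- unique(merge(eg, kg, by = "gene")[, c("endpoint_id", "ke_id")])
    if (is.null(whitelist) || !nrow(whitelist)) {
        warning("empty endpoint-KE whitelist: retaining ALL ", nrow(cand),
                " gene-overlap candidates (no manual-curation stand-in)")
    } else {
        cand <- merge(cand, unique(whitelist[, c("endpoint_id", "ke_id")]),
                      by = c("endpoint_id", "ke_id"))
    }
    cand <- cand[order(cand$endpoint_id, cand$ke_id), , drop = FALSE]
    rownames(cand) <- NULL
    cand
}

#' Full assay-evidence channel
#'
#' Chains hit-call filtering, cytotoxicity-burst exclusion and gene-overlap
#' endpoint-to-KE mapping into `(chemical, KE)` associations with channel
#' `"toxcast"`. Burst endpoints are excluded from KE mapping; the discarded
#' `(chemical, endpoint)` pairs are returned for auditing.
#'
#' @param hits data.frame (`chemical`, `endpoint_id`, `hitc`, `top`,
#'   `neg_log_ac50`).
#' @param cytotox data.frame (`chemical`, `cytotox_median_log`,
#'   `global_mad`); `global_mad` must be a single shared value.
#' @param endpointGenes,keGenes,whitelist,keLevels see
#'   [mapEndpointsToKes()].
#' @param hitcThreshold,burstBounds see [toxcastActive()],
#'   [cytotoxBurstZ()].
#' @return list with `associations` (data.frame chemical, ke_id, channel,
#'   direction, evidence) and `discardedBursts` (data.frame chemical,
#'   endpoint_id, z).
#' @export
toxcastChannel <- function(hits, cytotox, endpointGenes, keGenes,
                           whitelist = NULL, keLevels = NULL,
                           hitcThreshold = 0.9, burstBounds = c(-3, 3)) {
    act <- toxcastActive(hits, hitcThreshold)
    if (!nrow(act))
        return(list(associations = .empty_assoc(),
                    discardedBursts = data.frame(
                        chemical = character(0), endpoint_id = character(0),
                        z = numeric(0), stringsAsFactors = FALSE)))
    gmad <- unique(stats::na.omit(cytotox$global_mad))
    if (length(gmad) != 1L)
        stop("global_mad must be one shared value; found ", length(gmad))
    med <- cytotox$cytotox_median_log[match(act$chemical, cytotox$chemical)]
    zb <- cytotoxBurstZ(act$neg_log_ac50, med, gmad, bounds = burstBounds)
    discarded <- data.frame(chemical = act$chemical[zb$burst],
                            endpoint_id = act$endpoint_id[zb$burst],
                            z = zb$z[zb$burst], stringsAsFactors = FALSE)
    discarded <- discarded[order(discarded$chemical,
                                 discarded$endpoint_id), , drop = FALSE]
    rownames(discarded) <- NULL
    keep <- act[!zb$burst, , drop = FALSE]
    pairs <- mapEndpointsToKes(endpointGenes, keGenes, whitelist, keLevels)
    m <- merge(keep[, c("chemical", "endpoint_id", "direction")], pairs,
               by = "endpoint_id")
    assoc <- .assoc(m$chemical, m$ke_id, "toxcast", m$direction,
                    m$endpoint_id)
    list(associations = assoc, discardedBursts = discarded)
}

#' Chemical-gene-phenotype-disease (CGPD) tetramers
#'
#' Joins the four pairwise association tables: a tetramer (C, G, P, D) is
#' emitted iff C-G is a curated interaction, C-P is a curated phenotype
#' association, C-D is a direct-evidence disease association, and G-D is a
#' direct-evidence association. Which links require their evidence flag is
#' configurable via `require` (the exact rule lives in prior curation
#' practice); flags are matched against the `evidence` column of each table
#' equal to `"curated"`/`"direct"` respectively.
#'
#' @param cg data.frame (`chemical`, `gene`, `evidence`).
#' @param cp data.frame (`chemical`, `phenotype`, `evidence`).
#' @param cd data.frame (`chemical`, `disease`, `evidence`).
#' @param gd data.frame (`gene`, `disease`, `evidence`).
#' @param require named logical vector over `c(cg, cp, cd, gd)`; default all
#'   `TRUE`.
#' @return deduplicated data.frame (`chemical`, `gene`, `phenotype`,
#'   `disease`).
#' @export
buildCgpdTetramers <- function(cg, cp, cd, gd,
                               require = c(cg = TRUE, cp = TRUE,
                                           cd = TRUE, gd = TRUE)) {
    tabs <- list(cg = cg, cp = cp, cd = cd, gd = gd)
    want <- c(cg = "curated", cp = "curated", cd = "direct", gd = "direct")
    for (nm in names(tabs)) {
        if (is.null(tabs[[nm]]$evidence))
            stop("table '", nm, "' lacks the evidence column")
        if (isTRUE(require[[nm]]))
            tabs[[nm]] <- tabs[[nm]][tabs[[nm]]$evidence == want[[nm]], ,
                                     drop = FALSE]
    }
    m <- merge(tabs$cg[, c("chemical", "gene")],
               tabs$cp[, c("chemical", "phenotype")], by = "chemical")
    m <- merge(m, tabs$cd[, c("chemical", "disease")], by = "chemical")
    m <- merge(m, tabs$gd[, c("gene", "disease")],
               by = c("gene", "disease"))
    out <- unique(m[, c("chemical", "gene", "phenotype", "disease")])
    out <- out[order(out$chemical, out$gene, out$phenotype, out$disease), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Map tetramers to KEs via GO phenotypes and disease tables
#'
#' Phenotype channel: a `(chemical, KE)` association exists iff some GO term
#' in the immediate-neighbor expansion of a tetramer phenotype of the
#' chemical matches a process identifier of the KE, and the (tetramer
#' phenotype, KE) pair is whitelisted. Disease channel: association iff a
#' tetramer disease of the chemical maps to the KE in the curated
#' disease-to-KE map.
#'
#' @param tetramers output of [buildCgpdTetramers()].
#' @param goNeighbors named list, GO term -> neighbor term set (see
#'   [expandGoNeighbors()]).
#' @param keProcessIds data.frame (`ke_id`, `process_id`).
#' @param phenotypeWhitelist data.frame (`phenotype`, `ke_id`); empty gives
#'   an empty phenotype channel with a warning.
#' @param diseaseKeMap data.frame (`disease`, `ke_id`); empty gives an empty
#'   disease channel with a warning.
#' @return data.frame of associations (channels `ctd_phenotype`,
#'   `ctd_disease`).
#' @export
mapCtdToKes <- function(tetramers, goNeighbors, keProcessIds,
                        phenotypeWhitelist = NULL, diseaseKeMap = NULL) {
    out <- list()
    if (is.null(phenotypeWhitelist) || !nrow(phenotypeWhitelist)) {
        warning("empty phenotype whitelist: phenotype channel is empty")
    } else if (nrow(tetramers)) {
        cp <- unique(tetramers[, c("chemical", "phenotype")])
        recs <- list()
        for (i in seq_len(nrow(cp))) {
            ph <- cp$phenotype[i]
            nb <- goNeighbors[[ph]]
            if (is.null(nb)) nb <- ph
            hit_kes <- unique(keProcessIds$ke_id[
                keProcessIds$process_id %in% nb])
            ok <- phenotypeWhitelist$ke_id[
                phenotypeWhitelist$phenotype == ph]
            hit_kes <- intersect(hit_kes, ok)
            if (length(hit_kes))
                recs[[length(recs) + 1L]] <- data.frame(
                    chemical = cp$chemical[i], ke_id = hit_kes,
                    evidence = ph, stringsAsFactors = FALSE)
        }
        if (length(recs)) {
            r <- do.call(rbind, recs)
            out$phen <- .assoc(r$chemical, r$ke_id, "ctd_phenotype",
                               evidence = r$evidence)
        }
    }
    if (is.null(diseaseKeMap) || !nrow(diseaseKeMap)) {
        warning("empty disease-KE map: disease channel is empty")
    } else if (nrow(tetramers)) {
        cdp <- unique(tetramers[, c("chemical", "disease")])
        m <- merge(cdp, diseaseKeMap, by = "disease")
        if (nrow(m))
            out$dis <- .assoc(m$chemical, m$ke_id, "ctd_disease",
                              evidence = m$disease)
    }
    if (!length(out)) return(.empty_assoc())
    do.call(rbind, unname(out))
}

#' Curated endpoint channels (endocrine / neurotoxicity resources)
#'
#' Emits a `(chemical, KE)` association for every chemical-endpoint row
#' whose endpoint appears in the curated endpoint-to-KE map. Unmapped
#' endpoints are counted and reported as an attribute.
#'
#' @param chemicalEndpoints data.frame (`chemical`, `endpoint`).
#' @param endpointKeMap data.frame (`endpoint`, `ke_id`).
#' @param channel channel label, e.g. `"deduct"` or `"neurotoxkb"`.
#' @return association data.frame with attribute `unmapped` (count of
#'   distinct unmapped endpoints).
#' @export
mapCuratedEndpoints <- function(chemicalEndpoints, endpointKeMap, channel) {
    stopifnot(channel %in% .CHANNELS)
    unmapped <- setdiff(unique(chemicalEndpoints$endpoint),
                        unique(endpointKeMap$endpoint))
    if (length(unmapped))
        message(channel, ": ", length(unmapped),
                " endpoint(s) without a curated KE mapping")
    m <- merge(chemicalEndpoints, endpointKeMap, by = "endpoint")
    out <- .assoc(m$chemical, m$ke_id, channel, evidence = m$endpoint)
    attr(out, "unmapped") <- length(unmapped)
    out
}

#' AOP-Wiki stressor channel
#'
#' For every AOP listing a stressor resolvable to a CAS identifier, the
#' chemical is associated with every KE of that AOP. Unresolvable stressor
#' names are counted and reported.
#'
#' @param aopset an [AopSet-class].
#' @param chemicalNameMap data.frame (`name`, `chemical`) resolving stressor
#'   names to CAS.
#' @return association data.frame (channel `aopwiki_stressor`) with
#'   attribute `unresolved` (count of distinct unresolvable names).
#' @export
aopwikiStressorChannel <- function(aopset, chemicalNameMap) {
    ap <- aops(aopset)
    recs <- list(); unresolved <- character(0)
    for (i in seq_len(nrow(ap))) {
        for (nm in ap$stressor_names[[i]]) {
            cas <- chemicalNameMap$chemical[match(nm, chemicalNameMap$name)]
            if (is.na(cas)) {
                unresolved <- c(unresolved, nm)
                next
            }
            kes <- ap$ke_ids[[i]]
            if (length(kes))
                recs[[length(recs) + 1L]] <- data.frame(
                    chemical = cas, ke_id = kes,
                    evidence = ap$aop_id[i], stringsAsFactors = FALSE)
        }
    }
    unresolved <- unique(unresolved)
    if (length(unresolved))
        message("aopwiki_stressor: ", length(unresolved),
                " unresolvable stressor name(s)")
    out <- if (length(recs)) {
        r <- do.call(rbind, recs)
        .assoc(r$chemical, r$ke_id, "aopwiki_stressor", evidence = r$evidence)
    } else .empty_assoc()
    attr(out, "unresolved") <- length(unresolved)
    out
}

#' Merge per-channel association tables
#'
#' The unified association set is the union keyed by `(chemical, ke_id)`;
#' every evidence record is kept as its own row, so a pair supported by two
#' channels carries two rows. Rows are sorted by (chemical, ke_id, channel,
#' evidence).
#'
#' @param channels list of association data.frames.
#' @return a single association data.frame.
#' @export
mergeChannels <- function(channels) {
    channels <- Filter(function(x) !is.null(x) && nrow(x), channels)
    if (!length(channels)) return(.empty_assoc())
    out <- unique(do.call(rbind, lapply(channels, function(x) {
        attr(x, "unmapped") <- NULL; attr(x, "unresolved") <- NULL
        rownames(x) <- NULL
        x[, c("chemical", "ke_id", "channel", "direction", "evidence")]
    })))
    out <- out[order(out$chemical, out$ke_id, out$channel, out$evidence), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Distinct (chemical, KE) pairs of an association table
#'
#' @param associations association data.frame.
#' @return data.frame (`chemical`, `ke_id`).
#' @export
associationPairs <- function(associations) {
    out <- unique(associations[, c("chemical", "ke_id")])
    out <- out[order(out$chemical, out$ke_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
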