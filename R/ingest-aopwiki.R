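## AOP-Wiki XML ingestion and the high-confidence AOP filter.
##
## Elements are located by local name so that namespace and schema-version
## drift between quarterly releases does not break parsing.

.norm_id <- function(prefix, id) {
    id <- sub(paste0("^", prefix, ":"), "", as.character(id))
    paste0(prefix, ":", id)
}

.xfind <- function(node, name) {
    xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
}

.xchild <- function(node, name) {
    xml2::xml_find_all(node, paste0("./*[local-name()='", name, "']"))
}

.xtext1 <- function(node, name, default = "") {
    hit <- .xchild(node, name)
    if (length(hit) == 0) default else xml2::xml_text(hit[[1]])
}

.canon_enum <- function(x, levels, default = "unspecified") {
    x <- tolower(trimws(x))
    x[!(x %in% tolower(levels))] <- NA
    out <- levels[match(x, tolower(levels))]
    out[is.na(out)] <- default
    out
}

#' Parse an AOP-Wiki project-download XML release
#'
#' Extracts all AOPs, key events (KEs) and key event relationships (KERs)
#' into an [AopSet-class]. Identifiers are normalized to `"AOP:n"`,
#' `"KE:n"`, `"KER:n"`. Roles (MIE/AO) are resolved per AOP. References to
#' KEs or KERs absent from the release are quarantined with a warning
#' rather than silently dropped: a KER with a missing endpoint is excluded
#' from the relationship table, and an AOP's reference to a missing KE/KER
#' is removed from that AOP's membership, in both cases leaving a row in
#' `quarantined()`.
#'
#' @param path path to the XML file.
#' @return an [AopSet-class].
#' @examples
#' cfg <- worldConfig(seed = 1, n_aops = 5)
#' w <- generateWorld(cfg, dir = tempfile())
#' aopset <- parseAopWikiXml(worldPaths(w)$aopwiki_xml)
#' aopset
#' @export
parseAopWikiXml <- function(path) {
    if (!file.exists(path))
        stop("AOP-Wiki XML file not found: ", path)
    doc <- tryCatch(xml2::read_xml(path), error = function(e)
        stop("malformed XML in '", path, "': ", conditionMessage(e)))
    quarantine <- list()

    ## --- key events ---------------------------------------------------
    ke_nodes <- .xfind(doc, "key-event")
    ## key-event elements also occur inside <aop><key-events>; keep only
    ## definition nodes (those with a title child)
    is_def <- vapply(ke_nodes, function(n) length(.xchild(n, "title")) > 0,
                     logical(1))
    ke_nodes <- ke_nodes[is_def]
    keyEvents <- data.frame(
        ke_id = vapply(ke_nodes, function(n)
            .norm_id("KE", xml2::xml_attr(n, "id")), character(1)),
        title = vapply(ke_nodes, .xtext1, character(1), name = "title"),
        biological_level = .canon_enum(
            vapply(ke_nodes, .xtext1, character(1),
                   name = "biological-organization-level"), .BIO_LEVELS),
        action = vapply(ke_nodes, .xtext1, character(1), name = "action"),
        object_name = vapply(ke_nodes, .xtext1, character(1),
                             name = "object-name"),
        stringsAsFactors = FALSE)
    keyEvents$object_ids <- lapply(ke_nodes, function(n)
        xml2::xml_text(.xchild(n, "object-id")))
    keyEvents$process_ids <- lapply(ke_nodes, function(n)
        xml2::xml_text(.xchild(n, "process-id")))
    ke_ids <- keyEvents$ke_id

    ## --- key event relationships --------------------------------------
    ker_nodes <- .xfind(doc, "key-event-relationship")
    ker_nodes <- ker_nodes[vapply(ker_nodes, function(n)
        length(.xchild(n, "upstream-id")) > 0, logical(1))]
    kers <- data.frame(
        ker_id = vapply(ker_nodes, function(n)
            .norm_id("KER", xml2::xml_attr(n, "id")), character(1)),
        upstream_ke = vapply(ker_nodes, function(n)
            .norm_id("KE", .xtext1(n, "upstream-id")), character(1)),
        downstream_ke = vapply(ker_nodes, function(n)
            .norm_id("KE", .xtext1(n, "downstream-id")), character(1)),
        adjacency = .canon_enum(vapply(ker_nodes, .xtext1, character(1),
                                       name = "adjacency"), .ADJACENCY),
        woe = .canon_enum(vapply(ker_nodes, .xtext1, character(1),
                                 name = "evidence"), .WOE),
        quantitative_understanding = vapply(
            ker_nodes, .xtext1, character(1),
            name = "quantitative-understanding"),
        stringsAsFactors = FALSE)
    dangling <- !(kers$upstream_ke %in% ke_ids) |
        !(kers$downstream_ke %in% ke_ids)
    if (any(dangling)) {
        warning(sum(dangling), " KER(s) reference missing KEs; quarantined")
        for (i in which(dangling)) {
            miss <- setdiff(c(kers$upstream_ke[i], kers$downstream_ke[i]),
                            ke_ids)
            quarantine[[length(quarantine) + 1L]] <- data.frame(
                context = kers$ker_id[i], ref_type = "ke",
                ref_id = paste(miss, collapse = ";"),
                stringsAsFactors = FALSE)
        }
        kers <- kers[!dangling, , drop = FALSE]
    }

    ## --- stressor name lookup -----------------------------------------
    s_nodes <- .xfind(doc, "stressor")
    s_nodes <- s_nodes[vapply(s_nodes, function(n)
        length(.xchild(n, "name")) > 0, logical(1))]
    stressor_names <- stats::setNames(
        vapply(s_nodes, .xtext1, character(1), name = "name"),
        vapply(s_nodes, function(n) xml2::xml_attr(n, "id"), character(1)))

    ## --- AOPs ----------------------------------------------------------
    aop_nodes <- .xfind(doc, "aop")
    aop_nodes <- aop_nodes[vapply(aop_nodes, function(n)
        length(.xchild(n, "title")) > 0, logical(1))]
    n <- length(aop_nodes)
    aop_id <- character(n); title <- character(n)
    saaop_status <- character(n); oecd_status <- character(n)
    ke_l <- vector("list", n); mie_l <- vector("list", n)
    ao_l <- vector("list", n); ker_l <- vector("list", n)
    str_l <- vector("list", n); app_l <- vector("list", n)
    for (i in seq_len(n)) {
        nd <- aop_nodes[[i]]
        aop_id[i] <- .norm_id("AOP", xml2::xml_attr(nd, "id"))
        title[i] <- .xtext1(nd, "title")
        saaop_status[i] <- .xtext1(nd, "saaop-status")
        oecd_status[i] <- .xtext1(nd, "oecd-status")
        memb <- .xfind(nd, "key-event")
        memb <- memb[vapply(memb, function(m)
            length(.xchild(m, "title")) == 0, logical(1))]
        kes <- unique(.norm_id("KE", vapply(memb, function(m)
            xml2::xml_attr(m, "id"), character(1))))
        mies <- unique(.norm_id("KE", vapply(
            .xfind(nd, "molecular-initiating-event"), function(m)
                xml2::xml_attr(m, "key-event-id"), character(1))))
        aos <- unique(.norm_id("KE", vapply(
            .xfind(nd, "adverse-outcome"), function(m)
                xml2::xml_attr(m, "key-event-id"), character(1))))
        kes <- unique(c(kes, mies, aos))
        kids <- unique(.norm_id("KER", vapply(
            .xfind(nd, "relationship"), function(m)
                xml2::xml_attr(m, "id"), character(1))))
        ## quarantine references to entities absent from the release
        bad_ke <- setdiff(kes, ke_ids)
        if (length(bad_ke)) {
            warning(aop_id[i], " references missing KE(s): ",
                    paste(bad_ke, collapse = ", "), "; quarantined")
            quarantine[[length(quarantine) + 1L]] <- data.frame(
                context = aop_id[i], ref_type = "ke",
                ref_id = paste(bad_ke, collapse = ";"),
                stringsAsFactors = FALSE)
            kes <- setdiff(kes, bad_ke)
            mies <- setdiff(mies, bad_ke)
            aos <- setdiff(aos, bad_ke)
        }
        bad_ker <- setdiff(kids, kers$ker_id)
        if (length(bad_ker)) {
            quarantine[[length(quarantine) + 1L]] <- data.frame(
                context = aop_id[i], ref_type = "ker",
                ref_id = paste(bad_ker, collapse = ";"),
                stringsAsFactors = FALSE)
            kids <- setdiff(kids, bad_ker)
        }
        sids <- vapply(.xfind(nd, "aop-stressor"), function(m)
            xml2::xml_attr(m, "stressor-id"), character(1))
        str_l[[i]] <- unname(stressor_names[sids[sids %in%
                                                 names(stressor_names)]])
        app_nodes <- .xfind(nd, "applicability")
        app_l[[i]] <- if (length(app_nodes)) {
            kids2 <- xml2::xml_children(app_nodes[[1]])
            lapply(kids2, function(k) list(
                scope = xml2::xml_name(k),
                value = xml2::xml_attr(k, "name"),
                woe = xml2::xml_attr(k, "evidence")))
        } else list()
        ke_l[[i]] <- sort(kes); mie_l[[i]] <- sort(mies)
        ao_l[[i]] <- sort(aos); ker_l[[i]] <- sort(kids)
    }
    aops <- data.frame(aop_id = aop_id, title = title,
                       saaop_status = saaop_status,
                       oecd_status = oecd_status, stringsAsFactors = FALSE)
    aops$ke_ids <- ke_l; aops$mie_ids <- mie_l; aops$ao_ids <- ao_l
    aops$ker_ids <- ker_l; aops$stressor_names <- str_l
    aops$applicability <- app_l

    q <- if (length(quarantine)) do.call(rbind, quarantine) else
        emptyQuarantine()
    makeAopSet(aops, keyEvents, kers, quarantined = q)
}

.aop_edges <- function(aop_row, kers, pathEdges = "all") {
    kk <- kers[kers$ker_id %in% aop_row$ker_ids[[1]], , drop = FALSE]
    if (identical(pathEdges, "adjacent"))
        kk <- kk[kk$adjacency == "adjacent", , drop = FALSE]
    kk
}

#' Directed MIE-to-AO reachability over a KER edge set
#'
#' Returns `TRUE` iff a directed path of length at least one leads from any
#' molecular initiating event to any adverse outcome over the given key
#' event relationships. Empty MIE or AO sets (or an empty edge set) give
#' `FALSE`.
#'
#' @param mieIds,aoIds character vectors of KE identifiers.
#' @param kers data.frame with columns `upstream_ke`, `downstream_ke`.
#' @return logical scalar.
#' @examples
#' kers <- data.frame(upstream_ke = "KE:1", downstream_ke = "KE:2")
#' hasMieAoPath("KE:1", "KE:2", kers)  # TRUE
#' hasMieAoPath("KE:2", "KE:1", kers)  # FALSE
#' @export
hasMieAoPath <- function(mieIds, aoIds, kers) {
    if (!length(mieIds) || !length(aoIds) || !nrow(kers)) return(FALSE)
    verts <- unique(c(kers$upstream_ke, kers$downstream_ke, mieIds, aoIds))
    g <- igraph::graph_from_data_frame(
        kers[, c("upstream_ke", "downstream_ke")], directed = TRUE,
        vertices = verts)
    for (m in mieIds) {
        succ <- igraph::neighbors(g, m, mode = "out")
        if (!length(succ)) next
        reach <- unique(unlist(lapply(succ, function(s)
            names(igraph::subcomponent(g, s, mode = "out")))))
        if (any(aoIds %in% reach)) return(TRUE)
    }
    FALSE
}

.weakly_connected <- function(ke_ids, edges) {
    if (!length(ke_ids)) return(TRUE)
    g <- igraph::graph_from_data_frame(
        edges[, c("upstream_ke", "downstream_ke")], directed = TRUE,
        vertices = ke_ids)
    igraph::count_components(g, mode = "weak") == 1L
}

#' High-confidence AOP filter
#'
#' Applies, in order, the four acceptance rules defining a high-confidence
#' AOP: (1) SAAOP status is not "archived"; (2) no KE titled "unknown"
#' (whole-title, case-insensitive), at least one KE and at least one KER;
#' (3) the KER graph over the AOP's KE set is weakly connected and covers
#' every listed KE (an isolated KE counts as disconnection); (4) at least
#' one MIE, at least one AO, and a directed path from some MIE to some AO.
#' The first failing rule is recorded as the rejection reason, so every AOP
#' appears exactly once as accepted or rejected.
#'
#' @param aopset an [AopSet-class].
#' @param overrides optional data.frame (`aop_id`, `action`, `note`) with
#'   `action` in `force_accept`/`force_reject`, standing in for manual
#'   curation steps; applied after the rules.
#' @param pathEdges `"all"` (default) to use every KER as a path edge, or
#'   `"adjacent"` to restrict the rule-(4) path check to adjacent KERs.
#' @return list with elements `accepted` (an AopSet restricted to accepted
#'   AOPs) and `rejections` (data.frame `aop_id`, `reason`, `detail`).
#' @export
filterHighConfidence <- function(aopset, overrides = NULL,
                                 pathEdges = c("all", "adjacent")) {
    stopifnot(is(aopset, "AopSet"))
    pathEdges <- match.arg(pathEdges)
    ap <- aops(aopset); ke <- keyEvents(aopset); kr <- relationships(aopset)
    reasons <- character(nrow(ap)); details <- character(nrow(ap))
    for (i in seq_len(nrow(ap))) {
        row <- ap[i, , drop = FALSE]
        kes <- row$ke_ids[[1]]
        reason <- ""; detail <- ""
        if (tolower(trimws(row$saaop_status)) == "archived") {
            reason <- "archived"
        } else if (length(kes) &&
                   any(tolower(trimws(ke$title[match(kes, ke$ke_id)])) ==
                       "unknown")) {
            reason <- "unknown_ke_title"
            detail <- paste(kes[tolower(trimws(
                ke$title[match(kes, ke$ke_id)])) == "unknown"],
                collapse = ";")
        } else if (!length(kes)) {
            reason <- "no_kes"
        } else if (!length(row$ker_ids[[1]])) {
            reason <- "no_kers"
        } else {
            edges <- .aop_edges(row, kr, pathEdges = "all")
            if (!.weakly_connected(kes, edges)) {
                reason <- "disconnected"
            } else if (!length(row$mie_ids[[1]])) {
                reason <- "no_mie"
            } else if (!length(row$ao_ids[[1]])) {
                reason <- "no_ao"
            } else {
                pedges <- .aop_edges(row, kr, pathEdges = pathEdges)
                if (!hasMieAoPath(row$mie_ids[[1]], row$ao_ids[[1]], pedges))
                    reason <- "no_mie_ao_path"
            }
        }
        reasons[i] <- reason; details[i] <- detail
    }
    if (!is.null(overrides) && nrow(overrides)) {
        idx <- match(ap$aop_id, overrides$aop_id)
        forced <- !is.na(idx)
        act <- overrides$action[idx[forced]]
        note <- if (is.null(overrides$note)) rep("", sum(forced)) else
            overrides$note[idx[forced]]
        reasons[forced][act == "force_accept"] <- ""
        reasons[forced][act == "force_reject"] <- "override"
        details[forced][act == "force_reject"] <-
            note[act == "force_reject"]
    }
    rej <- data.frame(aop_id = ap$aop_id[reasons != ""],
                      reason = reasons[reasons != ""],
                      detail = details[reasons != ""],
                      stringsAsFactors = FALSE)
    rej <- rej[order(rej$aop_id), , drop = FALSE]
    rownames(rej) <- NULL
    list(accepted = subsetAops(aopset, ap$aop_id[reasons == ""]),
         rejections = rej)
}

#' Read a manual-curation override table
#'
#' TSV with columns `aop_id`, `action` (`force_accept`/`force_reject`) and
#' optional `note`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readOverrides <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("aop_id", "action")
    if (!all(need %in% names(df)))
        stop("override file must have columns aop_id, action")
    bad <- setdiff(unique(df$action), c("force_accept", "force_reject"))
    if (length(bad))
        stop("invalid override action(s): ", paste(bad, collapse = ", "))
    df
}
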