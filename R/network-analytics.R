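## Per-stressor AOP-AOP projection graphs, directed KE/KER union networks,
## node centrality reports and cumulative weight-of-evidence labels.

#' Undirected AOP-AOP projection by shared KEs
#'
#' Nodes are AOPs; an undirected edge joins two AOPs iff they share at
#' least one KE (edge attribute `shared` carries the count). Connected
#' components are returned sorted by size (ties broken by the smallest
#' lexicographic AOP id set); isolated AOPs are listed separately.
#'
#' @param aopset an [AopSet-class] (typically already restricted to the
#'   AOPs relevant for one stressor, see [subsetAops()]).
#' @param aopIds optional further restriction.
#' @return list with `graph` (undirected igraph), `components` (list of
#'   character vectors, size-sorted, components of two or more AOPs) and
#'   `isolated` (character vector).
#' @export
buildAopProjection <- function(aopset, aopIds = NULL) {
    ap <- aops(aopset)
    if (!is.null(aopIds)) ap <- ap[ap$aop_id %in% aopIds, , drop = FALSE]
    n <- nrow(ap)
    edges <- list()
    if (n >= 2) {
        for (i in seq_len(n - 1)) {
            for (j in seq(i + 1, n)) {
                sh <- length(intersect(ap$ke_ids[[i]], ap$ke_ids[[j]]))
                if (sh >= 1)
                    edges[[length(edges) + 1L]] <- data.frame(
                        from = ap$aop_id[i], to = ap$aop_id[j],
                        shared = sh, stringsAsFactors = FALSE)
            }
        }
    }
    ed <- if (length(edges)) do.call(rbind, edges) else
        data.frame(from = character(0), to = character(0),
                   shared = integer(0), stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                       vertices = ap$aop_id)
    comp <- igraph::components(g)
    groups <- split(names(comp$membership), comp$membership)
    groups <- lapply(groups, function(x) sort(x))
    ord <- order(-vapply(groups, length, integer(1)),
                 vapply(groups, function(x) x[1], character(1)))
    groups <- unname(groups[ord])
    isolated <- sort(unlist(groups[vapply(groups, length,
                                          integer(1)) == 1L]))
    if (is.null(isolated)) isolated <- character(0)
    comps <- groups[vapply(groups, length, integer(1)) >= 2L]
    list(graph = g, components = comps, isolated = isolated)
}

#' Directed KE/KER union network of a set of AOPs
#'
#' Nodes are the union of the member AOPs' KEs; edges are their KERs
#' deduplicated by (upstream, downstream). A node's role is `MIE` if it is
#' an MIE in at least one member AOP, else `AO` if an AO in at least one,
#' else `KE` (precedence MIE > AO; conflicts, where a KE is MIE in one
#' member and AO in another, are reported via a message). When a chemical
#' and its associations are supplied, each node carries an `associated`
#' flag.
#'
#' @param aopset an [AopSet-class].
#' @param aopIds member AOP ids (e.g. a projection component).
#' @param associations optional association data.frame.
#' @param chemical optional CAS identifier whose associations set the flag.
#' @return a directed igraph with vertex attributes `role`, `associated`,
#'   `biological_level`, `title` and edge attributes `adjacency`, `woe`.
#' @export
buildKeUnionGraph <- function(aopset, aopIds, associations = NULL,
                              chemical = NULL) {
    ap <- aops(aopset)
    ap <- ap[ap$aop_id %in% aopIds, , drop = FALSE]
    if (!nrow(ap)) stop("no member AOPs")
    ke <- keyEvents(aopset); kr <- relationships(aopset)
    nodes <- sort(unique(unlist(ap$ke_ids)))
    mies <- unique(unlist(ap$mie_ids)); aos <- unique(unlist(ap$ao_ids))
    conflict <- intersect(mies, aos)
    if (length(conflict))
        message("role conflict (MIE in one member, AO in another), ",
                "MIE precedence applied: ",
                paste(conflict, collapse = ", "))
    role <- ifelse(nodes %in% mies, "MIE",
            ifelse(nodes %in% aos, "AO", "KE"))
    kerIds <- unique(unlist(ap$ker_ids))
    ed <- kr[kr$ker_id %in% kerIds, , drop = FALSE]
    ed <- ed[!duplicated(ed[, c("upstream_ke", "downstream_ke")]), ,
             drop = FALSE]
    ed <- ed[order(ed$upstream_ke, ed$downstream_ke), , drop = FALSE]
    assocFlag <- rep(FALSE, length(nodes))
    if (!is.null(associations) && !is.null(chemical)) {
        pk <- associationPairs(associations)
        assocFlag <- nodes %in% pk$ke_id[pk$chemical == chemical]
    }
    vdf <- data.frame(
        name = nodes, role = role, associated = assocFlag,
        biological_level = ke$biological_level[match(nodes, ke$ke_id)],
        title = ke$title[match(nodes, ke$ke_id)],
        stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(
        ed[, c("upstream_ke", "downstream_ke", "adjacency", "woe")],
        directed = TRUE, vertices = vdf)
}

#' Node centrality report of a directed KE network
#'
#' In- and out-degree on the directed graph; betweenness on the directed,
#' unweighted graph (raw shortest-path counts, endpoints excluded, no
#' normalization); eccentricity on the undirected projection, restricted to
#' each node's connected component. A single-node graph yields all zeros.
#'
#' @param graph a directed igraph.
#' @return data.frame (`node`, `in_degree`, `out_degree`, `betweenness`,
#'   `eccentricity`) sorted by node name.
#' @export
centralityReport <- function(graph) {
    if (igraph::vcount(graph) == 0) stop("empty graph")
    nodes <- igraph::V(graph)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
    out <- data.frame(
        node = nodes,
        in_degree = as.integer(igraph::degree(graph, mode = "in")),
        out_degree = as.integer(igraph::degree(graph, mode = "out")),
        betweenness = as.numeric(igraph::betweenness(
            graph, directed = TRUE, normalized = FALSE)),
        eccentricity = as.integer(igraph::eccentricity(
            graph, mode = "all")),
        stringsAsFactors = FALSE)
    out <- out[order(out$node), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Nodes attaining the maximum of a centrality measure
#'
#' Ties are reported in full.
#'
#' @param report output of [centralityReport()].
#' @param measure column name, e.g. `"out_degree"`.
#' @return character vector of node names (sorted).
#' @export
topNodes <- function(report, measure) {
    stopifnot(measure %in% names(report))
    v <- report[[measure]]
    sort(report$node[v == max(v)])
}

.WOE_SCORE <- c(High = 3, Moderate = 2, Low = 1)

#' Cumulative weight of evidence of an AOP's KERs
#'
#' KER evidence labels are encoded High = 3, Moderate = 2, Low = 1
#' (unspecified labels ignored). Under the default `"mean"` rule the
#' cumulative label is High if the mean score is at least 2.5, Moderate if
#' at least 1.5, else Low; `"min"` takes the weakest label; `"majority"`
#' takes the most frequent label (ties resolved toward the stronger).
#' If every label is unspecified the result is `"undetermined"`.
#'
#' @param woeLabels character vector of KER evidence labels.
#' @param rule aggregation rule: `"mean"` (default), `"min"`, `"majority"`.
#' @return one of `"High"`, `"Moderate"`, `"Low"`, `"undetermined"`.
#' @export
cumulativeWoe <- function(woeLabels, rule = c("mean", "min", "majority")) {
    rule <- match.arg(rule)
    sc <- .WOE_SCORE[woeLabels[woeLabels %in% names(.WOE_SCORE)]]
    if (!length(sc)) return("undetermined")
    val <- switch(rule,
        mean = mean(sc),
        min = min(sc),
        majority = {
            tab <- table(factor(sc, levels = c(3, 2, 1)))
            as.numeric(names(tab)[which.max(tab)])
        })
    if (val >= 2.5) "High" else if (val >= 1.5) "Moderate" else "Low"
}

#' Per-AOP weight-of-evidence summary
#'
#' Counts each AOP's KER evidence labels and attaches the cumulative label.
#'
#' @param aopset an [AopSet-class].
#' @param aopIds optional restriction.
#' @param rule passed to [cumulativeWoe()].
#' @return data.frame (`aop_id`, `n_high`, `n_moderate`, `n_low`,
#'   `n_unspecified`, `cumulative`).
#' @export
woeSummary <- function(aopset, aopIds = NULL, rule = "mean") {
    ap <- aops(aopset); kr <- relationships(aopset)
    if (!is.null(aopIds)) ap <- ap[ap$aop_id %in% aopIds, , drop = FALSE]
    out <- do.call(rbind, lapply(seq_len(nrow(ap)), function(i) {
        labs <- kr$woe[kr$ker_id %in% ap$ker_ids[[i]]]
        data.frame(aop_id = ap$aop_id[i],
                   n_high = sum(labs == "High"),
                   n_moderate = sum(labs == "Moderate"),
                   n_low = sum(labs == "Low"),
                   n_unspecified = sum(labs == "unspecified"),
                   cumulative = cumulativeWoe(labs, rule = rule),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(out))
        out <- data.frame(aop_id = character(0), n_high = integer(0),
                          n_moderate = integer(0), n_low = integer(0),
                          n_unspecified = integer(0),
                          cumulative = character(0),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
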