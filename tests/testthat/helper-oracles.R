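# Independent brute-force oracles and small fixture builders.
# The oracles deliberately share no code with the package: paths and
# betweenness by exhaustive simple-path enumeration, components by
# union-find, tetramers by four nested loops.

# all simple paths from `from`, as list of node vectors
enumerate_simple_paths <- function(edges, from) {
    out <- list()
    walk <- function(path) {
        nxt <- edges$to[edges$from == path[length(path)]]
        for (n in nxt) {
            if (n %in% path) next
            out[[length(out) + 1L]] <<- c(path, n)
            walk(c(path, n))
        }
    }
    walk(from)
    out
}

oracle_path_exists <- function(mies, aos, edges) {
    if (!length(mies) || !length(aos) || !nrow(edges)) return(FALSE)
    for (m in mies) {
        paths <- enumerate_simple_paths(edges, m)
        ends <- unique(vapply(paths, function(p) p[length(p)],
                              character(1)))
        if (length(intersect(setdiff(aos, m), ends))) return(TRUE)
        # mie == ao needs a directed cycle through it: an edge (u, m)
        # with u reachable from m, or a self-loop
        if (m %in% aos) {
            preds <- edges$from[edges$to == m]
            if (m %in% preds || any(preds %in% ends)) return(TRUE)
        }
    }
    FALSE
}

# raw directed betweenness, endpoints excluded
oracle_betweenness <- function(nodes, edges) {
    bw <- stats::setNames(numeric(length(nodes)), nodes)
    for (s in nodes) {
        paths <- enumerate_simple_paths(edges, s)
        for (t in setdiff(nodes, s)) {
            st <- Filter(function(p) p[length(p)] == t, paths)
            if (!length(st)) next
            lens <- vapply(st, length, integer(1))
            short <- st[lens == min(lens)]
            for (v in setdiff(nodes, c(s, t))) {
                thru <- sum(vapply(short, function(p) v %in% p, logical(1)))
                bw[v] <- bw[v] + thru / length(short)
            }
        }
    }
    bw
}

# connected components of AOPs sharing KEs, by union-find
oracle_projection_components <- function(aop_ids, ke_sets) {
    parent <- stats::setNames(aop_ids, aop_ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    n <- length(aop_ids)
    if (n >= 2) {
        for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
            if (length(intersect(ke_sets[[i]], ke_sets[[j]])))
                parent[[find(aop_ids[i])]] <- find(aop_ids[j])
        }
    }
    roots <- vapply(aop_ids, find, character(1))
    unname(lapply(split(aop_ids, roots), sort))
}

oracle_tetramers <- function(cg, cp, cd, gd) {
    out <- list()
    for (i in seq_len(nrow(cg))) for (j in seq_len(nrow(cp)))
        for (k in seq_len(nrow(cd))) for (l in seq_len(nrow(gd))) {
            if (cg$evidence[i] != "curated" || cp$evidence[j] != "curated" ||
                cd$evidence[k] != "direct" || gd$evidence[l] != "direct")
                next
            if (cg$chemical[i] == cp$chemical[j] &&
                cg$chemical[i] == cd$chemical[k] &&
                cg$gene[i] == gd$gene[l] &&
                cd$disease[k] == gd$disease[l])
                out[[length(out) + 1L]] <- data.frame(
                    chemical = cg$chemical[i], gene = cg$gene[i],
                    phenotype = cp$phenotype[j], disease = cd$disease[k],
                    stringsAsFactors = FALSE)
        }
    if (!length(out))
        return(data.frame(chemical = character(0), gene = character(0),
                          phenotype = character(0), disease = character(0),
                          stringsAsFactors = FALSE))
    res <- unique(do.call(rbind, out))
    res <- res[order(res$chemical, res$gene, res$phenotype, res$disease), ]
    rownames(res) <- NULL
    res
}

random_digraph <- function(n_nodes, p_edge = 0.3) {
    nodes <- paste0("n", seq_len(n_nodes))
    pairs <- expand.grid(from = nodes, to = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- stats::runif(nrow(pairs)) < p_edge
    list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

# --- fixture builders ---------------------------------------------------

# a chain AOP "MIE -> k1 -> ... -> AO" with globally unique KE ids
chain_aop <- function(aop_id, ke_ids, archived = FALSE,
                      unknown_title = FALSE, reversed = FALSE,
                      extra_isolated_ke = NULL) {
    m <- length(ke_ids)
    ker_ids <- paste0("KER:", sub("^AOP:", "", aop_id), "_",
                      seq_len(m - 1))
    kers <- data.frame(
        ker_id = ker_ids,
        upstream_ke = if (reversed) ke_ids[-1] else ke_ids[-m],
        downstream_ke = if (reversed) ke_ids[-m] else ke_ids[-1],
        stringsAsFactors = FALSE)
    lvls <- c("molecular", rep("cellular", max(0, m - 2)),
              if (m > 1) "individual")
    kes <- data.frame(
        ke_id = ke_ids,
        title = paste0("event ", ke_ids),
        biological_level = lvls[seq_len(m)],
        stringsAsFactors = FALSE)
    if (unknown_title && m >= 2) kes$title[2] <- "unknown"
    all_kes <- ke_ids
    if (!is.null(extra_isolated_ke)) {
        kes <- rbind(kes, data.frame(
            ke_id = extra_isolated_ke,
            title = paste0("event ", extra_isolated_ke),
            biological_level = "cellular", stringsAsFactors = FALSE))
        all_kes <- c(all_kes, extra_isolated_ke)
    }
    aop <- data.frame(aop_id = aop_id,
                      saaop_status = if (archived) "archived" else "active",
                      stringsAsFactors = FALSE)
    aop$ke_ids <- list(all_kes)
    aop$mie_ids <- list(ke_ids[1])
    aop$ao_ids <- list(ke_ids[m])
    aop$ker_ids <- list(ker_ids)
    list(aop = aop, kes = kes, kers = kers)
}

bind_aopset <- function(...) {
    parts <- list(...)
    kes <- do.call(rbind, lapply(parts, `[[`, "kes"))
    makeAopSet(do.call(rbind, lapply(parts, `[[`, "aop")),
               kes[!duplicated(kes$ke_id), ],
               do.call(rbind, lapply(parts, `[[`, "kers")))
}

assoc_df <- function(chemical, ke_id, channel = "deduct") {
    data.frame(chemical = chemical, ke_id = ke_id, channel = channel,
               direction = "unspecified", evidence = "fixture",
               stringsAsFactors = FALSE)
}

quiet_pipeline <- function(...) {
    suppressMessages(suppressWarnings(runPipeline(...)))
}
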