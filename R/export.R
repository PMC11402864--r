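## GraphML / SIF / TSV export. SIF dialect: one interaction-type token per
## edge ("shares_ke" for AOP projections, "ker" for KE union graphs,
## "associated_with" for bipartite stressor-AOP links), compatible with
## Cytoscape import.

#' Write the stressor-AOP link table as TSV
#'
#' Columns: chemical, aop_id, coverage, level, shared_kes (semicolon
#' separated), sorted by (chemical, aop_id).
#'
#' @param network a [StressorAopNetwork-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeLinkTable <- function(network, path) {
    lk <- network@links
    out <- data.frame(chemical = lk$chemical, aop_id = lk$aop_id,
                      coverage = lk$coverage, level = lk$level,
                      shared_kes = vapply(lk$shared_kes, paste,
                                          character(1), collapse = ";"),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export a network as GraphML and/or SIF
#'
#' For a [StressorAopNetwork-class] the bipartite graph is written with a
#' logical `stressor` vertex attribute and `coverage`/`level` edge
#' attributes. igraph objects (projection or union graphs) are written with
#' whatever attributes they carry.
#'
#' @param x a [StressorAopNetwork-class] or an igraph object.
#' @param path output file; extension selects the format (`.graphml` or
#'   `.sif`).
#' @param sifType interaction token used in SIF output; defaults depend on
#'   the object (`associated_with` for bipartite networks, `ker` for
#'   directed graphs, `shares_ke` for undirected graphs).
#' @return the path, invisibly.
#' @export
exportNetwork <- function(x, path, sifType = NULL) {
    if (is(x, "StressorAopNetwork")) {
        lk <- x@links
        verts <- data.frame(
            name = c(unique(lk$chemical), unique(lk$aop_id)),
            stressor = c(rep(TRUE, length(unique(lk$chemical))),
                         rep(FALSE, length(unique(lk$aop_id)))),
            stringsAsFactors = FALSE)
        g <- igraph::graph_from_data_frame(
            data.frame(from = lk$chemical, to = lk$aop_id,
                       coverage = lk$coverage, level = lk$level,
                       stringsAsFactors = FALSE),
            directed = FALSE, vertices = verts)
        if (is.null(sifType)) sifType <- "associated_with"
    } else {
        g <- x
        if (is.null(sifType))
            sifType <- if (igraph::is_directed(g)) "ker" else "shares_ke"
    }
    ext <- tolower(tools::file_ext(path))
    if (ext == "graphml") {
        igraph::write_graph(g, path, format = "graphml")
    } else if (ext == "sif") {
        ed <- igraph::as_data_frame(g, what = "edges")
        lines <- if (nrow(ed))
            paste(ed$from, sifType, ed$to, sep = "\t") else character(0)
        iso <- setdiff(igraph::V(g)$name, unique(c(ed$from, ed$to)))
        writeLines(c(lines, iso), path)
    } else stop("unsupported export extension: ", ext)
    invisible(path)
}

#' Write a table deterministically as TSV
#'
#' Helper used by the CLI: stable column order, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
    listcols <- vapply(df, is.list, logical(1))
    for (cn in names(df)[listcols])
        df[[cn]] <- vapply(df[[cn]], paste, character(1), collapse = ";")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a TSV written by this package (all columns as character)
#'
#' @param path file path.
#' @param numeric character vector of column names to convert to numeric.
#' @return data.frame.
#' @export
readTsv <- function(path, numeric = character(0)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", check.names = FALSE)
    for (cn in intersect(numeric, names(df)))
        df[[cn]] <- as.numeric(df[[cn]])
    df
}
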