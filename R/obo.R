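## Minimal OBO reader for GO-style ontologies: term ids, names, is_a and
## relationship: part_of edges. Sufficient for immediate-neighbor expansion
## of phenotype terms; no installed R package provides OBO parsing.

#' Parse a (subset of an) OBO ontology file
#'
#' Reads `[Term]` stanzas, collecting `id`, `name`, `is_a` parents and,
#' optionally, `relationship: part_of` parents. Obsolete terms are skipped.
#'
#' @param path OBO file path.
#' @param partOf include `part_of` edges as parent links (default `TRUE`).
#' @return list with `terms` (character vector of ids), `names` (named
#'   character), `parents` (named list id -> parent ids), `children`
#'   (named list id -> child ids).
#' @export
parseObo <- function(path, partOf = TRUE) {
    lines <- readLines(path)
    terms <- character(0); nm <- character(0)
    parents <- list()
    cur <- NULL; cur_name <- NA_character_
    cur_parents <- character(0); obsolete <- FALSE
    flush <- function() {
        if (!is.null(cur) && !obsolete) {
            terms <<- c(terms, cur)
            nm[cur] <<- cur_name
            parents[[cur]] <<- unique(cur_parents)
        }
    }
    in_term <- FALSE
    for (ln in lines) {
        ln <- trimws(ln)
        if (ln == "[Term]") {
            flush()
            cur <- NULL; cur_name <- NA_character_
            cur_parents <- character(0); obsolete <- FALSE
            in_term <- TRUE
        } else if (grepl("^\\[", ln)) {
            flush(); cur <- NULL; in_term <- FALSE
        } else if (in_term) {
            if (grepl("^id:", ln)) {
                cur <- trimws(sub("^id:", "", ln))
            } else if (grepl("^name:", ln)) {
                cur_name <- trimws(sub("^name:", "", ln))
            } else if (grepl("^is_a:", ln)) {
                p <- trimws(sub("^is_a:", "", ln))
                cur_parents <- c(cur_parents,
                                 trimws(strsplit(p, "!")[[1]][1]))
            } else if (partOf && grepl("^relationship:\\s*part_of", ln)) {
                p <- trimws(sub("^relationship:\\s*part_of", "", ln))
                cur_parents <- c(cur_parents,
                                 trimws(strsplit(p, "!")[[1]][1]))
            } else if (grepl("^is_obsolete:\\s*true", ln)) {
                obsolete <- TRUE
            }
        }
    }
    flush()
    children <- list()
    for (t in terms) {
        for (p in parents[[t]]) {
            children[[p]] <- c(children[[p]], t)
        }
    }
    list(terms = terms, names = nm,
         parents = parents,
         children = lapply(children, unique))
}

#' Immediate-neighbor expansion of ontology terms
#'
#' For each input term, the neighbor set is the term itself, its direct
#' parents and its direct children (over `is_a` and, if parsed, `part_of`
#' edges). A term absent from the ontology expands to itself with a
#' warning.
#'
#' @param terms character vector of term ids.
#' @param ontology result of [parseObo()].
#' @return named list, term -> sorted neighbor set.
#' @export
expandGoNeighbors <- function(terms, ontology) {
    terms <- unique(terms)
    missing <- setdiff(terms, ontology$terms)
    if (length(missing))
        warning(length(missing), " term(s) absent from the ontology; ",
                "expanded to themselves")
    out <- lapply(terms, function(t) {
        if (t %in% missing) return(t)
        sort(unique(c(t, ontology$parents[[t]], ontology$children[[t]])))
    })
    names(out) <- terms
    out
}
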