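#' @rdname AopSet-class
#' @export
setMethod("aops", "AopSet", function(x) x@aops)

#' @rdname AopSet-class
#' @export
setMethod("keyEvents", "AopSet", function(x) x@keyEvents)

#' @rdname AopSet-class
#' @export
setMethod("relationships", "AopSet", function(x) x@relationships)

#' @rdname AopSet-class
#' @export
setMethod("quarantined", "AopSet", function(x) x@quarantined)

setMethod("show", "AopSet", function(object) {
    cat("AopSet with", nrow(object@aops), "AOPs,",
        nrow(object@keyEvents), "key events,",
        nrow(object@relationships), "key event relationships\n")
    if (nrow(object@quarantined))
        cat("  (", nrow(object@quarantined),
            "dangling references quarantined )\n")
    if (nrow(object@aops)) {
        n <- min(5L, nrow(object@aops))
        cat("  ", paste(object@aops$aop_id[seq_len(n)], collapse = ", "),
            if (nrow(object@aops) > n) ", ..." else "", "\n", sep = "")
    }
})

#' @rdname StressorAopNetwork-class
#' @export
setMethod("links", "StressorAopNetwork", function(x) x@links)

#' @rdname StressorAopNetwork-class
#' @export
setMethod("chemicalAnnotations", "StressorAopNetwork",
          function(x) x@chemicalAnnotations)

#' @rdname StressorAopNetwork-class
#' @export
setMethod("aopAnnotations", "StressorAopNetwork", function(x) x@aopAnnotations)

setMethod("show", "StressorAopNetwork", function(object) {
    lk <- object@links
    cat("StressorAopNetwork:", nrow(lk), "links between",
        length(unique(lk$chemical)), "chemicals and",
        length(unique(lk$aop_id)), "AOPs\n")
    if (nrow(lk)) {
        tab <- table(factor(lk$level, levels = 1:5))
        cat("  links per relevance level:",
            paste(sprintf("L%d=%d", 1:5, as.integer(tab)), collapse = " "),
            "\n")
    }
})

#' @rdname SyntheticWorld-class
#' @export
setMethod("groundTruth", "SyntheticWorld", function(x) x@manifest)

#' @rdname SyntheticWorld-class
#' @export
setMethod("worldPaths", "SyntheticWorld", function(x) x@paths)

setMethod("show", "SyntheticWorld", function(object) {
    cat("SyntheticWorld (seed ", object@config$seed, ") in ",
        object@dir, "\n", sep = "")
    cat("  planted:", nrow(object@manifest$rejections), "rejections,",
        nrow(object@manifest$bursts), "bursts,",
        nrow(object@manifest$links), "links\n")
})

#' Construct an AopSet from plain data frames
#'
#' Convenience constructor used by the parser, the synthetic generator and
#' tests. Missing optional columns are filled with defaults.
#'
#' @param aops data.frame with at least `aop_id` and list-columns `ke_ids`,
#'   `mie_ids`, `ao_ids`, `ker_ids`.
#' @param keyEvents data.frame with at least `ke_id`.
#' @param relationships data.frame with at least `ker_id`, `upstream_ke`,
#'   `downstream_ke`.
#' @param quarantined data.frame of dangling references, may be empty.
#' @return an [AopSet-class] object.
#' @export
makeAopSet <- function(aops, keyEvents, relationships,
                       quarantined = emptyQuarantine()) {
    aops <- .fillAopCols(aops)
    keyEvents <- .fillKeCols(keyEvents)
    relationships <- .fillKerCols(relationships)
    new("AopSet", aops = aops, keyEvents = keyEvents,
        relationships = relationships, quarantined = quarantined)
}

emptyQuarantine <- function() {
    data.frame(context = character(0), ref_type = character(0),
               ref_id = character(0), stringsAsFactors = FALSE)
}

.fillAopCols <- function(df) {
    n <- nrow(df)
    if (is.null(df$title)) df$title <- df$aop_id
    if (is.null(df$saaop_status)) df$saaop_status <- rep("active", n)
    if (is.null(df$oecd_status)) df$oecd_status <- rep("", n)
    if (is.null(df$ker_ids)) df$ker_ids <- replicate(n, character(0), FALSE)
    if (is.null(df$stressor_names))
        df$stressor_names <- replicate(n, character(0), FALSE)
    if (is.null(df$applicability))
        df$applicability <- replicate(n, list(), FALSE)
    rownames(df) <- NULL
    df
}

.fillKeCols <- function(df) {
    n <- nrow(df)
    if (is.null(df$title)) df$title <- df$ke_id
    if (is.null(df$biological_level))
        df$biological_level <- rep("unspecified", n)
    if (is.null(df$action)) df$action <- rep("", n)
    if (is.null(df$object_name)) df$object_name <- rep("", n)
    if (is.null(df$object_ids)) df$object_ids <- replicate(n, character(0), FALSE)
    if (is.null(df$process_ids))
        df$process_ids <- replicate(n, character(0), FALSE)
    rownames(df) <- NULL
    df
}

.fillKerCols <- function(df) {
    n <- nrow(df)
    if (is.null(df$adjacency)) df$adjacency <- rep("unspecified", n)
    if (is.null(df$woe)) df$woe <- rep("unspecified", n)
    if (is.null(df$quantitative_understanding))
        df$quantitative_understanding <- rep("", n)
    rownames(df) <- NULL
    df
}

#' Subset an AopSet to a set of AOP identifiers
#'
#' Key events and relationships are kept globally (they are shared objects);
#' only the AOP table is restricted.
#'
#' @param x an AopSet.
#' @param aopIds character vector of AOP identifiers to keep.
#' @return an AopSet.
#' @export
subsetAops <- function(x, aopIds) {
    stopifnot(is(x, "AopSet"))
    keep <- x@aops$aop_id %in% aopIds
    new("AopSet", aops = x@aops[keep, , drop = FALSE],
        keyEvents = x@keyEvents, relationships = x@relationships,
        quarantined = x@quarantined)
}
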