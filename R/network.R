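## HybridizationNetwork accessors, display and serialization (flat TSV and
## extended Newick with #H reticulation nodes).

#' @rdname accessors
#' @export
setMethod("reticulations", "HybridizationNetwork",
          function(x) x@reticulations)

#' @rdname accessors
#' @export
setMethod("backboneTree", "HybridizationNetwork", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("taxa", "HybridizationNetwork", function(x)
    sort(x@tree$tip.label, method = "radix"))

#' Per-step trace of an inference run
#'
#' @param net a [HybridizationNetwork-class].
#' @return data.frame of joins and removals in order.
#' @export
networkTrace <- function(net) {
    stopifnot(is(net, "HybridizationNetwork"))
    net@trace
}

setMethod("show", "HybridizationNetwork", function(object) {
    nret <- nrow(object@reticulations)
    cat(sprintf("HybridizationNetwork: %d tree leaves, %d reticulation(s)\n",
                length(object@tree$tip.label), nret))
    if (!is.null(object@params))
        cat(sprintf("  parameters: minScore=%g, alpha in [%g, %g]\n",
                    object@params@minScore, object@params@alphaMin,
                    object@params@alphaMax))
    if (nret > 0L) {
        r <- object@reticulations
        for (q in seq_len(nret))
            cat(sprintf("  %s <- %s (%.3g) + %s (%.3g), score %.3g\n",
                        r$recipient[q], r$donor1[q], r$degree1[q],
                        r$donor2[q], r$degree2[q], r$score[q]))
    }
})

## Find the graft target for a donor inside the nested node structure:
## the node with the donor's label, else the smallest node whose member set
## contains all of the donor's members (the root always qualifies).
.hasLabel <- function(node, label) {
    if (identical(node$label, label))
        return(TRUE)
    for (ch in node$children)
        if (.hasLabel(ch$node, label))
            return(TRUE)
    FALSE
}

.deepestSuperset <- function(node, members) {
    if (!all(members %in% node$members))
        return(NULL)
    for (ch in node$children) {
        hit <- .deepestSuperset(ch$node, members)
        if (!is.null(hit))
            return(hit)
    }
    node$label
}

.findGraftTarget <- function(node, label, members) {
    if (.hasLabel(node, label))
        return(label)
    hit <- .deepestSuperset(node, members)
    if (is.null(hit)) node$label else hit
}

.graftChild <- function(node, targetLabel, child) {
    if (identical(node$label, targetLabel)) {
        if (length(node$children) == 0L) {
            ## leaf donor: keep the leaf visible and attach the
            ## reticulation edge at its base
            leafCopy <- list(label = node$label, members = node$members,
                             offset = 0, children = list())
            node$children <- list(list(node = leafCopy, length = 0),
                                  child)
        } else {
            node$children <- c(node$children, list(child))
        }
        return(list(node = node, done = TRUE))
    }
    for (q in seq_along(node$children)) {
        res <- .graftChild(node$children[[q]]$node, targetLabel, child)
        if (res$done) {
            node$children[[q]]$node <- res$node
            return(list(node = node, done = TRUE))
        }
    }
    list(node = node, done = FALSE)
}

#' Extended-Newick string of a hybridization network
#'
#' Serializes the tree skeleton with each reticulation written as a node
#' with two parents: the recipient subtree is attached under donor 1 with
#' the label suffix \code{#Hq}, and a matching \code{#Hq} leaf is attached
#' under donor 2. The branch length of each reticulation edge carries the
#' degree attributed to that donor. A donor that is no longer present in
#' the final tree (for example one removed in a later detection) is grafted
#' at the smallest cluster containing its members.
#'
#' @param net a [HybridizationNetwork-class].
#' @return a single extended-Newick string.
#' @seealso [writeNetwork()]
#' @export
enewick <- function(net) {
    stopifnot(is(net, "HybridizationNetwork"))
    root <- net@nodes$root
    rets <- net@reticulations
    for (q in seq_len(nrow(rets))) {
        tag <- sprintf("#H%d", q)
        rec <- net@nodes$removed[[rets$recipient[q]]]
        if (is.null(rec))
            rec <- .leafNode(rets$recipient[q])
        rec$label <- paste0(rec$label, tag)
        t1 <- .findGraftTarget(root, rets$donor1[q],
                               strsplit(rets$donor1Members[q], "+",
                                        fixed = TRUE)[[1L]])
        t2 <- .findGraftTarget(root, rets$donor2[q],
                               strsplit(rets$donor2Members[q], "+",
                                        fixed = TRUE)[[1L]])
        root <- .graftChild(root, t1,
                            list(node = rec, length = rets$degree1[q]))$node
        root <- .graftChild(root, t2,
                            list(node = .leafNode(tag),
                                 length = rets$degree2[q]))$node
    }
    paste0(.fragmentNewick(root), ";")
}

#' Write a hybridization network to disk
#'
#' \code{format = "tsv"} writes the flat reticulation table (recipient,
#' donors with member lists, degrees, score, step); \code{"enewick"} writes
#' the extended-Newick string of [enewick()]; \code{"both"} writes
#' \code{<path>.tsv} and \code{<path>.nwk}.
#'
#' @param net a [HybridizationNetwork-class].
#' @param path output path (base path for \code{format = "both"}).
#' @param format \code{"enewick"}, \code{"tsv"} or \code{"both"}.
#' @return the path(s) written, invisibly.
#' @export
writeNetwork <- function(net, path, format = c("enewick", "tsv", "both")) {
    format <- match.arg(format)
    stopifnot(is(net, "HybridizationNetwork"))
    out <- character()
    if (format %in% c("enewick", "both")) {
        p <- if (format == "both") paste0(path, ".nwk") else path
        writeLines(enewick(net), p)
        out <- c(out, p)
    }
    if (format %in% c("tsv", "both")) {
        p <- if (format == "both") paste0(path, ".tsv") else path
        cols <- c("recipient", "recipientMembers", "donor1",
                  "donor1Members", "degree1", "donor2", "donor2Members",
                  "degree2", "score", "step")
        if ("round" %in% names(net@reticulations))
            cols <- c(cols, "round")
        utils::write.table(net@reticulations[, cols, drop = FALSE], p,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out <- c(out, p)
    }
    invisible(out)
}
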