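#' Accessor generics
#'
#' Small accessor generics for the package's containers: \code{taxa} returns
#' taxon labels, \code{cogsets} the homology-class labels, \code{meanings}
#' the character labels, \code{reticulations} the reticulation table of a
#' network, \code{backboneTree} its tree skeleton, and \code{wordTrees} the
#' per-character trees of a [WordTreeSet-class].
#'
#' @param x an object.
#' @return \code{taxa}, \code{cogsets}, \code{meanings}: character vectors;
#'   \code{reticulations}: a \code{data.frame}; \code{backboneTree}: an
#'   [ape::phylo] or \code{NULL}; \code{wordTrees}: a named list of
#'   [ape::phylo].
#' @name accessors
#' @examples
#' db <- exampleHybridDatabase()
#' taxa(db)
#' meanings(db)
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("cogsets", function(x) standardGeneric("cogsets"))

#' @rdname accessors
#' @export
setGeneric("meanings", function(x) standardGeneric("meanings"))

#' @rdname accessors
#' @export
setGeneric("reticulations", function(x) standardGeneric("reticulations"))

#' @rdname accessors
#' @export
setGeneric("backboneTree", function(x) standardGeneric("backboneTree"))

#' @rdname accessors
#' @export
setGeneric("wordTrees", function(x) standardGeneric("wordTrees"))
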