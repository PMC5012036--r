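## Per-character (per-meaning) word trees: one NJ tree per character with
## enough attested taxa, built from the per-meaning distance matrices.

#' Build per-meaning word trees
#'
#' For each character (meaning) of the database with at least \code{minTaxa}
#' attested taxa, computes the per-meaning distance matrix
#' ([meaningDistance()]) and infers the unrooted NJ word tree
#' ([njTree()]). Characters below the threshold are listed in the skip
#' report: trees with fewer than four leaves have identical topologies and
#' carry no grouping signal.
#'
#' @param db a non-empty [CognateDatabase-class].
#' @param minTaxa minimum number of attested taxa for a character to get a
#'   tree (default 4).
#' @return a [WordTreeSet-class].
#' @examples
#' wts <- buildWordTrees(exampleHybridDatabase())
#' length(wordTrees(wts))
#' @export
buildWordTrees <- function(db, minTaxa = 4L) {
    stopifnot(is(db, "CognateDatabase"))
    if (length(db) == 0L)
        stop("database is empty")
    minTaxa <- max(3L, as.integer(minTaxa))
    trees <- list()
    mats <- list()
    skipped <- list()
    for (ch in meanings(db)) {
        nTaxa <- length(unique(db@records$taxon[db@records$character == ch]))
        if (nTaxa < minTaxa) {
            skipped[[length(skipped) + 1L]] <-
                data.frame(character = ch, nTaxa = nTaxa,
                           stringsAsFactors = FALSE)
            next
        }
        Dm <- meaningDistance(db, ch)
        mats[[ch]] <- Dm
        trees[[ch]] <- njTree(Dm)
    }
    new("WordTreeSet", trees = trees, matrices = mats,
        skipped = if (length(skipped)) do.call(rbind, skipped) else
            data.frame(character = character(), nTaxa = integer(),
                       stringsAsFactors = FALSE),
        minTaxa = minTaxa)
}

#' @rdname accessors
#' @export
setMethod("wordTrees", "WordTreeSet", function(x) x@trees)

#' @describeIn buildWordTrees characters skipped for having too few taxa.
#' @param wts a \code{WordTreeSet}.
#' @export
skippedMeanings <- function(wts) {
    stopifnot(is(wts, "WordTreeSet"))
    wts@skipped
}

setMethod("show", "WordTreeSet", function(object) {
    cat(sprintf("WordTreeSet: %d tree(s) (minTaxa = %d), %d skipped\n",
                length(object@trees), object@minTaxa,
                nrow(object@skipped)))
})

#' Export word trees as a multi-Newick file
#'
#' One tree per line, preceded by the character label in a bracketed
#' Newick comment: \code{[character]newick;}. The file is suitable input
#' for consensus-network software; [readWordTrees()] parses it back.
#'
#' @param wts a non-empty [WordTreeSet-class].
#' @param path output path.
#' @param matrixDir optional directory; when given, the per-character
#'   distance matrices are also written there in PHYLIP square format.
#' @return \code{path}, invisibly.
#' @export
exportTrees <- function(wts, path, matrixDir = NULL) {
    stopifnot(is(wts, "WordTreeSet"))
    if (length(wts@trees) == 0L)
        stop("word tree set is empty")
    lines <- vapply(names(wts@trees), function(ch)
        paste0("[", ch, "]",
               ape::write.tree(wts@trees[[ch]])), "")
    writeLines(lines, path)
    if (!is.null(matrixDir)) {
        dir.create(matrixDir, showWarnings = FALSE, recursive = TRUE)
        for (ch in names(wts@matrices))
            writePhylipDist(wts@matrices[[ch]],
                            file.path(matrixDir, paste0(ch, ".phylip")))
    }
    invisible(path)
}

#' @rdname exportTrees
#' @return \code{readWordTrees}: a named list of [ape::phylo] trees.
#' @export
readWordTrees <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    labs <- sub("^\\[([^]]*)\\].*$", "\\1", lines)
    nwk <- sub("^\\[[^]]*\\]", "", lines)
    trees <- lapply(nwk, function(x) ape::read.tree(text = x))
    names(trees) <- labs
    trees
}
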