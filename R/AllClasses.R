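#' Cognate database
#'
#' Container for a character/cognate database: one record per observed word
#' form, giving the taxon (language), the character (meaning), the homology
#' class (cognate set) the form belongs to, and optionally the form itself.
#'
#' @slot records a \code{data.frame} with columns \code{taxon},
#'   \code{character}, \code{cogset} and \code{form} (character vectors;
#'   \code{form} may contain \code{NA}).
#'
#' @details Invariants enforced by the validity method: taxon and cogset
#' labels are non-empty; a cogset belongs to exactly one character; identical
#' \code{(taxon, cogset)} pairs may repeat only when their forms differ.
#'
#' @seealso [readCognateDatabase()], [buildPresenceAbsence()],
#'   [meaningDistance()], [buildWordTrees()]
#' @export
setClass("CognateDatabase", representation(records = "data.frame"))

setValidity("CognateDatabase", function(object) {
    rec <- object@records
    need <- c("taxon", "character", "cogset", "form")
    if (!all(need %in% names(rec)))
        return(sprintf("records must have columns %s",
                       paste(need, collapse = ", ")))
    if (nrow(rec) == 0L)
        return(TRUE)
    if (any(!nzchar(rec$taxon)) || any(!nzchar(rec$cogset)) ||
        any(is.na(rec$taxon)) || any(is.na(rec$cogset)))
        return("taxon and cogset labels must be non-empty")
    ## every cogset belongs to exactly one character
    byset <- tapply(rec$character, rec$cogset,
                    function(x) length(unique(x)))
    if (any(byset > 1L))
        return(sprintf("cogset(s) %s assigned to more than one character",
                       paste(names(byset)[byset > 1L], collapse = ", ")))
    key <- paste(rec$taxon, rec$cogset, ifelse(is.na(rec$form), "", rec$form),
                 sep = "\r")
    if (anyDuplicated(key))
        return("duplicate identical records present")
    TRUE
})

#' Presence-absence matrix
#'
#' Binary taxa-by-cogset matrix derived from a [CognateDatabase-class],
#' together with a taxa-by-character mask marking slots for which a taxon
#' has no recorded form (missing data).
#'
#' @slot values integer matrix (0/1), rows = taxa, columns = cogsets, both
#'   in lexicographic order.
#' @slot missing integer matrix (0/1), rows = taxa, columns = characters;
#'   1 marks a taxon with no recorded form for that character.
#' @slot cogsetCharacter named character vector mapping each cogset (names)
#'   to its character.
#'
#' @seealso [buildPresenceAbsence()], [hammingDistance()]
#' @export
setClass("PresenceAbsenceMatrix",
         representation(values = "matrix", missing = "matrix",
                        cogsetCharacter = "character"))

setValidity("PresenceAbsenceMatrix", function(object) {
    v <- object@values
    if (!all(v %in% c(0L, 1L)))
        return("values must be binary")
    if (ncol(v) != length(object@cogsetCharacter))
        return("one cogsetCharacter entry per column expected")
    if (!identical(colnames(v), names(object@cogsetCharacter)))
        return("column names must match cogsetCharacter names")
    m <- object@missing
    if (!identical(rownames(v), rownames(m)))
        return("values and missing must share row names")
    ## a missing slot implies all-zero values on that character's cogsets
    for (ch in colnames(m)) {
        cols <- names(object@cogsetCharacter)[object@cogsetCharacter == ch]
        bad <- m[, ch] == 1L & rowSums(v[, cols, drop = FALSE]) > 0
        if (any(bad))
            return(sprintf("taxon %s marked missing for %s but has a form",
                           rownames(m)[bad][1L], ch))
    }
    TRUE
})

#' Detection parameters
#'
#' User-set thresholds of the hybrid detection rule: the minimum reticulation
#' score \code{minScore} a candidate triplet must reach, and the admissible
#' range \code{[alphaMin, alphaMax]} for the estimated hybridization degree.
#'
#' @slot minScore numeric, minimum reticulation score.
#' @slot alphaMin,alphaMax numeric in (0, 1) with
#'   \code{0 < alphaMin < alphaMax < 1}.
#'
#' @seealso [DetectionParameters()], [defaultDetectionParameters()],
#'   [inferNetwork()]
#' @export
setClass("DetectionParameters",
         representation(minScore = "numeric", alphaMin = "numeric",
                        alphaMax = "numeric"))

setValidity("DetectionParameters", function(object) {
    if (length(object@minScore) != 1L || length(object@alphaMin) != 1L ||
        length(object@alphaMax) != 1L)
        return("all parameters must be scalars")
    if (!is.finite(object@alphaMin) || !is.finite(object@alphaMax))
        return("alpha bounds must be finite")
    if (!(object@alphaMin > 0 && object@alphaMin < object@alphaMax &&
          object@alphaMax < 1))
        return("need 0 < alphaMin < alphaMax < 1")
    TRUE
})

#' Hybridization network
#'
#' Result of [inferNetwork()] / [iterateRemoval()]: a tree over the
#' non-hybrid nodes plus a table of reticulations, each giving the recipient,
#' its two donors (possibly agglomerated ancestral clusters) and the degree
#' attributed to each donor.
#'
#' @slot tree an [ape::phylo] object (the tree skeleton), or \code{NULL}.
#' @slot reticulations a \code{data.frame} with one row per reticulation:
#'   \code{recipient}, \code{recipientMembers}, \code{donor1},
#'   \code{donor1Members}, \code{degree1}, \code{donor2},
#'   \code{donor2Members}, \code{degree2}, \code{score}, \code{ls},
#'   \code{delta}, \code{step} and (after iterated runs) \code{round}.
#'   Member columns hold "+"-separated taxon lists.
#' @slot params the [DetectionParameters-class] used.
#' @slot nodes internal nested node structure retained for extended-Newick
#'   output (list).
#' @slot trace \code{data.frame} log of per-step decisions (joins and
#'   removals).
#'
#' @seealso [reticulations()], [backboneTree()], [writeNetwork()]
#' @export
setClass("HybridizationNetwork",
         representation(tree = "ANY", reticulations = "data.frame",
                        params = "ANY", nodes = "list", trace = "data.frame"))

setValidity("HybridizationNetwork", function(object) {
    ret <- object@reticulations
    if (nrow(ret)) {
        if (anyDuplicated(ret$recipient))
            return("every recipient must appear in exactly one reticulation")
        if (max(abs(ret$degree1 + ret$degree2 - 1)) > 0)
            return("degrees of each reticulation must sum to exactly 1")
        if (!is.null(object@tree) &&
            any(ret$recipient %in% object@tree$tip.label))
            return("recipients must be absent from tree leaves")
    }
    TRUE
})

#' Word tree set
#'
#' Per-character (per-meaning) unrooted NJ trees built from the per-meaning
#' distance matrices, for characters with at least \code{minTaxa} taxa.
#'
#' @slot trees named list of [ape::phylo] objects, one per retained
#'   character.
#' @slot matrices named list of the per-character distance matrices used.
#' @slot skipped \code{data.frame} (\code{character}, \code{nTaxa}) listing
#'   characters below the taxon threshold.
#' @slot minTaxa integer threshold used.
#'
#' @seealso [buildWordTrees()], [exportTrees()]
#' @export
setClass("WordTreeSet",
         representation(trees = "list", matrices = "list",
                        skipped = "data.frame", minTaxa = "integer"))
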