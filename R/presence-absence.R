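#' Build the presence-absence matrix of a cognate database
#'
#' Encodes a [CognateDatabase-class] as a binary taxa-by-cogset matrix:
#' entry \code{(t, c)} is 1 iff taxon \code{t} has at least one recorded
#' form in cogset \code{c}. A taxon with no record at all for a character
#' (meaning) is flagged in the missing-data mask for that character; all of
#' that character's cogset columns are 0 for the taxon.
#'
#' Taxa and cogsets are ordered lexicographically so that all downstream
#' output is deterministic.
#'
#' @param db a non-empty [CognateDatabase-class].
#' @return a [PresenceAbsenceMatrix-class].
#' @examples
#' db <- exampleHybridDatabase()
#' pam <- buildPresenceAbsence(db)
#' dim(presenceValues(pam))
#' @export
buildPresenceAbsence <- function(db) {
    stopifnot(is(db, "CognateDatabase"))
    rec <- db@records
    if (nrow(rec) == 0L)
        stop("cannot build a presence-absence matrix from an empty database")
    tx <- taxa(db)
    cs <- cogsets(db)
    ch <- meanings(db)
    values <- matrix(0L, length(tx), length(cs), dimnames = list(tx, cs))
    values[cbind(match(rec$taxon, tx), match(rec$cogset, cs))] <- 1L
    miss <- matrix(1L, length(tx), length(ch), dimnames = list(tx, ch))
    miss[cbind(match(rec$taxon, tx), match(rec$character, ch))] <- 0L
    map <- tapply(rec$character, rec$cogset, function(x) x[1L])
    map <- structure(as.character(map), names = names(map))[cs]
    new("PresenceAbsenceMatrix", values = values, missing = miss,
        cogsetCharacter = map)
}

#' @describeIn buildPresenceAbsence binary values matrix of a
#'   [PresenceAbsenceMatrix-class].
#' @param pam a \code{PresenceAbsenceMatrix}.
#' @export
presenceValues <- function(pam) {
    stopifnot(is(pam, "PresenceAbsenceMatrix"))
    pam@values
}

#' @describeIn buildPresenceAbsence taxa-by-character missing-data mask.
#' @export
missingMask <- function(pam) {
    stopifnot(is(pam, "PresenceAbsenceMatrix"))
    pam@missing
}

#' @rdname accessors
#' @export
setMethod("taxa", "PresenceAbsenceMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("cogsets", "PresenceAbsenceMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("meanings", "PresenceAbsenceMatrix",
          function(x) colnames(x@missing))

setMethod("show", "PresenceAbsenceMatrix", function(object) {
    cat(sprintf(paste0("PresenceAbsenceMatrix: %d taxa x %d cogsets ",
                       "(%d characters); %.2f%% missing slots\n"),
                nrow(object@values), ncol(object@values),
                ncol(object@missing), 100 * mean(object@missing == 1L)))
})

#' Export a presence-absence matrix as wide TSV
#'
#' Writes the binary matrix with a leading \code{taxon} column; the
#' missing-data mask is written separately to \code{missingPath} in the
#' same layout (columns = characters) when given.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param path output path for the values matrix.
#' @param missingPath optional output path for the mask.
#' @return \code{path}, invisibly.
#' @export
writePresenceAbsence <- function(pam, path, missingPath = NULL) {
    stopifnot(is(pam, "PresenceAbsenceMatrix"))
    .writeWide <- function(m, p) {
        df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    .writeWide(pam@values, path)
    if (!is.null(missingPath))
        .writeWide(pam@missing, missingPath)
    invisible(path)
}
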