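#' Construct a cognate database from a data frame
#'
#' @param records data.frame with columns \code{taxon}, \code{character},
#'   \code{cogset} and optionally \code{form}.
#' @param deduplicate drop exact duplicate records with a warning
#'   (default \code{TRUE}).
#' @return a [CognateDatabase-class].
#' @examples
#' db <- CognateDatabase(data.frame(
#'     taxon = c("L1", "L2", "L3"), character = "fruit",
#'     cogset = c("c1", "c1", "c2"), form = c("foo", "fu", "bar")))
#' db
#' @export
CognateDatabase <- function(records, deduplicate = TRUE) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    if (is.null(records$form))
        records$form <- NA_character_
    records <- records[, c("taxon", "character", "cogset", "form")]
    for (cl in names(records))
        records[[cl]] <- as.character(records[[cl]])
    records$form[!is.na(records$form) & !nzchar(records$form)] <-
        NA_character_
    if (deduplicate && nrow(records)) {
        key <- do.call(paste, c(records, sep = "\r"))
        if (anyDuplicated(key)) {
            warning(sum(duplicated(key)),
                    " duplicate identical record(s) dropped")
            records <- records[!duplicated(key), , drop = FALSE]
        }
    }
    rownames(records) <- NULL
    new("CognateDatabase", records = records)
}

#' Read a cognate database from a delimited file
#'
#' Reads the package's 4-column tabular format: a header row naming the
#' columns \code{taxon}, \code{character}, \code{cogset}, \code{form}
#' (in any order; \code{form} may be empty), one record per row.
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return a [CognateDatabase-class]. Row order is preserved; exact
#'   duplicate records are dropped with a warning.
#' @details A row with a missing taxon, character or cogset field raises a
#'   parse error naming the offending line (header = line 1).
#' @seealso [writeCognateDatabase()]
#' @export
readCognateDatabase <- function(path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("input file not found: ", path)
    sep <- if (dialect == "tsv") "\t" else ","
    rec <- utils::read.table(path, sep = sep, header = TRUE,
                             colClasses = "character", quote = "\"",
                             na.strings = character(), fill = TRUE,
                             comment.char = "", stringsAsFactors = FALSE)
    need <- c("taxon", "character", "cogset")
    if (!all(need %in% names(rec)))
        stop("header must name columns taxon, character, cogset")
    if (nrow(rec)) {
        bad <- !nzchar(rec$taxon) | !nzchar(rec$character) |
            !nzchar(rec$cogset) | is.na(rec$taxon) | is.na(rec$character) |
            is.na(rec$cogset)
        if (any(bad))
            stop("malformed record at line ", which(bad)[1L] + 1L,
                 " of ", path, ": empty taxon, character or cogset field")
    }
    CognateDatabase(rec)
}

#' Write a cognate database to a delimited file
#'
#' @param db a [CognateDatabase-class].
#' @param path output path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeCognateDatabase <- function(db, path, dialect = c("tsv", "csv")) {
    dialect <- match.arg(dialect)
    stopifnot(is(db, "CognateDatabase"))
    rec <- db@records
    rec$form[is.na(rec$form)] <- ""
    utils::write.table(rec, path, sep = if (dialect == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname accessors
#' @export
setMethod("taxa", "CognateDatabase", function(x)
    sort(unique(x@records$taxon), method = "radix"))

#' @rdname accessors
#' @export
setMethod("cogsets", "CognateDatabase", function(x)
    sort(unique(x@records$cogset), method = "radix"))

#' @rdname accessors
#' @export
setMethod("meanings", "CognateDatabase", function(x)
    sort(unique(x@records$character), method = "radix"))

#' @describeIn CognateDatabase-class number of records.
#' @param x a \code{CognateDatabase}.
#' @export
setMethod("length", "CognateDatabase", function(x) nrow(x@records))

#' Records of a cognate database
#'
#' @param db a [CognateDatabase-class].
#' @return the underlying records \code{data.frame}.
#' @export
cognateRecords <- function(db) {
    stopifnot(is(db, "CognateDatabase"))
    db@records
}

setMethod("show", "CognateDatabase", function(object) {
    cat(sprintf(paste0("CognateDatabase: %d record(s), %d taxa, ",
                       "%d character(s), %d cogset(s)\n"),
                nrow(object@records), length(taxa(object)),
                length(meanings(object)), length(cogsets(object))))
})
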