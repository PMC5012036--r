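## Distance computations: Hamming over presence-absence profiles (two
## missing-data strategies), normalized Levenshtein between word forms, and
## the per-meaning distance combining cogset membership with form distances.

.checkDistanceMatrix <- function(D, what = "distance matrix") {
    if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
        stop(what, " must be a square numeric matrix")
    if (is.null(rownames(D)) || anyDuplicated(rownames(D)))
        stop(what, " must have unique row names")
    if (!identical(rownames(D), colnames(D)))
        stop(what, " must have identical row and column names")
    if (any(!is.finite(D)))
        stop(what, " must be finite")
    if (any(D < 0))
        stop(what, " must be nonnegative")
    if (max(abs(D - t(D))) > 0)
        stop(what, " must be symmetric")
    if (any(diag(D) != 0))
        stop(what, " must have a zero diagonal")
    invisible(D)
}

#' Hamming distances between presence-absence profiles
#'
#' Pairwise distances between taxa counted over cogset columns. Two
#' strategies handle missing data:
#' \describe{
#'   \item{\code{missing_as_zero}}{missing slots are encoded as 0, and the
#'     distance is the plain count of cogsets containing a form of exactly
#'     one of the two taxa;}
#'   \item{\code{normalized}}{the count is restricted to characters for
#'     which both taxa have a recorded form, and divided by the number of
#'     such shared characters.}
#' }
#'
#' @param pam a [PresenceAbsenceMatrix-class] with at least 2 taxa.
#' @param strategy \code{"missing_as_zero"} (default) or
#'   \code{"normalized"}.
#' @return a symmetric distance matrix over the taxa.
#' @details Under \code{normalized}, a pair of taxa with no shared
#'   non-missing character is an error naming the pair.
#' @examples
#' pam <- buildPresenceAbsence(exampleHybridDatabase())
#' hammingDistance(pam)["L3", "L4"]
#' @export
hammingDistance <- function(pam,
                            strategy = c("missing_as_zero", "normalized")) {
    strategy <- match.arg(strategy)
    stopifnot(is(pam, "PresenceAbsenceMatrix"))
    M <- pam@values
    if (nrow(M) < 2L)
        stop("need at least 2 taxa")
    storage.mode(M) <- "double"
    k <- rowSums(M)
    ## |x - y| summed over binary columns = k_i + k_j - 2 x.y
    Dfull <- outer(k, k, "+") - 2 * tcrossprod(M)
    if (strategy == "missing_as_zero") {
        diag(Dfull) <- 0
        return(.checkDistanceMatrix(round(Dfull)))
    }
    present <- 1 - pam@missing
    storage.mode(present) <- "double"
    shared <- tcrossprod(present)          # characters non-missing in both
    diag(shared) <- NA
    if (any(shared == 0, na.rm = TRUE)) {
        bad <- which(shared == 0, arr.ind = TRUE)[1L, ]
        stop("taxa ", rownames(M)[bad[1L]], " and ", rownames(M)[bad[2L]],
             " share no non-missing character; normalized Hamming undefined")
    }
    ## numerator restricted to characters non-missing in both taxa
    num <- matrix(0, nrow(M), nrow(M), dimnames = dimnames(Dfull))
    for (ch in colnames(pam@missing)) {
        cols <- names(pam@cogsetCharacter)[pam@cogsetCharacter == ch]
        Mc <- M[, cols, drop = FALSE]
        kc <- rowSums(Mc)
        ham <- outer(kc, kc, "+") - 2 * tcrossprod(Mc)
        both <- tcrossprod(present[, ch])
        num <- num + ham * both
    }
    D <- num / shared
    diag(D) <- 0
    .checkDistanceMatrix(D)
}

#' Normalized Levenshtein distance between two strings
#'
#' Minimum number of single-letter insertions, deletions and substitutions
#' turning one word into the other, divided by the length of the longer
#' word. Strings are compared by Unicode code point. Two empty strings are
#' at distance 0.
#'
#' @param w1,w2 character scalars (or equal-length vectors, compared
#'   elementwise).
#' @return numeric in \[0, 1\].
#' @examples
#' normalizedLevenshtein("fruit", "frukt")  # 1 edit / 5 letters = 0.2
#' @export
normalizedLevenshtein <- function(w1, w2) {
    w1 <- as.character(w1)
    w2 <- as.character(w2)
    len <- max(length(w1), length(w2))
    w1 <- rep_len(w1, len)
    w2 <- rep_len(w2, len)
    raw <- if (len == 1L) utils::adist(w1, w2)[1L, 1L]
           else mapply(function(a, b) utils::adist(a, b)[1L, 1L], w1, w2,
                       USE.NAMES = FALSE)
    denom <- pmax(nchar(w1), nchar(w2))
    ifelse(denom == 0L, 0, raw / denom)
}

#' Per-meaning distance matrix
#'
#' For one character (meaning) \eqn{m}, computes the distance between every
#' pair of taxa that have at least one form for \eqn{m}: each cogset of the
#' character contributes 0 if neither taxon has a form in it, 1 if exactly
#' one does, and otherwise the minimum normalized Levenshtein distance over
#' all cross-taxon form pairs in the set; the sum is divided by the number
#' of cogsets of the character containing a form of either taxon.
#'
#' @param db a [CognateDatabase-class].
#' @param character a character (meaning) label present in \code{db} with
#'   at least 2 taxa.
#' @return a symmetric distance matrix over the taxa attested for the
#'   character, entries in \[0, 1\].
#' @seealso [buildWordTrees()]
#' @export
meaningDistance <- function(db, character) {
    stopifnot(is(db, "CognateDatabase"))
    rec <- db@records[db@records$character == character, , drop = FALSE]
    if (nrow(rec) == 0L)
        stop("no records for character ", character)
    lm <- sort(unique(rec$taxon), method = "radix")
    if (length(lm) < 2L)
        stop("character ", character, " has fewer than 2 taxa")
    cm <- sort(unique(rec$cogset), method = "radix")
    ## forms per (cogset, taxon); a record with no form still counts as
    ## membership, with the cogset label standing in for form comparisons
    forms <- ifelse(is.na(rec$form), rec$cogset, rec$form)
    D <- matrix(0, length(lm), length(lm), dimnames = list(lm, lm))
    member <- matrix(FALSE, length(lm), length(cm),
                     dimnames = list(lm, cm))
    member[cbind(match(rec$taxon, lm), match(rec$cogset, cm))] <- TRUE
    for (a in seq_len(length(lm) - 1L)) {
        for (b in seq(a + 1L, length(lm))) {
            l1 <- lm[a]; l2 <- lm[b]
            denom <- sum(member[a, ] | member[b, ])
            total <- 0
            for (ci in seq_along(cm)) {
                in1 <- member[a, ci]; in2 <- member[b, ci]
                if (!in1 && !in2) next            # contributes 0
                if (xor(in1, in2)) { total <- total + 1; next }
                f1 <- forms[rec$taxon == l1 & rec$cogset == cm[ci]]
                f2 <- forms[rec$taxon == l2 & rec$cogset == cm[ci]]
                total <- total +
                    min(outer(f1, f2, normalizedLevenshtein))
            }
            D[a, b] <- D[b, a] <- total / denom
        }
    }
    .checkDistanceMatrix(D)
}

#' Read / write PHYLIP square distance matrices
#'
#' Plain square PHYLIP layout: the taxon count on the first line, then one
#' line per taxon giving its label followed by the full row of distances.
#' A relaxed dialect is used: labels are whitespace-delimited tokens of any
#' length (no 10-character truncation or padding).
#'
#' @param path file path.
#' @return \code{readPhylipDist}: a symmetric named distance matrix.
#' @export
readPhylipDist <- function(path) {
    if (!file.exists(path))
        stop("input file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(trimws(lines[1L]))
    if (is.na(n) || n < 1L)
        stop("first line must give the taxon count")
    if (length(lines) < n + 1L)
        stop("expected ", n, " taxon rows, found ", length(lines) - 1L)
    labs <- character(n)
    D <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) {
        tok <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1L]]
        if (length(tok) != n + 1L)
            stop("row ", i, ": expected label plus ", n, " values")
        labs[i] <- tok[1L]
        D[i, ] <- as.numeric(tok[-1L])
    }
    dimnames(D) <- list(labs, labs)
    .checkDistanceMatrix(D)
}

#' @rdname readPhylipDist
#' @param D symmetric named distance matrix.
#' @param digits significant digits written (default 6).
#' @return \code{writePhylipDist}: \code{path}, invisibly.
#' @export
writePhylipDist <- function(D, path, digits = 6) {
    .checkDistanceMatrix(D)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(format(nrow(D)), con)
    for (i in seq_len(nrow(D)))
        writeLines(paste(c(rownames(D)[i],
                           formatC(D[i, ], digits = digits, format = "g")),
                         collapse = " "), con)
    invisible(path)
}
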