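## Neighbor-joining agglomeration engine. The same stepwise machinery backs
## njTree() (plain NJ) and inferNetwork() (NJ with per-step hybrid
## detection). Distance matrices are plain symmetric numeric matrices with
## unique row/column names; agglomerated nodes are labeled by the sorted
## "+"-joined list of their member taxa, which also fixes all tie-breaking.

.TIE_EPS <- 1e-9

.mergeLabel <- function(i, j) {
    paste(sort(unique(c(strsplit(i, "+", fixed = TRUE)[[1L]],
                        strsplit(j, "+", fixed = TRUE)[[1L]])),
               method = "radix"), collapse = "+")
}

.leafNode <- function(label) {
    list(label = label, members = label, offset = 0, children = list())
}

.fragmentNewick <- function(node) {
    if (length(node$children) == 0L)
        return(node$label)
    inner <- vapply(node$children, function(ch)
        sprintf("%s:%.6g", .fragmentNewick(ch$node), ch$length), "")
    paste0("(", paste(inner, collapse = ","), ")")
}

.rootToPhylo <- function(root) {
    ape::read.tree(text = paste0(.fragmentNewick(root), ";"))
}

#' Select the pair of active nodes to be joined
#'
#' Returns the pair minimizing the neighbor-joining selection criterion
#' \eqn{Q(i,j) = (n-2)\,d(i,j) - R_i - R_j} (with \eqn{R_i} the row sum of
#' \eqn{i}), which is the pair whose joined configuration minimizes the
#' least-squares total branch length of the tree. Ties are broken
#' lexicographically on the sorted label pair.
#'
#' @param D symmetric named distance matrix over at least 3 active nodes.
#' @return character vector of the two selected labels, sorted.
#' @examples
#' D <- randomAdditiveMatrix(6, seed = 1)$D
#' njSelectPair(D)
#' @export
njSelectPair <- function(D) {
    .checkDistanceMatrix(D)
    n <- nrow(D)
    if (n < 3L)
        stop("pair selection requires at least 3 active nodes")
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hits <- which(Q <= qmin + .TIE_EPS * (1 + abs(qmin)), arr.ind = TRUE)
    labs <- rownames(D)
    pairs <- t(apply(hits, 1L, function(rc)
        sort(labs[rc], method = "radix")))
    pairs <- unique(pairs)
    pairs[order(pairs[, 1L], pairs[, 2L], method = "radix")[1L], ]
}

#' Agglomerate two active nodes in a distance matrix
#'
#' Replaces nodes \code{i} and \code{j} by their common ancestor \code{X}
#' with updated distances \eqn{d(X,k) = \frac{1}{2}(d(i,k) + d(j,k))} to
#' every remaining node; all other entries are unchanged.
#'
#' @param D symmetric named distance matrix.
#' @param i,j distinct active-node labels of \code{D}.
#' @param label label of the new node; defaults to the sorted
#'   "+"-joined union of the members encoded in \code{i} and \code{j}.
#' @return the reduced distance matrix (one row/column fewer).
#' @examples
#' D <- randomAdditiveMatrix(5, seed = 1)$D
#' njUpdate(D, "T01", "T02")
#' @export
njUpdate <- function(D, i, j, label = .mergeLabel(i, j)) {
    .checkDistanceMatrix(D)
    labs <- rownames(D)
    if (!all(c(i, j) %in% labs) || i == j)
        stop("i and j must be distinct active nodes of D")
    keep <- setdiff(labs, c(i, j))
    newRow <- (D[i, keep] + D[j, keep]) / 2
    out <- rbind(cbind(D[keep, keep, drop = FALSE], newRow), c(newRow, 0))
    dimnames(out) <- list(c(keep, label), c(keep, label))
    out
}

## Join the selected pair inside the engine state; returns updated state.
.joinPair <- function(state, i, j) {
    D <- state$D
    n <- nrow(D)
    ni <- state$nodes[[i]]
    nj <- state$nodes[[j]]
    if (n > 2L) {
        R <- rowSums(D)
        bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2)) - ni$offset
        bj <- D[i, j] / 2 + (R[j] - R[i]) / (2 * (n - 2)) - nj$offset
    } else {
        len <- D[i, j] - ni$offset - nj$offset
        bi <- bj <- len / 2
    }
    label <- .mergeLabel(i, j)
    node <- list(label = label,
                 members = sort(c(ni$members, nj$members), method = "radix"),
                 offset = D[i, j] / 2,
                 children = list(list(node = ni, length = bi),
                                 list(node = nj, length = bj)))
    state$D <- njUpdate(D, i, j, label)
    state$nodes[[i]] <- NULL
    state$nodes[[j]] <- NULL
    state$nodes[[label]] <- node
    state
}

## Resolve the last three active nodes with the three-point formulas.
.resolveFinal <- function(state) {
    D <- state$D
    n <- nrow(D)
    if (n == 1L)
        return(state$nodes[[1L]])
    if (n == 2L) {
        labs <- rownames(D)
        st <- .joinPair(state, labs[1L], labs[2L])
        return(st$nodes[[1L]])
    }
    labs <- sort(rownames(D), method = "radix")
    a <- labs[1L]; b <- labs[2L]; c <- labs[3L]
    ba <- (D[a, b] + D[a, c] - D[b, c]) / 2 - state$nodes[[a]]$offset
    bb <- (D[a, b] + D[b, c] - D[a, c]) / 2 - state$nodes[[b]]$offset
    bc <- (D[a, c] + D[b, c] - D[a, b]) / 2 - state$nodes[[c]]$offset
    list(label = .mergeLabel(.mergeLabel(a, b), c),
         members = sort(c(state$nodes[[a]]$members,
                          state$nodes[[b]]$members,
                          state$nodes[[c]]$members), method = "radix"),
         offset = 0,
         children = list(list(node = state$nodes[[a]], length = ba),
                         list(node = state$nodes[[b]], length = bb),
                         list(node = state$nodes[[c]], length = bc)))
}

## Core agglomeration loop. When detect = TRUE, each pending join is first
## screened with detectAtStep(); an accepted candidate removes the recipient
## instead of joining, and pair selection restarts on the reduced matrix.
.agglomerate <- function(D, detect = FALSE, params = NULL) {
    .checkDistanceMatrix(D)
    state <- list(D = D, nodes = NULL)
    state$nodes <- stats::setNames(
        lapply(rownames(D), .leafNode), rownames(D))
    rets <- list()
    removed <- list()
    trace <- list()
    step <- 0L
    while (nrow(state$D) > 3L) {
        step <- step + 1L
        pair <- njSelectPair(state$D)
        i <- pair[1L]; j <- pair[2L]
        cand <- NULL
        if (detect && nrow(state$D) >= 5L)
            cand <- detectAtStep(state$D, i, j, params)
        if (!is.null(cand)) {
            h <- cand$h
            recNode <- state$nodes[[h]]
            d1 <- state$nodes[[cand$donor1]]
            d2 <- state$nodes[[cand$donor2]]
            rets[[length(rets) + 1L]] <- data.frame(
                recipient = h,
                recipientMembers = paste(recNode$members, collapse = "+"),
                donor1 = cand$donor1,
                donor1Members = paste(d1$members, collapse = "+"),
                degree1 = cand$alpha,
                donor2 = cand$donor2,
                donor2Members = paste(d2$members, collapse = "+"),
                degree2 = 1 - cand$alpha,
                score = cand$score, ls = cand$ls, delta = cand$delta,
                step = step, stringsAsFactors = FALSE)
            removed[[h]] <- recNode
            keep <- setdiff(rownames(state$D), h)
            state$D <- state$D[keep, keep, drop = FALSE]
            state$nodes[[h]] <- NULL
            trace[[length(trace) + 1L]] <- data.frame(
                step = step, action = "remove", node1 = h,
                node2 = paste(cand$donor1, cand$donor2, sep = "|"),
                n = nrow(state$D), stringsAsFactors = FALSE)
        } else {
            state <- .joinPair(state, i, j)
            trace[[length(trace) + 1L]] <- data.frame(
                step = step, action = "join", node1 = i, node2 = j,
                n = nrow(state$D), stringsAsFactors = FALSE)
        }
    }
    root <- .resolveFinal(state)
    list(root = root,
         reticulations = if (length(rets)) do.call(rbind, rets) else
             .emptyReticulations(),
         removed = removed,
         trace = if (length(trace)) do.call(rbind, trace) else
             data.frame(step = integer(), action = character(),
                        node1 = character(), node2 = character(),
                        n = integer(), stringsAsFactors = FALSE))
}

.emptyReticulations <- function() {
    data.frame(recipient = character(), recipientMembers = character(),
               donor1 = character(), donor1Members = character(),
               degree1 = numeric(), donor2 = character(),
               donor2Members = character(), degree2 = numeric(),
               score = numeric(), ls = numeric(), delta = numeric(),
               step = integer(), stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Plain NJ agglomeration with the pair-selection criterion of
#' [njSelectPair()], the reduction formula of [njUpdate()], and pendant
#' branch lengths from the standard NJ estimator corrected for the
#' node-height offset that the plain-average reduction accumulates (see the
#' methods vignette). On an additive matrix the leaf-to-leaf path lengths of
#' the returned tree reproduce the input distances exactly.
#'
#' Negative branch-length estimates are reported as-is.
#'
#' @param D symmetric nonnegative named distance matrix, \eqn{n \ge 3}.
#' @return an unrooted [ape::phylo] tree with \eqn{n} leaves.
#' @examples
#' sim <- randomAdditiveMatrix(6, seed = 42)
#' tr <- njTree(sim$D)
#' @export
njTree <- function(D) {
    .checkDistanceMatrix(D)
    if (nrow(D) < 3L)
        stop("njTree requires at least 3 taxa")
    res <- .agglomerate(D, detect = FALSE)
    .rootToPhylo(res$root)
}
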