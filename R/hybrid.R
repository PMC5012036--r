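## Hybrid detection: closed-form least-squares hybridization degree, the
## four-point-condition reticulation score, the neighbor-deviation statistic
## of the pending NJ pair, the per-step acceptance rule, and the full
## network-inference loop.

.checkTriplet <- function(D, h, i, j, minN) {
    .checkDistanceMatrix(D)
    labs <- rownames(D)
    if (!all(c(h, i, j) %in% labs))
        stop("h, i and j must be active nodes of D")
    if (anyDuplicated(c(h, i, j)))
        stop("h, i and j must be distinct")
    if (nrow(D) < minN)
        stop("need at least ", minN, " active nodes")
    setdiff(labs, c(h, i, j))
}

#' Hybridization degree estimated by least squares
#'
#' Closed-form estimate of the degree \eqn{\alpha} with which donor \code{i}
#' contributed to putative hybrid \code{h} (donor \code{j} contributing
#' \eqn{1-\alpha}):
#' \deqn{\hat\alpha = \frac{\sum_{k \ne i,j,h} X_k (Y_k - S_h + S_j)}
#'                         {\sum_{k \ne i,j,h} X_k^2}}
#' with \eqn{S_l = \sum_{k \ne i,j,h} d(k,l) / (n-3)},
#' \eqn{Y_k = d(k,h) - d(k,j)} and
#' \eqn{X_k = S_j - S_i + d(k,i) - d(k,j)}, where \eqn{n} is the current
#' number of active nodes. This is the minimizer of [leastSquaresFit()].
#'
#' On a matrix satisfying \eqn{d(k,h) = \alpha d(k,i) + (1-\alpha) d(k,j)}
#' for every other node \eqn{k}, the estimate equals \eqn{\alpha} exactly.
#'
#' @param D symmetric named distance matrix with at least 5 active nodes.
#' @param h putative hybrid (recipient) label.
#' @param i,j putative donor labels.
#' @return the estimated degree, or \code{NA} when
#'   \eqn{\sum X_k^2 = 0} (donors indistinguishable from every remaining
#'   node; such a candidate is rejected, not an error).
#' @examples
#' sim <- randomAdditiveMatrix(6, seed = 7)
#' D <- injectHybrid(sim$D, "T01", "T04", alpha = 0.3)
#' estimateAlpha(D, "H1", "T01", "T04")
#' @export
estimateAlpha <- function(D, h, i, j) {
    ks <- .checkTriplet(D, h, i, j, minN = 5L)
    Sh <- mean(D[ks, h]); Si <- mean(D[ks, i]); Sj <- mean(D[ks, j])
    Y <- D[ks, h] - D[ks, j]
    X <- Sj - Si + D[ks, i] - D[ks, j]
    denom <- sum(X * X)
    if (denom == 0)
        return(NA_real_)
    sum(X * (Y - Sh + Sj)) / denom
}

#' Least-squares misfit of a hybrid hypothesis at a given degree
#'
#' \deqn{LS = \sum_{k \ne i,j,h} (Y_k - S_h + S_j - \alpha X_k)^2}
#' with the same auxiliaries as [estimateAlpha()]; nonnegative and minimized
#' at \code{alpha = estimateAlpha(D, h, i, j)}.
#'
#' @inheritParams estimateAlpha
#' @param alpha hybridization degree at which to evaluate the misfit.
#' @return nonnegative numeric.
#' @export
leastSquaresFit <- function(D, h, i, j, alpha) {
    ks <- .checkTriplet(D, h, i, j, minN = 5L)
    Sh <- mean(D[ks, h]); Si <- mean(D[ks, i]); Sj <- mean(D[ks, j])
    Y <- D[ks, h] - D[ks, j]
    X <- Sj - Si + D[ks, i] - D[ks, j]
    sum((Y - Sh + Sj - alpha * X)^2)
}

#' Four-point-condition reticulation score of a triplet
#'
#' \deqn{Sc = \min_{k \ne i,j,h} \{\, d(i,j)+d(k,h)-d(i,h)-d(k,j);\;
#'        d(i,j)+d(k,h)-d(j,h)-d(k,i) \,\}}
#' The score measures deviation from the four-point condition; it is 0 on
#' any additive (tree-realizable) matrix and grows as \code{h} is pulled
#' away from a tree position, so larger values indicate stronger non-tree
#' signal for \code{h} as a hybrid of \code{i} and \code{j}.
#'
#' @inheritParams estimateAlpha
#' @return numeric score.
#' @export
hybridizationScore <- function(D, h, i, j) {
    ks <- .checkTriplet(D, h, i, j, minN = 4L)
    e1 <- D[i, j] + D[ks, h] - D[i, h] - D[ks, j]
    e2 <- D[i, j] + D[ks, h] - D[j, h] - D[ks, i]
    min(pmin(e1, e2))
}

#' Neighbor-deviation statistic of a pending join
#'
#' For the pair \code{(i, j)} selected by NJ, evaluates for every other
#' active node \eqn{h}
#' \deqn{\Delta_{i,j}^h = \sum_{k \ne i,j}
#'   \big(d(j,h)+d(i,k)-d(j,k)-d(i,h)\big),}
#' which equals 0 for every \eqn{h} when \code{i} and \code{j} are true
#' neighbors in an additive tree. Returns the node \eqn{h_0} maximizing
#' \eqn{|\Delta|} (ties broken lexicographically) along with its
#' \eqn{\Delta} value and the full vector of deviations.
#'
#' @param D symmetric named distance matrix with at least 4 active nodes.
#' @param i,j the pending pair.
#' @return list with elements \code{h} (label), \code{delta} (its
#'   deviation) and \code{deviations} (named vector over all candidates).
#' @export
neighborDeviation <- function(D, i, j) {
    .checkDistanceMatrix(D)
    labs <- rownames(D)
    if (!all(c(i, j) %in% labs) || i == j)
        stop("i and j must be distinct active nodes of D")
    n <- nrow(D)
    if (n < 4L)
        stop("need at least 4 active nodes")
    hs <- sort(setdiff(labs, c(i, j)), method = "radix")
    S <- sum(D[i, hs] - D[j, hs])
    dev <- (n - 2) * (D[j, hs] - D[i, hs]) + S
    names(dev) <- hs
    m <- max(abs(dev))
    cand <- hs[abs(dev) >= m - .TIE_EPS * (1 + m)]
    h0 <- cand[1L]
    list(h = h0, delta = unname(dev[h0]), deviations = dev)
}

#' Detection parameters
#'
#' @param minScore minimum reticulation score a candidate triplet must
#'   reach (default 0).
#' @param alphaMin,alphaMax admissible range for the estimated degree
#'   (defaults 0.1 and 0.9); \code{0 < alphaMin < alphaMax < 1}.
#' @return a validated [DetectionParameters-class].
#' @examples
#' DetectionParameters(0, 0.1, 0.9)
#' @export
DetectionParameters <- function(minScore = 0, alphaMin = 0.1,
                                alphaMax = 0.9) {
    new("DetectionParameters", minScore = as.numeric(minScore),
        alphaMin = as.numeric(alphaMin), alphaMax = as.numeric(alphaMax))
}

setMethod("show", "DetectionParameters", function(object) {
    cat(sprintf("DetectionParameters: minScore=%g, alpha in [%g, %g]\n",
                object@minScore, object@alphaMin, object@alphaMax))
})

#' Default detection parameters by matrix size
#'
#' The permissive regime \code{(minScore = 0, alphaMin = 0.1,
#' alphaMax = 0.9)} for matrices of up to 20 nodes, and the restrictive
#' regime \code{(0.1, 0.25, 0.75)} above that, which curbs false positives
#' on large matrices.
#'
#' @param n number of taxa in the distance matrix.
#' @return a [DetectionParameters-class].
#' @export
defaultDetectionParameters <- function(n) {
    if (n <= 20L) DetectionParameters(0, 0.1, 0.9)
    else DetectionParameters(0.1, 0.25, 0.75)
}

#' Hybrid candidate test at one agglomeration step
#'
#' Given the pair \code{(i, j)} selected for joining, finds the
#' neighbor-deviation maximizer \eqn{h_0} ([neighborDeviation()]) and scans
#' all triplets \eqn{(h_0, i_0, k)} with \eqn{i_0 \in \{i, j\}} and \eqn{k}
#' any other active node. Triplets whose reticulation score falls below
#' \code{minScore}, or whose estimated degree falls outside
#' \code{[alphaMin, alphaMax]}, are discarded; among the rest the triplet
#' with minimal least-squares misfit is retained (ties broken
#' lexicographically on \eqn{(i_0, k)}). The candidate is accepted only if
#' \eqn{LS < \Delta^2} (strictly); otherwise \code{NULL} is returned and
#' the join proceeds.
#'
#' @param D symmetric named distance matrix with at least 5 active nodes.
#' @param i,j the pending NJ pair.
#' @param params a [DetectionParameters-class]; default chosen by matrix
#'   size via [defaultDetectionParameters()].
#' @return \code{NULL}, or a list with elements \code{h}, \code{donor1},
#'   \code{donor2}, \code{alpha} (degree of \code{donor1}), \code{ls},
#'   \code{score}, \code{delta}.
#' @export
detectAtStep <- function(D, i, j, params = NULL) {
    .checkDistanceMatrix(D)
    n <- nrow(D)
    if (n < 5L)
        stop("detection requires at least 5 active nodes")
    if (is.null(params))
        params <- defaultDetectionParameters(n)
    stopifnot(is(params, "DetectionParameters"))
    validObject(params)
    nd <- neighborDeviation(D, i, j)
    h0 <- nd$h
    delta <- nd$delta
    ## a deviation at rounding-noise scale is additive for all practical
    ## purposes: LS < Delta^2 could then only fire on noise squared
    if (abs(delta) <= .TIE_EPS * (1 + max(abs(D))))
        return(NULL)
    ks <- sort(setdiff(rownames(D), c(i, j, h0)), method = "radix")
    best <- NULL
    for (i0 in sort(c(i, j), method = "radix")) {
        for (k in ks) {
            a <- estimateAlpha(D, h0, i0, k)
            if (is.na(a))
                next
            if (a < params@alphaMin || a > params@alphaMax)
                next
            sc <- hybridizationScore(D, h0, i0, k)
            if (sc < params@minScore)
                next
            ls <- leastSquaresFit(D, h0, i0, k, a)
            if (is.null(best) || ls < best$ls)
                best <- list(h = h0, donor1 = i0, donor2 = k, alpha = a,
                             ls = ls, score = sc, delta = delta)
        }
    }
    if (is.null(best) || !(best$ls < delta^2))
        return(NULL)
    best
}

#' Infer an explicit hybridization network from a distance matrix
#'
#' NJ agglomeration with per-step hybrid detection: at each step the NJ
#' pair is selected; before joining, [detectAtStep()] is run. If a hybrid
#' candidate is accepted its row and column are removed from the matrix, a
#' reticulation (recipient, two donors, degrees \eqn{\alpha} and
#' \eqn{1-\alpha}, score) is recorded, and pair selection restarts on the
#' reduced matrix; otherwise the pair is joined as in conventional NJ.
#' Donors are whatever nodes are active at the detection step, so both
#' terminal taxa and agglomerated ancestral clusters can act as donors; the
#' reticulation table carries each donor's member list. Overall complexity
#' is \eqn{O(n^3)}, as for NJ.
#'
#' With 4 or fewer taxa detection is disabled (a warning is issued and a
#' plain NJ tree is returned): a distance matrix of size greater than four
#' is needed to evaluate a candidate triplet.
#'
#' @param D symmetric nonnegative named distance matrix, \eqn{n \ge 3}.
#' @param params a [DetectionParameters-class]; default chosen by matrix
#'   size via [defaultDetectionParameters()].
#' @return a [HybridizationNetwork-class].
#' @examples
#' db <- exampleHybridDatabase()
#' D <- hammingDistance(buildPresenceAbsence(db))
#' net <- inferNetwork(D, DetectionParameters(0, 0.1, 0.9))
#' reticulations(net)[, c("recipient", "donor1", "degree1",
#'                        "donor2", "degree2")]
#' @export
inferNetwork <- function(D, params = NULL) {
    .checkDistanceMatrix(D)
    n <- nrow(D)
    if (n < 3L)
        stop("need at least 3 taxa")
    if (is.null(params))
        params <- defaultDetectionParameters(n)
    stopifnot(is(params, "DetectionParameters"))
    validObject(params)
    detect <- n > 4L
    if (!detect)
        warning("hybrid detection needs a distance matrix of size greater ",
                "than four; returning a plain NJ tree")
    res <- .agglomerate(D, detect = detect, params = params)
    new("HybridizationNetwork",
        tree = .rootToPhylo(res$root),
        reticulations = res$reticulations,
        params = params,
        nodes = list(root = res$root, removed = res$removed),
        trace = res$trace)
}

#' Iterated network inference with hybrid removal
#'
#' Hybrids placed near one of their parents can distort the tree around
#' them and mask further reticulate signal. This wrapper reruns
#' [inferNetwork()] on progressively pruned matrices: after each run, the
#' taxa belonging to every detected recipient are removed from the input
#' matrix and the algorithm is run again, accumulating reticulations (with
#' a \code{round} column), until a run detects nothing new, the matrix
#' becomes too small, or \code{maxRounds} is reached.
#'
#' @inheritParams inferNetwork
#' @param maxRounds maximum number of runs (default 10);
#'   \code{maxRounds = 1} is identical to a single [inferNetwork()] run.
#' @return a [HybridizationNetwork-class] whose tree is that of the final
#'   run and whose reticulation table accumulates all rounds.
#' @export
iterateRemoval <- function(D, params = NULL, maxRounds = 10L) {
    .checkDistanceMatrix(D)
    if (is.null(params))
        params <- defaultDetectionParameters(nrow(D))
    stopifnot(maxRounds >= 1L)
    allRets <- list()
    removedAll <- list()
    Dcur <- D
    net <- NULL
    for (round in seq_len(maxRounds)) {
        net <- suppressWarnings(inferNetwork(Dcur, params))
        removedAll <- c(removedAll, net@nodes$removed)
        r <- reticulations(net)
        if (nrow(r) == 0L)
            break
        r$round <- round
        allRets[[round]] <- r
        drop <- unlist(strsplit(r$recipientMembers, "+", fixed = TRUE))
        keep <- setdiff(rownames(Dcur), drop)
        Dcur <- Dcur[keep, keep, drop = FALSE]
        if (nrow(Dcur) < 5L)
            break
    }
    rets <- if (length(allRets)) do.call(rbind, allRets) else {
        e <- .emptyReticulations()
        e$round <- integer()
        e
    }
    rownames(rets) <- NULL
    new("HybridizationNetwork", tree = net@tree, reticulations = rets,
        params = params,
        nodes = list(root = net@nodes$root, removed = removedAll),
        trace = net@trace)
}
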