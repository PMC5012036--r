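## Independent oracles used by the tests. These deliberately re-derive the
## quantities by brute force (dynamic programming, exhaustive scans, grid
## search), independently of the package implementation paths they check.

## Plain DP edit distance (insert/delete/substitute, unit costs).
dpEditDistance <- function(a, b) {
    x <- strsplit(a, "")[[1L]]
    y <- strsplit(b, "")[[1L]]
    n <- length(x); m <- length(y)
    prev <- 0:m
    for (q in seq_len(n)) {
        cur <- numeric(m + 1L)
        cur[1L] <- q
        for (w in seq_len(m))
            cur[w + 1L] <- min(prev[w + 1L] + 1L, cur[w] + 1L,
                               prev[w] + (x[q] != y[w]))
        prev <- cur
    }
    prev[m + 1L]
}

## Column-by-column Hamming count over a presence-absence object.
oracleHamming <- function(pam, strategy = "missing_as_zero") {
    V <- presenceValues(pam)
    M <- missingMask(pam)
    cc <- pam@cogsetCharacter
    taxa <- rownames(V)
    D <- matrix(0, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
    for (a in seq_along(taxa)) for (b in seq_along(taxa)) {
        if (a == b) next
        if (strategy == "missing_as_zero") {
            D[a, b] <- sum(V[a, ] != V[b, ])
        } else {
            num <- 0; den <- 0
            for (ch in colnames(M)) {
                if (M[a, ch] == 1L || M[b, ch] == 1L) next
                den <- den + 1
                cols <- names(cc)[cc == ch]
                num <- num + sum(V[a, cols] != V[b, cols])
            }
            D[a, b] <- num / den
        }
    }
    D
}

## Exhaustive NJ-step oracle: for every candidate pair, fit the branch
## lengths of the star-with-one-cherry configuration by ordinary least
## squares and return the pair minimizing the total branch length.
oracleSelectPair <- function(D) {
    labs <- rownames(D)
    n <- length(labs)
    ij <- t(utils::combn(n, 2L))
    best <- NULL
    bestLen <- Inf
    for (p in seq_len(nrow(ij))) {
        i <- labs[ij[p, 1L]]
        j <- labs[ij[p, 2L]]
        edges <- c(labs, "XC")       # pendant edges plus the X-C edge
        A <- matrix(0, nrow(ij), length(edges),
                    dimnames = list(NULL, edges))
        y <- numeric(nrow(ij))
        for (q in seq_len(nrow(ij))) {
            a <- labs[ij[q, 1L]]
            b <- labs[ij[q, 2L]]
            y[q] <- D[a, b]
            A[q, a] <- A[q, b] <- 1
            if (sum(c(a, b) %in% c(i, j)) == 1L)
                A[q, "XC"] <- 1       # path crosses the cherry-root edge
        }
        fit <- qr.coef(qr(A), y)
        tot <- sum(fit)
        cand <- sort(c(i, j), method = "radix")
        if (is.null(best) || tot < bestLen - 1e-10) {
            bestLen <- tot
            best <- cand
        } else if (abs(tot - bestLen) <= 1e-10 &&
                   (cand[1L] < best[1L] ||
                    (cand[1L] == best[1L] && cand[2L] < best[2L]))) {
            best <- cand
        }
    }
    best
}

## Grid search of the least-squares misfit over alpha.
gridMinLS <- function(D, h, i, j, grid = seq(0, 1, by = 0.01)) {
    vals <- vapply(grid, function(a) leastSquaresFit(D, h, i, j, a), 0)
    grid[which.min(vals)]
}

## Direct double-loop evaluation of the neighbor-deviation sum.
oracleDelta <- function(D, i, j, h) {
    ks <- setdiff(rownames(D), c(i, j))
    sum(vapply(ks, function(k)
        D[j, h] + D[i, k] - D[j, k] - D[i, h], 0))
}

## Random symmetric non-additive matrix.
randomNoisyMatrix <- function(n, seed, lo = 1, hi = 5) {
    set.seed(seed)
    M <- matrix(stats::runif(n * n, lo, hi), n)
    M <- (M + t(M)) / 2
    diag(M) <- 0
    dimnames(M) <- list(sprintf("N%02d", seq_len(n)),
                        sprintf("N%02d", seq_len(n)))
    M
}

## Unrooted topological distance between two trees.
rfDist <- function(t1, t2) {
    phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
}

## Small cognate database used across IO and distance tests.
tinyDatabase <- function() {
    CognateDatabase(data.frame(
        taxon = c("A", "B", "C", "A", "B", "C", "A", "B"),
        character = c(rep("one", 3L), rep("two", 3L), rep("three", 2L)),
        cogset = c("c1", "c1", "c2", "c3", "c4", "c4", "c5", "c6"),
        form = c("kala", "kale", "miro", "tupa", "reno", "rena",
                 "sopi", "vagu"),
        stringsAsFactors = FALSE))
}
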