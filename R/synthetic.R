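## Seeded synthetic-data generators: random additive matrices from random
## binary trees, distance-level hybrid injection following the convex rule
## underlying the degree estimator, and cognate-level hybrid datasets whose
## presence-absence encoding carries the same signal.

.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Random additive distance matrix
#'
#' Draws a random unrooted binary tree topology with branch lengths uniform
#' in \code{blRange} and returns the tree together with its leaf-to-leaf
#' path-length matrix, which is additive by construction (satisfies the
#' four-point condition for every quartet).
#'
#' @param nTaxa number of leaves (at least 4).
#' @param blRange length-2 numeric, branch-length range (default
#'   \code{c(0.1, 1)}).
#' @param seed optional integer; given the same seed the output is
#'   bit-reproducible.
#' @return list with elements \code{tree} ([ape::phylo]) and \code{D}
#'   (symmetric matrix, taxa in lexicographic order).
#' @examples
#' sim <- randomAdditiveMatrix(6, seed = 1)
#' sim$D["T01", "T02"]
#' @export
randomAdditiveMatrix <- function(nTaxa, blRange = c(0.1, 1), seed = NULL) {
    stopifnot(nTaxa >= 4L, length(blRange) == 2L, blRange[1L] > 0,
              blRange[1L] <= blRange[2L])
    .withSeed(seed, {
        labs <- sprintf("T%02d", seq_len(nTaxa))
        tree <- ape::rtree(nTaxa, rooted = FALSE, tip.label = labs,
                           br = function(nb)
                               stats::runif(nb, blRange[1L], blRange[2L]))
        D <- stats::cophenetic(tree)
        ord <- sort(rownames(D), method = "radix")
        list(tree = tree, D = D[ord, ord])
    })
}

#' Inject a hybrid row into a distance matrix
#'
#' Adds a node \code{label} whose distances follow the convex rule
#' \eqn{d(k,h) = \alpha\, d(k,p_1) + (1-\alpha)\, d(k,p_2)} for every node
#' \eqn{k} outside the parents, with \eqn{d(h,p_1) = (1-\alpha)\,
#' d(p_1,p_2)} and \eqn{d(h,p_2) = \alpha\, d(p_1,p_2)} by the same rule.
#' On such a matrix [estimateAlpha()] recovers \eqn{\alpha} exactly.
#'
#' @param D symmetric named distance matrix.
#' @param parent1,parent2 distinct node labels of \code{D}.
#' @param alpha hybridization degree of \code{parent1}, strictly inside
#'   (0, 1).
#' @param label label of the new node (default \code{"H1"}); must not
#'   collide with existing labels.
#' @return the enlarged distance matrix.
#' @export
injectHybrid <- function(D, parent1, parent2, alpha, label = "H1") {
    .checkDistanceMatrix(D)
    labs <- rownames(D)
    if (!all(c(parent1, parent2) %in% labs) || parent1 == parent2)
        stop("parents must be distinct nodes of D")
    if (!(alpha > 0 && alpha < 1))
        stop("alpha must lie strictly between 0 and 1")
    if (label %in% labs)
        stop("label ", label, " already present in D")
    row <- alpha * D[parent1, ] + (1 - alpha) * D[parent2, ]
    out <- rbind(cbind(D, row), c(row, 0))
    dimnames(out) <- list(c(labs, label), c(labs, label))
    out
}

#' Simulate a cognate database with known hybrids
#'
#' Generates a lineage-structured cognate database: a random rooted tree
#' over the base taxa fixes the lineages; for each character the taxa are
#' partitioned into \code{cogsetsPerCharacter} cogsets by cutting a
#' branch-length-resampled copy of that tree, so cogset membership is
#' lineage-consistent and varies across characters. Each hybrid taxon then
#' takes its per-character membership from its first parent's cogset for a
#' fraction \code{alpha} of the characters and from its second parent's for
#' the rest. In the default deterministic mode the first
#' \code{floor(alpha * nCharacters)} characters come from parent 1 (exact
#' degrees, reproducing worked-example splits); with
#' \code{stochastic = TRUE} each character is an independent
#' Bernoulli(\code{alpha}) draw.
#'
#' Word forms are generated per cogset from a random root string with at
#' most one per-taxon letter substitution.
#'
#' @param nTaxa number of base (non-hybrid) taxa.
#' @param nCharacters number of characters (meanings); default 4.
#' @param cogsetsPerCharacter cogsets per character; default 4.
#' @param hybrids \code{NULL} or a \code{data.frame} with columns
#'   \code{recipient}, \code{parent1}, \code{parent2}, \code{alpha}
#'   (parents must be distinct base taxa, alpha in (0, 1)).
#' @param stochastic use Bernoulli draws for hybrid memberships.
#' @param tree optional rooted [ape::phylo] over the base taxa (tip labels
#'   \code{sprintf("L\%02d", 1:nTaxa)}) fixing the lineage structure;
#'   drawn at random when \code{NULL}.
#' @param seed optional integer seed (single pseudo-random stream).
#' @return list with elements \code{db} (the [CognateDatabase-class]),
#'   \code{truth} (the ground-truth hybrid table, with the realized
#'   fraction of parent-1 memberships in column \code{alphaRealized}) and
#'   \code{tree} (the generating [ape::phylo] over base taxa).
#' @examples
#' sim <- simulateCognateDatabase(8, 20, 4,
#'     hybrids = data.frame(recipient = "HYB", parent1 = "L03",
#'                          parent2 = "L06", alpha = 0.5), seed = 3)
#' sim$truth
#' @export
simulateCognateDatabase <- function(nTaxa, nCharacters = 4L,
                                    cogsetsPerCharacter = 4L,
                                    hybrids = NULL, stochastic = FALSE,
                                    tree = NULL, seed = NULL) {
    stopifnot(nTaxa >= 4L, nCharacters >= 1L, cogsetsPerCharacter >= 2L)
    labs <- sprintf("L%02d", seq_len(nTaxa))
    if (!is.null(hybrids)) {
        stopifnot(all(c("recipient", "parent1", "parent2", "alpha") %in%
                      names(hybrids)))
        stopifnot(all(hybrids$parent1 %in% labs),
                  all(hybrids$parent2 %in% labs),
                  all(hybrids$parent1 != hybrids$parent2),
                  all(hybrids$alpha > 0 & hybrids$alpha < 1),
                  !any(hybrids$recipient %in% labs))
    }
    if (!is.null(tree) && !setequal(tree$tip.label, labs))
        stop("tree tip labels must be ", labs[1L], "..", labs[nTaxa])
    .withSeed(seed, {
        topo <- if (is.null(tree)) ape::rtree(nTaxa, rooted = TRUE,
                                              tip.label = labs) else tree
        k <- min(cogsetsPerCharacter, nTaxa)
        recs <- list()
        p1count <- if (is.null(hybrids)) integer() else
            integer(nrow(hybrids))
        for (ci in seq_len(nCharacters)) {
            ch <- sprintf("m%03d", ci)
            topo$edge.length <- stats::runif(nrow(topo$edge), 0.1, 1)
            coph <- stats::cophenetic(topo)
            grp <- stats::cutree(stats::hclust(stats::as.dist(coph),
                                               method = "average"), k = k)
            grp <- grp[labs]
            roots <- vapply(seq_len(k), function(g)
                paste(sample(letters, 6L, replace = TRUE), collapse = ""),
                "")
            mutate <- function(w) {
                if (stats::runif(1L) < 0.5) {
                    pos <- sample.int(nchar(w), 1L)
                    substr(w, pos, pos) <- sample(letters, 1L)
                }
                w
            }
            forms <- vapply(roots[grp], mutate, "")
            recs[[length(recs) + 1L]] <- data.frame(
                taxon = labs, character = ch,
                cogset = sprintf("%s_c%d", ch, grp),
                form = forms, stringsAsFactors = FALSE)
            if (!is.null(hybrids)) {
                for (hi in seq_len(nrow(hybrids))) {
                    fromP1 <- if (stochastic)
                        stats::runif(1L) < hybrids$alpha[hi]
                    else ci <= floor(hybrids$alpha[hi] * nCharacters)
                    p1count[hi] <- p1count[hi] + fromP1
                    src <- if (fromP1) hybrids$parent1[hi] else
                        hybrids$parent2[hi]
                    recs[[length(recs) + 1L]] <- data.frame(
                        taxon = hybrids$recipient[hi], character = ch,
                        cogset = sprintf("%s_c%d", ch, grp[src]),
                        form = mutate(roots[grp[src]]),
                        stringsAsFactors = FALSE)
                }
            }
        }
        truth <- if (is.null(hybrids))
            data.frame(recipient = character(), parent1 = character(),
                       parent2 = character(), alpha = numeric(),
                       alphaRealized = numeric(), stringsAsFactors = FALSE)
        else
            data.frame(hybrids[, c("recipient", "parent1", "parent2",
                                   "alpha")],
                       alphaRealized = p1count / nCharacters,
                       stringsAsFactors = FALSE)
        list(db = CognateDatabase(do.call(rbind, recs)), truth = truth,
             tree = topo)
    })
}

#' Worked-example cognate database (8 languages, 4 meanings, 16 cogsets)
#'
#' A symmetric, fully deterministic dataset in which language \code{L4} is
#' a lexical hybrid of \code{L3} and \code{L5}: for each of 4 meanings the
#' 8 languages are partitioned into 4 cognate sets; \code{L4}'s four
#' memberships are split evenly between \code{L3}'s lineage (meanings m1,
#' m3) and \code{L5}'s lineage (meanings m2, m4), and \code{L8} sits alone
#' in its own set for every meaning (outgroup). Running the full pipeline
#' (presence-absence encoding, Hamming distances, [inferNetwork()] at
#' \code{DetectionParameters(0, 0.1, 0.9)}) joins (L1, L2), then (L6, L7),
#' then detects \code{L4} as a hybrid of \code{L3} and \code{L5} with
#' degree 0.5 for both donors before the ((L1,L2), L3) join.
#'
#' @return a [CognateDatabase-class] with 32 records.
#' @examples
#' net <- inferNetwork(
#'     hammingDistance(buildPresenceAbsence(exampleHybridDatabase())),
#'     DetectionParameters(0, 0.1, 0.9))
#' reticulations(net)[, c("recipient", "donor1", "degree1", "donor2",
#'                        "degree2")]
#' @export
exampleHybridDatabase <- function() {
    parts <- list(
        m1 = list(c1 = c("L1", "L2"), c2 = c("L3", "L4"),
                  c3 = c("L5", "L6", "L7"), c4 = "L8"),
        m2 = list(c1 = c("L1", "L2", "L3"), c2 = c("L4", "L5"),
                  c3 = c("L6", "L7"), c4 = "L8"),
        m3 = list(c1 = c("L1", "L2", "L3", "L4"), c2 = "L5",
                  c3 = c("L6", "L7"), c4 = "L8"),
        m4 = list(c1 = c("L1", "L2"), c2 = "L3",
                  c3 = c("L4", "L5", "L6", "L7"), c4 = "L8"))
    roots <- list(
        m1 = c(c1 = "kamo", c2 = "selu", c3 = "dira", c4 = "utvi"),
        m2 = c(c1 = "bralo", c2 = "minta", c3 = "govek", c4 = "ashen"),
        m3 = c(c1 = "fodri", c2 = "lapsa", c3 = "tenik", c4 = "ormul"),
        m4 = c(c1 = "wesa", c2 = "pilku", c3 = "narod", c4 = "ilvet"))
    recs <- list()
    for (m in names(parts)) {
        for (cs in names(parts[[m]])) {
            members <- parts[[m]][[cs]]
            root <- roots[[m]][[cs]]
            ## vary the final letter for every second member of a set
            form <- vapply(seq_along(members), function(q) {
                if (q %% 2L == 0L)
                    paste0(substr(root, 1L, nchar(root) - 1L), "e")
                else root
            }, "")
            recs[[length(recs) + 1L]] <- data.frame(
                taxon = members, character = m,
                cogset = paste0(m, cs), form = form,
                stringsAsFactors = FALSE)
        }
    }
    CognateDatabase(do.call(rbind, recs))
}

## Topological (unit-branch-length) leaf-to-leaf edge counts of a tree.
.leafEdgeDistances <- function(tree) {
    t2 <- tree
    t2$edge.length <- rep(1, nrow(t2$edge))
    stats::cophenetic(t2)
}

#' Simulate a distance matrix with one injected hybrid of known degree
#'
#' Draws a random additive matrix ([randomAdditiveMatrix()]), samples a
#' donor pair at topological leaf distance of at least
#' \code{minDonorSeparation} edges, and injects a hybrid between them
#' ([injectHybrid()]) with degree \code{alpha} (drawn uniformly from
#' \code{alphaRange} when not given).
#'
#' Donor separation matters for identifiability: a convex mixture of two
#' leaves whose attachment nodes are joined by at most one internal edge is
#' itself tree-realizable (the hybrid attaches along the connecting path),
#' so such a hybrid leaves no reticulate signal in the distances. Requiring
#' at least two internal edges between the donors (leaf distance >= 4)
#' emulates reticulation between distinct clades, the identifiable regime;
#' see the methods vignette for the algebra.
#'
#' @inheritParams randomAdditiveMatrix
#' @param alpha hybridization degree of the first donor, or \code{NULL} to
#'   draw it from \code{alphaRange}.
#' @param alphaRange length-2 numeric range (default \code{c(0.25, 0.75)}).
#' @param minDonorSeparation minimum topological leaf distance (in edges)
#'   between the donors (default 4).
#' @param label hybrid label (default \code{"HYB"}).
#' @return list with \code{D} (matrix including the hybrid), \code{tree},
#'   \code{recipient}, \code{parent1}, \code{parent2}, \code{alpha}.
#' @export
simulateHybridMatrix <- function(nTaxa = 20L, alpha = NULL,
                                 alphaRange = c(0.25, 0.75),
                                 blRange = c(0.1, 1),
                                 minDonorSeparation = 4L,
                                 label = "HYB", seed = NULL) {
    .withSeed(seed, {
        sim <- randomAdditiveMatrix(nTaxa, blRange)
        ed <- .leafEdgeDistances(sim$tree)
        labs <- sort(rownames(ed), method = "radix")
        ed <- ed[labs, labs]
        cand <- which(upper.tri(ed) & ed >= minDonorSeparation,
                      arr.ind = TRUE)
        if (nrow(cand) == 0L)
            stop("no donor pair at the requested separation")
        pick <- cand[sample.int(nrow(cand), 1L), ]
        p1 <- labs[pick[1L]]
        p2 <- labs[pick[2L]]
        if (is.null(alpha))
            alpha <- stats::runif(1L, alphaRange[1L], alphaRange[2L])
        list(D = injectHybrid(sim$D, p1, p2, alpha, label),
             tree = sim$tree, recipient = label, parent1 = p1,
             parent2 = p2, alpha = alpha)
    })
}

## Check a network's reticulations for one (recipient, parent1, parent2)
## ground truth; returns NA alphaError when not recovered. A donor counts
## as matching a parent when the parent belongs to its member set and the
## two parents fall in different donors.
.matchTruth <- function(net, recipient, parent1, parent2) {
    ret <- reticulations(net)
    for (q in seq_len(nrow(ret))) {
        if (ret$recipient[q] != recipient)
            next
        m1 <- strsplit(ret$donor1Members[q], "+", fixed = TRUE)[[1L]]
        m2 <- strsplit(ret$donor2Members[q], "+", fixed = TRUE)[[1L]]
        if (parent1 %in% m1 && parent2 %in% m2)
            return(list(recovered = TRUE, alphaHat = ret$degree1[q]))
        if (parent1 %in% m2 && parent2 %in% m1)
            return(list(recovered = TRUE, alphaHat = ret$degree2[q]))
    }
    list(recovered = FALSE, alphaHat = NA_real_)
}

#' Simulation studies of hybrid recovery
#'
#' \code{hybridRecoveryStudy} runs \code{nRep} noise-free replicates of
#' [simulateHybridMatrix()] followed by [inferNetwork()] at the default
#' parameters and reports, per replicate, whether the recipient and both
#' donors were correctly identified (each true donor belonging to the
#' member set of a distinct inferred donor) and the degree estimation
#' error.
#'
#' @param nRep number of replicates (default 100).
#' @param nTaxa taxa per replicate (default 20).
#' @param alphaRange degree range (default \code{c(0.25, 0.75)}).
#' @param params detection parameters; the group-scale regime
#'   \code{DetectionParameters(0, 0.1, 0.9)} by default, so that the
#'   admissible degree interval strictly contains the simulated range.
#' @param seed integer; replicate \code{r} uses seed \code{seed + r}.
#' @return data.frame with columns \code{rep}, \code{alpha},
#'   \code{recovered}, \code{alphaError}.
#' @export
hybridRecoveryStudy <- function(nRep = 100L, nTaxa = 20L,
                                alphaRange = c(0.25, 0.75),
                                params = DetectionParameters(0, 0.1, 0.9),
                                seed = 1L) {
    out <- vector("list", nRep)
    for (r in seq_len(nRep)) {
        sim <- simulateHybridMatrix(nTaxa, alphaRange = alphaRange,
                                    seed = seed + r)
        net <- suppressWarnings(inferNetwork(sim$D, params))
        m <- .matchTruth(net, sim$recipient, sim$parent1, sim$parent2)
        out[[r]] <- data.frame(rep = r, alpha = sim$alpha,
                               recovered = m$recovered,
                               alphaError = abs(m$alphaHat - sim$alpha))
    }
    do.call(rbind, out)
}

#' @rdname hybridRecoveryStudy
#'
#' @description \code{cognateAlphaStudy} runs the full cognate-level
#' pipeline per replicate: [simulateCognateDatabase()] with one hybrid,
#' presence-absence encoding, Hamming distances (missing-as-zero) and
#' [inferNetwork()]; it reports the recovery flag and the absolute error
#' between the estimated degree and the realized membership fraction.
#'
#' @param nCharacters,cogsetsPerCharacter cognate-generator dimensions
#'   (defaults 50 and 4).
#' @param alphas degrees cycled over replicates (default
#'   \code{c(0.3, 0.5, 0.7)}).
#' @return \code{cognateAlphaStudy}: data.frame with columns \code{rep},
#'   \code{alpha}, \code{alphaRealized}, \code{recovered},
#'   \code{alphaError}.
#' @export
cognateAlphaStudy <- function(nRep = 100L, nTaxa = 8L, nCharacters = 50L,
                              cogsetsPerCharacter = 4L,
                              alphas = c(0.3, 0.5, 0.7),
                              params = DetectionParameters(0, 0.1, 0.9),
                              seed = 1L) {
    out <- vector("list", nRep)
    labs <- sprintf("L%02d", seq_len(nTaxa))
    for (r in seq_len(nRep)) {
        alpha <- alphas[(r - 1L) %% length(alphas) + 1L]
        sim <- .withSeed(seed + r, {
            topo <- ape::rtree(nTaxa, rooted = TRUE, tip.label = labs)
            ed <- .leafEdgeDistances(topo)
            cand <- which(upper.tri(ed) & ed >= 4, arr.ind = TRUE)
            pick <- cand[sample.int(nrow(cand), 1L), ]
            p1 <- rownames(ed)[pick[1L]]
            p2 <- rownames(ed)[pick[2L]]
            simulateCognateDatabase(
                nTaxa, nCharacters, cogsetsPerCharacter,
                hybrids = data.frame(recipient = "HYB", parent1 = p1,
                                     parent2 = p2, alpha = alpha,
                                     stringsAsFactors = FALSE),
                tree = topo)
        })
        D <- hammingDistance(buildPresenceAbsence(sim$db))
        net <- suppressWarnings(inferNetwork(D, params))
        m <- .matchTruth(net, "HYB", sim$truth$parent1, sim$truth$parent2)
        out[[r]] <- data.frame(
            rep = r, alpha = alpha,
            alphaRealized = sim$truth$alphaRealized,
            recovered = m$recovered,
            alphaError = abs(m$alphaHat - sim$truth$alphaRealized))
    }
    do.call(rbind, out)
}
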