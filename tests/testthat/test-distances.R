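test_that("Hamming distance counts symmetric-difference cogsets", {
    rec <- data.frame(
        taxon = rep(c("A", "B"), each = 4L),
        character = rep(sprintf("m%d", 1:4), 2L),
        cogset = c("m1a", "m2a", "m3a", "m4a",
                   "m1b", "m2b", "m3b", "m4b"),
        form = "w", stringsAsFactors = FALSE)
    pam <- buildPresenceAbsence(CognateDatabase(rec))
    ## profiles (1,0,1,0,...) vs (0,1,0,1,...) over 8 cogsets
    D <- hammingDistance(pam)
    expect_equal(D["A", "B"], 8)
    ## identical rows are at distance zero
    rec2 <- data.frame(
        taxon = rep(c("A", "B"), 4L),
        character = rep(sprintf("m%d", 1:4), each = 2L),
        cogset = rep(c("m1a", "m2a", "m3a", "m4a"), each = 2L),
        form = "w", stringsAsFactors = FALSE)
    D2 <- hammingDistance(buildPresenceAbsence(CognateDatabase(rec2)))
    expect_equal(D2["A", "B"], 0)
})

test_that("both Hamming strategies match the brute-force column scan", {
    ## 3 taxa x 4 characters x 8 cogsets with one missing slot (C, m4)
    rec <- data.frame(
        taxon = c("A", "B", "C", "A", "B", "C", "A", "B", "C",
                  "A", "B"),
        character = c(rep("m1", 3L), rep("m2", 3L), rep("m3", 3L),
                      rep("m4", 2L)),
        cogset = c("m1x", "m1x", "m1y", "m2x", "m2y", "m2y",
                   "m3x", "m3y", "m3y", "m4x", "m4y"),
        form = "w", stringsAsFactors = FALSE)
    pam <- buildPresenceAbsence(CognateDatabase(rec))
    expect_equal(length(cogsets(CognateDatabase(rec))), 8L)
    for (strat in c("missing_as_zero", "normalized"))
        expect_equal(hammingDistance(pam, strat),
                     oracleHamming(pam, strat))
})

test_that("normalized strategy errors when taxa share no character", {
    rec <- data.frame(taxon = c("A", "B"), character = c("m1", "m2"),
                      cogset = c("c1", "c2"), form = "w",
                      stringsAsFactors = FALSE)
    pam <- buildPresenceAbsence(CognateDatabase(rec))
    expect_error(hammingDistance(pam, "normalized"),
                 "share no non-missing character")
    expect_silent(hammingDistance(pam, "missing_as_zero"))
})

test_that("missing-as-zero Hamming satisfies the triangle inequality", {
    set.seed(7)
    for (r in 1:10) {
        rec <- data.frame(
            taxon = sample(sprintf("L%d", 1:6), 40L, replace = TRUE),
            character = sample(sprintf("m%d", 1:5), 40L, replace = TRUE),
            form = "w", stringsAsFactors = FALSE)
        rec$cogset <- paste0(rec$character, "_c",
                             sample(1:3, 40L, replace = TRUE))
        rec <- rec[!duplicated(rec[, c("taxon", "cogset")]), ]
        D <- hammingDistance(buildPresenceAbsence(CognateDatabase(rec)))
        n <- nrow(D)
        for (a in 1:n) for (b in 1:n) for (c in 1:n)
            expect_gte(D[a, b] + D[b, c] - D[a, c], 0)
    }
})

test_that("normalized Levenshtein follows the DP oracle", {
    expect_equal(normalizedLevenshtein("fruit", "fruit"), 0)
    expect_equal(normalizedLevenshtein("abc", ""), 1)
    expect_equal(normalizedLevenshtein("fruit", "frukt"),
                 dpEditDistance("fruit", "frukt") / 5)
    expect_equal(normalizedLevenshtein("fruit", "frukt"), 0.2)
    expect_equal(normalizedLevenshtein("", ""), 0)
    set.seed(11)
    for (r in 1:20) {
        a <- paste(sample(letters[1:5], sample(0:8, 1L), TRUE),
                   collapse = "")
        b <- paste(sample(letters[1:5], sample(1:8, 1L), TRUE),
                   collapse = "")
        got <- normalizedLevenshtein(a, b)
        expect_equal(got, dpEditDistance(a, b) / max(nchar(a), nchar(b)))
        expect_equal(got, normalizedLevenshtein(b, a))
        expect_equal(got == 0, a == b)
    }
})

test_that("per-meaning distances follow the per-cogset rules", {
    ## shared cogset with identical forms and nothing else: distance 0
    rec <- data.frame(taxon = c("A", "B"), character = "m1",
                      cogset = "c1", form = "same",
                      stringsAsFactors = FALSE)
    expect_equal(meaningDistance(CognateDatabase(rec), "m1")["A", "B"], 0)
    ## disjoint singletons: (1 + 1) / 2 = 1
    rec2 <- data.frame(taxon = c("A", "B"), character = "m1",
                       cogset = c("c1", "c2"), form = c("x", "y"),
                       stringsAsFactors = FALSE)
    expect_equal(meaningDistance(CognateDatabase(rec2), "m1")["A", "B"], 1)
})

test_that("per-meaning distances match a hand-expanded evaluation", {
    ## 3 taxa, 3 cogsets, mixed membership, one taxon with two forms
    rec <- data.frame(
        taxon = c("A", "B", "A", "C", "B", "C"),
        character = "m1",
        cogset = c("c1", "c1", "c2", "c2", "c3", "c3"),
        form = c("kala", "kalo", "miro", "mira", "tupa", "ropa"),
        stringsAsFactors = FALSE)
    db <- CognateDatabase(rec)
    D <- meaningDistance(db, "m1")
    ## A-B: c1 shared (1 edit / 4), c2 only A (1), c3 only B (1); 3 sets
    expect_equal(D["A", "B"], (0.25 + 1 + 1) / 3)
    ## A-C: c1 only A, c2 shared (1 edit / 4), c3 only C; 3 sets
    expect_equal(D["A", "C"], (1 + 0.25 + 1) / 3)
    ## B-C: c1 only B, c2 only C, c3 shared (2 edits / 4); 3 sets
    expect_equal(D["B", "C"], (1 + 1 + 0.5) / 3)
    expect_true(all(D >= 0 & D <= 1))
})

test_that("meaning distances stay in [0, 1] on simulated databases", {
    sim <- simulateCognateDatabase(6, 5, 3, seed = 99)
    for (ch in meanings(sim$db)) {
        D <- meaningDistance(sim$db, ch)
        expect_true(all(D >= 0 & D <= 1))
        expect_equal(D, t(D))
    }
})

test_that("PHYLIP square matrices round-trip", {
    sim <- randomAdditiveMatrix(6, seed = 2)
    f <- withr::local_tempfile(fileext = ".phylip")
    writePhylipDist(sim$D, f)
    back <- readPhylipDist(f)
    expect_equal(back, sim$D, tolerance = 1e-5)
    expect_equal(as.integer(readLines(f)[1L]), 6L)
    expect_error(readPhylipDist(tempfile()), "not found")
    g <- withr::local_tempfile()
    writeLines(c("2", "A 0 1"), g)
    expect_error(readPhylipDist(g), "taxon rows")
})
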