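# Base-pairing probabilities, pmcomp-style alignment, f_structure, NJ tree

test_that("sequences without complementary pairs give an all-zero matrix", {
    P <- basePairProbabilities("AAAAAAAA")
    expect_true(all(bppMatrix(P) == 0))
    expect_error(basePairProbabilities(""), "non-empty")
})

test_that("probabilities match exhaustive enumeration for short sequences", {
    set.seed(21)
    for (i in 1:12) {
        s <- randomSeq(sample(6:12, 1), gc = runif(1, 0.3, 0.7))
        got <- bppMatrix(basePairProbabilities(s))
        want <- oracleBpp(s)
        expect_lt(max(abs(got - want)), 1e-9)
    }
    # a GC stem dominates
    got <- bppMatrix(basePairProbabilities("GGGGAAAACCCC"))
    want <- oracleBpp("GGGGAAAACCCC")
    expect_lt(max(abs(got - want)), 1e-9)
    expect_gt(got[4, 9], 0.5)  # innermost stem pair
})

test_that("base-pair matrices satisfy their type invariants", {
    set.seed(31)
    for (i in 1:5) {
        b <- basePairProbabilities(randomSeq(30))
        expect_true(validObject(b))
        P <- bppMatrix(b)
        expect_true(all(P[row(P) >= col(P)] == 0))
        idx <- which(P > 0, arr.ind = TRUE)
        if (nrow(idx)) expect_true(all(idx[, 2] - idx[, 1] >= 4))
    }
})

test_that("pmcomp score reproduces hand-computed DP values", {
    A <- matrix(0, 10, 10); A[2, 7] <- 0.64
    B <- matrix(0, 10, 10); B[2, 7] <- 0.25
    # match the pair: sqrt(.64*.25) = 0.4; everything else matched unpaired
    expect_equal(pmcompScore(A, B, exact = TRUE), 0.4)
    # shifted pair needs two gapped positions: 0.4 - 2*0.1
    B2 <- matrix(0, 10, 10); B2[3, 8] <- 0.25
    expect_equal(pmcompScore(A, B2, exact = TRUE), 0.2)
    # empty matrices, equal length: all matched unpaired at sigma = 0
    expect_equal(pmcompScore(matrix(0, 5, 5), matrix(0, 5, 5),
                             exact = TRUE), 0)
    # unequal lengths pay the gap cost
    expect_equal(pmcompScore(matrix(0, 5, 5), matrix(0, 7, 7),
                             exact = TRUE), -0.2)
    # pair below the noise floor is ignored
    A2 <- matrix(0, 10, 10); A2[2, 7] <- 1e-5
    expect_equal(pmcompScore(A2, B, exact = TRUE), 0)
})

test_that("pmcomp score is symmetric", {
    set.seed(41)
    for (i in 1:6) {
        a <- basePairProbabilities(randomSeq(25))
        b <- basePairProbabilities(randomSeq(25))
        expect_equal(pmcompScore(a, b), pmcompScore(b, a),
                     tolerance = 1e-9)
    }
})

test_that("normalized self-similarity dominates alignments to shuffles", {
    # raw scores are not self-maximal in general (a shuffle can fold into
    # stronger stems and sqrt(p q) can exceed p), so the property is stated
    # in Cauchy-Schwarz-normalized form:
    # score(P,Q) <= sqrt(score(P,P) score(Q,Q))
    set.seed(51)
    s <- randomSeq(30, gc = 0.6)
    P <- basePairProbabilities(s)
    self <- pmcompScore(P, P, exact = TRUE)
    expect_gt(self, 0)
    ch <- strsplit(s, "")[[1]]
    ok <- vapply(1:40, function(i) {
        Q <- basePairProbabilities(paste(sample(ch), collapse = ""))
        cross <- pmcompScore(P, Q, exact = TRUE)
        selfQ <- pmcompScore(Q, Q, exact = TRUE)
        cross <= sqrt(max(self, 0) * max(selfQ, 0)) + 1e-9
    }, logical(1))
    expect_true(all(ok))
})

test_that("f_structure is the pairwise mean and needs n >= 2", {
    S2 <- matrix(c(NA, 42, 42, NA), 2, 2)
    diag(S2) <- 99
    expect_equal(fStructure(S2), 42)
    S3 <- matrix(0, 3, 3)
    S3[1, 2] <- S3[2, 1] <- 10
    S3[1, 3] <- S3[3, 1] <- 20
    S3[2, 3] <- S3[3, 2] <- 30
    expect_equal(fStructure(S3), 20)
    expect_error(fStructure(matrix(1, 1, 1)), "at least 2")
})

test_that("distances invert scores with capping of non-positive scores", {
    S <- matrix(c(1, 2, 2, 1), 2, 2)
    D <- structureDistances(S)
    expect_equal(D[1, 2], 0.5)
    expect_equal(diag(D), c(0, 0))
    S2 <- matrix(c(1, -1, -1, 1), 2, 2)
    expect_warning(D2 <- structureDistances(S2), "capped")
    expect_equal(D2[1, 2], 1e6)
})

test_that("NJ reproduces the 3-point formula exactly", {
    D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    D["a", "b"] <- D["b", "a"] <- 5
    D["a", "c"] <- D["c", "a"] <- 9
    D["b", "c"] <- D["c", "b"] <- 10
    tr <- neighborJoining(D)
    pd <- cophenetic(tr)
    expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("NJ recovers additive metrics from 5-taxon trees", {
    for (seed in 1:5) {
        ad <- additiveDistances(5, seed)
        tr <- neighborJoining(ad$D)
        pd <- cophenetic(tr)
        expect_equal(pd[rownames(ad$D), colnames(ad$D)], ad$D,
                     tolerance = 1e-9)
        expect_true(all(ape::dist.topo(ape::unroot(ad$tree), tr) == 0))
    }
})

test_that("NJ handles equidistant leaves and rejects bad input", {
    D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    diag(D) <- 0
    tr <- neighborJoining(D)
    expect_setequal(tr$tip.label, letters[1:4])
    expect_true(all(tr$edge.length >= 0))
    pend <- tr$edge.length[tr$edge[, 2] <= 4]
    expect_equal(pend, rep(pend[1], 4), tolerance = 1e-9)
    Dbad <- D; Dbad[1, 2] <- 2
    expect_error(neighborJoining(Dbad), "symmetric")
})

test_that("hairpin-planted clusters outscore shuffled regions structurally", {
    set.seed(61)
    gm <- pylseeker:::.makeGenomeModel(61)
    tpl <- pylseeker:::.iorfTemplate(gm, 5, 40, hairpin = TRUE)
    members <- vapply(1:3, function(i)
        pylseeker:::.mutateMember(tpl$seq, 0.05, 0.5, gm, tpl$uagOffset,
                                  tpl$hairpinRegion), character(1))
    regions <- substr(members, tpl$uagOffset + 4, tpl$uagOffset + 103)
    shuffled <- vapply(regions, function(r)
        paste(sample(strsplit(r, "")[[1]]), collapse = ""), character(1))
    names(shuffled) <- paste0("s", 1:3)
    names(regions) <- paste0("r", 1:3)
    fsReal <- fStructure(structureScoreMatrix(regions, band = 15))
    fsShuf <- fStructure(structureScoreMatrix(shuffled, band = 15))
    expect_gt(fsReal, fsShuf)
})
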