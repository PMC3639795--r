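# Codon-HMM coding potential: training, scoring, cluster filter

senseCodonsOf <- function(aa) {
    gc <- Biostrings::getGeneticCode("11")
    names(gc) <- chartr("U", "T", names(gc))
    names(gc)[gc == aa]
}

test_that("training yields smoothed, normalized parameters with ML ordering", {
    m <- trainCodingModel("ATGAAATAA", pseudocount = 1)
    # M has the single codon ATG: smoothed probability stays 1
    expect_equal(unname(m@emission["ATG"]), 1)
    # state K saw AAA once, AAG never: (1+1) / ((1+1) + (1+0))
    expect_equal(unname(m@emission["AAA"]), 2 / 3)
    expect_equal(unname(m@emission["AAG"]), 1 / 3)
    # two genes where K is encoded only by AAA
    m2 <- trainCodingModel(c("ATGAAAAAATAA", "ATGAAATAA"))
    expect_gt(m2@emission["AAA"], m2@emission["AAG"])
    # all rows normalized regardless of training set
    expect_true(validObject(m2))
})

test_that("invalid training sequences are dropped with a warning", {
    expect_warning(m <- trainCodingModel(c("ATGAAATAA", "ATGAA",
                                           "ATGTAAAAATAA", "CCCAAATAA")),
                   "dropped")
    expect_true(validObject(m))
    expect_error(trainCodingModel(character(0)), "empty")
    expect_error(suppressWarnings(trainCodingModel("ATGAA")), "no valid")
})

test_that("uniform model log-odds matches closed-form hand arithmetic", {
    # build a model with uniform within-state emissions and uniform
    # transitions; evaluate a 3-codon iORF body by hand
    m <- trainCodingModel("ATGAAATAA")
    sense <- Biostrings::getGeneticCode("11")
    names(sense) <- chartr("U", "T", names(sense))
    sense <- sense[!sense %in% "*"]
    emis <- m@emission
    for (aa in unique(unname(sense))) {
        idx <- names(sense)[sense == aa]
        emis[idx] <- 1 / length(idx)
    }
    m@emission <- emis
    m@transition[] <- 1 / 20
    m@initial[] <- 1 / 20
    # iORF: ATG GGG TAG AAA CCC ... TAA with body ATG GGG AAA CCC
    # after amber deletion: 4 codons
    nUp <- 2; nDown <- 34
    body <- c("ATG", "GGG", rep(c("AAA", "CCC"), 17))
    nt <- paste0("ATG", "GGG", "TAG", paste(rep(c("AAA", "CCC"), 17),
                 collapse = ""), "TAA")
    L <- length(body)
    sizes <- c(M = 1, G = 4, K = 2, P = 4)
    handHmm <- log2(1 / 20) + (L - 1) * log2(1 / 20) +
        log2(1 / sizes["M"]) + log2(1 / sizes["G"]) +
        17 * (log2(1 / sizes["K"]) + log2(1 / sizes["P"])) +
        log2(m@lengthModel[as.character(L)])
    want <- unname(handHmm) - nchar(nt) * log2(1 / 4)
    expect_equal(scoreIorf(m, nt), want, tolerance = 1e-12)
})

test_that("score is invariant to where the amber sits", {
    m <- trainCodingModel(c("ATGAAAGGGCCCTAA", "ATGCCCAAATAA"))
    body <- paste(rep(c("AAA", "GGG", "CCC"), 12), collapse = "")
    # amber early vs late; same codons after amber deletion, same nt length
    nt1 <- paste0("ATG", "TAG", body, "TAA")
    nt2 <- paste0("ATG", substr(body, 1, 3), "TAG",
                  substr(body, 4, nchar(body)), "TAA")
    expect_equal(scoreIorf(m, nt1), scoreIorf(m, nt2), tolerance = 1e-12)
})

test_that("summing exp(HMM log prob) over all codon strings gives the length model", {
    set.seed(2)
    cds <- c("ATGAAAGGGTTTCCCTAA", "ATGCTGGATAAATAA", "ATGGGGAAATAA")
    m <- trainCodingModel(cds, lengthSupport = c(1, 50))
    sense <- names(m@emission)
    for (L in 1:2) {
        strings <- if (L == 1) as.list(sense) else {
            eg <- expand.grid(sense, sense, stringsAsFactors = FALSE)
            split(as.matrix(eg), row(as.matrix(eg)))
        }
        tot <- sum(vapply(strings, function(cc)
            2^hmmLogProb(m, as.character(cc)), numeric(1)))
        expect_equal(tot, unname(m@lengthModel[as.character(L)]),
                     tolerance = 1e-9)
    }
})

test_that("parameters are recovered from simulated genomes", {
    # simulate 500 genes from a known model, retrain, compare emissions
    gm <- pylseeker:::.makeGenomeModel(99)
    set.seed(100)
    genes <- vapply(1:500, function(i) {
        paste0("ATG", paste(pylseeker:::.sampleCodingCodons(gm, 150),
                            collapse = ""), "TAA")
    }, character(1))
    m <- trainCodingModel(genes)
    # compare conditional codon-given-aa distributions
    sense <- pylseeker:::.senseCodons()
    for (aa in unique(unname(sense))) {
        idx <- names(sense)[unname(sense) == aa]
        if (length(idx) < 2) next
        expect_lt(max(abs(m@emission[idx] - gm$usage[idx])), 0.02)
    }
})

test_that("gene-like iORFs outscore codon-shuffled versions in >= 95% of pairs", {
    gm <- pylseeker:::.makeGenomeModel(7)
    set.seed(7)
    genes <- vapply(1:120, function(i)
        paste0("ATG", paste(pylseeker:::.sampleCodingCodons(gm, 150),
                            collapse = ""), "TAA"), character(1))
    m <- trainCodingModel(genes)
    wins <- vapply(1:60, function(i) {
        body <- pylseeker:::.sampleCodingCodons(gm, 120)
        nt <- paste0("ATG", paste(body[1:40], collapse = ""), "TAG",
                     paste(body[41:120], collapse = ""), "TAA")
        sh <- sample(body)
        ntSh <- paste0("ATG", paste(sh[1:40], collapse = ""), "TAG",
                       paste(sh[41:120], collapse = ""), "TAA")
        scoreIorf(m, nt) > scoreIorf(m, ntSh)
    }, logical(1))
    expect_gte(mean(wins), 0.95)
})

test_that("coding filter applies the configured predicate", {
    cl <- new("ClusterSet", clusterIds = c("c1", "c2"),
              members = list(c("i1", "i2"), c("i3", "i4")))
    sc <- c(i1 = -5, i2 = -5, i3 = 5, i4 = 5)
    f <- fCoding(cl, sc)
    expect_equal(unname(f), c(-5, 5))
    expect_equal(clusterIds(filterClustersByCoding(cl, f, "negative")), "c1")
    expect_equal(clusterIds(filterClustersByCoding(cl, f, "positive")), "c2")
    expect_equal(length(filterClustersByCoding(new("ClusterSet"), f)), 0)
    # mean of {10, 20, 30}
    cl3 <- new("ClusterSet", clusterIds = "c",
               members = list(c("x", "y", "z")))
    expect_equal(unname(fCoding(cl3, c(x = 10, y = 20, z = 30))), 20)
})
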