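# Synthetic genome generator and planted iORF families

test_that("background genomes have the requested composition and clean genes", {
    g <- generateBackgroundGenome(length = 50000, gc = 0.5, seed = 101,
                                  genomeId = "gx")
    expect_equal(nchar(g$seq), 50000)
    gcFrac <- mean(strsplit(g$seq, "")[[1]] %in% c("G", "C"))
    expect_lt(abs(gcFrac - 0.5), 0.02)
    cds <- cdsSequences(g$seq, g$features, "gx")
    expect_gt(length(cds), 5)
    aa <- translateCodons(cds)
    # terminal stop only, no internal stops
    expect_true(all(substr(aa, nchar(aa), nchar(aa)) == "*"))
    expect_false(any(grepl("\\*", substr(aa, 1, nchar(aa) - 1))))
})

test_that("generation is deterministic under a fixed seed", {
    g1 <- generateBackgroundGenome(length = 20000, seed = 55)
    g2 <- generateBackgroundGenome(length = 20000, seed = 55)
    expect_identical(g1$seq, g2$seq)
    expect_identical(as.data.frame(g1$features), as.data.frame(g2$features))
    b1 <- makeBenchmark(list(nGenomes = 2, genomeLength = 12000, gc = 0.5,
                             geneDensity = 0.4,
                             positives = list(list(
                                 name = "fam", nMembers = 2, spread = 2,
                                 upstreamCodons = 50, downstreamCodons = 40,
                                 subRate = 0.05, synBias = 0.5,
                                 hairpin = FALSE)),
                             decoys = NULL), seed = 9)
    b2 <- makeBenchmark(list(nGenomes = 2, genomeLength = 12000, gc = 0.5,
                             geneDensity = 0.4,
                             positives = list(list(
                                 name = "fam", nMembers = 2, spread = 2,
                                 upstreamCodons = 50, downstreamCodons = 40,
                                 subRate = 0.05, synBias = 0.5,
                                 hairpin = FALSE)),
                             decoys = NULL), seed = 9)
    expect_identical(b1$genomes, b2$genomes)
    expect_identical(b1$truth, b2$truth)
})

test_that("zero substitution rate gives identical members", {
    g <- generateBackgroundGenome(length = 20000, seed = 31, genomeId = "g1")
    res <- plantCluster(list(g), nMembers = 3, upstreamCodons = 60,
                        subRate = 0, seed = 5, templateId = "f")
    expect_equal(length(unique(res$truth$memberSeq)), 1)
    expect_equal(fDiversity(res$truth$pylisNt), 0)
    aa <- translateCodons(substr(res$truth$pylisNt, 1, 99))
    expect_equal(fSynCodons(aa), 100)
})

test_that("pure synonymous bias diverges nucleotides but not amino acids", {
    g <- generateBackgroundGenome(length = 30000, seed = 32, genomeId = "g1")
    res <- plantCluster(list(g), nMembers = 3, upstreamCodons = 60,
                        subRate = 0.2, synBias = 1, seed = 6,
                        templateId = "f")
    aa <- translateCodons(substr(res$truth$pylisNt, 1, 99))
    expect_equal(fSynCodons(aa), 100)
    expect_gt(fDiversity(res$truth$pylisNt), 0)
})

test_that("planted members are found verbatim by the scanner", {
    set.seed(1)
    g1 <- generateBackgroundGenome(length = 20000, seed = 61, genomeId = "p1")
    g2 <- generateBackgroundGenome(length = 20000, seed = 62, genomeId = "p2",
                                   model = g1$model)
    res <- plantCluster(list(g1, g2), nMembers = 4, upstreamCodons = 150,
                        subRate = 0.05, hairpin = TRUE, seed = 63,
                        templateId = "f")
    genomes <- setNames(vapply(res$genomes, `[[`, character(1), "seq"),
                        c("p1", "p2"))
    io <- findInterruptedOrfs(genomes)
    expect_true(all(res$truth$iorfId %in% iorfId(io)))
    py <- extractPylis(io)
    got <- py$nt[match(res$truth$iorfId, py$iorfId)]
    expect_identical(got, res$truth$pylisNt)
    # grammar validity re-checked, not assumed: the emitted set passed the
    # InterruptedORFSet validity; additionally the full member sequence
    # matches the planted one
    el <- as.data.frame(io)
    rows <- el[match(res$truth$iorfId, el$iorfId), ]
    expect_identical(rows$ntSeq, res$truth$memberSeq)
})

test_that("mutated members remain reciprocal-search hits at 1e-6", {
    g <- generateBackgroundGenome(length = 30000, seed = 71, genomeId = "g1")
    hits <- vapply(1:20, function(i) {
        res <- plantCluster(list(g), nMembers = 2, upstreamCodons = 40,
                            subRate = 0.1, synBias = 0.3, seed = 200 + i,
                            templateId = "f")
        aa <- translateCodons(substr(res$truth$pylisNt, 1, 99))
        py <- data.frame(iorfId = res$truth$iorfId, nt = res$truth$pylisNt,
                         aa = aa, stringsAsFactors = FALSE)
        nrow(pylisSearch(py)) == 1
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("infeasible planting raises a clear error", {
    g <- generateBackgroundGenome(length = 3000, gc = 0.5,
                                  geneDensity = 0.3, seed = 81,
                                  genomeId = "tiny")
    expect_error(plantCluster(list(g), nMembers = 2,
                              upstreamCodons = 2000, seed = 1),
                 "slot")
    expect_error(plantCluster(list(g), nMembers = 2, upstreamCodons = 10,
                              downstreamCodons = 30, seed = 1),
                 ">= 34")
})

test_that("the default benchmark recovers the planted families as clusters", {
    # reduced instance: same structure, smaller scale than the default
    cfg <- benchmarkConfig()
    cfg$nGenomes <- 4
    cfg$genomeLength <- 15000
    cfg$positives <- cfg$positives[c(1, 4)]
    cfg$positives[[1]]$spread <- 3
    cfg$decoys$nFamilies <- 5
    bench <- makeBenchmark(cfg, seed = 3)
    io <- findInterruptedOrfs(bench$genomes)
    py <- extractPylis(io)
    m <- pylisSearch(py)
    cl <- buildClusters(m, io)
    cm <- clusterMembers(cl)
    for (fam in bench$positives) {
        ids <- bench$truth$iorfId[bench$truth$templateId == fam]
        holding <- vapply(cm, function(mm) all(ids %in% mm), logical(1))
        expect_true(any(holding), info = fam)
    }
})
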