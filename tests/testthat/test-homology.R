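# Translated search backend, connected-component clustering, pruning rules

# small helper: an InterruptedORFSet of k iORFs with prescribed PYLIS codons
makeIorfSet <- function(pylisNtList, genomeIds = NULL) {
    k <- length(pylisNtList)
    if (is.null(genomeIds)) genomeIds <- paste0("g", seq_len(k))
    seqs <- character(0)
    for (i in seq_len(k)) {
        # upstream 5 codons of GCA, amber, the given 34-codon downstream, TAA
        stopifnot(nchar(pylisNtList[[i]]) >= 102)
        seqs[i] <- paste0("ATG", strrep("GCA", 5), "TAG",
                          substr(pylisNtList[[i]], 1, 102), "TAA")
    }
    genomes <- setNames(seqs, genomeIds)
    io <- findInterruptedOrfs(genomes)
    # keep only the constructed iORFs (chance hits on the reverse strand of
    # these tiny genomes are not part of the fixture)
    el <- as.data.frame(io)
    io[which(el$strand == "+" & el$uagPos == 18L)]
}

randomCodingNt <- function(nCodons, seed) {
    set.seed(seed)
    sense <- setdiff(mkAllCodons(), c("TAA", "TAG", "TGA"))
    paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}
mkAllCodons <- function() {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), b, paste0))
}

test_that("identical PYLIS regions across iORFs match far below 1e-6", {
    region <- randomCodingNt(34, 1)
    io <- makeIorfSet(list(region, region))
    py <- extractPylis(io)
    m <- pylisSearch(py)
    expect_equal(nrow(m), 1)
    expect_lt(m$evalue, 1e-10)
})

test_that("random unrelated 33-mers produce no matches at 1e-6", {
    regions <- lapply(1:12, function(i) randomCodingNt(34, 100 + i))
    io <- makeIorfSet(regions)
    py <- extractPylis(io)
    m <- pylisSearch(py)
    expect_equal(nrow(m), 0)
})

test_that("clusters are connected components matching a union-find oracle", {
    # A-B, B-C and D-E from prescribed identical regions
    r1 <- randomCodingNt(34, 7); r2 <- randomCodingNt(34, 8)
    io <- makeIorfSet(list(r1, r1, r1, r2, r2, randomCodingNt(34, 9)))
    ids <- iorfId(io)
    matches <- data.frame(query = c(ids[1], ids[2], ids[4]),
                          subject = c(ids[2], ids[3], ids[5]),
                          stringsAsFactors = FALSE)
    cl <- buildClusters(matches, io)
    expect_equal(length(cl), 2)
    expect_identical(sort(unname(unlist(clusterMembers(cl)[[1]]))),
                     sort(ids[1:3]))
    # oracle equivalence on random graphs, plus order invariance
    set.seed(5)
    for (rep in 1:20) {
        n <- sample(4:10, 1)
        nodes <- sort(ids[1:min(n, length(ids))])
        ne <- sample(0:8, 1)
        if (ne > 0) {
            e <- data.frame(query = sample(nodes, ne, replace = TRUE),
                            subject = sample(nodes, ne, replace = TRUE),
                            stringsAsFactors = FALSE)
            e <- e[e$query != e$subject, , drop = FALSE]
        } else e <- data.frame(query = character(0), subject = character(0))
        cl1 <- buildClusters(e, io)
        want <- oracleComponents(ids, e)
        expect_identical(unname(clusterMembers(cl1)), want)
        # order and direction invariance
        if (nrow(e) > 1) {
            e2 <- e[sample(nrow(e)), c("subject", "query")]
            names(e2) <- c("query", "subject")
            cl2 <- buildClusters(e2, io)
            expect_identical(clusterMembers(cl1), clusterMembers(cl2))
        }
    }
})

test_that("no matches yields an empty cluster set", {
    io <- makeIorfSet(list(randomCodingNt(34, 21), randomCodingNt(34, 22)))
    cl <- buildClusters(data.frame(query = character(0),
                                   subject = character(0)), io)
    expect_equal(length(cl), 0)
})

# --- pruning -----------------------------------------------------------

pruneFixture <- function() {
    region <- randomCodingNt(34, 31)
    io <- makeIorfSet(list(region, region), genomeIds = c("ga", "gb"))
    ids <- iorfId(io)
    cl <- buildClusters(data.frame(query = ids[1], subject = ids[2]), io)
    list(io = io, cl = cl, ids = ids)
}

grFeature <- function(genome, start1, end1, strand, kind, confident = TRUE) {
    gr <- GenomicRanges::GRanges(genome,
                                 IRanges::IRanges(start1, end1),
                                 strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        kind = kind, product = if (confident) "elongation factor Tu"
        else "hypothetical protein",
        isConfident = confident)
    gr
}

test_that("rule a removes different-frame containment, keeps same frame", {
    fx <- pruneFixture()
    el <- as.data.frame(fx$io)
    e1 <- el[el$genomeId == "ga", ]
    # pylis forward interval for a + strand iORF
    lo <- e1$uagPos + 3; hi <- e1$uagPos + 103  # 0-based half-open
    # containing CDS shifted by +1 frame
    shifted <- grFeature("ga", lo + 1 - 3 + 1, hi + 6, "+", "protein_coding")
    expect_equal(length(pruneClusters(fx$cl, fx$io, shifted)), 0)
    # same frame containment: feature codon start differs by a multiple of 3
    # from the iORF start
    sameframe <- grFeature("ga", e1$start + 1 - 3, hi + 6, "+",
                           "protein_coding")
    expect_equal(length(pruneClusters(fx$cl, fx$io, sameframe)), 1)
    # opposite strand counts as a different frame
    oppstrand <- grFeature("ga", lo + 1 - 3, hi + 6, "-", "protein_coding")
    expect_equal(length(pruneClusters(fx$cl, fx$io, oppstrand)), 0)
    # non-confident annotation never triggers
    shady <- grFeature("ga", lo + 1 - 2, hi + 6, "+", "protein_coding",
                       confident = FALSE)
    expect_equal(length(pruneClusters(fx$cl, fx$io, shady)), 1)
    # partial overlap (not containment) never triggers rule a
    partial <- grFeature("ga", lo + 10 + 1, hi + 50, "+", "protein_coding")
    expect_equal(length(pruneClusters(fx$cl, fx$io, partial)), 1)
})

test_that("rule b removes >= 1 nt overlap with a confident RNA gene", {
    fx <- pruneFixture()
    el <- as.data.frame(fx$io)
    e1 <- el[el$genomeId == "ga", ]
    lo <- e1$uagPos + 3
    trna <- grFeature("ga", lo + 1 - 10, lo + 1 - 10 + 14, "+", "rna_gene")
    expect_equal(length(pruneClusters(fx$cl, fx$io, trna)), 0)
    # adjacent but non-overlapping RNA gene is fine
    away <- grFeature("ga", 1, lo, "+", "rna_gene")  # ends right before
    expect_equal(length(pruneClusters(fx$cl, fx$io, away)), 1)
})

test_that("pruning is monotone in the annotation set", {
    fx <- pruneFixture()
    el <- as.data.frame(fx$io)
    e1 <- el[el$genomeId == "ga", ]
    lo <- e1$uagPos + 3; hi <- e1$uagPos + 103
    bad <- grFeature("ga", lo + 1 - 3 + 1, hi + 6, "+", "protein_coding")
    harmless <- grFeature("gb", 1, 9, "+", "protein_coding")
    expect_equal(length(pruneClusters(fx$cl, fx$io, bad)), 0)
    both <- suppressWarnings(c(bad, harmless))
    expect_equal(length(pruneClusters(fx$cl, fx$io, both)), 0)
})
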