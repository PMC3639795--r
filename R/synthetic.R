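# Synthetic prokaryote-like genomes with annotated codon-biased genes, into
# which homologous families of amber-interrupted iORFs are planted with
# controlled divergence, synonymous bias, and an optional conserved hairpin
# in the 100-nt downstream region. Everything is seeded and the planted
# truth is recorded, so every pipeline stage is testable without downloads.

.CONFIDENT_PRODUCTS <- c(
    "monomethylamine methyltransferase", "ABC transporter permease",
    "DNA polymerase III subunit", "ribosomal protein L2",
    "elongation factor Tu", "sensory transduction histidine kinase",
    "acetyl-CoA synthetase", "cell division protein FtsZ",
    "preprotein translocase subunit SecY", "glutamine synthetase")

# genome-level sequence model: biased codon usage per amino acid and a
# first-order amino-acid chain (real proteomes have nonuniform dipeptide
# composition, which is what gives codon order information content)
.makeGenomeModel <- function(seed) {
    .withSeed(seed, {
        sense <- .senseCodons()
        states <- sort(unique(unname(sense)))
        usage <- setNames(numeric(length(sense)), names(sense))
        for (aa in states) {
            idx <- names(sense)[unname(sense) == aa]
            g <- stats::rgamma(length(idx), 0.4)
            usage[idx] <- g / sum(g)
        }
        trans <- matrix(stats::rgamma(400, 0.5), 20, 20,
                        dimnames = list(states, states))
        trans <- trans / rowSums(trans)
        init <- stats::rgamma(20, 1)
        list(usage = usage, transition = trans,
             initial = setNames(init / sum(init), states),
             states = states, sense = sense)
    })
}

# sample a codon sequence of nCodons sense codons from the model
.sampleCodingCodons <- function(model, nCodons) {
    states <- model$states
    aa <- character(nCodons)
    aa[1] <- sample(states, 1, prob = model$initial)
    if (nCodons > 1) {
        for (t in 2:nCodons)
            aa[t] <- sample(states, 1, prob = model$transition[aa[t - 1], ])
    }
    vapply(aa, function(a) {
        idx <- names(model$sense)[unname(model$sense) == a]
        sample(idx, 1, prob = model$usage[idx])
    }, character(1), USE.NAMES = FALSE)
}

.randomBases <- function(n, gc) {
    if (n <= 0) return("")
    paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
}

#' Generate a random annotated background genome
#'
#' Random sequence at the requested GC content with non-overlapping,
#' codon-biased protein-coding genes (valid start, no internal stops,
#' terminal TAA) covering roughly \code{geneDensity} of the genome, on
#' random strands, annotated with confident product descriptions. Gene
#' content follows a genome-level codon-usage and amino-acid-chain model so
#' the genes can train a \linkS4class{CodingModel}. Intergenic gap lengths
#' are drawn from a mixture with a heavy tail, leaving slots large enough
#' for planting long iORFs later.
#'
#' @param length genome length in nt (>= 10000 recommended for end-to-end
#'   runs)
#' @param gc GC fraction of the intergenic background
#' @param geneDensity approximate fraction of the genome covered by genes
#' @param genomeId sequence name
#' @param seed RNG seed
#' @param model optional shared sequence model from an earlier call (so
#'   several genomes share codon usage); one is drawn from the seed if NULL
#' @param geneLenRange gene length range in codons
#' @return list with elements \code{seq} (character), \code{features}
#'   (\code{GRanges}), \code{model} and \code{genomeId}
#' @export
generateBackgroundGenome <- function(length = 25000, gc = 0.5,
                                     geneDensity = 0.45,
                                     genomeId = "synthetic_genome",
                                     seed = 1, model = NULL,
                                     geneLenRange = c(80, 300)) {
    if (length < 1000) stop("genome too short to be useful")
    if (is.null(model)) model <- .makeGenomeModel(seed)
    .withSeed(seed + 1, {
        target <- geneDensity * length
        pieces <- character(0)
        starts <- integer(0); ends <- integer(0); strands <- character(0)
        pos <- 0L  # 0-based
        covered <- 0
        repeat {
            gapLen <- if (runif(1) < 0.7) sample(100:400, 1) else
                sample(800:2000, 1)
            nCod <- sample(geneLenRange[1]:geneLenRange[2], 1)
            geneLen <- 3L * nCod + 6L
            if (pos + gapLen + geneLen > length - 200 || covered >= target) {
                pieces <- c(pieces, .randomBases(length - pos, gc))
                break
            }
            pieces <- c(pieces, .randomBases(gapLen, gc))
            pos <- pos + gapLen
            cds <- paste0("ATG",
                          paste(.sampleCodingCodons(model, nCod),
                                collapse = ""),
                          "TAA")
            strand <- sample(c("+", "-"), 1)
            pieces <- c(pieces, if (strand == "+") cds else revComp(cds))
            starts <- c(starts, pos + 1L)      # 1-based inclusive
            ends <- c(ends, pos + geneLen)
            strands <- c(strands, strand)
            pos <- pos + geneLen
            covered <- covered + geneLen
        }
        seq <- paste(pieces, collapse = "")
        feat <- GenomicRanges::GRanges(
            genomeId, IRanges::IRanges(starts, ends), strand = strands)
        S4Vectors::mcols(feat) <- S4Vectors::DataFrame(
            kind = rep("protein_coding", length(starts)),
            product = sample(.CONFIDENT_PRODUCTS, length(starts),
                             replace = TRUE),
            isConfident = rep(TRUE, length(starts)))
        list(seq = seq, features = feat, model = model, genomeId = genomeId)
    })
}

# build one iORF template; returns list(seq, uagOffset) with uagOffset the
# 0-based position of the amber codon within seq
.iorfTemplate <- function(model, upstreamCodons, downstreamCodons,
                          hairpin = FALSE, geneLike = TRUE) {
    sampleCodons <- function(n) {
        if (geneLike) .sampleCodingCodons(model, n)
        else sample(names(model$sense), n, replace = TRUE)
    }
    up <- sampleCodons(upstreamCodons)
    down <- sampleCodons(downstreamCodons)
    if (hairpin) {
        # GC-only 12-bp stem (stop codons all contain A, so codons fully
        # inside the stem can never be stops) + 6-nt loop, at offset 20 of
        # the downstream region
        repeat {
            stem <- paste(sample(c("G", "C"), 12, replace = TRUE),
                          collapse = "")
            loop <- paste(sample(c("A", "T"), 6, replace = TRUE),
                          collapse = "")
            hp <- paste0(stem, loop, revComp(stem))
            dn <- paste(down, collapse = "")
            substr(dn, 21, 50) <- hp
            cods <- .codons(dn)
            if (!any(cods %in% .STOP_CODONS)) {
                down <- cods
                break
            }
        }
    }
    seq <- paste0("ATG", paste(up, collapse = ""), "TAG",
                  paste(down, collapse = ""), "TAA")
    list(seq = seq, uagOffset = 3L + 3L * upstreamCodons,
         hairpinRegion = if (hairpin) c(21L, 50L) else NULL)
}

# mutate one member copy of a template; hairpinRegion (within the
# downstream nt region, 1-based) receives compensatory stem mutations
.mutateMember <- function(template, subRate, synBias, model,
                          uagOffset, hairpinRegion = NULL) {
    if (subRate == 0) return(template)
    sense <- model$sense
    cods <- .codons(template)
    nC <- length(cods)
    amberIdx <- uagOffset / 3L + 1L
    protected <- c(1L, amberIdx, nC)  # start, amber, terminal stop
    hpCodons <- integer(0)
    if (!is.null(hairpinRegion)) {
        # absolute nt positions of the hairpin within the template
        hpLo <- uagOffset + 3L + hairpinRegion[1]
        hpHi <- uagOffset + 3L + hairpinRegion[2]
        hpCodons <- unique(((hpLo - 1L) %/% 3L + 1L):((hpHi - 1L) %/% 3L + 1L))
    }
    for (ci in setdiff(seq_len(nC), c(protected, hpCodons))) {
        hit <- runif(3) < subRate
        if (!any(hit)) next
        old <- cods[ci]
        if (runif(1) < synBias) {
            syn <- names(sense)[unname(sense) == unname(sense[old])]
            cods[ci] <- if (length(syn) > 1) sample(setdiff(syn, old), 1)
                        else old
        } else {
            repeat {
                nt <- strsplit(old, "", fixed = TRUE)[[1]]
                for (p in which(hit))
                    nt[p] <- sample(setdiff(c("A", "C", "G", "T"), nt[p]), 1)
                cand <- paste(nt, collapse = "")
                if (!(cand %in% .STOP_CODONS)) {
                    cods[ci] <- cand
                    break
                }
            }
        }
    }
    out <- paste(cods, collapse = "")
    if (!is.null(hairpinRegion)) {
        # compensatory mutations on the 12 stem pairs keep complementarity
        hpLo <- uagOffset + 3L + hairpinRegion[1]
        pairsNt <- list(c("G", "C"), c("C", "G"), c("A", "T"), c("T", "A"),
                        c("G", "T"), c("T", "G"))
        for (k in 0:11) {
            if (runif(1) >= subRate) next
            i <- hpLo + k            # 1-based template positions
            j <- hpLo + 29 - k
            repeat {
                pr <- pairsNt[[sample(length(pairsNt), 1)]]
                cand <- out
                substr(cand, i, i) <- pr[1]
                substr(cand, j, j) <- pr[2]
                touched <- unique(c((i - 1L) %/% 3L + 1L, (j - 1L) %/% 3L + 1L))
                cc <- .codons(cand)
                if (!any(cc[touched] %in% .STOP_CODONS)) {
                    out <- cand
                    break
                }
            }
        }
    }
    out
}

# intergenic gaps (0-based half-open) of a genome given occupied intervals
.freeGaps <- function(genomeLength, occupied) {
    if (nrow(occupied) == 0)
        return(data.frame(lo = 0L, hi = genomeLength))
    occ <- occupied[order(occupied$lo), , drop = FALSE]
    lo <- c(0L, occ$hi)
    hi <- c(occ$lo, genomeLength)
    keep <- hi > lo
    data.frame(lo = lo[keep], hi = hi[keep])
}

#' Plant a homologous iORF family into genomes
#'
#' Synthesizes a grammar-valid template iORF (start, stop-free upstream
#' codons, amber, stop-free downstream codons, terminal stop; optionally
#' with a conserved GC-rich 12-bp stem / 6-nt loop hairpin at offset 20 of
#' the 100-nt downstream region), derives \code{nMembers} mutated copies
#' (per-site substitutions at \code{subRate}; a fraction \code{synBias} of
#' codon substitutions is forced synonymous; hairpin stems mutate
#' compensatorily so complementarity is preserved), and writes the copies
#' into intergenic positions of the given genomes (round robin), preceded
#' by an in-frame stop guard so the planted start codon is the 5'-most
#' valid start. Insertion overwrites intergenic background, so coordinates
#' of existing features are unchanged.
#'
#' @param genomes list of genome objects from
#'   \code{\link{generateBackgroundGenome}} (modified copies are returned)
#' @param nMembers number of member copies
#' @param upstreamCodons codons between start and amber
#' @param downstreamCodons codons between amber and terminal stop (>= 34 so
#'   the 100-nt rule holds)
#' @param subRate per-site substitution rate between template and member
#' @param synBias fraction of codon substitutions forced synonymous
#' @param hairpin plant the conserved hairpin?
#' @param geneLike if TRUE the template follows the genomes' codon-usage
#'   model; if FALSE codons are drawn uniformly from the 61 sense codons
#' @param spread number of distinct genomes to distribute members over
#' @param templateId family identifier recorded in the truth table
#' @param seed RNG seed
#' @return list with \code{genomes} (updated) and \code{truth} (data.frame
#'   with one row per planted member: templateId, genomeId, strand, the
#'   expected iORF id, coordinates, and the planted PYLIS region)
#' @export
plantCluster <- function(genomes, nMembers, upstreamCodons = 120,
                         downstreamCodons = 40, subRate = 0.05,
                         synBias = 0.5, hairpin = FALSE, geneLike = TRUE,
                         spread = min(nMembers, length(genomes)),
                         templateId = "family", seed = 1) {
    if (downstreamCodons < 34)
        stop("downstreamCodons must be >= 34 to satisfy the 100-nt rule")
    model <- genomes[[1]]$model
    .withSeed(seed, {
        tpl <- .iorfTemplate(model, upstreamCodons, downstreamCodons,
                             hairpin, geneLike)
        gset <- sample(seq_along(genomes), spread)
        rows <- list()
        for (j in seq_len(nMembers)) {
            member <- .mutateMember(tpl$seq, subRate, synBias, model,
                                    tpl$uagOffset, tpl$hairpinRegion)
            gi <- gset[(j - 1) %% length(gset) + 1]
            g <- genomes[[gi]]
            occ <- g$occupied
            if (is.null(occ)) {
                occ <- data.frame(
                    lo = GenomicRanges::start(g$features) - 1L,
                    hi = GenomicRanges::end(g$features))
            }
            insLen <- nchar(member) + 3L  # guard stop + member
            gaps <- .freeGaps(nchar(g$seq), occ)
            gaps <- gaps[gaps$hi - gaps$lo >= insLen + 6L, , drop = FALSE]
            if (nrow(gaps) == 0)
                stop("no intergenic slot long enough in genome ",
                     g$genomeId)
            gi2 <- sample(nrow(gaps), 1)
            slack <- gaps$hi[gi2] - gaps$lo[gi2] - insLen - 6L
            off <- gaps$lo[gi2] + 3L + sample.int(slack + 1L, 1) - 1L
            strand <- sample(c("+", "-"), 1)
            insSeq <- paste0("TAA", member)
            fwdSeq <- if (strand == "+") insSeq else revComp(insSeq)
            substr(g$seq, off + 1L, off + insLen) <- fwdSeq
            g$occupied <- rbind(occ, data.frame(lo = off, hi = off + insLen))
            genomes[[gi]] <- g
            L <- nchar(g$seq)
            # strand-local 0-based uag position of the planted member; for
            # '-' the local coords run over revComp(genome) and the member
            # begins at local position L - (off + insLen) + 3, right after
            # the guard stop
            uagLocal <- if (strand == "+") off + 3L + tpl$uagOffset else
                L - (off + insLen) + 3L + tpl$uagOffset
            pylis <- substr(member, tpl$uagOffset + 4L,
                            tpl$uagOffset + 103L)
            rows[[length(rows) + 1L]] <- data.frame(
                templateId = templateId, genomeId = g$genomeId,
                strand = strand,
                iorfId = sprintf("%s_%s_%08d", g$genomeId, strand, uagLocal),
                uagLocal = uagLocal, memberSeq = member, pylisNt = pylis,
                stringsAsFactors = FALSE)
        }
        list(genomes = genomes,
             truth = do.call(rbind, rows))
    })
}

#' Default benchmark configuration
#'
#' Thirteen 25-kb genomes at GC 0.5 with ~45% gene density; six planted
#' positive families emulating the known Pyl gene families at desk scale
#' (three multi-genome methyltransferase-like families with long upstream
#' regions, two of them carrying the conserved hairpin; two
#' transposase-like single-genome families, one of them with zero
#' divergence; one small TetR-like family), plus 30 weakly conserved,
#' shorter decoy families standing in for the spurious conserved clusters
#' that dominate real runs.
#'
#' @return a nested list understood by \code{\link{makeBenchmark}}
#' @export
benchmarkConfig <- function() {
    list(
        nGenomes = 13, genomeLength = 25000, gc = 0.5, geneDensity = 0.45,
        positives = list(
            list(name = "mttB_like", nMembers = 4, spread = 4,
                 upstreamCodons = 330, downstreamCodons = 40,
                 subRate = 0.05, synBias = 0.6, hairpin = FALSE),
            list(name = "mtbB_like", nMembers = 4, spread = 4,
                 upstreamCodons = 320, downstreamCodons = 40,
                 subRate = 0.05, synBias = 0.6, hairpin = TRUE),
            list(name = "mtmB_like", nMembers = 4, spread = 4,
                 upstreamCodons = 200, downstreamCodons = 40,
                 subRate = 0.05, synBias = 0.6, hairpin = TRUE),
            list(name = "transposase_1", nMembers = 3, spread = 1,
                 upstreamCodons = 100, downstreamCodons = 40,
                 subRate = 0.03, synBias = 0.5, hairpin = FALSE),
            list(name = "transposase_2", nMembers = 3, spread = 1,
                 upstreamCodons = 110, downstreamCodons = 40,
                 subRate = 0, synBias = 0.5, hairpin = FALSE),
            list(name = "tetR_like", nMembers = 2, spread = 1,
                 upstreamCodons = 100, downstreamCodons = 40,
                 subRate = 0.04, synBias = 0.5, hairpin = FALSE)),
        decoys = list(nFamilies = 30, sizeRange = c(2, 3),
                      spreadRange = c(1, 2), upstreamRange = c(5, 60),
                      downstreamRange = c(34, 60), subRate = 0.08,
                      synBias = 0.3))
}

#' Build a complete synthetic benchmark instance
#'
#' Generates the genomes, plants the positive and decoy families, and
#' returns everything a pipeline run needs plus the recorded truth.
#'
#' @param config configuration list (see \code{\link{benchmarkConfig}})
#' @param seed RNG seed; every stochastic step derives from it
#' @return list with \code{genomes} (named character vector),
#'   \code{annotations} (\code{GRanges}), \code{truth} (data.frame over all
#'   planted members), \code{positives} (template ids of the positive
#'   families) and \code{config}
#' @export
makeBenchmark <- function(config = benchmarkConfig(), seed = 1) {
    gm <- .makeGenomeModel(seed)
    genomes <- lapply(seq_len(config$nGenomes), function(i)
        generateBackgroundGenome(length = config$genomeLength,
                                 gc = config$gc,
                                 geneDensity = config$geneDensity,
                                 genomeId = sprintf("sg%02d", i),
                                 seed = seed * 1000 + i, model = gm))
    truths <- list()
    for (k in seq_along(config$positives)) {
        sp <- config$positives[[k]]
        res <- plantCluster(genomes, nMembers = sp$nMembers,
                            upstreamCodons = sp$upstreamCodons,
                            downstreamCodons = sp$downstreamCodons,
                            subRate = sp$subRate, synBias = sp$synBias,
                            hairpin = sp$hairpin, geneLike = TRUE,
                            spread = sp$spread, templateId = sp$name,
                            seed = seed * 100 + k)
        genomes <- res$genomes
        truths[[length(truths) + 1L]] <- res$truth
    }
    dc <- config$decoys
    if (!is.null(dc) && dc$nFamilies > 0) {
        dpar <- .withSeed(seed + 7, {
            data.frame(
                size = sample(dc$sizeRange[1]:dc$sizeRange[2],
                              dc$nFamilies, replace = TRUE),
                spread = sample(dc$spreadRange[1]:dc$spreadRange[2],
                                dc$nFamilies, replace = TRUE),
                up = sample(dc$upstreamRange[1]:dc$upstreamRange[2],
                            dc$nFamilies, replace = TRUE),
                down = sample(dc$downstreamRange[1]:dc$downstreamRange[2],
                              dc$nFamilies, replace = TRUE))
        })
        for (k in seq_len(dc$nFamilies)) {
            res <- plantCluster(genomes, nMembers = dpar$size[k],
                                upstreamCodons = dpar$up[k],
                                downstreamCodons = dpar$down[k],
                                subRate = dc$subRate, synBias = dc$synBias,
                                hairpin = FALSE, geneLike = TRUE,
                                spread = min(dpar$spread[k], dpar$size[k]),
                                templateId = sprintf("decoy_%02d", k),
                                seed = seed * 10 + 500 + k)
            genomes <- res$genomes
            truths[[length(truths) + 1L]] <- res$truth
        }
    }
    truth <- do.call(rbind, truths)
    seqs <- setNames(vapply(genomes, `[[`, character(1), "seq"),
                     vapply(genomes, `[[`, character(1), "genomeId"))
    ann <- unname(unlist(GenomicRanges::GRangesList(
        lapply(genomes, `[[`, "features"))))
    list(genomes = seqs, annotations = ann, truth = truth,
         positives = vapply(config$positives, `[[`, character(1), "name"),
         config = config)
}
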