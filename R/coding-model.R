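# Genome-specific coding-potential model: an HMM whose hidden states are
# amino acids, each emitting only its synonymous codons, with first-order
# amino-acid transitions and explicit gene-length modeling. iORFs are scored
# as log-odds (base 2) against a uniform-nucleotide null, with the amber
# codon deleted before decoding (the states may emit UAG with no effect on
# probability) while the null covers the full nucleotide length.

.AA_STATES <- function() sort(unique(unname(.senseCodons())))

#' Extract coding sequences for model training
#'
#' Pulls the nucleotide sequences of confident protein-coding features of
#' one genome, reverse-complementing minus-strand genes.
#'
#' @param genomeSeq the genome sequence (character scalar)
#' @param annotations \code{GRanges} for this genome
#' @param genomeId which seqname to use
#' @return character vector of CDS sequences
#' @export
cdsSequences <- function(genomeSeq, annotations, genomeId) {
    sel <- as.character(GenomicRanges::seqnames(annotations)) == genomeId &
        S4Vectors::mcols(annotations)$kind == "protein_coding" &
        S4Vectors::mcols(annotations)$isConfident
    ann <- annotations[sel]
    if (length(ann) == 0) return(character(0))
    s <- substring(genomeSeq, GenomicRanges::start(ann),
                   GenomicRanges::end(ann))
    neg <- as.character(GenomicRanges::strand(ann)) == "-"
    s[neg] <- revComp(s[neg])
    s
}

#' Train a genome-specific coding model
#'
#' Maximum-likelihood estimation with Laplace smoothing on annotated coding
#' sequences. Terminal stop codons are stripped (the model has no stop
#' state); start codons are emitted by the state of the amino acid they
#' literally encode (e.g. TTG by L). Sequences that are not a codon
#' multiple, lack a start codon, or contain internal stops are dropped with
#' a warning. The gene-length distribution (in codons) is the empirical
#' distribution kernel-smoothed with a Gaussian kernel and truncated to the
#' supported range.
#'
#' @param cds character vector of coding sequences
#' @param genomeId identifier stored in the model
#' @param pseudocount Laplace smoothing constant (default 1)
#' @param lengthBandwidth kernel bandwidth for the length model, in codons
#' @param lengthSupport integer range of supported lengths, in codons
#' @return a \linkS4class{CodingModel}
#' @export
trainCodingModel <- function(cds, genomeId = "", pseudocount = 1,
                             lengthBandwidth = 10,
                             lengthSupport = c(10, 3000)) {
    if (length(cds) == 0) stop("empty training set")
    ok <- nchar(cds) %% 3L == 0L & nchar(cds) >= 6L
    cods <- lapply(cds[ok], .codons)
    valid <- vapply(cods, function(cc) {
        if (!(cc[1] %in% .START_CODONS)) return(FALSE)
        body <- if (cc[length(cc)] %in% .STOP_CODONS)
            cc[-length(cc)] else cc
        !any(body %in% .STOP_CODONS) && length(body) >= 1L &&
            !any(grepl("N", body, fixed = TRUE))
    }, logical(1))
    if (sum(ok) < length(cds) || any(!valid))
        warning(length(cds) - sum(valid), " training sequence(s) dropped ",
                "(frame, start codon, or internal stop violations)")
    cods <- cods[valid]
    if (length(cods) == 0) stop("no valid training sequences")
    cods <- lapply(cods, function(cc)
        if (cc[length(cc)] %in% .STOP_CODONS) cc[-length(cc)] else cc)

    sense <- .senseCodons()
    states <- .AA_STATES()
    # emissions
    emisCount <- setNames(rep(pseudocount, length(sense)), names(sense))
    tab <- table(factor(unlist(cods), levels = names(sense)))
    emisCount <- emisCount + as.numeric(tab)
    emission <- emisCount
    for (aa in states) {
        idx <- names(sense)[unname(sense) == aa]
        emission[idx] <- emisCount[idx] / sum(emisCount[idx])
    }
    # transitions and initial
    trans <- matrix(pseudocount, length(states), length(states),
                    dimnames = list(states, states))
    init <- setNames(rep(pseudocount, length(states)), states)
    for (cc in cods) {
        aa <- unname(sense[cc])
        init[aa[1]] <- init[aa[1]] + 1
        if (length(aa) > 1) {
            for (t in 2:length(aa))
                trans[aa[t - 1], aa[t]] <- trans[aa[t - 1], aa[t]] + 1
        }
    }
    trans <- trans / rowSums(trans)
    init <- init / sum(init)
    # length model: kernel-smoothed empirical distribution of codon counts
    lens <- vapply(cods, length, integer(1))
    grid <- seq(lengthSupport[1], lengthSupport[2])
    dens <- rowSums(vapply(lens, function(l) dnorm(grid, l, lengthBandwidth),
                           numeric(length(grid))))
    dens <- pmax(dens, .Machine$double.xmin)
    lengthModel <- setNames(dens / sum(dens), as.character(grid))
    new("CodingModel", genomeId = genomeId, emission = emission,
        transition = trans, initial = init, lengthModel = lengthModel,
        pseudocount = pseudocount)
}

# log2 length-model probability; lengths outside the support fall back to
# the smallest supported probability
.log2Length <- function(model, L) {
    lm <- model@lengthModel
    p <- lm[as.character(L)]
    if (is.na(p)) p <- min(lm)
    log2(unname(p))
}

#' Log2 probability of a codon sequence under a coding model
#'
#' Evaluates initial x transitions x emissions x length model along the
#' single amino-acid path determined by translation (each codon determines
#' its state, so exactly one path has nonzero probability). Codons
#' containing N contribute a maximum-entropy emission (1/61) with uniform
#' transitions (1/20), and a message is logged.
#'
#' @param model a \linkS4class{CodingModel}
#' @param codons character vector of sense codons (no stops, no amber)
#' @return log2 probability (includes the length-model term)
#' @export
hmmLogProb <- function(model, codons) {
    if (length(codons) == 0) stop("empty codon sequence")
    if (any(codons %in% .STOP_CODONS))
        stop("stop codon in sequence passed to hmmLogProb")
    sense <- .senseCodons()
    hasN <- grepl("N", codons, fixed = TRUE)
    if (any(hasN))
        message(sum(hasN), " codon(s) containing N scored at maximum entropy")
    aa <- unname(sense[codons])
    lEmis <- log2(unname(model@emission[codons]))
    lEmis[hasN] <- log2(1 / 61)
    n <- length(codons)
    lp <- if (hasN[1]) log2(1 / 20) else log2(unname(model@initial[aa[1]]))
    lp <- lp + sum(lEmis)
    if (n > 1) {
        from <- aa[-n]; to <- aa[-1]
        lTrans <- log2(model@transition[cbind(from, to)])
        lTrans[hasN[-n] | hasN[-1]] <- log2(1 / 20)
        lp <- lp + sum(lTrans)
    }
    lp + .log2Length(model, n)
}

#' Coding-potential score of an iORF
#'
#' Log-odds (bits) of the iORF under the genome's coding model versus a
#' uniform-nucleotide null. The HMM term is evaluated on the iORF's codon
#' sequence with the amber codon deleted and the terminal stop stripped; the
#' null term is \code{nt_length x log2(1/4)} over the full nucleotide length
#' including the amber.
#'
#' @param model a \linkS4class{CodingModel}
#' @param ntSeq iORF nucleotide sequence (start..stop, containing exactly
#'   one in-frame internal TAG)
#' @return log-odds score in bits
#' @export
scoreIorf <- function(model, ntSeq) {
    cods <- .codons(ntSeq)
    nc <- length(cods)
    if (nc < 3) stop("iORF too short")
    if (!(cods[nc] %in% .STOP_CODONS)) stop("iORF lacks terminal stop codon")
    body <- cods[-nc]
    amber <- which(body == "TAG")
    if (length(amber) != 1)
        stop("iORF must contain exactly one internal in-frame TAG")
    body <- body[-amber]
    hmmLogProb(model, body) - nchar(ntSeq) * log2(1 / 4)
}

#' Score all iORFs with their genomes' models
#'
#' @param models named list of \linkS4class{CodingModel}, one per genome
#' @param iorfs an \linkS4class{InterruptedORFSet}
#' @return named numeric vector of log-odds scores by iORF id
#' @export
scoreIorfs <- function(models, iorfs) {
    el <- iorfs@elements
    missing <- setdiff(unique(el$genomeId), names(models))
    if (length(missing))
        stop("no coding model for genome(s): ",
             paste(missing, collapse = ", "))
    vapply(seq_len(nrow(el)), function(i)
        scoreIorf(models[[el$genomeId[i]]], el$ntSeq[i]),
        numeric(1)) |> setNames(el$iorfId)
}

#' Average coding potential per cluster
#'
#' @param clusters a \linkS4class{ClusterSet}
#' @param scores named per-iORF log-odds scores
#' @return named numeric vector, mean member score per cluster
#' @export
fCoding <- function(clusters, scores) {
    vapply(clusters@members, function(m) mean(scores[m]), numeric(1)) |>
        setNames(clusters@clusterIds)
}

#' Filter clusters by coding potential
#'
#' Retains clusters whose average coding potential satisfies the rule.
#' The default, \code{"negative"} (keep f < 0), follows the source
#' procedure's literal statement; \code{"positive"} (keep f > 0) is the
#' opposite reading, under which gene-like clusters with positive log-odds
#' survive. See the methods vignette for why both exist.
#'
#' @param clusters a \linkS4class{ClusterSet}
#' @param fcoding named per-cluster coding potential from \code{\link{fCoding}}
#' @param rule \code{"negative"}, \code{"positive"} or \code{"none"}
#' @return the filtered \linkS4class{ClusterSet}
#' @export
filterClustersByCoding <- function(clusters,
                                   fcoding,
                                   rule = c("negative", "positive", "none")) {
    rule <- match.arg(rule)
    if (length(clusters) == 0 || rule == "none") return(clusters)
    f <- fcoding[clusters@clusterIds]
    keep <- switch(rule, negative = f < 0, positive = f > 0)
    clusters[which(keep)]
}
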