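# Scanning genomes for amber-interrupted ORFs.
#
# An iORF is start, zero or more non-stop codons, exactly one amber (TAG),
# zero or more non-stop codons, then a stop codon -- on either strand. Since
# non-stop stretches exclude all stop codons, the amber is necessarily the
# first in-frame stop-like codon after the start and the terminal stop is the
# next in-frame stop after the amber, which the scan exploits: for each
# in-frame TAG we look up the previous and next in-frame stop and the first
# start codon since the previous stop.

# scan a single strand-local sequence; returns 0-based strand-local coords
.scanStrandLocal <- function(seqChar, minDownstream) {
    L <- nchar(seqChar)
    out <- list()
    for (f in 0:2) {
        ncod <- (L - f) %/% 3L
        if (ncod < 3L) next
        first <- f + 3L * (seq_len(ncod) - 1L) + 1L
        cods <- substring(seqChar, first, first + 2L)
        stopI <- which(cods %in% .STOP_CODONS)
        if (length(stopI) < 2L) next
        startI <- which(cods %in% .START_CODONS)
        if (length(startI) == 0L) next
        ambers <- which(cods == "TAG")
        if (length(ambers) == 0L) next
        nPrev <- findInterval(ambers - 1L, stopI)
        prevStop <- ifelse(nPrev > 0L, stopI[pmax(nPrev, 1L)], 0L)
        iNext <- findInterval(ambers, stopI) + 1L
        hasNext <- iNext <= length(stopI)
        nextStop <- stopI[pmin(iNext, length(stopI))]
        downOK <- hasNext & (3L * (nextStop - ambers - 1L) >= minDownstream)
        iStart <- findInterval(prevStop, startI) + 1L
        hasStart <- iStart <= length(startI) &
            startI[pmin(iStart, length(startI))] <= ambers - 1L
        keep <- which(downOK & hasStart)
        if (length(keep) == 0L) next
        firstStart <- startI[iStart[keep]]
        out[[length(out) + 1L]] <- data.frame(
            start = f + 3L * (firstStart - 1L),
            uagPos = f + 3L * (ambers[keep] - 1L),
            stopEnd = f + 3L * nextStop[keep])
    }
    if (length(out) == 0L)
        return(data.frame(start = integer(0), uagPos = integer(0),
                          stopEnd = integer(0)))
    do.call(rbind, out)
}

#' Find interrupted ORFs in genome sequences
#'
#' Scans both strands of each genome for iORFs: an in-frame TAG with a start
#' codon upstream (no intervening in-frame stop; the 5'-most valid start is
#' used) and at least \code{minDownstream} nucleotides strictly between the
#' amber codon and the next in-frame stop codon. Codons containing N never
#' act as start, amber or stop. Genomes are treated as linear.
#'
#' @param genomes named character vector of genome sequences over
#'   \{A,C,G,T,N\}
#' @param minDownstream minimum number of nucleotides between the amber and
#'   the terminal stop codon (default 100, enough to hold a PYLIS element)
#' @return an \linkS4class{InterruptedORFSet}
#' @export
findInterruptedOrfs <- function(genomes, minDownstream = 100) {
    if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
        stop("genomes must be named")
    rows <- list()
    for (gid in names(genomes)) {
        seqF <- genomes[[gid]]
        L <- nchar(seqF)
        for (strand in c("+", "-")) {
            s <- if (strand == "+") seqF else revComp(seqF)
            hits <- .scanStrandLocal(s, minDownstream)
            if (nrow(hits) == 0L) next
            nt <- substring(s, hits$start + 1L, hits$stopEnd)
            fwdStart <- if (strand == "+") hits$start else L - hits$stopEnd
            fwdEnd <- if (strand == "+") hits$stopEnd else L - hits$start
            rows[[length(rows) + 1L]] <- data.frame(
                iorfId = sprintf("%s_%s_%08d", gid, strand, hits$uagPos),
                genomeId = gid, strand = strand,
                start = hits$start, uagPos = hits$uagPos,
                stopEnd = hits$stopEnd, ntSeq = nt,
                fwdStart = fwdStart, fwdEnd = fwdEnd,
                genomeLength = L, stringsAsFactors = FALSE)
        }
    }
    el <- if (length(rows)) do.call(rbind, rows) else
        new("InterruptedORFSet")@elements
    el <- el[order(el$iorfId), , drop = FALSE]
    rownames(el) <- NULL
    new("InterruptedORFSet", elements = el, minDownstream = minDownstream)
}

#' Extract the PYLIS region of each iORF
#'
#' The PYLIS region is the 100 nt immediately 3' of the amber codon; its
#' amino-acid sequence is the translation of the first 33 complete codons
#' (nt 1-99; the 100th nucleotide is kept at the nucleotide level but never
#' translated).
#'
#' @param iorfs an \linkS4class{InterruptedORFSet} built with
#'   \code{minDownstream >= 100}
#' @return a data.frame with columns \code{iorfId}, \code{nt} (100 nt) and
#'   \code{aa} (33 residues)
#' @export
extractPylis <- function(iorfs) {
    stopifnot(is(iorfs, "InterruptedORFSet"))
    el <- iorfs@elements
    if (nrow(el) == 0L)
        return(data.frame(iorfId = character(0), nt = character(0),
                          aa = character(0), stringsAsFactors = FALSE))
    down <- el$stopEnd - 3L - (el$uagPos + 3L)
    if (any(down < 100L))
        stop("iORF(s) with fewer than 100 nt downstream of the amber codon")
    off <- el$uagPos - el$start
    nt <- substring(el$ntSeq, off + 4L, off + 103L)
    data.frame(iorfId = el$iorfId, nt = nt,
               aa = translateCodons(substring(nt, 1L, 99L)),
               stringsAsFactors = FALSE)
}

#' Write / read an iORF table (TSV, 1-based inclusive coordinates)
#'
#' @param iorfs an \linkS4class{InterruptedORFSet}
#' @param path output path
#' @rdname iorf-io
#' @export
writeIorfTsv <- function(iorfs, path) {
    el <- iorfs@elements
    out <- data.frame(iorf_id = el$iorfId, genome_id = el$genomeId,
                      strand = el$strand, start = el$start + 1L,
                      uag_pos = el$uagPos + 1L, stop_end = el$stopEnd,
                      genome_length = el$genomeLength, nt_seq = el$ntSeq,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @param minDownstream minimum downstream length the set was built with
#' @rdname iorf-io
#' @export
readIorfTsv <- function(path, minDownstream = 100) {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    L <- df$genome_length
    start0 <- df$start - 1L
    stopEnd0 <- df$stop_end
    el <- data.frame(iorfId = df$iorf_id, genomeId = df$genome_id,
                     strand = df$strand, start = start0,
                     uagPos = df$uag_pos - 1L, stopEnd = stopEnd0,
                     ntSeq = df$nt_seq,
                     fwdStart = ifelse(df$strand == "+", start0, L - stopEnd0),
                     fwdEnd = ifelse(df$strand == "+", stopEnd0, L - start0),
                     genomeLength = L, stringsAsFactors = FALSE)
    new("InterruptedORFSet", elements = el, minDownstream = minDownstream)
}
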