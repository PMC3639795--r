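# Reciprocal translated-homology search between PYLIS regions, connected
# component clustering, and the two cluster pruning rules.

# BLOSUM62 with amino acids coded as 0-based integers, plus the index map
.blosumSetup <- function() {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    sm <- data_env$BLOSUM62
    alphabet <- rownames(sm)
    list(mat = sm, alphabet = alphabet)
}

.encodePeptides <- function(aa, alphabet) {
    n <- nchar(aa[1])
    if (any(nchar(aa) != n)) stop("peptides must have equal length")
    m <- matrix(0L, nrow = length(aa), ncol = n)
    for (i in seq_along(aa)) {
        idx <- match(strsplit(aa[i], "", fixed = TRUE)[[1]], alphabet)
        if (anyNA(idx)) stop("peptide contains letters outside BLOSUM62: ", aa[i])
        m[i, ] <- idx - 1L
    }
    m
}

#' Translated homology search between PYLIS regions
#'
#' Built-in search backend: each 33-residue PYLIS peptide is aligned against
#' the PYLIS peptides of every other iORF with affine-gap Smith-Waterman
#' (BLOSUM62, gap open 11 / extend 1, with a shared 3-mer word prefilter),
#' and alignment scores are converted to expectation values with the
#' Karlin-Altschul formula E = K m n exp(-lambda S) using the gapped BLOSUM62
#' parameters lambda = 0.267, K = 0.041 and search space = query length x
#' total target length (amino acids). Hits at or below the e-value threshold
#' become matches. Hits of an iORF to itself are impossible by construction,
#' and restricting the target space to iORF PYLIS regions discards hits to
#' non-iORF regions by construction.
#'
#' @param pylis data.frame from \code{\link{extractPylis}}
#' @param eValueThreshold maximum expectation value for a match (default 1e-6)
#' @param gapOpen,gapExt affine gap penalties
#' @param lambda,K Karlin-Altschul parameters for gapped BLOSUM62
#' @param seedLength length of the exact shared word required before a pair
#'   is aligned
#' @return data.frame with columns \code{query}, \code{subject} (iORF ids,
#'   one row per unordered pair), \code{bitscoreRaw} (SW score) and
#'   \code{evalue}
#' @export
pylisSearch <- function(pylis, eValueThreshold = 1e-6, gapOpen = 11,
                        gapExt = 1, lambda = 0.267, K = 0.041,
                        seedLength = 3) {
    if (nrow(pylis) < 2)
        return(data.frame(query = character(0), subject = character(0),
                          bitscoreRaw = numeric(0), evalue = numeric(0),
                          stringsAsFactors = FALSE))
    bl <- .blosumSetup()
    peps <- .encodePeptides(pylis$aa, bl$alphabet)
    hits <- pylis_allpairs_cpp(peps, bl$mat, as.integer(gapOpen),
                               as.integer(gapExt), as.integer(seedLength))
    if (nrow(hits) == 0)
        return(data.frame(query = character(0), subject = character(0),
                          bitscoreRaw = numeric(0), evalue = numeric(0),
                          stringsAsFactors = FALSE))
    m <- nchar(pylis$aa[1])
    searchSpace <- m * sum(nchar(pylis$aa))
    evalue <- K * searchSpace * exp(-lambda * hits$score)
    keep <- evalue <= eValueThreshold
    data.frame(query = pylis$iorfId[hits$query[keep]],
               subject = pylis$iorfId[hits$subject[keep]],
               bitscoreRaw = hits$score[keep], evalue = evalue[keep],
               stringsAsFactors = FALSE)
}

#' Read external search hits in blast outfmt-6 format
#'
#' Adapter for a precomputed tabular search (12-column blast outfmt 6) whose
#' query and subject ids are iORF ids. Self hits and hits involving unknown
#' iORFs (e.g. hits to non-iORF regions) are discarded; hits above the
#' e-value threshold are dropped.
#'
#' @param path path to the tabular hits file
#' @param iorfs the \linkS4class{InterruptedORFSet} the ids refer to
#' @param eValueThreshold maximum expectation value
#' @return data.frame with columns \code{query}, \code{subject},
#'   \code{bitscoreRaw}, \code{evalue}
#' @export
readBlastHits <- function(path, iorfs, eValueThreshold = 1e-6) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 12) stop("expected 12-column blast outfmt 6")
    ids <- iorfId(iorfs)
    keep <- df[[1]] %in% ids & df[[2]] %in% ids & df[[1]] != df[[2]] &
        df[[11]] <= eValueThreshold
    data.frame(query = df[[1]][keep], subject = df[[2]][keep],
               bitscoreRaw = df[[12]][keep], evalue = df[[11]][keep],
               stringsAsFactors = FALSE)
}

#' Build clusters as connected components of the match graph
#'
#' iORFs are nodes and matches are undirected edges; clusters are the
#' connected components with more than one node (singletons are dropped).
#' Each cluster id is its lexicographically smallest member id, which makes
#' the output deterministic and invariant to match order and to swapping
#' query/subject.
#'
#' @param matches data.frame with columns \code{query} and \code{subject}
#' @param iorfs the \linkS4class{InterruptedORFSet} the matches refer to
#' @return a \linkS4class{ClusterSet}
#' @export
buildClusters <- function(matches, iorfs) {
    ids <- iorfId(iorfs)
    bad <- setdiff(c(matches$query, matches$subject), ids)
    if (length(bad))
        stop("matches reference unknown iORFs: ",
             paste(utils::head(bad, 3), collapse = ", "))
    if (nrow(matches) == 0)
        return(new("ClusterSet"))
    g <- igraph::graph_from_data_frame(
        matches[, c("query", "subject")], directed = FALSE,
        vertices = data.frame(name = ids))
    comp <- igraph::components(g)
    members <- split(ids, comp$membership)
    members <- members[lengths(members) >= 2L]
    members <- lapply(members, sort)
    cids <- vapply(members, `[`, character(1), 1L)
    o <- order(cids)
    new("ClusterSet", clusterIds = unname(cids[o]),
        members = unname(members[o]))
}

# forward-strand 0-based half-open interval of each iORF's PYLIS region,
# plus the phase needed for reading-frame comparisons
.pylisForwardIntervals <- function(iorfs) {
    el <- iorfs@elements
    L <- el$genomeLength
    lo <- ifelse(el$strand == "+", el$uagPos + 3L, L - (el$uagPos + 103L))
    hi <- ifelse(el$strand == "+", el$uagPos + 103L, L - (el$uagPos + 3L))
    data.frame(iorfId = el$iorfId, genomeId = el$genomeId,
               strand = el$strand, lo = lo, hi = hi,
               localStart = el$start, genomeLength = L,
               stringsAsFactors = FALSE)
}

#' Prune clusters overlapped by annotated genes
#'
#' Drops every cluster containing an iORF whose 100-nt downstream region is
#' (a) fully inside a confident protein-coding feature in a different
#' reading frame (including the opposite strand), or (b) overlaps a
#' confident RNA gene by at least one nucleotide. Same-frame overlaps never
#' trigger removal: known Pyl-incorporating genes are annotated in the same
#' reading frame as their iORF (often erroneously split in two at the UAG),
#' while rule (a) removes shadow ORFs that appear conserved only because a
#' real gene overlaps them in another frame.
#'
#' @param clusters a \linkS4class{ClusterSet}
#' @param iorfs the underlying \linkS4class{InterruptedORFSet}
#' @param annotations \code{GRanges} from \code{\link{readAnnotationsGff}}
#' @return the pruned \linkS4class{ClusterSet}
#' @export
pruneClusters <- function(clusters, iorfs, annotations) {
    if (length(clusters) == 0) return(clusters)
    reg <- .pylisForwardIntervals(iorfs)
    used <- unique(unlist(clusters@members))
    reg <- reg[reg$iorfId %in% used, , drop = FALSE]
    mc <- S4Vectors::mcols(annotations)
    conf <- mc$isConfident
    cds <- annotations[conf & mc$kind == "protein_coding"]
    rna <- annotations[conf & mc$kind == "rna_gene"]

    flagged <- setNames(logical(nrow(reg)), reg$iorfId)
    if (nrow(reg)) {
        q <- GenomicRanges::GRanges(reg$genomeId,
                                    IRanges::IRanges(reg$lo + 1L, reg$hi))
        if (length(cds)) {
            ov <- GenomicRanges::findOverlaps(q, cds, type = "within",
                                              ignore.strand = TRUE)
            for (h in seq_along(ov)) {
                i <- S4Vectors::queryHits(ov)[h]
                j <- S4Vectors::subjectHits(ov)[h]
                featStrand <- as.character(GenomicRanges::strand(cds))[j]
                if (featStrand != reg$strand[i]) {
                    flagged[i] <- TRUE
                    next
                }
                # same strand: compare codon phases in strand-local coords
                L <- reg$genomeLength[i]
                featLocal <- if (featStrand == "+")
                    GenomicRanges::start(cds)[j] - 1L
                else L - GenomicRanges::end(cds)[j]
                if ((reg$localStart[i] - featLocal) %% 3L != 0L)
                    flagged[i] <- TRUE
            }
        }
        if (length(rna)) {
            ov <- GenomicRanges::findOverlaps(q, rna, ignore.strand = TRUE)
            flagged[unique(S4Vectors::queryHits(ov))] <- TRUE
        }
    }
    keep <- !vapply(clusters@members,
                    function(m) any(flagged[intersect(m, names(flagged))]),
                    logical(1))
    clusters[which(keep)]
}
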