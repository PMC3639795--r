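#' A set of interrupted open reading frames
#'
#' Holds the iORFs extracted from one or more genomes. Coordinates are
#' 0-based half-open and strand-local: for a minus-strand iORF they refer to
#' the reverse-complemented genome sequence, with \code{fwdStart}/\code{fwdEnd}
#' giving the corresponding 0-based half-open interval on the forward strand.
#' \code{start} is the first nucleotide of the start codon, \code{uagPos} the
#' first nucleotide of the amber codon, and \code{stopEnd} one past the
#' terminal stop codon.
#'
#' Validity enforces the iORF grammar: in-frame amber, start codon from the
#' prokaryotic start set, terminal stop, no internal stop codons on either
#' side of the amber, and at least \code{minDownstream} nucleotides strictly
#' between the amber and the terminal stop.
#'
#' @slot elements a \code{data.frame} with columns \code{iorfId},
#'   \code{genomeId}, \code{strand}, \code{start}, \code{uagPos},
#'   \code{stopEnd}, \code{ntSeq}, \code{fwdStart}, \code{fwdEnd},
#'   \code{genomeLength}
#' @slot minDownstream minimum downstream length (nt) the set was built with
#' @exportClass InterruptedORFSet
setClass("InterruptedORFSet",
         representation(elements = "data.frame", minDownstream = "numeric"),
         prototype(elements = data.frame(iorfId = character(0),
                                         genomeId = character(0),
                                         strand = character(0),
                                         start = integer(0),
                                         uagPos = integer(0),
                                         stopEnd = integer(0),
                                         ntSeq = character(0),
                                         fwdStart = integer(0),
                                         fwdEnd = integer(0),
                                         genomeLength = integer(0),
                                         stringsAsFactors = FALSE),
                   minDownstream = 100))

.validInterruptedORFSet <- function(object) {
    el <- object@elements
    need <- c("iorfId", "genomeId", "strand", "start", "uagPos", "stopEnd",
              "ntSeq", "fwdStart", "fwdEnd", "genomeLength")
    if (!all(need %in% names(el)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(el)), collapse = ", ")))
    if (nrow(el) == 0L) return(TRUE)
    if (anyDuplicated(el$iorfId)) return("duplicated iorfId")
    if (!all(el$strand %in% c("+", "-"))) return("strand must be + or -")
    up <- el$uagPos - el$start
    down <- el$stopEnd - 3L - (el$uagPos + 3L)
    if (any(up %% 3L != 0L)) return("amber codon out of frame with start")
    if (any(down %% 3L != 0L)) return("terminal stop out of frame with amber")
    if (any(down < object@minDownstream))
        return("downstream region shorter than minDownstream")
    bad <- vapply(seq_len(nrow(el)), function(i) {
        cods <- .codons(el$ntSeq[i])
        nc <- length(cods)
        ai <- up[i] / 3L + 1L
        if (!(cods[1L] %in% .START_CODONS)) return(TRUE)
        if (cods[ai] != "TAG") return(TRUE)
        if (!(cods[nc] %in% .STOP_CODONS)) return(TRUE)
        internal <- cods[setdiff(seq_len(nc), c(ai, nc))]
        any(internal %in% .STOP_CODONS)
    }, logical(1))
    if (any(bad)) return("iORF grammar violated (start/amber/stop structure)")
    TRUE
}
setValidity("InterruptedORFSet", .validInterruptedORFSet)

#' Clusters of reciprocally matched iORFs
#'
#' Connected components (size >= 2) of the undirected graph whose nodes are
#' iORFs and whose edges are translated-homology matches between their PYLIS
#' regions. Member sets are disjoint; each cluster is identified by its
#' lexicographically smallest member id.
#'
#' @slot clusterIds character vector of cluster identifiers
#' @slot members list of character vectors of member iORF ids
#' @exportClass ClusterSet
setClass("ClusterSet",
         representation(clusterIds = "character", members = "list"),
         prototype(clusterIds = character(0), members = list()))

setValidity("ClusterSet", function(object) {
    if (length(object@clusterIds) != length(object@members))
        return("clusterIds and members lengths differ")
    if (length(object@members) == 0L) return(TRUE)
    sizes <- lengths(object@members)
    if (any(sizes < 2L)) return("clusters must have >= 2 members")
    all_m <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_m)) return("an iORF can only be member of one cluster")
    if (anyDuplicated(object@clusterIds)) return("duplicated cluster ids")
    TRUE
})

#' Genome-specific codon model of coding potential
#'
#' A hidden Markov model whose states are the 20 amino acids; each state
#' emits only the synonymous codons of its amino acid (translation table 11),
#' with first-order amino-acid transitions and an explicit gene-length
#' distribution (in codons). Trained by Laplace-smoothed maximum likelihood
#' on annotated coding sequences.
#'
#' @slot genomeId genome the model was trained on
#' @slot emission named numeric over the 61 sense codons, P(codon | aa(codon))
#' @slot transition 20 x 20 matrix, rows P(aa_t | aa_t-1)
#' @slot initial length-20 initial state distribution
#' @slot lengthModel named numeric over the supported lengths (codons), sums to 1
#' @slot pseudocount Laplace smoothing constant used for training
#' @exportClass CodingModel
setClass("CodingModel",
         representation(genomeId = "character", emission = "numeric",
                        transition = "matrix", initial = "numeric",
                        lengthModel = "numeric", pseudocount = "numeric"))

setValidity("CodingModel", function(object) {
    tol <- 1e-8
    sense <- .senseCodons()
    if (!setequal(names(object@emission), names(sense)))
        return("emission must be named by the 61 sense codons")
    byAA <- tapply(object@emission[names(sense)], unname(sense), sum)
    if (any(abs(byAA - 1) > tol)) return("emission rows must sum to 1 per state")
    if (any(abs(rowSums(object@transition) - 1) > tol))
        return("transition rows must sum to 1")
    if (abs(sum(object@initial) - 1) > tol) return("initial must sum to 1")
    if (abs(sum(object@lengthModel) - 1) > tol)
        return("length model must sum to 1")
    TRUE
})

#' Base-pairing probability matrix of a folded sequence
#'
#' Upper-triangular matrix of equilibrium probabilities that positions i < j
#' pair, computed from the partition function over nested structures.
#'
#' @slot seq the folded nucleotide sequence (T is read as U)
#' @slot prob the probability matrix
#' @exportClass BasePairMatrix
setClass("BasePairMatrix",
         representation(seq = "character", prob = "matrix"))

setValidity("BasePairMatrix", function(object) {
    P <- object@prob
    n <- nchar(object@seq)
    if (nrow(P) != n || ncol(P) != n) return("matrix dimension != sequence length")
    if (any(P < -1e-12 | P > 1 + 1e-9)) return("probabilities outside [0,1]")
    if (n > 1 && any(P[lower.tri(P, diag = TRUE)] != 0))
        return("matrix must be strictly upper triangular")
    tot <- rowSums(P) + colSums(P)
    if (any(tot > 1 + 1e-6)) return("per-position pairing probability exceeds 1")
    TRUE
})

#' Sampled null distribution of the mean of n ranks
#'
#' Normal fit to the means of \code{reps} samples, each the mean of \code{n}
#' ranks drawn without replacement from \code{1..N}. Used to judge whether a
#' set of clusters ranks unusually well under a feature.
#'
#' @slot N number of clusters ranked
#' @slot n number of positive clusters
#' @slot reps number of sampled means
#' @slot mu,sigma fitted normal parameters
#' @slot seed RNG seed used for sampling (NA if none)
#' @exportClass MeanRankNull
setClass("MeanRankNull",
         representation(N = "numeric", n = "numeric", reps = "numeric",
                        mu = "numeric", sigma = "numeric", seed = "numeric"))

setValidity("MeanRankNull", function(object) {
    if (object@n < 1 || object@n > object@N) return("need 1 <= n <= N")
    if (object@mu < 1 || object@mu > object@N) return("mu outside [1, N]")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
})

#' Fitted cluster-ranking model
#'
#' Weighted linear combination of the selected normalized features; weights
#' are non-negative, sum to one, and minimize the summed ranks of the
#' positive-example clusters.
#'
#' @slot selected names of the selected (significant) features
#' @slot weights named weight vector over the selected features
#' @slot positives ids of the positive-example clusters
#' @slot scores named per-cluster combined scores
#' @slot ranks named per-cluster ranks (1 = best)
#' @slot objective achieved sum of positive ranks
#' @slot meta list of fitting metadata (p-values, null parameters, seed)
#' @exportClass RankingModel
setClass("RankingModel",
         representation(selected = "character", weights = "numeric",
                        positives = "character", scores = "numeric",
                        ranks = "integer", objective = "numeric",
                        meta = "list"))

setValidity("RankingModel", function(object) {
    if (length(object@weights) != length(object@selected))
        return("one weight per selected feature required")
    if (length(object@ranks) &&
        !identical(sort(unname(object@ranks)), seq_along(object@ranks)))
        return("ranks must be a permutation of 1..N")
    TRUE
})
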