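# show/length/subset methods and accessors for the S4 containers

#' @describeIn InterruptedORFSet-class number of iORFs
#' @param x an \code{InterruptedORFSet}
#' @export
setMethod("length", "InterruptedORFSet", function(x) nrow(x@elements))

#' @export
setMethod("show", "InterruptedORFSet", function(object) {
    el <- object@elements
    cat(sprintf("InterruptedORFSet with %d iORFs from %d genome(s)\n",
                nrow(el), length(unique(el$genomeId))))
    cat(sprintf("  minimum downstream length: %g nt\n", object@minDownstream))
    if (nrow(el)) {
        cat(sprintf("  strands: +%d / -%d\n",
                    sum(el$strand == "+"), sum(el$strand == "-")))
        print(head(el[, c("iorfId", "strand", "start", "uagPos", "stopEnd")], 4))
        if (nrow(el) > 4) cat("  ...\n")
    }
})

#' @export
setMethod("[", "InterruptedORFSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@elements$iorfId)
    initialize(x, elements = x@elements[i, , drop = FALSE])
})

#' @describeIn InterruptedORFSet-class coerce to data.frame
#' @export
setMethod("as.data.frame", "InterruptedORFSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
    df <- x@elements
    rownames(df) <- row.names
    df
})

#' iORF accessors
#'
#' Column accessors for \linkS4class{InterruptedORFSet}.
#' @param x an \code{InterruptedORFSet}
#' @return a vector with one entry per iORF
#' @rdname iorf-accessors
#' @export
iorfId <- function(x) x@elements$iorfId
#' @rdname iorf-accessors
#' @export
iorfGenome <- function(x) x@elements$genomeId
#' @rdname iorf-accessors
#' @export
iorfStrand <- function(x) x@elements$strand
#' @rdname iorf-accessors
#' @export
iorfSeq <- function(x) setNames(x@elements$ntSeq, x@elements$iorfId)
#' @rdname iorf-accessors
#' @export
upstreamLength <- function(x) {
    setNames(x@elements$uagPos - x@elements$start, x@elements$iorfId)
}
#' @rdname iorf-accessors
#' @export
downstreamLength <- function(x) {
    setNames(x@elements$stopEnd - 3L - (x@elements$uagPos + 3L),
             x@elements$iorfId)
}

#' @describeIn ClusterSet-class number of clusters
#' @param x a \code{ClusterSet}
#' @export
setMethod("length", "ClusterSet", function(x) length(x@clusterIds))

#' @export
setMethod("show", "ClusterSet", function(object) {
    cat(sprintf("ClusterSet with %d cluster(s)\n", length(object@clusterIds)))
    if (length(object@clusterIds)) {
        sizes <- lengths(object@members)
        cat(sprintf("  sizes: %s\n",
                    paste(utils::head(sizes, 10), collapse = " ")))
    }
})

#' @export
setMethod("[", "ClusterSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@clusterIds)
    initialize(x, clusterIds = x@clusterIds[i], members = x@members[i])
})

#' Cluster accessors
#' @param x a \code{ClusterSet}
#' @rdname cluster-accessors
#' @export
clusterIds <- function(x) x@clusterIds
#' @rdname cluster-accessors
#' @export
clusterMembers <- function(x) setNames(x@members, x@clusterIds)
#' @rdname cluster-accessors
#' @export
clusterSizes <- function(x) setNames(lengths(x@members), x@clusterIds)

#' @export
setMethod("show", "CodingModel", function(object) {
    cat(sprintf("CodingModel for genome '%s'\n", object@genomeId))
    cat(sprintf("  20 amino-acid states, 61 sense codons, pseudocount %g\n",
                object@pseudocount))
    cat(sprintf("  length model support: %s..%s codons\n",
                names(object@lengthModel)[1],
                names(object@lengthModel)[length(object@lengthModel)]))
})

#' @export
setMethod("show", "BasePairMatrix", function(object) {
    n <- nchar(object@seq)
    cat(sprintf("BasePairMatrix for %d-nt sequence\n", n))
    cat(sprintf("  expected number of pairs: %.3f\n", sum(object@prob)))
})

#' BasePairMatrix accessors
#' @param x a \code{BasePairMatrix}
#' @rdname bpm-accessors
#' @export
bppMatrix <- function(x) x@prob
#' @rdname bpm-accessors
#' @export
bppSequence <- function(x) x@seq

#' @export
setMethod("show", "MeanRankNull", function(object) {
    cat(sprintf(
        "MeanRankNull: mean of %g ranks from 1..%g (%g samples)\n",
        object@n, object@N, object@reps))
    cat(sprintf("  fitted normal: mu = %.2f, sigma = %.2f\n",
                object@mu, object@sigma))
})

#' MeanRankNull accessors
#' @param x a \code{MeanRankNull}
#' @rdname null-accessors
#' @export
nullMu <- function(x) x@mu
#' @rdname null-accessors
#' @export
nullSigma <- function(x) x@sigma

#' @export
setMethod("show", "RankingModel", function(object) {
    cat(sprintf("RankingModel over %d feature(s): %s\n",
                length(object@selected),
                paste(object@selected, collapse = ", ")))
    w <- round(object@weights, 3)
    cat(sprintf("  weights: %s\n",
                paste(sprintf("%s=%g", names(w), w), collapse = " ")))
    cat(sprintf("  sum of positive ranks: %g (%d positives, %d clusters)\n",
                object@objective, length(object@positives),
                length(object@ranks)))
})

#' RankingModel accessors
#' @param x a \code{RankingModel}
#' @rdname ranking-accessors
#' @export
rankingWeights <- function(x) x@weights
#' @rdname ranking-accessors
#' @export
rankingScores <- function(x) x@scores
#' @rdname ranking-accessors
#' @export
rankingRanks <- function(x) x@ranks
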