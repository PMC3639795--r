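# RNA structure comparison of PYLIS regions: base-pairing probability
# matrices from a McCaskill-style partition function, pmcomp-style
# simultaneous alignment of two matrices, per-cluster structural similarity,
# and the neighbor-joining dendrogram over PYLIS regions.

#' Base-pairing probabilities of a sequence
#'
#' Computes the matrix of equilibrium probabilities that positions i < j
#' pair, from the partition function over nested secondary structures with a
#' deliberately simplified per-pair energy model (GC -3, AU -2, GU -1 in
#' kcal/mol-like units; kT = 0.6; minimum hairpin loop of 3; no stacking or
#' loop entropies). This is a self-contained stand-in for a full
#' thermodynamic folder and is exactly checkable against exhaustive
#' structure enumeration; any external tool emitting a dot-plot probability
#' matrix can be substituted where thermodynamic fidelity matters.
#'
#' @param seq an RNA or DNA string (T is read as U); length >= 1
#' @param kT thermal energy in the same units as the pair energies
#' @param energies named vector with elements GC, AU and GU
#' @param minHairpin minimum number of unpaired bases enclosed by a pair
#' @return a \linkS4class{BasePairMatrix}
#' @export
basePairProbabilities <- function(seq, kT = 0.6,
                                  energies = c(GC = -3, AU = -2, GU = -1),
                                  minHairpin = 3) {
    if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 1)
        stop("seq must be a non-empty string")
    P <- bpp_cpp(toupper(seq), kT, energies[["GC"]], energies[["AU"]],
                 energies[["GU"]], as.integer(minHairpin))
    new("BasePairMatrix", seq = toupper(chartr("T", "U", seq)), prob = P)
}

#' Align two base-pairing probability matrices (pmcomp-style)
#'
#' Sankoff-style simultaneous alignment maximizing the summed pair-of-pairs
#' bonus psi(p, q) = sqrt(p q) over matched base pairs (candidate pairs are
#' entries above the noise floor \code{pMin}), plus \code{sigmaMatch} for
#' every matched unpaired position and \code{gapCost} per gapped position.
#' The dynamic program runs over pairs of subsequence intervals with a
#' diagonal band of width \code{band} on both interval ends; \code{exact}
#' disables banding. The score is symmetric in its arguments.
#'
#' @param a,b \linkS4class{BasePairMatrix} objects (or plain square matrices)
#' @param sigmaMatch score for a matched unpaired position (default 0)
#' @param gapCost score per gapped position (default -0.1)
#' @param pMin noise floor below which pairing probabilities are ignored
#' @param band banding width for the interval DP
#' @param exact if TRUE, run the unbanded DP (small inputs only)
#' @return the alignment score (a number)
#' @export
pmcompScore <- function(a, b, sigmaMatch = 0, gapCost = -0.1, pMin = 1e-4,
                        band = 30, exact = FALSE) {
    Pa <- if (is(a, "BasePairMatrix")) a@prob else a
    Pb <- if (is(b, "BasePairMatrix")) b@prob else b
    if (!is.matrix(Pa) || !is.matrix(Pb) ||
        nrow(Pa) != ncol(Pa) || nrow(Pb) != ncol(Pb))
        stop("inputs must be square base-pairing probability matrices")
    w <- if (exact) max(nrow(Pa), nrow(Pb)) else as.integer(band)
    pmcomp_cpp(Pa, Pb, sigmaMatch, gapCost, pMin, w)
}

#' Pairwise structure scores for a set of PYLIS regions
#'
#' Folds every sequence once and aligns all pairs of probability matrices.
#'
#' @param nt named character vector of nucleotide sequences
#' @param ... passed to \code{\link{pmcompScore}}
#' @return symmetric matrix of alignment scores; the diagonal holds
#'   self-alignment scores
#' @export
structureScoreMatrix <- function(nt, ...) {
    n <- length(nt)
    mats <- lapply(nt, basePairProbabilities)
    S <- matrix(NA_real_, n, n, dimnames = list(names(nt), names(nt)))
    for (i in seq_len(n)) {
        S[i, i] <- pmcompScore(mats[[i]], mats[[i]], ...)
        if (i < n) for (j in seq((i + 1), n)) {
            S[i, j] <- S[j, i] <- pmcompScore(mats[[i]], mats[[j]], ...)
        }
    }
    S
}

#' Average structural similarity within a cluster
#'
#' Mean pmcomp-style alignment score over ordered pairs of distinct members,
#' i.e. \code{sum / (n^2 - n)}; by symmetry this equals the unordered-pair
#' mean.
#'
#' @param scoreMat symmetric score matrix for the cluster's members
#' @return a number
#' @export
fStructure <- function(scoreMat) {
    n <- nrow(scoreMat)
    if (is.null(n) || n < 2) stop("f_structure needs at least 2 members")
    off <- scoreMat[row(scoreMat) != col(scoreMat)]
    mean(off)
}

#' Structure distances from alignment scores
#'
#' dist = 1 / score. Pairs with score <= 0 have no defined inverse and are
#' set to \code{cap} (logged via a warning).
#'
#' @param scoreMat symmetric score matrix
#' @param cap distance assigned to non-positive scores (default 1e6)
#' @return symmetric distance matrix with zero diagonal
#' @export
structureDistances <- function(scoreMat, cap = 1e6) {
    d <- scoreMat
    bad <- d <= 0
    if (any(bad[row(d) != col(d)]))
        warning(sum(bad[row(d) != col(d)]) / 2,
                " pair(s) with non-positive score capped at ", cap)
    d[!bad] <- 1 / d[!bad]
    d[bad] <- cap
    diag(d) <- 0
    d
}

#' Neighbor-joining tree of PYLIS regions
#'
#' Canonical neighbor joining (Saitou-Nei Q-criterion, via \code{ape::nj})
#' with negative branch lengths clamped to zero.
#'
#' @param distMat symmetric non-negative distance matrix with zero diagonal
#'   and at least 3 rows
#' @return an \code{ape} \code{phylo} tree
#' @export
neighborJoining <- function(distMat) {
    if (!isSymmetric(unname(distMat), tol = 1e-8))
        stop("distance matrix must be symmetric")
    if (any(distMat < 0)) stop("distances must be non-negative")
    if (nrow(distMat) < 3) stop("need at least 3 leaves")
    tr <- ape::nj(as.dist(distMat))
    tr$edge.length[tr$edge.length < 0] <- 0
    tr
}

#' @importFrom stats as.dist
NULL
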