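# Per-cluster features, min-max normalization across clusters, and the two
# combined (geometric-mean) features.

#' Edit distance with gap runs restricted to multiples of m
#'
#' Minimal number of insertions, deletions or substitutions transforming
#' \code{s} into \code{t}, over edit scripts in which every maximal run of
#' insertions has length divisible by \code{m}, and likewise for deletions.
#' \code{m = 1} is the classical Levenshtein distance. Pairs whose length
#' difference is not divisible by \code{m} are unreachable under this
#' constraint and return \code{Inf}.
#'
#' @param s,t character strings over a common alphabet
#' @param m gap-run modulus (>= 1)
#' @return the minimal edit cost (possibly \code{Inf})
#' @export
distM <- function(s, t, m = 1) {
    if (m < 1) stop("m must be >= 1")
    dist_m_cpp(s, t, as.integer(m))
}

#' Nucleotide diversity of a cluster's PYLIS regions
#'
#' Mean DIST_3 edit distance (gap runs in multiples of 3, preserving codon
#' structure) over ordered pairs of distinct members:
#' \code{sum / (n^2 - n)}.
#'
#' @param nt character vector of the members' 100-nt PYLIS regions (n >= 2)
#' @return a number; 0 iff all regions are identical
#' @export
fDiversity <- function(nt) {
    n <- length(nt)
    if (n < 2) stop("f_diversity needs at least 2 members")
    pairs <- combn(n, 2)
    d <- vapply(seq_len(ncol(pairs)), function(k)
        distM(nt[pairs[1, k]], nt[pairs[2, k]], 3), numeric(1))
    mean(d)
}

#' Synonymous-codon conservation of a cluster
#'
#' Compares the members' translated PYLIS peptides pairwise with DIST_1
#' (Levenshtein). The default \code{percent_identity} variant reports the
#' mean of \code{100 (1 - DIST_1 / L)} over pairs (clamped to [0, 100]; L is
#' the peptide length, 33 for standard PYLIS regions), which is well defined
#' for identical pairs and matches the percent scale of reported values.
#' The \code{reciprocal} variant follows the printed formula literally:
#' mean of \code{1 / max(DIST_1, 1)}.
#'
#' @param aa character vector of the members' 33-residue peptides (n >= 2)
#' @param variant \code{"percent_identity"} (default) or \code{"reciprocal"}
#' @return a number
#' @export
fSynCodons <- function(aa, variant = c("percent_identity", "reciprocal")) {
    variant <- match.arg(variant)
    n <- length(aa)
    if (n < 2) stop("f_syn_codons needs at least 2 members")
    pairs <- combn(n, 2)
    vals <- vapply(seq_len(ncol(pairs)), function(k) {
        a <- aa[pairs[1, k]]; b <- aa[pairs[2, k]]
        d <- distM(a, b, 1)
        if (variant == "percent_identity") {
            L <- max(nchar(a), nchar(b))
            min(max(100 * (1 - d / L), 0), 100)
        } else 1 / max(d, 1)
    }, numeric(1))
    mean(vals)
}

#' Simple per-cluster features
#'
#' \code{fSize} is the member count; \code{fOrganisms} the number of
#' distinct genomes represented; \code{fUpstream} the mean distance in
#' nucleotides from the start codon to the amber codon (including the start
#' codon's 3 nt); \code{fDownstream} the mean distance from the amber to the
#' terminal stop, excluding both codons.
#'
#' @param clusters a \linkS4class{ClusterSet}
#' @param iorfs the underlying \linkS4class{InterruptedORFSet}
#' @return data.frame with one row per cluster
#' @export
simpleFeatures <- function(clusters, iorfs) {
    el <- iorfs@elements
    rownames(el) <- el$iorfId
    do.call(rbind, lapply(seq_along(clusters@clusterIds), function(i) {
        m <- clusters@members[[i]]
        e <- el[m, , drop = FALSE]
        data.frame(clusterId = clusters@clusterIds[i],
                   fSize = length(m),
                   fOrganisms = length(unique(e$genomeId)),
                   fUpstream = mean(e$uagPos - e$start),
                   fDownstream = mean(e$stopEnd - 3L - (e$uagPos + 3L)),
                   stringsAsFactors = FALSE)
    }))
}

#' Full raw feature table for a set of clusters
#'
#' Assembles the eight raw per-cluster features: size, organisms, upstream
#' and downstream lengths, nucleotide diversity (DIST_3), synonymous-codon
#' conservation (DIST_1 on peptides), structural similarity (pmcomp-style),
#' and coding potential.
#'
#' @param clusters a \linkS4class{ClusterSet}
#' @param iorfs the underlying \linkS4class{InterruptedORFSet}
#' @param pylis data.frame from \code{\link{extractPylis}}
#' @param codingScores named per-iORF scores from \code{\link{scoreIorfs}}
#' @param synVariant variant for \code{\link{fSynCodons}}
#' @param structureArgs list of arguments passed to
#'   \code{\link{structureScoreMatrix}} (band width etc.)
#' @return data.frame with one row per cluster and columns clusterId, fSize,
#'   fOrganisms, fUpstream, fDownstream, fDiversity, fSynCodons, fStructure,
#'   fCoding
#' @export
clusterFeatureTable <- function(clusters, iorfs, pylis, codingScores,
                                synVariant = "percent_identity",
                                structureArgs = list()) {
    if (length(clusters) == 0) stop("no clusters")
    simple <- simpleFeatures(clusters, iorfs)
    py <- setNames(pylis$nt, pylis$iorfId)
    pa <- setNames(pylis$aa, pylis$iorfId)
    fc <- fCoding(clusters, codingScores)
    extra <- do.call(rbind, lapply(seq_along(clusters@clusterIds),
                                   function(i) {
        m <- clusters@members[[i]]
        S <- do.call(structureScoreMatrix, c(list(py[m]), structureArgs))
        data.frame(fDiversity = fDiversity(py[m]),
                   fSynCodons = fSynCodons(pa[m], synVariant),
                   fStructure = fStructure(S))
    }))
    cbind(simple, extra,
          data.frame(fCoding = unname(fc[simple$clusterId])))
}

#' Min-max normalize feature columns across clusters
#'
#' Each numeric feature is mapped to [0, 1] by
#' \code{(f - min) / (max - min)} across clusters. A constant feature
#' (max = min) is set to 0 everywhere, with a warning.
#'
#' @param features data.frame with a \code{clusterId} column and numeric
#'   feature columns; needs >= 2 rows
#' @return data.frame of the same shape with normalized feature values
#' @export
normalizeFeatures <- function(features) {
    if (nrow(features) < 2) stop("normalization needs >= 2 clusters")
    out <- features
    num <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                   "clusterId")
    for (cn in num) {
        x <- features[[cn]]
        rng <- range(x)
        if (rng[1] == rng[2]) {
            warning("feature ", cn, " is constant across clusters; ",
                    "normalized to 0")
            out[[cn]] <- rep(0, length(x))
        } else {
            out[[cn]] <- (x - rng[1]) / (rng[2] - rng[1])
        }
    }
    out
}

#' Combined (geometric-mean) features
#'
#' Adds \code{fCodingUpstream}, the geometric mean of the normalized coding
#' and upstream features, and \code{fStructDivSyn}, the cube root of the
#' product of the normalized structure, diversity and synonymous-codon
#' features.
#'
#' @param normalized data.frame of normalized features (values in [0, 1])
#' @return the input with the two combined columns appended
#' @export
combinedFeatures <- function(normalized) {
    need <- c("fCoding", "fUpstream", "fStructure", "fDiversity",
              "fSynCodons")
    miss <- setdiff(need, names(normalized))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    normalized$fCodingUpstream <-
        sqrt(normalized$fCoding * normalized$fUpstream)
    normalized$fStructDivSyn <-
        (normalized$fStructure * normalized$fDiversity *
             normalized$fSynCodons)^(1 / 3)
    normalized
}
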