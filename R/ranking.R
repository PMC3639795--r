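# Feature significance against a sampled mean-rank null, weight estimation
# by minimizing the summed ranks of positive examples, and the final
# weighted ranking.

#' Sampled null distribution of the mean of n ranks
#'
#' Draws \code{reps} samples, each the mean of \code{n} ranks sampled
#' without replacement from \code{1..N}, and fits a normal distribution
#' (sample mean and standard deviation). By the central limit theorem the
#' distribution of such means is close to normal even for small n.
#'
#' @param N number of ranked clusters
#' @param n number of positive clusters
#' @param reps number of sampled means (default 1e5)
#' @param seed optional RNG seed (restores the caller's RNG state)
#' @return a \linkS4class{MeanRankNull}
#' @export
sampleMeanRankNull <- function(N, n, reps = 1e5, seed = NULL) {
    if (n > N) stop("n must not exceed N")
    if (reps < 1) stop("reps must be >= 1")
    means <- .withSeed(seed, {
        vapply(seq_len(reps), function(i) mean(sample.int(N, n)), numeric(1))
    })
    sigma <- if (reps > 1) sd(means) else 0
    if (sigma == 0)
        warning("degenerate null (sigma = 0); p-values will be 0/1 steps")
    new("MeanRankNull", N = N, n = n, reps = reps, mu = mean(means),
        sigma = sigma, seed = if (is.null(seed)) NA_real_ else seed)
}

#' Finite-population closed form for the mean-rank null
#'
#' Exact mean and standard deviation of the mean of n ranks drawn without
#' replacement from 1..N: mu = (N+1)/2 and
#' sigma = sqrt((N^2-1)/12 * (N-n)/(N-1) / n).
#'
#' @param N,n as in \code{\link{sampleMeanRankNull}}
#' @return list with elements \code{mu} and \code{sigma}
#' @export
meanRankNullExact <- function(N, n) {
    list(mu = (N + 1) / 2,
         sigma = sqrt((N^2 - 1) / 12 * (N - n) / (N - 1) / n))
}

#' Lower-tail p-value for a set of observed ranks
#'
#' Probability of a mean rank at least as low as the observed one by
#' chance, from the fitted normal's lower-tail CDF.
#'
#' @param ranks observed ranks of the positive clusters (each in 1..N)
#' @param null a \linkS4class{MeanRankNull}
#' @return the p-value
#' @export
meanRankPvalue <- function(ranks, null) {
    if (length(ranks) == 0) stop("empty rank list")
    if (any(ranks < 1 | ranks > null@N)) stop("ranks must be in 1..N")
    if (null@sigma == 0) return(as.numeric(mean(ranks) <= null@mu))
    pnorm((mean(ranks) - null@mu) / null@sigma)
}

#' Rank clusters by a feature value
#'
#' Ordinal ranking: rank 1 is best. With \code{decreasing = TRUE} (the
#' default orientation for every feature) high values rank first. Ties are
#' broken deterministically by cluster id.
#'
#' @param values named numeric vector (names are cluster ids)
#' @param decreasing if TRUE, high values are better
#' @return named integer vector of ranks, a permutation of 1..N
#' @export
rankClusters <- function(values, decreasing = TRUE) {
    ids <- names(values)
    if (is.null(ids)) stop("values must be named by cluster id")
    o <- if (decreasing) order(-values, ids) else order(values, ids)
    ranks <- integer(length(values))
    ranks[o] <- seq_along(values)
    setNames(ranks, ids)
}

#' Select significant features
#'
#' Retains the features whose mean-rank p-value is at most \code{alpha};
#' the others are not used for the final ranking.
#'
#' @param pvalues named numeric vector of per-feature p-values
#' @param alpha significance level (default 0.05)
#' @return character vector of selected feature names (possibly empty)
#' @export
selectSignificantFeatures <- function(pvalues, alpha = 0.05) {
    names(pvalues)[pvalues <= alpha]
}

# projection onto the probability simplex (Duchi et al. style)
.projectSimplex <- function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u - (css - 1) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(v - theta, 0)
}

.trueObjective <- function(w, X, positives) {
    ranks <- rankClusters(setNames(drop(X %*% w), rownames(X)))
    sum(ranks[positives])
}

.smoothObjective <- function(w, X, positives, tau) {
    s <- drop(X %*% w)
    pos <- match(positives, rownames(X))
    obj <- 0
    for (e in pos) {
        z <- (s[-e] - s[e]) / tau
        obj <- obj + 1 + sum(stats::plogis(z))
    }
    obj
}

.smoothGradient <- function(w, X, positives, tau) {
    s <- drop(X %*% w)
    pos <- match(positives, rownames(X))
    g <- numeric(ncol(X))
    for (e in pos) {
        z <- (s - s[e]) / tau
        d <- stats::dlogis(z) / tau
        d[e] <- 0
        g <- g + drop(t(X) %*% d) - sum(d) * X[e, ]
    }
    g
}

.gradientDescent <- function(w0, X, positives, tau, maxIter) {
    w <- w0
    eta <- 1
    for (it in seq_len(maxIter)) {
        g <- .smoothGradient(w, X, positives, tau)
        f0 <- .smoothObjective(w, X, positives, tau)
        improved <- FALSE
        while (eta > 1e-10) {
            w1 <- .projectSimplex(w - eta * g)
            if (.smoothObjective(w1, X, positives, tau) < f0 - 1e-12) {
                improved <- TRUE
                break
            }
            eta <- eta / 2
        }
        if (!improved) break
        if (sum(abs(w1 - w)) < 1e-12) { w <- w1; break }
        w <- w1
        eta <- min(eta * 2, 1e3)
    }
    w
}

.coordinateSearch <- function(w0, X, positives, maxIter) {
    w <- w0
    grid <- c(0, 0.05, 0.1, 0.2, 0.35, 0.5, 0.7, 1)
    best <- .trueObjective(w, X, positives)
    for (it in seq_len(maxIter)) {
        changed <- FALSE
        for (j in seq_along(w)) {
            for (v in grid) {
                wj <- w
                wj[j] <- v
                if (sum(wj) == 0) next
                wj <- wj / sum(wj)
                obj <- .trueObjective(wj, X, positives)
                if (obj < best) {
                    best <- obj
                    w <- wj
                    changed <- TRUE
                }
            }
        }
        if (!changed) break
    }
    w
}

#' Estimate feature weights by minimizing summed positive ranks
#'
#' Finds non-negative weights summing to one (the objective is
#' scale-invariant) that minimize the sum of ranks of the positive-example
#' clusters under the combined score \code{X w}. The rank objective is a
#' step function, so descent runs on a smoothed surrogate in which each
#' rank is \code{1 + sum over other clusters of sigmoid((s_j - s_e)/tau)};
#' the reported objective and the returned solution are judged by the true
#' (unsmoothed) sum of ranks.
#'
#' Restarts form a deterministic, permutation-symmetric set: every
#' single-feature vertex, equal weights, every pairwise 50/50 mixture, and
#' weights proportional to the inverse single-feature objectives. This
#' makes the result equivariant under permutations of the feature columns
#' and guarantees the solution is never worse than equal weights or the
#' best single feature. Seeded random Dirichlet restarts can be added.
#'
#' @param X matrix of normalized features (rows = clusters with rownames,
#'   columns = selected features)
#' @param positives cluster ids of the positive examples
#' @param tau temperature of the sigmoid surrogate (default 0.01)
#' @param maxIter maximum descent iterations per restart
#' @param method \code{"gradient"} (default) or \code{"coordinate"}
#'   (derivative-free)
#' @param extraRandomRestarts number of additional random restarts
#' @param seed RNG seed for the random restarts
#' @return list with elements \code{weights} (named, sums to 1) and
#'   \code{objective} (true summed positive ranks)
#' @export
optimizeWeights <- function(X, positives, tau = 0.01, maxIter = 200,
                            method = c("gradient", "coordinate"),
                            extraRandomRestarts = 0, seed = NULL) {
    method <- match.arg(method)
    if (is.null(rownames(X))) stop("X needs cluster ids as rownames")
    if (!all(positives %in% rownames(X)))
        stop("positives must be rows of X")
    if (length(positives) < 1) stop("need at least one positive example")
    k <- ncol(X)
    if (any(apply(X, 2, function(x) max(x) == min(x))) && k == 1)
        stop("degenerate: all features constant")
    starts <- lapply(seq_len(k), function(j) {
        w <- numeric(k); w[j] <- 1; w
    })
    starts <- c(starts, list(rep(1 / k, k)))
    if (k >= 2) {
        pr <- combn(k, 2)
        starts <- c(starts, lapply(seq_len(ncol(pr)), function(c2) {
            w <- numeric(k); w[pr[, c2]] <- 0.5; w
        }))
    }
    singleObj <- vapply(seq_len(k), function(j) {
        w <- numeric(k); w[j] <- 1
        .trueObjective(w, X, positives)
    }, numeric(1))
    starts <- c(starts, list((1 / singleObj) / sum(1 / singleObj)))
    if (extraRandomRestarts > 0) {
        rand <- .withSeed(seed, {
            lapply(seq_len(extraRandomRestarts), function(i) {
                g <- stats::rgamma(k, 1)
                g / sum(g)
            })
        })
        starts <- c(starts, rand)
    }
    cands <- list()
    for (w0 in starts) {
        w <- if (method == "gradient")
            .gradientDescent(w0, X, positives, tau, maxIter)
        else .coordinateSearch(w0, X, positives, maxIter)
        # starts themselves are admissible solutions too
        cands <- c(cands, list(list(w = w0), list(w = w)))
    }
    objs <- vapply(cands, function(c2) .trueObjective(c2$w, X, positives),
                   numeric(1))
    best <- which(objs == min(objs))
    if (length(best) > 1) {
        # canonical tie-break: compare weight vectors ordered by feature
        # name, lexicographically -- invariant under column permutations
        o <- order(colnames(X))
        keys <- vapply(best, function(i)
            paste(sprintf("%.12f", cands[[i]]$w[o]), collapse = ","),
            character(1))
        best <- best[order(keys)]
    }
    best <- best[1]
    list(weights = setNames(cands[[best]]$w, colnames(X)),
         objective = objs[best])
}

#' Final weighted ranking of clusters
#'
#' Scores every cluster as the weighted sum of its selected normalized
#' features, sorts descending and assigns ordinal ranks (ties broken by
#' cluster id), flagging the positive examples.
#'
#' @param X matrix of normalized features (rows = clusters with rownames)
#' @param weights named weight vector over columns of X
#' @param positives cluster ids of the positive examples
#' @return data.frame with columns clusterId, score, rank, isPositive,
#'   sorted by rank
#' @export
finalRanking <- function(X, weights, positives = character(0)) {
    w <- weights[colnames(X)]
    if (anyNA(w)) stop("weights must cover the columns of X")
    scores <- setNames(drop(X %*% w), rownames(X))
    ranks <- rankClusters(scores)
    out <- data.frame(clusterId = names(scores), score = unname(scores),
                      rank = unname(ranks),
                      isPositive = names(scores) %in% positives,
                      stringsAsFactors = FALSE)
    out[order(out$rank), , drop = FALSE]
}

#' Fit the full ranking model
#'
#' Convenience wrapper: ranks the clusters under each candidate feature,
#' computes mean-rank p-values for the positives with a sampled null,
#' selects the significant features, optimizes their weights and ranks all
#' clusters.
#'
#' @param features data.frame of normalized features (with combined
#'   features appended) and a \code{clusterId} column
#' @param positives cluster ids of the positive examples
#' @param alpha significance level for feature selection
#' @param reps null sample count
#' @param seed RNG seed for the null sampling
#' @return a \linkS4class{RankingModel}
#' @export
fitRankingModel <- function(features, positives, alpha = 0.05, reps = 1e5,
                            seed = NULL) {
    featCols <- setdiff(names(features), "clusterId")
    X <- as.matrix(features[, featCols, drop = FALSE])
    rownames(X) <- features$clusterId
    if (!all(positives %in% rownames(X)))
        stop("positive cluster(s) absent from the feature table: ",
             paste(setdiff(positives, rownames(X)), collapse = ", "))
    N <- nrow(X)
    null <- sampleMeanRankNull(N, length(positives), reps = reps,
                               seed = seed)
    pvals <- vapply(featCols, function(cn) {
        r <- rankClusters(setNames(X[, cn], rownames(X)))
        meanRankPvalue(unname(r[positives]), null)
    }, numeric(1))
    selected <- selectSignificantFeatures(pvals, alpha)
    if (length(selected) == 0)
        stop("no feature is significant at alpha = ", alpha,
             "; cannot build a ranking")
    opt <- optimizeWeights(X[, selected, drop = FALSE], positives)
    rk <- finalRanking(X[, selected, drop = FALSE], opt$weights, positives)
    new("RankingModel", selected = selected, weights = opt$weights,
        positives = positives,
        scores = setNames(rk$score, rk$clusterId),
        ranks = setNames(as.integer(rk$rank), rk$clusterId),
        objective = opt$objective,
        meta = list(pvalues = pvals, N = N, n = length(positives),
                    reps = reps, mu = null@mu, sigma = null@sigma,
                    alpha = alpha,
                    seed = if (is.null(seed)) NA_real_ else seed))
}
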