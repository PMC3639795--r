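# Independent brute-force oracles used to check the implementations.

# --- iORF grammar oracle -----------------------------------------------
# Walks every possible start position on both strands and applies the
# grammar definition literally, then keeps the 5'-most start per amber.
oracleIorfsStrand <- function(s, minDownstream = 100) {
    STOPS <- c("TAA", "TAG", "TGA")
    STARTS <- c("TTG", "CTG", "ATT", "ATC", "ATA", "ATG", "GTG")
    L <- nchar(s)
    found <- list()
    for (p0 in 0:(L - 3)) {
        if (!(substr(s, p0 + 1, p0 + 3) %in% STARTS)) next
        # walk codons until the first stop; it must be TAG (the amber)
        q <- p0
        amber <- NA
        repeat {
            q <- q + 3
            if (q + 3 > L) break
            cod <- substr(s, q + 1, q + 3)
            if (cod %in% STOPS) {
                if (cod == "TAG") amber <- q
                break
            }
        }
        if (is.na(amber)) next
        # walk on to the next stop after the amber
        q <- amber
        stopEnd <- NA
        repeat {
            q <- q + 3
            if (q + 3 > L) break
            cod <- substr(s, q + 1, q + 3)
            if (cod %in% STOPS) {
                stopEnd <- q + 3
                break
            }
        }
        if (is.na(stopEnd)) next
        if (stopEnd - 3 - (amber + 3) < minDownstream) next
        found[[length(found) + 1]] <- c(start = p0, uagPos = amber,
                                        stopEnd = stopEnd)
    }
    if (!length(found))
        return(data.frame(start = integer(0), uagPos = integer(0),
                          stopEnd = integer(0)))
    df <- as.data.frame(do.call(rbind, found))
    # 5'-most start per amber
    df <- df[order(df$uagPos, df$start), ]
    df <- df[!duplicated(df$uagPos), ]
    rownames(df) <- NULL
    df
}

oracleIorfs <- function(s, minDownstream = 100) {
    plus <- oracleIorfsStrand(s, minDownstream)
    minus <- oracleIorfsStrand(pylseeker::revComp(s), minDownstream)
    if (nrow(plus)) plus$strand <- "+"
    if (nrow(minus)) minus$strand <- "-"
    out <- rbind(if (nrow(plus)) plus,
                 if (nrow(minus)) minus)
    if (is.null(out))
        out <- data.frame(start = integer(0), uagPos = integer(0),
                          stopEnd = integer(0), strand = character(0))
    out
}

randomSeq <- function(n, gc = 0.5) {
    paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
}

# --- constrained edit distance oracle ----------------------------------
# Exhaustive DP-free recursion with memoization is itself a DP, so instead
# enumerate alignments directly: sequences of moves (M)atch/(I)ns/(D)el and
# check the run constraint on the full move string.
oracleDistM <- function(s, t, m) {
    sv <- strsplit(s, "")[[1]]
    tv <- strsplit(t, "")[[1]]
    ns <- length(sv); nt <- length(tv)
    best <- Inf
    rec <- function(i, j, moves, cost) {
        if (cost >= best) return()
        if (i > ns && j > nt) {
            runs <- rle(moves)
            ok <- all(runs$lengths[runs$values == "I"] %% m == 0) &&
                all(runs$lengths[runs$values == "D"] %% m == 0)
            if (ok) best <<- min(best, cost)
            return()
        }
        if (i <= ns && j <= nt)
            rec(i + 1, j + 1, c(moves, "M"),
                cost + (sv[i] != tv[j]))
        if (j <= nt) rec(i, j + 1, c(moves, "I"), cost + 1)
        if (i <= ns) rec(i + 1, j, c(moves, "D"), cost + 1)
    }
    rec(1, 1, character(0), 0)
    best
}

# --- partition-function enumeration oracle -----------------------------
# Enumerates every nested structure (min hairpin 3) explicitly and
# accumulates Boltzmann-weighted pair frequencies.
oracleBpp <- function(seq, kT = 0.6,
                      energies = c(GC = -3, AU = -2, GU = -1),
                      minHairpin = 3) {
    s <- chartr("T", "U", toupper(seq))
    n <- nchar(s)
    ch <- strsplit(s, "")[[1]]
    w <- function(i, j) {
        p <- paste0(ch[i], ch[j])
        if (p %in% c("GC", "CG")) return(exp(-energies[["GC"]] / kT))
        if (p %in% c("AU", "UA")) return(exp(-energies[["AU"]] / kT))
        if (p %in% c("GU", "UG")) return(exp(-energies[["GU"]] / kT))
        0
    }
    structures <- function(i, j) {
        # list of pair-lists over positions i..j
        if (j - i < minHairpin + 1) return(list(list()))
        out <- structures(i, j - 1)  # j unpaired
        for (k in i:(j - minHairpin - 1)) {
            if (w(k, j) == 0) next
            inner <- structures(k + 1, j - 1)
            outer <- if (k > i) structures(i, k - 1) else list(list())
            for (a in outer) for (b in inner)
                out[[length(out) + 1]] <- c(a, b, list(c(k, j)))
        }
        out
    }
    str <- structures(1, n)
    P <- matrix(0, n, n)
    Z <- 0
    for (st in str) {
        wt <- prod(vapply(st, function(p) w(p[1], p[2]), numeric(1)))
        if (length(st) == 0) wt <- 1
        Z <- Z + wt
        for (p in st) P[p[1], p[2]] <- P[p[1], p[2]] + wt
    }
    P / Z
}

# --- union-find oracle for connected components ------------------------
oracleComponents <- function(nodes, edges) {
    parent <- setNames(nodes, nodes)
    find <- function(x) {
        while (parent[[x]] != x) x <- parent[[x]]
        x
    }
    if (nrow(edges)) for (k in seq_len(nrow(edges))) {
        a <- find(edges[[1]][k]); b <- find(edges[[2]][k])
        if (a != b) parent[[a]] <- b
    }
    roots <- vapply(nodes, find, character(1))
    comps <- split(nodes, roots)
    comps <- comps[lengths(comps) >= 2]
    comps <- lapply(comps, sort)
    comps <- comps[order(vapply(comps, `[`, character(1), 1))]
    unname(comps)
}

# --- additive tree metric for NJ oracle --------------------------------
# path-length distance matrix of a random binary tree with known branch
# lengths, built with ape (the oracle is the additivity property itself)
additiveDistances <- function(nLeaves, seed) {
    set.seed(seed)
    tr <- ape::rtree(nLeaves, rooted = FALSE)
    tr$edge.length <- round(runif(nrow(tr$edge), 0.2, 2), 3)
    list(tree = tr, D = cophenetic(tr))
}
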