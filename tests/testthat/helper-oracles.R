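# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R dynamic programming, boolean-matrix
# transitive closure, direct codon-table translation, and pair counting.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

rand_pep <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# Reference quadratic-space affine-gap Smith-Waterman, score only.
ref_sw <- function(a, b, mat, go = 11, ge = 1) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    m <- length(A); n <- length(B)
    if (m == 0 || n == 0) return(0)
    H <- matrix(0, m + 1, n + 1)
    E <- matrix(-Inf, m + 1, n + 1)
    F <- matrix(-Inf, m + 1, n + 1)
    best <- 0
    for (i in seq_len(m) + 1) {
        for (j in seq_len(n) + 1) {
            E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
            F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
            H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                           E[i, j], F[i, j])
            best <- max(best, H[i, j])
        }
    }
    best
}

# Transitive closure over (bin-respecting) edges by repeated boolean
# matrix multiplication; returns a named cluster label per contig.
brute_components <- function(ids, edges) {
    n <- length(ids)
    M <- diag(n) > 0
    dimnames(M) <- list(ids, ids)
    if (nrow(edges)) {
        for (k in seq_len(nrow(edges))) {
            M[edges$contig_a[k], edges$contig_b[k]] <- TRUE
            M[edges$contig_b[k], edges$contig_a[k]] <- TRUE
        }
    }
    repeat {
        M2 <- (M %*% M) > 0 | M
        if (identical(M2, M)) break
        M <- M2
    }
    vapply(ids, function(i) min(ids[M[i, ]]), "")
}

# Direct codon-table translation (no package code), frames +-1..3.
GC_TAB <- {
    gc <- Biostrings::GENETIC_CODE
    stats::setNames(as.character(gc), names(gc))
}

oracle_translate <- function(nt, frame) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    s <- strsplit(nt, "")[[1]]
    if (frame < 0) s <- rev(unname(comp[s]))
    s <- s[abs(frame):length(s)]
    ncod <- length(s) %/% 3
    if (ncod < 1) return("")
    cods <- vapply(seq_len(ncod), function(k)
        paste(s[(3 * k - 2):(3 * k)], collapse = ""), "")
    aa <- GC_TAB[cods]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

# Longest stop-free stretch over all six frames (length and the set of
# peptides achieving it).
oracle_longest_orf <- function(nt) {
    best_len <- 0L
    best_peps <- character(0)
    for (f in c(1, 2, 3, -1, -2, -3)) {
        pep <- oracle_translate(nt, f)
        parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
        parts <- parts[nzchar(parts)]
        for (p in parts) {
            if (nchar(p) > best_len) {
                best_len <- nchar(p)
                best_peps <- p
            } else if (nchar(p) == best_len) {
                best_peps <- union(best_peps, p)
            }
        }
    }
    list(len = best_len, peptides = best_peps)
}

# Random additive distances from a random tree with positive branch
# lengths; returns the generating tree and its path-length matrix.
rand_additive <- function(n_taxa = 8) {
    tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    list(tree = ape::unroot(tr), D = D)
}

# Pair-counting ARI by explicit enumeration of all unordered pairs.
oracle_ari <- function(x, y) {
    n <- length(x)
    idx <- utils::combn(n, 2)
    sx <- x[idx[1, ]] == x[idx[2, ]]
    sy <- y[idx[1, ]] == y[idx[2, ]]
    a <- sum(sx & sy); b <- sum(sx); c <- sum(sy)
    np <- ncol(idx)
    exp_ <- b * c / np
    max_ <- (b + c) / 2
    if (max_ == exp_) return(1)
    (a - exp_) / (max_ - exp_)
}

# Synthetic hit-table row in the 12-column layout.
make_hit <- function(q, s, evalue, bits, len = 100L, qlen = NULL) {
    h <- data.frame(query_id = q, subject_id = s, pident = 90,
                    length = len, mismatch = 5L, gapopen = 0L,
                    qstart = 1L, qend = len, sstart = 1L, send = len,
                    evalue = evalue, bitscore = bits,
                    stringsAsFactors = FALSE)
    if (!is.null(qlen)) h$qlen <- qlen
    h
}
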