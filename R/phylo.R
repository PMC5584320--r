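## Neighbor-joining trees with bootstrap support from protein multiple
## alignments. Alignments are consumed, not produced. Trees are returned
## as ape "phylo" objects (unrooted, trifurcation at the root node) so the
## usual newick tooling applies; bootstrap supports are integer
## percentages stored as internal node labels.

alnMatrix <- function(alignment) {
    ch <- asCharSeqs(alignment)
    if (!length(ch)) stop("empty alignment")
    w <- unique(nchar(ch))
    if (length(w) != 1L)
        stop("aligned sequences must all have the same length")
    if (w < 1L) stop("alignment has zero columns")
    m <- do.call(rbind, strsplit(toupper(ch), "", fixed = TRUE))
    rownames(m) <- names(ch)
    m
}

#' Pairwise p-distances from a protein alignment
#'
#' `d[i,j]` is the fraction of mismatching residues over the columns where
#' neither sequence has a gap (`-` or `.`): pairwise deletion. A pair with
#' no comparable column is an error.
#'
#' @param alignment aligned protein sequences of equal length
#'   (`AAStringSet` or named character vector).
#' @return A symmetric labeled distance matrix with zero diagonal.
#' @examples
#' pDistance(c(a = "MKW-", b = "MKY-"))["a", "b"] # 1/3
#' @export
pDistance <- function(alignment) {
    m <- alnMatrix(alignment)
    n <- nrow(m)
    gaps <- m == "-" | m == "."
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            ok <- !gaps[i, ] & !gaps[j, ]
            if (!any(ok))
                stop("no comparable columns between '", rownames(m)[i],
                     "' and '", rownames(m)[j], "'")
            d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
        }
    }
    d
}

fmtBL <- function(x) sprintf("%.12f", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' the Q-criterion, with branch lengths from the usual formulas and the
#' reduction step `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties on the
#' Q minimum are broken toward the lowest index pair. A negative branch
#' length is clamped to 0 and the deficit moved to its sibling edge, so
#' the joined pair's path length is preserved. Exact on additive
#' matrices.
#'
#' @param d symmetric distance matrix with labels (or a `dist`).
#' @return An unrooted `phylo` tree (trifurcation at the root).
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(njTree(d)) # A:0.05, B:0.15, C:0.25
#' @export
njTree <- function(d) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    labels <- rownames(d)
    n <- nrow(d)
    if (is.null(labels)) stop("distance matrix must have labels")
    if (n < 3L) stop("neighbor-joining needs at least 3 taxa")
    if (any(d < 0) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
        stop("distance matrix must be symmetric, nonnegative, zero diagonal")
    frag <- labels
    D <- d
    while (nrow(D) > 3L) {
        r <- nrow(D)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, "+")
        diag(Q) <- Inf
        hit <- which(Q == min(Q), arr.ind = TRUE)
        hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
        hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
        i <- hit[1L, 1L]; j <- hit[1L, 2L]
        dij <- D[i, j]
        bi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
        bj <- dij - bi
        if (bi < 0) { bj <- bj + bi; bi <- 0 }
        if (bj < 0) { bi <- bi + bj; bj <- 0 }
        newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmtBL(bi),
                           frag[j], fmtBL(bj))
        dk <- (D[i, ] + D[j, ] - dij) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                    c(dk[keep], 0))
        frag <- c(frag[keep], newfrag)
        dimnames(D2) <- list(NULL, NULL)
        D <- D2
    }
    ## final trifurcation
    ba <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    bb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    bc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    ba <- max(ba, 0); bb <- max(bb, 0); bc <- max(bc, 0)
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], fmtBL(ba),
                      frag[2L], fmtBL(bb), frag[3L], fmtBL(bc))
    ape::read.tree(text = newick)
}

## Canonical unrooted bipartitions of a phylo tree: for every internal
## non-root node, the tip set below it, represented by the side NOT
## containing the reference tip (first label alphabetically) and encoded
## as a sorted, comma-joined string. Returns a character vector named by
## internal node number.
treeSplits <- function(tree) {
    nt <- length(tree$tip.label)
    nn <- tree$Nnode
    desc <- vector("list", nt + nn)
    for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
    for (e in ape::postorder(tree)) {  # children complete before parent
        p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        desc[[p]] <- c(desc[[p]], desc[[ch]])
    }
    ref <- sort(tree$tip.label)[1L]
    root <- nt + 1L
    nodes <- setdiff(seq.int(nt + 1L, nt + nn), root)
    out <- vapply(nodes, function(nd) {
        s <- desc[[nd]]
        if (ref %in% s) s <- setdiff(tree$tip.label, s)
        paste(sort(s), collapse = ",")
    }, "")
    names(out) <- nodes
    out
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data tree with [pDistance()] + [njTree()], then
#' resamples alignment columns with replacement `replicates` times,
#' rebuilds a tree from each resample, and reports for every internal
#' bipartition of the full-data tree the percentage of replicate trees
#' containing it (integer percent, stored as the internal node label;
#' the root carries an empty label). Reproducible under `seed`.
#'
#' @param alignment aligned protein sequences (>= 2 columns).
#' @param replicates number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice).
#' @param seed RNG seed.
#' @return A `phylo` tree with `node.label` supports.
#' @export
bootstrapSupport <- function(alignment, replicates = 1000L, seed = 1L) {
    stopifnot(replicates >= 1L)
    m <- alnMatrix(alignment)
    if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
    seqs_of <- function(mm) setNames(apply(mm, 1L, paste, collapse = ""),
                                     rownames(mm))
    full <- njTree(pDistance(seqs_of(m)))
    full_splits <- treeSplits(full)
    count <- setNames(rep(0L, length(full_splits)), full_splits)
    if (exists(".Random.seed", envir = globalenv())) {
        old_seed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
    for (b in seq_len(replicates)) {
        idx <- sample.int(ncol(m), replace = TRUE)
        rep_tree <- njTree(pDistance(seqs_of(m[, idx, drop = FALSE])))
        rs <- unique(treeSplits(rep_tree))
        hit <- full_splits %in% rs
        count[hit] <- count[hit] + 1L
    }
    support <- as.integer(round(100 * count / replicates))
    nt <- length(full$tip.label)
    labs <- character(full$Nnode)
    node_nums <- as.integer(names(full_splits))
    labs[node_nums - nt] <- as.character(support)
    full$node.label <- labs
    full
}
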