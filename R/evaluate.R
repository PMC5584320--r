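## Cluster-recovery scoring against simulator ground truth: pairwise
## precision/recall over unordered contig pairs and the adjusted Rand
## index, both computed from the contingency table of the two partitions.

checkUniverse <- function(truth_labels, predicted) {
    a <- names(truth_labels); b <- names(predicted)
    if (is.null(a) || is.null(b))
        stop("labels must be named by contig id")
    miss_p <- setdiff(a, b); miss_t <- setdiff(b, a)
    if (length(miss_p) || length(miss_t))
        stop("contig universes differ; only in truth: ",
             paste(miss_p, collapse = ", "), "; only in prediction: ",
             paste(miss_t, collapse = ", "))
}

pairCounts <- function(truth_labels, predicted) {
    tab <- table(truth_labels, predicted[names(truth_labels)])
    nij <- sum(choose(tab, 2))                   # same gene & same cluster
    a <- sum(choose(rowSums(tab), 2))            # same gene
    b <- sum(choose(colSums(tab), 2))            # same cluster
    list(tab = tab, together_both = nij, together_truth = a,
         together_pred = b, n = sum(tab))
}

#' Pairwise precision and recall of a predicted partition
#'
#' Over all unordered contig pairs: precision is the fraction of
#' same-cluster pairs that are truly same-gene; recall is the fraction of
#' same-gene pairs recovered as same-cluster.
#'
#' @param truth_labels named character/factor vector, contig id to true
#'   gene.
#' @param predicted named vector, contig id to predicted cluster; must
#'   cover exactly the same contigs.
#' @return `list(precision = , recall = )`; a denominator of zero yields
#'   `NA`.
#' @examples
#' truth <- c(a = "g1", b = "g1", c = "g2", d = "g2")
#' pred  <- c(a = "1",  b = "1",  c = "2",  d = "3")
#' pairMetrics(truth, pred) # precision 1, recall 0.5
#' @export
pairMetrics <- function(truth_labels, predicted) {
    checkUniverse(truth_labels, predicted)
    pc <- pairCounts(truth_labels, predicted)
    list(precision = if (pc$together_pred > 0)
             pc$together_both / pc$together_pred else NA_real_,
         recall = if (pc$together_truth > 0)
             pc$together_both / pc$together_truth else NA_real_)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement,
#' `(Index - Expected) / (Max - Expected)` from the contingency table.
#' Symmetric in its arguments and invariant to label renaming; 1 for
#' identical partitions, about 0 against random labellings.
#'
#' @inheritParams pairMetrics
#' @return The ARI, or `NA` when it is undefined (fewer than 2 contigs,
#'   or both partitions degenerate so that `Max == Expected`).
#' @export
adjustedRand <- function(truth_labels, predicted) {
    checkUniverse(truth_labels, predicted)
    pc <- pairCounts(truth_labels, predicted)
    if (pc$n < 2L) return(NA_real_)
    npairs <- choose(pc$n, 2)
    expected <- pc$together_truth * pc$together_pred / npairs
    maximum <- (pc$together_truth + pc$together_pred) / 2
    if (maximum == expected) {
        ## both partitions all-singletons or both one block: identical
        return(1)
    }
    (pc$together_both - expected) / (maximum - expected)
}

#' Score cluster recovery against simulator ground truth
#'
#' Contigs the pipeline left unclustered (no top-hit) are scored as
#' singleton clusters so the two partitions share a universe; their count
#' is additionally reported as `n_excluded`.
#'
#' @param truth the `truth` data.frame from [simulateTranscriptome()].
#' @param clusters a [GeneClusterSet-class].
#' @return A list with `n_true_genes`, `n_clusters`, `pair_precision`,
#'   `pair_recall`, `adjusted_rand`, `gene_count_error`
#'   (`|n_clusters - n_true_genes| / n_true_genes`) and `n_excluded`.
#' @export
recoveryReport <- function(truth, clusters) {
    truth_labels <- setNames(truth$gene_id, truth$contig_id)
    pred <- clusterAssignments(clusters)
    extra <- setdiff(names(pred), names(truth_labels))
    if (length(extra))
        stop("clustered contigs unknown to the truth: ",
             paste(extra, collapse = ", "))
    unassigned <- setdiff(names(truth_labels), names(pred))
    if (length(unassigned))
        pred <- c(pred, setNames(paste0("singleton_", unassigned),
                                 unassigned))
    pm <- pairMetrics(truth_labels, pred)
    n_true <- length(unique(truth_labels))
    n_clusters <- length(clusters)  # pipeline clusters; scoring singletons
                                    # for excluded contigs are not counted
    list(n_true_genes = n_true, n_clusters = n_clusters,
         pair_precision = pm$precision, pair_recall = pm$recall,
         adjusted_rand = adjustedRand(truth_labels, pred),
         gene_count_error = abs(n_clusters - n_true) / n_true,
         n_excluded = length(unassigned))
}
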