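## The central operation: consolidate contigs into "gene clusters". A
## cluster is a set of contigs that (i) top-hit the same reference gene at
## E < tophit_evalue_max and (ii) form a connected component of the
## homology-edge graph, where an edge joins two contigs of the same bin
## whose translated mutual homology reaches E < edge_evalue_max in at
## least one query/subject orientation. "Connected to at least one other
## member" is single linkage, hence connected components.

#' Strip an isoform suffix from subject identifiers
#'
#' Reference protein databases often carry isoform suffixes
#' (`AT1G01010.1`); top-hit binning works at the gene/locus level, so a
#' trailing `.<digits>` is removed by default.
#'
#' @param x character vector of subject ids.
#' @param rule regular expression removed from the ids.
#' @return Character vector of gene-level ids.
#' @export
stripIsoform <- function(x, rule = "\\.\\d+$") sub(rule, "", x)

#' Assign each contig to its reference top-hit gene
#'
#' Applies [topHit()] at the configured E-value cutoff (strict `<`) after
#' collapsing subject ids to gene level, and attaches the query coverage
#' `alignment_length / query ORF length`.
#'
#' @param hits tabular hits (from [searchTranslatedQuery()] or
#'   [readTabularHits()]).
#' @param thresholds a [ThresholdConfig-class].
#' @param query_lengths named vector of query ORF lengths in residues;
#'   may be omitted when `hits` carries a `qlen` column. Every query in
#'   `hits` must be covered.
#' @param isoform_rule passed to [stripIsoform()].
#' @return A data.frame with columns `contig_id`, `subject_gene_id`,
#'   `evalue`, `bit_score`, `coverage`.
#' @export
assignTopHits <- function(hits, thresholds = thresholdConfig(),
                          query_lengths = NULL,
                          isoform_rule = "\\.\\d+$") {
    empty <- data.frame(contig_id = character(0),
                        subject_gene_id = character(0), evalue = numeric(0),
                        bit_score = numeric(0), coverage = numeric(0),
                        stringsAsFactors = FALSE)
    if (!nrow(hits)) return(empty)
    if (is.null(query_lengths)) {
        if (is.null(hits$qlen))
            stop("'query_lengths' required when hits carry no 'qlen' column")
        qlen <- hits$qlen
    } else {
        missing <- setdiff(unique(hits$query_id), names(query_lengths))
        if (length(missing))
            stop("query length missing for: ", paste(missing, collapse = ", "))
        qlen <- unname(query_lengths[hits$query_id])
    }
    h <- hits
    h$subject_id <- stripIsoform(h$subject_id, isoform_rule)
    h$qlen <- qlen
    win <- topHit(h, thresholds@tophit_evalue_max)
    if (!nrow(win)) return(empty)
    data.frame(contig_id = win$query_id, subject_gene_id = win$subject_id,
               evalue = win$evalue, bit_score = win$bitscore,
               coverage = win$length / win$qlen, stringsAsFactors = FALSE)
}

#' Build homology edges between same-bin contigs
#'
#' For every unordered pair of contigs that share a top-hit gene, the pair
#' E-value is the minimum over the two (query ORF, subject contig)
#' orientations; an edge is kept when it is strictly below
#' `edge_evalue_max`. Cross-bin edges are never created.
#'
#' @param assignments output of [assignTopHits()].
#' @param pair_evalue either a function `f(contig_a, contig_b)` returning
#'   the E-value of the ORF-of-a vs contig-b comparison (called in both
#'   orientations, minimum taken), or a precomputed data.frame with
#'   columns `contig_a`, `contig_b`, `evalue` holding the
#'   orientation-minimum for each unordered pair.
#' @param thresholds a [ThresholdConfig-class].
#' @return A data.frame with columns `contig_a`, `contig_b`, `evalue`
#'   (one row per unordered pair that qualifies as an edge).
#' @export
buildEdges <- function(assignments, pair_evalue,
                       thresholds = thresholdConfig()) {
    empty <- data.frame(contig_a = character(0), contig_b = character(0),
                        evalue = numeric(0), stringsAsFactors = FALSE)
    if (!nrow(assignments)) return(empty)
    lookup <- NULL
    if (is.data.frame(pair_evalue)) {
        key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
        lookup <- setNames(pair_evalue$evalue,
                           key(pair_evalue$contig_a, pair_evalue$contig_b))
    }
    out <- vector("list", 64L); nout <- 0L
    missing_pairs <- character(0)
    for (gene in unique(assignments$subject_gene_id)) {
        members <- sort(assignments$contig_id[
            assignments$subject_gene_id == gene])
        if (length(members) < 2L) next
        pairs <- utils::combn(members, 2L)
        for (p in seq_len(ncol(pairs))) {
            a <- pairs[1L, p]; b <- pairs[2L, p]
            if (is.null(lookup)) {
                e <- min(pair_evalue(a, b), pair_evalue(b, a))
            } else {
                k <- paste(min(a, b), max(a, b), sep = "\r")
                if (!k %in% names(lookup)) {
                    missing_pairs <- c(missing_pairs, paste(a, b, sep = "--"))
                    next
                }
                e <- unname(lookup[k])
            }
            if (e < thresholds@edge_evalue_max) {
                nout <- nout + 1L
                out[[nout]] <- data.frame(contig_a = a, contig_b = b,
                                          evalue = e,
                                          stringsAsFactors = FALSE)
            }
        }
    }
    if (length(missing_pairs))
        stop("pair E-value missing for same-bin pair(s): ",
             paste(missing_pairs, collapse = ", "))
    if (!nout) return(empty)
    res <- do.call(rbind, out[seq_len(nout)])
    rownames(res) <- NULL
    res
}

#' Consolidate assigned contigs into gene clusters
#'
#' Within each top-hit bin, connected components of the homology-edge
#' graph become clusters; assigned contigs with no edge become singleton
#' clusters. The representative of each cluster is the member with the
#' lowest top-hit E-value (ties: highest bit score, then lexicographically
#' smallest contig id). Cluster ids are `<gene>_c<ordinal>` with ordinals
#' assigned by smallest member contig id, so the output is deterministic
#' and invariant to input order.
#'
#' @param assignments output of [assignTopHits()].
#' @param edges output of [buildEdges()].
#' @return A [GeneClusterSet-class].
#' @export
consolidate <- function(assignments, edges) {
    if (!nrow(assignments)) {
        return(geneClusterSet(data.frame(
            cluster_id = character(0), subject_gene_id = character(0),
            contig_id = character(0), is_representative = logical(0),
            stringsAsFactors = FALSE)))
    }
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(assignments),
                              name = assignments$contig_id)
    if (nrow(edges))
        g <- igraph::add_edges(g, rbind(edges$contig_a, edges$contig_b))
    comp <- igraph::components(g)$membership
    comp <- comp[assignments$contig_id]
    a <- assignments
    a$component <- comp
    ## deterministic ordinals: per gene, components ordered by their
    ## smallest member contig id
    rows <- vector("list", 64L); nrows <- 0L
    for (gene in sort(unique(a$subject_gene_id))) {
        sub <- a[a$subject_gene_id == gene, , drop = FALSE]
        comp_min <- tapply(sub$contig_id, sub$component, min)
        comp_order <- names(sort(comp_min))
        for (i in seq_along(comp_order)) {
            m <- sub[sub$component == comp_order[i], , drop = FALSE]
            ord <- order(m$evalue, -m$bit_score, m$contig_id)
            rep_id <- m$contig_id[ord[1L]]
            m <- m[order(m$contig_id), , drop = FALSE]
            nrows <- nrows + 1L
            rows[[nrows]] <- data.frame(
                cluster_id = sprintf("%s_c%d", gene, i),
                subject_gene_id = gene, contig_id = m$contig_id,
                is_representative = m$contig_id == rep_id,
                stringsAsFactors = FALSE)
        }
    }
    geneClusterSet(do.call(rbind, rows[seq_len(nrows)]))
}

#' Filter top-hit assignments down to ortholog candidates
#'
#' Keeps assignments with `evalue < tophit_evalue_max`, `bit_score >
#' ortholog_score_min` (strict) and `coverage >= ortholog_coverage_min`.
#'
#' @param assignments output of [assignTopHits()].
#' @param thresholds a [ThresholdConfig-class].
#' @return The qualifying rows of `assignments`.
#' @export
orthologCandidates <- function(assignments, thresholds = thresholdConfig()) {
    keep <- assignments$evalue < thresholds@tophit_evalue_max &
        assignments$bit_score > thresholds@ortholog_score_min &
        assignments$coverage >= thresholds@ortholog_coverage_min
    out <- assignments[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Summarize a cluster partition
#'
#' @param clusters a [GeneClusterSet-class].
#' @param n_contigs_total total number of input contigs (assigned or not).
#' @return A list with `n_contigs_total`, `n_assigned`, `n_clusters`,
#'   `n_subject_genes` and `cluster_ratio = n_clusters / n_assigned`
#'   (`NA` when nothing was assigned).
#' @export
summarizeClusters <- function(clusters, n_contigs_total) {
    m <- clusterMembers(clusters)
    n_assigned <- nrow(m)
    n_clusters <- length(unique(m$cluster_id))
    list(n_contigs_total = as.integer(n_contigs_total),
         n_assigned = n_assigned, n_clusters = n_clusters,
         n_subject_genes = length(unique(m$subject_gene_id)),
         cluster_ratio = if (n_assigned > 0) n_clusters / n_assigned
                         else NA_real_)
}

#' Per-family contig and cluster census
#'
#' Counts member contigs and clusters per gene-family label (e.g.
#' transcription-factor families or pathway enzymes). Reference genes not
#' covered by the family table are tallied under `"unassigned"`.
#'
#' @param clusters a [GeneClusterSet-class].
#' @param family_table data.frame with columns `subject_gene_id`, `family`.
#' @return A data.frame with columns `family`, `n_contigs`, `n_clusters`.
#' @export
familyCensus <- function(clusters, family_table) {
    m <- clusterMembers(clusters)
    if (!nrow(m))
        return(data.frame(family = character(0), n_contigs = integer(0),
                          n_clusters = integer(0), stringsAsFactors = FALSE))
    fam <- setNames(as.character(family_table$family),
                    family_table$subject_gene_id)
    lab <- fam[m$subject_gene_id]
    lab[is.na(lab)] <- "unassigned"
    nc <- tapply(m$contig_id, lab, length)
    nk <- tapply(m$cluster_id, lab, function(x) length(unique(x)))
    data.frame(family = names(nc), n_contigs = as.integer(nc),
               n_clusters = as.integer(nk[names(nc)]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' GO-slim category tally over assigned contigs
#'
#' For each annotation namespace (cellular component, molecular function,
#' biological process), counts contig-category incidences and their
#' fractions; fractions within a namespace sum to 1. Contigs whose
#' reference gene is absent from the annotation table count as
#' `"unknown"`.
#'
#' @param assignments output of [assignTopHits()].
#' @param go_table data.frame with columns `gene_id`, `namespace`,
#'   `category` (one row per gene-category incidence).
#' @return A data.frame with columns `namespace`, `category`, `count`,
#'   `fraction`.
#' @export
goTally <- function(assignments, go_table) {
    empty <- data.frame(namespace = character(0), category = character(0),
                        count = integer(0), fraction = numeric(0),
                        stringsAsFactors = FALSE)
    if (!nrow(assignments)) return(empty)
    namespaces <- unique(as.character(go_table$namespace))
    out <- list()
    for (ns in namespaces) {
        sub <- go_table[go_table$namespace == ns, , drop = FALSE]
        cats <- split(as.character(sub$category), as.character(sub$gene_id))
        inc <- unlist(lapply(assignments$subject_gene_id, function(g) {
            v <- cats[[g]]
            if (is.null(v)) "unknown" else unique(v)
        }))
        tab <- table(inc)
        out[[ns]] <- data.frame(namespace = ns, category = names(tab),
                                count = as.integer(tab),
                                fraction = as.numeric(tab) / sum(tab),
                                stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
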