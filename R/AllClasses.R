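## Central S4 containers: threshold configuration, alignment scoring scheme,
## simulator configuration, trim bookkeeping, and the gene-cluster partition.

#' Pipeline threshold configuration
#'
#' Holds every numeric cutoff the pipeline applies: the E-value ceiling for
#' reference top-hits, the (much stricter) E-value ceiling for contig-contig
#' homology edges, the ortholog-candidate bit-score floor and query-coverage
#' floor, the minimum read length retained after trimming, and the number of
#' bootstrap replicates for tree support.
#'
#' E-value cutoffs are applied as strict `<`; the bit-score floor is strict
#' `>`; coverage is inclusive `>=`; a read of exactly `min_read_length`
#' bases passes.
#'
#' @slot tophit_evalue_max numeric, E-value ceiling for top-hit assignment
#'   (default `1e-5`).
#' @slot edge_evalue_max numeric, E-value ceiling for homology edges between
#'   contigs of the same top-hit bin (default `1e-100`).
#' @slot ortholog_score_min numeric, bit-score floor (exclusive) for
#'   ortholog candidates (default `150`).
#' @slot ortholog_coverage_min numeric in (0, 1], minimum fraction of the
#'   query ORF covered by the alignment (default `0.20`).
#' @slot min_read_length integer, minimum read length in bases kept after
#'   trimming (default `40`).
#' @slot bootstrap_replicates integer, bootstrap replicates for tree
#'   support (default `1000`).
#' @export
setClass("ThresholdConfig",
    representation(
        tophit_evalue_max = "numeric",
        edge_evalue_max = "numeric",
        ortholog_score_min = "numeric",
        ortholog_coverage_min = "numeric",
        min_read_length = "integer",
        bootstrap_replicates = "integer"
    )
)

setValidity("ThresholdConfig", function(object) {
    msgs <- character(0)
    for (sl in c("tophit_evalue_max", "edge_evalue_max", "ortholog_score_min",
                 "ortholog_coverage_min", "min_read_length",
                 "bootstrap_replicates")) {
        v <- slot(object, sl)
        if (length(v) != 1L || is.na(v) || v <= 0)
            msgs <- c(msgs, sprintf("'%s' must be a single strictly positive value", sl))
    }
    if (length(object@ortholog_coverage_min) == 1L &&
        !is.na(object@ortholog_coverage_min) &&
        object@ortholog_coverage_min > 1)
        msgs <- c(msgs, "'ortholog_coverage_min' must be in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' Create a threshold configuration
#'
#' @param tophit_evalue_max E-value ceiling (strict `<`) for top-hit
#'   assignment.
#' @param edge_evalue_max E-value ceiling (strict `<`) for homology edges.
#' @param ortholog_score_min bit-score floor (strict `>`) for ortholog
#'   candidates.
#' @param ortholog_coverage_min minimum query coverage (inclusive `>=`).
#' @param min_read_length minimum read length retained (inclusive).
#' @param bootstrap_replicates bootstrap replicates for tree support.
#' @return A [ThresholdConfig-class] object.
#' @examples
#' thresholdConfig()
#' thresholdConfig(edge_evalue_max = 1e-80)
#' @export
thresholdConfig <- function(tophit_evalue_max = 1e-5,
                            edge_evalue_max = 1e-100,
                            ortholog_score_min = 150,
                            ortholog_coverage_min = 0.20,
                            min_read_length = 40L,
                            bootstrap_replicates = 1000L) {
    new("ThresholdConfig",
        tophit_evalue_max = as.numeric(tophit_evalue_max),
        edge_evalue_max = as.numeric(edge_evalue_max),
        ortholog_score_min = as.numeric(ortholog_score_min),
        ortholog_coverage_min = as.numeric(ortholog_coverage_min),
        min_read_length = as.integer(min_read_length),
        bootstrap_replicates = as.integer(bootstrap_replicates))
}

setMethod("show", "ThresholdConfig", function(object) {
    cat("ThresholdConfig\n")
    cat("  top-hit E-value   < ", format(object@tophit_evalue_max), "\n", sep = "")
    cat("  edge E-value      < ", format(object@edge_evalue_max), "\n", sep = "")
    cat("  ortholog score    > ", format(object@ortholog_score_min), "\n", sep = "")
    cat("  ortholog coverage >= ", format(object@ortholog_coverage_min), "\n", sep = "")
    cat("  min read length   ", object@min_read_length, " nt\n", sep = "")
    cat("  bootstrap reps    ", object@bootstrap_replicates, "\n", sep = "")
})

#' Protein alignment scoring scheme
#'
#' A substitution matrix with affine gap penalties and the Karlin-Altschul
#' statistical parameters used to convert raw local-alignment scores into
#' bit scores and E-values. A gap of length k costs
#' `gap_open + k * gap_extend` (the opening penalty is charged on the first
#' gap residue). Defaults are BLOSUM62 with gap open 11 / extend 1 and the
#' published gapped parameters lambda = 0.267, K = 0.041 for that scheme.
#' 'X' scores 0 against every residue.
#'
#' @slot matrix_name name of the substitution matrix.
#' @slot matrix integer substitution matrix (row/column names are the
#'   residue alphabet).
#' @slot gap_open gap opening penalty (positive score units).
#' @slot gap_extend gap extension penalty (positive score units).
#' @slot lambda Karlin-Altschul lambda (per score unit).
#' @slot K Karlin-Altschul K (dimensionless, in (0, 1)).
#' @export
setClass("ScoringScheme",
    representation(
        matrix_name = "character",
        matrix = "matrix",
        gap_open = "numeric",
        gap_extend = "numeric",
        lambda = "numeric",
        K = "numeric"
    )
)

setValidity("ScoringScheme", function(object) {
    msgs <- character(0)
    if (object@gap_extend > object@gap_open)
        msgs <- c(msgs, "'gap_extend' must be <= 'gap_open'")
    if (object@gap_open <= 0 || object@gap_extend <= 0)
        msgs <- c(msgs, "gap penalties must be strictly positive")
    if (object@lambda <= 0)
        msgs <- c(msgs, "'lambda' must be > 0")
    if (object@K <= 0 || object@K >= 1)
        msgs <- c(msgs, "'K' must be in (0, 1)")
    if (is.null(rownames(object@matrix)) ||
        !identical(rownames(object@matrix), colnames(object@matrix)))
        msgs <- c(msgs, "matrix must have identical row and column names")
    if (length(msgs)) msgs else TRUE
})

#' Create a scoring scheme
#'
#' @param matrix_name one of the substitution matrices shipped with
#'   Biostrings (e.g. "BLOSUM62", "BLOSUM45", "BLOSUM80", "PAM250"), or
#'   ignored when `matrix` is supplied directly.
#' @param gap_open,gap_extend affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters for the scheme.
#' @param matrix optional explicit integer substitution matrix with residue
#'   row/column names; overrides `matrix_name`.
#' @return A [ScoringScheme-class] object. The matrix is augmented so that
#'   'X' scores 0 against everything.
#' @examples
#' scoringScheme()
#' @export
scoringScheme <- function(matrix_name = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, lambda = 0.267, K = 0.041,
                          matrix = NULL) {
    if (is.null(matrix)) {
        env <- new.env()
        utils::data(list = matrix_name, package = "Biostrings", envir = env)
        matrix <- get(matrix_name, envir = env)
    }
    mode(matrix) <- "integer"
    if (!("X" %in% rownames(matrix))) {
        matrix <- rbind(cbind(matrix, X = 0L), X = 0L)
    }
    matrix["X", ] <- 0L
    matrix[, "X"] <- 0L
    new("ScoringScheme", matrix_name = matrix_name, matrix = matrix,
        gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend),
        lambda = as.numeric(lambda), K = as.numeric(K))
}

setMethod("show", "ScoringScheme", function(object) {
    cat("ScoringScheme: ", object@matrix_name,
        sprintf(" (gap %g/%g, lambda=%g, K=%g)\n", object@gap_open,
                object@gap_extend, object@lambda, object@K), sep = "")
})

#' Trimming report
#'
#' Bookkeeping for the read-cleanup stage: how many input reads were
#' touched by each trimming operation and how many survived the length
#' filter. Always satisfies `n_passed + n_too_short == n_input`.
#'
#' @slot n_input number of input reads.
#' @slot n_adapter_trimmed reads shortened by adapter removal.
#' @slot n_polyt_trimmed reads with a 5' poly-T tail removed.
#' @slot n_polya_trimmed reads with a 3' poly-A tail removed.
#' @slot n_too_short reads discarded below the length floor.
#' @slot n_passed reads retained.
#' @export
setClass("TrimReport",
    representation(
        n_input = "integer",
        n_adapter_trimmed = "integer",
        n_polyt_trimmed = "integer",
        n_polya_trimmed = "integer",
        n_too_short = "integer",
        n_passed = "integer"
    )
)

setValidity("TrimReport", function(object) {
    msgs <- character(0)
    cnt <- c(object@n_input, object@n_adapter_trimmed, object@n_polyt_trimmed,
             object@n_polya_trimmed, object@n_too_short, object@n_passed)
    if (any(cnt < 0)) msgs <- c(msgs, "all counts must be >= 0")
    if (object@n_passed + object@n_too_short != object@n_input)
        msgs <- c(msgs, "n_passed + n_too_short must equal n_input")
    if (length(msgs)) msgs else TRUE
})

trimReport <- function(n_input = 0L, n_adapter_trimmed = 0L,
                       n_polyt_trimmed = 0L, n_polya_trimmed = 0L,
                       n_too_short = 0L, n_passed = n_input - n_too_short) {
    new("TrimReport", n_input = as.integer(n_input),
        n_adapter_trimmed = as.integer(n_adapter_trimmed),
        n_polyt_trimmed = as.integer(n_polyt_trimmed),
        n_polya_trimmed = as.integer(n_polya_trimmed),
        n_too_short = as.integer(n_too_short),
        n_passed = as.integer(n_passed))
}

setMethod("show", "TrimReport", function(object) {
    cat("TrimReport:", object@n_input, "reads in;",
        object@n_passed, "passed,", object@n_too_short, "too short\n")
    cat("  adapter-trimmed:", object@n_adapter_trimmed,
        " polyT-trimmed:", object@n_polyt_trimmed,
        " polyA-trimmed:", object@n_polya_trimmed, "\n")
})

#' Gene cluster partition
#'
#' The result of consolidating contigs into gene clusters: a membership
#' table with one row per (cluster, contig) pair, exactly one
#' representative per cluster. Clusters partition the assigned contigs;
#' every member of a cluster top-hits the cluster's reference gene.
#'
#' @slot members data.frame with columns `cluster_id`, `subject_gene_id`,
#'   `contig_id`, `is_representative` (logical).
#' @export
setClass("GeneClusterSet", representation(members = "data.frame"))

setValidity("GeneClusterSet", function(object) {
    m <- object@members
    need <- c("cluster_id", "subject_gene_id", "contig_id", "is_representative")
    if (!all(need %in% names(m)))
        return(paste("members must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(m$contig_id))
        return("clusters must be disjoint: duplicated contig_id")
    if (nrow(m)) {
        reps <- tapply(m$is_representative, m$cluster_id, sum)
        if (any(reps != 1L))
            return("every cluster must have exactly one representative")
        sg <- tapply(m$subject_gene_id, m$cluster_id,
                     function(x) length(unique(x)))
        if (any(sg != 1L))
            return("all members of a cluster must share one subject_gene_id")
    }
    TRUE
})

geneClusterSet <- function(members) {
    rownames(members) <- NULL
    new("GeneClusterSet", members = members)
}

#' @describeIn GeneClusterSet-class number of clusters.
#' @param x A `GeneClusterSet`.
#' @export
setMethod("length", "GeneClusterSet", function(x)
    length(unique(x@members$cluster_id)))

#' Accessors for GeneClusterSet
#'
#' `clusterMembers()` returns the full membership table;
#' `clusterIds()` the cluster identifiers; `representatives()` a named
#' character vector mapping cluster_id to its representative contig;
#' `clusterAssignments()` a named vector mapping contig_id to cluster_id
#' (the form consumed by the recovery metrics).
#'
#' @param x A [GeneClusterSet-class].
#' @return See individual descriptions.
#' @export
clusterMembers <- function(x) x@members

#' @rdname clusterMembers
#' @export
clusterIds <- function(x) unique(x@members$cluster_id)

#' @rdname clusterMembers
#' @export
representatives <- function(x) {
    m <- x@members[x@members$is_representative, ]
    setNames(m$contig_id, m$cluster_id)
}

#' @rdname clusterMembers
#' @export
clusterAssignments <- function(x)
    setNames(x@members$cluster_id, x@members$contig_id)

setMethod("show", "GeneClusterSet", function(object) {
    m <- object@members
    cat("GeneClusterSet:", length(unique(m$cluster_id)), "clusters /",
        nrow(m), "contigs /", length(unique(m$subject_gene_id)),
        "reference genes\n")
    if (nrow(m)) {
        cat("  first clusters:\n")
        print(utils::head(m, 4L), row.names = FALSE)
    }
})
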