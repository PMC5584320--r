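## End-to-end orchestration: (optional trim) -> longest ORFs -> translated
## search -> top-hit assignment -> homology edges -> consolidation ->
## summary, with a machine-readable run manifest. The analytic path is
## fully deterministic given inputs and configuration.

configSnapshot <- function(thresholds, scheme, min_orf_aa) {
    list(tophit_evalue_max = thresholds@tophit_evalue_max,
         edge_evalue_max = thresholds@edge_evalue_max,
         ortholog_score_min = thresholds@ortholog_score_min,
         ortholog_coverage_min = thresholds@ortholog_coverage_min,
         min_read_length = thresholds@min_read_length,
         bootstrap_replicates = thresholds@bootstrap_replicates,
         matrix = scheme@matrix_name, gap_open = scheme@gap_open,
         gap_extend = scheme@gap_extend, lambda = scheme@lambda,
         K = scheme@K, min_orf_aa = min_orf_aa)
}

configHash <- function(snapshot) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(jsonlite::toJSON(snapshot, auto_unbox = TRUE), tf)
    unname(tools::md5sum(tf))
}

#' Run the full contig-to-cluster pipeline
#'
#' Extracts the longest ORF per contig, searches every qualifying ORF
#' against the reference proteome ([searchTranslatedQuery()]), assigns
#' top hits, computes same-bin pairwise homology
#' ([contigPairHomology()], longest ORF as query, minimum over the two
#' orientations), consolidates connected components into gene clusters,
#' and summarizes. Deterministic: rerunning with identical inputs and
#' configuration reproduces the outputs byte for byte.
#'
#' @param contigs contig FASTA path or `DNAStringSet`.
#' @param proteins reference proteome FASTA path or `AAStringSet`.
#' @param thresholds a [ThresholdConfig-class].
#' @param scheme a [ScoringScheme-class].
#' @param min_orf_aa minimum ORF length searched (residues).
#' @param seed_filter,seed_k shared-k-mer prescreen, see
#'   [searchTranslatedQuery()].
#' @param trim apply [trimReads()] to the contigs first (off by default:
#'   assembled contigs are normally already clean).
#' @param out_dir if non-NULL, write `clusters.tsv`, `summary.json` and
#'   `manifest.json` there.
#' @return A list with `orfs`, `hits`, `assignments`, `edges`, `clusters`
#'   (a [GeneClusterSet-class]), `summary` and `manifest`. The manifest
#'   carries the configuration snapshot, its hash, package version and
#'   per-stage record counts (each stage reconcilable with the previous
#'   one).
#' @examples
#' sim <- simulateTranscriptome(simConfig(n_genes = 4, seed = 1,
#'     cds_length_range = c(300L, 400L)))
#' res <- runPipeline(sim$contigs, sim$proteins)
#' res$summary$n_clusters
#' @export
runPipeline <- function(contigs, proteins, thresholds = thresholdConfig(),
                        scheme = scoringScheme(), min_orf_aa = 30L,
                        seed_filter = TRUE, seed_k = 5L, trim = FALSE,
                        out_dir = NULL) {
    if (is.character(contigs) && length(contigs) == 1L)
        contigs <- readFasta(contigs, "nucleotide")
    if (is.character(proteins) && length(proteins) == 1L)
        proteins <- readFasta(proteins, "protein")
    n_input <- length(contigs)
    trim_report <- NULL
    if (trim) {
        tr <- trimReads(contigs, min_len = thresholds@min_read_length)
        contigs <- tr$passed
        trim_report <- tr$report
    }
    ch <- asCharSeqs(contigs)
    message("stage orf: ", length(ch), " contigs")
    lorf <- longestOrf(contigs, min_orf_aa)
    message("stage search: ", nrow(lorf), " contigs with ORF >= ",
            min_orf_aa, " aa")
    if (length(ch) && length(proteins)) {
        hits <- searchTranslatedQuery(contigs, proteins, scheme, min_orf_aa,
                                      evalue_max = 10,
                                      seed_filter = seed_filter,
                                      seed_k = seed_k)
    } else {
        hits <- emptyHits(); hits$qlen <- integer(0)
    }
    assignments <- assignTopHits(hits, thresholds)
    message("stage cluster: ", nrow(assignments), " contigs assigned")
    lorf_pep <- setNames(lorf$peptide, lorf$contig_id)
    pair_fun <- function(a, b) {
        if (is.na(lorf_pep[a])) return(Inf)
        contigPairHomology(lorf_pep[[a]], ch[[b]], scheme,
                           seed_filter = seed_filter, seed_k = seed_k)
    }
    edges <- buildEdges(assignments, pair_fun, thresholds)
    clusters <- consolidate(assignments, edges)
    summary <- summarizeClusters(clusters, n_input)
    snapshot <- configSnapshot(thresholds, scheme, min_orf_aa)
    manifest <- list(
        package = "homeoclust",
        version = as.character(packageVersion("homeoclust")),
        config = snapshot,
        config_hash = configHash(snapshot),
        stages = list(
            n_input_contigs = n_input,
            n_after_trim = length(ch),
            n_with_orf = nrow(lorf),
            n_hits = nrow(hits),
            n_assigned = nrow(assignments),
            n_unassigned = length(ch) - nrow(assignments),
            n_edges = nrow(edges),
            n_clusters = summary$n_clusters))
    if (!is.null(trim_report))
        manifest$trim <- list(
            n_adapter_trimmed = trim_report@n_adapter_trimmed,
            n_polyt_trimmed = trim_report@n_polyt_trimmed,
            n_polya_trimmed = trim_report@n_polya_trimmed,
            n_too_short = trim_report@n_too_short)
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeClusters(clusters, file.path(out_dir, "clusters.tsv"))
        jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(orfs = lorf, hits = hits, assignments = assignments, edges = edges,
         clusters = clusters, summary = summary, manifest = manifest,
         trim_report = trim_report)
}
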