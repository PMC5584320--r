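## Synthetic allohexaploid transcriptome generator with ground truth.
## Genes are simulated as paralog pairs diverged from a shared root at
## family_divergence; each gene carries n_subgenomes homeologous copies
## independently diverged at homeolog_divergence under Jukes-Cantor
## substitutions with frame-preserving (whole-codon) indels; each
## surviving homeolog is emitted as a full-length, 5'- or 3'-fragment
## contig with short undiverged UTR padding. One reference protein per
## gene is derived from the gene's ancestral CDS at reference_divergence,
## so every gene has exactly one correct top-hit target.

senseCodons <- function() {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc != "*"]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulator configuration
#'
#' @slot n_genes number of simulated genes.
#' @slot n_subgenomes homeologous copies per gene (3 for an
#'   allohexaploid).
#' @slot homeolog_divergence substitutions/site on each homeolog branch.
#' @slot family_divergence substitutions/site on each gene branch from the
#'   shared paralog-family root.
#' @slot reference_divergence substitutions/site between a gene's
#'   ancestral CDS and its reference protein's CDS.
#' @slot fragment_profile length-3 proportions of full-length, 5'-fragment
#'   and 3'-fragment contigs (sums to 1).
#' @slot missing_homeolog_prob per-homeolog dropout probability.
#' @slot indel_rate per-site rate of whole-codon insertion/deletion
#'   events.
#' @slot cds_length_range min/max CDS length in amino acids.
#' @slot seed RNG seed; same seed, byte-identical output.
#' @export
setClass("SimConfig",
    representation(
        n_genes = "integer",
        n_subgenomes = "integer",
        homeolog_divergence = "numeric",
        family_divergence = "numeric",
        reference_divergence = "numeric",
        fragment_profile = "numeric",
        missing_homeolog_prob = "numeric",
        indel_rate = "numeric",
        cds_length_range = "integer",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msgs <- character(0)
    if (object@n_genes < 1L) msgs <- c(msgs, "n_genes must be >= 1")
    if (object@n_subgenomes < 1L) msgs <- c(msgs, "n_subgenomes must be >= 1")
    for (sl in c("homeolog_divergence", "family_divergence",
                 "reference_divergence"))
        if (slot(object, sl) < 0)
            msgs <- c(msgs, sprintf("'%s' must be >= 0", sl))
    fp <- object@fragment_profile
    if (length(fp) != 3L || any(fp < 0) || abs(sum(fp) - 1) > 1e-9)
        msgs <- c(msgs, "fragment_profile must be 3 proportions summing to 1")
    if (object@missing_homeolog_prob < 0 || object@missing_homeolog_prob > 1)
        msgs <- c(msgs, "missing_homeolog_prob must be in [0, 1]")
    if (object@indel_rate < 0 || object@indel_rate > 1)
        msgs <- c(msgs, "indel_rate must be in [0, 1]")
    if (length(object@cds_length_range) != 2L ||
        object@cds_length_range[1L] < 1L ||
        diff(object@cds_length_range) < 0L)
        msgs <- c(msgs, "cds_length_range must be an increasing pair >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Create a simulator configuration
#'
#' Defaults model the allohexaploid regime: three near-identical
#' homeologous copies per gene (branch divergence 0.03 substitutions per
#' site), paralogous genes far apart (0.5/branch, about 45% pairwise
#' nucleotide identity), a reference proteome at 0.15/branch, and the
#' mixed full-length / 5' / 3' library design (0.5/0.25/0.25).
#'
#' @param n_genes,n_subgenomes,homeolog_divergence,family_divergence,reference_divergence,fragment_profile,missing_homeolog_prob,indel_rate,cds_length_range,seed
#'   see [SimConfig-class].
#' @return A validated [SimConfig-class].
#' @examples
#' simConfig(n_genes = 10, seed = 1)
#' @export
simConfig <- function(n_genes = 200L, n_subgenomes = 3L,
                      homeolog_divergence = 0.03, family_divergence = 0.5,
                      reference_divergence = 0.15,
                      fragment_profile = c(full = 0.5, five_prime = 0.25,
                                           three_prime = 0.25),
                      missing_homeolog_prob = 0.1, indel_rate = 0.001,
                      cds_length_range = c(150L, 500L), seed = 1L) {
    new("SimConfig", n_genes = as.integer(n_genes),
        n_subgenomes = as.integer(n_subgenomes),
        homeolog_divergence = homeolog_divergence,
        family_divergence = family_divergence,
        reference_divergence = reference_divergence,
        fragment_profile = unname(fragment_profile),
        missing_homeolog_prob = missing_homeolog_prob,
        indel_rate = indel_rate,
        cds_length_range = as.integer(cds_length_range),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@n_genes, "genes x", object@n_subgenomes,
        "subgenomes\n")
    cat(sprintf("  divergence homeolog=%g family=%g reference=%g\n",
                object@homeolog_divergence, object@family_divergence,
                object@reference_divergence))
    cat(sprintf("  fragments %.2f/%.2f/%.2f dropout=%g indel=%g cds=%d-%d aa seed=%d\n",
                object@fragment_profile[1L], object@fragment_profile[2L],
                object@fragment_profile[3L], object@missing_homeolog_prob,
                object@indel_rate, object@cds_length_range[1L],
                object@cds_length_range[2L], object@seed))
})

#' Expected nucleotide identity after Jukes-Cantor divergence
#'
#' For two sequences that each accumulated `d` substitutions/site from a
#' common ancestor: `1 - 0.75 * (1 - exp(-8 d / 3))`.
#'
#' @param d per-branch divergence in substitutions/site (>= 0).
#' @return Expected fraction of identical sites.
#' @examples
#' expectedIdentity(0)     # 1
#' expectedIdentity(0.05)  # about 0.907
#' @export
expectedIdentity <- function(d) {
    stopifnot(all(d >= 0))
    1 - 0.75 * (1 - exp(-8 * d / 3))
}

## Jukes-Cantor site-wise substitution of a codon string. Stop codons
## arising inside the CDS are repaired by re-assigning one mutated site to
## a different non-ancestral base that is not a stop, which preserves the
## number of differing sites (so the closed-form calibration holds).
mutateCds <- function(cds, d) {
    if (d == 0) return(cds)
    bases <- c("A", "C", "G", "T")
    p <- 0.75 * (1 - exp(-4 * d / 3))
    x <- strsplit(cds, "", fixed = TRUE)[[1L]]
    orig <- x
    hit <- runif(length(x)) < p
    if (any(hit)) {
        x[hit] <- vapply(x[hit], function(b)
            sample(setdiff(bases, b), 1L), "")
    }
    ## repair stops codon by codon
    n_cod <- length(x) %/% 3L
    for (ci in seq_len(n_cod)) {
        idx <- (3L * ci - 2L):(3L * ci)
        cod <- paste(x[idx], collapse = "")
        if (!cod %in% STOP_CODONS) next
        mut_sites <- idx[x[idx] != orig[idx]]
        fixed <- FALSE
        for (site in mut_sites) {
            for (b in setdiff(bases, c(orig[site], x[site]))) {
                trial <- x[idx]
                trial[match(site, idx)] <- b
                if (!paste(trial, collapse = "") %in% STOP_CODONS) {
                    x[site] <- b
                    fixed <- TRUE
                    break
                }
            }
            if (fixed) break
        }
        if (!fixed && length(mut_sites))  # give the substitution back
            x[mut_sites[1L]] <- orig[mut_sites[1L]]
    }
    paste(x, collapse = "")
}

## Whole-codon insertions/deletions at rate per nucleotide site.
applyIndels <- function(cds, rate) {
    if (rate == 0) return(cds)
    n_events <- rbinom(1L, nchar(cds), rate)
    if (n_events == 0L) return(cds)
    sense <- senseCodons()
    for (i in seq_len(n_events)) {
        n_cod <- nchar(cds) %/% 3L
        if (runif(1L) < 0.5 && n_cod > 2L) {       # deletion
            ci <- sample.int(n_cod, 1L)
            cds <- paste0(substr(cds, 1L, 3L * (ci - 1L)),
                          substr(cds, 3L * ci + 1L, nchar(cds)))
        } else {                                   # insertion
            ci <- sample.int(n_cod + 1L, 1L) - 1L  # 0..n_cod boundaries
            cds <- paste0(substr(cds, 1L, 3L * ci),
                          sample(sense, 1L),
                          substr(cds, 3L * ci + 1L, nchar(cds)))
        }
    }
    cds
}

randomUtr <- function(min_len = 20L, max_len = 60L) {
    n <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate an allohexaploid transcriptome with ground truth
#'
#' See [simConfig()] for the generative model. Fragments cover a uniform
#' 40-90% of the CDS from the respective end; 5' fragments keep the 5'
#' UTR, 3' fragments keep the stop codon and 3' UTR. Fully reproducible
#' under the configured seed (the caller's RNG state is restored on
#' exit).
#'
#' @param config a [SimConfig-class].
#' @return A list with `contigs` (`DNAStringSet`), `proteins`
#'   (`AAStringSet`, one reference protein per gene, named by gene id),
#'   `truth` (data.frame `contig_id`, `gene_id`, `subgenome`,
#'   `fragment_type`) and `config`.
#' @examples
#' sim <- simulateTranscriptome(simConfig(n_genes = 5, seed = 7))
#' length(sim$contigs); head(sim$truth)
#' @export
simulateTranscriptome <- function(config) {
    validObject(config)
    if (exists(".Random.seed", envir = globalenv())) {
        old_seed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(config@seed)
    sense <- senseCodons()
    ftypes <- c("full", "five_prime", "three_prime")

    n <- config@n_genes
    gene_ids <- sprintf("G%05d", seq_len(n))
    ## paralog pairs share a family root (last family may be a singleton)
    fam_of <- rep(seq_len(ceiling(n / 2)), each = 2L)[seq_len(n)]
    fam_len <- integer(max(fam_of))

    contig_seq <- character(0)
    contig_id <- character(0)
    truth <- list()
    proteins <- character(n)

    fam_root <- character(max(fam_of))
    for (f in seq_len(max(fam_of))) {
        L <- sample(config@cds_length_range[1L]:config@cds_length_range[2L], 1L)
        fam_len[f] <- L
        fam_root[f] <- paste(sample(sense, L, replace = TRUE), collapse = "")
    }

    for (g in seq_len(n)) {
        cds_g <- mutateCds(fam_root[fam_of[g]], config@family_divergence)
        ref_cds <- mutateCds(cds_g, config@reference_divergence)
        proteins[g] <- translateFrame(ref_cds, 1L)
        utr5 <- randomUtr()
        utr3 <- randomUtr()
        for (s in seq_len(config@n_subgenomes)) {
            if (runif(1L) < config@missing_homeolog_prob) next
            cds_h <- applyIndels(mutateCds(cds_g, config@homeolog_divergence),
                                 config@indel_rate)
            ftype <- ftypes[sample.int(3L, 1L, prob = config@fragment_profile)]
            Lh <- nchar(cds_h)
            if (ftype == "full") {
                seq <- paste0(utr5, cds_h, "TAA", utr3)
            } else if (ftype == "five_prime") {
                keep <- ceiling(runif(1L, 0.4, 0.9) * Lh)
                seq <- paste0(utr5, substr(cds_h, 1L, keep))
            } else {
                keep <- ceiling(runif(1L, 0.4, 0.9) * Lh)
                seq <- paste0(substr(cds_h, Lh - keep + 1L, Lh), "TAA", utr3)
            }
            cid <- sprintf("%s_s%d", gene_ids[g], s)
            contig_id <- c(contig_id, cid)
            contig_seq <- c(contig_seq, seq)
            truth[[length(truth) + 1L]] <- data.frame(
                contig_id = cid, gene_id = gene_ids[g], subgenome = s,
                fragment_type = ftype, stringsAsFactors = FALSE)
        }
    }
    contigs <- Biostrings::DNAStringSet(setNames(contig_seq, contig_id))
    S4Vectors::mcols(contigs) <- S4Vectors::DataFrame(
        description = rep("", length(contigs)))
    prot <- Biostrings::AAStringSet(setNames(proteins, gene_ids))
    S4Vectors::mcols(prot) <- S4Vectors::DataFrame(
        description = rep("", length(prot)))
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(contig_id = character(0), gene_id = character(0),
                   subgenome = integer(0), fragment_type = character(0),
                   stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(contigs = contigs, proteins = prot, truth = truth, config = config)
}

#' Write simulator ground truth to TSV
#'
#' @param truth the `truth` data.frame from [simulateTranscriptome()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTruth <- function(truth, path) {
    write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a ground-truth TSV written by [writeTruth()]
#'
#' @param path path to the truth table.
#' @return The truth data.frame.
#' @export
readTruth <- function(path) {
    read.delim(path, header = TRUE, stringsAsFactors = FALSE,
               colClasses = c("character", "character", "integer",
                              "character"))
}
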