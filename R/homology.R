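## Local protein alignment with affine gaps and Karlin-Altschul statistics,
## in the two translated search modes the pipeline needs: translated
## contig query vs protein database (BLASTX role) and protein query vs
## translated contig (TBLASTN role). The dynamic programming kernel is in
## src/sw.cpp; an optional exact shared-k-mer prescreen skips hopeless
## subjects without changing any reported score.

alphabetOf <- function(scheme) paste(rownames(scheme@matrix), collapse = "")

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gap penalties: a gap of length k costs
#' `gap_open + k * gap_extend`, the opening penalty charged on the first
#' gap residue. Coordinates are 1-based inclusive and describe one optimal
#' alignment (the one with the smallest end coordinates, traceback
#' preferring substitutions over gaps -- deterministic).
#'
#' @param a,b protein strings (unknown symbols are normalized to `X`,
#'   which scores 0 against everything).
#' @param scheme a [ScoringScheme-class].
#' @return A list with `raw_score`, `bits`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `n_identical`, `alignment_length`, `n_gap_opens`. Empty input
#'   gives score 0 and an empty alignment.
#' @examples
#' localAlign("MKW", "MKW", scoringScheme())$raw_score # 21
#' @export
localAlign <- function(a, b, scheme = scoringScheme()) {
    a <- normalizeResidues(a, "protein")
    b <- normalizeResidues(b, "protein")
    r <- cpp_sw_align(a, b, scheme@matrix, alphabetOf(scheme),
                      as.integer(scheme@gap_open),
                      as.integer(scheme@gap_extend))
    list(raw_score = r$score, bits = toBits(r$score, scheme),
         q_start = r$q_start, q_end = r$q_end, s_start = r$s_start,
         s_end = r$s_end, n_identical = r$n_identical,
         alignment_length = r$aln_len, n_gap_opens = r$n_gap_opens)
}

#' Convert a raw alignment score to bits
#'
#' Karlin-Altschul normalization `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param raw raw score (score units, >= 0).
#' @param scheme a [ScoringScheme-class] supplying `lambda` and `K`.
#' @return Bit score (monotone increasing in `raw`).
#' @examples
#' toBits(100, scoringScheme()) # about 43.13
#' @export
toBits <- function(raw, scheme = scoringScheme()) {
    (scheme@lambda * raw - log(scheme@K)) / log(2)
}

#' E-value from a bit score and search space
#'
#' `E = m * n * 2^(-bits)`: the expected number of chance alignments of at
#' least that score between random sequences of the searched sizes. Linear
#' in each search-space dimension, monotone decreasing in bits.
#'
#' @param bits bit score.
#' @param m query length in residues (>= 1).
#' @param n database/subject length in residues (>= 1).
#' @return The E-value.
#' @examples
#' evalueKA(40, 100, 100) # about 9.09e-9
#' @export
evalueKA <- function(bits, m, n) {
    stopifnot(all(m >= 1), all(n >= 1))
    as.numeric(m) * as.numeric(n) * 2^(-bits)
}

## Map a peptide-coordinate interval [qs, qe] (1-based, within an ORF) to
## 1-based inclusive nucleotide coordinates on the forward strand of the
## contig. Minus-frame hits get qstart > qend, the usual convention.
orfNtCoords <- function(orf, contig_len, qs, qe) {
    if (orf$frame > 0) {
        ts <- orf$nt_start      # 0-based on forward strand
        c(ts + 3L * (qs - 1L) + 1L, ts + 3L * qe)
    } else {
        ts <- contig_len - orf$nt_end  # 0-based on the rc strand
        rc1 <- ts + 3L * (qs - 1L) + 1L
        rc2 <- ts + 3L * qe
        c(contig_len - rc1 + 1L, contig_len - rc2 + 1L)
    }
}

#' Translated-query search against a protein database
#'
#' The BLASTX-like mode: every ORF of at least `min_orf_aa` residues in
#' all six frames of each contig is aligned against every database
#' protein; per (contig, subject) pair only the best alignment (lowest
#' E-value, then highest bit score) is reported. The search space for
#' E-values is `m * n` with `m` the query ORF length and `n` the total
#' database residue count.
#'
#' @param contigs nucleotide sequences (`DNAStringSet` or named character).
#' @param proteins protein database (`AAStringSet` or named character);
#'   must be non-empty.
#' @param scheme a [ScoringScheme-class].
#' @param min_orf_aa minimum ORF length searched.
#' @param evalue_max report ceiling; pairs with best E-value above it are
#'   omitted from the output (default 10, the conventional report limit --
#'   the analysis cutoffs are applied downstream).
#' @param seed_filter require at least one exact shared k-mer (length
#'   `seed_k`) between ORF and subject before running the full dynamic
#'   program. Subjects skipped by the prescreen are treated as score 0;
#'   any reported hit carries its exact full-DP score.
#' @param seed_k k-mer length for the prescreen (default 5).
#' @return A data.frame in 12-column tabular-hit layout (`query_id`,
#'   `subject_id`, `pident`, `length`, `mismatch`, `gapopen`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`) plus a `qlen` column
#'   holding the query ORF length in residues (used downstream for
#'   coverage). Query coordinates are nucleotide positions on the contig.
#' @export
searchTranslatedQuery <- function(contigs, proteins, scheme = scoringScheme(),
                                  min_orf_aa = 30L, evalue_max = 10,
                                  seed_filter = TRUE, seed_k = 5L) {
    prot <- asCharSeqs(proteins)
    if (!length(prot)) stop("protein database is empty")
    prot <- normalizeResidues(prot, "protein")
    ch <- asCharSeqs(contigs)
    db_n <- sum(nchar(prot))
    orfs <- findOrfs(contigs, min_orf_aa)
    alpha <- alphabetOf(scheme)
    go <- as.integer(scheme@gap_open)
    ge <- as.integer(scheme@gap_extend)
    kk <- if (seed_filter) as.integer(seed_k) else 0L
    rows <- vector("list", 256L)
    nrows <- 0L
    for (cid in unique(orfs$contig_id)) {
        sub_orfs <- orfs[orfs$contig_id == cid, , drop = FALSE]
        ## best (lowest-E, then highest-score) hit per subject over this
        ## contig's ORFs
        best_score <- rep(0L, length(prot))
        best_orf <- rep(NA_integer_, length(prot))
        best_e <- rep(Inf, length(prot))
        for (k in seq_len(nrow(sub_orfs))) {
            sc <- cpp_sw_score_multi(sub_orfs$peptide[k], prot,
                                     scheme@matrix, alpha, go, ge, kk, 1L)$score
            m_k <- nchar(sub_orfs$peptide[k])
            e_k <- evalueKA(toBits(sc, scheme), m_k, db_n)
            upd <- sc > 0L & (e_k < best_e |
                              (e_k == best_e & sc > best_score))
            best_score[upd] <- sc[upd]
            best_orf[upd] <- k
            best_e[upd] <- e_k[upd]
        }
        hit_idx <- which(!is.na(best_orf) & best_e < evalue_max)
        if (!length(hit_idx)) next
        recs <- lapply(hit_idx, function(s) {
            k <- best_orf[s]
            al <- cpp_sw_align(sub_orfs$peptide[k], prot[s], scheme@matrix,
                               alpha, go, ge)
            qc <- orfNtCoords(sub_orfs[k, ], nchar(ch[[cid]]), al$q_start,
                              al$q_end)
            qcons <- al$q_end - al$q_start + 1L
            scons <- al$s_end - al$s_start + 1L
            c(s = s, pident = round(100 * al$n_identical / al$aln_len, 2),
              length = al$aln_len,
              mismatch = (qcons + scons - al$aln_len) - al$n_identical,
              gapopen = al$n_gap_opens, qstart = qc[1L], qend = qc[2L],
              sstart = al$s_start, send = al$s_end,
              bitscore = toBits(al$score, scheme))
        })
        m <- do.call(rbind, recs)
        nrows <- nrows + 1L
        rows[[nrows]] <- data.frame(
            query_id = cid, subject_id = names(prot)[m[, "s"]],
            pident = m[, "pident"], length = as.integer(m[, "length"]),
            mismatch = as.integer(m[, "mismatch"]),
            gapopen = as.integer(m[, "gapopen"]),
            qstart = as.integer(m[, "qstart"]),
            qend = as.integer(m[, "qend"]),
            sstart = as.integer(m[, "sstart"]),
            send = as.integer(m[, "send"]),
            evalue = best_e[hit_idx], bitscore = m[, "bitscore"],
            qlen = nchar(sub_orfs$peptide[best_orf[hit_idx]]),
            stringsAsFactors = FALSE)
    }
    if (!nrows) {
        out <- emptyHits()
        out$qlen <- integer(0)
        return(out)
    }
    out <- do.call(rbind, rows[seq_len(nrows)])
    rownames(out) <- NULL
    out
}

#' Best E-value between an ORF query and a translated contig
#'
#' The TBLASTN-like mode used for homology edges: the peptide is aligned
#' against every stop-free segment of all six frame translations of the
#' subject contig; the minimum E-value over segments is returned, with
#' search space `m * n` where `m` is the query peptide length and `n` the
#' subject length in residues (`nt/3`).
#'
#' @param query_pep the query peptide (typically a longest ORF).
#' @param subject_nt the subject contig nucleotide sequence.
#' @param scheme a [ScoringScheme-class].
#' @param seed_filter,seed_k optional exact shared-k-mer prescreen as in
#'   [searchTranslatedQuery()].
#' @return The minimum E-value (`Inf` when the subject is shorter than one
#'   codon or no segment scores above 0).
#' @export
contigPairHomology <- function(query_pep, subject_nt,
                               scheme = scoringScheme(),
                               seed_filter = TRUE, seed_k = 5L) {
    query_pep <- normalizeResidues(query_pep, "protein")
    n <- nchar(subject_nt) %/% 3L
    if (n < 1L) return(Inf)
    segs <- unlist(lapply(c(1L, 2L, 3L, -1L, -2L, -3L), function(f) {
        pep <- translateFrame(subject_nt, f)
        s <- strsplit(pep, "*", fixed = TRUE)[[1L]]
        s[nzchar(s)]
    }))
    if (!length(segs)) return(Inf)
    kk <- if (seed_filter) as.integer(seed_k) else 0L
    sc <- cpp_sw_score_multi(query_pep, segs, scheme@matrix,
                             alphabetOf(scheme),
                             as.integer(scheme@gap_open),
                             as.integer(scheme@gap_extend), kk, 1L)$score
    if (all(sc == 0L)) return(Inf)
    min(evalueKA(toBits(max(sc), scheme), nchar(query_pep), n))
}

#' Top hit per query
#'
#' For each query, the hit with the lowest E-value (ties: highest bit
#' score, then lexicographically smallest subject id), kept only when its
#' E-value is strictly below `cutoff`.
#'
#' @param hits a tabular-hit data.frame.
#' @param cutoff E-value cutoff, applied as strict `<`.
#' @return The winning rows, one per query that has a qualifying hit.
#' @export
topHit <- function(hits, cutoff = 1e-5) {
    if (!nrow(hits)) return(hits)
    ord <- order(hits$query_id, hits$evalue, -hits$bitscore,
                 hits$subject_id)
    h <- hits[ord, , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
    h <- h[h$evalue < cutoff, , drop = FALSE]
    rownames(h) <- NULL
    h
}
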