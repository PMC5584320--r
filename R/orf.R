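## Six-frame translation and longest-ORF extraction. An ORF here is a
## stop-to-stop stretch (no start codon required, sequence ends count as
## stops), because EST contigs are frequently 5'- or 3'-truncated.

.orf_cache <- new.env(parent = emptyenv())

codonTable <- function() {
    if (is.null(.orf_cache$tab)) {
        gc <- Biostrings::GENETIC_CODE
        .orf_cache$tab <- setNames(as.character(gc), names(gc))
    }
    .orf_cache$tab
}

## Translate one codon that may contain ambiguity codes: if every IUPAC
## expansion encodes the same residue (stop included) use it, else 'X'.
translateFuzzyCodon <- function(codon) {
    tab <- codonTable()
    iupac <- Biostrings::IUPAC_CODE_MAP
    chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
    sets <- lapply(chars, function(ch) {
        if (ch %in% c("A", "C", "G", "T")) ch
        else if (ch %in% names(iupac)) strsplit(iupac[[ch]], "")[[1L]]
        else c("A", "C", "G", "T")
    })
    cods <- apply(expand.grid(sets, stringsAsFactors = FALSE), 1L, paste,
                  collapse = "")
    aas <- unique(tab[cods])
    if (length(aas) == 1L && !is.na(aas)) aas else "X"
}

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Symbols outside
#' `{A,C,G,T,N}` are normalized to `N` first.
#'
#' @param nt a nucleotide string (or character vector of them).
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' revComp("AACN") # "NGTT"
#' @export
revComp <- function(nt) {
    nt <- normalizeResidues(nt, "nucleotide")
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(nt)))
}

#' Translate one reading frame
#'
#' Standard genetic code (table 1). Frames `1,2,3` read the forward strand
#' starting at offsets 0,1,2; frames `-1,-2,-3` read the reverse
#' complement likewise. Stops are reported as `*`; a trailing partial
#' codon is dropped. Codons containing `N` translate to the encoded
#' residue when all expansions are synonymous, otherwise to `X`.
#'
#' @param nt a nucleotide string.
#' @param frame one of `1, 2, 3, -1, -2, -3`.
#' @return The protein string (possibly empty).
#' @examples
#' translateFrame("ATGAAATGA", 1) # "MK*"
#' @export
translateFrame <- function(nt, frame) {
    stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    nt <- normalizeResidues(nt, "nucleotide")
    if (frame < 0) nt <- revComp(nt)
    off <- abs(frame) - 1L
    L <- nchar(nt)
    n_cod <- (L - off) %/% 3L
    if (n_cod <= 0L) return("")
    if (!grepl("N", nt, fixed = TRUE)) {
        ## unambiguous input: the fast C translator gives identical output
        dna <- Biostrings::subseq(Biostrings::DNAString(nt), off + 1L,
                                  off + 3L * n_cod)
        return(as.character(Biostrings::translate(dna, no.init.codon = TRUE)))
    }
    starts <- off + 1L + 3L * (seq_len(n_cod) - 1L)
    cods <- substring(nt, starts, starts + 2L)
    tab <- codonTable()
    aa <- tab[cods]
    fuzzy <- which(is.na(aa))
    if (length(fuzzy))
        aa[fuzzy] <- vapply(cods[fuzzy], translateFuzzyCodon, "")
    paste(aa, collapse = "")
}

emptyOrfs <- function() {
    data.frame(contig_id = character(0), frame = integer(0),
               nt_start = integer(0), nt_end = integer(0),
               peptide = character(0), stringsAsFactors = FALSE)
}

## Translate every sequence of a (normalized) character vector in one
## frame. Unambiguous sequences go through the vectorized Biostrings
## translator in a single call; sequences containing N fall back to the
## fuzzy-codon path of translateFrame.
translateSet <- function(chv, frame) {
    if (frame < 0)
        chv <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(chv)))
    off <- abs(frame) - 1L
    n_cod <- pmax((nchar(chv) - off) %/% 3L, 0L)
    out <- character(length(chv))
    hasN <- grepl("N", chv, fixed = TRUE)
    fast <- n_cod > 0L & !hasN
    if (any(fast)) {
        d <- Biostrings::DNAStringSet(substr(chv[fast], off + 1L,
                                             off + 3L * n_cod[fast]))
        out[fast] <- as.character(
            Biostrings::translate(d, no.init.codon = TRUE))
    }
    slow <- n_cod > 0L & hasN
    if (any(slow))
        out[slow] <- vapply(chv[slow], function(x)
            translateFrame(x, abs(frame)), "", USE.NAMES = FALSE)
    out
}

#' Enumerate open reading frames
#'
#' All stop-free translated stretches of at least `min_aa` residues across
#' the six frames of each contig. Coordinates are 0-based half-open on the
#' forward strand of the contig; `(nt_end - nt_start) == 3 * nchar(peptide)`.
#'
#' @param contigs nucleotide sequences (`DNAStringSet` or named character
#'   vector).
#' @param min_aa minimum peptide length in residues (>= 1).
#' @return A data.frame with columns `contig_id`, `frame`, `nt_start`,
#'   `nt_end`, `peptide`.
#' @export
findOrfs <- function(contigs, min_aa = 30L) {
    stopifnot(min_aa >= 1L)
    ch <- asCharSeqs(contigs)
    if (!length(ch)) return(emptyOrfs())
    ch <- normalizeResidues(ch, "nucleotide")
    ids <- names(ch)
    if (is.null(ids)) ids <- paste0("seq", seq_along(ch))
    L <- nchar(ch)
    frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
    parts <- vector("list", length(frames))
    for (fi in seq_along(frames)) {
        frame <- frames[fi]
        peps <- translateSet(ch, frame)
        ms <- gregexpr("[^*]+", peps)
        sub <- vector("list", length(ch)); nsub <- 0L
        for (i in seq_along(ch)) {
            m <- ms[[i]]
            if (m[1L] == -1L) next
            p1 <- as.integer(m)
            plen <- attr(m, "match.length")
            keep <- plen >= min_aa
            if (!any(keep)) next
            p1 <- p1[keep]; plen <- plen[keep]
            off <- abs(frame) - 1L
            st <- off + 3L * (p1 - 1L)        # 0-based, translated strand
            en <- off + 3L * (p1 + plen - 1L)
            if (frame < 0) {
                fwd_st <- L[i] - en
                fwd_en <- L[i] - st
            } else {
                fwd_st <- st
                fwd_en <- en
            }
            nsub <- nsub + 1L
            sub[[nsub]] <- data.frame(
                contig_id = ids[i], frame = frame, nt_start = fwd_st,
                nt_end = fwd_en,
                peptide = substring(peps[i], p1, p1 + plen - 1L),
                stringsAsFactors = FALSE)
        }
        if (nsub)
            parts[[fi]] <- do.call(rbind, sub[seq_len(nsub)])
    }
    parts <- parts[!vapply(parts, is.null, NA)]
    if (!length(parts)) return(emptyOrfs())
    out <- do.call(rbind, parts)
    ## stable order: contigs in input order, frames +1..+3,-1..-3, then
    ## 5'-most on the translated strand
    frame_rank <- match(out$frame, frames)
    strand_pos <- ifelse(out$frame > 0, out$nt_start, -out$nt_end)
    out <- out[order(match(out$contig_id, ids), frame_rank, strand_pos), ]
    rownames(out) <- NULL
    out
}

#' Longest open reading frame per contig
#'
#' Over all six frames, the longest stop-free stretch of at least `min_aa`
#' residues. Ties are broken by peptide string (lexicographic), then frame
#' order `+1, +2, +3, -1, -2, -3`, then 5'-most position on the translated
#' strand; resolving ties on the peptide first keeps the result invariant
#' under reverse complementation of the contig.
#'
#' @inheritParams findOrfs
#' @return A data.frame with one row per contig that has a qualifying ORF
#'   (contigs without one are absent), columns as in [findOrfs()].
#' @examples
#' longestOrf(c(c1 = "CCCTAAATGGCCGGATAACCC"), min_aa = 2)
#' @export
longestOrf <- function(contigs, min_aa = 30L) {
    orfs <- findOrfs(contigs, min_aa)
    if (!nrow(orfs)) return(orfs)
    frame_rank <- match(orfs$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
    ## 5'-most on the translated strand
    strand_pos <- ifelse(orfs$frame > 0, orfs$nt_start,
                         -(orfs$nt_end))
    ord <- order(orfs$contig_id, -nchar(orfs$peptide), orfs$peptide,
                 frame_rank, strand_pos)
    orfs <- orfs[ord, ]
    out <- orfs[!duplicated(orfs$contig_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write ORFs as protein FASTA
#'
#' Headers have the form `contig|frame|start-end` (0-based half-open
#' forward-strand coordinates).
#'
#' @param orfs a data.frame from [findOrfs()] or [longestOrf()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeOrfsFasta <- function(orfs, path) {
    x <- Biostrings::AAStringSet(orfs$peptide)
    names(x) <- sprintf("%s|%+d|%d-%d", orfs$contig_id, orfs$frame,
                        orfs$nt_start, orfs$nt_end)
    writeFasta(x, path)
}
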