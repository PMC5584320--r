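## Read cleanup: adapter removal at the sequence termini, 5' poly-T and
## 3' poly-A trimming, minimum-length filter. Operates on character
## vectors or XStringSets; all functions are vectorized over reads.

asCharSeqs <- function(x) {
    if (is.character(x)) x else as.character(x)
}

restoreType <- function(seqs, template) {
    if (is.character(template)) return(seqs)
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- names(seqs)
    out
}

## Count mismatches between the adapter and the window of s starting at
## position start (both fully inside s).
mismatchAt <- function(s_chars, a_chars, start) {
    sum(s_chars[start:(start + length(a_chars) - 1L)] != a_chars)
}

## One pass over one read: scan every full occurrence of each adapter
## (mismatches allowed); an occurrence is terminal when it lies within one
## adapter length of its nearer end, and everything outward of it (the
## occurrence included) is removed. Repeated until stable, so already
## trimmed reads pass through unchanged.
trimAdapterOne <- function(s, adapters, max_mismatch_rate) {
    changed <- FALSE
    repeat {
        hit <- FALSE
        for (ad in adapters) {
            sc <- strsplit(s, "", fixed = TRUE)[[1L]]
            L <- length(sc)
            ac <- strsplit(toupper(ad), "", fixed = TRUE)[[1L]]
            alen <- length(ac)
            if (alen == 0L || L < alen) next
            allowed <- floor(max_mismatch_rate * alen)
            starts <- seq_len(L - alen + 1L)
            mm <- vapply(starts, function(st) mismatchAt(sc, ac, st), 0L)
            ok <- starts[mm <= allowed]
            if (!length(ok)) next
            d5 <- ok - 1L
            d3 <- L - (ok + alen - 1L)
            near5 <- d5 <= d3
            terminal <- pmin(d5, d3) < alen
            five <- ok[near5 & terminal]
            if (length(five)) {
                mm5 <- mm[match(five, starts)]
                best <- five[mm5 == min(mm5)]
                st <- max(best)  # innermost: maximal trimming
                s <- substr(s, st + alen, L)
                hit <- TRUE; changed <- TRUE
                sc <- strsplit(s, "", fixed = TRUE)[[1L]]
                L <- length(sc)
                if (L < alen) next
                starts <- seq_len(L - alen + 1L)
                mm <- vapply(starts, function(st2) mismatchAt(sc, ac, st2), 0L)
                ok <- starts[mm <= allowed]
                if (!length(ok)) next
                d5 <- ok - 1L
                d3 <- L - (ok + alen - 1L)
                near5 <- d5 <= d3
                terminal <- pmin(d5, d3) < alen
            }
            three <- ok[!near5 & terminal]
            if (length(three)) {
                mm3 <- mm[match(three, starts)]
                best <- three[mm3 == min(mm3)]
                st <- min(best)
                s <- substr(s, 1L, st - 1L)
                hit <- TRUE; changed <- TRUE
            }
        }
        if (!hit) break
    }
    list(seq = s, changed = changed)
}

#' Trim adapter sequences from read termini
#'
#' For each adapter, the best terminal occurrence (within one adapter
#' length of either end, allowing up to `floor(max_mismatch_rate * nchar)`
#' mismatches) is located and everything outward of it (the occurrence
#' included) is removed. Ties on mismatch count are resolved toward the
#' innermost occurrence, i.e. maximal trimming. Interior occurrences are
#' untouched. Trimming is repeated until no terminal occurrence remains,
#' so the operation is idempotent.
#'
#' @param seqs reads as a named character vector or `DNAStringSet`.
#' @param adapters character vector of adapter sequences. Defaults to the
#'   two library PCR primers used for EST amplification.
#' @param max_mismatch_rate allowed mismatch fraction in `[0, 0.5)`.
#' @return Object of the same type as `seqs`, with an attribute
#'   `n_trimmed` counting reads that were shortened.
#' @examples
#' trimAdapter(c(r1 = "AAGCAGTGGACGTACGT"), "AAGCAGTGG", 0)
#' @export
trimAdapter <- function(seqs, adapters = defaultAdapters(),
                        max_mismatch_rate = 0.1) {
    stopifnot(length(adapters) >= 1L, all(nzchar(adapters)),
              length(max_mismatch_rate) == 1L, max_mismatch_rate >= 0,
              max_mismatch_rate < 0.5)
    ch <- asCharSeqs(seqs)
    res <- lapply(ch, trimAdapterOne, adapters = adapters,
                  max_mismatch_rate = max_mismatch_rate)
    out <- setNames(vapply(res, `[[`, "", "seq"), names(ch))
    out <- restoreType(out, seqs)
    attr(out, "n_trimmed") <- sum(vapply(res, `[[`, NA, "changed"))
    out
}

#' Default adapter set
#'
#' The two PCR primer sequences used to amplify the full-length, 5' and 3'
#' EST libraries; the only adapter-adjacent sequences shipped as defaults.
#' @return Character vector of two primer sequences (upper case).
#' @export
defaultAdapters <- function() {
    toupper(c("aagcagtggtatcaacgcagagt", "ATTCTAGAGGCCGAGGcggccgac"))
}

trimHomopolymerOne <- function(s, base, side, min_run, max_interrupts) {
    sc <- strsplit(s, "", fixed = TRUE)[[1L]]
    L <- length(sc)
    if (L == 0L) return(s)
    if (side == "three_prime") sc <- rev(sc)
    ## longest prefix that is a run of `base` with at most max_interrupts
    ## non-matching characters, never two consecutively, ending on `base`
    best <- 0L
    ints <- 0L
    prev_int <- FALSE
    for (i in seq_len(L)) {
        if (sc[i] == base) {
            prev_int <- FALSE
            best <- i
        } else {
            if (prev_int || ints >= max_interrupts) break
            ints <- ints + 1L
            prev_int <- TRUE
        }
    }
    if (best >= min_run) {
        keep <- if (side == "five_prime") substr(s, best + 1L, L)
                else substr(s, 1L, L - best)
        keep
    } else s
}

#' Trim a terminal homopolymer tail
#'
#' Removes the maximal terminal run of `base` (allowing up to
#' `max_interrupts` non-matching bases, never two consecutively) when the
#' run is at least `min_run` long; shorter runs leave the read unchanged.
#' Used for 5' poly-T and 3' poly-A signals left by oligo-dT priming.
#'
#' @param seqs reads as a character vector or `DNAStringSet`.
#' @param base `"T"` (5' side) or `"A"` (3' side), any single base allowed.
#' @param side `"five_prime"` or `"three_prime"`.
#' @param min_run minimum run length that triggers trimming (>= 4).
#' @param max_interrupts maximum number of isolated non-matching bases
#'   tolerated inside the run.
#' @return Object of the same type as `seqs`, with attribute `n_trimmed`.
#' @examples
#' trimHomopolymer("TTTTTTTTTTTTACGT", "T", "five_prime")
#' @export
trimHomopolymer <- function(seqs, base, side = c("five_prime", "three_prime"),
                            min_run = 10L, max_interrupts = 1L) {
    side <- match.arg(side)
    stopifnot(min_run >= 4L, nchar(base) == 1L)
    ch <- asCharSeqs(seqs)
    out <- vapply(ch, trimHomopolymerOne, "", base = toupper(base),
                  side = side, min_run = min_run,
                  max_interrupts = max_interrupts)
    names(out) <- names(ch)
    res <- restoreType(out, seqs)
    attr(res, "n_trimmed") <- sum(nchar(out) < nchar(ch))
    res
}

#' Length-filter reads
#'
#' Removes reads shorter than `min_len` bases; a read of exactly `min_len`
#' passes. Returns the survivors together with a [TrimReport-class]
#' accounting for the discarded reads.
#'
#' @param seqs reads as a character vector or `XStringSet`.
#' @param min_len minimum retained length in bases (>= 1).
#' @return `list(passed = , report = )`.
#' @examples
#' lengthFilter(c(a = "ACGT", b = "AC"), min_len = 3)
#' @export
lengthFilter <- function(seqs, min_len = 40L) {
    stopifnot(min_len >= 1L)
    len <- if (is.character(seqs)) nchar(seqs) else Biostrings::width(seqs)
    keep <- len >= min_len
    list(passed = seqs[keep],
         report = trimReport(n_input = length(seqs),
                             n_too_short = sum(!keep)))
}

#' Full read-cleanup stage
#'
#' Applies, in order: adapter trimming, 5' poly-T trimming, 3' poly-A
#' trimming, and the minimum-length filter. The composition is idempotent.
#'
#' @param seqs reads as a character vector or `DNAStringSet`.
#' @inheritParams trimAdapter
#' @inheritParams trimHomopolymer
#' @param min_len minimum retained length (bases).
#' @return `list(passed = , report = )` where `report` is a
#'   [TrimReport-class] with all trimming counts filled in.
#' @export
trimReads <- function(seqs, adapters = defaultAdapters(),
                      max_mismatch_rate = 0.1, min_run = 10L,
                      max_interrupts = 1L, min_len = 40L) {
    s1 <- trimAdapter(seqs, adapters, max_mismatch_rate)
    n_ad <- attr(s1, "n_trimmed")
    s2 <- trimHomopolymer(s1, "T", "five_prime", min_run, max_interrupts)
    n_t <- attr(s2, "n_trimmed")
    s3 <- trimHomopolymer(s2, "A", "three_prime", min_run, max_interrupts)
    n_a <- attr(s3, "n_trimmed")
    attr(s3, "n_trimmed") <- NULL
    lf <- lengthFilter(s3, min_len)
    rep <- trimReport(n_input = length(seqs), n_adapter_trimmed = n_ad,
                      n_polyt_trimmed = n_t, n_polya_trimmed = n_a,
                      n_too_short = lf$report@n_too_short)
    list(passed = lf$passed, report = rep)
}
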