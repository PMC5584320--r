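## FASTA, tabular-hit and cluster-table I/O. Sequences live in Biostrings
## XStringSet containers; ids are the header token before the first
## whitespace, the remainder is kept as a "description" metadata column.

## Nucleotides outside {A,C,G,T,N} become N; protein symbols outside the
## 20 residues + X/stop/gap become X. Gap codes ("-", ".") are preserved
## so pre-aligned protein FASTA survives a round trip.
normalizeResidues <- function(x, alphabet) {
    x <- toupper(x)
    if (alphabet == "nucleotide") {
        gsub("[^ACGTN]", "N", x)
    } else {
        gsub("[^ACDEFGHIKLMNPQRSTVWYX*.-]", "X", x)
    }
}

#' Read a FASTA file
#'
#' Reads sequences into a `DNAStringSet` or `AAStringSet`. The record id is
#' the header token before the first whitespace; the rest of the header is
#' stored in `mcols(x)$description`. Residues are upper-cased and unknown
#' symbols are normalized to `N` (nucleotide) or `X` (protein).
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return An `XStringSet` named by record id, with a `description`
#'   metadata column. An empty file yields an empty set with a warning.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 demo contig", "ACGT", "acgt"), tf)
#' readFasta(tf, "nucleotide")
#' @export
readFasta <- function(path, alphabet = c("nucleotide", "protein")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    if (file.size(path) == 0L) {
        warning("empty FASTA file: ", path)
        out <- if (alphabet == "nucleotide") Biostrings::DNAStringSet()
               else Biostrings::AAStringSet()
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = character(0))
        return(out)
    }
    raw <- Biostrings::readBStringSet(path)
    headers <- names(raw)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
    res <- normalizeResidues(as.character(raw), alphabet)
    out <- if (alphabet == "nucleotide") Biostrings::DNAStringSet(res)
           else Biostrings::AAStringSet(res)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
    out
}

#' Write sequences to FASTA
#'
#' Inverse of [readFasta()]: writes ids (plus any `description` metadata
#' column) as headers. Round-trips id, description and residues.
#'
#' @param x an `XStringSet` (or named character vector).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- Biostrings::BStringSet(x)
    desc <- S4Vectors::mcols(x)$description
    hdr <- names(x)
    if (!is.null(desc)) {
        has <- !is.na(desc) & nzchar(desc)
        hdr[has] <- paste(hdr[has], desc[has])
    }
    con <- file(path, "w")
    on.exit(close(con))
    seqs <- as.character(x)
    for (i in seq_along(seqs)) {
        writeLines(paste0(">", hdr[i]), con)
        writeLines(substring(seqs[i],
                             seq(1L, max(nchar(seqs[i]), 1L), 60L),
                             pmin(seq(60L, nchar(seqs[i]) + 59L, 60L),
                                  nchar(seqs[i]))), con)
    }
    invisible(path)
}

HIT_COLUMNS <- c("query_id", "subject_id", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

emptyHits <- function() {
    data.frame(query_id = character(0), subject_id = character(0),
               pident = numeric(0), length = integer(0),
               mismatch = integer(0), gapopen = integer(0),
               qstart = integer(0), qend = integer(0), sstart = integer(0),
               send = integer(0), evalue = numeric(0), bitscore = numeric(0),
               stringsAsFactors = FALSE)
}

#' Read a 12-column tabular hit file
#'
#' Parses the standard tab-separated pairwise-hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, E-value, bit score; coordinates 1-based
#' inclusive). Row order is preserved.
#'
#' @param path path to a tab-separated file.
#' @return A data.frame with columns
#'   `query_id, subject_id, pident, length, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore`.
#' @export
readTabularHits <- function(path) {
    if (!file.exists(path))
        stop("hit file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(emptyHits())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(parts)
    bad <- which(nfield != 12L)
    if (length(bad))
        stop(sprintf("line %d has %d columns, expected 12", bad[1L],
                     nfield[bad[1L]]))
    m <- do.call(rbind, parts)
    out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                      stringsAsFactors = FALSE)
    numcols <- list(pident = 3L, length = 4L, mismatch = 5L, gapopen = 6L,
                    qstart = 7L, qend = 8L, sstart = 9L, send = 10L,
                    evalue = 11L, bitscore = 12L)
    for (nm in names(numcols)) {
        v <- suppressWarnings(as.numeric(m[, numcols[[nm]]]))
        if (anyNA(v))
            stop(sprintf("line %d: cannot parse '%s' as a number in column %d",
                         which(is.na(v))[1L], m[which(is.na(v))[1L],
                         numcols[[nm]]], numcols[[nm]]))
        out[[nm]] <- if (nm %in% c("length", "mismatch", "gapopen", "qstart",
                                   "qend", "sstart", "send")) as.integer(v)
                     else v
    }
    if (any(out$evalue < 0)) stop("negative E-value in hit table")
    if (any(out$length < 1L)) stop("alignment length < 1 in hit table")
    out
}

#' Write hits in the 12-column tabular format
#'
#' @param hits a data.frame as returned by [readTabularHits()] or the
#'   search operations (extra columns are dropped).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTabularHits <- function(hits, path) {
    h <- hits[, HIT_COLUMNS, drop = FALSE]
    h$evalue <- formatC(h$evalue, format = "g", digits = 6)
    write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Write a gene-cluster partition to TSV
#'
#' One row per member contig, columns `cluster_id`, `subject_gene_id`,
#' `contig_id`, `is_representative` (0/1), ordered by cluster then contig
#' id so output is deterministic.
#'
#' @param clusters a [GeneClusterSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeClusters <- function(clusters, path) {
    m <- clusterMembers(clusters)
    m <- m[order(m$cluster_id, m$contig_id), ]
    m$is_representative <- as.integer(m$is_representative)
    write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

#' Read a gene-cluster partition written by [writeClusters()]
#'
#' @param path path to a cluster TSV.
#' @return A [GeneClusterSet-class].
#' @export
readClusters <- function(path) {
    m <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "integer"))
    m$is_representative <- m$is_representative == 1L
    geneClusterSet(m)
}

#' Read a threshold configuration from a key=value file
#'
#' Lines of the form `key = value`; keys are the [thresholdConfig()]
#' argument names. Unknown keys are an error; missing keys keep their
#' defaults. Lines starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return A [ThresholdConfig-class].
#' @export
readThresholdConfig <- function(path) {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    args <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) stop("cannot parse config line: ", ln)
        key <- trimws(kv[1L])
        if (!key %in% names(formals(thresholdConfig)))
            stop("unknown threshold key: ", key)
        args[[key]] <- as.numeric(trimws(kv[2L]))
    }
    do.call(thresholdConfig, args)
}
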