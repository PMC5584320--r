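test_that("readFasta parses headers, wraps, case and descriptions", {
    tf <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1", "ACGT"), tf)
    x <- readFasta(tf, "nucleotide")
    expect_equal(names(x), "c1")
    expect_equal(as.character(x), c(c1 = "ACGT"))

    writeLines(c(">c1", "AC", "GT"), tf)
    expect_equal(unname(as.character(readFasta(tf, "nucleotide"))), "ACGT")

    writeLines(c(">c1 desc a", "acgt"), tf)
    x <- readFasta(tf, "nucleotide")
    expect_equal(names(x), "c1")
    expect_equal(S4Vectors::mcols(x)$description, "desc a")
    expect_equal(unname(as.character(x)), "ACGT")
})

test_that("readFasta normalizes unknown symbols and rejects duplicates", {
    tf <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">c1", "ACRGT"), tf)  # R is ambiguity code
    expect_equal(unname(as.character(readFasta(tf, "nucleotide"))), "ACNGT")
    writeLines(c(">p1", "MKWOZ"), tf)  # O not in the 20+X alphabet
    expect_equal(unname(as.character(readFasta(tf, "protein"))), "MKWXX")
    writeLines(c(">c1", "ACGT", ">c1", "GGGG"), tf)
    expect_error(readFasta(tf, "nucleotide"), "c1")
    expect_error(readFasta(tempfile(), "nucleotide"), "not found")
    file.create(tf2 <- withr::local_tempfile(fileext = ".fa"))
    expect_warning(x <- readFasta(tf2, "nucleotide"), "empty")
    expect_length(x, 0)
})

test_that("FASTA write/read round-trips id, description and residues", {
    set.seed(42)
    tf <- withr::local_tempfile(fileext = ".fa")
    for (rep in 1:5) {
        n <- sample(1:6, 1)
        seqs <- vapply(seq_len(n), function(i) rand_dna(sample(1:200, 1)), "")
        ids <- paste0("seq", seq_len(n))
        desc <- ifelse(stats::runif(n) < 0.5, "", paste("note", seq_len(n)))
        x <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
        S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = desc)
        writeFasta(x, tf)
        y <- readFasta(tf, "nucleotide")
        expect_equal(names(y), ids)
        expect_equal(unname(as.character(y)), unname(seqs))
        expect_equal(S4Vectors::mcols(y)$description, desc)
    }
})

test_that("tabular hit reader types all 12 fields and keeps order", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(paste("c1", "AT1G01010", "98.0", "200", "4", "0", "1", "600",
                     "1", "200", "1e-120", "430", sep = "\t"), tf)
    h <- readTabularHits(tf)
    expect_equal(h$query_id, "c1")
    expect_equal(h$subject_id, "AT1G01010")
    expect_equal(h$evalue, 1e-120)
    expect_equal(h$bitscore, 430)
    expect_equal(h$length, 200L)
    expect_type(h$qstart, "integer")

    file.create(tf2 <- withr::local_tempfile(fileext = ".tsv"))
    expect_equal(nrow(readTabularHits(tf2)), 0L)

    writeLines(paste(rep("x", 11), collapse = "\t"), tf)
    expect_error(readTabularHits(tf), "line 1.*11 columns")
    writeLines(c(paste(c("c1", "s1", "90", "100", "1", "0", "1", "100", "1",
                         "100", "1e-5", "200"), collapse = "\t"),
                 paste(c("c2", "s1", "oops", "100", "1", "0", "1", "100",
                         "1", "100", "1e-5", "200"), collapse = "\t")), tf)
    expect_error(readTabularHits(tf), "line 2")
})

test_that("tabular hit write/read round-trips all fields", {
    set.seed(7)
    tf <- withr::local_tempfile(fileext = ".tsv")
    h <- do.call(rbind, lapply(1:10, function(i)
        make_hit(paste0("q", i), paste0("s", sample(3, 1)),
                 evalue = 10^-sample(3:150, 1),
                 bits = round(stats::runif(1, 30, 900), 1),
                 len = sample(30:300, 1))))
    writeTabularHits(h, tf)
    h2 <- readTabularHits(tf)
    expect_equal(h2$query_id, h$query_id)
    expect_equal(h2$length, h$length)
    expect_equal(h2$evalue, h$evalue, tolerance = 1e-5)
    expect_equal(h2$bitscore, h$bitscore, tolerance = 1e-5)
})

test_that("cluster table writes one representative per cluster and round-trips", {
    cl <- consolidate(
        data.frame(contig_id = c("c1", "c2", "c3"),
                   subject_gene_id = c("G1", "G1", "G2"),
                   evalue = c(1e-50, 1e-40, 1e-9),
                   bit_score = c(200, 180, 60), coverage = 1,
                   stringsAsFactors = FALSE),
        data.frame(contig_a = "c1", contig_b = "c2", evalue = 1e-120,
                   stringsAsFactors = FALSE))
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeClusters(cl, tf)
    lines <- readLines(tf)
    expect_length(lines, 4L)  # header + 3 members
    body <- read.delim(tf)
    expect_equal(sum(body$is_representative), 2L)
    cl2 <- readClusters(tf)
    expect_equal(clusterMembers(cl2), clusterMembers(cl))

    empty <- consolidate(data.frame(contig_id = character(0),
                                    subject_gene_id = character(0),
                                    evalue = numeric(0),
                                    bit_score = numeric(0),
                                    coverage = numeric(0)),
                         data.frame(contig_a = character(0),
                                    contig_b = character(0),
                                    evalue = numeric(0)))
    writeClusters(empty, tf)
    expect_length(readLines(tf), 1L)  # header only
    expect_equal(length(readClusters(tf)), 0L)
})

test_that("threshold configuration validates and reads key=value files", {
    th <- thresholdConfig()
    expect_equal(th@tophit_evalue_max, 1e-5)
    expect_equal(th@edge_evalue_max, 1e-100)
    expect_equal(th@ortholog_score_min, 150)
    expect_equal(th@ortholog_coverage_min, 0.2)
    expect_equal(th@min_read_length, 40L)
    expect_equal(th@bootstrap_replicates, 1000L)
    expect_error(thresholdConfig(tophit_evalue_max = 0), "positive")
    expect_error(thresholdConfig(ortholog_coverage_min = 1.5), "0, 1")

    tf <- withr::local_tempfile(fileext = ".cfg")
    writeLines(c("# comment", "edge_evalue_max = 1e-80",
                 "min_read_length=50"), tf)
    th2 <- readThresholdConfig(tf)
    expect_equal(th2@edge_evalue_max, 1e-80)
    expect_equal(th2@min_read_length, 50L)
    expect_equal(th2@tophit_evalue_max, 1e-5)
    writeLines("no_such_key = 3", tf)
    expect_error(readThresholdConfig(tf), "unknown")
})
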