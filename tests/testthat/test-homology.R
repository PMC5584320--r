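sch <- scoringScheme()

test_that("local alignment scores match hand values and handle edge cases", {
    expect_equal(localAlign("MKW", "MKW", sch)$raw_score, 21)  # 5 + 5 + 11
    expect_equal(localAlign("MKW", "AAA", sch)$raw_score, 0)
    expect_equal(localAlign("", "MKW", sch)$raw_score, 0)
    al <- localAlign("MKW", "MKW", sch)
    expect_equal(al$n_identical, 3L)
    expect_equal(al$alignment_length, 3L)
    expect_equal(c(al$q_start, al$q_end, al$s_start, al$s_end),
                 c(1L, 3L, 1L, 3L))
})

test_that("local alignment equals an independent reference DP", {
    set.seed(17)
    mats <- list(scoringScheme("BLOSUM62"),
                 scoringScheme("BLOSUM45", gap_open = 14, gap_extend = 2),
                 scoringScheme("PAM250", gap_open = 10, gap_extend = 1))
    for (i in 1:300) {
        s <- mats[[sample(3, 1)]]
        a <- rand_pep(sample(1:12, 1))
        b <- rand_pep(sample(1:12, 1))
        expect_equal(localAlign(a, b, s)$raw_score,
                     ref_sw(a, b, s@matrix, s@gap_open, s@gap_extend),
                     info = paste(a, b, s@matrix_name))
    }
})

test_that("alignment score is symmetric and monotone under truncation", {
    set.seed(23)
    for (i in 1:50) {
        a <- rand_pep(sample(5:40, 1))
        b <- rand_pep(sample(5:40, 1))
        expect_equal(localAlign(a, b, sch)$raw_score,
                     localAlign(b, a, sch)$raw_score)
        # dropping a suffix never increases the optimal local score
        a2 <- substr(a, 1, nchar(a) - sample(1:3, 1))
        expect_lte(localAlign(a2, b, sch)$raw_score,
                   localAlign(a, b, sch)$raw_score)
    }
})

test_that("bit scores and E-values follow the closed forms", {
    expect_equal(toBits(100, sch), (0.267 * 100 + 3.19418) / log(2),
                 tolerance = 1e-4)
    expect_equal(toBits(100, sch), 43.13, tolerance = 0.01)
    expect_equal(toBits(0, sch), -log(0.041) / log(2), tolerance = 1e-9)
    expect_gt(toBits(101, sch), toBits(100, sch))
    expect_equal(evalueKA(40, 100, 100), 1e4 * 2^-40)
    expect_equal(evalueKA(40, 100, 100), 9.09e-9, tolerance = 1e-3)
    expect_equal(evalueKA(0, 7, 13), 7 * 13)
    # linearity in each search-space dimension
    expect_equal(evalueKA(33, 100, 200), 2 * evalueKA(33, 100, 100))
    expect_equal(evalueKA(33, 300, 50), 3 * evalueKA(33, 100, 50))
    # monotone decreasing in bits
    bits <- sort(stats::runif(20, 0, 500))
    expect_true(all(diff(evalueKA(bits, 100, 100)) < 0))
})

test_that("translated-query search finds a planted subject and no decoys", {
    set.seed(41)
    pep <- rand_pep(250)
    codons <- names(Biostrings::GENETIC_CODE)
    aa_of <- as.character(Biostrings::GENETIC_CODE)
    enc <- vapply(strsplit(pep, "")[[1]], function(a)
        sample(codons[aa_of == a], 1), "")
    contig <- c(c1 = paste0("GG", paste(enc, collapse = ""), "TAAGG"))
    prots <- c(P1 = pep, P2 = rand_pep(250))
    hits <- searchTranslatedQuery(contig, prots, sch)
    hp1 <- hits[hits$subject_id == "P1", ]
    expect_equal(nrow(hp1), 1L)
    expect_lt(hp1$evalue, 1e-120)
    expect_equal(hp1$pident, 100)
    expect_false(any(hits$subject_id == "P2" & hits$evalue < 1e-5))
    # empty database violates the precondition
    expect_error(searchTranslatedQuery(contig, character(0), sch), "empty")
    # prescreen does not change reported hits on homologous input
    hits_full <- searchTranslatedQuery(contig, prots, sch,
                                       seed_filter = FALSE)
    expect_equal(hits[hits$subject_id == "P1", ],
                 hits_full[hits_full$subject_id == "P1", ])
})

test_that("random contigs almost never hit unrelated proteins at 1e-5", {
    set.seed(53)
    prots <- stats::setNames(vapply(1:5, function(i) rand_pep(300), ""),
                             paste0("P", 1:5))
    n_hit <- 0L
    for (i in 1:100) {
        contig <- stats::setNames(rand_dna(400), "c")
        hits <- searchTranslatedQuery(contig, prots, sch, min_orf_aa = 30)
        if (any(hits$evalue < 1e-5)) n_hit <- n_hit + 1L
    }
    expect_lte(n_hit, 5L)
})

test_that("contig-pair homology reaches E < 1e-100 only with long identity", {
    set.seed(61)
    pep <- rand_pep(250)
    codons <- names(Biostrings::GENETIC_CODE)
    aa_of <- as.character(Biostrings::GENETIC_CODE)
    enc <- paste(vapply(strsplit(pep, "")[[1]], function(a)
        sample(codons[aa_of == a], 1), ""), collapse = "")
    subject <- paste0("ACGT", enc, "TAAACGT")
    e <- contigPairHomology(pep, subject, sch)
    expect_lt(e, 1e-100)
    # closed-form check: raw self-score via the reference DP
    raw <- ref_sw(pep, pep, sch@matrix)
    expect_equal(e, evalueKA(toBits(raw, sch), 250, nchar(subject) %/% 3),
                 tolerance = 1e-9)
    # unrelated peptide: astronomically larger E
    expect_gt(contigPairHomology(rand_pep(250), subject, sch), 1e-50)
    # subject shorter than one codon: no edge possible
    expect_equal(contigPairHomology(pep, "AC", sch), Inf)
})

test_that("top-hit selection is strict and deterministically tie-broken", {
    h <- rbind(make_hit("c1", "S1", 1e-10, 100),
               make_hit("c1", "S2", 1e-40, 150))
    expect_equal(topHit(h, 1e-5)$subject_id, "S2")
    # E exactly at the cutoff fails (strict <)
    h2 <- make_hit("c1", "S1", 1e-5, 100)
    expect_equal(nrow(topHit(h2, 1e-5)), 0L)
    expect_equal(nrow(topHit(make_hit("c1", "S1", 9.9e-6, 100), 1e-5)), 1L)
    # equal E and bits: lexicographically smallest subject
    h3 <- rbind(make_hit("c1", "AT1G02", 1e-30, 120),
                make_hit("c1", "AT1G01", 1e-30, 120))
    expect_equal(topHit(h3, 1e-5)$subject_id, "AT1G01")
    # ties on E broken by bits first
    h4 <- rbind(make_hit("c1", "B", 1e-30, 200),
                make_hit("c1", "A", 1e-30, 120))
    expect_equal(topHit(h4, 1e-5)$subject_id, "B")
})
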