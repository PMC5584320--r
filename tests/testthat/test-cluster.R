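th <- thresholdConfig()

asg <- function(ids, genes, evalue = NULL, bits = NULL, cov = 1) {
    data.frame(contig_id = ids, subject_gene_id = genes,
               evalue = if (is.null(evalue)) rep(1e-50, length(ids)) else evalue,
               bit_score = if (is.null(bits)) rep(200, length(ids)) else bits,
               coverage = cov, stringsAsFactors = FALSE)
}

emptyHits_with_qlen <- function() {
    h <- make_hit("x", "y", 1, 1, qlen = 10L)
    h[0, ]
}

test_that("top-hit assignment applies the strict cutoff and coverage", {
    h <- rbind(make_hit("c1", "G1.1", 1e-50, 300, len = 100L, qlen = 200L),
               make_hit("c2", "G2.2", 1e-3, 40, len = 100L, qlen = 100L),
               make_hit("c3", "G1.1", 1e-7, 60, len = 50L, qlen = 100L),
               make_hit("c3", "G3.1", 1e-50, 200, len = 80L, qlen = 100L))
    a <- assignTopHits(h, th)
    expect_equal(sort(a$contig_id), c("c1", "c3"))  # c2 fails the cutoff
    expect_equal(a$subject_gene_id[a$contig_id == "c1"], "G1")  # isoform
    expect_equal(a$subject_gene_id[a$contig_id == "c3"], "G3")  # best E
    expect_equal(a$coverage[a$contig_id == "c1"], 0.5)
    expect_equal(nrow(assignTopHits(emptyHits_with_qlen(), th)), 0L)
    h_noqlen <- make_hit("c1", "G1", 1e-50, 300)
    expect_error(assignTopHits(h_noqlen, th), "query_lengths")
    a2 <- assignTopHits(h_noqlen, th, query_lengths = c(c1 = 100L))
    expect_equal(a2$coverage, 1)
})

test_that("edges take the orientation minimum and never cross bins", {
    a <- asg(c("c1", "c2", "c3"), c("G1", "G1", "G2"))
    tab <- data.frame(contig_a = "c1", contig_b = "c2", evalue = 1e-120,
                      stringsAsFactors = FALSE)
    e <- buildEdges(a, tab, th)
    expect_equal(nrow(e), 1L)
    # callable form: min of the two orientations passes
    f <- function(x, y) if (x < y) 1e-90 else 1e-110
    e2 <- buildEdges(asg(c("c1", "c2"), c("G1", "G1")), f, th)
    expect_equal(nrow(e2), 1L)
    expect_equal(e2$evalue, 1e-110)
    # both orientations above the cutoff: no edge
    e3 <- buildEdges(asg(c("c1", "c2"), c("G1", "G1")),
                     function(x, y) 1e-90, th)
    expect_equal(nrow(e3), 0L)
    # cross-bin pairs are never evaluated, even at E = 0
    e4 <- buildEdges(asg(c("c1", "c2"), c("G1", "G2")),
                     function(x, y) 0, th)
    expect_equal(nrow(e4), 0L)
    # precomputed table missing a same-bin pair is an error naming it
    expect_error(buildEdges(asg(c("c1", "c2", "c9"), c("G1", "G1", "G1")),
                            tab, th), "c9")
})

test_that("consolidation forms within-bin connected components", {
    a <- asg(c("c1", "c2", "c3", "c4"), c("G1", "G1", "G1", "G2"))
    e <- data.frame(contig_a = c("c1", "c2"), contig_b = c("c2", "c3"),
                    evalue = 1e-120, stringsAsFactors = FALSE)
    cl <- consolidate(a, e)
    expect_equal(length(cl), 2L)
    m <- clusterMembers(cl)
    expect_equal(sort(m$contig_id[m$cluster_id == "G1_c1"]),
                 c("c1", "c2", "c3"))
    # no edges: every assigned contig is a singleton cluster
    cl0 <- consolidate(a, e[0, ])
    expect_equal(length(cl0), 4L)
    # 12 contigs over 4 subject-gene bins/components -> 4 clusters
    a12 <- asg(sprintf("d%02d", 1:12), rep(paste0("DX", 1:4), each = 3))
    e12 <- do.call(rbind, lapply(1:4, function(g) {
        ids <- sprintf("d%02d", (3 * g - 2):(3 * g))
        data.frame(contig_a = ids[c(1, 2)], contig_b = ids[c(2, 3)],
                   evalue = 1e-150, stringsAsFactors = FALSE)
    }))
    expect_equal(length(consolidate(a12, e12)), 4L)
})

test_that("representatives minimize E with documented tie-breaks", {
    a <- asg(c("c1", "c2", "c3"), rep("G1", 3),
             evalue = c(1e-40, 1e-60, 1e-60), bits = c(100, 150, 180))
    e <- data.frame(contig_a = c("c1", "c2"), contig_b = c("c2", "c3"),
                    evalue = 1e-150, stringsAsFactors = FALSE)
    expect_equal(unname(representatives(consolidate(a, e))), "c3")
    # equal E and bits: lexicographically smallest contig
    a2 <- asg(c("c2", "c1"), rep("G1", 2))
    e2 <- data.frame(contig_a = "c1", contig_b = "c2", evalue = 1e-150,
                     stringsAsFactors = FALSE)
    expect_equal(unname(representatives(consolidate(a2, e2))), "c1")
})

test_that("consolidation equals brute-force transitive closure", {
    set.seed(71)
    for (rep in 1:100) {
        n <- sample(2:50, 1)
        ids <- sprintf("c%02d", seq_len(n))
        genes <- paste0("G", sample(1:max(1, n %/% 3), n, replace = TRUE))
        a <- asg(ids, genes)
        # random same-bin edges
        pairs <- list()
        for (g in unique(genes)) {
            mem <- ids[genes == g]
            if (length(mem) < 2) next
            cmb <- utils::combn(mem, 2)
            keep <- stats::runif(ncol(cmb)) < 0.3
            if (any(keep))
                pairs[[g]] <- data.frame(contig_a = cmb[1, keep],
                                         contig_b = cmb[2, keep],
                                         evalue = 1e-150,
                                         stringsAsFactors = FALSE)
        }
        e <- if (length(pairs)) do.call(rbind, pairs) else
            data.frame(contig_a = character(0), contig_b = character(0),
                       evalue = numeric(0))
        cl <- consolidate(a, e)
        got <- clusterAssignments(cl)
        want <- brute_components(ids, e)
        # same partition up to labeling
        expect_equal(oracle_ari(got[ids], want[ids]), 1, info = rep)
        # permutation invariance of the input order
        perm <- sample(n)
        cl2 <- consolidate(a[perm, ], e[sample(nrow(e)), , drop = FALSE])
        expect_equal(clusterMembers(cl2)[order(clusterMembers(cl2)$contig_id), ],
                     clusterMembers(cl)[order(clusterMembers(cl)$contig_id), ],
                     ignore_attr = TRUE)
        # partition: disjoint and covering
        expect_setequal(names(got), ids)
    }
})

test_that("adding edges never increases the cluster count", {
    set.seed(73)
    a <- asg(sprintf("c%02d", 1:12), rep("G1", 12))
    cmb <- utils::combn(a$contig_id, 2)
    base_keep <- stats::runif(ncol(cmb)) < 0.15
    e_base <- data.frame(contig_a = cmb[1, base_keep],
                         contig_b = cmb[2, base_keep], evalue = 1e-150,
                         stringsAsFactors = FALSE)
    n_base <- length(consolidate(a, e_base))
    extra <- which(!base_keep)[1]
    e_more <- rbind(e_base, data.frame(contig_a = cmb[1, extra],
                                       contig_b = cmb[2, extra],
                                       evalue = 1e-150))
    expect_lte(length(consolidate(a, e_more)), n_base)
    # and n_subject_genes <= n_clusters <= n_assigned
    s <- summarizeClusters(consolidate(a, e_base), 20)
    expect_lte(s$n_subject_genes, s$n_clusters)
    expect_lte(s$n_clusters, s$n_assigned)
})

test_that("cluster summary arithmetic and sentinel", {
    a <- asg(sprintf("c%d", 1:9), rep(c("G1", "G2", "G3"), each = 3))
    e <- do.call(rbind, lapply(c("G1", "G2", "G3"), function(g) {
        mem <- a$contig_id[a$subject_gene_id == g]
        data.frame(contig_a = mem[c(1, 2)], contig_b = mem[c(2, 3)],
                   evalue = 1e-150, stringsAsFactors = FALSE)
    }))
    s <- summarizeClusters(consolidate(a, e), 9)
    expect_equal(s$n_clusters, 3L)
    expect_equal(s$cluster_ratio, 1 / 3)
    s0 <- summarizeClusters(consolidate(a[0, ], e[0, ]), 0)
    expect_true(is.na(s0$cluster_ratio))
})

test_that("ortholog candidates enforce all three boundaries", {
    a <- asg(paste0("c", 1:5), paste0("G", 1:5),
             evalue = c(1e-50, 1e-50, 1e-50, 1e-5, 1e-50),
             bits = c(200, 150, 200, 200, 151),
             cov = c(0.5, 0.5, 0.19, 0.5, 0.20))
    keep <- orthologCandidates(a, th)$contig_id
    expect_true("c1" %in% keep)
    expect_false("c2" %in% keep)  # score exactly 150 fails (strict >)
    expect_false("c3" %in% keep)  # coverage below the floor
    expect_false("c4" %in% keep)  # E exactly 1e-5 fails (strict <)
    expect_true("c5" %in% keep)   # score 151 and coverage exactly 0.20 pass
})

test_that("family census counts contigs and clusters per label", {
    a <- asg(sprintf("t%02d", 1:8), rep(c("TPS1", "TPS2", "DXS1", "QQ1"),
                                        each = 2))
    e <- data.frame(contig_a = c("t01", "t03"), contig_b = c("t02", "t04"),
                    evalue = 1e-150, stringsAsFactors = FALSE)
    cl <- consolidate(a, e)
    fam <- data.frame(subject_gene_id = c("TPS1", "TPS2", "DXS1"),
                      family = c("TPS", "TPS", "DXS"))
    cen <- familyCensus(cl, fam)
    expect_equal(cen$n_contigs[cen$family == "TPS"], 4L)
    expect_equal(cen$n_clusters[cen$family == "TPS"], 2L)  # one merged bin
    expect_equal(cen$n_contigs[cen$family == "unassigned"], 2L)
    # empty family table: everything unassigned
    cen0 <- familyCensus(cl, fam[0, ])
    expect_equal(cen0$family, "unassigned")
    expect_equal(cen0$n_contigs, 8L)
    # one family, one contig
    cl1 <- consolidate(asg("x1", "F1"), e[0, ])
    cen1 <- familyCensus(cl1, data.frame(subject_gene_id = "F1",
                                         family = "fam"))
    expect_equal(cen1[cen1$family == "fam", c("n_contigs", "n_clusters")],
                 data.frame(n_contigs = 1L, n_clusters = 1L),
                 ignore_attr = TRUE)
})

test_that("GO tallies are incidence fractions per namespace", {
    a <- asg(c("c1", "c2"), c("G1", "G2"))
    go <- data.frame(gene_id = c("G1", "G2", "G2"),
                     namespace = "cellular component",
                     category = c("nucleus", "nucleus", "chloroplast"))
    t1 <- goTally(a, go)
    expect_equal(t1$fraction[t1$category == "nucleus"], 2 / 3)
    expect_equal(t1$fraction[t1$category == "chloroplast"], 1 / 3)
    expect_equal(sum(t1$fraction), 1, tolerance = 1e-9)
    expect_equal(nrow(goTally(a[0, ], go)), 0L)
    # unannotated genes count as unknown
    t2 <- goTally(asg("c9", "G9"), go)
    expect_equal(t2$category, "unknown")
    expect_equal(t2$fraction, 1)
})
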