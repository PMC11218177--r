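test_that("coverage gate requires 10 reads in tumor and normal, inclusive", {
  ev <- function(rd, ad) data.frame(ref_depth = rd, alt_depth = ad)
  expect_true(coverage_gate(ev(20, 10), ev(25, 0)))
  expect_false(coverage_gate(ev(20, 10), ev(9, 0)))
  expect_false(coverage_gate(ev(5, 4), ev(25, 0)))
  expect_true(coverage_gate(ev(5, 5), ev(10, 0)))   # boundary inclusive
  expect_error(coverage_gate(ev(-1, 5), ev(10, 0)), "negative")
})

test_that("classify_site applies the three rules with shared > LOH > unique", {
  v <- toy_variants(c(1000, 2000, 3000))
  loh <- data.frame(contig = "chr1", start = 2500L, end = 3500L,
                    loh = TRUE)
  partner <- data.frame(ref_depth = c(39, 40, 40), alt_depth = c(1, 0, 0))
  expect_equal(classify_site(v, partner, loh),
               c("shared", "unique", "excluded_loh"))
  # a single partner alt read dominates even inside LOH
  partner$alt_depth[3] <- 1
  expect_equal(classify_site(v, partner, loh)[3], "shared")
  # missing partner evidence is a configuration error
  expect_error(classify_site(v, partner[1:2, ], loh), "align")
  expect_error(
    classify_site(v, data.frame(ref_depth = c(1, 1, 1),
                                alt_depth = c(NA, 0, 0)), loh),
    "missing")
})

test_that("classify_site reproduces a 20-site rule truth table", {
  pos <- seq(1000, by = 1000, length.out = 20)
  v <- toy_variants(pos)
  in_loh <- pos >= 5000 & pos <= 9000
  alt <- rep(c(0L, 1L, 5L, 0L), 5)
  loh <- data.frame(contig = "chr1", start = 4500L, end = 9500L,
                    loh = TRUE)
  got <- classify_site(v, data.frame(ref_depth = 40L - alt,
                                     alt_depth = alt), loh)
  want <- ifelse(alt >= 1, "shared",
                 ifelse(in_loh, "excluded_loh", "unique"))
  expect_equal(got, want)
})

test_that("sharing_summary computes the Jaccard fraction over the union", {
  p <- toy_pair(n_shared = 2, n_unique_a = 100, n_unique_b = 98)
  s <- sharing_summary(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                       p$samples, "toy")
  expect_equal(s$n_shared, 2)
  expect_equal(s$n_unique_a, 100)
  expect_equal(s$n_unique_b, 98)
  expect_equal(s$shared_fraction_snv, 0.01)

  all_sh <- toy_pair(n_shared = 5, n_unique_a = 0, n_unique_b = 0)
  s2 <- sharing_summary(all_sh$va, all_sh$vb, all_sh$evidence,
                        all_sh$loh_a, all_sh$loh_b, all_sh$samples, "toy")
  expect_equal(s2$shared_fraction_snv, 1.0)
})

test_that("LOH-excluded sites leave both numerator and denominator", {
  p <- toy_pair(n_shared = 1, n_unique_a = 4, n_unique_b = 5, n_loh_a = 3)
  s <- sharing_summary(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                       p$samples, "toy")
  expect_equal(s$n_excluded_loh, 3)
  expect_equal(s$shared_fraction_snv, 1 / (1 + 4 + 5))
  expect_equal(s$n_shared + s$n_unique_a + s$n_unique_b +
                 s$n_excluded_loh + s$n_failed_coverage, s$n_total)
})

test_that("empty denominator warns and reports fraction 0", {
  p <- toy_pair(n_shared = 0, n_unique_a = 2, n_unique_b = 0, n_loh_a = 0)
  # fail the coverage gate everywhere by shrinking the normal depth
  p$evidence$ref_depth[p$evidence$sample_id == "TN"] <- 5L
  expect_warning(
    s <- sharing_summary(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                         p$samples, "toy"),
    "empty denominator")
  expect_equal(s$shared_fraction_snv, 0)
  expect_true(s$empty_denominator)
})

test_that("synonymous and non-exonic calls are excluded from the analysis set", {
  p <- toy_pair(n_shared = 2, n_unique_a = 2, n_unique_b = 2)
  p$va$consequence[3] <- "synonymous"
  p$vb$region[3] <- "intronic"
  s <- sharing_summary(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                       p$samples, "toy")
  expect_equal(s$n_unique_a, 1)
  expect_equal(s$n_unique_b, 1)
  expect_equal(s$n_total, 4)
})

test_that("added partner alt reads never convert shared to unique", {
  p <- toy_pair(n_shared = 2, n_unique_a = 5, n_unique_b = 3, n_loh_a = 2)
  base <- sharing_summary(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                          p$samples, "toy")
  # give one A-unique site a partner alt read: unique -> shared
  i <- which(p$evidence$sample_id == "TB" & p$evidence$alt_depth == 0)[1]
  p$evidence$alt_depth[i] <- 1L
  bumped <- sharing_summary(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                            p$samples, "toy")
  expect_equal(bumped$n_shared, base$n_shared + 1)
  expect_equal(bumped$n_unique_a, base$n_unique_a - 1)
  st_base <- setNames(base$detail$status, base$detail$key)
  st_bump <- setNames(bumped$detail$status, bumped$detail$key)
  moved <- names(st_base)[st_base != st_bump[names(st_base)]]
  expect_true(all(st_bump[moved] == "shared"))
})

test_that("sharing_summary matches the literal rule-by-rule oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    p <- toy_pair(n_shared = sample(0:6, 1), n_unique_a = sample(0:15, 1),
                  n_unique_b = sample(0:15, 1), n_loh_a = sample(0:3, 1))
    if (nrow(p$va) == 0 || nrow(p$vb) == 0) next
    s <- suppressWarnings(
      sharing_summary(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                      p$samples, "toy"))
    o <- oracle_sharing_counts(p$va, p$vb, p$evidence, p$loh_a, p$loh_b,
                               p$samples)
    expect_equal(s$n_shared, unname(o["shared"]))
    expect_equal(s$n_unique_a, unname(o["unique_a"]))
    expect_equal(s$n_unique_b, unname(o["unique_b"]))
    expect_equal(s$n_excluded_loh, unname(o["excluded"]))
    expect_equal(s$n_failed_coverage, unname(o["failed"]))
  }
})

test_that("shared CNV genes require direction agreement over the union", {
  genes <- load_gene_table()
  seg_for <- function(gene, cn) {
    gi <- genes[genes$gene == gene, ]
    data.frame(contig = gi$contig, start = gi$start - 1L, end = gi$end,
               copy_number = cn, baf = 0.25, genotype = "AAB",
               status = ifelse(cn > 2, "gain", ifelse(cn < 2, "loss",
                                                      "neutral")),
               loh = FALSE, stringsAsFactors = FALSE)
  }
  a <- rbind(seg_for("EGFR", 4L), seg_for("CDKN2A", 1L))
  b <- rbind(seg_for("EGFR", 5L), seg_for("MYC", 4L))
  ov <- cnv_gene_overlap(a, b, genes)
  expect_equal(ov$shared_genes, "EGFR")
  expect_equal(ov$fraction, 1 / 3)
  # direction mismatch is not shared
  ov2 <- cnv_gene_overlap(seg_for("CCND1", 4L), seg_for("CCND1", 1L),
                          genes)
  expect_equal(length(ov2$shared_genes), 0)
  expect_equal(ov2$fraction, 0)
  # partner without non-neutral segments
  ov3 <- cnv_gene_overlap(seg_for("EGFR", 4L), seg_for("EGFR", 2L), genes)
  expect_equal(ov3$fraction, 0)
})

test_that("SV matching respects type, tolerance and TRA symmetry", {
  sv <- function(c1, p1, c2, p2, type) {
    data.frame(chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = p2,
               svtype = type, orientation = "+-", stringsAsFactors = FALSE)
  }
  a <- sv("chr1", 1000, "chr1", 5000, "DEL")
  expect_equal(sv_overlap(a, a)$fraction, 1)
  expect_equal(sv_overlap(a, sv("chr1", 1000, "chr1", 5000, "DUP"))$n_matched, 0)
  expect_equal(sv_overlap(a, sv("chr1", 1025, "chr1", 5000, "DEL"))$n_matched, 0)
  expect_equal(sv_overlap(a, sv("chr1", 1008, "chr1", 4995, "DEL"))$n_matched, 1)
  tra <- sv("chr1", 1000, "chr2", 9000, "TRA")
  expect_equal(sv_overlap(tra, sv("chr2", 9000, "chr1", 1000, "TRA"))$n_matched, 1)
  expect_equal(sv_overlap(a[0, ], a[0, ])$fraction, 0)
  expect_error(sv_overlap(a, a, tol = -1), "tol")
})
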