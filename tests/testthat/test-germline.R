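toy_germline <- function(n = 1, depth = 50, af = 0, cosmic = FALSE,
                         region = "exonic", consequence = "nonsynonymous",
                         repeats = FALSE, gene = "TP53") {
  data.frame(chrom = "chr1", pos = seq_len(n) * 100, ref = "C", alt = "T",
             gene = gene, region = region, consequence = consequence,
             depth = depth, af_dbsnp = NA_real_, af_1kg = af,
             af_exac = NA_real_, cosmic_flag = cosmic,
             repeat_flag = repeats, stringsAsFactors = FALSE)
}

test_that("the filter cascade retains/drops the worked examples", {
  cats <- load_gene_categories()
  # COSMIC rescue: common in the population but cancer-recurrent
  p <- filter_germline(toy_germline(af = 0.005, cosmic = TRUE),
                       categories = cats)
  expect_equal(nrow(p$retained), 1)
  # depth 9 fails rule (i) even if otherwise perfect
  p <- filter_germline(toy_germline(depth = 9), categories = cats)
  expect_equal(unname(p$drops["depth"]), 1)
  expect_equal(nrow(p$retained), 0)
  # rare but intronic fails rule (iii)
  p <- filter_germline(toy_germline(af = 1e-5, region = "intronic"),
                       categories = cats)
  expect_equal(unname(p$drops["region"]), 1)
  # high AF without COSMIC fails rule (ii)
  p <- filter_germline(toy_germline(af = 0.05), categories = cats)
  expect_equal(unname(p$drops["af"]), 1)
  # repeat region fails rule (iv)
  p <- filter_germline(toy_germline(repeats = TRUE), categories = cats)
  expect_equal(unname(p$drops["repeat"]), 1)
  # missing depth is its own category
  p <- filter_germline(toy_germline(depth = NA), categories = cats)
  expect_equal(unname(p$drops["no_depth"]), 1)
  # boundary: AF exactly 0.001 is kept (rule is "greater than")
  p <- filter_germline(toy_germline(af = 0.001), categories = cats)
  expect_equal(nrow(p$retained), 1)
})

test_that("drop attribution goes to the first failing rule", {
  cats <- load_gene_categories()
  v <- toy_germline(depth = 5, af = 0.3, region = "intronic",
                    repeats = TRUE)
  p <- filter_germline(v, categories = cats)
  expect_equal(unname(p$drops["depth"]), 1)
  expect_equal(sum(p$drops), 1)
  v2 <- toy_germline(af = 0.3, region = "intronic", repeats = TRUE)
  expect_equal(unname(filter_germline(v2, categories = cats)$drops["af"]), 1)
})

test_that("the cascade is idempotent and its retained set order-invariant", {
  cats <- load_gene_categories()
  set.seed(5)
  v <- rbind(
    toy_germline(10), toy_germline(5, depth = 6),
    toy_germline(5, af = 0.2), toy_germline(5, region = "intronic"),
    toy_germline(5, repeats = TRUE),
    toy_germline(4, af = 0.01, cosmic = TRUE))
  v$pos <- seq_len(nrow(v))
  p1 <- filter_germline(v, categories = cats)
  p2 <- filter_germline(p1$retained, categories = cats)
  expect_equal(p2$retained, p1$retained)
  expect_equal(sum(p2$drops), 0)
  shuffled <- v[sample(nrow(v)), ]
  p3 <- filter_germline(shuffled, categories = cats)
  expect_setequal(p3$retained$pos, p1$retained$pos)
  expect_equal(p3$category_counts, p1$category_counts)
})

test_that("retained set shrinks monotonically as the AF cutoff tightens", {
  cats <- load_gene_categories()
  set.seed(8)
  v <- toy_germline(50, af = 0)
  v$af_1kg <- runif(50, 0, 0.01)
  v$pos <- 1:50
  prev <- NULL
  for (cutoff in c(0.01, 0.005, 0.001, 0.0001)) {
    kept <- filter_germline(v, af_max = cutoff,
                            categories = cats)$retained$pos
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("census screening intersects and de-duplicates genes", {
  cats <- load_gene_categories()
  v <- rbind(toy_germline(2, gene = "TP53"), toy_germline(1, gene = "WWOX"))
  v$pos <- 1:3
  p <- filter_germline(v, categories = cats)
  hit <- intersect_cgc(p, c("TP53", "BRCA2"))
  expect_equal(hit$genes, "TP53")
  expect_equal(nrow(hit$variants), 2)
  expect_equal(intersect_cgc(p, "KRAS")$genes, character(0))
  expect_warning(intersect_cgc(p, character(0)), "empty")
})

test_that("category comparison reuses the exact rank-sum test", {
  prof <- function(n_immune, pid) {
    v <- toy_germline(n_immune, gene = "TLR4")
    v$pos <- seq_len(n_immune)
    filter_germline(v, categories = load_gene_categories(),
                    patient_id = pid)
  }
  mc <- lapply(c(8, 9, 10, 11, 12, 13), prof, pid = "mc")
  me <- lapply(c(1, 2, 3, 4), prof, pid = "me")
  res <- compare_category(mc, me, "immune")
  expect_equal(res$p_value, 2 / 210, tolerance = 1e-12)
  expect_equal(compare_category(mc, mc, "immune")$p_value, 1.0)
  expect_error(compare_category(mc, me, "nonsense"), "unknown category")
})

test_that("hypergeometric enrichment matches the closed form and BH", {
  universe <- paste0("G", 1:100)
  ann <- data.frame(gene = universe[1:10], category = "setA",
                    stringsAsFactors = FALSE)
  res <- enrich_sets(universe[1:5], ann, universe)
  expect_equal(res$p, choose(10, 5) / choose(100, 5), tolerance = 1e-12)
  # query = universe makes every set certain
  res2 <- enrich_sets(universe, ann, universe)
  expect_equal(res2$p, 1.0)
  expect_error(enrich_sets(c("G1", "NOPE"), ann, universe), "NOPE")
  # BH on three sets
  ann3 <- data.frame(gene = c(universe[1:10], universe[11:30],
                              universe[31:70]),
                     category = rep(c("s1", "s2", "s3"), c(10, 20, 40)),
                     stringsAsFactors = FALSE)
  res3 <- enrich_sets(universe[c(1:6, 11:12, 31:32)], ann3, universe)
  # BH by hand: sort p ascending, p_adj_i = min_{j >= i} p_j * m / j
  ps <- sort(res3$p)
  expect_equal(res3$p_adj,
               pmin(1, rev(cummin(rev(ps * 3 / seq_len(3))))),
               tolerance = 1e-12)
})

test_that("hypergeometric p agrees with a permutation oracle", {
  set.seed(11)
  universe <- paste0("G", 1:40)
  set_members <- universe[1:12]
  ann <- data.frame(gene = set_members, category = "s",
                    stringsAsFactors = FALSE)
  genes <- c(universe[1:5], universe[20:24])
  p_exact <- enrich_sets(genes, ann, universe)$p
  p_perm <- oracle_enrichment_p(genes, set_members, universe,
                                n_draws = 10000)
  se <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(p_exact - p_perm), 3 * se + 1e-6)
})
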