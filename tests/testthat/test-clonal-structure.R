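test_that("CCF estimation inverts the allele-sampling model", {
  expect_equal(estimate_ccf(25, 25, 2, 1, 1)$ccf, 1.0)
  expect_equal(estimate_ccf(25, 75, 2, 1, 1)$ccf, 0.5)
  # vaf 0.4, CN 2, purity 0.8: 0.4 * (1.6 + 0.4) / 0.8 = 1.0
  expect_equal(estimate_ccf(40, 60, 2, 0.8, 1)$ccf, 1.0)
  expect_equal(estimate_ccf(60, 0, 2, 1, 1)$ccf, 1.5)  # capped
  expect_error(estimate_ccf(0, 0, 2, 1, 1), "zero total depth")
  expect_error(estimate_ccf(5, 5, 2, 1.2, 1), "purity")
})

test_that("multiplicity is 1 outside gains and estimated inside them", {
  expect_equal(infer_multiplicity(0.5, 2, 1, FALSE), 1L)
  # clonal mutation on 2 of 4 copies in a pure tumor: vaf 0.5
  expect_equal(infer_multiplicity(0.5, 4, 1, TRUE), 2L)
  expect_equal(infer_multiplicity(0.05, 4, 1, TRUE), 1L)   # floor at 1
  expect_equal(infer_multiplicity(2, 4, 1, TRUE), 4L)      # capped at CN
})

test_that("two well-separated clones are recovered with accurate means", {
  set.seed(21)
  n <- 100
  truth <- sample(c(1.0, 0.4), n, replace = TRUE)
  depth <- rpois(n, 50)
  alt <- rbinom(n, depth, truth * 0.5)
  cl <- fit_clusters(alt, depth, purity = 1, k_max = 4, restarts = 15,
                     seed = 9)
  expect_equal(cl$K, 2)
  expect_lt(abs(cl$means[1] - 1.0), 0.08)
  expect_lt(abs(cl$means[2] - 0.4), 0.08)
  expect_equal(sum(cl$weights), 1, tolerance = 1e-9)
  expect_equal(length(cl$assignment), n)
  expect_true(all(diff(cl$loglik_trace) > -1e-6))
})

test_that("identical CCFs collapse to a single cluster", {
  set.seed(22)
  depth <- rpois(80, 50)
  alt <- rbinom(80, depth, 0.5)
  cl <- fit_clusters(alt, depth, purity = 1, k_max = 4, restarts = 10,
                     seed = 1)
  expect_equal(cl$K, 1)
})

test_that("clustering is deterministic given a seed", {
  set.seed(23)
  depth <- rpois(60, 50)
  alt <- rbinom(60, depth, sample(c(0.5, 0.2), 60, TRUE))
  a <- fit_clusters(alt, depth, k_max = 3, restarts = 5, seed = 4)
  b <- fit_clusters(alt, depth, k_max = 3, restarts = 5, seed = 4)
  expect_equal(a$means, b$means)
  expect_equal(a$assignment, b$assignment)
})

test_that("fewer than 5 mutations fall back to one cluster with a warning", {
  expect_warning(cl <- fit_clusters(c(10, 12), c(20, 25)), "fewer than 5")
  expect_equal(cl$K, 1)
  expect_equal(length(cl$assignment), 2)
})

test_that("key mutations need clonal-scale CCF and a deleterious score", {
  cl <- list(K = 2L, means = c(0.8, 0.4), assignment = c(1L, 1L, 2L, 1L, 1L))
  v <- data.frame(
    gene = c("TP53", "MUC16", "DGKZ", "EGFR", "APC"),
    chrom = "chr1", pos = 1:5, ref = "C", alt = "T",
    sift = c(0.01, 0.5, 0.01, NA, 0.06),
    polyphen = c(0.2, 0.957, 0.99, NA, 0.956),
    stringsAsFactors = FALSE)
  key <- select_key_mutations(cl, v)
  # TP53: CCF 0.8 + SIFT 0.01 -> key; MUC16: PolyPhen boundary 0.957 -> key
  # DGKZ: deleterious but subclonal -> no; EGFR: missing scores -> no;
  # APC: SIFT 0.06 and PolyPhen 0.956 both just miss -> no
  expect_equal(key$gene, c("TP53", "MUC16"))
  expect_equal(key$cluster_mean_ccf, c(0.8, 0.8))
  # boundary: cluster mean exactly 0.5 qualifies
  cl2 <- list(K = 1L, means = 0.5, assignment = rep(1L, 5))
  expect_equal(nrow(select_key_mutations(cl2, v)), 3)
  # monotone in the CCF threshold
  expect_gte(nrow(select_key_mutations(cl, v, ccf_min = 0.3)),
             nrow(select_key_mutations(cl, v, ccf_min = 0.5)))
})

test_that("driver recurrence counts key-bearing foci over mutated foci", {
  mk <- function(genes, keys) {
    data.frame(gene = genes, is_key = keys, stringsAsFactors = FALSE)
  }
  foci <- c(
    lapply(1:8, function(i) mk("TP53", TRUE)),
    list(mk("TP53", FALSE)),                       # mutated, not key
    lapply(1:3, function(i) mk("EGFR", FALSE)))
  rec <- driver_recurrence(foci)
  tp53 <- rec[rec$gene == "TP53", ]
  expect_equal(tp53$n_foci_key, 8)
  expect_equal(tp53$n_foci_mutated, 9)
  expect_equal(tp53$ratio, 8 / 9)
  expect_equal(rec[rec$gene == "EGFR", ]$ratio, 0)
  expect_equal(rec$gene[1], "TP53")  # sorted by ratio
})
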