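test_that("a zero-target MC patient has no shared somatic variants", {
  b <- simulate_patient(small_entry(target = 0, n = 80, seed = 7))
  expect_equal(length(b$truth$shared_keys), 0)
  ka <- b$variants$key[b$variants$focus == "A"]
  kb <- b$variants$key[b$variants$focus == "B"]
  expect_equal(length(intersect(ka, kb)), 0)
})

test_that("an ME patient realizes its target shared fraction", {
  b <- simulate_patient(small_entry(origin = "ME", target = 0.65, n = 200,
                                    seed = 7))
  v <- b$variants[b$variants$consequence != "synonymous", ]
  ka <- unique(v$key[v$focus == "A"])
  kb <- unique(v$key[v$focus == "B"])
  f <- length(intersect(ka, kb)) / length(union(ka, kb))
  expect_gte(f, 0.60)
  expect_lte(f, 0.70)
})

test_that("single-cluster foci have uniform truth CCFs", {
  b <- simulate_patient(small_entry(n = 60, seed = 3,
                                    n_clusters_per_focus = c(1, 1)))
  for (fc in c("A", "B")) {
    expect_equal(unique(b$variants$ccf[b$variants$focus == fc]), 1.0)
  }
})

test_that("generation is deterministic and calibrated across seeds", {
  e <- small_entry(origin = "ME", target = 0.6, n = 200, seed = 99)
  b1 <- simulate_patient(e)
  b2 <- simulate_patient(e)
  expect_identical(b1$variants, b2$variants)
  expect_identical(b1$evidence, b2$evidence)
  expect_identical(b1$germline, b2$germline)

  realized <- vapply(1:20, function(s) {
    b <- simulate_patient(small_entry(origin = "ME", target = 0.6, n = 200,
                                      seed = 1000 + s))
    v <- b$variants[b$variants$consequence != "synonymous", ]
    ka <- unique(v$key[v$focus == "A"])
    kb <- unique(v$key[v$focus == "B"])
    length(intersect(ka, kb)) / length(union(ka, kb))
  }, numeric(1))
  expect_lt(abs(mean(realized) - 0.6), 0.03)
})

test_that("read evidence is consistent with the sharing truth", {
  b <- simulate_patient(small_entry(origin = "ME", target = 0.3, n = 100,
                                    seed = 13))
  ev <- b$evidence
  key_of <- function(e) paste(e$chrom, e$pos, e$ref, e$alt)
  alt_in <- function(keys, sample) {
    e <- ev[ev$sample_id == sample, ]
    e$alt_depth[match(keys, key_of(e))]
  }
  v <- b$variants
  shared <- b$truth$shared_keys
  shared_k <- paste(v$chrom, v$pos, v$ref, v$alt)[match(shared, v$key)]
  expect_true(all(alt_in(shared_k, b$samples$a) >= 1))
  expect_true(all(alt_in(shared_k, b$samples$b) >= 1))
  uq <- v[v$focus == "A" & !v$shared_truth & !v$is_planted_loh, ]
  expect_true(all(alt_in(paste(uq$chrom, uq$pos, uq$ref, uq$alt),
                         b$samples$b) == 0))
  # planted partner-unique variants sit inside the partner's LOH regions
  pl <- v[v$focus == "A" & v$is_planted_loh, ]
  loh_b <- b$truth$loh_regions$B
  expect_true(all(vapply(seq_len(nrow(pl)), function(i) {
    any(loh_b$contig == pl$chrom[i] & pl$pos[i] > loh_b$start &
          pl$pos[i] <= loh_b$end)
  }, logical(1))))
})

test_that("germline category counts match the configuration exactly", {
  e <- small_entry(n = 40, seed = 17,
                   germline = list(n_total = 45, n_immune = 7))
  b <- simulate_patient(e)
  g <- b$germline
  core <- g[g$retained_truth, ]
  expect_equal(nrow(core), 45)
  expect_equal(sum(core$category_truth == "immune"), 7)
  # the filter cascade recovers exactly the retained core
  p <- filter_germline(g, categories = load_gene_categories())
  expect_equal(nrow(p$retained), 45)
  expect_equal(unname(p$category_counts["immune"]), 7)
})

test_that("unreachable shared-fraction targets are a configuration error", {
  expect_error(simulate_patient(small_entry(target = 0.5, n = 0)),
               "unreachable")
})

test_that("cohorts write deterministic files and a complete manifest", {
  cfg <- default_cohort_config(base_seed = 5)
  cfg$patients <- cfg$patients[c(1, 7)]  # one MC, one ME
  cfg$patients <- lapply(cfg$patients, function(p) {
    p$n_somatic_per_focus <- 40L
    p
  })
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  sim1 <- simulate_cohort(cfg, d1)
  sim2 <- simulate_cohort(cfg, d2)
  expect_equal(length(sim1$manifest$patients), 2)
  for (p in sim1$manifest$patients) {
    for (f in unlist(p$files)) {
      f1 <- file.path(d1, p$id, f)
      f2 <- file.path(d2, p$id, f)
      expect_identical(readLines(f1), readLines(f2))
    }
  }
  # duplicate ids rejected
  cfg_bad <- cfg
  cfg_bad$patients[[2]]$id <- cfg_bad$patients[[1]]$id
  expect_error(simulate_cohort(cfg_bad, file.path(tempdir(), "coh_dup")),
               "duplicate")
  # empty cohort: no error, empty manifest
  cfg0 <- cfg
  cfg0$patients <- list()
  sim0 <- simulate_cohort(cfg0, file.path(tempdir(), "coh0"))
  expect_equal(sim0$manifest$n_patients, 0)
})

test_that("patient directories round-trip through the VCF/TSV readers", {
  cfg <- default_cohort_config(base_seed = 6)
  cfg$patients <- cfg$patients[1]
  cfg$patients[[1]]$n_somatic_per_focus <- 40L
  d <- file.path(tempdir(), "coh_rt")
  unlink(d, recursive = TRUE)
  sim <- simulate_cohort(cfg, d)
  b0 <- sim$bundles[[1]]
  b1 <- read_patient(file.path(d, b0$patient_id))
  for (fc in c("A", "B")) {
    v0 <- b0$variants[b0$variants$focus == fc, ]
    v1 <- b1$variants[b1$variants$focus == fc, ]
    expect_setequal(v1$key <- paste(v1$chrom, v1$pos, v1$ref, v1$alt),
                    paste(v0$chrom, v0$pos, v0$ref, v0$alt))
  }
  expect_equal(nrow(b1$evidence), nrow(b0$evidence))
  expect_equal(sort(b1$germline$pos), sort(b0$germline$pos))
  expect_equal(b1$germline$depth[order(b1$germline$pos)],
               b0$germline$depth[order(b0$germline$pos)])
  expect_equal(nrow(b1$affinity), nrow(b0$affinity))
  expect_equal(nrow(b1$segments), nrow(b0$segments))
  expect_equal(nrow(b1$svs), nrow(b0$svs))
})
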