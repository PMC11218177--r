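# Hand-built toy fixtures (generator-free) for the sharing classifier.

toy_variants <- function(pos, chrom = "chr1", ref = "C", alt = "T",
                         region = "exonic",
                         consequence = "nonsynonymous") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             region = rep_len(region, n),
             consequence = rep_len(consequence, n),
             stringsAsFactors = FALSE)
}

toy_evidence <- function(variants, sample_id, ref_depth, alt_depth,
                         hq_flag = NULL) {
  n <- nrow(variants)
  if (is.null(hq_flag)) hq_flag <- alt_depth >= 3
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt,
             sample_id = rep_len(sample_id, n),
             ref_depth = rep_len(ref_depth, n),
             alt_depth = rep_len(alt_depth, n),
             hq_flag = rep_len(hq_flag, n),
             stringsAsFactors = FALSE)
}

toy_samples <- list(a = "TA", b = "TB", normal = "TN")

# a focus pair with the given composition; evidence is fully consistent
# (shared sites have alt reads in both foci, unique sites none in the
# partner, LOH-planted sites sit inside the partner's LOH segment)
toy_pair <- function(n_shared = 2, n_unique_a = 3, n_unique_b = 3,
                     n_loh_a = 0, depth = 40) {
  pos_sh <- seq_len(n_shared) * 1000
  pos_a <- 100000 + seq_len(n_unique_a) * 1000
  pos_loh <- if (n_loh_a > 0) 5000000 + seq_len(n_loh_a) * 1000 else
    integer(0)
  pos_b <- 200000 + seq_len(n_unique_b) * 1000
  va <- toy_variants(c(pos_sh, pos_a, pos_loh))
  vb <- toy_variants(c(pos_sh, pos_b))
  loh_b <- data.frame(contig = "chr1", start = 4900000L, end = 6000000L,
                      copy_number = 2L, baf = 0, genotype = "AA",
                      status = "neutral", loh = TRUE,
                      stringsAsFactors = FALSE)
  drop_first <- function(v, k) {
    if (k > 0) v[-seq_len(k), , drop = FALSE] else v
  }
  ev <- rbind(
    toy_evidence(va, toy_samples$a, depth - 15L, 15L),
    toy_evidence(vb, toy_samples$b, depth - 15L, 15L),
    toy_evidence(drop_first(va, n_shared), toy_samples$b, depth, 0L),
    toy_evidence(drop_first(vb, n_shared), toy_samples$a, depth, 0L),
    toy_evidence(unique(rbind(va, vb)), toy_samples$normal, 30L, 0L))
  list(va = va, vb = vb, evidence = ev, loh_a = NULL, loh_b = loh_b,
       samples = toy_samples)
}

small_entry <- function(id = "T01", origin = "MC", target = 0,
                        n = 60, seed = 11, ...) {
  cfg <- list(id = id, origin_model = origin,
              target_shared_snv_fraction = target,
              n_somatic_per_focus = n, seed = seed, ...)
  mecclone:::normalize_entry(cfg, 1, seed)
}

aff_row <- function(mut = 300, wt = 800, id = "TP53_chr1_1_C_T",
                    focus = "P1_A", pep = "ACDEFGHIK") {
  data.frame(mutation_id = id, focus_id = focus, hla_allele = "HLA-A*02:01",
             peptide = pep, mut_affinity_nM = mut, wt_affinity_nM = wt,
             stringsAsFactors = FALSE)
}
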