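# Synthetic paired-foci cohort generator. Each patient is a trio (tumor
# focus A, tumor focus B, matched normal) with a known ground truth:
# origin model, per-variant shared flags, per-focus clonal clusters and
# CCFs, LOH regions, per-gene CNV truth, SV sharing, germline category
# counts and peptide-MHC affinities. Read depths are Poisson around the
# configured means; alternative counts are Binomial at the expected VAF
# ccf * purity * multiplicity / (purity * CN + (1 - purity) * 2).

ccf_menu <- function(k) {
  list(c(1.0), c(1.0, 0.4), c(1.0, 0.55, 0.25))[[k]]
}

cluster_probs <- function(k) {
  list(1, c(0.45, 0.55), c(0.4, 0.35, 0.25))[[k]]
}

# non-overlapping LOH regions on the designated contig, one per third of
# the contig, 1-12 Mb each (0-based half-open)
make_loh_regions <- function(k, genome, contig) {
  if (k == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), copy_number = integer(0),
                      baf = numeric(0), genotype = character(0),
                      status = character(0), loh = logical(0),
                      stringsAsFactors = FALSE))
  }
  L <- unname(genome[contig])
  block <- L %/% 3
  blocks <- sort(sample.int(3, min(k, 3)))
  len <- round(runif(length(blocks), 1e6, min(12e6, block - 1)))
  start <- vapply(seq_along(blocks), function(i) {
    lo <- (blocks[i] - 1) * block
    round(runif(1, lo, lo + block - len[i] - 1))
  }, numeric(1))
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(start + len), copy_number = 2L,
             baf = 0, genotype = "AA", status = "neutral", loh = TRUE,
             stringsAsFactors = FALSE)
}

# segments for a focus: CNV gene segments (gain CN4 / loss CN1) plus the
# focus's LOH regions
make_segments <- function(cnv_profile, loh_regions, genes) {
  if (nrow(cnv_profile) > 0) {
    gi <- genes[match(cnv_profile$gene, genes$gene), ]
    gain <- cnv_profile$direction == "gain"
    seg <- data.frame(
      contig = gi$contig,
      start = as.integer(gi$start - 1 - 200000),
      end = as.integer(gi$end + 200000),
      copy_number = ifelse(gain, 4L, 1L),
      baf = ifelse(gain, 0.25, 0),
      genotype = ifelse(gain, "AAAB", "A"),
      status = cnv_profile$direction,
      loh = !gain,
      stringsAsFactors = FALSE)
  } else {
    seg <- loh_regions[0, ]
  }
  out <- rbind(seg, loh_regions)
  out[order(match(out$contig, unique(out$contig)), out$start), ,
      drop = FALSE]
}

random_aa_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# draw k random somatic variants in the given gene pool
random_somatic <- function(k, gene_pool, indel_frac = 0.05,
                           consequence = NULL) {
  if (k == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), region = character(0),
                      consequence = character(0), sift = numeric(0),
                      polyphen = numeric(0), is_driver = logical(0),
                      is_planted_loh = logical(0), stringsAsFactors = FALSE))
  }
  gi <- gene_pool[sample.int(nrow(gene_pool), k, replace = TRUE), ]
  pos <- as.integer(round(runif(k, gi$start, gi$end)))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, k, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  is_indel <- runif(k) < indel_frac
  second <- sample(bases, k, replace = TRUE)
  del <- is_indel & runif(k) < 0.5
  ref[del] <- paste0(ref[del], second[del])
  alt[is_indel & !del] <- paste0(ref[is_indel & !del],
                                 second[is_indel & !del])
  cons <- if (is.null(consequence)) {
    ifelse(is_indel, "frameshift",
           sample(c("nonsynonymous", "stopgain"), k, replace = TRUE,
                  prob = c(0.85, 0.15)))
  } else rep(consequence, k)
  sift <- round(runif(k), 3)
  polyphen <- round(runif(k), 3)
  sift[runif(k) < 0.1] <- NA
  polyphen[runif(k) < 0.1] <- NA
  data.frame(chrom = gi$contig, pos = pos, ref = ref, alt = alt,
             gene = gi$gene,
             region = sample(c("exonic", "splicing"), k, replace = TRUE,
                             prob = c(0.95, 0.05)),
             consequence = cons, sift = sift, polyphen = polyphen,
             is_driver = FALSE, is_planted_loh = FALSE,
             stringsAsFactors = FALSE)
}

# fixed hotspot positions (and alleles) per driver gene: recurrent across
# patients, distinct between the two foci of one patient
driver_hotspots <- function(gene, genes) {
  gi <- genes[genes$gene == gene, ]
  data.frame(chrom = gi$contig, pos = gi$start + c(10000L, 20000L, 30000L),
             ref = c("C", "G", "A"), alt = c("T", "A", "G"),
             stringsAsFactors = FALSE)
}

# make every catalog row's (chrom,pos,ref,alt) key unique; driver and
# planted-LOH rows keep their positions (their keys are controlled), other
# duplicates are re-drawn within their gene
resolve_duplicate_keys <- function(v, genes) {
  for (it in 1:100) {
    keys <- variant_key(v$chrom, v$pos, v$ref, v$alt)
    dup <- which(duplicated(keys))
    if (length(dup) == 0) return(v)
    for (i in dup) {
      if (v$is_driver[i] || v$is_planted_loh[i]) {
        v$pos[i] <- v$pos[i] + 1L
      } else {
        gi <- genes[genes$gene == v$gene[i], ][1, ]
        v$pos[i] <- as.integer(round(runif(1, gi$start, gi$end)))
      }
    }
  }
  stop_input("resolve_duplicate_keys: could not make variant keys unique")
}

#' Simulate one paired-foci patient
#'
#' Generates somatic variant call sets for both tumor foci, read evidence
#' for the three samples at every called site, copy-number/BAF segments,
#' LOH regions, SV breakpoints, annotated germline variants, and
#' peptide-MHC affinity records, together with a ground-truth record.
#'
#' The shared trunk size `s` solves `s / (2n - s) = target`: rounded down
#' for MC entries and up for ME entries so realized fractions stay inside
#' their origin-model bands. ME patients receive a trunk clone present in
#' both foci plus private branch variants; MC patients receive two
#' independent variant sets with a small shared background at the target
#' fraction. Every truth-shared variant is guaranteed at least one
#' alternative read in both foci; truth-unique variants have zero
#' alternative reads in the partner focus unless deliberately planted
#' inside a partner LOH region.
#'
#' @param entry normalized per-patient config entry (see
#'   [load_cohort_config()]).
#' @param genome,genes,categories toy-genome resources.
#' @param tumor_depth,normal_depth mean sequencing depths.
#' @param hq_min_alt minimum alt reads for the high-quality support flag.
#' @param drivers data.frame `gene`, `prob`: per-focus planting
#'   probability of recurrent driver hotspot mutations.
#' @param loh_contig contig reserved for LOH regions.
#' @return patient bundle: `variants` (per-focus call sets, incl. a few
#'   synonymous calls excluded from the sharing analysis set), `evidence`,
#'   `segments`, `svs`, `germline`, `affinity`, `samples`, and `truth`.
#' @export
simulate_patient <- function(entry, genome = toy_genome(),
                             genes = load_gene_table(),
                             categories = load_gene_categories(),
                             tumor_depth = 50, normal_depth = 30,
                             hq_min_alt = 3L, drivers = default_drivers(),
                             loh_contig = "chr8") {
  with_seed(entry$seed, {
    pid <- entry$id
    mc <- entry$origin_model == "MC"
    n <- entry$n_somatic_per_focus
    f_target <- entry$target_shared_snv_fraction
    if (f_target > 0 && n == 0) {
      stop_input("simulate_patient: target fraction > 0 unreachable with ",
                 "n_somatic_per_focus = 0 (", pid, ")")
    }
    s <- if (n == 0) 0L else {
      raw <- 2 * n * f_target / (1 + f_target)
      as.integer(if (mc) floor(raw) else ceiling(raw))
    }
    s <- min(s, n)
    purity <- entry$purity
    somatic_pool <- genes[genes$contig != loh_contig, ]
    loh_genes <- genes[genes$contig == loh_contig, ]

    ## LOH regions and CNV profiles -> segments
    loh <- list(A = make_loh_regions(entry$n_loh_regions[1], genome,
                                     loh_contig),
                B = make_loh_regions(entry$n_loh_regions[2], genome,
                                     loh_contig))
    pool <- rbind(
      data.frame(gene = cnv_gain_pool(), direction = "gain",
                 stringsAsFactors = FALSE),
      data.frame(gene = cnv_loss_pool(), direction = "loss",
                 stringsAsFactors = FALSE))
    n_shared_cnv <- min(entry$n_cnv_shared, min(entry$n_cnv_per_focus))
    sh_idx <- sample.int(nrow(pool), n_shared_cnv)
    rest <- setdiff(seq_len(nrow(pool)), sh_idx)
    na_extra <- entry$n_cnv_per_focus[1] - n_shared_cnv
    nb_extra <- entry$n_cnv_per_focus[2] - n_shared_cnv
    if (na_extra + nb_extra > length(rest)) {
      stop_input("simulate_patient: CNV gene pool too small for the ",
                 "requested per-focus profiles (", pid, ")")
    }
    extra <- sample(rest, na_extra + nb_extra)
    cnv <- list(
      A = pool[c(sh_idx, extra[seq_len(na_extra)]), , drop = FALSE],
      B = pool[c(sh_idx, extra[na_extra + seq_len(nb_extra)]), ,
               drop = FALSE])
    segments <- lapply(c(A = "A", B = "B"), function(fc) {
      make_segments(cnv[[fc]], loh[[fc]], genes)
    })

    ## somatic call sets
    shared <- random_somatic(s, somatic_pool)
    priv <- list(A = random_somatic(n - s, somatic_pool),
                 B = random_somatic(n - s, somatic_pool))
    syn <- list(A = random_somatic(entry$n_synonymous_per_focus,
                                   somatic_pool, indel_frac = 0,
                                   consequence = "synonymous"),
                B = random_somatic(entry$n_synonymous_per_focus,
                                   somatic_pool, indel_frac = 0,
                                   consequence = "synonymous"))
    # plant recurrent driver hotspots (distinct hotspot per focus)
    for (d in seq_len(nrow(drivers))) {
      hs <- driver_hotspots(drivers$gene[d], genes)
      pick <- sample.int(nrow(hs), 2)
      for (i in 1:2) {
        fc <- c("A", "B")[i]
        if (runif(1) <= drivers$prob[d] && nrow(priv[[fc]]) >= d) {
          priv[[fc]][d, c("chrom", "pos", "ref", "alt")] <-
            hs[pick[i], c("chrom", "pos", "ref", "alt")]
          priv[[fc]]$gene[d] <- drivers$gene[d]
          priv[[fc]]$region[d] <- "exonic"
          priv[[fc]]$consequence[d] <- "nonsynonymous"
          priv[[fc]]$sift[d] <- 0.01
          priv[[fc]]$polyphen[d] <- 0.99
          priv[[fc]]$is_driver[d] <- TRUE
        }
      }
    }
    # plant partner-unique variants inside the partner focus's LOH regions
    n_drv <- nrow(drivers)
    for (fc in c("A", "B")) {
      partner <- if (fc == "A") "B" else "A"
      reg <- loh[[partner]]
      k <- min(entry$n_loh_planted, max(nrow(priv[[fc]]) - n_drv, 0))
      if (k > 0 && nrow(reg) > 0 && nrow(loh_genes) > 0) {
        rows <- n_drv + seq_len(k)
        r <- reg[1 + (seq_len(k) - 1) %% nrow(reg), ]
        pos <- as.integer(round(runif(k, r$start + 1, r$end)))
        priv[[fc]][rows, "chrom"] <- r$contig
        priv[[fc]][rows, "pos"] <- pos
        priv[[fc]][rows, "gene"] <-
          loh_genes$gene[sample.int(nrow(loh_genes), k, replace = TRUE)]
        priv[[fc]][rows, "region"] <- "exonic"
        priv[[fc]][rows, "consequence"] <- "nonsynonymous"
        priv[[fc]][rows, "is_planted_loh"] <- TRUE
      }
    }

    # resolve key collisions on the catalog of distinct variants; shared
    # rows appear once here and are then copied into both focus call sets
    n_cat <- c(nrow(shared), nrow(priv$A), nrow(priv$B),
               nrow(syn$A), nrow(syn$B))
    catalog <- resolve_duplicate_keys(
      rbind(shared, priv$A, priv$B, syn$A, syn$B), genes)
    grp <- rep(seq_along(n_cat), n_cat)
    shared <- catalog[grp == 1, , drop = FALSE]
    priv$A <- catalog[grp == 2, , drop = FALSE]
    priv$B <- catalog[grp == 3, , drop = FALSE]
    syn$A <- catalog[grp == 4, , drop = FALSE]
    syn$B <- catalog[grp == 5, , drop = FALSE]

    assemble_focus <- function(fc, k_clusters) {
      ccfs <- ccf_menu(k_clusters)
      sh <- shared
      pv <- priv[[fc]]
      sy <- syn[[fc]]
      cl_sh <- rep(1L, nrow(sh))
      cl_pv <- if (k_clusters == 1) rep(1L, nrow(pv)) else
        sample.int(k_clusters, nrow(pv), replace = TRUE,
                   prob = cluster_probs(k_clusters))
      cl_pv[pv$is_driver] <- 1L
      cl_sy <- if (k_clusters == 1) rep(1L, nrow(sy)) else
        sample.int(k_clusters, nrow(sy), replace = TRUE,
                   prob = cluster_probs(k_clusters))
      v <- rbind(sh, pv, sy)
      v$cluster <- c(cl_sh, cl_pv, cl_sy)
      v$ccf <- ccfs[v$cluster]
      v$shared_truth <- c(rep(TRUE, nrow(sh)), rep(FALSE, nrow(pv)),
                          rep(FALSE, nrow(sy)))
      v$focus <- fc
      v
    }
    va <- assemble_focus("A", entry$n_clusters_per_focus[1])
    vb <- assemble_focus("B", entry$n_clusters_per_focus[2])
    variants <- rbind(va, vb)
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
    variants$variant_class <- "somatic"
    variants$patient_id <- pid

    ## read evidence at every distinct site
    keys <- unique(variants$key)
    site <- variants[match(keys, variants$key),
                     c("chrom", "pos", "ref", "alt", "key")]
    idx_a <- match(keys, variants$key[variants$focus == "A"])
    idx_b <- match(keys, variants$key[variants$focus == "B"])
    va_all <- variants[variants$focus == "A", ]
    vb_all <- variants[variants$focus == "B", ]
    ccf_a <- va_all$ccf[idx_a]
    ccf_b <- vb_all$ccf[idx_b]
    vaf_for <- function(fc, ccf) {
      seg <- segments[[fc]]
      si <- segment_index_at(site$chrom, site$pos, seg)
      cn <- ifelse(is.na(si), 2L, seg$copy_number[si])
      ifelse(is.na(ccf), 0,
             ccf * purity / (purity * cn + (1 - purity) * 2))
    }
    draw_sample <- function(vaf, present, mean_depth, force_alt) {
      m <- length(vaf)
      depth <- pmax(rpois(m, mean_depth), 1L)
      alt <- rbinom(m, depth, ifelse(present, vaf, 0))
      if (force_alt) alt <- ifelse(present, pmax(alt, 1L), alt)
      list(depth = depth, alt = alt)
    }
    ev_a <- draw_sample(vaf_for("A", ccf_a), !is.na(idx_a), tumor_depth,
                        force_alt = TRUE)
    ev_b <- draw_sample(vaf_for("B", ccf_b), !is.na(idx_b), tumor_depth,
                        force_alt = TRUE)
    ev_n <- draw_sample(rep(0, length(keys)), rep(FALSE, length(keys)),
                        normal_depth, force_alt = FALSE)
    samples <- list(a = paste0(pid, "A"), b = paste0(pid, "B"),
                    normal = paste0(pid, "N"))
    one_ev <- function(sample_id, ev) {
      data.frame(chrom = site$chrom, pos = site$pos, ref = site$ref,
                 alt = site$alt, sample_id = sample_id,
                 ref_depth = ev$depth - ev$alt, alt_depth = ev$alt,
                 hq_flag = ev$alt >= hq_min_alt, stringsAsFactors = FALSE)
    }
    evidence <- rbind(one_ev(samples$a, ev_a), one_ev(samples$b, ev_b),
                      one_ev(samples$normal, ev_n))

    ## structural variants
    make_svs <- function(k) {
      if (k == 0) {
        return(data.frame(chrom1 = character(0), pos1 = integer(0),
                          chrom2 = character(0), pos2 = integer(0),
                          svtype = character(0), orientation = character(0),
                          stringsAsFactors = FALSE))
      }
      type <- sample(c("DEL", "DUP", "INV", "TRA"), k, replace = TRUE,
                     prob = c(0.4, 0.25, 0.2, 0.15))
      c1 <- sample(names(genome), k, replace = TRUE)
      p1 <- as.integer(round(runif(k, 1e5, 39e6)))
      c2 <- ifelse(type == "TRA",
                   sample(names(genome), k, replace = TRUE), c1)
      p2 <- ifelse(type == "TRA",
                   as.integer(round(runif(k, 1e5, 39e6))),
                   p1 + as.integer(round(runif(k, 1e3, 5e5))))
      data.frame(chrom1 = c1, pos1 = p1, chrom2 = c2, pos2 = as.integer(p2),
                 svtype = type,
                 orientation = sample(c("+-", "-+", "++", "--"), k,
                                      replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    sv_sh <- make_svs(min(entry$n_sv_shared, min(entry$n_sv_per_focus)))
    sv_a <- rbind(sv_sh, make_svs(entry$n_sv_per_focus[1] - nrow(sv_sh)))
    sv_b <- rbind(sv_sh, make_svs(entry$n_sv_per_focus[2] - nrow(sv_sh)))
    sv_a$focus <- rep("A", nrow(sv_a))
    sv_b$focus <- rep("B", nrow(sv_b))
    svs <- rbind(sv_a, sv_b)

    ## germline variants
    germline <- simulate_germline(entry, genes, categories, loh_contig)
    germline$patient_id <- pid

    ## peptide-MHC affinities
    affinity <- simulate_affinity(variants, samples, pid)

    truth <- list(
      patient_id = pid, origin_model = entry$origin_model,
      purity = purity, seed = entry$seed,
      target_shared_snv_fraction = f_target,
      n_shared_truth = s,
      shared_keys = unique(variants$key[variants$shared_truth]),
      variant_truth = variants[, c("key", "focus", "cluster", "ccf",
                                   "shared_truth", "is_driver",
                                   "is_planted_loh")],
      cluster_ccfs = list(A = ccf_menu(entry$n_clusters_per_focus[1]),
                          B = ccf_menu(entry$n_clusters_per_focus[2])),
      loh_regions = loh,
      cnv_truth = list(A = cnv$A, B = cnv$B),
      n_sv_shared = nrow(sv_sh),
      germline_counts = list(
        total = entry$germline$n_total,
        immune = entry$germline$n_immune))

    list(patient_id = pid, origin_model = entry$origin_model,
         purity = purity, seed = entry$seed, samples = samples,
         variants = variants, evidence = evidence,
         segments = do.call(rbind, lapply(c("A", "B"), function(fc) {
           cbind(segments[[fc]], focus = fc, stringsAsFactors = FALSE)
         })),
         svs = svs, germline = germline, affinity = affinity,
         truth = truth)
  })
}

# germline variants: a retained core whose per-category counts match the
# config exactly, plus noise sets engineered to fail each filter rule
simulate_germline <- function(entry, genes, categories, loh_contig) {
  gl <- entry$germline
  noise <- entry$germline_noise
  n_immune <- gl$n_immune
  n_rest <- gl$n_total - n_immune
  if (n_rest < 0) {
    stop_input("simulate_germline: n_immune exceeds n_total (", entry$id, ")")
  }
  other_cats <- c("cell_cycle", "proliferation", "dna_repair", "adhesion",
                  "other")
  rest_counts <- as.vector(rmultinom(1, n_rest, prob = rep(1 / 5, 5)))
  cat_genes <- split(categories$gene, categories$category)
  cat_genes$other <- setdiff(genes$gene[genes$contig != loh_contig],
                             categories$gene)

  draw <- function(k, category, depth_kind = "good", af_kind = "mixed",
                   region_kind = "coding", repeat_flag = FALSE) {
    if (k == 0) return(NULL)
    gene <- sample(cat_genes[[category]], k, replace = TRUE)
    gi <- genes[match(gene, genes$gene), ]
    pos <- as.integer(round(runif(k, gi$start, gi$end)))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                  character(1))
    depth <- switch(depth_kind,
                    good = pmax(rpois(k, 30), 10L),
                    low = sample(3:9, k, replace = TRUE))
    cosmic <- rbinom(k, 1, 0.1) == 1
    af <- numeric(k)
    if (af_kind == "mixed") {
      u <- runif(k)
      af[u >= 0.7 & u < 0.9] <- runif(sum(u >= 0.7 & u < 0.9), 0, 0.001)
      hi <- u >= 0.9
      af[hi] <- runif(sum(hi), 0.002, 0.05)
      cosmic[hi] <- TRUE            # COSMIC rescue keeps these
    } else if (af_kind == "high") {
      af <- runif(k, 0.01, 0.5)
      cosmic <- rep(FALSE, k)
    }
    if (region_kind == "coding") {
      region <- sample(c("exonic", "splicing"), k, replace = TRUE,
                       prob = c(0.9, 0.1))
      consequence <- sample(c("nonsynonymous", "stopgain", "frameshift"),
                            k, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    } else {
      region <- sample(c("intronic", "intergenic", "ncRNA", "UTR",
                         "exonic"), k, replace = TRUE,
                       prob = c(0.35, 0.25, 0.15, 0.1, 0.15))
      consequence <- ifelse(region == "exonic", "synonymous",
                            "nonsynonymous")
    }
    data.frame(chrom = gi$contig, pos = pos, ref = ref, alt = alt,
               gene = gene, region = region, consequence = consequence,
               depth = depth, af_dbsnp = NA_real_, af_1kg = af,
               af_exac = NA_real_, cosmic_flag = cosmic,
               repeat_flag = repeat_flag, sift = NA_real_,
               polyphen = NA_real_, category_truth = category,
               retained_truth = depth_kind == "good" &&
                 af_kind == "mixed" && region_kind == "coding" &&
                 !repeat_flag,
               stringsAsFactors = FALSE)
  }
  core <- rbind(
    draw(n_immune, "immune"),
    do.call(rbind, lapply(seq_along(other_cats), function(i) {
      draw(rest_counts[i], other_cats[i])
    })))
  noise_rows <- rbind(
    draw(noise$low_depth, "other", depth_kind = "low"),
    draw(noise$high_af, "other", af_kind = "high"),
    draw(noise$region, "other", region_kind = "noncoding"),
    draw(noise$repeats, "other", repeat_flag = TRUE))
  out <- rbind(core, noise_rows)
  out$variant_class <- "germline"
  rownames(out) <- NULL
  out
}

# peptide-MHC affinity records: planted driver mutations are forced below
# 500 nM and below wild type (guaranteed nonempty candidate set); other
# sampled mutations get independent log-uniform affinities in [10, 5000]
simulate_affinity <- function(variants, samples, pid) {
  alleles <- c("HLA-A*02:01", "HLA-A*11:01", "HLA-B*40:01", "HLA-C*07:02")
  rows <- list()
  for (fc in c("A", "B")) {
    v <- variants[variants$focus == fc &
                    variants$consequence != "synonymous", , drop = FALSE]
    drv <- v[v$is_driver, , drop = FALSE]
    rest <- v[!v$is_driver, , drop = FALSE]
    pick <- rest[sample.int(nrow(rest), min(20, nrow(rest))), ,
                 drop = FALSE]
    sel <- rbind(drv, pick)
    if (nrow(sel) == 0) next
    k <- nrow(sel)
    n_pep <- sample(1:2, k, replace = TRUE)
    for (i in seq_len(k)) {
      for (j in seq_len(n_pep[i])) {
        mut_aff <- if (sel$is_driver[i]) runif(1, 50, 400) else
          exp(runif(1, log(10), log(5000)))
        wt_aff <- if (sel$is_driver[i]) mut_aff + runif(1, 200, 4600) else
          exp(runif(1, log(10), log(5000)))
        rows[[length(rows) + 1]] <- data.frame(
          mutation_id = paste(sel$gene[i], sel$chrom[i], sel$pos[i],
                              sel$ref[i], sel$alt[i], sep = "_"),
          focus_id = paste0(pid, "_", fc),
          hla_allele = sample(alleles, 1),
          peptide = random_aa_peptide(sample(9:11, 1)),
          mut_affinity_nM = round(mut_aff, 1),
          wt_affinity_nM = round(wt_aff, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mutation_id = character(0), focus_id = character(0),
                      hla_allele = character(0), peptide = character(0),
                      mut_affinity_nM = numeric(0),
                      wt_affinity_nM = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate and write a cohort
#'
#' Runs [simulate_patient()] for every entry of the config, writes one
#' directory per patient plus a cohort `manifest.json` (files, seeds and
#' truth records). Deterministic given the config's seeds: rerunning with
#' the same config yields byte-identical outputs.
#'
#' @param config normalized cohort config ([load_cohort_config()] /
#'   [default_cohort_config()]).
#' @param out_dir cohort output directory.
#' @param ... passed to [simulate_patient()] (resources, depths).
#' @return invisibly, a list with `bundles` (in-memory patient bundles),
#'   `manifest`, and `dir`.
#' @export
simulate_cohort <- function(config, out_dir, ...) {
  ids <- vapply(config$patients, function(p) as.character(p$id),
                character(1))
  if (anyDuplicated(ids)) {
    stop_input("simulate_cohort: duplicate patient ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- toy_genome()
  bundles <- lapply(config$patients, function(entry) {
    simulate_patient(entry,
                     tumor_depth = config$depth$tumor_mean,
                     normal_depth = config$depth$normal_mean,
                     hq_min_alt = config$hq_min_alt, ...)
  })
  patients <- lapply(bundles, function(b) {
    files <- write_patient(b, file.path(out_dir, b$patient_id),
                           genome = genome)
    list(id = b$patient_id, seed = b$seed,
         origin_model = b$origin_model, purity = b$purity,
         files = as.list(files),
         truth = list(
           origin_model = b$truth$origin_model,
           target_shared_snv_fraction = b$truth$target_shared_snv_fraction,
           n_shared_truth = b$truth$n_shared_truth,
           n_sv_shared = b$truth$n_sv_shared,
           cluster_ccfs = b$truth$cluster_ccfs,
           germline_counts = b$truth$germline_counts))
  })
  manifest <- list(n_patients = length(patients),
                   base_seed = config$base_seed,
                   patients = patients)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bundles = bundles, manifest = manifest, dir = out_dir))
}
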