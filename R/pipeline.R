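# Cohort pipeline: simulate -> share -> classify -> germline -> clusters
# -> cnv -> neo -> report. Every stage is a plain function over patient
# bundles so the numbered analysis scripts, the tests and the acceptance
# script all drive the same code.

#' Read a simulated cohort directory
#'
#' @param dir cohort directory written by [simulate_cohort()].
#' @return list with `patients` (bundles keyed by id) and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  patients <- lapply(manifest$patients, function(p) {
    b <- read_patient(file.path(dir, p$id), patient_id = p$id)
    b$purity <- p$purity
    b$seed <- p$seed
    b
  })
  names(patients) <- vapply(manifest$patients, function(p) p$id,
                            character(1))
  list(patients = patients, manifest = manifest)
}

#' Sharing stage: per-patient shared fractions on all three channels
#'
#' @param bundle one patient bundle.
#' @param genes gene interval table.
#' @param sv_tol SV breakpoint tolerance (bp).
#' @param min_depth coverage gate.
#' @return list with the `sharing_summary` object and a one-row
#'   data.frame `fractions`.
#' @export
share_patient <- function(bundle, genes = load_gene_table(), sv_tol = 10L,
                          min_depth = 10L) {
  v <- bundle$variants
  seg <- bundle$segments
  ss <- sharing_summary(
    variants_a = v[v$focus == "A", , drop = FALSE],
    variants_b = v[v$focus == "B", , drop = FALSE],
    evidence = bundle$evidence,
    loh_a = seg[seg$focus == "A", , drop = FALSE],
    loh_b = seg[seg$focus == "B", , drop = FALSE],
    samples = bundle$samples, patient_id = bundle$patient_id,
    min_depth = min_depth)
  cg <- cnv_gene_overlap(seg[seg$focus == "A", , drop = FALSE],
                         seg[seg$focus == "B", , drop = FALSE], genes)
  sv <- sv_overlap(bundle$svs[bundle$svs$focus == "A", , drop = FALSE],
                   bundle$svs[bundle$svs$focus == "B", , drop = FALSE],
                   tol = sv_tol)
  fractions <- data.frame(
    patient_id = bundle$patient_id,
    n_shared = ss$n_shared, n_unique_a = ss$n_unique_a,
    n_unique_b = ss$n_unique_b, n_excluded_loh = ss$n_excluded_loh,
    n_failed_coverage = ss$n_failed_coverage,
    shared_fraction_snv = ss$shared_fraction_snv,
    shared_fraction_cnv_genes = cg$fraction,
    shared_fraction_sv = sv$fraction,
    stringsAsFactors = FALSE)
  list(summary = ss, cnv = cg, sv = sv, fractions = fractions)
}

#' Clonal-structure stage for one focus
#'
#' Restricts to the nonsynonymous exonic/splicing analysis set, estimates
#' per-mutation CCFs from the focus's own read evidence (copy number from
#' the focus segments, multiplicity inferred inside gains), fits the
#' binomial-mixture clustering, and selects key mutations.
#'
#' @param bundle patient bundle.
#' @param focus "A" or "B".
#' @param k_max,restarts,seed clustering controls.
#' @return list with `clusters` ([fit_clusters()]), `variants` (analysis
#'   set with `is_key`), `key_mutations`, `monoclonal`.
#' @export
cluster_focus <- function(bundle, focus, k_max = 6L, restarts = 50L,
                          seed = 1L) {
  v <- bundle$variants
  v <- v[v$focus == focus & v$region %in% c("exonic", "splicing") &
           v$consequence != "synonymous", , drop = FALSE]
  sample_id <- bundle$samples[[tolower(focus)]]
  ev <- bundle$evidence[bundle$evidence$sample_id == sample_id, ,
                        drop = FALSE]
  i <- match(variant_key(v$chrom, v$pos, v$ref, v$alt),
             variant_key(ev$chrom, ev$pos, ev$ref, ev$alt))
  alt <- ev$alt_depth[i]
  depth <- ev$ref_depth[i] + ev$alt_depth[i]
  seg <- bundle$segments[bundle$segments$focus == focus, , drop = FALSE]
  si <- segment_index_at(v$chrom, v$pos, seg)
  cn <- ifelse(is.na(si), 2L, seg$copy_number[si])
  in_gain <- !is.na(si) & seg$status[si] == "gain"
  mult <- infer_multiplicity(alt / depth, cn, bundle$purity, in_gain)
  cl <- fit_clusters(alt, depth, copy_number = cn, multiplicity = mult,
                     purity = bundle$purity, k_max = k_max,
                     restarts = restarts, seed = seed)
  key <- select_key_mutations(cl, v)
  v$is_key <- variant_key(v$chrom, v$pos, v$ref, v$alt) %in%
    variant_key(key$chrom, key$pos, key$ref, key$alt)
  list(clusters = cl, variants = v, key_mutations = key,
       monoclonal = cl$K == 1L)
}

#' Run the full cohort pipeline
#'
#' Simulates (or reuses) a cohort on disk, reads it back, and runs the
#' sharing, origin-classification, germline, clonal-structure, CNV
#' recurrence and neoantigen stages, writing per-stage TSVs and a cohort
#' `report.json` under `out_dir`. Deterministic given the config seeds.
#'
#' @param config cohort config; default the packaged 10-patient fixture.
#' @param out_dir output directory (cohort files under `cohort/`,
#'   stage outputs under `results/`).
#' @param seed optional base-seed override for the whole run.
#' @param origin_threshold MC/ME threshold on the shared SNV fraction.
#' @param sv_tol SV breakpoint tolerance (bp).
#' @param min_foci recurrence cutoff for CNV genes and neoantigens.
#' @param k_max,restarts clustering controls.
#' @param stages character subset of
#'   `c("share", "classify", "germline", "clusters", "cnv", "neo")`;
#'   stages build on earlier ones, and later stages needing a skipped one
#'   are skipped too (recorded in the report).
#' @return the cohort report (list), invisibly written as JSON.
#' @export
run_pipeline <- function(config = default_cohort_config(),
                         out_dir = tempfile("mecclone_run_"),
                         seed = NULL,
                         origin_threshold = 0.10, sv_tol = 10L,
                         min_foci = 3L, k_max = 6L, restarts = 50L,
                         stages = c("share", "classify", "germline",
                                    "clusters", "cnv", "neo")) {
  if (!is.null(seed)) {
    config <- default_rebase(config, seed)
  }
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- load_gene_table()
  categories <- load_gene_categories()
  cgc <- load_cgc_genes()

  sim <- simulate_cohort(config, file.path(out_dir, "cohort"))
  cohort <- read_cohort(sim$dir)
  patients <- cohort$patients
  report <- list(n_patients = length(patients),
                 base_seed = config$base_seed,
                 thresholds = list(origin = origin_threshold,
                                   sv_tol = sv_tol, min_foci = min_foci))
  skipped <- setdiff(c("share", "classify", "germline", "clusters",
                       "cnv", "neo"), stages)
  report$skipped_stages <- as.list(skipped)

  shares <- NULL
  if ("share" %in% stages) {
    shares <- lapply(patients, share_patient, genes = genes,
                     sv_tol = sv_tol)
    fractions <- do.call(rbind, lapply(shares, `[[`, "fractions"))
    rownames(fractions) <- NULL
    write_tsv(fractions, file.path(res_dir, "sharing.tsv"))
    report$sharing <- fractions
  }

  calls <- NULL
  if ("classify" %in% stages && !is.null(shares)) {
    calls <- do.call(rbind, lapply(shares, function(s) {
      classify_origin(s$summary, threshold = origin_threshold)
    }))
    rownames(calls) <- NULL
    rep0 <- cohort_report(calls, report$sharing)
    write_tsv(rep0$table, file.path(res_dir, "origin_calls.tsv"))
    report$origin <- list(table = rep0$table,
                          p_values = as.list(rep0$p_values),
                          n_mc = sum(rep0$table$label == "MC"),
                          n_me = sum(rep0$table$label == "ME"))
  }

  if ("germline" %in% stages && !is.null(calls)) {
    profiles <- lapply(patients, function(b) {
      filter_germline(b$germline, categories = categories,
                      patient_id = b$patient_id)
    })
    label_of <- setNames(calls$label, calls$patient_id)
    mc <- profiles[label_of[names(profiles)] == "MC"]
    me <- profiles[label_of[names(profiles)] == "ME"]
    counts <- do.call(rbind, lapply(profiles, function(p) {
      data.frame(patient_id = p$patient_id, total = nrow(p$retained),
                 t(p$category_counts), stringsAsFactors = FALSE)
    }))
    rownames(counts) <- NULL
    write_tsv(counts, file.path(res_dir, "germline_counts.tsv"))
    cgc_hits <- sort(unique(unlist(lapply(profiles, function(p) {
      intersect_cgc(p, cgc)$genes
    }))))
    enrich <- lapply(list(MC = mc, ME = me), function(group) {
      gg <- unique(unlist(lapply(group, function(p) p$retained$gene)))
      enrich_sets(gg, categories, unique(genes$gene))
    })
    report$germline <- list(
      counts = counts,
      p_immune = compare_category(mc, me, "immune")$p_value,
      p_total = compare_category(mc, me, "total")$p_value,
      cgc_genes = cgc_hits,
      enrichment = enrich)
  }

  if ("clusters" %in% stages && !is.null(shares)) {
    foci <- list()
    for (pid in names(patients)) {
      for (fc in c("A", "B")) {
        foci[[paste0(pid, "_", fc)]] <-
          cluster_focus(patients[[pid]], fc, k_max = k_max,
                        restarts = restarts,
                        seed = derive_seed(config$base_seed,
                                           match(pid, names(patients)),
                                           salt = match(fc, c("A", "B"))))
      }
    }
    cluster_tab <- do.call(rbind, lapply(names(foci), function(id) {
      cl <- foci[[id]]$clusters
      data.frame(focus_id = id, K = cl$K,
                 means = paste(round(cl$means, 3), collapse = ","),
                 monoclonal = foci[[id]]$monoclonal,
                 n_key = nrow(foci[[id]]$key_mutations),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(cluster_tab, file.path(res_dir, "clusters.tsv"))
    drivers <- driver_recurrence(lapply(foci, function(f) {
      f$variants[, c("gene", "is_key")]
    }))
    write_tsv(drivers, file.path(res_dir, "driver_recurrence.tsv"))
    report$clusters <- list(table = cluster_tab,
                            driver_recurrence = drivers)
  }

  if ("cnv" %in% stages) {
    seg_by_focus <- list()
    for (pid in names(patients)) {
      for (fc in c("A", "B")) {
        seg <- patients[[pid]]$segments
        seg_by_focus[[paste0(pid, "_", fc)]] <-
          seg[seg$focus == fc, , drop = FALSE]
      }
    }
    rec <- recurrence_matrix(seg_by_focus, genes, min_foci = min_foci)
    write_tsv(rec$counts, file.path(res_dir, "cnv_recurrence.tsv"))
    report$cnv <- list(recurrent = rec$recurrent,
                       n_recurrent = nrow(rec$recurrent))
  }

  if ("neo" %in% stages) {
    aff <- do.call(rbind, lapply(patients, `[[`, "affinity"))
    cand <- filter_candidates(aff)
    rec <- recurrent_neoantigens(cand, min_foci = min_foci)
    write_tsv(rec$counts, file.path(res_dir, "neoantigen_recurrence.tsv"))
    report$neoantigen <- list(n_candidates = nrow(cand),
                              recurrent = rec$recurrent)
  }

  jsonlite::write_json(report, file.path(res_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}

# re-derive all per-patient seeds of a config from a new base seed
default_rebase <- function(config, base_seed) {
  config$base_seed <- as.integer(base_seed)
  config$patients <- lapply(seq_along(config$patients), function(i) {
    e <- config$patients[[i]]
    e$seed <- derive_seed(base_seed, i)
    e
  })
  config
}
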