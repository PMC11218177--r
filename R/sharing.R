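# Shared / unique / excluded classification of somatic variants between
# the two tumor foci of one patient, with read-level rescue:
#   rule (i)   partner sample has >= 1 alternative-allele read  -> shared
#   rule (iii) would-be-unique site lies in a partner LOH region -> excluded
#   rule (ii)  partner sample shows only reference bases         -> unique
# plus a coverage gate (>= 10 reads in tumor and matched normal) and a
# high-quality alt-support requirement in the calling focus.

#' Coverage gate for somatic variant comparison
#'
#' A site is adequately covered for the shared/unique comparison when the
#' total read depth is at least `min_depth` in the calling tumor sample
#' *and* in the matched normal. The bound is inclusive.
#'
#' @param evidence_tumor data.frame with `ref_depth`, `alt_depth` for the
#'   calling tumor sample, one row per site.
#' @param evidence_normal matching data.frame for the matched normal.
#' @param min_depth minimum total depth (default 10).
#' @return logical vector, `TRUE` where the gate passes.
#' @export
coverage_gate <- function(evidence_tumor, evidence_normal, min_depth = 10L) {
  dt <- evidence_tumor$ref_depth + evidence_tumor$alt_depth
  dn <- evidence_normal$ref_depth + evidence_normal$alt_depth
  if (length(dt) != length(dn)) {
    stop_input("coverage_gate: tumor and normal evidence differ in length")
  }
  if (any(c(evidence_tumor$ref_depth, evidence_tumor$alt_depth,
            evidence_normal$ref_depth, evidence_normal$alt_depth) < 0)) {
    stop_input("coverage_gate: negative read depths")
  }
  dt >= min_depth & dn >= min_depth
}

#' Classify somatic sites against the partner focus
#'
#' Applies the three-rule sharing classification to variants called in one
#' focus, using the partner focus's read evidence at the same positions.
#' Precedence: a single partner alternative-allele read makes the site
#' shared; otherwise a site inside a partner LOH segment is excluded
#' (one cannot tell a truly unique variant from one lost with the allele);
#' otherwise the site is unique to the calling focus.
#'
#' Callers are expected to have applied [coverage_gate()] and the
#' high-quality alt-support requirement first.
#'
#' @param variants data.frame of variants called in the focus
#'   (columns `chrom`, `pos`, `ref`, `alt`).
#' @param partner_evidence data.frame aligned row-for-row with `variants`,
#'   holding the partner focus's `ref_depth` and `alt_depth` at each site.
#' @param partner_loh data.frame of the partner focus's LOH segments
#'   (columns `contig`, `start`, `end`, 0-based half-open), or `NULL`.
#' @return character vector: "shared", "unique" or "excluded_loh".
#' @export
classify_site <- function(variants, partner_evidence, partner_loh = NULL) {
  if (nrow(variants) != nrow(partner_evidence)) {
    stop_input("classify_site: partner evidence must align with variants ",
               "(missing partner evidence at some sites?)")
  }
  if (anyNA(partner_evidence$alt_depth)) {
    stop_input("classify_site: missing partner evidence at some sites")
  }
  in_loh <- points_in_segments(variants$chrom, variants$pos, partner_loh)
  ifelse(partner_evidence$alt_depth >= 1, "shared",
         ifelse(in_loh, "excluded_loh", "unique"))
}

# evidence rows for a set of variant keys in one sample, aligned to `keys`;
# NA-filled rows where evidence is absent
evidence_for <- function(evidence, keys, sample_id) {
  ev <- evidence[evidence$sample_id == sample_id, , drop = FALSE]
  i <- match(keys, variant_key(ev$chrom, ev$pos, ev$ref, ev$alt))
  ev[i, c("ref_depth", "alt_depth", "hq_flag")]
}

#' Per-patient sharing summary for the somatic SNV/indel channel
#'
#' Restricts both foci's somatic calls to nonsynonymous exonic/splicing
#' SNVs and indels, classifies every call against the partner focus in both
#' directions, de-duplicates by `(chrom, pos, ref, alt)`, and reports the
#' category counts and the shared fraction
#' `n_shared / (n_shared + n_unique_a + n_unique_b)` (a Jaccard-style
#' fraction over the union of analyzable variants). Sites excluded by the
#' LOH rule or failing the coverage/high-quality gate appear in neither
#' numerator nor denominator.
#'
#' A variant called in both foci is shared by construction (each call
#' attests alternative reads in its own focus).
#'
#' @param variants_a,variants_b somatic calls of focus A / focus B
#'   (`chrom`, `pos`, `ref`, `alt`, `region`, `consequence`).
#' @param evidence long per-site read-evidence table (`chrom`, `pos`,
#'   `ref`, `alt`, `sample_id`, `ref_depth`, `alt_depth`, `hq_flag`)
#'   covering both tumor samples and the matched normal at every call.
#' @param loh_a,loh_b segment tables of focus A / B; only rows with
#'   `loh == TRUE` are used for the exclusion rule.
#' @param samples named list with `a`, `b`, `normal` sample ids as used in
#'   `evidence`.
#' @param patient_id patient label carried into the summary.
#' @param min_depth coverage gate (default 10 reads, inclusive).
#' @return object of class `sharing_summary`: a list with the category
#'   counts (`n_shared`, `n_unique_a`, `n_unique_b`, `n_excluded_loh`,
#'   `n_failed_coverage`), `n_total`, `shared_fraction_snv`,
#'   `empty_denominator` flag, and a per-variant `detail` data.frame.
#' @export
sharing_summary <- function(variants_a, variants_b, evidence,
                            loh_a = NULL, loh_b = NULL,
                            samples, patient_id = "patient",
                            min_depth = 10L) {
  restrict <- function(v) {
    v[v$region %in% c("exonic", "splicing") &
        v$consequence != "synonymous", , drop = FALSE]
  }
  va <- restrict(variants_a)
  vb <- restrict(variants_b)
  key_a <- variant_key(va$chrom, va$pos, va$ref, va$alt)
  key_b <- variant_key(vb$chrom, vb$pos, vb$ref, vb$alt)
  loh_only <- function(s) {
    if (is.null(s) || nrow(s) == 0) return(NULL)
    s[s$loh %in% TRUE, , drop = FALSE]
  }

  classify_direction <- function(v, keys, own_sample, partner_sample,
                                 partner_loh) {
    if (nrow(v) == 0) {
      return(character(0))
    }
    own <- evidence_for(evidence, keys, own_sample)
    nrm <- evidence_for(evidence, keys, samples$normal)
    partner <- evidence_for(evidence, keys, partner_sample)
    if (anyNA(own$alt_depth) || anyNA(nrm$alt_depth)) {
      stop_input("sharing_summary: missing read evidence for called sites")
    }
    ok <- coverage_gate(own, nrm, min_depth) & own$hq_flag %in% TRUE
    status <- rep("failed_coverage", nrow(v))
    if (any(ok)) {
      status[ok] <- classify_site(v[ok, , drop = FALSE],
                                  partner[ok, , drop = FALSE],
                                  partner_loh)
    }
    status
  }

  st_a <- classify_direction(va, key_a, samples$a, samples$b, loh_only(loh_b))
  st_b <- classify_direction(vb, key_b, samples$b, samples$a, loh_only(loh_a))

  keys <- unique(c(key_a, key_b))
  in_a <- keys %in% key_a
  in_b <- keys %in% key_b
  sa <- st_a[match(keys, key_a)]
  sb <- st_b[match(keys, key_b)]

  combined <- character(length(keys))
  for (i in seq_along(keys)) {
    s <- c(sa[i], sb[i])
    s <- s[!is.na(s)]
    combined[i] <-
      if (any(s == "shared") || (in_a[i] && in_b[i] &&
                                   any(s != "failed_coverage"))) {
        "shared"
      } else if (any(s == "excluded_loh")) {
        "excluded_loh"
      } else if (any(s == "unique")) {
        if (in_a[i]) "unique_a" else "unique_b"
      } else {
        "failed_coverage"
      }
  }

  n_shared <- sum(combined == "shared")
  n_unique_a <- sum(combined == "unique_a")
  n_unique_b <- sum(combined == "unique_b")
  n_excluded <- sum(combined == "excluded_loh")
  n_failed <- sum(combined == "failed_coverage")
  denom <- n_shared + n_unique_a + n_unique_b
  empty <- denom == 0
  if (empty && length(keys) > 0) {
    warning("sharing_summary: empty denominator for patient ", patient_id,
            "; shared fraction reported as 0", call. = FALSE)
  }
  structure(list(
    patient_id = patient_id,
    n_shared = n_shared,
    n_unique_a = n_unique_a,
    n_unique_b = n_unique_b,
    n_excluded_loh = n_excluded,
    n_failed_coverage = n_failed,
    n_total = length(keys),
    shared_fraction_snv = if (empty) 0 else n_shared / denom,
    empty_denominator = empty,
    detail = data.frame(key = keys, status = combined,
                        stringsAsFactors = FALSE)
  ), class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf(
    "Sharing summary for %s: %d shared, %d unique (A) + %d (B), %d LOH-excluded, %d gate-failed; shared fraction %.4f\n",
    x$patient_id, x$n_shared, x$n_unique_a, x$n_unique_b,
    x$n_excluded_loh, x$n_failed_coverage, x$shared_fraction_snv))
  invisible(x)
}

# gene-level CNV status of one focus: non-neutral segments are intersected
# with gene intervals; on a (rare) gain/loss conflict for a gene the
# direction with the larger overlap wins
focus_cnv_genes <- function(segments, genes) {
  seg <- segments[segments$status %in% c("gain", "loss"), , drop = FALSE]
  if (nrow(seg) == 0) {
    return(data.frame(gene = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  lv <- unique(c(genes$contig, seg$contig))
  sg <- GenomicRanges::GRanges(factor(seg$contig, levels = lv),
                               IRanges::IRanges(seg$start + 1, seg$end))
  gg <- GenomicRanges::GRanges(factor(genes$contig, levels = lv),
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gg, sg)
  if (length(hits) == 0) {
    return(data.frame(gene = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gg)[S4Vectors::queryHits(hits)],
    IRanges::ranges(sg)[S4Vectors::subjectHits(hits)]))
  d <- data.frame(gene = genes$gene[S4Vectors::queryHits(hits)],
                  direction = seg$status[S4Vectors::subjectHits(hits)],
                  width = ov, stringsAsFactors = FALSE)
  agg <- aggregate(width ~ gene + direction, data = d, FUN = sum)
  agg <- agg[order(agg$gene, -agg$width), ]
  agg <- agg[!duplicated(agg$gene), ]
  data.frame(gene = agg$gene, direction = agg$direction,
             stringsAsFactors = FALSE)
}

#' Shared copy-number genes between two foci
#'
#' A gene is a CNV gene of a focus when it overlaps at least one
#' non-neutral segment (>= 1 bp overlap); it is shared when it is a CNV
#' gene of both foci with the same direction (gain/gain or loss/loss).
#' The fraction is over the union of CNV genes of the two foci.
#'
#' @param segments_a,segments_b annotated segment tables (with `status`).
#' @param genes gene interval table (`gene`, `contig`, `start`, `end`).
#' @return list with `genes_a`, `genes_b` (per-focus gene/direction),
#'   `shared_genes`, `n_union`, and `fraction`.
#' @export
cnv_gene_overlap <- function(segments_a, segments_b, genes) {
  if (!all(c("gene", "contig", "start", "end") %in% names(genes)) ||
      any(genes$start > genes$end)) {
    stop_input("cnv_gene_overlap: malformed gene interval table")
  }
  ga <- focus_cnv_genes(segments_a, genes)
  gb <- focus_cnv_genes(segments_b, genes)
  union_genes <- union(ga$gene, gb$gene)
  m <- merge(ga, gb, by = "gene", suffixes = c("_a", "_b"))
  shared <- m$gene[m$direction_a == m$direction_b]
  list(genes_a = ga, genes_b = gb, shared_genes = shared,
       n_union = length(union_genes),
       fraction = if (length(union_genes) == 0) 0
                  else length(shared) / length(union_genes))
}

#' Shared structural variants between two foci
#'
#' Two SVs match when they have the same type and both breakpoints lie
#' within `tol` bp of each other. Translocations may match with the two
#' breakpoint pairs in either order. Matching is one-to-one (greedy).
#' The fraction is matched pairs over the union
#' `n_a + n_b - n_matched`.
#'
#' @param sv_a,sv_b breakpoint tables (`chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `svtype`).
#' @param tol breakpoint tolerance in bp (default 10, must be >= 0).
#' @return list with `n_matched`, `n_union`, `fraction`.
#' @export
sv_overlap <- function(sv_a, sv_b, tol = 10L) {
  if (tol < 0) stop_input("sv_overlap: tol must be >= 0")
  na <- nrow(sv_a)
  nb <- nrow(sv_b)
  used <- logical(nb)
  matched <- 0L
  if (na > 0 && nb > 0) {
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        if (used[j] || sv_a$svtype[i] != sv_b$svtype[j]) next
        straight <- sv_a$chrom1[i] == sv_b$chrom1[j] &&
          sv_a$chrom2[i] == sv_b$chrom2[j] &&
          abs(sv_a$pos1[i] - sv_b$pos1[j]) <= tol &&
          abs(sv_a$pos2[i] - sv_b$pos2[j]) <= tol
        crossed <- sv_a$svtype[i] == "TRA" &&
          sv_a$chrom1[i] == sv_b$chrom2[j] &&
          sv_a$chrom2[i] == sv_b$chrom1[j] &&
          abs(sv_a$pos1[i] - sv_b$pos2[j]) <= tol &&
          abs(sv_a$pos2[i] - sv_b$pos1[j]) <= tol
        if (straight || crossed) {
          used[j] <- TRUE
          matched <- matched + 1L
          break
        }
      }
    }
  }
  n_union <- na + nb - matched
  list(n_matched = matched, n_union = n_union,
       fraction = if (n_union == 0) 0 else matched / n_union)
}
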