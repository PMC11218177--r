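# Copy-number / BAF segment model: gain/loss relative to ploidy, LOH from
# the segment genotype (single distinct allele symbol, including
# copy-neutral LOH), and gene-level recurrence across a cohort of foci.
# Segments are 0-based half-open; VCF-side positions are 1-based.

#' Validate a per-focus segment table
#'
#' Checks coordinates (`start < end`), BAF range (<= 0.5 when present) and
#' that segments within the focus do not overlap.
#'
#' @param segments data.frame with `contig`, `start`, `end`,
#'   `copy_number`, `baf`, `genotype`.
#' @return the table, invisibly, on success; error otherwise.
#' @export
validate_segments <- function(segments) {
  if (nrow(segments) == 0) return(invisible(segments))
  if (any(segments$start >= segments$end)) {
    stop_input("validate_segments: segment with start >= end")
  }
  if (any(!is.na(segments$baf) & segments$baf > 0.5)) {
    stop_input("validate_segments: BAF above 0.5")
  }
  gr <- GenomicRanges::GRanges(segments$contig,
                               IRanges::IRanges(segments$start + 1,
                                                segments$end))
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1)) {
    stop_input("validate_segments: overlapping segments within one focus")
  }
  invisible(segments)
}

#' Gain/loss/neutral status of segments
#'
#' Gain when copy number exceeds ploidy, loss when below, else neutral.
#'
#' @param copy_number integer copy numbers (vector).
#' @param ploidy reference ploidy (default 2, must be >= 1).
#' @return character vector of statuses.
#' @export
call_status <- function(copy_number, ploidy = 2L) {
  if (ploidy < 1) stop_input("call_status: ploidy must be >= 1")
  ifelse(copy_number > ploidy, "gain",
         ifelse(copy_number < ploidy, "loss", "neutral"))
}

#' LOH status of segments
#'
#' A segment is in loss of heterozygosity when its genotype contains
#' exactly one distinct allele symbol and at least one copy is present.
#' This includes copy-neutral LOH (e.g. genotype "AA" at copy number 2)
#' and hemizygous deletion (genotype "A" at copy number 1).
#'
#' @param genotype allele strings (e.g. "AB", "AA", "A").
#' @param copy_number integer copy numbers.
#' @return logical vector.
#' @export
call_loh <- function(genotype, copy_number) {
  if (any(is.na(genotype) | !nzchar(genotype))) {
    stop_input("call_loh: empty genotype")
  }
  distinct <- vapply(strsplit(genotype, ""),
                     function(a) length(unique(a)), integer(1))
  distinct == 1 & copy_number >= 1
}

#' Annotate segments with status and LOH calls
#'
#' @param segments segment table (validated).
#' @param ploidy reference ploidy.
#' @return the table with `status` and `loh` columns (re)computed.
#' @export
annotate_segments <- function(segments, ploidy = 2L) {
  validate_segments(segments)
  segments$status <- call_status(segments$copy_number, ploidy)
  segments$loh <- call_loh(segments$genotype, segments$copy_number)
  segments
}

#' Gene-by-focus copy-number recurrence matrix
#'
#' Builds the gene x focus status matrix (gain / loss / neutral by >= 1 bp
#' overlap with a non-neutral segment), counts for each gene the number of
#' foci with a non-neutral status, and retains genes recurrent in at least
#' `min_foci` foci.
#'
#' @param segments_by_focus named list of annotated segment tables, one
#'   per focus.
#' @param genes gene interval table.
#' @param min_foci recurrence cutoff (default 3, i.e. "more than 2 foci").
#' @return list with `matrix` (character, genes x foci), `counts`
#'   (data.frame `gene`, `n_foci`, `direction`), and `recurrent` (counts
#'   filtered at `min_foci`).
#' @export
recurrence_matrix <- function(segments_by_focus, genes, min_foci = 3L) {
  foci <- names(segments_by_focus)
  if (is.null(foci)) foci <- paste0("focus", seq_along(segments_by_focus))
  for (s in segments_by_focus) validate_segments(s)
  per_focus <- lapply(segments_by_focus, focus_cnv_genes, genes = genes)
  mat <- matrix("neutral", nrow = nrow(genes), ncol = length(foci),
                dimnames = list(genes$gene, foci))
  for (i in seq_along(per_focus)) {
    pf <- per_focus[[i]]
    mat[match(pf$gene, genes$gene), i] <- pf$direction
  }
  n_foci <- rowSums(mat != "neutral")
  # dominant direction across foci, for reporting
  direction <- apply(mat, 1, function(r) {
    r <- r[r != "neutral"]
    if (length(r) == 0) return("")
    names(sort(table(r), decreasing = TRUE))[1]
  })
  counts <- data.frame(gene = rownames(mat), n_foci = unname(n_foci),
                       direction = unname(direction),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_foci, counts$gene), , drop = FALSE]
  rownames(counts) <- NULL
  list(matrix = mat, counts = counts,
       recurrent = counts[counts$n_foci >= min_foci, , drop = FALSE])
}
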