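# Neoantigen candidate filtering from peptide-MHC affinity predictions and
# cross-focus recurrence. HLA typing and the affinity predictions are
# upstream inputs; this module only applies the candidacy rule and tallies.

#' Filter candidate neoantigens
#'
#' A peptide record is a candidate when the mutant binding affinity is
#' strictly below 500 nM *and* strictly below the wild-type peptide's
#' affinity (stronger binding than both the threshold and the unmutated
#' counterpart).
#'
#' @param records data.frame with `mutation_id`, `focus_id`,
#'   `hla_allele`, `peptide`, `mut_affinity_nM`, `wt_affinity_nM`.
#' @param affinity_max mutant affinity cutoff in nM (default 500,
#'   exclusive).
#' @return the candidate subset of `records`.
#' @export
filter_candidates <- function(records, affinity_max = 500) {
  if (any(records$mut_affinity_nM <= 0) || any(records$wt_affinity_nM <= 0)) {
    stop_input("filter_candidates: non-positive binding affinity")
  }
  len <- nchar(records$peptide)
  if (any(len < 9 | len > 11)) {
    stop_input("filter_candidates: peptide length outside 9-11 residues")
  }
  keep <- records$mut_affinity_nM < affinity_max &
    records$mut_affinity_nM < records$wt_affinity_nM
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recurrent neoantigens across tumor foci
#'
#' Counts, for each mutation, the number of distinct foci contributing at
#' least one candidate peptide, and retains mutations recurrent in at
#' least `min_foci` foci. The best (lowest) mutant affinity across
#' alleles, peptides and foci is reported alongside.
#'
#' @param candidates candidate records from [filter_candidates()].
#' @param min_foci recurrence cutoff (default 3, i.e. "more than 2 foci").
#' @return list with `counts` (all mutations: `mutation_id`, `n_foci`,
#'   `best_affinity_nM`) and `recurrent` (filtered at `min_foci`), both
#'   sorted by decreasing focus count.
#' @export
recurrent_neoantigens <- function(candidates, min_foci = 3L) {
  if (nrow(candidates) == 0) {
    empty <- data.frame(mutation_id = character(0), n_foci = integer(0),
                        best_affinity_nM = numeric(0),
                        stringsAsFactors = FALSE)
    return(list(counts = empty, recurrent = empty))
  }
  split_by <- split(candidates, candidates$mutation_id)
  counts <- do.call(rbind, lapply(split_by, function(d) {
    data.frame(mutation_id = d$mutation_id[1],
               n_foci = length(unique(d$focus_id)),
               best_affinity_nM = min(d$mut_affinity_nM),
               stringsAsFactors = FALSE)
  }))
  counts <- counts[order(-counts$n_foci, counts$best_affinity_nM), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts,
       recurrent = counts[counts$n_foci >= min_foci, , drop = FALSE])
}
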