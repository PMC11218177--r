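# Cohort configuration: a structured-text (YAML) description of the
# simulated patients. The packaged default fixture emulates the study
# conditions this pipeline is built for: 10 patients sequenced as paired
# foci plus matched normal (50x tumor / 30x normal), six multicentric-like
# entries with shared somatic fractions in the 0-2.7% band and four
# metastatic-like entries in the 58-67.6% band, 1-3 CCF clusters per
# focus, purity 0.8, LOH regions, oncogene-gain/TSG-loss profiles, sparse
# SV sharing in the MC group, and germline variants whose immune-category
# counts separate the groups while totals do not.

default_drivers <- function() {
  data.frame(gene = c("TP53", "MUC16", "DGKZ"),
             prob = c(1.0, 0.7, 0.5),
             stringsAsFactors = FALSE)
}

#' Default per-patient configuration values
#'
#' Fields a cohort config entry may omit; model-dependent defaults (CNV
#' and SV sharing) reflect the two origin models: independent clones share
#' almost nothing, a metastatic pair shares a large trunk.
#' @param origin_model "MC" or "ME".
#' @return named list of defaults.
#' @keywords internal
entry_defaults <- function(origin_model) {
  list(
    n_somatic_per_focus = 200L,
    n_synonymous_per_focus = 10L,
    n_clusters_per_focus = c(2L, 2L),
    purity = 0.8,
    n_cnv_per_focus = c(8L, 8L),
    n_cnv_shared = if (origin_model == "MC") 1L else 5L,
    n_sv_per_focus = c(30L, 30L),
    n_sv_shared = if (origin_model == "MC") 0L else 18L,
    n_loh_regions = c(2L, 2L),
    n_loh_planted = 2L,
    germline = list(n_total = 60L, n_immune = 5L),
    germline_noise = list(low_depth = 12L, high_af = 18L,
                          region = 20L, repeats = 8L)
  )
}

normalize_entry <- function(entry, index, base_seed) {
  if (is.null(entry$id)) stop_input("cohort config: patient entry without id")
  if (is.null(entry$origin_model) ||
      !entry$origin_model %in% c("MC", "ME")) {
    stop_input("cohort config: origin_model must be MC or ME (", entry$id, ")")
  }
  f <- entry$target_shared_snv_fraction
  if (is.null(f) || f < 0 || f > 1) {
    stop_input("cohort config: target_shared_snv_fraction must be in [0,1] (",
               entry$id, ")")
  }
  d <- entry_defaults(entry$origin_model)
  for (k in names(d)) {
    if (is.null(entry[[k]])) entry[[k]] <- d[[k]]
  }
  entry$n_clusters_per_focus <- as.integer(unlist(entry$n_clusters_per_focus))
  if (length(entry$n_clusters_per_focus) != 2 ||
      any(entry$n_clusters_per_focus < 1 | entry$n_clusters_per_focus > 3)) {
    stop_input("cohort config: n_clusters_per_focus must be two counts in ",
               "1..3 (", entry$id, ")")
  }
  if (entry$purity <= 0 || entry$purity > 1) {
    stop_input("cohort config: purity must be in (0,1] (", entry$id, ")")
  }
  for (k in c("n_cnv_per_focus", "n_sv_per_focus", "n_loh_regions")) {
    entry[[k]] <- rep_len(as.integer(unlist(entry[[k]])), 2)
  }
  if (is.null(entry$seed)) entry$seed <- derive_seed(base_seed, index)
  entry
}

#' Load a cohort configuration from YAML
#'
#' @param path YAML file with top-level keys `base_seed`, `depth`
#'   (`tumor_mean`, `normal_mean`), `hq_min_alt` and a `patients` list;
#'   see the packaged `default_cohort.yaml` for the schema.
#' @param base_seed optional override of the file's `base_seed` (used to
#'   re-seed the whole cohort reproducibly).
#' @return normalized config list with per-patient seeds filled in.
#' @export
load_cohort_config <- function(path, base_seed = NULL) {
  cfg <- yaml::read_yaml(path)
  cfg$base_seed <- as.integer(base_seed %||% cfg$base_seed %||% 1L)
  cfg$depth <- cfg$depth %||% list(tumor_mean = 50, normal_mean = 30)
  cfg$hq_min_alt <- cfg$hq_min_alt %||% 3L
  cfg$patients <- cfg$patients %||% list()
  ids <- vapply(cfg$patients, function(p) as.character(p$id), character(1))
  if (anyDuplicated(ids)) {
    stop_input("cohort config: duplicate patient ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cfg$patients <- lapply(seq_along(cfg$patients), function(i) {
    normalize_entry(cfg$patients[[i]], i, cfg$base_seed)
  })
  cfg
}

#' The packaged default 10-patient cohort configuration
#'
#' @inheritParams load_cohort_config
#' @return normalized config list.
#' @export
default_cohort_config <- function(base_seed = NULL) {
  load_cohort_config(extdata("default_cohort.yaml"), base_seed = base_seed)
}
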