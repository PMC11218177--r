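# Germline rare-variant analysis: a four-rule filter cascade, screening of
# retained genes against a cancer gene census list, functional-category
# counting, origin-group comparison, and a hypergeometric gene-set
# enrichment with Benjamini-Hochberg adjustment.

#' Germline rare-variant filter cascade
#'
#' Retains a germline variant when all of the following hold:
#' \enumerate{
#'   \item read depth >= `min_depth` (default 10);
#'   \item rare: maximum population allele frequency across dbSNP,
#'     1000 Genomes and ExAC (missing treated as 0) <= `af_max`
#'     (default 0.001) --- *or* the variant is in COSMIC, which rescues it
#'     from this rule only (cancer-recurrent variants are kept regardless
#'     of population frequency);
#'   \item protein-affecting: region exonic or splicing and consequence not
#'     synonymous (intergenic, noncoding, intronic, UTR variants drop here);
#'   \item not flagged as lying in a genomic repeat region.
#' }
#' Each removal is attributed to the first failing rule in the order above;
#' variants with missing depth are counted separately as `no_depth`.
#'
#' @param variants data.frame with `gene`, `depth`, `af_dbsnp`, `af_1kg`,
#'   `af_exac`, `cosmic_flag`, `region`, `consequence`, `repeat_flag`.
#' @param min_depth depth rule threshold (reads, inclusive).
#' @param af_max population allele-frequency cutoff.
#' @param categories optional gene-to-category table
#'   (see [load_gene_categories()]); genes not listed count as "other".
#' @param patient_id label carried into the profile.
#' @return object of class `germline_profile`: list with `retained`
#'   (data.frame), `drops` (named counts: no_depth, depth, af, region,
#'   repeat), `category_counts` (named integer vector) and `n_input`.
#' @export
filter_germline <- function(variants, min_depth = 10L, af_max = 0.001,
                            categories = NULL, patient_id = "patient") {
  n <- nrow(variants)
  af <- pmax(ifelse(is.na(variants$af_dbsnp), 0, variants$af_dbsnp),
             ifelse(is.na(variants$af_1kg), 0, variants$af_1kg),
             ifelse(is.na(variants$af_exac), 0, variants$af_exac))
  no_depth <- is.na(variants$depth)
  fail_depth <- !no_depth & variants$depth < min_depth
  fail_af <- !(variants$cosmic_flag %in% TRUE) & af > af_max
  fail_region <- !(variants$region %in% c("exonic", "splicing")) |
    variants$consequence == "synonymous"
  fail_repeat <- variants$repeat_flag %in% TRUE

  first_fail <- rep("retained", n)
  first_fail[fail_repeat] <- "repeat"
  first_fail[fail_region] <- "region"
  first_fail[fail_af] <- "af"
  first_fail[fail_depth] <- "depth"
  first_fail[no_depth] <- "no_depth"

  retained <- variants[first_fail == "retained", , drop = FALSE]
  rownames(retained) <- NULL
  drops <- c(no_depth = sum(first_fail == "no_depth"),
             depth = sum(first_fail == "depth"),
             af = sum(first_fail == "af"),
             region = sum(first_fail == "region"),
             "repeat" = sum(first_fail == "repeat"))

  cat_names <- germline_category_names()
  if (is.null(categories)) categories <- load_gene_categories()
  cat_of <- categories$category[match(retained$gene, categories$gene)]
  cat_of[is.na(cat_of)] <- "other"
  counts <- setNames(integer(length(cat_names)), cat_names)
  tb <- table(factor(cat_of, levels = cat_names))
  counts[names(tb)] <- as.integer(tb)

  structure(list(patient_id = patient_id, retained = retained,
                 drops = drops, category_counts = counts, n_input = n),
            class = "germline_profile")
}

#' @export
print.germline_profile <- function(x, ...) {
  cat(sprintf("Germline profile for %s: %d/%d retained (drops: %s)\n",
              x$patient_id, nrow(x$retained), x$n_input,
              paste(names(x$drops), x$drops, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Screen retained germline genes against a cancer gene census list
#'
#' @param profile a [filter_germline()] result.
#' @param cgc character vector of census gene symbols.
#' @return list with `variants` (retained variants in census genes) and
#'   `genes` (de-duplicated census genes hit).
#' @export
intersect_cgc <- function(profile, cgc) {
  if (length(cgc) == 0) {
    warning("intersect_cgc: empty census gene list", call. = FALSE)
  }
  hit <- profile$retained[profile$retained$gene %in% cgc, , drop = FALSE]
  list(variants = hit, genes = unique(hit$gene))
}

#' Compare a germline category count between origin groups
#'
#' Exact two-sided rank-sum comparison of per-patient retained-variant
#' counts in one functional category (or "total") between the MC and ME
#' groups.
#'
#' @param mc_profiles,me_profiles lists of [filter_germline()] profiles.
#' @param category one of the category names, or "total" for the overall
#'   retained count.
#' @return list with `p_value`, `mc_counts`, `me_counts`, `category`.
#' @export
compare_category <- function(mc_profiles, me_profiles, category = "immune") {
  valid <- c(germline_category_names(), "total")
  if (!category %in% valid) {
    stop_input("compare_category: unknown category '", category, "'")
  }
  count_of <- function(p) {
    if (category == "total") nrow(p$retained)
    else unname(p$category_counts[category])
  }
  x <- vapply(mc_profiles, count_of, numeric(1))
  y <- vapply(me_profiles, count_of, numeric(1))
  res <- exact_rank_sum(x, y)
  list(p_value = res$p_value, mc_counts = x, me_counts = y,
       category = category)
}

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' For each gene set, tests over-representation of the query genes with the
#' hypergeometric upper tail
#' `P(X >= k)` where `k` is the query/set overlap, drawing `|query|` genes
#' from a universe split into set and non-set members. P-values are
#' adjusted across sets with Benjamini-Hochberg.
#'
#' @param genes query gene symbols (must all be in `universe`).
#' @param annotation data.frame mapping `gene` to `category` (a gene may
#'   appear in several sets).
#' @param universe background gene symbols.
#' @return data.frame: `set`, `k` (overlap), `m` (set size in universe),
#'   `n_query`, `p`, `p_adj`, ordered by `p`.
#' @export
enrich_sets <- function(genes, annotation, universe) {
  genes <- unique(genes)
  universe <- unique(universe)
  bad <- setdiff(genes, universe)
  if (length(bad) > 0) {
    stop_input("enrich_sets: query genes not in universe: ",
               paste(bad, collapse = ", "))
  }
  sets <- split(annotation$gene, annotation$category)
  rows <- lapply(names(sets), function(s) {
    members <- intersect(unique(sets[[s]]), universe)
    m <- length(members)
    k <- length(intersect(genes, members))
    p <- phyper(k - 1, m, length(universe) - m, length(genes),
                lower.tail = FALSE)
    data.frame(set = s, k = k, m = m, n_query = length(genes), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
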