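# packaged toy-genome resources: gene intervals, functional categories,
# Cancer Gene Census screen list

extdata <- function(file) {
  system.file("extdata", file, package = "mecclone", mustWork = TRUE)
}

#' Toy genome contig sizes
#'
#' Eight 40 Mb contigs. `chr1`--`chr7` carry the packaged gene intervals;
#' `chr8` is kept gene-sparse and is where the cohort generator places LOH
#' regions, so that variants fall inside partner LOH only when planted
#' there deliberately.
#'
#' @return named integer vector of contig lengths (bp).
#' @export
toy_genome <- function() {
  setNames(rep(40000000L, 8), paste0("chr", 1:8))
}

#' Packaged gene interval table
#'
#' 73 genes laid out on the toy genome (100 kb intervals, 2 Mb apart):
#' recurrent esophageal/cardiac cancer drivers and copy-number genes plus
#' the functional-category genes used by the germline analysis.
#'
#' @param path optional path to an alternative TSV with columns
#'   `gene`, `contig`, `start`, `end` (1-based inclusive intervals).
#' @return data.frame with columns gene, contig, start, end.
#' @export
load_gene_table <- function(path = NULL) {
  g <- read.delim(path %||% extdata("genes.tsv"), stringsAsFactors = FALSE)
  need <- c("gene", "contig", "start", "end")
  if (!all(need %in% names(g))) {
    stop_input("gene table must have columns: ", paste(need, collapse = ", "))
  }
  g
}

#' Packaged gene-to-category annotation
#'
#' Maps genes to the tumorigenesis-related functional categories compared
#' between origin groups: immune, cell_cycle, proliferation, dna_repair,
#' adhesion. Genes absent from the table fall in category "other".
#'
#' @param path optional path to an alternative TSV (columns gene, category).
#' @return data.frame with columns gene, category.
#' @export
load_gene_categories <- function(path = NULL) {
  g <- read.delim(path %||% extdata("gene_categories.tsv"),
                  stringsAsFactors = FALSE)
  if (!all(c("gene", "category") %in% names(g))) {
    stop_input("category table must have columns gene, category")
  }
  g
}

#' Packaged Cancer Gene Census screen list (toy subset)
#'
#' @param path optional path to an alternative one-gene-per-line file.
#' @return character vector of gene symbols.
#' @export
load_cgc_genes <- function(path = NULL) {
  readLines(path %||% extdata("cgc_genes.txt"))
}

germline_category_names <- function() {
  c("immune", "cell_cycle", "proliferation", "dna_repair", "adhesion",
    "other")
}

# oncogene / tumor-suppressor pools the generator draws CNV profiles from
cnv_gain_pool <- function() {
  c("CCND1", "CTTN", "EGFR", "MYC", "PIK3CA", "SOX2", "BCL6", "FGFR1",
    "ERBB2", "CCNE1", "KRAS", "NOTCH3")
}

cnv_loss_pool <- function() {
  c("CDKN2A", "CDKN2B", "PTEN", "RB1", "SMAD4", "FAT2", "ZNF750", "CDH1")
}
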