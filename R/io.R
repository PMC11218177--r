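# On-disk cohort layout. One directory per patient:
#   somatic_A.vcf, somatic_B.vcf   somatic calls per focus (VCF v4.2)
#   germline.vcf                   germline calls of the matched normal
#   evidence.tsv                   per-site read support, all three samples
#   segments_A.tsv, segments_B.tsv copy-number/BAF segments (0-based
#                                  half-open, BED-derived)
#   sv_A.tsv, sv_B.tsv             SV breakpoints
#   affinity.tsv                   peptide-MHC binding affinities
# plus a cohort-level manifest.json listing files, seeds and truth.

fmt_info_num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g"))

vcf_header <- function(genome, sample, info_keys = TRUE) {
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", names(genome),
                 unname(genome)))
  if (info_keys) {
    h <- c(h,
      '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
      '##INFO=<ID=REGION,Number=1,Type=String,Description="Genic region class">',
      '##INFO=<ID=CSQ,Number=1,Type=String,Description="Coding consequence">',
      '##INFO=<ID=AF_DBSNP,Number=1,Type=Float,Description="dbSNP allele frequency">',
      '##INFO=<ID=AF_1KG,Number=1,Type=Float,Description="1000 Genomes allele frequency">',
      '##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description="ExAC allele frequency">',
      '##INFO=<ID=COSMIC,Number=1,Type=Integer,Description="Present in COSMIC (0/1)">',
      '##INFO=<ID=REPEAT,Number=1,Type=Integer,Description="In genomic repeat region (0/1)">',
      '##INFO=<ID=SIFT,Number=1,Type=Float,Description="SIFT score">',
      '##INFO=<ID=PPH2,Number=1,Type=Float,Description="PolyPhen-2 score">')
  }
  c(h,
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref,alt read depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample))
}

variant_info_string <- function(v) {
  paste0("GENE=", v$gene,
         ";REGION=", v$region,
         ";CSQ=", v$consequence,
         ";AF_DBSNP=", fmt_info_num(v$af_dbsnp),
         ";AF_1KG=", fmt_info_num(v$af_1kg),
         ";AF_EXAC=", fmt_info_num(v$af_exac),
         ";COSMIC=", as.integer(v$cosmic_flag %in% TRUE),
         ";REPEAT=", as.integer(v$repeat_flag %in% TRUE),
         ";SIFT=", fmt_info_num(v$sift),
         ";PPH2=", fmt_info_num(v$polyphen))
}

write_variant_vcf <- function(variants, ref_depth, alt_depth, file, genome,
                              sample) {
  ord <- order(match(variants$chrom, names(genome)), variants$pos)
  v <- variants[ord, , drop = FALSE]
  rd <- ref_depth[ord]
  ad <- alt_depth[ord]
  body <- if (nrow(v) == 0) character(0) else
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
          variant_info_string(v), "AD:DP",
          paste0(rd, ",", ad, ":", rd + ad), sep = "\t")
  writeLines(c(vcf_header(genome, sample), body), file)
}

info_num <- function(vcf, key) {
  x <- vcfR::extract.info(vcf, element = key)
  suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
}

read_variant_vcf <- function(file) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n <- nrow(fix)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ad_parts <- strsplit(as.character(ad[, 1]), ",")
  empty <- data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), gene = character(0), region = character(0),
    consequence = character(0), af_dbsnp = numeric(0), af_1kg = numeric(0),
    af_exac = numeric(0), cosmic_flag = logical(0),
    repeat_flag = logical(0), sift = numeric(0), polyphen = numeric(0),
    ref_depth = integer(0), alt_depth = integer(0), depth = integer(0),
    stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  info_chr <- function(key) as.character(vcfR::extract.info(vcf, key))
  rd <- vapply(ad_parts, function(p) as.integer(p[1]), integer(1))
  adp <- vapply(ad_parts, function(p) as.integer(p[2]), integer(1))
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT,
    gene = info_chr("GENE"), region = info_chr("REGION"),
    consequence = info_chr("CSQ"),
    af_dbsnp = info_num(vcf, "AF_DBSNP"),
    af_1kg = info_num(vcf, "AF_1KG"),
    af_exac = info_num(vcf, "AF_EXAC"),
    cosmic_flag = info_num(vcf, "COSMIC") == 1,
    repeat_flag = info_num(vcf, "REPEAT") == 1,
    sift = info_num(vcf, "SIFT"),
    polyphen = info_num(vcf, "PPH2"),
    ref_depth = rd, alt_depth = adp, depth = rd + adp,
    stringsAsFactors = FALSE)
}

write_tsv <- function(d, file) {
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Write one simulated patient to a directory
#'
#' @param bundle a patient bundle from [simulate_patient()].
#' @param dir output directory (created).
#' @param genome contig sizes for the VCF headers.
#' @return character vector of files written (relative names), invisibly.
#' @export
write_patient <- function(bundle, dir, genome = toy_genome()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  ev <- bundle$evidence
  for (fc in c("A", "B")) {
    v <- bundle$variants[bundle$variants$focus == fc, , drop = FALSE]
    sample_id <- bundle$samples[[tolower(fc)]]
    evf <- ev[ev$sample_id == sample_id, , drop = FALSE]
    i <- match(variant_key(v$chrom, v$pos, v$ref, v$alt),
               variant_key(evf$chrom, evf$pos, evf$ref, evf$alt))
    f <- paste0("somatic_", fc, ".vcf")
    write_variant_vcf(v, evf$ref_depth[i], evf$alt_depth[i],
                      file.path(dir, f), genome, sample_id)
    files <- c(files, f)

    seg <- bundle$segments[bundle$segments$focus == fc, , drop = FALSE]
    seg$focus <- NULL
    sf <- paste0("segments_", fc, ".tsv")
    write_tsv(seg, file.path(dir, sf))

    sv <- bundle$svs[bundle$svs$focus == fc, , drop = FALSE]
    sv$focus <- NULL
    vf <- paste0("sv_", fc, ".tsv")
    write_tsv(sv, file.path(dir, vf))
    files <- c(files, sf, vf)
  }
  g <- bundle$germline
  # AD is written as an even ref/alt split; only DP feeds the depth rule
  alt_d <- pmax(g$depth %/% 2, 1)
  write_variant_vcf(g, g$depth - alt_d, alt_d, file.path(dir, "germline.vcf"),
                    genome, bundle$samples$normal)
  write_tsv(bundle$evidence, file.path(dir, "evidence.tsv"))
  write_tsv(bundle$affinity, file.path(dir, "affinity.tsv"))
  files <- c(files, "germline.vcf", "evidence.tsv", "affinity.tsv")
  invisible(files)
}

#' Read one patient directory back into a bundle
#'
#' @param dir patient directory as written by [write_patient()].
#' @param patient_id patient label; defaults to the directory name.
#' @return list with the same tables as a [simulate_patient()] bundle
#'   (no truth).
#' @export
read_patient <- function(dir, patient_id = basename(dir)) {
  read_focus <- function(fc) {
    v <- read_variant_vcf(file.path(dir, paste0("somatic_", fc, ".vcf")))
    if (nrow(v) > 0) v$focus <- fc else v$focus <- character(0)
    v
  }
  va <- read_focus("A")
  vb <- read_focus("B")
  seg <- do.call(rbind, lapply(c("A", "B"), function(fc) {
    s <- read_tsv(file.path(dir, paste0("segments_", fc, ".tsv")))
    if (nrow(s) > 0) s$focus <- fc else s$focus <- character(0)
    s
  }))
  svs <- do.call(rbind, lapply(c("A", "B"), function(fc) {
    s <- read_tsv(file.path(dir, paste0("sv_", fc, ".tsv")))
    if (nrow(s) > 0) s$focus <- fc else s$focus <- character(0)
    s
  }))
  germ <- read_variant_vcf(file.path(dir, "germline.vcf"))
  list(patient_id = patient_id,
       samples = list(a = paste0(patient_id, "A"),
                      b = paste0(patient_id, "B"),
                      normal = paste0(patient_id, "N")),
       variants = rbind(va, vb),
       evidence = read_tsv(file.path(dir, "evidence.tsv")),
       segments = seg,
       svs = svs,
       germline = germ,
       affinity = read_tsv(file.path(dir, "affinity.tsv")))
}
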