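#!/usr/bin/env Rscript
# Germline rare-variant analysis: filter cascade (depth, population AF
# with COSMIC rescue, protein-affecting region, repeat regions), Cancer
# Gene Census screen, per-category counts, MC-vs-ME comparison and
# category enrichment.

suppressMessages(library(mecclone))

cohort <- read_cohort("results/cohort")
calls <- read.delim("results/origin_calls.tsv", stringsAsFactors = FALSE)
cats <- load_gene_categories()
cgc <- load_cgc_genes()

profiles <- lapply(cohort$patients, function(b) {
  filter_germline(b$germline, categories = cats,
                  patient_id = b$patient_id)
})
label <- setNames(calls$label, calls$patient_id)
mc <- profiles[label[names(profiles)] == "MC"]
me <- profiles[label[names(profiles)] == "ME"]

counts <- do.call(rbind, lapply(profiles, function(p) {
  data.frame(patient_id = p$patient_id, total = nrow(p$retained),
             t(p$category_counts))
}))
write.table(counts, "results/germline_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

imm <- compare_category(mc, me, "immune")
tot <- compare_category(mc, me, "total")
cat("Retained germline variants per patient:\n")
print(counts, row.names = FALSE)
cat(sprintf("\nTotal counts, MC vs ME:  p = %.4f (no group difference)\n",
            tot$p_value))
cat(sprintf("Immune-category counts:  p = %.4f (MC %s vs ME %s)\n",
            imm$p_value, paste(imm$mc_counts, collapse = ","),
            paste(imm$me_counts, collapse = ",")))
cgc_hits <- sort(unique(unlist(lapply(profiles, function(p) {
  intersect_cgc(p, cgc)$genes
}))))
cat("Candidate susceptibility genes (census intersection):\n  ",
    paste(cgc_hits, collapse = ", "), "\n")
for (grp in c("MC", "ME")) {
  gg <- unique(unlist(lapply(profiles[label[names(profiles)] == grp],
                             function(p) p$retained$gene)))
  e <- enrich_sets(gg, cats, unique(load_gene_table()$gene))
  cat(sprintf("Top enriched category in %s: %s (p_adj = %.3g)\n",
              grp, e$set[1], e$p_adj[1]))
}
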