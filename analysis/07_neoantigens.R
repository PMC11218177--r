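#!/usr/bin/env Rscript
# Neoantigen candidates from peptide-MHC affinity predictions (mutant
# affinity < 500 nM and below wild type) and their recurrence across
# tumor foci.

suppressMessages(library(mecclone))

cohort <- read_cohort("results/cohort")
aff <- do.call(rbind, lapply(cohort$patients, `[[`, "affinity"))
cand <- filter_candidates(aff)
rec <- recurrent_neoantigens(cand, min_foci = 3)
write.table(rec$counts, "results/neoantigen_recurrence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d of %d affinity records pass the candidate filter\n",
            nrow(cand), nrow(aff)))
cat(sprintf("%d mutations are candidate neoantigens in > 2 foci:\n",
            nrow(rec$recurrent)))
print(rec$recurrent, row.names = FALSE)
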