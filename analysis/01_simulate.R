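#!/usr/bin/env Rscript
# Generate the synthetic study datasets with known ground truth:
# a two-plex PSM dataset (20,000 PSMs, class-structured correct-match
# priors, decoy fraction matched to the incorrect-target fraction), a
# TMT-10 quantitation dataset (200 features, 50 PSMs each, true |log2
# fold change| of 1.0), and HLA class I/II peptide sets with seeded
# anchors and nested sets.

library(psmpolish)
dir.create("results", showWarnings = FALSE)
seed <- 101L

psm <- generate_psm_dataset(synthetic_psm_config(), seed = seed)
write_psm_table(psm$psms, "results/psm_table.tsv")
write.table(psm$truth, "results/psm_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PSM dataset: %d records, %d decoys, %d incorrect targets",
                nrow(psm$psms), sum(psm$psms$is_decoy),
                sum(!psm$truth$correct & !psm$psms$is_decoy)))

qd <- generate_quant_dataset(synthetic_quant_config(), seed = seed)
write_psm_table(qd$psms, "results/quant_psm_table.tsv")
write.table(qd$truth, "results/quant_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("Quant dataset: %d features x %d PSMs, %d channels",
                nrow(qd$truth), nrow(qd$psms) / nrow(qd$truth),
                length(qd$design$channels)))

hla <- generate_hla_peptides(synthetic_hla_config(), seed = seed)
writeLines(hla$class1, "results/hla_class1_peptides.txt")
write.table(hla$class2, "results/hla_class2_peptides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("HLA peptides: %d class I, %d class II in %d nested sets",
                length(hla$class1), nrow(hla$class2),
                length(unique(hla$class2$set_id))))
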