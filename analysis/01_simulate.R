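#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
# Emulates a seven-sample flooded-paddy survey: field physiochemistry with
# static-headspace N2O vials, 15N-spiked slurry incubations, qPCR plates and
# an annotated-ORF metagenome table. Every table gets a truth sidecar.

suppressPackageStartupMessages(library(denitflux))

out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- scenario_config(seed = 20210501)
field <- gen_field_survey(cfg)
incub <- gen_incubation(cfg)
orfs <- gen_orf_table(cfg)
qpcr <- gen_qpcr(cfg)

w <- function(d, f) write.csv(d, file.path(out_dir, f), row.names = FALSE)
w(field$survey, "field_survey.csv");   w(field$truth, "truth_field.csv")
w(incub$vials, "incubation_vials.csv"); w(incub$labeling, "labeling.csv")
w(incub$truth, "truth_incubation.csv")
w(qpcr$standards, "qpcr_standards.csv"); w(qpcr$samples, "qpcr_samples.csv")
w(qpcr$truth, "truth_qpcr.csv")
write.table(orfs$orfs, file.path(out_dir, "orf_table.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(orfs$nosz_hits, file.path(out_dir, "nosz_hits.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
w(orfs$truth_shares, "truth_orf_shares.csv")

cat(sprintf("simulated %d samples: %d headspace vials, %d incubation vials,\n",
            cfg$n_samples, nrow(field$survey), nrow(incub$vials)))
cat(sprintf("  %d ORFs across %d genes, %d qPCR wells -> %s/\n",
            nrow(orfs$orfs), length(cfg$community), nrow(qpcr$samples),
            out_dir))
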