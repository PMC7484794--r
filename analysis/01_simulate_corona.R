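#!/usr/bin/env Rscript
# Stage 1: simulate a five-sample corona experiment (four hard-corona
# controls + one click-captured HC+SC sample) with a planted soft-corona
# structure, and write the files the downstream stages consume: an emPAI
# table, a sample-measurement config, matching FASTA sequences, and the
# planted ground truth.

suppressPackageStartupMessages(library(softcorona))

seed <- 1
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- corona_sim_config(seed = seed)  # 80 proteins, 5 SC of each type
exp <- generate_corona_experiment(cfg)

write.csv(exp$records, file.path(outdir, "empai_table.csv"), row.names = FALSE)
write.csv(exp$truth, file.path(outdir, "ground_truth.csv"), row.names = FALSE)

cfg_list <- lapply(seq_len(nrow(exp$samples)), function(i) list(
  role = exp$samples$role[i],
  protein_mass_conc_ug_per_ml = exp$samples$protein_mass_conc[i] * 1e6,
  np_number_conc_per_ml = exp$samples$np_number_conc[i]))
names(cfg_list) <- exp$samples$label
yaml::write_yaml(cfg_list, file.path(outdir, "samples.yaml"))

seqs <- generate_sequences(nrow(exp$records),
                           accessions = exp$records$accession, seed = seed)
write_fasta(seqs, file.path(outdir, "sequences.fasta"))

n_sc <- sum(exp$truth$cluster == "SC")
cat(sprintf("Simulated corona: %d proteins (%d planted SC: %s)\n",
            nrow(exp$records), n_sc,
            paste(names(table(exp$truth$sc_type[exp$truth$cluster == "SC"])),
                  table(exp$truth$sc_type[exp$truth$cluster == "SC"]),
                  collapse = ", ")))
cat("Wrote emPAI table, sample config, FASTA and ground truth to", outdir, "\n")
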