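# Shared setup for the analysis drivers: one master seed, one synthetic
# study (deterministic, so every script reconstructs the same study), and
# the output directory. Scripts are numbered and can be run in any order
# after 01 has written the study files.

library(eggbiome)

SEED <- 20100212           # sampling season of the emulated field study
RESULTS <- "results"
STUDY_DIR <- file.path(RESULTS, "study")
dir.create(STUDY_DIR, recursive = TRUE, showWarnings = FALSE)

study_config <- function() {
  cfg <- simulation_config()
  cfg$seed <- sub_seed(SEED, "simulate")
  cfg
}

load_study <- function() simulate_study(study_config())

egg_ids <- function(study) study$ground_truth$egg_sample_ids

# decontaminated table (negative-control OTUs removed), shared downstream
decontaminated <- function(study)
  remove_control_otus(study$table, study$metadata)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
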