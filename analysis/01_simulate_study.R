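# Generate the synthetic study: nine spawning locations in two river
# systems, pooled egg samples (~4,780 reads each, SD 1,165), two water
# samples, one reagent-only negative control with 78 contaminant OTUs,
# 10-minute temperature logs over a 45-day incubation, and 11-locus
# microsatellite genotypes for the host populations. Everything is written
# in the package's plain-text formats under results/study/.

source("analysis/_common.R")

study <- load_study()

write_otu_table(study$table, file.path(STUDY_DIR, "otu_table.tsv"))
write_phylogeny(study$tree, file.path(STUDY_DIR, "tree.nwk"))
write_metadata(study$metadata, file.path(STUDY_DIR, "metadata.tsv"))
write_temperature_series(study$temperature,
                         file.path(STUDY_DIR, "temperature.tsv"))
write_genotypes(study$genotypes, file.path(STUDY_DIR, "genotypes.tsv"))
write_distance_matrix(study$geo_distance,
                      file.path(STUDY_DIR, "geo_distance.tsv"))
gt <- study$ground_truth
write_tsv(data.frame(location_id = names(gt$true_richness),
                     true_richness = unname(gt$true_richness),
                     mean_temperature = unname(gt$mean_temperature)),
          file.path(STUDY_DIR, "ground_truth.tsv"))

print(study$table)
cat(sprintf("Egg samples: %d, water: %d, control: 1\n",
            length(gt$egg_sample_ids), length(gt$water_sample_ids)))
cat(sprintf("True richness spans %d-%d taxa over %.1f-%.1f degC\n",
            min(gt$true_richness), max(gt$true_richness),
            min(gt$mean_temperature), max(gt$mean_temperature)))
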