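# Community-level comparisons: main river vs tributaries (PERMANOVA,
# ANOSIM, dispersion homogeneity at 99,999 permutations), the bootstrap
# one-vs-group tests (other-basin eggs vs main-river group; each water
# sample vs the egg communities), PERMANOVA power against group size,
# the core microbiome, and differential relative abundances egg vs water.

source("analysis/_common.R")

study <- load_study()
dec <- decontaminated(study)
md <- study$metadata[study$metadata$sample_type != "negative_control", ]
beta <- unifrac(dec$table, study$tree)
n_perm <- 99999

grp_ids <- md$sample_id[md$sample_type == "egg" &
                          md$river_group %in% c("main_river", "tributary")]
labels <- setNames(md$river_group[match(grp_ids, md$sample_id)], grp_ids)
dd <- beta[grp_ids, grp_ids]

perm <- permanova(dd, labels, n_perm = n_perm,
                  seed = sub_seed(SEED, "permanova"))
print(perm)
anos <- anosim_test(dd, labels, n_perm = n_perm,
                    seed = sub_seed(SEED, "anosim"))
print(anos)
disp <- dispersion_test(dd, labels, n_perm = n_perm,
                        seed = sub_seed(SEED, "dispersion"))
print(disp)

ob <- md$sample_id[md$sample_type == "egg" &
                     md$river_group == "other_basin"]
mains <- md$sample_id[md$sample_type == "egg" &
                        md$river_group == "main_river"]
boot <- bootstrap_one_vs_group(dec$table, study$tree, ob, mains,
                               B = 1000, seed = sub_seed(SEED, "boot"))
cat("\nOther-basin egg community vs main-river group:\n  ")
cat(format(boot), "\n")

conn_eggs <- md$sample_id[md$sample_type == "egg" &
                            md$river_group != "other_basin"]
for (wid in md$sample_id[md$sample_type == "water"]) {
  wb <- bootstrap_one_vs_group(dec$table, study$tree, wid, conn_eggs,
                               B = 1000, seed = sub_seed(SEED, wid))
  cat(wid, "vs egg communities:\n  ", format(wb), "\n")
}

pow <- permanova_power_curve(
  otu_table(unclass(dec$table)[grp_ids, ]), study$tree, labels,
  group_sizes = c(4, 6, 8, 10), n_boot = 50, n_perm = 199,
  seed = sub_seed(SEED, "power"))
cat("\nPERMANOVA power by per-group size (read resampling):\n")
print(pow)
write_tsv(pow, file.path(RESULTS, "permanova_power.tsv"))

eggs <- egg_ids(study)
core <- core_microbiome(otu_table(unclass(dec$table)[eggs, ]),
                        min_fraction = 0.77)
cat(sprintf("\nCore microbiome (present in >77%% of %d samples): %d OTUs\n",
            length(eggs), length(core)))
writeLines(core, file.path(RESULTS, "core_otus.txt"))

sel <- c(eggs, md$sample_id[md$sample_type == "water"])
rel <- unclass(dec$table)[sel, ]; rel <- rel / rowSums(rel)
difff <- differential_features(
  rel, setNames(md$sample_type[match(sel, md$sample_id)], sel))
cat(sprintf("Differential OTUs egg vs water (BH < 0.05, diff > 5%%): %d\n",
            sum(difff$significant)))
write_tsv(difff, file.path(RESULTS, "differential_features.tsv"))
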