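# Alpha diversity (Chao 1, observed species, Faith's PD) with rarefaction,
# rarefaction curves, unweighted UniFrac distances and principal
# coordinates, all on the decontaminated table.

source("analysis/_common.R")

study <- load_study()
dec <- decontaminated(study)
eggs <- egg_ids(study)
egg_table <- otu_table(unclass(dec$table)[eggs, ])

alpha <- alpha_table(egg_table, study$tree, n_reps = 10,
                     seed = sub_seed(SEED, "alpha"))
write_tsv(alpha, file.path(RESULTS, "alpha.tsv"))
cat("Alpha diversity at common depth", alpha$depth[1], "reads:\n")
print(reshape(alpha[, c("sample_id", "metric", "mean")],
              idvar = "sample_id", timevar = "metric",
              direction = "wide"), digits = 4)

curves <- rarefaction_curves(egg_table, study$tree, n_reps = 5,
                             seed = sub_seed(SEED, "curves"))
write_tsv(curves, file.path(RESULTS, "rarefaction_curves.tsv"))

beta <- unifrac(dec$table, study$tree)
write_distance_matrix(beta, file.path(RESULTS, "unifrac.tsv"))
cat(sprintf("\nUnweighted UniFrac over %d samples: range %.3f-%.3f\n",
            nrow(beta), min(beta[lower.tri(beta)]),
            max(beta[lower.tri(beta)])))

pc <- principal_coordinates(beta)
explained <- 100 * pmax(pc$eigenvalues, 0) / sum(pmax(pc$eigenvalues, 0))
cat(sprintf("PCoA: first two axes explain %.1f%% + %.1f%%\n",
            explained[1], explained[2]))
write_tsv(data.frame(sample_id = rownames(pc$coordinates),
                     pc$coordinates, check.names = FALSE),
          file.path(RESULTS, "pcoa.tsv"))
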