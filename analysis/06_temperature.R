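# Temperature-diversity association: Kendall rank correlation of each
# alpha metric with mean incubation temperature (one-sided, increasing),
# partial Mantel of community distances vs |dT| controlling river
# distance, five-period incubation means, and forward stepwise regression
# of each alpha metric on the period means.

source("analysis/_common.R")

study <- load_study()
dec <- decontaminated(study)
md <- study$metadata
eggs <- egg_ids(study)

alpha <- alpha_table(otu_table(unclass(dec$table)[eggs, ]), study$tree,
                     n_reps = 10, seed = sub_seed(SEED, "alpha"))

egg_md <- md[md$sample_type == "egg", ]
pm_list <- lapply(seq_len(nrow(egg_md)), function(i)
  period_means(study$temperature, egg_md$spawn_date[i],
               egg_md$sample_date[i], k = 5,
               location_id = egg_md$location_id[i]))
pm_mat <- do.call(rbind, lapply(pm_list, `[[`, "period_means"))
dimnames(pm_mat) <- list(egg_md$location_id, paste0("period_", 1:5))
overall <- setNames(vapply(pm_list, `[[`, numeric(1), "overall_mean"),
                    egg_md$location_id)
write_tsv(data.frame(location_id = rownames(pm_mat), pm_mat,
                     overall_mean = overall, check.names = FALSE),
          file.path(RESULTS, "period_means.tsv"))

conn <- egg_md$location_id[egg_md$river_group != "other_basin"]
egg_of <- setNames(egg_md$sample_id, egg_md$location_id)
beta <- unifrac(dec$table, study$tree)
u <- beta[egg_of[conn], egg_of[conn]]; dimnames(u) <- list(conn, conn)
geo <- corrected_geo_distance(study$network, conn, lambda_up = 1)

assoc <- temperature_association(
  alpha, overall, u, geo,
  location_of = setNames(egg_md$location_id, egg_md$sample_id),
  n_perm = 99999, seed = sub_seed(SEED, "assoc"))
cat("Alpha diversity vs mean incubation temperature:\n")
for (met in names(assoc$kendall)) {
  cat(sprintf("  %-17s", met)); print(assoc$kendall[[met]])
}
cat("UniFrac vs |dT| controlling river distance: ")
print(assoc$partial_mantel)

cat("\nForward stepwise regression on five period means:\n")
for (met in unique(alpha$metric)) {
  sub <- alpha[alpha$metric == met, ]
  y <- sub$mean[match(egg_md$sample_id, sub$sample_id)]
  cat(sprintf("  %-17s", met))
  print(forward_stepwise(y, pm_mat, entry_p = 0.05))
}
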