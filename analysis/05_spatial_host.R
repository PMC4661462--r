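# Spatial and host-genetic structure within the connected river system:
# Mantel test of UniFrac vs along-river distance (and the flow-corrected
# variant, reported side by side), partial Mantel controlling for
# temperature differences, Jost's D over the microsatellite genotypes and
# its Mantel association with community distances, and the
# slope-convergence subsampling diagnostic.

source("analysis/_common.R")

study <- load_study()
dec <- decontaminated(study)
md <- study$metadata
n_perm <- 99999

conn <- md$location_id[md$sample_type == "egg" &
                         md$river_group != "other_basin"]
egg_of <- setNames(md$sample_id[md$sample_type == "egg"],
                   md$location_id[md$sample_type == "egg"])
beta <- unifrac(dec$table, study$tree)
u <- beta[egg_of[conn], egg_of[conn]]
dimnames(u) <- list(conn, conn)

geo1 <- corrected_geo_distance(study$network, conn, lambda_up = 1)
geo2 <- corrected_geo_distance(study$network, conn, lambda_up = 2)

m1 <- mantel_test(u, geo1, n_perm = n_perm, tail = "greater",
                  seed = sub_seed(SEED, "mantel1"))
cat("UniFrac vs plain river distance:      "); print(m1)
m2 <- mantel_test(u, geo2, n_perm = n_perm, tail = "greater",
                  seed = sub_seed(SEED, "mantel2"))
cat("UniFrac vs flow-corrected (lambda=2): "); print(m2)

tt <- study$ground_truth$mean_temperature[conn]
tdiff <- abs(outer(tt, tt, "-")); dimnames(tdiff) <- dimnames(geo1)
pm <- partial_mantel_test(u, geo1, tdiff, n_perm = n_perm,
                          tail = "greater",
                          seed = sub_seed(SEED, "partial"))
cat("UniFrac vs distance | temperature:    "); print(pm)

dest <- jost_dest(study$genotypes)
print(dest)
write_distance_matrix(dest$pairwise, file.path(RESULTS, "dest.tsv"))
md_mantel <- mantel_test(u, dest$pairwise[conn, conn], n_perm = n_perm,
                         tail = "greater", seed = sub_seed(SEED, "dest"))
cat("UniFrac vs host D_est:                "); print(md_mantel)

sl <- slope_convergence(u, geo2, max_removed = length(conn) - 4,
                        n_draws = 200, seed = sub_seed(SEED, "slopes"))
cat("\nSlope of UniFrac on corrected distance under subsampling:\n")
print(sl$summary, digits = 3)
write_tsv(sl$summary, file.path(RESULTS, "slope_convergence.tsv"))
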