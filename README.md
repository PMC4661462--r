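# eggbiome

Phylogeny-aware analysis of bacterial communities on naturally spawned
fish eggs across river networks.

Salmonid eggs incubate for weeks in river gravel, open to microbial
colonization. Given a 16S rRNA amplicon survey of pooled egg samples
from spawning locations in one or more river systems — an OTU count
table, a rooted phylogeny over the OTUs, temperature-logger series,
along-river distances and host microsatellite genotypes — this package
answers the questions such a survey poses:

* **How diverse is each community?** Chao 1, observed species and
  Faith's phylogenetic diversity (`chao1()`, `observed_species()`,
  `faith_pd()`), with rarefaction to a common depth (`rarefy_counts()`,
  `alpha_table()`, `rarefaction_curves()`).
* **How different are communities?** Unweighted (and weighted) UniFrac
  (`unifrac()`), principal coordinates (`principal_coordinates()`),
  one-way PERMANOVA / ANOSIM / dispersion homogeneity (`permanova()`,
  `anosim_test()`, `dispersion_test()`), and a read-resampling
  **bootstrap test of one community against a group**
  (`bootstrap_one_vs_group()`) for the comparisons where equal-variance
  assumptions fail, plus a PERMANOVA power curve against group size
  (`permanova_power_curve()`).
* **Is there spatial or host-genetic structure?** Mantel and partial
  Mantel tests (`mantel_test()`, `partial_mantel_test()`),
  flow-corrected along-river distances (`corrected_geo_distance()`),
  Jost's D population differentiation from diploid microsatellites
  (`jost_dest()`), and a slope-stability subsampling diagnostic
  (`slope_convergence()`).
* **Does diversity track temperature?** Kendall's tau-b with a
  tie-corrected normal approximation (`kendall_tau()`), incubation-period
  temperature means (`period_means()`), forward stepwise regression on
  period temperatures (`forward_stepwise()`), and a bundled association
  report (`temperature_association()`).
* **Quality control**: barcode/primer/length/ambiguity read filtering
  (`filter_reads()`) and negative-control decontamination
  (`remove_control_otus()`).
* **A synthetic study generator** (`simulate_study()`) that emulates the
  whole field design — nine locations in two river systems, ~4,780
  reads per pooled sample (SD 1,165), water samples, a blank control
  with 78 contaminant OTUs, a temperature-driven richness gradient and
  11-locus host genotypes — with ground truth recorded, so the entire
  workflow runs and is tested at desk scale with no external data.

The statistical core in brief: unweighted UniFrac between communities A
and B is

    d(A, B) = sum of branch lengths unique to A or B
              -----------------------------------------
              sum of branch lengths covered by A or B

and the bootstrap one-vs-group test compares the observed mean UniFrac
distance from a query community to a group against a null built by
re-sampling reads with replacement from the pooled group counts
(multinomial pseudo-communities at the query's depth), reported as
`null mean (95% CI: lo; hi), observed, p` with the add-one rule
`p = (#{null >= observed} + 1)/(B + 1)`.

## Worked example

```r
library(eggbiome)

study <- simulate_study(simulation_config(seed = 42))
dec   <- remove_control_otus(study$table, study$metadata)
length(dec$removed_otus)
#> [1] 78

beta <- unifrac(dec$table, study$tree)
eggs <- study$ground_truth$egg_sample_ids

# the lone other-basin community against the main-river group
boot <- bootstrap_one_vs_group(
  dec$table, study$tree,
  query_id  = "egg_loc_01",
  group_ids = c("egg_loc_02", "egg_loc_03", "egg_loc_04",
                "egg_loc_05", "egg_loc_06"),
  B = 1000, seed = 1)
print(boot)
#> Bootstrap one-vs-group test (egg_loc_01 vs 5 samples, B = 1000)
#>   mean UniFrac bootstrapping distance of 0.374 (95% CI: 0.370; 0.377), observed UniFrac distance 0.512, p = 0.000999

# alpha diversity vs incubation temperature
m <- unclass(dec$table)[eggs, ]
y <- apply(m, 1, chao1)
print(kendall_tau(study$ground_truth$mean_temperature, y,
                  tail = "greater"))
#> Kendall: tau = 1, z = 3.75, p = 8.73e-05 (greater, n = 9)
```

The observed distance far above the resampling null says the other-basin
community is not a plausible re-draw of the main-river communities' reads;
the positive tau recovers the temperature-richness gradient the generator
planted (25 taxa per degC).

The numbered scripts under `analysis/` run the full study analysis —
simulation, quality control, diversity, community comparisons, spatial
and host-genetic structure, temperature association — writing tables
under `results/`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_quality_control.R
# ... through 06
```

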