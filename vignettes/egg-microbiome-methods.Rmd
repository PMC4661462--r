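---
title: "Methods: phylogeny-aware analysis of egg-associated bacterial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-aware analysis of egg-associated bacterial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

Salmonid eggs incubate for weeks in river gravel, open to microbial
colonization. A 16S rRNA amplicon survey of such eggs across a river
network asks three questions this package operationalizes: (1) do
egg-associated bacterial communities show isolation by distance along the
river network, (2) do they track the neutral genetic differentiation of
their host populations, and (3) does their diversity respond to water
temperature during incubation? The unit of observation is a *spawning
location*: eggs from several nests are pooled into one sequencing sample
per location, accompanied by water samples at a subset of locations and a
reagent-only negative control.

All computation lives in the package (`R/`); the numbered scripts under
`analysis/` are thin drivers that run the stages on a synthetic study and
write tables under `results/`.

# Quality control

Reads are retained iff they (i) carry a perfect match to their 10-bp
barcode and the 16S primer, (ii) are at least 300 bp long after
trimming the barcode + primer prefix, and (iii) contain at most two
ambiguous bases. Two choices here were genuinely open:

* **Failure attribution.** A read can violate several criteria; the
  report attributes it to the first violated criterion in the order
  (i), (ii), (iii). Retention is unaffected by this choice.
* **Where the length is measured.** The 300-bp threshold is applied to
  the read after the barcode and primer are removed, because the 311-bp
  amplicon is defined downstream of the primer.

Decontamination removes every OTU *detected* (count >= 1, no abundance
threshold) in the blank control from all samples, then drops the control
sample. Reference-database filters and chimera removal are out of scope
(they require external, version-dependent references).

# Diversity

* **Chao 1** uses the bias-corrected form
  `S_obs + F1(F1-1)/(2(F2+1))`, finite even without doubletons; the
  classic form is available by flag.
* **Faith's PD** sums the branch lengths of the minimal subtree
  connecting the present taxa *and the root* (the convention of the
  QIIME toolchain this analysis style descends from); a flag excludes
  the root connection.
* **Rarefaction** subsamples reads without replacement (multivariate
  hypergeometric). The default common depth is the minimum sample depth
  — the most conservative choice when per-location depths vary and no
  single depth is canonical. `alpha_table()` averages metrics over
  `n_reps` rarefactions and reports the Monte-Carlo SD.
* **Unweighted UniFrac** is the ratio of branch length unique to either
  community to the branch length covered by their union, computed from a
  branch x tip incidence matrix so whole distance matrices reduce to a
  few matrix products. Distances are computed on raw presence/absence by
  default; rarefying first is possible but not forced, since presence
  profiles at these depths are stable. The normalized weighted variant
  is provided for abundance-driven questions.
* **PCoA** is classical scaling of `-D^2/2`. All eigenvalues are
  reported, including negative ones from non-Euclidean distance
  matrices; negative axes are dropped from coordinates without
  correction by default (the simplest faithful choice). The Cailliez
  correction — the smallest additive constant making the configuration
  Euclidean, found as the largest eigenvalue of the standard 2n x 2n
  companion matrix — is switched on by default only inside the
  dispersion test, which needs a complete embedding.

# Community comparisons

`permanova()` implements the one-way Anderson decomposition
(`SS_total = sum d^2 / N`, within-group sums weighted by group size);
`anosim_test()` the mid-rank R statistic; `dispersion_test()` distances
to group centroids in the (Cailliez-corrected) embedding with a
label-permutation ANOVA F. All permutation p-values use the add-one rule
`(hits + 1)/(n_perm + 1)` and can never return zero; when `n!` fits
within the permutation budget the tests switch to exhaustive enumeration
and report the exact proportion instead. The permutation unit is the raw
group label — appropriate for these one-way designs.

**The bootstrap one-vs-group test** addresses comparisons a PERMANOVA
handles badly: one community (a single water sample, or the lone
other-basin location) against a group, where the equal-variance
assumption between a "group" of one and a group of many fails. The
observed statistic is the mean unweighted UniFrac distance from the
query to each group member. The null resamples *reads* with replacement
from the pooled group counts: each replicate draws a multinomial
pseudo-community at the query's depth and records its mean distance to
the members. Reported: null mean, percentile 95% CI, one-sided
`p = (#{null >= observed}+1)/(B+1)`, with B = 1,000 by default. The
resampling unit (reads), replicate count and CI method are configuration
knobs; read-level resampling was chosen because the sequencing sample is
the natural exchangeable unit for "re-sampling with replacement" on
amplicon data. The same resampling drives the PERMANOVA power curve
against per-group sample size.

The core microbiome keeps OTUs present in at least
`ceiling(min_fraction * n_samples)` samples (0.77 of nine samples
resolves to seven). Differential features between eggs and water use
Welch's two-sided t-test per feature, Benjamini-Hochberg adjustment, and
a practical-effect filter (absolute difference of group means > 5
percentage points); only features present in both groups are compared.

# Spatial and host-genetic structure

Mantel and partial Mantel tests correlate lower-triangle entries, with
simultaneous row/column permutation of the first matrix (the simple
permutation scheme, as in common `ecodist` usage). The partial
correlation uses the first-order closed form; the degenerate case where
the second matrix *is* the control returns the algebraic zero. Spatial
and temperature hypotheses are tested one-sided by default.

River distances are along-network path lengths. Because upstream travel
against the current is costlier than downstream drift, a *flow-corrected*
distance is offered: the unique network path is decomposed into
downstream and upstream lengths relative to the travel direction, the
directed cost is `L_down + lambda_up * L_up`, and the symmetric distance
is the mean of the two directed costs. `lambda_up = 1` recovers the plain
distance; the default correction uses `lambda_up = 2`, and the analysis
reports plain and corrected results side by side. This cost model is
this package's own explicit construction for flow correction; its single
parameter is configurable. One consequence worth knowing: on a
tree-shaped network the two directed costs always sum to
`(1 + lambda)(L_down + L_up)`, so the symmetrized corrected matrix is a
global rescaling of the plain one and scale-invariant statistics
(Mantel r) coincide for all `lambda_up`. A correction that changes
relative distances would need asymmetric statistics or a non-additive
cost, both outside this model.

Host differentiation uses Jost's "actual differentiation" D:
within-population heterozygosity with the Nei-Chesson small-sample
correction on the harmonic-mean sample size, total heterozygosity from
the pair's mean allele frequencies *with the matching small-sample
correction* `H_T += H_S/(2 N' n)` (without it, null populations show
spuriously positive D of the order of `1/(2N)`), and
`D = ((H_T - H_S)/(1 - H_S)) * n/(n-1)` per pair. Loci combine through
across-locus means of the H components rather than averaging per-locus D
(per-locus values are also reported); small negative estimates are
clamped to zero with the raw values retained. The slope-convergence
diagnostic refits the OLS slope of one distance matrix on another over
random sample subsets of decreasing size, showing whether a slope
estimate is stable at the study's number of pairwise comparisons.

# Temperature analysis

Kendall's tau uses the tau-b tie correction in both margins (alpha
diversity tables contain exact ties, so tie handling is mandatory) and
the classical tie-adjusted normal approximation for z; exact enumeration
is available for n <= 8. The incubation interval is split into five
consecutive periods of equal calendar-day length (remainder days to the
last period); period means average the 10-minute readings in each
half-open period, and the overall mean is the duration-weighted mean of
period means. Forward stepwise regression enters, at each step, the
candidate with the largest partial F if its p-value is below the entry
threshold (default 0.05, configurable), reporting the cumulative model F
with `(q, n-q-1)` degrees of freedom. The "variation in water
temperature" matrix for the partial Mantel test is `|T_i - T_j|` over
location mean temperatures — a construction of this package, as no
canonical definition exists.

# The synthetic study generator

`simulate_study()` emulates the sampling design so every stage runs at
desk scale with known ground truth:

* **Design constants**: nine locations (one in a separate alpine basin,
  ~60% of the rest on the main river, the others on tributaries), read
  depths `Normal(4780, 1165^2)` truncated at 500, two water samples, one
  negative control carrying 78 contaminant OTUs, 11 microsatellite loci
  with 20-36 individuals per population, 10-minute temperature logging.
* **Abundance model**: each location draws its available taxa from a
  600-taxon pool with log-normal relative abundances (sigma = 1.2) and
  multinomial read sampling — a standard construction that produces the
  singleton/doubleton structure Chao 1 relies on.
* **Temperature**: per location, a base temperature in 2-6 degC (the
  separate-basin site pinned to the cold end), a sinusoidal daily cycle
  (amplitude 0.5 degC), a mild seasonal trend, AR(1) per-period weather
  regimes (SD 0.8, autocorrelation 0.6, emulating multi-day synoptic
  weather), and logger noise. Available richness is
  `S_i = round(80 + 25 * T_i)` on the *realized* mean of the driver
  periods (the whole incubation by default), so parameter-recovery tests
  compare against exactly what was planted.
* **Contamination**: the control detects every contaminant at least
  once; each contaminant leaks into each real sample with the carryover
  probability, contributing about 2% relative abundance in total.
* **Genotypes**: per locus, pool frequencies are Dirichlet(1) over eight
  alleles; population frequencies drift along the river-network order via
  `Dirichlet(prev * (1-theta)/(theta * step))` (Balding-Nichols style),
  so differentiation rises with both `theta_div` and network distance,
  and `theta_div = 0` gives identical frequencies everywhere.

What the generator does *not* emulate: within-location egg-to-egg
variance (eggs are pooled before sequencing, and no variance estimate
exists to calibrate it), sequencing error beyond the three QC-relevant
corruption modes, chimeras, taxonomic identity, and any ecological
interaction between taxa. Passing tests therefore demonstrate that the
statistics recover what this generative model plants — not that the
model captures every feature of real amplicon data.

# Numerical and reproducibility choices

Distance matrices tolerate asymmetry up to 1e-8 (symmetrized by
averaging; larger asymmetry errors). Permutation statistics compare with
a 1e-12 slack so exact ties count as "at least as extreme". Every
stochastic function takes a `seed`; seeding is scoped (the previous RNG
state is restored on exit), so seeded calls are deterministic without
freezing the randomness of surrounding simulation loops. The pipeline
derives per-stage sub-seeds from the master seed and the stage name, so
reconfiguring one stage never shifts another stage's draws; rerunning a
configuration reproduces results files byte for byte (timestamps only in
the log).

Problem sizes in the test-suite simulations — 500 replicates for null
calibration, 100 studies for parameter recovery, 200 random instances
for oracle equivalence — were chosen as the smallest sizes at which the
binomial/Monte-Carlo error of the checked rates is comfortably inside
the asserted bands.

# Known limitations

* The flow-correction cost model and the `|dT|` matrix are this
  package's constructions for procedures whose exact definitions are not
  recoverable; both are parameterized and reported alongside the plain
  variants.
* PERMANOVA is one-way only (no strata, no multi-factor designs).
* The bootstrap test's null pools the whole reference group; pooling a
  subset per comparison is possible via the `group_ids` argument but no
  default subsetting is imposed.
* Binary BIOM/HDF5, NEXUS and GenePop binary formats are not read; the
  plain-text dialects documented in the IO functions are the interface.
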