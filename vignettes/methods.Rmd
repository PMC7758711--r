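---
title: "Methods: trajectory analysis, parallelism and community statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis, parallelism and community statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`ecoevo` implements the statistical core of a serial-transfer evolution
experiment in which a focal *Stenotrophomonas* species adapts to wheat
straw either alone (monoculture, MC), in a polyculture reset to the
ancestral community each transfer (RP), or in a polyculture whose
eco-evolutionary dynamics play out freely (DP). Four analyses operate on
four table kinds:

1. **Phenotypic trajectory analysis (PTA)** of the multivariate
   substrate-use phenotype: respiration on seven lignocellulose
   substrates (xylan, arabinoxylan, galactomannan, pectin, β-glucan,
   cellulose, lignin) per replicate population and transfer.
2. **Mutational parallelism** from a called-variant table of evolved
   clones, via Jaccard similarity and permutational ANOVA.
3. **Community–phenotype covariance** from a compositional species
   time series, via Bray–Curtis dissimilarity and regression.
4. **Growth statistics** from CFU density pairs, via the Malthusian
   parameter and classical ANOVA.

A seed-reproducible generator simulates all four table kinds with the
experiment's shapes, so the whole pipeline runs and is tested without
any external data.

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions
and write their tables under `results/`; the functions themselves (plus
the scripts and this vignette) are the interface, and no shell wrapper
is provided.

# The trajectory model

The response is the matrix $Y$ ($n \times p$, $p = 7$ substrates) of
respiration profiles, one row per population sample. The full model is
the factorial MANOVA

$$Y = \mu + \text{treatment} + \text{time} + \text{treatment:time} + E,$$

with **time (transfer) as a categorical factor**: trajectories are
sequences of points, one per assayed transfer, not a dose–response
curve. Sums of squares are sequential (treatment, then time, then the
interaction), each the trace of the corresponding cross-product matrix;
on the balanced designs this experiment uses, term order is irrelevant,
and unbalanced inputs get a warning. The observed interaction statistic
is the multivariate pseudo-F

$$F = \frac{\mathrm{tr}(SS_{\text{int}})/df_{\text{int}}}
          {\mathrm{tr}(SS_{\text{res}})/df_{\text{res}}},$$

which reduces exactly to the classical two-way interaction F when
$p = 1$ (a test asserts agreement to 1e-8, and to the Euclidean
distance-based permutational MANOVA of `vegan::adonis2`).

**RRPP.** Significance comes from randomization of residuals in a
permutation procedure: residuals of the reduced additive model
(`treatment + time`) are permuted across observations, added back to
the reduced-model fitted values, and the full model is refit to each
pseudo-dataset. The reduced model embodies the null of parallel
trajectories while preserving both main effects.

**Trajectory attributes.** Least-squares cell means (for this saturated
factorial, the cell means of the fitted values) ordered by transfer
form one trajectory per treatment. Three attributes are compared
pairwise between treatments, each against the same RRPP null:

* *path length* — summed Euclidean distance between consecutive points;
  statistic $|d_A - d_B|$;
* *direction* — first eigenvector of the covariance of a trajectory's
  points, sign-oriented so the first-to-last displacement projects
  positively; statistic the angle $\arccos |u_A \cdot u_B|$ in degrees,
  hence in $[0^\circ, 90^\circ]$;
* *shape* — configurations translated to a common centroid, scaled to
  unit centroid size and optimally rotated (orthogonal Procrustes via
  SVD, reflections allowed); statistic the root summed squared
  difference of superimposed configurations. This matches
  `vegan::procrustes(symmetric = TRUE, scale = FALSE)` and is zero for
  any translated/scaled/rotated copy.

The ordination reported alongside is a covariance PCA **of the fitted
values** with all observations projected onto its components, so the
plot shows the modelled trajectories with the raw data scattered around
them. Substrates enter on their raw respiration scale by default
(`scale = TRUE` rescales to unit variance).

**Ancestral time point.** When transfer 0 is present it is included as
a shared first trajectory point, and the default generator includes it;
analyses restricted to transfers 4–16 simply omit those rows.

# Permutation conventions

* $p = (b + 1)/(m + 1)$, counting the observed arrangement; hence
  $p \ge 1/(m+1)$ and the test is valid at any $m$.
* Whenever $m \ge n! - 1$ and $n! \le 5040$, the complete enumeration
  of row permutations is used and the p-value is exact; a test checks
  it against an independently enumerated brute-force oracle.
* The effect size $Z$ is the standard deviate of the observed statistic
  against the permutation distribution (observed included). Published
  trajectory-analysis implementations differ in whether they transform
  the distribution first; `transform = "log"` applies a log transform
  for positive statistics, plain is the default. Exact equality of $Z$
  with published values is therefore not promised, only the
  sign/significance structure.
* Ties are counted with a relative tolerance of `1e-8` so permutations
  equivalent by design symmetry (e.g. residual swaps within a cell)
  count as ties despite round-off.
* F statistics with a term sum of squares of exactly zero are reported
  as 0 (not 0/0), so degenerate inputs (identical groups, noise-free
  additive data) give $F = 0$, $p = 1$.
* Eigenvector sign ties in the direction attribute are broken by
  orienting along increasing time; exact ties raise a
  degenerate-direction error rather than guessing.

# Parallelism statistics

Each sequenced clone contributes a set of mutated locus tags,
restricted by default to **non-synonymous** mutations (the biological
claim concerns loci affected by non-synonymous change; `classes =
"all"` reproduces count-based analyses). Similarity between clones is
the Jaccard index — loci mutated in common over loci mutated in either.
Two mutation-free clones are identical profiles, so the empty-union
Jaccard defaults to 1; because the source analyses do not state their
convention, `empty_union = "zero"` is available.

The permutational ANOVA takes as observations **all $N^2$ ordered cells
of the similarity matrix, diagonal included**, grouped by the unordered
treatment pair of the two clones ($T(T+1)/2$ groups; 6 for three
treatments). This observation set is what reproduces the
$(5,\,570)$-type degrees of freedom of a 24-clone experiment
($24^2 - 6 = 570$). The observed statistic is the one-way F across
groups. Pairwise contrasts compare, for each treatment pair (A, B), the
between-treatment cells (A:B) against the pooled within-treatment cells
(A:A and B:B) with a pooled-variance t; a negative t means clones are
less similar across treatments than within — genetic differentiation.
Which cells the source contrasts compared is not stated; this choice
reproduces their sign structure and is flagged as an inference.

**Permutation schemes.** Two are provided because the published unit of
permutation is unstated:

* `clone_labels` (default): permute the clone-to-treatment map and
  regroup the cells. This respects the dependence structure of the
  matrix (each clone's row and column move together, the diagonal's
  contribution to within-groups is invariant) and is exactly calibrated
  under the uniform-hotspot null — the acceptance suite measures its
  size at the nominal 0.05.
* `cell_values`: permute the cell values over the fixed grouping. This
  treats dependent cells as exchangeable and, because the unit diagonal
  is concentrated in within-treatment groups for the observed labelling
  but scattered by permutation, it rejects far above nominal under the
  null. It is provided for sensitivity analysis.

These two schemes trade power for validity in opposite directions. Under
`clone_labels` the null distribution of F is heavy-tailed: the F value
depends on how cliques of mutually similar clones — the hotspot-sharing
clones, and under the empty-union-1 convention the mutation-free
clones — scatter across cell groups of very different sizes, and
arrangements that concentrate a clique in a small group (e.g. a 6-clone
treatment's 36-cell within-group) produce larger F than arrangements
spreading it over a large group. The consequence, measured by the
acceptance suite, is that the calibrated scheme detects a
hotspot-driven parallelism signal of the magnitude this experiment
produced (a hotspot locus hit in roughly half the clones of two
treatments) with power well below the suite's 0.8 target at 24 clones,
whereas near-floor p-values of the kind published for such data are
reachable only under cell-value permutation, whose size is not
controlled here. We keep the calibrated scheme as the default and
report this tension rather than hiding it; with only 24 clones, label
permutation simply has limited resolution for this statistic.

Mutation-count comparisons use Welch's heteroscedastic one-way ANOVA
(`stats::oneway.test`), with the Welch–Satterthwaite denominator df.

# Community and growth statistics

Bray–Curtis dissimilarity $\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ is
applied both to species relative-abundance profiles and to substrate
respiration profiles, so community divergence and phenotypic divergence
are measured on the same scale. The covariance analysis regresses
phenotype dissimilarity on community dissimilarity, **transfer as a
continuous covariate**, and their product, reporting the sequential F
of the interaction with 1 numerator df — the continuous-time form is
what yields a single-df interaction test of a strengthening
association. The observation unit is the replicate pair × transfer with
no correction for the non-independence of pairs sharing a replicate;
this mirrors the source analysis and is a known caveat, so the
interaction p-value should be read as descriptive. Endpoint
associations (e.g. cellulose respiration against final *Bacillus*
abundance) are simple linear regressions with $F(1, n-2)$.

Growth rates are Malthusian parameters $\ln(N_f/N_0)$ per 6-day cycle
(the default unit; within a fixed cycle the time scale cancels from all
comparisons, and `per_day = TRUE` divides by the duration). The
treatment × growth-condition interaction is a fixed-effects two-way
ANOVA on these rates; competitive outcomes across treatments use a
one-way ANOVA with Tukey HSD (studentized range, pooled within-group
variance), both via `stats::aov`.

# The synthetic-data generator

The generator's defaults are the study conditions: treatments MC/RP/DP
with 12/6/6 replicates, transfers 0, 4, 8, 12, 16, seven substrates,
one sequenced clone per replicate (24 clones) with Poisson mean
$33/24 = 1.375$ mutations per clone of which 66.6% are non-synonymous,
a six-species community followed in the DP replicates, and 6-day growth
assays from $10^6$ CFU/mL.

* **Phenotypes** are baseline + per-treatment displacement at each
  transfer + a per-replicate scalar + Gaussian noise, truncated at zero
  (respiration is nonnegative; the truncated-Gaussian choice is the
  simplest model matching the assay floor — the source gives no
  distributional description of the assay, so this is a stand-in, not
  an inference). The default displacement field encodes the study's
  qualitative finding: a short MC path, an RP path toward labile
  substrates, and a DP path that pivots from labile toward recalcitrant
  substrates mid-experiment. Default noise scales (residual SD 0.15,
  replicate SD 0.10, baseline 1.2 labile / 0.6 recalcitrant respiration
  units) are chosen once as plausible assay-scale values. The replicate
  effect is a single additive scalar shared across substrates and
  transfers, mimicking population-level growth differences.
* **Mutations** are locus draws without replacement under per-treatment
  hotspot weights over a 60-locus pool; the default puts elevated
  weight on a `tctE`-like regulator locus in DP and MC (0.36/0.24)
  versus RP (0.12), emulating the observed hit fractions.
* **Community** composition is a phenomenological log-abundance random
  walk (species sorting) softmax-normalised per transfer; the
  reinvasion scenario forces the designated species (default
  *Bacillus*) to near-zero over the middle transfers and lets it
  recover in the first $\lceil n/2 \rceil$ replicates, mirroring
  reinvasion of half the replicate communities. No mechanistic
  cross-feeding or resource competition is simulated.
* **Growth** is exponential with Gaussian noise on the log scale, so
  the configured mean rate is recovered exactly at zero noise. The
  default rate table makes community context always beneficial and
  gives RP-evolved populations a distinctively large competitive boost,
  reproducing the published interaction structure.

Each generator draws from its own RNG stream (master seed + a fixed
offset), so adding one generator to a pipeline never perturbs
another's draws, and equal seeds give byte-identical outputs.

What the generator does **not** emulate: within-replicate temporal
autocorrelation of the phenotype beyond the constant replicate effect,
any mechanistic coupling between community composition and the evolved
phenotype (the two streams are independent, so community–phenotype
regressions on default synthetic data hover near their null), linkage
among mutations, or measurement error in CFU counts. Passing tests on
synthetic data therefore certify the statistics, not the biology.

# Operating characteristics and problem sizes

The acceptance suite measures, besides oracle equivalence on small
fixtures:

* **Size**: with zero displacement everywhere (and `replicate_sd = 0`,
  see below) the RRPP interaction test, and with uniform hotspots the
  parallelism permANOVA, reject at 0.05 ± 0.03 over 500 simulations
  with 199 permutations each.
* **Power**: with one treatment's trajectory displaced by 3 residual
  SDs per transfer on one substrate, RRPP power exceeds 0.8 at 6
  replicates (200 simulations); the parallelism power scenario (hotspot
  weight 0.5 in DP and MC, absent in RP, 24 clones) is measured
  likewise and falls short of 0.8 under the calibrated default scheme,
  as discussed above.
* **Recovery**: the covariance regression recovers a known interaction
  slope within 3 standard errors at $n = 100$.

The calibration and power runs set `replicate_sd = 0`: the
per-replicate scalar induces within-replicate correlation across
transfers, under which raw observations are not exchangeable and any
residual-permutation test is conservative for the interaction (time
contrasts cancel the replicate effect from the signal but not from the
permuted error). This is a real limitation for applying RRPP to
repeated-measures designs like this experiment; the repeated-measures
mixed model that would absorb it is deliberately out of scope here.

Simulation sizes (500 null and 200 power replicates at 199
permutations; 999 permutations for trajectory tests and 10,000 for
parallelism in the full pipeline) follow the operating-characteristic
conventions above and keep the whole suite comfortably reproducible on
a single CPU.

# Known limitations

* Observed RRPP F is permutation-free, but p and Z depend on the seed
  unless the enumeration is exact; report `n_permutations` and `seed`
  (the pipeline report does this automatically).
* The parallelism F's null distribution under label permutation is
  heavy-tailed at small clone counts; treat non-significant results at
  $N \approx 24$ as low-resolution, not as evidence of absence.
* Replicate-pair dissimilarity observations are not independent;
  interaction inference there is descriptive.
* Jaccard similarity treats loci as exchangeable labels: no windowing,
  gene-family collapsing, or correction for locus length/mutability.
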