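---
title: "Methods and design notes for deepspring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for deepspring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepspring)
```

`deepspring` supports a specific comparative question: whether the microbial
communities of thermal springs resemble those of the deep fracture water
that may feed them.  The data that question produces are awkward —
a handful of sites, wildly unequal sequencing depth (hundreds of reads for
springs, tens of thousands for boreholes), different amplicon regions per
environment, and no replicates — and every method in the package is chosen
with those constraints in mind.  This vignette records the models, the
defaults, and the design decisions that were genuinely open.

## Diversity statistics

Within-site diversity uses base-2 logarithms throughout: Shannon entropy
`shannon()` is reported in bits and Pielou's evenness divides by
`log2(G_obs)`, so a perfectly even community scores 1 regardless of
richness.  The base is a parameter for users who prefer nats.

`chao1()` extrapolates richness as `G_obs + F1^2 / (2 F2)`.  Two numerical
choices were open:

* **No doubletons.**  The defining ratio is undefined at `F2 = 0`, which
  happens routinely in shallow samples.  We use the bias-corrected form
  `G_obs + F1 (F1 - 1) / 2`, the standard fallback, rather than failing.
* **The standard error.**  Published tables attach a "±" to Chao1 without
  stating a formula.  We implement the classical Chao (1987) variance for
  both branches and document it as an interpretation: if the "±" was a
  confidence half-width instead, our values will differ by a constant
  factor.

Coverage (`coverage_percent()`) is the rounded percentage of estimated
richness actually observed; it is how an inventory says "this site is about
two-thirds done".

Rarefaction (`rarefaction_curve()`, `rarefy()`) subsamples reads without
replacement, so its expectation follows the hypergeometric closed form
`E[S_d] = sum_i (1 - C(N - n_i, d) / C(N, d))`; the test suite checks the
Monte-Carlo mean against that closed form rather than against another
simulation.

## Between-site comparison

The Sørensen index `2c/(a+b)` is shared-presence bookkeeping and is highly
sensitive to sequencing depth — deeper sampling finds more shared taxa.
The Morisita index is the primary between-site statistic precisely because
its λ-normalisation makes it approximately depth-invariant; the test suite
demonstrates this by rarefying one member of a site pair to a quarter of
its reads and bounding the change in C_λ by 0.05, a bound Sørensen would
not meet in general.

Three decisions were open:

* **Raw counts, not rarefied or relative abundances.**  The defining
  formula uses integer `n (n - 1)` terms; feeding it proportions would
  silently change the statistic.
* **Clamping.**  The classical form (unlike Morisita–Horn) can exceed 1
  for small, concentrated samples — `morisita(c(2, 2), c(2, 2))` gives
  C_λ = 1.5.  A dissimilarity of `1 - C_λ` must stay nonnegative to be
  clusterable, so it is clamped at 0 with a warning rather than passed
  through.
* **Linkage.**  The dendrogram uses UPGMA (average linkage) by default,
  the convention for community dissimilarity trees; single and complete
  linkage are available.  Agglomeration is implemented in the package with
  a deterministic lowest-pair-index tie-break so results are reproducible
  across platforms; `stats::hclust` serves as an independent oracle in the
  tests, never as the implementation.

## Environmental correlation

`bioenv()` answers "which environmental variables, jointly, best mirror
community turnover?" by brute force: every nonempty subset of the candidate
variables is z-scored (sample standard deviation, n − 1), converted to a
Euclidean site-by-site distance matrix, and Pearson-correlated with the
community dissimilarity matrix.  With k = 9 variables that is 511 matrix
correlations — trivial at these site counts, and exhaustiveness removes any
model-selection ambiguity.  A guard refuses k > 20 unless overridden.

Matrix correlation vectorises the strictly upper triangles by default,
avoiding the zero diagonal and double-counted symmetric pairs.  Whether a
spreadsheet-style analysis would have correlated the full matrices is
unknowable in general, so `mode = "full"` reproduces that behaviour; the
two modes give identical r for symmetric matrices up to the diagonal's
dilution effect.  Ties in the subset ranking resolve toward the
smaller, earlier-enumerated subset (parsimony and determinism).

Geographic distances (`great_circle_matrix()`) are haversine distances on
a 6371-km mean-radius sphere via `geosphere`.  At nearest-kilometre
rounding the radius convention does not matter for any distance under
several hundred km.

`estimate_depth()` converts a spring temperature into a minimum
groundwater circulation depth, `(T_water - T_surface) / gradient`, with a
20 °C surface temperature and a 20-30 °C km⁻¹ gradient range as defaults
(typical stable continental crust).  Temperature ranges use their
midpoint; output is rounded to the nearest metre, which is also why the
linearity of the estimate in ΔT holds only up to 1 m in tests.

The phylum-by-environment screen (`taxon_env_correlation()`) takes its
relative abundances from `mean_relative_abundance()` — each site repeatedly
subsampled to 85 % of the smallest site's reads over 1,000 iterations —
so that depth differences do not masquerade as abundance differences.  The
85 % depth uses `floor()`, guaranteeing the common depth never exceeds any
site's total.  Pairs with missing metadata are handled pairwise-complete,
since dropping a whole site for one missing ion would be wasteful at n = 6.
Multiple testing uses Benjamini–Hochberg by default: at these tiny test
families (tens of pairs) BH is deterministic and well-defined, whereas
spline-based π₀ estimation is unstable.  A fixed-λ Storey option
(`method = "storey"`, λ = 0.5) is provided for sensitivity analysis.
Significance requires both p < 0.05 and q < 0.05.

## Sequence operations

Distances between aligned sequences follow the eachgap convention with
terminal gaps ignored: the comparable span excludes leading/trailing gap
runs of either sequence (so a short read aligned inside a longer one is
not penalised for its ends), a gap opposite a base counts as one
difference, and gap-gap columns are excluded from numerator and
denominator alike.

`precluster()` is deliberately *pseudo*-single-linkage: records are
processed in descending abundance and each merges greedily into the first
retained record within `max_diffs` columns.  A chain A–B–C with 1-diff
steps does not collapse into one record, because C is never compared to
the absorbed B.  This matches the denoising behaviour the convention
implies, and the tests pin the greedy trace explicitly.

`cluster_otus()` runs the same average-linkage engine as the community
dendrogram on the eachgap distance matrix, cut at 0.03 (the conventional
97 % identity proxy for genus-like units).  Representatives are the most
abundant members, ties broken lexicographically.  The cross-site
`shared_otus()` procedure reduces each site to its representatives, pools
and dereplicates them, and reclusters at 0.0049 — tight enough that only
near-identical representatives are called shared.  A consistent alignment
across sites is a precondition: the package does not re-align pooled
representatives, and refuses length-mismatched input.

`kmismatch_map()` reports every ungapped placement of a query on a
reference within 0 or 2 mismatches, on both strands.  Strand handling was
an open question; both-strand search is the emulated tools' default and a
forward-only subset is recoverable by filtering the `strand` column.
Offsets are 1-based, the R convention, throughout the package (the same
applies to oligotype component positions).

## Oligotyping

`entropy_profile()` computes per-column Shannon entropy of the
abundance-weighted symbol distribution.  Entropy is in bits so that the
0.2 noise floor heuristic for sequencing error applies on the same scale.
Gaps count as a fifth symbol by default — indel variation is biological
signal in an alignment — with `include_gaps = FALSE` to score only residue
variation.  `decompose()` keys each read by its residues at the component
positions and discards keys below the minimum substantive abundance
(M = 20 by default); retained plus filtered abundance always equals the
input total, so nothing is silently lost.  The package implements a single
supervised pass, not the iterative refinement of full minimum-entropy
decomposition: for the small, pre-grouped read sets this workflow targets
(one genus or one OTU at a time), one pass with a well-chosen component
count is the method actually exercised.

## Synthetic data: what it does and does not emulate

The generators exist so every pipeline stage can be tested end-to-end
without any sequencing data.  `community_scenario()` fixes the study
conditions:

* **subsurface preset** — 7 sites, 900 taxa, a 220-taxon core present at
  every site, 14,000–23,400 reads per site, core carrying 85 % of
  probability mass with lognormal rank-abundance (σ = 0.8) and mild
  per-site lognormal jitter (σ = 0.3).  This produces the signature of
  deeply sequenced fracture-water communities: every pair of sites shares
  the full core and pairwise Morisita dissimilarities stay low.
  `ensure_core = TRUE` moves single reads from the most abundant taxon to
  any core taxon the multinomial draw missed, emulating the
  deep-sequencing guarantee that core taxa are observed.
* **spring preset** — 6 sites, 120–800 reads, a single ubiquitous taxon
  (2 % of mass), and each site dominated (45 % of mass) by its own private
  taxon over a lognormal tail (σ = 1.2).  This reproduces the turnover
  signature of spring communities: dissimilarities near 1 and almost no
  shared presence.

Abundances follow a lognormal rank-abundance model because it reproduces
dominance plus a long rare tail with two parameters; read totals are drawn
uniformly and counts multinomially, so configured totals are conserved
exactly.  What the generator does **not** emulate: chimeras and PCR
artefacts, taxonomic annotation error, the depth of the real rare
biosphere (synthetic subsurface sites saturate their richness, so Chao1
coverage runs near 100 % rather than the ~80 % of real boreholes), spatial
autocorrelation of environmental variables, and compositional coupling
between taxa.  Tests passing on these synthetics therefore validate the
*statistics*, not any claim about real spring biology.

`generate_env()` plants environmental drivers by adding Gaussian noise to
principal-coordinate embeddings of the community dissimilarity matrix, so
the planted variables' Euclidean distances correlate with community
structure by construction.  A single planted variable can only reach
R² ≈ 1 when the dissimilarity matrix is itself one-dimensionally
embeddable; recovery tests therefore use a line-structured dissimilarity
for that case.  The default planted-variable noise (0.2 × the
coordinate's SD) was chosen once as a realistic signal strength for
geochemical drivers.  `generate_reads()` draws reads from planted
haplotypes (default alignment length 61, the V6 amplicon span) with iid
substitution errors at 1 % per base.

## Packaged fixtures

`load_fixture()` serves machine-readable transcriptions of the published
spring and borehole site tables (coordinates in DMS text, parsed to signed
decimal degrees; temperature and pH ranges kept as min/max with midpoints)
plus per-site diversity summaries and printed shared-genus counts.
Censored cells are handled conservatively: "n.a." and "<d.l." become
`NA`, while printed bounds (">1862", "<1e-4") keep the bound as the value
— the least-wrong scalar for distance-based analyses, and flagged here so
users can drop those columns instead.  The
`springs_genus_counts_synthetic` fixture is generated, not observed, data:
a spring-regime community whose per-site totals match the published spring
read counts, shipped so file-reading code has a realistic target.

## Problem sizes and runtime

The test suite runs everything at small scale chosen to keep the full
suite under a minute while leaving Monte-Carlo margins comfortable:
10-sequence sets for the 200 clustering-oracle replicates, 8 environmental
variables (255 subsets) for the 100 bioenv-recovery replicates, 1,000
null replicates for the false-discovery study, and 1,000–2,000 iterations
for subsampling expectations.  All randomness is seeded; every stochastic
assertion states either a closed-form expectation with a 3-standard-error
band or a fixed-seed frozen value.

## Known limitations

* Morisita dissimilarity is undefined for sites whose taxa are all
  singletons (λ₁ + λ₂ = 0) and requires ≥ 2 reads per site; such sites
  must be merged or dropped upstream.
* The shared-OTU procedure assumes alignment columns are consistent across
  sites; when representatives come from separately aligned runs they must
  be re-aligned externally first.
* `bioenv()` reports correlations, not significance: no permutation test
  is attached, by design, since the exhaustive search invalidates naive
  Mantel p-values.
* The average-linkage engine is O(n³) in sequence count; it is meant for
  representative sets and per-genus read groups, not for clustering an
  entire HiSeq run.
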