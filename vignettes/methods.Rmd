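---
title: "Methods: models, null distributions and design choices in cryocomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, null distributions and design choices in cryocomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cryocomm` analyses seasonal marker-gene surveys of glacier-surface
microbial communities: paired 16S/18S ZOTU tables over sampling periods,
qPCR gene-copy totals, a phylogeny, and (optionally) predicted enzyme
abundances. This vignette records how each statistic is defined, which
knobs matter, and why the genuinely open design decisions were resolved the
way they were. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## Data model

Count tables are wide tibbles (`taxon_id` + one numeric column per sample)
carrying a `unit` attribute: `reads`, `relative_fraction` (columns sum
to 1 ± 1e-9) or `copies_per_ml`. Duplicate ids, negative values and NA are
rejected at construction. Readers accept TSV (taxon ids in the first
column, sample ids in the header) and BIOM-JSON via `biomformat`;
taxonomies may be 7-column tables or QIIME-style lineage strings; trees are
newick via `ape`.

## qPCR integration

qPCR reports marker-specific totals (16S and 18S gene copies per mL), so
the only arithmetic consistent with the unit is per marker: prokaryote
relative fractions × 16S copies/mL, eukaryote fractions × 18S copies/mL,
then row-concatenation. The per-sample total of the merged table therefore
equals `copies_16s + copies_18s` exactly (tested to 1e-9 relative).
Unmatched samples and overlapping taxon ids are errors, not silent drops —
a pipeline should fail loudly.

Whether downstream diversity and ordination should use the merged absolute
table or per-marker tables is not decidable from first principles; both are
supported (`pipeline_config(scope = "merged" | "per_marker")`) and the
default is `merged`, which treats the ecosystem as one community on the
copies/mL scale.

Organelle filtering removes any lineage containing the substrings
`chloroplast` or `mitochondria`, case-insensitively at any rank; substring
matching is deliberate because classifiers place the labels at different
ranks.

## The synthetic-community generator

The generator is first-class, tested code; it defines the conditions under
which every recovery property is checked.

* **Design**: 3 periods (accumulation, melt, late melt) × 10 samples;
  sequencing depth Poisson around 5 × 10⁴ reads (16S) and 2 × 10⁴ (18S);
  qPCR totals log-normal (log-scale sd 0.3) around period means
  1.8 × 10⁴, 2 × 10⁸ and 3.8 × 10⁸ copies/mL with the 16S share rising
  0.2 → 0.8 → 0.92 — eukaryote-dominated early, prokaryote-dominated late.
* **Compositional counts**: latent per-taxon log-abundances are multivariate
  normal with a correlation matrix embedding all planted structure
  (a Gaussian copula); per-sample counts are multinomial draws of the
  softmax composition. This is the simplest generator that gives both
  controllable basis correlations and the compositional distortion SparCC
  exists to undo.
* **Planted structure**: taxon mean log-abundances are N(0, 1.5²) (a
  realistic several-orders-of-magnitude abundance spread); a focal phylum
  (default Cyanobacteria) gets per-period multipliers 0.02 / 1 / 3.2 so its
  absolute abundance rises sharply across periods; a keystone phylum
  (default the focal phylum) receives a dense intra-block basis correlation
  of 0.7 plus alternating-sign cross-correlations of 0.3; arbitrary pairs
  can be planted via `correlation_spec`. The assembled matrix must be
  positive definite or the generator refuses with advice to shrink.
* **Environmental filtering**: traits evolve Brownian on a Yule tree,
  are standardised, and `−(trait − optimum_p)² / (2σ_env²)` is added to the
  latent mean; period optima default to an equally spaced grid (−1.2 … 1.2).
  `σ_env = Inf` disables filtering; σ_env ≈ 0.3 is "strong" on the
  standardised trait scale.
* **Function table**: enzyme e in sample s is
  `α_e + β·z(focal abundance) + N(0, σ)`, shifted non-negative. For the
  averaged z-score index the population R² is `β² / (β² + σ²/E)` over `E`
  enzymes; `beta_for_r2()` inverts this, e.g. β for a population R² of 0.5.
* **Determinism**: one master seed; every stage consumes a documented
  substream `seed + 104729·k (mod 2³¹ − 1)`, so identical configurations
  are byte-identical regardless of call order.

What the generator does **not** emulate: sequence-level error, chimeras,
taxonomy misassignment, overdispersion beyond multinomial sampling,
spatial autocorrelation between samples, and copy-number variation between
taxa. Passing recovery tests therefore show the estimators work on
compositional data with known structure — not that real glacier data meet
these assumptions.

## SparCC

For fractions drawn from the per-sample Dirichlet posterior with unit
prior (or the deterministic `(count+1)/total` mode used in unit tests), the
log-ratio variance matrix `t_ij = var log(x_i/x_j)` satisfies
`t_ij = ω_i + ω_j − 2ρ_ij √(ω_i ω_j)`. Summing each row under the sparsity
assumption (correlation terms cancel) gives the linear system
`t_i = (D−2)ω_i + Σ_j ω_j`, which is exactly the normal-equation solution
of least squares on the pairwise system — the test suite checks this
against a brute-force least-squares oracle at D = 4 to 1e-8. Correlations
are `ρ_ij = (ω_i + ω_j − t_ij)/(2√(ω_i ω_j))`, clipped to [−1, 1].

Iterative exclusion then removes the strongest pair above the exclusion
threshold from the system (diagonal decrements, off-diagonal zeroed, t-sums
reduced) for up to `exclusion_rounds` passes; a taxon is never reduced
below three partners, and basis variances are clamped at 1e-12 before the
square root. The final estimate is the element-wise median over
`iterations` Dirichlet draws, re-symmetrised with unit diagonal. Defaults
(50 iterations, 10 exclusion rounds, threshold 0.1) are the reference
defaults for this estimator family.

Bootstrap p-values resample each taxon's counts independently across
samples (destroying inter-taxon association, preserving marginals),
recompute ρ, and use the two-sided `(1 + #{|ρ*| ≥ |ρ|})/(1 + B)` estimator,
which cannot return 0. With ten samples per period SparCC is noisy; the
estimator still runs but small-n results should be read as exploratory.

The edge filter keeps `|ρ| > 0.6` and `p ≤ 0.05` and drops isolated nodes.
The magnitude reading of the correlation threshold is deliberate: the
cohesion and focal-association analyses require negative edges, so a
positive-only filter would contradict the rest of the pipeline.

## Network ecology

* **Modules**: greedy modularity agglomeration on the unweighted simple
  graph. The dendrogram is cut at the community count maximising
  modularity, ties resolved toward fewer modules (the library's default cut
  can stop one merge early on exact ties). Deterministic, so the `seed`
  argument is interface sugar.
* **Zi/Pi**: `Zi = (k_is − mean_s)/sd_s` over the node's own module
  (sd = 0 ⇒ Zi = 0), `Pi = 1 − Σ_m (k_im/k_i)²`. Role thresholds are the
  standard Zi ≥ 2.5 / Pi ≥ 0.62 rules, boundaries inclusive; module hubs,
  connectors and network hubs are collectively "keystones". The
  classification is a pure threshold function, property-tested over a grid.
* **Cohesion**: each taxon's mean qualifying positive (negative)
  correlation r̄⁺ (r̄⁻), abundance-weighted per sample:
  `C± = Σ_i p_i r̄±_i`. Qualifying pairs default to the filtered network's
  edges, consistent with building stability analysis on the reported
  network; the original null-corrected Pearson formulation is available as
  `method = "pearson_null"`. Cohesion is linear in relative abundance
  (tested to 1e-12).
* **Removal stability**: for fractions 0, 0.1, …, 1 a uniform random subset
  of the phylum's taxa is deleted, abundances renormalised, r̄ recomputed on
  the remaining submatrix, and cohesion averaged over samples and
  `n_reps` replicates; the summary is the OLS slope of mean cohesion on
  fraction. Fraction 0 reproduces the unperturbed value exactly and
  fraction 1 equals the phylum-absent community exactly (both asserted
  without tolerance). The 11-point grid and 100-replicate default are
  package choices; the comparison of "decreasing cohesion trends" needs a
  number, and an OLS slope is the simplest one.
* **Focal association**: a non-focal node with edges to the focal set is
  classed by the sign of the summed edge weights; an exact zero sum — a
  probability-zero tie with continuous weights — is classed positive by
  documented convention. Abundance-weighted class fractions (positive /
  negative / none / focal) partition 1 per period; weighting uses absolute
  abundance (copies/mL), since on a seasonal gradient relative shares hide
  the bloom the classes are meant to track.

## Phylogenetic structure

All metrics are computed from primary definitions on `ape` structures
(the phylogenetic correlation matrix `C = vcv(tree, corr = TRUE)` and the
cophenetic distance matrix), with `picante` used only as an independent
oracle in the tests.

* Faith PD spans the present tips and, by default (`include_root = TRUE`),
  the path to the root, so a singleton community has its root-to-tip
  length.
* PSV = `(n·tr C − ΣC)/(n(n−1))`, PSR = n·PSV (exact identity, tested),
  PSC = `1 − mean_i max_{j≠i} C_ij`, PSE uses the published
  abundance-weighted form `(M Σ c_ii m_i − m'Cm)/(M² − M·m̄)`. PSV is
  invariant to uniform branch scaling. Fewer than two taxa ⇒ NA flags.
* NRI/NTI are **negated** z-scores of MPD/MNTD against a tip-shuffle null
  over the full taxon pool (999 draws by default), so positive values mean
  phylogenetic clustering — stated explicitly because sign conventions
  vary. Null sd = 0 ⇒ NA, never a fabricated value. Weighted MPD excludes
  self-pairs (some implementations include the zero diagonal; the primary
  definition does not).
* βMNTD averages, in both directions, each taxon's distance to its nearest
  taxon in the other community; abundance-weighted by default with a
  presence/absence option, and both variants are available because the
  weighting choice is not decidable from the method's description alone.
  βNTI standardises against the same tip-shuffle null. Identical
  communities give βMNTD = 0 under every shuffle, hence a degenerate null
  and an NA flag — the honest answer for that input.

## Diversity, ordination, concordance

Shannon and Gini-Simpson come from `vegan::diversity`; Bray-Curtis and
Sørensen from `vegan::vegdist` (Sørensen as binary Bray-Curtis); PERMANOVA
from `vegan::adonis2`; Procrustes M² and its permutation p from
`vegan::protest` with symmetric scaling, so M² ∈ [0, 1]. All permutation
p-values use the `(1 + m)/(1 + M)` estimator. PCA defaults to
Hellinger-transformed profiles (raw and CLR selectable); axis signs are
fixed by making the largest-magnitude loading positive; zero total
variance is returned as an explicit degenerate flag rather than an error.
Alpha-diversity period contrasts use two-sided Welch t-tests with BH-FDR
across all comparisons, and the Procrustes screen of dominant phyla
BH-adjusts across phyla.

Turnover pools each period's samples to presence sets and reports
`(gained + lost)/(gained + lost + shared)` per phylum — the fraction of the
pooled union that changed (the Jaccard dissimilarity of the presence
sets). A phylum absent from both periods has no defined rate and is
reported as missing.

## Multifunctionality

Each enzyme is z-scored across samples with the n−1 sd convention (the
usual default when "z-score" is stated without qualification); the index
is the enzyme-mean z-score, so indices centre on 0 across samples. Zero-
variance enzymes are dropped with a warning and cannot affect the others
(tested). The shipped 39-entry nitrogen-cycle EC list names the table
schema only — it is a synthetic placeholder, clearly marked, because the
actual enzyme selection of any given study travels with its prediction
pipeline. The focal phylum is excluded from the table used for prediction
so the index describes the *other* organisms.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to make each
property measurable while keeping a full run in minutes on one CPU:
SparCC recovery at 50 taxa × 200 samples × depth 5 × 10⁴ with one planted
ρ = 0.8; bootstrap calibration on ~10³ null pairs at B = 199; keystone
removal recovery over 20 generator replicates at 50 reps/trajectory;
NRI/NTI calibration over 100 random communities at 199 nulls; the βNTI
filtering contrast at 64 taxa, depth 800 (so communities are proper
subsets of the pool and the tip-shuffle null is non-degenerate), 25
cross-period pairs; Procrustes null coverage over 30 replicates; the
multifunctionality recovery at the study's n = 30 over 100 function-table
replicates; and a reduced-permutation end-to-end pipeline run asserted to
be byte-identical across repeats. Pipeline permutation counts default to
999 and can be reduced, in which case the report carries a
`reduced_precision` flag.

Numerical conventions collected in one place: basis variances clamped at
1e-12; correlations clipped to [−1, 1]; exclusion never leaves a taxon
with fewer than three partners; zero-length branches are legal (distance
0); sd = 0 situations yield explicit zeros (Zi) or NA flags (NRI/NTI/βNTI,
PSV with n < 2) as documented; an all-zero sample is an error wherever a
composition is required.

## Known limitations

SparCC at 10 samples per period is noisy; results at that scale are
exploratory, and the calibration tests run at larger n. The qPCR scaling
inherits marker copy-number bias (18S copy numbers inflate eukaryote
abundance). The generator's multinomial sampling underdisperses relative
to real amplicon data. Procrustes screening compares two-axis ordinations
by default; structure beyond the first two axes is invisible to it.
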