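---
title: "Methods: target-decoy validation, site assembly, grouping and TMT quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: target-decoy validation, site assembly, grouping and TMT quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmpolish)
```

psmpolish implements the data-interpretation layer that sits between a
database search engine and biological analysis of multi-ome, TMT-labeled
LC-MS/MS experiments (deep-scale proteome, phospho-, acetyl- and
ubiquitylome, and HLA class I/II immunopeptidomes). The pipeline starts
at peptide-spectrum match (PSM) tables — one row per candidate
peptide-to-spectrum assignment with identification scores, decoy flags
and reporter-ion intensities — and produces validated PSM sets,
variable-modification (VM) site tables, parsimony protein subgroups, and
normalized relative-abundance matrices.

## Target-decoy FDR model

Every stage of error control rests on the target-decoy assumption:
matches to a reversed/shuffled decoy database are statistically
exchangeable with incorrect target matches, so the decoy count D among
an accepted set estimates its incorrect-target count, and

$$\widehat{\mathrm{FDR}} = D / T$$

for T accepted targets. The estimator lives in a single function
(`estimate_fdr()`) so conservative variants such as (1+D)/T or
2D/(T+D) are one-line swaps.

`autovalidate()` optimizes a pair of thresholds — the identification
score and the delta rank1-rank2 score — separately for each scope:
precursor charges 2, 3 and 4 within each LC-MS/MS run at a 0.8% FDR
target, charges 5-6 pooled per TMT plex at 0.4% (too few high-charge
spectra per run for stable counts), and, for immunopeptidomes, all
fractions pooled at 1.0% with class-specific charge ranges (HLA-I 1-4,
HLA-II 2-6). Within a scope the optimizer accepts as many targets as
possible subject to the FDR estimate staying at or below the target.

Two numerical safeguards matter here, and both exist because threshold
*optimization* interacts with the *estimator*. The candidate thresholds
are quantiles of the observed score values, capped by default at 25
score x 15 delta levels per scope, and the feasibility rule during the
search counts one extra pseudo-decoy, (D+1)/T <= target. Searching every
observed value pair (often millions of cells per scope) and accepting
the cell that maximizes targets systematically picks cells where the
finite decoy sample *undercounts* incorrect targets; in simulation this
inflates the realized false-discovery proportion to roughly 1.8x the
nominal target. With the capped grid and the pseudo-decoy the realized
FDP on datasets with known ground truth sits just below the nominal
target (about 0.7% at a 0.8% target) while costing about 1% of accepted
depth. The reported `fdr_estimate` remains the plain D/T of the selected
thresholds and always satisfies the target. A scope containing no decoys
at all has no decoy sample to overfit and is accepted in full at the
minimal thresholds. Infeasible scopes accept nothing and are flagged —
never silently relaxed.

Thresholds are deterministic: ties between equally deep cells resolve
toward fewer accepted decoys, then higher thresholds, and all scope
iteration is over sorted identifiers, so any row order of the input
produces the identical result.

## Subset-specific (class-conditional) FDR

Rarely observed peptide classes — unannotated ORF (nuORF) categories,
sequence variants — are enriched for false matches relative to the
aggregate, so a dataset-wide 1% FDR does not imply 1% within the class.
`run_subset_fdr()` applies a two-step tightening to each non-canonical
class while canonical PSMs pass through untouched:

1. fixed thresholds from the named `filter_profile()`: minimum score 7,
   minimum scored peak intensity 50%, |mass error| strictly below 5 ppm;
   plus minimum backbone cleavage score (BCS) 5 and lengths 8-12/9-50
   for HLA-I/II, or BCS 4 and lengths 7-50 for PTM-omes;
2. if the class FDR estimate still sits at or above 1%: a grid search
   over (BCS, score) pairs that retains the most targets with FDR
   strictly below 1%, ties resolved toward the smaller BCS and then the
   smaller score — the least aggressive tightening that achieves the
   target. Classes with no feasible pair retain nothing and are flagged.

The default grids start at the profile minima and extend 10 BCS units
and 10 score units (half-unit steps); endpoints are configurable since
nothing in the method constrains them.

## VM-site localization and assembly

The localization score of a modified PSM is the difference between the
identification scores of its two best site placements; a difference
strictly greater than 1.1 marks a confident localization. A PSM with a
single candidate site has no competitor and is confident by convention.
`build_site_table()` merges observations of the same site — across
charge states, missed-cleavage forms and sample-handling modifications —
into one row keyed by (protein, modification type, site count, position
set). Observations with different site counts, or different confident
position sets, never merge. An ambiguous observation carries an
ambiguity window (every acceptor residue of its modification type within
the peptide: S/T/Y for phospho, K for acetyl and diGly, mapped to
protein coordinates); it joins a confident row whose positions its
window contains, preferring the highest-scoring such row, and otherwise
forms a row keyed by its full window, merged only with identical
windows. Overlapping-but-unequal ambiguous windows deliberately stay
separate: the merge is then a pure function of the input and rebuilding
from the same PSMs is idempotent. Representatives prefer confident
localization, then higher score, then longer peptide, then the smaller
spectrum id.

Site polishing across plexes retains rows with a best score of at least
8.0 *or* observation in at least two TMT plexes, removing low-scoring
sites seen only once. For ubiquitylome and acetylome data,
`cterm_mod_lysine_filter()` removes peptides whose last three residues
match `[^K][^K]k` (modified lysine written as lowercase k): trypsin and
Lys-C cannot cleave C-terminal to a modified lysine, so such peptides
are artifacts unless an unmodified K in the last two positions leaves a
missed-cleavage explanation open.

## Protein grouping and polishing

Proteins sharing a peptide longer than 8 residues join one protein
group (connected components); shorter shared peptides support proteins
but never link groups. Within a group, proteins with identical peptide
support are indistinguishable and form one candidate subgroup; a
subgroup is seeded when at least one peptide is unique to it. Subgroup
ranking uses the unique-peptide score sums, computed once, and each
shared peptide is then allocated to the highest-ranked subgroup that
contains it ("top uses shared") — a single deterministic pass, with
accession-lexicographic tie-breaks. The protein score is the sum over
allocated distinct peptides of each peptide's best PSM score, a distinct
peptide being the single highest-scoring instance of a sequence. The
"unexpand" mode reports one row per group (used for PTM-site reports,
where a site is reported once per group under its top subgroup). A
peptide short enough to span two groups is allocated exactly once,
globally.

Protein polishing runs twice. Within each plex, the maximum protein
score among subgroups consisting *entirely* of likely-false peptides
(every supporting PSM has a negative delta forward-reverse score)
defines a floor; all PSMs of subgroups scoring strictly below that floor
are removed — this implements a protein-level FDR threshold of zero and
removes "one-hit wonders". Subgroups scoring exactly at the floor are
kept, per the strict reading of "below". Across plexes, subgroups
survive with a protein score of at least 25 or observation in both
plexes.

## TMT quantitation

Reporter-ion intensities are corrected for reagent isotope impurities by
solving M x = observed, where column j of M distributes reagent j's
signal over its -2/-1/+1/+2 series neighbors (certificate-of-analysis
percentages; spill outside the plex is lost mass, so edge columns sum to
less than one). The solve uses Cramer's rule — each component is a ratio
of determinants — and is cross-checked against the generic LU solver to
1e-9 in tests. Matrices with a condition number above 1e8 are rejected.
Corrected components driven negative by noise are clamped to zero and
flagged, since intensities are physical quantities.

PSMs enter quantitation only if TMT-labeled, with precursor isolation
purity of at least 50% (co-isolated precursors compress ratios toward
zero), and with a non-negative delta forward-reverse score (about half
of negative-delta PSMs are false identifications). Log2 ratios divide by
the per-PSM median of positive channel intensities by default — the
cohort design has no common reference channel — with a
reference-channel policy available for designs that have one. Zero
intensities yield missing ratios, never -Inf. Feature-level (protein
subgroup or VM site) ratios are medians over contributing PSM ratios,
with per-channel ratio counts recorded; reported protein matrices
require at least 2 fully quantified unique peptides and ratio counts of
at least 2.

Median/MAD normalization centers each channel at zero median and
rescales it so all channel MADs equal the pre-normalization median of
per-channel MADs. The MAD is used without the 1.4826 Gaussian
consistency factor — only relative channel scaling matters. The
operation is idempotent; channels with fewer than 3 observations (or
zero MAD) are centered only and flagged. Variant (SAAV) features are
additionally screened for patient consistency: the robust z-score must
reach 2.0 in every carrier channel and stay below it in every
non-carrier channel.

## HLA immunopeptidome filtering

The class I/II filter chain runs in a fixed order mirroring the
processing narrative: spectral quality (sequence tag length > 1,
precursor MH+ 600-4000 Da; the global mode uses tag > 0 and 800-6000),
minimum length 7, minimum BCS 5, class charge range, pooled 1.0% FDR
autovalidation, contaminant removal (blank-bead negative-control IP
list, tryptic contaminant list, non-human annotations), modified-peptide
quality (score strictly above 6 and scored peak intensity strictly above
60% for phospho/acetyl peptides), and finally the class I restriction to
8-11mers. Every removal is attributed to exactly one named stage in an
audit table whose removals sum to input minus output, and the chain is
idempotent.

Summaries include length histograms, per-length position-frequency
matrices (columns sum to one), the modification-position distribution,
and HLA-II nested-set grouping: peptides join one set when one contains
the other or they share a common substring of at least 9 residues — the
typical class II binding-core length, configurable since nested sets
are named but not formally defined in the processing conventions this
package follows.

## What the synthetic data emulate — and what they do not

The generators produce the statistical structure the filters assume,
with full determinism under (config, seed):

- `generate_psm_dataset()`: correct-match scores from a shifted normal
  (mean 11, sd 2.5), incorrect/decoy scores from a right-skewed Gumbel
  (location 4, scale 1.2) — standard search-score phenomenology; BCS,
  scored peak intensity, tag length, mass error, delta scores all
  correlated with correctness; class priors of 0.85 (canonical), 0.45
  and 0.35 (nuORF classes) and 0.60 (variants) encode the class-error
  enrichment that motivates subset-specific control. Decoys are
  label-flipped draws from the incorrect distribution, with the decoy
  fraction matched to the expected incorrect-target fraction so D/T is
  calibrated. 20,000 PSMs across 4 runs and 2 plexes by default.
- `generate_quant_dataset()`: 200 features x 50 PSMs on a TMT-10 plex;
  known per-feature log2 profiles (alternate features regulated up or
  down by 1.0 between channel halves, so channel medians stay near
  zero — the mostly-null structure median/MAD normalization assumes);
  intensities pass through the CoA impurity matrix and multiplicative
  log-normal noise with sigma 0.3 (log2 units). Precursor purity is
  Beta(16, 1.6); the co-isolation background defaults to zero so that
  fold-change recovery isolates noise from interference — raising
  `contamination_intensity` mixes a flat background in proportion to
  (1 - purity), and a monotonicity test confirms the expected ratio
  compression toward zero.
- `generate_hla_peptides()`: class I lengths 8-12 with the canonical
  mode at 9, a P2 leucine anchor at probability 0.9 and a C-terminal
  valine anchor at 0.7; class II nested sets built by extending shared
  9-mer cores with ragged flanks.

Decoys are generated by label-flipping rather than sequence reversal,
and sequences are random strings: passing tests demonstrate the
correctness and calibration of the decision rules, not search-engine
behavior on real spectra. Real data additionally contain correlated
scores across co-eluting peptides, charge-dependent score scales,
shared-peptide structure between real protein families, and
interference that is not flat across channels — none of which the
generators model. Headline identification counts from deposited
large-scale datasets are therefore out of reach at desk scale, by
design; the test surface checks properties (calibration, oracle
equivalence, parameter recovery, invariants) instead.

## Problem sizes and tolerances

The test suite and the acceptance script use: 20 seeds x 20,000 PSMs
for FDR calibration (realized FDP within target + 3 binomial SE);
exhaustive enumeration oracles on discrete-score instances (about 23 x 9
threshold grids, up to 1,500 PSMs) and 17 x 37 subset grids; impurity
round-trips on random 10- and 16-channel systems (recovery to 1e-10
relative, Cramer vs LU to 1e-9); fold-change recovery over 200 features
(|bias| < 0.05, RMSE < 0.15); 50 random matrices for normalization
post-conditions (medians to 1e-12); 200 random grouping instances (up to
10 proteins x 30 peptides) against a naive restatement; the exhaustive
441-suffix check of the modified-lysine regex; 100 random site-table
builds; a 25-record staged HLA fixture; and anchor/nested-set recovery
at n = 5,000 (anchor frequency within 0.03).
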