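---
title: "Clone-resolved chromatin analytics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-resolved chromatin analytics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromclone)
```

# The scientific problem

Clonal hematopoiesis arises when a blood stem-cell clone carrying a somatic
mutation (prototypically *Tet2* loss) expands without overt malignancy. A
central question is whether the *pre-existing*, heritable epigenetic state of
a clone conditions how strongly it responds to the mutation. Answering it
requires a chain of single-cell chromatin analytics over paired scATAC +
scRNA (multiome) data plus clone-level functional readouts and lineage
barcoding. `chromclone` implements that chain as reusable, tested components:

1. a disjoint fixed-width reference peak set from per-condition summit calls;
2. per-cell gene activity scores and background-matched motif deviation
   Z-scores;
3. permutation-tested peak–gene cis-regulatory links and DORCs (domains of
   regulatory chromatin);
4. co-accessible peak modules from TF high/low fold-change profiles;
5. pseudobulk negative-binomial differential accessibility, Wilcoxon DORC
   testing, and kNN neighborhood localization;
6. the clone Functional Perturbation Score and clone-level correlation
   analyses;
7. a lineage-barcode abundance pipeline with error-correction clustering.

Every stage is exercised end to end on a synthetic paired multiome with
planted ground truth, so the statistical behaviour of the pipeline (type-I
error, power, recovery) is itself under test.

# Models and procedures

## Reference peak set

MACS-style summits are extended to 800 bp windows (`pos ± 400`, half-open
width 801), pooled across conditions, ranked by summit significance, and kept
greedily iff they overlap no previously kept window. Score ties are broken by
(chromosome, position) so the output is invariant to input order. Atlas peaks
may be appended afterwards — appended, not re-ranked against the data peaks —
iff they do not overlap the kept set; this follows the reading that an
external atlas *supplements* the data-driven peaks. Kept windows are resized
to `summit ± 150` (301 bp). Because resized peaks are subsets of disjoint
800 bp windows, disjointness is inherited and not re-enforced. Coordinates
are 0-based half-open throughout; strand is ignored (ATAC is unstranded).

## Gene activity scores

The activity of gene $g$ in cell $i$ sums peak counts near the TSS with
exponential distance decay:

$$ s_{g,i} \;=\; \sum_{p:\,|d_{p,g}| \le W/2} e^{-|d_{p,g}|/\lambda}\, c_{p,i}, $$

with $d_{p,g}$ the peak-centre-to-TSS distance, decay length
$\lambda = 1000$ bp and window $W = 2\lceil \lambda \ln(1/0.01) \rceil =
9212$ bp, i.e. the window outside which each one-sided tail holds 1% of the
total weight. The decay constant is interpreted as an e-folding length
because only that convention reproduces the 9,212 bp window; a strict base-2
half-life is available via `convention = "half_life"`. Scores are normalised
per cell by the mean over *scored* genes (genes with at least one in-window
peak); genes without an in-window peak score 0 and are flagged rather than
diluting the normaliser.

## Motif deviations with matched backgrounds

For an annotation (peak set) $A$ and cell $i$, with $X = \sum_{p\in A}
c_{p,i}$, $f_A$ the annotation's share of the grand total and $T_i$ the cell
total, the raw deviation is $(X - f_A T_i)/(f_A T_i)$. Each of $n_{bg} = 100$
background iterations replaces every peak in $A$ by one of its matched
background peaks and recomputes the deviation, yielding a null sample $d_b$;
the deviation Z-score is $(\mathrm{raw} - \bar d)/\mathrm{sd}(d)$ with the
unbiased ($n-1$) standard deviation. Background peaks are matched on GC
content and `log1p` mean accessibility: both covariates are standardised and
each peak's backgrounds are drawn with replacement from its 50 nearest
neighbours in that plane (self excluded, distance ties broken by index). A
kNN pool is the simplest scheme that satisfies "matched on GC and mean
accessibility"; it degrades gracefully when all peaks are identical (the pool
becomes all other peaks). Entries with zero expectation (empty cells or
annotations) are masked as `NA` and counted, never silently zeroed.

## Peak–gene links and DORCs

Candidate pairs are genes and peaks whose centre lies within 10 kb of the
TSS. The observed statistic is the Spearman correlation across cells of
depth-normalised accessibility and normalised expression; Spearman is the
default because sparse counts make Pearson fragile (Pearson is available via
`method`). The null replaces the peak by each of its 100 matched background
peaks; the permutation p-value uses the add-one estimator
$p = (1 + \#\{r_b \ge r_{obs}\})/(1 + n_{perm})$, so $p \in \{1/101, \dots,
1\}$ and is never exactly zero. Links are retained when $r_{obs} > 0$ and
$p \le 0.05$; genes with $\ge 3$ retained links are DORCs.

A note on calibration: under a permuted-RNA negative control the permutation
p-value is uniform over *all* candidate pairs, so about 5% of candidates are
retained. Conditioned on $r_{obs} > 0$ the rate is roughly twice nominal,
because a small permutation p already implies the upper tail of the null —
the two filters are not independent. The package's calibration checks
therefore measure retention against all testable candidates.

DORC per-cell scores are depth-normalised sums over linked peaks
($\sum_p c_{p,i} / T_i \cdot \mathrm{median}(T)$), optionally kNN-smoothed in
an embedding (off by default: smoothing helps visualisation but blurs the
unit of statistical testing). The accessibility–expression residual is the
row-z-scored DORC score minus the row-z-scored expression; positive residuals
mark chromatin running ahead of transcription. TFs are classified as
activators or repressors of their cognate DORC by the sign of the Pearson
correlation between motif Z and DORC score across units; the function is
agnostic about whether the units are cells or clone-aggregated profiles, so
the caller chooses the level of analysis.

## Co-accessibility modules

Motifs are deduplicated by single-linkage clustering at absolute profile
correlation $\ge 0.8$ (at a fixed threshold, single linkage is the connected
components of the thresholded similarity graph); per cluster the motif with
the highest deviation-Z variance represents the group. Similarity is computed
on motif–peak match profiles because PWMs are not inputs here. Significantly
variable motifs are selected by a jackstraw: PCA on the motif-by-cell Z
matrix, statistic per motif $\max_k (\text{loading}^2_k \cdot
\text{var(PC}_k))$ over the first 10 PCs, null built from 100 iterations each
permuting a random 10% of motifs, add-one empirical p, threshold 0.05.

For each variable TF, cells are split at the median Z; each peak's
depth-normalised, per-cell mean-centred accessibility is compared between the
high and low groups with a two-tailed Welch t-test (Welch rather than pooled
variance, for robustness), with Benjamini–Hochberg control at FDR
$\le 10^{-6}$. The high-minus-low fold-change profiles of peaks significant
for at least one TF are clustered into modules: a kNN graph (k = 30,
Euclidean; an undirected edge joins peaks when either lists the other, and
ties at the k-th distance are all included so identical profiles form one
component) partitioned by Louvain under a fixed seed, resolution 1. The
module count on real data is data-dependent and is not a target. Modules are
emitted as a binary peak-by-module annotation consumable by
`compute_deviations()`, closing the loop back to per-cell module scores.

## Differential testing and localization

Pseudobulk profiles sum raw counts per (sample, cell type, genotype); groups
under 10 cells are dropped with a warning. Size factors are median-of-ratios
against per-peak geometric means (peaks containing zeros excluded from the
reference), rescaled to geometric mean 1. Each peak is fit with a
negative-binomial GLM (log link, offsets `log` size factors, design
`~ genotype + celltype`), dispersion estimated per peak by maximum likelihood
via `MASS::glm.nb` with a Poisson fallback when the dispersion diverges; the
genotype coefficient is tested with a two-sided Wald statistic against the
standard normal and BH-adjusted, significance at FDR $\le 0.01$. Dispersion
shrinkage across peaks is deliberately not applied: at pseudobulk depths the
Wald test is the operative statistic, and empirical-Bayes moderation is a
separate contribution with its own behaviour. Non-converged peaks are
flagged and excluded from the FDR correction. Neither outlier refitting nor
independent filtering is applied.

DORC differential testing is a two-sided Wilcoxon rank-sum per (DORC, cell
type) with BH across all tests; cell types with a single genotype are skipped
with a log message, and all-tied score vectors are skipped as undefined.

Neighborhood localization reports, per cell, the fraction of its k = 50
Euclidean nearest neighbours (self excluded, ties broken by cell index)
carrying a query label. The statistic is embedding-agnostic by contract; the
package provides a PCA embedding (depth-normalised, `log1p`, deterministic
sign convention: the largest-magnitude loading of each component is positive)
as a stand-in where a topic-model embedding with batch integration would be
used on real data. Cluster-restricted analyses are expressed by subsetting
cells, never by hard-coded cluster ids.

## Clone-level analytics

The Functional Perturbation Score standardises each assay column across all
rows (WT and KO pooled — matching a single `scale()` call over the dataset;
per-genotype standardisation is available via a flag) and reports the
Euclidean distance between a clone's standardised WT and KO rows. Pooled
standardisation makes the score invariant to any affine transform of an assay
column; constant columns are dropped with a warning and logged so scores are
comparable only within one run. Feature ranking against the score uses
Spearman correlation with BH-adjusted `cor.test` p-values; the strongest
positive correlates mark a sensitised chromatin state.

## Barcode pipeline

Reads are scanned for an exact 5' flank; the next 28 bases are the candidate
barcode, which must be followed immediately by the exact 3' flank and match
the constant-base template exactly. Error correction visits barcodes in
descending count order (ties lexicographic) and merges each into the most
abundant earlier surviving barcode within Levenshtein distance 2 whose count
is at least 5 times its own — radius and ratio mirror the defaults of
message-passing error-correction clustering for barcodes of this length, and
both are exposed as arguments. Merging conserves total assigned reads;
survivors with fewer than 10 reads are then removed. Because reads with a
substitution at a constant position are discarded at extraction, absolute
counts sit below truth by a factor $\approx 1-(1-e)^{8}$ at per-base error
rate $e$, uniformly across clones; clone *fractions* are therefore the
faithful abundance estimate, and sister-sample comparisons convert to
fractions before the regression.

# The synthetic generator

`simulate_multiome()` draws counts from a Gamma–Poisson (negative-binomial)
observation model with shared dispersion — the simplest observation model
whose parameters the pipeline should recover. The per-peak log-rate is

$$ \log \mu_{p,i} = \beta_p + \textstyle\sum_m L_{p,m}\, a_{m,i} +
   \gamma_{\mathrm{clone}(i),p} + \ln(2)\,\phi\,[p \in KO][i \in KO] +
   \varepsilon_{p,i}, $$

then rates are rescaled per cell to a log-normal sequencing depth, so column
sums track `depth_mean` by construction. The planted structure:

* **Trajectory.** Pseudotime uniform on $[0,1]$; cells past 0.5 commit to one
  of two branches with equal probability — a deliberately minimal bifurcation
  that mirrors a stem-to-monocytic/neutrophilic split without committing to a
  specific dynamical process.
* **TF programs.** A stemness program ($1.5(1-u)$) and one program per branch
  ($1.5u$ on the branch) load on random distal peak sets; additional
  background motifs carry weaker smooth activities. Motif matches are 1 on
  loaded peaks plus Bernoulli(0.02) background matches.
* **cis links.** Each DORC gene owns $\ge 3$ peaks within 10 kb of its TSS
  sharing a latent activity: a smooth phase-shifted pseudotime wave (sd 0.8)
  *plus* a gene-specific per-cell co-fluctuation (sd 0.8) shared with the
  gene's expression. The co-fluctuation is essential to what "planted link"
  means: a cis link is covariation between a peak and its gene beyond the
  global trajectory mode, which is exactly what the matched-background
  permutation null is designed to isolate. Only the wave component is
  evaluated at $u - \texttt{lead\_lag}$ for RNA, implementing chromatin
  "foreshadowing" as a pure lag rather than a causal model.
* **Stochastic accessibility noise.** Every peak receives iid
  $N(0, 0.6)$ log-rate noise per cell. Besides realism, this keeps planted
  peaks from being marginal-variance outliers relative to their matched
  background pools — a prerequisite for the rank-permutation null to be
  calibrated.
* **Knockout effect.** `ko_log_fc` log2 units on a designated distal peak
  subset in KO cells; samples are nested in genotype so pseudobulk replicates
  exist. Because per-cell rates are renormalised to depth, the realised
  pseudobulk log2 ratio is attenuated by the KO peaks' share of the total
  (about 0.13 log2 units under defaults), within the ±0.2 band the generator
  promises.
* **Clone structure.** Each clone inherits iid $N(0,
  \texttt{clone\_offset\_sd})$ peak-wise offsets. No study estimate of this
  magnitude exists, so it is an explicit free knob (default 0.2), not an
  estimate.
* **Clone assays.** `simulate_clone_function()` plants a per-clone
  perturbation magnitude along a shared assay direction with assay-specific
  scales and centres, so column standardisation has real work to do.
* **Barcodes.** 28-mers honouring the constant-base template, reads framed by
  exact flanks with iid substitution errors across all barcode positions
  (constant positions included — such reads are lost at the constant-base
  filter, as in real data).

What the generator does **not** emulate: read-level fragments, doublets,
batch effects beyond clone offsets, chromatin-state-dependent GC bias (GC is
drawn uniform in [0.3, 0.7] independently of signal), or realistic genomic
peak spacing. Passing tests therefore demonstrate that the algorithms recover
the statistical structures they target at realistic counts and depths — not
that they are robust to every artefact of real scATAC data.

# Problem sizes and numerical choices

The packaged checks run at the scale the methods are specified for:
recovery analyses use 2,000 cells, 1,000 peaks, 200 genes, depth 5,000, 100
background iterations and 100 permutations; null calibration of the
pseudobulk test uses 2,000 peaks across 24 pseudobulk groups; the jackstraw
null uses 500 motifs by 200 cells; clone-level recovery uses 28 clones, 8
assays and 100 seeds. Degenerate inputs are handled explicitly rather than
by `NA` propagation: empty annotations and zero-depth cells are masked and
reported, constant assay columns dropped with a warning, all-tied Wilcoxon
inputs skipped, non-converged GLM fits flagged. Ties break
deterministically everywhere (peak score ties by coordinates, kNN distance
ties by index, barcode count ties lexicographically), so every result is
reproducible under a fixed seed.

# Known limitations

* The NB Wald test without dispersion shrinkage is anticonservative for very
  few replicates; with the 3–4 samples per genotype used here the null
  simulations show FDR control holds, but two-replicate designs should be
  treated with caution.
* Background matching uses a 2-D covariate kNN pool; peaks whose variance far
  exceeds their accessibility class can still inflate permutation tails.
* `gene_activity()` normalises over scored genes only; with very sparse TSS
  tables the normaliser is correspondingly noisy.
* The barcode merge is greedy and order-dependent by design (count-ranked);
  pathological count profiles (long chains of 5:1 ratios) can cascade merges
  that exact clustering would split.
* Clone-level correlation analyses assume clones are exchangeable units;
  with fewer than ~10 clones the feature ranking is dominated by noise, and
  the functions refuse to run below 3.
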