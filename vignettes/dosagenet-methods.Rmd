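---
title: "Methods: dosage-aware co-expression analysis of indel populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-aware co-expression analysis of indel populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagenet)
```

## Setting

`dosagenet` analyzes transcriptomes from populations in which lines carry
large chromosomal deletions or insertions (indels), such as poplar F1
hybrids derived from gamma-irradiated pollen. Two features of such data
drive the design:

* **Cis-dosage effects.** A gene inside a deletion is present in one copy
  instead of two; inside an insertion, in three. In log2 expression units
  a fully dosage-proportional ("cis") gene shifts by
  $\gamma \log_2(\mathrm{RDS})$, where the relative dosage score RDS is
  0.5, 1.0 or 1.5 for deletion, unaltered and insertion lines and
  $\gamma$ is the cis responsiveness (1 = proportional).
* **Indel-induced co-expression.** Every gene inside the same indel shares
  the same dosage shift across lines, so indels can seed artificial
  modules. The package therefore offers *indel normalization*: for each
  gene, values in lines with RDS ≠ 1 are replaced by that gene's mean
  over RDS = 1 lines. The default replacement pool is the RDS = 1 lines
  only — averaging over literally "all other lines" would re-introduce
  the cis signal of other indel carriers — but a literal `all_other`
  mode is provided. The operation is idempotent and leaves all RDS = 1
  entries bit-identical, and afterwards the regression of the gene's
  values on RDS has slope exactly zero. Because indel normalization can
  also erase genuine biological correlation, the pipeline default is the
  *non*-normalized network, with the normalized variant one flag away
  (`indel_normalize: true`) for comparison.

## Preprocessing model

Counts are filtered by maximum expression (a gene whose maximum count
over all libraries is below 10 is removed; 10 itself is kept). Library
scaling uses the trimmed mean of M-values (TMM): the reference library is
the one whose 75th-percentile count fraction is closest to the
cross-library mean; per library, gene-wise log ratios M and abundances A
against the reference (over genes nonzero in both) are trimmed two-sided
at 30 % (M) and 5 % (A); the factor is $2^{\bar M_w}$ with inverse
delta-method variances as weights, rescaled to geometric mean 1. The
test suite checks this arithmetic against a step-by-step oracle and
against edgeR's implementation.

Expression is $\log_2\!\big((c + 0.5) / (L \cdot f + 1) \cdot 10^6\big)$
(moderated CPM on TMM-effective library sizes). Precision weights follow
the standard mean–variance construction: per-gene residual standard
deviations from a genotype-means fit, square-rooted, lowess-smoothed
(span 0.5) against mean log2 abundance, and inverted to weights as
trend$^{-4}$. The trend is interpolated at each observation's fitted
value; because only genotype means differ within a gene, within-gene
weight variation enters only through genotype means — library-size
differences are already absorbed by the CPM denominator. With a
genotype-indicator design and no intercept, the weighted least-squares
coefficient per (gene, genotype) is simply the weighted mean of that
genotype's libraries; these coefficients are the genotype-level
expression used by the dosage scan.

## Network model

The network is built on per-library normalized expression (all clonal
replicates as samples); a switch allows genotype coefficients instead.
Adjacency is *unsigned*, $a_{ij} = |r_{ij}|^\beta$ with default
$\beta = 12$ — unsigned is the historical default of the methodology and
the signed transform $((1+r)/2)^\beta$ is available. The scale-free fit
index bins connectivity $k_i = \sum_{j \ne i} a_{ij}$ into 10 equal-width
bins and regresses log10 frequency on log10 mean connectivity; the index
is $R^2$ signed by minus the slope, so decaying (scale-free-like) degree
distributions score positively. `choose_soft_power()` returns the
smallest candidate reaching a target fit of 0.80, falling back to the
argmax with a warning.

Topological overlap is
$\mathrm{TOM}_{ij} = \big(\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}\big) /
\big(\min(k_i, k_j) + 1 - a_{ij}\big)$, clustering is average-linkage
(UPGMA) on $1 - \mathrm{TOM}$, and modules are the connected components
below a *static* cut at height 0.99 with clusters smaller than 30 genes
relabeled grey. The full dynamic-hybrid tree-cut algorithm is a
documented deviation: the simple height-cut variant plus the minimum-size
rule is transparent, exactly reproducible, and sufficient for the planted
structures the package is validated on. Tie-breaking during
agglomeration is delegated to `stats::hclust`, which is deterministic for
fixed input order; the pipeline fixes gene order, so labelings are
reproducible across runs and platforms.

Module eigengenes are the first principal component across samples of the
standardized member genes, rescaled to unit variance and oriented so the
mean correlation with members is nonnegative. Modules whose eigengenes
correlate at ≥ 0.75 are merged iteratively, highest pair first, the
merged module inheriting the larger member's name. Module stability
rebuilds the labeling on resamples of 63 % of libraries (49 iterations by
default) and scores each reference module by the median of its best
Jaccard overlap with any resampled module — the resampling scheme is
standard, the best-Jaccard-median statistic is this package's
construction.

## Integration, enrichment, dosage response

Correlation p-values use the exact t transform
$t = r\sqrt{(n-2)/(1-r^2)}$ (two-sided). Eigengenes and expression are
averaged over clonal replicates to genotype level before correlating with
genotype-level traits (the trait tables have one value per genotype);
module membership (kME) stays per-sample by convention. Candidate genes
within a module are the genes annotated with at least one enriched term,
ranked by the *worst* of their |GS| rank and MM rank — a candidate must
score well on both axes — with ties broken by |GS| then gene id.

GO overrepresentation is the upper-tail hypergeometric probability
$P[X \ge k]$ with the background defaulting to all network genes carrying
at least one annotation (configurable to all genes). The mapping is flat:
no propagation through the GO graph, a documented limitation. Raw
p < 0.05 flags mirror standard practice in this analysis style; a BH
column can be added downstream but is never used for the default flags.

The dQTL scan groups lines by RDS at a region (deletion lines 0.5,
insertion lines 1.5, and a seeded draw of k = 4 control lines from the
non-lesion pool), then per expressed gene in the region runs a one-way
fixed-effects ANOVA on genotype-level coefficients — one value per line,
matching a design of e.g. 3 deletion, 4 control and 2 insertion lines —
followed by Tukey HSD pairwise tests (Tukey–Kramer standard errors for
unequal n, studentized-range p via `ptukey`) and a compact letter display
computed from the maximal cliques of the not-significantly-different
graph. The dosage-response slope is the OLS slope of expression on
numeric RDS; a noiseless cis gene with $\gamma = 1$ gives exactly
$1 + \log_2 1.5 \approx 1.585$.

## The synthetic-data generator

The generator emulates the structure of a 3'-tag count study of 33
genotypes with 2–3 clonal replicates (91 libraries by default): genes are
laid in non-overlapping 1-based intervals along 19 chromosomes; two
default indel regions mirror a chromosome-9 (6.3–6.8 Mbp; 3 deletions, 2
insertions) and a chromosome-16 (0–0.5 Mbp; 4 deletions, 2 insertions)
design; four 50-gene modules are planted with genotype-level latent
factors $f_{m,g} \sim N(0, 2)$ in log2 units; and nine wood-anatomy trait
columns (TH, VF, cVF, MVD, cMVD, MVC, VGI, NF, BT) load on module factors
with noise sd 0.5 (loaded traits) or are pure noise. Counts are negative
binomial with variance $= \mu + \phi\mu^2$ and constant $\phi = 0.1$,
means proportional to compositional within-genotype abundances times a
uniform library size (1.5–2.5 million), so depth is set by library size
as in sequencing. Replicates share the latent expression and differ only
by depth and sampling noise.

Choices a user should know:

* The count noise model of real tag-seq data is not knowable from
  summaries alone; constant-dispersion NB is the simplest testable
  assumption and is validated against its own moments, not against real
  data.
* Planted module members are drawn *outside* the indel regions so module
  recovery and cis-dosage recovery can be scored independently; real
  indel-induced modules are exactly what the indel-normalization switch
  exists to probe.
* Module gene loadings are 1 for all members; real modules have graded
  membership. Recovery scores on this generator are therefore upper
  bounds for real data.
* Each planted module is GO-tagged with one synthetic term covering 50 %
  of members plus a 2 % background rate, a regime where the planted term
  is essentially always the module's top term.
* All stages derive their RNG streams from one seed with fixed offsets;
  identical configurations are byte-identical on disk across runs.

## Numerical choices and degenerate inputs

Constant genes are dropped (correlation) or errored (eigengenes);
conflicting deletion+insertion overlap on one (gene, line) is an error
rather than an arithmetic guess, as is a gene dosed in every line (no
replacement pool). ANOVA with zero within-group variance reports p = 0
with a `degenerate` flag when groups differ and errors when all values
are identical. The TMM reference pairing requires at least one doubly
nonzero gene. Eigengene sign, color assignment (decreasing size, ties by
first cluster index), merge order (highest correlation first) and Tukey
letters are all deterministic.

## Problem sizes used in validation

The test suite validates oracle equivalence on 5–12-point instances
(exhaustive enumeration and brute-force loops), parameter recovery on a
2000-gene × 91-library simulation with four 50-gene modules (adjusted
Rand index of non-grey labels vs truth ≥ 0.8, planted trait and GO
recovery), dosage-scan calibration at the 3/4/2 group design (type-I
error over 1000 null genes, power over 200 cis simulations), and pipeline
determinism on 200–300-gene configurations. These sizes were chosen to
make every property sharply testable at interactive speed; nothing in the
implementation is specific to them, and the network stage handles the
full simulated design (2000 × 91) in seconds.

## Known limitations

* Static height cut, not dynamic-hybrid tree cutting.
* No empirical-Bayes variance moderation, batch correction or
  mixed-model/kinship-aware association.
* Flat GO mapping; no ontology propagation.
* Dosage arithmetic is strictly three-valued; nested or multiple
  overlapping events on the same gene/line are rejected.
* Dense matrices throughout; for networks much beyond ~20k genes a
  block-wise implementation would be needed.
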