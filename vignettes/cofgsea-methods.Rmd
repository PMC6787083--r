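---
title: "Methods: cofactor-focused gene set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cofactor-focused gene set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofgsea)
```

# The scientific question

Loss of a metabolic enzyme — the motivating case is the knockout of
medium-chain acyl-CoA dehydrogenase (MCAD), an enzyme of mitochondrial
fatty-acid β-oxidation — often produces only subtle transcriptional
changes, spread over many genes, and spread differently across
experimental conditions (diet, feeding status). Two questions then arise:

1. Which *gene sets* (pathways) move coherently up or down in the knockout
   relative to wildtype, per condition? This is classical pre-ranked gene
   set enrichment analysis (GSEA).
2. Are genes encoding enzymes that use the cofactors coenzyme A (CoASH)
   and NAD(P)(H) *overrepresented* among the responding genes — in either
   direction, and consistently across conditions? Classical GSEA cannot
   answer this, because a gene set containing a mixture of up- and
   downregulated genes washes out of the running-sum statistic even though
   such a mixture can strongly perturb metabolite levels.

`cofgsea` implements both analyses plus the two risk-ratio statistics that
connect them to cofactor biology, and a synthetic-data generator so every
statistical property can be exercised without access to the original
sequencing data.

# Classical pre-ranked GSEA

## Enrichment score

Genes are ranked by a per-gene differential-expression statistic (the
t-value of the knockout-vs-wildtype contrast; `makeRankedList()` sorts
decreasingly with ties broken by gene symbol). For a gene set $S$ with
$N_h$ members inside a ranked list of $N$ genes, a running sum is
accumulated from the top of the list:

- at a member gene: $+|s_i|^w / \sum_{j \in S} |s_j|^w$,
- at a non-member: $-1/(N - N_h)$,

with weight exponent $w = 1$ by default (the "weighted" statistic; $w = 0$
recovers the classic Kolmogorov–Smirnov form). The enrichment score (ES)
is the running-sum value of maximal absolute deviation from zero; its sign
is the direction of the enrichment. The *leading edge* — called the
contributing genes here — is the member subset at or before the
ES-attaining position (positive ES) or at or after it (negative ES).

Numerical choices: on an exact tie between the positive and negative
extremum the positive one is reported; if all member weights are exactly
zero (possible when every member score is 0 and $w > 0$), members are
weighted equally rather than dividing by zero. A set with no member in the
list is skipped with a warning; a set spanning the whole list leaves no
miss pool and is an error.

## Permutation null, NES, FDR

Phenotype permutation is unavailable for a pre-ranked list, so the null is
*gene-set permutation*: for each set, `nPermutations` (default 1000)
random same-size member sets are drawn from the ranked universe under a
fixed seed. The nominal p-value is the one-sided tail frequency among null
scores of the matching sign, smoothed by $+1/(n+1)$ so it is never exactly
zero. NES divides the observed ES by the mean absolute null ES of the
matching sign. The FDR q-value follows the standard permutation recipe:
null scores are sign-normalized the same way and pooled over all sets, and
the q-value of an observed NES is the ratio of the pooled-null tail
fraction to the observed tail fraction, clipped to $[0,1]$ and monotonized
so a more extreme NES never receives a larger q. Results are reported in
two tiers, FDR < 0.05 (significant) and FDR < 0.25 (explorative).

Defaults: 1000 permutations, weighted statistic, set-size filter 15–500
(common pre-ranked practice; the package's own statistical tests disable
the filter to exercise all set sizes). Bit-compatibility with any specific
desktop GSEA implementation is not promised — the tests instead verify the
ES against an exhaustive position-by-position oracle and against an
independent implementation (`fgsea::calcGseaStat`).

# Cofactor risk ratio over contributing genes

For every gene set reported at FDR < 0.25, the package asks whether
cofactor genes are overrepresented among its contributing genes:

$$RR_{cof} = \frac{\#CG_{cof} / \#CG}
  {(\#genes_{cof} - \#CG_{cof}) / (\#genes - \#CG)}$$

with $\#CG$ the number of contributing genes, $\#CG_{cof}$ those that are
cofactor genes, $\#genes$ the set size, $\#genes_{cof}$ the cofactor genes
in the whole set. $RR > 1$ flags overrepresentation. The formula is
evaluated exactly as written even though it is not the canonical 2×2
relative risk (its denominator conditions on the same set); no correction
is applied, because the `>1` decision rule is defined on this exact
quantity. Degenerate cases are explicit: numerator zero gives $RR = 0$;
denominator zero with positive numerator gives $RR = +\infty$ (flagged);
$\#CG = 0$ and $\#genes = \#CG$ are errors.

"Cofactor genes" pools the CoA flag with the NAD(P)(H)-*main* flag (all
reactions involving NAD(P)$^+$/NAD(P)H); the redox flag marks the subset
catalysing only NAD(P)(H) redox chemistry and can be selected instead
(`nadphClass = "redox"`). Per-class ratios and a Fisher exact p-value are
emitted as purely informational extra columns; the overrepresentation call
never uses them.

# The alternative, direction-aware enrichment

## DE gene lists

Per condition and per DGE method, a gene is *differentially expressed* iff

$$(|\log_2 FC| > 0.5 \;\text{AND}\; p < 0.1) \;\text{OR}\; p < 0.05,$$

all inequalities strict. The nominal p-value is used by default: the
criterion trades statistical significance against biological relevance,
and an adjusted p would re-tighten what the relaxed clause deliberately
loosens; `pColumn = "padj"` switches if desired. Separate up and down
lists are kept (sign of the fold change; a fold change of exactly 0
belongs to neither). Lists from the two DGE methods are combined by
*union* by default — the most inclusive reading, with `intersection` and
single-method modes available — and a gene called up by one method and
down by the other is contradictory and excluded from both directions.

## Percentage, ranking, aggregation

For each (condition × direction), each gene set receives the percentage of
DE *metabolic* genes that fall inside it,
$100 \cdot \#DEG_{set} / \#DEG_{all}$. Both counts are restricted to the
collection's universe (the union of all sets, including the three cofactor
sets) so the percentage shares its denominator with the risk ratio below.
Sets are ranked by decreasing percentage with two special rules: tied
percentages share the *competition* (minimum) rank — the rule is stated
only as "the same ranking" in the source method, so a dense variant is
available via `tieMethod` — and every zero-percentage set receives the
rank equal to the number of sets in the collection. Within a condition the
denominator is shared, so this ranking is equivalent to ranking by raw DE
counts; across sets it therefore favours large sets, a structural property
of the method worth keeping in mind (see the recovery-study design below).

Per-condition ranks are aggregated per direction by their *median* (an
even number of conditions averages the two middle values — four conditions
here), and the overall rank is the competition rank of the median with
ties broken by set name for determinism.

## Per-set risk ratio and multi-condition flags

Each (set × condition × direction) cell also receives

$$RR_{set} = \frac{\#DEG_{set} / \#DEG_{all}}
  {(\#genes_{set} - \#DEG_{set}) / (\#metabolic - \#DEG_{all})}$$

with the same exact-as-printed evaluation and degenerate-case conventions
as above ($\#DEG_{all} = 0$ leaves the cell undefined rather than
overrepresented). A set overrepresented ($RR > 1$) in two or more
conditions in a direction receives the multi-condition flag reported in
the top-k table, which cross-references the classical GSEA tiers when
supplied.

# The synthetic-data generator

The generator emulates the *statistical output* of a two-diet ×
fed/fasted, knockout-vs-wildtype design analysed by two DGE methods — not
the raw data. Per table, null genes draw their t-statistic from
Student-t(`df`), the p-value is the exact two-sided tail of that
statistic (hence exactly uniform under the null), the log2 fold change is
centred Gaussian noise, and adjusted p-values are Benjamini–Hochberg
within the table. A planted signal shifts the t-statistic of a fixed,
seeded subset of one set's members by ±`delta` and gives them a fold
change whose sign matches the realized shifted statistic (mean magnitude
`delta * nullSigmaLfc`), which guarantees sign-consistency between the
statistic and the fold change for responsive genes. Planted membership is
drawn once per signal, so the same genes respond in every affected
condition and method — the concordance the median rank rewards.

Default parameters, chosen once for realism: 10,000 genes (a filtered
liver transcriptome), 100 sets of 20–150 members (typical metabolic
pathways after restriction to measured genes), cofactor fractions 0.1 per
class (redox drawn conditionally inside main, enforcing the subset
invariant), `df = 10` (residual degrees of freedom at 6–8 animals per
group), `nullSigmaLfc = 0.4` (null fold changes mostly within ±1). Random
substreams per table are derived from the master seed by fixed offsets, so
the bundle is a pure function of the spec and adding a condition never
perturbs earlier tables.

What the generator deliberately does **not** model: counts, library sizes,
dispersion shrinkage, gene–gene correlation, and correlation between the
two DGE methods beyond shared planted membership (real DESeq2 and voom
outputs on the same samples are strongly correlated; union combination of
their DE lists is therefore *more* variable here than in practice).
Passing tests consequently demonstrate the correctness and calibration of
the statistics, not the biological sensitivity attainable on real data.

# The recovery study design

The package's recovery experiment plants three concordant upward signals
(`delta = 2`, 30% of members responsive, all four conditions) among 100
sets and requires the planted sets to attain the three smallest median
ranks, the multi-condition flag, and classical-GSEA FDR < 0.25. Because
the percentage ranking is count-driven and thus size-biased, the signals
are planted in the three sets nearest the *median* set size (deterministic
tie-break by name): planting in extreme small sets would probe the size
bias rather than signal recovery, and planting in the largest sets would
trivialize it. This choice was fixed analytically at design time.

At these settings roughly 60% of responsive genes pass the inclusion
criteria per method (about 84% under the union), so a median-size set of
~85 members contributes ~25 DE genes against a null expectation of ~6 for
even the largest null set — a comfortable margin for the median rank,
while GSEA sees 30% of members shifted by two null standard deviations.

# Degenerate inputs and numerical conventions

- Missing values (`NA`) exclude a gene from ranking and DE selection;
  nothing is imputed.
- Empty DE lists mark all cells of that condition × direction degenerate:
  percentage 0, rank = number of sets, RR undefined.
- All TSV writers format doubles with 15 significant digits, so re-reading
  reproduces values to ~1e-15 relative error and reruns are byte-identical.
- Seeds are 32-bit integers; derived substream seeds are reduced modulo
  `.Machine$integer.max`.

# Problem sizes used by the shipped tests

The unit tests run on universes of 300–3,000 genes with 5–50 sets. The
statistical acceptance checks use the defaults stated above: one
200-set/10,000-gene null GSEA run at 1000 permutations, twenty 100-set
null replicates for the alternative analysis, twenty recovery replicates,
and a demo pipeline (5,000 genes, 100 sets, 500 permutations, four
conditions) run twice to verify byte-identical determinism.

# Known limitations

- Gene identity is case-sensitive symbol matching; identifier translation
  is limited to a simple mapping layer outside the core statistics.
- The gene-set permutation null treats genes as exchangeable; correlated
  genes (co-expression modules) make it anti-conservative on real data,
  which is a known property of this null, not of this implementation.
- The median-rank aggregation has no attached significance test — the
  method defines none; the multi-condition flag is a descriptive rule
  (`RR > 1` in ≥ 2 conditions).
- The percentage ranking favours large gene sets (shared denominator);
  compare like-sized sets or consult the RR column when interpreting it.
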