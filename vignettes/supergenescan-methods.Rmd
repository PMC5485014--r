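---
title: "Methods: scanning haploid genomes for a non-recombining supergene region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning haploid genomes for a non-recombining supergene region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supergenescan)
```

## The problem

Some genomes carry a *supergene*: a large cluster of linked loci inherited
as a single unit because recombination between its alternative haplotypes
is suppressed. The motivating system for this package is a social
polymorphism in an ant, where a pair of "social chromosomes" behaves like
a young XY pair: one variant (call it SB) still recombines with itself in
homozygous queens, while the other (Sb) effectively never recombines
because its homozygotes die. Haplodiploidy makes the system unusually
tractable — males are haploid, so sequencing sons of heterozygous queens
yields fully phased haplotypes of each variant with no genotype ambiguity.

Given two groups of haploid genomes (n per group, default 8, sampled as
full-brother pairs from heterozygous colonies), the package asks four
questions:

1. **Where is the region?** Sliding-window differentiation (multilocus
   FST and fixed-difference counts) along linkage-group-anchored
   scaffolds; the region is called as a run of consecutive
   non-overlapping windows with FST above a threshold.
2. **How diverged and how diverse is it?** Nucleotide diversity within
   each group, per window, contrasted between the region and the rest of
   the mapped genome; synonymous/nonsynonymous divergence between group
   consensus coding sequences.
3. **Is there internal structure (evolutionary strata)?** A scan for a
   contiguous block of genes with lower divergence than the rest,
   assessed against a Poisson substitution null.
4. **Is purifying selection weaker on the non-recombining variant?** A
   McDonald-Kreitman contrast of nonsynonymous:synonymous ratios in fixed
   differences versus polymorphisms, and comparison of gene dN/dS against
   a between-species background distribution.

## Statistical machinery

### Multilocus FST on haploid indicators

FST is estimated by two-level variance components on haploid
allele-indicator variables (Weir–Cockerham style). For each site and
allele, one-way ANOVA of the 0/1 indicator across the two groups yields
an among-group component $a = (\mathrm{MSB} - \mathrm{MSW})/n_c$ and a
within-group component $b = \mathrm{MSW}$, with
$n_c = n - (n_1^2 + n_2^2)/n$. Components are summed over alleles and
sites and combined as a ratio of sums, $F_{ST} = \sum a / \sum (a + b)$.
Monomorphic sites contribute nothing; a window with a zero denominator is
*undefined* (NA), never 0, and downstream consumers (region calling,
means) treat NA windows explicitly. Negative estimates are legitimate and
expected here: because samples are sibling pairs split across the groups,
within-group variance exceeds between-group variance outside the
supergene, and the background FST is slightly negative. The estimator is
checked against an independent `lm()`-based ANOVA oracle to 1e-12 in the
test suite.

### Nucleotide diversity

Nei's per-site diversity with the small-sample correction,
$\hat\pi_{site} = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, summed over
variant sites and divided by the *accessible* (non-N) bases of the
window, which equals the mean pairwise difference rate. Sites with fewer
than two called samples in the group are skipped. The frequency formula
is multiallelic, so triallelic SNPs need no special casing.

### Windows in non-N coordinate space

Assemblies contain N gaps; a fixed-width physical window overlapping a
gap would silently hold fewer informative bases. Windows here cover a
fixed number of *non-N* positions (default 30 kb sliding every 10 kb for
scans, 10 kb tiling for summaries and region calls), stretching over gaps
in physical coordinates. A terminal window short of the full size is kept
but flagged `partial`, is excluded from genome-wide means, and retained in
scans.

### Quality filters

Variant sites are kept when site confidence exceeds 15 and, for every
sample in scope, genotype confidence exceeds 10 (low-coverage samples) or
2 (high-coverage samples) and the called allele has coverage of at least
one read. STR loci require reference repeat counts strictly above 9/5/4
for period 1/2/≥3, and calls require Q ≥ 0.25, ≥ 2 supporting reads and
coverage ≤ 25 (inclusive, the plain reading of "a maximum coverage of
25"). For within-group diversity the per-sample filters are applied
*separately per group*, so one group's call quality cannot depress the
other group's diversity estimate. The strict (`>`) reading of the STR
unit thresholds is the default; an `inclusive` flag switches to `>=`
since the source description is ambiguous between the two.

### Genome map

Scaffolds are anchored to linkage groups through RAD markers from seven
families. A scaffold whose markers all come from a single single-queen
family map with fewer than four markers is dropped as low-confidence.
Scaffolds with markers in two or more linkage groups are treated as
assembly chimeras and split, each linkage group keeping the span of its
own markers; interleaved marker ranges are an unresolvable error.
Ordering within a linkage group is by mean marker cM and orientation by
the sign of the cM–bp correlation, with "unknown" propagated on ties and
single-marker segments rather than guessed. This deliberately replaces
genetic-algorithm map ordering: every downstream statistic depends only
on segment-to-linkage-group assignment and coarse order, which mean-cM
ordering reproduces on clean maps. Internally segment arithmetic is
0-based half-open; VCF/GFF coordinates are 1-based at the boundary, and
`scaffold_to_pseudo()` is the single conversion point.

### Coding divergence (NG86)

For each gene surviving the filters (not partial, standard nuclear code,
length divisible by three, no N, no indel variant overlapping the CDS in
any sample), one consensus CDS per group is built from the
fixed-difference SNPs; the reference individual belongs to the first
group, so that group's consensus is the reference CDS unless a fixed
difference says otherwise. Divergence uses Nei–Gojobori (1986) counting:
per-codon synonymous site fractions averaged over both sequences, equal
weighting of minimal mutation paths for multi-hit codons (paths through
stop codons excluded), and the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. dN/dS is undefined when
dS = 0, and the correction is flagged saturated at p ≥ 3/4. Stop codons
participate as their own identity class, preserving the invariant
N + S = CDS length. NG86 was chosen over rate-weighted counting methods
because every quantity is hand-checkable; the worked examples frozen in
the tests are derived from the codon table directly. Note that the
two-sequence averaging matters even in toy examples: a single Gly→Ser
first-position change gives S = (3 + 7/3)/2 = 8/3 over three codons, not
3.

### Contingency tests

Welch t, Wilcoxon rank-sum, Pearson chi-squared and Fisher's exact test
are delegated to the corresponding base R routines behind thin wrappers
that fix the conventions used throughout: Yates continuity correction is
the default for 2×2 chi-squared (with the published count tables it is
the corrected statistic that reproduces the reported value; uncorrected
Pearson gives 47.1 instead of 46.3), and two-sided Fisher p-values use
the probability-mass rule. The McDonald-Kreitman test is the corrected
chi-squared on the [fixed; polymorphic] × [nonsynonymous; synonymous]
table plus the neutrality index NI = (pN/pS)/(dN/dS counts).

### Strata scan and its null

The scan computes a two-sided Welch t-test of every contiguous span of at
least `min_span` (default 30) neighbouring genes against all other genes,
on per-gene substitution rates (fixed differences per coding bp; dS can
be supplied instead), and takes the span minimising p among spans whose
mean is *lower* than the complement's — the candidate young stratum. The
null model draws per-gene counts from Poisson(rate × length) at the
global rate (default one substitution per 3000 coding bp) and repeats the
scan (default 10,000 simulations); the empirical p is the fraction of
simulations whose minimum p is at least as small as observed, ties
counted as stronger (conservative).

One design choice deserves emphasis: the maximum span length defaults to
leaving at least `min_span` genes in the complement (never more than
G − 2). If spans are allowed to grow until the complement holds only two
genes, the null scan's minimum is dominated by near-degenerate spans
whose tiny complements have almost no variance — Welch p-values of
1e-100 and smaller arise routinely under the null — and a genuine
planted stratum can no longer win the comparison (detection power
collapsed to ~15% in our experiments). Bounding the span restores both
calibration (empirical p uniform under the null, KS p > 0.05 at 1,000
replicates) and power (97% detection of a 30-gene span at a tenth of the
rate among 400 genes). Only the lowest-divergence direction is scanned,
since the question is whether a *younger* stratum exists; the bound is a
user-facing parameter.

### Permutation and robustness checks

Group labels are permuted across all samples (group sizes preserved) and
the statistic (fixed-difference count or FST) recomputed; the p-value
uses the add-one Monte-Carlo convention (1 + #{null ≥ obs})/(n + 1),
which cannot return zero. A `stratified` mode instead forces each
permuted group to mix the two true genotypes equally, which under a real
supergene signal collapses fixed differences to near zero — the sanity
check that observed differentiation reflects the genotype grouping, not
an arbitrary one. Unmapped scaffolds are assigned to the region when at
least one window clears both an FST threshold (default 0.75) and a
fixed-difference density threshold (default 25 SNPs per 30 kb window);
one qualifying window suffices by default, exposed as
`min_qualifying_windows`. Total region size is extrapolated to genome
size bounds under the assumption that unassembled sequence carries the
region proportionally.

## The synthetic study design

`simulate_dataset()` emulates the study design the analysis assumes, not
a population-genetic process. Variants are planted by independent
per-site Bernoulli draws in four truth classes, because every statistic
the pipeline computes is a marginal site quantity:

* **fixed differences** inside the region at 1.4 per kb (group A all
  reference, group B all alternate);
* **group-private polymorphisms** inside the region, calibrated to
  within-group diversities of 6.7e-4 (A) and 1.3e-6 (B) per bp;
* **shared background polymorphisms** outside the region calibrated to
  8.2e-4 per bp within each group;
* **pair-private variants** (when `paired_siblings = TRUE`) carried by
  exactly one sample of each group — full brothers — which reproduce the
  slightly negative background FST of a paired design. Their fraction of
  background polymorphic sites (0.2) is a package choice: large enough
  that the negative-FST signature is unmistakable, small enough not to
  distort the site-frequency spectrum.

Within-group allele frequencies are drawn with a neutral-like 1/i
weighting over minor counts; this is a stand-in (the real site-frequency
spectrum is not specified by the design), chosen because it keeps the
diversity calibration analytic. Group-private sites use the exact
expectation of the corrected heterozygosity under that weighting; shared
sites additionally integrate over the hypergeometric split of carriers
into one group. Densities are therefore matched in expectation without
any empirical tuning. N gaps are placed as contiguous blocks (2% of each
scaffold) specifically to exercise the window-stretching logic. Genes are
single-exon, alternating strands, half inside the region, with
codon-aware alternate alleles at fixed coding sites targeting a
nonsynonymous fraction of 374/791; three decoy models (partial,
mitochondrial code, broken frame) exercise the gene filters. Indels are
kept out of CDS spans so planted per-gene substitution counts stay exact;
the indel-veto rule of `filter_genes()` is exercised with constructed
tables in the tests instead. Quality annotations are drawn so a small
fraction of sites (0.5%) and calls (0.1% genotype confidence, 0.02%
coverage) fail each filter — enough to exercise the filters while
biasing post-filter diversity by well under the 5% recovery tolerance.

What the generator does *not* model: linkage and recombination maps,
demography, selection, sequencing reads, genotyping error correlated with
coverage. Passing tests therefore demonstrate that the estimators recover
the marginal structure they are defined on, not that they are robust to
every artefact of real resequencing data.

## Problem sizes and numerical choices

The default synthetic genome is 8 Mb in four scaffolds (3/2/2/1 Mb) with
a 1 Mb region planted on the first — large enough that background
diversity is recovered within 5% relative error and the region boundary
within a window, small enough to run the full pipeline in about two
minutes. Calibration experiments use reduced inner simulation counts
(200) with 1,000 outer replicates; the planted-stratum power experiment
uses 400 genes of 1.5 kb with 100 replicates. Expected within-region
diversity for the Sb-like group at these sizes is only a handful of
variant sites, so its *ratio* to background is reported and asserted
qualitatively (two orders of magnitude reduction) rather than to a
relative tolerance that a Poisson count of ~3 cannot meet.

Degenerate-input conventions, in one place: zero-variance Welch
comparisons return p = 1 (equal means) or a flagged p = 0 (unequal);
monomorphic windows have undefined FST; dN/dS is NA when dS = 0;
permutation p-values are bounded below by 1/(n_perm + 1); empirical
strata p counts ties as stronger; region calls break runs at
undefined-FST windows.

## Limitations

* The FST estimator variant is normative here (ANOVA on haploid
  indicators, ratio of sums); other estimators differ in small samples.
* Consensus building assumes the reference individual belongs to the
  first group; with a reference from neither group, fixed differences
  where both groups differ from the reference would need a third allele
  path that is not implemented.
* The strata scan tests a single candidate stratum; it is not a
  changepoint segmentation and will not resolve multiple strata.
* Mean-cM ordering can misorder scaffolds within a linkage group when
  marker cM values are noisy; the statistics consumed downstream are
  robust to coarse ordering errors but figures drawn from the map are
  not.
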