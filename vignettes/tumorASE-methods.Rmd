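---
title: "Modelling allele-specific expression and somatic copy number in tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allele-specific expression and somatic copy number in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorASE)
```

## The problem

A gene with allele-specific expression (ASE) transcribes its two copies
unequally. In tumors, ASE is a readout of dosage-altering lesions: a
hemizygous deletion removes one haplotype outright, a stop-gain mutation
triggers nonsense-mediated decay (NMD) of one haplotype's transcripts,
promoter hypermethylation can silence one allele, and imprinting does so
constitutively in normal tissue too. tumorASE measures ASE and DNA
allelic imbalance from allele-specific read counts at heterozygous
sites, classifies genes with tumor-specific recurrent ASE, attributes
that ASE to somatic copy-number alterations (SCNAs) where the DNA
supports it, and tests whether the remainder is enriched for
NMD-triggering mutations.

## The allelic-imbalance model

At a heterozygous site $i$ with $n_i$ reads matching either allele, the
reference-allele count $x_{R,i}$ is modelled as beta-binomial with mean
proportion $p = 0.5 + a$ and concentration $d$:

$$\Pr(X = x \mid p, d, n) =
  \binom{n}{x}\frac{B(x + dp,\; n - x + d(1-p))}{B(dp,\; d(1-p))}$$

The allelic imbalance $a \in [-0.5, 0.5]$ is the deviation of the
reference proportion from one half; $d > 0$ absorbs the extra-binomial
variance of sequencing coverage (larger $d$ means closer to binomial;
the implementation evaluates everything through log-gamma functions, so
no beta function is ever formed in linear space).

### Genotyping and sequencing errors

A site called heterozygous may actually be homozygous; such sites look
perfectly monoallelic and would fake strong ASE. Each site carries a
Phred-scaled genotype quality, converted to an error probability
$\epsilon_G = 10^{-GQ/10}$. With probability $1 - \epsilon_G$ the site
is truly heterozygous; otherwise it is homozygous reference or
alternate (equally likely) and the minor-allele reads are sequencing
errors at rate $\epsilon_S$. The site likelihood is the three-component
mixture

$$(1-\epsilon_G)\, p_X(0.5 + a, d)
  + \tfrac{\epsilon_G}{2}\, p_X(\epsilon_S, d)
  + \tfrac{\epsilon_G}{2}\, p_X(1 - \epsilon_S, d),$$

combined with log-sum-exp. The mixture is used for per-gene RNA calls,
where a single bad site among few can flip a call; DNA bin estimates
pool dozens of sites and use the pure beta-binomial form.

### Phase marginalization

All sites of a unit (a 20-exon DNA bin, or one gene's exons for RNA)
share one $a$, but which allele of each site sits on which haplotype is
unknown. The likelihood averages over all $2^{m-1}$ haplotype
configurations, anchored so that the first site's reference allele
defines haplotype A. A dynamic program computes this in linear time:
the first site enters unflipped, and each later site contributes the
sum of its likelihood at the observed and at the flipped count
($x \to n - x$); the result is divided by $2^{m-1}$. All of it runs in
log space — the literal product underflows for realistic bins.

Because the anchor fixes the first site's phase, the marginalized
likelihood is *not* an even function of $a$; the exact symmetry is
$L(a \mid x) = L(-a \mid n - x)$, a global relabelling of which allele
is called "reference". The sign of the fitted $\hat a$ is therefore
anchored to an arbitrary labelling choice, and every downstream use
works with $|\hat a|$. We keep $\hat a$ signed in the fit object rather
than folding it, so the symmetry remains testable.

### Nuisance parameters and the test

One dispersion $\hat d$ is estimated per sample by fixing $a = 0$ and
maximizing the total likelihood across all heterozygous sites
genome-wide (log-scale search in $[10^{-2}, 10^8]$). For RNA,
$(\hat d, \hat\epsilon_S)$ are maximized jointly with L-BFGS-B, both on
the log scale so finite-difference gradients stay proportionate near
small $\epsilon_S$ (bounds $\epsilon_S \in [10^{-6}, 0.1]$). Fixing
$a = 0$ is deliberate model misspecification: genuinely imbalanced
genes inflate the apparent overdispersion, biasing $\hat d$ low. This
is conservative (it widens per-gene likelihoods), and in extreme cases
— a near-pure tumor where a third of sites sit in deleted, imprinted or
NMD-degraded regions — $\hat d$ can collapse toward 1 and per-gene
power in that sample suffers. The cohort-level classifications below
are designed to ride over single-sample power loss.

Per unit, $\hat a$ maximizes the marginalized likelihood over
$a \in [-0.5 + 10^{-4}, 0.5 - 10^{-4}]$ (keeping both beta shapes
positive): a 21-point grid locates the basin — the likelihood can be
bimodal in sign — and golden-section refinement polishes to $10^{-8}$.
A likelihood-ratio test against $a = 0$ is referred to $\chi^2_1$;
since the anchored likelihood is regular at the interior null, the
standard asymptotics apply (simulated type-I error at $p < 0.05$ is
0.05, and it is an acceptance check of this package).

## SCNA scoring from DNA imbalance

Heterozygous sites are defined in the matched normal; counts at shared
positions are collected from the tumor. Exons are pooled across genes,
exact duplicates from overlapping transcripts dropped, sorted, and
grouped per chromosome into bins of 20 consecutive exons (a trailing
remainder bin is kept and subject to the same filters). Sites need
$\ge 10$ reads in both samples; bins keep $\ge 10$ such sites. Each bin
gets independent tumor and normal fits, and

$$\delta_a = |a_\mathrm{tumor}| - |a_\mathrm{normal}|$$

is segmented per chromosome with circular binary segmentation:
recursively, the maximal absolute two-sample $t$-statistic over all
circular arcs is found, its significance assessed by permuting the bin
values (1000 permutations, $\alpha = 0.01$, minimum arc 2 bins;
permutations stop early once the exceedance count already guarantees
non-significance, which cannot change any split decision), and accepted
splits recursed into. The mean $\delta_a$ of a final segment is its
**SCNA score**; a gene gets the score of the segment overlapping its
promoter (TSS $\pm$ 1500 bp), the TSS-containing segment winning when a
promoter spans a breakpoint. Scores $\ge 0.09$ call an SCNA.

Two properties of $\delta_a$ are worth keeping in mind. First, tumor
purity $\rho$ dilutes it: a hemizygous deletion shifts the retained
allele's DNA fraction to $1/(2 - \rho)$, so at $\rho = 0.5$ the
expected tumor imbalance is $1/6$, not $1/2$. Second, $|\hat a|$ is a
folded estimate, so under the null it has positive mean (about 0.03 at
20 sites of depth 80 with $d = 40$); $\delta_a$ subtracts the normal's
folded estimate and therefore sits slightly below the closed-form
tumor imbalance (simulation gives 0.135 rather than 0.167 at the
conditions above). The 0.09 decision threshold leaves headroom for
both effects.

## Cohort-level ASE calling and classification

RNA sites are filtered for depth ($\ge 10$ reads) and for "other"
reads (more than two reads matching neither allele disqualify a site,
pointing at mapping artifacts). Per sample, each gene with at least one
qualifying exonic site is fitted and tested; p-values are
Benjamini-Hochberg corrected *within the sample* across its testable
genes (the correction scope matches the per-sample significance counts
used downstream), significant at $q < 0.1$.

A gene has **tumor-specific recurrent ASE** when (a) it is testable in
at least 10 tumors and 10 normal samples, and (b) significant in at
least 3 tumors and at most 1 normal sample. The two normal
sub-cohorts (adrenal-like and blood-like) are counted combined in both
(a) and (b) — the defensible alternative of requiring 10 per tissue
would only shrink the testable set, and a gene not expressed in one
normal tissue simply contributes no testable samples there. Imprinted
genes are significant in normals too, so criterion (b) removes them by
construction.

For each such gene, tumor samples are partitioned into `non_ASE`
(not significant), `ASE_SCNA` (significant, SCNA score $\ge 0.09$ at
the promoter) and `ASE_non_SCNA` (significant, no SCNA; a missing
score counts as no SCNA evidence but stays distinguishable as `NA`
upstream).

## Integration statistics

*ASE-SCNA association.* Spearman correlation (average-rank ties)
between $|a_\mathrm{RNA}|$ and SCNA score per gene across tumors,
restricted to genes with non-zero variance in both quantities and a
score $\ge 0.09$ in at least one sample; BH across tested genes, FDR
10%.

*Stop-gain burden.* Two complementary permutation designs. The
gene-set sampling draws 100 genes from each set (tumor-specific ASE,
ASE-in-both, random mutated genes) 500 times and counts genes carrying
stop-gains per draw; the distributions separate when one set is
enriched. The category-rate test computes the stop-gain mutation rate
per sample category and compares it with rates under 1000 within-gene
label permutations, which exactly preserve each gene's mutation burden
and its category multiset, controlling for gene length and
mutation-rate heterogeneity. Rates are reported as
$\log_2(\mathrm{obs}/\mathrm{exp})$ with a 0.5 pseudocount on both
counts so a zero expected count cannot produce an infinite ratio; the
cell denominators cancel because permutation preserves category sizes.

*Methylation and expression.* Promoter methylation is the mean
$\beta$ over CpG probes in TSS $\pm$ 1500 bp, requiring $\ge 3$
probes; Spearman + BH as above. Expression matrices are quantile
normalized (averaged quantiles on ties, via limma) and row z-scored;
the stage-4 contrast is a per-gene Welch $t$-test of stage-4 tumors
against the rest on $\log_2(1 + x)$ values — the fold change is the
difference of group means on that log scale, since published matrices
of this kind are log-scale — with hits requiring $q \le 0.05$ and
$|\log_2 FC| \ge 0.5$. Two-sided tests throughout.

*Frequency contrast.* Whether ASE is more frequent in tumors than in a
normal tissue is a two-sided Fisher exact test on the 2×2 table of
ASE-positive versus testable samples.

## The synthetic cohort generator

Every pipeline stage is validated on generated cohorts with known
ground truth, because the real data equivalents live under protected
access. The generator draws, per sample: DNA depths NB(mean 80, size
8) and RNA depths NB(mean 60, size 5) — exome-like and bulk-RNA-like
coverage; beta-binomial counts at concentration 40 (DNA) and 25 (RNA),
matching the stronger technical overdispersion of RNA; tumor purity
from Beta(8, 2) (mean 0.8, occasional near-pure and sub-0.5 samples);
recurrent arm-scale events (a hemizygous deletion over 40% of one
chromosome in half the tumors, a duplication over 30% of another in a
quarter) whose allele fractions follow the purity mixture above;
stop-gain mutations in 10% of genes at 30% per-tumor carrier rate,
degrading the mutated haplotype's RNA output by 80% (NMD efficiency
0.8); 5% imprinted genes, monoallelic (residual 2% output) in every
sample of every cohort; 5% tumor-acquired regulatory silencing and
5% methylation-silenced genes (promoter $\beta$ drawn high in
silenced tumors); and 3% genotyping errors — truly homozygous sites
labelled heterozygous with GQ in 3–20, their minor reads pure
sequencing error at rate 0.005 — against GQ 30–99 for correct calls.
A master seed derives one stream per sample, so enlarging a cohort
never perturbs existing samples.

What the generator does *not* emulate: read-level artifacts (mapping
bias is assumed removed upstream), linkage between neighboring sites
beyond shared gene effects, focal SCNAs smaller than a bin,
subclonality (one purity per sample, clonal events), and germline
regulatory ASE shared between tumor and normal. Passing tests
therefore demonstrate correctness of the inference machinery under the
model's own assumptions and realistic magnitudes — not robustness to
every artifact of real sequencing data.

## Validation problem sizes

The shipped checks run at deliberately modest scale: the phasing
dynamic program is compared with exhaustive enumeration on 1000 bins
of up to 10 sites; dispersion recovery uses 10,000 sites; LRT
calibration uses 2000 null genes and 50 null cohorts of 40 genes;
segmentation is checked on 100-bin chromosomes over 200 noise
replicates; and the end-to-end cohort has 200 genes and 12 + 12
samples. These sizes keep the full suite in the minutes range while
leaving every statistical conclusion stable across seeds.

## Known limitations

- The genome-wide dispersion is estimated under $a = 0$; pervasive
  true imbalance (very pure tumors with large SCNAs) deflates
  $\hat d$ and with it per-gene power in that sample. Cohort-level
  classification absorbs this; single-sample calls in near-pure tumors
  are conservative.
- $|\hat a|$ is biased upward under the null at finite depth, so
  $\delta_a$ underestimates the closed-form tumor imbalance slightly;
  thresholds were set with this in mind.
- The sign of $\hat a$ is a labelling artifact of the phase anchor;
  only $|\hat a|$ is biologically meaningful.
- CBS significance uses plain permutation p-values; very long
  chromosomes would benefit from the tail approximations used by
  specialized packages, at the cost of reproducing their exact
  behavior.
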