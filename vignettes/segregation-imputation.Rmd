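---
title: "Imputing non-genotyped individuals from genotyped relatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing non-genotyped individuals from genotyped relatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(segimpute)
```

## The problem

Historical livestock datasets often hold valuable phenotypes — feed intake,
health records — on cows that were never genotyped and can no longer be
sampled. Their relatives, however, frequently are genotyped: sires and
maternal grandsires almost routinely, and sometimes offspring. `segimpute`
imputes the genotypes of such non-genotyped individuals from their relatives
alone, scores how well that works, and predicts animal-specific imputation
accuracy from pedigree relationships before any genotyping is done.

Because the target individuals have *no* genotypes of their own, there are
no typed markers to anchor linkage-disequilibrium or haplotype methods at
the individual itself. The package therefore deliberately uses single-locus
information only: Mendelian inheritance rules and segregation analysis
(iterative peeling) over the pedigree, with population allele frequencies as
priors. No linkage, LD or haplotype information enters anywhere.

## The model

### Segregation analysis (iterative peeling)

At one biallelic SNP, each individual has a genotype $g \in \{0, 1, 2\}$
counting copies of the coded allele. The pedigree defines a factor graph:
founders carry a Hardy–Weinberg prior at allele frequency $p$, each
parent–offspring trio contributes the Mendelian transmission probability
$T(g_o \mid g_s, g_d)$ (a parent with genotype 0, 1 or 2 transmits the coded
allele with probability 0, ½ or 1), and observed genotypes enter as
indicator penetrances. Peeling passes two kinds of messages per individual:

* the **anterior**, carrying information from ancestors and full sibs
  downwards, and
* one **posterior** per mating, carrying information from mates and
  descendants upwards.

The anterior of an individual sums over its parents' genotype pairs,
weighting each pair by the parents' own anterior, penetrance and
posteriors from their *other* matings, by the likelihood of the
individual's full sibs, and by the transmission probability. The posterior
a mating sends to one parent marginalises the mate and multiplies the
offspring likelihoods. The final genotype probability triplet is
proportional to anterior × penetrance × posterior product, and the
**dosage** is its expectation $p_1 + 2 p_2 \in [0, 2]$.

On loop-free pedigrees a fixpoint of these equations gives the exact
single-locus marginals — the test suite checks this against brute-force
enumeration of all $3^n$ genotype configurations on random pedigrees. Real
livestock pedigrees are looped (shared sires, shared mate pools), so the
messages are iterated to convergence; this is the standard approximate
behaviour of iterative peeling, and the pipeline's accuracy results
quantify how well it works exactly where the loops occur.

Before peeling, a deterministic pass (`mendelian_rules_fill()`) iterates
the basic inheritance rules to a fixpoint: homozygous parents force
offspring alleles, homozygous offspring force parental alleles, and a
genotype is written only when both alleles are forced. Peeling then treats
the forced genotypes as observed. The fill changes no probabilities — a
forced genotype gets posterior probability one from peeling anyway, which
the tests cross-check — but it detects Mendelian conflicts early and gives
the peeling iteration a warm, consistent start.

### Calling, dosages and the "not imputed" state

A genotype is *called* when the largest probability in the triplet reaches
`call_threshold`; otherwise it is reported as not imputed (code 9 in file
output), while its dosage is always reported. The threshold defaults to
0.98: calls should be near-certain, because an imputed genotype used in a
downstream GWAS carries no flag saying how confident it was. All accuracy
statistics that matter here use dosages, which are insensitive to the
threshold; the threshold only moves genotypes between the "correct /
incorrect / not imputed" call-rate columns.

### Allele frequencies

Frequencies are estimated per SNP as half the mean genotype code over the
*reference* (genotyped) individuals and clamped to
$[1/(2 n_\mathrm{ref} + 2),\; 1 - 1/(2 n_\mathrm{ref} + 2)]$. The clamp
keeps a SNP that happens to be fixed in a finite reference from zeroing
out the unobserved allele pedigree-wide; its value is the Laplace-style
pseudocount of one extra heterozygote.

## Scoring imputation

The headline statistic is the **corrected animal-specific accuracy**: the
Pearson correlation, across SNPs, of the true genotypes *minus the mean
gene content* with the dosages *minus the mean gene content*, where mean
gene content ($2p$) is the per-SNP mean genotype of the reference set.
SNPs differ in allele frequency, so raw genotypes of different SNPs have
different means; correlating raw values mixes that between-SNP variance —
which any method reproduces for free from allele frequencies alone — into
the accuracy. The uncorrected correlation is therefore reported too, but
only to show its upward bias: for a parent-average prediction with both
parents genotyped the corrected accuracy sits at the selection-index value
$\sqrt{0.5} \approx 0.71$ while the uncorrected one is near 0.88.

Undefined correlations (zero variance in either argument, e.g. a SNP
monomorphic among the tests) are flagged `NA` and excluded from means
rather than zero-filled, which would bias category means downward for
edge cases. Call rates per animal and per SNP partition into
correct / incorrect / not-imputed percentages summing to 100.

Aggregation pools animal-by-replicate values for means and standard
deviations by relative category — both parents genotyped, sire plus
maternal grandsire, dam plus paternal grandsire, single parent, or other,
assigned in that precedence order — and bins per-SNP accuracy by reference
minor allele frequency (20 equal bins on $[0, 0.5]$ by default, a
deterministic summary standing in for a LOESS curve).

## Predicting accuracy from the pedigree

Gene content behaves as an additive trait with heritability one, so
selection index theory predicts the accuracy of imputing a candidate from
genotyped relatives as $r = \sqrt{G' P^{-1} G}$, where $P$ holds the
additive relationships among the information sources (diagonal $1 + F$)
and $G$ the relationships between sources and candidate.
`predict_grid()` evaluates the standard design grid — ancestors
{both parents, sire + maternal grandsire, one parent} × {0, 1, 2, 4}
genotyped maternal-half-sib offspring with unrelated, ungenotyped mates —
on an explicit fixture pedigree, so every relationship is computed, not
hard-coded:

```{r}
predict_grid()
```

These predictions assume the sources' genotypes are known without error
and everyone else is uninformative. With genotyped offspring the simulated
pipeline beats them, because the offspring's *other* parents (the shared
mate-sire pool) become partially inferable from their many genotyped
offspring — information the three-relative index ignores.

## The synthetic data generator

No real dataset ships with the package; the generator emulates the data
structure the methods are aimed at.

**Pedigree** (`generate_study_pedigree()`): ungenotyped test cows, each
with a genotyped sire (drawn from a sire pool, about 16 daughters per
sire — a realistic dairy half-sib family size), an ungenotyped dam who is
herself the daughter of a genotyped maternal grandsire, and 0–4 genotyped
offspring; offspring sires come from a shared pool of ungenotyped mate
sires (60 at full scale), drawn without replacement within a cow so the
offspring are strict maternal half sibs. `extra_reference` adds unrelated
genotyped founders, emulating the large genotyped reference populations
(thousands of animals) such studies have; they sharpen allele-frequency
and mean-gene-content estimates but carry no pedigree information about
the tests. Offspring scenarios `Off0`–`Off4` differ only in masking: one
pedigree, one truth, nested reference sets.

**Founder haplotypes** (`simulate_founder_haplotypes()`): two modes.
The *coalescent* mode simulates sequence chunks under a piecewise-constant
cattle demography (effective size 100 now, 1256 at 1000 years, 4350 at
10 000 years, 43 500 at 100 000 years; mutation rate $2.5 \times 10^{-8}$
per site) and samples SNPs uniformly from segregating sites with no
frequency filter, giving the slightly U-shaped spectrum (mean minor allele
frequency ≈ 0.23) characteristic of random sequence variants in such a
population. Chunks are independent genealogies standing in for
recombination along the chromosome; the default chunk length of 100 kb
keeps enough independent deep genealogies that the spectrum is stable
across replicates. The demography is specified in years; converting to
coalescent generations uses a generation interval of 5 years, a typical
dairy-cattle value (the spectrum is sensitive to this choice — longer
intervals compress the bottleneck and raise the mean MAF). The *sfs* mode
draws per-SNP frequencies from a symmetric Beta distribution whose default
shape 0.815 is calibrated so the pool mean MAF matches the coalescent
mode's ≈ 0.23, then samples alleles independently per site. Since
segregation analysis uses no linkage or LD, the two modes are
interchangeable for imputation experiments, and the cheaper sfs mode is
the default there; the coalescent mode exists to make the simulated
spectrum itself faithful.

**Gene dropping** (`gene_drop()`): founders take two pool haplotypes;
every non-founder receives one recombinant gamete per parent with
crossovers from a Poisson process at one event per 100 cM (Haldane, no
interference) and a fair-coin starting strand. Phase and crossover
positions are recorded, and the tests verify each gamete is a mosaic of
exactly the two parental gametes with boundaries at the recorded
crossovers. SNP map positions are uniform on the 100 cM chromosome rather
than derived from simulated physical coordinates; all reported metrics are
map-agnostic, so only the crossover process itself matters.

What the generator does *not* emulate: genotyping error (penetrances are
indicators), selection and non-random mating, X-linked inheritance,
within-chromosome LD in sfs mode, and the idiosyncratic structure of any
real herd pedigree. Passing tests therefore show the method's behaviour
under clean Mendelian data on the stated family structures, not
robustness to data errors.

## Numerical choices

* Convergence is the maximum absolute change of any stored probability
  between rounds, default tolerance $10^{-6}$, maximum 30 rounds; the
  study-like pedigrees converge in 2–6 rounds. Non-convergence warns and
  returns the current state.
* Messages are renormalised to sum one at every step; an all-zero message
  (impossible for Mendelian-consistent input) falls back to uniform.
* Ties at the call threshold are not called.
* Individuals with exactly one known parent get a phantom unrelated
  founder as the other parent, which is equivalent to marginalising it
  over Hardy–Weinberg; phantoms never appear in output.
* The peeling kernel is C++ (via Rcpp): the hot loop visits every mating
  at every SNP in every round, and compiled code keeps full experiments in
  minutes on one core.

## Problem sizes used by the shipped experiments

The packaged acceptance analysis runs a scaled-down replica of the full
design: 200 test cows with a 15-strong mate-sire pool (preserving the
805 : 60 cow-to-mate-sire ratio of the full-scale design), 1000 extra
reference founders (preserving the roughly 6 : 1 reference-to-test ratio),
500 unlinked SNPs and 3 genotype replicates, with scenarios Off0–Off4 by
masking. Parent-average properties use 60 independent trios over 2000
unlinked SNPs whose allele frequencies come from a coalescent run under
the cattle demography (4000 haplotypes over 8 Mb), replicated four times;
sites are sampled independently given those frequencies because the
per-animal accuracy is a Pearson correlation across SNPs, and the fully
linked blocks inside a chunked coalescent pool would shrink the effective
SNP count and bias the estimate downward — linkage that segregation
analysis ignores anyway. The allele-frequency spectrum check itself uses
the haplotype pools directly (frequencies are linkage-agnostic), averaging
eight pools of 4000 haplotypes over 48 Mb. These sizes give standard
errors comfortably inside the tolerances quoted for the corresponding
quantities while a full run stays in the minutes range.

## Known limitations

* Iterative peeling is approximate on looped pedigrees; the
  exactness oracle covers loop-free cases only.
* Accuracy predictions treat the sources' genotypes as known; they
  under-predict when ungenotyped mates become inferable (many genotyped
  half-sib offspring per mate sire) and over-predict under genotyping
  error.
* Single-locus treatment throws away real linkage information by design;
  methods using phased haplotypes can call far more genotypes, at the
  price of more incorrect calls for individuals with no own genotypes.
* The generator's category mix is idealised (all test cows SireMGS by
  default); real datasets mix categories, which the `p_sire_genotyped` /
  `p_mgs_genotyped` and `extra_reference` knobs only approximate.
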