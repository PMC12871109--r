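---
title: "Somatic mutation, selection and phasing from ultra-deep duplex panels"
author: "DuplexSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mutation, selection and phasing from ultra-deep duplex panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DuplexSelect)
```

# Scope and model

Duplex sequencing builds a consensus from both strands of each original DNA
molecule, pushing the error floor below 10^-4^ and making it possible to
call somatic mutations carried by single molecules in normal tissue. This
package implements the *post-calling* analysis of such data on targeted
gene panels: it starts from per-sample variant calls annotated with alt
duplex read counts, duplex depth, a no-call fraction and a mismatch
annotation, and ends with burden statistics, selection inference, a
pathogenicity summary, and read-backed phasing against a germline
heterozygous site. Raw consensus calling, mutational-signature extraction
and external annotation services are out of scope.

Every stage is exercised end to end on a synthetic cohort generator whose
defaults emulate the study conditions the package targets: eleven blood
subjects aged 25--76 (three carriers of a germline *TP53* variant, two
subjects with chemotherapy exposure), panels at a mean duplex depth of
15,000x, and a somatic base rate of 10^-8^ mutations per duplex nucleotide
per year.

# The filter cascade

Calls pass a fixed sequence of rules; the order makes rejection reasons
stable and reproducible:

1. **depth** -- duplex depth below 1000 reads;
2. **no_call** -- no-call fraction above 0.1 (an upstream annotation the
   pipeline never recomputes);
3. **germline_vaf** -- VAF above 0.3, the signature of a germline
   polymorphism at these depths;
4. **mask** -- position inside the excluded-region BED (0-based half-open
   on disk, converted to 1-based closed `GRanges` on import);
5. **recurrent_artifact** -- the variant key (chrom:pos:ref>alt; an MNV
   such as CC>TT is one key) occurs in three or more samples *and* carries
   a mismatch annotation of 8 or more. The mismatch condition is applied
   as "in at least one carrying sample", the conservative
   artifact-removal reading; a mode requiring it in every carrying sample
   is available;
6. **cross_sample_germline** -- any key seen above VAF 0.3 in *any* sample
   is excluded from all samples. The evidence for this rule is taken from
   the pre-filter table, because the high-VAF record itself has already
   been removed by rule 3.

All comparisons are strict: a call sitting exactly at a threshold
survives. The cascade conserves records (kept plus removed equals input,
each removal with one reason) and is idempotent.

Coding classification: an SNV or MNV is coding if it lies in a CDS exon or
at most 2 nt into an adjacent intron (the splice padding); an indel is
coding if its reference span overlaps any CDS exon.

# Burden metrics

For a region with summed per-position duplex depth $T$ (the "total duplex
nucleotides sequenced"):

* **Mutation frequency** $\mathrm{MF} = \#\{\text{unique variant keys}\}/T$
  -- every mutation counts once, whatever its clone size.
* **Mutation burden** $\mathrm{MB} = \sum_i r_i / T_{\mathrm{coding}}$,
  where $r_i$ are alt duplex read counts of coding calls and the
  denominator sums depth over coding positions only -- burden weighs each
  mutation by its clone size, so $\mathrm{MB} \ge \mathrm{MF}$ on matched
  regions.
* The coding/non-coding MF ratio is reported as missing when the
  non-coding MF is zero; infinities must not propagate into group
  summaries.
* A sample shows allelic imbalance (LOH flag) when the germline variant's
  VAF at the phasing site strictly exceeds 0.5; an uncovered site yields a
  missing flag, never `FALSE`.

Burden regressions are ordinary least squares: univariate on age in years,
multivariate (`Y ~ 1 + age + LFS + CTx`) on age in decades plus two binary
covariates, a Gaussian identity-link model kept deliberately simple for
fidelity to standard practice; responses are typically scaled per 10^7^
bases, which rescales coefficients but not t-statistics. A count model
would arguably fit mutation counts better, but the linear form is what
this analysis style reports; nothing bespoke is claimed here.

# Selection: pseudocounted dN/dS with bootstrap

For a CDS, every position admits three single-nucleotide changes; each is
classified through the codon table (synonymous / missense / nonsense), so
the possible-site counts obey $N_{sites} + S_{sites} = 3L$. The terminal
stop codon is included: stop-retained changes count as synonymous,
stop-lost as nonsynonymous. With observed counts $N_{obs}$ (missense +
nonsense + splice) and $S_{obs}$,

$$ \mathrm{dN/dS} \;=\; \frac{(N_{obs} + f_N)/N_{sites}}
                             {(S_{obs} + f_S)/S_{sites}},
   \qquad f_N = \frac{N_{sites}}{N_{sites}+S_{sites}},\;
   f_S = 1 - f_N. $$

The pseudocounts keep the estimator defined with zero synonymous
observations and are neutral-preserving: observed counts exactly
proportional to the site counts -- including $(0,0)$ -- give exactly 1.

Splice-region mutations are counted among the observed nonsynonymous
events, but the +/-2 nt splice positions are *excluded* from the
possible-site denominator by default, since sites are enumerated within
the coding region; `enumerateSiteCounts(..., spliceSiteCount =)` adds them
as purely nonsynonymous sites when wanted. For variants with multiple
annotations the most severe wins (nonsense > splice > missense >
synonymous).

Uncertainty comes from resampling the combined observed mutation list
(unstratified) with replacement 5000 times, recomputing the pseudocounted
estimate in every replicate, and reporting the 25th/75th percentiles with
linear interpolation on the sorted replicates (`quantile` type 7), so IQRs
are exactly reproducible for a fixed seed. Groups (gene x carrier status,
carrier x chemotherapy, tissue category) are analyzed only when they hold
at least 10 mutations.

One calibration fact worth stating plainly: the 25th--75th percentile
band is a 50% interval, so across repeated neutral simulations it covers
the true value of 1 in roughly half of the runs -- the test suite computes
about 54% under the default conditions (~100 coding mutations, B = 5000).
It is an uncertainty summary, not a 95% confidence interval.

# Pathogenicity annotation

Missense variants take their score from a user-supplied table (scores in
[0, 1]; keys in protein notation like `R248Q` or genomic notation like
`chr17:7674220:C>T`, collisions rejected at load) with the category rules:
score > 0.564 Likely Pathogenic, 0.34--0.564 Ambiguous, < 0.34 Likely
Benign. Nonsense variants, coding indels, splice mutations and
multi-nucleotide substitutions are Likely Pathogenic with score 1;
synonymous variants Likely Benign with score 0. A *large clone* is any
mutation supported by more than one duplex read, since each duplex read is
an independent molecule.

The background for score-distribution comparisons -- all possible missense
substitutions of the gene -- is enumerated internally from the CDS, so the
comparison needs no external download. The comparison is reported
descriptively (quantiles, median difference, probability that a random
observed score exceeds a random background score) without a p-value.

# Read-backed phasing

Somatic variants within 150 bp of the configured germline heterozygous
site (default chr17:7675070, ref C, carrier base T; the window approximates
the maximum duplex read length) are phasing candidates. Only reads
carrying the variant's *alternate* base and covering the germline site are
informative -- reference-carrying reads say nothing about the mutant
haplotype. The germline-site base of the informative reads assigns the
variant to the carrier or non-carrier chromosome copy; no informative read
leaves it unphased; disagreeing reads yield a distinct `conflict` state
rather than a majority vote, so inconsistencies surface loudly instead of
being resolved silently. The carrier allele is configured as a base at a
genomic coordinate, strand-agnostic, so the minus-strand gene needs no
special-case complement logic.

Phase bias is tested with a two-sided exact binomial test against 0.5
(minimum-likelihood convention, which at p = 0.5 equals twice the upper
tail, capped at 1): 25 of 29 gives p = 1.04 x 10^-4^, printing as 0.0001.

Domain enrichment uses the domain's base-pair share of the coding region
as the expected proportion and an exact binomial test with a
Clopper-Pearson interval on the observed proportion. The DNA-binding
domain is annotated at residues 102--282 (181 of 393 residues, 46% of the
coding length); these boundaries are a reverse-consistent inference from
the printed 46% expectation, not a citation, and are configurable on the
gene model. Because it is not stated whether pooled tests used every call
or unique keys, `dbdEnrichment()` exposes both pooling modes.

# The synthetic cohort generator

What it emulates, and why:

* **Depth**: per-position negative binomial with
  variance $= \mu + \phi\mu^2$ (default $\phi = 0.05$); capture depth in
  duplex panels is overdispersed, and zero dispersion degenerates to a
  constant track for exact tests.
* **Mutation counts**: Poisson with mean `base_rate x age x total duplex
  nucleotides` (masked positions excluded), so MF recovers
  `base_rate x age` and counts scale linearly in rate, age, region and
  depth.
* **Selection**: each mutation is drawn as a (position, alternate base)
  pair with weight depth x omega for nonsynonymous changes and depth x 1
  for synonymous/non-coding ones, making the expected draw ratio
  omega x N~sites~ : S~sites~ within a gene -- exactly what the estimator
  should recover. Optionally missense draws are further weighted by twice
  their pathogenicity score to emulate selection for disruptive alleles.
* **Clone sizes**: geometric on {1, 2, ...} (default p = 0.8), the
  simplest law that is heavy at 1 read; real clone-size distributions are
  not quantified in the data this emulates, so geometric is a stand-in,
  not a fit.
* **Confounders**: recurrent artifacts shared by >= 3 samples with
  mismatch annotations >= 8, and germline SNPs at VAF ~0.5 with low-VAF
  echoes of the same allele in other samples; every record carries a
  ground-truth label so filter recovery is measurable (100% of confounders
  removed, 0% of clean calls, in the shipped tests).
* **Phasing**: each eligible variant's phase is drawn once (non-carrier
  copy with probability `phase_bias`, default 25/29); its supporting reads
  span both sites when the variant is within the window and agree on the
  phase. Variants beyond 150 bp get reads that do not reach the germline
  site and phase as unphased.

The gene models are deterministic synthetic stand-ins, not real gene
sequences: a single-exon minus-strand *TP53* model anchored so codon 181
(CGC, Arg) maps to chr17:7675070 and codon 248 is CGG (so the R248Q/R248W
hotspot spellings arise), plus multi-exon models for *DNMT3A*, *TET2* and
*GATA2* with positive, positive and negative default selection. A fixed
seed yields a bit-identical cohort.

What it does **not** emulate: trinucleotide-context mutation rates and
signatures, realistic indels, copy-number loss (LOH appears only as a
scalar VAF shift), contamination between samples beyond the germline
echoes, or sequencing-error processes -- passing tests therefore
demonstrate the correctness of the analysis logic under the stated
statistical structure, not robustness to every artifact of real duplex
data.

# Numerical choices and degenerate inputs

* All filter thresholds strict; equality survives.
* Bootstrap percentiles: type-7 linear interpolation, documented so IQRs
  reproduce.
* `dndsPoint` errors when either site count is zero; `dndsBootstrap`
  errors on an empty mutation list (use the point estimator alone).
* The coding/non-coding ratio and the LOH flag report missing values
  rather than infinities or silent `FALSE`s.
* Variant identity is (chrom, pos, ref, alt); a unique mutation is a
  distinct key within one sample, and the same key in two samples counts
  once per sample.
* Seeds: every stochastic routine takes an explicit seed and restores the
  global RNG state; derived sub-seeds stay below 2^31.

# Problem sizes in the shipped tests

The test suite and the reproduction script run entirely on generated
data: the default cohort (11 subjects, ~30 kb of panel at 15,000x,
~2,400 calls) builds in a few seconds; selection recovery uses 50
simulated datasets of ~100 coding mutations per gene with 5,000 bootstrap
replicates; phase-bias recovery uses 500 simulated read sets of 29
variants. These sizes give the binomial/Poisson checks enough power while
keeping a full run in the low minutes on one CPU.

# Known limitations

* The consequence classifier covers SNVs, MNVs and simple indels against a
  single transcript per gene; no multi-transcript or UTR logic.
* Splice-region handling is the +/-2 nt padding only.
* The regression module is intentionally plain OLS/GLM; overdispersed
  count models are out of scope.
* The score-distribution comparison is descriptive by design.
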