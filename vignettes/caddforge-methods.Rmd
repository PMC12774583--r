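---
title: "Methods and design of caddforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of caddforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scoring problem

Combined Annotation Dependent Depletion (CADD) scores rank every possible
single-nucleotide variant of a genome by predicted deleteriousness without
any curated set of pathogenic variants. The trick is to manufacture two
proxy classes from evolution itself:

* **derived (proxy-neutral) variants** — positions where the reference
  genome carries a base different from the inferred ancestral base and that
  difference is (nearly) fixed in the present-day population. These
  substitutions survived selection and are therefore depleted of strongly
  deleterious alleles.
* **simulated (proxy-deleterious) variants** — draws from the local
  ancestor-to-reference substitution spectrum. They mimic the mutational
  input *before* selection, so relative to the derived class they are
  enriched for deleterious alleles.

A penalised logistic classifier is trained to separate the two classes from
genomic annotations; every possible SNV (three alternate alleles per
position) is then scored and the scores are PHRED-scaled:
`-10 * log10(i / N)` for the variant of rank `i` among `N` scored variants,
rank 1 being the most deleterious-looking. A score of 20 therefore means
"in the top 1% of all possible SNVs".

`caddforge` implements this workflow species-agnostically: the inputs are a
reference FASTA, a MAF multiple alignment containing either an explicit
ancestor row or outgroup rows, an optional population VCF with allele
frequencies, and any number of annotation tracks.

## Ancestral-allele extraction

The ancestor map assigns each reference position one of `A/C/G/T`,
*unaligned* (`.`) or *ambiguous* (`?`). MAF blocks are walked in file
order; minus-strand reference rows are converted to forward coordinates
(`start_fwd = src_size - start - size`) with aligned column characters
complemented. Two modes identify the ancestral base:

* **ancestor row** (primary): the aligned character of the named ancestor
  row, as ancestral-reconstruction pipelines such as Cactus emit;
* **outgroup consensus** (fallback, for alignments without ancestor rows):
  `strict_consensus` records a base only when every outgroup row present
  shows the same base and none shows a gap; `majority` takes the modal base
  with ties ambiguous.

Design choices that the underlying format leaves open, fixed here once:

* a gap or `N` in the ancestor column means *no information*, so the
  position stays (or becomes) unaligned rather than ambiguous;
* when overlapping blocks assert **different concrete bases** the position
  becomes ambiguous and is excluded downstream — conservative and
  deterministic, in contrast to first-block-wins; a concrete base does beat
  a gap, since the gap carries no evidence;
* coordinates are 1-based inclusive internally; the MAF's 0-based half-open
  convention is converted at the parser boundary.

Both unaligned and ambiguous positions are excluded from *both* variant
classes: only sites that align with the ancestral genome are considered.

## Variant sets

**Derived calls.** At positions where ancestor and reference both carry
concrete bases and differ, a derived SNV `ancestor -> reference` is
emitted. If a population VCF is supplied and lists the position, the
reference (derived) allele frequency is computed as one minus the sum of
alternate-allele frequencies there (multiallelic records decomposed per
alternate), and the variant is kept only when it exceeds `af_fixed`
(default 0.9, strictly greater). Positions absent from the VCF count as
fixed.

**Rate model.** Windows of `window_size` (default 100 kb — the method only
requires "local" rates, and 100 kb windows keep at least thousands of
aligned bases per window at realistic divergences) accumulate a 4x4
substitution count matrix and ancestral base counts; the rate of
`from -> to` is their ratio. Windows with fewer than `min_window_bases`
(default 1,000) aligned bases fall back to the genome-wide matrix. Context
effects such as CpG hypermutability are deliberately *not* modelled: the
rate contrast is a plain reference/ancestor 4x4 table.

**Simulation.** Candidates are all (aligned position, alternate allele)
pairs, weighted by the local window rate for substituting the *reference*
base by that alternate. Exclusions: candidates whose alternate allele
segregates in the population above `af_exclude` (default 0.1) — such
alleles are evidently tolerated — and candidates that would recreate the
ancestral allele at a derived-variant position, which would put the same
substitution in both classes (the method is silent here; exclusion is this
package's choice and affects a fraction of a percent of candidates).
Exactly as many variants are drawn as the derived set contains, giving
balanced training classes by construction.

Sampling is *without replacement* with weights, implemented by exponential
race keys (`rexp(n)/w`, keep the `n_target` smallest), which is exactly
weighted sequential sampling and fully deterministic under the seed. A
consequence worth knowing: inclusion probabilities deviate from the raw
weights as the pool is depleted, so empirical draw frequencies converge to
the normalised rates only while the draw is small relative to the pool
(the rate-recovery test draws 1% of its pool).

## Annotation and encoding

Annotations join per position (bedGraph/BED intervals, expanded from their
0-based half-open convention) or per variant (TSV keyed on chromosome,
position and allele pair; VCF INFO fields). Built-ins computed from the
inputs alone: GC fraction and CpG count in a +-75 bp window (window
configurable; 75 bp matches common CADD practice and is small enough to
stay local, large enough to estimate composition), the reference base, a
minimal consequence caller over a GFF3 annotation (intergenic, intronic,
splice site within 2 bp of exon ends, non-coding exonic, synonymous,
missense, stop gained — it assumes CDS in frame and takes the first
overlapping transcript; it is a fixture-scale stand-in for a full effect
predictor, which is out of scope), and the published Grantham distance for
missense variants.

Missing values follow the declared per-feature strategy: an indicator
column (value 0 plus 0/1 missingness column), the mean over
*simulated-class rows only* (frozen at training time and reused verbatim
when scoring, so the encoder is a pure function of the training
statistics), or a fixed constant. Categorical features are one-hot encoded
over declared levels and always carry an indicator column, which also
absorbs levels unseen in training. Using only the simulated class for means
matters: simulated variants approximate the neutral mutational background,
and means taken over the mixed classes would leak label information into
the imputation.

## Classifier and validation

The model is logistic regression with an L2 penalty on the weights (not the
intercept), minimising `sum log-loss + ||w||^2 / (2 * l2)`. The penalty
constant is interpreted as an *inverse* regularisation strength in the
convention of the reference implementation, so the default `l2 = 0.1` is a
strong penalty. The solver is damped Newton from a zero start with step
halving — deterministic, no stochastic steps — capped at `max_iter`
(default 100) with a convergence flag recorded. Features are not
standardised by default (the penalty acts on the raw encoded scale); the
choice is configurable and recorded in the model artifact. The unit tests
cross-check the solver against an independent ridge-logistic implementation
on the same objective.

Validation is stratified k-fold cross-validation (default 5): fold
assignment is seeded and stratified per class, each fold's held-out AUC is
the Mann-Whitney statistic computed from midranks (ties count one half),
and out-of-fold scores support AUC reports over configured variant subsets
(e.g. consequence categories). Raw scores are the linear predictor — the
monotone equivalence with predicted probabilities makes the choice
irrelevant to ranks, and therefore to PHRED scores.

**PHRED scaling.** Rank 1 is the largest raw score; ties share the
*minimum* rank of their tie group, so equal raw scores always map to equal
PHRED scores and a higher raw score never gets a lower PHRED score. The
floor value 0 is attained exactly when the lowest raw score is untied.
Ranking is global over whatever set was scored (whole genome or a region);
region runs rank relative to the region's `N`.

## The synthetic study

`synth_config()` fixes the toy study conditions; its defaults are the ones
the end-to-end checks run at: a 1 Mb i.i.d. genome, ancestor/reference
divergence 1% with a 2:1 transition/transversion mix, 5% of the ancestor
unaligned in geometric spans (mean 200 bp), one minus-strand MAF block per
chromosome, an outgroup row at 1% further divergence, 2,000 polymorphic
sites with `Beta(0.5, 0.5)` allele frequencies (a U-shaped spectrum that
exercises both the >0.9 and >0.1 thresholds), four numeric planted features
with class-1 mean shifts (1.0, 0.8, 0.5, 0.3) at unit noise, one 3-level
categorical with class-conditional probabilities (0.5, 0.3, 0.2) vs
(0.2, 0.3, 0.5), and 10% missingness per feature. Everything is a
deterministic function of one seed, and every written file is re-read by
the package's own parsers in the round-trip tests.

Because the planted features are class-conditional, the generator runs the
variant stages itself (with the seeds the pipeline will later use) to learn
which variants exist before planting tracks; the subsequent pipeline run
reproduces those variant sets exactly, which is itself asserted in tests.
Numeric tracks are per-position, so on the rare occasion a derived and a
simulated variant share a position the first variant's class determines the
planted value — at the default densities this touches well under 1% of
variants and is invisible at the tested tolerance.

The generator also emits the **Bayes-optimal AUC** of its own generative
model, estimated by Monte Carlo (1e6 draws) of the exact log-likelihood
ratio, with missingness carrying no class information. Since the true
log-likelihood ratio of this design is linear in the encoded features
(Gaussian equal-variance numerics, one-hot categoricals, missing
indicators), a well-fit logistic model can reach that ceiling, and the
end-to-end check asserts the 5-fold mean CV AUC lands within 0.03 of it.
One planted feature uses simulated-mean imputation, which deviates slightly
from the Bayes treatment of missingness; the effect is far below that
tolerance.

What the toy study does **not** emulate: real base composition and
isochores, phylogenetically structured substitution rates, CpG
hypermutability, linkage between sites, selection acting on the planted
"population", or realistic annotation correlation structure. Passing tests
therefore demonstrate that the machinery is correct and calibrated on a
known generative model — not that any particular organism's scores will
reach a given AUC.

## Numerical and procedural choices

* Stage seeds are derived from the run seed by fixed offsets (simulation:
  `seed + 101`; cross-validation folds: `seed + 202`), so one configuration
  value reproduces the whole run; two runs of an identical configuration
  are byte-identical, which a test asserts via checksums.
* The model artifact (JSON) stores weights, hyperparameters, column layout,
  imputation statistics and the feature specs *without file paths*, keeping
  it portable and reproducible across directories.
* Problem sizes in the test suite are the package's own choices for a
  desk-scale demonstration: the shared end-to-end study is the 1 Mb default
  above; the rate-recovery check draws 100,000 variants from a 10 Mb
  single-base pool; parameter recovery uses n = 20,000 with planted
  coefficients (2, -1, 0.5, 0); determinism is double-checked on a 150 kb
  study.
* Genome-wide scoring streams in 1e6-SNV chunks; ranking is done once,
  globally, in memory.

## Limitations

* SNVs only; insertions/deletions and structural variants are not modelled.
* The built-in consequence caller ignores CDS phase and multiple overlapping
  transcripts; supply per-variant consequence tracks from a dedicated
  annotator for production use.
* The rate model conditions only on the reference/ancestor base pair, not
  on sequence context.
* Probabilistic ancestral reconstruction and alignment generation are out
  of scope: the MAF (with its ancestor or outgroups) is taken as given.
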