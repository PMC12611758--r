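---
title: "Duplex consensus calling, mutation burdens and somatic selection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling, mutation burdens and somatic selection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexome)
```

`duplexome` analyses targeted single-molecule duplex sequencing of
polyclonal tissues: calling somatic mutations from duplex read bundles,
estimating mutation burdens and mutational spectra, and quantifying somatic
selection with dN/dS statistics at the gene, site and site-set level. This
vignette records the models behind each stage, the parameters that matter,
what the built-in simulator does and does not emulate, and the design
choices made where the problem was genuinely open.

## 1. Duplex consensus calling

A *read bundle* is the set of reads (PCR copies) derived from the two
strands of one original DNA fragment. A base is called only where

1. each strand has at least `min_reads_per_strand = 2` reads that agree
   unanimously at the position (within-strand consensus quality = minimum
   base quality among the agreeing reads),
2. the two strand consensuses agree, and the combined consensus quality —
   the minimum of the two strand qualities — is at least
   `min_consensus_qual = 60`,
3. the bundle passes its gates: alignment-score margin (AS-XS) at least 10,
   and a mean per-read mismatch count of at most 3 (4 when the bundle calls
   a variant; the variant base itself is counted), and
4. the position lies outside the trimmed fragment ends
   (`end_trim_bp = 8` on each side).

Within-strand **unanimity** is the conservative reading of the 2+2 rule:
any within-strand disagreement nulls the position rather than majority
voting. The min/min quality combination makes the threshold act on the
weakest evidence in the bundle; base qualities in this package live on the
consensus scale on which the 60 threshold is meaningful. The mean-mismatch
rule is applied per bundle (the average over its reads), which is how an
aligner-level "average mismatches per read" limit behaves.

Called non-reference bases become SNV candidates; two adjacent substitutions
in the same bundle are emitted as one doublet (DBS) and excluded from SBS
catalogues; runs of three or more adjacent substitutions are rare, counted,
and excluded from both.

Site-level filters then remove candidates at SNP+noise mask sites, sites
with matched-normal coverage below 25× or normal VAF ≥ 0.1 (matched mode),
or sample BAM VAF ≥ 10% (self mode, appropriate for highly polyclonal
samples where germline variants are the only high-VAF calls). Recurrent
mapping artefacts concentrate the mutant base at particular within-read
positions; a two-sample Kolmogorov–Smirnov test compares mutant-base
positions against the positions of all called bases at the locus and flags
variants with `p < ks_alpha` given at least `ks_min_support` supporting
molecules. No flagging threshold is canonical for this test; the defaults
`ks_alpha = 1e-3`, `ks_min_support = 4` are deliberately conservative, are
config-exposed, and every flag is logged. Indels are filtered by four
conjunctive rules: ≥50% overlap with the mask, an uncalled site, VAF > 0.1,
or presence in more than 50 samples.

Every filter writes its own flag column, removals are attributed to the
first failing rule, and attributed removals plus kept calls always equal the
candidate count, so any rule can be ablated and audited.

### The three VAFs

* **duplex VAF** `v_d`: mutant callable bundles / callable bundles at the
  locus — the single-molecule estimate used for clonality;
* **BAM VAF**: over one representative read per bundle (calling and
  non-calling alike). Representatives are chosen by a seeded shuffle so the
  value is deterministic given the seed;
* **unbiased BAM VAF**: representatives of non-calling bundles only.
  Because discovery used the calling bundles, `v_d` and the BAM VAF
  overestimate the cell fraction of a *discovered* mutation; the unbiased
  VAF excludes exactly the molecules used for discovery and is reported as
  missing when no non-calling bundle spans the locus.

## 2. The synthetic-data generator

The simulator emulates a polyclonal epithelium: the tissue is partitioned
into `n_clones` clones whose sizes follow a configurable law. The default
*plateauing* model draws sizes from an exponential distribution capped at
`clone_cap` (clones grow to a constrained size), normalised to
`total_fraction`; exponential, quadratic and equal-fraction alternatives
exist for contrast. Each clone carries a Poisson number of somatic
mutations placed on a per-(site, alternate) rate grid: `mut_rate` mutations
per base per cell lineage, shaped across SBS96 channels by `rate_profile`
(default mildly C>T-elevated, a generic pyrimidine-deamination flavour), and
multiplied by `omega` for planted driver (gene, impact class) combinations —
so drivers receive non-synonymous mutations at `omega` times the neutral
expectation, which is what the selection statistics should recover.
Germline SNPs are shared across clones at `germline_density` per bp.

Read bundles are then sampled fragment by fragment: each bundle draws one
clone by cell fraction and one haplotype; germline and clonal variants are
applied haplotype-consistently; reads per strand follow a zero-truncated
Poisson (mean 3, reflecting 2+2 calling economics); **damage** lesions are
applied to one strand of the molecule only (so they can never produce
duplex consensus — the central error-suppression property); sequencing/PCR
**errors** are independent per read; **artefact** sites inject mutant bases
at molecule level only when the site falls at configured within-read
offsets, reproducing the read-positional bias of mapping artefacts;
a configurable fraction of bundles comes from a second individual
(**contamination**). Every emitted variant traces to one origin in the truth
table.

A sequencing-free companion, `simulate_site_counts()`, draws observed
mutant-molecule counts directly as `Poisson(rate × depth)` on the same
grid — the observation model the selection stack assumes — and is used for
calibration studies at mutation counts that would be wasteful to push
through read-level simulation.

What the simulator does **not** emulate: real base-quality distributions and
their error correlation, indel errors in reads (indel candidates enter the
filter battery as tables), PCR family phylogenies, mapping itself (bundles
are born aligned), transcription-strand asymmetries, and regional mutation
rate variation beyond the trinucleotide channel. Passing tests therefore
demonstrate the correctness and calibration of the *estimators* under their
stated model, not robustness to every artefact of real libraries.

## 3. Mutation burdens and catalogues

Burden is the number of **mutant duplex bases over total duplex bases**:
each mutant molecule counts, which weights mutations by their VAF and makes
the estimate robust to clonal composition; a per-site-collapsed mode is
available as an explicit lower bound. Confidence intervals are exact
Poisson by default; `method = "site_bootstrap"` resamples per-site
mutant-base counts with Poisson(1) multipliers (10,000 replicates, seeded),
giving honestly wider intervals when one large clone dominates the count.
Burdens are corrected to whole-genome sequence composition via
`sum_t (m_t/n_t) F_t / sum_t F_t` over pyrimidine-centred trinucleotide
contexts (`m` mutant bases, `n` duplex coverage, `F` genome frequencies);
when panel composition equals genome composition this reduces to the raw
burden exactly. Burden-vs-age regression is ordinary least squares after
excluding samples whose burden CI ratio (upper/lower) exceeds 5.

Catalogues exist in five systems (SBS96, strand-wise TSW192, T>C
pentanucleotide 256, DBS78, ID83), ordered per the COSMIC conventions for
interoperability with reference signatures. The TSW strand label records
whether the pyrimidine of the mutated pair lies on the untranscribed (U) or
transcribed (T) strand of the containing gene. The pentanucleotide system
is unstranded: 4^4 flank combinations around T>C are exactly 256 channels.
Mutations whose context is undeterminable are excluded and counted, so
channel counts plus exclusions always equal the input. Spectrum correction
rescales channel counts by genome/observed opportunity ratios; cosine
similarities carry multinomial resampling CIs (1,000 draws, seeded; our own
scheme, stated here because resampling conventions differ between tools).
Fixed-signature exposures are multinomial maximum likelihood via EM over
the simplex, after opportunity-adjusting the reference signatures to the
observed composition; de novo extraction is out of scope.

## 4. Selection

### Background rate model

The neutral model is Poisson with 192 strand-resolved trinucleotide
substitution channel rates per duplex base, estimated from synonymous
site-alternates (or every site of declared passenger genes), weighted by
per-site duplex coverage. Desk-scale panels leave many of the 192 channels
with little or no synonymous opportunity, so rates are shrunk
hierarchically, coarse to fine: global mean → substitution type (6) →
strand-pooled trinucleotide channel (96) → strand-wise channel (192), each
level shrunk toward its parent with pseudocount `a = 0.5`
(`r = (m + a) / (n + a / r_parent)`); a channel with no opportunity
inherits its parent's rate and is flagged. Expected counts per gene and
impact class enumerate *every* possible substitution at every covered site
(`enumerate_gene_sites()`), classify its consequence through the genetic
code, and accumulate `rate × coverage` — the duplex-coverage correction.

Because the rates are estimated from finite synonymous data, expected
counts carry sampling variance. The fit is linearised exactly (the Jacobian
of the 192 rates with respect to the neutral channel counts is computed by
closed-form refits), so the variance of any depth-weighted expectation —
per gene, per class, or pooled over a gene set — includes the full
covariance induced by the shrinkage hierarchy. Tests and CIs then use a
gamma-mixed Poisson (negative binomial) with shape `k = E²/Var(E)`; with no
variance information `k = ∞` recovers the pure Poisson model. This is the
package's overdispersion mechanism; per-gene epigenomic covariates and
negative-binomial gene-to-gene rate variation of larger frameworks are
deliberately not reproduced (no covariate tracks exist at this scale).

### Tests

For each class, `ω = observed/expected`; the two-sided p-value is the
likelihood-ratio test against `ω = 1` (χ², 1 df); one-sided
negative-selection p-values are constructed by directional halving (`p/2`
when `ω < 1`, else `1 − p/2`; symmetrically for positive selection). The
construction is declared rather than canonical; its type-I control is
verified by simulation in the test suite. Profile-likelihood CIs come from
the same deviance. Benjamini–Hochberg q-values are computed within
explicitly declared families: per impact class across genes for each test
side, within the site-wide family, or within a restricted hotspot list
only. Default significance conventions are q < 0.05 for genes and q < 0.01
for sites.

Site-level tests use `λ_s = r_t(s) × coverage(s) × ρ` and the Poisson upper
tail `P(Poisson(λ_s) ≥ k)`; `ρ` optionally inherits the gene's fitted
non-synonymous ω so that hotspot tests inside strong driver genes are
conservative (pure-rate mode `ρ = 1` is available). Amino-acid-level
results aggregate all site/alternate combinations producing the same
protein change. Within-gene site-set tests (`withingene_dnds()`) evaluate
declared subsets — last-exon nonsense, splice-flank intronic positions,
stop-loss, listed synonymous sites — against the same coverage-corrected
expectation, with a likelihood-ratio contrast between two sets; overlapping
sets must be declared. Indel selection uses a single global indel rate per
duplex base scaled by footprint.

Driver quantities follow from ω: the driver fraction `(ω − 1)/ω` for
classes with ω ≥ 1, excess-driver counts `n(ω − 1)/ω` summed over selected
classes with CIs propagated from the ω CIs, and mutant-cell fractions from
summed duplex VAFs: `F = 2Σv_d` under diploid, at-most-one-heterozygous-
mutation-per-gene assumptions, `F = Σv_d` under haploidy, and the range
`[Σv_d, 2Σv_d]` in general; driver-cell fractions multiply per-class cell
fractions by per-class driver fractions computed without collapsing
recurrent mutations.

### Consequence annotation

Impact classes: synonymous/missense/nonsense/stop-loss through the genetic
code; the two intronic bases flanking each CDS exon boundary are essential
splice sites; positions 3–10 bp into the intron are "intronic near splice"
(the outer bound is a parameter, `splice_window`, because no canonical
window exists for that class); then intronic-other, annotated
UTR/promoter intervals, and noncoding-other. Coordinates are 0-based
half-open internally and 1-based in VCF output.

## 5. Quality control

Genotypes at common SNP sites use fixed VAF bins (hom-alt > 0.8, het
0.3–0.7, hom-ref < 0.1; below 20× or between bins → missing — gap VAFs are
never force-assigned). The contamination metric is the median
reference-base fraction across hom-alt sites, flagged above 0.01 (strict).
Sample pass/fail is conjunctive over: mean duplex coverage ≥ 50 dx,
contamination ≤ 0.01, externally supplied non-human read fraction ≤ 0.25%
(taxonomic classification is consumed, not performed), burden CI ratio ≤ 5,
and genotype concordance with the expected donor; every failure cites its
rule and threshold, so reports reconstruct decisions exactly. Per-sample
passenger-gene dN/dS serves as a cross-species contamination diagnostic:
conserved foreign reads deplete non-synonymous calls and pull ω below 1.

## 6. Numerical choices and degenerate inputs

* Ties and determinism: deduplication representatives, bootstrap draws and
  resampling CIs all derive from named substreams of one seed.
* Empty inputs: zero duplex coverage, empty site sets, a missing germline
  source, and recurrence at zero-coverage sites are errors with typed
  conditions; a rate model fitted with zero neutral mutations is degenerate
  and downstream site tests return missing p-values rather than false
  significance.
* The exposure EM runs to a 1e-12 relative log-likelihood tolerance and
  matches a brute-force grid search to <1e-3 on two-signature problems.
* Poisson upper tails agree with direct series summation to 1e-12 relative
  error.

## 7. Test problem sizes

The suite validates calibration at sizes a laptop handles comfortably:
neutral calibration on a 120-gene synthetic panel with ≥10,000 coding SNVs
per replicate (five replicates); gene-level false-positive control over 100
neutral replicates of a 60-gene panel; ω recovery for planted
ω ∈ {0.5, 5, 20} over 40 replicates each on a 60-gene panel (the rate model
then sees far more neutral data than any single gene, as in a real targeted
design, and measured CI coverage is ~95–97%); burden recovery over 20
replicates of a composition-biased panel; and read-level error suppression
on ~25 dx simulations of a six-gene panel. Mutation rates in these runs are
calibration rates chosen to reach the stated counts at those panel sizes,
not biological per-division rates.

## 8. Known limitations

* The background model has no gene-level covariates; systematic
  genic/intergenic rate differences are out of reach of a targeted panel
  and are inherited by extrapolated genome-wide burdens.
* The one-sided test construction and the KS flagging threshold are
  declared conventions, validated for type-I behaviour by simulation, not
  reproductions of any external tool's internals.
* Indels are filtered and counted (ID83, global rate) but not called from
  read bundles; indel candidates are table inputs.
* The simulator's clone-growth laws are qualitative stand-ins for testing
  estimators, not fitted models of tissue dynamics.
* SAM/BAM export of bundles is not implemented; the bundle TSV dialect is
  the interchange format.
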