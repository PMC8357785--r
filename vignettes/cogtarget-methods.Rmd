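---
title: "From overlapping cognition GWAS to nootropic drug targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From overlapping cognition GWAS to nootropic drug targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogtarget)
```

# Overview

`cogtarget` implements a summary-statistics pipeline that starts from
two genome-wide association studies (GWAS) of the same quantitative
trait — general cognitive ability (GCA) is the motivating case — whose
cohorts overlap substantially, and ends with a ranked table of
druggable genes annotated with the mechanism of action (MOA) a
cognition-enhancing compound would need. The stages are:

1. **Harmonization** of the two summary-statistics tables to shared,
   allele-aligned variants (`read_sumstats()`, `harmonize()`).
2. **Overlap-aware combination** into a single set of summary
   statistics, with power accounting and winner's-curse adjustment
   (`estimate_error_correlation()`, `meta_combine()`, `effective_n()`,
   `fiqt_adjust()`, `winners_curse_flag()`).
3. **Locus definition** by LD clumping and interval merging, and
   classification of loci against the input studies (`clump()`,
   `merge_loci()`, `classify_loci()`).
4. **Gene mediation analysis**: summary-data Mendelian randomization
   (SMR) with the HEIDI heterogeneity test (`smr_test()`,
   `heidi_test()`, `smr_scan()`, `heidi_filter()`).
5. **Evidence integration** across gene-identification streams with a
   per-gene method count (`gene_test()`, `load_stream()`,
   `build_evidence()`).
6. **Druggability filtering and MOA prediction** by eQTL direction
   voting (`preliminary_filter()`, `indication_filter()`,
   `direction_vote()`, `match_moa()`, `prioritize_targets()`).
7. A **sample-overlap inflation experiment** (`simulate_cohort()`,
   `run_overlap_experiment()`) and a **synthetic-data generator**
   (`make_ld_genotypes()`, `make_gwas_pair()`,
   `make_mediation_genes()`, `make_drug_fixture()`) so that every
   stage can be exercised, and its operating characteristics
   measured, without any external download.

The exported functions are the interface; the usual way to run the
pipeline from a shell is a short `Rscript` calling them in sequence
(the repository's `scripts/acceptance.R` is one example).

# Overlap-aware combination

## Model

When two GWAS index the same phenotype with equal heritability and
genetic correlation 1, their per-variant z-scores estimate the same
signal and differ only in sampling error. Shared individuals make
those sampling errors correlated: for two equal-size cohorts sharing
$N_o$ of $N$ individuals, the error correlation under the null is
$r = N_o/\sqrt{N_1 N_2}$. The combined statistic is the constrained
fixed-effect form

$$ z = \frac{w_1 z_1 + w_2 z_2}
          {\sqrt{w_1^2 + w_2^2 + 2\,r\,w_1 w_2}}, $$

with weights $w_j = \sqrt{N_j}$ by default (configurable to equal or
user-supplied weights). At $r = 0$ this is the classical weighted
z-score meta-analysis; at $r = 1$ with equal weights the second study
adds nothing and the combined z equals the input z. The general
multi-trait moment machinery (trait-specific effect covariances) is
deliberately **not** implemented: for a same-trait pair under the
equal-heritability, unit-genetic-correlation constraint it reduces to
the formula above, which is the computation the pipeline actually
needs.

## Estimating the error correlation

`estimate_error_correlation()` uses the variants that look null in
both studies ($|z| < z_\mathrm{cut}$, default 1.96) and correlates
their z-scores — the desk-scale surrogate for the bivariate LD-score
regression intercept, which would be the tool of choice when an LD
reference is available (a natural extension point). Two numerical
points matter:

* **Truncation attenuation.** Restricting both coordinates of a
  bivariate normal to $|z| < c$ shrinks the Pearson correlation; at
  $c = 1.96$ the attenuation is roughly 10% at $r = 0.5$. The raw
  null-window correlation is therefore inverted through the
  truncated-bivariate-normal moment relation (midpoint quadrature on
  the truncation square plus root finding) before being reported. The
  raw value is kept as `r_null`.
* **Signal contamination.** Under a polygenic trait every variant
  carries some signal, which inflates the null-window correlation
  slightly (the same individuals also share the genetic effects).
  This residual bias is second-order at the per-variant signal sizes
  used here, and it acts conservatively in the combination (a larger
  $r$ yields a larger denominator).

At least 1,000 null variants are required; fewer is an error rather
than a silent fallback.

## Power accounting

For a polygenic trait the expected GWAS mean chi-square is
approximately $1 + N h^2 \ell / m$, linear in $N$. The projected
"GWAS-equivalent sample size" of the combined analysis is therefore
reconstructed from mean chi-squares as

$$ N_\mathrm{eff} = \tfrac12 \sum_{j=1,2}
   \frac{\bar\chi^2_\mathrm{meta} - 1}{\bar\chi^2_j - 1}\, N_j . $$

This reconstruction, applied to the published mean chi-squares
(1.783; 1.624, 1.544) and input sizes (269,867; 283,531) of the two
cognition GWAS, reproduces the published 373,617 within 0.07% — the
residual is consistent with the three-decimal rounding of the printed
chi-squares — and is adopted as the package's definition.

## Winner's-curse adjustment

`fiqt_adjust()` implements the FDR inverse quantile transformation:
two-sided p-values from the z-scores, Benjamini–Hochberg adjustment
across all $m$ tests (step-up with the cumulative-minimum
enforcement), and back-transformation of the adjusted p through the
normal quantile with the original sign. Adjusted p-values are floored
at $10^{-300}$ before inversion to avoid infinities. The map is
sign-preserving, magnitude-non-increasing, and rank-preserving within
each sign (ties can arise from the BH step-up); with $m = 1$ it is
the identity. `winners_curse_flag()` applies the transformation to
the lead variants of loci that dropped out of the combined analysis,
using their rank among the supplied leads as the rank within the full
$m$-variant experiment (lost-locus leads are by construction among
the experiment's top order statistics); a locus whose adjusted p
exceeds $5\times10^{-8}$ is flagged as a likely winner's-curse false
positive in the originating study.

# Loci

`clump()` uses greedy p-ordered clumping: the most significant
unassigned variant seeds a locus and absorbs every unassigned
significant variant within 1 Mb whose $r^2$ with it exceeds 0.6 (ties
in p broken by chromosome, then position). This mirrors the common
"$r^2 > 0.6$ locus" definition of web annotation pipelines; the
two-tier refinement some tools add (independent lead SNPs at
$r^2 > 0.1$ inside merged regions) is simplified to one tier. Pairs
beyond the window or absent from the LD reference count as $r^2 = 0$
(one consolidated warning names variants entirely absent from the
reference). `merge_loci()` then merges same-chromosome loci whose
gap is at most 250 kb, transitively; the merged lead is the
smallest-p constituent lead. Merging is idempotent, order-invariant,
and conserves members; the suite checks it against a brute-force
interval-graph connected-components oracle. `classify_loci()` calls
two loci overlapping when their intervals intersect after symmetric
250 kb padding — the same distance as the merge rule, chosen because
no separate cross-list matching rule is stated anywhere; combined
loci overlapping neither input study are *gained*, input loci
overlapping no combined locus are *lost*. The major
histocompatibility complex region is not special-cased. On disk,
loci are BED-like (0-based half-open); in memory coordinates are
1-based inclusive.

# SMR and HEIDI

## Mediation statistic

With a cis-eQTL as instrument, the expression-to-trait effect is the
Wald ratio $\hat b_{xy} = \hat b_\mathrm{GWAS}/\hat b_\mathrm{eQTL}$
at the top instrument, tested by

$$ T_\mathrm{SMR} = \frac{z_g^2\, z_e^2}{z_g^2 + z_e^2}
   \;\sim\; \chi^2_1, $$

which never exceeds the weaker of the two squared z-scores. Two
significance tiers are annotated across a scan: Bonferroni at the
number of genes tested (the "significant" tier) and nominal
$p < 0.05$ (a follow-up tier whose genes enter downstream evidence
only through pathway membership, not as stand-alone hits).

## Heterogeneity (HEIDI)

A mediation signal can be mimicked by two distinct causal variants in
LD (linkage). HEIDI tests the null that a single causal variant
explains both traits: for each selected cis variant $i$ beyond the
top, $d_i = \hat b_{xy}(i) - \hat b_{xy}(\mathrm{top})$ should be
zero. Each $d_i$ is standardized by its delta-method variance (GWAS
and eQTL standard errors propagate through the ratio; GWAS errors at
two variants are correlated by the LD $r$, and independently so are
the eQTL errors), the joint statistic is $\sum_i z_{d,i}^2$, and the
dependent sum is referred to a Satterthwaite-scaled chi-square whose
two moments come from the correlation matrix of the $z_{d,i}$.
Instrument selection follows the conventions of the published SMR
software: top eQTL at $p < 5\times10^{-8}$, test variants at eQTL
$p < 1.57\times10^{-3}$, LD with the top inside $[0.05, 0.9]$,
pairwise pruning at $r^2 > 0.9$, at most 20 variants; fewer than 3
leaves the gene "untested". Untested genes pass downstream with a
logged caveat (excluding them would silently discard every gene with
a sparse cis region); genes with $p_\mathrm{HEIDI} < 0.01$ in any
tissue are excluded from druggability.

Two deliberate approximation choices: the Satterthwaite reference was
compared against the exact weighted-chi-square (eigenvalue) tail in a
controlled replica and the two agree closely (rejection 0.024 vs
0.021 at the 0.01 level), so the cheaper form is kept, with the
covariance matrix construction exposed as the natural swap-in point
for an exact Davies-type evaluation. Second, the measured
false-exclusion rate at $\alpha = 0.01$ under single-causal mediation
is about 0.04 rather than 0.01 at the simulated instrument strengths
(brain-eQTL panel of 1,500, top cis-eQTL $z \approx 13.6$): the
excess is driven by the non-normality of Wald ratios at moderately
strong test instruments and by top-instrument selection, a behavior
inherent to the method rather than to this implementation. Users
should read the 0.01 exclusion threshold as a pragmatic screen, not
as a calibrated error rate.

# Gene evidence

`gene_test()` is a light gene-based association test standing in for
the heavier SNP-wise multi models of dedicated software: the mean
chi-square of the variants in the gene window (0 kb symmetric
extension by default, the common convention), referred to a scaled
chi-square whose mean and variance come from the LD matrix (Brown's
method; variance $2\sum_{ij} r_{ij}^2$). It is exact for a single
variant, collapses to one degree of freedom under perfect LD, and its
tail agreement with a Monte-Carlo null is within 0.004 at
$p \le 0.05$ (the worst mid-range deviation of the two-moment
approximation, about 0.025, occurs near $p \approx 0.2$ where no
decision is made).

`load_stream()` applies each identification stream's stated
correction — Bonferroni for the TWAS, SMR and gene-based-test
streams, Benjamini–Hochberg FDR for the QTL-mapping streams, a
set-level Bonferroni for pathway membership — and collects signed
per-tissue directions where present. `build_evidence()` unions the
streams into one evidence matrix. Because the streams are many but
not independent lines of evidence, the "identified by two or more
methods" rule counts *approaches*, not streams; the default grouping
is

* TWAS (tissue-wide + brain),
* SMR,
* QTL mapping (eQTL, sQTL, rQTL, evQTL),
* gene-based test,
* pathway membership,

five approaches, configurable via `approach_groups`. Directions alone
are never evidence: a gene with directions but no stream flag stays
in the table with `method_count = 0`. Pathway enrichment itself is
not re-implemented; pathway membership arrives as a table of
`(set, gene, set_p)` from whatever enrichment tool produced it.

# Druggability

`preliminary_filter()` keeps genes that are (i) in the consolidated
druggable set, (ii) not HEIDI-excluded, and (iii) supported by at
least two approaches. `indication_filter()` then removes a gene only
when *all* of its drug records carry an excluded indication term
(case-insensitive substring, default `"oncology"`); a single
non-oncology record keeps the gene. The wording "filtering out drug
indications" is ambiguous between dropping records and dropping
genes; the gene-level rule is the default because a gene with any
non-oncology delivery route remains actionable, and `drop_records =
TRUE` gives the record-level alternative.

`direction_vote()` casts one vote per (analysis source × tissue) pair
— duplicates within a pair collapse by majority — and predicts an
**agonist** when up-regulation is associated with higher cognition in
more votes than down-regulation, an **antagonist** in the reverse
case, and eliminates ties as **ambiguous**. Sources are unweighted
because no weighting is defensible a priori; the vote universe is
whatever direction table the caller supplies. `match_moa()` matches
predictions against free-text MOA strings through an editable synonym
map ({agonist, activator, positive allosteric modulator, opener} vs
{antagonist, inhibitor, blocker, negative allosteric modulator}),
lowercased, punctuation-stripped, and word-boundary anchored so that
"agonist" never fires inside "antagonist". A match is `direct` when
the MOA also names the gene's own target class (per-gene keyword
lists supplied by the user), otherwise `indirect`. The final
manual-curation step that a human analyst performs on such a table is
intentionally out of scope: `prioritize_targets()` ends with the
ranked human-review table.

# The sample-overlap inflation experiment

`simulate_cohort()` draws $m$ independent biallelic variants (MAF
uniform on [0.05, 0.5]), additive standardized effects summing to
$h^2$, a Gaussian residual, and standardizes the phenotype. Genotypes
are stored one byte per dosage in column chunks, so the default
experiment (20,000 × 20,000) holds ~400 MB. `run_overlap_experiment()`
draws two equal subsamples at the configured overlap fraction $f$,
runs the per-variant GWAS on each and on the full cohort in a single
chunked pass, combines with the estimated error correlation exactly
as on real data, and regresses combined z on full-cohort z (OLS over
all variant × replicate pairs; per-replicate slopes and their
Monte-Carlo spread are also reported).

Design choices: variants are independent because the z-on-z slope and
$R^2$ do not require LD structure; subsample sizes default to
$1/(2-f)$ of the cohort — the largest equal subsamples whose union
exactly tiles it — giving 80% subsamples at $f = 0.75$ and 90% at
$f = 0.889$, the two published scenarios; the regression is on
z-scores (not effect sizes), and that choice is echoed in the report.

One structural point deserves emphasis. With both subsamples nested
in the cohort, the combined statistic has GWAS-equivalent size
$2 n_\mathrm{sub}/(1+f)$, which is necessarily below the full-cohort
$N$ for $0 < f < 1$; the population slope of combined-on-full z is
therefore slightly **below** 1 (about 0.96–0.99 across the grid at
the default configuration, the deficit largest at intermediate
overlap), approaching 1 as $f \to 1$ or $f \to 0$. An idealized
multi-trait-software run reported slopes marginally above 1
(1.011/1.015) on the same design; a correctly overlap-corrected
combination cannot exceed 1 in expectation here, so slopes in the
high 0.9s with adjusted $R^2 \ge 0.9$ are the no-inflation signature
this implementation reproduces. For the same reason the adjusted
$R^2$ is *not* monotone in $f$: at $f = 0$ the two disjoint halves
tile the cohort and their combination nearly reproduces the
full-cohort GWAS.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
study conditions under which every operating characteristic above is
measured.

* `make_ld_genotypes()`: haplotypes follow a first-order Markov
  copying process within blocks (copy probability = target adjacent
  correlation, one allele frequency per block), so dosage LD is
  AR(1) with the nominal $\rho$ **on the Pearson scale** — unlike
  thresholded-Gaussian constructions, which attenuate it. Realized
  within-block correlations are emitted in the package's LD format.
* `make_gwas_pair()`: plants sparse standardized effects on those
  genotypes and returns overlapping-subsample GWAS tables plus truth.
* `make_mediation_genes()`: simulates at the summary-statistic level
  — eQTL and GWAS z-vectors drawn from $N(\mu, R)$ with independent
  noise for the two cohorts — with three planted classes: *mediated*
  (one shared causal variant, slope $b_{xy} = 0.1$ of random sign),
  *linkage* (expression and trait causals adjacent, $r = 0.7$), and
  *null* (eQTL only). Default sizes emulate the motivating study:
  eQTL panel 1,500 (a PsychENCODE-scale brain panel), GWAS 370,000,
  causal cis-eQTL effect 0.35 (top $z \approx 13.6$), linked trait
  variant just past genome-wide significance ($z \approx 6$), 25 cis
  variants per gene at AR(1) $\rho = 0.7$.
* `make_drug_fixture()`: builds the evidence streams, HEIDI
  statuses, directions, druggable list, and drug annotations with
  planted priority targets and one decoy per failure mode
  (undruggable, HEIDI-excluded, single approach, oncology-only,
  tied votes, opposing MOA), enabling exact precision/recall checks.

What the generator does **not** emulate: realistic allele-frequency
spectra, population structure and relatedness, binary phenotypes,
long-range LD, imputation error, and cross-tissue correlation of
eQTL effects. Passing tests therefore demonstrate the statistical
machinery under clean polygenic sampling, not robustness to those
real-data complications.

# Problem sizes and reproducibility

The default test-suite sizes are chosen so the whole suite runs on a
laptop core: cohorts of 1,500–3,000 for estimator-recovery checks,
500 genes for HEIDI calibration and power, 2,000 replicates for
gene-test calibration, and the full 20,000 × 20,000 × 10-replicate
configuration for the overlap experiment (a few minutes). Every
generator is a pure function of its parameters and seed; repeated
calls are byte-identical, and `scripts/acceptance.R` reruns the
overlap experiment end to end from a single `--seed`.

# Known limitations

* The error-correlation estimator assumes the null window is
  signal-free; under strong polygenicity it retains a small upward
  bias that makes the combination marginally conservative.
* HEIDI's exclusion rate under true mediation exceeds its nominal
  level at realistic instrument strength (see above); genes excluded
  near the 0.01 boundary deserve inspection rather than silent
  discard.
* The gene-based test matches dedicated gene-analysis software only
  in spirit (mean-chi-square statistic, two-moment null); it is not
  a drop-in replacement for SNP-wise multi models.
* MOA matching is lexical. Free-text MOA strings with negations or
  unusual vocabulary need additions to the synonym map, and
  `direct` versus `indirect` match quality is only as good as the
  per-gene keyword lists.
* The oncology-indication exclusion and the two-or-more-approaches
  rule are screens, not causal claims; the output table is a ranked
  starting point for curation, not a list of validated targets.
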