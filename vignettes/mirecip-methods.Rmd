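---
title: "mirecip: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirecip: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirecip` analyses paired miRNA-seq and mRNA-seq from two-group tissue
designs and pairs differentially expressed mRNAs with inversely expressed
miRNAs through canonical 3′-UTR seed sites. This vignette documents the
statistical model behind each stage, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open.

## 1. Small-RNA quantification

**Trimming.** The 3′ adapter is removed by finding the earliest read
position at which the remainder of the read matches a prefix of the
adapter. A partial match at the read end must cover at least
`min_overlap = 7` adapter bases; a full internal occurrence removes the
adapter and everything after it. `max_error_rate` defaults to 0 because
the synthetic reads are error-free; 0.1 reproduces the usual trimmer
default for real data. Trimming is idempotent: a trimmed read contains no
qualifying match, so a second pass is a no-op.

**Length filter.** Inserts of 15–27 nt (inclusive) are kept — the
window that retains mature miRNAs (19–23 nt) plus modest isomiR
variation while discarding adapter dimers and longer fragments.

**Alignment.** Reads are matched exactly (zero mismatches, full length)
on both strands. The reported coordinate is the 5′ end of the read:
leftmost matched base on `+`, rightmost on `-`. All coordinates are
1-based inclusive.

**Counting rule.** A hit is attributed to a mature miRNA when reference
sequence and strand agree and `|hit 5' − annotated 5' start| ≤ 5`
(inclusive; so −5 and +5 both count, ±6 does not). Per read, hits to
multiple loci of one miRNA collapse to a single count; a read attributed
to `k` distinct miRNAs contributes `1/k` to each. This makes total
fractional counts equal the number of assigned reads — the conservation
property the tests verify to 1e-9 (fractions are IEEE doubles, not exact
rationals). Reads aligned somewhere but assigned to no miRNA still count
as *mappable*, which matters for two choices:

* the RPM denominator is the per-sample total of mappable reads (reads
  with ≥ 1 genomic hit), matching the "mappable reads" vocabulary of the
  QC gates; counts-assigned can be substituted by passing different
  `library_sizes` to `count_table()`;
* the apportionment denominator `k` counts matched *mature miRNAs*, not
  genomic loci — hits outside every annotation window do not dilute
  assigned reads.

Antisense hits (same position, opposite strand) are never counted.

**Filters and gates.** The presence filter keeps a feature only if it is
nonzero in at least `ceiling(n/2)` replicates of *every* group — the
consistent reading, for even and odd `n`, of omitting features that are
zero in more than half the samples. The QC gates drop miRNA samples with
≤ 1e6 and mRNA samples with ≤ 3e7 mappable reads (strict inequalities:
exactly 1e6 fails); losing every sample of a group is a hard error.

## 2. Differential expression

Counts for feature *f* in sample *s* are modelled as negative binomial
with `Var = mu + alpha_f * mu^2` and

`log mu_fs = beta_0f + beta_1f * x_s + W_s' gamma_f + log sf_s`

where `x_s` indicates the treatment group, `W` holds latent
unwanted-variation scores and `sf` are size factors.

**Size factors** are DESeq-style median-of-ratios against the
geometric-mean pseudo-reference over all-nonzero features, rescaled to
geometric mean 1; with no all-nonzero feature the code falls back to
upper-quartile scaling and warns.

**Unwanted variation** is estimated RUVg-style: the first `k` left
singular vectors of the feature-centred `log(normalized count + 0.5)`
matrix restricted to control features, scaled to unit variance. When no
control set is supplied, controls are chosen empirically as features with
first-pass (no-W) p > 0.5. The default removes `k = 3` factors; the
singular-value scree is attached to the result to support choosing 4.
The RUV variant is not prescribed by the pipeline's contract; the
control-feature (RUVg) formulation was chosen because it needs no
replicate structure beyond the design itself.

**Testing.** The group coefficient is tested with a Wald statistic. Two
small-sample choices depart from the textbook ML recipe, and they matter:
with plain per-feature ML dispersion and a normal reference, the null
rejection rate at nominal 0.01 measured 0.0475 at n = 5 per group. The
package instead uses (i) Cox–Reid adjusted profile likelihood for the
dispersion (the adjustment used by DESeq2 and edgeR, correcting the
downward bias of ML dispersion when the mean is estimated), optimized on
`log(alpha)` with a floor of 1e-8; and (ii) a t reference with
`n − p` degrees of freedom for the Wald statistic. Measured calibration
on 2,000 null features at n = 5/group, mean 200, dispersion 0.05: 1.0%
rejections at nominal 1%, 4.8% at 5%, Kolmogorov–Smirnov uniformity
p = 0.82 — the properties the acceptance tests assert. IRLS convergence
tolerance is 1e-8 with at most 100 iterations; all-zero features and
non-convergent fits are flagged with p = 1 and a warning, never an error.

**Calling.** Benjamini–Hochberg FDR < 0.01 for both assays; mRNAs
additionally need linear FC > 2 or < 0.5. The symmetric down-regulation
rule (< 0.5) is implied rather than stated by the upstream analyses this
package emulates (every published down-regulated row sits below 0.5); it
is implemented symmetrically. Fold changes are reported as
treatment/control on the linear scale; values below 1 are "down".
`intersect_consistent()` implements the cross-comparison filter: features
called in both comparisons with the same direction.

This NB Wald GLM deliberately replaces the full DESeq2 machinery
(shrunken dispersions, LFC moderation): the pipeline's contract is the
thresholds, and the validation target is parameter recovery on synthetic
data, not bit-equality with another implementation.

## 3. Seed sites and reciprocal integration

For a miRNA with seed `m2..m8`, the target-strand site sequences are the
reverse complement of nt 2–8 (7mer-m8, 7 nt), the same followed by an A
(8mer, 8 nt), and the reverse complement of nt 2–7 followed by an A
(7mer-A1, 7 nt). The A1 position must be an A in the target regardless of
the miRNA's first nucleotide (the convention of the predictors this
mimics); G:U wobble is not allowed; 6mer-class sites are not reported.
When candidates of different types overlap for one miRNA, only the
highest-precedence one (8mer > 7mer-m8 > 7mer-A1) is kept; overlapping
same-type matches (periodic seeds) are all reported, as are overlapping
sites of *different* miRNAs. Positions are 1-based inclusive on the UTR
5′→3′ strand, so an 8mer spans 8 positions and both 7mers span 7.

`integrate_reciprocal()` emits one row per (mRNA, miRNA, site) where the
mRNA passes FDR < 0.01 and the FC rule, the miRNA passes FDR < 0.01,
directions are opposite, and (optionally) miRNA and site are flagged
conserved. Conservation is always consumed as an annotation — computing
it would require multiple-genome alignments that are out of scope. Rows
are ordered like the published tables: the up-regulated mRNA block by
descending FC, then the down-regulated block by ascending FC (i.e.,
strongest repression first), then miRNA FC, name, and site position; ties
between equal mRNA FCs are broken alphabetically, a convention the source
tables do not fully determine.

Whether a miRNA must additionally pass the cross-comparison consistency
filter to appear in a pair table is left to the caller
(`intersect_consistent()` composes with `call_de()`); the fixture-driven
acceptance path does not need to decide this.

## 4. qPCR

`ddct_fold_change()` computes per-sample `dCt = Ct_target −
Ct_reference`, takes arithmetic means of per-sample dCt within each
condition (the standard Livak formulation — not the dCt of mean Cts),
and reports `FC = 2^−(mean dCt_treated − mean dCt_control)`. Adding any
constant to all Ct values cancels; swapping conditions inverts the FC
exactly. Amplification-efficiency correction is out of scope.

## 5. The synthetic world

The generator's defaults state one fixed world; they were chosen once to
match the design the pipeline assumes and are not tuned to test
outcomes:

* 5 replicates per group (the emulated design uses 4–5), groups
  TA/Nic/NAWD with TA as reference;
* NB dispersion 0.05 — a typical bulk-tissue value; lognormal baselines
  (median ≈ 200 counts, log-sd 1) and lognormal size factors (log-sd
  0.2);
* 3 latent unwanted factors (the emulated normalization removes 3–4)
  with N(0, 0.25) log-scale loadings;
* 5′-offset distribution peaked at 0 (67%), decaying symmetrically to
  ±5, with 2% of reads starting outside the window — exercising the
  window boundary; out-of-window reads are mappable but unassigned,
  which also exercises the RPM denominator;
* 5% unmappable decoy reads (rejection-sampled against the genome);
* the standard Illumina small-RNA 3′ adapter, read length 36 so most
  reads contain adapter sequence;
* the toy reference always contains one miRNA at two identical loci and
  one paralog pair sharing a ≥ 16 nt 5′ stretch, forcing both
  multi-locus collapsing and 1/k apportionment; the last miRNA sits on
  the minus strand.

Read depth of the emulated libraries is unstated upstream, so `n_reads`
is a free parameter of each call.

Planted UTR sites use rejection sampling of the background against seed
matches of the *planned* miRNAs only (not all conceivable miRNAs), which
keeps generation fast and the round-trip tests exact: the scanner must
report exactly the planted truth, so recall and precision are both 100%
by construction when the generator succeeds, and generation fails loudly
otherwise.

**What a green test does not establish.** The generator has no
base-calling errors, no quality scores worth reading, no isomiR 3′
heterogeneity, no secondary-structure-aware biogenesis, no real genome
coordinates, and planted effects are log-linear with exactly NB noise.
Passing recovery tests therefore validates the pipeline's logic and
calibration under its own model assumptions, not robustness to real-data
pathologies (sequencing error, GC bias, unmodelled overdispersion). In
the same spirit, the published DE counts for the real dataset are not
reproducible here — they require the deposited libraries — which is why
the acceptance battery combines printed-table re-derivation with
synthetic recovery properties. The RUV-benefit property is run at 25
simulation replicates × 240 features (half the nominal replicate count)
to stay inside the test-time budget; the measured effect is far from the
decision boundary.

## 6. Numerical conventions

* pseudo-count 0.5 for log transforms; dispersion floor 1e-8; IRLS
  tolerance 1e-8, max 100 iterations; dispersion search on
  `log(alpha) ∈ [log 1e-8, log 100]`;
* BH implemented as the step-up `min_{j≥i} m p_(j)/j`, capped at 1;
* fractional counts accumulate as doubles; conservation is asserted to
  1e-9;
* minus-strand 5′ ends are rightmost aligned bases; every interval is
  1-based inclusive;
* pipeline configs are JSON; reruns with the same config and seed are
  byte-identical (every generator seeds its own RNG stream and restores
  the caller's state).

## 7. Known limitations

No mismatch-tolerant alignment, UMI handling, or quality trimming; no
context scores, site accessibility, or 3′-supplementary pairing for
target prediction; two-group contrasts with covariates only; conservation
classes are annotations, never computed. The printed-table fixtures were
transcribed once into TSV and are validated on load (seed-type spans,
FDR and FC rules), so acceptance does not depend on parsing any external
document.
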