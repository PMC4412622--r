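---
title: "Binary expression patterning: model, cutoffs and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary expression patterning: model, cutoffs and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binpat)
```

## The problem and the model

A staged experiment profiles one tissue at S ordered physiological
stages — the motivating design is the four-stage crustacean molt cycle
(inter-molt, early pre-molt, late pre-molt, post-molt) with 1–4 RNA-seq
libraries per stage, some of them single pooled samples. The question
asked of every gene is deliberately qualitative: *in which stages is this
gene high, and in which is it low?* The answer is a binary code of length
S; with S = 4 there are sixteen codes, and `0110` means "high in both
pre-molt stages". Codes are positional: position k always refers to stage
k of the declared stage order, which is why `binpat` refuses to infer
stage order alphabetically.

Counts are modeled as negative binomial with mean μ and variance
μ + αμ². The pipeline is:

1. median-of-ratios size factors and normalized counts;
2. per-gene dispersion α by method of moments, shrunk against a
   mean-dispersion trend;
3. a conditional NB exact test for each of the C(S,2) stage pairs;
4. the binary pattern call under two cutoffs (significance and minimum
   reads);
5. per-pattern term over-representation with an FDR-then-nominal
   significance ladder and most-specific-term reduction.

## Parameters that matter

| parameter | default | units | why |
| --------- | ------- | ----- | --- |
| `alpha` (caller) | 0.05 | p-value | pairwise significance cutoff of the patterning rule |
| `min_reads` | 1000 | mean normalized reads per high stage | retains calls likely to carry biological meaning; also separates `1111` from `0000` |
| `consistency` | `"strict"` | — | strict additionally forbids significant same-bit pairs, making the assigned code unique |
| `high_stage_rule` | `"every_high_stage"` | — | how `min_reads` quantifies over the high stages |
| `sharing` (dispersion) | `"max"` | — | conservative gene/trend combination for small replicate numbers |
| `max_enum` | 10000 | total counts | largest pair total enumerated exactly by the exact test |
| `fdr_cut`, `p_cut` | 0.05 / 0.05 | — | primary FDR tier and nominal fallback tier of the enrichment step |

The 10³-read cutoff is applied to the **mean normalized count per high
stage** (averaging replicates). The raw description of the rule — "a
minimum of 10³ reads in the high stage(s)" — is ambiguous between
per-sample, per-stage-mean and per-stage-sum readings; the mean is the
only one invariant to replicate number, which is essential when one stage
has four libraries and another has one. `high_stage_rule` exposes the
quantifier; summed-raw readings can be emulated by adjusting `min_reads`.

## The pattern-calling rule, precisely

For a gene with stage means m₁…m_S and pairwise p-values p_{uv}, a mixed
code c (containing both 0 and 1) is *consistent* when

* for every pair with c_h = 1, c_l = 0: p_{hl} < α **and** m_h > m_l
  (ties fail — a high call demands a strictly positive fold change);
* (strict mode) for every same-bit pair: p_{uv} ≥ α;
* every high stage has m_h ≥ `min_reads`.

Strict mode is the default even though the patterning rule is usually
stated only as the high-versus-low condition. The reason is uniqueness: a
consistent mixed code forces the significance graph to be the complete
bipartite graph between its high and low sets, with nothing significant
inside either set, and the direction constraint selects exactly one of
the two orientations. Hence **at most one** mixed code can ever be
strict-consistent — verified exhaustively in the test suite over all 64
significance-graph topologies × 24 mean orderings for S = 4. Lenient mode
implements the literal high-versus-low reading; it can match several
codes (e.g. a strictly graded profile matches `1000`, `1100` and `1110`),
in which case the gene is reported grey with the multiplicity recorded,
since nothing in the rule itself chooses among them.

The decision rule is then: one consistent mixed code → assigned; no
consistent mixed code and no significant pair at all → `1…1` when every
stage passes `min_reads`, otherwise `0…0` (the few-reads-everywhere
class, reported with status `low`); otherwise → grey. Grey genes are
first-class outputs with diagnostics (`n_consistent_codes`,
`n_significant_pairs`), not silently dropped: the grey area is the
acknowledged weakness of binary patterning, and making it auditable is
the best defense. A gene with no significance but a mixture of
above- and below-threshold stages falls to `0…0`, because the all-ones
pattern is meant as a well-expressed housekeeping-like class.

## Differential-testing choices

**Size factors.** Genes containing any zero are excluded from the
median-of-ratios reference. When no gene is expressed in every sample the
estimator stops and points at the `fallback` flag, which switches the
reference to the geometric mean over positive counts only — a deliberate
opt-in, since matrices that sparse deserve the analyst's attention.

**Dispersion.** The raw method-of-moments estimate subtracts the
shot-noise term μξ (ξ = mean of 1/s_j over the replicate set) so that
pure Poisson sampling yields α ≈ 0. With `mode = "per_stage"` the
variance is pooled within stages over all stages with ≥ 2 replicates;
`mode = "blind"` pools all samples of the tissue into one replicate set
and is automatically used for any contrast in which either condition has
fewer than two replicates — the documented single-replicate strategy,
deliberately conservative because real stage effects inflate the blind
variance. The trend is a two-coefficient log-log regression (deterministic
and dependency-free, adequate at these scales; ε = 1e-8), multiplied by
the smearing factor exp(s²/2) of the residuals: back-transforming a
log-scale fit estimates the geometric conditional mean of α, and the
smearing correction retargets the arithmetic mean that the working
dispersion should track. `sharing = "max"` then takes the elementwise
maximum of gene and trend estimates, trading power for protection against
anti-conservative p-values at 1–4 replicates. With fewer than 10 usable
genes the trend degrades to a pooled constant with a warning.

**Exact test.** Splits of the pair total K are enumerated in log space;
ties at the observed probability count toward the numerator, with a
1e-7 log-scale slack guarding mirrored splits against float asymmetry.
K = 0 returns p = 1 by convention. Beyond `max_enum = 10,000` the test
switches to the normal approximation of the conditional law of k_A given
K (mean μ_A + v_A/(v_A+v_B)(K−μ_A−μ_B), variance v_Av_B/(v_A+v_B)), which
keeps runtime bounded for highly expressed genes; at the boundary the two
routes agree to a few parts in a thousand. The per-condition variances
use the exact sums of squared size factors (`sA2`, `sB2`), so unequal
library depths within a condition are weighted correctly.

**What is deliberately not invariant.** Multiplying one library's counts
by a constant c is absorbed by its size factor only in *ratio* terms:
the geometric-mean reference moves, so every normalized count shifts by
the common factor c^{1/n}, and the raw condition totals that the exact
test conditions on genuinely change. Pairwise p-values are therefore
stable under depth re-scaling (significance calls agree at the
percent level, as the property tests document) but not bit-identical —
an unavoidable consequence of testing on summed raw counts, which is
also what gives deeper libraries their legitimately larger weight.

**Multiple testing across genes** is *not* applied before pattern
calling: the patterning cutoff is a raw pairwise p < 0.05 by design.
The BH machinery in the package belongs to the enrichment step, where the
family (terms within one pattern list) is well-defined.

## Enrichment choices

"FDR" is implemented as Benjamini–Hochberg; GUI annotation suites (the
Blast2GO family and kin) often leave their exact multiple-testing
procedure undocumented, so equivalence with any of them is not claimed —
BH is the field default. Gene–term pairs are
deduplicated before counting, the only reading under which the 2×2 table
is well-formed. The default universe is the annotated genes of the
assignment table (standard over-representation convention; configurable
to all genes). The nominal fallback applies per pattern list: only when a
list's term family contains no FDR-significant row does the tier drop to
nominal p < 0.05. Reduction drops a significant term when any of its
transitive descendants in the supplied (child, parent) hierarchy is also
significant; terms missing from the hierarchy are treated as leaves with
a warning. Under-representation is out of scope.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe a four-stage, one-tissue design with
unbalanced replication (2/4/3/3 libraries, exercising the per-stage
path) — the mandible-like preset 1/1/3/2 in the test suite exercises the
blind path. Baseline abundances are log-normal (heavy right tail, like
transcriptome abundance distributions), counts NB with the same
(μ, α) parameterization as the testing model so parameter-recovery checks
are interpretable, overdispersion defaults to α = 0.1 (a typical
between-animal biological CV of ~30%), planted fold change defaults to 8
(molt-scale effects), and roughly 40% of genes default to a
few-reads-everywhere class, mirroring the observation that about half of
a de novo transcriptome library attracts almost no reads. Planted
annotations attach a term to genes of one code with an elevated
probability.

The simulator does **not** emulate read-level artifacts (mapping
ambiguity of de novo contigs, isoform splitting, positional bias),
correlated annotation structure, or library-preparation batch effects.
Passing tests on simulated data therefore demonstrates correctness of
the statistical machinery under its own model, not robustness to
assembly artifacts; with real de novo transcriptomes, multi-mapping and
fragmented contigs will push extra genes into the grey and `0000`
classes.

Study-scale choices in the tests and the acceptance script: calibration
runs use 2,000 genes × 12 libraries, recovery runs 800–1,000 genes —
sizes at which empirical rates stabilize to within a percent or two while
the whole suite stays interactive on a single CPU.

## Numerical corner cases

* log2 fold changes: both stage means zero → `NA`; exactly one zero →
  signed infinity. The caller compares raw means and never consumes the
  sentinels.
* A constant gene has v = 0, hence α_raw = 0 and p = 1 in every
  contrast.
* `0/0` stage-mean ties fail the direction requirement (strict
  inequality).
* BH adjustment is order-invariant; the enrichment table is sorted by
  p only for presentation.
* All simulation randomness is scoped: `simulate_counts()` saves and
  restores the caller's RNG state and is bit-reproducible given the
  configuration.

## Known limitations

* The strict caller's within-group condition makes a multiplicity-driven
  fraction of genuinely flat genes grey (≈ 1 − (1 − r)^{C(S,2)} for
  per-test rejection r); abundance fractions are therefore best compared
  among non-grey genes.
* Method-of-moments dispersions at 1–4 replicates are noisy; the
  max-sharing rule buys calibration at some cost in power, so weak
  (< 2-fold) stage effects are routinely missed — consistent with the
  method's qualitative intent.
* No claim of bit-compatibility with any particular release of the
  historical NB-exact-test implementations is made; variance weighting,
  trend form and sharing rule are fixed here as documented above.
* Cyclic designs are handled only in the sense that stage order is
  positional; no circular-statistics structure is modeled.
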