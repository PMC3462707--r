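---
title: "The decision core of a multiple-template modeling pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The decision core of a multiple-template modeling pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbmcore)
```

# The problem

Template-based modeling (TBM) predicts the structure of a target protein
from solved structures of homologous proteins.  The heavy numerical engines
of such a pipeline — profile-based homology search, multiple sequence
alignment, restraint-based model building, ab initio loop sampling — are
mature external tools.  What decides the quality of the final model is the
logic *between* those engines: which hits become templates, which residues
form the reliable core, which of a hundred candidate models represents the
run, and which local regions are untrustworthy enough to rebuild.  `tbmcore`
implements exactly that decision layer, together with native implementations
of the structural metrics it needs, and treats the external engines as
file-level interfaces.

# Hit rescoring

A homology search returns hits ranked mostly by sequence-profile similarity.
For hard targets — remote homologs, low sequence conservation — secondary
structure similarity carries more signal than sequence similarity.  The
package re-ranks hits by

$$S = Z_\mathrm{seq} + w\, Z_\mathrm{ss},$$

where $Z_\mathrm{seq}$ and $Z_\mathrm{ss}$ are population z-scores of the
raw sequence and secondary-structure similarity scores over the hit list,
and the weight $w$ grows as the search probability $p$ (percent) of the
original top ranker drops:

| condition        | $w$ |
|------------------|-----|
| $p \ge 90$       | 1.0 |
| $80 \le p < 90$  | 1.5 |
| $60 \le p < 80$  | 2.0 |
| $p < 60$         | 2.6 |

The bins are inclusive at their lower bounds and ship as constants
(`weight_schedule()`); the target difficulty is always judged from the
*original* top ranker, since the re-ranked list does not exist yet when $w$
is chosen.  Ties in $S$ are broken by the original search rank (stable
sort), so re-ranking is fully deterministic.

# Multiple-template selection

From the top 20 re-ranked hits, `select_templates()` builds a consensus set
in three steps:

1. **High/low split.** High-rankers have $S \ge 0.95\, S_\mathrm{top}$.
   Because z-score sums can make $S_\mathrm{top} \le 0$, where a fraction
   rule is meaningless, the high-ranker set is then defined as the top 3 —
   which coincides with the background-pool fallback below.
2. **Pool outlier removal.** The background pool is the high-rankers or the
   top 3, whichever is larger.  Each candidate's similarity to the pool is
   its mean TM-score to the pool members; a pool member is excluded from its
   own mean, since a self-similarity of 1 would bias pool members upward.
   Candidates below $m_\mathrm{pool} - \alpha\,\sigma_\mathrm{pool}$ are
   removed, with $\alpha = 1$ for high-rankers and
   $\alpha = S/S_\mathrm{top}$ for low-rankers, clamped to $[0, 1]$ — a
   negative or $>1$ ratio would invert the removal logic.
   $\sigma_\mathrm{pool}$ is the population standard deviation: the pool is
   the entire population of interest and is often only 3 structures, where
   the $n-1$ estimator is noisy.
3. **Top-similarity filter.** Candidates with TM-score $< 0.5$ to the new
   top ranker are removed (strictly below; 0.5 survives), with the top
   ranker's sequence length as the TM reference length.  This filter runs
   after pool filtering, following the procedure's stated order.

The top re-ranked hit is never removed by any stage.  Pairwise template
TM-scores are computed over the residue pairs where both templates align to
a common target position — the alignments composed through the target — with
the target sequence length as the reference length.  This is the only
correspondence available without running a structure aligner, and it makes
the similarity matrix symmetric by construction.

# Core region and termini

Target termini aligned to no selected template cannot be modeled from
templates and only distract the external MSA engine.  `find_trim()` removes
the longest such prefix and suffix (interior residues are never trimmed);
after the external MSA is built over the trimmed sequence, `reattach()`
restores the termini as terminal columns gapped in every template row — no
alignment is attempted for them, they are left to local remodeling.  The
*core region* (`core_mask()`) is the set of target residues aligned with the
single top template in the MSA; core-restricted scores use exactly those
positions and reduce to whole-structure scores when the mask is full.

# Representative models and consensus fluctuation

A model-building run produces an ensemble (typically 100 structures).
`representative()` clusters them by single linkage on full-chain CA-RMSD at
a 2.0 Å cutoff and returns the member of the largest cluster with the
smallest mean RMSD to its co-members.  Single linkage at a fixed cutoff was
chosen because it is parameter-light, reproducible, and testable against a
brute-force transcription; 2.0 Å is a conventional "same fold, same
conformation" scale for near-identical models.  Ties resolve to the lowest
model index.

`fluctuation()` quantifies local disagreement among models: every model is
superposed onto the representative on a consensus core found by iterative
trimming (drop residues deviating more than twice the median deviation,
refit, at most 10 rounds), and the profile is the mean CA deviation per
residue over models.  The trimming rule keeps the fit anchored on the rigid
consensus even when a third of the chain is flexible; the factor 2 on the
median is deliberately loose so that genuinely rigid residues are never
trimmed.  The consensus estimator itself — deviation from one reference
model rather than all-pairs distances — is a design choice of this package:
it is the simplest estimator consistent with "fluctuation among models", it
costs $O(n)$ superpositions instead of $O(n^2)$, and the reference is itself
the consensus structure.

# Unreliable local regions

`detect_ulr()` marks maximal runs of residues with fluctuation at or above a
threshold (default 2.0 Å), merging runs separated by at most 2 residues.  A
region touching either chain end is a terminus, otherwise a loop.
`filter_and_select()` then applies the reconstruction rules: regions shorter
than 6 or longer than 20 residues are eliminated, and of the survivors at
most 3 with the largest fluctuations are selected, ties going to the earlier
start.  The detection threshold and merge gap are not part of the printed
rules; the defaults were fixed once against the synthetic generator so that
planted 3 Å-noise loops are detected while rigid regions are not, and are
configurable.  The length filter applies uniformly to loops and termini by
default; a flag can exempt termini from the upper bound, documenting the
ambiguity of applying a loop-length cap to a 40-residue disordered tail.

Rebuilt coordinates from any external builder are spliced in by `graft()`:
atoms outside the grafted regions are bit-identical to the input, and
peptide-bond continuity at the junctions (C–N distance within 1.2–1.5 Å) is
checked and *reported*, not enforced — junction repair is the loop builder's
job, not the splicer's.  `ulr_rmsd()` evaluates a region against a native
structure in the whole-structure frame: one superposition on all shared
non-disordered CA atoms, then RMSD over the region's CA atoms without
re-superposition, so a well-packed core with a wrong loop scores exactly the
loop error.  Regions with more than half of their native residues disordered
are excluded from scoring (returned as `NA` with a warning) rather than
scored against coordinates that do not exist.

# Structural metrics

All metrics are implemented natively on one search scaffold.

**Kabsch superposition** (`kabsch()`) is the SVD solution with the
reflection branch excluded; collinear point sets are rejected rather than
silently reflected.

**TM-score** (`tm_score()`) is
$\max \frac{1}{L_\mathrm{ref}} \sum_i \frac{1}{1 + (d_i/d_0)^2}$ over rigid
superpositions, with $d_0 = 1.24\,(L_\mathrm{ref}-15)^{1/3} - 1.8$ floored
at 0.5 Å (the cube-root form is negative for short chains; for
$L_\mathrm{ref} \le 15$ the floor is used directly).  The reference length
is a caller decision — the target length for template similarity, the top
ranker's length for the final filter.  The maximization seeds superpositions
from all gapless aligned fragments of lengths $n$, $n/2$, $n/4$ (at least 4
residues), then iterates "superpose on residues within $d_0$, rescore" to
convergence and reports the maximum over every visited fit.

**GDT-TS** (`gdt_ts()`) is the mean over 1/2/4/8 Å thresholds of the
maximal percentage of aligned CA pairs fitting under the threshold,
normalized by the reference residue count.  Exact GDT is exponential; the
per-threshold search reuses the fragment-seeded heuristic and always
includes the full-set fit, so it can never score below the plain Kabsch
superposition.  At toy sizes (up to 12 pairs) every minimal 4-point fit
subset is enumerated as well, making the search effectively exhaustive
there — which is also how it is validated against an independent
exhaustive-subset oracle in the tests.

**Side-chain accuracy** (`chi_accuracy()`) reports the percentage of
residues with $\chi_1$ (or both $\chi_1$ and $\chi_2$) within 30° of the
native values, over residues possessing the dihedral(s) in both structures.
Differences are circular, and $\chi_2$ of ASP/PHE/TYR is compared modulo
180° for their symmetric terminal groups (GLU's symmetric dihedral is
$\chi_3$, outside the $\chi_1/\chi_2$ scope).  A structure with no eligible
residues yields `NA` with a warning rather than an arbitrary 0 or 100.

**Paired comparisons** use the two-tailed paired Student's t-test
(`paired_t_test()`, a validated wrapper over `stats::t.test`), with the
sample $(n-1)$ standard deviation of the differences per the test's
definition.  Zero-variance differences are an error: a shift measured
without noise has no meaningful t statistic.

# The synthetic generator

`synth_spec()` and its generators replace every external tool in tests.
Native chains are built on ideal backbone geometry (N–CA 1.458 Å, CA–C
1.525 Å, C–N 1.329 Å; helix $\varphi/\psi = -57/-47$°) by
natural-extension-of-reference-frame placement; any self-consistent geometry
would do, as all downstream metrics are rigid-invariant.  Templates are
copies with per-residue Gaussian noise (default 0.5 Å), decoys additionally
have a half-chain rigidly displaced, which drives their TM-score to the
native below 0.5 and exercises the final filter across its threshold.  Hit
tables plant a known ranking with score gaps of 6 (sequence) and 4
(secondary structure) units against unit Gaussian noise — large enough that
rescoring recovers the planted order in well over 95% of seeds, small
enough that the scores look like scores rather than labels.  Ensembles are
copies of the native with small rigid jitter plus Gaussian noise confined to
declared loop intervals (default $\sigma = 3$ Å, the scale of a genuinely
wrong loop) — precisely the statistical structure the consensus detector
assumes: a rigid core with high-variance local regions.

What the generator does *not* emulate: real decoys are physically plausible
alternative folds, not noise around the truth; real ensemble disagreement is
correlated along the chain rather than independent per residue; real hit
scores are heavy-tailed.  Passing tests therefore demonstrate that the
decision rules are implemented exactly and behave correctly on data with
known ground truth — not that the shipped thresholds are optimal for any
particular search tool's output.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
desk scale: targets of 30–60 residues, 4–8 candidate templates, ensembles of
8–20 models, 50–100 seeds per property — sizes chosen so the full suite
exercises every rule many times while remaining a few-minute run.  Oracle
comparisons (pool filtering, single-linkage clustering, exhaustive GDT) are
restricted to at most 8 candidates, 10 models and 12 residue pairs, where
brute force is exact.

Remaining numerical conventions: residue indexing is 1-based and contiguous
over the target sequence, with author numbering kept as metadata; alignment
intervals are half-open only in the BED-like core-mask output; incomplete
(missing backbone) and disordered residues are excluded from every metric;
all tie-breaks (sort order, cluster choice, region selection) are
deterministic and documented at the function level.  The pipeline report
embeds its effective configuration and contains no timestamps, so identical
configuration and inputs produce byte-identical reports.

# Limitations

The package does not search, align, build or refine: it decides.  TM-score
and GDT-TS use a fragment-seeded heuristic rather than the full published
search programs, and at realistic sizes can in principle score slightly
below the true optimum (never above it); the consensus fluctuation estimator
is reference-based by design and will under-report disagreement if the
representative itself sits in a minority conformation, which the largest-
cluster rule makes unlikely but not impossible.  Multi-chain targets,
insertion codes and mmCIF input are out of scope.
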