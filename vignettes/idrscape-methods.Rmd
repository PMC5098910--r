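---
title: "Methods: physicochemical characterization of disordered proteins with idrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical characterization of disordered proteins with idrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrscape)
```

## Scope

`idrscape` characterizes intrinsically disordered protein regions (IDRs) from
sequence alone, and triages candidate members of multi-domain protein
families from homology-search tables. It covers six computations that are
routinely chained in IDR studies: a per-group ionization model of net charge
and isoelectric point; charge–hydropathy (Uversky-plane) classification;
amino-acid composition enrichment with bootstrap errors; short-linear-motif
and tandem-repeat scanning plus disorder-track smoothing; rule-based
ortholog calling from per-domain E-value tables; and average-linkage
clustering of negative-log-probability dissimilarity matrices. A seeded
synthetic-data layer generates every input class with known ground truth so
the whole pipeline is testable offline.

The package deliberately does not predict disorder (IUPred-style predictors
are consumed as score tracks, not reimplemented), does not run HMM or BLAST
searches (their tabular outputs are inputs), and does not infer phylogenies.

## The charge model

Net charge at a given pH is the classic per-group Henderson–Hasselbalch sum.
Every chain carries exactly one N-terminal amino and one C-terminal carboxyl
group; side chains of K, R, H are basic, and D, E, C, Y acidic:

$$Z(\mathrm{pH}) = \sum_{g \in \mathrm{basic}} \frac{n_g}{1 + 10^{\,\mathrm{pH} - pK_g}}
 \;-\; \sum_{g \in \mathrm{acidic}} \frac{n_g}{1 + 10^{\,pK_g - \mathrm{pH}}}.$$

The default pK set (`paperPKSet()`) is the EMBOSS-derived table: Amino 8.6,
Carboxyl 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1 (pH
units). $Z$ is continuous and strictly decreasing in pH, and the termini
guarantee at least one group of each sign, so the isoelectric point — the
unique root of $Z$ — is found by bisection on $(0, 14)$; the stopping
bracket width `tol` defaults to $10^{-4}$ pH units. The test suite checks
the bisection root against an independent pH-grid-scan (step $10^{-5}$) to
within $10^{-3}$ on batches of random sequences, plus the analytic
two-group case: for the dipeptide GG, $pI = (3.6 + 8.6)/2 = 6.10$ exactly.

Proteome acidity percentiles use a *strict* comparison — the percentage of
proteome pIs strictly greater than the query ("more acidic than") — so a
protein tied with the whole proteome is more acidic than 0% of it. Masked
residues (`X`, produced by permissive FASTA reading) carry no pK and are
excluded from all charge statistics.

## The charge–hydropathy plane

Per-residue hydropathy uses the 20 standard Kyte–Doolittle values rescaled
affinely to $[0,1]$ via $(kd + 4.5)/9$ (the published scale spans
$[-4.5, 4.5]$), averaged over a centered window of 5 residues. Windows
*shrink* at the termini rather than dropping positions, which keeps one
value per residue and makes the mean-over-all-residues definition exact.
The two plane coordinates are:

* $\langle H\rangle$: mean of the windowed scaled hydropathy profile;
* $\langle R\rangle$: absolute net charge at pH 7.0 divided by chain
  length. This uses the full Henderson–Hasselbalch charge with the default
  pK set, not the common integer count $|K + R - D - E|$; the count
  approximation is available behind `approx = TRUE`.

The empirical boundary between natively folded and natively unfolded
proteins is $\langle H\rangle_b = (\langle R\rangle + 1.151)/2.785$; a
sequence is called `disordered` when $\langle H\rangle <
\langle H\rangle_b$. Points exactly on the boundary are called `folded`:
disorder is the strict-inequality side. Inputs should be the candidate
disordered regions themselves (e.g. pre-cut N-terminal IDRs); how IDR
boundaries are delimited upstream is the caller's responsibility.

## Composition enrichment and its error bars

For a query dataset with pooled residue frequencies $C_x$ and a reference
(ordered) dataset with frequencies $C_{order}$, enrichment is the
normalized excess $(C_x - C_{order})/C_{order}$. Residues absent from the
reference are reported `NA` rather than $\pm\infty$. Two identities are
asserted in the tests: enrichment of a dataset against itself is zero
everywhere, and $\sum_r C_{order}(r)\,e(r) = \sum C_x - \sum C_{order} = 0$
(to $10^{-9}$), a useful conservation check on any implementation.

Error bars are bootstrap standard deviations: query and reference are
independently resampled with replacement at their original sizes, the
enrichment recomputed per replicate, and the per-residue SD over replicates
reported. The resampling unit is the *residue* (resampling $N$ residues at
fixed $N$ is exactly a multinomial draw from the observed frequencies, which
is how it is implemented — `stats::rmultinom` — making $10^4$ replicates
cheap); a per-sequence mode is available behind `unit = "sequence"` for
datasets where between-sequence variance matters. Everything is reproducible
from an explicit seed, and the suite checks the expected
$1/\sqrt{N}$ shrinkage: quadrupling both dataset sizes halves the SDs
(ratio asserted $0.5 \pm 0.1$).

The classic published reference compositions (ordered and disordered
protein datasets) are external databases; the package instead ships
*synthetic* ordered-like and disordered-like frequency profiles
(`compositionProfile()`) that follow the qualitative enrichment directions
of such references (disordered: D, E, S, T, P, K up; W, C, F, I, Y, V
down). They drive the generators and tests and are documented as synthetic
constants, not measurements; real analyses should supply their own
reference FASTA or frequency table.

## Motifs, repeats, and score tracks

The SUMO-interacting-motif (SIM) pattern is the ELM-style regular
expression

```
[DEST]{0,5}.[VILPTM][VIL][DESTVILMA][VIL].{0,1}[DEST]{1,10}
```

— a hydrophobic core flanked by acidic/phosphorylatable residues, with the
longer acidic stretch C-terminal. Because discrete motif calls (one bar per
site) are the common downstream use, the default scan reports the maximal
*non-overlapping* set, scanning left to right with each match leftmost and
greedy; `overlapping = TRUE` enumerates a match at every admissible start
instead, since the pattern itself permits overlaps. Coordinates are 0-based
half-open internally and converted to 1-based only in human-facing reports.

Tandem repeats of a fixed-length degenerate unit (default the murine
`GE[PMS]E[ST]EAK` 8-mer) are counted as non-overlapping left-to-right
matches.

Disorder score tracks (one value per residue) are smoothed with
spreadsheet-convention exponential smoothing: with damping factor $d$
(default 0.9), $s_1 = x_1$ and $s_t = (1-d)x_t + d\,s_{t-1}$. Note the
convention: the *damping factor* is $d$, the smoothing constant is $1-d$ —
the convention used by common spreadsheet tools, adopted here and asserted
by the impulse-response test $(1, d, d^2, \dots)$. Smoothing never leaves
the $[\min x, \max x]$ envelope.

## Ortholog triage from domain hit tables

Candidates arrive as per-(protein, domain) E-values, either HMMER3
`--domtblout` files (the full-sequence independent E-value, column 7, is
used; per-domain conditional E-values are ignored because significance is a
whole-protein property here) or a simple TSV with explicit species, strain,
gene, and length tags. The decision rules, in order:

1. **Significance**: keep hits with E-value strictly below the threshold
   (default $10^{-5}$; a hit at exactly the threshold is excluded).
2. **Isoform collapse**: per gene, keep the longest isoform (gene tag when
   present, else the id root before the isoform delimiter `-`); ties go to
   the lexicographically smallest id.
3. **Strain collapse**: per species, keep the strain contributing the
   longest protein (same tie-break). The published procedure does not state
   how the representative strain was chosen; longest-protein is this
   package's documented rule.
4. **Status**: `full` iff all three diagnostic domains (protease, zinc
   finger, HMG box) are present; `partial` iff protease and zinc finger are
   present but not all three; otherwise `none`.

`dedupIdentical()` additionally collapses connected components of an
externally supplied identity relation (e.g. reciprocal-best-hit pairs) to
their longest member. The statuses partition the surviving proteins, and
lowering the threshold can only shrink the `full` set — both are asserted
as properties.

## Family clustering

An HMM–HMM match probability matrix $P$ (auto-rescaled from percentages
when entries exceed 1) becomes a dissimilarity matrix via
$D = -\ln \max(p, 0.001)$. The 0.001 floor exists to keep zero
probabilities finite; it is applied to *every* entry below 0.001, not only
literal zeros, so that the probability-to-dissimilarity map stays monotone
(the literal-zero-only behaviour is available via `zero_only = TRUE` for
strict fidelity to the original description). The log base is natural;
any other base rescales all heights uniformly and cannot change topology.
Directional score pairs are symmetrized by their arithmetic mean
(`symmetrize = "max"` keeps the more confident direction instead), and the
diagonal is forced to zero.

Average linkage (UPGMA-style) is implemented in-package with the exact
Lance–Williams running-mean update and a *deterministic tie-break*: among
tied cluster pairs, the pair whose smallest-member labels are
lexicographically smallest merges first, making results independent of
input row order. `stats::hclust` does not expose a documented tie rule,
which is why the step is implemented here; `hclust` and `cophenetic` serve
as independent cross-checks in the tests, alongside a from-scratch
$O(n^3)$ agglomeration oracle that recomputes every cluster-pair mean from
the original matrix (merge-sequence equality asserted over 100 seeded
random matrices of size up to 8). Average-linkage merge heights are
non-decreasing (reducibility), and on ultrametric inputs the cophenetic
distances reproduce the input exactly (asserted to $10^{-9}$).

The returned object is a standard `hclust`, so `cutree`, `cophenetic` and
`plot` apply. Newick export places leaves at height zero with branch length
= parent merge height minus child height; tip-to-tip path lengths are
therefore twice the cophenetic heights, and `ape::read.tree` round-trips
the output.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of a root seed; child streams are derived
from fixed component labels, so adding a generator never perturbs existing
outputs, and generators restore the caller's RNG state.

* `genSequences()` draws i.i.d. residues from a composition profile and
  splices literal motifs at recorded offsets. I.i.d. sampling captures
  composition bias — the signal the charge/hydropathy and enrichment
  analyses actually use — but none of the positional structure (repeat
  grammar, motif clustering, local charge patterning) of real IDRs.
  Passing the ≥90% plane-separation test (200 sequences per class, length
  300) therefore shows the classifier respects compositional contrast, not
  that it would reproduce any particular empirical dataset's scatter.
* `genHitTable()` plants full/partial/other domain architectures with
  E-values log-uniform on $[10^{-12}, 10^{-6}]$ for true domains and
  $[10^{-4}, 1]$ for decoys. The gap straddles the $10^{-5}$ threshold, so
  exact ground-truth recovery tests the decision logic, not threshold
  robustness to borderline E-values (which real searches do produce).
* `genBlockMatrix()` draws within-block probabilities Beta-concentrated
  near 0.9 and between-block near 0.01 — a far cleaner separation than real
  HMM–HMM probability matrices, which is the point: planted-block recovery
  validates the clustering machinery, not its behaviour on ambiguous
  family structure.
* `genScoreTrack()` emulates predictor output as a 0.2/0.8 step function
  with Gaussian noise ($\sigma = 0.1$); geometric smoothing is asserted to
  cross 0.5 within 25 residues of each true boundary.
* `syntheticGcnaCdna()` deterministically constructs a cDNA whose
  translation carries the documented qualitative features of the murine
  germ-cell protein GCNA — strongly acidic, repetitive, predicted
  disordered, with exactly 25 tandem `GE[PMS]E[ST]EAK` units, four repeat
  classes, two SIMs, an NLS-like stretch, and ATG-free UTRs around a
  capitalized-start-style ORF. It is a labelled *stand-in*: the real
  transcript is not bundled, so values computed on the stand-in (its pI of
  about 3.5, its motif coordinates) characterize the construction, not the
  real protein — with the single exception of the repeat count, which is
  planted ground truth. End-to-end checks on this sequence exercise the
  translate → charge-model → scan pipeline; they do not validate any
  published measurement of the real protein.

## Numerical choices and degenerate inputs

* Bisection runs on $(10^{-6}, 14 - 10^{-6})$; reported pIs are rounded to
  two decimals only in human-facing output, with full `tol` precision kept
  internally.
* Translation starts at the first ATG at/after the frame offset; a missing
  stop codon returns the full read-through product with a distinct
  warning (documented contract for 3'-truncated clones); a trailing
  partial codon is ignored; ambiguous codons are errors.
* FASTA reading is strict by default (first offending character is
  reported with record and position); permissive mode masks to `X`/`N`,
  and `X` is excluded from every downstream statistic because no pK or
  hydropathy value exists for it.
* Empty inputs error early everywhere (empty FASTA, empty proteome pI set,
  empty tracks, matrices with fewer than two items).
* Probability matrices must be square with matching labels; `NA`
  dissimilarities are rejected before clustering.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` size their simulations to run
comfortably on a single CPU: 100-sequence batches for the grid-scan pI
comparison, 200 sequences per class for plane separation, 2000 bootstrap
replicates for the SD-scaling ratio, a 200-protein hit table for triage
recovery, and 100 random matrices of size ≤ 8 for the clustering oracle.
These sizes give comfortable statistical margins for every asserted
property; all are package choices and can be scaled up by the user.

## Known limitations

* The ionization model has no position-specific pK corrections, no Cys
  disulfide awareness, and no post-translational modifications; pIs for
  heavily modified proteins will differ from gel-observed values.
* The bundled reference composition profiles are synthetic; enrichment
  analyses against them demonstrate machinery, not biology. Supply real
  reference datasets for scientific use.
* The triage strain rule (longest protein wins) is an explicit assumption;
  with richer metadata a curated strain choice may be preferable.
* Average linkage is quadratic in memory and cubic-ish in time as
  implemented; it is comfortable for the hundreds-of-families regime it
  targets, not for tens of thousands of items.
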