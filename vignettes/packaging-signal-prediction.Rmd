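---
title: "Predicting coat-protein binding sites on +ssRNA genomes from primary sequence"
author: "capsidMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting coat-protein binding sites on +ssRNA genomes from primary sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidMatch)
library(IRanges)
```

## The model

Positive-sense single-stranded RNA viruses package their genomic RNA
(gRNA) through interactions with their coat protein (CP), often
nucleated at dedicated high-affinity regions (packaging signals). This
package predicts where along a gRNA such CP contacts are favoured,
using primary sequence only and an assumption of extensive structural
disorder in the interacting stretches. Two complementary predictors are
implemented.

**Profile matching.** A gRNA is summarized by a nucleobase-density
profile: for every triplet start $i$ the fraction of the three
nucleotides $i..i+2$ belonging to a chosen base set (pyrimidines by
default), smoothed with a centred window of $w = 21$ triplets taken
in frame (stride 3). A CP is summarized by a nucleobase-affinity
profile: each residue's relative affinity for the base (or a mimetic),
smoothed with a centred window of $w = 21$ residues. The CP profile is
slid along the genome in steps of one nucleotide, each residue aligned
to one triplet, and the Pearson correlation $R$ between the two
smoothed profiles is assigned to the central nucleotide of the gRNA
fragment. Because affinities are written so that lower values mean
stronger binding, *matched* profiles — density mirroring affinity —
produce strongly negative $R$; the adenine convention is inverted
(maxima matter), and the scale's `direction` slot records which applies.
Predicted interaction sites are all positions with $R$ beyond a cutoff.

**Additive interaction energy.** The relative interaction energy of the
whole CP placed at fragment start $p$ is
$$E(p) \;=\; \sum_{j=1}^{N}\ \sum_{b \in \{A,G,C,U\}}
\mathrm{aff}_b(a_j)\; n_b(t_j),$$
where $a_j$ is residue $j$, $t_j$ its aligned triplet and $n_b$ the
count (0–3) of base $b$ in that triplet. $E$ is assigned to the
fragment's central nucleotide, the track is window-averaged over 63 nt,
and the smoothed values are standardized to z-scores over all defined
positions. Energies are relative: only the ranking of positions is
meaningful. Binding regions are reported as the positions in the lowest
1% (or 5%) of smoothed energies, collapsed into intervals and merged
when separated by fewer than 10 nt.

**Evaluation.** Agreement with reference binding sites (e.g. the 15
cryo-EM stem-loops of bacteriophage MS2, bundled as
`ms2StemLoops()`) is quantified by binding-site coverage (BSC): the
fraction of reference nucleotides recovered by the prediction, counting
only positions where the profile is defined. Significance comes from a
permutation test: the gRNA or the CP is shuffled (composition
preserved), the whole profile is recomputed per shuffle, and the
p-value is the fraction of shuffles whose BSC is at least the native
one — no pseudocount, so an empirical p of 0 is reportable and the
granularity is $1/n$.

## Margins and centre assignment

Smoothing with an odd window $w$ leaves the first and last $(w-1)/2$
units undefined. A CP of $N$ residues has a smoothed profile of length
$l = N - w + 1$; combining fragment-centre assignment with smoothing,
the Pearson profile is undefined at the first and last $(3l-1)/2 +
3(w-1)/2$ genome positions for odd $l$ (e.g. 193 for $N = 129$, $w =
21$) and $3N/2$ for even $N$. For even $N$ the fragment centre falls
between two nucleotides; position $i$ then receives the mean of the two
values belonging to $i - 0.5$ and $i + 0.5$, and no half-integer
positions are ever emitted. The energy profile, smoothed over 63 nt,
is undefined at the first and last $(3N-1)/2 + 31$ positions for odd
$N$ (224 for $N = 129$) and $3N/2 + 31$ for even $N$. These identities
are exercised exactly in the test suite.

## Affinity scales

The only built-in scale is Woese's polar requirement
(`polarRequirement()`), the experimental partitioning of the twenty
amino acids with substituted pyridines, used as a pyrimidine-mimetic
affinity proxy (`PYR'`): hydrophobic residues (low polar requirement)
bind pyrimidine mimetics strongly, so the scale's direction is `min`.
Knowledge-based single-base scales (ADE/GUA/CYT/URA) are not
redistributed here; they load from two-column TSV files
(`loadAffinityScale()`), with scales named `ADE` defaulting to the
anti-matching `max` direction. For self-contained work,
`pairScaleFamily()` derives a consistent four-base family from any
single scale by centring its values and negating them for the
complementary bases. All downstream statistics are invariant to
positive affine rescaling of a scale, to using fractional instead of
integer triplet content (raw energies scale by 1/3, z-scores are
unchanged) and to adding a constant to all four base scales (raw
energies shift uniformly).

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| profile window | 21 | residues / triplets | odd; both profile types |
| energy window | 63 | nucleotides | odd; boxcar average |
| Pearson cutoff | −0.6 typical | — | `min` direction; `max` for ADE |
| z cutoff | −1.5 typical | sd | z between −1.8 and −1.3 is the informative band |
| percentile | 1 or 5 | % | lowest smoothed energies |
| merge gap | 10 | nt | strict: a gap of exactly 10 keeps regions separate |
| shuffles | 1000 | — | p granularity 1/n |

## Numerical choices

* **Quantile.** The lowest-percentile threshold uses the
  linear-interpolation quantile (R type 7) and the comparison is
  inclusive (`<=`), so ties at the threshold are reported.
* **z-scores.** The denominator is the population standard deviation
  (divide by $n$); `sdType = "sample"` switches to $n-1$. Degenerate
  profiles (zero variance, e.g. constant-composition genomes) carry no
  z-scores rather than infinities.
* **Zero-variance windows.** Pearson is undefined where either smoothed
  window has (numerically) zero variance; such positions are excluded
  from site calling, BSC denominators and shuffle statistics rather
  than propagating NaN. The variance floor (1e−18 per window value) is
  far below the 1/63 quantum of smoothed density tracks, so it only
  catches true degeneracy.
* **Precision.** The sliding correlation is computed with explicitly
  centred windows (BLAS matrix products), which agrees with per-fragment
  textbook recomputation to better than 1e−12.
* **Coordinates.** Everything internal is 1-based inclusive
  (`IRanges`); BED input/output is converted at the boundary
  (0-based half-open), and the conversion is property-tested as a
  bijection.
* **p-values.** Pure fractions without the +1 pseudocount, matching the
  granularity convention above; fixed seeds make every permutation
  result bit-reproducible.

## The synthetic generator

`syntheticPair()` provides the test bed: a 4000-nt i.i.d. background
genome (uniform base frequencies), a 50-residue protein, and four
planted 150-nt sites (one full protein fragment each) in which the
in-frame triplet density of the target bases linearly tracks the
negated residue affinities, plus Gaussian noise (sd 0.1 by default) on
the density scale rounded to realizable triplet compositions. These
defaults are the package's reference study conditions and are used
unchanged by the acceptance checks.

Three design choices deserve explanation:

* **Protein draw.** Residues are sampled around a smoothed latent curve
  (window 9) shifted by 0.7 scale-sd toward strong binders. The
  autocorrelation gives the affinity profile the smooth, heterogeneous
  shape real CP profiles have; the compositional bias makes the protein
  a net binder, so fragments partially overlapping a planted site also
  score favourably and the energy profile develops the broad
  funnel-shaped minimum seen for real packaging signals rather than a
  one-position spike that 63-nt smoothing would erase.
* **Repeated motif with guards.** All planted sites are copies of one
  realized motif flanked by 33 nt of fixed background-like sequence
  (one energy-smoothing half-window). This emulates a dispersed,
  repeated packaging-signal-like element and guarantees the copies are
  equally deep: the smoothed energy apex of every copy is computed from
  identical bases, so a lowest-1% threshold that admits one site admits
  them all. Without the guards, fragments overhanging into random
  flanking sequence make site depths differ by several percent, more
  than a 1%-of-genome budget tolerates.
* **Noise semantics.** Because the density noise is clipped to [0, 1],
  very large noise drives planted triplets toward extreme compositions
  rather than literally toward background composition; what large noise
  does destroy is the anti-correlation with the protein profile, and
  that is the property the tests assert.

What the generator does **not** emulate: RNA secondary structure,
codon-usage and dinucleotide biases, real CP compositions, genome-scale
compositional gradients, or the noise processes of SELEX/CLIP
experiments. Passing the synthetic recovery checks therefore
demonstrates the correctness and statistical calibration of the
machinery, not predictive performance on real viruses; the latter is
benchmarked against the MS2 cryo-EM reference sites when a copy of the
MS2 genome (RefSeq NC_001417) is supplied by the user (it is not
redistributed with the package).

The null-calibration experiment (no planted sites) uses a reference of
many short dispersed intervals: smoothed calls arrive in a few long
runs, so against a few long reference intervals BSC has a large atom at
exactly zero and the permutation p piles up conservatively at 1; with a
dispersed reference the BSC becomes quasi-continuous and the p-values
are approximately uniform, which is what the calibration check asserts.

## Screening annotated records

`selectCpRecords()` reproduces the batch selection rules: product names
must contain `coat`, `capsid` or `core` (plus `VP0`–`VP4` for
*Picornaviridae*), must not contain any exclusion term (`precursor`,
`polyprotein`, `readthrough`, `read-through`, `leader`, `duplicate`,
`homolog`, `coat-like`, `extension`, `extended`, `RNA replicase`), and
sequences must be unambiguous with at least 50 residues. The exclusion
term `proteins` is matched as a whole token — a plain substring match
would reject every record containing the singular `protein`, which
cannot be the intent of a list whose other members are modifiers.
Record retrieval itself (e.g. from NCBI) is out of scope; the input is
a local TSV of annotated records, and a two-pass search (proteins and
mature peptides first, annotated regions only as a fallback) is the
recommended way to assemble it.

## Problem sizes used by the checks

The bundled checks run on desk-scale instances chosen as the package's
reference conditions: oracle comparisons on 50 random instances with
genomes up to 1 kb and proteins up to 80 residues; recovery and power
on 100 generator cases with 200 shuffles each; null calibration on 200
cases with 50 shuffles each. `runConfig()` records the production
defaults (1000 shuffles) used for real analyses.

## Known limitations

* Energies are relative; no absolute binding free energies.
* Plus-strand only; no reverse-complement scan.
* The centre-of-fragment assignment can displace a prediction when only
  part of the CP drives binding; displacements of ~100 nt are plausible.
* Terminal margins (about $3N/2$ nt per end) are structurally
  unpredictable for this method; references confined to the termini
  cannot be evaluated.
* Results depend on the affinity scale used; only the polar-requirement
  scale ships with the package, and exact reproduction of published
  MS2 numbers presumes the canonical Woese values bundled here.
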