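---
title: "Mass-accuracy-driven sequence tag inference: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-accuracy-driven sequence tag inference: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovotag)
```

## The problem and the model

Shotgun proteomics fragments tryptic peptides by collision-induced
dissociation and records the fragments in MS/MS scans. On hybrid
instruments the fragments can be mass-analyzed at high resolution, and the
measurement error of a fragment mass becomes small enough (a few mDa) that
mass accuracy alone carries most of the evidence about which peaks are
adjacent y/b ions. This package infers *sequence tags* — partial peptide
reads of the form Mp–R₁…Rm–Mq, a residue string plus two residual masses to
the peptide termini — directly from such spectra, without a protein
database. Tags are direction-free: a tag and its reversal (with Mp and Mq
swapped) are the same object, because a ladder of cleavage sites can be
read from either terminus.

The model makes only arithmetic assumptions. After deisotoping, a spectrum
is the neutral parent mass P and ascending neutral fragment masses with a
zero-mass anchor prepended. For ions mᵢ < mⱼ and residue masses M(Ω) over
the 19-letter alphabet (I/L merged into J so every letter has a unique
mass), four relations define the spectrum-graph edges: same-series
adjacency (arrow), complementarity (vertical bar), and the two mixed-series
adjacencies (forward slash, backslash). Each relation's residual ε must be
below the tolerance Δ. Because systematic calibration error cancels in
these differences, the *relative* errors concentrate well inside the
per-ion accuracy, which is what makes Δ = 0.01 Da workable.

Intensity is deliberately not scored. At high resolution and dynamic range,
low-intensity peaks are as likely to be genuine y/b ions as intense ones,
and a principled intensity model would need training data; mass error has a
clean null model instead. The only uses of intensity are in deisotoping and
as weights in the parent-mass filter.

## From ions to tags

A candidate residue is a *sequence vertex*: 2–4 spectrum vertices split
into two cleavage-site groups, complementary (vertical-bar) pairs within a
group and residue-labeled edges across the groups. Construction seeds one
candidate per residue-labeled edge and greedily absorbs vertical-bar
partners of the endpoints — lowest relative error first — keeping a partner
only if every cross-group pair retains a correctly labeled edge; duplicate
and non-maximal candidates are dropped. A fully supported residue
(two adjacent complementary pairs) rests on six spectrum edges; a residue
seen only through a lone adjacency rests on one. This asymmetry is exactly
what the scoring rewards.

Sequence vertices sharing ions get one edge: *traversable* if some
orientation merges one site group of each into a single shared cleavage
site (at most two ions which, if two, are complementary) while the other
two groups stay disjoint; *short-circuit* otherwise. Valid paths repeat no
vertex or traversable edge, contain no short-circuited pair, and must chain
orientations — a vertex entered through one site group is left through the
other. Chaining is what forbids reading a residue "down" and its neighbor
"up" from the same site: in branch-versus-chain ambiguities it eliminates
the folded readings while keeping all genuine alternatives. Enumeration is
an exhaustive depth-first recursion per connected component (components are
defined by traversable edges only); sequence graphs are small enough that
brute force beats dynamic programming, which the short-circuit constraint
would complicate anyway. A guard (`max_paths`, default 10⁶ per component)
protects against pathological inputs; a skipped component flags its
spectrum unsequenced rather than returning a partial answer.

A path's score is the summed standardized weight of its covered spectrum
edges, ω = 2(1 − Φ(ε/(Δ/2))): 1.00 at zero error, 0.05 at ε = Δ. Weights
are positive, so longer valid paths never score below their sub-paths. The
residual mass Mp is estimated at the path's first cleavage site by
averaging the largest mutually consistent cluster of readings — each ion at
each site implies the site's prefix mass either directly or through its
complement P − m — and Mq follows from closure, so
Mp + ΣM(Rᵢ) + Mq = P holds exactly on exact data. Ranking is by score, then
length, then residue string; a spectrum counts as sequenced when its top
tag reaches the score cutoff (default 4.0, i.e. roughly six perfect edges'
worth of evidence beyond a lone ladder) and has at least 3 residues.

The *consensus tag* is the longest common contiguous substring of the top
two tags, trying both directions. "Substring" rather than subsequence is
intrinsic: a tag reads consecutive cleavage sites, so any common partial
read must be contiguous. When equally long candidates arise from different
alignments, the lexicographically smallest canonical form is kept — a pure
determinism device; a score-weighted tie-break was considered but the
consensus operates on strings and ties are rare and symmetric. Spectra with
a single surviving tag produce no consensus (the construction needs two
parents). Because the consensus is a substring of both parents, it is
correct whenever either parent is — so consensus accuracy can only exceed
top-tag accuracy on the same spectra, at the cost of roughly one residue of
length and of spectra whose consensus drops under 3 residues.

## Preprocessing and the parent-mass filter

Deisotoping is greedy and intensity-ordered: each unassigned peak is tried
as a monoisotopic peak at candidate charges (its annotated charge when
present, else 1..parent charge), partners are collected at spacings of
1.003355/z within 0.01 Th, and observed intensity ratios must stay within a
factor of 3 of an averagine-predicted envelope. Charge-1 ions may stand
alone; multiply charged envelopes need at least two peaks. The original
preprocessing behind the method is not specified beyond its existence, so
this stand-in is validated by synthetic recovery (idempotence and
round-trip tests), not against a reference implementation.

The parent-mass filter computes a peptide's isotopic envelope from its
elemental composition by convolution on the neutron-offset grid (truncated
at 1% relative intensity and renormalized), matches expected peaks within
±0.05 Th in the six full scans surrounding the MS/MS scan — read as three
before and three after, the symmetric and unambiguous choice — takes the
intensity-weighted mean of per-peak errors on the neutral-mass scale,
subtracts the run median (systematic calibration), and retains
identifications below 0.02 Da. The FDR uses the concatenated target-decoy
estimator 2D/(T+D); with decoy counting stated but no estimator named, the
standard concatenated-search formula is the defensible default. When
multiple observed peaks fall in one matching window the nearest is taken —
the least biased simple rule.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `delta` | 0.01 | Da | spectrum-edge error tolerance; also sets the weight scale (sd = Δ/2) |
| `min_tag_length` | 3 | residues | shortest reportable tag |
| `score_cutoff` | 4.0 | — | minimum top-tag score for a sequenced spectrum |
| `max_paths` | 10⁶ | paths | per-component enumeration guard |
| `ratio_tolerance` | 3 | fold | deisotoping envelope-shape gate |
| `iso_mz_tol` | 0.01 | Th | isotopic partner matching window |
| mass filter threshold | 0.02 | Da | normalized parent-mass error cutoff |
| mass filter window | 0.05 | Th | envelope matching half-window |

Residue masses are computed from elemental compositions, so identities like
M(G) + M(A) = M(Q) are exact; per-residue overrides (e.g.
carbamidomethyl-C) can be supplied in a configuration file.

## What the synthetic data does and does not show

The generator emulates tryptic peptides (random residues, K/R C-terminus,
lengths 7–20), y/b ladders with per-ion coverage probability, Gaussian
fragment mass error (default sd 0.0025 Da = Δ/4, which keeps most relative
errors between adjacent fragments inside ±0.01 Da), uniform-m/z noise peaks
drawn from the lower quartile of signal intensities, and full scans with
isotopic envelopes at a controllable calibration offset defined on the
neutral-mass scale (so an offset δ is recovered as a median error δ
regardless of charge). All randomness derives from one seed, with
per-spectrum offsets so individual spectra are reproducible.

What it does not emulate: realistic CID intensity patterns, a-ions and
neutral losses, co-isolated precursors, or correlated (non-Gaussian) mass
error. Passing tests on this data therefore demonstrate the algorithmic
properties — exact recovery on exact data, the consensus guarantee,
brute-force equivalence of the path search, calibration recovery — not the
accuracy figures one would obtain on a particular instrument's data, which
depend on fragmentation physics the generator does not model.

## Numerical choices and degenerate inputs

All masses are monoisotopic doubles; the proton is 1.00727646688 Da and the
isotope spacing 1.0033548378 Da. Near-duplicate neutral masses (within
0.005 Da) are merged after deisotoping so spectrum-graph vertices stay
distinct. Ions at or above P + Δ are dropped with a warning; a parent
charge of 0 rejects the spectrum rather than guessing. Residual-mass
clustering uses a tolerance of (m+1)·Δ and breaks ties toward the smaller
estimate. Two geometric filters discard paths that cannot be linear reads
of cleavage sites: residuals below −m·Δ, and "folded" paths in which some
ion fails to read (directly or through its complement) as its site's
clustered ladder position. The latter matters even on exact spectra:
near-isobaric arithmetic coincidences — F+J exceeds K plus water by just
4 mDa, i.e. within Δ of an N residue — can otherwise splice a jump back to
a distant cleavage site onto a genuine tag and outscore it. Path output order (length desc, residue string,
vertex sequence) and all tie-breaks are deterministic, so identical inputs
give byte-identical outputs.

Test problem sizes were chosen to exercise the guarantees at scale while
keeping the default suite quick: 200 random graphs for the enumeration
oracle, 500 zero-error and 1000 noisy synthetic spectra for the recovery
and consensus properties, 30 identifications per calibration offset for the
filter.

## Known limitations

- Tag quality degrades sharply for charge-1 spectra of long peptides, where
  complementary ions fall outside the measured range; the method is at its
  best for 2+ and 3+ tryptic peptides.
- The exhaustive search is exponential in pathological, densely connected
  sequence graphs; the `max_paths` guard trades completeness for bounded
  runtime there.
- End residues of long tags are the least reliable (the ranking prefers
  longer paths), and Q/GA, N/GG ambiguities are unresolvable at Δ = 0.01 Da
  when the intermediate fragment is missing; downstream users should treat
  a single end-residue mismatch as a probable inference error rather than a
  genuine polymorphism.
- Deisotoping is a pragmatic stand-in validated on synthetic envelopes
  only.
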