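---
title: "Consensus spectrum generation and cluster-quality evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus spectrum generation and cluster-quality evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccons)
```

## The problem

Large tandem mass spectrometry experiments acquire many near-identical MS2
spectra of the same analyte. Spectrum clustering groups them, and each
cluster is then summarized by a single *representative* (consensus)
spectrum for database searching or spectral-library construction. The
choice of summarization algorithm affects every downstream identification,
yet it is often treated as an afterthought. This package implements the
four consensus strategies in common use, the statistics needed to judge
the quality of the representatives they produce, and a seeded simulator of
replicate-spectrum clusters so that all of it can be exercised and tested
without external data.

## The four methods

Let a cluster contain member spectra $S_1, \dots, S_n$, each a centroided
peak list $\{(m_i, I_i)\}$.

**AVERAGE** pools all member peaks, sorts them by $m/z$, and merges peaks
with close $m/z$ in a single greedy left-to-right pass: a peak joins the
open group when its $m/z$ is within `merge_tolerance` of the group's
running intensity-weighted mean, otherwise it starts a new group. A group
$G$ is emitted as one peak with

$$ m_G = \frac{\sum_{i \in G} I_i\, m_i}{\sum_{i \in G} I_i}, \qquad
   I_G = \frac{1}{|G|} \sum_{i \in G} I_i . $$

**BIN** overlays a fixed grid of half-open bins $[kw, (k+1)w)$, $w =$
`bin_width`, anchored at $m/z = 0$, and assigns every peak of every member
to its bin. A bin's *occupancy* is the number of distinct members
contributing at least one peak. Bins with occupancy fraction strictly
below `min_fraction` are discarded — at the defaults, a bin touched by
exactly 25% of members is kept, one touched by less is not. Surviving bins
emit one peak whose $m/z$ and intensity are unweighted means of the peak
values in the bin (deliberately unlike AVERAGE's intensity-weighted
$m/z$).

**MOST** selects the cluster medoid: each member is vectorized on the same
kind of fixed grid (`similarity_bin_width`), normalized to unit Euclidean
norm, and scored by the summed dot product against every *other* member
(self-similarity excluded). The member with the maximal sum is returned
verbatim.

**BEST** selects the member with the best peptide-spectrum match score
(orientation set by `score_direction`) and returns it verbatim. A cluster
in which no member is identified has no valid representative under this
method; `generate_consensus()` skips and counts such clusters.

AVERAGE and BIN synthesize new spectra; MOST and BEST return an untouched
member, recorded in `source_member_id`.

## Parameters

| parameter | unit | default | why |
|---|---|---|---|
| `bin_width` | Th | 0.02 | grid fine enough to separate fragment ions on Orbitrap-class data while aggregating replicate jitter |
| `min_fraction` | fraction | 0.25 | a peak must be reproducible across members to survive; strictly-below semantics keep the exact 25% boundary |
| `merge_tolerance` | Th | 0.02 | AVERAGE's merge window; kept equal to the grid width so both averaging methods operate at one resolution |
| `similarity_bin_width` | Th | 0.02 | vectorization grid of the dot product |
| `bin_intensity` | — | `"peaks"` | BIN's intensity denominator: mean over contributing peaks, or `"members"` to divide by cluster size, down-weighting sparse bins |
| `intensity_transform` | — | `"none"` | `"sqrt"` variance-stabilizes the dot product, reducing the dominance of the base peak |
| `score_direction` | — | `"higher"` | raw search-engine scores usually increase with match quality; E-value-like scores use `"lower"` |
| `tie_break` | — | `"first_id"` | deterministic by design; `"random"` (with a mandatory seed) reproduces the behavior of tools that draw among tied medoids, a known source of irreproducibility |

The merge tolerance, the BIN intensity denominator, and the dot product's
intensity normalization are genuinely open choices — different published
implementations disagree — so all three are parameters with logged
defaults rather than hard-wired guesses. Every run report materializes
the full resolved parameter set.

### Precursor of a synthesized consensus

Nothing canonical exists for the precursor of an AVERAGE/BIN spectrum. We
use the median member precursor $m/z$ and the modal charge, breaking
charge ties toward the smaller charge (the more common state in tryptic
data), and warn when members disagree on charge. Unknown charges are
propagated as unknown, never imputed.

## Evaluation statistics

A cluster is *multispectral* when it has at least two members.
`majority_peptidoform()` finds, among the cluster's identified members,
the modal peptidoform (sequence plus modification sites) and its fraction;
the majority exists only when that fraction is strictly greater than 0.5.
The denominator is the identified members only: the majority rule
references matches, and unidentified spectra carry no evidence about which
peptide they are. `filter_multispectral()` keeps multispectral clusters
with a defined majority.

`classify_representative()` compares a representative's identification
with its cluster: `majority` (high quality), `minority` (matches a member
but not the majority), `novel` (matches no member — possible only for the
synthesizing methods AVERAGE and BIN), or `unidentified`.
`quality_ratios()` reports category fractions over clusters with an
identified representative; the high-quality ratio is the `majority`
fraction and the low-quality ratio the sum of `minority` and `novel`,
reported both aggregated and split out, since published accountings do not
always resolve the residual category.

`score_by_cluster_size()` stratifies representative scores into the size
strata 1, 2, 3, 4, 5, (5,10], (10,20], (20,∞): each size up to five has
its own stratum, so a size-5 cluster is in {5}, not (5,10].

`compare_methods()` takes two representative identification tables keyed
by a shared identifier (the cluster id, carried in the `spectrum_id`
column) and partitions the shared keys into *corroborative* PSMs
(identical peptidoforms), *site-divergent* PSMs (same sequence, different
modification sites), and *peptide-divergent* PSMs (different sequences).
Peptidoform identity uses the full site list by default; a
`sequence_only` flag relaxes it to the bare sequence where modification
reporting differs between engines.

## The simulator

`make_dataset()` emulates the one structure everything above depends on:
clusters of replicate spectra of a shared template. Per cluster it draws a
template of `n_template_peaks` peaks placed uniformly over `mz_range`
subject to a 0.04 Th minimum spacing (twice the default bin width, so
template peaks can never collide within one bin), with log-normal
intensities (`meanlog` 7, `sdlog` 1: median ≈ 1100 arbitrary units and a
roughly two-decade dynamic range, as in centroided Orbitrap MS2 data).
Replicates then apply, in order: peak dropout (`dropout_p` = 0.1),
Gaussian $m/z$ jitter (sd 0.005 Th, well inside a 0.02 Th bin),
multiplicative log-normal intensity noise (log-sd 0.2), and
`n_noise_peaks` = 5 uniform-random additive peaks kept below the
template's 25th intensity percentile — low so that the occupancy filter,
not intensity, is what removes them. The default cluster size is 5: the
smallest size at which one member's private peaks fall strictly below the
25% occupancy threshold, i.e. the smallest clusters on which BIN's filter
can act at all. Member PSM scores follow
$100 \cdot \mathrm{sim}(\text{member}, \text{template}) + N(0, 2)$, so
better replicates score higher, and `contamination_fraction` of clusters
receive one member replicated from a different template carrying that
template's peptidoform label — the mixed clusters the quality statistics
are about.

What the simulator does **not** emulate: fragmentation chemistry (peaks
are random positions, not b/y ions), correlated noise, chimeric
co-isolation beyond the single-contaminant design, retention time
structure, or a real search engine (labels and scores are synthetic).
Passing tests therefore demonstrate the algebra and selection logic of the
methods under controlled replicate noise — not identification performance
on real data, which depends on search engines and spectral libraries
outside this package's scope.

## Numerical choices and degenerate inputs

* Bins are half-open, anchored at 0; a peak at an exact boundary belongs
  to the upper bin. Occupancy counts distinct members, not peaks.
* The occupancy comparison is strict (`< min_fraction` discards), so the
  boundary case is kept by construction, and tested at 1/4 vs 1/5.
* AVERAGE's groups whose intensities are all zero fall back to the
  unweighted mean $m/z$; groups of one peak pass through bit-exactly.
* Zero-intensity peaks are retained by the reader; a spectrum whose
  binned intensity vector is all zero has no defined direction and the
  dot product raises an error rather than returning a value.
* Medoid ties are resolved to the lexicographically smallest spectrum
  identifier by default; `"random"` requires an explicit seed, and a
  `generate_consensus()` run seeds once so the whole run is a single
  reproducible stream.
* MGF output prints $m/z$ to 4 decimals and intensities to 4 significant
  digits; the write/read round trip is exact at that precision.

## Test problem sizes

The shipped test-suite checks run at sizes chosen to exercise every code
path while keeping the whole suite quick on one core: exhaustive-oracle
comparisons on 500 simulated clusters of 2–8 members, noise-suppression
and template-recovery harnesses on 200 clusters each, and hand-computed
fixtures for every worked example. The acceptance script
(`scripts/acceptance.R`) re-runs the pipeline end to end on 200-cluster
benchmarks.

## Known limitations

* Fixed-grid binning splits peaks that straddle a bin boundary. Template
  positions are uniform modulo the grid, so at jitter sd 0.005 Th roughly
  a fifth of peaks can land on either side of a boundary in different
  members; when both sides survive the occupancy filter, the BIN
  consensus carries the peak twice. Under a grid-based cosine this
  duplication is penalized, and in our recovery harness the BIN consensus
  beats the median member's template similarity in about 92–96% of
  clusters rather than essentially all of them. This is a property of the
  algorithm itself, not of the implementation: no jitter magnitude
  eliminates boundary straddling.
* BEST requires identifications before consensus generation and is
  undefined for fully unidentified clusters, so it cannot serve
  identification-free archives.
* The evaluation statistics take identifications as given; no
  target-decoy control or site-localization scoring is performed.
* The cluster reader accepts the normalized TSV and the blank-line
  dialect; identifier mismatches between clustering output and MGF titles
  are handled by an explicit `--id-map`, never by heuristics.
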