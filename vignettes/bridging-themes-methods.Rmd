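---
title: "Detecting bridging themes: models, parameters and design choices"
author: "bridgethemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bridging themes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgethemes)
```

## The problem

Protein domains are grouped into evolutionary lineages by hierarchical
classifications (A.X.H.T.F in ECOD); domains in *different* X-groups are
treated as independent lineages — their overall sequences and structures
are unrelated. A **bridging theme** is a short segment (tens of
residues) whose variations occur in domains of two different X-groups
with sequence similarity far above chance, while the rest of the two
domains shows none. Such segments are candidates for ancient peptide
building blocks that predate, or were copied between, the two folds.

The detection problem therefore combines two opposing requirements: a
strongly similar matched segment, and demonstrably *dissimilar*
surroundings. This package implements the corresponding pipeline on top
of externally produced profile-search hits: the expensive sensitive
search (profile HMMs against a sequence database) is out of scope and
its results are consumed as a tabular hit list.

## Pipeline model and assumptions

Given filtered hits (E-value and coverage thresholds below), domains
hit by the same theme are partitioned by X-group, and every domain pair
across an X-group pair is a candidate. Each domain splits into
before / theme / after segments around its hit interval. Assumptions:

* Hit intervals are trusted as matched envelopes; gap structure inside
  the original profile match is not revisited.
* Sequence similarity is measured by pairwise alignment under BLOSUM62;
  homology of the theme and non-homology of the flanks are judged from
  the same alignment machinery, so both judgements share one scoring
  model.
* X-group labels are authoritative: within-X-group pairs are discarded
  outright, with no attempt to detect misclassification.

### Alignment rule

The theme segments are aligned with local Smith–Waterman. A local
aligner maximises score, not length, and may trim a genuine match to a
short, highly similar core; when the local alignment covers **at most
20** aligned residues the global Needleman–Wunsch alignment (end gaps
penalised) replaces it. The published description of this rule is
one-sided ("more than 20" for keeping the local alignment, "fewer than
20" for falling back), leaving exactly 20 ambiguous; this implementation
takes the global branch at 20, i.e. the local alignment is kept only
when it is strictly longer than 20 residues. Flanks are always aligned
locally: a global alignment of flanks of very different lengths would be
dominated by end gaps and uninformative.

Percent identity (equal residues) and percent similarity (substitution
score > 0, the usual "positives" rule) are computed over aligned
non-gap columns, not over alignment length, matching the convention of
reporting "aligned residues" counts next to the percentages. Since the
BLOSUM62 diagonal is strictly positive, identity ≤ similarity always
holds and is asserted in the tests.

### Alignment significance

The score $S$ of the chosen theme alignment is compared with scores of
alignments between the first segment and $n$ = 1,000 random segments of
the second segment's length, drawn i.i.d. from the second segment's
residue composition with an add-one pseudocount over the 20 standard
amino acids. A Gumbel distribution is fitted to the null scores by
maximum likelihood and

$$p = 1 - \exp\!\big(-\exp(-(S-\mu)/\beta)\big).$$

The Gumbel scale is solved by the standard fixed-point iteration with a
method-of-moments start; on non-convergence the method-of-moments
estimate is used. A zero-variance null sample (possible for degenerate
scoring schemes) is flagged and reported as $p \in \{0, 1\}$.

Calibration is verified in the tests by holding out one draw of the
null generator as the "observed" score: its p-values must be
approximately Uniform(0,1) (Kolmogorov–Smirnov statistic < 0.1 over 500
replicates). Note that the literal design "score of a random query
against the fixed database sequence" is *not* exactly exchangeable with
the null sample — the pseudocount flattens the sampled composition
relative to the concrete sequence — so the held-out-draw design is the
correct calibration target; the p-values of the pipeline are used as
filters and interesting-case rankings, not as exact tail probabilities.

### Representative selection

With $n_1 \times n_2 > 1$ candidates for a theme / X-group pair, theme
alignment scores and flank scores are z-normalised across the group and
the two candidates maximising $z_{\text{theme}} - z_{\text{flank}}$ are
returned. Open details resolved here:

* the "scores" entering the normalisation are raw alignment scores (not
  bit scores);
* the flank score of a candidate is the arithmetic mean of the before
  and after local scores, an absent flank contributing 0;
* a zero standard deviation across the group defines all z-scores as 0;
* ties break deterministically by lower hit E-value, then lexicographic
  domain-id pair.

When one domain pair is reached through several themes, only the theme
whose alignment covers the most residues is kept (ties: higher score,
then smallest theme id). Redundancy between similar baits beyond this
per-pair rule (bait-level clustering) is out of scope.

## Structural divergence

Over the aligned theme residue pairs that have coordinates on both
sides (`n_used`; missing residues are dropped pairwise):

* **Cα RMSD** after optimal superposition (SVD-based Kabsch,
  reflection-free).
* **dRMSD**: RMS difference of all intramolecular pairwise distances —
  superposition-free, hence insensitive to the relative placement.
* **Contact-map change** at 9 and 11 Å thresholds over Cβ atoms (Cα for
  glycine): percentage of differing entries out of all $l^2$ entries.
  The diagonal and near-diagonal entries are identical on both sides by
  construction and are deliberately *not* excluded, matching the plain
  "differing entries / $l^2$" normalisation.
* **Secondary-structure agreement** after the standard 8→3-state
  collapse (H,G,I→helix; E,B→strand; else coil).

A pair is *similar* when Cα RMSD < 6 Å, strictly; the boundary value
classifies as dissimilar (the published threshold statement is
directionless, and the strict-less rule is exposed in the
configuration). The RMSD values of all pairs can be decomposed with a
two-component univariate Gaussian mixture fitted by EM: 2-means
initialisation with 10 restarts under a seed, convergence when the
log-likelihood gains less than 1e-8 or after 500 iterations, component
standard deviations floored to avoid collapse, components
reported in ascending order of mean. The log-likelihood trace is kept
and its monotonicity asserted per step in the tests. Whether such a fit
runs on local-only or all alignments is a flag; by default all values
enter.

## Binding enrichment

Binding residues are found by an **inclusive** 4.5 Å criterion — a
residue binds when any non-hydrogen atom lies ≤ 4.5 Å from any ligand
atom — or read from BioLiP-style annotations. Ligands are filtered
through an exclusion list (water/unknowns, crystallographic additives,
modified residues) shipped as an editable text file; a published
whitelist of "relevant" codes is not recoverable, so exclusion is the
default and an optional whitelist file is accepted. A residue bound by
several ligands counts once per domain.

The enrichment statistic compares the fraction of residues inside
themes (theme residues / all residues, over binding-annotated domains)
with the fraction of binding residues inside themes. Under uniform
random placement of binding residues, the two aggregate fractions agree
in expectation *provided* the number of binding residues per domain is
proportional to domain length — the aggregate is a ratio of sums, not a
mean of ratios; the null simulation in the tests respects this by
assigning ~10 % of each domain's residues.

## Networks

The overview network has one node per X-group, coloured by the
structural class of its architecture level (all-α blue, all-β red, α+β
yellow, α/β green, mixed yellow-green, others cyan; unknown gray with a
warning); colours are categorical strings so renderers decide the
palette. One edge per X-group pair, solid when at least one
representative pair keeps a local theme alignment of more than 20
residues, dashed otherwise; parallel instances collapse into a count
attribute. Nested networks are bipartite domain graphs per X-group
pair, with the sub-X classification (H.T.F) as a border attribute.
Exports are GraphML (attributes preserved) and SIF plus an attribute
sidecar TSV, with sorted, deterministic ordering so repeated exports
are byte-identical.

## The synthetic benchmark

The generator emulates the statistical skeleton of a curated
bridging-theme study, with defaults chosen to mirror the reported set
properties:

| parameter | default | rationale |
|---|---|---|
| `theme_length` | 49 | mean curated theme length (~49 residues) |
| `theme_substitution_rate` | 0.2 | two variations then share ≈ 64 % identity, the upper end of the observed identity/similarity band |
| `flank_length_range` | (15, 40) | hosts of ~80–130 residues, matching ~100-residue domains |
| `ligand_fraction` | 0.5 | roughly half of curated domains have an identifiable ligand |
| `same_conformation_fraction` | 0.28 | the similar-conformation component weight of the observed RMSD mixture |
| `n_xgroups`, `domains_per_group`, `n_themes` | 20, 5, 10 | benchmark scale used by the acceptance checks |

Each planted theme is an i.i.d. ancestor (uniform background by
default, a BLOSUM62-style background is configurable) evolved
independently into two variations (per-site substitution, no indels —
hits are matched envelopes, alignment handles gaps), embedded between
independently random flanks in two domains with different X-group
labels. Backbones are ideal-geometry toys: helix (1.5 Å rise, 100°
twist, 2.3 Å radius), strand (3.3 Å rise, alternating lateral offset)
or coil (3.8 Å random walk), with pseudo-Cβ atoms 1.53 Å off the local
axis, so consecutive Cα distances always fall in [3.7, 3.9] Å. Ligands
are single atoms (or 2.2 Å-edge tetrahedral clusters) placed 3.0 Å from
a designated theme residue's Cβ, guaranteeing detection at the 4.5 Å
cutoff; the shipped BioLiP-style table is computed geometrically from
the same ligands, so the two binding routes agree exactly by
construction. Hit tables list every planted occurrence at E = 10⁻⁶,
coverage 1.0, plus one decoy per theme at E = 10⁻² — above the
filtering threshold by construction, so decoy survival must be zero.

What the generator does **not** emulate: realistic folding (toy
backbones have no side chains, packing or sterics), indels within
themes, profile-HMM emission statistics, correlated substitution
patterns, or classification noise. Passing the planted-recovery tests
therefore demonstrates the correctness of the pipeline's filtering,
alignment, selection and bookkeeping — not the sensitivity of a
profile search on real sequences.

## Numerical choices and degenerate inputs

* Gap parameters are not dictated by the published method; the standard
  BLOSUM62 pairing (open 11, extend 1, gap of length $k$ costing
  $11 + k$) is the default and both are configuration-exposed, as is
  whether end gaps are penalised (they are, via the global mode).
* Alignment tie-breaks among co-optimal tracebacks follow the
  underlying aligner; all reported statistics come from the returned
  alignment, and score equality with an independent brute-force DP is
  what the tests assert.
* An all-negative local alignment returns an empty result with score 0.
* Empty flanks are allowed and yield empty flank alignments (score 0,
  length 0 — which *passes* the flank filter via the length rule, so
  short contexts never block a candidate).
* A domain hit twice by one theme contributes its lowest-E-value hit.
* Intervals are 1-based closed inside R (the idiomatic convention);
  the on-disk hit/truth tables use 0-based half-open intervals and the
  readers/writers convert. PDB author residue numbers are carried as
  metadata only.
* Kabsch uses SVD with a determinant sign correction, so colinear and
  reflected configurations are handled; fewer than 3 coordinate pairs
  is an error.
* The EM mixture requires ≥ 10 values and errors on zero variance; on
  single-population data it reports its convergence status honestly
  rather than forcing two components apart.

## Problem sizes in the tests

The test-suite sizes are chosen to exercise every code path quickly:
oracle equivalence on all pairs from a pool of twelve ≤ 8-mers over a
4-letter alphabet; P-value calibration at 500 replicates × 1,000 null
samples on 60-mers; mixture recovery on 5,000 draws from
0.28·N(3.3, 1²) + 0.72·N(9.8, 2²); planted-theme recovery on the
20 × 5 / 10-theme benchmark at substitution rate 0.2 (seed 42); the
enrichment null at 1,000 resamples. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch on
the installed package.

## Known limitations

* Profile searches, theme HMM construction, structure alignment
  (TM-align) and secondary-structure assignment (DSSP) are upstream
  tools whose outputs are ingested, never recomputed; TM-scores are
  passed through to reports when supplied.
* Significance values are calibrated filters, not multiple-testing
  corrected probabilities; the pipeline uses them to rank and select,
  and so should its users.
* The flank criterion judges local alignments only; a homologous but
  gap-displaced context can pass it, which is why flagged-but-failing
  candidates are retained in the output rather than silently dropped.
* mmCIF input is not supported; domain coordinates are expected as
  PDB-format single-chain extracts.
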