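---
title: "Methods: profile surveys, subfamily classification, and conserved-site paralog divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile surveys, subfamily classification, and conserved-site paralog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`paraldiv` implements a desk-scale version of a classic comparative-genomics
workflow: survey a proteome for a domain family with a position-specific
scoring profile, screen family members for secondary motifs, classify them
into subfamilies against labeled anchor sequences on a bootstrap-supported
tree, and — the core computation — scan a duplicated paralog pair against a
deep ortholog alignment for positions where one paralog has abandoned a
residue that everything else has kept. That last scan is the question one
asks after a recent whole-genome duplication: when two young homeologs (for
example the maize phytochrome B pair, duplicated ~11 Mya) behave differently
in a protein–protein interaction, which of their few sequence differences
sit at positions that evolution has otherwise frozen?

This vignette describes the models, the tunable parameters and their
defaults, the synthetic-data generator that stands in for downloadable
proteomes, the numerical choices, and the limitations.

## Profile model and domain search

A profile is built from a seed alignment by per-column residue counts with
Dirichlet-style pseudocounts against a background distribution $b$
(Robinson–Robinson frequencies by default):

$$s(c,a) = \log_2 \frac{(n_{ca} + w\,b_a)/(n_c + w)}{b_a},$$

with pseudocount mass $w = 1$ by default. Columns that are more than 50%
gap in the seed are dropped from the model, so fragmentary seed rows do not
stretch it. The expected score of every column under the background is
$-\mathrm{KL}(b \,\|\, f_c) \le 0$, which keeps random sequence from
accumulating score.

Scanning is local (Smith–Waterman-style) dynamic programming of the profile
against each protein with affine gap penalties, 4 bits to open and 1 bit to
extend — the conventional order of magnitude for profile local alignment;
both are configurable on `build_profile()`. After a hit is reported its
residue interval is masked and the scan repeats, so multiple domain copies
are found without overlaps. This is deliberately *not* a full profile-HMM
implementation (no Plan7 state machine, no forward algorithm, no
composition filters); for well-separated domain families the log-odds
profile recovers the same intervals, and the package's planted-domain tests
quantify exactly what it does recover.

### E-value calibration

E-values are calibrated per model by scoring shuffled background sequences
(default 200 sequences of length 300) and fitting a Gumbel distribution to
the per-sequence maximal scores. The fit is a *left-censored* maximum
likelihood: observations below the sample median enter only through the
CDF. Empirical maxima of gapped local alignment scores follow the Gumbel
law only in their upper tail, and a full-sample fit lets the bulk drag the
tail slope; censoring at the median makes the fitted $\lambda$ track the
tail the E-values are computed from. The reported E-value is per search:

$$E(S) = \frac{N_{\mathrm{search}}}{L_{\mathrm{calib}}}\,
e^{-\lambda (S - \mu)},$$

where $N_{\mathrm{search}}$ is the total number of residues scanned (the
whole proteome in `survey_proteome()`), so a cutoff of 1 means "about one
random hit per whole search" — the interpretation under which the
conventional permissive motif cutoff of $E \le 1$ is meaningful. The test
suite checks this self-consistency directly: fresh shuffled databases must
yield on the order of one $E \le 1$ hit per search.

### Completeness and the one-per-locus rule

A hit is *complete* when it covers at least 80% of the model columns
(configurable); planted domains truncated below half the consensus length
always classify as partial. When several isoforms of one locus have hits,
one protein is kept per locus: complete domain beats partial, then the
longer protein, then the lexicographically smallest accession. This mirrors
the standard filtered-gene-set practice of reducing a survey to unique loci
before phylogenetics.

## Motif catalog and DNA-binding classification

Secondary motifs are short profiles built and calibrated exactly like the
domain model, screened across full-length proteins at a permissive default
cutoff of $E \le 1$. The catalog is data-driven — whatever seed alignments
are supplied define the motif id set — because published motif inventories
for this family disagree internally about their own count. Presence calls
are anti-monotone in the cutoff by construction.

DNA-binding class uses the standard plant-bHLH basic-region diagnostic over
the first 13 model columns: His-5, Glu-9, Arg-13 call a G-box binder;
Glu-9 with Arg-13 but no His-5 an E-box binder; fewer than five basic
residues (K/R/H) in the region a non-binder. The literature names the
activity more often than the rule, so the rule is explicit and every part
of it (diagnostic columns, region width, basic-residue minimum) is a
parameter.

## Distance trees and anchored classification

Tree building is deliberately a distance method: Kimura-corrected
fractional mismatch $d = -\ln(1 - p - 0.2p^2)$ on pairwise-complete
columns, neighbor-joining, and nonparametric bootstrap over alignment
columns (default 100 replicates, configurable to 1000). A
maximum-likelihood analysis with a substitution matrix and rate
heterogeneity would be the full-scale choice; NJ is consistent on additive
distances, runs in seconds, and is adequate for subfamily-level grouping —
the package labels its outputs NJ-based so nobody mistakes the provenance.
Raw mismatch fractions at or above 0.85 would push the correction past its
pole, so they are capped there and flagged saturated. Negative NJ branch
lengths are clamped to zero with the deficit moved to the sibling edge.
Before distances are computed, gapped columns are stripped; the default
removes any column containing a gap (`max_gap_fraction = 0`), the strictest
reading of "regions with gaps were removed", and the column map returned by
`strip_gap_columns()` carries coordinates back.

Subfamily assignment is anchor-based: a query joins subfamily $L$ iff the
smallest bipartition side with bootstrap support at least 50 that contains
the query and at least one anchor contains anchors of subfamily $L$ only.
Working with bipartition sides rather than rooted clades makes the rule
independent of where the unrooted NJ tree happens to be rooted; a
mixed-anchor side leaves the query unclassified rather than guessing.
Ties everywhere (modal residues, guide-tree joins, hit ordering) break
lexicographically, so every stage is deterministic given its seed.

The progressive aligner used to pool queries with anchors builds its guide
tree from 3-mer distances and merges groups by profile–profile global
alignment over BLOSUM62 (gap open 10, extend 1). Inputs are sorted by id
first, so the alignment is invariant to input order.

## The divergence scan

Given an alignment containing reference orthologs plus the two paralogs,
`conservation_profile()` computes, per column and over references only, the
modal residue and its frequency with gaps excluded from the denominator.
`scan_paralog_divergence()` then reports a column iff:

1. consensus fraction $\ge$ `min_conservation` (default **0.9**),
2. reference gap fraction $\le$ `max_gap_fraction` (default 0.2),
3. the partner paralog carries the consensus residue (default on), and
4. the query paralog carries a non-gap residue different from the
   consensus.

The 0.9 floor is the single most result-sensitive knob. "Highly conserved"
is not a number; 0.9 over a few dozen references tolerates the occasional
lineage-specific exception at an otherwise frozen position (the motivating
family has a position that is usually proline but occasionally serine or
histidine) while still excluding merely common residues. An alternative
`mode = "unseen-residue"` reports a column only when the query residue was
*never* observed among the references — the strictest reading of "not found
in any other sequence" — and is useful as a confirmatory filter; the
frequency mode stays the default because it also flags positions where the
query residue exists at trace frequency among references.

Requiring the partner to match the consensus (3) is what turns "this column
is odd" into "this paralog diverged after duplication": the contrast is
explicitly query-vs-(partner + references).

Each site is mapped from alignment column to both paralogs' own ungapped
numbering (`map_column_to_position()`: count of non-gap characters up to
and including the column, 1-based). Insertions upstream in one paralog
shift the two numberings apart — the same columns then carry different
residue numbers in the two proteins, which is why the notation
(consensus residue + query position + query residue, e.g. `F113L`) is
always expressed in the query's numbering. Domain context is annotated
from a user-supplied interval table (inclusive bounds); predicting domain
boundaries is out of scope. `pairwise_paralog_report()` reports percent
identity, substitution columns and indel columns separately, because
"N differences including indels" is ambiguous about whether indels are
inside or on top of the count.

## The synthetic-data generator

The generator defines the conditions under which the package's claims are
tested; its defaults are fixed, not tuned:

* **Proteome**: background proteins of 150–400 residues drawn i.i.d. from
  the background distribution; planted domain copies mutated at 0.05
  substitutions/site; truncated copies keep a prefix of 25–45% of the
  consensus (always under the 50% completeness boundary).
* **Ortholog family**: a random bifurcating tree rescaled to mean
  root-to-tip depth 1 substitution/site; each column is invariant-class
  (weight 0.7, relative rate 0.02) or variable-class (weight 0.3, rate
  0.5). These weights make a 0.9 conservation floor meaningful: invariant
  columns essentially always pass it, variable columns essentially never
  do, and the fraction of columns passing tracks the invariant weight.
* **Indels**: per-sequence insertion and deletion events at 0.01 events per
  column total, geometric lengths with mean 2 — the shortest model that
  produces the few-residue numbering offsets seen between real paralog
  pairs.
* **Planted divergence**: `paralogA` copies the column consensus;
  `paralogB` differs at exactly `n_sites` sampled conserved columns, with
  the substituted residue drawn from the background *excluding* the
  consensus residue, so a planted site is divergent by construction.
* Substituted residues never include ambiguity codes; the alphabet is the
  20 canonical amino acids throughout.

What the generator does **not** emulate: compositional bias and repeats
(real proteomes produce more marginal profile hits than i.i.d. background),
heterotachy and site-specific amino-acid preferences (real conservation is
not a two-class mixture), alignment error (families are generated *as*
alignments; only the re-alignment tests exercise the aligner), and
gene-model misprediction beyond simple truncation. Passing the planted
tests therefore demonstrates correctness of the algorithms under clean
conditions, not robustness to dirty orthology or alignment artifacts.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the divergence scan on
50 families of 20 references × 300 columns with 4 planted sites, the
survey on 50-protein proteomes with 20 planted domains, calibration checks
over 50 fresh null searches, NJ recovery on 100 random 8-taxon additive
matrices, and anchored assignment on 15-leaf three-subfamily alignments —
sizes chosen so the full suite completes in a few minutes while estimates
(sensitivity, precision, false-hit counts) are averaged over enough
replicates to be stable. Every random draw in the package flows through an
explicit integer seed argument; identical arguments and seed give
bit-identical output, including written files.

## Known limitations

* Bit scores are not comparable to HMMER's; only intervals, completeness
  calls and E-value behavior are designed to correspond.
* The Gumbel length-rescaling of E-values is first-order; very short or
  very long targets relative to the calibration length inherit some bias.
* NJ topology is a surrogate for ML at full scale; deep, short internal
  edges that ML might resolve can come out unsupported here.
* The divergence scan treats reference choice as given. With few or
  phylogenetically skewed references, `min_conservation` and `min_refs`
  (default 10) are the only guards against calling ordinary polymorphism
  "deep conservation".
* Saturated distance pairs (capped at $p = 0.85$) compress deep branches;
  subfamily assignment is robust to this, branch-length interpretation is
  not.
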