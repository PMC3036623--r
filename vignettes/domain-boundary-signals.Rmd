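---
title: "Detecting and classifying domain boundary signals in anchored alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying domain boundary signals in anchored alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boundscan)
```

## The model

`boundscan` predicts protein domain boundaries in two steps. The first step
exploits an evolutionary regularity: domains recombine during evolution, so
the homologs of a multi-domain query frequently contain only a subset of
its domains. In a multiple sequence alignment anchored on the query (every
row rendered in query coordinates, insertions relative to the query
discarded), such a homolog appears as a row whose alignment stops abruptly —
a long gap run starting at one end of the row — approximately at a domain
boundary of the query. The second step is discriminative: each candidate
site is encoded from its sequence and structural context and scored by a
cascade of two support vector machines.

### Signal extraction

A *boundary signal* fires on a hit row when a terminal gap run is at least
`min_gap` residues long and the row keeps at least `min_aligned` non-gap
residues once all gaps (terminal and interior) are removed. The second
condition reads "the remaining sequence with the gaps removed" literally:
interior gaps do not count toward the aligned length. The signal's position
is the aligned residue adjacent to the gap run: the first non-gap residue
for an N-terminal run and, symmetrically, the last non-gap residue for a
C-terminal run. The C-terminal placement is our symmetric completion of a
rule that is naturally stated for the N-terminal case; the alternative
(first gap column) differs by one residue, far below the 20-residue
labeling tolerance, so nothing downstream is sensitive to the choice.

Rows are processed in order of increasing e-value so that the most
trustworthy homologs speak first, and every signal event is logged: events
recurring at one residue accumulate *multiplicity*, which later feeds the
density features. Collection halts the moment signals exist at
`max_unique_sites` distinct residues. We treat the cap as an event-level
condition: it can trip between the N-side and C-side signals of a single
row, in which case the C-side signal of that row is discarded. This makes
the processed-event sequence a strict prefix of the uncapped sequence,
which is what the property tests verify against a brute-force replay.

Because a signal needs `min_gap` terminal gaps plus `min_aligned` aligned
residues in a row of query length, no chain shorter than
`min_gap + min_aligned` (= 90 at defaults) can produce one — the package's
rationale for treating sub-90-residue chains as signal-free.

### Truth geometry

Domain definitions are ordered 1-based inclusive residue ranges
(`7-339, 364-561`). The *boundary points* of a definition are both flanks
of every inter-domain transition — the end of each range and the start of
its successor — while the two chain termini are never boundary points. We
chose the both-flank reading over linker midpoints because ranges in the
wild are frequently non-contiguous (`339 | 364` leaves a 24-residue
linker), and either flank is a legitimate cut point; a site near one flank
is near the transition in every sense that matters at a 20-residue
tolerance. Sites on single-domain chains are labeled `FALSE_BOUNDARY`;
sites on multi-domain chains are `NEAR` when within `near_tol` residues
(inclusive) of any boundary point, else `AWAY`.

### Feature encoding

Each site is encoded over a `window` of 41 residues centered on it. Per
window position: 21 profile features — the normalized frequencies of the 20
amino acids and the gap character in that MSA column, over the query row
and all hit rows — and 5 indicators for the externally predicted secondary
structure (H/E/C) and solvent accessibility (buried/exposed). We use raw
column frequencies rather than a search profile (PSSM) because the gap
frequency, which carries the domain-architecture signal, has no PSSM
analogue. Appended are the site's residue index divided by 100, its
distance to the C terminus divided by 100, the count of distinct signal
sites within 5 residues (self-inclusive, so an isolated site scores 1),
the chain length divided by 100, and the site's signal-density z-score.
Total: 41 × 26 + 5 = 1071.

Numerical choices: window positions outside the chain contribute all-zero
26-blocks, keeping the dimension fixed and marking out-of-range explicitly
(a zero profile block is impossible for a real column, which sums to 1);
ambiguity codes (B, Z, J, X) are spread uniformly over their member
residues so columns still sum to 1; the density z-score uses the population
standard deviation over all residues of the chain, with a flat profile
(sd = 0) mapped to all zeros rather than NaN. The feature order is frozen
(`feature_names()`), hashed (`feature_schema_hash()`), embedded in every
trained model, and verified at prediction time.

### Two-stage classification

Stage 1 separates `FALSE_BOUNDARY` from `NEAR`/`AWAY` — effectively,
whether the signal came from a single- or multi-domain protein. Stage 2 is
trained only on multi-domain sites and separates `NEAR` from `AWAY`. Both
stages are C-classification SVMs with an RBF kernel, `gamma = 0.015` and
`cost = 1`, fit on unscaled features (the encoding already lives on
commensurate scales, and per-fold feature scaling would make margin scores
incomparable across folds). Scores are signed margin distances, not
probabilities, so a decision threshold swept over roughly −1.5..1.5 is
meaningful. The soft-margin cost is not dictated by the method; we expose
it in `classifier_config()` and keep the common default of 1 with
unweighted classes. The underlying solver's score sign depends on class
ordering, so the trained stage records an orientation flag making positive
scores always favour the positive class.

At prediction time stage 2 is only consulted for stage-1-positive sites: a
stage-1-negative site is called `FALSE_BOUNDARY` and carries no stage-2
score. A protein with at least one stage-1-positive site is called
multi-domain; `NEAR` calls at the threshold become its predicted
boundaries. Raising the threshold can only shrink the `NEAR` set — a
monotonicity the tests assert as set inclusion.

### Evaluation

*Signal coverage* is the fraction of boundary points with a signal site
within 20 residues (inclusive — "within n residues" is read as ≤ n
everywhere). *Site-level precision* at a threshold is the fraction of
`NEAR` calls within 20 residues of a boundary point; *recall* is counted
per boundary, not per site — several calls near one boundary count once —
over boundary points more than 40 residues from both sequence termini (the
termini are taken as the outermost defined residues). An empty prediction
set leaves precision undefined and flagged (`NA`), never silently 0 or 1.
The break-even point is located at the sign change of precision − recall
along the sweep and refined by linear interpolation between the adjacent
thresholds (grid step 0.05 by default); the tests check the interpolation
against a fine-grid brute force. Cross-validation always splits at the
protein level — all sites of a chain stay in one fold — because sites of
one chain share their profile columns and density features, and site-level
splits would leak. Fold assignment is a seeded shuffle with fold sizes
differing by at most one. In the pooled report, stage-2 accuracy is
measured by scoring the true multi-domain sites of held-out folds with
stage 2 directly, since the gated path would conflate stage-1 and stage-2
errors.

## The synthetic generator

`simulate_dataset()` emulates exactly the data regime the extractor is
built for. A chain is 1–3 concatenated domains (lengths uniform on
`domain_length_range`, default 90–160 residues, so even a single domain is
long enough to align and a lost domain is long enough to gap). Residues are
i.i.d. with a per-domain compositional bias — enough to make profile
columns informative without simulating substitution matrices, which the
consumers never look at. Hits are full-length homologs with point
substitutions, or partial homologs covering a contiguous subset of domains
with endpoints jittered by rounded zero-mean Gaussian noise
(`boundary_jitter_sd`), or randomly truncated rows (the source of `AWAY`
and `FALSE_BOUNDARY` signals; truncation points are drawn where a signal is
geometrically possible). Domain subsets are cycled deterministically so
that, with enough partial hits, every boundary flank is exercised. E-values
are rank-assigned by corruption (substitutions + missing residues), making
the e-value ordering of the extractor meaningful. Secondary structure is
loop-enriched and accessibility exposure-enriched within ±3 residues of
true boundaries, mimicking linkers.

The presets fix the study conditions: `easy` (balanced single/multi mix,
jitter sd 1, strong linker enrichment 0.95) is the regime where the
end-to-end pipeline must demonstrably learn — the test suite requires
stage-1 and stage-2 site accuracy ≥ 0.85 and protein-level accuracy ≥ 0.9
under 10-fold cross-validation on 100 chains; `planted` (zero jitter, all
hits boundary-subset partials) guarantees a signal exactly at every
eligible boundary flank, so coverage must be 1.0; `hard` degrades all of
these knobs at once. What the simulator does *not* reproduce: real
phylogenetic correlation between hits, insertions within aligned regions,
discontinuous domains, biased linker compositions, or the noise profile of
real search e-values. Passing on synthetic data therefore demonstrates that
the machinery is correct and that the signal geometry is learnable — not
that real-data accuracies will match.

## Problem sizes and runtime choices

The test suite works at deliberately modest sizes: oracle-equivalence over
1,000 random MSAs of up to 300 residues and 20 hits; learnability on 100
chains (≈ 1,000 sites × 1071 features, 10 SVM fits); everything else on
toys of a few hundred residues. These sizes already exercise every branch
of the extraction, encoding and evaluation logic; the methods scale
linearly in hits × length for extraction and in sites × window for
encoding.

## Known limitations

- The method is signal-bound: a chain with no qualifying homolog rows (too
  short, or no partial homologs found) yields no sites and is necessarily
  called single-domain.
- Only continuous domain ranges are modeled; discontinuous domains are out
  of scope in both labeling and evaluation.
- The search step itself (PSI-BLAST) and the structure predictor are
  consumed as files, never invoked; the default of taking hits from the
  final search iteration (with `iteration =` to override) is a convention,
  not a finding.
- Margin scores are uncalibrated; thresholds transfer between datasets only
  insofar as the feature distributions do.
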