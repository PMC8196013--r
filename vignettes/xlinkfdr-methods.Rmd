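---
title: "Multi-level FDR estimation for crosslinking MS: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level FDR estimation for crosslinking MS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkfdr)
library(dplyr)
```

## The problem

Crosslinking mass spectrometry identifies pairs of covalently linked
peptides from single MS2 spectra. Each crosslink-spectrum match (CSM)
carries *two* peptide identifications, so there are two chances for a
random (false) assignment, and evidence accumulates across four
identification levels: CSMs merge into peptide pairs, peptide pairs into
residue pairs, and residue pairs into protein–protein interactions (PPIs).
Two structural facts make error estimation at the PPI level treacherous:

1. **Self versus heteromeric random spaces.** A link within one protein
   sequence (a self link) is symmetric — a link from residue $i$ to $j$
   is the same observation as $j$ to $i$ — while a link between two
   different proteins is not. Over a database of $N$ proteins the
   heteromeric random space is therefore roughly an order of magnitude
   larger, and a single pooled score threshold funnels random matches
   preferentially into the heteromeric class, the class that defines PPIs.

2. **Asymmetric merging.** True interactions attract repeated, independent
   CSMs; random matches scatter across the enormous space of protein
   pairs and rarely corroborate each other. Merging therefore *shrinks*
   the true class far more than the false class, so an error rate
   controlled at CSM level silently inflates several-fold by the time the
   CSMs have been merged into a PPI list.

`xlinkfdr` implements decoy-based FDR estimation that confronts both
effects, plus the decoy database generator, three decoy-independent error
controls, coelution scoring, and a ground-truth simulator that makes the
whole chain testable.

## The estimator

### Decoy counting

With reversed-sequence decoys in the database, every match is
target–target (TT), target–decoy (TD) or decoy–decoy (DD). A false match
involves at least one random peptide; the decoy classes model the rates of
those random events, giving the crosslink-specific estimate implemented in
`fdr_point()`:

$$\widehat{\mathrm{FDR}} = \frac{TD - DD}{TT}$$

DD is subtracted because matches with *one* random peptide are counted by
TD twice over (either side may be random), while fully random matches
appear in TD and DD both. The estimate is clamped to $[0, 1]$; when
$TD < DD$ — pure estimator noise — it is clamped to 0 rather than reported
negative.

### Curves, q-values and grouping

`build_fdr_curve()` sorts matches by descending score and evaluates the
estimator at every prefix. Score ties are ordered decoys-first, which
over-counts decoys at the boundary and is therefore conservative; the
convention is deliberate because the alternative silently flatters the
results. Prefix FDRs are monotonised into q-values by a running minimum
from the low-score end, so acceptance sets are nested in the threshold.
Self and heteromeric matches are split into separate groups with separate
curves by default (`group_self_separately = TRUE`); switching the grouping
off reproduces the pooled ("naive") estimation that the error-inflation
tests show to be unreliable.

### Aggregation

`merge_to_level()` groups matches by the key of the target level and
combines scores as the root sum of squares,
$s_{\mathrm{higher}} = \sqrt{\sum s_{\mathrm{lower}}^2}$. This composes:
merging CSM → peptide pair → residue pair → PPI gives identical keys and
scores as merging CSMs straight to PPIs, which the test suite asserts.
Decoy class and self flag are part of every grouping key — a decoy protein
pair must survive aggregation as its own record, otherwise nothing is left
to count at PPI level. Unique-CSM keys include the precursor charge by
default (`include_charge`); the strictest common choice, configurable
because search engines disagree. Spectrum-redundant CSMs are collapsed by
`deduplicate_csms()` *before* any estimation: repeated spectra of one
peptide pair are one observation, and counting them repeatedly distorts
both the score distribution and the decoy tallies.

### Cascading

When the deliverable is a PPI list, `apply_fdr(level = "ppi",
cascade = TRUE)` thresholds each lower level at the *same* nominal alpha
on its own curve first, re-merges the survivors, and only then thresholds
the target level. Lower-level filtering removes stray random CSMs that
would otherwise attach to otherwise-genuine aggregates, and the identical
per-level threshold keeps the procedure to a single tunable. Decoy
matches pass through every stage on the same terms as targets — the
cutoffs are score cutoffs, not class-dependent — so the surviving decoys
remain a fair model of the surviving false targets.

### Score normalisation and dataset merging

Score scales are not comparable between search configurations (e.g. two
crosslinker chemistries), so before merging datasets each match score is
replaced by $1 - \mathrm{localFDR}$ (`normalize_scores()`). The local FDR
is the decoy estimate evaluated on a sliding window of the 101
nearest-by-rank matches within the match's group, monotonised to be
non-decreasing as score decreases. The window of 101 ranks is a
bias/variance compromise: wide enough that the three class counts have
usable resolution, narrow enough to stay local; groups smaller than the
window simply use the whole group. `merge_datasets()` then concatenates
the normalised tables, combines records sharing a key across datasets by
root sum of squares of the normalised scores, rebuilds the curve and
thresholds — reproducing the "filter each dataset, normalise, concatenate,
re-filter" protocol used to assemble a final network from two
crosslinkers.

## Decoy database generation

`make_decoy()` reverses each target sequence, then scans the reversed
sequence left to right and swaps every enzyme-specific residue (K/R for
trypsin) at position ≥ 2 with its preceding residue. Reversal destroys
the peptide identities; the swap then restores the cleavage-site
adjacency structure, so decoy tryptic peptides reproduce the target's
peptide-length and mass distribution. The left-to-right scan order is
fixed to make output deterministic for adjacent K/R runs; a leading
enzyme residue on the reversed sequence stays put. Composition, length
and K+R count are preserved exactly, which the suite asserts for 1,000
random proteins.

## Independent error controls

Decoys are a *model* of false matches. Three controls estimate PPI error
without decoys:

* **Entrapment** (`build_entrapment_db()`, `entrapment_error()`): foreign
  proteins are added to the database — one per foreground protein, chosen
  greedily in descending K+R order as the unused candidate with the
  nearest K+R count (ties: nearest length, then accession). Any accepted
  PPI touching an entrapment protein is known false. The observed
  fraction is scaled by the search-space factor
  $(KR_{fg} + KR_{ent})/KR_{ent}$, with K+R content standing in for the
  number of tryptic peptides a partition offers; equal partitions give a
  factor of exactly 2. A globally optimal assignment would change the
  factor negligibly; the greedy rule is deterministic and transparent.
* **Non-crosslinkable pairs** (`best_lower_ibaq()`, `ibaq_threshold()`,
  `classify_plausible()`, `noncrosslinkable_error()`): when crosslinking
  is performed inside SEC fractions, proteins never co-occurring in a
  fraction above the detection limit cannot be crosslinked, so accepted
  pairs of that kind are false. The detection limit is set from the data:
  the 5th percentile (nearest-rank, `ceil(0.05 n)`-th order statistic) of
  the "best lower iBAQ" distribution — per pair, the maximum over
  fractions of the lower of the two iBAQ values — over pairs identified
  at a loose FDR. The K+R factor here is computed over the distinct
  proteins of the plausible versus false interaction sets, a protein
  appearing in both sets counting in both.
* **Wrong crosslinker** (`wrong_crosslinker_error()`): matches assigned to
  a fictional crosslinker of shifted mass are known false; adding it
  doubled the search space, so the observed fraction is scaled by 2. The
  same protein pair matched by the correct and the wrong crosslinker is
  kept as two records.

## Coelution scoring

`correlate_pair()` normalises each profile to its maximum, detects local
maxima (strict; a plateau counts once at its leftmost fraction), forms the
union of fractions within ±3 of any peak of either protein, and computes
Pearson's r over that window when it spans at least 7 fractions. Pairs
with an undersized window or zero variance on either side get an
undefined r and are never called "similar" — mapping degenerate cases to
r = 0 would quietly mix them with genuinely uncorrelated pairs. The ±3
half-width makes a single shared peak produce exactly the minimum 7
fractions; both parameters are configurable. `coelution_support()`
reports the similar fraction at r > 0.5 and the stricter r > 0.8 tier;
`complex_profile()` averages raw member abundances for complex-level
traces.

## The simulator and what it does (not) show

`simulate_proteome()` / `simulate_search_output()` generate the full test
bed: random sequences at ~11% combined K/R density, log-normal abundances
(`abundance_sigma = 1.0` on log10, spanning about six orders of magnitude
across a proteome), true interactions drawn abundance-weighted among
non-entrapment proteins, and elution profiles in which interaction
partners share a Gaussian peak. True CSMs are drawn on the true
interactions and on self links (default 70% self, reflecting the
dominance of self links in real data), with repeated draws giving true
PPIs multi-CSM support. False CSMs pick proteins proportionally to K+R
count, heteromeric with 10:1 weight over self (the random-space ratio is
scenario-dependent in reality; this default mirrors its order of
magnitude), and each false peptide is independently a decoy with
probability 1/2 — so TT:TD:DD is 1:2:1 in expectation and $E[TD - DD]$
equals the number of false TT matches. That identity is the keystone: it
makes the decoy estimate's calibration a testable claim rather than an
assumption. Score distributions are Normal(7, 1.5) for true and
Normal(3.5, 1.5) for false matches, overlapping enough that thresholds
land in a mixed region. Peptides are genuine tryptic peptides of the
simulated sequences, so deduplication, prefilters and residue-level keys
are exercised realistically.

The default scenario (500 proteins, 300 true PPIs, 5,000 true + 5,000
false CSMs) runs in a few seconds per seed; the calibration checks pool
20 seeds. What the simulator does *not* model: spectra and fragment-level
evidence, retention behaviour, modification chemistry, score-abundance
correlations, and protein-level homology. Passing calibration here shows
the estimator machinery is correct under the stated randomness
assumptions; it does not certify any particular real dataset, where those
assumptions (notably decoy representativeness) can be violated. Note also
that thresholding at the dip of a noisy estimate is a mild selection
effect: single runs at a 5% nominal threshold realize errors scattering
roughly between 3% and 7%, for the simulator and for real data alike.

## Numerical and degenerate-input choices

* Prefilters (`filter_csms()`): fragments ≥ 3 *per peptide*, unmodified
  length ≥ 6, delta ≥ 15% of score, single-protein peptides only (a
  target sharing a peptide with its own decoy is bookkeeping, not
  ambiguity), non-covalent-flagged spectra removed. A CSM failing several
  rules is counted under the first failing rule in that order. Setting
  all thresholds to degenerate values returns the input unchanged.
* A missing delta-score column disables the delta rule with a warning —
  engines differ, and failing hard would make the tool unusable on
  otherwise fine output.
* Negative FDR clamps to 0; empty groups give empty curves, not errors;
  all-decoy groups give q = 1.
* All residue coordinates are 1-based; the protein link site is
  `protein_position + link_position - 1`. When a peptide occurs at
  several positions within its single protein, the first listed position
  is used for the residue key.
* Modifications are opaque substrings: they distinguish keys but are
  never interpreted chemically.

## Limitations

Protein grouping/parsimony across shared peptides is out of scope
(ambiguous matches are removed up front). Positional ambiguity of link
sites within a peptide is not scored. The local-FDR window estimator is a
documented choice, not a claim about what any specific external tool
does. The wrong-precursor-mass control requires a search engine re-run
and is represented only by its accounting (`wrong_crosslinker_error()`
covers the analogous wrong-crosslinker case).
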