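---
title: "Methods: rule-based secretome inference in secretr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based secretome inference in secretr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretr)
```

## The problem

Archaea export proteins mainly through the Sec pathway. An exported
preprotein carries an N-terminal signal peptide (SP) with three regions: a
positively charged **n-region**, a hydrophobic **h-region**, and — for
ordinary secreted proteins — a short **c-region** of small, uncharged
residues ending at the cleavage site. Three signal peptidases define three
substrate classes:

* **SPase I** substrates: full n/h/c architecture; the mature protein is
  released after cleavage in the c-region.
* **SPase II** substrates (**lipoproteins**): the cleavage site sits in a
  conserved *lipobox*; the first mature residue is an invariant cysteine
  that receives the lipid anchor. In *Pyrococcus* the motif around the
  site is `[S/A]G / C-I-G-G`.
* **Class III** (prepilin-like) substrates: no c-region; cleavage occurs
  directly after the short basic n-region, at a glycine, and the
  h-region stays in the mature protein.

`secretr` classifies protein N-termini into these classes with explicit,
parameterised rules, predicts the cleavage position, summarises the
resulting secretome, quantifies proteins from replicated MS peptide
evidence via emPAI, and builds cleavage-aligned residue-frequency
matrices. A synthetic-data module generates labelled proteomes and
evidence so that every stage can be validated end to end.

The classifier is calibrated on the N-terminal fragments of the 15
experimentally verified extracellular proteins of *P. furiosus* DSM 3638
bundled with the package (`pfu_secretome_fixture()`): 7 SPase I
substrates, 5 lipoproteins and 3 class III substrates, all reproduced
exactly (class and cleavage position) by the defaults described below.

## The classification rules

All rules operate on a bounded N-terminal prefix (31 residues with
default parameters), which makes the classifier *local* by construction:
residues appended beyond the prefix can never change a call. Rules are
applied in strict precedence — lipobox, then class III, then SPase I —
mirroring the biological argument that a lipobox is the stronger signal
when patterns co-occur (the verified secretome contains one protein whose
N-terminus matches both the class III and the lipobox pattern, and which
is a lipoprotein).

### h-region detection

The h-region is the contiguous stretch that maximises **mean
Kyte–Doolittle hydropathy**, subject to: length at least `h_min_len` (7),
start at or before `h_start_max` (12), and mean at or above
`hydropathy_threshold` (1.0). Ties prefer the longer, then the more
N-terminal stretch. The maximal-mean formulation (rather than a
threshold run over a smoothed profile) keeps the detected core compact:
a smoothed threshold run absorbs trailing alanine-rich c-region residues,
which would push the allowed SPase I candidate region (`h_end + 2`
onward) past genuine cleavage sites. A brute-force search over all
stretches is cheap at this prefix length and is what the unit tests use
as the independent oracle. The windowed profile (window 5) is still
reported for inspection and plotting (`plot_hydropathy()`).

### Lipobox rule

The first position `p` within `lipobox_window` (25) with glycine at `p`,
cysteine at `p + 1`, and `p` at or after the end of a valid h-region is
called a lipobox; cleavage is after `p`. The 25-residue window bounds the
**glycine** (so the anchor cysteine may be residue 26): counted this way
all five verified lipoproteins (glycine positions 18–22) fall inside the
window, and this choice is recorded in `sp_classifier_params()` rather
than hard-coded.

### Class III rule

A glycine at position 4–6 is a class III cleavage site when the residues
between position 2 and the glycine contain no hydrophobic residue
(`{A,V,L,I,F,M,W,C}`) but at least one K/R, and the 8 residues after the
glycine have mean hydropathy at or above the threshold (the retained
h-region). These bounds admit the three verified class III substrates
(glycine at 4, 5, 4) while rejecting every verified SPase I entry (whose
early glycines, if any, are preceded by hydrophobic residues).

### SPase I rule

Candidate cleavage positions `p` lie in `spase1_search_window`
(18–30), carry an allowed −1 residue (`minus1_allowed = {A}`; every
verified site has alanine at −1) and satisfy `p ≥ h_end + 2` (at least
one c-region residue). Each candidate gets a (−3,−1)-style score: +1 for
alanine at −1, +1 for a small/hydrophobic −3 residue
(`{A,V,S,T,G,I,L}`), −1 for a charged residue at −2.

**Site selection.** Among candidates scoring at least `spase1_min_score`
(1), the **most C-terminal** wins; only when no candidate reaches that
score is the best-scoring candidate taken (ties to the larger position).
This is deliberately not plain argmax. On the verified set, plain
argmax-with-largest-tie-break mispredicts one protein whose true site is
preceded by a lysine at −2 (scoring it below an upstream
higher-scoring alanine), while the true site of another protein scores 0
(both −3 = P and −2 = K), which is why a pure score threshold without a
fallback would also fail. The two-stage rule — "take the latest
acceptable site, otherwise the least bad one" — reproduces all seven
verified SPase I sites and is the package's calibrated default.

Finally, an SPase I call requires a net positive N-terminal charge:
`n_charge ≥ 1`, where `n_charge` is #(K,R) − #(D,E) over the predicted
signal peptide. Histidine is excluded from the positivity rule (all
verified n-regions use K/R only) but counted as basic by
`basic_residue_usage()`, whose reported K/R/H shares are composition
statistics, not charge. How exactly an "uncharged" N-terminus should be
windowed is not fixed by the data; the default charge window (the
predicted SP, else the first 30 residues) is exposed in the parameters.

`X` (unknown) residues score 0 hydropathy, carry no charge and never
match a motif.

## MS evidence: filtering and emPAI

`filter_identifications()` implements a two-replicate identification
rule: a protein is accepted when its protein-level probability is ≥ 0.98
and it has at least one unique peptide with peptide probability ≥ 0.95
in **each** of two replicates (all four thresholds are parameters). The
filter is monotone: raising any threshold never adds a protein.

`quantify_proteins()` computes, per accepted protein,

\[
\mathrm{PAI} = \frac{n_\text{observed}}{n_\text{observable}},
\qquad
\mathrm{emPAI} = 10^{\mathrm{PAI}} - 1 ,
\]

where `n_observed` is the number of distinct unique peptide sequences
passing the peptide-probability threshold and `n_observable` comes from
an in-silico tryptic digest (cleavage after K/R, not before proline; the
digest module also enumerates peptides with up to 1 missed cleavage).
**Observable** means: fully cleaved, monoisotopic mass within 600–4000 Da
— the singly/doubly charged image of an m/z 300–2000 survey scan. Since
the exact observable-peptide definition used by any given instrument
pipeline varies, it is exposed in `digest_params()`; the denominator is
floored at 1 so degenerate proteins cannot divide by zero. Modified
residues are out of scope: peptides are matched and weighed unmodified.

## Cleavage-aligned composition

`align_cleavage_windows()` extracts 16 residues up to the cleavage site
and 10 after it, padding with `-` where the SP or the mature fragment is
short; `frequency_matrix()` normalises per position over **non-gap**
residues only (standard logo convention), and reports absolute counts
next to frequencies so count-based statements stay checkable at genome
scale. Dominance ties are broken alphabetically and flagged — the data
offer no principled tie-break.

## The synthetic generator

`generate_proteome()` emits sequences from class templates that mirror
the observed architecture: n-regions drawn K/R-enriched with two K/R
enforced (2–6 residues after the initiator methionine), leucine-dominated
h-regions (8–15 residues), small-residue c-regions ending in alanine
with a preferred −3 residue (3–7), the `[S|A]G-C-I-G-G` lipobox, class
III glycines at position 4–6 followed by a retained hydrophobic run, and
mature/cytoplasmic segments from a fixed average amino-acid composition
table (an embedded documented constant, not fitted to any organism).
SPase I region lengths are resampled until the SP total lies in 18–28
residues, matching both the observed length range and the classifier's
search window. Two deliberate biases reflect real sequences and keep the
ground truth well defined: mature N-termini directly after a cleavage
site are charged/polar and alanine-poor (as in the verified mature
starts), and cytoplasmic N-termini are acidic/polar, so neither
accidentally recreates a signal-peptide architecture. A
`zero_charge_fraction` emits signal peptides with uncharged n-regions to
exercise the charge partition.

`simulate_evidence()` assigns log-normal abundances (secreted proteins
always present; cytoplasmic proteins leak with probability 0.25 at
ten-fold lower median abundance), detects each observable peptide per
replicate with probability
`plogis(detect_slope * (log A - detect_midpoint))`, and draws
peptide/protein probability scores from Beta distributions whose mass
sits mostly above the filter thresholds (so score noise occasionally
rejects genuine peptides, as in real searches). The slope default (1.5)
was calibrated once so that per-peptide detectability spans roughly
0.05–0.95 over ±2 SD of log abundance; with a flatter dependence the
emPAI ranking of the accepted set loses rank resolution at the saturated
top end and the rank-agreement property the generator is designed to
exhibit (Spearman ρ > 0.8 between emPAI and true abundance) becomes
marginal. Uniqueness is computed against the digest of the whole
synthetic proteome.

What the generator does **not** emulate: spectra, retention times,
modification states, realistic search-engine score distributions,
homologous protein families (shared peptides are rare by construction),
or Tat substrates. Passing the recovery tests therefore shows the rules
are implemented self-consistently at the stated noise levels — not that
they would reach the same accuracy on arbitrary real proteomes.

## Validation sizes and numerical choices

The test suite validates: exact reproduction of the 15 verified calls;
the SPase I (24–28) and lipoprotein (18–22) length ranges; the ≥2 K/R
charge rule; emPAI closed forms against direct evaluation; digestion
against brute-force cut-subset enumeration; masses against standard
monoisotopic tables; and, on synthetic data, class-label recovery
≥ 0.95 with exact cleavage recovery ≥ 0.90 on a 1000-protein proteome at
zero noise (misses are logged to the test output), frequency-matrix
normalisation/permutation invariance, filter monotonicity, classifier
determinism and locality, and emPAI–abundance rank agreement
(ρ > 0.8, 200 proteins, 2 replicates). All stochastic checks run under
fixed seeds threaded through the generator configs; the package itself
never touches the global RNG except via those explicit seeds
(`withr::local_seed`).

Remaining numerical conventions: coordinates are 1-based and inclusive,
`cleavage_after` is the last SP residue and the mature protein starts at
`cleavage_after + 1`; reported percentages round half-up to one decimal;
frequency-matrix columns sum to 1 within 1e-9 over non-gap residues.

## Known limitations

* The rules are calibrated on one organism's verified secretome (15
  sequences); on distant archaea the defaults — especially
  `minus1_allowed = {A}` — will be too strict and should be widened via
  `sp_classifier_params()`.
* No HMM or machine-learned scoring, no transmembrane topology, no Tat
  pathway, no Pfam annotation: rule-based classification only.
* h-region boundaries are validated only loosely (leucine-enriched, ends
  before the cleavage site); no machine-readable reference boundaries
  exist for the verified set.
* emPAI is validated at the formula and property level; absolute
  agreement with any particular instrument pipeline's emPAI values is
  not claimed, because observable-peptide definitions differ.
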