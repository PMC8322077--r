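---
title: "Mapping N-terminal ubiquitination from GG-remnant proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping N-terminal ubiquitination from GG-remnant proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggscan)
```

## The problem

Trypsin cleaves ubiquitin after its C-terminal ...LRGG, leaving a diglycine
(GG) stub of +114.0429 Da on the modified residue. For canonical
ubiquitination the stub sits on a lysine side chain (K-ε-GG). For
*N-terminal* ubiquitination — conjugation of ubiquitin to a protein's
α-amino group — the stub sits on the very first residue of the protein's
tryptic N-terminal peptide, so the peptide reads Gly-Gly-X with X the
protein's first residue. UBE2W is the E2 enzyme known to produce this
modification, preferring disordered N-termini.

The analytical difficulty is that a peptide beginning GG-X admits three
explanations of identical mass:

1. the proteome *encodes* GG internally, immediately after a tryptic K/R
   (an R/K-GG-X motif), and trypsin simply exposed it;
2. the GG is a remnant on a lysine side chain (K-ε-GG);
3. the GG is a remnant on the peptide's α-amine — true N-terminal
   ubiquitination, at the initiator Met or at a neo-N-terminus exposed by
   Met-aminopeptidase (MetAP) clipping.

`ggscan` implements the full desk-side analysis that separates these cases
and quantifies condition-dependent changes: in-silico digestion and decoy
databases, monoisotopic mass arithmetic, proteome-aware classification,
target-decoy FDR filtering, TMT/label-free quantitative statistics with
Tukey median polish summarization, substrate calling, and a synthetic-data
generator that makes every stage testable against known truth.

## Classification logic

For each GG-bearing PSM, `classify_gg_psm()` applies, in order:

1. no GG modification → `NO_GG`;
2. GG on a lysine side chain → `K_EPS_GG`;
3. GG on the peptide N-terminus: if any matching target protein encodes
   "GG" immediately before the peptide start, preceded by K or R (or with
   the encoded GG at protein positions 1–2), the remnant is genome-encoded →
   `INTERNAL_ENCODED_GGX`;
4. else if every matching protein is an unreviewed fragment starting with
   the variable residue 'X' (TrEMBL-style entries) → `REJECT_X_START`;
5. else if the peptide begins at a valid N-terminal form →
   `NTERM_UB_INITIATOR_MET` (start 1) or `NTERM_UB_NEO_NTERM` (Met-clipped
   start 2);
6. else `AMBIGUOUS`.

Across multiple matching proteins, an encoded-GG explanation dominates
(conservative: if the peptide *could* be genome-encoded, it is never called
an N-terminal site), then a valid N-terminal match, then `AMBIGUOUS`. The
initiator-Met match is preferred over a neo-N-terminus when both exist. The
dominance order for multi-mapping peptides is a documented package choice;
search engines do not report how such ties were adjudicated.

Neo-N-termini are restricted by default to Met-clipped position 2 with a
MetAP-susceptible second residue — Ala, Cys, Gly, Pro, Ser, Thr or Val. Pro
is kept in the susceptible set as the aminopeptidase rule states, although
Met-Pro N-termini resist N-terminal acetylation; Met-Pro clips are flagged
`met-pro_clip_uncertain` by `enumerate_nterm_forms()`. A permissive mode
(`permissive_nterm = TRUE`) accepts any internal start as a neo-N-terminus
for signal-peptide or proteolysis exploration, but it is off by default
because validated N-terminal sites in this workflow sit almost exclusively
on the initiator Met.

## Digestion and mass model

Digestion cleaves after K/R; cleavage before Pro is suppressed by default
(classical trypsin rule; LysC+trypsin digestion is modelled as one
K/R-specific enzyme since their specificities coincide on lysine). The
protein N-terminus, a *valid* Met-clipped start (initiator Met followed by a
MetAP-susceptible residue), and the protein C-terminus count as tryptic
termini; "semi-tryptic" means exactly one tryptic terminus. A peptide is
excluded once its countable internal K/R sites (Pro-suppressed) exceed
`max_missed` (default 2). The same terminus definitions are used by the
brute-force enumeration oracle in the test suite, so digestion is verified
against an independent implementation on all substrings of random proteins.

Masses are monoisotopic: a 5-decimal residue table, water 18.0105646 Da,
proton 1.0072765 Da, and a modification registry holding the GG remnant
(+114.042927), carbamidomethyl (+57.021464), oxidation (+15.994915) and TMT
(+229.162932); the familiar 4-decimal values are the reporting precision of
these constants. Printed figure-level precursor m/z values are treated as
*observed* measurements and checked to ≤5 ppm rather than digit-for-digit;
b/y fragment complementarity and mass additivity are exact (1e-9 Da) by
construction. N-terminal modifications ride the b-ion series from b₁.

Decoys are full-sequence reversals with a reserved `REV_` accession prefix —
the simplest reproducible construction, preserving residue composition.

## FDR model

PSMs are rescored with a two-class linear discriminant (`MASS::lda`, pooled
within-class covariance) on search score, |precursor ppm error|, peptide
length and missed cleavages; the discriminant axis is oriented so targets
score higher, and a degenerate covariance falls back to the raw search
score with a warning. The published feature set of the original LDA filter
is not recorded anywhere, so these four features are a documented stand-in.

The FDR estimate at threshold t is the plain decoy/target ratio
`#(decoys ≥ t) / #(targets ≥ t)` — no q-value interpolation. Candidate
thresholds are the target scores (the retained set only changes there), and
the smallest threshold whose estimate meets the target is chosen, with ties
at the threshold retained. Peptide-level filtering first collapses to the
best-scoring PSM per peptide (sequence + modification multiset; charge
ignored). The precursor window filter retains signed ppm errors in the
closed, asymmetric interval [−5, +4] ppm.

## Quantitative model

TMT PSMs pass five enumerated filters (decoy; length < 7; isolation
specificity < 50%; reporter intensity < 256; summed reporters < 30,000),
label-free PSMs four (decoy; length < 7; confidence < 71; peak area < 256);
every inequality is strict, so values exactly at a threshold survive, and
each rule's removal count is reported. The "reporter intensity < 256" rule
is applied to the per-channel minimum; this reading of an ambiguous phrase
is configurable (`min_reporter_rule`).

Redundant PSMs collapse by channel-wise maximum per fraction, keeping the
fraction with the maximal summed reporters (TMT), or by per-run maximum
peak area (LFQ). Label-free matrices are completed by match-between-runs:
anchors are identified peptides, runs are aligned by a per-run median RT
shift (the simplest monotone correction), and a feature qualifies within
±10 ppm of the theoretical precursor m/z and ±2 min of the expected RT; the
maximum-area feature is transferred and anything else stays missing.
Missing values are never imputed.

Peptide forms summarize to one protein N-terminal site by Tukey median
polish (`stats::medpolish`, tolerance 0.01, ≤10 iterations, NAs ignored);
the per-sample abundance is overall + column effect, and the additive
reconstruction is exact at observed cells. Site identity is the
(accession, site-kind) pair, so fully and semi-tryptic forms of one site
collapse into one feature, as substrate counting works at the protein
level.

Differential abundance uses a per-feature one-way fixed-effects layout on
log2 abundances: the contrast estimate is a difference of condition means,
its standard error uses the variance pooled across *all* observed
conditions, and the two-sided p-value uses the t distribution at the
feature's residual degrees of freedom — in a balanced two-condition design
this is exactly the classical pooled t-test, and it is what a mixed-effects
formulation degenerates to in a single-run design with no technical-replicate
term. Declaring a `batch` column in the design adds an additive batch term
via `stats::lm`. An optional method-of-moments variance moderation
(inverse-chi-square prior toward the cross-feature mean) exists but is off
by default; the full empirical-Bayes machinery of the MSstats family is out
of scope. A contrast needs ≥2 observations in each of its two conditions,
otherwise the feature is flagged missing and excluded from the
Benjamini–Hochberg adjustment, which is applied per contrast across
features (`stats::p.adjust`).

Substrate gates are strict: a feature passes a contrast iff log2FC > 1
*and* p < 0.05 (raw model p by default — matching how volcano cutoffs are
drawn — with the BH-adjusted value always carried alongside), and is
high-confidence iff it passes both informative contrasts, UBE2W−Control and
Combo−RNF4. Sequence preference profiling reports the X-position residue
frequencies and a pseudocount-smoothed (0.5) position-probability matrix
with information content `log2(20) − H` bits against a uniform 20-residue
background.

## What the synthetic generator emulates

`generate_proteome()` draws random sequences at uniform residue frequencies
(a configurable table could replace this; uniformity keeps motif statistics
transparent), plants internal R/K-GG-X motifs at recorded positions in 10%
of proteins, emits 5% as 'X'-start unreviewed fragments, starts everything
else with Met, and *scrubs* chance [K/R]GG motifs so the planted set is the
complete truth. `generate_experiment()` then emits the study-shaped design —
Control/UBE2W/RNF4/Combo with 3/3/2/3 replicates, i.e. an 11-channel TMT
layout — with:

* N-terminal GG PSMs for substrates (planted log2 effects, default drawn
  from {1, 2}, added in the UBE2W-expressing conditions) and for null
  N-terminal features (no effect); a third of features carry a second,
  semi-tryptic peptide form;
* condition-invariant internal-GGX and K-ε-GG PSMs;
* noise matches: decoy PSMs *and an equal number of incorrect-target PSMs*
  (unmodified internal peptides), both drawn from the lower of two unit-SD
  score Gaussians separated by 2.5. Pairing decoys with incorrect targets
  is what makes the decoy-based FDR estimate track the realized
  false-discovery proportion; the default noise share (60 pairs against
  roughly 360 correct PSMs, ~15% of target PSMs) reflects reasonably clean
  search output from an enriched sample.
* Noise is Normal on the log2 scale (log-normal abundances), σ = 0.25 by
  default, matching the additive linear model downstream. LFQ mode spreads
  PSMs over 11 runs with a per-run RT shift and a 15% identification
  dropout, plus an MS1 feature table, so match-between-runs is genuinely
  exercised.

All randomness flows through one seed (Mersenne-Twister, inversion normals,
rejection sampling discipline), with the caller's RNG state restored.

What the generator does **not** emulate: real proteome residue composition
and homology (multi-mapping peptides are vanishingly rare here but common
in human data), spectra and search-engine score idiosyncrasies, reporter
ion isotope impurity and ratio compression, chromatographic peak shape, and
shared peptides between isoforms. Passing tests therefore demonstrate
correctness of the pipeline's logic under its own statistical assumptions,
not performance on real LC-MS data.

## Validation posture and known limitations

Problem sizes in the test suite are chosen to keep the whole suite fast
while leaving no stage untested: 500-protein proteomes for end-to-end runs,
5,000 PSMs for FDR calibration, 10,000 features for type-I error, brute
force digestion oracles on proteins of ≤40 residues.

One validation target is structurally out of reach and intentionally left
failing rather than papered over: end-to-end sensitivity ≥0.9 under the
default regime with planted effects {1, 2}. A substrate whose true effect
is exactly 1.0 sits *on* the strict log2FC > 1 gate; an unbiased estimator
exceeds the gate with probability ~0.5 per contrast, and the two informative
contrasts use disjoint condition pairs, so such substrates are called at
~25% and overall sensitivity settles near 0.6 regardless of noise level or
replicate count. Substrates planted at effect 2 are recovered at ≥90% with
a false-call fraction of 0–5%, which is the meaningful power statement; the
boundary behaviour is asserted in its own right (a noiseless effect-1
feature is *not* called).

Other limitations: no site-localization scoring; no distinction of Ub from
NEDD8/ISG15 remnants (needs longer LysC remnants); no isotope envelopes or
neutral losses; protein inference is by exact substring mapping; the
permissive neo-N-terminus mode can over-call in repetitive sequence.
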