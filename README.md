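# ggscan — N-terminal ubiquitination discovery from GG-remnant proteomics

Trypsin digestion of a ubiquitinated protein leaves a diglycine (GG) stub of
+114.0429 Da on the modified residue. Canonically that stub sits on a lysine
side chain (K-ε-GG); for **N-terminal ubiquitination** — conjugation of
ubiquitin's Gly76 to a substrate's α-amino group, the modification written
by the E2 enzyme UBE2W — it sits on the first residue of the protein's
tryptic N-terminal peptide, which then reads Gly-Gly-X. A GG-X peptide,
however, has three mass-identical explanations: a genome-encoded internal
R/K-GG-X motif exposed by trypsin, a K-ε-GG remnant, or genuine N-terminal
ubiquitination at the initiator Met or a Met-aminopeptidase neo-N-terminus.

`ggscan` is the analysis side of a GG-remnant immunoaffinity-enrichment
proteomics workflow, for proteomics analysts working from PSM tables:

* **proteolysis** — UniProt-dialect FASTA I/O, tryptic/semi-tryptic
  digestion with Pro-suppressed cleavage, N-terminal form enumeration under
  the MetAP rule (clipping before A, C, G, P, S, T, V), reversed-decoy
  databases;
* **mass arithmetic** — monoisotopic peptide masses, precursor m/z, b/y
  fragment series, signed ppm errors, a modification registry (GG
  +114.0429, carbamidomethyl +57.0215, oxidation +15.9949, TMT +229.1629);
* **classification** — the verdict for every GG-bearing PSM against the
  proteome: `NTERM_UB_INITIATOR_MET`, `NTERM_UB_NEO_NTERM`,
  `INTERNAL_ENCODED_GGX`, `K_EPS_GG`, `REJECT_X_START` ('X'-start TrEMBL
  fragments), `AMBIGUOUS`, `NO_GG`;
* **FDR** — LDA target-decoy rescoring, peptide/protein-level decoy FDR,
  the asymmetric [−5, +4] ppm precursor window;
* **quantitative statistics** — the enumerated TMT and label-free PSM
  filters, redundancy collapse, match-between-runs (±10 ppm, ±2 min), Tukey
  median polish summarization to protein N-terminal sites, per-feature
  linear-model contrasts with Benjamini–Hochberg adjustment;
* **substrate calling** — strict log2FC > 1 and p < 0.05 gates per
  contrast, high-confidence calls across UBE2W−Control *and* Combo−RNF4,
  Venn intersections across experiments, X-position profiles, sequence-logo
  matrices, MetAP-compatibility annotation;
* **synthetic data** — a seeded generator producing the full study shape
  (proteome with planted motifs and 'X'-start fragments; TMT or LFQ PSM
  tables over a Control/UBE2W/RNF4/Combo, 3/3/2/3-replicate design) with
  known ground truth, plus recovery metrics.

## Worked example

```r
library(ggscan)

# Theoretical [M+3H]3+ of the GG-modified S11IP N-terminal peptide
precursor_mz(peptide_mass("MFGSAPQRPVAMTTAQR", "gg@0"), 3)
#> [1] 654.9927            # printed observed value: 654.9938 (-1.6 ppm)

# A GG peptide that the genome already encodes is never an N-terminal site
proteome <- read_proteome_fasta("proteome.fasta")   # ...K GG MLTNAR...
classify_gg_psm("MLTNAR", "gg@0", proteome)
#> $verdict   [1] "INTERNAL_ENCODED_GGX"
#> $accession [1] "INTHOST"
#> $start     [1] 10
#> $encoded_gg [1] TRUE

# End-to-end on synthetic data with known truth (TMT, 11 channels)
sim <- simulate_experiment(seed = 11, mode = "tmt", n_proteins = 300,
                           n_substrates = 20, n_null_nterm = 80,
                           n_keps = 15, n_decoy_psms = 30, effect_levels = 2)
res <- run_pipeline(sim$psms, sim$proteome, sim$design, mode = "tmt",
                    truth = sim$truth)
#> peptide FDR <= 0.03 (achieved 0.025): 160 PSMs retained
#> classification: INTERNAL_ENCODED_GGX=21, K_EPS_GG=14, NO_GG=5,
#>   NTERM_UB_INITIATOR_MET=103, NTERM_UB_NEO_NTERM=11, REJECT_X_START=6
#> median-polish summarization: 97 features x 11 samples
#> substrate calls: 20 high-confidence of 97 features
#> recovery: sensitivity 1.000, false-call 0.000, RMSE 0.147

head(res$x_profile, 3)
#>   residue count fraction
#> 8       M   103    0.763     # X-position preference: mostly Met starts
#> 1       A     5    0.037
#> 2       C     4    0.030
```

All 20 substrates planted at log2FC 2 are recovered with no false calls
among the 80 null N-terminal features; the log2FC estimates have RMSE 0.147
against the planted effects at σ = 0.25 and 3 replicates.

A thin command-line wrapper over the same functions lives at
`inst/cli/ggscan.R`:

```sh
Rscript inst/cli/ggscan.R run --seed 7 --mode tmt --out outdir
```

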