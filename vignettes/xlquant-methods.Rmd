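---
title: "Methods: quantitative cross-linking MS with isobaric reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative cross-linking MS with isobaric reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlquant)
```

## The model

`xlquant` quantifies cross-linked residue pairs across multiplexed samples.
Each MS2 spectrum of a TMTpro-labeled cross-linked peptide carries 18
low-mass reporter ions; their intensities are the per-sample measurements.
The processing chain is deliberately simple and fully deterministic:

* **Reporter matching.** A peak matches channel $c$ when
  $|m/z - r_c| / r_c \times 10^6 \le \tau$ with $\tau$ the ppm tolerance
  (default 15, boundary inclusive). Several peaks inside one window are
  summed; the reported $\Delta m/z$ is the most intense peak's. Peaks are
  assigned to their *nearest* channel only, so no peak is ever counted
  twice — a situation that can only arise at tolerances above ~20 ppm,
  which is why such tolerances trigger a warning (they exceed half the
  6.32 mDa spacing of N/C isotopologue pairs).
* **Aggregation.** CSM intensities are summed channel-wise per canonical
  residue pair. Cross-links and loop-links spanning $\ge 5$ residues
  contribute; short loops (bridging near-neighbour lysines, structurally
  uninformative), monolinks, regular peptides and shared-peptide links do
  not.
* **Normalization.** Sample totals are equalized to the maximum total
  ($f_s = T_s / \max_t T_t$, $v' = v/f_s$); rows are scaled to their mean
  and log2-transformed, so every retained row has linear-scale mean exactly
  1. Replicate CV (SD/mean × 100, $n-1$ SD) is computed on the normalized
  *pre-log* values.
* **Regression.** Per intralink, OLS with intercept of the cross-link
  profile on its protein's abundance profile (normalized identically). The
  residuals are the net cross-linking differences; by construction they sum
  to zero and are orthogonal to the predictor.
* **Event selection.** For cell lines carrying a missense mutation inside
  the closed cross-link interval, an event requires $|r| > 0.4$ **and**
  $|r| > 2\,\mathrm{SD}$ of that pair's residuals across all cell lines,
  discretized to $\pm 1$.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `tol_ppm` | 15 | ppm | reporter window; > 20 ppm risks merging adjacent channels |
| `loop_min` | 5 | amino acids | loop-links at or above this span behave like cross-links |
| `constraint` | 20 | Å | expected maximum Cα–Cα span of the cross-linker |
| `lfc_cut` | 0.4 | log2 | minimum regressed effect size for an event |
| `sd_mult` | 2 | — | effect must exceed 2 × the pair's cross-line dispersion |
| `min_intralinks` | 6 | links | minimum mappable intralinks before a protein is profiled |

## Design choices where the design was open

* **Loop distance** is the absolute difference of the 1-based linked sites
  (adjacent lysines → 1), the reading under which the ≥ 5 threshold is
  well-defined.
* **Channel-total ("beta") normalization** of the extraction table
  implements $f_c = T_c/\max T$, value $= \mathrm{raw}/f_c$. It assumes
  equal total signal per channel and is therefore **off by default**
  (wrong for fractionated or intentionally unbalanced designs).
* **Zero intensities.** Rows containing any zero are excluded from the
  log2 stage (complete case) and counted. A pseudo-count would silently
  alter ratios; downstream comparisons assume profiles with no missing
  values.
* **Multi-peak delta.** When summed peaks share a channel, the reported
  $\Delta m/z$ is that of the most intense peak — the table has one delta
  column per channel and the most intense peak dominates the sum.
* **Tie at 20 Å.** A protein whose mean intralink distance is exactly
  20 Å is classed "longer" (strict `<` for "shorter"), following the
  printed inequalities; exact ties are measure-zero.
* **Event averaging.** Replicate channels are averaged to cell-line level
  *before* the thresholds (switchable via `average_replicates`); the SD is
  taken across all cell lines, not only mutated ones.
* **Decoy shuffle.** Entrapment decoys are unconstrained seeded
  permutations (length and residue multiset preserved exactly);
  tryptic-terminus preservation is available but off by default.
* **Title matching** defaults to exact string equality after whitespace
  trimming; the `"scan"` rule reduces `file.scan.scan.charge(.ext).dta`
  titles to `file.scan.charge` for converters that disagree on decorations.
* **Reporter reference.** The TMTpro 18-plex m/z values are computed from
  the reporter ion's elemental composition (C8H16N+, 126.127726 Th) plus
  exact ¹³C/¹⁵N mass differences rather than hard-coded; any plex can be
  supplied as a two-column table.
* **Intra/inter classification of shared-peptide CSMs** uses the first
  listed accession pair but flags the link, which removes it from both
  residue-pair quantification and the external-FDR input.

## The synthetic world

`simulate_bundle()` emulates the study design the package targets: 18
TMTpro channels covering 14 cell lines, the first four in technical
duplicate; ~9% of cross-links interprotein; loop spans split between short
(1–4) and long (5–25) residues; reporter noise multiplicative lognormal
with log2-SD 0.15 (≈ 10–11% CV, comfortably inside the ≤ 15% replicate-CV
regime expected of the workflow); per-protein, per-cell-line abundance
effects (SD 0.5 log2) shared between a protein's cross-links and the
protein matrix, so regression can remove them; peptide precursor masses
follow the cross-linker arithmetic of `phox_crosslinker()` (+209.972 Da
bridge, +227.982 Da hydrolyzed dead-end, TMTpro +304.207146 Da at
N-terminus and lysines, carbamidomethyl-C +57.021464 Da).

What it does **not** emulate: fragment-ion ladders (spectra contain only
reporter ions plus random high-mass noise), retention time, isotopic
impurity, missed cleavage statistics, search-engine score distributions,
or co-isolation interference. A green end-to-end test therefore
establishes bookkeeping correctness — extraction, mapping, aggregation,
normalization, regression and selection arithmetic — not robustness to
real acquisition artifacts.

## Numerical notes

* Peak lists are sorted on read; matching uses a binary
  search (`findInterval`) whose results are asserted equal to a
  brute-force linear scan in the tests.
* The inclusive ppm boundary carries a $10^{-9}$ relative slack so that a
  peak constructed *at* the boundary ($r_c (1 \pm \tau\,10^{-6})$) is not
  lost to floating-point rounding of the product.
* All files the package writes use fixed decimal formatting, so identical
  inputs and seeds give byte-identical outputs; all seeded randomness is
  evaluated under a saved-and-restored RNG state.
* Sample SD ($n-1$) is used throughout; with duplicate channels the SD
  estimator of a pair is noisy, which is why the Monte-Carlo CV check uses
  four replicates (with $n=2$ the estimator's *median* sits near 0.67 of
  the true CV — an estimator property, not a pipeline defect).
* Degenerate inputs: zero-total samples are errors naming the sample;
  zero-variance regression predictors fall back to the intercept-only
  model with a warning; sites absent from a structure model yield an
  explicit `NA` ("unmappable"), never a silent skip.

## Known limitations

* Only the PDB flavour of model files is parsed (CA atoms, pLDDT in the
  B-factor column); mmCIF is not supported.
* Accessions must not contain `-` or `;`, which the hierarchical CSV
  dialect uses as side and alternative separators.
* No isotopic impurity correction, MS3 quantification, imputation, batch
  correction across plexes, or multiple-testing correction of events (the
  thresholds are the selection rule; this is documented rather than
  silently added).
* PPI-level FDR is delegated to external tooling; the package only
  guarantees a well-formed CSM input with decoy flags.
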