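---
title: "Hit calling in arrayed siRNA high-content screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hit calling in arrayed siRNA high-content screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
library(dplyr)
```

## The experiment this package models

In an arrayed RNAi high-content screen, two genome-scale siRNA libraries
(here sized 9,102 and 12,162 genes, three independent siRNAs per gene, one
siRNA per well) are printed on 384-well plates. Cells are seeded (about 600
per well), knocked down for two days, then transduced with a GFP reporter
virus — in the motivating application, an AAV2 vector — and imaged a day
later in two channels: Hoechst-stained nuclei and the GFP reporter. Per
well, automated image analysis yields a cell count and a mean per-cell
reporter intensity. Genes whose knockdown *raises* the reporter are
candidate host-cell restriction factors (HRF); genes whose knockdown
*lowers* it are dependency factors (HDF).

`hcscreen` implements the downstream computation as a reusable, tested
pipeline — image quantification, quality filtering, normalization, gene
scoring and hit calling — plus a synthetic screen generator that lets every
statistical property of the pipeline be checked against a known ground
truth, and a scanner for the SUMOylation consensus motif in capsid protein
sequences used when interpreting such screens.

## The statistical model

Let $I_{pw}$ be the raw mean reporter intensity of well $w$ on plate $p$.
The pipeline assumes a lognormal well model with multiplicative plate
effects:

$$\log I_{pw} = \mu + \beta_{g(w)} + \log f_p + \varepsilon_{pw},
  \qquad \varepsilon_{pw} \sim N(0, \sigma^2),$$

where $\beta_g$ is the knockdown effect of the gene targeted in the well
($\beta > 0$ for restriction factors), and $f_p > 0$ is a plate effect
(staining, exposure, transfection batch). The stages are:

1. **Log transform** (`log_transform()`): natural log of intensity. The
   pseudocount defaults to 0 so that a multiplicative plate effect is an
   exact additive shift on the log scale; wells with zero intensity are
   flagged excluded rather than mapped to $-\infty$. (A nonzero pseudocount
   is available, but it breaks the exactness of plate-scale invariance, so
   it is not the default.)
2. **Cytotoxicity filter** (`filter_cytotoxic()`): the wells in the lowest
   5% of cell counts — screen-wide, not per plate — are excluded, removing
   wells where the siRNA killed the cells and the reporter readout is
   meaningless. Exactly $\lfloor 0.05\,N \rfloor$ wells are removed; ties
   break lexicographically by plate and well so the excluded set is
   deterministic. A per-plate mode exists for screens with strong
   plate-to-plate density differences.
3. **Robust plate normalization** (`normalize_plates()`): per plate and
   replicate, $z_{pw} = (\log I_{pw} - \mathrm{med}_p) / (1.4826 \cdot
   \mathrm{MAD}_p)$, with both statistics computed over that plate's
   included siRNA (non-control) wells. Median/MAD is used instead of
   mean/SD so the hit wells themselves do not inflate the scale. Because
   the statistics are per plate on the log scale, $f_p$ cancels exactly.
4. **Gene scores** (`gene_zscores()`): a gene's wells — all siRNAs, both
   replicates, up to 6 wells — are pooled:
   $z_g = \overline{z}_{w \in g}\,\sqrt{n_g}$. Under the null
   (independent standard-normal well z-scores) $z_g$ is standard normal for
   any $n_g$, so a fixed threshold has the same tail probability for genes
   with different numbers of surviving wells.
5. **Hit calling** (`call_hits()`): HRF if $z_g > 1.7$, HDF if
   $z_g < -1.7$, strict inequalities. The one-sided normal tail at 1.7 is
   `tail_probability(1.7)` $= 0.0446 < 0.05$, which is what makes the
   conventional 1.7 cutoff a $p < 0.05$ rule. HRFs are ranked by
   decreasing $z$, HDFs by increasing $z$, ties broken by gene symbol so
   output files are reproducible byte for byte.

Two design points were genuinely open and are worth stating. First, the
per-gene statistic: we pool all of a gene's wells into one
$\text{mean}\times\sqrt{n}$ score rather than scoring replicates separately
and averaging, because pooling maximizes $n$ and keeps the null
distribution exactly standard normal; a median-based gene score was
rejected because its null calibration depends on $n$ in an opaque way.
Second, the cytotoxicity cut is applied screen-wide by default (the
per-plate alternative is a flag), since the 5% convention refers to the
distribution of cell counts over the whole screen.

No multiple-testing correction is applied beyond the fixed threshold: the
screen convention is a ranking device, and validation happens in follow-up
assays.

## The synthetic screen generator

`simulate_screen()` draws data exactly from the model above, so it is the
ground truth against which the pipeline is tested, not a simplification of
it. Its defaults are the study conditions:

| parameter | default | why |
|---|---|---|
| `sirnas_per_gene` | 3 | library design: three independent siRNAs per gene |
| `replicates` | 2 | the screen is run in duplicate |
| `cells_per_well_mean` | 600 | seeding density; counts are Poisson around it |
| `log_noise_sd` | 1 | effects are expressed in well-noise SD units |
| `baseline_log_intensity` | 6 | arbitrary intensity units (~400 counts) |
| `plate_factor_sdlog` | 0.3 | plate effects spanning roughly ±2-fold |
| `toxic_fraction` | 0.02 | a small fraction of siRNAs are cytotoxic |
| toxic cell-count factor | 0.1 | cytotoxic wells retain ~10% of cells |
| `controls_per_plate` | 16 | enough scrambled wells for stable plate QC |

Cytotoxicity is tied to specific siRNAs (not random wells), matching how
off-target toxicity behaves; toxic wells draw cell counts from a mean
depressed to 10%. The generator does **not** emulate spatial (row/column)
plate gradients, cell-cycle heterogeneity, siRNA off-target intensity
effects, or correlated noise between neighbouring wells — so a green test
suite shows the pipeline is correct *under its stated model*, not that the
model captures every artefact of a real screen (a B-score-style positional
polish, for instance, is deliberately out of scope).

```{r simulate}
cfg <- screen_config(n_genes_lib1 = 2000, n_genes_lib2 = 0, seed = 1)
scr <- simulate_screen(cfg, n_hrf = 50, effect_size = 3)
res <- run_screen_pipeline(scr$wells)
glance(res)
```

```{r recovery}
planted <- filter(scr$truth$gene_effects, effect > 0)$gene
called <- filter(tidy(res), hit_class == "HRF")$gene
mean(planted %in% called)
```

With 50 genes planted at $+3\sigma$ among 2,000, recovery is essentially
complete: a $+3\sigma$ effect over 6 pooled wells has expected gene score
$3\sqrt{6} \approx 7.3$, far beyond the 1.7 threshold. With no planted
effects, the fraction of genes with $|z| > 1.7$ sits near the theoretical
$2(1-\Phi(1.7)) \approx 8.9\%$; the test suite checks this over five seeds
against the 99% binomial interval. The z distribution is the standard
screen display:

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(res)
```

## Image quantification

The well images of a high-content screen are reduced to (cell count, mean
reporter intensity) pairs. The published analyses of such screens rely on
bespoke in-house methods; here the contract is re-specified as a standard,
deterministic chain built on EBImage: Gaussian smoothing → global Otsu
threshold → connected components → area filter → optional
distance-transform watershed for touching nuclei (`segment_nuclei()`).
The reporter readout (`quantify_reporter()`) is the mean channel-2
intensity over each nuclear footprint — there is no cytoplasm channel, so
nuclear footprints stand in for cells — and the well value is the mean of
per-cell means. Wells with zero segmented nuclei are flagged
`qc_excluded` rather than given intensity 0, to avoid fabricating a low
signal; `quantify_plate()` applies the same rule to missing images.

`render_well_image()` draws the matching synthetic fixtures: circular
nuclei placed without overlap, uniform per-cell reporter values
(Gamma-distributed across cells, CV 0.2), additive Gaussian background.
Disk blobs are sufficient to exercise the segmentation and quantification
contracts; they make no attempt at realistic chromatin texture, debris, or
clumping, so segmentation accuracy on fixtures (100% on non-overlapping
blobs) is a statement about the code path, not about biological images.

## Motif scanning

The SUMOylation consensus acceptor motif is $\Psi$-K-X-(D/E) with $\Psi$
hydrophobic. `scan_consensus()` reports every acceptor lysine (1-based
position of the K), all overlapping matches, with `X` never satisfying a
residue class. The hydrophobic alphabet is configurable: the default
preset is {A, I, L, M, F, P, V}; a stricter {V, I, L, M, F, P} preset
excludes alanine, and any custom alphabet can be passed — published
site-prediction tools draw this boundary differently, and alanine is the
most common point of disagreement.

Coordinates are 1-based over VP1 for capsid proteins. The package bundles
a synthetic offline reconstruction of the canonical 735-residue AAV2 VP1
(`inst/extdata/aav2_vp1_synthetic.fasta`; landmark-checked at the VP3
start M203 and the heparin-binding residues R585/R588, but not a database
download). On this sequence the serotype-conserved candidate acceptor
lysine near position 527/528 sits in an S-H-**K**-D-D context: the −1
residue is histidine, so the *strict* hydrophobic consensus does not fire
there, and the site is only recovered when the hydrophobicity requirement
is dropped. This is expected: graphical serotype comparisons of candidate
sites come from statistical predictors whose scoring models (and their
inverted-consensus and SUMO-interaction-motif classes) are beyond a pure
consensus scan and deliberately out of scope here. The test suite records
both facts — the strict scanner's behaviour and the relaxed-alphabet
recovery of K527.

```{r motif}
scan_consensus("AVKTE")
fasta <- system.file("extdata", "aav2_vp1_synthetic.fasta",
                     package = "hcscreen")
scan_fasta(fasta)
```

## Validation fold changes

Follow-up assays (flow cytometry MFI, luciferase RLU) are reported
relative to a scrambled negative-control siRNA set to 100. `fold_change()`
implements that convention replicate-by-replicate: each readout is scaled
by the control mean *of its own replicate experiment*, then per-condition
means and SDs are taken across replicates, so the control maps to exactly
100 and day-to-day instrument scale drops out.

```{r fold}
assay <- tibble::tibble(
  condition = rep(c("scrambled", "UBE2I_kd"), 3),
  replicate = rep(1:3, each = 2),
  readout   = c(1000, 3100, 820, 2700, 1190, 3900)
)
fold_change(assay, "scrambled")
```

## Numerical choices and degenerate inputs

* Plate statistics use `median` and `stats::mad` (constant 1.4826); a
  plate-replicate with MAD 0, or with fewer than 8 usable siRNA wells, is
  excluded entirely with a classed warning rather than scored.
* The cytotoxicity cut takes `floor(p/100 * N)` wells; ties in cell count
  break by (plate, well, replicate) lexicographic order.
* A gene whose wells are all excluded is omitted from the score table with
  a warning, never scored 0.
* Hit ranking ties break by gene symbol; result files are written with
  fixed float formats (4 decimals in the score table, 2 in hit lists) and
  fully sorted rows, so identical runs are byte-identical.
* All simulation entry points take integer seeds and restore the caller's
  RNG state.

## Scale of the shipped checks

The test suite exercises the pipeline at 2,000 genes (one plate set of
~34 plate-replicates, ~12,500 wells) for calibration and power checks,
five seeds each; segmentation accuracy uses 200 rendered 192×192 fixtures;
the motif scanner is compared against an independent regular-expression
oracle on 1,000 random proteins up to 2,000 residues. These sizes were
chosen as the smallest at which the binomial calibration intervals are
informative; the full 21,264-gene layout is exercised for its arithmetic
(63,792 siRNA wells per replicate) without simulating intensities.

## Known limitations

* The pipeline scores mean reporter intensity only; a %-positive readout
  is a trivial extension of `quantify_reporter()` but is not the primary
  statistic.
* No positional (row/column) normalization, no multiple-testing
  correction, no replicate-concordance score: the scope is the
  fixed-threshold z-score convention.
* The image module assumes co-registered channels and nuclear footprints
  as the per-cell region; there is no illumination correction or
  cytoplasm segmentation.
* The motif scanner is a consensus scan, not a trained site predictor; it
  will not reproduce predictor-specific sites that deviate from the
  strict consensus (the AAV2 K527/528 case above is exactly such a site).
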