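---
title: "Quantifying barcoded promoter screens: model, scores, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying barcoded promoter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoscreen)
```

## The assay and its model

A barcoded promoter screen packages each candidate promoter in front of a
common reporter cassette carrying a unique 15-nt barcode in the 3' UTR,
pools equal vector-genome amounts of all constructs, and delivers the pool
systemically. Two weeks later, each tissue yields two barcode count
vectors: one from genomic DNA (how many vector genomes of each construct
arrived) and one from reverse-transcribed mRNA (how much each construct
transcribed). Because every construct shares the same capsid, the gDNA
barcode proportions reflect the injected pool, while the cDNA proportions
additionally carry the promoter activities.

The quantity of interest for promoter $\alpha$ in tissue $\beta$ is

$$R_{\alpha\beta} \;=\; \frac{P_{\alpha\beta}(\mathrm{cDNA})}{P_{\alpha\beta}(\mathrm{gDNA})}\; C_\beta,$$

where the $P$ are within-sample barcode proportions and $C_\beta$ is the
tissue's bulk reporter expression measured by qPCR as $2^{-\Delta C_t}$
against a housekeeper. The proportion ratio removes delivery differences
between constructs; $C_\beta$ restores the tissue's absolute expression
scale, which proportions alone cannot carry.

$R_{\alpha\beta}$ is read out through two complementary rescalings:

* **Efficiency** $E_{\alpha\beta} = 100\, R_{\alpha\beta} / \sum_\alpha
  R_{\alpha\beta}$ answers "which promoter is strongest in this tissue".
  Within a tissue, $C_\beta$ cancels, so efficiency is robust to the bulk
  measurement; it sums to 100 over promoters per tissue per animal.
* **Specificity** $S_{\alpha\beta} = 100\, R_{\alpha\beta} / \sum_\beta
  R_{\alpha\beta}$ answers "where does this promoter act". Here $C_\beta$
  matters — it is what weighs tissues against each other — and the score
  sums to 100 over tissues per promoter per animal.

The model's key assumptions: transcription is proportional to delivered
genome copies (so the ratio of proportions is meaningful), barcodes do not
affect expression or packaging, and the bulk measurement $C_\beta$ is a
valid scale for the whole tissue. Promoter interference (competition for
transcription factors in co-transduced cells) is assumed negligible; the
single-vector validation path exists precisely to check that assumption on
selected candidates.

### Single-vector validation

For individually injected constructs there are no competing barcodes, so
normalization uses absolute measurements instead:
$C_{\alpha\beta} = 2^{-\Delta C_t}$ from qPCR and
$G_{\alpha\beta} = \text{reporter copies} / (\text{Rpp30 copies}/2)$ from
ddPCR (Rpp30 is autosomal and diploid, hence the division by two), giving
$Q_{\alpha\beta} = C_{\alpha\beta}/G_{\alpha\beta}$ — expression per
delivered vector copy. Scores are computed from $Q$ exactly as from $R$,
with one asymmetry mirroring how such cohorts are measured: specificity is
computed per animal (each animal carries one construct across all
tissues), while efficiency compares constructs within a tissue and
therefore uses $Q^*_{\alpha\beta}$, the mean across each construct's
replicate animals.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_reads` (per-sample floor) | 1000 | assigned reads | below this, proportions are too noisy to use; the sample is flagged failed and excluded |
| `gdna_floor` | 10 | gDNA reads / promoter / sample | the gDNA proportion is a denominator; below ~10 reads the ratio is explosive, so the cell is masked |
| `max_anchor_mismatch` | 1 | substitutions per anchor | tolerates sequencer error in the constant regions without admitting spurious placements |
| `max_bc_mismatch` | 1 | substitutions | one error in a 15-mer is common at typical error rates; two would start bridging barcodes unless the set's minimum distance is large |
| qPCR duplicate window | 1 | cycles | duplicates further apart are flagged (but still averaged); 1 cycle = a factor of 2 |

Masking is the **only** zero-handling mechanism: no pseudocounts are added
anywhere, because a pseudocount in a ratio of proportions biases exactly
the low-coverage cells it pretends to rescue. Masked cells are excluded
from all score sums and from replicate aggregation (each aggregated cell
records its own $n$).

Scores are computed per animal and then averaged (mean ± SD across
animals); a pooled-counts alternative would weight animals by sequencing
depth rather than equally. When bulk expression is available only as
per-tissue means, it is broadcast to all animals with a notice — both
granularities occur in practice.

## Barcode extraction and assignment

Reads are single-end, 84 nt, with the barcode flanked by constant
sequence. The constant sequence immediately adjacent to the barcode
depends on the cloning context, so anchors are required configuration
rather than package constants (`amplicon_config()`); the simulator ships
synthetic defaults so examples are concrete.

Extraction locates the 5' anchor at its best-scoring placement (fewest
mismatches, ties broken leftmost — deterministic for a fixed layout),
takes the next 15 bases, and, if a 3' anchor is configured, requires it to
follow within the mismatch limit. There is no backtracking to
worse-scoring placements: a read whose best placement fails validation is
a `no_anchor` tally, not an exception. Assignment is substitution-only
Hamming matching: the unique nearest map barcode within
`max_bc_mismatch` wins; ties are `ambiguous` and excluded from counts
rather than fractionally split (splitting would correlate noise across
promoters). Indels are not modelled — extraction is anchored and barcodes
have fixed length — which is a documented limitation rather than an
oversight. The bookkeeping is conservative by construction:
`assigned + no_anchor + unassigned + ambiguous = reads_seen`, exactly.

## The synthetic-screen generator

`screen_truth()` fixes the study conditions the package is tested under:
53 promoters, the 16-tissue panel, 6 animals, $10^5$ reads per sample,
per-base substitution error 0.005 on the FASTQ path, Ct noise 0.25
cycles, and lognormal copy-number/bulk noise with $\sigma = 0.2$. These
noise levels are plausible for modern short-read sequencing and
probe-based qPCR/ddPCR, are documented as synthetic, and are overridable.

The generative structure mirrors the assay's causal chain:

1. each animal's pool composition is a Dirichlet perturbation of the
   injected proportions (concentration $5000 L$ — soft jitter modelling
   injection and biodistribution variability; the real inter-animal
   variance structure is unknown, so this concentration is a free
   parameter, not an estimate);
2. gDNA counts are multinomial draws from that composition;
3. cDNA counts are multinomial draws proportional to the *realized* gDNA
   proportions times the true activities — transcription happens from the
   genomes actually delivered, which is exactly the structure the
   $R_{\alpha\beta}$ ratio assumes;
4. bulk expression is $c_0 D_\beta \sum_\alpha L_\alpha A_{\alpha\beta}$
   with lognormal noise, $D_\beta$ being the tissue's mean vector load;
5. the single-vector path draws ddPCR channels around $G \times$ cells
   and $2 \times$ cells and builds target Ct values as
   $C_t^{hk} - \log_2(G A_{\alpha\beta}/c_0)$ plus Gaussian cycle noise;
   zero-activity cells yield no amplification (missing Ct), as a real
   instrument would report.

The default activity matrix contains one ubiquitous-strong construct
(a CAG-like benchmark), a lognormal background, and ~40% of constructs
boosted 25-fold in one tissue (assigned round-robin so every tissue has a
clear top candidate) — the qualitative structure such screens find.

`simulate_counts(..., exact = TRUE)` replaces every draw by its
expectation. This noiseless, error-free mode composed with the full
pipeline is an exact fixed point: recovered within-tissue shares equal
$100 A_{\alpha\beta}/\sum_\alpha A_{\alpha\beta}$ to floating-point
accuracy, through both the library and the single-vector path. That
identity — not any tuned tolerance — is what the fixed-point tests
assert.

What the generator does **not** emulate: PCR duplicates and jackpotting,
GC bias, index hopping, capsid tropism beyond the per-tissue load vector,
promoter interference, ITR-driven background transcription, and
RNA-extraction or reverse-transcription efficiency differences between
tissues. Passing recovery tests therefore demonstrates that the
*arithmetic* is correct and statistically well-behaved under realistic
sampling noise — not that any particular wet-lab screen is free of those
artifacts.

## Numerical choices

* Ct duplicates are averaged on the Ct (log) scale before
  exponentiation, matching standard $\Delta C_t$ practice; undetermined
  Ct is missing, never imputed to a ceiling such as 40 cycles.
* Differing ddPCR input masses (e.g. less liver DNA to avoid droplet
  saturation) need no correction: $G$ is a ratio of channels from the
  same well.
* Heatmap preparation maps values through $\ln(\max(x, \varepsilon))$
  with $\varepsilon$ = half the smallest positive entry — monotone on
  positive values, finite at zero. Clustering defaults to euclidean
  distance with complete linkage; the upstream tools' defaults, stated
  rather than inferred, since the original parameters are unpublished.
  Constant matrices are returned unclustered in input order.
* PCA is column-centered but not variance-scaled by default (scores
  share a 0–100 scale); each component is oriented so its
  largest-magnitude loading is positive, making outputs comparable
  across runs and implementations.
* Correlations between score sets are computed on untransformed scores,
  pairing by tissue (and animal where applicable), masked pairs dropped
  listwise; zero-variance inputs are reported as undefined rather than
  silently `NA`.
* `generate_barcodes()` uses seeded rejection sampling with a draw cap —
  simple, reproducible, and adequate below a few hundred barcodes; it is
  not a coding-theory construction and will refuse dense, tight-distance
  requests.

## Problem sizes

The test suite exercises the full study geometry (53 × 16 × 6 at $10^5$
reads per sample) for the recovery checks, and smaller geometries
(8–20 promoters, 2–6 tissues, 1e4–2e4 reads) for oracle comparisons and
property checks; the demultiplexer is verified read-for-read against
exhaustive-offset, exhaustive-Hamming oracles at $10^4$ reads. These sizes
keep every oracle brute-forceable while preserving the statistics that
matter (multinomial noise at realistic per-promoter coverage).

## Known limitations

* Substitution-only matching: an indel inside the barcode loses the read.
* The read model is substitution-only with uniform error; no quality
  modelling, and qualities are not used for filtering.
* $C_\beta$ compares tissues through bulk qPCR; RT efficiency differences
  between tissues propagate directly into specificity scores.
* The validator reports, but does not enforce, a minimum pairwise barcode
  distance — an inherited barcode set may be tighter than the matching
  tolerance deserves; check `attr(map, "min_hamming")` before relaxing
  `max_bc_mismatch`.
* Efficiency scores are relative within a tissue: a tissue where every
  promoter is weak still sums to 100.

```{r}
# the pipeline in one breath, at desk scale
truth <- screen_truth(n_promoters = 10,
                      tissues = c("liver", "heart", "brain"),
                      n_animals = 2, depth_gdna = 2e4, depth_cdna = 2e4,
                      seed = 1)
sim <- simulate_counts(truth)
res <- quantify_screen(sim$counts, sim$samples, sim$bulk)
rec <- recovery_report(res$efficiency_mean, truth)
rec
attr(rec, "overall_spearman")
```
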