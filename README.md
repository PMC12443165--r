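# promoscreen

Quantification of barcoded AAV promoter library screens.

In an *in vivo* promoter biopanning screen, dozens of candidate promoters
are cloned in front of a reporter gene, each tagged with a unique 15-nt DNA
barcode in the reporter's 3' UTR, individually packaged into an AAV capsid,
pooled in equal vector-genome amounts, and injected into a small cohort of
animals. Amplicon sequencing of the barcode region in each tissue's genomic
DNA measures vector delivery (biodistribution), while sequencing of the
reverse-transcribed mRNA measures transcriptional output. `promoscreen`
turns those reads — plus bulk qPCR and ddPCR measurements — into comparable
per-promoter, per-tissue activity scores, and ships a synthetic-screen
generator with known ground truth so the entire pipeline can be verified
end to end without any external data.

It is intended for groups running MPRA-style barcoded vector screens
(promoters, capsids, or other cassette elements) who need a tested,
reproducible normalization path from FASTQ to scores.

## The model

For promoter α in tissue β of one animal, with `Pαβ(cDNA)` and `Pαβ(gDNA)`
the barcode proportions in cDNA and gDNA and `Cβ` the tissue's bulk
reporter expression (qPCR, `2^−ΔCt` against a housekeeper), normalized
expression is

    Rαβ = ( Pαβ(cDNA) / Pαβ(gDNA) ) × Cβ

and is deconstructed into two 0–100 scores:

* **efficiency** `Eαβ = 100 × Rαβ / Σα Rαβ` — which promoter is strongest
  within tissue β (sums to 100 over promoters; the bulk factor `Cβ`
  cancels);
* **specificity** `Sαβ = 100 × Rαβ / Σβ Rαβ` — where promoter α acts
  (sums to 100 over tissues, per animal).

For single-vector validation cohorts the same scores are computed from

    Qαβ = Cαβ / Gαβ

where `Cαβ = 2^−ΔCt` is relative reporter expression and
`Gαβ = reporter copies / (Rpp30 copies / 2)` is vector genomes per diploid
genome from ddPCR (Rpp30 being a two-copy autosomal reference). Specificity
is computed per animal; efficiency per tissue from `Q*αβ`, the mean across
a promoter's replicate animals.

Promoters whose gDNA signal sits below a configurable detection floor are
masked, never pseudocounted: the gDNA proportion is a denominator, and low
counts make the ratio explosive.

## Worked example

A small synthetic screen with known ground truth — 12 promoters, 4
tissues, 3 animals, 2 × 10⁴ reads per sample:

```r
library(promoscreen)

truth <- screen_truth(n_promoters = 12,
                      tissues = c("liver", "heart", "brain", "muscle"),
                      n_animals = 3, depth_gdna = 2e4, depth_cdna = 2e4,
                      seed = 8)
sim <- simulate_counts(truth)
res <- quantify_screen(sim$counts, sim$samples, sim$bulk)
res$ne
#> Normalized expression: 12 promoters x 12 (animal, tissue) samples; 0 masked entries

round(res$efficiency_mean$mean[1:5, ], 1)
#>     liver heart brain muscle
#> P01  17.0  28.5  29.3   21.1
#> P02   2.1  54.6   4.2    4.1
#> P03   1.3   0.7   1.6    2.7
#> P04   0.7   2.4  47.8    1.2
#> P05   8.1   4.5   6.5    7.2
```

Promoter P02 carries 54.6% of heart expression and P04 47.8% of brain
expression — these are the tissue-specific constructs the generator
planted. Specificity for the ubiquitous-strong P01 shows where its output
actually goes once biodistribution and bulk expression are factored in:

```r
round(res$specificity_mean$mean["P01", ], 1)
#>  liver  heart  brain muscle
#>   74.7   22.2    0.3    2.7

rec <- recovery_report(res$efficiency_mean, truth)
rec
#>   tissue spearman top1_match    mae
#> 1  liver    1.000       TRUE 0.0627
#> 2  heart    0.993       TRUE 0.0775
#> 3  brain    1.000       TRUE 0.0400
#> 4 muscle    1.000       TRUE 0.0842
attr(rec, "overall_spearman")
#> [1] 0.9995
```

Recovered efficiency scores rank promoters almost exactly as the true
activity matrix does (Spearman ρ = 0.9995 over all cells), and the top
promoter is identified in every tissue.

The FASTQ layer works the same way: `simulate_fastq()` writes
84-nt reads (anchor + barcode + anchor + filler, with per-base
substitution error) and `count_sample()` demultiplexes them back through
anchored extraction and bounded-mismatch Hamming matching.

## Vignette

`vignettes/promoter-screen-quantification.Rmd` documents the model and its
assumptions, the masking and aggregation choices, what the synthetic
generator does and does not emulate, and known limitations.
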