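# SDRtools

Tools for dissecting young plant sex chromosomes from sequencing data, built
around the analysis chain used for dioecious hemp: delineate the
male-specific **sex-determining region (SDR)** from pooled female/male read
depth, catalogue **gametologs** (X/Y copies of the same ancestral gene) and
quantify Y gene loss, estimate synonymous divergence (**Ks**) and date the
X–Y split with a molecular clock, detect **inversions** from gametolog
anchor order, and contrast **population diversity** (π, Tajima's D, Hudson's
F<sub>ST</sub>) between X- and Y-referenced call sets. A seeded simulator
generates every input with known ground truth, so the whole chain is
testable without external data.

Intended users: plant genomicists working on dioecious species with
young/heteromorphic sex chromosomes, and anyone who needs a compact, fully
tested reference implementation of these classic statistics.

## The statistics at the core

* **SDR calling.** In a male pool the hemizygous SDR sits at half the
  autosomal depth; in a female pool it drops to mismapping background. After
  normalising each pool by its autosomal median depth, windows with ratio
  r = d<sub>F</sub> / max(d<sub>M</sub>, floor) below a threshold are merged
  into maximal runs (tolerating short interior gaps) and reported as SDR
  calls.
* **Nei–Gojobori Ks.** Each codon position contributes a synonymous-site
  fraction (synonymous single-base changes over non-stop changes); observed
  differences are attributed by averaging over all minimal mutational
  pathways between the two codons, excluding pathways through stop codons
  where possible. The proportions p<sub>S</sub> = S<sub>d</sub>/S and
  p<sub>N</sub> = N<sub>d</sub>/N are corrected with Jukes–Cantor,
  d = −(3/4)·ln(1 − (4/3)p).
* **Molecular clock.** T = Ks̄ / (2λ) with λ either given directly
  (default 6.1×10⁻⁹ substitutions/synonymous site/year) or derived from a
  calibration pair as λ = Ks<sub>cal</sub> / (2·T<sub>cal</sub>).
* **Inversions.** Gametolog anchors are ranked along X and Y; maximal runs
  of consecutive anchors whose Y ranks descend stepwise are inverted blocks,
  with breakpoints at block boundaries.
* **Diversity.** π = (1/L)·Σ 2j(n−j)/(n(n−1)), Tajima's (1989) D from S, n
  and the π sum, and Hudson's ratio-of-averages F<sub>ST</sub> estimator.

## Worked example

A desk-scale system — 100 kb autosome, 80 kb X, 60 kb Y carrying a 40 kb SDR
and 20 kb PAR, 150 gametolog pairs at mean true Ks 0.46, 40× pools, and the
two-run inverted anchor structure:

```r
library(SDRtools)

cfg <- sim_config(seed = 42)
sim <- simulate_sex_genome(cfg)

## 1. SDR from pooled depth
pools <- simulate_pool_depth(sim$truth, cfg, window = 1000)
calls <- call_sdr(normalize_track(pools$female, "A1"),
                  normalize_track(pools$male, "A1"))
calls
#>   chrom start   end n_windows mean_ratio male_relative_depth
#> 1     Y     0 40000        40 0.04702775           0.5171053
```

The caller recovers the simulated SDR `[0, 40000)` exactly: near-zero
female/male ratio and the half-depth male signature of hemizygosity.

```r
## 2. gametolog catalogue and Y gene loss
xg <- sim$cds[sim$genes$id[sim$genes$chrom == "X" & sim$genes$region != "PAR"]]
yg <- sim$cds[sim$genes$id[sim$genes$chrom == "Y" & sim$genes$region == "SDR"]]
catalog <- find_rbh_pairs(xg, yg)
catalog
#> homology catalog: 150 gametolog pairs, 34 X-specific, 19 Y-specific

gene_loss_fraction(570, 1529)$rounded   # the hemp Y-SDR vs X-SDR gene counts
#> [1] 63

## 3. Ks distribution and clock dating
ks <- ks_table(sim$cds[c(catalog$pairs$x_id, catalog$pairs$y_id)])
filt <- remove_outliers(setNames(ks$Ks, ks$pair_id))
date_divergence(filt$values, clock_model(rate = 6.1e-9))
#> X-Y divergence: 39.8 Mya (95% CI 38.4-41.1), mean Ks = 0.485 (n = 148, lambda = 6.1e-09 /site/yr)

## 4. inversion detection from anchor order
coords <- data.frame(id = sim$genes$id, mid = (sim$genes$start + sim$genes$end) / 2)
pr <- merge(catalog$pairs, setNames(coords, c("x_id", "x_mid")))
pr <- merge(pr, setNames(coords, c("y_id", "y_mid")))
anchors <- rank_anchors(pr)
blocks <- detect_inversions(anchors)
blocks
#>   anchor_start anchor_end n_anchors orientation  x_span  y_span
#> 1            1         65        65    inverted 26081.0 17284.0
#> 2           66        150        85    inverted 32932.5 22013.5

## 5. population diversity, X versus Y-SDR
vcf <- simulate_population_vcf(cfg, out_vcf = "pop.vcf")
ac <- vcf_allele_counts("pop.vcf")
wd <- windowed_diversity(ac, 10000, cfg$chrom_lengths)
mean(wd$pi[wd$chrom == "X"])                      # 0.0034
mean(wd$pi[wd$chrom == "Y" & wd$end <= 40000])    # 0.0007
```

The estimated mean Ks (0.485) sits within sampling error of the simulated
target (0.46 ± 0.1 across pairs); the two inverted blocks of 65 and 85
anchors match the constructed permutation, and the realized diversities
recover the configured θ of 0.0034 (X) and 0.0008 (Y-SDR).

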