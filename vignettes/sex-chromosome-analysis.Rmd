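---
title: "Methods: pooled-depth SDR detection, gametolog divergence and X/Y population genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-depth SDR detection, gametolog divergence and X/Y population genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SDRtools implements the analysis chain used to characterise a young plant
sex-chromosome system: a Y chromosome whose sex-determining region (SDR) has
stopped recombining with the X, degenerates by gene loss and rearrangement,
and leaves diagnostic signatures in pooled sequencing depth, in the
synonymous divergence of surviving gametolog pairs, and in population
diversity. This vignette documents the models, the tunable parameters, the
simulator that provides ground truth, and the design choices that were
genuinely open.

## 1. The coverage model behind SDR calling

A male pool carries one Y and one X per individual, so the SDR — present in
a single copy — sequences at half the autosomal depth; in a female pool the
SDR is absent and only mismapping background remains. `call_sdr()` operates
on window-mean depth tracks normalised by the autosomal *median*
(`normalize_track()`; the median resists depth spikes from collapsed
repeats). Per window the ratio

r = d_F / max(d_M, floor)

is compared against `ratio_threshold`; candidate windows are merged into
maximal runs tolerating `max_gap_windows` interior non-candidates, and runs
spanning fewer than `min_windows` windows are dropped.

Parameter defaults, with rationale:

* `window`: 1 kb at the simulator's toy scale, 10 kb recommended for
  chromosome-scale data — small enough to resolve boundaries to ~1% of a
  toy SDR, large enough that Poisson noise per window is a few percent at
  typical 40x pool depth.
* `ratio_threshold = 0.3`: the female SDR signal sits near 2 x leak (~0.04
  with the default 2% mismapping leak), while PAR and autosomal windows
  fluctuate around 1; 0.3 splits the two modes with wide margin on both
  sides.
* `male_floor = 0.05` (normalised units): caps the ratio where the male
  track locally drops out, preventing spurious non-candidates inside the
  SDR.
* `max_gap_windows = 2`, `min_windows = 5`: tolerate repeat-induced mapping
  dropouts without fragmenting one region into many calls, while
  suppressing isolated low-ratio windows.

`male_relative_depth` (mean normalised male depth over the call, expected
~0.5) is reported as a hemizygosity annotation but never enforced, because
collapsed repeats routinely distort it on real assemblies. Coordinates are
0-based half-open internally and in the returned tables; depth is
strandless. Statistical significance testing of the depth contrast is
deliberately out of scope — the contrast is an effect-size statement.

## 2. The homology catalogue

`find_rbh_pairs()` builds gametolog pairs by reciprocal best hit (RBH) over
global protein alignments (BLOSUM62, gap open 10, extension 0.5) of the
translated CDS. A pair is accepted only if the score reaches
`min_score_fraction` (default 0.3) of the self-alignment score of the
*shorter* gene, so a fragment cannot pass merely by aligning its full
length. Unpaired genes become X- or Y-specific, and
`gene_loss_fraction(n_y, n_x) = 100 (n_x - n_y) / n_x` summarises Y decay.

Determinism: inputs are sorted by gene id before scoring, and best-hit ties
resolve to the first (lexicographically smallest) id at the maximal score.
An alignment-length tie-break was considered and dropped: scores are
computed in vectorised score-only mode, ties at identical scores are
vanishingly rare for real sequences, and the id rule already makes results
reproducible under input shuffling (a property the test suite asserts).

`partition_by_region()` assigns genes by midpoint containment in half-open
intervals — unambiguous, order-free, and stable for genes straddling a
boundary.

## 3. Synonymous divergence and dating

`estimate_ks()` implements Nei–Gojobori (1986) counting with a
Jukes–Cantor correction:

* **Sites.** For each codon position, the synonymous fraction is the number
  of the three single-base changes that preserve the amino acid divided by
  the number that do not create a stop codon; mutations to stops are
  excluded from the denominator. Site counts of a codon always sum to 3,
  and S + N = 3 x (aligned codons) exactly.
* **Differences.** For each differing codon pair all minimal mutational
  pathways are enumerated (k! orders for k differing positions); each step
  is synonymous or nonsynonymous by amino-acid identity, and counts are
  averaged over pathways. Pathways through stop codons are excluded unless
  every pathway passes through one — the standard NG86 convention.
* **Correction.** d = -(3/4) ln(1 - (4/3) p) for p = pS and pN; estimates
  with (4/3) pS >= 1 are flagged saturated and excluded from downstream
  means. The method was chosen over ML codon models for its closed form:
  every quantity is checkable against an independent brute-force
  enumerator, which the test suite does for all 3,660 ordered sense-codon
  pairs.

Codon alignment (`align_codons()`) aligns the translated proteins and
back-threads nucleotides, so gaps are whole codons and frameshifts cannot
contaminate the counts; columns containing ambiguity characters are
dropped.

`remove_outliers()` applies Tukey fences (1.5 x IQR) after discarding
saturated estimates — a conventional, scale-free rule for the long right
tail that anciently diverged or misaligned pairs produce.

`date_divergence()` maps the mean Ks through a molecular clock,
T = Ks̄ / (2 lambda), the factor 2 counting substitutions on both lineages.
The default rate lambda = 6.1e-9 substitutions per synonymous site per year
is the value jointly implied by a mean Ks of 0.46 and a divergence time of
37.7 Myr (0.46 / (2 x 37.7e6)); calibration mode instead derives
lambda = Ks_cal / (2 T_cal) from a dated outgroup split and is exactly
equivalent to rate mode at the implied rate (asserted in the tests). The
95% CI is a normal approximation on the mean Ks mapped through the clock
and floored at zero; a bootstrap would add nothing at n = 150 pairs and
would make the report seed-dependent.

## 4. Inversion detection

Gametolog anchors are ranked along X and Y (`rank_anchors()`), and
`detect_inversions()` segments the Y-rank sequence, walked in X order, into
maximal runs of constant direction. Strict mode requires exact unit steps
(|delta y_rank| = 1), the appropriate model when anchors are dense and
clean, as for a constructed permutation; `tolerant = TRUE` accepts any
sign-constant monotone run for sparse or noisy real anchor sets. Blocks
shorter than `min_block` (default 3, suppressing single-anchor noise) are
merged into the larger neighbour, which keeps the orientation of the
majority of merged anchors. Breakpoints are the boundaries between
consecutive blocks; spans are midpoint extents within each block.
`displaced_pairs()` counts anchors whose Y rank differs from their X rank —
note that the central anchor of an odd, self-centred reversed run keeps its
rank, so a 65-anchor reversal displaces 64 pairs; both the overall and
per-block tallies are reported rather than guessing which a reader wants.

## 5. Population statistics

`classify_variants()` follows VCF left-aligned anchor-base conventions:
equal length-1 alleles are SNPs; a longer ALT (REF) sharing the first base
is an insertion (deletion); anything else is retained as `other`, never
silently dropped. Multi-allelic records are split per alternate allele
before classification, so class counts always sum to the allele total.
Density per kb uses `##contig` header lengths (an explicit `chrom_lengths`
argument overrides; missing lengths for observed chromosomes are an error).

Diversity uses the unbiased per-site estimator
pi = (1/L) sum_s 2 j (n - j) / (n (n - 1)); missing genotypes reduce n at
that site, and sites left with fewer than 2 called haplotypes are skipped.
Only biallelic SNPs enter pi, Tajima's D and FST, matching standard
practice. Tajima's D uses the 1989 constants with the window's median
per-site n; D is undefined for S = 0. Hudson's FST is computed
ratio-of-averages (sum of numerators over sum of denominators), which is
stable for low-information sites, unlike averaging per-site ratios.
Window means are unweighted; the default window is 10 kb at toy scale and
100 kb for chromosome-scale data.

## 6. What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions at desk scale: a 100 kb
autosome, an 80 kb X and a 60 kb Y carrying a 40 kb SDR plus a 20 kb PAR;
150 SDR gametolog pairs with per-pair true Ks drawn from Normal(0.46, 0.1)
(truncated to [0, 0.74], below Jukes–Cantor saturation); 34 X-specific and
19 Y-specific genes; 40x pools with a 2% female-pool mismapping leak over
the SDR; anchor order carrying two reversed runs splitting the pair set at
~43% (65/150); diversity theta of 0.0034 on the X and 0.0008 in the SDR
over 20 haplotypes; 13% of variants short indels. Where a quantity was
needed but unavailable (the mismapping leak, the indel fraction, gene
sizes), values were chosen once at field-realistic levels and documented
here, not tuned.

Implementation notes:

* **Gametolog evolution** draws an ancestral CDS with uniform codon usage
  over the 61 sense codons (avoiding composition bias in site counts) and
  applies single-base synonymous substitutions — nonsynonymous ones first,
  to a mild Ka target of 0.05 — with exact incremental Nei–Gojobori
  bookkeeping until the realised corrected divergence reaches the pair's
  target. Realised Ks therefore overshoots the target by at most one
  mutation's worth; the truth table records both. Because substitutions are
  applied ancestrally, multiple hits and reversals occur naturally.
* **Depth** is drawn per window as Poisson with the configured mean
  (overlap-weighted across SDR boundaries); read-level simulation and
  alignment are deliberately out of scope since the pipeline consumes depth
  tracks (BAM depth extraction is supported for real data).
* **The population VCF** sprinkles segregating sites at Watterson density
  theta x a1 per bp with derived-allele counts from the neutral site
  frequency spectrum P(i) proportional to 1/i, which makes the expected
  per-site SNP pi equal theta and the expected Tajima's D zero. Indels are
  added on top so theta calibrates SNP diversity exactly. Sites are
  independent: there is no linkage, no recombination structure, no
  selection, and no demography, so passing recovery tests validates the
  estimators, not population-genetic realism.
* **Determinism.** All draws flow from per-operation sub-streams derived
  from the master seed; identical configurations produce byte-identical
  FASTA/GFF3/VCF/TSV outputs (asserted in the tests).
* Gene sizes auto-scale to their region so the toy chromosome lengths can
  hold 150+ genes; at defaults SDR genes are 12–65 codons. Short genes make
  per-pair Ks noisier, which is why estimator-recovery tests use
  `evolve_gametologs()` directly with 100–300-codon CDS.

## 7. Numerical choices and degenerate inputs

* Saturation: p >= 3/4 returns NA and a `saturated` flag rather than -Inf;
  saturated pairs are dropped before fencing.
* `remove_outliers()` passes through with a warning below 4 finite values
  (fences are meaningless there).
* The SDR ratio denominator floor and the zero-median error in
  `normalize_track()` guard division by zero explicitly.
* Ties everywhere (best hits, anchor ranks, window boundaries) break by
  deterministic lexicographic or first-index rules; the half-open
  convention decides all boundary membership.
* Windows tile chromosomes exactly; the final short window uses its true
  length in all per-bp quantities.

## 8. Problem sizes used by the test suite

The suite runs the oracle-equivalence checks exhaustively where the space
is small (all sense-codon pairs; all permutations up to n = 6 plus sampled
n = 7), and uses 150-pair / 20-seed / 600 kb-chromosome simulations for the
recovery properties — sizes at which Monte-Carlo error is far below the
asserted tolerances while the whole suite stays in the low minutes on one
CPU. Constructed variant tables at the published X and Y call-set sizes
(1.6M and 1.1M records) verify the classifier's counting at scale.

## 9. Known limitations

* RBH with protein scores is a deliberate simplification of synteny-aware
  orthology; tandem duplicates can steal best hits in dense paralog
  families. Counts on real annotations will differ from any particular
  published pipeline.
* NG86 with Jukes–Cantor ignores transition/transversion bias and codon
  frequency bias, typically underestimating Ks above ~1; within the range
  simulated here (<= 0.74) the estimator is unbiased in the tests.
* The clock CI propagates only the sampling error of the mean Ks — rate
  uncertainty, which dominates in reality, enters only through the user's
  choice of lambda or calibration.
* The strict inversion detector assumes dense, exactly ranked anchors;
  real anchor sets should use tolerant mode and treat single-anchor blocks
  with suspicion.
* Tajima's D per window uses the median per-site n, a simplification when
  missingness varies strongly within a window.
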