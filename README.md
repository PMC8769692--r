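# tebench

Benchmarking locus-level transposable element (TE) expression analysis
with fully synthetic ground truth.

## The problem

TE families contain hundreds of near-identical genomic copies, so short
RNA-seq reads frequently align equally well to many loci at once. This
multi-mapping problem has historically pushed TE expression analysis to
the family / consensus level, hiding which individual copy is
transcribed — yet regulation, pathology and reinsertion all act on
single instances. Evaluating whether instance-level quantification is
feasible requires data where the per-locus truth is known, which only
simulation can provide.

`tebench` builds that simulation world and the scoring machinery around
it:

* **Synthetic genome** — plants TE copies from fabricated family
  consensus sequences into a background genome, with per-copy divergence
  controlled on the Kimura two-parameter scale
  (*K* = −½ ln(1 − 2*P* − *Q*) − ¼ ln(1 − 2*Q*), reported in percent as
  RepeatMasker does), and emits matching RepeatMasker-style `.align` /
  `.out` annotation plus a BED6 + FASTA per-instance reference library.
  Every instance is tracked by an id of the form
  `chr|start|end|order|family|subfamily|score|kimura`.
* **Expression simulator** — a two-set × five-replicate design in which
  5% of the selected TEs (length ≥ 100 bp, known Kimura distance) are
  spiked as differentially expressed (2.5% up, 2.5% down; default fold
  changes 2 and 0.5). Counts are negative-binomial around a 20× mean
  coverage target (size = μ/3); reads are emitted as FASTQ with
  paired-end fragment lengths ~ N(250 bp, 25 bp) and optional empirical
  quality-profile sequencing errors.
* **Baseline quantifier** — an exact k-mer seed + Hamming-verification
  mapper over the instance library with EM re-assignment of
  multi-mapping reads (cap 100 loci), so the pipeline runs end-to-end
  without external tools. External per-instance count tables and SAM
  alignments can be ingested instead; foreign id dialects are unified by
  one-to-one genomic-coordinate matching.
* **Evaluation** — TEs with ≤ 10 reads over the 10 samples are removed;
  a TE counts as detected at ≥ 5 reads; per-replicate TP/FP/FN/TN yield
  recall, precision and F-score, overall and stratified by Kimura bins
  of width 5 and TE order; per-set baseMeans give r²(TP). The
  differential arm derives a ground-truth DETE set by running a built-in
  negative-binomial Wald test (median-of-ratios normalization,
  trend-shrunk dispersions, BH adjustment) on the simulated counts, then
  scores any tool's DE table by cumulative TPR/FDR curves, TPR at a
  fixed FDR of 0.1, a false-positive inflation diagnostic and rank
  aggregation across tools.

## Worked example

```r
library(tebench)
bm <- run_te_benchmark(seed = 11, n_expressed = 120L, coverage = 5,
                       layout = "PE100")
print(bm)
#> Synthetic TE expression benchmark
#>   planted TEs: 480 | expressed: 120 | layout: PE100
#>   baseline quantifier mean F-score: 0.963
#>   ground-truth DETEs: 3 | TPR at FDR 0.1: 0.333
print(bm$detection)
#> Detection evaluation (cutoff 5, filter > 10 total reads)
#>   mean F-score over 10 replicates: 0.963
#>   mean recall 0.961, mean precision 0.965
#>   per-set baseMean confusion / r2(TP):
#>  set  TP FP FN     r2_tp
#>    1 110  4  5 0.9404936
#>    2 109  4  4 0.9444291
#>   F by Kimura bin:
#>  stratum n_tes   mean_f
#>    [0,5)    43 0.884003
#>  [10,15)    17 1.000000
#>  ...
```

The pipeline plants 480 TE copies (4 orders × 3 families spanning
Kimura 0–25%) into a 2 Mb genome, expresses 120 of them, quantifies the
simulated reads with the baseline EM mapper and scores the result. The
mean F-score of 0.963 says most expressed instances are recovered; the
Kimura-stratified table shows the expected difficulty gradient — young,
near-identical copies (`[0,5)` bin, F = 0.88) are harder to attribute
than diverged ones (F = 1.0), because reads from a young copy also match
its silent family twins and the EM splits that evidence. r²(TP) ≈ 0.94
measures how faithfully per-copy expression levels are recovered among
true positives. The ground-truth DETE set is deliberately derived from
the *simulated* counts (not the spike-in list), so a perfect aligner has
a differential-expression recovery power of exactly 1.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the
differential-expression recovery power of a perfect read assignment: it
simulates a truth count matrix over N = 2000 synthetic TEs with the
default spike-in design, derives the ground-truth DETE set with the
built-in DE engine at adjusted p < 0.05, re-evaluates the same matrix as
a tool's output, and writes the recovered fraction as JSON.
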