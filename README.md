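# burstDE

Distribution-based differential expression for single-cell RNA-seq,
interpreted through the transcriptional bursting model.

## The problem

Single-cell RNA-seq yields a whole distribution of transcript counts per
gene in each condition, not just a mean. Methods inherited from bulk
sequencing call a gene differentially expressed (DE) when its mean shifts,
and are blind to changes in variance, zero fraction or modality that leave
the mean in place — changes that are biologically meaningful at the single
cell level. `burstDE` is for analysts who want (1) a DE test that compares
the *full* per-gene count distribution between two groups of cells, and
(2) a mechanistic readout of *what* changed.

## The model and the tests

Transcription is modeled by the two-state (telegraph) model: the promoter
activates at rate α, inactivates at rate β, transcribes at rate γ while
active, and transcripts degrade at rate λ. The stationary transcript count
is a Poisson-Beta mixture,

    X ~ Poisson(cγ/λ),  c ~ Beta(α/λ, β/λ),

identifiable from snapshot data only up to λ. Fitted parameters are
translated into the field's derived quantities: duty cycle α/(α+β), burst
size γ/β, burst frequency αβ/(α+β), mean expression γα/(α+β), CV, and —
when degradation rates are supplied — the autocorrelation time
τ_c = S(0)/2R(0) of expression fluctuations.

Per gene, two groups of cells are compared with one of:

* **Cramér-von Mises** — rank-based criterion
  T = U/(NM(N+M)) − (4NM+1)/(6(N+M)), midranks for ties, p-value from the
  asymptotic Bessel-function series (100 terms, zero beyond T = 12);
* **Kolmogorov-Smirnov** — two-sample D with the asymptotic p-value;
* **likelihood ratio** — Monte-Carlo Poisson-Beta likelihoods (N = 1000
  shared Beta draws) of the test group under both groups' fitted
  parameters, 2Δℓ against a chi-squared(6) reference.

Parameters are fitted per gene and group by closed-form moment inversion
(exact on exact moments, fragile on sparse data, never silently clipped)
or by a collapsed Gibbs sampler with slice sampling and ridge-targeting
Metropolis moves (Rcpp). Counts are normalized by median-of-ratios size
factors (spike-in aware), and significance comes from Benjamini-Hochberg
FDR control or from the empirical split-control threshold 0.1·p*. A
synthetic benchmark module reproduces the validation suite: sensitivity
grids with a composite score, null-control calibration, mean-preserving
variance changes, a dropout model p_dropout = 1 − exp(−μ²/b), and
parameter-recovery experiments.

## Worked example

Sixty genes, 50 cells per group; genes 1–6 get a 4-fold transcription-rate
(γ) increase in the treated group. The simulation has no library-size
variation, so normalization is disabled (see the vignette on composition
bias for why that matters).

```r
library(burstDE)
set.seed(42)
ngene <- 60
gamma <- exp(runif(ngene, log(30), log(100)))
counts <- matrix(0L, ngene, 100)
for (i in 1:ngene) {
  g_b <- if (i <= 6) 4 * gamma[i] else gamma[i]
  counts[i, ] <- c(rpb(50, pb_params(1, 1, gamma[i])),
                   rpb(50, pb_params(1, 1, g_b)))
}
cm <- count_matrix(counts, rep(c("ctrl", "treated"), each = 50),
                   gene_ids = sprintf("gene%02d", 1:ngene))
res <- burst_de(cm, "ctrl", "treated", test = "cvm", method = "mom",
                threshold = "bh", seed = 1, normalize = FALSE)
res
summary(res, n = 6)
```

```
burst_de: ctrl vs treated, 60 genes, test = cvm, 6 significant
threshold_decision (bh): critical p = 8.673e-09
Top 6 genes by p-value (cvm test, ctrl vs treated):
 gene_id statistic   p_value significant fold_change log2_change_burst_size
  gene05     6.073 1.388e-14        TRUE       4.610                 2.5622
  gene04     5.790 5.740e-14        TRUE       4.308                 1.3644
  gene06     4.665 1.652e-11        TRUE       4.678                 2.5427
  gene02     4.380 6.932e-11        TRUE       3.808                 1.1020
  gene01     3.886 8.433e-10        TRUE       4.403                 3.7653
  gene03     3.426 8.673e-09        TRUE       3.135                 0.7922
```

Exactly the six perturbed genes are called significant: their mean fold
changes sit near the injected 4 (sampling noise aside), and the burst-size
columns show the change expressed in model terms. Fitting a single gene
directly:

```r
fit <- pb_fit(counts[1, 1:50], method = "bayes", seed = 1)
fit
pb_derived(fit$params)
```

```
Poisson-Beta fit (bayes), n = 50 cells
Poisson-Beta (telegraph) parameters: alpha = 1.904, beta = 6.033, gamma = 176.5 (units of lambda = 1)
duty cycle 0.2399 | burst size 29.26 | burst frequency 1.447 | mean 42.34 | CV 0.615 | tau_c 1.118
```

`pb_fit` objects support `coef`, `summary`, `simulate`, `predict` (the
fitted pmf), `logLik`, `residuals` (randomized quantile) and `plot`.

A shell interface wraps the same functions:

```sh
burstde run input.tsv output.tsv --group-a ctrl --group-b treated --test cvm --seed 1
burstde bench null-control --test cvm --n-reps 1000 --seed 1 --out report.tsv
```

Input is tab-separated with gene ids in the first column and one group
label per cell in the header row.

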