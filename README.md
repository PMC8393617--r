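# capdet

Detection of **cyclic alternating pattern (CAP)** phase A versus phase B
activity in NREM sleep EEG.

CAP is a recurring NREM-sleep EEG pattern in which short periods of
cerebral activation (phase A: K-complexes, delta bursts, arousals, 2–60 s
long) alternate with the intervening background (phase B). The fraction of
NREM sleep spent in CAP — the CAP rate — is a marker of sleep instability
that rises in insomnia, sleep apnea, periodic leg movement and several
other disorders. Scoring CAP by hand is slow and subjective; `capdet`
implements an automated phase A/B classifier for two-channel sleep EEG
(monopolar C4-A1 and bipolar F4-C4 montages) together with the rule engine
that turns phase annotations into CAP sequences and CAP rates.

## Method

1. **Preprocessing.** Each channel is bandpass filtered (zero-phase
   Butterworth, order 4, 0.5–35 Hz), min-max normalized to [0, 1] once per
   recording, and resampled to the 64 Hz analysis rate by Fourier (sinc)
   resampling.
2. **Optimal orthogonal filter bank.** The discrete wavelet transform uses
   an orthogonal lowpass/highpass pair designed for minimum mean-squared
   (RMS) bandwidth

   B² = (1/2π) ∫ ω² |H(ω)|² dω = (π²/3)·r[0] + 4·Σₖ (−1)ᵏ r[k]/k²,

   a linear functional of the filter autocorrelation r. Minimizing B²
   subject to orthogonality (r[0] = 1, vanishing even lags), p vanishing
   moments (a zero of order 2p of R(ω) at ω = π) and spectral
   nonnegativity R(ω) ≥ 0 is a convex program; `capdet` solves it exactly
   as a semi-infinite LP (interior-point barrier iteration in the
   null space of the moment constraints plus a cutting-plane exchange on
   the nonnegativity constraint) and recovers the filter by spectral
   factorization with a minimum-phase root split. The deployed bank has
   length 12 and 4 vanishing moments; its B² = 0.86785 undercuts
   Daubechies-6 (0.90561) and Symlet-6 at equal length and moment count.
3. **Subbands and features.** Five decomposition levels at 64 Hz give six
   subbands (16–32, 8–16, 4–8, 2–4, 1–2, 0–1 Hz). Each subband of each
   channel contributes four features — the wavelet entropy
   E = −Σ|cᵢ| log|cᵢ| and the three Hjorth parameters (activity = σ²,
   mobility = σ(Δx)/σ(x), complexity = mobility(Δx)/mobility(x)) — for 48
   features per two-channel epoch. Features are ranked by the
   Kruskal–Wallis test.
4. **Classification.** Bagged trees (default), boosted trees, RBF-SVM,
   KNN, logistic regression and a single decision tree, evaluated by
   stratified sample-wise 10-fold cross-validation with the per-fold
   predictions pooled into one confusion matrix; metrics are ACA (average
   classification accuracy), precision, recall, F1, Cohen's κ and AUC.
5. **CAP rules.** Annotated phase A events closer than 2 s merge; chains
   of at least three A phases separated by admissible B intervals
   (durations in [2, 60] s, gaps ≤ 60 s) form CAP sequences; CAP rate =
   CAP time / NREM time.

A synthetic sleep-EEG generator (1/f background plus delta-burst or
K-complex-like phase-A transients, two correlated channels) provides
ground truth, so the whole pipeline runs and is tested without any
external recordings.

## Worked example

```r
library(capdet)

fb <- designMinBandwidthFilter(12, 4, 5)
fb
#> WaveletFilterBank: length 12, 4 vanishing moments, 5 levels
#>   RMS bandwidth: 0.93159 rad/sample (B^2 = 0.86785)
#>   h:  0.20954  0.64726  0.65592  0.12074 -0.23804 -0.09820  0.13562
#>       0.03802 -0.07568  0.00568  0.01975 -0.00639

es <- simulateEpochSet(synthParams(nEpochs = 200, ampRatio = 5, seed = 7))
feats <- extractFeatures(preprocessEpochs(es), fb)
m <- crossValidate("bagged_trees", feats, k = 10, seed = 42)
m
#> CAP phase classification metrics
#>   confusion (counts, predicted x actual):
#>          actual
#> predicted   A   B
#>         A 198   7
#>         B   2 193
#>   column % (per actual class):
#>          actual
#> predicted  A    B
#>         A 99  3.5
#>         B  1 96.5
#>   ACA 97.75%  Pcn 0.97  Rcl 0.99  F1 0.98  kappa 0.96  AUC 1.00
```

The ACA of 97.75% says that on strongly separable synthetic data
(phase-A bursts five times the background RMS) the full chain — filter
design, decomposition, 48 features, bagged trees under 10-fold CV —
recovers the known labels almost perfectly; with `ampRatio = 1` (classes
drawn from one distribution) the same chain stays at chance, as it must.
Feature ranking on the same data puts delta-band (2–4 Hz) Hjorth activity
first, matching the physiological picture of phase A as high-amplitude
slow-wave activity:

```r
rk <- rankFeatures(feats)
head(rk[order(rk$rank), ], 3)
#>              feature        H      p_value rank
#> 14 C4-A1.D4.activity 178.6035 9.779805e-41    1
#> 38 F4-C4.D4.activity 158.8820 1.985702e-36    2
#> 13  C4-A1.D4.entropy 107.1569 4.112896e-25    3
```

CAP rule arithmetic on annotation events:

```r
A <- data.frame(onset = c(0, 40, 80), duration = 10, label = "A")
seqs <- buildCapSequences(A)             # one A-B-A-B-A sequence
computeCapParameters(seqs, nremTime = 10)$cap_rate
#> [1] 0.15
```

## Command line

A thin CLI over the same functions lives at `inst/cli/capdet.R`:

```sh
Rscript inst/cli/capdet.R design-filter --length 12 --vm 4 --out omsbm12.txt
Rscript inst/cli/capdet.R simulate --n 500 --amp-ratio 5 --seed 7 --out epochs.csv
Rscript inst/cli/capdet.R features --epochs epochs.csv --filter omsbm12.txt --out features.csv
Rscript inst/cli/capdet.R evaluate --features features.csv --classifier ebagt --folds 10 --seed 42
```

Subcommands `preprocess`, `segment` and `run` operate on EDF recordings
plus annotation files (simple TSV or the PhysioNet CAP event dialect).

## See also

The methods vignette (`vignettes/cap-phase-detection.Rmd`) documents the
model assumptions, every tunable parameter, the numerical choices in the
filter design, and what the synthetic benchmark does and does not show
about real polysomnography.
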