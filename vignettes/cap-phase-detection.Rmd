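---
title: "Methods: CAP phase detection with an optimal orthogonal wavelet filter bank"
author: "capdet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAP phase detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdet)
```

## The problem

During NREM sleep the EEG often settles into the cyclic alternating
pattern: stereotyped activation events — K-complexes, bursts of
high-amplitude delta waves, brief arousals — recur every 20–40 s against a
lower-amplitude background. The activation events are phase A, the
background between two of them phase B, and the proportion of NREM sleep
occupied by such cycling (the CAP rate) indexes sleep instability. This
package classifies 1–2 s EEG epochs into phase A versus phase B from two
standard montages (C4-A1, F4-C4) and implements the scoring rules that
aggregate phase events into CAP sequences and rates.

## Signal model and preprocessing

Sleep EEG carries its clinically relevant content below roughly 35 Hz, and
slow drift below 0.5 Hz is artifactual. Each channel is therefore bandpass
filtered with a fourth-order Butterworth applied forward-backward.
Zero-phase filtering was chosen over a single causal pass because phase-A
transients are morphological objects — a phase-shifted K-complex smears
into neighbouring epochs; the price is that the effective magnitude
response is that of an eighth-order filter, which we document rather than
hide.

Amplitudes are min-max normalized to [0, 1] **once per channel per
recording**, never per epoch. Per-epoch scaling would erase exactly the
signal the classifier needs: a phase-A burst is distinguished from phase B
background largely by its amplitude relative to the rest of the recording.
(When the unit of processing is an epoch collection rather than a
continuous recording, the collection plays the role of the recording: one
min/max per channel across all its epochs.)

The subband ladder below requires a 64 Hz analysis rate, while the target
recordings run at 512 Hz, so preprocessing ends with resampling. We use
Fourier (sinc) resampling — discard Fourier coefficients above the new
Nyquist frequency and invert at the new length — which is inherently
anti-aliased and exact for band-limited content; after the 0.5–35 Hz
bandpass the signal is band-limited well inside the new 32 Hz Nyquist.
The pipeline order is fixed: bandpass, normalize, resample, segment.

An alternative reading of the decomposition would keep the 512 Hz rate and
take eight dyadic levels, retaining the lowest six subbands; it produces
the same nominal frequency ranges through a different filter cascade. We
implement the resample-then-five-levels route because it makes the
six-subband structure exact and epochs conveniently short (128 samples for
2 s); the alternative is noted here, not silently mixed in.

## The minimum-bandwidth orthogonal filter bank

Orthogonal two-channel filter banks preserve energy (Parseval), so
subband energies partition epoch energy — a property the features rely
on. Among orthogonal filters of a given length we want the one whose
lowpass is best localized in frequency. The criterion is the mean-squared
bandwidth

$$B^2 = \frac{1}{2\pi}\int_{-\pi}^{\pi} \omega^2\,|H(\omega)|^2\,
d\omega,$$

which penalizes the entire spectrum rather than ripple at designated band
edges. Writing $r[k]=\sum_n h[n]h[n+k]$ for the filter autocorrelation and
using $\frac{1}{2\pi}\int \omega^2 e^{-j\omega k}\,d\omega =
2(-1)^k/k^2$ (and $\pi^2/3$ at $k=0$),

$$B^2 = \frac{\pi^2}{3}\,r[0] + 4\sum_{k\ge 1} \frac{(-1)^k}{k^2}\,r[k],$$

a *linear* functional of $r$. The design constraints are linear too:
$r[0]=1$ and $r[2k]=0$ (orthogonality), and $2p$ vanishing-moment
conditions forcing $R(\omega)=r[0]+2\sum_k r[k]\cos\omega k$ to have a
zero of order $2p$ at $\omega=\pi$. The one non-trivial constraint is
that $R(\omega)\ge 0$ must hold for all $\omega$ — the condition for $r$
to be an autocorrelation at all. The design problem is therefore convex.

### How it is solved

The classical route expresses $R(\omega)\ge 0$ through a positive
semidefinite Gram-matrix parameterization and hands the problem to an SDP
solver. We solve the identical convex program with machinery that needs
nothing beyond base numerics:

* the equality constraints are eliminated analytically (pseudo-inverse
  particular solution plus null-space basis), so vanishing moments hold to
  machine precision by construction;
* the structural zero at $\omega=\pi$ is divided out of $R$ in the
  Chebyshev basis ($2p$ synthetic divisions by $2+2\cos\omega$), leaving a
  deflated polynomial $Q$ with $Q(\pi)$ free — without this the barrier
  below would be singular at $\pi$ on the whole feasible set;
* $Q(\omega_i)\ge 0$ is imposed on a 1025-point frequency grid and the
  resulting LP is solved by a log-barrier interior-point iteration
  (Newton steps, $\mu: 10^{-2}\to 10^{-12}$), started from the
  strictly feasible maxflat (Daubechies) autocorrelation of the same
  moment count;
* a cutting-plane exchange loop then evaluates $R$ on a 20001-point grid,
  adds any violated local minima (polished by `optimize`) as new
  constraints, and re-solves until $\min_\omega R \ge -10^{-10}$.

All settings are fixed and nothing is randomized, so repeated designs are
identical to verification tolerance. For the deployed configuration
(length 12, 4 vanishing moments) the optimum reaches
$B^2 = 0.86785$ versus $0.90561$ for Daubechies-6 and larger still for
Symlet-6, with $\min R \approx -7\times10^{-16}$.

### Spectral factorization

The lowpass is recovered from $r$ by root splitting of
$z^{L-1}P(z)=\sum_k r[|k|]z^{k+L-1}$. Zeros at $z=-1$ (there are exactly
$2p$) are deflated analytically and assigned half multiplicity, so the
$(1+z)^p$ factor of the result is exact; the remaining roots occur in
reciprocal pairs and the minimum-phase half (smallest moduli) is kept —
a deterministic, reproducible convention. Two refinements matter
numerically. At the bandwidth optimum $R$ touches zero at an interior
frequency, creating a double root **on** the unit circle that `polyroot`
splits radially; such near-circle roots are projected back onto the
circle. Finally two Gauss-Newton polish stages, both parameterized so the
$(1+z)^p$ factor stays exact, (i) fit the autocorrelation of the
candidate to $r$ and (ii) for orthogonal inputs drive the even-lag
orthogonality conditions to machine precision. Without the polish the
raw root-finding error (≈2×10⁻⁵ in the autocorrelation) would leak into
perfect reconstruction; with it the orthogonality defect is ≈10⁻¹⁵ and
five-level analysis/synthesis round-trips below 10⁻⁸.

Tolerances used throughout: constraint satisfaction 10⁻⁸ at design time,
10⁻⁶ for filter-bank validity checks, 10⁻⁵ for the factorization
round-trip — the practical limit of double-precision root-finding on
degree-22 polynomials. Filter lengths beyond about 40 are out of scope
for the same reason.

## Decomposition and features

`dwt` iterates two-channel filtering and downsampling with **periodic
boundary extension**, which preserves orthogonality exactly and yields
the exact dyadic coefficient counts $N/2^j$ on short epochs (at deep
levels the filter is longer than the signal; the wrapped transform
remains orthogonal because all non-zero even autocorrelation lags
vanish). Five levels at 64 Hz give six subbands covering 16–32, 8–16,
4–8, 2–4, 1–2 and 0–1 Hz; the lowest is the approximation band, the rest
detail bands.

Each subband contributes four features:

* **wavelet entropy** $E=-\sum_i |c_i|\log|c_i|$, with the natural
  logarithm and $0\log 0 = 0$. The magnitudes are deliberately *not*
  normalized to probabilities — that is the form the feature set is
  defined with; a normalized Shannon mode exists behind a flag
  (`normalize = TRUE`) but is off by default.
* **Hjorth activity** (population variance — no $n-1$ correction, the
  definition is a moment, not an estimator), **mobility**
  $\sigma(\Delta x)/\sigma(x)$ and **complexity**
  $\mu(\Delta x)/\mu(x)$, with derivatives as raw first differences and
  no sampling-rate scaling: the features feed a rank-based test and
  scale-free classifiers, and the common EEG convention keeps them
  dimensionless after normalization. For an iid sequence mobility tends
  to $\sqrt 2$; for a tone at frequency $f$ it is $2\sin(\pi f/f_s)$ —
  both serve as oracles in the tests.

A constant (degenerate) subband would make mobility 0/0; the feature
vector then records 0 with a warning rather than NaN, so classifiers
never see non-finite inputs. With 6 subbands × 4 features × 2 channels
the epoch vector has 48 named entries
(`"{channel}.{subband}.{feature}"`). Features are ranked by the
tie-corrected Kruskal–Wallis H against a $\chi^2_1$ reference; ranks
order by ascending p, ties broken by descending H then index.

## CAP rules

Two different B-phase notions are implemented and kept separate
deliberately. For **classification labels**, every merged annotated A
interval is class A and *all remaining NREM time* is class B — the
pragmatic labelling used when building epoch datasets. For **CAP
parameters**, only the strict sequence grammar counts: A phases merge
when separated by under 2 s (strictly; applied to a fixed point),
admissible phases last 2–60 s, an inter-A interval over 60 s breaks the
chain, and three A phases (A-B-A-B-A) are the minimum for a sequence,
which runs from its first A onset to its terminal A end. Isolated A
phases are non-CAP for sequence purposes but keep their expert "A" label
for classification — they are genuine activations, and the expert label
outranks atlas duration limits for the learning task. The same reasoning
keeps annotation events with out-of-range durations in the classification
stream while the sequence builder filters them.

Epoch windows tile each labeled interval from its onset, dropping
trailing partial windows; anchoring at the onset means the minimum legal
2 s A phase contributes exactly one 2 s epoch. Class balancing undersamples
the majority class without replacement under a dedicated seed.

## Classifiers and evaluation

Defaults mirror widespread ensemble presets: bagging with 30 unpruned
bootstrap trees (majority vote; the score is the mean vote), boosting
with 30 depth-limited trees at learning rate 0.1, an RBF SVM, KNN with
k = 10, penalized-free logistic regression and a single decision tree.
All are configurable; none are tuned to any benchmark. Cross-validation
is sample-wise and stratified (stratification reduces fold variance at
no cost; a subject-wise split is the right tool when subject leakage is a
concern and can be built from the per-epoch subject ids the containers
carry). Per-fold predictions are pooled into one confusion matrix —
matching how a single summary matrix is conventionally reported — and
ACA, precision, recall, F1 and Cohen's κ are computed from the pooled
counts; AUC comes from the pooled scores via the midrank Mann–Whitney
formulation. For balanced binary data κ = 2·ACA/100 − 1 exactly, a handy
cross-check. `metricsFromConfusion` recomputes the suite from a
column-percentage matrix (with configurable priors), which is how the
package verifies published tables; note that a matrix rounded to print
precision determines the summary metrics only to within that rounding.

Four seeds (balancing, fold assignment, model fitting, synthesis) keep
each stochastic stage independently reproducible.

## The synthetic benchmark

`simulateEpochSet` draws phase-B epochs as 0.5–35 Hz band-limited
$1/f^\beta$ noise with unit RMS ($\beta = 1$ by default — the canonical
EEG background slope), and phase-A epochs as the same background plus
either a raised-cosine-windowed 0.5–4 Hz burst or, with probability 0.2,
a biphasic ~0.8 s K-complex-like transient. The transient peak amplitude
is $(\rho - 1)\times$ background RMS where $\rho$ is `ampRatio`, so
$\rho = 1$ makes the two classes *literally identically distributed* —
the chance-level control — and $\rho$ approximates the phase-A envelope
to background ratio. The two channels share half their background
variance (one common source plus channel noise), mimicking the gain a
second montage brings in practice; transients are common to both. The
default study condition is $\rho = 5$, 1000 epochs per class, 2 s epochs
at 512 Hz.

What the generator does **not** emulate: spindles and alpha intrusions,
sub-type structure (A1/A2/A3), stage-dependent background
non-stationarity, artifacts, inter-subject variability. Passing the
end-to-end recovery test (ACA ≥ 90% at $\rho = 5$, chance at $\rho = 1$)
therefore demonstrates that the pipeline's plumbing, features and
evaluation are sound and leak-free — not that real polysomnograms reach
any particular accuracy. Real-data performance must be established on
scored recordings.

## Problem sizes used by the test suite

Filter design checks run at the deployed size (L = 12, p = 4).
Feature-level property tests use tens of epochs; the end-to-end recovery
experiment uses the full study condition of 1000 epochs per class for
both the separable and the chance-level setting; distributional checks on
the generator use 500 epochs per class. These sizes put every stochastic
assertion's noise floor well inside its margin (e.g. chance-level ACA at
n = 2000 has a binomial standard error of about 1.1 percentage points
against a ±5 point band).

## Known limitations

* The filter design supports even lengths up to ≈40; beyond that,
  double-precision spectral factorization degrades.
* The EDF codec handles continuous 16-bit EDF with per-channel rates; it
  does not implement EDF+ discontinuous records or annotation channels
  (CAP annotations arrive as separate text files).
* Republished rounded confusion matrices constrain recomputed summary
  metrics only to their printing precision; disagreement at the last
  printed digit is evidence about rounding, not about the arithmetic.
* Stratified sample-wise cross-validation shares subjects between folds.
  With multi-subject data and a clinical question, split by subject
  instead.
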