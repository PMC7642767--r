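---
title: "Estimating genome size by flow cytometry and k-mer spectra"
author: "cytokmer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genome size by flow cytometry and k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytokmer)
```

## The problem

The C-value — the haploid nuclear DNA content of a species, in picograms
(1 pg = 978 Mb) — is the basic quantity of genome-size research and a
prerequisite for planning genome sequencing. Grasshoppers and their
relatives (Orthoptera: Caelifera) carry some of the largest genomes known
in insects, from roughly 6 to beyond 18 pg, which makes them awkward
subjects for the standard measurement protocols: the usual internal
standards (chicken red blood cells at 1.165 pg, mouse at 3.30 pg) are an
order of magnitude smaller than the genomes being measured, and
ratio-based calibration degrades when sample and standard are far apart.

`cytokmer` implements the full analysis chain for this setting:

1. **Flow cytometry (FCM)**: turn per-particle fluorescence intensities
   from a co-preparation of sample and internal standard into calibrated
   1C estimates, with quality control and replicate aggregation.
2. **Internal standards**: a registry of calibration organisms, each with
   an optimal measurable range, plus selection logic and the classical
   statistics (pooled *t*, one-way ANOVA, Tukey HSD) used to compare
   estimates across standards and sexes.
3. **K-mer spectra**: count canonical k-mers in sequencing reads and
   estimate genome size, repeat content and heterozygosity from the depth
   histogram — the independent, sequence-based route to the same quantity.
4. **Comparative methods**: quantify how strongly C-values track the
   phylogeny with Pagel's $\lambda$ and Blomberg's $K$.
5. **Synthetic data**: seeded generators for every input type, carrying
   known ground truth, so each stage is testable without instrument or
   sequencer output.

## Flow cytometry: model and procedure

Propidium-iodide fluorescence is taken as linear in DNA content
(a single gain constant). Diploid G1 nuclei of the sample form a Gaussian
"2C" peak; the co-prepared internal standard forms its own 2C peak; nuclei
in G2 or endoreduplicated sit at exactly twice the corresponding 2C
position ("4C"); fragmented nuclei and debris form a decaying background
below the peaks. The estimator is the peak-position ratio

$$
1C_\text{sample} \;=\; 1C_\text{standard} \times
\frac{\text{sample 2C mean peak position}}
     {\text{standard 2C mean peak position}},
\qquad \text{Mb} = \text{pg} \times 978 .
$$

The chain is `build_histogram()` → `detect_and_fit_peaks()` →
`classify_peaks()` → `estimate_gs()` → `aggregate_replicates()`.

**Peak detection.** Events are binned into 1024 equal-width channels
(mimicking instrument resolution). Candidate modes are interior local
maxima of a moving average; because a population's flat top carries
counting noise, the detection average is deliberately wide
(4 × `smooth_window` + 1 channels, default 21) and uses honest partial
windows at the histogram edges (zero-padding would bend a monotone debris
slope into a spurious interior maximum). Two further guards make detection
scale-free:

* a **topographic prominence** rule — a mode must rise at least half its
  own height above the saddles connecting it to higher ground — which
  collapses ripple on a flat top to its single highest mode; and
* a **peak-to-base** rule — the mode must stand at least twice the level
  just outside its window — which rejects the broad maximum that any
  noisy monotone slope (pure debris) otherwise presents.

Each surviving peak is fitted over the window descending from its mode to
the valley floor on both flanks (shallow dips above half the mode height
are crossed). Position and spread are Gaussian moment estimates; when the
original event table is supplied, moments are computed from the raw event
values inside the window, removing channel-quantization error entirely —
with zero simulated CV the fitted position is exact.

**Classification.** Which peak is the standard is not guessed: the caller
declares an `expected_sample_range` (pg), every ordered pair of peaks is
tried as (standard 2C, sample 2C), and a pairing is consistent when the
implied sample 1C falls inside the range. Remaining peaks at twice an
assigned 2C position (within 3 combined standard deviations) are labelled
4C and excluded. Two equally consistent pairings raise an ambiguity error
— the instrument-side remedy is a different internal standard, and the
software refuses to guess.

**Quality control and reporting.** A peak passes QC when its coefficient
of variation, $100\,\sigma/\mu$, is strictly below 5% — the conventional
acceptance bar for C-value cytometry. Replicates aggregate to a mean 1C
(reported at 2 decimals), its Mb equivalent (rounded from the *unrounded*
mean — rounding is purely presentational), and a standard error of the
mean, $\mathrm{sd}/\sqrt{n}$, reported in Mb and omitted for $n = 1$.

## Internal standards and their suitability ranges

Ratio calibration is trusted only within a fixed band of sample/standard
DNA ratios, by default $(0.33,\ 3.30)$. The band is a *calibration*, not a
measurement: it is chosen so that the migratory locust male standard
(1C = 6.20 pg) covers genomes of roughly 2–20 Gb, the working range
reported for that standard, and it is user-configurable. On this rule the
four registry standards tile the range from a few hundred Mb (chicken) to
20 Gb (locust), and `select_standards()` ranks covering standards by
log-distance between target and standard 1C. A covering standard whose 2C
peak would sit within 3 combined standard deviations of the sample's
(computed from a nominal 3% CV) is flagged as overlapping — numerically
usable but practically ambiguous, so an alternative is recommended.

Group comparisons use the classical machinery: pooled-variance two-sample
*t* (Welch behind a flag; the pooled form is the common reporting
convention in this literature), one-way ANOVA, and Tukey–Kramer HSD with
studentized-range p-values. A species with a single replicate of one sex
is still testable: the pooled variance then comes entirely from the larger
group (df $= n_a + n_b - 2$) and the result is flagged low-confidence.

## K-mer spectra: estimators and numerical choices

Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
complement) are counted in C++ with 2-bit packed 64-bit codes, capping
$k$ at 31; $k$ must be odd so a k-mer can never be its own reverse
complement, and $k = 21$ is the default. Windows containing non-ACGT
symbols are skipped. The spectrum $N_d$ (distinct k-mers seen exactly
$d$ times) is interchangeable with the two-column `depth count` histogram
dialect of standalone counters.

With base coverage $C$ and read length $R$, the per-k-mer coverage is
$\lambda_k = C\,(R - k + 1)/R$. The estimators:

* **Error cutoff** $c$: sequencing errors pile distinct k-mers at depth
  1–2; $c$ is the first valley of the spectrum — the smallest $d \ge 2$
  with $N_{d-1} > N_d \le N_{d+1}$. The rule only applies when the
  spectrum *descends* at the origin (i.e. an error spike exists);
  otherwise the first dip would be the genuine valley between the
  heterozygous and homozygous peaks, so everything is kept ($c = 1$).
* **Genome size**: $G = T(c) / d_\text{hom}$, where
  $T(c) = \sum_{d \ge c} d\,N_d$ and $d_\text{hom}$ is the depth of the
  homozygous peak. The integer mode is refined by three-point parabolic
  interpolation on log counts **plus one half**: for a Poisson depth law
  the interpolated maximum of the pmf sits exactly half a unit below the
  mean (the pmf ties at $\lambda - 1$ and $\lambda$), and it is the mean,
  not the interpolated mode, that divides the mass correctly. With this
  correction the noiseless single-component spectrum at $\lambda_k = 26$
  is recovered exactly; without it the estimate is biased high by
  $\approx \lambda/(\lambda - \tfrac12)$, about 2%.
* **Repeat fraction**: the share of retained mass above
  $1.5 \times d_\text{hom}$ — the midpoint between the single-copy and
  two-copy peaks; configurable.
* **Heterozygosity**: a k-mer window is haplotype-specific as soon as it
  covers one heterozygous site, so the fraction of single-copy k-mers
  affected is $f = 1 - (1 - h)^k$. The package measures
  $\hat f = m_\text{het} / (m_\text{het} + m_\text{hom})$ from the
  occurrence mass in the windows $[0.35, 0.65)\,d_\text{hom}$ (het) and
  $[0.65, 1.5]\,d_\text{hom}$ (hom), then inverts:
  $\hat h = 1 - (1 - \hat f)^{1/k}$.

This is deliberately a ratio/threshold toolkit, not a four-component
mixture fit: no distributional model is optimized. The cost is a known
bias of the window-based $\hat f$ when the Poisson peaks are wide relative
to their separation — at $\lambda_k = 26$ roughly a quarter of the
heterozygous mass leaks out of its window, and simulated *expected*
spectra under-recover $h$ by ~25–30%. On simulated *reads* (the more
realistic target, where window overlap among nearby heterozygous sites
partially compensates) recovery at $h = 0.005$, 30-fold coverage and 30%
repeats is within ~12% relative; the test suite asserts the end-to-end
read-based recovery. Peaks below depth 4 are declared unresolvable rather
than estimated.

## Phylogenetic signal of C-values

Under Brownian motion on a tree, tip covariances equal the shared
root-to-tip path lengths $C_{ij}$. `fit_lambda()` profiles the likelihood
of the $\lambda$-transform (off-diagonals of $C$ scaled by $\lambda$):
for fixed $\lambda$ the root state and rate have closed-form GLS/ML
solutions through a Cholesky factorization (no explicit inverse), and
$\lambda$ is optimized on $[0, 1]$ by bounded scalar search (absolute
tolerance $10^{-6}$) with both endpoints evaluated explicitly.
$\lambda > 1$ is excluded because the transform can lose positive
definiteness there. Likelihood-ratio tests against $\lambda = 0$ (no
signal) and $\lambda = 1$ (pure Brownian motion) use $\chi^2_1$.

`blomberg_k()` implements
$K = (\mathrm{MSE}_0/\mathrm{MSE}) \big/
\big[(\mathrm{tr}\,C - n/\mathbf{1}^\top C^{-1}\mathbf{1})/(n-1)\big]$
with the GLS phylogenetic mean; $K = 1$ matches the Brownian expectation,
and on a star tree (identity covariance) $K$ equals 1 identically —
which also means a star tree cannot calibrate the permutation test, so
null calibration is checked with exchangeable (iid) traits on structured
trees instead. Significance uses the add-one permutation estimator
$p = (1 + \#\{K_\text{perm} \ge K_\text{obs}\})/(n_\text{perm} + 1)$ with
a mandatory seed (default $n_\text{perm} = 999$).

Numerical safeguards: near-singular covariances get a $10^{-10}$-scale
diagonal jitter (logged via a message); zero-length terminal branches are
perturbed by $10^{-8} \times$ tree depth with a warning; trait vectors
must biject onto tip labels, with an underscore/space normalization.

## What the synthetic generators do and do not emulate

* **FCM events** (`simulate_fcm_events`): Gaussian 2C populations for
  sample and standard (CVs configurable), 4C nuclei at exactly twice each
  2C centre, and debris as a truncated exponential below the lowest 2C
  centre. Event counts default to 20,000, matching acquisition practice.
  No instrument gives empirical debris or 4C fractions for this protocol,
  so the defaults (5% debris, 10% 4C) are conventional and configurable.
  Not modelled: stain stoichiometry, S-phase continuum between 2C and 4C,
  doublets, instrument drift or nonlinearity. Passing tests therefore
  demonstrate correctness of the estimation chain under the stated peak
  model, not robustness to every instrument artefact.
* **K-mer spectra and reads** (`simulate_kmer_spectrum`,
  `simulate_reads`): a diploid genome with independent per-site
  heterozygous substitutions (no linkage), one repeat family at a fixed
  copy number, uniform read sampling balanced across haplotypes,
  independent per-base errors, and Poisson depth spread. Real genomes have
  repeat *families* with mixed copy numbers, GC-dependent coverage and
  correlated errors; the simulator intentionally matches the estimators'
  model so that deviations measure estimator error, not model mismatch.
* **Trees and traits** (`simulate_yule_tree`, `simulate_bm_trait`):
  pure-birth trees via `ape`, multivariate-normal tips with covariance
  $\sigma^2 C(\lambda)$. No extinction, no rate heterogeneity.

Every generator takes an explicit integer seed and is a pure function of
its configuration; no global RNG state leaks in or out.

## Problem sizes used by the test suite

The suite exercises deliberately desk-scale versions of the study design:
20,000-event FCM replicates at 2% CV with 5% debris (1C recovered within
1%); 200-kb diploid genomes at 30-fold coverage with $h = 0.005$ and 30%
repeats (genome size within 5%, repeat fraction within $\pm 0.05$,
heterozygosity within $\pm 30\%$ relative); 64-tip Yule trees with 50–200
Brownian replicates (mean $\hat\lambda \ge 0.9$, mean $K$ within 3 Monte
Carlo standard errors of 1); 2000-replicate null simulations for ANOVA
p-value uniformity and Tukey family-wise error. These sizes were chosen so
the whole suite runs in well under a minute of compute per module while
keeping Monte Carlo error far below the asserted tolerances.

## Known limitations

* The window-based heterozygosity estimator is biased low on wide Poisson
  peaks (see above); a mixture-model fit would remove this at the cost of
  a distributional commitment that is out of scope here.
* Peak moments are truncated-window estimates; for overlapping FCM peaks
  (CV $\gtrsim$ 5%) the fitted CV underestimates the true spread — such
  peaks fail QC anyway, which is the intended behaviour.
* The packaged survey tables report the unweighted mean of per-species
  sex differences computed from rounded summary values (0.59 pg on the
  bundled data); published summaries computed from unrounded or
  replicate-weighted data can differ by a few hundredths of a pg, so the
  report carries a footnote rather than asserting one convention.
* FCS binary parsing is out of scope; event tables arrive as CSV.
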