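---
title: "Methods: polygenic risk and developmental trajectories of EEG coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk and developmental trajectories of EEG coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohertraj)
```

## What the package computes

`cohertraj` links an individual-level polygenic score to resting-state EEG
connectivity as it changes across adolescence and young adulthood, separately
by sex. The phenotype is magnitude-squared coherence between 27 pairs of
bipolar electrode derivations of the 10--20 montage, band-averaged in theta
(3--7 Hz), alpha (7--12 Hz), high-alpha (9--12 Hz) and beta (12--28 Hz). The
exposure is a standardized polygenic score built from GWAS summary statistics
by LD clumping and p-value thresholding. The estimand, for each sex, band,
pair and integer age $a \in \{12, \dots, 31\}$, is the locally weighted
regression slope $\beta(a)$ of standardized coherence on the standardized
score: SD of coherence per SD of score.

Because the cohorts such analyses are run on are not publicly deposited, the
package ships a first-class synthetic cohort generator that produces every
input the pipeline needs -- pedigree, LD-structured genotypes, summary
statistics, longitudinal visits and coherence phenotypes with known planted
effects -- so the whole chain is testable end to end.

## Coherence estimation

Each of the 27 pairs is a pair of *bipolar derivations* (anode minus cathode
of adjacent electrodes), which attenuates volume conduction relative to
referential signals. For derivations $x$ and $y$ we estimate Welch-averaged
spectra and form

$$C(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

then average $C(f)$ over the FFT bins in each band.

Numerical choices, with rationale:

* **Segments**: 2-s Hann-tapered, demeaned segments with 50% overlap over
  the 256-s resting interval, giving $K = 255$ segments and 0.5-Hz
  resolution. Two seconds is the standard resting-EEG compromise -- 0.5 Hz
  resolves the 3-Hz lower band edge while keeping $K$ large; single-segment
  coherence is identically 1, so `coherence_spectrum()` refuses $K < 2$.
* **Band edges are half-open** $[f_{lo}, f_{hi})$: 7 Hz belongs to alpha,
  not theta, and no bin is double counted.
* **Estimator bias**: under independence $E[\hat C] \approx 1/K$; the test
  suite checks this closed form with non-overlapping segments, where it is
  exact (overlapping Hann segments are correlated and the bias constant
  becomes an effective $K$).
* **Degenerate inputs**: a zero-power derivation (e.g. identical channels)
  is an error naming the pair, never a silent NaN.
* The alternative of band-averaging spectra *before* forming the ratio is
  not used; we band-average $C(f)$ itself and note that the two disagree
  slightly when spectra are steep within a band.

The generator `simulate_eeg_pair(target)` mixes a shared white source into
two channels so that true coherence equals `target` at every frequency,
giving a closed-form oracle for the estimator.

## Polygenic scoring

Summary records carry an effect allele and odds ratio. The pipeline applies,
in fixed order: INFO $< 0.30$, palindromic (A/T, C/G), monomorphic, call
rate $< 95\%$, Hardy--Weinberg failure, MAF $< 0.05\%$. The
Hardy--Weinberg threshold is exact-test $p < 10^{-6}$ (conventional for
imputed panels) and configurable. Effects are oriented to the panel's
counted allele ($+\ln \mathrm{OR}$ or $-\ln \mathrm{OR}$); unmatched allele
sets are excluded with a reason, and every exclusion is logged.

Clumping is greedy by ascending p-value: the best remaining variant indexes
a clump and removes all unselected variants within $\pm 500$ kb on the same
chromosome with dosage $r^2 \ge 0.1$ in the founder reference; variants
beyond the window are never removed. Ties in p break to the lower
(chromosome, position) so output is deterministic. The retained set is
re-checked post hoc for independence on every run, and equality against an
exhaustively coded oracle is part of the test suite.

Scores at the nine thresholds $T \in \{10^{-4}, 10^{-3}, 0.01, 0.05, 0.1,
0.2, 0.3, 0.4, 0.5\}$ are $\mathrm{PRS}_i = \sum_j d_{ij} \ln \mathrm{OR}_j$
over clumped variants with $p < T$, missing dosages mean-imputed as
$2\,\mathrm{MAF}$, then Z-standardized over the scored sample (denominator
$n-1$; a founders-only standardization is a flag). Raw scores shift by a
constant under allele-orientation flips; Z-scores and ranks are invariant,
and the tests assert exactly that.

## The trajectory estimator

At grid age $a$, within one sex stratum, we fit weighted least squares of
standardized coherence on the standardized score plus covariates (genotyping
array, ancestry PCs, optional substance-use indicators), with weight

$$w_{\text{obs}} = \underbrace{\frac{1}{v_i \, m_f}}_{\text{structural}}
 \times \underbrace{\left(1 - |u|^3\right)^3_{+},\;
 u = \frac{\mathrm{age} - a}{h}}_{\text{tricube kernel}}$$

where $v_i$ is the individual's visit count and $m_f$ the number of sampled
family members: each individual's weights sum to $1/m_f$ and each family's
to 1, so families -- not visits -- carry equal influence. The tricube kernel
with bandwidth $h = 2$ years reproduces smooth age-resolved association
maps while keeping each fit local; the estimator at integer ages 12--31 is
fully specified here since the upstream literature leaves it to cited prior
work. Grid points with effective sample size below `min_neff` (default 30)
or a rank-deficient design are masked with a reason, not silently dropped.

**Inference.** The package's default Wald test uses a family-clustered CR2
sandwich variance (Bell--McCaffrey leverage adjustment) with Satterthwaite
degrees of freedom. The design choice was empirical: the structural weights
downweight repeated and related observations but do not remove their
correlation, and in calibration runs under the global null the
model-based test with Kish effective-sample-size degrees of freedom
($n_{\mathrm{eff}} = (\sum w)^2 / \sum w^2$) rejected at about 6.3--6.5%
at nominal 5%, while the clustered CR2 test rejected at about 5.6%. The
calibration experiment itself ships in the acceptance suite, and the
$n_{\mathrm{eff}}$-based test remains available as `variance = "model"`.
Both sex-stratified fits and a pooled sex-by-score interaction model are
implemented, since either could produce headline sex-specific effects.

**Multiplicity.** Benjamini--Hochberg step-up masking at $q = 0.01$ is
applied within one family per sex $\times$ band: all 27 pairs $\times$ 20
grid points jointly, matching the scale of family at which a $10^{-4}$
cutoff corresponds to FDR $< 0.01$. A cell is flagged significant only if
it is BH-significant *and* $p < 10^{-4}$ (`p_ceiling`, configurable): BH
controls the false discovery *rate*, so in a family rich in true signal its
step-up boundary rises and would admit occasional null cells; the joint
rule is the operational criterion the flagged tables are meant to mirror.
`fdr_mask()` itself is the pure step-up procedure and reports the implied
cutoff.

Age-binned summaries reduce each pair's grid cells within 12--17, 18--25
and 26--31 to a quantile of $\beta$ and of $-\log_{10} p$. The default is
the first quartile (25th percentile across grid points); whether the
analogous published tables use exactly this within-bin reduction is
ambiguous, so the probability is an argument, not an assertion.

## The synthetic cohort

The generator emulates a multi-generation family study: ~913 nuclear
families yielding ~1,400 genotyped offspring (mean 1.56 offspring/family,
~50% female), enrolled at a uniform age between 12 and 22 and re-assessed
every 2 years ($\pm$ 0.5-year jitter) until age 31. The visit count is
$1 + \mathrm{Binomial}(6, 5/12)$ -- mean 3.5, range 1--7 -- chosen because
only the mean and the assessment cadence are documented for the cohorts
being emulated; the distribution is a knob.

*Genotypes.* Founder haplotypes are drawn from a finite per-block ancestral
pool (a copying model) and offspring inherit one haplotype per parent per
block, so Mendelian consistency holds exactly at every locus and blocks
recombine freely. Within a block, pool haplotypes come from a latent
equicorrelated Gaussian whose correlation is calibrated semi-analytically
(bivariate-normal orthant probabilities, inverted with `uniroot`) so the
mean within-block dosage $r^2$ matches `r2_target`; smaller pools share
haplotypes more and inflate realized $r^2$, which the tests exploit as a
monotonicity check. Blocks sit 1 Mb apart so default clumping windows never
span blocks.

*Phenotypes.* Coherence is generated on the variance-stabilizing scale
$z = \operatorname{atanh}\sqrt{C}$:

$$z = \mu_{\text{pair}}(\mathrm{age}) + \sigma_z\left(\textstyle\sum\beta
\cdot \mathrm{score} \cdot \mathbf{1}[\text{sex, age window, pair, band}]
+ u_{\text{family}} + v_{\text{individual}} + \varepsilon\right),
\qquad C = \tanh(z)^2.$$

The variance components (defaults 0.10 / 0.30 / 0.55) are *proportions* of
the unit-variance latent part and must sum, with the planted effect
variance, to at most 1. The absolute spread $\sigma_z = 0.18$ is a
realistic between-visit SD for Fisher-z coherence and is deliberately small
enough that $z$ stays on the monotone branch of $\tanh(z)^2$; with a large
$\sigma_z$ the latent crosses zero, the back-transform folds, and a planted
$\beta$ is attenuated beyond recovery. Because coherence is re-standardized
per pair $\times$ band before fitting, a planted $\beta$ is recovered on
the SD-per-SD scale regardless of $\sigma_z$. Random effects are drawn
independently per pair $\times$ band, which induces the within-family and
within-person correlation the weights and the clustered variance are
designed for.

The default planted regime -- $\beta = 0.2$ for males aged 15--19 on the
posterior pairs (11--21) in high-alpha -- sits at the top of the
0.15--0.21 effect-size range that motivates the design, localized in sex,
age and topography.

*What the generator does not emulate:* population structure and admixture,
genotyping-batch artifacts beyond a categorical label, EEG artifacts
(blinks, muscle), genotype imputation error, and assortative or
multi-generational mating beyond nuclear families. Passing tests therefore
demonstrate that the pipeline recovers what it is pointed at under clean,
correctly specified family structure -- not robustness to those real-data
complications.

## Problem sizes and reproducibility

All randomness flows from one master seed through named substreams
(pedigree, genotypes, sumstats, visits, phenotypes, signals), so components
re-run independently and byte-identically. The validation suite runs the
full study-scale cohort (913 families, ~5,000 visits) with 20 replicates
for effect recovery and 50 for calibration and localization; spectral
checks use the full 256 s at 256 Hz. These sizes were chosen so every
Monte-Carlo tolerance in the tests is derived from the replicate count
actually run.

The orchestration layer (`run_pipeline()`) validates a strict YAML
configuration (unknown keys are errors), writes TSV artifacts plus a
manifest with md5 checksums of every output, and caches stages by parameter
hash so a change to, say, only the FDR level leaves simulation and scoring
artifacts bit-identical.

## Known limitations

* The trajectory estimator is cross-sectional in age at each grid point; it
  does not model within-person change (no growth curves), matching its
  descriptive use.
* CR2-with-Satterthwaite is well calibrated at hundreds of clusters but
  grid points near the age boundaries rest on few effective families; such
  points are masked by `min_neff` rather than reported with unstable
  inference.
* The PRS stage implements clumping + thresholding only; shrinkage-based
  re-weighting is out of scope by design.
* EDF ingestion and binary PLINK files are outside the I/O surface; the
  engine accepts labelled channel matrices / wide TSVs, and genotypes
  travel as dosage TSVs or VCF.
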