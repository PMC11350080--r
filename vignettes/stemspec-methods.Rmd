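---
title: "Models and methods behind stemspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stemspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemspec)
```

stemspec analyses Fourier-transform infrared (FTIR) measurements of plant
stem bases in two complementary modes: bulk ATR spectra of pulverized
tissue from a genotype panel, and hyperspectral images of stem
cross-sections. Both modes share one spectral model; this vignette lays
out that model, the statistical rules built on top of it, the synthetic
data generator used to validate the pipeline, and the design decisions
taken where the methodology leaves freedom.

## The EMSC decomposition

Every preprocessed spectrum $s(\tilde\nu)$ on the fingerprint axis
(1800–800 cm$^{-1}$) is modelled as

$$
s = a\,\bar m + \sum_{i=0}^{p} d_i P_i(\tilde\nu)
      + \sum_{j=1}^{J} c_j K_j + e,
$$

where $\bar m$ is a reference spectrum capturing multiplicative scatter,
$P_i$ are Legendre polynomials on the wavenumber axis rescaled to
$[-1, 1]$ (a baseline basis chosen for numerical conditioning; raw
monomials give visibly worse condition numbers at $p \ge 2$), and $K_j$
are the unit-norm reference component spectra of the library
(hemicellulose monomer signatures Ara/Gal/Man/Xyl, cellulose, lignin
variants, pectin, proteins, …). The default baseline order is $p = 2$
(quadratic), the common choice for transmission FTIR of thin sections;
it is configurable.

The least-squares fit (`emsc_fit()`, solver `"ols"`) is exact on
noise-free data whenever the design is full rank, and this is tested to
$10^{-9}$. Two alternative solvers exist: `"nnls"` constrains the
component coefficients to be nonnegative (solved by projecting the free
reference/baseline block out and running nonnegative least squares on
the reduced system), and `"pls"` is an uncentred NIPALS partial least
squares whose regression vector equals the OLS solution when all latent
variables are kept — retained as an option for noise robustness, with
the equivalence tested to $10^{-8}$.

**Relative absorbance.** A component's relative absorbance is
$|c_j| / \sum_k |c_k|$ — its absorbance in relation to the total fitted
chemical absorbance. The baseline and reference terms are excluded from
the total so the quantity is chemistry-only and invariant to global
rescaling of the spectrum (tested property). Because relative
absorbances are compositional, raising one component mechanically
depresses all others ("closure"); the consequences for inference are
discussed under *Limitations*.

**Choice of reference spectrum.** For measured data the default
reference is the mean spectrum of the batch under analysis, the
standard EMSC convention; measured spectra always contain structure
outside any finite component library, which keeps the design full rank.
Purely synthetic mixtures are different: their batch mean lies exactly
in the span of the library and the polynomial baseline, so a batch-mean
reference would make the model singular. The generator therefore emits
a dedicated broad-band reference spectrum (`make_reference()`) with
structure outside the library span. For data generated without any
reference-spectrum contribution the exact fit allocates $a = 0$ and
$c_j = a_{\text{scatter}} w_j$; the exported ground truth records
exactly those products, and the recovery tests compare against them.

**Degenerate fits.** A physically meaningful scatter scale is
nonnegative. Since $a \approx 0$ is the *expected* solution for spectra
without reference-specific structure, a fixed sign test would flag
perfectly healthy fits; instead a fit is flagged degenerate when $a$ is
negative beyond three times its own sampling uncertainty under the
fitted residual noise ($\mathrm{se}(\hat a) =
\hat\sigma \sqrt{[(X^TX)^{-1}]_{aa}}$). Degenerate pixels are reported,
excluded from downstream cluster statistics, and never imputed.

## Tissue clustering of hyperspectral images

Images are truncated to the fingerprint region, vector normalized
(unit Euclidean norm — the standard "vector normalization" of FTIR
chemometrics; the norm is not specified more precisely in common usage,
and L2 is what makes spectral distances scale-free), and the unmasked
pixel spectra are clustered hierarchically (`hcluster()`), by default
with Ward linkage on Euclidean distances — the standard pairing for
spectral histology. $k$ is a required parameter (stem sections resolve
into seven interpretable tissue regions at $k = 7$); no automatic
selection is attempted because cluster count is a tissue-interpretation
choice, not a statistical one. Cluster ids are renumbered by descending
pixel area so labels are canonical, and a user-supplied name map is the
only way clusters acquire anatomical names — the algorithm cannot know
anatomy.

Above `max_pixels` (default 20 000) a seeded uniform subsample is
clustered and the held-out pixels are assigned to the nearest cluster
centroid. This keeps memory quadratic only in the subsample while
degrading recovery gracefully (tested: ARI within 0.1 of the full run
on the default synthetic cube). When two genotype sections are
compared, their pixels are pooled and clustered *jointly* so the
cluster scheme is shared — comparisons per cluster are otherwise
meaningless. Joint clustering across genotypes is an assumption: it
presumes the same tissue types occur in both sections.

## Two-group statistics per cluster and component

For every (cluster, component) pair the two genotypes' pixel
distributions are compared with:

* **Mann–Whitney U**, $U = \#\{x > y\} + \tfrac12\#\{x = y\}$, exact
  permutation p-value when $n_x + n_y \le 16$ and tie-free, otherwise
  the tie-corrected normal approximation with continuity correction.
  The exact mode is verified against brute-force enumeration of all
  label assignments up to $n_x + n_y = 10$.
* **Divergence effect size** $D = |\bar x - \bar y| / s_{\text{pooled}}$
  — implemented as Cohen's d, since the small/medium/strong thresholds
  0.2/0.5/0.8 used with it are Cohen's conventions. Its variance-
  explained form is $R^2_D = D^2/(D^2+4)$, so $D = 2$ corresponds to
  $R^2_D = 0.5$ exactly. A robust variant (medians and pooled QAD) is
  available behind a flag.
* **Descriptives**: median, IQR, and QAD — the quantile absolute
  difference, implemented as the unscaled median absolute deviation
  from the median.
* **Relative difference**: $100\,(m_A - m_B)/m_B$ on cluster medians,
  group B serving as the 100 % reference. Medians (not means) because
  the per-cluster summaries are boxplot-style; the choice is
  configurable only by computing from the returned tibble.

The verdict for a record is *significant* iff $p < 0.001$ **and**
($D > 0.8$ **or** $R^2_D > 0.5$). The stringent $p$ threshold is the
imaging-scale default — pixel counts are in the hundreds and pixels are
not biological replicates, so the $p$-value alone is nearly
meaningless; the effect-size clause carries the decision. The bulk
screening uses $p < 0.05$ at genotype scale. No multiple-testing
correction is applied across records by default (a Benjamini–Hochberg
option exists), matching common practice for these descriptive tissue
comparisons.

`area_weighted_mean()` aggregates per-cluster means over merged
clusters weighting by cluster pixel area, for summarising quantities
measured on merged tissue domains.

## Bulk compound screening

Per compound, genotype-level mean relative absorbances are computed
(genotypes — not individual spectra — are the observation unit, because
the rooting traits exist per genotype). The decision rule is:

1. relative percent difference between the easy- and difficult-to-root
   group means $> 3$ (RPD $= 100\,|\Delta| / \text{mean}$, the standard
   symmetric, scale-invariant form; a reference-based variant is behind
   a flag), **and**
2. Pearson correlation with at least two of the three adventitious-
   rooting traits (AR% after 10 d +IBA, 21 d +IBA, 21 d −IBA)
   significant at $\alpha = 0.05$.

Only compounds passing both gates receive a Mann–Whitney test of easy
vs difficult genotype-level means (5 vs 10 genotypes by default: small
enough that the exact distribution is used). Constant inputs have no
defined correlation and are treated as non-significant rather than
errors. A `predictive_performance` column is reported all-NA: the
screening literature the rule descends from also ranks compounds by a
predictive-performance criterion whose definition is not available, so
the column is surfaced but never filled.

## The synthetic data generator

`synth_config()` + `make_library()` / `make_panel()` / `make_cube()`
generate everything the pipeline consumes, with exported ground truth,
fully determined by one seed. The generative model is *exactly* the
EMSC forward model — Gaussian-band component spectra mixed with
nonnegative weights, lognormal multiplicative scatter, random Legendre
baselines, additive i.i.d. channel noise — which is what makes exact
recovery oracles possible. Defaults, chosen once as field-plausible
study conditions:

* axis 1800 → 804 cm$^{-1}$ at 6 cm$^{-1}$ (167 channels, the imaging
  spectral resolution; 11 µm pixels),
* 10 components with 3 Gaussian bands each, pairwise cosine similarity
  $< 0.95$ enforced by regeneration,
* additive channel noise sd 0.008 absorbance, scatter sigma 0.1,
  baseline coefficient sds (0.02, 0.01, 0.005),
* cube: 96 × 96 pixels, concentric stem rings (epidermis, shoot
  cortex, pith + vascular ring) with three primordium domes subdivided
  into root cap, meristem, root vasculature and root cortex — seven
  regions; within-region pixel-level component variability 12 %
  (lognormal), roughly the tissue texture that still lets real
  sections cluster into clean tissue domains;
* region mixing profiles with strong, tissue-motivated contrasts
  (arabinan-rich epidermis, protein-rich meristem, lignin/cellulose-
  rich pith, pectin-rich root cortex, …);
* planted imaging effect: pectin × 1.5 in the root-cap region of the
  "affected" genotype,
* panel: 5 easy- / 10 difficult-to-root genotypes, 6 replicate spectra
  each, genotype-level compound variability 10 %, the planted compound
  (a mannose-hemicellulose signature, fixed at a mid-abundance base
  weight so its compositional share is stable across seeds) × 1.4 in
  the easy group, and three rooting traits generated as logistic
  functions of the planted compound's genotype weight plus Gaussian
  noise (16 percentage points, which places the planted trait
  correlation near 0.8), clipped to [0, 100].

What the generator deliberately does **not** emulate: Mie-type
scattering distortions, detector-correlated noise, atmospheric residual
lines, anatomical irregularity beyond labelled regions, spatial
autocorrelation of tissue texture, and registration error between
sections. Tests passing on synthetic data therefore demonstrate the
correctness of the *computational* pipeline under its own model
assumptions — not robustness to every artefact of real microspectroscopy.

## Numerical and procedural choices

* Axes are stored descending (instrument convention); readers accept
  either direction and canonicalize, which removes a whole class of
  sign errors in band handling.
* Range truncation uses a closed interval on both ends.
* Pipeline order is truncate → vector-normalize → decompose. The
  normalization is scale-removal only, so the decomposition's relative
  absorbances are unaffected by where it happens; truncating first
  makes the unit norm refer to the fingerprint region.
* The ENVI reader/writer supports BSQ/BIL/BIP interleaves, float32/
  float64/int16 (+ reflectance scale factor), both byte orders; format
  errors name the offending header field. CSV round-trips are written
  with 17 significant digits so float64 survives bit-faithfully.
* Cluster label images use 0 for masked pixels and 1..k for clusters;
  all reported areas are convertible to µm² via the pixel size.
* Tests and the acceptance script run the full clustering on the
  default 96 × 96 cube (≈ 6 100 tissue pixels) and use the
  subsample-then-assign path (3 000 pixels) for the joint two-section
  runs; panel analyses use the full default panel. These sizes are the
  package's validation choices and keep every check at desk scale.

## Limitations

* **Pseudo-replication.** Imaging statistics treat pixels as
  observations. Pixels within a tissue are spatially correlated and are
  not biological replicates; the stringent effect-size clause mitigates
  but does not remove this. Replicate-aware inference is out of scope.
* **Compositional closure.** Relative absorbances sum to one, so a
  genuine increase in one component induces apparent decreases in all
  others. With the default generator conditions the induced effects
  stay well below the $D > 0.8$ verdict threshold, and this is exactly
  what the null/planted acceptance checks verify — but on real data
  with larger planted shares, closure can produce correlated spurious
  differences, and the same mechanism can induce weak spurious trait
  correlations in the bulk screening (visible as occasional inert
  eligibility in the replicate checks).
* **No spatial regularization.** Label maps are purely spectral;
  no smoothing, no registration to histology.
* **Library completeness.** Component quantification is only as good
  as the reference library; absent constituents are absorbed into
  coefficients of spectrally similar components. Real reference
  libraries are user-supplied; the bundled one is synthetic.
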