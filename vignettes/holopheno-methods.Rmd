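---
title: "holopheno: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{holopheno: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`holopheno` is a simulation and analysis toolkit for stain-free phenotyping
of rolling cells imaged by off-axis holographic flow cytometry. This
vignette documents the physical model, the numerical choices, and the
design decisions behind each stage; it is written as a methods section, so
no chunk here is executed at build time (the heavier stages take minutes).

## 1. Physical model

A quantitative phase map (QPM) records the optical path delay accumulated
by light crossing a semi-transparent cell:

$$\varphi(x, y) = \frac{2\pi}{\lambda}\int \big(n(x, y, z) - n_0\big)\,dz,$$

with $\lambda$ the illumination wavelength, $n$ the local refractive index
(RI) and $n_0$ the medium index. The default optical train
(`optics_config()`) uses $\lambda = 0.532\,\mu m$, a $4.5\,\mu m$ camera
pixel demagnified $36\times$, i.e. an object-plane pitch of
$0.125\,\mu m$/px, $200 \times 200$-px QPMs and a $1024\times1024$-px
off-axis hologram grid with carrier $(0.25, 0.25)$ cycles/px.

Two derived quantities anchor the feature scale: the peak phase of a
homogeneous sphere, $\varphi_{max} = (2\pi/\lambda)\,\Delta n \cdot 2R$
(4.72 rad for $R = 5\,\mu m$, $\Delta n = 0.04$), and the dry mass
$m = \frac{\lambda}{2\pi\gamma}\sum_{ij}\varphi_{ij}\,p^2$ in picograms,
with refractive increment $\gamma = 0.2\,\mu m^3/pg$ and pixel pitch $p$.

## 2. Synthetic cell generator

`make_phantom()` draws one cell from a `phenotype_spec()`:

* **Body.** A slightly triaxial ellipsoid: the equivalent radius is
  truncated-normal, the three semi-axes receive a fixed 5% log-normal
  jitter and are renormalised to preserve the volume.
* **Granules.** A Poisson-distributed number of spheres of extra RI
  contrast, rejection-sampled uniformly inside a shrunk copy of the
  ellipsoid so they stay fully internal.
* **Boundary roughness.** A low-order azimuthal Fourier modulation
  (orders 2–5, random phases) of the boundary with a specified total
  amplitude, evaluated in the phantom frame so the pattern rotates
  rigidly with the cell.
* **Rolling.** The rotation axis is the in-plane $x$ axis, transverse to
  the optical axis, emulating out-of-plane rolling in a microfluidic
  channel. `roll_sequence()` samples monotone angles over half a turn and
  adds i.i.d. Gaussian phase noise per frame (default $\sigma = 0.02$ rad).

**Projection.** `project_qpm()` integrates chords analytically rather
than ray-tracing a voxel grid: for a rotated ellipsoid the chord along
$z$ at $(x, y)$ solves a quadratic in the lab-frame quadratic form
$A_{lab} = R A R^\top$, and each granule contributes a spherical chord.
This makes the projection exact (to pixel sampling), fast, linear in
$\Delta n$, and exactly zero in the background. The roughness term is an
approximation: it modulates the in-plane boundary scale rather than
deforming the full 3-D surface, so phase volume is conserved exactly only
for the unperturbed convex body (numerically, rotation changes the
integrated phase of a granular phantom by $<10^{-3}$ relative).

**Calibrated default panel.** `default_phenotypes()` ships one
monocyte-like class (`THP1`: small, optically dense) and four
neuroblastoma-like lines forming two super-groups — NB1 =
{`CHP212`, `SKNBE2`} (large, dense, granule-rich) and NB2 = {`SHSY5Y`,
`SKNSH`} (smaller, lighter, boundary-rough). The two NB2 members are
deliberately identical in size and RI contrast and differ only in
granularity and boundary roughness, so they are separable mainly along
texture/fractal axes; the NB1 members differ modestly in size, density
and granularity. Differences within a super-group are smaller than
between super-groups, giving a structured five-class problem in which a
hierarchical classifier is the natural fit. These defaults were fixed
once, from the generator's design goals, before the evaluation runs.

## 3. Hologram encoding and reconstruction

`encode_hologram()` interferes the object wave $O = e^{i\varphi}$ with a
tilted plane reference and records $H = |O + R|^2$. Reconstruction
(`reconstruct_qpm()`) chains:

1. **Demodulation** — FFT, automatic carrier detection as the strongest
   peak outside a DC exclusion zone in the $f_y < 0$ half-plane (matching
   the encode convention, so $n > n_0$ maps to positive phase), circular
   hard mask of radius half the carrier–DC distance, re-centring on the
   carrier, inverse FFT.
2. **Refocusing** — angular-spectrum propagation with the exact transfer
   function $\exp(iz\sqrt{k^2 - k_x^2 - k_y^2})$ (evanescent band
   zeroed), with autofocus by minimising the Tamura coefficient
   $\sqrt{\sigma(I)/\mu(I)}$ of the amplitude image; exact ties resolve
   to the smallest $|z|$.
3. **Compensation** — subtraction of the phase of a reference hologram
   reconstructed through the same chain, removing carrier tilt and static
   aberrations.
4. **Unwrapping** — a quality-guided, reliability-sorted region-merging
   unwrapper (second-difference reliabilities, edges processed in
   decreasing reliability, regions merged with integer $2\pi$ shifts),
   implemented in C++ since no pre-installed R package provides 2-D
   unwrapping. The output differs from the input by an exact integer
   multiple of $2\pi$ at every pixel.
5. **Background zeroing** — the median of a border ring is subtracted.

On a noise-free $512^2$ hologram of a granular phantom, the full round
trip reconstructs the $200^2$ QPM with RMSE $\approx 0.04$ rad, dominated
by the hard Fourier mask; the acceptance suite asserts $< 0.05$ rad.

## 4. Segmentation and the 37-feature descriptor

`segment_qpm()` thresholds the phase at $0.1\times$ its maximum with a
noise floor of $5\times$ the background MAD, then closes (disc radius 2),
fills holes and keeps the largest component. A fraction-of-maximum
threshold (rather than a bimodal-histogram criterion such as Otsu) is a
deliberate design choice: a cell's phase falls smoothly to zero at the
rim, so histogram-split thresholds clip $\sim 14\%$ of the analytic disk
area, while the low fixed fraction recovers the support to within 1% and
keeps the dry-mass error below 0.1% on the sphere oracle.

`extract_features()` produces the canonical 37-element hybrid vector
(`feature_groups()`):

* **11 OPL statistics** over the support — mean, sd, max, skewness,
  kurtosis, 64-bin Shannon entropy and histogram mode, median, quartiles,
  and dry mass.
* **9 morphology features** of the binary support — area, extent,
  solidity (convex hull rasterised by point-in-polygon), max/min Feret
  diameters from the hull, circularity $4\pi A/P^2$ with the perimeter
  from Kulpa-corrected chain codes (weights 0.948/1.340; a raw
  8-connected chain length overestimates smooth perimeters by ~5% and
  would push a disk's circularity out of its analytic band), equivalent
  ellipse major axis and eccentricity from second moments with the
  $+1/12$ pixel-extent correction, and the binary-vs-phase-weighted
  centroid distance normalised by the equivalent radius.
* **4 GLCM texture features** — contrast, correlation, energy,
  homogeneity from a support-masked, symmetrised co-occurrence matrix at
  offset 1, direction 0°, 8 gray levels over the support range.
* **13 fractal features** — from two binary maps on a zero-padded
  $256^2$ grid: the support map and the "hole"/vertex map (normalised
  gradient magnitude $> 0.3$). Dyadic box counting ($s = 2^0 \dots 2^7$)
  yields dimension, regularity ($R^2$) and fit RMSE; gliding-box
  lacunarity $\Lambda(s) = \mathrm{var}/\mathrm{mean}^2 + 1$ (stride 1,
  computed with summed-area tables) yields the mean-log index and its fit
  RMSE; plus fill ratio, vertex density, normalised support-vs-hole
  contrasts, and a fine-vs-coarse lacunarity contrast of the hole map.
  These operational definitions are self-consistent stand-ins: dimension
  and lacunarity estimates on finite, mostly-filled cell masks are
  descriptors, not asymptotic fractal measurements (a filled disk on this
  grid fits to $\approx 1.5$–$1.7$, not 2, because coarse-scale counts
  saturate).

## 5. Hierarchical shallow-network classifier

Each node of the three-level tree — L1 monocyte/NB, L2 NB1/NB2, L3.1
CHP212/SKNBE2, L3.2 SHSY5Y/SKNSH — is a one-hidden-layer network: 100
ReLU units, softmax cross-entropy, Glorot-uniform initialisation,
L-BFGS (`optim(method = "L-BFGS-B")`, 1000-iteration cap, tolerance
$10^{-6}$ mapped to `factr`), features z-scored with training statistics
only. The net is implemented in-package because `nnet` offers neither
ReLU activations nor L-BFGS. Five-fold cross-validated accuracy is
reported per node. Feature sets are per-level: hybrid at L1/L2/L3.1 and
fractal-only at L3.2, where the two classes are constructed (and, in the
motivating study, observed) to differ mainly in fine texture.

Cells are classified by per-level **max-voting** (`max_vote()`): all
frames of a cell are predicted at a node, the majority class wins, and
even splits are broken by the larger mean posterior. `classify_frames()`
provides the no-voting per-frame baseline. Multiplying per-level voted
recalls along a root-to-leaf path (`global_probability()`) gives the
global probability of correctly classifying a cell of that line;
`reference_recalls()` stores the benchmark per-level recalls whose
products are 97.9% (monocyte), 89.1/78.4% (NB1 lines) and 74.5/73.6%
(NB2 lines).

## 6. Evaluation design and problem sizes

`build_split()` reproduces the reference split logic: sample a fixed
number of training cells per class among those with at least
`qpms_per_cell` frames, take exactly that many frames from each
(remaining frames of training cells are discarded), and keep *all* frames
of the other cells for testing, so no cell ever appears in both sets.
The monocyte training count equals the summed NB count, balancing L1.

The default study scale (`run_config()`) is a desk-scale choice of this
package: 52 monocyte + 4 × 24 NB cells, 8 frames each, training on
32 + 4 × 8 cells with 6 frames per training cell, a $512^2$ hologram
grid, and seed-derived sub-seeds for every stochastic stage. A full run
(simulate → extract → split → train → evaluate) takes ~2–3 minutes on one
CPU; feature tables are cached on disk keyed by a configuration hash when
`out_dir` is set. The deliberately small per-class test samples keep the
run fast and leave per-frame errors visible, which is what makes the
qualitative effects of interest — voting beating per-frame
classification, and the three-level tree at least matching a flat
five-class baseline on structured data — measurable at desk scale.

Analysis utilities mirror the study's inspection toolkit: PCA on z-scored
features with a deterministic sign convention, Fisher's two-class
criterion $J = \lVert\mu_A - \mu_B\rVert^2 / (\mathrm{tr}\Sigma_A +
\mathrm{tr}\Sigma_B)$ on the first two components, group-averaged
absolute Pearson correlations between the four feature families, and a
correlation-filtered (cutoff 0.9) binary ReliefF ranking (k = 10).

## 7. Limitations

* The roughness model perturbs the projected boundary, not the 3-D
  surface; roughness-heavy phantoms conserve phase volume only
  approximately under rotation.
* Phantoms are piecewise-homogeneous; real cytoplasm has continuous RI
  texture, so GLCM features on clean phantoms are driven by granules and
  rim geometry plus the additive noise.
* The fractal descriptors are operational (finite-scale) definitions;
  their absolute values depend on the padded grid and scale set and
  should be compared only within this package's conventions.
* The benchmark recalls in `reference_recalls()` describe a real-data
  study and are not regenerated by the synthetic pipeline; the pipeline
  reproduces the qualitative structure (hierarchy, voting gains), not
  those exact numbers.
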