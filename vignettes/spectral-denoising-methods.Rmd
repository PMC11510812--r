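---
title: "Self-supervised denoising for spectral CT: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised denoising for spectral CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spectraln2i)
```

## The problem

Photon-counting detectors resolve each X-ray event by energy, so a single CT
scan yields one sinogram per energy channel and, after channel-wise
reconstruction, an energy-resolved image stack of linear attenuation
coefficients (LAC, 1/cm). The price of spectral resolution is noise: a fixed
photon budget divided over a hundred channels leaves only a few hundred counts
per channel and pixel, and the low- and high-energy tails of the tube spectrum
are starved. Channel-wise filtered backprojection (FBP) of such data is very
noisy exactly where the spectral information (e.g. a K-edge fingerprint) is
most interesting, and clean reference images for supervised training do not
exist.

This package implements an unsupervised route: reconstructions from disjoint
subsets of projection angles carry *independent* noise realisations of the
same object, because counting noise is independent from projection to
projection. A network trained to predict one subset reconstruction from the
average of the others can therefore only learn the predictable part — the
object — and the noise averages out. No clean data enter the procedure at any
point.

## The measurement model

The simulation follows the poly-energetic Beer–Lambert law. For incident
fluence $I_0(E)$ (photons per detector pixel and channel) and line integrals
$y_p(E)$ of the LAC along each ray,

$$ N_p(E) \sim \mathrm{Poisson}\!\left(I_0(E)\, e^{-y_p(E)}\right), \qquad
   \tilde y_p(E) = \ln \frac{I_0(E)}{\max(N_p(E), 1)} . $$

Counts are clipped at one photon before the logarithm (a zero count carries no
finite attenuation estimate); the clip is recorded in the design here rather
than hidden, and at the photon budgets used it fires rarely. Noise is drawn
independently per channel, angle and detector cell — the physical model of a
photon-counting detector and the premise that makes the leave-one-out
training targets valid. Scatter, pulse pile-up, detector cross-talk and
beam hardening corrections are out of scope.

### Source spectrum

`build_source_spectrum()` implements a semi-empirical tungsten-anode model:

* a Kramers-type continuum, $N(E) \propto Z\,(E_0/E - 1)$ photons/keV per
  electron, with the absolute constant fixed by the standard thick-target
  efficiency rule $\eta \approx 1.1\times 10^{-9}\,ZV$;
* target self-absorption at the 12° take-off angle, with production depths
  from the Thomson–Whiddington relation
  $\rho x(E) = (E_0^2 - E^2)/c_{TW}$, $c_{TW} = 7.5\times10^{5}$ keV² cm²/g;
* the tungsten K fluorescence lines (Kα₁, Kα₂, Kβ₁, Kβ₂ at their tabulated
  energies and branching ratios), with a thick-target yield
  $N_K = y_K (U_0 - 1)^{1.63}$ anchored at about $2\times10^{-4}$ photons per
  electron at 100 kV;
* Beer–Lambert filtration (default 4 mm Al + 1 mm Be + 1000 mm air) through
  the packaged attenuation tables, and $1/4\pi z^2$ geometry at the 100 cm
  reference distance.

The spectral *shape*, the line positions, and everything downstream of the
normalisation step are robust. The *absolute* fluence scale of any
semi-empirical tube model is only good to a few tens of percent — the
efficiency constant and the K-yield each carry that much spread across the
literature — and since the whole pipeline normalises the spectrum to a fixed
photon budget (60 000 photons per detector pixel summed over channels), the
absolute scale never influences a reconstruction or a denoising result. It
only matters if one compares the raw peak fluence against a value produced by
a different generator.

The spectral channels of the reference configuration are built exactly as the
protocol prescribes: native 0.5 keV bins, linear interpolation of the fluence
density onto a 0.1 keV grid between 19.550 and 150.450 keV, then averaging
blocks of ten — 131 one-keV channels centred at 20–150 keV
(`reference_channel_spectrum()`).

### Attenuation data

Elemental mass attenuation coefficients are packaged as a plain-text table
transcribed from the public NIST/XCOM tabulations (H, C, N, O, Be, Al, I, W,
plus dry air as a mixture), with explicit grid points bracketing the Al, I
and W K-edges. Compounds use the mixture rule over parsed chemical formulas;
interpolation is log-log, the standard convention for attenuation curves on
sparse grids. Material densities follow the usual handbook values. The table
is sparse (22 points per element over 1–500 keV), which reproduces smooth
regions to well under a percent; values within a few hundred eV of an edge
are only as sharp as the bracketing points.

`find_k_edge()` reports the energy of the largest positive jump between
consecutive samples of a profile, provided the jump exceeds 20% of the local
value. On a 0.05 keV grid the iodine K-edge is recovered within one sample of
33.17 keV.

### Phantoms

The two four-material phantoms (water / olive oil / nitromethane / acetone
and methanol / ethylenediamine / aluminium / nitrobenzene) are 100×100 maps
of circles on a zero background. The published protocol does not fix the
object geometry, so the presets place four circles at the quadrant centres
with radii of 12–18% of the grid — explicit, recorded in the output metadata,
and configurable. Densities are modulated sinusoidally along x
($a = 0.05$, period 25 px by default; amplitude and period are likewise
unstated upstream and chosen as a small relative variation). LAC is assigned
per pixel as $(\mu/\rho)(E) \times \rho(x)$; there is no partial-volume
mixing at object borders.

### Geometry and projection

The fan-beam geometry uses the stated distances (57.50 cm source–object,
58.05 cm object–detector; magnification 2.0096) and a 256-cell, 0.8 mm-pitch
linear detector, 360 projections at 1°. The reconstruction grid spans the
detector field of view demagnified to the isocentre, i.e. 1.019 mm pixels for
the 100-pixel phantom. The projector samples each ray at half-pixel steps
with bilinear interpolation; its adjoint is the exact transpose (verified by
inner-product tests), which the iterative reconstruction requires. A
parallel-beam mode exists for analytic cross-checks.

## Reconstruction

`fbp_channelwise()` is a flat-detector fan-beam FBP: detector coordinates are
rebinned to the isocentre plane, projections are cosine-weighted, ramp
filtered, and backprojected with the $R^2/U^2$ distance weight. Two details
matter for the training scheme:

* The ramp filter is built from the exact band-limited spatial kernel (not a
  sampled $|f|$), which removes the DC bias of naive frequency sampling; a
  uniform disc reconstructs to its true attenuation within a fraction of a
  percent.
* The per-angle weight is $2\pi/n$ for a subset of $n$ equally spaced
  angles. Filtering is per-projection, so reconstruction is linear in the
  sinogram and the mean of the $K$ subset reconstructions equals the
  all-angle reconstruction *exactly* — the algebraic backbone of the
  leave-one-out averaging, tested to $10^{-6}$.

Filter windows: `"ram-lak"` truncates the ramp at $s \cdot f_{Nyquist}$;
`"hann"` multiplies it by a raised cosine reaching zero at
$s \cdot f_{Nyquist}$. The cutoff convention follows common FBP
implementations since the upstream description names the filters without
defining $s$.

`split_angles()` assigns angle indices $j, j+K, j+2K, \dots$ to subset $j$ —
every subset is itself an equally spaced schedule, and the subsets partition
the angles. The offset convention is asserted as the natural reading of
"equally spaced"; any fixed offset permutation would do equally well.

## The denoiser

For $K$ subset reconstructions, pair $j$ takes the mean of the other $K-1$
stacks as input and stack $j$ as target (`make_loo_pairs()`); the mean over
$j$ of the inputs equals the mean of all $K$ stacks, which is exactly what
the trained network later receives at inference (`denoise()`).

Training operates on 4×16×16 energy–spatial blocks cut on a regular stride
grid (`block_spec()`): the 4-deep energy axis maps to the network's channel
axis, so a 2D convolutional network learns from spectral context without a
3D architecture. Overlap is 75% by default on all axes at full scale;
flush-to-border blocks guarantee full coverage without padding, and
overlapping predictions are recombined by uniform averaging
(`assemble_blocks()`), the simplest unbiased choice. The round trip
extract → assemble is exact for any overlap.

The network (`unet_init()`) is a depth-3 U-Net: two 3×3 convolutions per
level, batch normalisation and ReLU after each, 2×2 max pooling, nearest-
neighbour upsampling with skip concatenation, and a 1×1 output projection.
Channel widths double per level from `base_channels` (default 32; the
upstream description fixes depth, activations, normalisation and pooling but
not the width). Training minimises the mean squared error over all blocks of
all pairs with Adam (learning rate $10^{-4}$, batch 32, fixed 100-epoch
schedule, no validation split or early stopping — the unsupervised setting
has nothing to validate against). The forward and backward passes are
implemented in R with C++ gather/scatter primitives and BLAS matrix
products; gradients are verified against finite differences in the test
suite. One integer seed drives weight initialisation and block shuffling;
training logs are bitwise reproducible for a fixed seed on one machine.

Block values are standardised by a single scalar mean/SD computed from the
training inputs (inverted at inference) — a data-scale convention that makes
the optimisation independent of the attenuation units, recorded in the model
checkpoint.

## Baselines

*Low2High* (`low2high_denoise()`): input = Hann($s=0.2$) FBP, target =
Ram-Lak FBP of the *same* full-angle data; training reuses the identical
block machinery and loss. Inference applies the model to the Hann-filtered
reconstruction — the upstream description trains the network to predict the
high-frequency content *from* the low-frequency image, and the low-filtered
image is what exists at test time. As reported there, the filter makes the
result smoother but biased low; the test suite checks both behaviours.

*IR-TV* (`tv_reconstruct()`): FISTA on
$\tfrac12\|Ax - \tilde y\|^2 + \alpha\,\mathrm{TV}(x)$, isotropic 2D TV per
channel with *no* energy coupling — deliberately, since the comparison point
is a purely spatial regulariser. The TV proximal step uses a Chambolle dual
iteration (20 inner iterations, step 0.25); the FISTA step size comes from a
power-iteration estimate of the projector norm (30 iterations). All channels
advance together with one multi-channel projection per iteration. Reference
strengths: $\alpha = 1$ (phantom 1), $0.5$ (phantom 2), $0.035$ (low-dose
real data). With $\alpha = 0$ the solver reduces to plain least squares and
matches a dense pseudo-inverse on a small system to $10^{-4}$.

## Metrics

`psnr()` uses $20\log_{10}(\max(f,g)) - 10\log_{10}(\mathrm{MSE})$ — the
*joint* maximum as printed in the reference definition, with a flag to switch
to the more common reference-max convention. Identical images return the
`Inf` sentinel, never a capped value. `ssim()` is a local 7×7 uniform-window
implementation with $c_1 = (0.01L)^2$, $c_2 = (0.03L)^2$, $L$ the reference
data range (community defaults; the upstream text says only "very small
values", and does not state whether its SSIM was windowed or global — the
windowed form is the field's default). `cnr()` implements
$|S_T - S_B|/(\sigma_T + \sigma_B)$; the denominator is taken as
$\sigma_T + \sigma_B$ (the printed formula line; the prose beneath it
contains an obvious typo repeating $\sigma_T$). ROI noise summaries average
per-channel SDs across channels. `evaluate_stack()` assembles channel-wise
PSNR/SSIM, their means and SDs across the energy axis, ROI profiles and
profile-MSE tables.

## The reduced study and what it shows

The full-scale configuration (131 channels, 100×100, K = 4, 75% overlap,
base-32 network, 100 epochs) is expressed in `paper_run_config()` but is not
what the test suite runs; the packaged study (`fixture_run_config()`,
`make_fixture()`) is a scaled-down version chosen once:

* 32 channels (the first 128 one-keV channels averaged in blocks of four),
  64×64 phantom with the first two preset-1 materials, 96-cell detector,
  360 angles, K = 4;
* photon budget 60000 × 32/131 ≈ 14 656 photons per pixel — this preserves
  the *per-channel* flux of the full study, hence its per-channel noise
  regime, which is the quantity the method's claims are about; keeping the
  total budget instead would make the reduced study four times cleaner per
  channel than the original;
* blocks 4×16×16 with 75% energy / 50% spatial overlap (the reduced spatial
  overlap mirrors the volumetric configuration upstream, which prioritised
  energy overlap when memory forced a cut);
* base-8 network, 20 epochs, learning rate $10^{-3}$. With roughly fifty
  times fewer gradient steps than the full schedule, the full-scale learning
  rate of $10^{-4}$ leaves the network visibly under-trained; the rate is
  raised one order of magnitude so the fixed 20-epoch budget reaches the
  loss plateau. This is a property of the reduced problem size, not a tuning
  knob of the method.

On this study the denoised stack beats the noisy all-angle FBP in
channel-mean PSNR and SSIM, with the largest PSNR gains in the low-flux edge
channels — the same qualitative pattern reported for the full-scale
experiments. What the reduced study does *not* show: behaviour under real
detector physics (spectral distortions, charge sharing), cone-beam geometry,
anatomical image content, or the volumetric (3D convolution) variant — all
outside this package's scope.

## Numerical details and degenerate inputs

* Zero counts are clipped to one before the log (flagged above).
* FBP of an all-zero sinogram is exactly zero; projections of an empty
  phantom are exactly zero; both are tested.
* `normalize_total_counts()` refuses all-zero spectra; `rebin_average()`
  refuses indivisible bin counts; block extraction refuses blocks larger
  than the stack; assembly refuses uncovered voxels.
* PSNR of identical images is `Inf`; CNR of two exactly constant regions
  with different means is `Inf` — sentinels are reported, never silently
  capped.
* The TV prox with $\lambda = 0$ is the identity, so $\alpha = 0$ runs cost
  nothing extra.
* All randomness (Poisson draws, weight init, shuffling, power-iteration
  start) flows from explicit integer seeds; artifact manifests record seed
  and configuration hash.

## Known limitations

* The tube model's absolute fluence scale inherits the uncertainty of its
  literature constants (see above); spectra are best used normalised.
* The attenuation table is compact; sub-keV structure near absorption edges
  is limited by the bracketing grid points.
* The fan-beam projector is 2D; the volumetric path and cone-beam FDK are
  out of scope.
* Training on a single CPU restricts the practical problem size; the
  full-scale configuration is provided for completeness and runs, but is not
  exercised by the automated tests.
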