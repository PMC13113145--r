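---
title: "Internal-coordinate diffusion for target-conditioned peptide design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-coordinate diffusion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`torsdiff` generates peptide-binder backbones with a denoising diffusion
probabilistic model (DDPM) that operates in internal coordinates rather
than Cartesian space. Each residue *i* carries a six-angle state

\[ a_i = (\phi_i, \psi_i, \omega_i, \theta_{1,i}, \theta_{2,i}, \theta_{3,i}), \]

the three backbone dihedrals plus the three local bond angles
(N–CA–C, CA–C–N, C–N–CA). Cartesian backbones never enter the diffusion
process: they are reconstructed from angles by the Natural Extension
Reference Frame (NeRF) algorithm with fixed Engh–Huber bond lengths
(N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å), so every generated structure
satisfies exact bond lengths and planar angles by construction, and
backbone-level chirality is inherited from the angle distribution rather
than enforced by a penalty.

Because angles live on a torus, each angle is embedded as the pair
\((\cos\alpha, \sin\alpha)\); the diffusion state is therefore an
\(L \times 12\) matrix. Noise is added by the closed-form forward kernel

\[ x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1 - \bar\alpha_t}\,\varepsilon,
   \qquad \varepsilon \sim \mathcal N(0, I), \]

and removed by the standard DDPM ancestral sampler with
\(\sigma_t = \sqrt{\beta_t}\) and a deterministic final step. Angles are
recovered from the (generally off-circle) sampled pairs by the
two-argument arctangent without renormalisation.

**Why diffuse the 12 embedded components rather than 6 raw angles?**
Gaussian noise is ill-defined on a torus but well-defined in the embedded
plane, and the embedding is what removes the \(2\pi\) discontinuity the
network would otherwise have to learn across. The inverse map is total:
any point in the plane yields an angle, with a zero-norm fallback to
ideal-geometry sentinels. We also diffuse \(\omega\) rather than clamping
it to trans; it is part of the residue state, and the trans preference is
left to be learned.

## Conditioning on the target

Per-residue experimental resolution \(R_i\) (Å) is mapped to a
reliability weight \(w_i = 1/(R_i + \epsilon)\) with \(\epsilon = 10^{-6}\),
a parameter-free inverse law: halving the quality (doubling \(R_i+\epsilon\))
halves a residue's feature magnitude. The weights gate the *raw*
geometric descriptors before any learnable layer, so unreliable geometry
is attenuated at the source. For X-ray entries that report a single
global resolution the map is a constant broadcast (gating then acts as a
uniform scale); a per-residue sidecar table serves heterogeneous
cryo-EM-style inputs. When no resolution is available at all, 2.0 Å is
broadcast with a warning — a mid-range default for PDB depositions.

The geometric half of the context uses rigid-invariant descriptors
(torsion trig embedding, sorted CA neighbour distances with k = 16,
local-frame dot products; 32 features), stacked over a width-3 sequence
window and linearly mapped to 256 features. The "width-3 convolution over
the chain" reading was chosen over a spatial-graph convolution because a
kernel *width* is a sequence-convolution notion; the descriptors
themselves already encode spatial neighbourhoods. The sequence half
projects a frozen per-residue embedding (\(L \times 1280\)) to 256
features. The two halves are concatenated into the \(L \times 512\)
context memory. The default embedding provider is a deterministic stub —
a seeded random projection of residue one-hots — so the package builds
and tests with no model download; a real protein-language-model provider
can be substituted behind the same one-argument interface, and its
choice is recorded in run metadata.

## The denoiser

The noise predictor is a pre-LayerNorm transformer decoder: 4 layers,
8 heads, width 512 (head width 64), FFN expansion 4, GELU activations.
The noisy state is projected to the latent width, scaled by
\(\sqrt{d}\) (the standard embedding convention; without it the state
signal is comparable to the additive encodings and learning any
input-dependent prediction is drastically delayed), and injected with
sinusoidal positional and time-step encodings to form queries; the
context memory — corrected by lifting the resolution weights through a
2-layer SiLU MLP and *adding* the result (addition keeps the 512-wide
memory; concatenation would not) and given positional encodings — forms
keys and values. Each block self-attends over binder positions before
cross-attending to the target, the standard decoder ordering. The
sequence branch is an architecturally identical parallel decoder without
time injection; it consumes clean angle embeddings and emits per-position
logits over the 20 canonical residues.

No deep-learning framework for R is used: the network, its training
loop, and a small tape-based reverse-mode automatic-differentiation
engine over matrices are implemented in the package, and every operator's
gradient is tested against central finite differences through the full
network.

## Schedules and training

Two variance schedules are provided: the linear schedule
(\(\beta\) from 0.001 to 0.02) and the squared-cosine schedule with
offset 0.008 and \(\beta\) clipped at 0.999. The linear schedule is the
training default; the family in force is a config field recorded in run
metadata. The composite loss is the static weighted sum
\(\lambda_{geo}\,\mathrm{MSE}(\varepsilon_\theta, \varepsilon) +
\lambda_{seq}\,\mathrm{CE}\), with \(\lambda_{geo} = \lambda_{seq} = 1\)
by default and the cross-entropy taken as a per-residue *mean* so loss
magnitudes are length-independent. Masked terminal angles are excluded
from the MSE. One Adam optimiser updates both branches and the
conditioning encoders in a single computation graph; training is fully
seeded and bit-reproducible.

Optimisation details that the architecture leaves open were fixed as
follows and are config fields: Adam with moment decays (0.9, 0.98) —
the faster second moment is standard transformer practice on small data
and was decisive for stability here — peak learning rate \(10^{-4}\)
for full-scale settings (\(3 \times 10^{-3}\) in the reduced desk-scale
experiments), 50 linear warmup steps, global gradient-norm clipping at
5 (single-sample gradients occasionally spike two orders of magnitude
above their running level), uniform sampling of the time step, one
complex per step. The learning-rate decay is *click-adaptive*: the peak
rate is held until the denoising loss leaves its initial plateau
(running mean below 0.5, against ~1.0 for the trivial zero predictor),
then cosine-annealed to 10% of the peak over the remaining steps. The
plateau-exit step varies between runs, and a decay fixed in advance
either starves a late exit of training time or never tightens an early
one; anchoring the decay to the observed exit gives every run a full
convergence phase. The sequence branch trains on native angles
perturbed by small torsional jitter (\(\sigma = 0.05\) rad, applied as
a rotation of each \((\cos,\sin)\) pair): whether that branch should
see native angles only or also sampled ones was genuinely open, and
jitter makes decoding robust on sampled conformations that sit close
to, but not exactly on, the training manifold — at zero extra cost. The
geometric branch always sees exact angles.

Joint single-sample training of two branches through a shared context
has a dead attractor: both heads predicting their marginals (zero
noise, uniform logits), where gradients nearly vanish. Training is
therefore multi-start: 45% of the way through, an attempt whose
denoising loss is still at the trivial-predictor level (or whose
sequence loss is still near uniform) is abandoned and restarted from a
shifted seed, up to four times, with the restart attempts scanning a
bracket of peak rates around the nominal one (which rate escapes the
plateau depends on the initialisation); the last attempt always runs to
completion. The detection thresholds sit halfway between the trivial
and the converged loss levels, far from both. The whole procedure
remains deterministic given the training seed, and the number of
restarts taken is reported alongside the loss trace.

Every training pair can be doubled by bidirectional role-swap
augmentation: the binder becomes the conditioning target (inheriting a
default resolution map if it has none) and the target becomes the
generation subject, which is how 2850 curated pairs become 5700
effective samples.

Sequence redundancy between training and test sets is controlled by a
greedy all-vs-all filter on global-alignment identity
(Needleman–Wunsch, match 1 / mismatch 0 / gap −1, identities divided by
the *longer* length so length mismatches are penalised), removing test
sequences at or above 30% identity — the homology "twilight zone"
boundary — to any training sequence. At desk scale this exact filter
replaces external clustering binaries; a hook accepts externally
clustered lists unchanged.

## Metrics

- **Interface contacts**: cross-chain heavy-atom pairs within 4.5 Å
  (boundary included, matching the indicator's \(\le\)). Generated
  backbones carry no side chains, so backbone-only counting is permitted
  and flagged in the report.
- **Radius of gyration / shape ratio**: RMS distance of CA atoms from
  their centroid; the shape ratio is the largest-to-smallest
  principal-radius ratio of the gyration tensor (smallest eigenvalue
  floored at \(10^{-6}\), ratio capped at \(10^3\) for degenerate
  clouds). The shape-ratio definition is a package choice; it is stated
  here because reported values depend on it.
- **Secondary structure**: a deterministic torsion-window classifier —
  helix for \(\phi \in [-100°, -30°]\), \(\psi \in [-67°, -7°]\); strand
  for \(\phi \in [-180°, -90°]\), \(\psi \in [90°, 180°]\); coil
  otherwise, with masked termini coil. This replaces hydrogen-bond-based
  assignment (which needs an external binary and full-atom geometry) and
  is documented as a deviation; window membership is exact and
  self-contained.
- **Clashes**: heavy-atom pairs closer than 2.5 Å, excluding
  intra-residue pairs and pairs between adjacent residues of one chain
  (which contain the covalent backbone bonds). The clash definition is a
  package choice, stated for the same reason.
- **Physicochemistry**: GRAVY as mean Kyte–Doolittle hydropathy;
  aromaticity as the F/W/Y fraction; isoelectric point by bisection of
  the net-charge function under the EMBOSS pKa table (recorded in report
  metadata).
- **Sequence identity**: the global-alignment scorer above, reported in
  percent.

All metrics are invariant under joint rigid transforms of the complex;
the test suite checks this property directly, along with brute-force
oracles for the spatial counts.

## What the synthetic fixtures emulate — and what they do not

Fixtures are built entirely in code: idealized helices
(\(\phi = -57°, \psi = -47°\)), strands (\(-135°, 135°\)), coils sampled
inside the broad allowed \(\beta\)/PPII basin (so fixtures remain
stereochemically clean but non-helical), and mixed chains; all trans
(\(\omega = 180°\)) with ideal bond angles. Toy complexes place a binder
at a controlled minimum cross-chain distance from a helical target
(bisection to ±0.1 Å along a seeded random direction), draw per-residue
resolution uniformly from 1.0–3.5 Å — a realistic span from good X-ray
to moderate cryo-EM quality — and store the resulting contact count as
planted ground truth. Binder lengths 8–15 and target lengths 20–28
mirror short peptide binders against small target domains at a size the
whole pipeline can train on in minutes on one CPU.

Passing tests on these fixtures demonstrates that the machinery is
correct: exact round trips, exact metric oracles, a reduced model that
memorizes and reproduces one complex through the full
noise-to-backbone-and-sequence path. It does **not** demonstrate
generalisation to real protein–protein interfaces: fixtures contain no
hydrogen-bond networks, desolvation, side-chain packing, or evolutionary
signal, and the stub embedding carries no biology. Conclusions about
real binder quality require training on curated complex data with a real
language-model provider.

## Numerical choices and degenerate inputs

- Dihedrals use the standard atan2 convention, wrapped to \((-\pi, \pi]\);
  NeRF placement is verified against the three defining identities
  (length, angle, dihedral) to \(10^{-9}\) rather than any particular
  trigonometric convention, since \(\theta\) vs \(\pi - \theta\)
  conventions differ between formulations.
- Collinear atom triples make dihedrals undefined; extraction and
  placement raise errors naming the residue rather than guessing.
- Bond angles recovered from sampled embeddings are folded into
  \((0, \pi)\) (absolute value, clamped away from the boundary), since a
  noisy \((\cos, \sin)\) pair can land below the axis.
- Masked terminal angles hold ideal-geometry sentinels so arrays keep a
  fixed shape; losses and metrics consult the mask, never the sentinel.
- The reduced test configuration (2 layers, width 64, T = 100,
  ≤ 2000 steps, one complex) is the package's memorization experiment;
  problem sizes throughout the suite (50-residue round-trip tables,
  10,000-draw moment checks, 200-instance contact oracles) were chosen
  so the full suite runs in minutes on one CPU while keeping each check
  statistically meaningful.

## Known limitations

- Internal-coordinate generation produces a *conformation*, not a pose:
  NeRF-reconstructed backbones live in a canonical frame, so the rigid
  placement of a generated binder relative to its target is undefined.
  Interface metrics (contacts, clashes) on generated complexes are only
  meaningful after an external placement or superposition step
  ([superpose_structures()] covers the memorization experiments, where a
  reference pose exists); the evaluation commands therefore operate on
  posed complexes such as the synthetic fixtures.
- Backbone-only generation: no side chains, no oxygen atoms beyond the
  optional cosmetic placement, no cis-proline handling.
- The torsion-window secondary-structure classifier is coarser than
  hydrogen-bond-based assignment near window boundaries.
- Per-residue resolution for X-ray structures is a broadcast global
  value; true local quality requires a user-supplied sidecar.
- The model is insensitive to heteroatoms, cofactors and ordered water;
  targets whose binding depends on them are outside the design envelope.
- Generated complexes may contain modest steric clashes by construction
  of the unconstrained sampler; downstream relaxation is expected in a
  real pipeline.
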