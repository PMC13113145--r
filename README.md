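# torsdiff

Internal-coordinate diffusion for target-conditioned peptide backbone
design, in R.

Designing peptide binders for protein–protein interfaces is hard for
rigid-body generative models: peptides are flexible, experimental target
structures vary widely in quality, and decoupled backbone-then-sequence
pipelines produce geometries no real sequence can support. `torsdiff`
addresses all three points in one framework, for computational structural
biologists who want a fully inspectable, dependency-light implementation:

- **Diffusion in internal coordinates.** Each residue is a six-angle
  state $a_i = (\phi_i, \psi_i, \omega_i, \theta_{1,i}, \theta_{2,i},
  \theta_{3,i})$, embedded on the unit circle as $(\cos\alpha,
  \sin\alpha)$ pairs, so the DDPM forward kernel
  $x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\varepsilon$
  and its reverse sampler act on an $L \times 12$ state. Cartesian
  backbones are reconstructed by the NeRF algorithm with fixed bond
  lengths, so generated structures obey exact stereochemistry.
- **Resolution-aware conditioning.** Per-residue resolution $R_i$ maps
  to reliability weights $w_i = 1/(R_i + \epsilon)$ that gate the
  target's geometric features at the source and are injected into the
  denoiser through a SiLU MLP.
- **Joint structure + sequence generation.** A cross-attention
  transformer decoder predicts the diffusion noise while a parallel
  branch decodes per-position amino-acid logits; one optimiser trains
  both with $L = \lambda_{geo}\,\mathrm{MSE}(\varepsilon_\theta,
  \varepsilon) + \lambda_{seq}\,\mathrm{CE}$ in a single graph
  (the network and its reverse-mode autodiff are implemented in the
  package; no deep-learning framework is required).
- **A metric suite** for generated complexes: interface contacts
  (4.5 Å heavy-atom cutoff), radius of gyration, gyration-tensor shape
  ratio, torsion-window secondary structure, clash counts,
  global-alignment sequence identity, GRAVY, aromaticity, isoelectric
  point.

Everything runs from synthetic fixtures generated in code — no downloads.

## Worked example

Train a reduced model on one synthetic complex, then sample a binder for
its target and evaluate it:

```r
library(torsdiff)

pair <- make_toy_complex(fixture_spec(kind = "helix", length = 10,
                                      target_length = 20, seed = 3))
cfg <- denoiser_config(n_layers = 2, n_heads = 2, model_dim = 64)
sch <- make_schedule("linear", T_steps = 100)
fit <- train(list(pair), cfg, sch, steps = 2000, lr = 3e-3, seed = 11)

ctx <- build_context(pair$target$structure, pair$target$sequence,
                     pair$target$resolution, fit$model)
tab <- sample_trajectory(make_denoiser(fit$model, ctx), ctx,
                         L = 10, sch, seed = 101)
seq <- logits_to_sequence(predict_sequence(embed_angles(tab), ctx, fit$model))
# generated conformations live in a canonical frame; superpose onto the
# native pose before computing interface metrics
binder <- superpose_structures(nerf_reconstruct(tab, sequence = seq, chain_id = "B"),
                               pair$binder$structure)
evaluate_complex(pair$target$structure, binder, binder_sequence = seq,
                 native_sequence = pair$binder$sequence)
```

On this memorization task the run above prints a final evaluation loss
of 0.031 (geometry MSE plus sequence cross-entropy, uniform over all
diffusion steps), the sampled backbone sits 1.1 Angstrom RMSD from the
memorized pose, and the decoded sequence `MAPFSYDLVG` recovers the
native binder exactly. The metric report prints one row:

```
  length contacts       rg seq_identity helicity rama_helix shape_ratio clashes
1     10        5 4.774728          100        1          1    3.017829       0
  gravy aromaticity isoelectric_point
1  0.69         0.2          3.749987
```

`contacts` counts cross-chain heavy-atom pairs within 4.5 Angstrom (the
fixture plants 6; the sampled conformation reproduces 5),
`helicity`/`rama_helix` are torsion-window fractions (1 for an ideal
helix), `shape_ratio` ~3 reflects a short rod-like helix, and the
physicochemical columns describe the decoded sequence.

The same pipeline is available from the shell:

```sh
inst/cli/torsdiff fixtures --config run.yaml
inst/cli/torsdiff train    --config run.yaml
inst/cli/torsdiff sample   --config run.yaml sample.target_pdb=fixtures/..._target.pdb
inst/cli/torsdiff evaluate --config run.yaml
```

Each command writes its effective config, package version and seeds next
to its outputs.

## Scope

Backbone-level generation only (N/CA/C): no side chains, no
heteroatoms/cofactors, no binding free energies. The methods vignette
(`vignettes/torsion-diffusion.Rmd`) documents the model, every tunable
parameter, the design decisions taken where the architecture left
choices open, and what the synthetic fixtures do and do not demonstrate.
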