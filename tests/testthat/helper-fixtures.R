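# Shared test fixtures, built once per test run.

# a random but physically plausible angle table
random_angle_table <- function(L, seed) {
  torsdiff:::with_seed(seed, {
    ang <- cbind(stats::runif(L, -pi, pi), stats::runif(L, -pi, pi),
                 stats::runif(L, -pi, pi),
                 stats::runif(L, 1.4, 2.6), stats::runif(L, 1.4, 2.6),
                 stats::runif(L, 1.4, 2.6))
    angle_table(ang)
  })
}

flat_coords <- function(structure) {
  matrix(aperm(structure$coords, c(2, 1, 3)), ncol = 3)
}

# hand-written PDB ATOM line (fixed-width) for synthetic parser inputs
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z, insert = " ") {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial, elety, resid, chain, resno, insert, x, y, z,
          substr(elety, 1, 1))
}

# tiny shared model/complex for network-level tests (kept deliberately small)
tiny_cfg <- denoiser_config(n_layers = 1, n_heads = 2, model_dim = 16,
                            ffn_ratio = 2, res_hidden = 8, parameter_seed = 7)
tiny_pair <- make_toy_complex(fixture_spec(kind = "helix", length = 6,
                                           target_length = 20, seed = 42))
tiny_model <- init_model(tiny_cfg)
tiny_provider <- stub_provider(123)
tiny_context <- build_context(tiny_pair$target$structure, tiny_pair$target$sequence,
                              tiny_pair$target$resolution, tiny_model, tiny_provider)
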