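# Self-contained synthetic fixtures: idealized secondary-structure chains
# with known torsions, toy target/binder complexes placed at a controlled
# interface distance, and reproducible toy datasets. Everything is built
# in code from the ideal geometry constants -- no downloads, no data files.

#' Fixture specification
#'
#' @param kind chain kind: `"helix"`, `"strand"`, `"coil"` or `"mixed"`.
#' @param length binder length (>= 4).
#' @param target_length target chain length (>= 20).
#' @param interface_distance desired minimum cross-chain heavy-atom
#'   distance in Angstrom.
#' @param res_range uniform range (Angstrom) the per-residue resolution is
#'   drawn from; emulates mixed-quality experimental structures.
#' @param seed integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = "helix", length = 12, target_length = 24,
                         interface_distance = 4.0, res_range = c(1.0, 3.5),
                         seed = 1) {
  stopifnot(length >= 4, target_length >= 20, res_range[1] > 0)
  structure(list(kind = kind, length = length, target_length = target_length,
                 interface_distance = interface_distance,
                 res_range = res_range, seed = seed),
            class = "fixture_spec")
}

ideal_torsions <- function(kind, L, seed) {
  deg <- pi / 180
  sent <- geometry_constants()$sentinels
  phi_psi <- with_seed(seed, switch(
    kind,
    helix = cbind(rep(-57 * deg, L), rep(-47 * deg, L)),
    strand = cbind(rep(-135 * deg, L), rep(135 * deg, L)),
    # coil: sampled inside the broad allowed beta/PPII basin, away from the
    # helical window, so fixtures stay stereochemically clean but non-helical
    coil = cbind(stats::runif(L, -180 * deg, -60 * deg),
                 stats::runif(L, 60 * deg, 180 * deg)),
    mixed = {
      half <- floor(L / 2)
      rbind(cbind(rep(-57 * deg, half), rep(-47 * deg, half)),
            cbind(rep(-135 * deg, L - half), rep(135 * deg, L - half)))
    },
    stop("unknown fixture kind: ", kind)))
  ang <- cbind(phi_psi[, 1], phi_psi[, 2], rep(pi, L),
               rep(sent["theta1"], L), rep(sent["theta2"], L), rep(sent["theta3"], L))
  colnames(ang) <- ANGLE_NAMES
  ang
}

#' Build an idealized chain with known torsions
#'
#' Helix uses phi = -57, psi = -47 degrees; strand phi = -135, psi = 135;
#' coil draws torsions from the allowed beta/PPII basin; mixed is half
#' helix, half strand. Omega is trans (180 degrees) and bond angles take
#' the ideal values, so [extract_angles()] on the result returns exactly
#' the constructed table (an extraction/construction inverse pair).
#'
#' @param kind `"helix"`, `"strand"`, `"coil"` or `"mixed"`.
#' @param length chain length (>= 4).
#' @param seed seed for coil torsions and the random sequence.
#' @param chain_id chain identifier.
#' @return list with `structure` ([backbone_structure()]), `angles`
#'   ([angle_table()]) and `sequence` (one-letter string).
#' @export
make_ideal_chain <- function(kind, length, seed = 1, chain_id = "A") {
  ang <- ideal_torsions(kind, length, seed)
  tab <- angle_table(ang)
  sequence <- with_seed(seed + 1,
                        paste(sample(CANONICAL_AA, length, replace = TRUE), collapse = ""))
  st <- nerf_reconstruct(tab, sequence = sequence, chain_id = chain_id)
  list(structure = st, angles = tab, sequence = sequence)
}

min_cross_distance <- function(a, b) {
  sqrt(min(cross_dist2(a, b)))
}

all_atoms <- function(structure) heavy_atom_coords(structure)$coords

#' Build a toy target/binder complex
#'
#' The binder is rigidly rotated (seeded) and translated along a random
#' direction from the target centroid until the minimum cross-chain
#' heavy-atom distance matches `interface_distance` to within 0.1 Angstrom
#' (bisection). A per-residue resolution map is drawn uniformly from
#' `res_range`, and the resulting contact count is stored as planted ground
#' truth.
#'
#' @param spec a [fixture_spec()].
#' @return a `complex_pair`: list with `pair_id`, `target`
#'   (structure/sequence/resolution), `binder` (structure/sequence),
#'   `role_swapped` flag and `planted_contacts`.
#' @export
make_toy_complex <- function(spec) {
  tgt <- make_ideal_chain("helix", spec$target_length, seed = spec$seed, chain_id = "A")
  bnd <- make_ideal_chain(spec$kind, spec$length, seed = spec$seed + 1000, chain_id = "B")
  placed <- with_seed(spec$seed + 2000, {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    rot <- random_rotation()
    b0 <- transform_structure(bnd$structure, rot, c(0, 0, 0))
    tgt_atoms <- all_atoms(tgt$structure)
    tgt_centroid <- colMeans(tgt_atoms)
    shift_to <- function(s) {
      b_atoms <- all_atoms(b0)
      delta <- tgt_centroid + s * u - colMeans(b_atoms)
      transform_structure(b0, diag(3), delta)
    }
    f <- function(s) min_cross_distance(all_atoms(shift_to(s)), tgt_atoms)
    lo <- 0; hi <- 10
    while (f(hi) < spec$interface_distance) hi <- hi * 2
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) < spec$interface_distance) lo <- mid else hi <- mid
      if (abs(f(mid) - spec$interface_distance) < 0.01) break
    }
    shift_to((lo + hi) / 2)
  })
  resmap <- with_seed(spec$seed + 3000,
                      resolution_map(stats::runif(spec$target_length,
                                                  spec$res_range[1], spec$res_range[2]),
                                     source = "fixture"))
  planted <- interface_contacts(all_atoms(placed), all_atoms(tgt$structure))
  structure(list(pair_id = sprintf("fixture_%s_%d", spec$kind, spec$seed),
                 target = list(structure = tgt$structure, sequence = tgt$sequence,
                               resolution = resmap),
                 binder = list(structure = placed, sequence = bnd$sequence,
                               angles = bnd$angles),
                 role_swapped = FALSE,
                 planted_contacts = planted),
            class = "complex_pair")
}

#' Build a reproducible toy dataset of complex pairs
#'
#' Cycles through chain kinds and varies binder/target lengths, interface
#' distances and resolution draws, all derived from `seed`.
#'
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @param kinds chain kinds cycled over.
#' @return list of `complex_pair` objects.
#' @export
make_dataset <- function(n_pairs, seed = 1, kinds = c("helix", "strand", "coil", "mixed")) {
  lapply(seq_len(n_pairs), function(k) {
    sp <- with_seed(seed + 17 * k, fixture_spec(
      kind = kinds[(k - 1) %% length(kinds) + 1],
      length = sample(8:15, 1),
      target_length = sample(20:28, 1),
      interface_distance = stats::runif(1, 4, 6),
      seed = seed + 1000 * k))
    make_toy_complex(sp)
  })
}

#' Write fixture files (PDB + FASTA + resolution sidecars) to a directory
#'
#' @param pairs list of `complex_pair` objects (e.g. from [make_dataset()]).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture_files <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in pairs) {
    base <- file.path(dir, p$pair_id)
    write_pdb(p$target$structure, paste0(base, "_target.pdb"))
    write_pdb(p$binder$structure, paste0(base, "_binder.pdb"))
    write_fasta(data.frame(id = c(paste0(p$pair_id, "_target"), paste0(p$pair_id, "_binder")),
                           sequence = c(p$target$sequence, p$binder$sequence)),
                paste0(base, ".fasta"))
    write_resolution(p$target$resolution, paste0(base, "_target.res"))
  }
  invisible(dir)
}
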