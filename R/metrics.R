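# Evaluation metric suite: interface geometry (contacts, clashes),
# topology (radius of gyration, gyration-tensor shape ratio, torsion-window
# secondary structure), sequence novelty (global-alignment identity) and
# physicochemistry (GRAVY, aromaticity, isoelectric point).

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# EMBOSS pKa values used for the isoelectric point
PKA_TABLE <- list(name = "EMBOSS",
                  nterm = 8.6, cterm = 3.6,
                  acidic = c(C = 8.5, D = 3.9, E = 4.1, Y = 10.1),
                  basic = c(H = 6.5, K = 10.8, R = 12.5))

#' Heavy-atom coordinates of a structure
#'
#' Uses the retained heavy-atom records when present, otherwise the N/CA/C
#' backbone atoms (generated structures carry no side chains; reports note
#' backbone-only counting).
#' @param structure a [backbone_structure()].
#' @return list with `coords` (n x 3) and `res_index` (residue of each atom).
#' @export
heavy_atom_coords <- function(structure) {
  if (!is.null(structure$heavy_atoms) && nrow(structure$heavy_atoms) > 0) {
    h <- structure$heavy_atoms
    list(coords = as.matrix(h[, c("x", "y", "z")]), res_index = h$res_index,
         backbone_only = FALSE)
  } else {
    L <- n_residues(structure)
    list(coords = matrix(aperm(structure$coords, c(2, 1, 3)), ncol = 3),
         res_index = rep(seq_len(L), each = 3), backbone_only = TRUE)
  }
}

cross_dist2 <- function(a, b) {
  # squared Euclidean distances between rows of a and rows of b
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Interface contact count
#'
#' Number of cross-chain heavy-atom pairs whose Euclidean distance is at
#' most `d_cutoff` (4.5 Angstrom), a direct measure of the density of the
#' non-covalent interaction network at the interface.
#'
#' @param ligand_atoms,target_atoms n x 3 coordinate matrices (heavy atoms).
#' @param d_cutoff distance threshold in Angstrom; the comparison is `<=`.
#' @return integer contact count (equals the brute-force double loop).
#' @export
interface_contacts <- function(ligand_atoms, target_atoms, d_cutoff = 4.5) {
  ligand_atoms <- as.matrix(ligand_atoms)
  target_atoms <- as.matrix(target_atoms)
  if (nrow(ligand_atoms) == 0 || nrow(target_atoms) == 0) return(0L)
  sum(cross_dist2(ligand_atoms, target_atoms) <= d_cutoff^2 + 1e-12)
}

#' Radius of gyration
#'
#' Root-mean-square distance of the alpha-carbon atoms from their centroid
#' (unit masses); small values indicate compact folds, large values extended
#' or coil states.
#' @param calpha_coords n x 3 coordinate matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(calpha_coords) {
  m <- as.matrix(calpha_coords)
  if (nrow(m) == 0) stop("radius of gyration needs at least one atom")
  centred <- sweep(m, 2, colMeans(m))
  sqrt(mean(rowSums(centred^2)))
}

#' Gyration-tensor shape ratio
#'
#' Ratio of the largest to the smallest principal radius (square roots of
#' the gyration-tensor eigenvalues). Near 1 for sphere-like clouds, large
#' for rod-like chains; the smallest eigenvalue is floored at `floor_eig`
#' and the ratio capped at `max_ratio` to keep degenerate (collinear)
#' inputs finite.
#' @param calpha_coords n x 3 coordinate matrix.
#' @param floor_eig eigenvalue floor (1e-6).
#' @param max_ratio reported cap for degenerate inputs.
#' @export
shape_ratio <- function(calpha_coords, floor_eig = 1e-6, max_ratio = 1e3) {
  m <- as.matrix(calpha_coords)
  centred <- sweep(m, 2, colMeans(m))
  gyr <- crossprod(centred) / nrow(m)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  min(sqrt(ev[1] / max(ev[3], floor_eig)), max_ratio)
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment (match 1, mismatch 0, linear gap -1);
#' the number of identically aligned residues is divided by
#' `max(L_pred, L_nat)` so that length discrepancies are strictly
#' penalised, and reported as a percentage.
#'
#' @param pred_seq,nat_seq one-letter sequences.
#' @return identity in percent (0..100).
#' @export
sequence_identity <- function(pred_seq, nat_seq) {
  a <- strsplit(pred_seq, "")[[1]]
  b <- strsplit(nat_seq, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0)
  gap <- -1
  score <- matrix(0, n + 1, m + 1)
  score[, 1] <- gap * (0:n)
  score[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    si <- score[i, ]
    diag_sc <- si[1:m] + (a[i] == b)          # match 1, mismatch 0
    row <- numeric(m + 1)
    row[1] <- gap * i
    up <- si[2:(m + 1)] + gap
    for (j in seq_len(m)) {
      row[j + 1] <- max(diag_sc[j], up[j], row[j] + gap)
    }
    score[i + 1, ] <- row
  }
  # traceback preferring diagonal moves, counting identities
  i <- n; j <- m; nmatch <- 0L
  while (i > 0 && j > 0) {
    sub <- if (a[i] == b[j]) 1 else 0
    if (score[i + 1, j + 1] == score[i, j] + sub) {
      nmatch <- nmatch + (a[i] == b[j])
      i <- i - 1; j <- j - 1
    } else if (score[i + 1, j + 1] == score[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  100 * nmatch / max(n, m)
}

# torsion windows (radians)
HELIX_WINDOW <- list(phi = c(-100, -30) * pi / 180, psi = c(-67, -7) * pi / 180)
STRAND_WINDOW <- list(phi = c(-180, -90) * pi / 180, psi = c(90, 180) * pi / 180)

in_window <- function(phi, psi, w) {
  phi >= w$phi[1] & phi <= w$phi[2] & psi >= w$psi[1] & psi <= w$psi[2]
}

#' Torsion-window secondary-structure assignment
#'
#' Deterministic, self-contained classifier on backbone torsions:
#' H (helix) for phi in -100..-30 and psi in -67..-7 degrees,
#' E (strand) for phi in -180..-90 and psi in 90..180 degrees,
#' C otherwise. Residues with a masked phi or psi (termini) are labelled C.
#'
#' @param angles an [angle_table()].
#' @return character vector of per-residue labels in {H, E, C}.
#' @export
assign_secondary <- function(angles) {
  phi <- angles$angles[, "phi"]
  psi <- angles$angles[, "psi"]
  ok <- angles$valid[, "phi"] & angles$valid[, "psi"]
  lab <- rep("C", angles$length)
  lab[ok & in_window(phi, psi, HELIX_WINDOW)] <- "H"
  lab[ok & in_window(phi, psi, STRAND_WINDOW)] <- "E"
  lab[!ok] <- "C"
  lab
}

#' Helical content
#'
#' Fraction of residues with both torsions defined that fall in the helical
#' torsion window.
#' @param angles an [angle_table()].
#' @export
helicity <- function(angles) {
  lab <- assign_secondary(angles)
  ok <- angles$valid[, "phi"] & angles$valid[, "psi"]
  if (!any(ok)) return(0)
  mean(lab[ok] == "H")
}

#' Fraction of residues in the helical Ramachandran window
#' @param angles an [angle_table()].
#' @export
rama_helix_fraction <- function(angles) {
  phi <- angles$angles[, "phi"]
  psi <- angles$angles[, "psi"]
  ok <- angles$valid[, "phi"] & angles$valid[, "psi"]
  if (!any(ok)) return(0)
  mean(in_window(phi[ok], psi[ok], HELIX_WINDOW))
}

#' Ramachandran histogram
#'
#' 2-D count histogram of defined (phi, psi) pairs on a regular grid over
#' (-pi, pi]^2.
#' @param angles an [angle_table()].
#' @param bins grid size per axis (36).
#' @return `bins x bins` integer matrix (rows phi, columns psi).
#' @export
rama_density <- function(angles, bins = 36) {
  phi <- angles$angles[, "phi"]
  psi <- angles$angles[, "psi"]
  ok <- angles$valid[, "phi"] & angles$valid[, "psi"]
  brk <- seq(-pi, pi, length.out = bins + 1)
  cut2 <- function(x) pmin(pmax(findInterval(x, brk, left.open = TRUE, all.inside = TRUE), 1), bins)
  h <- matrix(0L, bins, bins)
  for (k in which(ok)) {
    i <- cut2(phi[k]); j <- cut2(psi[k])
    h[i, j] <- h[i, j] + 1L
  }
  h
}

#' Steric clash count
#'
#' Number of heavy-atom pairs closer than `cutoff` (2.5 Angstrom),
#' excluding pairs within one residue and pairs between adjacent residues
#' of the same chain (which include the covalently bonded backbone atoms).
#'
#' @param structures a [backbone_structure()] or list of them (a complex).
#' @param cutoff clash distance in Angstrom; the comparison is strict `<`.
#' @return integer clash count.
#' @export
clash_count <- function(structures, cutoff = 2.5) {
  if (inherits(structures, "backbone_structure")) structures <- list(structures)
  coords <- list(); res <- integer(0); chain <- integer(0)
  for (k in seq_along(structures)) {
    h <- heavy_atom_coords(structures[[k]])
    coords[[k]] <- h$coords
    res <- c(res, h$res_index)
    chain <- c(chain, rep(k, nrow(h$coords)))
  }
  xyz <- do.call(rbind, coords)
  n <- nrow(xyz)
  if (n < 2 || cutoff <= 0) return(0L)
  d2 <- cross_dist2(xyz, xyz)
  close_pair <- d2 < cutoff^2 - 1e-12
  same_chain <- outer(chain, chain, "==")
  res_gap <- abs(outer(res, res, "-"))
  excluded <- same_chain & (res_gap <= 1)
  close_pair[excluded] <- FALSE
  sum(close_pair[upper.tri(close_pair)])
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence; positive values are
#' hydrophobic.
#' @param seq one-letter sequence.
#' @export
gravy <- function(seq) {
  validate_sequence(seq)
  mean(KYTE_DOOLITTLE[strsplit(seq, "")[[1]]])
}

#' Aromatic residue fraction
#' @param seq one-letter sequence; aromatic residues are F, W and Y.
#' @export
aromaticity <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  mean(chars %in% c("F", "W", "Y"))
}

#' Net peptide charge at a given pH
#' @param seq one-letter sequence.
#' @param pH pH value.
#' @keywords internal
net_charge <- function(seq, pH) {
  chars <- strsplit(seq, "")[[1]]
  pos <- 1 / (1 + 10^(pH - PKA_TABLE$nterm)) +
    sum(vapply(names(PKA_TABLE$basic), function(a)
      sum(chars == a) / (1 + 10^(pH - PKA_TABLE$basic[[a]])), numeric(1)))
  neg <- 1 / (1 + 10^(PKA_TABLE$cterm - pH)) +
    sum(vapply(names(PKA_TABLE$acidic), function(a)
      sum(chars == a) / (1 + 10^(PKA_TABLE$acidic[[a]] - pH)), numeric(1)))
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the net charge (EMBOSS pKa values, including termini)
#' crosses zero, found by bisection; the pKa table name is recorded in
#' report metadata.
#' @param seq one-letter sequence.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq) {
  validate_sequence(seq)
  stats::uniroot(function(p) net_charge(seq, p), c(0, 14), tol = 1e-8)$root
}

#' Pearson correlation between chain length and contact count
#'
#' @param records data.frame (or list of pairs) with columns `length` and
#'   `contacts`.
#' @return Pearson r; `NA` with attribute `reason` when fewer than 3 records
#'   or a zero-variance margin makes it undefined.
#' @export
length_contact_correlation <- function(records) {
  records <- as.data.frame(records)
  x <- records$length; y <- records$contacts
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "undefined: n < 3 or zero variance"
    return(out)
  }
  stats::cor(x, y)
}

#' Evaluate one target/binder complex
#'
#' Runs the full metric suite and returns one report row. Sequence identity
#' to the native binder is included when `native_sequence` is given.
#'
#' @param target target [backbone_structure()].
#' @param binder binder [backbone_structure()].
#' @param binder_sequence one-letter binder sequence.
#' @param native_sequence optional native binder sequence for the identity
#'   metric.
#' @return one-row data.frame (a metric report); attribute `backbone_only`
#'   records whether contacts/clashes used backbone atoms only.
#' @export
evaluate_complex <- function(target, binder, binder_sequence = structure_sequence(binder),
                             native_sequence = NULL) {
  lig <- heavy_atom_coords(binder)
  tgt <- heavy_atom_coords(target)
  ang <- extract_angles(binder)
  ca <- binder$coords[, "CA", ]
  rep_row <- data.frame(
    length = n_residues(binder),
    contacts = interface_contacts(lig$coords, tgt$coords),
    rg = radius_of_gyration(ca),
    seq_identity = if (is.null(native_sequence)) NA_real_ else
      sequence_identity(binder_sequence, native_sequence),
    helicity = helicity(ang),
    rama_helix = rama_helix_fraction(ang),
    shape_ratio = shape_ratio(ca),
    clashes = clash_count(list(target, binder)),
    gravy = gravy(binder_sequence),
    aromaticity = aromaticity(binder_sequence),
    isoelectric_point = isoelectric_point(binder_sequence))
  attr(rep_row, "backbone_only") <- lig$backbone_only || tgt$backbone_only
  attr(rep_row, "pka_table") <- PKA_TABLE$name
  rep_row
}

#' Evaluate a batch of complexes
#'
#' @param complexes list of lists with elements `target`, `binder` and
#'   optionally `binder_sequence`, `native_sequence`.
#' @return list with `per_complex` (one row each) and `aggregate`
#'   (mean/median/sd per metric).
#' @export
evaluate_batch <- function(complexes) {
  rows <- lapply(complexes, function(cx) {
    evaluate_complex(cx$target, cx$binder,
                     binder_sequence = cx$binder_sequence %||% structure_sequence(cx$binder),
                     native_sequence = cx$native_sequence)
  })
  per <- do.call(rbind, rows)
  num <- per[vapply(per, is.numeric, logical(1))]
  agg <- data.frame(metric = names(num),
                    mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1)),
                    median = vapply(num, function(v) stats::median(v, na.rm = TRUE), numeric(1)),
                    sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
                    row.names = NULL)
  list(per_complex = per, aggregate = agg)
}
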