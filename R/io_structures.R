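# Structure and sequence I/O: PDB backbones, per-residue resolution maps,
# FASTA records. PDB parsing/writing is delegated to bio3d; this module
# enforces the backbone completeness contract and field extraction that the
# rest of the framework relies on.

CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Backbone structure container
#'
#' Ordered N/CA/C backbone coordinates with residue identities. The core
#' Cartesian representation used throughout: NeRF output, metric input,
#' PDB round-trip unit.
#'
#' @param coords numeric array `L x 3 x 3`: residues x atoms (N, CA, C) x xyz, in Angstrom.
#' @param residue_names character vector of 3-letter residue codes.
#' @param resno integer residue numbers (1-based by default).
#' @param insert insertion codes, `""` when absent.
#' @param chain_id single chain character.
#' @param heavy_atoms optional data.frame of all heavy atoms
#'   (columns `res_index`, `resno`, `elety`, `x`, `y`, `z`) for contact/clash metrics.
#' @return an object of class `backbone_structure`.
#' @export
backbone_structure <- function(coords, residue_names, resno = seq_len(dim(coords)[1]),
                               insert = rep("", dim(coords)[1]), chain_id = "A",
                               heavy_atoms = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3, dim(coords)[3] == 3)
  L <- dim(coords)[1]
  stopifnot(length(residue_names) == L, length(resno) == L, length(insert) == L)
  dimnames(coords) <- list(NULL, c("N", "CA", "C"), c("x", "y", "z"))
  structure(list(coords = coords, residue_names = as.character(residue_names),
                 resno = as.integer(resno), insert = as.character(insert),
                 chain_id = chain_id, heavy_atoms = heavy_atoms),
            class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  cat(sprintf("<backbone_structure> chain %s, %d residues\n", x$chain_id, n_residues(x)))
  invisible(x)
}

#' Number of residues in a backbone structure
#' @param structure a `backbone_structure`.
#' @export
n_residues <- function(structure) dim(structure$coords)[1]

#' Residue identifiers (residue number + insertion code)
#' @param structure a `backbone_structure`.
#' @export
residue_ids <- function(structure) paste0(structure$resno, structure$insert)

#' One-letter sequence of a backbone structure
#' @param structure a `backbone_structure`.
#' @return one-letter sequence string; unknown residues become `X`.
#' @export
structure_sequence <- function(structure) {
  one <- AA_ONE[structure$residue_names]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Read a backbone structure from a PDB file
#'
#' Residues missing any of the three backbone atoms (N, CA, C) are dropped
#' with a warning; remaining heavy atoms of kept residues are retained for
#' contact/clash metrics. Residue order follows the chain order in the file
#' and insertion codes are preserved.
#'
#' @param path PDB file path.
#' @param chain chain identifier to extract; `NULL` selects the first chain.
#' @return a [backbone_structure()].
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not present in %s; available chains: %s",
                 chain, path, paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  rid <- paste0(at$resno, at$insert)
  rid_order <- unique(rid)                       # file order
  keep <- logical(length(rid_order))
  coords <- array(NA_real_, c(length(rid_order), 3, 3))
  resnames <- character(length(rid_order))
  for (k in seq_along(rid_order)) {
    rows <- at[rid == rid_order[k], , drop = FALSE]
    has <- vapply(c("N", "CA", "C"), function(e) any(rows$elety == e), logical(1))
    if (all(has)) {
      keep[k] <- TRUE
      for (j in 1:3) {
        r <- rows[rows$elety == c("N", "CA", "C")[j], , drop = FALSE][1, ]
        coords[k, j, ] <- c(r$x, r$y, r$z)
      }
      resnames[k] <- rows$resid[1]
    }
  }
  if (!all(keep)) {
    warning(sprintf("dropped %d residue(s) with incomplete backbone in %s chain %s",
                    sum(!keep), basename(path), chain))
  }
  if (!any(keep)) stop("no residue with a complete N/CA/C backbone in chain ", chain)
  kept_ids <- rid_order[keep]
  sel <- rid %in% kept_ids & !grepl("^H", at$elety)   # heavy atoms of kept residues
  heavy <- data.frame(res_index = match(rid[sel], kept_ids),
                      resno = at$resno[sel], elety = at$elety[sel],
                      x = at$x[sel], y = at$y[sel], z = at$z[sel],
                      stringsAsFactors = FALSE)
  idx <- match(kept_ids, rid)
  backbone_structure(coords[keep, , , drop = FALSE], resnames[keep],
                     resno = at$resno[idx], insert = at$insert[idx],
                     chain_id = chain, heavy_atoms = heavy)
}

#' Write a backbone structure as PDB ATOM records
#'
#' Writes N/CA/C per residue with occupancy 1.00 and the element column set.
#' `read_pdb(write_pdb(x))` preserves coordinates to the PDB fixed-width
#' precision (1e-3 Angstrom).
#'
#' @param structure a [backbone_structure()].
#' @param path output file path.
#' @export
write_pdb <- function(structure, path) {
  L <- n_residues(structure)
  if (L == 0) stop("refusing to write an empty structure")
  atom_mat <- matrix(aperm(structure$coords, c(2, 1, 3)), ncol = 3)  # (3L) x 3, N/CA/C per residue
  if (any(atom_mat >= 10000) || any(atom_mat <= -1000)) {
    stop("coordinates outside the PDB fixed-width field range (-999.999 .. 9999.999 Angstrom)")
  }
  coords_flat <- as.numeric(t(atom_mat))       # x,y,z per atom, residue-major
  n_atoms <- 3L * L
  bio3d::write.pdb(file = path,
                   xyz = coords_flat,
                   type = rep("ATOM", n_atoms),
                   resno = rep(structure$resno, each = 3),
                   insert = rep(structure$insert, each = 3),
                   resid = rep(structure$residue_names, each = 3),
                   eleno = seq_len(n_atoms),
                   elety = rep(c("N", "CA", "C"), L),
                   chain = rep(structure$chain_id, n_atoms),
                   o = rep(1, n_atoms), b = rep(0, n_atoms),
                   elesy = rep(c("N", "C", "C"), L))
  invisible(path)
}

#' Per-residue resolution map
#'
#' @param values strictly positive resolution values in Angstrom, one per residue.
#' @param source provenance label: `"header-global"`, `"sidecar-table"`,
#'   `"fixture"` or `"default"`.
#' @return object of class `resolution_map`.
#' @export
resolution_map <- function(values, source = "fixture") {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("resolution values must be strictly positive and finite")
  }
  structure(list(values = values, source = source), class = "resolution_map")
}

parse_pdb_resolution <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rem <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem) == 0) rem <- grep("RESOLUTION\\.", lines, value = TRUE)
  if (length(rem) == 0) return(NA_real_)
  m <- regmatches(rem[1], regexpr("RESOLUTION\\.\\s*([0-9]*\\.?[0-9]+)", rem[1]))
  if (length(m) == 0) return(NA_real_)
  as.numeric(sub("RESOLUTION\\.\\s*", "", m))
}

#' Read a per-residue resolution map
#'
#' Resolution is attached to each target residue so that structural features
#' from poorly resolved regions can be down-weighted. Three sources are
#' supported, tried in this order: a sidecar two-column table
#' (`residue_index resolution_A`, whitespace-separated), the global value in
#' a PDB `REMARK 2 RESOLUTION.` header broadcast to every residue, and a
#' configured default broadcast with a warning when neither is available.
#'
#' @param path sidecar table or PDB file; `NULL` to fall back to `default`.
#' @param n_residues expected number of residues (> 0).
#' @param default fallback resolution in Angstrom (2.0).
#' @return a [resolution_map()].
#' @export
read_resolution <- function(path = NULL, n_residues, default = 2.0) {
  stopifnot(n_residues > 0)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("resolution source not found: ", path)
    lines <- readLines(path, warn = FALSE)
    is_pdb <- any(grepl("^(ATOM|HETATM|REMARK|HEADER)", lines))
    if (!is_pdb) {
      tab <- utils::read.table(path, header = FALSE,
                               col.names = c("residue_index", "resolution"))
      if (nrow(tab) != n_residues) {
        stop(sprintf("sidecar resolution table has %d rows but %d residues were expected",
                     nrow(tab), n_residues))
      }
      vals <- tab$resolution[order(tab$residue_index)]
      return(resolution_map(vals, source = "sidecar-table"))
    }
    res <- parse_pdb_resolution(path)
    if (is.finite(res)) {
      return(resolution_map(rep(res, n_residues), source = "header-global"))
    }
  }
  warning(sprintf("no resolution information available; broadcasting default %.2f Angstrom", default))
  resolution_map(rep(default, n_residues), source = "default")
}

#' Write a sidecar resolution table
#' @param resmap a [resolution_map()].
#' @param path output path (two columns: residue index, resolution in Angstrom).
#' @export
write_resolution <- function(resmap, path) {
  utils::write.table(data.frame(seq_along(resmap$values), resmap$values),
                     path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read FASTA records
#' @param path FASTA file.
#' @return data.frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  data.frame(id = names(set), sequence = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write FASTA records
#' @param records data.frame with columns `id` and `sequence` (or a named character vector).
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records))
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Validate a model-bound amino-acid sequence
#'
#' Model input is restricted to the 20 canonical one-letter codes.
#' @param sequence one-letter sequence string.
#' @return the sequence, invisibly, if valid; otherwise an error naming the
#'   first offending position.
#' @export
validate_sequence <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% CANONICAL_AA)
  if (length(bad) > 0) {
    stop(sprintf("non-canonical residue '%s' at position %d", chars[bad[1]], bad[1]))
  }
  invisible(sequence)
}
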