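# Resolution-weighted multimodal target context. Per-residue experimental
# resolution is mapped to reliability weights w = 1/(R + eps), the raw
# geometric descriptors are gated by those weights at the source, a
# sequence-local convolution encodes them to 256 features, a frozen
# per-residue sequence embedding is projected to 256 features, and the two
# halves are concatenated into the L x 512 context memory consumed by the
# denoiser's cross-attention.

K_NEIGHBORS <- 16L
DESC_DIM <- 32L          # 12 torsion trig + 16 neighbour distances + 4 frame dots
CTX_GEO_DIM <- 256L
CTX_SEQ_DIM <- 256L
CTX_DIM <- CTX_GEO_DIM + CTX_SEQ_DIM
PROVIDER_DIM <- 1280L

#' Resolution reliability weights
#'
#' w_i = 1 / (R_i + epsilon): strictly decreasing in the resolution value,
#' so poorly resolved (large Angstrom) residues are attenuated.
#'
#' @param resmap a [resolution_map()].
#' @param epsilon smoothing constant preventing division-by-zero (1e-6).
#' @return object of class `resolution_weights` with fields `w`, `epsilon`.
#' @export
resolution_weights <- function(resmap, epsilon = 1e-6) {
  structure(list(w = 1 / (resmap$values + epsilon), epsilon = epsilon),
            class = "resolution_weights")
}

#' Gate per-residue features by reliability weights
#'
#' Multiplies row i of the feature matrix by w_i (broadcast across
#' features): magnitude is modulated, direction within a row is preserved.
#'
#' @param features `L x d` matrix.
#' @param weights a [resolution_weights()] (lengths must agree).
#' @export
gate_features <- function(features, weights) {
  features <- as.matrix(features)
  if (nrow(features) != length(weights$w)) {
    stop("feature rows and resolution weights have different lengths")
  }
  features * weights$w
}

#' Rigid-invariant per-residue geometric descriptors
#'
#' Backbone torsion/bond-angle trig embedding (12), sorted distances from
#' each CA to its nearest neighbours (16, zero-padded for short chains) and
#' local-frame dot products (4). All entries are functions of internal
#' distances and angles only, hence invariant under rigid transforms.
#'
#' @param structure a [backbone_structure()] with >= 3 residues.
#' @return `L x 32` descriptor matrix.
#' @export
geo_descriptors <- function(structure) {
  L <- n_residues(structure)
  if (L < 3) stop("geometric descriptors require at least 3 residues")
  trig <- embed_angles(extract_angles(structure))
  ca <- structure$coords[, "CA", ]
  d <- sqrt(cross_dist2(ca, ca))
  nb <- t(apply(d, 1, function(row) {
    v <- sort(row[-which.min(row)])[seq_len(K_NEIGHBORS)]
    v[is.na(v)] <- 0
    v
  }))
  frame <- matrix(0, L, 4)
  for (i in seq_len(L)) {
    n_ca <- vunit(structure$coords[i, "N", ] - ca[i, ])
    c_ca <- vunit(structure$coords[i, "C", ] - ca[i, ])
    u <- if (i < L) vunit(ca[i + 1, ] - ca[i, ]) else c(0, 0, 0)
    v <- if (i > 1) vunit(ca[i, ] - ca[i - 1, ]) else c(0, 0, 0)
    frame[i, ] <- c(sum(n_ca * c_ca), sum(u * v), sum(n_ca * u), sum(c_ca * u))
  }
  cbind(trig, nb, frame)
}

# width-3 sequence-local stacking: row i holds [d_{i-1}, d_i, d_{i+1}]
# (zero-padded at the termini), so a linear map on it is a width-3
# convolution over the chain
stack_width3 <- function(desc) {
  L <- nrow(desc)
  z <- matrix(0, 1, ncol(desc))
  prev <- rbind(z, desc[-L, , drop = FALSE])
  nxt <- rbind(desc[-1, , drop = FALSE], z)
  cbind(prev, desc, nxt)
}

#' Encode target geometry to the 256-dimensional context half
#'
#' Raw rigid-invariant descriptors are gated by the resolution weights
#' (when given), stacked over a width-3 sequence window and passed through
#' the model's learnable linear map -- a sequence-local convolution of
#' receptive width 3 followed by projection to 256 features.
#'
#' @param structure target [backbone_structure()] (>= 3 residues).
#' @param model a model from [init_model()] (owns the encoder weights).
#' @param weights optional [resolution_weights()] applied to the raw
#'   descriptors before encoding.
#' @return `L x 256` matrix.
#' @export
geo_encoder <- function(structure, model, weights = NULL) {
  desc <- geo_descriptors(structure)
  if (!is.null(weights)) desc <- gate_features(desc, weights)
  p <- model$params
  op_add_rowvec(op_matmul(stack_width3(desc), p$cond_geo_W), p$cond_geo_b)
}

#' Deterministic stub sequence-embedding provider
#'
#' Stand-in for a frozen protein language model: each residue's 20-dim
#' one-hot is lifted to 1280 dimensions by a fixed seeded random
#' projection, so embeddings are deterministic across processes, require
#' no download, and differ between residue types.
#'
#' @param seed seed of the projection matrix (recorded on the provider).
#' @return function `sequence -> L x 1280` matrix, with attributes
#'   `provider_name` and `seed`.
#' @export
stub_provider <- function(seed = 20260101) {
  proj <- with_seed(seed, matrix(stats::rnorm(20 * PROVIDER_DIM, sd = 1 / sqrt(20)),
                                 20, PROVIDER_DIM))
  f <- function(sequence) {
    validate_sequence(sequence)
    idx <- match(strsplit(sequence, "")[[1]], CANONICAL_AA)
    proj[idx, , drop = FALSE]
  }
  attr(f, "provider_name") <- "stub-onehot-projection"
  attr(f, "seed") <- seed
  f
}

#' Fuse gated geometric features with sequence embeddings
#'
#' Projects the provider's `L x 1280` embedding to 256 features with the
#' model's learnable map and concatenates it with the (already gated)
#' geometric half into the `L x 512` context memory.
#'
#' @param f_geo `L x 256` gated geometric features (e.g. [geo_encoder()]).
#' @param sequence target sequence (length must equal `nrow(f_geo)`).
#' @param model a model from [init_model()].
#' @param provider embedding provider (default [stub_provider()]).
#' @param weights the [resolution_weights()] carried along in the context.
#' @return object of class `target_context` with fields `memory`,
#'   `geo_part`, `seq_part`, `weights`, `provider_name`.
#' @export
fuse_context <- function(f_geo, sequence, model, provider = stub_provider(),
                         weights = NULL) {
  if (nrow(node_val(f_geo)) != nchar(sequence)) {
    stop("geometric features and sequence have different lengths")
  }
  p <- model$params
  emb <- provider(sequence)
  f_seq <- op_add_rowvec(op_matmul(emb, p$cond_seq_W), p$cond_seq_b)
  memory <- op_cbind(list(f_geo, f_seq))
  structure(list(memory = memory, geo_part = f_geo, seq_part = f_seq,
                 weights = weights,
                 provider_name = attr(provider, "provider_name") %||% "custom"),
            class = "target_context")
}

#' Build the full target context in one call
#'
#' Convenience wrapper: resolution weights, gated geometric encoding,
#' sequence embedding projection and fusion.
#'
#' @param structure target [backbone_structure()].
#' @param sequence target sequence.
#' @param resmap a [resolution_map()] for the target.
#' @param model a model from [init_model()].
#' @param provider embedding provider (default [stub_provider()]).
#' @param epsilon smoothing constant for the weights.
#' @return a `target_context`.
#' @export
build_context <- function(structure, sequence, resmap, model,
                          provider = stub_provider(), epsilon = 1e-6) {
  w <- resolution_weights(resmap, epsilon)
  f_geo <- geo_encoder(structure, model, weights = w)
  fuse_context(f_geo, sequence, model, provider, weights = w)
}
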