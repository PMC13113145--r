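# Conditional noise-prediction network: a pre-LayerNorm transformer
# decoder whose queries carry the noisy binder state plus sinusoidal
# positional and time-step encodings, and whose keys/values come from the
# resolution-corrected target context memory. A parallel branch of the
# same architecture (without time injection) decodes per-position amino
# acid logits from clean angle embeddings.

#' Denoiser configuration
#'
#' Defaults follow the full architecture: 4 decoder layers, 8 attention
#' heads, latent width 512 (head width 64), FFN expansion 4, pre-LayerNorm,
#' GELU feed-forward activations, a 2-layer SiLU MLP lifting the resolution
#' weights into the context, and sinusoidal time embeddings at the latent
#' width. The reduced test configuration (2 layers, width 64) uses the same
#' code path.
#'
#' @param n_layers decoder depth.
#' @param n_heads attention heads; `model_dim` must equal
#'   `n_heads * head_dim`.
#' @param model_dim latent width.
#' @param ffn_ratio feed-forward expansion ratio.
#' @param res_hidden hidden width of the resolution MLP.
#' @param dropout kept for completeness; 0 disables it (the default -- all
#'   desk-scale runs are deterministic).
#' @param parameter_seed seed for weight initialisation.
#' @return list of class `denoiser_config`.
#' @export
denoiser_config <- function(n_layers = 4, n_heads = 8, model_dim = 512,
                            ffn_ratio = 4, res_hidden = 64, dropout = 0,
                            parameter_seed = 1) {
  head_dim <- model_dim / n_heads
  if (head_dim != round(head_dim)) {
    stop("model_dim must be divisible by n_heads")
  }
  structure(list(n_layers = n_layers, n_heads = n_heads, model_dim = model_dim,
                 head_dim = as.integer(head_dim), ffn_ratio = ffn_ratio,
                 res_hidden = res_hidden, dropout = dropout,
                 parameter_seed = parameter_seed),
            class = "denoiser_config")
}

#' Sinusoidal time-step embedding
#'
#' Standard interleaved sine/cosine pairs over a geometric frequency ladder
#' (base 10000): position 2k holds sin(t / 10000^(2k/dim)), position 2k+1
#' the matching cosine.
#' @param t nonnegative integer step.
#' @param dim even embedding width.
#' @return `1 x dim` matrix.
#' @export
time_embedding <- function(t, dim) {
  stopifnot(t >= 0, dim %% 2 == 0)
  k <- seq_len(dim / 2) - 1
  freq <- 1 / 10000^(2 * k / dim)
  out <- numeric(dim)
  out[2 * k + 1] <- sin(t * freq)
  out[2 * k + 2] <- cos(t * freq)
  matrix(out, 1)
}

#' Sinusoidal positional encoding
#' @param L number of positions (rows are positions 0..L-1).
#' @param dim even embedding width.
#' @return `L x dim` matrix.
#' @export
positional_encoding <- function(L, dim) {
  do.call(rbind, lapply(seq_len(L) - 1, time_embedding, dim = dim))
}

init_weight <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)

branch_param_shapes <- function(cfg, out_dim) {
  d <- cfg$model_dim
  f <- d * cfg$ffn_ratio
  shapes <- list(W_in = c(12, d), b_in = c(1, d))
  for (l in seq_len(cfg$n_layers)) {
    pl <- function(nm) paste0("l", l, "_", nm)
    layer <- list(c(1, d), c(1, d), c(d, d), c(d, d), c(d, d), c(d, d),
                  c(1, d), c(1, d), c(d, d), c(CTX_DIM, d), c(CTX_DIM, d), c(d, d),
                  c(1, d), c(1, d), c(d, f), c(1, f), c(f, d), c(1, d))
    names(layer) <- vapply(c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo",
                             "ln2_g", "ln2_b", "Wq2", "Wkc", "Wvc", "Wo2",
                             "ln3_g", "ln3_b", "Wf1", "bf1", "Wf2", "bf2"), pl, "")
    shapes <- c(shapes, layer)
  }
  c(shapes, list(lnf_g = c(1, d), lnf_b = c(1, d),
                 W_out = c(d, out_dim), b_out = c(1, out_dim)))
}

model_param_shapes <- function(cfg) {
  shared <- list(cond_geo_W = c(3 * DESC_DIM, CTX_GEO_DIM), cond_geo_b = c(1, CTX_GEO_DIM),
                 cond_seq_W = c(PROVIDER_DIM, CTX_SEQ_DIM), cond_seq_b = c(1, CTX_SEQ_DIM),
                 res_W1 = c(1, cfg$res_hidden), res_b1 = c(1, cfg$res_hidden),
                 res_W2 = c(cfg$res_hidden, CTX_DIM), res_b2 = c(1, CTX_DIM))
  den <- branch_param_shapes(cfg, 12)
  names(den) <- paste0("den_", names(den))
  sq <- branch_param_shapes(cfg, 20)
  names(sq) <- paste0("seq_", names(sq))
  c(shared, den, sq)
}

#' Initialise a model
#'
#' Creates every parameter group (conditioning encoders, resolution MLP,
#' denoising branch, sequence branch) with fan-in-scaled Gaussian weights,
#' unit LayerNorm gains and zero biases, from a recorded seed: two models
#' built from the same config and seed are bit-identical. The output heads
#' are initialised like every other weight by default; `"zero"` head
#' initialisation (exact zero initial prediction, uniform initial logits)
#' is available but on very small training sets it can funnel the
#' optimiser into a dead predict-the-marginal optimum, so it is not the
#' default.
#'
#' @param config a [denoiser_config()].
#' @param seed initialisation seed (default `config$parameter_seed`).
#' @param head_init `"random"` (default) or `"zero"` initialisation of the
#'   two output projections.
#' @return list of class `torsdiff_model` with fields `config`, `params`,
#'   `seed`.
#' @export
init_model <- function(config = denoiser_config(), seed = config$parameter_seed,
                       head_init = c("random", "zero")) {
  head_init <- match.arg(head_init)
  shapes <- model_param_shapes(config)
  params <- with_seed(seed, lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (grepl("_g$", nm)) matrix(1, sh[1], sh[2])                 # LayerNorm gains
    else if (grepl("_b$|_b[0-9]$|b_in$|b_out$|bf[0-9]$", nm)) matrix(0, sh[1], sh[2])
    else if (grepl("W_out$", nm) && head_init == "zero") matrix(0, sh[1], sh[2])
    else init_weight(sh[1], sh[2])
  }))
  names(params) <- names(shapes)
  structure(list(config = config, params = params, seed = seed),
            class = "torsdiff_model")
}

#' @export
print.torsdiff_model <- function(x, ...) {
  cat(sprintf("<torsdiff_model> %d layers, width %d, %d parameters (seed %d)\n",
              x$config$n_layers, x$config$model_dim, count_parameters(x), x$seed))
  invisible(x)
}

#' Total trainable parameter count
#'
#' Depends only on the configuration, never on input lengths.
#' @param model a `torsdiff_model`.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

multi_head_attention <- function(q_in, kv_in, Wq, Wk, Wv, Wo, n_heads, head_dim) {
  q <- op_matmul(q_in, Wq)
  k <- op_matmul(kv_in, Wk)
  v <- op_matmul(kv_in, Wv)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * head_dim + 1):(h * head_dim)
    qh <- op_cols(q, idx); kh <- op_cols(k, idx); vh <- op_cols(v, idx)
    scores <- op_scale(op_matmul(qh, op_transpose(kh)), 1 / sqrt(head_dim))
    heads[[h]] <- op_matmul(op_softmax_rows(scores), vh)
  }
  op_matmul(if (n_heads == 1) heads[[1]] else op_cbind(heads), Wo)
}

# shared decoder trunk for both branches; params may be plain matrices
# (inference) or tape nodes (training)
decoder_forward <- function(x_in, mem, params, prefix, cfg, t = NULL) {
  p <- function(nm) params[[paste0(prefix, "_", nm)]]
  L <- nrow(node_val(x_in))
  d <- cfg$model_dim
  extra <- positional_encoding(L, d)
  if (!is.null(t)) extra <- sweep(extra, 2, as.numeric(time_embedding(t, d)), "+")
  # input embedding scaled by sqrt(d) (standard transformer convention) so
  # the state signal dominates the additive positional/time encodings
  h <- op_add(op_scale(op_add_rowvec(op_matmul(x_in, p("W_in")), p("b_in")),
                       sqrt(d)), extra)
  for (l in seq_len(cfg$n_layers)) {
    q <- function(nm) p(paste0("l", l, "_", nm))
    u <- op_layernorm(h, q("ln1_g"), q("ln1_b"))
    h <- op_add(h, multi_head_attention(u, u, q("Wq"), q("Wk"), q("Wv"), q("Wo"),
                                        cfg$n_heads, cfg$head_dim))
    u <- op_layernorm(h, q("ln2_g"), q("ln2_b"))
    h <- op_add(h, multi_head_attention(u, mem, q("Wq2"), q("Wkc"), q("Wvc"), q("Wo2"),
                                        cfg$n_heads, cfg$head_dim))
    u <- op_layernorm(h, q("ln3_g"), q("ln3_b"))
    ff <- op_add_rowvec(op_matmul(op_gelu(op_add_rowvec(op_matmul(u, q("Wf1")), q("bf1"))),
                                  q("Wf2")), q("bf2"))
    h <- op_add(h, ff)
  }
  out <- op_layernorm(h, p("lnf_g"), p("lnf_b"))
  op_add_rowvec(op_matmul(out, p("W_out")), p("b_out"))
}

# resolution-corrected context memory: the weight vector is lifted by the
# 2-layer SiLU MLP to the context width and added to the fused memory,
# together with positional encodings over target positions
corrected_memory <- function(context, params) {
  mem <- context$memory
  w <- matrix(context$weights$w, ncol = 1)
  lift <- op_add_rowvec(op_matmul(op_silu(op_add_rowvec(op_matmul(w, params$res_W1),
                                                        params$res_b1)),
                                  params$res_W2), params$res_b2)
  op_add(op_add(mem, lift), positional_encoding(nrow(w), CTX_DIM))
}

#' Predict the forward noise for a noisy binder state
#'
#' The core denoising network: the noisy `L x 12` angle embedding is
#' projected to the latent width, injected with positional and time
#' encodings, and passed through the stacked decoder (self-attention over
#' binder positions, cross-attention to the resolution-corrected target
#' memory, GELU feed-forward, all pre-LayerNorm with residuals), ending in
#' a projection back to 12 channels.
#'
#' @param x_t `L x 12` noisy angle embedding.
#' @param t time step (1..T of the schedule in use).
#' @param context a `target_context` from [build_context()].
#' @param model a `torsdiff_model`.
#' @return `L x 12` noise prediction.
#' @export
predict_noise <- function(x_t, t, context, model) {
  stopifnot(t >= 1)
  mem <- corrected_memory(context, model$params)
  node_val(decoder_forward(as.matrix(x_t), mem, model$params, "den",
                           model$config, t = t))
}

#' Predict per-position amino-acid logits
#'
#' Same architecture as [predict_noise()] but consuming clean angle
#' embeddings and no time embedding (the branch is not part of the
#' diffusion chain).
#'
#' @param angle_emb `L x 12` clean angle embedding (e.g. [embed_angles()]).
#' @param context a `target_context`.
#' @param model a `torsdiff_model`.
#' @return `L x 20` logit matrix over the canonical alphabet
#'   `ACDEFGHIKLMNPQRSTVWY`.
#' @export
predict_sequence <- function(angle_emb, context, model) {
  mem <- corrected_memory(context, model$params)
  node_val(decoder_forward(as.matrix(angle_emb), mem, model$params, "seq",
                           model$config, t = NULL))
}

#' Bind a model and context into a denoiser function
#'
#' Precomputes the resolution-corrected context memory once and returns the
#' `(x_t, t, context)` closure consumed by [sample_trajectory()].
#' @param model a `torsdiff_model`.
#' @param context a `target_context`.
#' @export
make_denoiser <- function(model, context) {
  mem <- corrected_memory(context, model$params)
  function(x_t, t, ...) {
    node_val(decoder_forward(as.matrix(x_t), mem, model$params, "den",
                             model$config, t = t))
  }
}

#' Decode logits to a one-letter sequence (argmax)
#' @param logits `L x 20` matrix.
#' @export
logits_to_sequence <- function(logits) {
  paste(CANONICAL_AA[max.col(as.matrix(logits), ties.method = "first")], collapse = "")
}
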