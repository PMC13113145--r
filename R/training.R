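# Dataset assembly (bidirectional role-swap augmentation, sequence
# redundancy filtering), the composite loss (weighted denoising MSE +
# sequence cross-entropy), and the joint Adam optimisation loop that
# updates both branches and the conditioning encoders in one computation
# graph.

#' Bidirectional symmetry augmentation
#'
#' For every complex pair, appends a role-swapped twin in which the binder
#' becomes the conditioning target (with a default resolution map when it
#' has none) and the target becomes the generation subject. Doubles the
#' effective sample count without introducing noise; the input list is
#' never mutated.
#'
#' @param pairs list of `complex_pair` objects.
#' @return list of length `2 * length(pairs)`; originals first, twins
#'   (with `role_swapped = TRUE`) after.
#' @export
bidirectional_augment <- function(pairs) {
  twins <- lapply(pairs, function(p) {
    res <- p$binder$resolution
    if (is.null(res)) {
      L <- if (!is.null(p$binder$structure)) n_residues(p$binder$structure)
           else nchar(p$binder$sequence)
      res <- resolution_map(rep(2.0, L), source = "default")
    }
    structure(list(pair_id = p$pair_id,
                   target = list(structure = p$binder$structure,
                                 sequence = p$binder$sequence, resolution = res),
                   binder = list(structure = p$target$structure,
                                 sequence = p$target$sequence,
                                 resolution = p$target$resolution),
                   role_swapped = !isTRUE(p$role_swapped),
                   planted_contacts = p$planted_contacts),
              class = "complex_pair")
  })
  c(pairs, twins)
}

#' Remove test sequences homologous to the training set
#'
#' Greedy all-vs-all filter: any test sequence whose global-alignment
#' identity ([sequence_identity()]) to ANY training sequence reaches the
#' threshold is removed, keeping the retained test set below the homology
#' "twilight zone".
#'
#' @param train_seqs,test_seqs character vectors of one-letter sequences.
#' @param identity_threshold percent identity cutoff (30).
#' @return the filtered test sequences.
#' @export
redundancy_filter <- function(train_seqs, test_seqs, identity_threshold = 30) {
  if (length(train_seqs) == 0) return(test_seqs)
  keep <- vapply(test_seqs, function(ts) {
    for (tr in train_seqs) {
      if (sequence_identity(ts, tr) >= identity_threshold) return(FALSE)
    }
    TRUE
  }, logical(1))
  test_seqs[keep]
}

# constant per-pair tensors reused across training steps
pair_precompute <- function(pair, provider) {
  tgt <- pair$target
  w <- resolution_weights(tgt$resolution)
  desc <- gate_features(geo_descriptors(tgt$structure), w)
  binder_tab <- pair$binder$angles %||% extract_angles(pair$binder$structure)
  x0 <- embed_angles(binder_tab)
  mask6 <- binder_tab$valid
  mask12 <- matrix(0, nrow(mask6), 12)
  mask12[, seq(1, 11, 2)] <- mask6
  mask12[, seq(2, 12, 2)] <- mask6
  list(desc_stacked = stack_width3(desc),
       seq_emb = provider(tgt$sequence),
       w = matrix(w$w, ncol = 1),
       x0 = x0, mask12 = mask12,
       classes = match(strsplit(pair$binder$sequence, "")[[1]], CANONICAL_AA),
       L_tgt = n_residues(tgt$structure))
}

# context memory node from precomputed constants and (node) params
context_forward <- function(pre, p) {
  f_geo <- op_add_rowvec(op_matmul(pre$desc_stacked, p$cond_geo_W), p$cond_geo_b)
  f_seq <- op_add_rowvec(op_matmul(pre$seq_emb, p$cond_seq_W), p$cond_seq_b)
  mem <- op_cbind(list(f_geo, f_seq))
  lift <- op_add_rowvec(op_matmul(op_silu(op_add_rowvec(op_matmul(pre$w, p$res_W1),
                                                        p$res_b1)), p$res_W2), p$res_b2)
  op_add(op_add(mem, lift), positional_encoding(pre$L_tgt, CTX_DIM))
}

#' Denoising (geometric) loss for one sample
#'
#' Embeds the binder angles, forms x_t by the closed-form forward kernel at
#' step t, and returns the mean squared error between the predicted and the
#' true noise over unmasked positions/channels. Invariant to rigid
#' transforms of the binder because internal coordinates are.
#'
#' @param model a `torsdiff_model`.
#' @param pair a `complex_pair`.
#' @param t diffusion step.
#' @param schedule a [make_schedule()].
#' @param seed seed for the noise draw.
#' @param provider embedding provider.
#' @return scalar loss.
#' @export
diffusion_loss <- function(model, pair, t, schedule, seed = 1,
                           provider = stub_provider()) {
  pre <- pair_precompute(pair, provider)
  eps <- with_seed(seed, matrix(stats::rnorm(length(pre$x0)), nrow(pre$x0), 12))
  fs <- forward_sample(pre$x0, t, schedule, noise = eps)
  mem <- context_forward(pre, model$params)
  eps_pred <- decoder_forward(fs$x, mem, model$params, "den", model$config, t = t)
  as.numeric(node_val(op_mse(eps_pred, eps, pre$mask12)))
}

#' Sequence cross-entropy loss for one sample
#'
#' Mean per-residue negative log-likelihood of the native binder sequence
#' under [predict_sequence()] given the clean angle embedding and the
#' target context (mean rather than sum, so magnitudes are
#' length-independent).
#'
#' @inheritParams diffusion_loss
#' @export
sequence_loss <- function(model, pair, provider = stub_provider()) {
  pre <- pair_precompute(pair, provider)
  mem <- context_forward(pre, model$params)
  logits <- decoder_forward(pre$x0, mem, model$params, "seq", model$config)
  as.numeric(node_val(op_cross_entropy(logits, pre$classes)))
}

#' Compose a loss report
#'
#' @param geo,seq branch losses.
#' @param lambda_geo,lambda_seq static weights.
#' @return list with `total = lambda_geo * geo + lambda_seq * seq` and the
#'   components (identity holds to machine precision by construction).
#' @export
loss_report <- function(geo, seq, lambda_geo = 1, lambda_seq = 1) {
  list(total = lambda_geo * geo + lambda_seq * seq, geo = geo, seq = seq,
       lambda_geo = lambda_geo, lambda_seq = lambda_seq)
}

# Adam runs on a single flat parameter vector through the compiled
# kernels; the per-tensor matrices are refreshed in place each step.
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  off <- 0L
  for (nm in names(template)) {
    k <- length(template[[nm]])
    m <- template[[nm]]
    m[] <- flat[(off + 1L):(off + k)]
    out[[nm]] <- m
    off <- off + k
  }
  out
}

#' Train the joint model
#'
#' Single Adam optimiser over both branches and the conditioning encoders.
#' Each step samples a complex pair and a uniform diffusion step t, builds
#' the composite loss `lambda_geo * L_geo + lambda_seq * L_seq` in one
#' computation graph, and backpropagates through the shared context.
#' Fully seeded: identical calls give identical loss traces.
#'
#' @param dataset non-empty list of `complex_pair` objects.
#' @param config a [denoiser_config()].
#' @param schedule a [make_schedule()].
#' @param lambdas named vector `c(geo = , seq = )` of static loss weights.
#' @param steps optimisation steps.
#' @param lr peak Adam learning rate.
#' @param seed seed for sampling (pairs, t, noise).
#' @param provider embedding provider (default deterministic stub).
#' @param model optional warm-start model (default fresh [init_model()]).
#' @param trace_every record the loss trace every this many steps.
#' @param lr_warmup linear warmup steps to the peak rate (0 disables).
#' @param lr_decay `"cosine"` holds the peak rate until the denoising loss
#'   leaves its initial plateau, then anneals to `lr_floor * lr` by the
#'   final step (tightens late convergence); `"none"` keeps it constant.
#' @param lr_floor final fraction of the peak rate under cosine decay.
#' @param clip_norm global gradient-norm clip (0 disables); guards the
#'   single-sample updates against occasional exploding steps.
#' @param ema decay of the exponential moving average of the weights
#'   (0, the default, disables). When enabled the returned model carries
#'   the bias-corrected averaged weights and the raw final weights are
#'   kept in the `raw_params` field.
#' @param adam_betas Adam moment decays; the second moment uses 0.98
#'   (transformer practice for small-data stability) rather than 0.999.
#' @param max_restarts joint training of the two branches occasionally
#'   falls into a dead optimum in which both heads predict marginals
#'   (noise 0, uniform logits) and gradients vanish. Training is
#'   multi-start: if the denoising loss is still
#'   at the trivial-predictor level (mean over the preceding 200 steps
#'   above `restart_loss`) or the sequence loss still near uniform
#'   (above 1) 45% of the way through, the attempt is abandoned and
#'   restarted from a shifted seed, at most `max_restarts` times; the
#'   last attempt always runs to completion. Restart attempts also scan a
#'   bracket of peak rates around `lr` (a deterministic line-search, since
#'   which rate escapes the plateau varies with the initialisation).
#'   Deterministic given `seed`.
#' @param restart_loss collapse-detection threshold for the geometric
#'   loss (0.6; the trivial zero predictor scores ~1).
#' @param seq_jitter standard deviation (radians) of the torsional jitter
#'   added to the sequence-branch input angles, so decoding stays robust on
#'   sampled conformations that deviate slightly from the training
#'   manifold; 0 trains on exact native angles.
#' @return list with `model`, `trace` (data.frame step/t/geo/seq/total) and
#'   `provider_seed`.
#' @export
train <- function(dataset, config = denoiser_config(), schedule = make_schedule("linear", 100),
                  lambdas = c(geo = 1, seq = 1), steps = 500, lr = 1e-4, seed = 1,
                  provider = stub_provider(), model = NULL, trace_every = 1,
                  lr_warmup = 50, lr_decay = c("cosine", "none"), lr_floor = 0.1,
                  seq_jitter = 0.05, clip_norm = 5, ema = 0,
                  adam_betas = c(0.9, 0.98),
                  max_restarts = 4, restart_loss = 0.6) {
  lr_decay <- match.arg(lr_decay)
  if (length(dataset) == 0) stop("training dataset is empty")
  if (!is.null(model)) config <- model$config
  pres <- lapply(dataset, pair_precompute, provider = provider)
  check_step <- if (max_restarts > 0 && steps >= 500) floor(0.45 * steps) else Inf

  # restart attempts scan a bracket around the nominal peak rate: which
  # rate lets the denoising branch leave its plateau varies with the
  # initialisation, so the multi-start doubles as a deterministic
  # line-search
  lr_ladder <- c(1, 1.5, 0.7, 1.2, 2)

  run_attempt <- function(attempt) {
  lr_peak <- lr * lr_ladder[(attempt %% length(lr_ladder)) + 1]
  start <- if (is.null(model)) init_model(config, config$parameter_seed + attempt)
           else model
  # private copies: the step kernel updates these matrices in place
  start$params <- lapply(start$params, function(m) m + 0)
  plens <- vapply(start$params, length, integer(1))
  flat <- flatten_params(start$params)
  adam_m <- numeric(length(flat))
  adam_v <- numeric(length(flat))
  gflat <- numeric(length(flat))
  ema_flat <- numeric(if (ema > 0) length(flat) else 0)
  trace <- vector("list", steps)
  recent_geo <- rep(NA_real_, 200)
  recent_seq <- rep(NA_real_, 200)
  collapsed <- FALSE
  clicked_at <- NA_integer_
  lr_click <- lr_peak
  lr_slow <- function(step) {
    lr_peak * (0.3 + 0.7 * 0.5 * (1 + cos(pi * step / steps)))
  }
  with_seed(seed + 7777 * attempt, {
    for (step in seq_len(steps)) {
      k <- sample.int(length(pres), 1)
      pre <- pres[[k]]
      t <- sample.int(schedule$T_steps, 1)
      eps <- matrix(stats::rnorm(length(pre$x0)), nrow(pre$x0), 12)
      fs <- forward_sample(pre$x0, t, schedule, noise = eps)

      seq_in <- if (seq_jitter > 0) {
        jit <- matrix(stats::rnorm(nrow(pre$x0) * 6, sd = seq_jitter), nrow(pre$x0), 6)
        cs <- cos(jit); sn <- sin(jit)
        out <- pre$x0
        ic <- seq(1, 11, 2); is <- seq(2, 12, 2)
        # rotate each (cos, sin) pair by the jitter angle
        out[, ic] <- pre$x0[, ic] * cs - pre$x0[, is] * sn
        out[, is] <- pre$x0[, ic] * sn + pre$x0[, is] * cs
        out
      } else pre$x0

      tape <- tape_new()
      pnodes <- lapply(start$params, function(v) param_node(tape, v))
      mem <- context_forward(pre, pnodes)
      eps_pred <- decoder_forward(fs$x, mem, pnodes, "den", config, t = t)
      l_geo <- op_mse(eps_pred, eps, pre$mask12)
      logits <- decoder_forward(seq_in, mem, pnodes, "seq", config)
      l_seq <- op_cross_entropy(logits, pre$classes)
      total <- op_axpy(l_geo, lambdas[["geo"]], l_seq, lambdas[["seq"]])
      tv <- as.numeric(node_val(total))
      if (!is.finite(tv)) {
        stop(sprintf("training diverged at step %d (total loss %g); lower the learning rate",
                     step, tv))
      }
      ad_backward(total)
      gather_grads_(lapply(pnodes, function(n) n$grad), plens, gflat)
      # click-adaptive schedule. Before the denoising branch leaves its
      # plateau (running mean < 0.5) the rate anneals slowly (cosine to
      # 30% of peak over the whole run: sweeping the rate band is itself
      # what often triggers the plateau exit). After the exit the decay is
      # re-anchored: cosine from the current rate down to lr_floor * peak
      # over the remaining steps, so late exits still get a full
      # convergence phase.
      if (is.na(clicked_at) && step > lr_warmup + 100 &&
          mean(recent_geo, na.rm = TRUE) < 0.5) {
        clicked_at <- step
        lr_click <- lr_slow(step)
      }
      lr_t <- lr_peak
      if (lr_warmup > 0 && step <= lr_warmup) {
        lr_t <- lr_peak * step / lr_warmup
      } else if (lr_decay == "cosine") {
        lr_t <- if (is.na(clicked_at)) lr_slow(step) else {
          frac <- (step - clicked_at) / max(1, steps - clicked_at)
          floor_frac <- min(1, max(0.02, lr_floor * lr_peak / lr_click))
          lr_click * (floor_frac + (1 - floor_frac) * 0.5 * (1 + cos(pi * frac)))
        }
      }
      adam_update_(flat, gflat, adam_m, adam_v, ema_flat, lr_t, step,
                   adam_betas[1], adam_betas[2], 1e-8, clip_norm, ema)
      scatter_params_(flat, start$params)
      gval <- as.numeric(node_val(l_geo))
      sval <- as.numeric(node_val(l_seq))
      recent_geo[(step - 1) %% 200 + 1] <- gval
      recent_seq[(step - 1) %% 200 + 1] <- sval
      if (step %% trace_every == 0) {
        trace[[step]] <- data.frame(step = step, t = t, geo = gval,
                                    seq = sval, total = tv)
      }
      # either branch still at its trivial-predictor level -> dead attempt
      if (step == check_step &&
          (mean(recent_geo, na.rm = TRUE) > restart_loss ||
           (lambdas[["seq"]] > 0 && mean(recent_seq, na.rm = TRUE) > 1))) {
        collapsed <- TRUE
        break
      }
    }
  })
  if (ema > 0) {
    start$raw_params <- start$params
    start$params <- unflatten_params(ema_flat / (1 - ema^steps), start$params)
  }
  list(model = start, trace = do.call(rbind, trace), collapsed = collapsed)
  }

  attempt <- 0
  res <- run_attempt(attempt)
  while (res$collapsed && attempt < max_restarts) {
    attempt <- attempt + 1
    # last attempt: run to completion even if the check would trip again
    if (attempt == max_restarts) check_step <- Inf
    res <- run_attempt(attempt)
  }
  list(model = res$model, trace = res$trace,
       provider_seed = attr(provider, "seed"), restarts = attempt)
}

#' Deterministic evaluation loss, uniform over all diffusion steps
#'
#' Averages the composite loss over every diffusion step (or an evenly
#' spaced subset) with seeded noise draws, matching the uniform-t training
#' objective; used to report a final loss that is not subject to
#' single-step sampling variance.
#'
#' @param model a `torsdiff_model`.
#' @param pair a `complex_pair`.
#' @param schedule a [make_schedule()].
#' @param n_t number of grid steps (`NULL` for every step).
#' @param n_draws noise draws averaged per step.
#' @param seed seed for the evaluation noise.
#' @param lambdas loss weights.
#' @param provider embedding provider.
#' @return a [loss_report()].
#' @export
evaluate_losses <- function(model, pair, schedule, n_t = NULL, n_draws = 2,
                            seed = 99, lambdas = c(geo = 1, seq = 1),
                            provider = stub_provider()) {
  pre <- pair_precompute(pair, provider)
  ts <- if (is.null(n_t)) seq_len(schedule$T_steps) else {
    unique(round(seq(1, schedule$T_steps, length.out = n_t)))
  }
  mem <- context_forward(pre, model$params)
  geo <- with_seed(seed, {
    vapply(ts, function(t) {
      mean(vapply(seq_len(n_draws), function(k) {
        eps <- matrix(stats::rnorm(length(pre$x0)), nrow(pre$x0), 12)
        fs <- forward_sample(pre$x0, t, schedule, noise = eps)
        pred <- decoder_forward(fs$x, mem, model$params, "den", model$config, t = t)
        as.numeric(node_val(op_mse(pred, eps, pre$mask12)))
      }, numeric(1)))
    }, numeric(1))
  })
  logits <- decoder_forward(pre$x0, mem, model$params, "seq", model$config)
  seqloss <- as.numeric(node_val(op_cross_entropy(logits, pre$classes)))
  loss_report(mean(geo), seqloss, lambdas[["geo"]], lambdas[["seq"]])
}

#' Save a model checkpoint
#'
#' Writes the weight container (`<prefix>.rds`) plus a JSON sidecar
#' (`<prefix>.json`) holding the configuration, the schedule description
#' and the seeds, for compatibility checking on load.
#'
#' @param model a `torsdiff_model`.
#' @param prefix path prefix (without extension).
#' @param schedule optional schedule to record.
#' @param extra optional named list merged into the sidecar.
#' @export
save_checkpoint <- function(model, prefix, schedule = NULL, extra = list()) {
  saveRDS(model$params, paste0(prefix, ".rds"))
  side <- c(list(config = unclass(model$config), seed = model$seed,
                 geometry = geometry_constants(),
                 schedule = if (!is.null(schedule))
                   list(family = schedule$family, T_steps = schedule$T_steps,
                        beta_start = schedule$beta[1],
                        beta_end = schedule$beta[schedule$T_steps])),
            extra)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Load a model checkpoint
#'
#' @param prefix path prefix used by [save_checkpoint()].
#' @param config optional expected [denoiser_config()]; a mismatch errors
#'   listing the differing fields.
#' @return a `torsdiff_model` (with the sidecar in attribute `sidecar`).
#' @export
load_checkpoint <- function(prefix, config = NULL) {
  params <- readRDS(paste0(prefix, ".rds"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  stored <- do.call(denoiser_config, side$config[names(side$config) %in%
                                                   names(formals(denoiser_config))])
  if (!is.null(config)) {
    same_field <- function(a, b) {
      if (is.numeric(a) && is.numeric(b)) isTRUE(all.equal(as.numeric(a), as.numeric(b)))
      else identical(a, b)
    }
    diff <- names(which(vapply(names(unclass(config)), function(nm)
      !same_field(config[[nm]], stored[[nm]]), logical(1))))
    if (length(diff) > 0) {
      stop("checkpoint/config mismatch in fields: ", paste(diff, collapse = ", "))
    }
  }
  model <- structure(list(config = stored, params = params,
                          seed = side$seed %||% NA_integer_),
                     class = "torsdiff_model")
  attr(model, "sidecar") <- side
  model
}
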