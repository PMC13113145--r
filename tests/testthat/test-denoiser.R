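test_that("time and positional embeddings follow the sinusoidal contract", {
  e0 <- time_embedding(0, 8)
  expect_equal(as.numeric(e0), rep(c(0, 1), 4))
  emb <- do.call(rbind, lapply(1:200, time_embedding, dim = 64))
  expect_false(any(duplicated(round(emb, 10))))
  pe <- positional_encoding(30, 64)
  expect_equal(dim(pe), c(30, 64))
  expect_false(any(duplicated(round(pe, 10))))
  expect_error(time_embedding(1, 7))
})

test_that("config invariants are enforced and parameters depend only on config", {
  expect_error(denoiser_config(n_heads = 3, model_dim = 64), "divisible")
  m1 <- init_model(tiny_cfg)
  m2 <- init_model(tiny_cfg)
  expect_identical(m1$params, m2$params)       # seeded init is reproducible
  expect_identical(count_parameters(m1), count_parameters(m2))
})

test_that("noise prediction has the right shape and is bit-stable", {
  L <- 6
  x <- matrix(torsdiff:::with_seed(2, stats::rnorm(L * 12)), L, 12)
  o1 <- predict_noise(x, 3, tiny_context, tiny_model)
  o2 <- predict_noise(x, 3, tiny_context, tiny_model)
  expect_equal(dim(o1), c(L, 12))
  expect_identical(o1, o2)
  # a different binder length works with the same weights
  x2 <- matrix(0.1, 9, 12)
  expect_equal(dim(predict_noise(x2, 3, tiny_context, tiny_model)), c(9, 12))
})

test_that("sequence logits have the right shape and are deterministic", {
  emb <- embed_angles(tiny_pair$binder$angles)
  l1 <- predict_sequence(emb, tiny_context, tiny_model)
  expect_equal(dim(l1), c(nrow(emb), 20))
  expect_identical(l1, predict_sequence(emb, tiny_context, tiny_model))
  expect_match(logits_to_sequence(l1), "^[ACDEFGHIKLMNPQRSTVWY]+$")
})

test_that("cross-attention is invariant to consistent context permutations but
           sensitive to re-indexed target positions", {
  x <- matrix(torsdiff:::with_seed(5, stats::rnorm(6 * 12)), 6, 12)
  mem <- torsdiff:::corrected_memory(tiny_context, tiny_model$params)
  out <- torsdiff:::decoder_forward(x, mem, tiny_model$params, "den",
                                    tiny_model$config, t = 4)
  # permuting memory rows wholesale (positional encodings travel with the
  # rows) leaves attention output unchanged
  perm <- rev(seq_len(nrow(mem)))
  out_perm <- torsdiff:::decoder_forward(x, mem[perm, ], tiny_model$params, "den",
                                         tiny_model$config, t = 4)
  expect_equal(out, out_perm, tolerance = 1e-10)
  # rebuilding the context with reordered target residues re-indexes the
  # positional encodings, so the output must change
  st <- tiny_pair$target$structure
  L <- n_residues(st)
  flip <- backbone_structure(st$coords[L:1, , , drop = FALSE],
                             st$residue_names[L:1], chain_id = st$chain_id)
  ctx_flip <- build_context(flip,
                            paste(rev(strsplit(tiny_pair$target$sequence, "")[[1]]),
                                  collapse = ""),
                            resolution_map(rev(tiny_pair$target$resolution$values)),
                            tiny_model, tiny_provider)
  out_flip <- predict_noise(x, 4, ctx_flip, tiny_model)
  expect_gt(max(abs(out_flip - out)), 1e-6)
})

test_that("one joint backward pass reaches every parameter group", {
  sch <- make_schedule("linear", 20)
  pre <- torsdiff:::pair_precompute(tiny_pair, tiny_provider)
  tape <- torsdiff:::tape_new()
  pnodes <- lapply(tiny_model$params, function(v) torsdiff:::param_node(tape, v))
  eps <- matrix(torsdiff:::with_seed(6, stats::rnorm(length(pre$x0))),
                nrow(pre$x0), 12)
  fs <- forward_sample(pre$x0, 7, sch, noise = eps)
  mem <- torsdiff:::context_forward(pre, pnodes)
  eps_pred <- torsdiff:::decoder_forward(fs$x, mem, pnodes, "den", tiny_cfg, t = 7)
  l_geo <- torsdiff:::op_mse(eps_pred, eps, pre$mask12)
  logits <- torsdiff:::decoder_forward(pre$x0, mem, pnodes, "seq", tiny_cfg)
  l_seq <- torsdiff:::op_cross_entropy(logits, pre$classes)
  torsdiff:::ad_backward(torsdiff:::op_axpy(l_geo, 1, l_seq, 1))
  gmax <- vapply(pnodes, function(n) if (is.null(n$grad)) 0 else max(abs(n$grad)),
                 numeric(1))
  expect_true(all(gmax > 0), info = paste("dead parameters:",
                                          paste(names(gmax)[gmax == 0], collapse = ", ")))
})

test_that("autodiff gradients match finite differences through the full network", {
  sch <- make_schedule("linear", 20)
  pre <- torsdiff:::pair_precompute(tiny_pair, tiny_provider)
  eps <- matrix(torsdiff:::with_seed(8, stats::rnorm(length(pre$x0))),
                nrow(pre$x0), 12)
  fs <- forward_sample(pre$x0, 11, sch, noise = eps)
  loss_at <- function(params) {
    mem <- torsdiff:::context_forward(pre, params)
    p1 <- torsdiff:::decoder_forward(fs$x, mem, params, "den", tiny_cfg, t = 11)
    l1 <- torsdiff:::op_mse(p1, eps, pre$mask12)
    l2 <- torsdiff:::op_cross_entropy(
      torsdiff:::decoder_forward(pre$x0, mem, params, "seq", tiny_cfg), pre$classes)
    as.numeric(torsdiff:::node_val(torsdiff:::op_axpy(l1, 1, l2, 1)))
  }
  tape <- torsdiff:::tape_new()
  pnodes <- lapply(tiny_model$params, function(v) torsdiff:::param_node(tape, v))
  mem <- torsdiff:::context_forward(pre, pnodes)
  p1 <- torsdiff:::decoder_forward(fs$x, mem, pnodes, "den", tiny_cfg, t = 11)
  l1 <- torsdiff:::op_mse(p1, eps, pre$mask12)
  l2 <- torsdiff:::op_cross_entropy(
    torsdiff:::decoder_forward(pre$x0, mem, pnodes, "seq", tiny_cfg), pre$classes)
  torsdiff:::ad_backward(torsdiff:::op_axpy(l1, 1, l2, 1))
  # spot-check coordinates spread over different tensor kinds
  picks <- list(c("den_W_in", 3), c("den_l1_Wq", 10), c("den_l1_Wkc", 25),
                c("den_l1_ln1_g", 2), c("den_l1_Wf1", 7), c("den_W_out", 4),
                c("seq_l1_Wvc", 12), c("seq_W_out", 9),
                c("cond_geo_W", 40), c("cond_seq_W", 123),
                c("res_W2", 17), c("res_b1", 3))
  h <- 1e-5
  for (pk in picks) {
    nm <- pk[1]; i <- as.integer(pk[2])
    up <- tiny_model$params; up[[nm]][i] <- up[[nm]][i] + h
    dn <- tiny_model$params; dn[[nm]][i] <- dn[[nm]][i] - h
    fd <- (loss_at(up) - loss_at(dn)) / (2 * h)
    expect_equal(pnodes[[nm]]$grad[i], fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
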