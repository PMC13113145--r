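# Minimal tape-based reverse-mode automatic differentiation over matrices.
# The denoiser and sequence decoder are expressed once in terms of these
# ops; when every operand is a plain matrix the ops compute values directly
# (inference fast path), and when any operand is a tape node they record
# the backward function for gradient accumulation (training path).
# Every op's gradient is unit-tested against central finite differences.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

is_node <- function(x) inherits(x, "ad_node")

node_val <- function(x) if (is_node(x)) x$val else x

ad_node <- function(tape, val, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  class(e) <- "ad_node"
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- e
  e
}

#' Create a differentiable leaf (parameter) node
#' @keywords internal
ad_param <- function(tape, val) ad_node(tape, val)

find_tape <- function(...) {
  for (x in list(...)) if (is_node(x)) return(attr(x, "tape"))
  NULL
}

# Each op locates the tape through an attribute stored on nodes at creation.
with_tape <- function(tape, node) {
  attr(node, "tape") <- tape
  node
}

param_node <- function(tape, val) with_tape(tape, ad_param(tape, val))

record <- function(args, val, backfn) {
  nds <- Filter(is_node, args)
  if (length(nds) == 0) return(val)
  tape <- attr(nds[[1]], "tape")
  # parents holds ALL operands (plain ones included) so that backfn return
  # values align positionally; backward skips the non-node entries
  with_tape(tape, ad_node(tape, val, parents = args, backfn = backfn))
}

accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

#' Run backpropagation from a scalar loss node
#' @keywords internal
ad_backward <- function(loss) {
  tape <- attr(loss, "tape")
  loss$grad <- matrix(1, 1, 1)
  for (k in seq(tape$n, 1)) {
    nd <- tape$nodes[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (is_node(p) && i <= length(gs) && !is.null(gs[[i]])) accum(p, gs[[i]])
    }
  }
  invisible(loss)
}

op_matmul <- function(a, b) {
  av <- node_val(a); bv <- node_val(b)
  v <- av %*% bv
  record(list(a, b), v, function(g) {
    out <- list()
    if (is_node(a)) out[[1]] <- g %*% t(bv) else out[1] <- list(NULL)
    if (is_node(b)) out[[2]] <- crossprod(av, g) else out[2] <- list(NULL)
    out
  })
}

op_add <- function(a, b) {
  av <- node_val(a); bv <- node_val(b)
  v <- av + bv
  record(list(a, b), v, function(g) list(if (is_node(a)) g, if (is_node(b)) g))
}

# add a 1 x d row vector to every row of an L x d matrix
op_add_rowvec <- function(a, v) {
  av <- node_val(a); vv <- node_val(v)
  out <- sweep(av, 2, as.numeric(vv), "+")
  record(list(a, v), out, function(g) {
    list(if (is_node(a)) g,
         if (is_node(v)) matrix(colSums(g), 1))
  })
}

op_scale <- function(a, s) {
  av <- node_val(a)
  record(list(a), av * s, function(g) list(g * s))
}

op_transpose <- function(a) {
  record(list(a), t(node_val(a)), function(g) list(t(g)))
}

op_cols <- function(a, idx) {
  av <- node_val(a)
  record(list(a), av[, idx, drop = FALSE], function(g) {
    z <- matrix(0, nrow(av), ncol(av))
    z[, idx] <- g
    list(z)
  })
}

op_cbind <- function(args) {
  vals <- lapply(args, node_val)
  widths <- vapply(vals, ncol, integer(1))
  v <- do.call(cbind, vals)
  ends <- cumsum(widths)
  starts <- c(1, utils::head(ends, -1) + 1)
  record(args, v, function(g) {
    out <- vector("list", length(args))
    for (i in seq_along(args)) {
      if (is_node(args[[i]])) out[[i]] <- g[, starts[i]:ends[i], drop = FALSE]
    }
    out
  })
}

op_gelu <- function(a) {
  x <- node_val(a)
  k <- sqrt(2 / pi)
  u <- k * (x + 0.044715 * x^3)
  th <- tanh(u)
  v <- 0.5 * x * (1 + th)
  record(list(a), v, function(g) {
    du <- k * (1 + 3 * 0.044715 * x^2)
    list(g * (0.5 * (1 + th) + 0.5 * x * (1 - th^2) * du))
  })
}

op_silu <- function(a) {
  x <- node_val(a)
  s <- 1 / (1 + exp(-x))
  record(list(a), x * s, function(g) list(g * (s * (1 + x * (1 - s)))))
}

op_softmax_rows <- function(a) {
  x <- node_val(a)
  m <- x - apply(x, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  record(list(a), y, function(g) {
    list((g - rowSums(g * y)) * y)
  })
}

# row-wise layer normalisation with learnable gain/bias (1 x d each)
op_layernorm <- function(a, gain, bias, eps = 1e-5) {
  x <- node_val(a)
  gv <- as.numeric(node_val(gain)); bv <- as.numeric(node_val(bias))
  mu <- rowMeans(x)
  xc <- x - mu
  varr <- rowMeans(xc^2)
  inv <- 1 / sqrt(varr + eps)
  y <- xc * inv
  out <- sweep(y * 1, 2, gv, "*")
  out <- sweep(out, 2, bv, "+")
  record(list(a, gain, bias), out, function(g) {
    res <- list()
    dy <- sweep(g, 2, gv, "*")
    if (is_node(a)) {
      res[[1]] <- (dy - rowMeans(dy) - y * rowMeans(dy * y)) * inv
    } else res[1] <- list(NULL)
    if (is_node(gain)) res[[2]] <- matrix(colSums(g * y), 1) else res[2] <- list(NULL)
    if (is_node(bias)) res[[3]] <- matrix(colSums(g), 1) else res[3] <- list(NULL)
    res
  })
}

# mean squared error against a constant target over a 0/1 mask
op_mse <- function(pred, target, mask = NULL) {
  pv <- node_val(pred)
  if (is.null(mask)) mask <- matrix(1, nrow(pv), ncol(pv))
  n <- sum(mask)
  diff <- (pv - target) * mask
  v <- matrix(sum(diff^2) / n, 1, 1)
  record(list(pred), v, function(g) list(as.numeric(g) * 2 * diff / n))
}

# mean cross-entropy of integer class labels under row logits
op_cross_entropy <- function(logits, classes) {
  x <- node_val(logits)
  L <- nrow(x)
  m <- x - apply(x, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(L), classes)]
  v <- matrix(-mean(log(pmax(picked, 1e-300))), 1, 1)
  record(list(logits), v, function(g) {
    oh <- matrix(0, L, ncol(x))
    oh[cbind(seq_len(L), classes)] <- 1
    list(as.numeric(g) * (p - oh) / L)
  })
}

# scalar combination a*wa + b*wb of two 1x1 nodes
op_axpy <- function(a, wa, b, wb) {
  v <- node_val(a) * wa + node_val(b) * wb
  record(list(a, b), v, function(g) {
    list(if (is_node(a)) g * wa, if (is_node(b)) g * wb)
  })
}
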