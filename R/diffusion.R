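# DDPM machinery on the embedded angle manifold: variance schedules,
# the closed-form forward kernel, its algebraic inverse, and the reverse
# (ancestral) sampler.

#' Build a variance schedule
#'
#' Two families are supported. `linear` interpolates beta from
#' `beta_start` (0.001) to `beta_end` (0.02) over T steps and is the
#' training default. `cosine` uses the squared-cosine alpha-bar profile
#' with offset s = 0.008 and per-step beta clipped to at most 0.999, whose
#' flat boundaries stabilise late reverse-sampling steps. The per-step
#' sampler noise scale is sigma_t = sqrt(beta_t).
#'
#' @param family `"linear"` or `"cosine"`.
#' @param T_steps total diffusion steps (default 1000).
#' @param beta_start,beta_end linear-family endpoints.
#' @return object of class `noise_schedule` with fields `beta`, `alpha`,
#'   `alpha_bar`, `sigma`, `T_steps`, `family`.
#' @export
make_schedule <- function(family = c("linear", "cosine"), T_steps = 1000,
                          beta_start = 0.001, beta_end = 0.02) {
  family <- match.arg(family)
  stopifnot(T_steps >= 1)
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1)) {
    stop("schedule bounds must satisfy 0 < beta_start <= beta_end < 1")
  }
  if (family == "linear") {
    beta <- if (T_steps == 1) beta_start else {
      beta_start + (seq_len(T_steps) - 1) / (T_steps - 1) * (beta_end - beta_start)
    }
  } else {
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    abar <- f(seq_len(T_steps)) / f(0)
    abar_prev <- c(1, abar[-T_steps])
    beta <- pmin(1 - abar / abar_prev, 0.999)
  }
  alpha <- 1 - beta
  structure(list(family = family, T_steps = as.integer(T_steps),
                 beta = beta, alpha = alpha, alpha_bar = cumprod(alpha),
                 sigma = sqrt(beta)),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s, T = %d, beta in [%g, %g]\n",
              x$family, x$T_steps, x$beta[1], x$beta[x$T_steps]))
  invisible(x)
}

check_t <- function(t, schedule) {
  if (!(length(t) == 1 && t >= 1 && t <= schedule$T_steps)) {
    stop(sprintf("time step t = %s outside [1, %d]", toString(t), schedule$T_steps))
  }
  as.integer(t)
}

#' Closed-form forward noising
#'
#' Samples x_t = sqrt(alpha_bar_t) x0 + sqrt(1 - alpha_bar_t) eps directly
#' from the clean state, eps standard normal per entry.
#'
#' @param x0 clean state (`L x 12` angle embedding).
#' @param t step in 1..T.
#' @param schedule a [make_schedule()] object.
#' @param noise optional fixed eps matrix (same shape as `x0`); drawn
#'   internally when `NULL`.
#' @return list with `x` (noisy state), `eps` (the noise used), `t`.
#' @export
forward_sample <- function(x0, t, schedule, noise = NULL) {
  t <- check_t(t, schedule)
  x0 <- as.matrix(x0)
  if (is.null(noise)) {
    noise <- matrix(stats::rnorm(length(x0)), nrow(x0), ncol(x0))
  }
  stopifnot(all(dim(noise) == dim(x0)))
  ab <- schedule$alpha_bar[t]
  list(x = sqrt(ab) * x0 + sqrt(1 - ab) * noise, eps = noise, t = t)
}

#' Algebraic inverse of the forward kernel
#'
#' Recovers x0 = (x_t - sqrt(1 - alpha_bar_t) eps) / sqrt(alpha_bar_t);
#' exact when `eps` is the noise actually used by [forward_sample()].
#'
#' @param x_t noisy state.
#' @param eps the noise realisation.
#' @param t step in 1..T.
#' @param schedule a [make_schedule()] object.
#' @export
invert_forward <- function(x_t, eps, t, schedule) {
  t <- check_t(t, schedule)
  ab <- schedule$alpha_bar[t]
  (x_t - sqrt(1 - ab) * eps) / sqrt(ab)
}

#' One DDPM reverse (ancestral) step
#'
#' x_{t-1} = (x_t - (1 - alpha_t)/sqrt(1 - alpha_bar_t) eps_pred) /
#' sqrt(alpha_t) + sigma_t z. The injected noise z is forced to zero at
#' t = 1 so the returned clean state is deterministic given eps_pred.
#'
#' @param x_t current state.
#' @param eps_pred model noise prediction (same shape as `x_t`).
#' @param t step in 1..T.
#' @param schedule a [make_schedule()] object.
#' @param z optional fixed standard-normal draw.
#' @export
reverse_step <- function(x_t, eps_pred, t, schedule, z = NULL) {
  t <- check_t(t, schedule)
  x_t <- as.matrix(x_t)
  eps_pred <- as.matrix(eps_pred)
  if (!all(dim(x_t) == dim(eps_pred))) {
    stop("shape mismatch between x_t and the predicted noise")
  }
  a <- schedule$alpha[t]
  ab <- schedule$alpha_bar[t]
  mean_part <- (x_t - (1 - a) / sqrt(1 - ab) * eps_pred) / sqrt(a)
  if (t == 1) return(mean_part)
  if (is.null(z)) z <- matrix(stats::rnorm(length(x_t)), nrow(x_t), ncol(x_t))
  mean_part + schedule$sigma[t] * z
}

#' Sample a binder conformation by reverse diffusion
#'
#' Starts from standard-normal x_T in the 12-dimensional embedded angle
#' space and applies [reverse_step()] for t = T..1, querying `denoiser`
#' with (x_t, t, context) at each step; the final state is converted back
#' to angles with [unembed_angles()]. Fully reproducible given `seed`.
#'
#' @param denoiser function `(x_t, t, context) -> L x 12` noise prediction.
#' @param context target context consumed by the denoiser (opaque here).
#' @param L binder length (>= 2).
#' @param schedule a [make_schedule()] object.
#' @param seed integer seed controlling x_T and all injected noise.
#' @param trace if `TRUE`, attach the x_t trajectory as an attribute.
#' @return an [angle_table()] for the sampled binder.
#' @export
sample_trajectory <- function(denoiser, context, L, schedule, seed = 1, trace = FALSE) {
  stopifnot(L >= 2)
  with_seed(seed, {
    x <- matrix(stats::rnorm(L * 12), L, 12)
    traj <- if (trace) vector("list", schedule$T_steps) else NULL
    for (t in seq(schedule$T_steps, 1)) {
      eps_pred <- denoiser(x, t, context)
      x <- reverse_step(x, eps_pred, t, schedule)
      if (trace) traj[[schedule$T_steps - t + 1]] <- x
    }
    out <- unembed_angles(x)
    if (trace) attr(out, "trajectory") <- traj
    out
  })
}
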