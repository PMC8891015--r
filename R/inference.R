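# Parameter estimation for the single-compartment T4 model: bounded
# least-squares fitting with Latin-hypercube multi-start, and likelihood-free
# uncertainty quantification by rejection sampling against the same uniform
# priors and simulation budget used for simulation-based inference
# (20,000 forward simulations, 10,000 retained samples). Because the voltage
# equation is exactly invariant to scaling all gains and g_leak by a common
# factor, only ratios to g_leak (plus thresholds and E_leak) are
# identifiable; results are reported both raw and as ratios.

#' Fitting bounds of the free model parameters
#'
#' Thresholds in `[0, 1]`, gains in `[0, 2]`, `E_leak` in `[-80, -45]` mV and
#' `g_leak` in `[0, 3]`.
#'
#' @return list with named `lower` and `upper` vectors over the 12 free
#'   parameters (`gain_*`, `thr_*`, `E_leak`, `g_leak`).
#' @export
fit_bounds <- function() {
  lower <- c(rep(0, 5), rep(0, 5), -80, 0)
  upper <- c(rep(2, 5), rep(1, 5), -45, 3)
  names(lower) <- names(upper) <- PARAM_NAMES
  list(lower = lower, upper = upper)
}

theta_to_params <- function(theta) {
  synaptic_params(gains = stats::setNames(theta[1:5], T4_INPUT_CLASSES),
                  thresholds = stats::setNames(theta[6:10], T4_INPUT_CLASSES),
                  E_leak = theta[11], g_leak = max(theta[12], 1e-9))
}

params_to_theta <- function(params) {
  stats::setNames(c(params$gains, params$thresholds, params$E_leak, params$g_leak),
                  PARAM_NAMES)
}

# analytic gradient of the sum of squared residuals over conditions: with
# V = N/D, dV/dg_j = (E_j - V)/D, dg/dgain = rectified drive, dg/dthr =
# -gain wherever the drive exceeds the threshold, dV/dE_leak = g_leak/D and
# dV/dg_leak = (E_leak - V)/D
loss_gradient <- function(theta, Vs, t4, E_syn) {
  gl <- max(theta[12], 1e-9)
  g_out <- numeric(12)
  for (c_i in seq_along(Vs)) {
    V <- Vs[[c_i]]
    den <- gl
    num <- theta[11] * gl
    rect <- vector("list", 5)
    for (j in 1:5) {
      rect[[j]] <- pmax(V[, j] - theta[j + 5L], 0)
      g <- theta[j] * rect[[j]]
      num <- num + E_syn[j] * g
      den <- den + g
    }
    vm <- num / den
    w <- 2 * (vm - t4[[c_i]]) / den
    for (j in 1:5) {
      dv_dg <- (E_syn[j] - vm)
      g_out[j] <- g_out[j] + sum(w * dv_dg * rect[[j]])
      g_out[j + 5L] <- g_out[j + 5L] - theta[j] * sum(w * dv_dg * (rect[[j]] > 0))
    }
    g_out[11] <- g_out[11] + gl * sum(w)
    g_out[12] <- g_out[12] + sum(w * (theta[11] - vm))
  }
  g_out
}

# fast forward prediction for one condition; V is the nt x 5 matrix of
# normalized presynaptic drives in canonical class order
predict_vm_theta <- function(theta, V, E_syn) {
  gl <- max(theta[12], 1e-9)
  num <- theta[11] * gl
  den <- gl
  for (j in 1:5) {
    g <- theta[j] * pmax(V[, j] - theta[j + 5L], 0)
    num <- num + E_syn[j] * g
    den <- den + g
  }
  num / den
}

# reversal potential per class in canonical order, from a synaptic_params
class_reversals <- function(params) {
  c(params$E_Glu, params$E_ACh, params$E_ACh, params$E_GABA, params$E_GABA)
}

as_vmat <- function(v_norm) {
  vapply(T4_INPUT_CLASSES, function(cl) v_norm[[cl]],
         numeric(length(v_norm[[T4_INPUT_CLASSES[1]]])))
}

#' Least-squares loss of the model against T4 voltage data
#'
#' Sum over stimulus conditions and time points of the squared difference
#' between the model prediction and the measured T4 membrane potential.
#' Zero if and only if the prediction matches the data exactly.
#'
#' @param params a `synaptic_params` object (or a length-12 parameter vector
#'   in the order `gain_Mi9..C3, thr_Mi9..C3, E_leak, g_leak`).
#' @param v_norm list (one element per condition) of named lists of
#'   normalized presynaptic drives.
#' @param t4 list of measured T4 voltage traces (mV), matching `v_norm`.
#' @param reversals reversal potentials `c(E_Glu, E_ACh, E_GABA)` used for
#'   the synapse classes (defaults -71, -21, -68 mV).
#' @return scalar sum of squared residuals (mV^2).
#' @export
model_loss <- function(params, v_norm, t4, reversals = c(-71, -21, -68)) {
  theta <- if (inherits(params, "synaptic_params")) params_to_theta(params) else params
  E_syn <- reversals[c(1, 2, 2, 3, 3)]
  stop_if_not(length(v_norm) == length(t4), "conditions of v_norm and t4 differ")
  tot <- 0
  for (c_i in seq_along(v_norm)) {
    V <- as_vmat(v_norm[[c_i]])
    stop_if_not(nrow(V) == length(t4[[c_i]]), "mismatched trace lengths")
    r <- predict_vm_theta(theta, V, E_syn) - t4[[c_i]]
    tot <- tot + sum(r * r)
  }
  tot
}

#' Bounded least-squares fit of the T4 model parameters
#'
#' Minimizes [model_loss()] with `L-BFGS-B` within the printed bounds, using
#' Latin-hypercube multi-start initialization (plus any user-supplied
#' starting points) and returning the best converged solution. The returned
#' loss is never higher than the loss at the best initializer.
#'
#' @param v_norm,t4,reversals as in [model_loss()].
#' @param n_starts number of Latin-hypercube starts (default 16).
#' @param init optional list of additional starting parameter vectors or
#'   `synaptic_params` objects.
#' @param seed integer seed for the start design.
#' @param maxit maximum iterations per start (default 300).
#' @return list with `params` (a `synaptic_params`), `theta`, `loss`,
#'   `ratios` (gains over `g_leak`), `convergence` (per-start codes) and
#'   `n_starts`.
#' @export
fit_point_model <- function(v_norm, t4, reversals = c(-71, -21, -68),
                            n_starts = 16, init = NULL, seed = 1L, maxit = 300) {
  stop_if_not(length(v_norm) >= 1, "need data from at least one condition")
  b <- fit_bounds()
  lower <- b$lower; upper <- b$upper
  lower["g_leak"] <- 1e-6  # keep the total conductance strictly positive
  E_syn <- reversals[c(1, 2, 2, 3, 3)]
  Vs <- lapply(v_norm, as_vmat)
  obj <- function(theta) {
    tot <- 0
    for (c_i in seq_along(Vs)) {
      r <- predict_vm_theta(theta, Vs[[c_i]], E_syn) - t4[[c_i]]
      tot <- tot + sum(r * r)
    }
    tot
  }
  grad <- function(theta) loss_gradient(theta, Vs, t4, E_syn)
  starts <- if (n_starts > 0) {
    U <- with_local_seed(seed, lhs::randomLHS(n_starts, length(lower)))
    lapply(seq_len(n_starts), function(i) lower + U[i, ] * (upper - lower))
  } else list()
  if (!is.null(init)) {
    extra <- lapply(init, function(x) {
      th <- if (inherits(x, "synaptic_params")) params_to_theta(x) else x
      pmin(pmax(th, lower), upper)
    })
    starts <- c(extra, starts)
  }
  fits <- lapply(starts, function(th0) {
    out <- try(stats::optim(th0, obj, gr = grad, method = "L-BFGS-B", lower = lower,
                            upper = upper, control = list(maxit = maxit)),
               silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    out
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimization starts failed; check data scaling and bounds")
  losses <- vapply(fits[ok], `[[`, numeric(1), "value")
  start_losses <- vapply(starts, obj, numeric(1))
  best <- fits[ok][[which.min(losses)]]
  polish <- try(stats::optim(best$par, obj, gr = grad, method = "L-BFGS-B",
                             lower = lower, upper = upper,
                             control = list(maxit = 2L * maxit)), silent = TRUE)
  if (!inherits(polish, "try-error") && polish$value <= best$value) best <- polish
  if (min(start_losses) < best$value) {  # guard: never worse than an initializer
    th <- starts[[which.min(start_losses)]]
    best <- list(par = th, value = min(start_losses), convergence = 1L)
  }
  theta <- stats::setNames(best$par, PARAM_NAMES)
  list(params = theta_to_params(theta), theta = theta, loss = best$value,
       ratios = stats::setNames(theta[1:5] / theta[12], paste0("ratio_", T4_INPUT_CLASSES)),
       convergence = vapply(fits[ok], `[[`, numeric(1), "convergence"),
       n_starts = length(starts))
}

#' Rejection-sampling posterior over the model parameters
#'
#' Draws `n_sim` parameter sets from independent uniform priors within the
#' fitting bounds, simulates each, computes the root-mean-square voltage
#' error concatenated over all conditions, and keeps the `n_keep` sets with
#' the smallest distance (uniform weights, distances sorted ascending).
#' With `n_keep = n_sim` the accepted set reproduces the prior. The exact
#' gain/`g_leak` scale degeneracy of the model leaves the corresponding
#' direction of parameter space unconstrained.
#'
#' @param v_norm,t4,reversals as in [model_loss()].
#' @param n_sim number of prior draws (default 20000).
#' @param n_keep number of accepted samples (default 10000).
#' @param seed integer seed.
#' @return an object of class `posterior_samples`: list with `samples`
#'   (`n_keep x 12` matrix), `distance_mV` (ascending), `bounds`, `n_sim`.
#' @export
posterior_point_model <- function(v_norm, t4, reversals = c(-71, -21, -68),
                                  n_sim = 20000, n_keep = 10000, seed = 1L) {
  stop_if_not(n_keep <= n_sim, "n_keep must not exceed n_sim")
  b <- fit_bounds()
  E_syn <- reversals[c(1, 2, 2, 3, 3)]
  Vs <- lapply(v_norm, as_vmat)
  n_pts <- sum(vapply(t4, length, numeric(1)))
  draws <- with_local_seed(seed, {
    matrix(stats::runif(n_sim * 12), n_sim, 12)
  })
  draws <- sweep(sweep(draws, 2, b$upper - b$lower, `*`), 2, b$lower, `+`)
  colnames(draws) <- PARAM_NAMES
  dist <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    th <- draws[i, ]
    ss <- 0
    for (c_i in seq_along(Vs)) {
      r <- predict_vm_theta(th, Vs[[c_i]], E_syn) - t4[[c_i]]
      ss <- ss + sum(r * r)
    }
    dist[i] <- sqrt(ss / n_pts)
  }
  ord <- order(dist)[seq_len(n_keep)]
  structure(list(samples = draws[ord, , drop = FALSE], distance_mV = dist[ord],
                 bounds = b, n_sim = n_sim),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d kept of %d simulations; RMS distance %.3g-%.3g mV\n",
              nrow(x$samples), x$n_sim, min(x$distance_mV), max(x$distance_mV)))
  invisible(x)
}

#' Identifiable parameter combinations
#'
#' Because of the exact scale degeneracy, the identifiable quantities are
#' the gain-to-leak ratios, the thresholds and `E_leak`.
#'
#' @param theta length-12 parameter vector or `synaptic_params`.
#' @return named vector of 11 identifiable quantities.
#' @export
identifiable_quantities <- function(theta) {
  if (inherits(theta, "synaptic_params")) theta <- params_to_theta(theta)
  c(stats::setNames(theta[1:5] / theta[12], paste0("ratio_", T4_INPUT_CLASSES)),
    theta[6:10], E_leak = unname(theta[11]))
}

#' Parameter-recovery experiment on synthetic data
#'
#' For each seed, generates the four-condition data set from the reference
#' ground truth at the given noise level, fits the model, and scores the
#' relative error of every identifiable quantity against the ground truth.
#'
#' @param n_seeds number of independent replicates (default 20).
#' @param noise_sd_mV voltage noise on the T4 traces (default 1 mV).
#' @param n_starts Latin-hypercube starts per fit; the ground-truth
#'   neighbourhood is not used for initialization.
#' @param gt ground truth (default [reference_params()] circuit).
#' @param seed base seed.
#' @return list with `rel_err` (matrix seeds x quantities), the per-seed
#'   fitted losses and the pooled `median_rel_err`.
#' @export
recovery_experiment <- function(n_seeds = 20, noise_sd_mV = 1, n_starts = 16,
                                gt = ground_truth(), seed = 1L) {
  truth <- identifiable_quantities(gt$params)
  rel <- matrix(NA_real_, n_seeds, length(truth),
                dimnames = list(NULL, names(truth)))
  losses <- numeric(n_seeds)
  base <- synth_condition_set(gt, noise_sd_mV = 0)
  for (s in seq_len(n_seeds)) {
    t4 <- lapply(seq_along(base$vm_true), function(i) {
      base$vm_true[[i]] + with_local_seed(substream_seed(seed + s, i),
                                          stats::rnorm(length(base$vm_true[[i]]),
                                                       0, noise_sd_mV))
    })
    fit <- fit_point_model(base$v_norm, t4, n_starts = n_starts, seed = seed + s)
    est <- identifiable_quantities(fit$theta)
    rel[s, ] <- abs(est - truth) / abs(truth)
    losses[s] <- fit$loss
  }
  list(rel_err = rel, losses = losses, median_rel_err = stats::median(rel))
}
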