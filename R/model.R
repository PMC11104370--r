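#' Network architecture configuration
#'
#' Describes the fixed architecture of an S-CTRNNPB: a hierarchical recurrent
#' network whose neurons fall into five contiguous groups — external input,
#' parametric bias (PB, the higher level), lower-level recurrent neurons, and
#' output neurons predicting the mean and variance of the next input.  The PB
#' internal state is constant over time within a sequence (an infinitely slow
#' time constant), which is what makes the PB a higher-level representation:
#' sequence identity is encoded in where the PB sits, not in its dynamics.
#'
#' @param n_input Number of input dimensions (features per time step).
#' @param n_pb Number of parametric-bias neurons.
#' @param n_lower Number of lower-level recurrent neurons.
#' @param tau_lower Time constant of the lower-level neurons, in steps
#'   (leaky-integration constant; larger is slower).  Must be >= 1.
#' @param variance_floor Additive floor on the predicted variance, keeping the
#'   Gaussian likelihood finite.
#' @param u_var_cap Upper cap on the variance pre-activation before
#'   exponentiation, guarding against overflow.  Not reached in normal runs.
#'
#' @return An object of class `"sctrnnpb_config"`.
#' @examples
#' network_config(n_input = 9)
#' @export
network_config <- function(n_input, n_pb = 2L, n_lower = 30L,
                           tau_lower = 2, variance_floor = 1e-6,
                           u_var_cap = 10) {
  stop_if_not(n_input >= 1 && n_pb >= 1 && n_lower >= 1,
              "all neuron counts must be >= 1")
  stop_if_not(tau_lower >= 1, "tau_lower must be >= 1")
  stop_if_not(variance_floor > 0, "variance_floor must be positive")
  structure(list(n_input = as.integer(n_input), n_pb = as.integer(n_pb),
                 n_lower = as.integer(n_lower),
                 n_mean = as.integer(n_input), n_var = as.integer(n_input),
                 tau_lower = tau_lower, variance_floor = variance_floor,
                 u_var_cap = u_var_cap),
            class = "sctrnnpb_config")
}

#' @export
print.sctrnnpb_config <- function(x, ...) {
  cat("S-CTRNNPB architecture: ", x$n_input, " input -> ", x$n_lower,
      " lower (tau = ", x$tau_lower, ") <- ", x$n_pb, " PB; ",
      x$n_mean, " mean + ", x$n_var, " variance outputs\n", sep = "")
  invisible(x)
}

#' Initialize model parameters for one experimental condition
#'
#' Draws connectivity masks for the inter-level weight blocks at the
#' condition's connection proportions (higher-level proportion for PB->lower,
#' lower-level proportion for input->lower, lower->mean and lower->variance),
#' draws the fixed lower-level activity thresholds from a centred Gaussian
#' with variance `K`, and initializes the weights at small random values
#' (scaled by inverse square-root fan-in).  Lower-level recurrent connectivity
#' is always full and PB neurons are never connected to each other.
#'
#' The threshold vector `a_lower` is fixed at its draw and never updated by
#' learning; its variance `K` is the network-excitability-homogeneity
#' manipulation (small `K` = homogeneous excitability).
#'
#' @param config A [network_config()].
#' @param condition A [condition_spec()].
#' @param seed Integer seed for masks, thresholds, and weight draws;
#'   `NULL` uses the current RNG stream.
#' @return An object of class `"sctrnnpb_params"`: a named list of weight
#'   matrices `W_xl`, `W_ll`, `W_pl`, `W_lm`, `W_lv`, masks `M_xl`, `M_pl`,
#'   `M_lm`, `M_lv`, thresholds `a_lower` (fixed), and trainable output biases
#'   `a_mean`, `a_var`.
#' @export
init_parameters <- function(config, condition, seed = NULL) {
  stopifnot(inherits(config, "sctrnnpb_config"),
            inherits(condition, "condition_spec"))
  with_seed(seed, {
    H <- config$n_lower; D <- config$n_input; P <- config$n_pb
    M_pl <- build_fc_mask(H, P, condition$fc_high)
    M_xl <- build_fc_mask(H, D, condition$fc_low)
    M_lm <- build_fc_mask(config$n_mean, H, condition$fc_low)
    M_lv <- build_fc_mask(config$n_var, H, condition$fc_low)
    a_lower <- init_thresholds(H, condition$K)
    w <- function(r, c, fan) matrix(rnorm(r * c, sd = 1 / sqrt(fan)), r, c)
    p <- list(W_xl = w(H, D, D) * M_xl,
              W_ll = w(H, H, H),
              W_pl = w(H, P, P) * M_pl,
              W_lm = w(D, H, H) * M_lm,
              W_lv = w(D, H, H) * M_lv,
              a_lower = a_lower,
              a_mean = numeric(D), a_var = numeric(D),
              M_xl = M_xl, M_pl = M_pl, M_lm = M_lm, M_lv = M_lv)
    structure(p, class = "sctrnnpb_params")
  })
}

#' Output nonlinearities of the Gaussian read-out
#'
#' Maps the internal states of the mean and variance output neurons to the
#' predicted mean (squashed into (-1, 1) by tanh) and the predicted variance
#' (made positive by exponentiation plus a small floor).
#'
#' @param u_mean,u_var Real vectors of output-neuron internal states.
#' @param variance_floor Additive variance floor (default `1e-6`).
#' @param u_var_cap Cap applied to `u_var` before exponentiation.
#' @return A list with components `y` (predicted mean, strictly in (-1, 1))
#'   and `v` (predicted variance, strictly positive).
#' @examples
#' output_activation(0, log(2))  # y = 0, v = 2 + 1e-6
#' @export
output_activation <- function(u_mean, u_var, variance_floor = 1e-6,
                              u_var_cap = 10) {
  stop_if_not(all(is.finite(u_mean)) && all(is.finite(u_var)),
              "non-finite output internal states")
  list(y = tanh(u_mean), v = exp(pmin(u_var, u_var_cap)) + variance_floor)
}

#' One step of the forward dynamics
#'
#' Advances the lower level by one leaky-integration step and produces the
#' Gaussian read-out.  The lower-level internal state is a convex combination
#' of its previous value and the weighted drive from the current input, the
#' previous lower-level activities, the (constant) PB activities and the fixed
#' threshold; the mixing weight is the inverse time constant.  The PB internal
#' state is left untouched — its constancy over time is the defining property
#' of the higher level.
#'
#' This is the reference single-step implementation; whole-sequence runs and
#' training use an equivalent compiled path (see [run_sequence()]).
#'
#' @param params An `"sctrnnpb_params"` object.
#' @param config The matching [network_config()].
#' @param prev Previous state: a list with `u_lower` (internal states) and
#'   `l` (activities); use [initial_state()] at the first step.
#' @param x_t Input vector at the current step, each entry in \[-1, 1\].
#' @param pb_internal PB internal-state vector (constant over the sequence).
#' @return A list of class `"sctrnnpb_state"`: `u_lower`, `l`, `p`
#'   (PB activity), `y` (predicted mean), `v` (predicted variance).
#' @export
forward_step <- function(params, config, prev, x_t, pb_internal) {
  if (!all(is.finite(prev$u_lower)) || !all(is.finite(x_t)))
    stop("non-finite network input at this step", call. = FALSE)
  it <- 1 / config$tau_lower
  p <- tanh(pb_internal)
  drive <- (params$W_xl * params$M_xl) %*% x_t +
    params$W_ll %*% prev$l +
    (params$W_pl * params$M_pl) %*% p +
    params$a_lower
  u <- it * drive + (1 - it) * prev$u_lower
  l <- tanh(u)
  u_m <- (params$W_lm * params$M_lm) %*% l + params$a_mean
  u_v <- (params$W_lv * params$M_lv) %*% l + params$a_var
  out <- output_activation(drop(u_m), drop(u_v), config$variance_floor,
                           config$u_var_cap)
  structure(list(u_lower = drop(u), l = drop(l), p = p,
                 y = out$y, v = out$v),
            class = "sctrnnpb_state")
}

#' @rdname forward_step
#' @export
initial_state <- function(config) {
  list(u_lower = numeric(config$n_lower), l = numeric(config$n_lower))
}

#' Gaussian negative log-likelihood of a predicted sequence
#'
#' The training loss: for every predicted step and dimension,
#' `ln(2 pi v)/2 + (target - y)^2 / (2 v)` — a precision-weighted squared
#' prediction error plus a variance penalty.  The total is the sum over all
#' entries.
#'
#' @param y_all,v_all Matrices (steps x dims) of predicted means/variances.
#' @param targets Matrix of target values, same shape.
#' @return A list of class `"sctrnnpb_loss"` with `total` (nats) and
#'   `per_step_per_dim` (the matrix of entry-wise losses).
#' @examples
#' sequence_nll(0, 1, 0)$total  # log(2*pi)/2
#' @export
sequence_nll <- function(y_all, v_all, targets) {
  y_all <- as.matrix(y_all); v_all <- as.matrix(v_all)
  targets <- as.matrix(targets)
  stop_if_not(all(dim(y_all) == dim(v_all)) &&
                all(dim(y_all) == dim(targets)), "shapes must conform")
  if (any(v_all <= 0)) stop("nonpositive predicted variance", call. = FALSE)
  per <- log(2 * pi * v_all) / 2 + (targets - y_all)^2 / (2 * v_all)
  structure(list(total = sum(per), per_step_per_dim = per),
            class = "sctrnnpb_loss")
}

# internal: sequence matrix from an emotion_sequence or plain matrix
seq_values <- function(sequence) {
  x <- if (inherits(sequence, "emotion_sequence")) sequence$values
       else as.matrix(sequence)
  stop_if_not(nrow(x) >= 2, "sequence must have length >= 2")
  x
}

#' Run the network over a whole sequence
#'
#' Open-loop mode feeds the true sequence values as inputs (the network
#' predicts each next step from real sensory input); closed-loop mode feeds
#' the network's own previous predicted mean back as input from the second
#' step onward (generation driven purely by the top-down PB), with only the
#' first input taken from the sequence.
#'
#' @param params An `"sctrnnpb_params"` object.
#' @param config The matching [network_config()].
#' @param sequence An [emotion_sequence()] or a numeric T x D matrix.
#' @param pb_internal PB internal-state vector.
#' @param mode `"open_loop"` or `"closed_loop"`.
#' @return A list: `y`, `v` ((T-1) x D predicted means/variances), `u_lower`,
#'   `l` ((T-1) x n_lower states/activities), `loss` (a `"sctrnnpb_loss"`),
#'   `mse` (mean squared prediction error over all steps and dimensions),
#'   and `pb_activity`.
#' @export
run_sequence <- function(params, config, sequence, pb_internal,
                         mode = c("open_loop", "closed_loop")) {
  mode <- match.arg(mode)
  x <- seq_values(sequence)
  r <- cpp_run_sequence(unclass(params), config$tau_lower,
                        config$variance_floor, config$u_var_cap, x,
                        as.numeric(pb_internal), mode == "closed_loop")
  r$loss <- structure(list(total = r$nll, per_step_per_dim = r$per_step_per_dim),
                      class = "sctrnnpb_loss")
  r$per_step_per_dim <- NULL
  r$pb_activity <- drop(r$pb_activity)
  r
}

#' Exact gradients of the sequence loss
#'
#' Backpropagation through time of the total negative log-likelihood of an
#' open-loop run, with respect to every trainable quantity: the masked
#' inter-level weights, the full lower-level recurrent weights, the output
#' biases, and the sequence's PB internal state.  The fixed lower-level
#' thresholds have no gradient, and gradients of masked-out weight entries
#' are identically zero.
#'
#' @inheritParams run_sequence
#' @return A named list of gradient arrays (`W_xl`, `W_ll`, `W_pl`, `W_lm`,
#'   `W_lv`, `a_mean`, `a_var`, `pb`) plus the loss value `nll`.
#' @export
gradients <- function(params, config, sequence, pb_internal) {
  x <- seq_values(sequence)
  g <- cpp_gradients(unclass(params), config$tau_lower, config$variance_floor,
                     config$u_var_cap, x, as.numeric(pb_internal))
  g$a_mean <- drop(g$a_mean); g$a_var <- drop(g$a_var); g$pb <- drop(g$pb)
  g
}

#' Serialize model parameters
#'
#' Writes/restores a parameter set (or a whole fitted model) as a single
#' binary archive of named arrays; the round-trip is exact.
#'
#' @param object An `"sctrnnpb_params"` or fitted `"sctrnnpb"` object.
#' @param path File path for the archive.
#' @return `load_model()` returns the restored object; `save_model()` its
#'   path, invisibly.
#' @export
save_model <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
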