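#' Optimization settings for the two learning phases
#'
#' @param epochs_train Full-batch epochs of developmental training.
#' @param epochs_test Epochs of PB-only optimization in the recognition
#'   (test) phase.
#' @param learning_rate Adaptive-moment step size.
#' @param beta1,beta2 Exponential decay rates of the first and second
#'   gradient moments, each in (0, 1).
#' @param pb_init Initial PB internal state (scalar, default 0).
#' @param global_seed Seed controlling weight/mask/threshold draws when not
#'   overridden.
#' @return An object of class `"training_hyper"`.
#' @export
training_hyper <- function(epochs_train = 3000L, epochs_test = 2000L,
                           learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           pb_init = 0, global_seed = 1L) {
  stop_if_not(epochs_train >= 1, "epochs_train must be >= 1")
  stop_if_not(epochs_test >= 0, "epochs_test must be >= 0")
  stop_if_not(learning_rate > 0, "learning_rate must be positive")
  stop_if_not(beta1 > 0 && beta1 < 1 && beta2 > 0 && beta2 < 1,
              "moment decay rates must lie in (0, 1)")
  structure(list(epochs_train = as.integer(epochs_train),
                 epochs_test = as.integer(epochs_test),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 pb_init = pb_init, global_seed = as.integer(global_seed)),
            class = "training_hyper")
}

#' Identity-blocked cross-validation folds
#'
#' Identities are partitioned into `n_folds` equal groups (at random); each
#' fold holds out every sequence of its identity group across all emotions
#' and trains on the rest, so recognition is always tested on unseen
#' individuals, never unseen emotions.
#'
#' @param set A `"sequence_set"`.
#' @param n_folds Number of folds; must divide the number of identities.
#' @param seed Optional integer seed for the identity shuffle.
#' @return A list of `n_folds` lists with integer vectors `train_ids` and
#'   `test_ids` (indices into `set$sequences`).
#' @export
make_folds <- function(set, n_folds = 8L, seed = NULL) {
  S <- set$S
  if (S %% n_folds != 0)
    stop("number of identities (", S, ") not divisible by n_folds (",
         n_folds, ")", call. = FALSE)
  with_seed(seed, {
    perm <- sample.int(S)
    per <- S %/% n_folds
    identity_of <- vapply(set$sequences, `[[`, integer(1), "identity")
    lapply(seq_len(n_folds), function(f) {
      held <- perm[((f - 1) * per + 1):(f * per)]
      test <- which(identity_of %in% held)
      list(train_ids = setdiff(seq_along(set$sequences), test),
           test_ids = test)
    })
  })
}

#' Fit an S-CTRNNPB by developmental learning
#'
#' The training phase of the experiment: starting from small random weights,
#' condition-specific connectivity masks and fixed Gaussian thresholds, the
#' network structure (masked weights, output biases) and one PB
#' internal-state vector per training sequence are optimized jointly by
#' full-batch adaptive-moment gradient descent on the summed Gaussian
#' negative log-likelihood of next-step prediction.  No emotion labels enter
#' training; any emotion structure in the final PB activities is
#' self-organized.
#'
#' @param sequences A list of [emotion_sequence()] objects (or a whole
#'   `"sequence_set"`, in which case all its sequences are used).
#' @param condition A [condition_spec()] fixing connection proportions and
#'   threshold variance.
#' @param config A [network_config()]; defaults to the standard architecture
#'   sized to the data (2 PB, 30 lower-level neurons).
#' @param hyper A [training_hyper()].
#' @param init_seed Seed for masks, thresholds and initial weights
#'   (default `hyper$global_seed`).
#' @param params Optionally, a pre-built `"sctrnnpb_params"` to start from
#'   (then `init_seed` is ignored).
#' @return An object of class `"sctrnnpb"` with components `params`
#'   (trained), `config`, `condition`, `hyper`, `pb_internal` (matrix,
#'   one row per training sequence), `train_pbs` (tanh activities),
#'   `emotions`, `identities`, `learning_curve` (per-epoch mean training
#'   MSE), `nll_curve`, `train_error` (final mean MSE) and `sequences`.
#' @seealso [infer_pb()] for the recognition phase, [cross_validate()] for
#'   the full protocol.
#' @examples
#' set <- generate_sequence_set(E = 2, S = 2, D = 3, T = 15, seed = 1)
#' fit <- sctrnnpb(set, condition_spec(100, 100, 10),
#'                 network_config(n_input = 3, n_lower = 10),
#'                 training_hyper(epochs_train = 50))
#' fit$train_error < fit$learning_curve[1]
#' @export
sctrnnpb <- function(sequences, condition = condition_spec(),
                     config = NULL, hyper = training_hyper(),
                     init_seed = hyper$global_seed, params = NULL) {
  if (inherits(sequences, "sequence_set")) sequences <- sequences$sequences
  stop_if_not(length(sequences) >= 1, "training set must be nonempty")
  D <- ncol(sequences[[1]]$values)
  if (is.null(config)) config <- network_config(n_input = D)
  stop_if_not(config$n_input == D, "config n_input must match the data")
  if (is.null(params)) params <- init_parameters(config, condition, init_seed)
  X <- lapply(sequences, `[[`, "values")
  PBq <- matrix(hyper$pb_init, length(sequences), config$n_pb)
  r <- cpp_train(unclass(params), config$tau_lower, config$variance_floor,
                 config$u_var_cap, X, PBq, hyper$epochs_train,
                 hyper$learning_rate, hyper$beta1, hyper$beta2)
  trained <- structure(r$params, class = "sctrnnpb_params")
  structure(list(params = trained, config = config, condition = condition,
                 hyper = hyper, pb_internal = r$pb_internal,
                 train_pbs = tanh(r$pb_internal),
                 emotions = vapply(sequences, `[[`, integer(1), "emotion"),
                 identities = vapply(sequences, `[[`, integer(1), "identity"),
                 learning_curve = drop(r$curve_mse),
                 nll_curve = drop(r$curve_nll),
                 train_error = mean(r$final_mse),
                 per_sequence_mse = drop(r$final_mse),
                 sequences = sequences,
                 call = match.call()),
            class = "sctrnnpb")
}

#' @export
print.sctrnnpb <- function(x, ...) {
  cat("S-CTRNNPB fit (", format(x$condition), "): ",
      length(x$sequences), " sequences, ", x$hyper$epochs_train,
      " epochs\n", sep = "")
  cat(sprintf("  training MSE: %.5f (initial %.5f)\n",
              x$train_error, x$learning_curve[1]))
  invisible(x)
}

#' @export
summary.sctrnnpb <- function(object, ...) {
  s <- list(condition = object$condition,
            n_sequences = length(object$sequences),
            train_error = object$train_error,
            per_sequence_mse = object$per_sequence_mse,
            pb_range = range(object$train_pbs),
            final_nll = mean(object$nll_curve[length(object$nll_curve)]))
  class(s) <- "summary.sctrnnpb"
  s
}

#' @export
print.summary.sctrnnpb <- function(x, ...) {
  print(x$condition)
  cat(sprintf("sequences: %d   mean train MSE: %.5f\n",
              x$n_sequences, x$train_error))
  cat(sprintf("per-sequence MSE: [%.5f, %.5f]   PB activity range: [%.3f, %.3f]\n",
              min(x$per_sequence_mse), max(x$per_sequence_mse),
              x$pb_range[1], x$pb_range[2]))
  invisible(x)
}

#' @export
coef.sctrnnpb <- function(object, ...) object$params

#' Predict a sequence with a fitted network
#'
#' With `pb` supplied, runs the network in the requested mode from that PB.
#' With `pb = NULL`, first performs recognition ([infer_pb()]) on `newdata`
#' and then predicts from the inferred PB.
#'
#' @param object A fitted `"sctrnnpb"`.
#' @param newdata An [emotion_sequence()] or T x D matrix.
#' @param pb PB internal-state vector, or `NULL` to infer it.
#' @param mode `"open_loop"` or `"closed_loop"`.
#' @param ... Unused.
#' @return The [run_sequence()] result, plus `pb_internal` used.
#' @export
predict.sctrnnpb <- function(object, newdata, pb = NULL,
                             mode = c("open_loop", "closed_loop"), ...) {
  mode <- match.arg(mode)
  if (is.null(pb)) pb <- infer_pb(object, newdata)$pb_internal
  out <- run_sequence(object$params, object$config, newdata, pb, mode)
  out$pb_internal <- pb
  out
}

#' @export
residuals.sctrnnpb <- function(object, ...) {
  lapply(seq_along(object$sequences), function(i) {
    x <- object$sequences[[i]]$values
    r <- run_sequence(object$params, object$config, x,
                      object$pb_internal[i, ], "open_loop")
    x[-1, , drop = FALSE] - r$y
  })
}

#' @export
plot.sctrnnpb <- function(x, ...) {
  plot(seq_along(x$learning_curve), x$learning_curve, type = "l", log = "y",
       xlab = "epoch", ylab = "mean training MSE",
       main = paste("learning curve,", format(x$condition)), ...)
  invisible(x)
}

#' Closed-loop generation from a fitted network
#'
#' Generates trajectories driven purely top-down: from a PB internal state
#' and an initial input frame, the network's own predicted mean is fed back
#' as the next input.
#'
#' @param object A fitted `"sctrnnpb"`.
#' @param nsim Number of trajectories; PB rows are recycled over the
#'   training PBs if `pb` is missing.
#' @param seed Unused (generation is deterministic); kept for the generic.
#' @param pb Matrix of PB internal states (rows), default the training PBs.
#' @param x1 Initial input frame(s): a vector, or matrix with `nsim` rows;
#'   default the first frame of each corresponding training sequence.
#' @param steps Trajectory length (default the training length).
#' @param ... Unused.
#' @return A list of `nsim` generated (steps-1) x D matrices.
#' @export
simulate.sctrnnpb <- function(object, nsim = 1, seed = NULL, pb = NULL,
                              x1 = NULL, steps = NULL, ...) {
  if (is.null(steps)) steps <- nrow(object$sequences[[1]]$values)
  lapply(seq_len(nsim), function(i) {
    j <- (i - 1) %% length(object$sequences) + 1
    q <- if (is.null(pb)) object$pb_internal[j, ]
         else if (is.matrix(pb)) pb[(i - 1) %% nrow(pb) + 1, ] else pb
    x0 <- if (is.null(x1)) object$sequences[[j]]$values[1, ]
          else if (is.matrix(x1)) x1[(i - 1) %% nrow(x1) + 1, ] else x1
    # closed loop only needs the first row of the "sequence"; the rest of the
    # matrix serves as dummy targets
    dummy <- matrix(0, steps, length(x0)); dummy[1, ] <- x0
    run_sequence(object$params, object$config, dummy, q, "closed_loop")$y
  })
}

#' Recognition phase: infer the PB for a new sequence
#'
#' Optimizes only the sequence's PB internal state (initialized at
#' `hyper$pb_init`) against the open-loop prediction loss; the trained
#' network structure is read-only and left bit-identical.  The resulting PB
#' activity is the network's "recognition" of the sequence: if training
#' self-organized emotion clusters in PB space, a test sequence of a known
#' emotion should land near its cluster.
#'
#' @param model A fitted `"sctrnnpb"`.
#' @param sequence An [emotion_sequence()] or T x D matrix.
#' @param hyper Optimization settings; defaults to the model's own, with
#'   `epochs_test` iterations.
#' @return A list: `pb_activity`, `pb_internal`, `mse` (final open-loop
#'   mean squared error), `nll`, and `curve_mse` (per-epoch MSE).
#' @export
infer_pb <- function(model, sequence, hyper = model$hyper) {
  x <- seq_values(sequence)
  q0 <- rep(hyper$pb_init, model$config$n_pb)
  r <- cpp_infer_pb(unclass(model$params), model$config$tau_lower,
                    model$config$variance_floor, model$config$u_var_cap,
                    x, q0, hyper$epochs_test, hyper$learning_rate,
                    hyper$beta1, hyper$beta2)
  r$pb_activity <- drop(r$pb_activity)
  r$pb_internal <- drop(r$pb_internal)
  r$curve_mse <- drop(r$curve_mse)
  r
}

#' Cross-validated two-phase protocol for one condition
#'
#' Runs the full developmental protocol under identity-blocked
#' cross-validation: per fold, train on the retained identities
#' ([sctrnnpb()]), then infer a PB for every held-out sequence
#' ([infer_pb()]).  One mask/threshold/weight initialization is drawn per
#' replicate (from `seed`) and shared across folds, so folds differ only in
#' the data split.  The aggregate `test_error` is the ASD-like
#' generalization measure; `eri` is the emotion recognition index of the
#' held-out PBs against the training clusters, averaged over folds.
#'
#' @param set A `"sequence_set"`.
#' @param condition A [condition_spec()].
#' @param config A [network_config()] (default sized to the data).
#' @param hyper A [training_hyper()].
#' @param n_folds Number of identity folds (default 8).
#' @param seed Replicate seed driving fold assignment and initialization.
#' @return An object of class `"sctrnnpb_cv"`: `folds` (per fold:
#'   `learning_curve_train`, `learning_curve_test`, `train_pbs`, `test_pbs`,
#'   emotion labels, `train_error`, `test_error`, `eri`, and the fitted
#'   `model`), plus aggregate `train_error`, `test_error`, `eri`.
#' @export
cross_validate <- function(set, condition, config = NULL,
                           hyper = training_hyper(), n_folds = 8L,
                           seed = hyper$global_seed) {
  if (is.null(config)) config <- network_config(n_input = set$D)
  folds <- make_folds(set, n_folds, seed = seed)
  params0 <- init_parameters(config, condition, seed = seed)
  results <- lapply(seq_along(folds), function(f) {
    fold <- folds[[f]]
    train_seqs <- set$sequences[fold$train_ids]
    test_seqs <- set$sequences[fold$test_ids]
    model <- tryCatch(
      sctrnnpb(train_seqs, condition, config, hyper, params = params0),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                               call. = FALSE))
    inf <- lapply(test_seqs, function(sq) infer_pb(model, sq))
    test_pbs <- do.call(rbind, lapply(inf, `[[`, "pb_activity"))
    test_mse <- vapply(inf, `[[`, numeric(1), "mse")
    curve_test <- rowMeans(do.call(cbind, lapply(inf, `[[`, "curve_mse")))
    list(learning_curve_train = model$learning_curve,
         learning_curve_test = curve_test,
         train_pbs = model$train_pbs,
         test_pbs = test_pbs,
         train_emotions = model$emotions,
         test_emotions = vapply(test_seqs, `[[`, integer(1), "emotion"),
         train_error = model$train_error,
         test_error = mean(test_mse),
         eri = emotion_recognition_index(
           test_pbs, vapply(test_seqs, `[[`, integer(1), "emotion"),
           model$train_pbs, model$emotions),
         model = model)
  })
  structure(list(folds = results, condition = condition,
                 train_error = mean(vapply(results, `[[`, numeric(1),
                                           "train_error")),
                 test_error = mean(vapply(results, `[[`, numeric(1),
                                          "test_error")),
                 eri = mean(vapply(results, `[[`, numeric(1), "eri")),
                 n_folds = n_folds, seed = seed),
            class = "sctrnnpb_cv")
}

#' @export
print.sctrnnpb_cv <- function(x, ...) {
  cat("S-CTRNNPB ", x$n_folds, "-fold cross-validation (",
      format(x$condition), ")\n", sep = "")
  cat(sprintf("  train MSE %.5f   test MSE %.5f   emotion recognition index %.3f\n",
              x$train_error, x$test_error, x$eri))
  invisible(x)
}
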