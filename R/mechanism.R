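#' Closed-loop tolerance of one PB point
#'
#' How many training sequences can a single PB value reproduce?  For each
#' training target, one closed-loop trajectory is generated from the given
#' PB with the target's first frame as initial input, and the target counts
#' as reproduced when the trajectory's mean squared error against it falls
#' below `threshold`.  High counts mean the PB region generalizes across
#' sequences (a tolerant PB space); counts near 1 mean each PB is overfitted
#' to a single sequence.
#'
#' @param model A fitted `"sctrnnpb"`.
#' @param pb_activity PB activity vector (tanh scale, entries in (-1, 1));
#'   mapped to internal state by inverse tanh.
#' @param sequences Training sequences to score against (default the
#'   model's own).
#' @param threshold MSE threshold for "well predicted" (default 0.005;
#'   0.01 is the other conventional choice).
#' @return Integer count in `0:length(sequences)`.
#' @export
tolerance_count <- function(model, pb_activity, sequences = model$sequences,
                            threshold = 0.005) {
  stop_if_not(threshold > 0, "threshold must be positive")
  q <- atanh(pmin(pmax(pb_activity, -1 + 1e-12), 1 - 1e-12))
  mse <- vapply(sequences, function(sq) {
    run_sequence(model$params, model$config, sq, q, "closed_loop")$mse
  }, numeric(1))
  sum(mse < threshold)
}

#' Tolerance map over all training PB points
#'
#' Applies [tolerance_count()] at every training PB activity; the average
#' count is the per-network summary of PB-space tolerance.
#'
#' @inheritParams tolerance_count
#' @param pb_points Matrix of PB activities to probe (default the model's
#'   training PBs).
#' @return An object of class `"tolerance_map"`: `pb_points`, `counts`,
#'   `threshold`, `average_count`.
#' @export
tolerance_map <- function(model, pb_points = model$train_pbs,
                          sequences = model$sequences, threshold = 0.005) {
  counts <- vapply(seq_len(nrow(pb_points)), function(i)
    tolerance_count(model, pb_points[i, ], sequences, threshold), integer(1))
  structure(list(pb_points = pb_points, counts = counts,
                 threshold = threshold, average_count = mean(counts)),
            class = "tolerance_map")
}

#' @export
print.tolerance_map <- function(x, ...) {
  cat(sprintf("tolerance map: %d PB points, threshold %g, average count %.2f\n",
              nrow(x$pb_points), x$threshold, x$average_count))
  invisible(x)
}

#' @export
plot.tolerance_map <- function(x, ...) {
  cols <- hcl.colors(max(x$counts) + 1, "Viridis")[x$counts + 1]
  plot(x$pb_points[, 1], x$pb_points[, 2], col = cols, pch = 19,
       xlab = "PB 1 activity", ylab = "PB 2 activity",
       xlim = c(-1, 1), ylim = c(-1, 1),
       main = sprintf("sequences reproduced per PB (MSE < %g)",
                      x$threshold), ...)
  invisible(x)
}

#' Prediction error of sensory-input-driven generation
#'
#' Runs open-loop prediction with uninformative PBs: for each sequence and
#' each of `n_random_pb` PB activities drawn uniformly on (-1, 1) per
#' dimension, the open-loop MSE is computed; the grand mean is returned.
#' Networks that rely on bottom-up sensory input predict well even with a
#' meaningless PB; top-down-dependent networks do not.
#'
#' @param model A fitted `"sctrnnpb"`.
#' @param sequences Sequences to predict (default the model's training set).
#' @param n_random_pb Number of random PB draws per sequence.
#' @param seed Optional integer seed for the PB draws.
#' @return Grand-mean open-loop MSE.
#' @export
sensory_driven_error <- function(model, sequences = model$sequences,
                                 n_random_pb = 10L, seed = NULL) {
  stop_if_not(n_random_pb >= 1, "n_random_pb must be >= 1")
  with_seed(seed, {
    pbs <- matrix(runif(n_random_pb * model$config$n_pb, -1, 1),
                  n_random_pb, model$config$n_pb)
    q <- atanh(pbs)
    mse <- vapply(sequences, function(sq)
      vapply(seq_len(n_random_pb), function(i)
        run_sequence(model$params, model$config, sq, q[i, ],
                     "open_loop")$mse, numeric(1)),
      numeric(n_random_pb))
    mean(mse)
  })
}

#' Prediction error of top-down-only generation
#'
#' For each sequence, first infer its PB with the trained structure frozen
#' ([infer_pb()]), then generate the sequence closed-loop from that PB and
#' score the mean squared error against the target; the mean over sequences
#' is returned.  Networks that carry sequence information top-down through
#' the PB generate well; sensory-dependent networks do not.
#'
#' @param model A fitted `"sctrnnpb"`.
#' @param sequences Sequences to generate (default the model's training set).
#' @param hyper Optimization settings for the PB inference step.
#' @return Mean closed-loop MSE over sequences.
#' @export
top_down_error <- function(model, sequences = model$sequences,
                           hyper = model$hyper) {
  mse <- vapply(sequences, function(sq) {
    q <- infer_pb(model, sq, hyper)$pb_internal
    run_sequence(model$params, model$config, sq, q, "closed_loop")$mse
  }, numeric(1))
  mean(mse)
}
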