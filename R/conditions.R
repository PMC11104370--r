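#' One cell of the experimental condition grid
#'
#' A condition couples the two manipulated parameters: the inter-level
#' connection proportion (the model analogue of functional connectivity),
#' split into a higher-level proportion applied to the PB->lower block and a
#' lower-level proportion applied to the input->lower, lower->mean and
#' lower->variance blocks, and the lower-level threshold variance `K`
#' controlling neural-excitability homogeneity (K = 0.1, 1, 10 name the
#' highly homogeneous, modestly homogeneous and heterogeneous conditions).
#'
#' @param fc_high,fc_low Connection proportions in percent, normally from
#'   \{20, 40, 60, 80, 100\}.
#' @param K Threshold variance, > 0; normally from \{0.1, 1, 10\}.
#' @param condition_seed Integer seed tag carried with the condition.
#' @return An object of class `"condition_spec"`.
#' @export
condition_spec <- function(fc_high = 100, fc_low = 100, K = 10,
                           condition_seed = 1L) {
  stop_if_not(fc_high > 0 && fc_high <= 100 && fc_low > 0 && fc_low <= 100,
              "connection proportions must be in (0, 100]")
  stop_if_not(K > 0, "threshold variance K must be positive")
  structure(list(fc_high = fc_high, fc_low = fc_low, K = K,
                 condition_seed = as.integer(condition_seed)),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("condition: fc_high = %g%%, fc_low = %g%%, K = %g (seed %d)\n",
              x$fc_high, x$fc_low, x$K, x$condition_seed))
  invisible(x)
}

#' @export
format.condition_spec <- function(x, ...)
  sprintf("fc%g-%g_K%g", x$fc_high, x$fc_low, x$K)

#' Binary inter-level connectivity mask
#'
#' Exactly `round(proportion/100 * rows * cols)` entries (ties rounded
#' upward) are set to one, chosen uniformly at random without replacement;
#' all other entries are zero.  The ones-count is exact, not probabilistic.
#'
#' @param rows,cols Mask dimensions.
#' @param proportion Connection proportion in percent, in (0, 100].
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @return A `rows` x `cols` binary matrix.
#' @examples
#' sum(build_fc_mask(30, 2, 20, seed = 1))  # exactly 12
#' @export
build_fc_mask <- function(rows, cols, proportion, seed = NULL) {
  stop_if_not(proportion > 0 && proportion <= 100,
              "proportion must be in (0, 100]")
  with_seed(seed, {
    n <- rows * cols
    k <- round_half_up(proportion / 100 * n)
    m <- matrix(0, rows, cols)
    m[sample.int(n, k)] <- 1
    m
  })
}

#' Lower-level activity thresholds
#'
#' Draws i.i.d. thresholds from a centred Gaussian with variance `K`.  The
#' draw is made once per network and fixed: thresholds are never updated by
#' learning, so `K` sets how heterogeneous the intrinsic excitability of the
#' lower level is for the whole developmental run.
#'
#' @param n_lower Number of lower-level neurons.
#' @param K Threshold variance (>= 0; `K = 0` gives the all-zero vector).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_lower`.
#' @export
init_thresholds <- function(n_lower, K, seed = NULL) {
  stop_if_not(K >= 0, "threshold variance K must be nonnegative")
  with_seed(seed, rnorm(n_lower, 0, sqrt(K)))
}

#' Cartesian grid of experimental conditions
#'
#' The default levels give the full 5 x 5 x 3 = 75-condition design.
#' Ordering is stable: `fc_high` varies slowest, then `fc_low`, then `K`.
#'
#' @param fc_levels Connection-proportion levels in percent.
#' @param K_levels Threshold-variance levels.
#' @return A list of [condition_spec()] objects with sequential
#'   `condition_seed` tags.
#' @examples
#' length(condition_grid())  # 75
#' @export
condition_grid <- function(fc_levels = c(20, 40, 60, 80, 100),
                           K_levels = c(0.1, 1, 10)) {
  stop_if_not(length(fc_levels) >= 1 && length(K_levels) >= 1,
              "level lists must be nonempty")
  grid <- list(); k <- 0L
  for (fh in fc_levels) for (fl in fc_levels) for (K in K_levels) {
    k <- k + 1L
    grid[[k]] <- condition_spec(fh, fl, K, condition_seed = k)
  }
  grid
}

#' Write a reproducibility manifest for a condition grid
#'
#' Records every condition and its seed tag as YAML so that any single grid
#' cell can be re-run independently.
#'
#' @param grid A list of [condition_spec()] objects.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_grid_manifest <- function(grid, path) {
  yaml::write_yaml(lapply(grid, unclass), path)
  invisible(path)
}
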