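#' Configuration for a full experiment run
#'
#' Bundles and validates every setting the sweep needs: the sequence
#' generator, the network architecture, the condition grid and replicate
#' seeds, the optimization settings, the mechanism-analysis settings, the
#' cohort generator, and the output directory.  All randomness in a run is
#' determined by the seeds recorded here.
#'
#' @param data Named list of [generate_sequence_set()] arguments.
#' @param model Named list of [network_config()] arguments (without
#'   `n_input`, which follows the data).
#' @param grid Named list: `fc_levels`, `K_levels`, `replicate_seeds`,
#'   `n_folds`.
#' @param training Named list of [training_hyper()] arguments.
#' @param mechanism Named list: `threshold`, `n_random_pb`.
#' @param cohort Named list of [generate_cohort()] arguments.
#' @param output_dir Directory for result tables and figures.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(data = list(), model = list(), grid = list(),
                              training = list(), mechanism = list(),
                              cohort = list(), output_dir = tempfile("run")) {
  data <- modifyList(list(E = 6L, S = 16L, D = 9L, T = 60L,
                          identity_sd = 0.1, noise_sd = 0.02, seed = 1L),
                     data)
  model <- modifyList(list(n_pb = 2L, n_lower = 30L, tau_lower = 2,
                           variance_floor = 1e-6, u_var_cap = 10), model)
  grid <- modifyList(list(fc_levels = c(20, 40, 60, 80, 100),
                          K_levels = c(0.1, 1, 10),
                          replicate_seeds = 1:5, n_folds = 8L), grid)
  training <- modifyList(list(epochs_train = 3000L, epochs_test = 2000L,
                              learning_rate = 1e-3, beta1 = 0.9,
                              beta2 = 0.999, pb_init = 0, global_seed = 1L),
                         training)
  mechanism <- modifyList(list(threshold = 0.005, n_random_pb = 10L),
                          mechanism)
  cohort <- modifyList(list(n = 849L, beta_reho = 0.3, beta_fc = 0,
                            beta_interaction = 0.4, symptom_slope = 0.5,
                            seed = 1L), cohort)
  # schema validation: constructors reject invalid settings up front
  do.call(network_config, c(list(n_input = data$D), model))
  do.call(training_hyper, training)
  stop_if_not(data$S %% grid$n_folds == 0,
              "identities must divide evenly into folds")
  stop_if_not(mechanism$threshold > 0 && mechanism$n_random_pb >= 1,
              "invalid mechanism settings")
  structure(list(data = data, model = model, grid = grid,
                 training = training, mechanism = mechanism,
                 cohort = cohort, output_dir = output_dir),
            class = "experiment_config")
}

#' Run one condition of the experiment
#'
#' Executes the full per-condition pipeline: generate the sequence set,
#' cross-validate the two-phase protocol, and run the mechanism analyses on
#' the first fold's trained network.  Returns one summary row.
#'
#' @param config An [experiment_config()].
#' @param condition A [condition_spec()].
#' @param replicate_seed Seed for this replicate (folds + initialization).
#' @return A one-row data.frame: `fc_high`, `fc_low`, `K`, `replicate_seed`,
#'   `train_error`, `test_error`, `eri`, `tolerance_avg`, `sensory_error`,
#'   `top_down_error`.
#' @export
run_condition <- function(config, condition, replicate_seed) {
  set <- do.call(generate_sequence_set, config$data)
  net_config <- do.call(network_config,
                        c(list(n_input = set$D), config$model))
  hyper <- do.call(training_hyper, config$training)
  cv <- tryCatch(
    cross_validate(set, condition, net_config, hyper,
                   n_folds = config$grid$n_folds, seed = replicate_seed),
    error = function(e)
      stop("condition ", format(condition), ", replicate ", replicate_seed,
           ": ", conditionMessage(e), call. = FALSE))
  model <- cv$folds[[1]]$model
  tol <- tolerance_map(model, threshold = config$mechanism$threshold)
  sens <- sensory_driven_error(model,
                               n_random_pb = config$mechanism$n_random_pb,
                               seed = replicate_seed)
  topdown <- top_down_error(model)
  data.frame(fc_high = condition$fc_high, fc_low = condition$fc_low,
             K = condition$K, replicate_seed = replicate_seed,
             train_error = cv$train_error, test_error = cv$test_error,
             eri = cv$eri, tolerance_avg = tol$average_count,
             sensory_error = sens, top_down_error = topdown)
}

#' Run the full experiment: condition sweep plus cohort mapping
#'
#' Sweeps the condition grid over the replicate seeds (resumable: rows
#' already present in `<output_dir>/conditions.csv` are skipped), aggregates
#' per-condition medians over replicates, then generates the synthetic
#' cohort, partitions it into the subgroup grid, attaches the per-condition
#' performance measures, and runs the association analyses.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per completed condition row.
#' @return A list: `conditions` (per-replicate rows), `condition_summary`
#'   (per-condition medians), `cohort` (with attached measures),
#'   `association` (logistic coefficient table),
#'   `performance_tests`, `symptom_correlations`, and `failed` (a
#'   data.frame of failed condition rows, if any).
#' @export
run_experiment <- function(config, progress = interactive()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- condition_grid(config$grid$fc_levels, config$grid$K_levels)
  write_grid_manifest(grid, file.path(config$output_dir, "grid.yaml"))
  store <- file.path(config$output_dir, "conditions.csv")
  done <- if (file.exists(store)) read.csv(store) else NULL
  key <- function(d) paste(d$fc_high, d$fc_low, d$K, d$replicate_seed,
                           sep = "|")
  failed <- list()
  for (cond in grid) for (rs in config$grid$replicate_seeds) {
    k <- paste(cond$fc_high, cond$fc_low, cond$K, rs, sep = "|")
    if (!is.null(done) && k %in% key(done)) next
    row <- tryCatch(run_condition(config, cond, rs), error = function(e) e)
    if (inherits(row, "error")) {
      failed[[length(failed) + 1]] <- data.frame(
        fc_high = cond$fc_high, fc_low = cond$fc_low, K = cond$K,
        replicate_seed = rs, message = conditionMessage(row))
      next
    }
    done <- rbind(done, row)
    write.csv(done, store, row.names = FALSE)
    if (progress)
      cat(sprintf("done %s seed %d: test %.4f eri %.3f\n", format(cond),
                  rs, row$test_error, row$eri))
  }
  # per-condition medians over replicates
  agg <- stats::aggregate(
    cbind(train_error, test_error, eri, tolerance_avg, sensory_error,
          top_down_error) ~ fc_high + fc_low + K,
    data = done, FUN = stats::median)
  write.csv(agg, file.path(config$output_dir, "condition_summary.csv"),
            row.names = FALSE)
  grDevices::pdf(file.path(config$output_dir, "condition_summary.pdf"),
                 width = 9, height = 4)
  op <- par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  lab <- paste0("fc", agg$fc_high, "-", agg$fc_low, " K", agg$K)
  barplot(agg$test_error, names.arg = lab, las = 2, cex.names = 0.6,
          ylab = "test MSE", main = "generalization error")
  barplot(agg$eri, names.arg = lab, las = 2, cex.names = 0.6,
          ylab = "emotion recognition index", main = "recognition")
  par(op)
  grDevices::dev.off()
  cohort <- do.call(generate_cohort, config$cohort)
  cohort <- partition_subjects(cohort, fc_levels = config$grid$fc_levels,
                               K_levels = rev(sort(config$grid$K_levels)))
  cohort <- attach_performance(cohort, agg)
  write.csv(cohort, file.path(config$output_dir, "cohort.csv"),
            row.names = FALSE)
  out <- list(conditions = done, condition_summary = agg, cohort = cohort,
              association = logistic_association(cohort),
              performance_tests = performance_diagnosis_tests(cohort),
              symptom_correlations = symptom_correlations(cohort),
              failed = if (length(failed)) do.call(rbind, failed) else NULL)
  if (!is.null(out$failed))
    warning(nrow(out$failed), " condition rows failed; see $failed")
  out
}
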