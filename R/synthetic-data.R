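#' Construct a single emotion-labelled target sequence
#'
#' @param values Numeric T x D matrix, entries in \[-0.9, 0.9\].  Row `t` is
#'   both the external input at step `t` and the prediction target for the
#'   prediction made at step `t - 1`.
#' @param emotion Integer emotion label.
#' @param identity Integer identity (subject) label.
#' @param sequence_id Integer id.
#' @return An object of class `"emotion_sequence"`.
#' @export
emotion_sequence <- function(values, emotion, identity, sequence_id = 1L) {
  values <- as.matrix(values)
  stop_if_not(nrow(values) >= 2 && ncol(values) >= 1,
              "sequence needs T >= 2 and D >= 1")
  stop_if_not(all(is.finite(values)) && max(abs(values)) <= 0.9,
              "sequence values must be finite and within [-0.9, 0.9]")
  structure(list(sequence_id = as.integer(sequence_id),
                 emotion = as.integer(emotion),
                 identity = as.integer(identity), values = values),
            class = "emotion_sequence")
}

# Deterministic per-emotion prototype: per-feature sinusoid plus linear ramp
# with emotion-specific frequency and feature-specific phase/amplitude.
# Depends only on (e, D, T), never on the RNG, so the zero-noise sequence IS
# the prototype.
emotion_prototype <- function(e, D, T) {
  tt <- (seq_len(T) - 1) / (T - 1)                   # [0, 1]
  freq <- 0.75 + 0.5 * e                             # cycles over the window
  d <- seq_len(D)
  amp <- 0.45 + 0.2 * sin(1.7 * e + 1.3 * d)         # in [0.25, 0.65]
  phase <- 2 * pi * (d - 1) / D + 0.7 * e
  ramp <- 0.25 * cos(1.1 * e + 0.9 * d)
  proto <- outer(tt, d, function(ti, di)
    amp[di] * sin(2 * pi * freq * ti + phase[di]) + ramp[di] * (ti - 0.5))
  proto
}

#' Generate an emotion-structured set of multivariate sequences
#'
#' Stands in for feature series extracted from facial-expression videos: one
#' sequence per (emotion, identity) pair.  Each emotion has a deterministic
#' smooth prototype trajectory (sinusoid plus ramp with emotion-specific
#' frequency, phase and amplitude per feature); each identity adds a smooth
#' low-frequency perturbation of scale `identity_sd`, and i.i.d. Gaussian
#' observation noise of scale `noise_sd` is added on top.  Values are clipped
#' to \[-0.9, 0.9\], inside the invertible region of the network's saturating
#' output nonlinearity.
#'
#' @param E Number of emotions (default 6).
#' @param S Number of identities (default 16).
#' @param D Number of features per step (default 9).
#' @param T Sequence length in steps (default 60).
#' @param identity_sd Scale of the identity-specific smooth perturbation.
#' @param noise_sd Scale of the i.i.d. observation noise.
#' @param seed Integer seed; the same seed reproduces the set bit-identically.
#' @return An object of class `"sequence_set"`: a list with `sequences`
#'   (E*S [emotion_sequence()] objects, emotion varying slowest), and the
#'   dimensions `E`, `S`, `D`, `T`.
#' @examples
#' set <- generate_sequence_set(E = 2, S = 2, D = 3, T = 20, seed = 1)
#' length(set$sequences)
#' @export
generate_sequence_set <- function(E = 6L, S = 16L, D = 9L, T = 60L,
                                  identity_sd = 0.1, noise_sd = 0.02,
                                  seed = 1L) {
  stop_if_not(E >= 1 && S >= 1 && D >= 1 && T >= 1,
              "E, S, D, T must all be positive")
  stop_if_not(identity_sd >= 0 && noise_sd >= 0,
              "identity_sd and noise_sd must be nonnegative")
  with_seed(seed, {
    sequences <- vector("list", E * S)
    k <- 0L
    for (e in seq_len(E)) {
      proto <- emotion_prototype(e, D, T)
      for (s in seq_len(S)) {
        k <- k + 1L
        tt <- (seq_len(T) - 1) / (T - 1)
        # smooth identity perturbation: one low-frequency sinusoid per feature
        c1 <- rnorm(D); c2 <- rnorm(D); psi <- runif(D, 0, 2 * pi)
        pert <- outer(tt, seq_len(D), function(ti, di)
          c1[di] * sin(2 * pi * ti + psi[di]) + c2[di] * (ti - 0.5))
        x <- proto + identity_sd * pert +
          noise_sd * matrix(rnorm(T * D), T, D)
        x <- pmin(pmax(x, -0.9), 0.9)
        sequences[[k]] <- emotion_sequence(x, e, s, k)
      }
    }
    structure(list(sequences = sequences, E = as.integer(E),
                   S = as.integer(S), D = as.integer(D), T = as.integer(T)),
              class = "sequence_set")
  })
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", x$E, "emotions x", x$S, "identities,",
      x$T, "steps x", x$D, "features\n")
  invisible(x)
}

#' Read and write sequence sets as tidy CSV
#'
#' Long format with columns `sequence_id`, `emotion`, `identity`, `t`, and
#' `feature_1` ... `feature_D`; one row per time step.
#'
#' @param set A `"sequence_set"`.
#' @param path CSV file path.
#' @return `write_sequences_csv()` returns `path` invisibly;
#'   `read_sequences_csv()` the reconstructed `"sequence_set"`.
#' @export
write_sequences_csv <- function(set, path) {
  rows <- lapply(set$sequences, function(sq) {
    d <- as.data.frame(sq$values)
    names(d) <- paste0("feature_", seq_len(ncol(d)))
    cbind(data.frame(sequence_id = sq$sequence_id, emotion = sq$emotion,
                     identity = sq$identity, t = seq_len(nrow(d))), d)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences_csv
#' @export
read_sequences_csv <- function(path) {
  d <- read.csv(path)
  feat <- grep("^feature_", names(d), value = TRUE)
  ids <- unique(d$sequence_id)
  sequences <- lapply(ids, function(i) {
    di <- d[d$sequence_id == i, , drop = FALSE]
    di <- di[order(di$t), , drop = FALSE]
    emotion_sequence(as.matrix(di[, feat, drop = FALSE]),
                     di$emotion[1], di$identity[1], i)
  })
  structure(list(sequences = sequences,
                 E = length(unique(d$emotion)),
                 S = length(unique(d$identity)),
                 D = length(feat),
                 T = max(d$t)),
            class = "sequence_set")
}

#' Generate a synthetic imaging cohort
#'
#' Emulates, at the parameter level, a resting-state fMRI cohort: per-subject
#' higher- and lower-level functional-connectivity values on correlation
#' scale, a positive right-skewed regional-homogeneity (ReHo) value, nuisance
#' covariates (age, sex, full-scale IQ, mean framewise displacement, site), a
#' binary diagnosis drawn from a logistic model with planted ReHo main effect
#' and ReHo-by-FC interaction, and ADI-R-style symptom scores for affected
#' subjects correlated with the diagnostic linear predictor.
#'
#' The logistic linear predictor is
#' `b0 + beta_reho * z(log reho) + beta_fc * z(fc) + beta_interaction *
#' z(log reho) * z(fc)` plus small covariate effects, where `z()` denotes
#' within-sample standardization and `fc` is the mean of the two standardized
#' connectivity values; `b0` is set so the marginal diagnosis rate is close
#' to 48% when all planted effects are zero.
#'
#' @param n Number of subjects (>= 30; default 849).
#' @param beta_reho Planted main effect of (standardized log) ReHo on the
#'   log-odds of diagnosis.
#' @param beta_fc Planted main effect of the combined FC value.
#' @param beta_interaction Planted ReHo-by-FC interaction.
#' @param symptom_slope Link between the diagnostic linear predictor and the
#'   symptom scores of affected subjects.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A `data.frame` with columns `subject_id`, `diagnosis` (1 = ASD,
#'   0 = TD), `fc_high`, `fc_low` (in (-1, 1)), `reho` (> 0), `age`, `sex`,
#'   `fiq`, `mean_fd`, `site`, and `adir_social`, `adir_communication`,
#'   `adir_rrb` (nonnegative integers, `NA` for unaffected subjects).
#' @examples
#' head(generate_cohort(n = 100, seed = 1))
#' @export
generate_cohort <- function(n = 849L, beta_reho = 0.3, beta_fc = 0,
                            beta_interaction = 0.4, symptom_slope = 0.5,
                            seed = 1L) {
  stop_if_not(n >= 30, "cohort size n must be >= 30")
  with_seed(seed, {
    # correlated FC pair on atanh scale, squashed back to correlation scale
    z1 <- rnorm(n); z2 <- 0.2 * z1 + sqrt(1 - 0.04) * rnorm(n)
    fc_high <- tanh(0.35 + 0.2 * z1)
    fc_low <- tanh(0.35 + 0.2 * z2)
    reho <- rlnorm(n, meanlog = 0, sdlog = 0.4)      # right-skewed, positive
    age <- 6 + rgamma(n, shape = 2, scale = 6)
    sex <- rbinom(n, 1, 0.85)
    fiq <- rnorm(n, 105, 15)
    mean_fd <- rlnorm(n, log(0.1), 0.5)
    site <- factor(sample(paste0("site_", sprintf("%02d", 1:10)), n,
                          replace = TRUE))
    z <- function(x) (x - mean(x)) / sd(x)
    z_reho <- z(log(reho))
    z_fc <- z((z(atanh(fc_high)) + z(atanh(fc_low))) / 2)
    b0 <- qlogis(0.48)
    eta <- b0 + beta_reho * z_reho + beta_fc * z_fc +
      beta_interaction * z_reho * z_fc +
      0.05 * z(age) + 0.1 * (sex - mean(sex)) - 0.05 * z(fiq) +
      0.05 * z(log(mean_fd))
    diagnosis <- rbinom(n, 1, plogis(eta))
    # ADI-R-style scores only for affected rows, tied to eta by symptom_slope
    score <- function(base, spread) {
      s <- rep(NA_integer_, n)
      idx <- diagnosis == 1
      raw <- base + symptom_slope * spread * eta[idx] +
        rnorm(sum(idx), 0, spread)
      s[idx] <- pmax(0L, as.integer(round_half_up(raw)))
      s
    }
    data.frame(subject_id = seq_len(n), diagnosis = diagnosis,
               fc_high = fc_high, fc_low = fc_low, reho = reho,
               age = age, sex = sex, fiq = fiq, mean_fd = mean_fd,
               site = site,
               adir_social = score(20, 4),
               adir_communication = score(16, 3.5),
               adir_rrb = score(6, 2))
  })
}
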