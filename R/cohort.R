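#' Fisher r-to-z transform
#'
#' Maps a correlation-scale value in (-1, 1) to the real line by
#' `z = atanh(r)`, normalizing the sampling distribution of correlations.
#'
#' @param r Numeric vector with entries strictly inside (-1, 1).
#' @return `atanh(r)`.
#' @export
fisher_rz <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}

#' Box-Cox power transform with profile-likelihood lambda
#'
#' Chooses lambda on the fixed grid -3 to 3 (step 0.01) by maximizing the
#' Gaussian profile log-likelihood of the transformed sample, then applies
#' `(x^lambda - 1) / lambda` (natural log at lambda = 0).
#'
#' @param x Positive numeric vector (apply a shift upstream if needed).
#' @return A list: `transformed` vector and the selected `lambda`.
#' @examples
#' box_cox(rlnorm(200))$lambda  # near 0 for lognormal input
#' @export
box_cox <- function(x) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values",
                        call. = FALSE)
  n <- length(x)
  lx <- log(x)
  grid <- seq(-3, 3, by = 0.01)
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) lx else (x^l - 1) / l
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(lx)
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  y <- if (abs(lambda) < 1e-12) lx else (x^lambda - 1) / lambda
  list(transformed = y, lambda = lambda)
}

#' Residualize values on nuisance covariates
#'
#' Ordinary least-squares adjustment: returns the residuals of `values`
#' regressed on age, sex, FIQ, mean framewise displacement and dummy-coded
#' site (with intercept), removing nuisance structure before ranking
#' subjects.
#'
#' @param values Numeric vector.
#' @param covariates A data.frame with columns `age`, `sex`, `fiq`,
#'   `mean_fd`, `site` (any factor columns are dummy-coded).
#' @return Residual vector (mean zero).
#' @export
adjust_covariates <- function(values, covariates) {
  stop_if_not(length(values) == nrow(covariates),
              "values and covariates must have the same rows")
  mm <- model.matrix(~ age + sex + fiq + mean_fd + site, data = covariates)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.numeric(qr.resid(qr_mm, values))
}

# contiguous near-equal groups of ranks 1..k over n subjects, ties broken
# by stable subject order
rank_groups <- function(x, k) {
  n <- length(x)
  ord <- order(x)                        # stable: ties keep original order
  bounds <- round_half_up(n * seq_len(k) / k)
  g <- integer(n)
  lo <- 1L
  for (j in seq_len(k)) {
    g[ord[lo:bounds[j]]] <- j
    lo <- bounds[j] + 1L
  }
  g
}

#' Partition a cohort into the 5 x 5 x 3 subgroup grid
#'
#' Subjects are ranked on their adjusted higher-level FC (quintiles),
#' adjusted lower-level FC (quintiles), and adjusted ReHo (tertiles), and
#' each rank triple indexes an experimental condition: FC rank 1 maps to a
#' 20% connection proportion and rank 5 to 100%; ReHo rank 1 (lowest local
#' homogeneity) maps to the heterogeneous network (K = 10) and rank 3 to the
#' highly homogeneous network (K = 0.1), following the reading of ReHo as
#' local synchronization and hence excitability homogeneity.
#'
#' @param cohort A cohort data.frame (see [generate_cohort()]) carrying
#'   adjusted columns `fc_high_adj`, `fc_low_adj`, `reho_adj`; if absent,
#'   they are computed via [fisher_rz()]/[box_cox()] + [adjust_covariates()].
#' @param fc_levels Connection-proportion levels, lowest FC rank first
#'   (their count sets the number of FC groups).
#' @param K_levels Threshold-variance levels, lowest ReHo rank first, i.e.
#'   heterogeneous first (their count sets the number of ReHo groups).
#' @return The cohort with added columns `fc_high_rank`, `fc_low_rank`,
#'   `reho_rank`, and the mapped condition levels `cond_fc_high`,
#'   `cond_fc_low`, `cond_K`.
#' @export
partition_subjects <- function(cohort, fc_levels = c(20, 40, 60, 80, 100),
                               K_levels = c(10, 1, 0.1)) {
  if (nrow(cohort) < length(fc_levels)^2 * length(K_levels))
    warning("fewer subjects than subgroups; some subgroups will be empty")
  if (is.null(cohort$fc_high_adj)) {
    cov <- cohort[, c("age", "sex", "fiq", "mean_fd", "site")]
    cohort$fc_high_adj <- adjust_covariates(fisher_rz(cohort$fc_high), cov)
    cohort$fc_low_adj <- adjust_covariates(fisher_rz(cohort$fc_low), cov)
    cohort$reho_adj <- adjust_covariates(box_cox(cohort$reho)$transformed,
                                         cov)
  }
  cohort$fc_high_rank <- rank_groups(cohort$fc_high_adj, length(fc_levels))
  cohort$fc_low_rank <- rank_groups(cohort$fc_low_adj, length(fc_levels))
  cohort$reho_rank <- rank_groups(cohort$reho_adj, length(K_levels))
  cohort$cond_fc_high <- fc_levels[cohort$fc_high_rank]
  cohort$cond_fc_low <- fc_levels[cohort$fc_low_rank]
  cohort$cond_K <- K_levels[cohort$reho_rank]
  cohort
}

#' Attach per-condition performance measures to subjects
#'
#' Joins a condition-level results table onto a partitioned cohort so every
#' subject carries the test error and emotion recognition index of the
#' network condition its subgroup maps to.
#'
#' @param assignments A partitioned cohort (see [partition_subjects()]).
#' @param condition_results A data.frame with columns `fc_high`, `fc_low`,
#'   `K`, `test_error`, `eri` (one row per condition).
#' @return `assignments` with columns `test_error` and `eri` added.
#' @export
attach_performance <- function(assignments, condition_results) {
  key <- function(fh, fl, K) paste(fh, fl, K, sep = "|")
  res_key <- key(condition_results$fc_high, condition_results$fc_low,
                 condition_results$K)
  subj_key <- key(assignments$cond_fc_high, assignments$cond_fc_low,
                  assignments$cond_K)
  missing <- setdiff(unique(subj_key), res_key)
  if (length(missing) > 0)
    stop("no condition results for: ", paste(missing, collapse = "; "),
         call. = FALSE)
  idx <- match(subj_key, res_key)
  assignments$test_error <- condition_results$test_error[idx]
  assignments$eri <- condition_results$eri[idx]
  assignments
}

#' Logistic main-effect and interaction analysis of diagnosis
#'
#' Fits, by maximum likelihood, `diagnosis ~ z(reho_adj) + z(fc_adj) +
#' z(reho_adj):z(fc_adj)`, where `fc_adj` is the mean of the two
#' standardized adjusted FC values (a single combined FC term) and `z()`
#' standardizes.  Wald statistics are reported per coefficient.
#'
#' @param cohort A cohort carrying `diagnosis`, `reho_adj`, `fc_high_adj`,
#'   `fc_low_adj` (run [partition_subjects()] first if needed).
#' @param separate_fc Use both FC terms separately instead of the combined
#'   mean (then two main effects and two interactions are reported).
#' @return A data.frame with `term`, `estimate`, `std_error`, `z_value`,
#'   `p_value`.
#' @export
logistic_association <- function(cohort, separate_fc = FALSE) {
  stop_if_not(!is.null(cohort$diagnosis), "binary diagnosis required")
  z <- function(x) (x - mean(x)) / sd(x)
  zr <- z(cohort$reho_adj)
  if (separate_fc) {
    zh <- z(cohort$fc_high_adj); zl <- z(cohort$fc_low_adj)
    fit <- glm(cohort$diagnosis ~ zr * zh + zr * zl, family = binomial())
  } else {
    zf <- z((z(cohort$fc_high_adj) + z(cohort$fc_low_adj)) / 2)
    fit <- glm(cohort$diagnosis ~ zr * zf, family = binomial())
  }
  if (!fit$converged || any(abs(coef(fit)) > 15))
    stop("logistic fit did not converge (possible separation); ",
         "consider a penalized fit", call. = FALSE)
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
             z_value = s[, 3], p_value = s[, 4], row.names = NULL)
}

#' Association of attached performance measures with diagnosis
#'
#' Three tests mirroring the group-level analyses: (i) logistic regression
#' of diagnosis on the standardized attached test error; (ii) the same on
#' the standardized attached emotion recognition index; (iii) subjects are
#' clustered into three groups in the (test error, recognition index) plane
#' (k-means, 3 centres, fixed seed) and diagnosis-by-group is tested by
#' chi-square.
#'
#' @param cohort A cohort with attached `test_error` and `eri`
#'   (see [attach_performance()]).
#' @param seed Seed for the 3-centre clustering.
#' @return A list: `test_error` and `eri` (each a one-row data.frame with
#'   `estimate` and `p_value` for the standardized slope), `group_test`
#'   (`statistic`, `df`, `p_value`), `group` (the per-subject cluster
#'   label, ordered so group 1 has the lowest mean test error).
#' @export
performance_diagnosis_tests <- function(cohort, seed = 1L) {
  for (m in c("test_error", "eri"))
    if (sd(cohort[[m]]) == 0)
      stop("attached measure '", m, "' is constant", call. = FALSE)
  z <- function(x) (x - mean(x)) / sd(x)
  slope <- function(x) {
    s <- summary(glm(cohort$diagnosis ~ z(x),
                     family = binomial()))$coefficients
    data.frame(estimate = s[2, 1], std_error = s[2, 2], p_value = s[2, 4])
  }
  xy <- cbind(z(cohort$test_error), z(cohort$eri))
  km <- with_seed(seed, kmeans(xy, centers = 3, nstart = 10))
  # relabel clusters by increasing mean test error for stable reporting
  ord <- order(tapply(cohort$test_error, km$cluster, mean))
  group <- match(km$cluster, ord)
  ct <- chisq.test(table(cohort$diagnosis, group))
  list(test_error = slope(cohort$test_error),
       eri = slope(cohort$eri),
       group_test = data.frame(statistic = unname(ct$statistic),
                               df = unname(ct$parameter),
                               p_value = ct$p.value),
       group = group)
}

#' Spearman correlations between performance measures and symptom scores
#'
#' For affected (diagnosed) subjects only, computes Spearman's rho between
#' each ADI-R-style scale and each attached performance measure, with 95%
#' confidence intervals via the Fisher transform of rho
#' (`SE = 1/sqrt(n - 3)`).
#'
#' @param cohort A cohort with attached measures and symptom columns
#'   `adir_social`, `adir_communication`, `adir_rrb`.
#' @param measures Names of the measure columns (default
#'   `c("test_error", "eri")`).
#' @return A data.frame with `scale`, `measure`, `n`, `rho`, `ci_lower`,
#'   `ci_upper`.
#' @export
symptom_correlations <- function(cohort,
                                 measures = c("test_error", "eri")) {
  asd <- cohort[cohort$diagnosis == 1, , drop = FALSE]
  scales <- c("adir_social", "adir_communication", "adir_rrb")
  out <- list()
  for (sc in scales) for (m in measures) {
    ok <- complete.cases(asd[[sc]], asd[[m]])
    n <- sum(ok)
    stop_if_not(n >= 10, paste("need >= 10 affected rows with", sc))
    if (sd(asd[[sc]][ok]) == 0)
      stop("constant score vector for ", sc, call. = FALSE)
    rho <- cor(asd[[sc]][ok], asd[[m]][ok], method = "spearman")
    zr <- atanh(rho); se <- 1 / sqrt(n - 3)
    out[[length(out) + 1]] <- data.frame(
      scale = sc, measure = m, n = n, rho = rho,
      ci_lower = tanh(zr - qnorm(0.975) * se),
      ci_upper = tanh(zr + qnorm(0.975) * se))
  }
  do.call(rbind, out)
}
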