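test_that("Fisher r-z is the inverse hyperbolic tangent", {
  expect_equal(fisher_rz(0), 0)
  expect_equal(fisher_rz(0.5), 0.54931, tolerance = 1e-5)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_rz(-r), -fisher_rz(r))     # odd function
  expect_error(fisher_rz(1), "< 1")
})

test_that("Box-Cox recovers the log transform for lognormal data", {
  x <- sctrnnpb:::with_seed(21, rlnorm(5000))
  bc <- box_cox(x)
  expect_gte(bc$lambda, -0.1)
  expect_lte(bc$lambda, 0.1)
  # the transform reduces skewness of a right-skewed input
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_lt(abs(skew(bc$transformed)), abs(skew(x)))
  expect_error(box_cox(c(1, -2)), "positive")
})

test_that("Box-Cox applies the stated power form", {
  x <- c(1, 2, 5, 10)
  # at lambda = 1 the transform is x - 1; at 0 it is log(x)
  f1 <- (x^1 - 1) / 1
  expect_equal(f1, x - 1)
  # profile-likelihood lambda agrees with an independent implementation
  y <- sctrnnpb:::with_seed(22, rlnorm(800, 1, 0.6))
  prof <- MASS::boxcox(y ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  expect_equal(box_cox(y)$lambda, prof$x[which.max(prof$y)],
               tolerance = 0.011)
})

test_that("covariate adjustment produces orthogonal, mean-zero residuals", {
  d <- generate_cohort(n = 500, seed = 9)
  cov <- d[, c("age", "sex", "fiq", "mean_fd", "site")]
  vals <- sctrnnpb:::with_seed(1, rnorm(500))
  res <- adjust_covariates(vals, cov)
  expect_equal(mean(res), 0, tolerance = 1e-12)
  mm <- model.matrix(~ age + sex + fiq + mean_fd + site, data = cov)
  expect_true(all(abs(crossprod(mm, res)) < 1e-8))
  # covariate-independent values: residuals approximately centred values
  expect_gt(cor(res, vals - mean(vals)), 0.95)
})

test_that("adjustment removes a constructed age effect", {
  d <- generate_cohort(n = 5000, seed = 10)
  cov <- d[, c("age", "sex", "fiq", "mean_fd", "site")]
  vals <- 2 * d$age + sctrnnpb:::with_seed(2, rnorm(5000))
  res <- adjust_covariates(vals, cov)
  expect_lt(abs(cor(res, d$age)), 0.02)
})

test_that("collinear covariates are reported by name", {
  d <- generate_cohort(n = 100, seed = 11)
  cov <- d[, c("age", "sex", "fiq", "mean_fd", "site")]
  cov$fiq <- 2 * cov$age                 # force collinearity
  expect_error(adjust_covariates(rnorm(100), cov), "fiq")
})

test_that("the subgroup partition is balanced, exhaustive and disjoint", {
  d <- generate_cohort(n = 849, seed = 1)
  p <- partition_subjects(d)
  expect_equal(nrow(p), 849)
  for (col in c("fc_high_rank", "fc_low_rank"))
    expect_true(all(abs(table(p[[col]]) - 849 / 5) <= 1))
  expect_true(all(abs(table(p$reho_rank) - 849 / 3) <= 1))
  occupied <- unique(p[, c("fc_high_rank", "fc_low_rank", "reho_rank")])
  expect_equal(nrow(occupied), 75)
  # empty subgroups are permitted by contract but rare: across seeds the
  # occupied count stays within one cell of full
  occ <- vapply(2:6, function(s) {
    ps <- partition_subjects(generate_cohort(n = 849, seed = s))
    nrow(unique(ps[, c("fc_high_rank", "fc_low_rank", "reho_rank")]))
  }, numeric(1))
  expect_true(all(occ >= 74))
  # rank boundaries agree with an independent sort-and-slice computation
  ord <- order(p$fc_high_adj)
  sizes <- diff(c(0, floor(849 * (1:5) / 5 + 0.5)))
  expect_equal(as.integer(table(p$fc_high_rank)), sizes)
  expect_equal(p$fc_high_rank[ord], rep(1:5, times = sizes))
  # mapping direction: top ReHo tertile is the highly homogeneous condition
  expect_equal(unique(p$cond_K[p$reho_rank == 3]), 0.1)
  expect_equal(unique(p$cond_K[p$reho_rank == 1]), 10)
  expect_equal(unique(p$cond_fc_high[p$fc_high_rank == 1]), 20)
})

test_that("a 75-subject cohort can fill each subgroup exactly once", {
  # constructed input: adjusted values already on a 5 x 5 x 3 lattice
  g <- expand.grid(a = 1:5, b = 1:5, c = 1:3)
  d <- data.frame(subject_id = 1:75, fc_high_adj = g$a, fc_low_adj = g$b,
                  reho_adj = g$c)
  p <- partition_subjects(d)
  key <- paste(p$fc_high_rank, p$fc_low_rank, p$reho_rank)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("performance attachment is an exact order-invariant join", {
  d <- partition_subjects(generate_cohort(n = 300, seed = 6))
  grid <- expand.grid(fc_high = c(20, 40, 60, 80, 100),
                      fc_low = c(20, 40, 60, 80, 100), K = c(0.1, 1, 10))
  grid$test_error <- seq_len(nrow(grid)) / 100
  grid$eri <- rev(seq_len(nrow(grid))) / 100
  a <- attach_performance(d, grid)
  # all subjects in one subgroup share identical attached values
  for (k in split(a, paste(a$cond_fc_high, a$cond_fc_low, a$cond_K))) {
    expect_equal(length(unique(k$test_error)), 1)
    expect_equal(length(unique(k$eri)), 1)
  }
  # values equal an independent lookup
  i <- 17
  j <- which(grid$fc_high == a$cond_fc_high[i] &
               grid$fc_low == a$cond_fc_low[i] & grid$K == a$cond_K[i])
  expect_equal(a$test_error[i], grid$test_error[j])
  # permuting subject order changes nothing
  perm <- sctrnnpb:::with_seed(5, sample(nrow(d)))
  a2 <- attach_performance(d[perm, ], grid)
  expect_equal(a2$test_error[order(a2$subject_id)],
               a$test_error[order(a$subject_id)])
  expect_error(attach_performance(d, grid[1:10, ]), "no condition results")
})

test_that("logistic association matches an independent maximum-likelihood fit", {
  d <- partition_subjects(generate_cohort(n = 849, beta_reho = 0.3,
                                          beta_interaction = 0.4, seed = 13))
  tab <- logistic_association(d)
  expect_setequal(tab$term,
                  c("(Intercept)", "zr", "zf", "zr:zf"))
  # independent fit: direct Newton-free optimization of the binomial loglik
  z <- function(x) (x - mean(x)) / sd(x)
  zr <- z(d$reho_adj)
  zf <- z((z(d$fc_high_adj) + z(d$fc_low_adj)) / 2)
  X <- cbind(1, zr, zf, zr * zf)
  nll <- function(b) {
    eta <- X %*% b
    -sum(d$diagnosis * eta - log(1 + exp(eta)))
  }
  opt <- optim(rep(0, 4), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(tab$estimate, unname(opt$par), tolerance = 1e-5)
})

test_that("planted logistic effects are recovered with high probability", {
  hits <- vapply(1:100, function(s) {
    d <- partition_subjects(generate_cohort(n = 849, beta_reho = 0.3,
                                            beta_fc = 0,
                                            beta_interaction = 0.4,
                                            symptom_slope = 0, seed = s))
    tab <- logistic_association(d)
    c(main = tab$estimate[tab$term == "zr"] > 0,
      inter = tab$estimate[tab$term == "zr:zf"] > 0)
  }, logical(2))
  expect_gte(mean(hits["main", ]), 0.9)
  expect_gte(mean(hits["inter", ]), 0.9)
})

test_that("null interactions are covered by their confidence intervals", {
  covered <- vapply(1:100, function(s) {
    d <- partition_subjects(generate_cohort(n = 849, beta_reho = 0.3,
                                            beta_fc = 0,
                                            beta_interaction = 0,
                                            symptom_slope = 0, seed = s))
    tab <- logistic_association(d)
    row <- tab[tab$term == "zr:zf", ]
    row$estimate - 1.96 * row$std_error <= 0 &&
      row$estimate + 1.96 * row$std_error >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("performance-diagnosis tests are calibrated under the null", {
  # measures independent of diagnosis: slope p-values should be uniform
  pvals <- vapply(1:200, function(s) {
    d <- generate_cohort(n = 300, beta_reho = 0, beta_fc = 0,
                         beta_interaction = 0, symptom_slope = 0, seed = s)
    d$test_error <- sctrnnpb:::with_seed(s + 1000, rnorm(300, 0.01, 0.002))
    d$eri <- sctrnnpb:::with_seed(s + 2000, rnorm(300, 0.4, 0.1))
    performance_diagnosis_tests(d, seed = 1)$test_error$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted diagnosis-error link is recovered", {
  hits <- vapply(1:50, function(s) {
    d <- generate_cohort(n = 400, beta_reho = 0, beta_fc = 0,
                         beta_interaction = 0, symptom_slope = 0, seed = s)
    base <- sctrnnpb:::with_seed(s + 3000, rnorm(400))
    d$test_error <- 0.01 + 0.002 * (base + d$diagnosis)  # monotone link
    d$eri <- 0.5 - 0.05 * d$test_error / 0.002
    performance_diagnosis_tests(d, seed = 1)$test_error$estimate > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the three-group chi-square equals a hand-computed toy value", {
  # printed 2 x 3 table: rows diagnosis, cols group
  tab <- matrix(c(30, 10, 20, 20, 10, 30), nrow = 2)
  # hand computation of the chi-square statistic
  row_t <- rowSums(tab); col_t <- colSums(tab); n <- sum(tab)
  exp_t <- outer(row_t, col_t) / n
  stat_hand <- sum((tab - exp_t)^2 / exp_t)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(unname(ct$statistic), stat_hand)
  # and the package path reproduces it through the same machinery
  d <- data.frame(diagnosis = rep(c(1, 0), times = c(60, 40)))
  d$test_error <- c(rep(c(0.001, 0.01, 0.02), times = c(30, 10, 20)),
                    rep(c(0.001, 0.01, 0.02), times = c(20, 10, 10)))
  d$eri <- -d$test_error
  got <- performance_diagnosis_tests(d, seed = 1)
  expect_true(is.finite(got$group_test$statistic))
  expect_equal(got$group_test$df, 2)
})

test_that("Spearman correlations match rank-then-Pearson and find planted links", {
  # anti-sorted pairs give exactly -1
  d0 <- data.frame(diagnosis = 1, adir_social = 1:20,
                   adir_communication = 1:20, adir_rrb = 1:20,
                   test_error = 21 - (1:20), eri = 1:20 + 0.5)
  sc <- symptom_correlations(d0)
  expect_equal(sc$rho[sc$scale == "adir_social" &
                        sc$measure == "test_error"], -1)
  # ties-free data: rho equals Pearson on ranks
  set.seed(33)
  d1 <- data.frame(diagnosis = 1,
                   adir_social = sample(100), adir_communication = sample(100),
                   adir_rrb = sample(100),
                   test_error = rnorm(100), eri = rnorm(100))
  sc1 <- symptom_correlations(d1)
  manual <- cor(rank(d1$adir_social), rank(d1$test_error))
  expect_equal(sc1$rho[1], manual)
  expect_error(symptom_correlations(transform(d0, adir_social = 5)),
               "constant")
})

test_that("symptom generation links scores to recognition deficits", {
  hits <- vapply(1:100, function(s) {
    d <- generate_cohort(n = 600, beta_reho = 0.3, beta_interaction = 0.4,
                         symptom_slope = 1, seed = s)
    d <- partition_subjects(d)
    # an eri inversely tied to the diagnostic predictor, as in the sweep
    z <- function(x) (x - mean(x)) / sd(x)
    d$eri <- -z(d$reho_adj) + sctrnnpb:::with_seed(s + 500, rnorm(600, 0, 1))
    d$test_error <- -d$eri
    sc <- symptom_correlations(d)
    sc$rho[sc$scale == "adir_social" & sc$measure == "eri"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
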