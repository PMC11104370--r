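test_that("forward_step matches hand-evaluated leaky integration", {
  cfg <- network_config(n_input = 1, n_pb = 1, n_lower = 1, tau_lower = 2)
  p <- zero_params(cfg)
  p$W_xl[1, 1] <- 1
  st <- forward_step(p, cfg, initial_state(cfg), x_t = 0.5, pb_internal = 0)
  expect_equal(st$u_lower, 0.25)          # (1/2) * (1 * 0.5)
  expect_equal(st$l, tanh(0.25))
  expect_equal(unname(st$l), 0.2449, tolerance = 1e-4)
})

test_that("zero-parameter network stays at zero", {
  cfg <- tiny_config()
  p <- zero_params(cfg)
  st <- forward_step(p, cfg, initial_state(cfg), x_t = c(0.5, -0.2, 0.1),
                     pb_internal = c(1, -1))
  expect_equal(st$u_lower, rep(0, cfg$n_lower))
  expect_equal(st$l, rep(0, cfg$n_lower))
  expect_equal(st$y, rep(0, cfg$n_input))
})

test_that("a huge time constant freezes the lower-level state", {
  cfg <- network_config(n_input = 2, n_pb = 2, n_lower = 4, tau_lower = 1e9)
  p <- tiny_params(network_config(n_input = 2, n_pb = 2, n_lower = 4,
                                  tau_lower = 1e9))
  prev <- list(u_lower = c(0.3, -0.5, 0.1, 0.9), l = tanh(c(0.3, -0.5, 0.1, 0.9)))
  st <- forward_step(p, cfg, prev, x_t = c(0.7, -0.7), pb_internal = c(1, 2))
  expect_equal(st$u_lower, prev$u_lower, tolerance = 1e-7)
})

test_that("forward_step rejects non-finite input with a clear error", {
  cfg <- tiny_config()
  p <- tiny_params(cfg)
  expect_error(forward_step(p, cfg, initial_state(cfg),
                            x_t = c(NaN, 0, 0), pb_internal = c(0, 0)),
               "non-finite")
})

test_that("output activations have the declared closed forms and ranges", {
  out <- output_activation(0, 0, variance_floor = 1e-6)
  expect_equal(out$y, 0)
  expect_equal(out$v, 1 + 1e-6)
  expect_equal(output_activation(0, log(2))$v, 2 + 1e-6)
  u <- c(-15, -3, 0, 3, 15)
  y <- output_activation(u, u)$y
  expect_true(all(y > -1 & y < 1))
  expect_true(all(abs(output_activation(c(-1e6, 1e6), c(0, 0))$y) <= 1))
  # overflow guarded by the cap
  expect_true(is.finite(output_activation(0, 1e4)$v))
})

test_that("the Gaussian loss matches its closed forms and decomposes", {
  expect_equal(sequence_nll(0, 1, 0)$total, log(2 * pi) / 2)
  expect_equal(sequence_nll(0, 1, 0)$total, 0.91894, tolerance = 1e-5)
  expect_equal(sequence_nll(0, 1, 1)$total, log(2 * pi) / 2 + 0.5)
  expect_equal(sequence_nll(0, 1, 1)$total, 1.41894, tolerance = 1e-5)
  expect_equal(sequence_nll(0, 2, 2)$total, log(4 * pi) / 2 + 1)
  expect_equal(sequence_nll(0, 2, 2)$total, 2.26551, tolerance = 1e-5)
  y <- matrix(rnorm(12), 4, 3); v <- matrix(exp(rnorm(12)), 4, 3)
  tg <- matrix(rnorm(12), 4, 3)
  loss <- sequence_nll(y, v, tg)
  expect_equal(loss$total, sum(loss$per_step_per_dim))
  expect_error(sequence_nll(0, -1, 0), "variance")
})

test_that("run_sequence agrees with iterated forward_step and recomputed MSE", {
  cfg <- tiny_config()
  p <- tiny_params(cfg)
  sq <- tiny_sequence()
  pb <- c(0.4, -0.3)
  r <- run_sequence(p, cfg, sq, pb, "open_loop")
  st <- initial_state(cfg)
  for (t in 1:(nrow(sq$values) - 1)) {
    st <- forward_step(p, cfg, st, sq$values[t, ], pb)
    expect_equal(unname(r$y[t, ]), unname(st$y), tolerance = 1e-12)
    expect_equal(unname(r$v[t, ]), unname(st$v), tolerance = 1e-12)
  }
  targets <- sq$values[-1, , drop = FALSE]
  expect_equal(r$mse, mean((targets - r$y)^2))
  expect_equal(r$loss$total,
               sequence_nll(r$y, r$v, targets)$total, tolerance = 1e-10)
})

test_that("zero network predicts zero so MSE is the target mean square", {
  cfg <- tiny_config()
  p <- zero_params(cfg)
  sq <- tiny_sequence()
  r <- run_sequence(p, cfg, sq, c(0, 0))
  expect_true(all(r$y == 0))
  expect_equal(r$mse, mean(sq$values[-1, ]^2))
})

test_that("open and closed loop agree at the first predicted step", {
  cfg <- tiny_config()
  p <- tiny_params(cfg)
  sq <- tiny_sequence()
  ro <- run_sequence(p, cfg, sq, c(0.2, 0.1), "open_loop")
  rc <- run_sequence(p, cfg, sq, c(0.2, 0.1), "closed_loop")
  expect_equal(ro$y[1, ], rc$y[1, ])
  expect_error(run_sequence(p, cfg, sq, c(0, 0), mode = "sideways"))
})

test_that("PB internal state is constant across every step of a run", {
  cfg <- tiny_config()
  p <- tiny_params(cfg)
  pb <- c(0.7, -0.7)
  st <- initial_state(cfg)
  for (t in 1:5) {
    st <- forward_step(p, cfg, st, runif(3, -0.5, 0.5), pb)
    expect_identical(st$p, tanh(pb))
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- network_config(n_input = 3, n_pb = 2, n_lower = 5)
  p <- tiny_params(cfg, fc = 60, K = 1, seed = 2)
  sq <- tiny_sequence(D = 3, T = 10)
  pb <- c(0.3, -0.2)
  g <- gradients(p, cfg, sq, pb)
  for (nm in c("W_xl", "W_ll", "W_pl", "W_lm", "W_lv", "a_mean", "a_var")) {
    idx <- seq_along(p[[nm]])
    for (i in idx) {
      fd <- fd_gradient(p, cfg, sq, pb, nm, i)
      if (abs(fd) > 1e-7)
        expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
      else
        expect_lt(abs(g[[nm]][i] - fd), 1e-6)
    }
  }
  for (i in 1:2)
    expect_equal(g$pb[i], fd_gradient(p, cfg, sq, pb, "pb", i),
                 tolerance = 1e-4)
})

test_that("masked-out weights carry exactly zero gradient", {
  cfg <- tiny_config()
  p <- tiny_params(cfg, fc = 40)
  g <- gradients(p, cfg, tiny_sequence(), c(0.1, 0.1))
  for (pair in list(c("W_xl", "M_xl"), c("W_pl", "M_pl"),
                    c("W_lm", "M_lm"), c("W_lv", "M_lv"))) {
    masked_out <- p[[pair[2]]] == 0
    expect_true(any(masked_out))  # fc = 40% guarantees missing connections
    expect_true(all(g[[pair[1]]][masked_out] == 0))
  }
})

test_that("the variance gradient is stationary where v equals the squared error", {
  # zero-weight network predicting y = 0 for a constant sequence at level c:
  # the per-entry loss in v is minimized at v = c^2, so with a_var chosen to
  # give exactly that variance, the a_var gradient vanishes.
  cfg <- network_config(n_input = 1, n_pb = 1, n_lower = 2)
  p <- zero_params(cfg)
  cc <- 0.6
  p$a_var[] <- log(cc^2 - cfg$variance_floor)
  sq <- matrix(cc, 6, 1)
  g <- gradients(p, cfg, sq, 0)
  expect_equal(g$a_var, 0, tolerance = 1e-12)
})

test_that("model parameters round-trip through the binary archive exactly", {
  p <- tiny_params()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(p, path)
  expect_identical(load_model(path), p)
})
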