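# Small shared fixtures, all built in code.

tiny_config <- function(D = 3, H = 5, P = 2)
  network_config(n_input = D, n_pb = P, n_lower = H)

tiny_params <- function(config = tiny_config(), fc = 60, K = 1, seed = 2)
  init_parameters(config, condition_spec(fc, fc, K), seed = seed)

# a parameter set with every weight zero (and full masks), for degenerate cases
zero_params <- function(config = tiny_config()) {
  p <- init_parameters(config, condition_spec(100, 100, 1), seed = 1)
  for (nm in c("W_xl", "W_ll", "W_pl", "W_lm", "W_lv"))
    p[[nm]][] <- 0
  p$a_lower[] <- 0
  p
}

tiny_sequence <- function(D = 3, T = 10, seed = 3)
  generate_sequence_set(E = 1, S = 1, D = D, T = T, seed = seed)$sequences[[1]]

# independent O(n^2) silhouette oracle: test points against training clusters
brute_silhouette <- function(test_pbs, test_emotions, train_pbs,
                             train_emotions) {
  s <- numeric(nrow(test_pbs))
  for (i in seq_len(nrow(test_pbs))) {
    dists <- tapply(seq_along(train_emotions), train_emotions, function(idx) {
      mean(apply(train_pbs[idx, , drop = FALSE], 1, function(r)
        sqrt(sum((r - test_pbs[i, ])^2))))
    })
    a <- dists[[as.character(test_emotions[i])]]
    b <- min(unlist(dists[names(dists) != as.character(test_emotions[i])]))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# numeric NLL via central finite differences of one parameter entry
fd_gradient <- function(params, config, sequence, pb, name, index,
                        h = 1e-5) {
  f <- function(delta) {
    p <- params
    if (name == "pb") {
      q <- pb; q[index] <- q[index] + delta
      return(run_sequence(p, config, sequence, q)$loss$total)
    }
    p[[name]][index] <- p[[name]][index] + delta
    run_sequence(p, config, sequence, pb)$loss$total
  }
  (f(h) - f(-h)) / (2 * h)
}
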