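# Small fixtures shared across test files; everything is generated in code.

tiny_model <- function(f = 3, m = 2, d = 2, h = 3, blocks = 1, seed = 5,
                       rho = "tanh") {
  mem_init(f, n_units = m, mem_dim = d, hidden_dim = h, n_blocks = blocks,
           rho = rho, seed = seed)
}

tiny_bags <- function(n_bags = 4, n = 5, f = 3, sep = 2, seed = 100) {
  lapply(seq_len(n_bags), function(i) {
    s <- bag_spec(n, f, signal_fraction = 0.5, class_separation = sep,
                  noise_scale = 1, seed = substream_seed(seed, paste0("b", i)))
    make_bag(s, i %% 2, paste0("bag", i))
  })
}

# Clearly separable bag collection used for training sanity checks.
separable_bags <- function(n_bags = 60, f = 8, seed = 42) {
  spec <- bag_spec(c(8L, 15L), f, signal_fraction = 0.5,
                   class_separation = 4.0, noise_scale = 1.0, seed = seed)
  lapply(seq_len(n_bags), function(i) {
    s <- spec; s$seed <- substream_seed(seed, paste0("sep", i))
    make_bag(s, i %% 2, paste0("sep", i))
  })
}

# Brute-force oracle: mean-pool each bag and fit a logistic classifier.
meanpool_oracle_accuracy <- function(train, test = train) {
  pool <- function(bags) t(vapply(bags, function(b) colMeans(b$x),
                                  numeric(ncol(bags[[1]]$x))))
  y <- vapply(train, `[[`, numeric(1), "label")
  d <- data.frame(y = y, pool(train))
  fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
  newd <- data.frame(pool(test))
  pred <- as.integer(stats::predict(fit, newdata = newd, type = "response") > 0.5)
  mean(pred == vapply(test, `[[`, numeric(1), "label"))
}
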