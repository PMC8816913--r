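#' Differentially private SGD configuration
#'
#' The reference setting of the study this package emulates is batch size 32
#' split into 32 microbatches of size 1, clip norm 1.0, noise multiplier 4.0
#' (noise standard deviation sigma * C), Adam with learning rate 2e-5.
#'
#' @param clip_norm Positive per-microbatch gradient clipping norm C. May be
#'   `Inf` to disable clipping.
#' @param noise_multiplier Nonnegative sigma; the Gaussian noise added to the
#'   summed clipped gradients has standard deviation `sigma * clip_norm`.
#' @param microbatches Number of microbatches each batch is split into.
#' @return An object of class `dp_config`.
#' @export
dp_config <- function(clip_norm = 1.0, noise_multiplier = 4.0,
                      microbatches = 32L) {
  if (clip_norm <= 0) stop("clip_norm must be positive")
  if (noise_multiplier < 0) stop("noise_multiplier must be nonnegative")
  if (microbatches < 1) stop("microbatches must be >= 1")
  structure(list(clip_norm = clip_norm, noise_multiplier = noise_multiplier,
                 microbatches = as.integer(microbatches)),
            class = "dp_config")
}

#' Local training configuration
#'
#' @param lr Learning rate.
#' @param batch_size Minibatch size B.
#' @param epochs Number of passes over the data.
#' @param optimizer "sgd" or "adam" (betas 0.9/0.999, eps 1e-8).
#' @param dp A [dp_config()] for DP-SGD, or NULL for plain training.
#' @param seed Seed controlling epoch shuffles and DP noise.
#' @param log_metrics Record loss/accuracy over the training set per epoch
#'   (one extra forward pass per epoch).
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, batch_size = 8L, epochs = 1L,
                         optimizer = c("sgd", "adam"), dp = NULL, seed = 1L,
                         log_metrics = TRUE) {
  optimizer <- match.arg(optimizer)
  if (!is.null(dp) && !inherits(dp, "dp_config")) stop("dp must be a dp_config")
  if (!is.null(dp) && dp$microbatches > batch_size)
    stop("microbatches cannot exceed batch_size")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer, dp = dp,
                 seed = as.integer(seed), log_metrics = isTRUE(log_metrics)),
            class = "train_config")
}

#' Clip a gradient to a global L2 norm bound
#'
#' The norm is taken over all parameter arrays jointly (one bound per
#' microbatch, the standard DP-SGD construction); the direction is preserved.
#'
#' @param g Numeric vector (a flattened gradient).
#' @param clip_norm Positive bound C (may be `Inf`).
#' @return `g * min(1, C / ||g||)`, with norm at most C.
#' @export
clip_gradient <- function(g, clip_norm) {
  nrm <- sqrt(sum(g^2))
  g * min(1, clip_norm / nrm)
}

opt_init <- function(model, optimizer) {
  npar <- length(params_flatten(model))
  if (optimizer == "adam")
    list(step = 0L, m = numeric(npar), v = numeric(npar))
  else
    list(step = 0L)
}

opt_update <- function(flat, g, state, optimizer, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  if (optimizer == "sgd") {
    flat <- flat - lr * g
  } else {
    state$m <- beta1 * state$m + (1 - beta1) * g
    state$v <- beta2 * state$v + (1 - beta2) * g^2
    mhat <- state$m / (1 - beta1^state$step)
    vhat <- state$v / (1 - beta2^state$step)
    flat <- flat - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# Split 1..n into k nearly equal contiguous microbatches.
split_microbatches <- function(n, k) {
  k <- min(k, n)
  split(seq_len(n), ceiling(seq_len(n) / (n / k)))
}

#' One DP-SGD update on a batch of bags
#'
#' Per-microbatch gradients are clipped to the global-norm bound, summed,
#' perturbed once with independent per-coordinate Gaussian noise of standard
#' deviation `sigma * C`, divided by the number of microbatches, and applied
#' through the configured optimizer. With `sigma = 0`, `C = Inf` and one
#' microbatch this reduces exactly to a plain step on the batch-mean
#' gradient. Noise is drawn from R's current RNG stream; seed it for
#' reproducible updates.
#'
#' @param model A `mem_model`.
#' @param opt_state State from `opt_init` (internal; pass the previous value).
#' @param bags Batch of `feature_bag`s.
#' @param cfg A [train_config()] with a non-NULL `dp` (or NULL dp for plain).
#' @return List with updated `model`, `opt_state`, and the mean microbatch
#'   `loss`.
#' @export
dp_sgd_step <- function(model, opt_state, bags, cfg) {
  flat <- params_flatten(model)
  if (is.null(cfg$dp)) {
    lg <- loss_and_grad(model, bags)
    g <- params_flatten(lg$grad)
    loss <- lg$loss
  } else {
    dp <- cfg$dp
    idx <- split_microbatches(length(bags), dp$microbatches)
    acc <- numeric(length(flat))
    loss <- 0
    for (mb in idx) {
      lg <- loss_and_grad(model, bags[mb])
      acc <- acc + clip_gradient(params_flatten(lg$grad), dp$clip_norm)
      loss <- loss + lg$loss
    }
    loss <- loss / length(idx)
    if (dp$noise_multiplier > 0)
      acc <- acc + stats::rnorm(length(acc),
                                sd = dp$noise_multiplier * dp$clip_norm)
    g <- acc / length(idx)
  }
  up <- opt_update(flat, g, opt_state, cfg$optimizer, cfg$lr)
  list(model = params_unflatten(model, up$flat), opt_state = up$state,
       loss = loss)
}

#' Train a model locally on one dataset
#'
#' Runs the configured number of epochs of shuffled minibatch updates
#' (plain SGD/Adam, or DP-SGD when `cfg$dp` is set). Epoch e shuffles with
#' the substream seed of `("epoch-", epoch_offset + e)`, so a federated
#' schedule of R rounds of E epochs with offsets 0, E, 2E, ... consumes
#' exactly the same randomness as one local run of R*E epochs.
#'
#' @param model A `mem_model`.
#' @param bags Training bags (list of `feature_bag`).
#' @param cfg A [train_config()].
#' @param epoch_offset Epoch-numbering offset for the shuffle substreams.
#' @param opt_state Optional optimizer state to resume from.
#' @return List with `model`, `opt_state`, and `log` (data frame with epoch,
#'   loss, accuracy; empty when `log_metrics` is FALSE).
#' @export
train_local <- function(model, bags, cfg, epoch_offset = 0L, opt_state = NULL) {
  if (length(bags) == 0) stop("empty training set")
  if (is.null(opt_state)) opt_state <- opt_init(model, cfg$optimizer)
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  n <- length(bags)
  for (e in seq_len(cfg$epochs)) {
    set.seed(substream_seed(cfg$seed, paste0("epoch-", epoch_offset + e)))
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    for (s in starts) {
      take <- ord[s:min(s + cfg$batch_size - 1L, n)]
      st <- dp_sgd_step(model, opt_state, bags[take], cfg)
      if (!is.finite(st$loss))
        stop(sprintf("non-finite loss at epoch %d (bags %s)",
                     epoch_offset + e, paste(take, collapse = ",")))
      model <- st$model; opt_state <- st$opt_state
    }
    if (cfg$log_metrics) {
      ev <- evaluate_bags(model, bags)
      log <- rbind(log, data.frame(epoch = epoch_offset + e,
                                   loss = ev$loss, accuracy = ev$accuracy))
    }
  }
  list(model = model, opt_state = opt_state, log = log)
}

# Mean loss and accuracy of hard predictions over a set of bags.
evaluate_bags <- function(model, bags, labels = NULL) {
  if (is.null(labels)) labels <- vapply(bags, `[[`, numeric(1), "label")
  loss <- 0; correct <- 0
  for (k in seq_along(bags)) {
    p <- classify(bags[[k]], model)
    loss <- loss - log(max(p[labels[k] + 1], 1e-300))
    correct <- correct + as.integer(which.max(p) - 1L == labels[k])
  }
  list(loss = loss / length(bags), accuracy = correct / length(bags))
}

#' Write a training configuration to YAML
#' @param cfg A [train_config()].
#' @param path Output path.
#' @export
write_train_config <- function(cfg, path) {
  obj <- unclass(cfg)
  if (!is.null(obj$dp)) obj$dp <- unclass(obj$dp)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a training configuration from YAML
#' @param path YAML path written by [write_train_config()].
#' @return A [train_config()].
#' @export
read_train_config <- function(path) {
  obj <- yaml::read_yaml(path)
  dp <- if (!is.null(obj$dp))
    dp_config(obj$dp$clip_norm, obj$dp$noise_multiplier, obj$dp$microbatches)
  train_config(lr = obj$lr, batch_size = obj$batch_size, epochs = obj$epochs,
               optimizer = obj$optimizer, dp = dp, seed = obj$seed,
               log_metrics = obj$log_metrics)
}
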