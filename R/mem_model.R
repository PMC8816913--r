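#' Memory-based permutation-invariant set classifier
#'
#' The model pools a bag of n instance vectors (n x f matrix) into a fixed
#' size representation through one or more memory blocks and classifies it
#' with a softmax head. Each memory block holds:
#'
#' * m memory units. Unit i embeds the instances with a trainable matrix
#'   A_i (f x d) through a nonlinearity, `U_i = rho(X A_i)`; the memory
#'   vectors are deliberately not normalized, so magnitude participates in
#'   the cross-correlation. The unit then forms `S_i = column-wise-softmax
#'   (U_i U_i^T)` and averages the rows, `p_i = row-wise-average(S_i)`, a
#'   probability distribution ("attention") over the instances.
#' * a per-instance linear encoder/decoder pair (f -> h -> f). The encoder
#'   output `C` is a permutation-equivariant sequence; the decoder defines a
#'   reconstruction penalty that keeps the map close to invertible without
#'   enforcing exact invertibility.
#'
#' The block output is the m x h matrix with rows `xhat_i = sum_j p_i[j] C_j`
#' — a weighted pooling of C under the m attention distributions, invariant
#' to instance permutations. Blocks stack: the output sequence of one block
#' is the input sequence of the next. The head concatenates the final m x h
#' output row-wise and applies a dense layer with a 2-class softmax.
#'
#' @param feature_dim Input instance dimension f.
#' @param n_units Number of memory units m per block.
#' @param mem_dim Embedding dimension d of each memory unit.
#' @param hidden_dim Encoder output dimension h.
#' @param n_blocks Number of stacked memory blocks.
#' @param rho Nonlinearity for the memory units: "tanh" (default; bounded and
#'   smooth, which keeps finite-difference checks well conditioned) or
#'   "identity".
#' @param lambda_rec Weight of the reconstruction penalty in the loss.
#' @param seed Seed for the scaled-Gaussian initialization (sd 1/sqrt(fan-in)).
#' @param init Either "gaussian" or "identity" (identity encoder/decoder and
#'   zero head; requires `hidden_dim == feature_dim`; useful for tests).
#' @return An object of class `mem_model`: list with `par` (named list of
#'   arrays) and `hyper`.
#' @export
mem_init <- function(feature_dim, n_units = 2L, mem_dim = 4L, hidden_dim = 8L,
                     n_blocks = 1L, rho = c("tanh", "identity"),
                     lambda_rec = 0.1, seed = 1L, init = c("gaussian", "identity")) {
  rho <- match.arg(rho)
  init <- match.arg(init)
  if (init == "identity" && hidden_dim != feature_dim)
    stop("identity init requires hidden_dim == feature_dim")
  par <- list()
  with_seed(seed, {
    fb <- feature_dim
    for (b in seq_len(n_blocks)) {
      pre <- sprintf("block%d.", b)
      for (i in seq_len(n_units)) {
        par[[paste0(pre, "A", i)]] <-
          matrix(stats::rnorm(fb * mem_dim, sd = 1 / sqrt(fb)), fb, mem_dim)
      }
      if (init == "identity") {
        par[[paste0(pre, "W_enc")]] <- diag(1, fb, hidden_dim)
        par[[paste0(pre, "W_dec")]] <- diag(1, hidden_dim, fb)
      } else {
        par[[paste0(pre, "W_enc")]] <-
          matrix(stats::rnorm(fb * hidden_dim, sd = 1 / sqrt(fb)), fb, hidden_dim)
        par[[paste0(pre, "W_dec")]] <-
          matrix(stats::rnorm(hidden_dim * fb, sd = 1 / sqrt(hidden_dim)), hidden_dim, fb)
      }
      par[[paste0(pre, "b_enc")]] <- rep(0, hidden_dim)
      par[[paste0(pre, "b_dec")]] <- rep(0, fb)
      fb <- hidden_dim
    }
    nh <- n_units * hidden_dim
    par[["head.W"]] <- if (init == "identity") matrix(0, nh, 2) else
      matrix(stats::rnorm(nh * 2, sd = 1 / sqrt(nh)), nh, 2)
    par[["head.b"]] <- rep(0, 2)
  })
  structure(list(par = par,
                 hyper = list(feature_dim = feature_dim, n_units = n_units,
                              mem_dim = mem_dim, hidden_dim = hidden_dim,
                              n_blocks = n_blocks, rho = rho,
                              lambda_rec = lambda_rec, seed = seed)),
            class = "mem_model")
}

rho_fun <- function(z, rho) if (rho == "tanh") tanh(z) else z
# derivative expressed through the activation value u = rho(z)
rho_deriv <- function(u, rho) if (rho == "tanh") 1 - u^2 else array(1, dim(u))

col_softmax <- function(g) {
  s <- exp(sweep(g, 2, apply(g, 2, max)))
  sweep(s, 2, colSums(s), "/")
}

#' Forward pass of a single memory unit
#'
#' @param x Numeric n x f matrix (a bag).
#' @param A Embedding matrix f x d.
#' @param rho Nonlinearity identifier ("tanh" or "identity").
#' @return List with `p` (attention, length n, sums to 1), `S` (n x n
#'   column-stochastic matrix) and `U` (n x d memory vectors).
#' @export
memory_unit_forward <- function(x, A, rho = "tanh") {
  x <- as.matrix(x)
  if (ncol(x) != nrow(A)) stop("instance dimension does not match embedding matrix")
  U <- rho_fun(x %*% A, rho)
  S <- col_softmax(U %*% t(U))
  list(p = rowMeans(S), S = S, U = U)
}

#' Per-instance encoder of the bijective-transformation unit
#'
#' Applies the affine encoder independently to each instance, hence the
#' output sequence is permutation-equivariant. With `decode = TRUE` the
#' decoder reconstruction and its mean squared error are returned as well.
#'
#' @param x n x f matrix.
#' @param par Named parameter list containing `W_enc`, `b_enc`, `W_dec`,
#'   `b_dec` (use a block's slice of `model$par`, names without prefix).
#' @param decode Also compute the decoder reconstruction.
#' @return List with `C` (n x h) and, if requested, `x_rec` and `rec_mse`.
#' @export
bijective_forward <- function(x, par, decode = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(par$W_enc)) stop("instance dimension does not match encoder")
  C <- sweep(x %*% par$W_enc, 2, par$b_enc, "+")
  out <- list(C = C)
  if (decode) {
    x_rec <- sweep(C %*% par$W_dec, 2, par$b_dec, "+")
    out$x_rec <- x_rec
    out$rec_mse <- mean((x - x_rec)^2)
  }
  out
}

block_par <- function(model, b) {
  pre <- sprintf("block%d.", b)
  nm <- names(model$par)
  sel <- startsWith(nm, pre)
  out <- model$par[sel]
  names(out) <- substring(nm[sel], nchar(pre) + 1L)
  out
}

#' Forward pass of one memory block
#'
#' @param x n x f input sequence.
#' @param model A `mem_model`.
#' @param block Block index.
#' @return List with `xhat` (m x h pooled output), `P` (m x n attention
#'   matrix), `C`, `x_rec`, `rec_mse`, and the per-unit caches.
#' @export
memory_block_forward <- function(x, model, block = 1L) {
  hp <- model$hyper
  bp <- block_par(model, block)
  units <- lapply(seq_len(hp$n_units), function(i)
    memory_unit_forward(x, bp[[paste0("A", i)]], hp$rho))
  P <- do.call(rbind, lapply(units, `[[`, "p"))
  enc <- bijective_forward(x, bp, decode = TRUE)
  list(xhat = P %*% enc$C, P = P, C = enc$C, x_rec = enc$x_rec,
       rec_mse = enc$rec_mse, units = units, x = as.matrix(x))
}

mem_forward <- function(bag_x, model, keep_cache = FALSE) {
  hp <- model$hyper
  x <- as.matrix(bag_x)
  caches <- vector("list", hp$n_blocks)
  for (b in seq_len(hp$n_blocks)) {
    caches[[b]] <- memory_block_forward(x, model, b)
    x <- caches[[b]]$xhat
  }
  z <- as.vector(t(x))                       # concatenate rows of final m x h
  logits <- drop(crossprod(model$par[["head.W"]], z)) + model$par[["head.b"]]
  lmax <- max(logits)
  probs <- exp(logits - lmax); probs <- probs / sum(probs)
  rec <- mean(vapply(caches, `[[`, numeric(1), "rec_mse"))
  out <- list(probs = probs, logits = logits, rec_mse = rec, z = z)
  if (keep_cache) out$caches <- caches
  out
}

#' Classify a feature bag
#'
#' Deterministic given the parameters, and invariant to the order of
#' instances in the bag.
#'
#' @param bag A `feature_bag` (or bare matrix).
#' @param model A `mem_model`.
#' @return Numeric length-2 vector of class probabilities (classes 0, 1).
#' @export
classify <- function(bag, model) {
  x <- if (inherits(bag, "feature_bag")) bag$x else as.matrix(bag)
  if (nrow(x) < 1) stop("cannot classify an empty bag")
  if (any(!is.finite(x))) stop("bag contains non-finite features")
  p <- mem_forward(x, model)$probs
  names(p) <- c("0", "1")
  p
}

#' Loss and gradient over a batch of bags
#'
#' Mean cross-entropy plus `lambda_rec` times the mean reconstruction error,
#' with the gradient computed by hand-derived backpropagation in the same
#' named-array layout as `model$par`.
#'
#' @param model A `mem_model`.
#' @param bags List of `feature_bag` objects.
#' @param labels Optional numeric labels (defaults to the bags' own labels).
#' @return List with `loss`, `grad` (named list of arrays), `ce`, `rec`,
#'   and `correct` (count of correct hard predictions).
#' @export
loss_and_grad <- function(model, bags, labels = NULL) {
  if (length(bags) == 0) stop("empty batch")
  if (is.null(labels)) labels <- vapply(bags, `[[`, numeric(1), "label")
  hp <- model$hyper
  grad <- lapply(model$par, function(a) array(0, dim = dim(a) %||% length(a)))
  loss <- 0; ce_sum <- 0; rec_sum <- 0; correct <- 0
  nb <- length(bags)
  for (k in seq_len(nb)) {
    x0 <- if (inherits(bags[[k]], "feature_bag")) bags[[k]]$x else as.matrix(bags[[k]])
    y <- labels[k]
    fw <- mem_forward(x0, model, keep_cache = TRUE)
    if (any(!is.finite(fw$logits)))
      stop(sprintf("non-finite forward pass on bag '%s'",
                   if (inherits(bags[[k]], "feature_bag")) bags[[k]]$bag_id else k))
    ce <- -log(max(fw$probs[y + 1], 1e-300))
    ce_sum <- ce_sum + ce
    rec_sum <- rec_sum + fw$rec_mse
    loss <- loss + ce + hp$lambda_rec * fw$rec_mse
    correct <- correct + as.integer(which.max(fw$probs) - 1L == y)

    # ---- backward ----
    onehot <- c(0, 0); onehot[y + 1] <- 1
    dlogits <- fw$probs - onehot                       # d ce / d logits
    grad[["head.W"]] <- grad[["head.W"]] + outer(fw$z, dlogits)
    grad[["head.b"]] <- grad[["head.b"]] + dlogits
    dxhat <- matrix(model$par[["head.W"]] %*% dlogits,
                    hp$n_units, hp$hidden_dim, byrow = TRUE)
    for (b in rev(seq_len(hp$n_blocks))) {
      cc <- fw$caches[[b]]
      x <- cc$x; n <- nrow(x); fb <- ncol(x)
      pre <- sprintf("block%d.", b)
      rec_scale <- 2 * hp$lambda_rec / (n * fb * hp$n_blocks)
      dP <- dxhat %*% t(cc$C)
      dC <- t(cc$P) %*% dxhat
      dxrec <- rec_scale * (cc$x_rec - x)
      grad[[paste0(pre, "W_dec")]] <- grad[[paste0(pre, "W_dec")]] + t(cc$C) %*% dxrec
      grad[[paste0(pre, "b_dec")]] <- grad[[paste0(pre, "b_dec")]] + colSums(dxrec)
      dC <- dC + dxrec %*% t(model$par[[paste0(pre, "W_dec")]])
      dx <- rec_scale * (x - cc$x_rec)                 # direct term of the MSE
      grad[[paste0(pre, "W_enc")]] <- grad[[paste0(pre, "W_enc")]] + t(x) %*% dC
      grad[[paste0(pre, "b_enc")]] <- grad[[paste0(pre, "b_enc")]] + colSums(dC)
      dx <- dx + dC %*% t(model$par[[paste0(pre, "W_enc")]])
      for (i in seq_len(hp$n_units)) {
        un <- cc$units[[i]]
        dS <- matrix(dP[i, ] / n, n, n)                # p = rowMeans(S)
        dG <- un$S * (dS - matrix(colSums(un$S * dS), n, n, byrow = TRUE))
        dU <- (dG + t(dG)) %*% un$U
        dpre_act <- dU * rho_deriv(un$U, hp$rho)
        Ai <- paste0(pre, "A", i)
        grad[[Ai]] <- grad[[Ai]] + t(x) %*% dpre_act
        dx <- dx + dpre_act %*% t(model$par[[Ai]])
      }
      dxhat <- dx                                      # input of block b is xhat of b-1
    }
  }
  grad <- lapply(grad, function(g) g / nb)
  list(loss = loss / nb, grad = grad, ce = ce_sum / nb, rec = rec_sum / nb,
       correct = correct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten model parameters into one named numeric vector
#' @param model A `mem_model` (or a gradient list in the same layout).
#' @return Numeric vector; [params_unflatten()] inverts it exactly.
#' @export
params_flatten <- function(model) {
  par <- if (inherits(model, "mem_model")) model$par else model
  unlist(par, use.names = FALSE)
}

#' Restore a flat parameter vector into a model
#' @param model Template `mem_model` providing layout and hyperparameters.
#' @param flat Numeric vector from [params_flatten()].
#' @return A `mem_model` with the given parameter values.
#' @export
params_unflatten <- function(model, flat) {
  par <- model$par
  pos <- 0L
  for (nm in names(par)) {
    len <- length(par[[nm]])
    vals <- flat[(pos + 1L):(pos + len)]
    if (is.matrix(par[[nm]])) {
      par[[nm]] <- matrix(vals, nrow(par[[nm]]), ncol(par[[nm]]))
    } else {
      par[[nm]] <- vals
    }
    pos <- pos + len
  }
  if (pos != length(flat)) stop("flat vector length does not match model layout")
  model$par <- par
  model
}

#' Save a model checkpoint to a single text file
#'
#' JSON with a header (hyperparameters, array names and shapes) and the
#' parameter values base64-encoded as little-endian doubles, so the
#' round-trip through [mem_load()] is bit-exact.
#'
#' @param model A `mem_model`.
#' @param path Output file path.
#' @export
mem_save <- function(model, path) {
  flat <- params_flatten(model)
  obj <- list(
    format = "dpfedmil-checkpoint-1",
    hyper = model$hyper,
    shapes = lapply(model$par, function(a) dim(a) %||% length(a)),
    values = jsonlite::base64_enc(writeBin(flat, raw(), size = 8, endian = "little"))
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a model checkpoint written by [mem_save()]
#' @param path Checkpoint path.
#' @return A `mem_model`, bit-identical to the saved one.
#' @export
mem_load <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = ""),
                            simplifyVector = TRUE)
  if (!identical(obj$format, "dpfedmil-checkpoint-1")) stop("not a checkpoint file")
  hp <- obj$hyper
  model <- mem_init(hp$feature_dim, hp$n_units, hp$mem_dim, hp$hidden_dim,
                    hp$n_blocks, hp$rho, hp$lambda_rec, hp$seed)
  raw <- jsonlite::base64_dec(obj$values)
  flat <- readBin(raw, "double", n = length(raw) / 8, size = 8, endian = "little")
  params_unflatten(model, flat)
}
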