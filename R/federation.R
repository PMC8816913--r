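#' IID partition of bags among clients
#'
#' Within each class, bags are shuffled and dealt round-robin so class sizes
#' per client differ by at most one; the dealing start rotates across classes
#' so total client sizes also stay within one of each other.
#'
#' @param labels Vector of bag labels (the bags are referenced by index).
#' @param n_clients Number of clients (`>= 1`, at most the number of bags).
#' @param seed Integer seed.
#' @return A `partition_plan`: list with `assignment` (client index per bag),
#'   `mode`, `n_clients`, `proportions` (class x client realized shares) and
#'   `seed`.
#' @export
partition_iid <- function(labels, n_clients, seed = 1L) {
  n <- length(labels)
  if (n_clients < 1) stop("need at least one client")
  if (n_clients > n) stop("more clients than bags")
  assignment <- integer(n)
  offset <- 0L
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- ((seq_along(idx) - 1L + offset) %% n_clients) + 1L
      offset <- (offset + length(idx)) %% n_clients
    }
  })
  new_partition_plan(assignment, labels, n_clients, "iid", seed)
}

#' Non-IID partition of bags among clients
#'
#' Per class, one positive random value is drawn per client and normalized
#' into a probability vector; each bag of that class is then assigned to a
#' client sampled from it. This reproduces heterogeneous class mixes across
#' clients; some clients can end up empty for a class (or entirely).
#'
#' @inheritParams partition_iid
#' @param rdist Function drawing the positive per-client values (default
#'   `runif`).
#' @return A `partition_plan` (see [partition_iid()]); `proportions` records
#'   the realized per-class client shares.
#' @export
partition_noniid <- function(labels, n_clients, seed = 1L, rdist = stats::runif) {
  n <- length(labels)
  if (n_clients < 1) stop("need at least one client")
  if (n_clients > n) stop("more clients than bags")
  assignment <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      w <- rdist(n_clients)
      p <- w / sum(w)
      assignment[idx] <- sample.int(n_clients, length(idx), replace = TRUE, prob = p)
    }
  })
  new_partition_plan(assignment, labels, n_clients, "noniid", seed)
}

new_partition_plan <- function(assignment, labels, n_clients, mode, seed) {
  tab <- table(factor(labels), factor(assignment, levels = seq_len(n_clients)))
  structure(list(assignment = assignment, labels = labels,
                 n_clients = as.integer(n_clients), mode = mode,
                 proportions = prop.table(tab, 1), counts = tab,
                 seed = as.integer(seed)),
            class = "partition_plan")
}

#' Serialize a partition plan as CSV (bag_id, client, class)
#' @param plan A `partition_plan`.
#' @param path Output path.
#' @param bag_ids Optional bag identifiers (defaults to indices).
#' @export
write_partition_plan <- function(plan, path, bag_ids = NULL) {
  if (is.null(bag_ids)) bag_ids <- seq_along(plan$assignment)
  utils::write.csv(data.frame(bag_id = bag_ids, client = plan$assignment,
                              class = plan$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' Sample-size-weighted federated average of model parameters
#'
#' Every parameter array of the result equals the weighted mean of the
#' clients' arrays with weights `n_i / sum(n_i)` — the FedAvg aggregation
#' rule.
#'
#' @param models List of `mem_model`s with identical parameter layouts.
#' @param n_i Per-client sample counts (aggregation weights).
#' @return The aggregated `mem_model`.
#' @export
fedavg_aggregate <- function(models, n_i) {
  if (length(models) < 1) stop("need at least one model")
  if (length(n_i) != length(models)) stop("one sample count per model")
  if (sum(n_i) <= 0) stop("total sample count must be positive")
  flats <- lapply(models, params_flatten)
  len <- unique(vapply(flats, length, integer(1)))
  nms <- unique(vapply(models, function(m) paste(names(m$par), collapse = ";"),
                       character(1)))
  if (length(len) != 1 || length(nms) != 1)
    stop("parameter layouts differ across clients")
  w <- n_i / sum(n_i)
  agg <- numeric(len)
  for (i in seq_along(flats)) agg <- agg + w[i] * flats[[i]]
  params_unflatten(models[[1]], agg)
}

#' Split one client's bags 80:20 into train and test
#'
#' The training share is `floor(split * n)` bags, stratified by class with
#' largest-remainder rounding where both classes are present (applied to the
#' hospital cohort table, the four clients' training shares pool to 705
#' bags).
#'
#' @param bags List of `feature_bag`s.
#' @param split Training fraction (default 0.8).
#' @param seed Seed for the within-class shuffles.
#' @return List with `train` and `test` bag lists.
#' @export
split_train_test <- function(bags, split = 0.8, seed = 1L) {
  labels <- vapply(bags, `[[`, numeric(1), "label")
  n <- length(bags)
  n_train <- floor(split * n)
  classes <- sort(unique(labels))
  target <- floor(split * vapply(classes, function(cl) sum(labels == cl), numeric(1)))
  rem <- split * vapply(classes, function(cl) sum(labels == cl), numeric(1)) - target
  short <- n_train - sum(target)
  if (short > 0) {
    for (j in order(rem, decreasing = TRUE)[seq_len(short)])
      target[j] <- target[j] + 1
  }
  train_idx <- integer(0)
  with_seed(seed, {
    for (j in seq_along(classes)) {
      idx <- which(labels == classes[j])
      idx <- idx[sample.int(length(idx))]
      train_idx <- c(train_idx, idx[seq_len(target[j])])
    }
  })
  train_idx <- sort(train_idx)
  list(train = bags[train_idx], test = bags[setdiff(seq_len(n), train_idx)])
}

#' Run federated averaging over a set of clients
#'
#' Per round: the central weights are broadcast, every client runs its local
#' epochs (plain or DP-SGD per the local config), and the server forms the
#' sample-size-weighted average. Clients with no training bags are skipped
#' with weight zero. The client's shuffle/noise substreams advance with the
#' round number, so a single-client federation reproduces exactly the
#' trajectory of uninterrupted local training with the same seed schedule.
#'
#' @param clients List of lists with elements `train` and `test` (bag lists)
#'   and optionally `name`.
#' @param model Initial central `mem_model` (broadcast at round 1).
#' @param rounds Number of communication rounds.
#' @param local_epochs Local epochs per round.
#' @param local_cfg A [train_config()]; its `epochs` and `seed` are managed
#'   by the federation loop (per-client substreams of `seed`).
#' @param seed Master seed.
#' @param eval_every Evaluate the central model on every client's test set
#'   each `eval_every` rounds (default 1; the final round is always
#'   evaluated).
#' @return List with `model` (final central model), `metrics` (data frame:
#'   round, client, accuracy, loss) and `weights` (the n_i used).
#' @export
run_federated <- function(clients, model, rounds, local_epochs, local_cfg,
                          seed = 1L, eval_every = 1L) {
  if (length(clients) == 0) stop("no clients")
  if (rounds < 1 || local_epochs < 1) stop("rounds and local epochs must be >= 1")
  n_i <- vapply(clients, function(cl) length(cl$train), numeric(1))
  if (any(n_i == 0)) warning("client(s) with zero training bags are skipped")
  if (all(n_i == 0)) return(list(model = model, metrics = NULL, weights = n_i))
  names <- vapply(seq_along(clients), function(i)
    clients[[i]]$name %||% paste0("client", i), character(1))
  opt_states <- lapply(seq_along(clients), function(i)
    opt_init(model, local_cfg$optimizer))
  metrics <- NULL
  for (r in seq_len(rounds)) {
    updates <- list(); weights <- numeric(0)
    for (i in seq_along(clients)) {
      if (n_i[i] == 0) next
      cfg <- local_cfg
      cfg$epochs <- as.integer(local_epochs)
      cfg$seed <- substream_seed(seed, paste0("client-", i))
      res <- train_local(model, clients[[i]]$train, cfg,
                         epoch_offset = (r - 1L) * local_epochs,
                         opt_state = opt_states[[i]])
      opt_states[[i]] <- res$opt_state
      updates[[length(updates) + 1L]] <- res$model
      weights <- c(weights, n_i[i])
    }
    model <- fedavg_aggregate(updates, weights)
    if (r %% eval_every == 0 || r == rounds) {
      for (i in seq_along(clients)) {
        if (length(clients[[i]]$test) == 0) next
        ev <- evaluate_bags(model, clients[[i]]$test)
        metrics <- rbind(metrics, data.frame(
          round = r, client = names[i], accuracy = ev$accuracy, loss = ev$loss))
      }
    }
  }
  list(model = model, metrics = metrics, weights = n_i)
}

#' Evaluate a model on several datasets
#'
#' @param model A `mem_model`.
#' @param datasets Named list of bag lists.
#' @return List with `table` (data frame: dataset, accuracy, loss), `mean`
#'   and `sd` (sample standard deviation across datasets; 0 for a single
#'   dataset).
#' @export
evaluate_model <- function(model, datasets) {
  if (length(datasets) == 0) stop("no datasets")
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  tab <- do.call(rbind, lapply(names(datasets), function(nm) {
    ev <- evaluate_bags(model, datasets[[nm]])
    data.frame(dataset = nm, accuracy = ev$accuracy, loss = ev$loss)
  }))
  acc <- tab$accuracy
  list(table = tab, mean = mean(acc), sd = if (length(acc) > 1) stats::sd(acc) else 0)
}
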