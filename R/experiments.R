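#' Desk-scale defaults for the federated experiments
#'
#' Total of 400 bags (balanced classes), 16-dimensional features, bag sizes
#' 20-50, a one-block model with m = 2 memory units, d = 4, h = 8, and 60
#' communication rounds — sized so the full series-1 grid runs in minutes on
#' one CPU while preserving the qualitative behaviour of interest
#' (federated vs non-collaborative vs centralized).
#'
#' @return List of default settings consumed by [run_series1()] and
#'   [run_series2()].
#' @export
experiment_defaults <- function() {
  list(total_bags = 400L, feature_dim = 16L, bag_size = c(20L, 50L),
       signal_fraction = 0.2, class_separation = 2.0, noise_scale = 1.0,
       n_units = 2L, mem_dim = 4L, hidden_dim = 8L, rounds = 60L,
       local_epochs = 1L, lr = 0.01, batch_size = 8L, test_split = 0.8)
}

# Generate the pooled, balanced bag collection for series 1 (no domain shift:
# the partitions themselves create the client structure).
series1_bags <- function(def, seed) {
  spec <- cohort_spec("pool", n_bags = def$total_bags,
                      n_pos = def$total_bags %/% 2L,
                      shift_magnitude = 0, seed = seed)
  bs <- bag_spec(def$bag_size, def$feature_dim, def$signal_fraction,
                 def$class_separation, def$noise_scale, seed = seed)
  cohort_bags(make_cohort(spec, bs))
}

# Build per-client train/test datasets from a partition plan.
clients_from_plan <- function(bags, plan, split, seed) {
  lapply(seq_len(plan$n_clients), function(i) {
    mine <- bags[plan$assignment == i]
    if (length(mine) == 0)
      return(list(name = paste0("client", i), train = list(), test = list()))
    sp <- split_train_test(mine, split, substream_seed(seed, paste0("split-", i)))
    list(name = paste0("client", i), train = sp$train, test = sp$test)
  })
}

#' Experiment series 1: client count and data distribution
#'
#' For every (distribution in `{iid, noniid}`, number of clients n in the
#' grid) and every replicate seed: partitions a pooled synthetic cohort,
#' trains (a) each client alone ("without FL"), (b) a FedAvg central model
#' ("with FL"), and optionally (c) one centralized model on the pooled
#' training data, all with plain SGD and matched epoch budgets
#' (`rounds * local_epochs`). Headline accuracies are measured on the shared
#' pooled test set (union of all per-client test splits), which makes client
#' and central models directly comparable; the per-replicate attribute also
#' carries the own-test-split view (`*_own` columns), where a client whose
#' skewed class mix matches its own test split can look deceptively strong.
#' The table reports the mean and standard deviation across replicates.
#'
#' @param n_grid Client counts to sweep (default `c(4, 8)`).
#' @param distributions Subset of `c("iid", "noniid")`.
#' @param replicates Number of replicate seeds (default 5).
#' @param seed Master seed; replicate r uses the substream `("rep-", r)`.
#' @param include_centralized Also train the pooled baseline.
#' @param defaults Settings from [experiment_defaults()].
#' @return Data frame with columns distribution, n_clients, without_fl,
#'   without_fl_sd, with_fl, with_fl_sd, centralized, centralized_sd, and a
#'   `per_replicate` attribute with the raw replicate-level results.
#' @export
run_series1 <- function(n_grid = c(4L, 8L), distributions = c("iid", "noniid"),
                        replicates = 5L, seed = 1L, include_centralized = TRUE,
                        defaults = experiment_defaults()) {
  def <- defaults
  cfg <- train_config(lr = def$lr, batch_size = def$batch_size, epochs = 1L,
                      optimizer = "sgd", dp = NULL, log_metrics = FALSE)
  raw <- NULL
  for (r in seq_len(replicates)) {
    rseed <- substream_seed(seed, paste0("rep-", r))
    dat <- series1_bags(def, rseed)
    central_acc <- NA_real_
    if (include_centralized) {
      model0 <- mem_init(def$feature_dim, def$n_units, def$mem_dim,
                         def$hidden_dim, seed = substream_seed(rseed, "init"))
      sp <- split_train_test(dat$bags, def$test_split,
                             substream_seed(rseed, "central-split"))
      ccfg <- cfg
      ccfg$epochs <- as.integer(def$rounds * def$local_epochs)
      ccfg$seed <- substream_seed(rseed, "central")
      fit <- train_local(model0, sp$train, ccfg)
      central_acc <- evaluate_bags(fit$model, sp$test)$accuracy
    }
    for (dist in distributions) {
      for (n in n_grid) {
        plan <- if (dist == "iid")
          partition_iid(dat$labels, n, substream_seed(rseed, paste0("part-", dist, n)))
        else
          partition_noniid(dat$labels, n, substream_seed(rseed, paste0("part-", dist, n)))
        clients <- clients_from_plan(dat$bags, plan, def$test_split, rseed)
        pooled_test <- unlist(lapply(clients, `[[`, "test"), recursive = FALSE)
        model0 <- mem_init(def$feature_dim, def$n_units, def$mem_dim,
                           def$hidden_dim, seed = substream_seed(rseed, "init"))
        # without FL: each client trains alone with the same epoch budget;
        # models are scored both on the shared pooled test set (headline,
        # comparable across clients) and on the client's own test split
        local_pool <- local_own <- rep(NA_real_, length(clients))
        for (i in seq_along(clients)) {
          cl <- clients[[i]]
          if (length(cl$train) == 0) next
          lcfg <- cfg
          lcfg$epochs <- as.integer(def$rounds * def$local_epochs)
          lcfg$seed <- substream_seed(rseed, paste0("solo-", dist, n, "-", i))
          fit <- train_local(model0, cl$train, lcfg)
          local_pool[i] <- evaluate_bags(fit$model, pooled_test)$accuracy
          if (length(cl$test) > 0)
            local_own[i] <- evaluate_bags(fit$model, cl$test)$accuracy
        }
        fed <- suppressWarnings(run_federated(
          clients, model0, rounds = def$rounds, local_epochs = def$local_epochs,
          local_cfg = cfg, seed = substream_seed(rseed, paste0("fed-", dist, n)),
          eval_every = def$rounds))
        last <- fed$metrics[fed$metrics$round == max(fed$metrics$round), ]
        raw <- rbind(raw, data.frame(
          replicate = r, distribution = dist, n_clients = n,
          without_fl = mean(local_pool, na.rm = TRUE),
          with_fl = evaluate_bags(fed$model, pooled_test)$accuracy,
          without_fl_own = mean(local_own, na.rm = TRUE),
          with_fl_own = mean(last$accuracy),
          centralized = central_acc))
      }
    }
  }
  agg <- do.call(rbind, lapply(split(raw, list(raw$distribution, raw$n_clients),
                                     drop = TRUE), function(d) {
    data.frame(distribution = d$distribution[1], n_clients = d$n_clients[1],
               without_fl = mean(d$without_fl), without_fl_sd = stats::sd(d$without_fl),
               with_fl = mean(d$with_fl), with_fl_sd = stats::sd(d$with_fl),
               centralized = mean(d$centralized), centralized_sd = stats::sd(d$centralized))
  }))
  agg <- agg[order(agg$distribution, agg$n_clients), ]
  rownames(agg) <- NULL
  attr(agg, "per_replicate") <- raw
  agg
}

#' Experiment series 2: four-hospital federation under differential privacy
#'
#' Builds the hospital cohort (four clients plus a pooled external
#' validation cohort), splits each client 80:20, and trains four model
#' families with matched budgets: non-collaborative (one per client),
#' DP-FL (FedAvg with DP-SGD locally), FL (FedAvg without noise), and
#' combined (one model on the pooled training data). Each family is
#' evaluated on every client's internal test set and on the external cohort,
#' and the DP configurations are priced by the Renyi accountant from the
#' realized pooled training size.
#'
#' @param dp A [dp_config()] for the DP runs.
#' @param delta Accountant target delta.
#' @param rounds,local_epochs Federation schedule.
#' @param lr,batch_size,optimizer Local optimizer settings.
#' @param internal_shift,external_shift Domain-shift magnitudes of the
#'   cohort generator.
#' @param seed Master seed.
#' @param defaults Model/bag settings from [experiment_defaults()].
#' @return List with `results` (data frame: model, dataset type, accuracy),
#'   `privacy` (a `privacy_report`), and `pooled_train_size`.
#' @export
run_series2 <- function(dp = dp_config(1.0, 4.0, 32L), delta = 1e-4,
                        rounds = 30L, local_epochs = 1L, lr = 0.01,
                        batch_size = 32L, optimizer = "sgd",
                        internal_shift = 0.4, external_shift = 1.2,
                        seed = 1L, defaults = experiment_defaults()) {
  def <- defaults
  hs <- hospital_cohort_spec(internal_shift, external_shift,
                             seed = substream_seed(seed, "cohort"))
  bs <- bag_spec(def$bag_size, def$feature_dim, def$signal_fraction,
                 def$class_separation, def$noise_scale, seed = seed)
  cohort <- make_cohort(hs$clients, bs)
  external <- cohort_bags(make_cohort(hs$external, bs))$bags
  clients <- lapply(cohort, function(cl) {
    sp <- split_train_test(cl$bags, def$test_split,
                           substream_seed(seed, paste0("split-", cl$name)))
    list(name = cl$name, train = sp$train, test = sp$test)
  })
  pooled_train <- unlist(lapply(clients, `[[`, "train"), recursive = FALSE)
  n_train <- length(pooled_train)
  privacy <- epsilon_for_run(N = n_train, B = batch_size,
                             epochs = rounds * local_epochs,
                             sigma = dp$noise_multiplier, delta = delta)
  model0 <- mem_init(def$feature_dim, def$n_units, def$mem_dim, def$hidden_dim,
                     seed = substream_seed(seed, "init"))
  base_cfg <- train_config(lr = lr, batch_size = batch_size, epochs = 1L,
                           optimizer = optimizer, dp = NULL, log_metrics = FALSE)
  dp_cfg <- base_cfg; dp_cfg$dp <- dp
  epochs_total <- as.integer(rounds * local_epochs)

  eval_family <- function(model, family) {
    internal <- evaluate_model(model, stats::setNames(
      lapply(clients, `[[`, "test"), vapply(clients, `[[`, character(1), "name")))
    ext <- evaluate_bags(model, external)
    rbind(data.frame(model = family, dataset = internal$table$dataset,
                     type = "test", accuracy = internal$table$accuracy),
          data.frame(model = family, dataset = "external", type = "external",
                     accuracy = ext$accuracy))
  }

  results <- NULL
  for (i in seq_along(clients)) {
    cfg <- base_cfg
    cfg$epochs <- epochs_total
    cfg$seed <- substream_seed(seed, paste0("solo-", i))
    fit <- train_local(model0, clients[[i]]$train, cfg)
    ev_t <- evaluate_bags(fit$model, clients[[i]]$test)
    ev_e <- evaluate_bags(fit$model, external)
    results <- rbind(results,
      data.frame(model = "non_collaborative", dataset = clients[[i]]$name,
                 type = "test", accuracy = ev_t$accuracy),
      data.frame(model = "non_collaborative", dataset = clients[[i]]$name,
                 type = "external", accuracy = ev_e$accuracy))
  }
  fed_dp <- run_federated(clients, model0, rounds, local_epochs, dp_cfg,
                          seed = substream_seed(seed, "dpfl"), eval_every = rounds)
  results <- rbind(results, eval_family(fed_dp$model, "dp_fl"))
  fed <- run_federated(clients, model0, rounds, local_epochs, base_cfg,
                       seed = substream_seed(seed, "fl"), eval_every = rounds)
  results <- rbind(results, eval_family(fed$model, "fl"))
  ccfg <- base_cfg
  ccfg$epochs <- epochs_total
  ccfg$seed <- substream_seed(seed, "combined")
  comb <- train_local(model0, pooled_train, ccfg)
  results <- rbind(results, eval_family(comb$model, "combined"))
  rownames(results) <- NULL
  list(results = results, privacy = privacy, pooled_train_size = n_train)
}

#' Summarize a series-1 results table as aligned text
#'
#' @param tab Data frame from [run_series1()].
#' @return Character vector of report lines (also printed).
#' @export
format_series1 <- function(tab) {
  lines <- c(sprintf("%-12s %4s  %-15s %-15s %-15s",
                     "distribution", "n", "without FL", "with FL", "centralized"),
             vapply(seq_len(nrow(tab)), function(i) {
               fmt <- function(m, s) if (is.na(m)) "-" else sprintf("%.3f +/- %.3f", m, s)
               sprintf("%-12s %4d  %-15s %-15s %-15s", tab$distribution[i],
                       tab$n_clients[i],
                       fmt(tab$without_fl[i], tab$without_fl_sd[i]),
                       fmt(tab$with_fl[i], tab$with_fl_sd[i]),
                       fmt(tab$centralized[i], tab$centralized_sd[i]))
             }, character(1)))
  cat(lines, sep = "\n")
  invisible(lines)
}
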