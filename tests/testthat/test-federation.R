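test_that("IID partitions conserve bags and balance classes", {
  labels <- rep(c(0, 1), each = 4)
  plan <- partition_iid(labels, 4, seed = 3)
  expect_equal(sort(unique(plan$assignment)), 1:4)
  for (i in 1:4) {
    mine <- labels[plan$assignment == i]
    expect_equal(sum(mine == 0), 1)
    expect_equal(sum(mine == 1), 1)
  }
  # single client holds everything
  plan1 <- partition_iid(labels, 1, seed = 3)
  expect_true(all(plan1$assignment == 1))
  expect_error(partition_iid(labels, 9), "more clients")

  # 1806 bags over 4 clients: totals within {451, 452}
  labels1806 <- rep(c(0, 1), each = 903)
  plan <- partition_iid(labels1806, 4, seed = 8)
  sizes <- as.vector(table(plan$assignment))
  expect_equal(sum(sizes), 1806)
  expect_true(all(sizes %in% c(451, 452)))
  # per-class sizes differ by at most one
  for (cl in 0:1) {
    cs <- as.vector(table(plan$assignment[labels1806 == cl]))
    expect_lte(diff(range(cs)), 1)
  }
})

test_that("non-IID partitions conserve bags and track normalized uniforms", {
  labels <- rep(c(0, 1), each = 100)
  plan <- partition_noniid(labels, 3, seed = 5)
  expect_length(plan$assignment, 200)
  expect_equal(sum(plan$counts), 200)
  expect_identical(plan$assignment,
                   partition_noniid(labels, 3, seed = 5)$assignment)
  p1 <- partition_noniid(labels, 1, seed = 2)
  expect_true(all(as.vector(p1$proportions) == 1))

  # expectation oracle: mean realized share of client 1 over many seeds
  # approaches E[u1/(u1+u2)] = 1/2 for iid uniforms
  shares <- vapply(1:500, function(s) {
    pl <- partition_noniid(rep(0, 40), 2, seed = s)
    mean(pl$assignment == 1)
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.5), 0.02)
  # heterogeneity is real: realized shares spread far beyond binomial noise
  expect_gt(sd(shares), 0.15)
})

test_that("FedAvg aggregation equals the brute-force weighted mean", {
  models <- lapply(1:5, function(i) tiny_model(seed = i))
  n_i <- c(10, 3, 7, 1, 9)
  agg <- fedavg_aggregate(models, n_i)
  manual <- Reduce(`+`, Map(function(m, w) w * params_flatten(m),
                            models, n_i / sum(n_i)))
  expect_lt(max(abs(params_flatten(agg) - manual)), 1e-12)

  # idempotence and the simple scalar case
  expect_identical(params_flatten(fedavg_aggregate(models[1], 5)),
                   params_flatten(models[[1]]))
  m0 <- tiny_model(seed = 1); m2 <- tiny_model(seed = 1)
  m0$par <- lapply(m0$par, function(a) { a[] <- 0; a })
  m2$par <- lapply(m2$par, function(a) { a[] <- 2; a })
  half <- fedavg_aggregate(list(m0, m2), c(1, 1))
  expect_true(all(abs(params_flatten(half) - 1) < 1e-15))

  # linearity in the parameters
  scaled <- lapply(models, function(m) params_unflatten(m, 3 * params_flatten(m)))
  expect_equal(params_flatten(fedavg_aggregate(scaled, n_i)),
               3 * params_flatten(agg), tolerance = 1e-12)

  bad <- tiny_model(f = 4)
  expect_error(fedavg_aggregate(list(models[[1]], bad), c(1, 1)), "layout")
})

test_that("80:20 splits are floored and stratified", {
  hs <- hospital_cohort_spec(seed = 1)
  bs <- bag_spec(c(3, 5), 2, 0.5, 1, 1, seed = 1)
  cohort <- make_cohort(hs$clients, bs)
  sizes <- vapply(cohort, function(cl)
    length(split_train_test(cl$bags, 0.8, seed = 2)$train), numeric(1))
  expect_equal(sizes, floor(0.8 * c(267, 211, 207, 199)))
  expect_equal(sum(sizes), 705)
  # class counts in the train split stay proportional
  sp <- split_train_test(cohort[[1]]$bags, 0.8, seed = 2)
  y <- vapply(sp$train, `[[`, numeric(1), "label")
  expect_equal(sum(y == 1), 151)   # floor-with-remainder allocation of 189 LUAD
})

test_that("single-client federation reproduces centralized training exactly", {
  bags <- tiny_bags(10, n = 5, f = 4, seed = 90)
  sp <- split_train_test(bags, 0.8, seed = 1)
  model <- tiny_model(f = 4, seed = 11)
  cfg <- train_config(lr = 0.05, batch_size = 4, epochs = 1,
                      optimizer = "adam", seed = 0, log_metrics = FALSE)
  fed <- run_federated(list(list(train = sp$train, test = sp$test)),
                       model, rounds = 4, local_epochs = 2, local_cfg = cfg,
                       seed = 77)
  ccfg <- cfg
  ccfg$epochs <- 8L
  ccfg$seed <- substream_seed(77, "client-1")
  cen <- train_local(model, sp$train, ccfg)
  expect_identical(params_flatten(fed$model), params_flatten(cen$model))
})

test_that("federation handles empty clients and reports metrics", {
  bags <- separable_bags(40, f = 6, seed = 13)
  sp <- split_train_test(bags, 0.8, seed = 1)
  clients <- list(list(name = "a", train = sp$train[1:16], test = sp$test[1:4]),
                  list(name = "b", train = sp$train[17:32], test = sp$test[5:8]),
                  list(name = "empty", train = list(), test = list()))
  model <- mem_init(6, 2, 2, 4, seed = 4)
  cfg <- train_config(lr = 0.02, batch_size = 8, epochs = 1,
                      optimizer = "sgd", log_metrics = FALSE)
  expect_warning(fed <- run_federated(clients, model, rounds = 3,
                                      local_epochs = 1, local_cfg = cfg,
                                      seed = 5), "zero training bags")
  expect_equal(sort(unique(fed$metrics$client)), c("a", "b"))
  expect_equal(max(fed$metrics$round), 3)
  expect_equal(fed$weights, c(16, 16, 0))
})

test_that("evaluation reports per-dataset accuracy with mean and sd", {
  m <- tiny_model(f = 3)
  m$par[["head.W"]][] <- 0; m$par[["head.b"]] <- c(1, 0)  # constant class 0
  bags <- tiny_bags(8, n = 4, f = 3, seed = 31)           # balanced labels
  ev <- evaluate_model(m, list(all = bags))
  expect_equal(ev$mean, 0.5)
  expect_equal(ev$sd, 0)
  ev2 <- evaluate_model(m, list(a = bags[1:4], b = bags))
  expect_equal(nrow(ev2$table), 2)
  expect_equal(ev2$mean, mean(ev2$table$accuracy))

  # mean of explicit accuracies sanity
  expect_equal(mean(c(0.8, 0.9)), 0.85)
})

test_that("partition plans serialize to CSV", {
  labels <- rep(c(0, 1), 10)
  plan <- partition_noniid(labels, 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition_plan(plan, path)
  back <- read.csv(path)
  expect_equal(names(back), c("bag_id", "client", "class"))
  expect_equal(back$client, plan$assignment)
})
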