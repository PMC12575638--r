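test_that("the global-pull coefficient matches its closed form and is strictly decreasing", {
  expect_equal(mixing_coefficient(0.5), 0.5)
  expect_equal(mixing_coefficient(0.2), 2.0)
  expect_lt(mixing_coefficient(0.999), 1e-3)  # pure local focus
  lam <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(mixing_coefficient(lam)) < 0))
  expect_error(mixing_coefficient(1), "strictly inside")
  expect_error(mixing_coefficient(0), "strictly inside")
  expect_error(fil_config(lambda = 1), "strictly inside")
})

test_that("one personalized-model step with zero data gradient contracts toward the global model", {
  # two samples with the same x and opposite labels cancel the data gradient
  # at v = 0, so the first step is v' = -eta * q * (v - w) exactly
  X <- rbind(c(1, 2), c(1, 2))
  y <- c(0L, 1L)
  m <- 2L; C <- 2L
  v <- ppfil:::linear_model_init(m, C)
  w <- rep(0.5, length(v))
  cfg <- fil_config(lambda = 0.5, lr = 0.1, pim_iters = 1L)
  out <- pim_update(v, w, X, y, C, cfg)
  q <- mixing_coefficient(0.5)
  expect_equal(out$pim, v - 0.1 * q * (v - w), tolerance = 1e-12)
  expect_true(all(abs(out$pim - w) < abs(v - w)))  # strictly closer

  # fixed point: v = w and zero data gradient leaves v unchanged
  out2 <- pim_update(w, w, X, y, C, cfg)
  expect_equal(out2$pim, w, tolerance = 1e-12)
})

test_that("lambda near one reduces the personalized update to plain local descent", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(0:1, 5)
  v <- rnorm(6, sd = 0.1)
  w <- rnorm(6)
  cfg <- fil_config(lambda = 1 - 1e-9, lr = 0.01, pim_iters = 3L)
  out <- pim_update(v, w, X, y, 2L, cfg)
  # manual heavy-ball descent on the summed data gradient only
  vm <- v; vel <- numeric(6)
  for (p in 1:3) {
    g <- ppfil:::linear_grad(vm, X, y, 2L, reduce = "sum")
    vel <- 0.9 * vel - 0.01 * g
    vm <- vm + vel
  }
  expect_equal(out$pim, vm, tolerance = 1e-6)
})

test_that("per-sample gradient norms match a central-difference oracle", {
  set.seed(2)
  X <- matrix(rnorm(6), 3, 2)
  y <- c(0L, 1L, 0L)
  theta <- rnorm(6, sd = 0.3)
  for (i in 1:3) {
    G <- sample_gradient_norm(theta, X[i, ], y[i], 2L)
    num <- vapply(seq_along(theta), function(j) {
      h <- 1e-5
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (ppfil:::linear_loss(tp, X[i, , drop = FALSE], y[i], 2L) -
         ppfil:::linear_loss(tm, X[i, , drop = FALSE], y[i], 2L)) / (2 * h)
    }, 0)
    expect_equal(G, sum(num^2), tolerance = 1e-4 * max(1, sum(num^2)))
  }
  # squared-norm homogeneity: doubling the residual quadruples the norm is
  # covered by the closed form; at least assert nonnegativity
  expect_gte(sample_gradient_norm(theta, X[1, ], y[1], 2L), 0)
})

test_that("importance accumulation weights early iterations harmonically", {
  expect_equal(accumulate_importance(c(4, 2, 1)), 4 + 1 + 1 / 3)
  expect_equal(accumulate_importance(rep(0, 5)), 0)
  expect_equal(accumulate_importance(7), 7)
  expect_error(accumulate_importance(numeric(0)), "empty")
})

test_that("cache selection keeps the top-M with recency-then-index tie-breaks", {
  expect_equal(select_cache(c(5, 1, 3), 2), c(1L, 3L))
  expect_equal(select_cache(c(5, 1, 3), 10), 1:3)       # no eviction
  expect_equal(select_cache(c(2, 4, 4, 1), 2), c(2L, 3L))
  # tie at the cut: the more recent (larger index) sample wins
  expect_equal(select_cache(c(3, 3, 3), 2), c(2L, 3L))
})

test_that("local training is deterministic, inert at zero rate, and descends on convex data", {
  d <- make_normalized_dataset(n = 120, m = 4, k = 2, seed = 3)
  theta <- ppfil:::linear_model_init(4, 2)
  cfg0 <- fil_config(lr = 0)
  expect_identical(local_train(theta, d$features, d$labels, 2L, cfg0, seed = 1),
                   theta)
  cfg <- fil_config(lr = 0.05, momentum = 0, batch_size = 1000L,
                    local_epochs = 1L)
  losses <- numeric(10)
  th <- theta
  for (e in 1:10) {
    th <- local_train(th, d$features, d$labels, 2L, cfg, seed = e)
    losses[e] <- ppfil:::linear_loss(th, d$features, d$labels, 2L)
  }
  expect_true(all(diff(losses) <= 1e-10))  # full-batch descent on convex loss
  th1 <- local_train(theta, d$features, d$labels, 2L, cfg, seed = 42)
  th2 <- local_train(theta, d$features, d$labels, 2L, cfg, seed = 42)
  expect_identical(th1, th2)
})

test_that("replay caches respect capacity and match an independent importance recomputation", {
  d <- make_normalized_dataset(n = 80, m = 4, k = 2, seed = 4)
  cfg <- fil_config(cache_size = 10L, pim_iters = 5L)
  cl <- ppfil:::client_state("c1", 4, 2)
  global <- ppfil:::linear_model_init(4, 2)
  cl <- ppfil:::client_receive_task(cl, global, d$features, d$labels, 2L, cfg)
  expect_lte(length(cl$cache_y), 10L)
  # recompute Eq-style importances independently: rerun the PIM trajectory
  upd <- pim_update(global, global, d$features, d$labels, 2L, cfg)
  imp <- apply(upd$norms, 2L, function(g) sum(g / seq_along(g)))
  keep <- select_cache(imp, 10L)
  expect_equal(sort(cl$cache_importance), sort(imp[keep]), tolerance = 1e-8)
})

test_that("a single-client round reproduces that client's local model and equals are aggregated to themselves", {
  d <- make_normalized_dataset(n = 100, m = 4, k = 2, seed = 5)
  cfg <- fil_config(rounds = 1L)
  global <- ppfil:::linear_model_init(4, 2)
  cl <- ppfil:::client_state("c1", 4, 2)
  cl <- ppfil:::client_receive_task(cl, global, d$features, d$labels, 2L, cfg)
  res <- global_round(list(cl), global, 2L, cfg, seed = 7)
  expect_equal(res$global, res$clients[[1]]$local, tolerance = 1e-12)
  expect_false(res$aborted)

  # identical clients: the aggregate equals the shared local result
  cls <- lapply(1:3, function(k) { c2 <- cl; c2$id <- paste0("c", k); c2 })
  res3 <- global_round(cls, global, 2L, cfg, seed = 7)
  # all clients trained identically? seeds differ per client, so instead
  # check the aggregate lies coordinate-wise within the locals' range
  locals <- vapply(res3$clients, `[[`, numeric(10), "local")
  expect_true(all(res3$global >= apply(locals, 1, min) - 1e-12 &
                    res3$global <= apply(locals, 1, max) + 1e-12))
})

test_that("parameter length is conserved through a federated round", {
  d <- make_normalized_dataset(n = 120, m = 5, k = 2, seed = 6)
  part <- partition_clients(d, 3, "iid", seed = 1)
  cfg <- fil_config(rounds = 1L)
  global <- ppfil:::linear_model_init(5, 2)
  clients <- lapply(1:3, function(k) {
    cl <- ppfil:::client_state(paste0("c", k), 5, 2)
    idx <- part$indices[[k]]
    ppfil:::client_receive_task(cl, global, d$features[idx, , drop = FALSE],
                                d$labels[idx], 2L, cfg)
  })
  res <- global_round(clients, global, 2L, cfg, seed = 3)
  expect_length(res$global, length(global))
  for (u in res$updates) expect_length(u$params, length(global))
})
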