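test_that("min-max parameters read off per-feature extremes and flag degenerate columns", {
  d <- tabular_dataset(cbind(a = c(2, 4, 6), b = c(5, 5, 5)), c(0, 1, 0))
  p <- fit_minmax(d)
  expect_equal(unname(p$min), c(2, 5))
  expect_equal(unname(p$max), c(6, 5))
  expect_equal(unname(p$degenerate), c(FALSE, TRUE))

  d2 <- tabular_dataset(cbind(c(0, 1), c(10, 20)), c(0, 1))
  p2 <- fit_minmax(d2)
  expect_equal(unname(p2$min), c(0, 10))
  expect_equal(unname(p2$max), c(1, 20))
})

test_that("min-max transform maps endpoints, zeroes degenerate columns, clips test values", {
  train <- tabular_dataset(cbind(a = c(2, 4, 6), b = c(5, 5, 5)), c(0, 1, 0))
  p <- fit_minmax(train)
  out <- apply_minmax(train, p)
  expect_equal(unname(out$features[, 1]), c(0, 0.5, 1))
  expect_equal(unname(out$features[, 2]), c(0, 0, 0))

  test <- tabular_dataset(cbind(a = c(8, 1), b = c(7, 7)), c(0, 1))
  ot <- apply_minmax(test, p)
  expect_equal(unname(ot$features[, 1]), c(1, 0))  # clipped both sides

  # normalizing already-normalized data with parameters refit on it is the
  # identity (the bounds are then exactly [0, 1])
  p_norm <- fit_minmax(out)
  expect_equal(apply_minmax(out, p_norm)$features, out$features)

  bad <- tabular_dataset(cbind(1:3), c(0, 1, 0))
  expect_error(apply_minmax(bad, p), "arity")
})

test_that("dataset construction rejects missing values and label mismatches", {
  expect_error(tabular_dataset(cbind(c(1, NA)), c(0, 1)), "missing")
  expect_error(tabular_dataset(cbind(1:3), c(0, 1)), "labels")
  expect_error(tabular_dataset(cbind(1:2), c(0, 0)), "two classes")
})

test_that("synthetic generation is seed-deterministic and honours the null effect", {
  sp <- synthetic_spec(100, 6, 2, effect_size = 1.5, seed = 7)
  d1 <- generate_synthetic_tabular(sp)
  d2 <- generate_synthetic_tabular(sp)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$labels, d2$labels)

  sp0 <- synthetic_spec(4000, 6, 2, effect_size = 0, seed = 3)
  d0 <- generate_synthetic_tabular(sp0)
  # no class signal: per-class means of the "informative" columns agree
  m0 <- colMeans(d0$features[d0$labels == 0, 1:2])
  m1 <- colMeans(d0$features[d0$labels == 1, 1:2])
  expect_lt(max(abs(m0 - m1)), 0.15)
})

test_that("informative features carry the specified standardized mean separation", {
  # Monte-Carlo check of the generator's stated moments
  sp <- synthetic_spec(600, 20, 5, effect_size = 1.5, seed = 11)
  d <- generate_synthetic_tabular(sp)
  for (j in 1:5) {
    x0 <- d$features[d$labels == 0, j]
    x1 <- d$features[d$labels == 1, j]
    smd <- (mean(x1) - mean(x0)) / 1  # noise_sd = 1
    se <- sqrt(1 / length(x0) + 1 / length(x1))
    expect_lt(abs(smd - 1.5), 3 * se)
  }
})

test_that("synthetic spec validates its counts and proportions", {
  expect_error(synthetic_spec(10, 3, 5), "exceed")
  expect_error(synthetic_spec(10, 3, 1, effect_size = -1), "effect_size")
  expect_error(synthetic_spec(10, 3, 1, label_balance = c(0.5, 0.2)),
               "summing to 1")
})

test_that("class-incremental task streams introduce disjoint label groups covering the label set", {
  base <- synthetic_spec(400, 6, 4, effect_size = 1, class_count = 4, seed = 2)
  ts <- generate_task_stream(base, 2, mode = "class")
  l1 <- sort(unique(ts$tasks[[1]]$labels))
  l2 <- sort(unique(ts$tasks[[2]]$labels))
  expect_equal(l1, c(0L, 1L))
  expect_equal(l2, c(2L, 3L))
  expect_length(intersect(l1, l2), 0)
  expect_equal(sort(union(l1, l2)), 0:3)
  expect_error(generate_task_stream(base, 5, mode = "class"), "class per task")
})

test_that("domain-incremental streams shift means and a zero shift gives replicates", {
  base <- synthetic_spec(2000, 4, 2, effect_size = 0, seed = 5)
  ts0 <- generate_task_stream(base, 2, mode = "domain", shift = 0)
  expect_equal(mean(ts0$tasks[[1]]$features), mean(ts0$tasks[[2]]$features),
               tolerance = 0.1)
  ts <- generate_task_stream(base, 2, mode = "domain", shift = 1)
  expect_equal(mean(ts$tasks[[2]]$features) - mean(ts$tasks[[1]]$features), 1,
               tolerance = 0.1)
})

test_that("client partitions are disjoint, conserving, and scheme-faithful", {
  d <- generate_synthetic_tabular(synthetic_spec(100, 4, 2, seed = 1))
  p <- partition_clients(d, 4, "iid", seed = 3)
  expect_equal(sort(unlist(p$indices)), 1:100)
  expect_equal(lengths(p$indices), rep(25L, 4))

  # 10% per-class quota with 10 clients and 200 per class
  d2 <- tabular_dataset(matrix(rnorm(400 * 3), 400, 3), rep(0:1, each = 200))
  q <- partition_clients(d2, 10, "per_class_quota", seed = 4)
  for (idx in q$indices) {
    expect_equal(sum(d2$labels[idx] == 0), 20L)
    expect_equal(sum(d2$labels[idx] == 1), 20L)
  }
  expect_length(unique(unlist(q$indices)), 400)
})

test_that("dirichlet partitioning approaches global class proportions as alpha grows", {
  d <- tabular_dataset(matrix(rnorm(2000 * 2), 2000, 2),
                       rep(0:1, c(1200, 800)))
  p <- partition_clients(d, 4, "dirichlet", alpha = 1e4, seed = 9)
  for (idx in p$indices) {
    expect_equal(mean(d$labels[idx] == 0), 0.6, tolerance = 0.08)
  }
  # small alpha produces visible label skew for at least one client
  ps <- partition_clients(d, 4, "dirichlet", alpha = 0.2, seed = 9)
  props <- vapply(ps$indices, function(i) mean(d$labels[i] == 0), 0)
  expect_gt(max(abs(props - 0.6), na.rm = TRUE), 0.15)
})

test_that("CSV round trip preserves values and labels", {
  d <- generate_synthetic_tabular(synthetic_spec(50, 5, 2, seed = 6))
  path <- tempfile(fileext = ".csv")
  write_tabular_csv(d, path)
  back <- read_tabular_csv(path)
  expect_equal(back$features, d$features, tolerance = 1e-12)
  expect_identical(back$labels, d$labels)
  unlink(path)
})

test_that("stratified split keeps class proportions and the 80/20 default", {
  d <- generate_synthetic_tabular(synthetic_spec(500, 4, 2, seed = 8))
  sp <- split_train_test(d, seed = 2)
  expect_equal(nrow(sp$test$features), round(0.2 * 500), tolerance = 2)
  expect_equal(mean(sp$train$labels), mean(d$labels), tolerance = 0.05)
  expect_equal(nrow(sp$train$features) + nrow(sp$test$features), 500L)
})
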