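#' Configure an end-to-end experiment
#'
#' Bundles every stage of the pipeline: synthetic data (or a loaded
#' dataset), the train/test split, wrapper feature selection, client
#' partitioning, the federated incremental rounds with privacy, attacks,
#' robust filtering and ledger gating, and the final classifier.
#'
#' @param data_spec A [synthetic_spec()] describing the data, or a
#'   [tabular_dataset()] to use directly.
#' @param n_clients Number of simulated clients (default 10).
#' @param partition_scheme Client partition scheme (see
#'   [partition_clients()]).
#' @param partition_alpha Dirichlet concentration when applicable.
#' @param test_fraction Held-out test fraction (default 0.2, i.e. the
#'   80/20 split).
#' @param val_fraction Fraction of the training split held by the server
#'   for validation gating and update accuracies (default 0.1).
#' @param n_tasks Tasks per client (1 = plain federated learning; > 1
#'   streams class-incremental tasks).
#' @param fil A [fil_config()].
#' @param use_cboa Run CBOA feature selection before federated training.
#' @param cboa A [cboa_config()] (used when `use_cboa`).
#' @param use_edbn Train the entropy DBN on the selected features as the
#'   final classifier; otherwise the aggregated linear model is evaluated.
#' @param edbn_grid Candidate hidden widths for the EDBN structure search.
#' @param edbn_epochs,edbn_finetune_epochs EDBN pre-training/fine-tuning
#'   epochs.
#' @param privacy Optional [privacy_config()].
#' @param attack Optional [attack_config()].
#' @param filter_c Robust-filter multiplier (`NULL` disables the filter).
#' @param weighting `"xai"` (accuracy times attribution alignment) or
#'   `"samples"` (plain federated averaging by sample count).
#' @param cache_selection `"importance"` (gradient-norm replay selection)
#'   or `"random"` (uniform baseline).
#' @param ledger_tolerance Accuracy-gate tolerance for block admission.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(data_spec = synthetic_spec(600, 12, 4,
                                                         effect_size = 2),
                              n_clients = 10L,
                              partition_scheme = "iid",
                              partition_alpha = 0.5,
                              test_fraction = 0.2, val_fraction = 0.1,
                              n_tasks = 1L,
                              fil = fil_config(),
                              use_cboa = FALSE, cboa = cboa_config(),
                              use_edbn = FALSE,
                              edbn_grid = c(6L, 8L, 10L, 12L),
                              edbn_epochs = 5L,
                              edbn_finetune_epochs = 300L,
                              privacy = NULL, attack = NULL, filter_c = 3,
                              weighting = c("xai", "samples"),
                              cache_selection = c("importance", "random"),
                              ledger_tolerance = 0.01, seed = 1L) {
  weighting <- match.arg(weighting)
  cache_selection <- match.arg(cache_selection)
  structure(
    list(data_spec = data_spec, n_clients = as.integer(n_clients),
         partition_scheme = partition_scheme,
         partition_alpha = partition_alpha,
         test_fraction = test_fraction, val_fraction = val_fraction,
         n_tasks = as.integer(n_tasks), fil = fil,
         use_cboa = use_cboa, cboa = cboa,
         use_edbn = use_edbn, edbn_grid = edbn_grid,
         edbn_epochs = as.integer(edbn_epochs),
         edbn_finetune_epochs = as.integer(edbn_finetune_epochs),
         privacy = privacy, attack = attack, filter_c = filter_c,
         weighting = weighting, cache_selection = cache_selection,
         ledger_tolerance = ledger_tolerance, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run an end-to-end experiment
#'
#' Pipeline: generate or take the dataset, split 80/20 stratified,
#' min-max-normalize on the training statistics, optionally select features
#' with CBOA, partition the training data across clients, stream the task
#' sequence through federated incremental rounds (replay caching, local
#' training, privacy perturbation, attack injection, robust filtering,
#' weighted aggregation, ledger admission), then evaluate the final
#' classifier on the held-out test split. Deterministic under `seed`.
#'
#' @param config An [experiment_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An `experiment_report`: classification metrics of the final
#'   classifier, the global linear model's test accuracy, per-round trace,
#'   the ledger, the selected feature mask, simulated latency/throughput
#'   counters, and per-task test accuracies for incremental streams.
#' @export
run_experiment <- function(config = experiment_config(), seed = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seeds <- derive_seeds(config$seed, 10L)

  ## data
  data <- if (inherits(config$data_spec, "tabular_dataset")) {
    config$data_spec
  } else {
    sp <- config$data_spec
    sp$seed <- seeds[1L]
    generate_synthetic_tabular(sp)
  }
  sp <- split_train_test(data, config$test_fraction, seeds[2L])
  nrm <- fit_minmax(sp$train)
  train <- apply_minmax(sp$train, nrm)
  test <- apply_minmax(sp$test, nrm)

  ## feature selection
  if (config$use_cboa) {
    cb <- config$cboa
    cb$seed <- seeds[3L]
    sel <- run_cboa(train, cb)
    mask <- sel$best_mask
  } else {
    sel <- NULL
    mask <- rep(TRUE, ncol(train$features))
  }
  train$features <- train$features[, mask, drop = FALSE]
  test$features <- test$features[, mask, drop = FALSE]
  train$feature_names <- train$feature_names[mask]
  test$feature_names <- test$feature_names[mask]

  ## server validation split
  vsp <- split_train_test(train, config$val_fraction, seeds[4L])
  train <- vsp$train
  val <- vsp$test

  ## clients and tasks
  part <- partition_clients(train, config$n_clients, config$partition_scheme,
                            alpha = config$partition_alpha, seed = seeds[5L])
  C <- data$n_classes
  m <- ncol(train$features)
  ids <- sprintf("client%02d", seq_len(config$n_clients))
  clients <- lapply(seq_len(config$n_clients), function(k) {
    client_state(ids[k], m, C)
  })
  task_groups <- if (config$n_tasks > 1L) {
    split(0:(C - 1L), cut(seq_len(C), config$n_tasks, labels = FALSE))
  } else {
    list(0:(C - 1L))
  }
  attackers <- if (!is.null(config$attack)) {
    attacker_ids(ids, config$attack$fraction)
  } else character(0)

  global <- linear_model_init(m, C)
  ledger <- ledger_create(
    list(model_digest = sha256_hex(global), note = "model initialization"),
    config$ledger_tolerance)
  rounds_per_task <- max(1L, config$fil$rounds %/% config$n_tasks)
  trace <- list()
  round_id <- 0L
  task_seeds <- derive_seeds(seeds[6L], config$n_tasks * config$n_clients +
                               config$fil$rounds + 2L)
  si <- 0L

  for (task in seq_along(task_groups)) {
    keep_lbl <- task_groups[[task]]
    for (k in seq_len(config$n_clients)) {
      si <- si + 1L
      idx <- part$indices[[k]]
      idx <- idx[train$labels[idx] %in% keep_lbl]
      X <- train$features[idx, , drop = FALSE]
      y <- train$labels[idx]
      if (ids[k] %in% attackers && !is.null(config$attack) &&
          config$attack$tag == "label_flip") {
        y <- flip_labels(y, config$attack$flip_fraction, C, task_seeds[si])
      }
      if (length(y) > 0L) {
        clients[[k]] <- client_receive_task(
          clients[[k]], global, X, y, C, config$fil,
          selection = config$cache_selection, seed = task_seeds[si])
      }
    }
    active <- which(vapply(clients, function(cl) !is.null(cl$task_X), TRUE))
    for (r in seq_len(rounds_per_task)) {
      round_id <- round_id + 1L
      si <- si + 1L
      res <- global_round(clients[active], global, C, config$fil,
                          privacy = config$privacy,
                          filter_c = config$filter_c,
                          attack = config$attack,
                          val_X = val$features, val_y = val$labels,
                          seed = task_seeds[si])
      clients[active] <- res$clients
      if (config$weighting == "samples" && !res$aborted) {
        # plain federated averaging: reweight the kept updates by samples
        kept <- Filter(function(u) u$id %in% res$kept, res$updates)
        w <- vapply(kept, `[[`, 0L, "n_samples")
        res$global <- aggregate_updates(kept, w)
      }
      val_acc <- mean(linear_predict(res$global, val$features, C) ==
                        val$labels)
      adm <- append_block(
        ledger,
        list(model_digest = sha256_hex(res$global), round = round_id,
             task = task, val_accuracy = val_acc,
             kept = as.list(res$kept), excluded = as.list(res$excluded)),
        val_acc, timestamp = round_id)
      ledger <- adm$ledger
      if (!res$aborted && adm$admitted) global <- res$global
      trace[[round_id]] <- data.frame(
        round = round_id, task = task, val_accuracy = val_acc,
        admitted = adm$admitted, aborted = res$aborted,
        n_kept = length(res$kept), n_excluded = length(res$excluded))
    }
  }

  ## per-task test accuracy of the global model (incremental diagnostics)
  task_accuracy <- vapply(task_groups, function(g) {
    idx <- test$labels %in% g
    if (!any(idx)) return(NA_real_)
    mean(linear_predict(global, test$features[idx, , drop = FALSE], C) ==
           test$labels[idx])
  }, 0)
  global_acc <- mean(linear_predict(global, test$features, C) == test$labels)

  ## final classifier
  if (config$use_edbn) {
    model <- search_structure(train$features, config$edbn_grid,
                              depth = min(3L, length(config$edbn_grid)),
                              epochs = config$edbn_epochs, pad_grid = TRUE,
                              seed = seeds[7L])
    fit <- finetune_and_predict(model, train, test,
                                epochs = config$edbn_finetune_epochs,
                                seed = seeds[8L])
    pred <- fit$predictions
    final_loss <- fit$loss
  } else {
    pred <- linear_predict(global, test$features, C)
    final_loss <- linear_loss(global, test$features, test$labels, C)
  }
  metrics <- classification_metrics(confusion_counts(test$labels, pred, C))
  metrics$cross_entropy <- final_loss
  counters <- simulated_latency_throughput(round_id, max(1L, round_id),
                                           length(ledger$blocks) - 1L)

  structure(
    list(metrics = metrics, global_accuracy = global_acc,
         task_accuracy = task_accuracy,
         trace = do.call(rbind, trace), ledger = ledger,
         selected = mask, cboa = sel, counters = counters,
         config = config, seed = config$seed),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<experiment_report> accuracy %.2f%% (precision %.2f%%, recall %.2f%%, ",
    "F %.2f%%)\n  global linear model: %.2f%% | ledger: %d blocks | ",
    "features: %d/%d\n"),
    x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
    x$metrics$f_measure, 100 * x$global_accuracy, length(x$ledger$blocks),
    sum(x$selected), length(x$selected)))
  invisible(x)
}

#' Sweep the privacy level
#'
#' Reruns the experiment at each noise multiplier over several seeds and
#' reports the mean final global accuracy, tracing the privacy/utility
#' trade-off of the perturbation mechanism itself. The sweep runs on the
#' plain federated path — sample-count weighting, no robust filter, no
#' accuracy-gated admission — because those defenses actively repair noise
#' damage and would mask the cost being measured.
#'
#' @param config Base [experiment_config()].
#' @param multipliers Noise multipliers to sweep.
#' @param seeds Integer vector of seeds.
#' @param clip Clipping norm for the per-round update deltas; the default
#'   sits an order of magnitude above the median per-round local update
#'   norm on the standard cohort, so clipping never distorts honest
#'   updates and the multiplier range spans mild to dominating noise.
#' @return Data frame with `multiplier` and mean `accuracy` (percent).
#' @export
privacy_sweep <- function(config = experiment_config(),
                          multipliers = c(0, 0.5, 1, 2, 4),
                          seeds = 1:10, clip = 0.05) {
  config$weighting <- "samples"
  config$filter_c <- NULL
  config$ledger_tolerance <- 1
  acc <- vapply(multipliers, function(mult) {
    runs <- vapply(seeds, function(s) {
      cfg <- config
      cfg$privacy <- privacy_config(multiplier = mult, clip = clip)
      run_experiment(cfg, seed = s)$global_accuracy
    }, 0)
    mean(runs)
  }, 0)
  data.frame(multiplier = multipliers, accuracy = 100 * acc)
}

#' Compare attack mitigation with and without robust filtering
#'
#' Runs attack-free, attacked-filtered and attacked-unfiltered pipelines
#' over several seeds (sample-count weighting in every arm, isolating the
#' filter) and reports the mean accuracy drops.
#'
#' @param config Base [experiment_config()].
#' @param attack An [attack_config()].
#' @param seeds Integer vector of seeds.
#' @return List with mean accuracies `clean`, `filtered`, `unfiltered` and
#'   the drops `drop_filtered`, `drop_unfiltered` (percentage points).
#' @export
attack_mitigation <- function(config = experiment_config(),
                              attack = attack_config("label_flip",
                                                     fraction = 0.2),
                              seeds = 1:10) {
  config$weighting <- "samples"
  run_arm <- function(att, fc) {
    vapply(seeds, function(s) {
      cfg <- config
      cfg$attack <- att
      cfg$filter_c <- fc
      run_experiment(cfg, seed = s)$global_accuracy
    }, 0)
  }
  clean <- mean(run_arm(NULL, config$filter_c))
  filtered <- mean(run_arm(attack, if (is.null(config$filter_c)) 3 else
    config$filter_c))
  unfiltered <- mean(run_arm(attack, NULL))
  list(clean = 100 * clean, filtered = 100 * filtered,
       unfiltered = 100 * unfiltered,
       drop_filtered = 100 * (clean - filtered),
       drop_unfiltered = 100 * (clean - unfiltered))
}
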