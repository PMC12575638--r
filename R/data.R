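#' Construct a tabular classification dataset
#'
#' The common substrate for every stage of the pipeline: a numeric feature
#' matrix plus integer class labels coded `0..C-1` (label `1` is the positive
#' class for binary clinical data, e.g. disease present).
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer vector of class labels in `0..n_classes-1`.
#' @param feature_names Character vector of column names; defaults to the
#'   matrix column names or `f1..fm`.
#' @param n_classes Number of classes `C >= 2`. Defaults to `max(labels) + 1`
#'   so that class-incremental task slices keep the global label space.
#' @return An object of class `tabular_dataset` with fields `features`,
#'   `labels`, `feature_names`, `n_classes` and (after [fit_minmax()])
#'   `bounds`.
#' @export
tabular_dataset <- function(features, labels, feature_names = NULL,
                            n_classes = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("`labels` length must equal the number of feature rows", call. = FALSE)
  }
  if (nrow(features) == 0L) stop("dataset has no samples", call. = FALSE)
  if (anyNA(features) || any(!is.finite(features))) {
    stop("`features` contains missing or non-finite values", call. = FALSE)
  }
  if (anyNA(labels) || any(labels < 0L)) {
    stop("`labels` must be non-negative integers", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- paste0("f", seq_len(ncol(features)))
    }
  }
  if (length(feature_names) != ncol(features)) {
    stop("`feature_names` length must equal the number of columns", call. = FALSE)
  }
  colnames(features) <- feature_names
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least two classes", call. = FALSE)
  if (any(labels >= n_classes)) {
    stop("labels exceed `n_classes` - 1", call. = FALSE)
  }
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, n_classes = n_classes,
         bounds = NULL),
    class = "tabular_dataset"
  )
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d samples x %d features, %d classes%s\n",
              nrow(x$features), ncol(x$features), x$n_classes,
              if (is.null(x$bounds)) "" else ", normalized"))
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$features)

# subset a dataset by row index, keeping the global label space
dataset_slice <- function(data, idx) {
  out <- tabular_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                         data$feature_names, data$n_classes)
  out$bounds <- data$bounds
  out
}

#' Fit per-feature min-max normalization parameters
#'
#' Records the per-feature minimum and maximum of a reference (training)
#' split. Parameters are always fitted on training data only and then applied
#' to any split with [apply_minmax()], so no test information leaks into the
#' scaling.
#'
#' @param train A [tabular_dataset()].
#' @return A `minmax_params` object: list with numeric vectors `min`, `max`,
#'   logical `degenerate` flagging constant columns, and `feature_names`.
#' @export
fit_minmax <- function(train) {
  stopifnot(inherits(train, "tabular_dataset"))
  if (nrow(train$features) == 0L) stop("no data to fit", call. = FALSE)
  mins <- apply(train$features, 2L, min)
  maxs <- apply(train$features, 2L, max)
  structure(
    list(min = mins, max = maxs, degenerate = maxs == mins,
         feature_names = train$feature_names),
    class = "minmax_params"
  )
}

#' Apply min-max normalization
#'
#' Linearly rescales each feature, `x' = (x - min) / (max - min)`, using
#' parameters fitted on the training split. Values outside the training range
#' are clipped to `[0, 1]`; constant (degenerate) training columns map to 0.
#' The transform is idempotent given the clipping.
#'
#' @param data A [tabular_dataset()].
#' @param params A `minmax_params` object from [fit_minmax()].
#' @return The dataset with features in `[0, 1]` and `bounds` recorded.
#' @export
apply_minmax <- function(data, params) {
  stopifnot(inherits(data, "tabular_dataset"), inherits(params, "minmax_params"))
  if (ncol(data$features) != length(params$min)) {
    stop("feature arity does not match the fitted parameters", call. = FALSE)
  }
  rng <- params$max - params$min
  rng[params$degenerate] <- 1  # avoid 0/0; numerator forced to 0 below
  scaled <- sweep(data$features, 2L, params$min, "-")
  scaled[, params$degenerate] <- 0
  scaled <- sweep(scaled, 2L, rng, "/")
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  out <- tabular_dataset(scaled, data$labels, data$feature_names, data$n_classes)
  out$bounds <- params
  out
}

#' Specify a synthetic clinical-style tabular dataset
#'
#' Emulates small mixed continuous/ordinal clinical tables (blood pressure,
#' cholesterol, chest-pain type, ...): `k_informative` of the `m_features`
#' columns carry a class-conditional location shift of `effect_size` standard
#' deviations; the rest are pure noise, a fraction of which are ordinal
#' (small integer levels) to mimic coded clinical attributes.
#'
#' @param n_samples,m_features,k_informative Counts; `k_informative <=
#'   m_features`.
#' @param effect_size Standardized class-conditional mean separation on each
#'   informative feature (>= 0).
#' @param class_count Number of classes (default 2).
#' @param label_balance Class proportion vector summing to 1; default uniform.
#' @param noise_sd Within-class standard deviation of continuous features.
#' @param ordinal_fraction Fraction of the *noise* features generated as
#'   integer-coded ordinal columns (default 1/3).
#' @param seed Integer seed; generation is bitwise deterministic under it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples, m_features, k_informative,
                           effect_size = 1, class_count = 2L,
                           label_balance = NULL, noise_sd = 1,
                           ordinal_fraction = 1 / 3, seed = 1L) {
  if (k_informative > m_features) {
    stop("`k_informative` cannot exceed `m_features`", call. = FALSE)
  }
  if (n_samples < 1L || m_features < 1L || k_informative < 0L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (is.null(label_balance)) label_balance <- rep(1 / class_count, class_count)
  if (length(label_balance) != class_count ||
      abs(sum(label_balance) - 1) > 1e-8) {
    stop("`label_balance` must have `class_count` entries summing to 1",
         call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), m_features = as.integer(m_features),
         k_informative = as.integer(k_informative), effect_size = effect_size,
         class_count = as.integer(class_count), label_balance = label_balance,
         noise_sd = noise_sd, ordinal_fraction = ordinal_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# class-by-feature {0,1} shift pattern: binary code of the class index cycled
# over informative features, so any two classes differ on at least one column
class_shift_pattern <- function(class_count, k_informative) {
  if (k_informative == 0L) return(matrix(0, class_count, 0L))
  if (class_count == 2L) {
    # binary case: class 1 shifted on every informative feature
    return(matrix(rep(c(0, 1), k_informative), nrow = 2L))
  }
  bits <- max(1L, ceiling(log2(class_count)))
  H <- matrix(0, class_count, k_informative)
  for (j in seq_len(k_informative)) {
    bit <- (j - 1L) %% bits
    H[, j] <- (seq_len(class_count) - 1L) %/% 2^bit %% 2L
  }
  H
}

#' Generate a synthetic tabular dataset
#'
#' Draws labels from `label_balance`, then informative features
#' class-conditionally as `N(shift, noise_sd^2)` with mean separation
#' `effect_size * noise_sd` between shifted and unshifted classes, and the
#' remaining features as pure noise (a fraction of them ordinal-coded).
#'
#' @param spec A [synthetic_spec()].
#' @return A [tabular_dataset()]; the informative columns are the first
#'   `k_informative`, also recorded in `attr(, "informative")`.
#' @export
generate_synthetic_tabular <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_samples
    m <- spec$m_features
    k <- spec$k_informative
    y <- sample(0:(spec$class_count - 1L), n, replace = TRUE,
                prob = spec$label_balance)
    X <- matrix(stats::rnorm(n * m, sd = spec$noise_sd), n, m)
    if (k > 0L) {
      H <- class_shift_pattern(spec$class_count, k)
      shift <- spec$effect_size * spec$noise_sd
      X[, seq_len(k)] <- X[, seq_len(k), drop = FALSE] +
        H[y + 1L, , drop = FALSE] * shift
    }
    n_noise <- m - k
    n_ord <- floor(spec$ordinal_fraction * n_noise)
    if (n_ord > 0L) {
      ord_cols <- (m - n_ord + 1L):m
      X[, ord_cols] <- matrix(
        sample(0:3, n * n_ord, replace = TRUE), n, n_ord)
    }
    nm <- c(if (k > 0L) paste0("inf", seq_len(k)),
            if (n_noise > 0L) paste0("noise", seq_len(n_noise)))
    out <- tabular_dataset(X, y, nm, spec$class_count)
    attr(out, "informative") <- seq_len(k)
    out
  })
}

#' Generate an incremental task stream
#'
#' Class-incremental mode slices the label space into `n_tasks` disjoint
#' groups (task `t` introduces previously unseen labels over a shared feature
#' domain); domain-incremental mode keeps the label space fixed and shifts
#' every feature mean by `(t - 1) * shift * noise_sd` per task. The union of
#' the task label sets equals the full label set.
#'
#' @param base A [synthetic_spec()]; class-incremental mode requires
#'   `class_count >= n_tasks` so every task gets at least one class.
#' @param n_tasks Number of tasks.
#' @param mode `"class"` or `"domain"`.
#' @param shift Per-task mean drift in units of `noise_sd`
#'   (domain-incremental mode only; 0 gives i.i.d. replicate tasks).
#' @return A `task_stream`: list of [tabular_dataset()] tasks plus the mode.
#' @export
generate_task_stream <- function(base, n_tasks, mode = c("class", "domain"),
                                 shift = 0.5) {
  stopifnot(inherits(base, "synthetic_spec"))
  mode <- match.arg(mode)
  n_tasks <- as.integer(n_tasks)
  if (mode == "class") {
    if (base$class_count < n_tasks) {
      stop("class-incremental mode needs at least one class per task",
           call. = FALSE)
    }
    groups <- split(0:(base$class_count - 1L),
                    cut(seq_len(base$class_count), n_tasks, labels = FALSE))
    full <- generate_synthetic_tabular(base)
    tasks <- lapply(groups, function(g) {
      dataset_slice(full, which(full$labels %in% g))
    })
  } else {
    tasks <- lapply(seq_len(n_tasks), function(t) {
      sp <- base
      sp$seed <- base$seed + t - 1L
      d <- generate_synthetic_tabular(sp)
      d$features <- d$features + (t - 1L) * shift * base$noise_sd
      d
    })
  }
  structure(list(tasks = unname(tasks), mode = mode, n_tasks = n_tasks),
            class = "task_stream")
}

#' Partition a dataset across simulated federated clients
#'
#' @param data A [tabular_dataset()].
#' @param n_clients Number of clients.
#' @param scheme `"iid"` (shuffle and deal evenly), `"per_class_quota"` (each
#'   client receives `floor(quota * class size)` samples of every class; with
#'   the default `quota = 1/n_clients` and 10 clients this is the 10%-per-class
#'   non-IID split), or `"dirichlet"` (per-client class proportions drawn from
#'   a symmetric Dirichlet with concentration `alpha`, producing label skew).
#' @param alpha Dirichlet concentration (default 0.5).
#' @param quota Per-class fraction for the quota scheme; default `1/n_clients`.
#' @param seed Integer seed.
#' @return A `client_partition`: list of disjoint index vectors (one per
#'   client) plus the scheme tag.
#' @export
partition_clients <- function(data, n_clients,
                              scheme = c("iid", "per_class_quota", "dirichlet"),
                              alpha = 0.5, quota = NULL, seed = 1L) {
  stopifnot(inherits(data, "tabular_dataset"))
  scheme <- match.arg(scheme)
  n_clients <- as.integer(n_clients)
  if (n_clients < 1L) stop("need at least one client", call. = FALSE)
  n <- nrow(data$features)
  with_local_seed(seed, {
    idx <- switch(scheme,
      iid = {
        perm <- sample.int(n)
        split(perm, cut(seq_len(n), n_clients, labels = FALSE))
      },
      per_class_quota = {
        if (is.null(quota)) quota <- 1 / n_clients
        classes <- sort(unique(data$labels))
        per_client <- vector("list", n_clients)
        for (cl in classes) {
          pool <- sample(which(data$labels == cl))
          take <- floor(quota * length(pool))
          if (take * n_clients > length(pool)) {
            stop("quota infeasible for class ", cl, call. = FALSE)
          }
          for (k in seq_len(n_clients)) {
            got <- pool[seq_len(take) + (k - 1L) * take]
            per_client[[k]] <- c(per_client[[k]], got)
          }
        }
        per_client
      },
      dirichlet = {
        classes <- sort(unique(data$labels))
        per_client <- replicate(n_clients, integer(0), simplify = FALSE)
        for (cl in classes) {
          pool <- sample(which(data$labels == cl))
          # symmetric Dirichlet via normalized gammas
          g <- stats::rgamma(n_clients, shape = alpha)
          if (sum(g) == 0) g <- rep(1, n_clients)
          p <- g / sum(g)
          counts <- drop(stats::rmultinom(1L, length(pool), p))
          at <- 1L
          for (k in seq_len(n_clients)) {
            if (counts[k] > 0L) {
              per_client[[k]] <- c(per_client[[k]], pool[at:(at + counts[k] - 1L)])
              at <- at + counts[k]
            }
          }
        }
        per_client
      })
    idx <- lapply(unname(idx), function(v) sort(as.integer(v)))
    structure(list(indices = idx, scheme = scheme, n_clients = n_clients),
              class = "client_partition")
  })
}

#' Stratified train/test split
#'
#' Default 80/20 split, stratified by class so both splits keep the label
#' proportions.
#'
#' @param data A [tabular_dataset()].
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` datasets.
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(data, "tabular_dataset"))
  with_local_seed(seed, {
    test_idx <- integer(0)
    for (cl in sort(unique(data$labels))) {
      pool <- which(data$labels == cl)
      n_test <- round(test_fraction * length(pool))
      test_idx <- c(test_idx, sample(pool, n_test))
    }
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_len(nrow(data$features)), test_idx)
    list(train = dataset_slice(data, train_idx),
         test = dataset_slice(data, test_idx))
  })
}

#' Read a tabular dataset from CSV
#'
#' Expects a header row and one integer label column (named `target` by
#' default, matching common clinical exports). Rows with missing values are
#' rejected rather than imputed.
#'
#' @param path CSV file path.
#' @param target Name of the label column.
#' @return A [tabular_dataset()].
#' @export
read_tabular_csv <- function(path, target = "target") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!target %in% names(df)) {
    stop("target column '", target, "' not found", call. = FALSE)
  }
  if (anyNA(df)) stop("CSV contains missing values", call. = FALSE)
  y <- df[[target]]
  if (any(y != round(y))) stop("labels must be integers", call. = FALSE)
  X <- as.matrix(df[setdiff(names(df), target)])
  tabular_dataset(X, as.integer(y))
}

#' Write a tabular dataset to CSV
#'
#' @param data A [tabular_dataset()].
#' @param path Output path.
#' @param target Name for the label column.
#' @export
write_tabular_csv <- function(data, path, target = "target") {
  stopifnot(inherits(data, "tabular_dataset"))
  df <- as.data.frame(data$features)
  df[[target]] <- data$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
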