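#' Confusion counts
#'
#' One-vs-rest counts per class; for binary labels the positive class is
#' label 1 (e.g. disease present).
#'
#' @param truth,predicted Integer label vectors of equal length.
#' @param n_classes Number of classes; defaults to the labels observed.
#' @return A `confusion_counts` object: integer matrix with one row per
#'   class and columns TP, FP, FN, TN.
#' @export
confusion_counts <- function(truth, predicted, n_classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` lengths differ", call. = FALSE)
  }
  if (is.null(n_classes)) n_classes <- max(truth, predicted) + 1L
  M <- matrix(0L, n_classes, 4L,
              dimnames = list(paste0("class", 0:(n_classes - 1L)),
                              c("TP", "FP", "FN", "TN")))
  for (cl in 0:(n_classes - 1L)) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    M[cl + 1L, ] <- c(tp, fp, fn, length(truth) - tp - fp - fn)
  }
  structure(M, class = c("confusion_counts", class(M)))
}

#' Classification metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic-mean
#' F-measure `2PR/(P+R)`, and accuracy, all reported as percentages.
#' Binary problems use the class-1 (positive) row; multi-class metrics are
#' macro-averaged one-vs-rest. Zero denominators give 0 by convention.
#'
#' @param counts A [confusion_counts()] matrix.
#' @return Named list with `precision`, `recall`, `f_measure`, `accuracy`
#'   (percent) and `loss_percent` (= 100 - accuracy).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  per_class <- function(row) {
    tp <- row["TP"]; fp <- row["FP"]; fn <- row["FN"]
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }
  if (nrow(counts) == 2L) {
    prf <- per_class(counts["class1", ])
  } else {
    prf <- rowMeans(apply(counts, 1L, per_class))
  }
  n <- sum(counts[1L, ])
  acc <- sum(counts[, "TP"]) / n * 100
  list(precision = unname(prf[1L]) * 100, recall = unname(prf[2L]) * 100,
       f_measure = unname(prf[3L]) * 100, accuracy = acc,
       loss_percent = 100 - acc)
}

#' Average per-client loss
#'
#' Arithmetic mean of the clients' local loss values.
#'
#' @param losses Numeric vector, one loss per client.
#' @return The mean loss.
#' @export
average_client_loss <- function(losses) {
  if (length(losses) == 0L) stop("no client losses", call. = FALSE)
  mean(losses)
}

#' Simulated latency and throughput counters
#'
#' Logical bookkeeping only: latency is total simulated time divided by the
#' round count, throughput the transaction count divided by total time.
#' Both depend on the machine and simulation granularity and are reported
#' for completeness, never used in any acceptance check.
#'
#' @param total_time Total simulated time units.
#' @param n_rounds Number of rounds (>= 1).
#' @param n_transactions Number of ledger transactions.
#' @return List with `latency` and `throughput`.
#' @export
simulated_latency_throughput <- function(total_time, n_rounds,
                                         n_transactions) {
  if (n_rounds < 1L) stop("need at least one round", call. = FALSE)
  list(latency = total_time / n_rounds,
       throughput = if (total_time > 0) n_transactions / total_time else NA_real_)
}
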