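#' A client model update
#'
#' @param id Client identifier (character).
#' @param params Parameter vector (the locally trained model).
#' @param n_samples Local sample count (>= 1).
#' @param val_accuracy Local/server validation accuracy of the update
#'   (`NA` allowed).
#' @param attribution Optional per-feature importance vector used by the
#'   explanation-guided weighting.
#' @return A `client_update` list.
#' @export
client_update <- function(id, params, n_samples, val_accuracy = NA_real_,
                          attribution = NULL) {
  stopifnot(n_samples >= 1L)
  structure(list(id = as.character(id), params = as.numeric(params),
                 n_samples = as.integer(n_samples),
                 val_accuracy = val_accuracy, attribution = attribution),
            class = "client_update")
}

#' Local differential privacy configuration
#'
#' @param mechanism `"gaussian"` (noise on clipped continuous updates) or
#'   `"randomized_response"` (sign bits flipped, magnitudes bucketed).
#' @param level Discrete privacy level 1-5, mapped monotonically to the
#'   noise multipliers `c(0.25, 0.5, 1, 2, 4)`; overridden by `multiplier`.
#' @param multiplier Direct noise multiplier (0 = identity).
#' @param clip Clipping norm `C` applied before perturbation.
#' @return A `privacy_config` list.
#' @export
privacy_config <- function(mechanism = c("gaussian", "randomized_response"),
                           level = NULL, multiplier = NULL, clip = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(clip > 0)
  level_map <- c(0.25, 0.5, 1, 2, 4)
  if (is.null(multiplier)) {
    if (is.null(level)) level <- 3L
    if (!level %in% 1:5) stop("privacy level must be 1..5", call. = FALSE)
    multiplier <- level_map[level]
  }
  structure(list(mechanism = mechanism, multiplier = multiplier, clip = clip),
            class = "privacy_config")
}

#' Clip an update to a norm bound
#'
#' Rescales the parameter vector by `min(1, C / ||u||)`, preserving its
#' direction, so the privacy noise can be calibrated to a known sensitivity.
#'
#' @param update A [client_update()].
#' @param C Clipping norm (> 0).
#' @return The clipped update.
#' @export
clip_update <- function(update, C) {
  stopifnot(C > 0)
  nrm <- sqrt(sum(update$params^2))
  if (nrm > C) update$params <- update$params * (C / nrm)
  update
}

#' Perturb an update under local differential privacy
#'
#' Gaussian mode adds zero-mean noise with per-coordinate standard deviation
#' `multiplier * clip` (unbiased); randomized-response mode flips each
#' coordinate's sign with probability `multiplier / (2 (1 + multiplier))`
#' and quantizes magnitudes to 8 buckets of the clipping norm. A zero
#' multiplier is the identity.
#'
#' @param update A clipped [client_update()].
#' @param cfg A [privacy_config()].
#' @param seed Integer seed.
#' @return The perturbed update.
#' @export
ldp_perturb <- function(update, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "privacy_config"))
  if (cfg$multiplier == 0) return(update)
  with_local_seed(seed, {
    d <- length(update$params)
    if (cfg$mechanism == "gaussian") {
      update$params <- update$params +
        stats::rnorm(d, sd = cfg$multiplier * cfg$clip)
    } else {
      p_flip <- cfg$multiplier / (2 * (1 + cfg$multiplier))
      flip <- stats::runif(d) < p_flip
      s <- sign(update$params)
      s[flip] <- -s[flip]
      width <- cfg$clip / 8
      mag <- (floor(abs(update$params) / width) + 0.5) * width
      update$params <- s * mag
    }
    update
  })
}

#' Filter aberrant updates by median/MAD distance
#'
#' Computes each update's distance to the coordinate-wise median update and
#' excludes those whose distance deviates from the median distance by more
#' than `c` times the MAD of the distances (scaled by the usual 1.4826
#' Gaussian-consistency factor, i.e. a robust z-score test at `c` robust
#' standard deviations), with a relative dispersion floor: an update whose
#' distance deviates from the median distance by less than `rel_floor`
#' times the median distance is always kept. The floor caps the false
#' positive rate when the distances are tightly dispersed, where a pure
#' MAD test on a handful of values is oversensitive. Because one extreme
#' update inflates the MAD and can mask a second, smaller outlier, the
#' rule is re-applied to the kept set until it converges; at most strictly
#' less than half of the updates can ever be excluded (breakdown guard).
#' Identical updates are never excluded; with fewer than 3 updates all are
#' kept (with a warning flag), as no meaningful median exists.
#'
#' @param updates List of [client_update()]s.
#' @param c Exclusion multiplier (default 3).
#' @param rel_floor Relative exclusion floor (default 0.5): deviations
#'   below `rel_floor * median(distance)` are never excluded.
#' @param iterate Re-apply the rule to the kept set until no further
#'   exclusion (default TRUE); `FALSE` gives the single-pass rule.
#' @return List with `kept` and `excluded` update lists, the first-pass
#'   `distances`, and logical `degraded` (TRUE when too few updates to
#'   filter).
#' @export
robust_filter <- function(updates, c = 3, rel_floor = 0.5, iterate = TRUE) {
  if (length(updates) < 3L) {
    return(list(kept = updates, excluded = list(),
                distances = rep(0, length(updates)), degraded = TRUE))
  }
  one_pass <- function(ups) {
    P <- do.call(rbind, lapply(ups, `[[`, "params"))
    med <- apply(P, 2L, stats::median)
    d <- sqrt(rowSums(sweep(P, 2L, med, "-")^2))
    md <- stats::median(d)
    s <- stats::mad(d, center = md)
    cut <- if (s == 0) 1e-9 * max(1, md) else max(c * s, rel_floor * md)
    list(out = abs(d - md) > cut, d = d)
  }
  max_excl <- ceiling(length(updates) / 2) - 1L
  first <- one_pass(updates)
  kept <- updates[!first$out]
  excluded <- updates[first$out]
  if (iterate) {
    repeat {
      if (length(excluded) >= max_excl || length(kept) < 3L) break
      p <- one_pass(kept)
      if (!any(p$out)) break
      if (length(excluded) + sum(p$out) > max_excl) {
        # admit only the most aberrant up to the breakdown guard
        room <- max_excl - length(excluded)
        worst <- order(abs(p$d - stats::median(p$d)),
                       decreasing = TRUE)[seq_len(room)]
        sel <- logical(length(kept))
        sel[worst] <- TRUE
        p$out <- sel & p$out
        if (!any(p$out)) break
      }
      excluded <- c(excluded, kept[p$out])
      kept <- kept[!p$out]
    }
  }
  list(kept = kept, excluded = excluded, distances = first$d,
       degraded = FALSE)
}

# saliency attribution: mean |gradient x input| per feature of the local
# model on the client's own data
attribution_vector <- function(theta, X, y, n_classes) {
  Th <- param_matrix(theta, ncol(X), n_classes)
  W <- Th[seq_len(ncol(X)), , drop = FALSE]
  P <- linear_forward(theta, X, n_classes)
  R <- P - one_hot(y, n_classes)
  # d loss / d x_j for each sample = sum_c R_c W_jc
  G <- R %*% t(W)
  colMeans(abs(G * X))
}

#' Explanation-guided aggregation weights
#'
#' Each kept update is weighted by its validation accuracy times the
#' nonnegative cosine similarity between its feature-attribution vector and
#' the consensus (mean) attribution, normalized to sum 1. Missing
#' attributions count as fully aligned; if every weight vanishes the
#' weights fall back to sample counts (plain federated averaging).
#'
#' @param updates List of kept [client_update()]s.
#' @return Numeric weight vector summing to 1.
#' @export
xai_weights <- function(updates) {
  stopifnot(length(updates) >= 1L)
  acc <- vapply(updates, function(u) {
    if (is.na(u$val_accuracy)) 1 else u$val_accuracy
  }, 0)
  attrs <- lapply(updates, `[[`, "attribution")
  have <- !vapply(attrs, is.null, TRUE)
  sim <- rep(1, length(updates))
  if (any(have)) {
    consensus <- colMeans(do.call(rbind, attrs[have]))
    cn <- sqrt(sum(consensus^2))
    for (k in which(have)) {
      an <- sqrt(sum(attrs[[k]]^2))
      sim[k] <- if (cn == 0 || an == 0) 1 else {
        max(0, sum(attrs[[k]] * consensus) / (an * cn))
      }
    }
  }
  w <- acc * sim
  if (sum(w) <= 0) {
    w <- vapply(updates, `[[`, 0L, "n_samples")
  }
  w / sum(w)
}

#' Weighted federated aggregation
#'
#' `M <- sum_k W_k (M_k + delta_k) / sum_k W_k`; the explanation-based
#' correction terms `delta_k` default to zero vectors, in which case the
#' result is the convex combination of the kept updates.
#'
#' @param updates List of kept [client_update()]s.
#' @param weights Nonnegative weight vector (any positive scale).
#' @param deltas Optional list of correction vectors, one per update.
#' @return The aggregated parameter vector.
#' @export
aggregate_updates <- function(updates, weights, deltas = NULL) {
  if (length(updates) == 0L) stop("no updates to aggregate", call. = FALSE)
  stopifnot(length(weights) == length(updates), all(weights >= 0),
            sum(weights) > 0)
  d <- length(updates[[1L]]$params)
  acc <- numeric(d)
  for (k in seq_along(updates)) {
    u <- updates[[k]]$params
    if (!is.null(deltas)) u <- u + deltas[[k]]
    acc <- acc + weights[k] * u
  }
  acc / sum(weights)
}
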