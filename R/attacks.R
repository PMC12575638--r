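#' Configure a threat model
#'
#' Generators for the attacks the robustness layer is stress-tested
#' against. Label flipping corrupts attacker-held training labels before
#' local training; the remaining attacks corrupt submitted model updates.
#'
#' @param tag One of `"extra_noise"` (additive Gaussian noise on attacker
#'   updates), `"label_flip"` (a fraction of attacker labels permuted to
#'   other classes), `"stat_opt"` (attacker updates set against the mean
#'   honest direction with a fixed scale), `"dyn_opt"` (the scale is chosen
#'   per round as the largest grid value that still evades the robust
#'   filter), `"sybil"` (the attacker update is replicated under fabricated
#'   identities), or `"collusion"` (all attackers submit one shared crafted
#'   update).
#' @param fraction Fraction of clients that are attackers (attacker count
#'   must stay below the client count).
#' @param scale Attack strength: noise standard deviation for
#'   `extra_noise`, direction scale `gamma` for `stat_opt`/`collusion`,
#'   upper grid bound for `dyn_opt`.
#' @param flip_fraction Fraction of attacker-held labels flipped
#'   (`label_flip`; default 1).
#' @param n_sybils Fabricated identities per attacker (`sybil`; default 3).
#' @param seed Integer seed.
#' @return An `attack_config` list.
#' @export
attack_config <- function(tag = c("extra_noise", "label_flip", "stat_opt",
                                  "dyn_opt", "sybil", "collusion"),
                          fraction = 0.2, scale = 1, flip_fraction = 1,
                          n_sybils = 3L, seed = 1L) {
  tag <- match.arg(tag)
  if (fraction < 0 || fraction >= 1) {
    stop("attacker fraction must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(scale >= 0, flip_fraction >= 0, flip_fraction <= 1)
  structure(list(tag = tag, fraction = fraction, scale = scale,
                 flip_fraction = flip_fraction, n_sybils = as.integer(n_sybils),
                 seed = as.integer(seed)),
            class = "attack_config")
}

# ids of attacker-controlled clients: the first ceiling(fraction * K)
attacker_ids <- function(ids, fraction) {
  n_att <- min(length(ids) - 1L, ceiling(fraction * length(ids)))
  if (n_att <= 0L) character(0) else ids[seq_len(n_att)]
}

#' Flip a fraction of labels to other classes
#'
#' Each selected label is replaced by a uniformly drawn *different* class;
#' with binary labels and fraction 1 this is exact inversion.
#'
#' @param y Integer label vector in `0..n_classes-1`.
#' @param fraction Fraction of labels to flip.
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @return The corrupted label vector.
#' @export
flip_labels <- function(y, fraction, n_classes, seed = 1L) {
  n_flip <- round(fraction * length(y))
  if (n_flip == 0L) return(y)
  with_local_seed(seed, {
    idx <- sample(seq_along(y), n_flip)
    y[idx] <- vapply(y[idx], function(cl) {
      sample(setdiff(0:(n_classes - 1L), cl), 1L)
    }, 0L)
    y
  })
}

#' Corrupt submitted updates under a threat model
#'
#' Applies the configured model-level attack to the updates of
#' attacker-controlled clients (the first `ceiling(fraction * K)` ids).
#' `label_flip` is a data-level attack and passes updates through unchanged
#' (it is injected before local training by the experiment orchestrator).
#'
#' @param updates List of [client_update()]s.
#' @param cfg An [attack_config()].
#' @param filter_c Robust-filter multiplier the `dyn_opt` attacker adapts
#'   to.
#' @param seed Integer seed.
#' @return The corrupted update list (possibly longer under `sybil`).
#' @export
apply_attack <- function(updates, cfg, filter_c = 3, seed = cfg$seed) {
  stopifnot(inherits(cfg, "attack_config"))
  ids <- vapply(updates, `[[`, "", "id")
  att <- attacker_ids(ids, cfg$fraction)
  if (length(att) == 0L || cfg$tag == "label_flip") return(updates)
  is_att <- ids %in% att
  honest_mean <- colMeans(do.call(rbind,
    lapply(updates[!is_att], `[[`, "params")))
  with_local_seed(seed, {
    switch(cfg$tag,
      extra_noise = {
        for (k in which(is_att)) {
          updates[[k]]$params <- updates[[k]]$params +
            stats::rnorm(length(updates[[k]]$params), sd = cfg$scale)
        }
        updates
      },
      stat_opt = {
        crafted <- -cfg$scale * honest_mean
        for (k in which(is_att)) updates[[k]]$params <- crafted
        updates
      },
      dyn_opt = {
        # largest gamma on a descending grid whose crafted update survives
        # the robust filter alongside the honest updates; if every negative
        # scale is caught the attacker falls back to mimicking the honest
        # mean (a zero-damage but undetectable submission)
        grid <- cfg$scale * seq(1, 0.05, by = -0.05)
        chosen <- NA_real_
        for (g in grid) {
          trial <- updates
          for (k in which(is_att)) trial[[k]]$params <- -g * honest_mean
          part <- robust_filter(trial, filter_c)
          if (!any(att %in% vapply(part$excluded, `[[`, "", "id"))) {
            chosen <- g
            break
          }
        }
        crafted <- if (is.na(chosen)) {
          # nothing evades: mimic the honest update whose distance from the
          # honest median is the most typical (sitting at the median of the
          # distance distribution defeats the two-sided rule)
          H <- do.call(rbind, lapply(updates[!is_att], `[[`, "params"))
          medh <- apply(H, 2L, stats::median)
          dh <- sqrt(rowSums(sweep(H, 2L, medh, "-")^2))
          H[which.min(abs(dh - stats::median(dh))), ]
        } else {
          -chosen * honest_mean
        }
        for (k in which(is_att)) updates[[k]]$params <- crafted
        attr(updates, "dyn_opt_gamma") <- chosen
        updates
      },
      sybil = {
        for (k in which(is_att)) {
          base <- updates[[k]]
          for (s in seq_len(cfg$n_sybils)) {
            fake <- base
            fake$id <- paste0(base$id, "_sybil", s)
            updates[[length(updates) + 1L]] <- fake
          }
        }
        updates
      },
      collusion = {
        crafted <- -cfg$scale * honest_mean
        for (k in which(is_att)) updates[[k]]$params <- crafted
        updates
      })
  })
}
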