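# Hash-chained model ledger: an append-only list of blocks, each carrying a
# model digest plus round metadata, linked by SHA-256 over a canonical
# key-sorted JSON encoding so any retroactive edit invalidates the chain.

GENESIS_HASH <- strrep("0", 64L)

# canonical serialization: recursively key-sorted lists, numerics rounded to
# 12 significant digits for platform-stable hashes, compact UTF-8 JSON
canonical_json <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && any(nzchar(names(v)))) {
        v <- v[order(names(v), method = "radix")]
      }
      lapply(v, canon)
    } else if (is.double(v)) {
      signif(v, 12L)
    } else v
  }
  as.character(jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' SHA-256 digest of arbitrary content
#'
#' Hashes the UTF-8 bytes of a string, or the canonical JSON encoding of any
#' other object. Produces the 64-character lowercase hex digest.
#'
#' @param x A character scalar (hashed as raw bytes) or any serializable
#'   object.
#' @return 64-character hex string.
#' @export
sha256_hex <- function(x) {
  if (!(is.character(x) && length(x) == 1L)) x <- canonical_json(x)
  digest::digest(x, algo = "sha256", serialize = FALSE)
}

#' Hash a ledger block
#'
#' SHA-256 over the canonical key-sorted JSON of all block fields except the
#' hash itself (index, timestamp, payload, previous hash).
#'
#' @param index Block index (genesis = 0).
#' @param timestamp Logical round counter (kept non-wall-clock for
#'   reproducibility).
#' @param payload Named list of block content (model digest, metadata,
#'   contribution records).
#' @param previous_hash Hex digest of the predecessor block.
#' @return 64-character hex string.
#' @export
compute_block_hash <- function(index, timestamp, payload, previous_hash) {
  sha256_hex(canonical_json(list(index = as.integer(index),
                                 timestamp = as.integer(timestamp),
                                 payload = payload,
                                 previous_hash = previous_hash)))
}

#' Create a model ledger
#'
#' Initializes the chain with a genesis block recording the initial model
#' digest, mirroring model initialization on-chain before any training.
#'
#' @param genesis_payload Named list stored in the genesis block (e.g. the
#'   digest of the initial global model).
#' @param accuracy_tolerance Admission gate: a later block is admitted only
#'   if its validation accuracy is at least the last admitted accuracy minus
#'   this tolerance (default 0.01, i.e. accept non-regressions).
#' @return A `model_ledger` object.
#' @export
ledger_create <- function(genesis_payload = list(note = "genesis"),
                          accuracy_tolerance = 0.01) {
  blk <- list(index = 0L, timestamp = 0L, payload = genesis_payload,
              previous_hash = GENESIS_HASH)
  blk$hash <- compute_block_hash(blk$index, blk$timestamp, blk$payload,
                                 blk$previous_hash)
  structure(list(blocks = list(blk), accuracy_tolerance = accuracy_tolerance,
                 last_accuracy = -Inf, contributions = list()),
            class = "model_ledger")
}

#' @export
print.model_ledger <- function(x, ...) {
  cat(sprintf("<model_ledger> %d blocks, head %s...\n", length(x$blocks),
              substr(x$blocks[[length(x$blocks)]]$hash, 1L, 12L)))
  invisible(x)
}

#' Append a model block, gated on validation accuracy
#'
#' The block is admitted only when `validation_accuracy` meets the ledger's
#' gate (at least the last admitted accuracy minus the tolerance); a
#' rejected update leaves the chain untouched and is reported explicitly.
#'
#' @param ledger A `model_ledger`.
#' @param payload Named list of block content.
#' @param validation_accuracy Server-side validation accuracy of the model
#'   the block records.
#' @param timestamp Logical timestamp; defaults to the new block index.
#' @return List with the (possibly unchanged) `ledger` and logical
#'   `admitted`.
#' @export
append_block <- function(ledger, payload, validation_accuracy,
                         timestamp = NULL) {
  stopifnot(inherits(ledger, "model_ledger"))
  gate <- ledger$last_accuracy - ledger$accuracy_tolerance
  if (validation_accuracy < gate) {
    return(list(ledger = ledger, admitted = FALSE))
  }
  head_blk <- ledger$blocks[[length(ledger$blocks)]]
  idx <- head_blk$index + 1L
  if (is.null(timestamp)) timestamp <- idx
  blk <- list(index = idx, timestamp = as.integer(timestamp),
              payload = payload, previous_hash = head_blk$hash)
  blk$hash <- compute_block_hash(blk$index, blk$timestamp, blk$payload,
                                 blk$previous_hash)
  ledger$blocks[[length(ledger$blocks) + 1L]] <- blk
  ledger$last_accuracy <- validation_accuracy
  list(ledger = ledger, admitted = TRUE)
}

#' Validate the hash chain
#'
#' Recomputes every block's hash and checks each link to its predecessor;
#' any single-field alteration of any block is detected at the earliest
#' violating index.
#'
#' @param ledger A `model_ledger`.
#' @return List with logical `valid` and `first_bad_index` (`NA` when
#'   valid); indices follow the blocks' own 0-based numbering.
#' @export
validate_chain <- function(ledger) {
  stopifnot(inherits(ledger, "model_ledger"))
  prev_hash <- GENESIS_HASH
  for (b in ledger$blocks) {
    if (!identical(b$previous_hash, prev_hash) ||
        !identical(b$hash, compute_block_hash(b$index, b$timestamp,
                                              b$payload, b$previous_hash))) {
      return(list(valid = FALSE, first_bad_index = b$index))
    }
    prev_hash <- b$hash
  }
  list(valid = TRUE, first_bad_index = NA_integer_)
}

#' Proof-of-contribution score
#'
#' A client's contribution in a round is its leave-one-out marginal gain in
#' global validation accuracy, floored at zero so harmful updates earn
#' nothing.
#'
#' @param acc_with Validation accuracy of the global model aggregated with
#'   the client's update.
#' @param acc_without Accuracy aggregated without it.
#' @return Nonnegative score.
#' @export
poc_score <- function(acc_with, acc_without) {
  stopifnot(acc_with >= 0, acc_with <= 1, acc_without >= 0, acc_without <= 1)
  max(0, acc_with - acc_without)
}

#' Record a contribution on the ledger state
#'
#' @param ledger A `model_ledger`.
#' @param client_id Client identifier.
#' @param round Round index.
#' @param score Contribution score from [poc_score()].
#' @return The updated ledger.
#' @export
record_contribution <- function(ledger, client_id, round, score) {
  stopifnot(score >= 0)
  prev <- ledger$contributions[[client_id]]
  cum <- if (is.null(prev)) score else prev$cumulative + score
  ledger$contributions[[client_id]] <-
    list(client_id = client_id, round = round, score = score,
         cumulative = cum)
  ledger
}

#' Select the block proposer by cumulative contribution
#'
#' The client with the highest cumulative proof-of-contribution score
#' proposes; ties break toward the lexicographically smallest client id.
#'
#' @param ledger A `model_ledger` with recorded contributions.
#' @return The proposing client id.
#' @export
select_proposer <- function(ledger) {
  if (length(ledger$contributions) == 0L) {
    stop("no contribution records", call. = FALSE)
  }
  ids <- names(ledger$contributions)
  cum <- vapply(ledger$contributions, `[[`, 0, "cumulative")
  ord <- order(-cum, ids, method = "radix")
  ids[ord[1L]]
}

#' Export a ledger as JSON lines
#'
#' One canonical-JSON block per line; the round trip through
#' [ledger_read_jsonl()] is bit-exact.
#'
#' @param ledger A `model_ledger`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
ledger_write_jsonl <- function(ledger, path) {
  lines <- vapply(ledger$blocks, canonical_json, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Import a ledger from JSON lines
#'
#' @param path File written by [ledger_write_jsonl()].
#' @param accuracy_tolerance Admission tolerance for further appends.
#' @return A `model_ledger`.
#' @export
ledger_read_jsonl <- function(path, accuracy_tolerance = 0.01) {
  lines <- readLines(path)
  blocks <- lapply(lines, function(l) {
    b <- jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    b$index <- as.integer(b$index)
    b$timestamp <- as.integer(b$timestamp)
    b
  })
  structure(list(blocks = blocks, accuracy_tolerance = accuracy_tolerance,
                 last_accuracy = -Inf, contributions = list()),
            class = "model_ledger")
}
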