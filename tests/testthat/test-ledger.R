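test_that("SHA-256 matches the FIPS reference vector and is tamper-sensitive", {
  expect_identical(
    sha256_hex("abc"),
    "ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad")
  h1 <- compute_block_hash(1, 1, list(x = 1), strrep("0", 64))
  h2 <- compute_block_hash(1, 1, list(x = 1), strrep("0", 64))
  h3 <- compute_block_hash(1, 1, list(x = 2), strrep("0", 64))
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
  expect_match(h1, "^[0-9a-f]{64}$")
})

test_that("canonical serialization is key-order independent and byte-stable across processes", {
  a <- list(beta = 2, alpha = 1, nested = list(z = 1, a = c(1.5, 2.5)))
  b <- list(nested = list(a = c(1.5, 2.5), z = 1), alpha = 1, beta = 2)
  expect_identical(ppfil:::canonical_json(a), ppfil:::canonical_json(b))

  # a fresh R process must produce the identical digest
  blk <- list(index = 3L, timestamp = 3L,
              payload = list(model_digest = sha256_hex("m"), acc = 0.9125),
              previous_hash = strrep("a", 64))
  here <- compute_block_hash(blk$index, blk$timestamp, blk$payload,
                             blk$previous_hash)
  script <- sprintf(
    "cat(ppfil::compute_block_hash(3L, 3L, list(model_digest = ppfil::sha256_hex('m'), acc = 0.9125), strrep('a', 64)))")
  other <- system2(file.path(R.home("bin"), "Rscript"),
                   c("--vanilla", "-e", shQuote(script)), stdout = TRUE)
  expect_identical(tail(other, 1), here)
})

test_that("block admission is gated on validation accuracy and rejection leaves the head untouched", {
  led <- ledger_create(accuracy_tolerance = 0.01)
  r1 <- append_block(led, list(model_digest = "d1"), 0.80)
  expect_true(r1$admitted)
  expect_length(r1$ledger$blocks, 2L)
  head1 <- r1$ledger$blocks[[2]]$hash
  # a regression beyond the tolerance is rejected, chain unchanged
  r2 <- append_block(r1$ledger, list(model_digest = "d2"), 0.70)
  expect_false(r2$admitted)
  expect_length(r2$ledger$blocks, 2L)
  expect_identical(r2$ledger$blocks[[2]]$hash, head1)
  # a non-regression within tolerance is admitted and relinks the head
  r3 <- append_block(r1$ledger, list(model_digest = "d3"), 0.795)
  expect_true(r3$admitted)
  expect_identical(r3$ledger$blocks[[3]]$previous_hash, head1)
})

test_that("the genesis block links to the all-zero hash", {
  led <- ledger_create()
  expect_identical(led$blocks[[1]]$previous_hash, strrep("0", 64))
  expect_identical(led$blocks[[1]]$index, 0L)
  expect_true(validate_chain(led)$valid)
})

test_that("any single-field mutation of any block invalidates the chain at that index", {
  led <- make_chain(5)
  expect_true(validate_chain(led)$valid)
  fields <- list(
    payload = function(b) { b$payload$round <- 99L; b },
    timestamp = function(b) { b$timestamp <- b$timestamp + 1L; b },
    index = function(b) { b$index <- b$index + 1L; b },
    hash = function(b) { b$hash <- strrep("f", 64); b },
    previous_hash = function(b) { b$previous_hash <- strrep("e", 64); b })
  for (i in 2:5) {
    for (f in names(fields)) {
      bad <- led
      bad$blocks[[i + 1L]] <- fields[[f]](bad$blocks[[i + 1L]])
      v <- validate_chain(bad)
      expect_false(v$valid)
      # an index mutation is reported under the (mutated) stored index
      want <- if (f == "index") i + 1L else i
      expect_equal(v$first_bad_index, want,
                   label = sprintf("mutating %s of block %d", f, i))
    }
  }
  # mutating only the stored hash of block 3 trips at 3, before block 4's
  # dangling link could be reached
  bad <- led
  bad$blocks[[4]]$hash <- strrep("9", 64)
  expect_equal(validate_chain(bad)$first_bad_index, 3)
})

test_that("proof-of-contribution scores are floored marginal gains and pick the right proposer", {
  expect_equal(poc_score(0.9, 0.9), 0)
  expect_equal(poc_score(0.9, 0.85), 0.05)
  expect_equal(poc_score(0.8, 0.9), 0)  # harmful update earns nothing
  led <- ledger_create()
  led <- record_contribution(led, "A", 1, 0.02)
  led <- record_contribution(led, "B", 1, 0.05)
  led <- record_contribution(led, "A", 2, 0.01)
  expect_identical(select_proposer(led), "B")
  led <- record_contribution(led, "A", 3, 0.02)  # tie at 0.05
  expect_identical(select_proposer(led), "A")    # lowest id wins ties
  expect_error(select_proposer(ledger_create()), "no contribution")
})

test_that("JSON-lines export and import round-trip bit-exactly and revalidate", {
  led <- make_chain(4)
  path <- tempfile(fileext = ".jsonl")
  ledger_write_jsonl(led, path)
  back <- ledger_read_jsonl(path)
  expect_true(validate_chain(back)$valid)
  path2 <- tempfile(fileext = ".jsonl")
  ledger_write_jsonl(back, path2)
  expect_identical(readLines(path), readLines(path2))
  unlink(c(path, path2))
})
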