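# Shared fixture: one synthetic file plus its blocked form.
fix_recs <- generate_fastq(500, read_length = c(40L, 80L), seed = 17,
                           quality = "random")
fix_path <- write_tmp_fastq(fix_recs)
fix_B <- 4096L
fix_N <- max_reads_per_block(fix_recs, fix_B)
fix_spec <- block_spec(fix_B, fix_N)
fix_blocked <- tempfile(fileext = ".fastq")
pad_fastq(fix_recs, fix_spec, output = fix_blocked)
fix_blocks <- file.size(fix_blocked) / fix_B

consume_table <- function(res) {
  df <- res$records
  df[c("name", "sequence", "quality")]
}

test_that("critical-section entry counts obey the strategy laws", {
  for (n in c(96L, 500L)) {
    recs <- if (n == 500L) fix_recs else fix_recs[seq_len(n)]
    path <- if (n == 500L) fix_path else write_tmp_fastq(recs)
    o <- consume_fastq(path, "O", threads = 2)
    d <- consume_fastq(path, "D", threads = 2)
    b <- consume_fastq(path, "B", threads = 2, batch_size = 32)
    expect_identical(o$cs$entries, as.numeric(n))
    expect_identical(d$cs$entries, as.numeric(n))
    expect_identical(b$cs$entries, ceiling(n / 32))
  }
  # 3200 records at the default batch size: 100 entries
  big <- generate_fastq(3200, read_length = 30L, seed = 23)
  b32 <- consume_fastq(big, "B", threads = 4)
  expect_identical(b32$cs$entries, 100)

  l <- consume_fastq(fix_blocked, "L", threads = 2, block_spec = fix_spec)
  expect_identical(l$cs$entries, as.numeric(fix_blocks))
  expect_identical(l$blocks, as.integer(fix_blocks))
})

test_that("every strategy at 1, 2 and 8 threads consumes each record exactly once", {
  oracle <- oracle_read_fastq(fix_path)
  want <- sorted_triples(oracle)
  for (strategy in c("O", "D", "B", "L")) {
    for (threads in c(1L, 2L, 8L)) {
      res <- consume_fastq(
        if (strategy == "L") fix_blocked else fix_path, strategy,
        threads = threads,
        block_spec = if (strategy == "L") fix_spec)
      expect_identical(sorted_triples(consume_table(res)), want,
                       label = paste(strategy, threads))
    }
  }
})

test_that("strategies run under every lock discipline", {
  want <- sorted_triples(oracle_read_fastq(fix_path))
  for (lock in c("pessimistic", "spin", "queueing")) {
    res <- consume_fastq(fix_path, "B", threads = 4, lock = lock)
    expect_identical(sorted_triples(consume_table(res)), want,
                     label = lock)
    expect_gte(res$lock_stats$acquisitions, res$cs$entries)
  }
})

test_that("single-threaded consumption preserves input order", {
  res <- consume_fastq(fix_path, "D", threads = 1)
  expect_identical(res$records$name,
                   vapply(fix_recs, `[[`, "", "name"))
})

test_that("mean CS hold per record does not grow from O to D", {
  # smoke property with generous tolerance, not a benchmark: O parses in
  # the CS, D only boundary-scans there
  recs <- generate_fastq(5000, read_length = 100L, seed = 29)
  path <- write_tmp_fastq(recs)
  hold <- function(strategy) {
    r <- consume_fastq(path, strategy, threads = 1)
    r$cs$hold_us / 5000
  }
  o <- hold("O")
  d <- hold("D")
  expect_lt(d, o * 1.5 + 2)
})

test_that("paired reading pairs mates and enforces name agreement", {
  p <- generate_fastq(200, read_length = c(50L, 100L), seed = 37,
                      paired = TRUE)
  p1 <- write_tmp_fastq(p$end1)
  p2 <- write_tmp_fastq(p$end2)

  res <- consume_fastq(p1, "B", threads = 4, input2 = p2)
  df <- res$records
  expect_identical(nrow(df), 400L)
  m1 <- df[df$mate == 1L, ]
  m2 <- df[df$mate == 2L, ]
  expect_identical(sort(sub("/1$", "", m1$name)),
                   sort(sub("/2$", "", m2$name)))

  # equal single-record files -> one pair
  tiny <- consume_fastq(write_tmp_fastq(p$end1[1]), "O",
                        input2 = write_tmp_fastq(p$end2[1]))
  expect_identical(nrow(tiny$records), 2L)

  # shuffled end2 -> pairing error
  shuf <- p$end2[c(2:200, 1)]
  expect_error(
    consume_fastq(p1, "B", threads = 2,
                  input2 = write_tmp_fastq(shuf)),
    "pairing error")
})

test_that("paired L-parsing returns matching mates from matched blocks", {
  p <- generate_fastq(200, read_length = 100L, seed = 41, paired = TRUE)
  spec <- block_spec(12288, 44)
  b1 <- tempfile(); b2 <- tempfile()
  pad_fastq_paired(p$end1, p$end2, spec, out1 = b1, out2 = b2)
  res <- consume_fastq(b1, "L", threads = 4, block_spec = spec,
                       input2 = b2)
  df <- res$records
  expect_identical(nrow(df), 400L)
  # oracle: join on the stripped name, then compare sequences per mate
  key <- sub("/[12]$", "", df$name)
  for (mate in 1:2) {
    sub_df <- df[df$mate == mate, ]
    src <- if (mate == 1) p$end1 else p$end2
    oracle <- fastq_table(src)
    oracle$key <- sub("/[12]$", "", oracle$name)
    merged <- merge(data.frame(key = sub("/[12]$", "", sub_df$name),
                               sequence = sub_df$sequence), oracle,
                    by = "key")
    expect_identical(nrow(merged), 200L)
    expect_identical(merged$sequence.x, merged$sequence.y)
  }
})

test_that("misconfiguration and malformed input are reported", {
  expect_error(consume_fastq(fix_path, "L", threads = 1),
               "configuration error")
  # L over a nonconforming (unblocked) file
  expect_error(consume_fastq(fix_path, "L", threads = 2,
                             block_spec = fix_spec),
               "boundary violation|truncated record")
  bad <- "@r1\nACGT\n+\nIII\n"
  expect_error(consume_fastq(bad, "D", threads = 2), "length mismatch")
  expect_error(consume_fastq(bad, "O", threads = 1), "length mismatch")
})
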