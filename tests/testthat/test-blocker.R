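test_that("block_spec validates its arguments", {
  s <- block_spec(12288, 44)
  expect_identical(s$block_bytes, 12288L)
  expect_error(block_spec(17, 2), "infeasible")
  expect_error(block_spec(0, 1), "positive")
})

test_that("pad_fastq produces exact block arithmetic", {
  # two 28-byte reads, one 64-byte block with 8 pad spaces
  recs <- make_uniform_records(2L)
  spec <- block_spec(64, 2)
  b <- pad_fastq(recs, spec)
  expect_identical(length(b), 64L)
  expect_true(endsWith(rawToChar(b),
                       paste0("IIIIIIIIII", strrep(" ", 8), "\n")))
  expect_identical(sum(b == charToRaw(" ")), 8L)

  # one record, N = 1, B = record size: output identical to input
  one <- make_uniform_records(1L)
  expect_identical(pad_fastq(one, block_spec(28, 1)),
                   serialize_fastq_record(one[[1L]]))

  # 3 records of 28 bytes -> 2 blocks; final block 1 record + 36 pads
  three <- make_uniform_records(3L)
  b3 <- pad_fastq(three, spec)
  expect_identical(length(b3), 128L)
  last_block <- rawToChar(b3[65:128])
  expect_identical(sum(b3[65:128] == charToRaw(" ")), 36L)
  expect_true(endsWith(last_block, paste0(strrep(" ", 36), "\n")))

  # infeasible group names its block index
  expect_error(pad_fastq(make_uniform_records(4L, len = 40L),
                         block_spec(64, 2)),
               "infeasible spec: block 0")
})

test_that("size law and '@'-offset invariant hold on generated inputs", {
  for (cfg in list(list(n = 7L, B = 256L), list(n = 100L, B = 2048L),
                   list(n = 501L, B = 4096L))) {
    recs <- generate_fastq(cfg$n, read_length = c(20L, 60L),
                           seed = cfg$n, quality = "random")
    N <- max_reads_per_block(recs, cfg$B)
    spec <- block_spec(cfg$B, N)
    b <- pad_fastq(recs, spec)
    expect_identical(length(b), as.integer(ceiling(cfg$n / N) * cfg$B))
    starts <- seq(1L, length(b), by = cfg$B)
    expect_true(all(b[starts] == charToRaw("@")))
  }
})

test_that("pad/unpad round trip is byte-identical and conserves content", {
  recs <- generate_fastq(123, read_length = c(30L, 70L), seed = 8,
                         quality = "random")
  spec <- block_spec(4096, max_reads_per_block(recs, 4096))
  blocked <- pad_fastq(recs, spec)
  back <- unpad_fastq(blocked, spec)
  expect_identical(back, write_fastq(recs))

  # content conservation as multiset
  expect_identical(sorted_triples(fastq_table(read_fastq(back))),
                   sorted_triples(fastq_table(recs)))

  # empty file round trip
  expect_identical(unpad_fastq(pad_fastq(list(), spec), spec), raw(0))

  # record spanning a B boundary -> validation error
  plain <- write_fastq(recs)
  expect_error(unpad_fastq(plain, spec), "validation error")
})

test_that("validate_blocked enumerates violations without throwing", {
  recs <- generate_fastq(90, read_length = 40L, seed = 2)
  spec <- block_spec(1024, max_reads_per_block(recs, 1024))
  rep_ok <- validate_blocked(pad_fastq(recs, spec), spec)
  expect_true(rep_ok$conforming)
  expect_identical(rep_ok$records_found, 90L)
  expect_identical(nrow(rep_ok$violations), 0L)

  # standard (unpadded) FASTQ against a blocked spec
  rep_bad <- validate_blocked(write_fastq(recs), block_spec(12288, 44))
  expect_false(rep_bad$conforming)
  expect_gt(nrow(rep_bad$violations), 0L)

  # truncation mid-block -> size-divisibility violation
  b <- pad_fastq(recs, spec)
  rep_tr <- validate_blocked(b[1:(length(b) - 10L)], spec)
  expect_true(any(grepl("not a multiple", rep_tr$violations$description)))

  # padding smuggled onto a header line (block size is otherwise exact)
  hdr_pad <- "@r1  \nACGT\n+\nIIII\n"
  rep_pad <- validate_blocked(hdr_pad, block_spec(nchar(hdr_pad), 1))
  expect_false(rep_pad$conforming)
  expect_true(any(grepl("outside the quality line",
                        rep_pad$violations$description)))
})

test_that("max_reads_per_block matches the brute-force window oracle", {
  # uniform 28-byte records
  expect_identical(max_reads_per_block(make_uniform_records(10L), 64), 2L)
  expect_error(max_reads_per_block(make_uniform_records(3L), 27),
               "infeasible")

  # mixed sizes: brute force over all N and windows
  recs <- generate_fastq(40, read_length = c(5L, 50L), seed = 21)
  sizes <- vapply(recs, function(r) length(serialize_fastq_record(r)), 0L)
  brute <- function(B) {
    best <- 0L
    for (n in seq_along(sizes)) {
      ok <- TRUE
      for (i in seq_len(length(sizes) - n + 1L)) {
        if (sum(sizes[i:(i + n - 1L)]) > B) { ok <- FALSE; break }
      }
      if (ok) best <- n else break
    }
    best
  }
  for (B in c(100L, 300L, 1000L, 5000L)) {
    if (brute(B) == 0L) {
      expect_error(max_reads_per_block(recs, B), "infeasible")
    } else {
      expect_identical(max_reads_per_block(recs, B), brute(B))
    }
  }
})

test_that("paired padding preserves the corresponding-block guarantee", {
  # mirrored worked example: end-1 10 nt, end-2 9 nt, N = 2, B = 64
  e1 <- list(fastq_record("r1", "CTGACTGAAC", strrep("I", 10)),
             fastq_record("r2", "ATCGCCAGGA", strrep("I", 10)))
  e2 <- list(fastq_record("r1", "GTCAGGTCA", strrep("I", 9)),
             fastq_record("r2", "TTCGATCCG", strrep("I", 9)))
  b <- pad_fastq_paired(e1, e2, block_spec(64, 2))
  expect_identical(length(b$end1), 64L)
  expect_identical(length(b$end2), 64L)
  # differing amounts of padding in the two files
  expect_identical(sum(b$end1 == charToRaw(" ")), 8L)
  expect_identical(sum(b$end2 == charToRaw(" ")), 12L)

  # identical end files give identical outputs
  same <- pad_fastq_paired(e1, e1, block_spec(64, 2))
  expect_identical(same$end1, same$end2)

  # 100 synthetic pairs: per-block name lists equal (independent scan)
  p <- generate_fastq(100, read_length = 100L, seed = 31, paired = TRUE)
  spec <- block_spec(12288, 44)
  pb <- pad_fastq_paired(p$end1, p$end2, spec)
  n1 <- oracle_block_names(pb$end1, 12288L)
  n2 <- oracle_block_names(pb$end2, 12288L)
  expect_identical(lapply(n1, function(x) sub("/1$", "", x)),
                   lapply(n2, function(x) sub("/2$", "", x)))

  # unequal record counts
  expect_error(pad_fastq_paired(e1, e2[1L], block_spec(64, 2)),
               "pairing error")
})

test_that("padding inflation is reported, not asserted", {
  recs <- generate_fastq(200, read_length = 100L, seed = 5)
  spec <- block_spec(12288, max_reads_per_block(recs, 12288))
  inf <- padding_inflation(write_fastq(recs), pad_fastq(recs, spec))
  expect_gt(inf$raw_inflation_pct, 0)
  expect_lt(inf$gzip_inflation_pct, inf$raw_inflation_pct)
})
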