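test_that("boundary scanning cuts at the 4th newline and flags truncation", {
  s <- fastq_stream("@r\nAC\n+\n!!\n@s\nGG\n+\n!!\n")
  buf <- scan_record_boundary(s)
  expect_identical(rawToChar(buf), "@r\nAC\n+\n!!\n")
  buf2 <- scan_record_boundary(s)
  expect_identical(rawToChar(buf2), "@s\nGG\n+\n!!\n")
  expect_null(scan_record_boundary(s))

  expect_null(scan_record_boundary(fastq_stream(raw(0))))
  expect_error(scan_record_boundary(fastq_stream("@r\nAC\n+\n")),
               "truncated")
})

test_that("boundary scanning over k records returns k buffers covering the input", {
  for (n in c(1L, 5L, 37L)) {
    recs <- generate_fastq(n, read_length = c(5L, 30L), seed = n,
                           quality = "random")
    bytes <- write_fastq(recs)
    s <- fastq_stream(bytes)
    bufs <- list()
    repeat {
      b <- scan_record_boundary(s)
      if (is.null(b)) break
      bufs[[length(bufs) + 1L]] <- b
    }
    expect_length(bufs, n)
    expect_identical(do.call(c, bufs), bytes)
  }
})

test_that("parsing splits the header, strips pad spaces, validates", {
  r <- parse_fastq_record("@r1\nACGT\n+\nIIII\n")
  expect_s3_class(r, "fastq_record")
  expect_identical(r$name, "r1")
  expect_identical(nchar(r$sequence), 4L)

  # 8 pad spaces on the quality line are transparent
  padded <- parse_fastq_record("@r1\nACGT\n+\nIIII        \n")
  expect_identical(padded[c("name", "sequence", "quality")],
                   r[c("name", "sequence", "quality")])

  cmt <- parse_fastq_record("@r1 len=4 x\nACGT\n+r1\nIIII\n")
  expect_identical(cmt$comment, "len=4 x")
  expect_identical(cmt$plus_text, "r1")

  expect_error(parse_fastq_record("@r1\nACGT\n+\nIII\n"), "length mismatch")
  expect_error(parse_fastq_record("r1\nACGT\n+\nIIII\n"), "'@'")
  expect_error(parse_fastq_record("@r1\nACGT\n-\nIIII\n"), "'\\+'")
  expect_error(parse_fastq_record("@r1\r\nACGT\r\n+\r\nIIII\r\n"),
               "carriage return")
  expect_error(parse_fastq_record("@\nACGT\n+\nIIII\n"), "empty read name")
  expect_error(parse_fastq_record("@r1\nAC GT\n+\nII II\n"),
               "whitespace in sequence")
})

test_that("serialization matches byte-count oracle and honours pad_to", {
  r <- fastq_record("r1", "ACGTACGTAC", strrep("I", 10))
  # oracle: sum of line lengths 4 + 11 + 2 + 11
  expect_identical(length(serialize_fastq_record(r)), 28L)

  b <- serialize_fastq_record(r, pad_to = 36)
  expect_identical(length(b), 36L)
  expect_identical(rawToChar(b[28:36]), paste0(strrep(" ", 8), "\n"))

  expect_error(serialize_fastq_record(r, pad_to = 10),
               "infeasible padding")
})

test_that("parse/serialize round trip holds for any feasible pad_to", {
  recs <- generate_fastq(25, read_length = c(1L, 40L), seed = 11,
                         quality = "random")
  recs[[3L]]$comment <- "weird comment"
  recs[[4L]]$plus_text <- "plus tail"
  for (r in recs) {
    base <- length(serialize_fastq_record(r, keep_plus_text = TRUE))
    for (pad in c(base, base + 1L, base + 17L)) {
      again <- parse_fastq_record(
        serialize_fastq_record(r, pad_to = pad, keep_plus_text = TRUE))
      expect_identical(again, r)
    }
  }
})

test_that("read_fastq agrees with the line-based oracle", {
  recs <- generate_fastq(200, read_length = c(10L, 60L), seed = 4,
                         quality = "random")
  p <- write_tmp_fastq(recs)
  got <- fastq_table(read_fastq(p))
  want <- oracle_read_fastq(p)
  expect_identical(got[c("name", "sequence", "quality")], want)
})
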